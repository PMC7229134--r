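test_that("network validation checks every definition clause and reports violations as data", {
  net <- networkFixture("pendant-triangle")
  expect_s4_class(net, "PhyloNetwork")
  expect_length(leafLabels(net), 4L)

  ## middle vertex of a labeled path has degree 2
  bad <- validateNetwork(mg(c("a", "b"), c("b", "c")), c("1" = "a", "2" = "c"))
  expect_s3_class(bad, "data.frame")
  expect_true("degree-2-vertex" %in% bad$code)

  ## K2 with both vertices labeled is the valid single-edge network
  expect_s4_class(validateNetwork(mg(c("a", "b")), c("1" = "a", "2" = "b")),
                  "PhyloNetwork")

  ## one violation code per broken clause
  g <- mg(c("a", "b"), c("a", "b"), c("c", "c"), c("a", "c"), c("a", "d"), c("x", "y"))
  v <- validateNetwork(g, c("1" = "d", "2" = "d", "3" = "a", "4" = "zz"))
  for (code in c("not-connected", "parallel-edge", "loop", "duplicate-label",
                 "labeled-non-leaf", "unlabeled-leaf"))
    expect_true(code %in% v$code, label = code)
})

test_that("block and blob decomposition matches direct articulation/bridge analysis", {
  decB <- decomposeGraph(networkGraph(networkFixture("k4-leaves")))
  expect_length(decB@blocks, 3L)   # the K4 and the two leaf edges
  expect_equal(sum(!vapply(decB@blobs, `[[`, logical(1), "trivial")), 1L)
  expect_true(all(decB@cutEdges$trivial))

  ## in a tree every edge is its own block and all blobs are trivial
  tree <- networkFixture("double-star")
  decT <- decomposeGraph(networkGraph(tree))
  expect_length(decT@blocks, igraph::ecount(networkGraph(tree)))
  expect_true(all(vapply(decT@blobs, `[[`, logical(1), "trivial")))

  ## a triangle is one block, one blob, no cut vertices
  decTri <- decomposeGraph(triangleGraph())
  expect_length(decTri@blocks, 1L)
  expect_length(decTri@blobs, 1L)
  expect_length(decTri@cutVertices, 0L)

  expect_error(decomposeGraph(mg(c("a", "b"), c("c", "d"))), "not-connected")
})

test_that("properness detects leafless components behind cut elements", {
  expect_true(isProper(networkFixture("pendant-triangle")))
  expect_true(isProper(networkFixture("single-edge")))

  ## K4 with one leaf: removing the attachment vertex leaves a leafless triangle
  oneLeaf <- validateNetwork(mg(c("a", "b"), c("a", "c"), c("a", "d"), c("b", "c"),
                                c("b", "d"), c("c", "d"), c("a", "x")), c("1" = "x"))
  pr <- isProper(oneLeaf)
  expect_false(pr)
  expect_equal(attr(pr, "cutElement"), "a")
  expect_setequal(attr(pr, "component"), c("b", "c", "d"))

  ## the fast check used by the enumerator agrees on random networks
  set.seed(11)
  for (i in 1:25) {
    net <- genTreePlusEdges(nLeaves = sample(2:5, 1L), kExtra = sample(0:2, 1L), seed = i)$network
    em <- edgeMatrix(networkGraph(net))
    expect_identical(
      phynetclass:::properFast(em, networkLeaves(net), igraph::V(networkGraph(net))$name),
      isTRUE(isProper(net)))
  }
})

test_that("simple networks are exactly those whose cut edges are all trivial", {
  expect_true(isSimpleNetwork(networkFixture("k4-leaves")))
  expect_false(isSimpleNetwork(networkFixture("pendant-triangle")))
  expect_false(isSimpleNetwork(networkFixture("double-star")))  # inner tree edge
})

test_that("degree sums and block/blob structure hold on random multigraphs", {
  set.seed(5)
  for (i in 1:40) {
    g <- rConnectedMultigraph(sample(3:8, 1L), extras = sample(0:3, 1L),
                              parallels = sample(0:2, 1L), loops = sample(0:2, 1L))
    expect_equal(sum(igraph::degree(g, loops = TRUE)), 2L * igraph::ecount(g))
    dec <- decomposeGraph(g)
    ## every cut edge is itself a block
    ek <- paste(dec@cutEdges$u, dec@cutEdges$v)
    blockKeys <- vapply(dec@blocks, function(b) paste(sort(b), collapse = " "), character(1))
    for (e in ek) expect_true(e %in% blockKeys)
    ## every block with >= 3 vertices lies inside exactly one non-trivial blob
    for (b in dec@blocks) {
      if (length(b) < 3L) next
      inside <- vapply(nontrivialBlobs <- Filter(function(x) !x$trivial, dec@blobs),
                       function(bl) all(b %in% bl$vertices), logical(1))
      expect_equal(sum(inside), 1L)
    }
  }
})

test_that("binary networks have inner degree exactly three", {
  set.seed(7)
  for (i in 1:10) {
    net <- genBinaryChordal(nBlobs = sample(1:4, 1L), seed = i)
    expect_true(isBinaryNetwork(net))
    iv <- innerVertices(net)
    expect_true(all(igraph::degree(networkGraph(net), iv) == 3L))
  }
})
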