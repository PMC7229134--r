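test_that("leaf cutting removes labeled leaves only and keeps new low-degree vertices", {
  lcA <- lcut(networkFixture("pendant-triangle"))
  expect_equal(igraph::vcount(lcA), 4L)                 # triangle plus pendant
  expect_equal(sum(igraph::degree(lcA) == 1L), 1L)      # one new unlabeled leaf
  expect_true(phynetclass:::isSimpleGraph(lcA))

  expect_true(phynetclass:::isK2(lcut(networkFixture("double-star"))))

  expect_warning(e <- lcut(networkFixture("single-edge")), "empty")
  expect_equal(igraph::vcount(e), 0L)
  expect_true(attr(e, "empty"))
})

test_that("applicable operations honour definitions and the two-vertex guard", {
  expect_equal(nrow(applicableOps(k4graph())), 0L)

  tri <- applicableOps(triangleGraph())
  expect_equal(nrow(tri), 3L)
  expect_true(all(tri$kind == "suppress-degree2"))

  ## two vertices with a parallel pair: only copy deletion is offered
  par2 <- applicableOps(mg(c("a", "b"), c("a", "b")))
  expect_equal(par2$kind, "delete-parallel-copy")

  ## a loop at |V| = 2 may be deleted, the vertices may not be touched
  lp2 <- applicableOps(mg(c("a", "b"), c("b", "b")))
  expect_equal(lp2$kind, "delete-loop")
})

test_that("leaf shrinking reaches the known shrink graphs and replays bit-exactly", {
  trA <- leafShrink(networkFixture("pendant-triangle"))
  expect_true(phynetclass:::isK2(trA@final))
  expect_silent(replayTrace(trA))

  trB <- leafShrink(networkFixture("k4-leaves"))
  expect_true(isomorphicMultigraph(trB@final, k4graph()))

  ## any tree with >= 2 leaves shrinks to a single edge
  set.seed(3)
  for (i in 1:10) {
    tree <- genTreePlusEdges(nLeaves = sample(2:6, 1L), kExtra = 0L, seed = i)$network
    expect_true(phynetclass:::isK2(leafShrink(tree)@final))
  }

  expect_error(leafShrink(mg(c("a", "b"), c("b", "c"), c("c", "a"))), "degree-1")
})

test_that("the shrink graph is unique whatever the operation order (confluence)", {
  set.seed(17)
  for (i in 1:40) {
    g <- rConnectedMultigraph(sample(3:8, 1L), extras = sample(0:3, 1L),
                              parallels = sample(0:2, 1L), loops = sample(0:2, 1L))
    keys <- vapply(1:4, function(s)
      canonicalKey(leafShrink(g, policy = "random", seed = s)@final), character(1))
    keys <- c(keys, canonicalKey(leafShrink(g)@final))
    expect_length(unique(keys), 1L)
  }
})

test_that("growing or pruning decorations never changes the shrink graph", {
  set.seed(23)
  addLeaf <- function(g) { u <- sample(igraph::V(g)$name, 1L)
    igraph::add_edges(igraph::add_vertices(g, 1L, name = "zz"), c(u, "zz")) }
  subdivide <- function(g) {
    em <- edgeMatrix(g); e <- em[sample.int(nrow(em), 1L), ]
    g2 <- igraph::delete_edges(g, which(phynetclass:::edgeKeys(g) ==
                                          paste(min(e), max(e), sep = "|"))[1L])
    igraph::add_edges(igraph::add_vertices(g2, 1L, name = "zz"), c(e[1L], "zz", "zz", e[2L])) }
  addParallel <- function(g) { em <- edgeMatrix(g)
    e <- em[sample.int(nrow(em), 1L), ]; if (e[1L] == e[2L]) return(g)
    igraph::add_edges(g, e) }
  addLoop <- function(g) igraph::add_edges(g, rep(sample(igraph::V(g)$name, 1L), 2L))
  for (i in 1:25) {
    g <- rConnectedMultigraph(sample(3:7, 1L), extras = sample(0:2, 1L),
                              parallels = 1L, loops = 1L)
    base <- canonicalKey(phynetclass:::lsGraph(g)@final)
    for (grow in list(addLeaf, subdivide, addParallel, addLoop))
      expect_equal(canonicalKey(phynetclass:::lsGraph(grow(g))@final), base)
    ## deleting one loop or one parallel copy (when present) changes nothing
    av <- applicableOps(g, ops = c("delete-parallel-copy", "delete-loop"), guard = FALSE)
    for (j in seq_len(nrow(av))) {
      g2 <- phynetclass:::applyOp(g, av$kind[j], av$t1[j], av$t2[j])
      expect_equal(canonicalKey(phynetclass:::lsGraph(g2)@final), base)
    }
    ## and the underlying simple graph has the same shrink graph
    simple <- phynetclass:::underlyingSimple(g)
    expect_equal(canonicalKey(phynetclass:::lsGraph(simple)@final), base)
  }
})

test_that("restricted topological subgraph search is exact on small instances", {
  k2 <- mg(c("a", "b"))
  gA <- networkGraph(networkFixture("pendant-triangle"))
  expect_true(isRestrictedTopologicalSubgraph(gA, k2))
  expect_false(isRestrictedTopologicalSubgraph(k4graph(), k2))
  expect_true(isRestrictedTopologicalSubgraph(gA, gA))
  ## triangle is reachable from the pendant-triangle network graph
  expect_true(isRestrictedTopologicalSubgraph(gA, triangleGraph()))
  ## cap produces an explicit indeterminate, not a guess
  expect_true(is.na(isRestrictedTopologicalSubgraph(gA, k2, cap = 1L)))
})

test_that("traces serialize to JSON with ordered steps", {
  tr <- leafShrink(networkFixture("pendant-triangle"))
  j <- jsonlite::fromJSON(traceJSON(tr))
  expect_equal(nrow(j$steps), nrow(tr@steps))
  expect_equal(j$steps$kind[1L], "delete-leaf")
})
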