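test_that("fixtures have the documented shapes", {
  netA <- networkFixture("pendant-triangle")
  expect_equal(igraph::vcount(networkGraph(netA)), 8L)
  expect_equal(igraph::ecount(networkGraph(netA)), 8L)
  expect_true(isBinaryNetwork(netA))
  expect_true(isProper(netA))

  netB <- networkFixture("k4-leaves")
  expect_equal(igraph::vcount(networkGraph(netB)), 6L)
  expect_equal(igraph::ecount(networkGraph(netB)), 8L)

  pet <- networkFixture("petersen")
  expect_equal(igraph::vcount(pet), 10L)
  expect_equal(igraph::ecount(pet), 15L)
  expect_true(all(igraph::degree(pet) == 3L))

  expect_error(networkFixture("no-such"), "arg")
})

test_that("generators are deterministic in their seed and carry ground truth", {
  g1 <- genGspNetwork(nPieces = 5L, seed = 42L)
  g2 <- genGspNetwork(nPieces = 5L, seed = 42L)
  expect_true(phynetclass:::sameMultigraph(networkGraph(g1), networkGraph(g2)))
  expect_true(as.logical(isEdgeBased(g1)))
  expect_true(isProper(g1))

  r1 <- genTreePlusEdges(5L, 2L, seed = 8L)
  r2 <- genTreePlusEdges(5L, 2L, seed = 8L)
  expect_true(phynetclass:::sameMultigraph(networkGraph(r1$network), networkGraph(r2$network)))
  ## the returned support tree verifies verbatim against the network
  expect_silent(phynetclass:::verifySupportTree(r1$supportTree, r1$network))
  ## zero extra edges gives a tree
  expect_true(isTreeNetwork(genTreePlusEdges(4L, 0L, seed = 1L)$network))

  b0 <- genBinaryChordal(nBlobs = 0L, seed = 1L)
  expect_true(isTreeNetwork(b0))
  for (s in 1:8) {
    b <- genBinaryChordal(nBlobs = sample(1:4, 1L), seed = s)
    expect_true(isBinaryNetwork(b))
    expect_true(isChordalGraph(networkGraph(b)))
    expect_true(isProper(b))
    expect_true(as.logical(isEdgeBased(b)))
  }
})

test_that("the enumerator is complete and duplicate-free at tiny sizes", {
  ## no two yielded networks are isomorphic
  nets <- enumerateNetworks(3L, 4L)
  keys <- vapply(nets, phynetclass:::networkKey, character(1))
  expect_equal(anyDuplicated(keys), 0L)

  ## single inner vertex: star networks with 3..L leaves plus the single edge
  expect_length(enumerateNetworks(1L, 3L), 2L)
  expect_length(enumerateNetworks(1L, 4L), 3L)

  ## independent naive enumeration (generate all labeled graphs, filter,
  ## deduplicate by VF2) reproduces the counts for two inner vertices
  naiveCount <- function(maxInner, maxLeaves) {
    found <- list()
    total <- 0L
    for (ninner in 1:maxInner) for (nl in 1:maxLeaves) {
      n <- ninner + nl
      vs <- as.character(seq_len(n))
      inner <- vs[seq_len(ninner)]; lf <- vs[-seq_len(ninner)]
      prs <- utils::combn(vs, 2L)
      for (mask in seq_len(2^ncol(prs)) - 1L) {
        sel <- bitwAnd(mask, 2^(seq_len(ncol(prs)) - 1L)) > 0
        if (!any(sel)) next
        g <- multigraph(t(prs[, sel, drop = FALSE]), isolated = vs)
        deg <- igraph::degree(g)
        if (any(deg[lf] != 1L) || any(deg[inner] < 3L)) next
        if (!igraph::is_connected(g)) next
        net <- validateNetwork(g, stats::setNames(lf, paste0("L", seq_along(lf))))
        if (!methods::is(net, "PhyloNetwork")) next
        if (!isTRUE(isProper(net))) next
        col <- ifelse(igraph::V(g)$name %in% lf, 2L, 1L)
        dup <- FALSE
        for (h in found) {
          if (igraph::vcount(h$g) != igraph::vcount(g) ||
              igraph::ecount(h$g) != igraph::ecount(g)) next
          if (igraph::isomorphic(h$g, g, method = "vf2",
                                 vertex.color1 = h$col, vertex.color2 = col)) { dup <- TRUE; break }
        }
        if (!dup) { found[[length(found) + 1L]] <- list(g = g, col = col); total <- total + 1L }
      }
    }
    total + 1L  # plus the single-edge network (no inner vertices)
  }
  expect_equal(length(enumerateNetworks(2L, 4L)), naiveCount(2L, 4L))
  expect_equal(length(enumerateNetworks(3L, 3L)), naiveCount(3L, 3L))
})

test_that("connected graph classes match the known counts", {
  counts <- vapply(1:5, function(n) length(phynetclass:::connectedGraphClasses(n)), integer(1))
  expect_equal(counts, c(1L, 1L, 2L, 6L, 21L))
})
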