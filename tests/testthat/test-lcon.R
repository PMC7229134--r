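test_that("pre-processing leaves one leaf per attachment vertex and suppresses", {
  preA <- lconPreprocess(networkFixture("pendant-triangle"))
  expect_equal(attr(preA, "xr"), c("1", "3", "4"))
  expect_equal(igraph::vcount(networkGraph(preA)), 6L)  # triangle, one leaf each
  expect_true(isomorphicMultigraph(
    lcut(preA), triangleGraph()))

  preB <- lconPreprocess(networkFixture("k4-leaves"))
  expect_equal(length(leafLabels(preB)), 2L)
  expect_true(isomorphicMultigraph(networkGraph(preB),
                                   networkGraph(networkFixture("k4-leaves"))))

  ## a vertex with three leaves and one inner neighbour loses two leaves and
  ## is suppressed
  net <- validateNetwork(mg(c("v", "1"), c("v", "2"), c("v", "3"), c("v", "c"),
                            c("c", "d"), c("c", "e"), c("d", "e"), c("d", "4"), c("e", "5")),
                         c("1" = "1", "2" = "2", "3" = "3", "4" = "4", "5" = "5"))
  pre <- lconPreprocess(net)
  expect_false("v" %in% igraph::V(networkGraph(pre))$name)
  expect_equal(length(attr(pre, "xr")), 3L)

  expect_error(lconPreprocess(networkFixture("double-star")), "lcon-undefined-for-trees")
})

test_that("leaf connecting yields the known graphs with correct provenance", {
  ## pendant-triangle: a single class, the complete graph on 4 vertices
  LA <- lcon(networkFixture("pendant-triangle"))
  expect_length(LA, 1L)
  expect_true(isomorphicMultigraph(LA[[1L]]@graph, k4graph()))
  expect_true(LA[[1L]]@pairGadget)
  expect_equal(attr(LA, "xrSize"), 3L)

  ## k4-leaves: one class where the K4 edge {u,v} is replaced by two length-2
  ## paths through the gadget vertices plus the edge {a,b}
  LB <- lcon(networkFixture("k4-leaves"))
  expect_length(LB, 1L)
  g <- LB[[1L]]@graph
  expect_equal(igraph::vcount(g), 6L)
  expect_length(LB[[1L]]@newVertices, 2L)
  expect_equal(sum(igraph::E(g)$provenance == "gadget"), 5L)
  ## gadget vertices touch only gadget-tagged edges
  for (a in LB[[1L]]@newVertices) {
    eids <- igraph::incident(g, a)
    expect_true(all(igraph::edge_attr(g, "provenance", eids) == "gadget"))
  }

  ## a 4-taxon network whose pairings yield three distinct classes
  net45 <- validateNetwork(
    mg(c("1", "2"), c("1", "4"), c("1", "5"), c("2", "3"), c("2", "5"), c("3", "4"),
       c("2", "t1"), c("4", "t2"), c("5", "t3"), c("3", "t4")),
    c(a = "t1", b = "t2", c = "t3", d = "t4"))
  expect_length(lcon(net45), 3L)
})

test_that("leaf connect outputs satisfy the structural invariants", {
  set.seed(6)
  nets <- list(networkFixture("pendant-triangle"), networkFixture("k4-leaves"), squareNet())
  for (i in 1:15) nets[[length(nets) + 1L]] <-
    genGspNetwork(nPieces = sample(2:6, 1L), seed = i)
  for (net in nets) {
    if (isTreeNetwork(net)) next
    set <- lcon(net)
    expect_gt(length(set), 0L)
    for (ag in set) {
      g <- ag@graph
      expect_lte(igraph::vcount(g), igraph::vcount(networkGraph(net)))
      expect_true(phynetclass:::isSimpleGraph(g))
      expect_true(all(igraph::degree(g) >= 2L))
      expect_true(all(igraph::E(g)$provenance %in%
                        c("original", "pair-join", "gadget", "last-leaf")))
      ## original-tagged edges are edges of the input network
      em <- igraph::as_edgelist(g)
      orig <- igraph::E(g)$provenance == "original"
      netKeys <- phynetclass:::edgeKeys(networkGraph(net))
      for (j in which(orig))
        expect_true(paste(min(em[j, ]), max(em[j, ]), sep = "|") %in% netKeys)
      ## gadget vertices are incident to new edges only
      for (a in ag@newVertices)
        expect_true(all(igraph::edge_attr(g, "provenance", igraph::incident(g, a)) !=
                          "original"))
    }
  }
})

test_that("annotated graphs round-trip to GraphML with provenance", {
  ag <- lcon(networkFixture("k4-leaves"))[[1L]]
  f <- tempfile(fileext = ".graphml")
  writeAnnotatedGraph(ag, f)
  g <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::graph_attr(g, "xr_size"), 2)
  expect_setequal(unique(igraph::E(g)$provenance), unique(igraph::E(ag@graph)$provenance))
})
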