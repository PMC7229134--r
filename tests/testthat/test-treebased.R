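test_that("the exact oracle finds support trees where they exist", {
  tbA <- isTreeBased(networkFixture("pendant-triangle"))
  expect_true(as.logical(tbA))
  expect_s4_class(attr(tbA, "supportTree"), "SupportTree")

  expect_true(as.logical(isTreeBased(networkFixture("single-edge"))))
  expect_true(as.logical(isTreeBased(networkFixture("k4-leaves"))))

  ## a chordal proper network that is not tree-based (chordality alone is not
  ## sufficient in the non-binary case)
  expect_false(as.logical(isTreeBased(chordalNonTreeBasedNet())))
  expect_true(isChordalGraph(networkGraph(chordalNonTreeBasedNet())))
  expect_true(isProper(chordalNonTreeBasedNet()))
})

test_that("valid spanning trees of SP blocks have only block-degree-2 leaves", {
  vtTri <- validSpanningTree(triangleGraph())
  expect_equal(igraph::ecount(vtTri), 2L)

  dia <- mg(c("a", "b"), c("a", "c"), c("a", "d"), c("b", "c"), c("b", "d"))
  vt <- validSpanningTree(dia)
  expect_setequal(igraph::V(vt)$name[igraph::degree(vt) == 1L], c("c", "d"))

  k2 <- mg(c("a", "b"))
  expect_true(phynetclass:::isK2(validSpanningTree(k2)))

  expect_error(validSpanningTree(k4graph()), "not-sp")
})

test_that("the block construction yields a verified support tree for edge-based networks", {
  stA <- supportTreeEdgeBased(networkFixture("pendant-triangle"))
  expect_equal(igraph::ecount(stA@tree), 7L)
  expect_equal(igraph::vcount(stA@tree), 8L)
  expect_setequal(igraph::V(stA@tree)$name[igraph::degree(stA@tree) == 1L],
                  c("1", "2", "3", "4"))

  ## a tree network is its own support tree
  tree <- networkFixture("double-star")
  stT <- supportTreeEdgeBased(tree)
  expect_true(phynetclass:::sameMultigraph(stT@tree, networkGraph(tree)))

  ## a two-blob network: the base tree has exactly the taxa as leaves
  tb <- validateNetwork(mg(c("a", "b"), c("b", "c"), c("c", "a"),
                           c("d", "e"), c("e", "f"), c("f", "d"), c("a", "d"),
                           c("b", "1"), c("c", "2"), c("e", "3"), c("f", "4")),
                        c("1" = "1", "2" = "2", "3" = "3", "4" = "4"))
  st <- supportTreeEdgeBased(tb)
  bt <- baseTree(st)
  expect_setequal(igraph::V(bt)$name[igraph::degree(bt) == 1L], c("1", "2", "3", "4"))

  expect_error(supportTreeEdgeBased(networkFixture("k4-leaves")), "not edge-based")
})

test_that("edge-based networks are tree-based, with agreeing oracle (and not conversely)", {
  set.seed(19)
  for (i in 1:25) {
    net <- genGspNetwork(nPieces = sample(2:7, 1L), seed = i)
    st <- supportTreeEdgeBased(net)
    expect_silent(phynetclass:::verifySupportTree(st, net))
    expect_true(as.logical(isTreeBased(net)))
  }
  ## converse fails: tree-based but not edge-based
  netB <- networkFixture("k4-leaves")
  expect_true(as.logical(isTreeBased(netB)))
  expect_false(as.logical(isEdgeBased(netB)))
})

test_that("the four sufficient criteria behave as derived on the fixtures", {
  netA <- networkFixture("pendant-triangle")
  netB <- networkFixture("k4-leaves")
  expect_false(criterionPath(netA))
  expect_true(criterionPath(netB))
  expect_false(criterionPath(networkFixture("single-edge")))

  expect_false(criterionHConnected(netA))
  expect_true(criterionHConnected(netB))
  expect_true(criterionHConnected(networkFixture("double-star")))  # leaf cut = K2

  expect_true(criterionLconNewEdge(netA))
  expect_true(criterionLconNewEdge(netB))
  expect_false(criterionLconNewEdge(lconNewEdgeFalseNet()))
  expect_true(as.logical(isTreeBased(lconNewEdgeFalseNet())))  # sufficiency only

  expect_true(criterionLconGadget(netA))
  expect_true(criterionLconGadget(netB))
})

test_that("chordality and the binary chordal reduction certificate", {
  expect_true(isChordalGraph(triangleGraph()))
  expect_false(isChordalGraph(cycleGraph(4L)))
  expect_true(isChordalGraph(networkGraph(networkFixture("pendant-triangle"))))
  expect_error(isChordalGraph(mg(c("a", "b"), c("a", "b"))), "simple")

  trsA <- chordalBinaryReduction(networkFixture("pendant-triangle"))
  expect_length(trsA, 1L)
  expect_true(phynetclass:::isK2(trsA[[1L]]@final))
  expect_silent(replayTrace(trsA[[1L]]))

  set.seed(27)
  for (i in 1:10) {
    net <- genBinaryChordal(nBlobs = sample(1:4, 1L), seed = i)
    trs <- chordalBinaryReduction(net)
    for (tr in trs) {
      expect_true(phynetclass:::isK2(tr@final))
      expect_silent(replayTrace(tr))
    }
    expect_true(as.logical(isEdgeBased(net)))
  }

  ## binary non-chordal input is rejected up front
  sq <- squareNet()
  expect_true(isBinaryNetwork(sq))
  expect_error(chordalBinaryReduction(sq), "not-chordal")
})

test_that("toughness is the brute-force minimum over separating sets", {
  expect_equal(unclass(graphToughness(cycleGraph(4L)))[1L], 1)
  expect_equal(unclass(graphToughness(mg(c("a", "b"), c("b", "c"))))[1L], 0.5)
  expect_equal(unclass(graphToughness(k4graph()))[1L], Inf)
  t5 <- graphToughness(cycleGraph(5L))
  expect_equal(unclass(t5)[1L], 1)   # C5: remove 2 non-adjacent, 2 components
  expect_length(attr(graphToughness(cycleGraph(4L)), "set"), 2L)
})

test_that("the tough-chordal criterion needs a non-Hamiltonian leaf cut graph", {
  ## pendant-triangle: leaf cut graph not Hamiltonian, K4 in the leaf-connect
  ## set is chordal with infinite toughness
  expect_true(criterionToughChordal(networkFixture("pendant-triangle")))
  ## k4-leaves: leaf cut graph K4 is Hamiltonian, first clause fails
  expect_false(criterionToughChordal(networkFixture("k4-leaves")))
  ## square network: leaf cut graph C4 is Hamiltonian
  expect_false(criterionToughChordal(squareNet()))
})

test_that("classification reports are internally consistent on the fixtures", {
  repA <- classifyNetwork(networkFixture("pendant-triangle"))
  fA <- repA@flags
  expect_true(fA$proper); expect_true(fA$binary); expect_true(fA$chordal)
  expect_true(fA$edgeBased); expect_true(fA$treeBased)
  expect_false(fA$hConnected)
  expect_equal(repA@method, "edge-based")
  expect_s4_class(repA@witnesses$supportTree, "SupportTree")

  repB <- classifyNetwork(networkFixture("k4-leaves"))
  expect_false(repB@flags$edgeBased)
  expect_true(repB@flags$treeBased)
  expect_true(repB@flags$hConnected)

  repE <- classifyNetwork(networkFixture("single-edge"))
  expect_true(repE@flags$treeBased)

  j <- jsonlite::fromJSON(reportJSON(repA))
  expect_true(j$flags$edgeBased)
})
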