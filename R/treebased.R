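## Tree-basedness: exact spanning-tree oracle, the constructive support-tree
## builder for edge-based networks, the Hamiltonicity-based sufficient
## criteria, chordality, the chordal-binary reduction, toughness, and the
## combined classifier.

## ---- spanning-tree searches ------------------------------------------------

## Backtracking search for a spanning tree of `g` that (a) contains all edges
## in `forced` (indices into the edge list) and (b) in which every vertex of
## `needTwo` ends with tree degree >= 2.  Returns edge-index vector or NULL.
constrainedSpanningTree <- function(g, forced, needTwo, cap = 5e5) {
  n <- igraph::vcount(g)
  nm <- igraph::V(g)$name
  em <- igraph::as_edgelist(g, names = TRUE)
  m <- nrow(em)
  target <- n - 1L
  free <- setdiff(seq_len(m), forced)
  parent <- stats::setNames(seq_len(n), nm)
  findRoot <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  ## union-find over vertex indices
  idx <- stats::setNames(seq_len(n), nm)
  uf <- seq_len(n)
  root <- function(x) { while (uf[x] != x) x <- uf[x]; x }
  chosen <- logical(m)
  degTree <- stats::setNames(integer(n), nm)
  remDeg <- stats::setNames(integer(n), nm)   # undecided incident edges
  for (i in seq_len(m)) { remDeg[em[i, 1L]] <- remDeg[em[i, 1L]] + 1L
                          remDeg[em[i, 2L]] <- remDeg[em[i, 2L]] + 1L }
  addEdge <- function(i) {
    ru <- root(idx[[em[i, 1L]]]); rv <- root(idx[[em[i, 2L]]])
    if (ru == rv) return(FALSE)
    uf[ru] <<- rv
    chosen[i] <<- TRUE
    degTree[em[i, 1L]] <<- degTree[em[i, 1L]] + 1L
    degTree[em[i, 2L]] <<- degTree[em[i, 2L]] + 1L
    TRUE
  }
  for (i in forced) if (!addEdge(i)) return(NULL)
  for (i in forced) { remDeg[em[i, 1L]] <- remDeg[em[i, 1L]] - 1L
                      remDeg[em[i, 2L]] <- remDeg[em[i, 2L]] - 1L }
  nodes <- 0L
  capped <- FALSE
  rec <- function(pos, count, uf, degTree, remDeg) {
    nodes <<- nodes + 1L
    if (nodes > cap) { capped <<- TRUE; return(NULL) }
    if (count == target) {
      if (all(degTree[needTwo] >= 2L)) return(which(chosen))
      return(NULL)
    }
    if (pos > length(free)) return(NULL)
    ## prune: not enough undecided edges left to reach degree 2 everywhere
    if (any(degTree[needTwo] + remDeg[needTwo] < 2L)) return(NULL)
    if (count + (length(free) - pos + 1L) < target) return(NULL)
    i <- free[pos]
    u <- em[i, 1L]; v <- em[i, 2L]
    rootL <- function(x, uf) { while (uf[x] != x) x <- uf[x]; x }
    ru <- rootL(idx[[u]], uf); rv <- rootL(idx[[v]], uf)
    remDeg2 <- remDeg; remDeg2[u] <- remDeg2[u] - 1L; remDeg2[v] <- remDeg2[v] - 1L
    if (ru != rv) {   # try including
      uf2 <- uf; uf2[ru] <- rv
      deg2 <- degTree; deg2[u] <- deg2[u] + 1L; deg2[v] <- deg2[v] + 1L
      chosen[i] <<- TRUE
      res <- rec(pos + 1L, count + 1L, uf2, deg2, remDeg2)
      if (!is.null(res) || capped) return(res)
      chosen[i] <<- FALSE
    }
    rec(pos + 1L, count, uf, degTree, remDeg2)
  }
  res <- rec(1L, length(forced), uf, degTree, remDeg)
  if (is.null(res) && capped) return(NA)
  res
}

treeFromEdges <- function(g, eidx) {
  igraph::subgraph_from_edges(g, eidx, delete.vertices = FALSE)
}

#' Exact tree-basedness oracle
#'
#' Backtracking search for a spanning tree whose leaf set equals the taxon
#' set X (a support tree).  Every leaf edge is forced into the tree (any
#' support tree must contain them) and every inner vertex must end with tree
#' degree at least 2.
#'
#' @param net a [PhyloNetwork-class].
#' @param cap bound on search nodes; NA (indeterminate) when exceeded.
#' @return TRUE with attribute \code{supportTree} (a [SupportTree-class]),
#'   FALSE, or NA.
#' @export
isTreeBased <- function(net, cap = 5e5) {
  stopifnot(is(net, "PhyloNetwork"))
  g <- net@graph
  lv <- networkLeaves(net)
  if (igraph::vcount(g) == length(lv)) {
    ## single-edge network: the network is its own support tree
    st <- new("SupportTree", tree = g, labels = net@labels)
    return(structure(TRUE, supportTree = st))
  }
  em <- edgeMatrix(g)
  forced <- which(em[, 1L] %in% lv | em[, 2L] %in% lv)
  needTwo <- innerVertices(net)
  res <- constrainedSpanningTree(g, forced, needTwo, cap)
  if (length(res) == 1L && is.na(res[1L])) return(NA)
  if (is.null(res)) return(FALSE)
  st <- new("SupportTree", tree = treeFromEdges(g, res), labels = net@labels)
  verifySupportTree(st, net)
  structure(TRUE, supportTree = st)
}

verifySupportTree <- function(st, net) {
  tr <- st@tree
  g <- net@graph
  stopifnot(igraph::vcount(tr) == igraph::vcount(g),
            igraph::ecount(tr) == igraph::vcount(g) - 1L,
            igraph::is_connected(tr),
            all(edgeKeys(tr) %in% edgeKeys(g)))
  tleaves <- igraph::V(tr)$name[igraph::degree(tr) == 1L]
  stopifnot(setequal(tleaves, networkLeaves(net)))
  invisible(TRUE)
}

#' Valid spanning tree of an SP block
#'
#' For a simple biconnected series-parallel graph with at least three
#' vertices there is a spanning tree whose leaves are exactly vertices of
#' degree 2 in the block; K2 returns itself.  Found by backtracking with the
#' degree constraint; the postcondition is re-verified.
#'
#' @param block K2 or a simple biconnected SP graph (checked).
#' @return spanning tree as an \pkg{igraph} graph.
#' @export
validSpanningTree <- function(block) {
  if (igraph::vcount(block) == 2L && igraph::ecount(block) == 1L) return(block)
  stopifnot(isSimpleGraph(block), igraph::vcount(block) >= 3L)
  if (length(igraph::articulation_points(block)) > 0L) stop("block must be biconnected")
  if (!isSP(block)@verdict) stop("not-sp: valid spanning trees are guaranteed for SP blocks only")
  needTwo <- igraph::V(block)$name[igraph::degree(block) > 2L]
  res <- constrainedSpanningTree(block, integer(), needTwo)
  if (is.null(res) || (length(res) == 1L && is.na(res[1L])))
    stop("internal error: SP block without a valid spanning tree")
  tr <- treeFromEdges(block, res)
  tleaves <- igraph::V(tr)$name[igraph::degree(tr) == 1L]
  stopifnot(all(igraph::degree(block, tleaves) == 2L))
  tr
}

#' Constructive support tree for an edge-based network
#'
#' Decomposes the network into blocks: each cut-edge block contributes
#' itself, each SP block with three or more vertices contributes a valid
#' spanning tree; the union is a support tree, which is re-verified.
#'
#' @param net a proper edge-based [PhyloNetwork-class] with |X| >= 2.
#' @return a [SupportTree-class].
#' @export
supportTreeEdgeBased <- function(net) {
  stopifnot(is(net, "PhyloNetwork"))
  if (length(net@labels) < 2L) stop("requires |X| >= 2")
  if (!as.logical(isEdgeBased(net))) stop("network is not edge-based")
  g <- net@graph
  dec <- decomposeGraph(g)
  keys <- character()
  for (vs in dec@blocks) {
    sub <- igraph::induced_subgraph(g, vs)
    keys <- c(keys, edgeKeys(if (length(vs) == 2L) sub else validSpanningTree(sub)))
  }
  allKeys <- edgeKeys(g)
  eidx <- match(unique(keys), allKeys)
  st <- new("SupportTree", tree = treeFromEdges(g, eidx), labels = net@labels)
  verifySupportTree(st, net)
  st
}

#' @describeIn supportTreeEdgeBased the base tree: the support tree with its
#'   degree-2 vertices suppressed.
#' @param st a [SupportTree-class].
#' @export
baseTree <- function(st) {
  g <- st@tree
  if (igraph::ecount(g) != igraph::vcount(g) - 1L || !igraph::is_connected(g))
    stop("not a tree")
  repeat {
    d2 <- igraph::V(g)$name[igraph::degree(g) == 2L]
    if (length(d2) == 0L) break
    g <- applyOp(g, "suppress-degree2", d2[1L])
  }
  g
}

setMethod("show", "SupportTree", function(object) {
  cat(sprintf("SupportTree: %d vertices, leaves {%s}\n", igraph::vcount(object@tree),
              paste(sort(names(object@labels)), collapse = ",")))
})

## ---- sufficient criteria ---------------------------------------------------

#' Sufficient criteria for tree-basedness
#'
#' Four polynomially-motivated (though exponentially decided here) sufficient
#' conditions.  \code{criterionPath}: two leaves whose attachment points are
#' adjacent and joined by a path through all inner vertices.
#' \code{criterionHConnected}: the leaf cut graph is Hamilton connected.
#' \code{criterionLconNewEdge}: some leaf-connect graph has a Hamiltonian
#' cycle through an edge that is new (pair-join or gadget) and not created by
#' the last-leaf rule.  \code{criterionLconGadget}: some Hamiltonian
#' leaf-connect graph needed the two-vertex parallel-avoidance gadget.
#' Each TRUE verdict implies the network is tree-based.
#'
#' @param net a proper [PhyloNetwork-class] with |X| >= 2 (criteria 3-4 also
#'   require a non-tree).
#' @param cap brute-force bound, propagated to the searches.
#' @return logical (possibly NA when a cap was hit), with a witness attribute
#'   where applicable.
#' @export
criterionPath <- function(net, cap = 2e6) {
  stopifnot(is(net, "PhyloNetwork"), length(net@labels) >= 2L)
  lc <- suppressWarnings(lcut(net))
  if (igraph::vcount(lc) < 2L) return(FALSE)
  g <- net@graph
  att <- vapply(networkLeaves(net), function(x)
    igraph::V(g)$name[as.integer(igraph::neighbors(g, x))][1L], character(1))
  prs <- utils::combn(att, 2L, simplify = FALSE)
  anyCap <- FALSE
  for (p in prs) {
    if (p[1L] == p[2L] || !adjacent(g, p[1L], p[2L])) next
    res <- hamiltonianPath(lc, p[1L], p[2L], cap = cap)
    if (length(res) > 1L || (length(res) == 1L && !is.na(res[1L])))
      return(structure(TRUE, witness = res))
    if (length(res) == 1L && is.na(res[1L])) anyCap <- TRUE
  }
  if (anyCap) NA else FALSE
}

#' @rdname criterionPath
#' @export
criterionHConnected <- function(net, cap = 2e6) {
  stopifnot(is(net, "PhyloNetwork"), length(net@labels) >= 2L)
  if (!isTRUE(isProper(net))) stop("H-connected networks are defined for proper networks")
  isHamiltonConnected(suppressWarnings(lcut(net)), cap = cap)
}

#' @rdname criterionPath
#' @export
criterionLconNewEdge <- function(net, cap = 2e6) {
  stopifnot(is(net, "PhyloNetwork"), length(net@labels) >= 2L)
  if (isTreeNetwork(net)) stop("lcon-undefined-for-trees")
  set <- lcon(net)
  anyCap <- isTRUE(attr(set, "incomplete"))
  for (ag in set) {
    g <- ag@graph
    prov <- igraph::E(g)$provenance
    cand <- which(prov %in% c(PROV_PAIR, PROV_GADGET))
    em <- igraph::as_edgelist(g, names = TRUE)
    for (i in cand) {
      gm <- igraph::delete_edges(g, i)
      res <- hamiltonianPath(gm, em[i, 1L], em[i, 2L], cap = cap)
      if (length(res) > 1L) return(structure(TRUE, witness = list(graph = ag, cycle = res)))
      if (length(res) == 1L && is.na(res[1L])) anyCap <- TRUE
    }
  }
  if (anyCap) NA else FALSE
}

#' @rdname criterionPath
#' @export
criterionLconGadget <- function(net, cap = 2e6) {
  stopifnot(is(net, "PhyloNetwork"), length(net@labels) >= 2L)
  if (isTreeNetwork(net)) stop("lcon-undefined-for-trees")
  set <- lcon(net)
  anyCap <- isTRUE(attr(set, "incomplete"))
  for (ag in set) {
    if (!ag@pairGadget) next
    cyc <- hamiltonianCycle(ag@graph, cap = cap)
    if (length(cyc) > 1L) return(structure(TRUE, witness = list(graph = ag, cycle = cyc)))
    if (length(cyc) == 1L && is.na(cyc[1L])) anyCap <- TRUE
  }
  if (anyCap) NA else FALSE
}

## ---- chordality, toughness -------------------------------------------------

#' Chordality test
#'
#' TRUE when every cycle of length four or more has a chord (perfect
#' elimination ordering test).
#'
#' @param g simple graph (multigraph input errors).
#' @return logical.
#' @export
isChordalGraph <- function(g) {
  if (!isSimpleGraph(g)) stop("chordality is defined for simple graphs")
  igraph::is_chordal(g)$chordal
}

#' Reduction certificate for binary chordal networks
#'
#' Executes, per non-trivial blob, the constructive loop that certifies
#' edge-basedness of proper binary chordal networks: find a degree-2 vertex
#' lying in a triangle, suppress it, delete the resulting parallel edge,
#' repeat until a single edge remains.  The triangle membership is verified
#' at every iteration rather than assumed.
#'
#' @param net a proper binary chordal [PhyloNetwork-class] with |X| >= 2
#'   (checked; violations error).
#' @return list of [ReductionTrace-class], one per non-trivial blob, each
#'   ending in K2; an empty list when the network is a tree.
#' @export
chordalBinaryReduction <- function(net) {
  stopifnot(is(net, "PhyloNetwork"))
  if (length(net@labels) < 2L) stop("requires |X| >= 2")
  if (!isTRUE(isProper(net))) stop("not-proper")
  if (!isBinaryNetwork(net)) stop("not-binary")
  if (!isChordalGraph(net@graph)) stop("not-chordal")
  dec <- decomposeGraph(net@graph)
  lapply(nontrivialBlobs(dec), function(b) {
    g0 <- igraph::induced_subgraph(net@graph, b$vertices)
    g <- g0
    steps <- list()
    repeat {
      if (igraph::vcount(g) == 2L && igraph::ecount(g) == 1L) break
      deg <- igraph::degree(g, loops = TRUE)
      cand <- sort(igraph::V(g)$name[deg == 2L])
      picked <- NULL
      for (u in cand) {
        nb <- incidentEnds(g, u)
        if (nb[1L] != nb[2L] && adjacent(g, nb[1L], nb[2L])) { picked <- list(u = u, nb = nb); break }
      }
      if (is.null(picked))
        stop("internal error: no degree-2 vertex in a triangle; precondition violated")
      g <- applyOp(g, "suppress-degree2", picked$u)
      steps[[length(steps) + 1L]] <- data.frame(kind = "suppress-degree2", t1 = picked$u, t2 = NA_character_)
      v <- min(picked$nb); w <- max(picked$nb)
      g <- applyOp(g, "delete-parallel-copy", v, w)
      steps[[length(steps) + 1L]] <- data.frame(kind = "delete-parallel-copy", t1 = v, t2 = w)
    }
    newReductionTrace(g0, do.call(rbind, steps), g)
  })
}

#' Graph toughness
#'
#' Minimum over separating vertex sets C of |C| / c(G - C), by brute force
#' over all vertex subsets.  Complete graphs have no separating set and
#' return \code{Inf}.
#'
#' @param g simple connected graph.
#' @param cap maximum vertex count for the brute force (subset count grows as
#'   2^n); NA beyond it.
#' @return numeric (possibly Inf) with attribute \code{set} (an attaining
#'   separating set).
#' @export
graphToughness <- function(g, cap = 16L) {
  stopifnot(isSimpleGraph(g), igraph::is_connected(g))
  n <- igraph::vcount(g)
  if (n > cap) return(NA_real_)
  nm <- igraph::V(g)$name
  best <- Inf
  bestSet <- character()
  for (k in seq_len(max(n - 2L, 0L))) {
    if (k / 2 >= best) break   # even the best k-set cannot improve
    sets <- utils::combn(nm, k, simplify = FALSE)
    for (C in sets) {
      comp <- igraph::components(igraph::delete_vertices(g, C))
      if (comp$no >= 2L) {
        val <- k / comp$no
        if (val < best) { best <- val; bestSet <- C }
      }
    }
  }
  structure(best, set = bestSet)
}

#' @rdname criterionPath
#' @details \code{criterionToughChordal}: the leaf cut graph is not
#'   Hamiltonian and some leaf-connect graph is chordal with toughness at
#'   least 10 (every 10-tough chordal graph is Hamiltonian, and the cycle
#'   must then use a new edge).  FALSE for trees (no leaf-connect set).
#' @export
criterionToughChordal <- function(net, cap = 2e6) {
  stopifnot(is(net, "PhyloNetwork"), length(net@labels) >= 2L)
  if (isTreeNetwork(net)) return(FALSE)
  lc <- suppressWarnings(lcut(net))
  cyc <- hamiltonianCycle(lc, cap = cap)
  if (length(cyc) == 1L && is.na(cyc[1L])) return(NA)
  if (!is.null(cyc)) return(FALSE)
  set <- lcon(net)
  anyCap <- isTRUE(attr(set, "incomplete"))
  for (ag in set) {
    if (!isChordalGraph(ag@graph)) next
    t <- graphToughness(ag@graph)
    if (is.na(t)) { anyCap <- TRUE; next }
    if (t >= 10) return(structure(TRUE, witness = ag))
  }
  if (anyCap) NA else FALSE
}

## ---- combined classifier ---------------------------------------------------

#' Classify a phylogenetic network
#'
#' Runs every membership test in the package and assembles a
#' [ClassificationReport-class]: properness, binarity, chordality, simple
#' network, edge-basedness (= GSP of the underlying graph), Hamilton
#' connectedness of the leaf cut graph, the four sufficient criteria, and
#' tree-basedness (by the cheapest decisive route, falling back to the exact
#' oracle).  Internal consistency is asserted: edge-based implies tree-based,
#' and proper + binary + chordal implies edge-based.
#'
#' @param net a [PhyloNetwork-class].
#' @param cap brute-force bound passed to the searches.
#' @return a [ClassificationReport-class].
#' @export
classifyNetwork <- function(net, cap = 2e6) {
  stopifnot(is(net, "PhyloNetwork"))
  flags <- list()
  witnesses <- list()
  capsHit <- character()
  method <- NA_character_
  flags$proper <- isTRUE(isProper(net))
  flags$binary <- isBinaryNetwork(net)
  flags$chordal <- isChordalGraph(net@graph)
  flags$simpleNetwork <- isSimpleNetwork(net)
  eb <- isEdgeBased(net)
  flags$edgeBased <- as.logical(eb)
  flags$gsp <- flags$edgeBased   # network graphs are loopless
  witnesses$leafShrink <- attr(eb, "trace")
  manyTaxa <- length(net@labels) >= 2L
  tree <- isTreeNetwork(net)
  if (flags$proper && manyTaxa) {
    flags$hConnected <- criterionHConnected(net, cap = cap)
    if (is.na(flags$hConnected)) capsHit <- c(capsHit, "hConnected")
    flags$criterionPath <- criterionPath(net, cap = cap)
    if (is.na(flags$criterionPath)) capsHit <- c(capsHit, "criterionPath")
    if (!tree) {
      flags$criterionLconNewEdge <- criterionLconNewEdge(net, cap = cap)
      flags$criterionLconGadget <- criterionLconGadget(net, cap = cap)
      flags$criterionToughChordal <- criterionToughChordal(net, cap = cap)
      for (nmx in c("criterionLconNewEdge", "criterionLconGadget", "criterionToughChordal"))
        if (is.na(flags[[nmx]])) capsHit <- c(capsHit, nmx)
    } else {
      flags$criterionLconNewEdge <- NA
      flags$criterionLconGadget <- NA
      flags$criterionToughChordal <- FALSE
    }
  } else {
    flags[c("hConnected", "criterionPath", "criterionLconNewEdge",
            "criterionLconGadget", "criterionToughChordal")] <- NA
  }
  ## tree-basedness: constructive route when edge-based and proper, criteria
  ## next, exact oracle last
  if (flags$edgeBased && flags$proper && manyTaxa) {
    witnesses$supportTree <- supportTreeEdgeBased(net)
    flags$treeBased <- TRUE
    method <- "edge-based"
  } else {
    crit <- c(path = isTRUE(flags$criterionPath),
              hConnected = isTRUE(flags$hConnected),
              lconNewEdge = isTRUE(flags$criterionLconNewEdge),
              lconGadget = isTRUE(flags$criterionLconGadget))
    if (any(crit)) {
      flags$treeBased <- TRUE
      method <- paste0("criterion-", names(crit)[which(crit)[1L]])
    } else {
      tb <- isTreeBased(net, cap = cap)
      flags$treeBased <- if (is.na(tb)) NA else as.logical(tb)
      if (is.na(tb)) capsHit <- c(capsHit, "treeBasedOracle")
      if (isTRUE(tb)) witnesses$supportTree <- attr(tb, "supportTree")
      method <- "oracle"
    }
  }
  if (isTRUE(flags$edgeBased) && flags$proper && manyTaxa) stopifnot(isTRUE(flags$treeBased))
  if (flags$proper && manyTaxa && flags$binary && flags$chordal) stopifnot(isTRUE(flags$edgeBased))
  new("ClassificationReport", flags = flags, method = method,
      witnesses = witnesses, capsHit = unique(capsHit))
}

setMethod("show", "ClassificationReport", function(object) {
  fmt <- function(x) if (is.na(x)) "?" else if (isTRUE(x)) "yes" else "no"
  cat("ClassificationReport\n")
  for (nm in names(object@flags))
    cat(sprintf("  %-24s %s\n", nm, fmt(object@flags[[nm]])))
  cat(sprintf("  tree-based method: %s\n", object@method))
  if (length(object@capsHit)) cat("  caps hit:", paste(object@capsHit, collapse = ", "), "\n")
})

#' @describeIn classifyNetwork serialize a report to JSON.
#' @param report a [ClassificationReport-class].
#' @export
reportJSON <- function(report) {
  jsonlite::toJSON(list(schema = 1L, flags = report@flags, method = report@method,
                        caps_hit = report@capsHit), auto_unbox = TRUE, na = "null")
}
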