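## Fixtures, random generators with ground-truth labels, and the exhaustive
## isomorphism-free enumerator of small proper phylogenetic networks.

#' Built-in network and graph fixtures
#'
#' \describe{
#'   \item{pendant-triangle}{binary proper network: triangle w,p,q with a
#'     pendant inner vertex s on w; leaves 1,2 on s, 3 on p, 4 on q.  Its
#'     leaf cut graph has one unlabeled leaf; its leaf shrink graph is a
#'     single edge (edge-based).}
#'   \item{k4-leaves}{K4 with leaves 1 and 2 on two of its vertices:
#'     tree-based (Hamilton-connected leaf cut graph) but not edge-based.}
#'   \item{double-star}{two adjacent inner vertices with two leaves each.}
#'   \item{single-edge}{the two-taxon single-edge network.}
#'   \item{petersen}{the Petersen graph (a plain graph, not a network):
#'     3-regular, non-Hamiltonian, but traceable.}
#' }
#'
#' @param name fixture name.
#' @return a [PhyloNetwork-class], or an \pkg{igraph} graph for
#'   \code{petersen}.
#' @export
networkFixture <- function(name = c("pendant-triangle", "k4-leaves", "double-star",
                                    "single-edge", "petersen")) {
  name <- match.arg(name)
  switch(name,
    "pendant-triangle" = newNetwork(
      multigraph(rbind(c("w", "p"), c("w", "q"), c("p", "q"), c("w", "s"),
                       c("s", "1"), c("s", "2"), c("p", "3"), c("q", "4"))),
      c("1" = "1", "2" = "2", "3" = "3", "4" = "4")),
    "k4-leaves" = newNetwork(
      multigraph(rbind(t(utils::combn(c("u", "v", "x", "y"), 2L)),
                       c("u", "1"), c("v", "2"))),
      c("1" = "1", "2" = "2")),
    "double-star" = newNetwork(
      multigraph(rbind(c("a", "b"), c("a", "1"), c("a", "2"), c("b", "3"), c("b", "4"))),
      c("1" = "1", "2" = "2", "3" = "3", "4" = "4")),
    "single-edge" = newNetwork(multigraph(rbind(c("x", "y"))), c("1" = "x", "2" = "y")),
    "petersen" = {
      outer <- paste0("o", 1:5); inner <- paste0("i", 1:5)
      em <- rbind(cbind(outer, outer[c(2:5, 1L)]),
                  cbind(outer, inner),
                  cbind(inner, inner[c(3L, 4L, 5L, 1L, 2L)]))
      multigraph(em)
    })
}

freshLabel <- function(labels) {
  i <- 1L
  while (as.character(i) %in% names(labels)) i <- i + 1L
  as.character(i)
}

## attach a new labeled leaf to vertex v; returns list(graph, labels)
attachLeaf <- function(g, labels, v) {
  lf <- paste0("t", length(igraph::V(g)) + 1L)
  while (lf %in% igraph::V(g)$name) lf <- paste0(lf, "x")
  g <- igraph::add_vertices(g, 1L, name = lf)
  g <- igraph::add_edges(g, c(v, lf))
  labels[freshLabel(labels)] <- lf
  list(graph = g, labels = labels)
}

## make a graph with degree>=1 vertices into a proper phylogenetic network by
## labeling degree-1 vertices, attaching leaves to degree-2 vertices, and
## repairing properness by extra leaves; leaf additions never change the leaf
## shrink graph, so edge-basedness of the core is preserved
leafCompletion <- function(g) {
  labels <- stats::setNames(character(0), character(0))
  for (v in igraph::V(g)$name[igraph::degree(g) == 1L]) labels[freshLabel(labels)] <- v
  for (v in igraph::V(g)$name[igraph::degree(g) == 2L]) {
    res <- attachLeaf(g, labels, v); g <- res$graph; labels <- res$labels
  }
  if (length(labels) < 2L) {
    cand <- setdiff(igraph::V(g)$name, unname(labels))
    res <- attachLeaf(g, labels, cand[1L]); g <- res$graph; labels <- res$labels
  }
  repeat {
    net <- newNetwork(g, labels)
    pr <- isProper(net)
    if (isTRUE(pr)) return(net)
    comp <- attr(pr, "component")
    res <- attachLeaf(g, labels, comp[1L])
    g <- res$graph; labels <- res$labels
  }
}

#' Random edge-based network via GSP compositions
#'
#' Builds a generalized series-parallel core by random series, parallel and
#' generalized-series compositions of single edges, takes its underlying
#' simple graph (which has the same leaf shrink graph), and completes it into
#' a proper phylogenetic network by labeling and leaf attachment.  The output
#' is edge-based by construction.
#'
#' @param nPieces number of primitive single-edge pieces composed (>= 1).
#' @param seed integer seed; identical spec + seed gives an identical
#'   network.
#' @param spOnly use only series and parallel compositions (the core is then
#'   SP whenever biconnected).
#' @return a [PhyloNetwork-class].
#' @export
genGspNetwork <- function(nPieces = 6L, seed = 1L, spOnly = FALSE) {
  set.seed(seed)
  counter <- 0L
  mkK2 <- function() {
    counter <<- counter + 1L
    u <- paste0("v", counter, "a"); v <- paste0("v", counter, "b")
    list(graph = multigraph(rbind(c(u, v))), u = u, v = v)
  }
  pool <- replicate(max(1L, nPieces), mkK2(), simplify = FALSE)
  while (length(pool) > 1L) {
    ij <- sample.int(length(pool), 2L)
    g1 <- pool[[ij[1L]]]; g2 <- pool[[ij[2L]]]
    op <- if (spOnly) sample(c("series", "parallel"), 1L) else
      sample(c("series", "parallel", "genseries"), 1L)
    merged <- multigraph(rbind(edgeMatrix(g1$graph), edgeMatrix(g2$graph)))
    comb <- switch(op,
      series = {   # identify v1 with u2; terminals u1, v2
        g <- mergeVertices(merged, g1$v, g2$u)
        list(graph = g, u = g1$u, v = g2$v)
      },
      parallel = { # identify u1=u2 and v1=v2; terminals u1, v1
        g <- mergeVertices(merged, g1$u, g2$u)
        g <- mergeVertices(g, g1$v, g2$v)
        list(graph = g, u = g1$u, v = g1$v)
      },
      genseries = { # identify v1 with u2; terminals u2(=v1), v2
        g <- mergeVertices(merged, g1$v, g2$u)
        list(graph = g, u = g1$v, v = g2$v)
      })
    pool[[ij[1L]]] <- comb
    pool <- pool[-ij[2L]]
  }
  core <- underlyingSimple(pool[[1L]]$graph)
  if (igraph::vcount(core) < 2L) core <- multigraph(rbind(c("v1a", "v1b")))
  net <- leafCompletion(core)
  stopifnot(as.logical(isEdgeBased(net)))
  net
}

## identify vertex b into a (keeping a's name); multi-edges preserved
mergeVertices <- function(g, a, b) {
  em <- edgeMatrix(g)
  em[em == b] <- a
  multigraph(em, isolated = setdiff(igraph::V(g)$name, c(b, as.vector(em))))
}

#' Random tree-based network from a tree plus chords
#'
#' Grows a random binary phylogenetic tree on \code{nLeaves} taxa, then adds
#' \code{kExtra} chords between fresh subdivision points of distinct tree
#' edges.  The construction tree (with its subdivision points) is a support
#' tree, returned alongside; any vertex still of degree 2 at the end receives
#' an extra labeled leaf.
#'
#' @param nLeaves taxa in the initial tree (>= 2).
#' @param kExtra number of added chords (>= 0).
#' @param seed integer seed.
#' @return list(network = [PhyloNetwork-class], supportTree =
#'   [SupportTree-class]).
#' @export
genTreePlusEdges <- function(nLeaves = 4L, kExtra = 1L, seed = 1L) {
  stopifnot(nLeaves >= 2L)
  set.seed(seed)
  g <- multigraph(rbind(c("x1", "x2")))
  labels <- c("1" = "x1", "2" = "x2")
  inner <- 0L
  for (i in seq_len(max(0L, nLeaves - 2L))) {
    em <- edgeMatrix(g)
    e <- em[sample.int(nrow(em), 1L), ]
    inner <- inner + 1L
    mid <- paste0("n", inner)
    g <- igraph::delete_edges(g, which(edgeKeys(g) == paste(min(e), max(e), sep = "|"))[1L])
    g <- igraph::add_vertices(g, 1L, name = mid)
    lf <- paste0("x", 2L + i)
    g <- igraph::add_vertices(g, 1L, name = lf)
    g <- igraph::add_edges(g, c(e[1L], mid, mid, e[2L], mid, lf))
    labels[as.character(2L + i)] <- lf
  }
  treeKeys <- edgeKeys(g)
  chords <- character(0)
  for (k in seq_len(max(0L, kExtra))) {
    em <- edgeMatrix(g)
    keys <- edgeKeys(g)
    treeIdx <- which(keys %in% treeKeys & !(keys %in% chords))
    if (length(treeIdx) < 2L) break
    pick <- sample(treeIdx, 2L)
    pickEdges <- list(em[pick[1L], ], em[pick[2L], ])
    mids <- character(2)
    for (j in 1:2) {
      e <- pickEdges[[j]]
      inner <- inner + 1L
      mids[j] <- paste0("n", inner)
      g <- igraph::add_vertices(g, 1L, name = mids[j])
      g <- igraph::delete_edges(g, which(edgeKeys(g) == paste(min(e), max(e), sep = "|"))[1L])
      g <- igraph::add_edges(g, c(e[1L], mids[j], mids[j], e[2L]))
      treeKeys <- setdiff(treeKeys, paste(min(e), max(e), sep = "|"))
      treeKeys <- c(treeKeys, paste(pmin(e, mids[j]), pmax(e, mids[j]), sep = "|"))
      em <- edgeMatrix(g)
    }
    g <- igraph::add_edges(g, mids)
    chords <- c(chords, paste(min(mids), max(mids), sep = "|"))
  }
  ## repair leftover degree-2 vertices (e.g. subdivision points that gained
  ## no chord partner on tiny trees) with extra labeled leaves on the tree
  repeat {
    d2 <- igraph::V(g)$name[igraph::degree(g) == 2L]
    if (length(d2) == 0L) break
    res <- attachLeaf(g, labels, d2[1L])
    g <- res$graph; labels <- res$labels
    treeKeys <- c(treeKeys, paste(pmin(d2[1L], unname(res$labels[length(res$labels)])),
                                  pmax(d2[1L], unname(res$labels[length(res$labels)])), sep = "|"))
  }
  net <- newNetwork(g, labels)
  st <- new("SupportTree", tree = treeFromEdges(g, which(edgeKeys(g) %in% treeKeys)),
            labels = labels)
  verifySupportTree(st, net)
  list(network = net, supportTree = st)
}

#' Random proper binary chordal network
#'
#' Binary chordal proper networks have a restricted shape: every non-trivial
#' blob is a triangle or a diamond (K4 minus an edge), connected in a tree of
#' blobs, degree-3 branch vertices and leaves.  The generator builds a random
#' such blob tree; the result is binary, chordal, proper, and hence
#' edge-based.  With \code{nBlobs = 0} the single-edge network is returned.
#'
#' @param nBlobs number of non-trivial blobs (0 gives a tree).
#' @param seed integer seed.
#' @param pBranch probability that a blob port spawns a further unit rather
#'   than a leaf (decays with depth).
#' @return a [PhyloNetwork-class].
#' @export
genBinaryChordal <- function(nBlobs = 2L, seed = 1L, pBranch = 0.4) {
  set.seed(seed)
  if (nBlobs == 0L) return(networkFixture("single-edge"))
  counter <- 0L
  g <- multigraph(matrix(character(), ncol = 2))
  budget <- nBlobs
  newBlob <- function() {
    counter <<- counter + 1L
    kind <- sample(c("triangle", "diamond"), 1L)
    p <- function(s) paste0("b", counter, s)
    if (kind == "triangle") {
      g <<- igraph::add_vertices(g, 3L, name = p(c("u", "v", "w")))
      g <<- igraph::add_edges(g, c(p("u"), p("v"), p("v"), p("w"), p("w"), p("u")))
      p(c("u", "v", "w"))                       # three ports (degree 2)
    } else {
      g <<- igraph::add_vertices(g, 4L, name = p(c("u", "v", "w", "x")))
      g <<- igraph::add_edges(g, c(p("u"), p("v"), p("v"), p("w"), p("w"), p("u"),
                                   p("v"), p("x"), p("x"), p("w")))
      p(c("u", "x"))                            # two ports (degree 2)
    }
  }
  openPorts <- newBlob()
  budget <- budget - 1L
  labels <- stats::setNames(character(0), character(0))
  depth <- 0L
  while (length(openPorts)) {
    port <- openPorts[1L]; openPorts <- openPorts[-1L]
    if (budget > 0L && stats::runif(1) < pBranch) {
      ports <- newBlob(); budget <- budget - 1L
      ## connect via a cut edge to one port of the new blob
      g <- igraph::add_edges(g, c(port, ports[1L]))
      openPorts <- c(openPorts, ports[-1L])
    } else {
      res <- attachLeaf(g, labels, port); g <- res$graph; labels <- res$labels
    }
  }
  ## force remaining budget in as chains if branching never fired
  while (budget > 0L) {
    att <- unname(labels[length(labels)])
    lfv <- att
    anchor <- igraph::V(g)$name[as.integer(igraph::neighbors(g, lfv))][1L]
    g <- igraph::delete_vertices(g, lfv)
    labels <- labels[-length(labels)]
    ports <- newBlob(); budget <- budget - 1L
    g <- igraph::add_edges(g, c(anchor, ports[1L]))
    for (p in ports[-1L]) { res <- attachLeaf(g, labels, p); g <- res$graph; labels <- res$labels }
  }
  net <- newNetwork(g, labels)
  stopifnot(isBinaryNetwork(net), isChordalGraph(g), isTRUE(isProper(net)))
  net
}

## ---- exhaustive enumeration ------------------------------------------------

allPermutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- allPermutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i)) |> unname()
  }))
}

## connected simple graphs on exactly n labeled vertices, up to isomorphism,
## by minimising the edge-set bitmask over all n! vertex permutations
## (desk-scale: n <= 7); connectivity via vertex-bitmask closure
connectedGraphClasses <- function(n) {
  if (n == 1L) return(list(multigraph(matrix(character(), ncol = 2), isolated = "1")))
  prs <- utils::combn(seq_len(n), 2L)
  npr <- ncol(prs)
  pow2 <- 2^(seq_len(npr) - 1L)
  perms <- allPermutations(n)
  ## pair index of each permuted pair, per permutation
  pairId <- matrix(0L, n, n)
  for (j in seq_len(npr)) pairId[prs[1L, j], prs[2L, j]] <- pairId[prs[2L, j], prs[1L, j]] <- j
  permEdge <- t(apply(perms, 1L, function(p) pairId[cbind(p[prs[1L, ]], p[prs[2L, ]])]))
  vbit <- 2^(seq_len(n) - 1L)
  repMasks <- integer(0)
  seen <- new.env(parent = emptyenv())
  for (mask in seq_len(2^npr - 1L)) {
    sel <- which(bitwAnd(mask, pow2) > 0L)
    if (length(sel) < n - 1L) next
    ## connectivity: bitmask closure from vertex 1
    nbr <- integer(n)
    for (j in sel) {
      a <- prs[1L, j]; b <- prs[2L, j]
      nbr[a] <- bitwOr(nbr[a], vbit[b]); nbr[b] <- bitwOr(nbr[b], vbit[a])
    }
    reach <- 1L
    repeat {
      nxt <- bitwOr(reach, Reduce(bitwOr, nbr[bitwAnd(reach, vbit) > 0L], 0L))
      if (nxt == reach) break
      reach <- nxt
    }
    if (reach != 2^n - 1L) next
    vals <- rowSums(matrix(pow2[permEdge[, sel, drop = FALSE]], nrow = nrow(permEdge)))
    key <- as.character(min(vals))
    if (!exists(key, envir = seen, inherits = FALSE)) {
      assign(key, TRUE, envir = seen)
      repMasks <- c(repMasks, mask)
    }
  }
  lapply(repMasks, function(mask) {
    sel <- which(bitwAnd(mask, pow2) > 0L)
    em <- t(prs[, sel, drop = FALSE])
    multigraph(matrix(as.character(em), ncol = 2), isolated = as.character(seq_len(n)))
  })
}

#' Exhaustive enumeration of small proper phylogenetic networks
#'
#' Yields, up to isomorphism with exchangeable leaf labels, every proper
#' phylogenetic network whose inner graph has at most \code{maxInner}
#' vertices and at most \code{maxLeaves} leaves: connected simple inner
#' graphs are enumerated up to isomorphism, leaves are attached in all ways
#' that eliminate degree-1 and degree-2 inner vertices, and results are
#' filtered for validity and properness and deduplicated canonically.
#'
#' @param maxInner at most 7 (enumeration guard).
#' @param maxLeaves maximum taxa.
#' @param proper keep only proper networks (default TRUE).
#' @return list of [PhyloNetwork-class] objects, deterministic order.
#' @export
enumerateNetworks <- function(maxInner, maxLeaves, proper = TRUE) {
  stopifnot(maxInner >= 1L, maxLeaves >= 1L)
  if (maxInner > 7L) stop("enumeration guard: maxInner must be <= 7")
  out <- list()
  seen <- new.env(parent = emptyenv())
  if (maxLeaves >= 2L) {
    ## the one proper network with an empty inner graph: the single edge
    out[[1L]] <- networkFixture("single-edge")
  }
  for (n in seq_len(maxInner)) {
    for (core in connectedGraphClasses(n)) {
      deg <- igraph::degree(core)
      minNeed <- pmax(0L, 3L - deg)
      if (sum(minNeed) > maxLeaves) next
      ## all per-vertex leaf counts: at least max(0, 3 - deg) so that no
      ## inner vertex ends with degree 1 or 2, within the total leaf budget
      counts <- list(integer(0))
      for (v in seq_len(n)) {
        restMin <- if (v < n) sum(minNeed[(v + 1L):n]) else 0L
        nxt <- list()
        for (c0 in counts) {
          lo <- minNeed[v]
          hi <- maxLeaves - sum(c0) - restMin
          if (hi < lo) next
          for (k in lo:hi) nxt[[length(nxt) + 1L]] <- c(c0, k)
        }
        counts <- nxt
      }
      coreEdges <- edgeMatrix(core)
      nm <- igraph::V(core)$name
      for (c0 in counts) {
        nl <- sum(c0)
        if (nl < 1L) next
        leafNames <- paste0("t", seq_len(nl))
        att <- rep(nm, c0)
        em <- rbind(coreEdges, cbind(att, leafNames))
        allNm <- c(nm, leafNames)
        g <- multigraph(em)
        col <- stats::setNames(c(rep(0L, length(nm)), rep(1L, nl)), allNm)
        key <- canonicalKey(g, vcolor = col)
        if (exists(key, envir = seen, inherits = FALSE)) next
        assign(key, TRUE, envir = seen)
        if (proper && !properFast(em, leafNames, allNm)) next
        labels <- stats::setNames(leafNames, as.character(seq_len(nl)))
        out[[length(out) + 1L]] <- newNetwork(g, labels)
      }
    }
  }
  out
}
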