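## Series-parallel / generalized series-parallel recognition, edge-basedness
## via two independent routes, the K4-topological-minor oracle, and the
## reduce-to-a-chosen-edge search.
##
## The deterministic operation priority deletes parallel copies before
## suppressing degree-2 vertices, so reductions restricted to leaf deletion,
## suppression and parallel-copy deletion never create loops on loopless
## input; this makes the greedy run a valid full leaf shrink and hence, by
## confluence, a complete decision procedure.

checkLoopless <- function(g) {
  if (hasLoop(g)) stop("loops present: SP/GSP recognition is defined for loopless graphs")
  if (!igraph::is_connected(g)) stop("not-connected")
}

#' Series-parallel (SP) recognition
#'
#' A connected loopless graph is SP when it can be reduced to a single edge by
#' suppressing degree-2 vertices and deleting parallel-edge copies only.
#'
#' @param g connected loopless multigraph.
#' @return a [GspCertificate-class]; on a true verdict the trace ends in K2
#'   and \code{terminals} holds its endpoints.
#' @export
isSP <- function(g) {
  checkLoopless(g)
  tr <- reduceGraph(g, ops = c("delete-parallel-copy", "suppress-degree2"))
  ok <- isK2(tr@final)
  new("GspCertificate", verdict = ok, route = "reduction", trace = tr,
      terminals = if (ok) igraph::V(tr@final)$name else character())
}

#' Generalized series-parallel (GSP) recognition
#'
#' A connected loopless graph is GSP iff every block (maximal biconnected
#' subgraph) is SP; equivalently iff it reduces to a single edge by leaf
#' deletion, degree-2 suppression and parallel-copy deletion.  Both routes are
#' computed and must agree; the block route is the reported certificate.
#'
#' @param g connected loopless multigraph.
#' @return a [GspCertificate-class] with route "block-sp"; slot \code{trace}
#'   holds the per-block SP certificates.
#' @export
isGSP <- function(g) {
  checkLoopless(g)
  dec <- decomposeGraph(g)
  blockCerts <- lapply(dec@blocks, function(vs) {
    sub <- igraph::induced_subgraph(g, vs)
    if (igraph::vcount(sub) == 2L && igraph::ecount(sub) == 1L) TRUE else isSP(sub)@verdict
  })
  blockVerdict <- all(vapply(blockCerts, isTRUE, logical(1)))
  tr <- reduceGraph(g, ops = c("delete-leaf", "delete-parallel-copy", "suppress-degree2"))
  redVerdict <- isK2(tr@final)
  if (blockVerdict != redVerdict)
    stop("internal error: block-SP and reduction routes disagree on GSP membership")
  new("GspCertificate", verdict = blockVerdict, route = "block-sp",
      trace = list(blocks = dec@blocks, sp = blockCerts, reduction = tr),
      terminals = if (redVerdict) igraph::V(tr@final)$name else character())
}

setMethod("show", "GspCertificate", function(object) {
  cat(sprintf("GspCertificate: verdict %s via %s%s\n", object@verdict, object@route,
              if (length(object@terminals)) paste0(", terminals {", paste(object@terminals, collapse = ","), "}") else ""))
})

#' Edge-basedness of a graph or network
#'
#' A connected graph is edge-based when its leaf shrink graph is a single
#' edge.  For loopless input the verdict provably coincides with GSP
#' membership; both are computed and any disagreement is an internal error.
#'
#' @param g connected multigraph with at least two vertices, or a
#'   [PhyloNetwork-class].
#' @return logical with attribute \code{trace} (the leaf-shrink
#'   [ReductionTrace-class] certificate).
#' @export
isEdgeBased <- function(g) {
  if (is(g, "PhyloNetwork")) g <- g@graph
  if (igraph::vcount(g) < 2L) stop("edge-basedness requires |V| >= 2")
  if (!igraph::is_connected(g)) stop("not-connected")
  tr <- lsGraph(g)
  verdict <- isK2(tr@final)
  if (!hasLoop(g)) {
    if (isGSP(g)@verdict != verdict)
      stop("internal error: edge-based and GSP verdicts disagree on loopless input")
  }
  structure(verdict, trace = tr)
}

#' K4 topological minor oracle (brute force)
#'
#' Searches for four branch vertices of degree >= 3 joined pairwise by six
#' internally vertex-disjoint paths.  Used as an independent test oracle for
#' SP/GSP recognition (a loopless connected graph is GSP iff it has no K4
#' topological minor); never the production decision procedure.
#'
#' @param g connected multigraph (parallels/loops are ignored: they cannot
#'   contribute to a K4 subdivision).
#' @param cap bound on search node expansions; NA when exceeded.
#' @return TRUE / FALSE / NA.
#' @export
hasK4TopologicalMinor <- function(g, cap = 2e6) {
  g <- underlyingSimple(g)
  n <- igraph::vcount(g)
  if (n < 4L) return(FALSE)
  nm <- igraph::V(g)$name
  adj <- lapply(nm, function(v) igraph::V(g)$name[as.integer(igraph::neighbors(g, v))])
  names(adj) <- nm
  deg <- igraph::degree(g)
  branchCand <- nm[deg >= 3L]
  if (length(branchCand) < 4L) return(FALSE)
  nodes <- 0L
  capped <- FALSE
  ## connect pairs (b1,b2),(b1,b3),(b1,b4),(b2,b3),(b2,b4),(b3,b4) by paths
  ## whose internal vertices are pairwise disjoint and avoid branch vertices
  connect <- function(pairs, used) {
    nodes <<- nodes + 1L
    if (nodes > cap) { capped <<- TRUE; return(FALSE) }
    if (length(pairs) == 0L) return(TRUE)
    p <- pairs[[1L]]
    rest <- pairs[-1L]
    ## DFS for a path from p[1] to p[2] through unused internal vertices
    extend <- function(cur, usedNow) {
      for (w in adj[[cur]]) {
        if (w == p[2L]) {
          if (connect(rest, usedNow)) return(TRUE)
        } else if (!(w %in% usedNow) && !(w %in% branch)) {
          if (extend(w, c(usedNow, w))) return(TRUE)
        }
        if (capped) return(FALSE)
      }
      FALSE
    }
    extend(p[1L], used)
  }
  combs <- utils::combn(branchCand, 4L)
  for (j in seq_len(ncol(combs))) {
    branch <- combs[, j]
    pairs <- utils::combn(branch, 2L, simplify = FALSE)
    if (connect(pairs, character())) return(TRUE)
    if (capped) return(NA)
  }
  FALSE
}

#' Edge-basedness via blob decomposition
#'
#' A proper network is edge-based iff every non-trivial blob is edge-based,
#' where each blob is considered with its incident cut edges re-attached as
#' new leaves.  The verdict is cross-checked against the whole-network leaf
#' shrink.
#'
#' @param net a proper [PhyloNetwork-class] with at least two taxa.
#' @return logical with attribute \code{blobVerdicts}.
#' @export
edgeBasedByBlobs <- function(net) {
  stopifnot(is(net, "PhyloNetwork"))
  if (length(net@labels) < 2L) stop("requires |X| >= 2")
  if (!isTRUE(isProper(net))) stop("network is not proper")
  g <- net@graph
  dec <- decomposeGraph(g)
  blobs <- nontrivialBlobs(dec)
  verdicts <- logical(0)
  if (length(blobs)) {
    em <- edgeMatrix(g)
    for (b in blobs) {
      vs <- b$vertices
      sub <- igraph::induced_subgraph(g, vs)
      ## re-attach each incident cut edge as a fresh leaf
      inc <- em[xor(em[, 1L] %in% vs, em[, 2L] %in% vs), , drop = FALSE]
      for (i in seq_len(nrow(inc))) {
        inside <- if (inc[i, 1L] %in% vs) inc[i, 1L] else inc[i, 2L]
        lf <- paste0(".leaf", i)
        sub <- igraph::add_vertices(sub, 1L, name = lf)
        sub <- igraph::add_edges(sub, c(inside, lf))
      }
      verdicts <- c(verdicts, as.logical(isEdgeBased(sub)))
    }
  }
  verdict <- all(verdicts)
  whole <- as.logical(isEdgeBased(g))
  if (verdict != whole)
    stop("internal error: blob decomposition disagrees with whole-network leaf shrink")
  structure(verdict, blobVerdicts = verdicts)
}

#' Reduce a GSP graph to a chosen edge
#'
#' Any edge of a GSP graph can serve as the terminal pair: there is a sequence
#' of leaf deletions, degree-2 suppressions and parallel-copy deletions ending
#' in exactly that edge.  Found by backtracking over operation choices that
#' never remove the edge's endpoints, with memoization on canonical states.
#'
#' @param g connected loopless multigraph, GSP (checked).
#' @param edge character vector c(u, v), an edge of \code{g}.
#' @param cap bound on search states; exceeding it returns a failure flag
#'   (unreachable at the sizes this package targets).
#' @return a [ReductionTrace-class] ending in K2 on \code{edge}'s endpoints,
#'   or NULL with a warning if the cap was hit.
#' @export
reduceToEdge <- function(g, edge, cap = 100000L) {
  stopifnot(length(edge) == 2L)
  u <- edge[1L]; v <- edge[2L]
  if (!paste(min(u, v), max(u, v), sep = "|") %in% edgeKeys(g))
    stop("edge not present in graph")
  if (!isGSP(g)@verdict) stop("reduce-to-edge requires a GSP graph")
  termColor <- function(gg) {
    nm <- igraph::V(gg)$name
    stats::setNames(ifelse(nm %in% c(u, v), 1L, 0L), nm)
  }
  seen <- new.env(parent = emptyenv())
  states <- 0L
  search <- function(gg) {
    states <<- states + 1L
    if (states > cap) return(NULL)
    if (igraph::vcount(gg) == 2L && igraph::ecount(gg) == 1L &&
        setequal(igraph::V(gg)$name, c(u, v)))
      return(list())
    key <- canonicalKey(gg, vcolor = termColor(gg))
    if (exists(key, envir = seen, inherits = FALSE)) return(NULL)
    assign(key, TRUE, envir = seen)
    av <- applicableOps(gg, ops = c("delete-leaf", "delete-parallel-copy", "suppress-degree2"),
                        guard = FALSE)
    if (nrow(av)) {
      keep <- !(av$kind %in% c("delete-leaf", "suppress-degree2") & av$t1 %in% c(u, v))
      av <- av[keep, , drop = FALSE]
    }
    for (i in seq_len(nrow(av))) {
      res <- search(applyOp(gg, av$kind[i], av$t1[i], av$t2[i]))
      if (!is.null(res)) return(c(list(av[i, , drop = FALSE]), res))
    }
    NULL
  }
  path <- search(g)
  if (is.null(path)) {
    if (states > cap) { warning("reduce-to-edge search cap exceeded"); return(NULL) }
    stop("internal error: GSP graph could not be reduced to the chosen edge")
  }
  steps <- if (length(path)) do.call(rbind, path) else
    data.frame(kind = character(), t1 = character(), t2 = character())
  rownames(steps) <- NULL
  final <- g
  for (i in seq_len(nrow(steps))) final <- applyOp(final, steps$kind[i], steps$t1[i], steps$t2[i])
  newReductionTrace(g, steps, final)
}
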