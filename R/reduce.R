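## Leaf cutting, leaf shrinking, trace replay, and the small-instance
## restricted-topological-subgraph oracle.

#' Leaf cut graph
#'
#' Deletes all labeled leaves (and their incident edges) from a network.  New
#' degree-1 or degree-2 vertices that arise are kept: leaf cutting performs no
#' further reduction.  On the degenerate single-edge network (both vertices
#' labeled) the result is the empty graph, flagged with attribute
#' \code{empty = TRUE}.
#'
#' @param net a [PhyloNetwork-class] with at least 2 vertices and 2 taxa.
#' @return simple \pkg{igraph} graph on the inner vertices.
#' @export
lcut <- function(net) {
  stopifnot(is(net, "PhyloNetwork"))
  if (igraph::vcount(net@graph) < 2L || length(net@labels) < 2L)
    stop("leaf cutting requires |V| >= 2 and |X| >= 2")
  g <- igraph::delete_vertices(net@graph, networkLeaves(net))
  if (igraph::vcount(g) == 0L) {
    warning("all vertices were labeled leaves; leaf cut graph is empty")
    attr(g, "empty") <- TRUE
  }
  g
}

#' Leaf shrink graph
#'
#' Exhaustively applies the four restriction operations (delete a leaf,
#' suppress a degree-2 vertex, delete a parallel-edge copy, delete a loop)
#' until none applies, never dropping below two vertices.  The result is
#' simple and unique up to isomorphism regardless of the operation order, so
#' the policy only affects the certificate trace.
#'
#' @param g connected multigraph with at least two vertices, at least two of
#'   which have degree 1; pass a [PhyloNetwork-class] to shrink its graph.
#' @param policy,seed see [reduceGraph()].
#' @return a [ReductionTrace-class]; the shrunk graph is in slot
#'   \code{final}.
#' @export
leafShrink <- function(g, policy = c("deterministic", "random"), seed = NULL) {
  if (is(g, "PhyloNetwork")) g <- g@graph
  if (igraph::vcount(g) < 2L) stop("leaf shrinking requires |V| >= 2")
  if (sum(igraph::degree(g, loops = TRUE) == 1L) < 2L)
    stop("leaf shrinking requires at least two degree-1 vertices")
  reduceGraph(g, ops = opKinds, policy = match.arg(policy), seed = seed)
}

## unrestricted variant used internally (edge-basedness of arbitrary
## connected graphs, e.g. re-leafed blobs or leafless cores)
lsGraph <- function(g, policy = "deterministic", seed = NULL) {
  if (is(g, "PhyloNetwork")) g <- g@graph
  stopifnot(igraph::vcount(g) >= 2L)
  reduceGraph(g, ops = opKinds, policy = policy, seed = seed)
}

#' @describeIn leafShrink replay a trace from its initial graph; errors if
#'   the replay does not reproduce \code{final} exactly.
#' @param trace a [ReductionTrace-class].
#' @export
replayTrace <- function(trace) {
  g <- trace@initial
  st <- trace@steps
  for (i in seq_len(nrow(st))) g <- applyOp(g, st$kind[i], st$t1[i], st$t2[i])
  if (!sameMultigraph(g, trace@final)) stop("trace replay did not reproduce the final graph")
  g
}

#' @describeIn leafShrink serialize a trace to JSON (ordered op list with
#'   targets plus initial/final edge lists).
#' @export
traceJSON <- function(trace) {
  jsonlite::toJSON(list(
    initial = edgeMatrix(trace@initial),
    steps = trace@steps,
    final = edgeMatrix(trace@final)
  ), auto_unbox = TRUE)
}

setMethod("show", "ReductionTrace", function(object) {
  cat(sprintf("ReductionTrace: %d step(s), %d/%d -> %d/%d vertices/edges\n",
              nrow(object@steps),
              igraph::vcount(object@initial), igraph::ecount(object@initial),
              igraph::vcount(object@final), igraph::ecount(object@final)))
  if (nrow(object@steps)) print(utils::head(object@steps, 10L))
})

#' Restricted topological subgraph test (small instances)
#'
#' Decides whether \code{candidate} can be reached from \code{g} by some
#' sequence of the four restriction operations, by breadth-first search over
#' isomorphism-canonicalized intermediate states.  Operation counts shrink the
#' graph monotonically, so states smaller than the candidate are pruned.
#'
#' @param g,candidate connected multigraphs.
#' @param cap maximum number of explored states; when exceeded the result is
#'   \code{NA} (indeterminate), never a guess.
#' @return TRUE / FALSE / NA.
#' @export
isRestrictedTopologicalSubgraph <- function(g, candidate, cap = 50000L) {
  targetKey <- canonicalKey(candidate)
  tn <- igraph::vcount(candidate); te <- igraph::ecount(candidate)
  seen <- new.env(parent = emptyenv())
  queue <- list(g)
  explored <- 0L
  assign(canonicalKey(g), TRUE, envir = seen)
  while (length(queue)) {
    cur <- queue[[1L]]; queue <- queue[-1L]
    explored <- explored + 1L
    if (explored > cap) return(NA)
    if (canonicalKey(cur) == targetKey) return(TRUE)
    av <- applicableOps(cur, guard = FALSE)
    for (i in seq_len(nrow(av))) {
      nxt <- applyOp(cur, av$kind[i], av$t1[i], av$t2[i])
      if (igraph::vcount(nxt) < tn || igraph::ecount(nxt) < te) next
      key <- canonicalKey(nxt)
      if (!exists(key, envir = seen, inherits = FALSE)) {
        assign(key, TRUE, envir = seen)
        queue[[length(queue) + 1L]] <- nxt
      }
    }
  }
  FALSE
}
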