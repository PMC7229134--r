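#' Build an undirected multigraph from an edge list
#'
#' Multigraphs are the substrate of all reductions in this package: parallel
#' edges and loops are allowed and are meaningful (a loop contributes 2 to the
#' degree of its vertex). Vertices are identified by opaque character ids.
#'
#' @param edges two-column character matrix (or data.frame) of endpoints, one
#'   row per edge instance; repeated rows are parallel edges, rows with equal
#'   endpoints are loops.
#' @param isolated character vector of additional vertices without edges.
#' @return an undirected \pkg{igraph} graph with named vertices.
#' @examples
#' g <- multigraph(rbind(c("a", "b"), c("a", "b"), c("b", "b")))
#' igraph::degree(g)  # a: 2, b: 4
#' @export
multigraph <- function(edges, isolated = character()) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    if (length(isolated)) g <- igraph::add_vertices(g, length(isolated), name = as.character(isolated))
    return(g)
  }
  storage.mode(edges) <- "character"
  verts <- unique(c(as.vector(t(edges)), as.character(isolated)))
  g <- igraph::make_empty_graph(n = length(verts), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = verts)
  igraph::add_edges(g, as.vector(t(edges)))
}

#' @rdname multigraph
#' @param g a multigraph.
#' @export
edgeMatrix <- function(g) {
  m <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(m) == 0L) return(matrix(character(), ncol = 2))
  cbind(pmin(m[, 1L], m[, 2L]), pmax(m[, 1L], m[, 2L]))
}

## sorted "u|v" keys, one per edge instance
edgeKeys <- function(g) {
  m <- edgeMatrix(g)
  if (nrow(m) == 0L) return(character())
  paste(m[, 1L], m[, 2L], sep = "|")
}

## identical labeled multigraph (same vertex names, same edge multiset)
sameMultigraph <- function(g1, g2) {
  setequal(igraph::V(g1)$name, igraph::V(g2)$name) &&
    identical(sort(edgeKeys(g1)), sort(edgeKeys(g2)))
}

isK2 <- function(g) {
  igraph::vcount(g) == 2L && igraph::ecount(g) == 1L && !any(igraph::which_loop(g))
}

hasParallel <- function(g) any(igraph::which_multiple(g))
hasLoop <- function(g) any(igraph::which_loop(g))
isSimpleGraph <- function(g) !hasParallel(g) && !hasLoop(g)

## underlying simple graph (drop loops, collapse parallels)
underlyingSimple <- function(g) igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)

## neighbors via edge ends, loop-aware; returns character vector with
## multiplicity (a loop contributes the vertex itself twice)
incidentEnds <- function(g, v) {
  eids <- igraph::incident(g, v, mode = "all")
  if (length(eids) == 0L) return(character())
  m <- igraph::ends(g, eids, names = TRUE)
  ends <- character()
  for (i in seq_len(nrow(m))) {
    if (m[i, 1L] == v && m[i, 2L] == v) ends <- c(ends, v, v)
    else ends <- c(ends, setdiff(m[i, ], v))
  }
  ends
}

opKinds <- c("delete-leaf", "delete-parallel-copy", "delete-loop", "suppress-degree2")

#' Restriction operations applicable to a multigraph
#'
#' Lists every restriction operation that is currently legal: leaf deletion,
#' suppression of a degree-2 vertex, deletion of one copy of a parallel edge,
#' and deletion of a loop.  When the graph has exactly two vertices only
#' parallel-copy and loop deletions are offered, so that a reduction can never
#' drop below two vertices (the guard of the leaf-shrinking algorithm).
#'
#' A degree-2 vertex carrying a loop is not suppressible (its two edge ends
#' meet the same vertex); such a vertex cannot arise during the reduction of a
#' connected graph with at least two vertices.
#'
#' @param g multigraph.
#' @param ops subset of operation kinds to consider (default all four).
#' @param guard apply the two-vertex guard (default TRUE).
#' @return data.frame with columns \code{kind}, \code{t1}, \code{t2} (second
#'   target endpoint, \code{NA} for vertex-targeted ops), in the package's
#'   deterministic order.
#' @export
applicableOps <- function(g, ops = opKinds, guard = TRUE) {
  out <- list()
  n <- igraph::vcount(g)
  deg <- igraph::degree(g, loops = TRUE)
  nm <- igraph::V(g)$name
  loopv <- character()
  if (igraph::ecount(g) > 0L) {
    em <- igraph::as_edgelist(g, names = TRUE)
    loopv <- em[em[, 1L] == em[, 2L], 1L]
  }
  allowVertexRemoval <- !(guard && n <= 2L)
  if ("delete-leaf" %in% ops && allowVertexRemoval) {
    lv <- sort(nm[deg == 1L])
    if (length(lv)) out[[length(out) + 1L]] <- data.frame(kind = "delete-leaf", t1 = lv, t2 = NA_character_)
  }
  if ("delete-parallel-copy" %in% ops && igraph::ecount(g) > 0L) {
    ek <- edgeKeys(g)
    tab <- table(ek)
    par <- names(tab)[tab >= 2L]
    par <- par[!vapply(strsplit(par, "|", fixed = TRUE), function(x) x[1L] == x[2L], logical(1))]
    if (length(par)) {
      sp <- do.call(rbind, strsplit(sort(par), "|", fixed = TRUE))
      out[[length(out) + 1L]] <- data.frame(kind = "delete-parallel-copy", t1 = sp[, 1L], t2 = sp[, 2L])
    }
  }
  if ("delete-loop" %in% ops && length(loopv)) {
    out[[length(out) + 1L]] <- data.frame(kind = "delete-loop", t1 = sort(unique(loopv)), t2 = NA_character_)
  }
  if ("suppress-degree2" %in% ops && allowVertexRemoval) {
    sv <- nm[deg == 2L]
    sv <- sort(setdiff(sv, loopv))
    if (length(sv)) out[[length(out) + 1L]] <- data.frame(kind = "suppress-degree2", t1 = sv, t2 = NA_character_)
  }
  if (length(out) == 0L) {
    return(data.frame(kind = character(), t1 = character(), t2 = character()))
  }
  res <- do.call(rbind, out)
  res$kind <- factor(res$kind, levels = opKinds)
  res <- res[order(res$kind, res$t1, res$t2, na.last = TRUE), , drop = FALSE]
  res$kind <- as.character(res$kind)
  rownames(res) <- NULL
  res
}

applyOp <- function(g, kind, t1, t2 = NA_character_) {
  switch(kind,
    "delete-leaf" = {
      stopifnot(igraph::degree(g, t1, loops = TRUE) == 1L)
      igraph::delete_vertices(g, t1)
    },
    "suppress-degree2" = {
      stopifnot(igraph::degree(g, t1, loops = TRUE) == 2L)
      nb <- incidentEnds(g, t1)
      stopifnot(length(nb) == 2L, !any(nb == t1))
      g2 <- igraph::delete_vertices(g, t1)
      igraph::add_edges(g2, nb)
    },
    "delete-parallel-copy" = {
      ek <- edgeKeys(g)
      key <- paste(min(t1, t2), max(t1, t2), sep = "|")
      idx <- which(ek == key)
      stopifnot(length(idx) >= 2L)
      igraph::delete_edges(g, idx[1L])
    },
    "delete-loop" = {
      ek <- edgeKeys(g)
      idx <- which(ek == paste(t1, t1, sep = "|"))
      stopifnot(length(idx) >= 1L)
      igraph::delete_edges(g, idx[1L])
    },
    stop("unknown operation kind: ", kind)
  )
}

#' Reduce a multigraph by restriction operations
#'
#' Repeatedly applies restriction operations from \code{ops} until none is
#' applicable, honouring the two-vertex guard.  Under the deterministic policy
#' the lexicographically smallest applicable operation (by kind rank, then
#' target ids) is taken; under the random policy one is drawn uniformly using
#' \code{seed}.  The leaf shrink graph is unique up to isomorphism whatever
#' the policy, so the choice only affects the recorded trace.
#'
#' @param g multigraph, at least one vertex.
#' @param ops operation kinds allowed.
#' @param policy "deterministic" or "random".
#' @param seed integer seed for the random policy.
#' @return a [ReductionTrace-class] whose \code{final} slot holds the fully
#'   reduced graph.
#' @export
reduceGraph <- function(g, ops = opKinds, policy = c("deterministic", "random"), seed = NULL) {
  policy <- match.arg(policy)
  rng <- NULL
  if (policy == "random") {
    if (is.null(seed)) seed <- 1L
    rng <- local({ set.seed(seed); NULL })
  }
  initial <- g
  steps <- list()
  repeat {
    av <- applicableOps(g, ops = ops)
    if (nrow(av) == 0L) break
    i <- if (policy == "deterministic") 1L else sample.int(nrow(av), 1L)
    g <- applyOp(g, av$kind[i], av$t1[i], av$t2[i])
    steps[[length(steps) + 1L]] <- av[i, , drop = FALSE]
  }
  steps <- if (length(steps)) do.call(rbind, steps) else
    data.frame(kind = character(), t1 = character(), t2 = character())
  rownames(steps) <- NULL
  newReductionTrace(initial, steps, g)
}
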