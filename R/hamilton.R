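## Exact Hamiltonian path / cycle searches and Hamilton-connectedness.
## Backtracking over integer adjacency lists; caps return NA (indeterminate),
## never a guess.

adjList <- function(g) {
  nm <- igraph::V(g)$name
  al <- lapply(nm, function(v) sort(igraph::V(g)$name[as.integer(igraph::neighbors(g, v))]))
  names(al) <- nm
  al
}

## integer adjacency (vertex ids 1..n)
adjInt <- function(g) {
  n <- igraph::vcount(g)
  em <- igraph::as_edgelist(g, names = FALSE)
  adj <- vector("list", n)
  for (i in seq_len(nrow(em))) {
    a <- em[i, 1L]; b <- em[i, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  lapply(adj, unique)
}

## exact search; goal = 0 means any endpoint; returns integer path, NULL, or
## NA (cap hit)
hamSearchInt <- function(adj, start, goal, cap) {
  n <- length(adj)
  visited <- logical(n)
  path <- integer(n)
  nodes <- 0L
  capped <- FALSE
  dfs <- function(cur, len) {
    nodes <<- nodes + 1L
    if (nodes > cap) { capped <<- TRUE; return(NULL) }
    if (len == n) {
      if (goal == 0L || cur == goal) return(path)
      return(NULL)
    }
    for (w in adj[[cur]]) {
      if (visited[w] || (goal != 0L && w == goal && len < n - 1L)) next
      visited[w] <<- TRUE; path[len + 1L] <<- w
      res <- dfs(w, len + 1L)
      visited[w] <<- FALSE
      if (!is.null(res)) return(res)
      if (capped) return(NULL)
    }
    NULL
  }
  visited[start] <- TRUE
  path[1L] <- start
  res <- dfs(start, 1L)
  if (is.null(res) && capped) return(NA)
  res
}

#' Hamiltonian path search
#'
#' Exact backtracking search for a path visiting every vertex exactly once,
#' optionally with fixed endpoints.
#'
#' @param g simple connected graph.
#' @param from,to optional endpoint vertex names (both or neither).
#' @param cap bound on search node expansions.
#' @return the ordered vertex vector of a witness path, NULL when provably
#'   absent, or NA when the cap was hit.
#' @export
hamiltonianPath <- function(g, from = NULL, to = NULL, cap = 2e6) {
  stopifnot(isSimpleGraph(g))
  n <- igraph::vcount(g)
  if (n == 0L) return(NULL)
  nm <- igraph::V(g)$name
  if (n == 1L) return(nm)
  if (!igraph::is_connected(g)) return(NULL)
  adj <- adjInt(g)
  if (!is.null(from)) {
    if (is.null(to)) stop("give both endpoints or neither")
    if (from == to) stop("endpoints must differ")
    res <- hamSearchInt(adj, match(from, nm), match(to, nm), cap)
    if (length(res) > 1L) return(nm[res])
    return(if (length(res) == 1L && is.na(res)) NA else NULL)
  }
  anyCap <- FALSE
  for (s in seq_len(n)) {
    res <- hamSearchInt(adj, s, 0L, cap)
    if (length(res) > 1L) return(nm[res])
    if (length(res) == 1L && is.na(res)) anyCap <- TRUE
  }
  if (anyCap) NA else NULL
}

#' Hamiltonian cycle search
#'
#' @inheritParams hamiltonianPath
#' @return ordered vertex vector of a witness cycle (first vertex not
#'   repeated), NULL when provably absent, NA when the cap was hit.
#' @export
hamiltonianCycle <- function(g, cap = 2e6) {
  stopifnot(isSimpleGraph(g))
  n <- igraph::vcount(g)
  if (n < 3L) return(NULL)
  if (!igraph::is_connected(g)) return(NULL)
  if (any(igraph::degree(g) < 2L)) return(NULL)
  nm <- igraph::V(g)$name
  adj <- adjInt(g)
  anyCap <- FALSE
  ## a cycle is a Hamiltonian path from a fixed start to one of its neighbors
  for (goal in adj[[1L]]) {
    res <- hamSearchInt(adj, 1L, goal, cap)
    if (length(res) > 1L) return(nm[res])
    if (length(res) == 1L && is.na(res)) anyCap <- TRUE
  }
  if (anyCap) NA else NULL
}

#' Hamilton-connectedness
#'
#' TRUE when every unordered vertex pair is joined by a Hamiltonian path.
#' The one-vertex and two-vertex (K2) graphs are Hamilton connected by the
#' package's convention, so that leaf cut graphs consisting of a single
#' vertex or a single edge compose with the H-connected network class.
#'
#' @inheritParams hamiltonianPath
#' @return TRUE / FALSE / NA (cap hit with no falsifying pair found).
#' @export
isHamiltonConnected <- function(g, cap = 2e6) {
  stopifnot(isSimpleGraph(g))
  n <- igraph::vcount(g)
  if (n <= 2L) return(TRUE)
  if (!igraph::is_connected(g)) return(FALSE)
  adj <- adjInt(g)
  anyCap <- FALSE
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    res <- hamSearchInt(adj, i, j, cap)
    if (is.null(res)) return(FALSE)
    if (length(res) == 1L && is.na(res)) anyCap <- TRUE
  }
  if (anyCap) NA else TRUE
}
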