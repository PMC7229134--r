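## shared fixtures and independent oracles for the test suite

mg <- function(...) multigraph(rbind(...))

k4graph <- function() multigraph(t(combn(c("a", "b", "c", "d"), 2L)))

triangleGraph <- function() mg(c("x", "y"), c("y", "z"), c("z", "x"))

cycleGraph <- function(n) {
  v <- paste0("c", seq_len(n))
  multigraph(cbind(v, v[c(seq(2L, n), 1L)]))
}

## random connected multigraph: random spanning tree + extras; optionally
## parallel copies, loops, and >= 2 pendant leaves (callers set the seed)
rConnectedMultigraph <- function(n, extras = 2L, parallels = 1L, loops = 1L,
                                 leaves = 2L) {
  v <- paste0("v", seq_len(n))
  em <- NULL
  for (i in seq(2L, length.out = n - 1L))
    em <- rbind(em, c(v[sample.int(i - 1L, 1L)], v[i]))
  for (i in seq_len(extras)) em <- rbind(em, sample(v, 2L))
  for (i in seq_len(parallels)) em <- rbind(em, em[sample.int(nrow(em), 1L), ])
  for (i in seq_len(loops)) { u <- sample(v, 1L); em <- rbind(em, c(u, u)) }
  for (i in seq_len(leaves)) {
    lf <- paste0("leaf", i)
    em <- rbind(em, c(sample(v, 1L), lf))
  }
  multigraph(em)
}

## loopless variant (parallels allowed), no pendant guarantee
rLooplessConnected <- function(n, extras = 2L, parallels = 1L) {
  rConnectedMultigraph(n, extras = extras, parallels = parallels, loops = 0L, leaves = 0L)
}

## independent Hamiltonian-path oracle: permutation brute force (n <= 8)
bruteHamiltonianPath <- function(g, from = NULL, to = NULL) {
  nm <- igraph::V(g)$name
  n <- length(nm)
  if (n == 1L) return(TRUE)
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
  perms <- phynetclass:::allPermutations(n)
  for (r in seq_len(nrow(perms))) {
    p <- nm[perms[r, ]]
    if (!is.null(from) && (p[1L] != from || p[n] != to)) next
    ok <- TRUE
    for (i in seq_len(n - 1L)) if (!adj[p[i], p[i + 1L]]) { ok <- FALSE; break }
    if (ok) return(TRUE)
  }
  FALSE
}

## tree-based network on which no leaf-connect graph has a Hamiltonian cycle
## through a new edge (analog located by exhaustive enumeration)
lconNewEdgeFalseNet <- function() {
  em <- rbind(c("1", "2"), c("1", "3"), c("1", "4"), c("1", "5"), c("1", "6"),
              c("2", "3"), c("2", "4"), c("2", "5"), c("2", "6"), c("3", "4"),
              c("1", "t1"), c("2", "t2"), c("5", "t3"), c("6", "t4"))
  validateNetwork(multigraph(em), c(a = "t1", b = "t2", c = "t3", d = "t4"))
}

## chordal proper (non-binary) network that is not tree-based (located by
## exhaustive enumeration; witnesses that chordality alone is insufficient)
chordalNonTreeBasedNet <- function() {
  em <- rbind(c("1", "2"), c("1", "3"), c("1", "4"), c("1", "5"), c("1", "6"),
              c("2", "3"), c("2", "4"), c("2", "5"), c("2", "6"), c("3", "4"),
              c("3", "5"), c("3", "6"), c("2", "t1"), c("3", "t2"))
  validateNetwork(multigraph(em), c(a = "t1", b = "t2"))
}

## square core with one leaf per corner: a proper edge-based 4-taxon network
squareNet <- function() {
  validateNetwork(mg(c("a", "b"), c("b", "c"), c("c", "d"), c("d", "a"),
                     c("a", "1"), c("b", "2"), c("c", "3"), c("d", "4")),
                  c("1" = "1", "2" = "2", "3" = "3", "4" = "4"))
}
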