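## Canonical forms for small multigraphs.
##
## igraph's isomorphism machinery (BLISS, VF2) addresses simple graphs, so
## multigraphs are encoded faithfully as vertex-colored simple graphs first:
## every bundle of parallel edges {u,v} becomes an auxiliary vertex colored by
## its multiplicity and adjacent to u and v, and every vertex's loop count is
## folded into an auxiliary pendant vertex with its own color range.  Two
## multigraphs are isomorphic iff their encodings are isomorphic as colored
## graphs, and BLISS canonical permutations of the encodings yield a canonical
## key.  Color ranges: original vertices 0..999 (caller-supplied roles),
## 1000+ for edge bundles / simple-graph edge colors, 100000+ for loop counts.

auxEncoding <- function(g, vcolor = NULL, ecolor = NULL) {
  nm <- igraph::V(g)$name
  if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(g)))
  if (is.null(vcolor)) {
    vcolor <- stats::setNames(rep(0L, length(nm)), nm)
  } else {
    stopifnot(all(nm %in% names(vcolor)), all(vcolor >= 0L), all(vcolor < 1000L))
    vcolor <- vcolor[nm]
  }
  em <- edgeMatrix(g)
  colors <- as.integer(vcolor)
  edges <- character()
  auxnames <- character()
  if (nrow(em) > 0L) {
    loop <- em[, 1L] == em[, 2L]
    lem <- em[loop, , drop = FALSE]
    sem <- em[!loop, , drop = FALSE]
    if (nrow(sem) > 0L) {
      key <- paste(sem[, 1L], sem[, 2L], sep = "|")
      if (!is.null(ecolor)) {
        ## per-edge colors only make sense on simple graphs
        stopifnot(!anyDuplicated(key), length(ecolor) == nrow(em))
        ec <- as.integer(ecolor[!loop])
        stopifnot(all(ec >= 0L), all(ec < 90000L))
      } else {
        ec <- NULL
      }
      ukey <- unique(key)
      for (i in seq_along(ukey)) {
        k <- ukey[i]
        idx <- which(key == k)
        col <- if (is.null(ec)) 1000L + length(idx) else 1000L + ec[idx[1L]]
        av <- paste0(".e", i)
        auxnames <- c(auxnames, av)
        colors <- c(colors, col)
        uv <- strsplit(k, "|", fixed = TRUE)[[1L]]
        edges <- c(edges, av, uv[1L], av, uv[2L])
      }
    }
    if (nrow(lem) > 0L) {
      tab <- table(lem[, 1L])
      for (i in seq_along(tab)) {
        av <- paste0(".l", i)
        auxnames <- c(auxnames, av)
        colors <- c(colors, 100000L + as.integer(tab[i]))
        edges <- c(edges, av, names(tab)[i])
      }
    }
  }
  aux <- igraph::make_empty_graph(n = length(nm) + length(auxnames), directed = FALSE)
  aux <- igraph::set_vertex_attr(aux, "name", value = c(nm, auxnames))
  if (length(edges)) aux <- igraph::add_edges(aux, edges)
  list(graph = aux, colors = colors)
}

#' Canonical key of a multigraph
#'
#' A string that is identical for two multigraphs iff they are isomorphic
#' (respecting optional vertex roles and, on simple graphs, edge colors).
#' Adequate for the small graphs handled by this package; loops and edge
#' multiplicities are part of the form.
#'
#' @param g multigraph.
#' @param vcolor optional named integer vector of vertex roles (0..999), e.g.
#'   1 for leaves when leaf labels are exchangeable.
#' @param ecolor optional integer vector of edge colors, in edge order
#'   (simple graphs only).
#' @return character scalar.
#' @export
canonicalKey <- function(g, vcolor = NULL, ecolor = NULL) {
  if (is.null(ecolor) && igraph::ecount(g) > 0L && isSimpleGraph(g)) {
    ## fast path: simple graphs need no auxiliary encoding
    nm <- igraph::V(g)$name
    colors <- if (is.null(vcolor)) rep(0L, length(nm)) else as.integer(vcolor[nm])
    enc <- list(graph = g, colors = colors)
  } else {
    enc <- auxEncoding(g, vcolor, ecolor)
  }
  n <- igraph::vcount(enc$graph)
  if (n == 0L) return("0|")
  perm <- igraph::canonical_permutation(enc$graph, colors = enc$colors)$labeling
  cg <- igraph::permute(enc$graph, perm)
  ccol <- integer(n)
  ccol[perm] <- enc$colors
  em <- igraph::as_edgelist(cg, names = FALSE)
  estr <- ""
  if (nrow(em) > 0L) {
    em <- t(apply(em, 1L, sort))
    em <- em[order(em[, 1L], em[, 2L]), , drop = FALSE]
    estr <- paste(em[, 1L], em[, 2L], sep = "-", collapse = ";")
  }
  paste0(n, "|", paste(ccol, collapse = ","), "|", estr)
}

#' Multigraph isomorphism
#'
#' @inheritParams canonicalKey
#' @param g1,g2 multigraphs.
#' @param vcolor1,vcolor2 optional vertex roles for each graph.
#' @return logical.
#' @export
isomorphicMultigraph <- function(g1, g2, vcolor1 = NULL, vcolor2 = NULL) {
  if (igraph::vcount(g1) != igraph::vcount(g2) || igraph::ecount(g1) != igraph::ecount(g2))
    return(FALSE)
  canonicalKey(g1, vcolor1) == canonicalKey(g2, vcolor2)
}

## canonical key of a network with exchangeable leaf labels
networkKey <- function(net) {
  g <- net@graph
  nm <- igraph::V(g)$name
  col <- stats::setNames(rep(0L, length(nm)), nm)
  col[unname(net@labels)] <- 1L
  canonicalKey(g, vcolor = col)
}
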