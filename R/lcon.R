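## The leaf connecting procedure: pre-processing, then all orders of joining
## leaf pairs (with the two-vertex gadget avoiding parallel edges, and the
## odd-last-leaf rule), producing annotated simple graphs without degree-1
## vertices.  Defined for networks that are not trees.

PROV_ORIGINAL <- "original"; PROV_PAIR <- "pair-join"
PROV_GADGET <- "gadget"; PROV_LAST <- "last-leaf"

#' Leaf-connect pre-processing
#'
#' While some inner vertex has two or more attached leaves, all but one of
#' those leaves (the lexicographically smallest label is kept) are deleted;
#' if the vertex then has degree 2 it is suppressed.  This suppression cannot
#' create parallel edges, which is asserted.  Repeats until stable.
#'
#' @param net a [PhyloNetwork-class] that is not a tree, with |X| >= 2.
#' @return the reduced [PhyloNetwork-class]; attribute \code{xr} holds the
#'   reduced leaf label set.
#' @export
lconPreprocess <- function(net) {
  stopifnot(is(net, "PhyloNetwork"))
  if (isTreeNetwork(net)) stop("lcon-undefined-for-trees")
  if (length(net@labels) < 2L) stop("leaf connecting requires |X| >= 2")
  g <- net@graph
  labels <- net@labels
  repeat {
    leaf2att <- vapply(unname(labels), function(v)
      igraph::V(g)$name[as.integer(igraph::neighbors(g, v))][1L], character(1))
    names(leaf2att) <- names(labels)
    tab <- table(leaf2att)
    multi <- names(tab)[tab >= 2L]
    if (length(multi) == 0L) break
    v <- multi[1L]
    here <- sort(names(leaf2att)[leaf2att == v])
    drop <- here[-1L]
    g <- igraph::delete_vertices(g, unname(labels[drop]))
    labels <- labels[setdiff(names(labels), drop)]
    if (igraph::degree(g, v, loops = TRUE) == 2L) {
      nb <- incidentEnds(g, v)
      g2 <- igraph::delete_vertices(g, v)
      stopifnot(!paste(min(nb), max(nb), sep = "|") %in% edgeKeys(g2))  # never parallel
      g <- igraph::add_edges(g2, nb)
    }
  }
  out <- newNetwork(g, labels)
  attr(out, "xr") <- sort(names(labels))
  out
}

freshVertex <- function(g, stem) {
  i <- 1L
  nm <- igraph::V(g)$name
  while (paste0(".", stem, i) %in% nm) i <- i + 1L
  paste0(".", stem, i)
}

addTaggedEdge <- function(g, u, v, tag) {
  g <- igraph::add_edges(g, c(u, v))
  igraph::set_edge_attr(g, "provenance", igraph::ecount(g), tag)
}

deleteEdgeBetween <- function(g, u, v) {
  idx <- which(edgeKeys(g) == paste(min(u, v), max(u, v), sep = "|"))
  stopifnot(length(idx) >= 1L)
  igraph::delete_edges(g, idx[1L])
}

adjacent <- function(g, u, v) paste(min(u, v), max(u, v), sep = "|") %in% edgeKeys(g)

## one pair-join step; returns list(graph, gadget = logical, newVertices)
joinPair <- function(g, x1, x2) {
  u1 <- igraph::V(g)$name[as.integer(igraph::neighbors(g, x1))][1L]
  u2 <- igraph::V(g)$name[as.integer(igraph::neighbors(g, x2))][1L]
  g <- igraph::delete_vertices(g, c(x1, x2))
  stopifnot(u1 != u2)
  if (adjacent(g, u1, u2)) {
    ## the joining edge would be parallel: replace both it and the existing
    ## edge by length-2 paths through fresh vertices a, b, plus edge {a,b}
    a <- freshVertex(g, "a"); g <- igraph::add_vertices(g, 1L, name = a)
    b <- freshVertex(g, "b"); g <- igraph::add_vertices(g, 1L, name = b)
    g <- deleteEdgeBetween(g, u1, u2)
    for (e in list(c(u1, a), c(a, u2), c(u1, b), c(b, u2), c(a, b)))
      g <- addTaggedEdge(g, e[1L], e[2L], PROV_GADGET)
    list(graph = g, gadget = TRUE, newVertices = c(a, b))
  } else {
    list(graph = addTaggedEdge(g, u1, u2, PROV_PAIR), gadget = FALSE, newVertices = character())
  }
}

## the odd-last-leaf rule; returns list(graph, newVertices)
removeLastLeaf <- function(g, x) {
  u <- igraph::V(g)$name[as.integer(igraph::neighbors(g, x))][1L]
  g <- igraph::delete_vertices(g, x)
  if (igraph::degree(g, u, loops = TRUE) != 2L) return(list(graph = g, newVertices = character()))
  nb <- incidentEnds(g, u)
  y <- nb[1L]; z <- nb[2L]
  if (!adjacent(g, y, z)) {
    ## plain suppression
    g2 <- igraph::delete_vertices(g, u)
    return(list(graph = addTaggedEdge(g2, y, z, PROV_LAST), newVertices = character()))
  }
  ## suppression would create a parallel edge: keep u on its two original
  ## edges, delete the pre-existing {y,z}, route it through a new vertex a,
  ## and connect u to a
  a <- freshVertex(g, "a")
  g <- igraph::add_vertices(g, 1L, name = a)
  g <- deleteEdgeBetween(g, y, z)
  for (e in list(c(y, a), c(a, z), c(u, a)))
    g <- addTaggedEdge(g, e[1L], e[2L], PROV_LAST)
  list(graph = g, newVertices = a)
}

#' Leaf connecting set LCON
#'
#' Enumerates every order of choosing leaf pairs (the order may alter the
#' result), applying the pair-join rule with its parallel-edge gadget and the
#' odd-last-leaf rule, after [lconPreprocess()].  Results are deduplicated up
#' to isomorphism respecting edge provenance.  Every output graph is simple,
#' has no degree-1 vertices, and has at most as many vertices as the input
#' network.
#'
#' @param net a [PhyloNetwork-class] that is not a tree, with |X| >= 2.
#' @param cap bound on the number of pair-order sequences explored; when
#'   exceeded the returned list carries attribute \code{incomplete = TRUE}.
#' @return list of [AnnotatedGraph-class] objects; attribute \code{xrSize}
#'   gives the reduced leaf count.
#' @export
lcon <- function(net, cap = 20000L) {
  pre <- lconPreprocess(net)
  xr <- attr(pre, "xr")
  g0 <- igraph::set_edge_attr(pre@graph, "provenance", value = PROV_ORIGINAL)
  inputVcount <- igraph::vcount(net@graph)
  results <- list()
  seenKeys <- new.env(parent = emptyenv())
  sequences <- 0L
  incomplete <- FALSE
  finish <- function(g, newV, pairGadget) {
    stopifnot(all(igraph::degree(g, loops = TRUE) != 1L), isSimpleGraph(g),
              igraph::vcount(g) <= inputVcount)
    provCode <- match(igraph::E(g)$provenance,
                      c(PROV_ORIGINAL, PROV_PAIR, PROV_GADGET, PROV_LAST)) - 1L
    key <- paste0(canonicalKey(g, ecolor = provCode), "|pg", pairGadget)
    if (!exists(key, envir = seenKeys, inherits = FALSE)) {
      assign(key, TRUE, envir = seenKeys)
      results[[length(results) + 1L]] <<- new("AnnotatedGraph", graph = g,
        newVertices = newV, pairGadget = pairGadget, xrSize = length(xr))
    }
  }
  recurse <- function(g, leaves, newV, pairGadget) {
    if (incomplete) return()
    if (length(leaves) == 0L) {
      sequences <<- sequences + 1L
      if (sequences > cap) { incomplete <<- TRUE; return() }
      finish(g, newV, pairGadget)
      return()
    }
    if (length(leaves) == 1L) {
      sequences <<- sequences + 1L
      if (sequences > cap) { incomplete <<- TRUE; return() }
      res <- removeLastLeaf(g, unname(leaves[1L]))
      finish(res$graph, c(newV, res$newVertices), pairGadget)
      return()
    }
    prs <- utils::combn(names(leaves), 2L, simplify = FALSE)
    for (p in prs) {
      res <- joinPair(g, unname(leaves[p[1L]]), unname(leaves[p[2L]]))
      recurse(res$graph, leaves[setdiff(names(leaves), p)],
              c(newV, res$newVertices), pairGadget || res$gadget)
      if (incomplete) return()
    }
  }
  recurse(g0, pre@labels, character(), FALSE)
  attr(results, "xrSize") <- length(xr)
  if (incomplete) attr(results, "incomplete") <- TRUE
  results
}

setMethod("show", "AnnotatedGraph", function(object) {
  tab <- table(igraph::E(object@graph)$provenance)
  cat(sprintf("AnnotatedGraph: %d vertices, %d edges (%s), |Xr|=%d%s\n",
              igraph::vcount(object@graph), igraph::ecount(object@graph),
              paste(names(tab), tab, sep = ":", collapse = ", "), object@xrSize,
              if (object@pairGadget) ", pair gadget used" else ""))
})

#' @describeIn lcon export an annotated graph to GraphML with the
#'   \code{provenance} edge attribute and an \code{xr_size} graph attribute.
#' @param ag an [AnnotatedGraph-class].
#' @param path output file.
#' @export
writeAnnotatedGraph <- function(ag, path) {
  g <- igraph::set_graph_attr(ag@graph, "xr_size", ag@xrSize)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
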