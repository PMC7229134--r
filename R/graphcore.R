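## Network validation and the block/blob decompositions every other module
## consumes.

networkViolations <- function(graph, labels) {
  bad <- list()
  add <- function(code, detail) bad[[length(bad) + 1L]] <<- data.frame(code = code, detail = detail)
  nm <- igraph::V(graph)$name
  if (is.null(nm)) {
    add("unnamed-vertices", "graph vertices must carry names")
    return(do.call(rbind, bad))
  }
  if (igraph::vcount(graph) > 0L && !igraph::is_connected(graph)) add("not-connected", "graph is not connected")
  if (hasParallel(graph)) {
    em <- edgeMatrix(graph)
    dup <- unique(paste(em[duplicated(paste(em[, 1], em[, 2])), 1L],
                        em[duplicated(paste(em[, 1], em[, 2])), 2L]))
    for (d in dup) add("parallel-edge", d)
  }
  if (hasLoop(graph)) {
    em <- edgeMatrix(graph)
    for (v in unique(em[em[, 1L] == em[, 2L], 1L])) add("loop", v)
  }
  deg <- igraph::degree(graph, loops = TRUE)
  for (v in nm[deg == 2L]) add("degree-2-vertex", v)
  leaves <- nm[deg == 1L]
  if (anyDuplicated(names(labels))) {
    for (d in unique(names(labels)[duplicated(names(labels))])) add("duplicate-label", d)
  }
  if (anyDuplicated(unname(labels))) {
    for (d in unique(unname(labels)[duplicated(unname(labels))])) add("duplicate-label", paste("vertex", d))
  }
  unknown <- setdiff(unname(labels), nm)
  for (v in unknown) add("labeled-non-leaf", paste("unknown vertex", v))
  lbl <- unname(labels)[unname(labels) %in% nm]
  for (v in setdiff(lbl, leaves)) add("labeled-non-leaf", v)
  for (v in setdiff(leaves, lbl)) add("unlabeled-leaf", v)
  if (length(bad) == 0L) data.frame(code = character(), detail = character())
  else do.call(rbind, bad)
}

#' Validate a labeled graph as a phylogenetic network
#'
#' Checks every clause of the definition of an unrooted phylogenetic network
#' (connected, simple, no degree-2 vertices, degree-1 vertices bijectively
#' labeled).  Violations are returned as data, not raised as conditions, so a
#' caller can report them all at once.
#'
#' @param graph a named \pkg{igraph} graph.
#' @param labels named character vector: taxon label -> leaf vertex name.
#' @return a [PhyloNetwork-class] when valid; otherwise a data.frame with
#'   columns \code{code} (one of not-connected, parallel-edge, loop,
#'   degree-2-vertex, unlabeled-leaf, labeled-non-leaf, duplicate-label) and
#'   \code{detail}.
#' @export
validateNetwork <- function(graph, labels) {
  labels <- stats::setNames(as.character(labels), names(labels))
  obj <- tryCatch(new("PhyloNetwork", graph = graph, labels = labels),
                  error = function(e) NULL)
  if (!is.null(obj)) return(obj)
  networkViolations(graph, labels)
}

newNetwork <- function(graph, labels) {
  res <- validateNetwork(graph, labels)
  if (!is(res, "PhyloNetwork"))
    stop("invalid network: ", paste(res$code, res$detail, sep = ":", collapse = ", "))
  res
}

#' @describeIn validateNetwork underlying graph accessor.
#' @param net a [PhyloNetwork-class].
#' @export
networkGraph <- function(net) net@graph

#' @describeIn validateNetwork taxon label -> leaf vertex map.
#' @export
leafLabels <- function(net) net@labels

#' @describeIn validateNetwork leaf vertex names.
#' @export
networkLeaves <- function(net) unname(net@labels)

#' @describeIn validateNetwork non-leaf vertex names.
#' @export
innerVertices <- function(net) setdiff(igraph::V(net@graph)$name, networkLeaves(net))

#' @describeIn validateNetwork edges not incident to a leaf, as a two-column
#'   matrix.
#' @export
innerEdges <- function(net) {
  em <- edgeMatrix(net@graph)
  lv <- networkLeaves(net)
  em[!(em[, 1L] %in% lv) & !(em[, 2L] %in% lv), , drop = FALSE]
}

#' @describeIn validateNetwork TRUE when every inner vertex has degree 3.
#' @export
isBinaryNetwork <- function(net) {
  iv <- innerVertices(net)
  length(iv) == 0L || all(igraph::degree(net@graph, iv) == 3L)
}

#' @describeIn validateNetwork TRUE when the network is a tree.
#' @export
isTreeNetwork <- function(net) {
  igraph::ecount(net@graph) == igraph::vcount(net@graph) - 1L
}

setMethod("show", "PhyloNetwork", function(object) {
  cat(sprintf("PhyloNetwork: %d vertices, %d edges, %d taxa (%s)%s\n",
              igraph::vcount(object@graph), igraph::ecount(object@graph),
              length(object@labels),
              paste(utils::head(sort(names(object@labels)), 6L), collapse = ","),
              if (isBinaryNetwork(object)) ", binary" else ""))
})

#' Block and blob decomposition of a connected graph
#'
#' Blocks are the maximal biconnected subgraphs; blobs are the maximal
#' connected subgraphs without a cut edge (computed as the components left
#' after deleting all cut edges).  A cut edge is trivial when one side of its
#' split is a single vertex; a blob is trivial when it is a single vertex.
#' Output is canonically ordered by sorted vertex ids so downstream results
#' are deterministic.
#'
#' @param g connected multigraph.
#' @return a [Decomposition-class].
#' @export
decomposeGraph <- function(g) {
  if (!igraph::is_connected(g)) stop("not-connected")
  nm <- igraph::V(g)$name
  arts <- sort(igraph::V(g)$name[as.integer(igraph::articulation_points(g))])
  bid <- igraph::bridges(g)
  em <- igraph::as_edgelist(g, names = TRUE)
  cutEdges <- data.frame(u = character(), v = character(), trivial = logical())
  if (length(bid)) {
    be <- em[as.integer(bid), , drop = FALSE]
    be <- t(apply(be, 1L, sort))
    deg <- igraph::degree(g, loops = TRUE)
    trivial <- deg[be[, 1L]] == 1L | deg[be[, 2L]] == 1L
    o <- order(be[, 1L], be[, 2L])
    cutEdges <- data.frame(u = be[o, 1L], v = be[o, 2L], trivial = unname(trivial[o]))
  }
  bc <- igraph::biconnected_components(g)
  blocks <- lapply(bc$components, function(vs) sort(igraph::V(g)$name[as.integer(vs)]))
  blocks <- blocks[order(vapply(blocks, `[`, character(1), 1L),
                         vapply(blocks, length, integer(1)))]
  gnb <- igraph::delete_edges(g, bid)
  comp <- igraph::components(gnb)
  blobs <- lapply(seq_len(comp$no), function(i) {
    vs <- sort(nm[comp$membership == i])
    list(vertices = vs, trivial = length(vs) == 1L)
  })
  blobs <- blobs[order(vapply(blobs, function(b) b$vertices[1L], character(1)))]
  new("Decomposition", cutVertices = arts, cutEdges = cutEdges,
      blocks = blocks, blobs = blobs)
}

setMethod("show", "Decomposition", function(object) {
  cat(sprintf("Decomposition: %d block(s), %d blob(s) (%d non-trivial), %d cut vertex/vertices, %d cut edge(s)\n",
              length(object@blocks), length(object@blobs),
              sum(!vapply(object@blobs, `[[`, logical(1), "trivial")),
              length(object@cutVertices), nrow(object@cutEdges)))
})

nontrivialBlobs <- function(dec) Filter(function(b) !b$trivial, dec@blobs)

#' Properness of a phylogenetic network
#'
#' A network is proper when removing any cut edge or cut vertex leaves
#' connected components that each contain at least one labeled leaf.
#'
#' @param net a [PhyloNetwork-class].
#' @return TRUE, or FALSE carrying attributes \code{cutElement} (the
#'   offending cut vertex or edge) and \code{component} (a leafless component
#'   witness).
#' @export
isProper <- function(net) {
  g <- net@graph
  leaves <- networkLeaves(net)
  nm <- igraph::V(g)$name
  dec <- decomposeGraph(g)
  componentLeafless <- function(gg) {
    comp <- igraph::components(gg)
    vn <- igraph::V(gg)$name
    for (i in seq_len(comp$no)) {
      vs <- vn[comp$membership == i]
      if (!any(vs %in% leaves)) return(vs)
    }
    NULL
  }
  for (v in dec@cutVertices) {
    bad <- componentLeafless(igraph::delete_vertices(g, v))
    if (!is.null(bad)) {
      out <- FALSE
      attr(out, "cutElement") <- v
      attr(out, "component") <- bad
      return(out)
    }
  }
  if (nrow(dec@cutEdges)) {
    for (i in seq_len(nrow(dec@cutEdges))) {
      u <- dec@cutEdges$u[i]; v <- dec@cutEdges$v[i]
      ek <- edgeKeys(g)
      gg <- igraph::delete_edges(g, which(ek == paste(min(u, v), max(u, v), sep = "|"))[1L])
      bad <- componentLeafless(gg)
      if (!is.null(bad)) {
        out <- FALSE
        attr(out, "cutElement") <- c(u, v)
        attr(out, "component") <- bad
        return(out)
      }
    }
  }
  TRUE
}

## fast properness check on a connected simple graph given its edge matrix
## and leaf vertex set; pure integer BFS, no witnesses (used by enumeration)
properFast <- function(em, leaves, nm) {
  n <- length(nm)
  id <- stats::setNames(seq_len(n), nm)
  ea <- id[em[, 1L]]; eb <- id[em[, 2L]]
  isLeaf <- nm %in% leaves
  ## with a single leaf, removing its pendant cut edge leaves a leafless side
  if (sum(isLeaf) == 1L && n > 1L) return(FALSE)
  adj <- vector("list", n)
  for (i in seq_along(ea)) {
    adj[[ea[i]]] <- c(adj[[ea[i]]], eb[i])
    adj[[eb[i]]] <- c(adj[[eb[i]]], ea[i])
  }
  deg <- lengths(adj)
  comps <- function(drop, skipEdge = NULL) {
    alive <- setdiff(seq_len(n), drop)
    unseen <- rep(TRUE, n); unseen[drop] <- FALSE
    out <- list()
    for (s in alive) {
      if (!unseen[s]) next
      comp <- s; unseen[s] <- FALSE; frontier <- s
      while (length(frontier)) {
        nxt <- integer(0)
        for (u in frontier) for (w in adj[[u]]) {
          if (!unseen[w]) next
          if (!is.null(skipEdge) &&
              ((u == skipEdge[1L] && w == skipEdge[2L]) || (u == skipEdge[2L] && w == skipEdge[1L]))) next
          unseen[w] <- FALSE; nxt <- c(nxt, w)
        }
        comp <- c(comp, nxt); frontier <- nxt
      }
      out[[length(out) + 1L]] <- comp
    }
    out
  }
  for (v in which(deg >= 2L)) {
    cc <- comps(v)
    if (length(cc) >= 2L && !all(vapply(cc, function(c0) any(isLeaf[c0]), logical(1))))
      return(FALSE)
  }
  for (i in seq_along(ea)) {
    if (isLeaf[ea[i]] || isLeaf[eb[i]]) next
    cc <- comps(integer(0), skipEdge = c(ea[i], eb[i]))
    if (length(cc) >= 2L && !all(vapply(cc, function(c0) any(isLeaf[c0]), logical(1))))
      return(FALSE)
  }
  TRUE
}

#' Simple network test
#'
#' A network is a simple network when all of its cut edges are trivial, i.e.
#' every bridge has a leaf on one side.
#'
#' @param net a [PhyloNetwork-class].
#' @return logical.
#' @export
isSimpleNetwork <- function(net) {
  dec <- decomposeGraph(net@graph)
  nrow(dec@cutEdges) == 0L || all(dec@cutEdges$trivial)
}
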