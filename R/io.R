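## File formats: GraphML and TSV edge lists for networks, GraphML for support
## trees, Newick for base trees, JSON for reports and traces; plus the thin
## command-line front end.

#' Read a phylogenetic network from disk
#'
#' GraphML files carry taxon labels in a \code{taxon} vertex attribute
#' (non-empty on leaves).  The TSV dialect is one edge per line
#' (\code{u<TAB>v}) with labels in a sidecar file of \code{leaf<TAB>label}
#' lines.  Input is validated; violations are reported in the error.
#'
#' @param path input file.
#' @param format "graphml" or "tsv".
#' @param labelsPath sidecar label file (TSV format; defaults to
#'   \code{<path>.labels.tsv}).
#' @return a [PhyloNetwork-class].
#' @export
readNetwork <- function(path, format = c("graphml", "tsv"), labelsPath = NULL) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    taxa <- igraph::vertex_attr(g, "taxon")
    if (is.null(taxa)) stop("GraphML file lacks the 'taxon' vertex attribute")
    keep <- !is.na(taxa) & taxa != ""
    labels <- stats::setNames(igraph::V(g)$name[keep], taxa[keep])
    g <- igraph::delete_vertex_attr(g, "taxon")
    if (!is.null(igraph::vertex_attr(g, "id"))) g <- igraph::delete_vertex_attr(g, "id")
  } else {
    em <- utils::read.table(path, sep = "\t", header = FALSE,
                            colClasses = "character", comment.char = "#")
    if (ncol(em) != 2L) stop("TSV edge list must have two columns")
    g <- multigraph(as.matrix(em))
    if (is.null(labelsPath)) labelsPath <- paste0(path, ".labels.tsv")
    lm <- utils::read.table(labelsPath, sep = "\t", header = FALSE,
                            colClasses = "character", comment.char = "#")
    labels <- stats::setNames(lm[[1L]], lm[[2L]])
  }
  res <- validateNetwork(g, labels)
  if (!is(res, "PhyloNetwork"))
    stop("invalid network in ", path, ": ",
         paste(res$code, res$detail, sep = ":", collapse = ", "))
  res
}

#' @describeIn readNetwork write a network (same formats; TSV writes the
#'   sidecar label file alongside).
#' @param net a [PhyloNetwork-class].
#' @export
writeNetwork <- function(net, path, format = c("graphml", "tsv"), labelsPath = NULL) {
  format <- match.arg(format)
  g <- net@graph
  if (format == "graphml") {
    taxa <- rep("", igraph::vcount(g))
    taxa[match(unname(net@labels), igraph::V(g)$name)] <- names(net@labels)
    g <- igraph::set_vertex_attr(g, "taxon", value = taxa)
    igraph::write_graph(g, path, format = "graphml")
  } else {
    em <- edgeMatrix(g)
    utils::write.table(em, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    if (is.null(labelsPath)) labelsPath <- paste0(path, ".labels.tsv")
    utils::write.table(data.frame(unname(net@labels), names(net@labels)), labelsPath,
                       sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Export trees
#'
#' Support trees keep network vertex ids and are written as GraphML; base
#' trees are labeled trees over X and are written as Newick (via \pkg{ape}).
#'
#' @param st a [SupportTree-class].
#' @param path output file.
#' @export
writeSupportTree <- function(st, path) {
  igraph::write_graph(st@tree, path, format = "graphml")
  invisible(path)
}

#' @describeIn writeSupportTree Newick string of the base tree (built as an
#'   \pkg{ape} \code{phylo} object rooted at an inner vertex and written with
#'   \code{ape::write.tree}).
#' @export
baseTreeNewick <- function(st) {
  bt <- baseTree(st)
  nm <- igraph::V(bt)$name
  lab <- stats::setNames(names(st@labels), unname(st@labels))
  tips <- nm[igraph::degree(bt) == 1L]
  if (igraph::vcount(bt) == 2L)   # two taxa on one edge: no internal node
    return(paste0("(", lab[tips[1L]], ",", lab[tips[2L]], ");"))
  inner <- setdiff(nm, tips)
  id <- c(stats::setNames(seq_along(tips), tips),
          stats::setNames(length(tips) + seq_along(inner), inner))
  edges <- matrix(0L, 0L, 2L)
  walk <- function(v, parent) {
    for (w in igraph::V(bt)$name[as.integer(igraph::neighbors(bt, v))]) {
      if (!is.null(parent) && w == parent) next
      edges <<- rbind(edges, c(id[[v]], id[[w]]))
      walk(w, v)
    }
  }
  walk(inner[1L], NULL)
  phy <- structure(list(edge = edges, tip.label = unname(lab[tips]),
                        Nnode = length(inner)), class = "phylo")
  ape::write.tree(phy)
}

## ---- command-line interface ------------------------------------------------

cliUsage <- paste(
  "usage: phynetclass <command> [options] [file]",
  "commands:",
  "  validate <net>                 validate a network file",
  "  classify <net>                 full classification report (JSON)",
  "  reduce {lcut|ls|lcon} <net>    run a reduction procedure",
  "  support-tree <net>             constructive support tree (edge-based input)",
  "  toughness <net>                toughness of the leaf cut graph",
  "  generate {gsp|tree|chordal}    emit a random network (GraphML to --out)",
  "  enumerate                      enumerate small proper networks",
  "options: --format graphml|tsv  --cap N  --seed N  --out FILE",
  "         --max-inner N --max-leaves N --size N", sep = "\n")

cliOpt <- function(args, name, default = NULL) {
  i <- which(args == paste0("--", name))
  if (length(i) == 0L) return(default)
  if (i[1L] == length(args)) stop("missing value for --", name)
  args[i[1L] + 1L]
}

cliPositional <- function(args) {
  drop <- integer(0)
  i <- 1L
  while (i <= length(args)) {
    if (startsWith(args[i], "--")) { drop <- c(drop, i, i + 1L); i <- i + 2L }
    else i <- i + 1L
  }
  if (length(drop)) args[-drop] else args
}

emitJSON <- function(x) cat(jsonlite::toJSON(x, auto_unbox = TRUE, na = "null", digits = NA), "\n")

#' Command-line entry point
#'
#' Thin wrapper over the package's functions; JSON reports go to stdout.
#' Exit codes: 0 success, 1 error (including usage errors), 2 indeterminate
#' (a brute-force cap was hit).  A ready-to-use Rscript launcher is installed
#' at \code{system.file("scripts", "phynetclass", package = "phynetclass")}.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit code, invisibly.
#' @export
phynetCLI <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    pos <- cliPositional(args)
    if (length(pos) == 0L) { message(cliUsage); return(invisible(1L)) }
    cmd <- pos[1L]
    fmt <- cliOpt(args, "format", "graphml")
    cap <- as.numeric(cliOpt(args, "cap", "2e6"))
    seed <- as.integer(cliOpt(args, "seed", "1"))
    out <- cliOpt(args, "out")
    loadNet <- function() readNetwork(pos[length(pos)], format = fmt)
    switch(cmd,
      validate = {
        net <- loadNet()
        emitJSON(list(schema = 1L, valid = TRUE,
                      vertices = igraph::vcount(net@graph),
                      edges = igraph::ecount(net@graph),
                      taxa = sort(names(net@labels))))
        0L
      },
      classify = {
        rep <- classifyNetwork(loadNet(), cap = cap)
        emitJSON(list(schema = 1L, flags = rep@flags, method = rep@method,
                      cap = cap, caps_hit = rep@capsHit))
        if (length(rep@capsHit)) 2L else 0L
      },
      reduce = {
        what <- pos[2L]
        net <- loadNet()
        switch(what,
          lcut = {
            g <- suppressWarnings(lcut(net))
            emitJSON(list(schema = 1L, procedure = "lcut", vertices = igraph::vcount(g),
                          edges = edgeMatrix(g)))
            0L
          },
          ls = {
            tr <- leafShrink(net)
            emitJSON(list(schema = 1L, procedure = "leaf-shrink", steps = tr@steps,
                          final_vertices = igraph::vcount(tr@final),
                          final_edges = edgeMatrix(tr@final),
                          edge_based = isK2(tr@final)))
            0L
          },
          lcon = {
            set <- lcon(net, cap = cap)
            emitJSON(list(schema = 1L, procedure = "lcon", cap = cap,
                          xr_size = attr(set, "xrSize"),
                          incomplete = isTRUE(attr(set, "incomplete")),
                          graphs = lapply(set, function(ag)
                            list(vertices = igraph::vcount(ag@graph),
                                 pair_gadget = ag@pairGadget,
                                 edges = cbind(edgeMatrix(ag@graph),
                                               igraph::E(ag@graph)$provenance)))))
            if (isTRUE(attr(set, "incomplete"))) 2L else 0L
          },
          stop("unknown reduction: ", what))
      },
      "support-tree" = {
        net <- loadNet()
        st <- supportTreeEdgeBased(net)
        if (!is.null(out)) writeSupportTree(st, out)
        emitJSON(list(schema = 1L, tree_edges = edgeMatrix(st@tree),
                      base_tree_newick = baseTreeNewick(st)))
        0L
      },
      toughness = {
        net <- loadNet()
        tg <- suppressWarnings(lcut(net))
        t <- graphToughness(tg)
        emitJSON(list(schema = 1L, toughness = if (is.na(t)) NULL else unclass(t),
                      cap_hit = is.na(t)))
        if (is.na(t)) 2L else 0L
      },
      generate = {
        kind <- pos[2L]
        size <- as.integer(cliOpt(args, "size", "4"))
        net <- switch(kind,
          gsp = genGspNetwork(nPieces = size, seed = seed),
          tree = genTreePlusEdges(nLeaves = size, kExtra = 2L, seed = seed)$network,
          chordal = genBinaryChordal(nBlobs = size, seed = seed),
          stop("unknown generator: ", kind))
        if (is.null(out)) stop("generate requires --out")
        writeNetwork(net, out, format = fmt)
        emitJSON(list(schema = 1L, generator = kind, seed = seed,
                      vertices = igraph::vcount(net@graph), taxa = length(net@labels)))
        0L
      },
      enumerate = {
        mi <- as.integer(cliOpt(args, "max-inner", "3"))
        ml <- as.integer(cliOpt(args, "max-leaves", "4"))
        nets <- enumerateNetworks(mi, ml)
        emitJSON(list(schema = 1L, max_inner = mi, max_leaves = ml,
                      count = length(nets),
                      networks = lapply(nets, function(n) edgeMatrix(n@graph))))
        0L
      },
      { message(cliUsage); 1L })
  }, error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(as.integer(status))
}
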