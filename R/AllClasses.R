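#' @import methods
NULL

setOldClass("igraph")

#' Phylogenetic network class
#'
#' An unrooted phylogenetic network on a taxon set X: a connected simple graph
#' with no degree-2 vertices whose degree-1 vertices (the leaves) are
#' bijectively labeled by X.  Construct with [validateNetwork()], which checks
#' every clause of the definition and reports violations as data.
#'
#' @slot graph the underlying \pkg{igraph} graph (simple, connected).
#' @slot labels named character vector mapping taxon labels to leaf vertex
#'   names.
#' @aliases PhyloNetwork
#' @export
setClass("PhyloNetwork", representation(graph = "igraph", labels = "character"))

setValidity("PhyloNetwork", function(object) {
  v <- networkViolations(object@graph, object@labels)
  if (nrow(v) == 0L) TRUE else paste(v$code, v$detail, sep = ": ", collapse = "; ")
})

#' Reduction trace class
#'
#' A certificate for a sequence of restriction operations: replaying
#' \code{steps} from \code{initial} reproduces \code{final} exactly.
#'
#' @slot initial,final multigraphs before and after the reduction.
#' @slot steps data.frame of applied operations (kind, t1, t2).
#' @aliases ReductionTrace
#' @export
setClass("ReductionTrace",
  representation(initial = "igraph", steps = "data.frame", final = "igraph"))

newReductionTrace <- function(initial, steps, final) {
  new("ReductionTrace", initial = initial, steps = steps, final = final)
}

#' Block/blob decomposition class
#'
#' @slot cutVertices character vector of articulation vertices.
#' @slot cutEdges data.frame (u, v, trivial): bridges, flagged trivial when
#'   one side of the split is a single vertex.
#' @slot blocks list of vertex-name vectors, the maximal biconnected
#'   subgraphs.
#' @slot blobs data.frame-free list of lists with elements \code{vertices}
#'   and \code{trivial}; blobs are the maximal cut-edge-free connected
#'   subgraphs, trivial when a single vertex.
#' @aliases Decomposition
#' @export
setClass("Decomposition",
  representation(cutVertices = "character", cutEdges = "data.frame",
                 blocks = "list", blobs = "list"))

#' GSP / SP recognition certificate
#'
#' @slot verdict logical.
#' @slot route "reduction" (operation trace ending in a single edge) or
#'   "block-sp" (per-block series-parallel verdicts).
#' @slot trace a [ReductionTrace-class] or a list of block certificates.
#' @slot terminals the final edge's endpoints when the verdict is true via
#'   reduction.
#' @aliases GspCertificate
#' @export
setClass("GspCertificate",
  representation(verdict = "logical", route = "character", trace = "ANY",
                 terminals = "character"))

#' Leaf-connect output graph with edge provenance
#'
#' One member of the leaf connecting set LCON: a simple graph without
#' degree-1 vertices whose edges carry provenance tags
#' (\code{original}, \code{pair-join}, \code{gadget}, \code{last-leaf}).
#'
#' @slot graph simple \pkg{igraph} graph with edge attribute
#'   \code{provenance}.
#' @slot newVertices gadget vertices added during construction.
#' @slot pairGadget TRUE when some pair join required the two-vertex gadget
#'   that avoids parallel edges.
#' @slot xrSize size of the reduced leaf set after pre-processing.
#' @aliases AnnotatedGraph
#' @export
setClass("AnnotatedGraph",
  representation(graph = "igraph", newVertices = "character",
                 pairGadget = "logical", xrSize = "integer"))

#' Support tree class
#'
#' A spanning tree of a phylogenetic network whose leaf set equals the
#' network's taxon set X.  The base tree is obtained by suppressing degree-2
#' vertices; see [baseTree()].
#'
#' @slot tree spanning tree as an \pkg{igraph} graph on the network's
#'   vertices.
#' @slot labels the network's taxon-to-leaf map.
#' @aliases SupportTree
#' @export
setClass("SupportTree", representation(tree = "igraph", labels = "character"))

#' Per-network classification report
#'
#' Records every class membership computed by [classifyNetwork()] together
#' with witnesses (support tree, Hamiltonian paths, reduction traces) and the
#' brute-force caps that were hit.  Any true sufficient criterion forces
#' \code{treeBased} to TRUE.
#'
#' @slot flags named list of logicals (NA = indeterminate).
#' @slot method how tree-basedness was established.
#' @slot witnesses named list of witness objects.
#' @slot capsHit character vector of computations that hit their cap.
#' @aliases ClassificationReport
#' @export
setClass("ClassificationReport",
  representation(flags = "list", method = "character", witnesses = "list",
                 capsHit = "character"))
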