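#' @import methods
NULL

.PROVENANCE_TAGS <- c("ground-truth", "individualized", "inferred-FA", "inferred-RJ")

#' SemanticNetwork: an undirected, weighted, labeled graph
#'
#' The central container of the package. Nodes are words (opaque strings,
#' stored in lexicographic order); edges are unordered node pairs with a
#' strictly positive real weight. A pair without a stored edge has weight 0.
#' The `provenance` tag records which pipeline stage produced the network.
#'
#' @slot nodes character vector of node identifiers, lexicographically sorted,
#'   no duplicates.
#' @slot edges data.frame with columns `node_i`, `node_j`, `weight`; one row
#'   per unordered pair with `node_i < node_j` and `weight > 0`.
#' @slot provenance one of `"ground-truth"`, `"individualized"`,
#'   `"inferred-FA"`, `"inferred-RJ"`.
#'
#' @seealso [semanticNetwork()], [inducedSubgraph()], [measurePanel()]
#' @export
setClass("SemanticNetwork",
  slots = c(nodes = "character", edges = "data.frame", provenance = "character")
)

setValidity("SemanticNetwork", function(object) {
  msg <- character()
  nd <- object@nodes
  if (anyDuplicated(nd)) msg <- c(msg, "duplicate node identifiers")
  if (is.unsorted(nd)) msg <- c(msg, "nodes must be lexicographically sorted")
  ed <- object@edges
  if (!identical(colnames(ed), c("node_i", "node_j", "weight"))) {
    msg <- c(msg, "edges must have columns node_i, node_j, weight")
  } else if (nrow(ed) > 0) {
    if (!all(ed$node_i %in% nd) || !all(ed$node_j %in% nd)) {
      msg <- c(msg, "edge endpoints must be nodes of the network")
    }
    if (any(ed$node_i == ed$node_j)) msg <- c(msg, "self-loops are not allowed")
    if (any(ed$node_i > ed$node_j)) msg <- c(msg, "edges must be stored with node_i < node_j")
    if (anyDuplicated(paste(ed$node_i, ed$node_j, sep = "\r"))) {
      msg <- c(msg, "duplicate edges")
    }
    if (!is.numeric(ed$weight) || any(!is.finite(ed$weight)) || any(ed$weight <= 0)) {
      msg <- c(msg, "edge weights must be finite and strictly positive")
    }
  }
  if (length(object@provenance) != 1L ||
      !object@provenance %in% .PROVENANCE_TAGS) {
    msg <- c(msg, sprintf(
      "provenance must be one of: %s", paste(.PROVENANCE_TAGS, collapse = ", ")
    ))
  }
  if (length(msg)) msg else TRUE
})

#' Lexicon: a vocabulary with relative word frequencies
#'
#' Holds the relative frequency of each word (the global retrieval bias in the
#' free-association response model). Frequencies are strictly positive and sum
#' to one.
#'
#' @slot freq named numeric vector of relative frequencies.
#' @seealso [lexicon()], [synthFrequencies()], [faDistribution()]
#' @export
setClass("Lexicon", slots = c(freq = "numeric"))

setValidity("Lexicon", function(object) {
  f <- object@freq
  msg <- character()
  if (is.null(names(f)) || anyDuplicated(names(f))) {
    msg <- c(msg, "frequencies must be uniquely named by word")
  }
  if (any(!is.finite(f)) || any(f <= 0)) msg <- c(msg, "frequencies must be positive")
  if (length(f) && abs(sum(f) - 1) > 1e-9) msg <- c(msg, "frequencies must sum to 1 (within 1e-9)")
  if (length(msg)) msg else TRUE
})

#' CueSet: an ordered list of cue words for a study design
#'
#' @slot cues character vector of distinct node identifiers, in the order
#'   they were generated.
#' @slot type one of `"narrow"`, `"broad"`, `"mixed"`.
#' @slot seed integer seed the generator was called with.
#' @seealso [narrowCues()], [broadCues()], [mixedCues()]
#' @export
setClass("CueSet",
  slots = c(cues = "character", type = "character", seed = "integer")
)

setValidity("CueSet", function(object) {
  msg <- character()
  if (anyDuplicated(object@cues)) msg <- c(msg, "cues must be distinct")
  if (length(object@type) != 1L || !object@type %in% c("narrow", "broad", "mixed")) {
    msg <- c(msg, "type must be narrow, broad or mixed")
  }
  if (length(msg)) msg else TRUE
})

#' MeasurePanel: the six structural measures of one network
#'
#' Within-network measures (`edgeWeights`, `nodeStrengths`) are vectors;
#' between-network measures (`averageStrength`, `aspl`, `averageCC`,
#' `modularity`) are scalars. Measures that are undefined on a given network
#' (e.g. ASPL with no connected pair, clustering with no node of degree >= 2,
#' modularity of an edgeless graph) are stored as `NA`.
#'
#' @slot edgeWeights named numeric vector (names `"i|j"`, `i < j`).
#' @slot nodeStrengths named numeric vector over all nodes.
#' @slot averageStrength,aspl,averageCC,modularity numeric scalars (or `NA`).
#' @seealso [measurePanel()]
#' @export
setClass("MeasurePanel",
  slots = c(
    edgeWeights = "numeric", nodeStrengths = "numeric",
    averageStrength = "numeric", aspl = "numeric",
    averageCC = "numeric", modularity = "numeric"
  )
)

setValidity("MeasurePanel", function(object) {
  ok <- isTRUE(all.equal(
    unname(object@averageStrength),
    mean(object@nodeStrengths),
    tolerance = 1e-9
  ))
  if (length(object@nodeStrengths) && !ok) {
    "averageStrength must equal mean(nodeStrengths)"
  } else TRUE
})
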