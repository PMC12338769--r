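#' Construct a SemanticNetwork
#'
#' @param edges data.frame (or coercible) with columns `node_i`, `node_j`,
#'   `weight`. Rows are unordered pairs; symmetric duplicates with identical
#'   weights collapse to one edge, conflicting duplicates are an error.
#'   Zero-weight rows are dropped (weight 0 means "no edge").
#' @param nodes optional character vector of node identifiers; defaults to the
#'   endpoints occurring in `edges`. Extra nodes become isolated nodes.
#' @param provenance provenance tag, one of `"ground-truth"`,
#'   `"individualized"`, `"inferred-FA"`, `"inferred-RJ"`.
#'
#' @return A [SemanticNetwork-class] object.
#' @examples
#' tri <- semanticNetwork(data.frame(
#'   node_i = c("a", "a", "b"), node_j = c("b", "c", "c"), weight = 0.5
#' ))
#' numEdges(tri)
#' @export
semanticNetwork <- function(edges = NULL, nodes = NULL,
                            provenance = "ground-truth") {
  if (is.null(edges)) {
    edges <- data.frame(node_i = character(), node_j = character(),
                        weight = numeric())
  }
  edges <- as.data.frame(edges)
  if (ncol(edges) < 3) stop("edges must have three columns: node_i, node_j, weight")
  edges <- edges[, 1:3]
  colnames(edges) <- c("node_i", "node_j", "weight")
  edges$node_i <- as.character(edges$node_i)
  edges$node_j <- as.character(edges$node_j)
  if (!is.numeric(edges$weight)) stop("edge weights must be numeric")
  if (any(edges$node_i == edges$node_j)) stop("self-loops are not allowed")
  ## canonical orientation node_i < node_j
  flip <- edges$node_i > edges$node_j
  if (any(flip)) {
    tmp <- edges$node_i[flip]
    edges$node_i[flip] <- edges$node_j[flip]
    edges$node_j[flip] <- tmp
  }
  key <- paste(edges$node_i, edges$node_j, sep = "\r")
  if (anyDuplicated(key)) {
    w_by_key <- split(edges$weight, key)
    bad <- vapply(w_by_key, function(w) diff(range(w)) > 0, logical(1))
    if (any(bad)) {
      stop("conflicting duplicate weights for pair(s): ",
           paste(gsub("\r", "--", names(w_by_key)[bad]), collapse = ", "))
    }
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  edges <- edges[edges$weight != 0, , drop = FALSE]
  if (is.null(nodes)) nodes <- union(edges$node_i, edges$node_j)
  nodes <- sort(unique(as.character(nodes)))
  edges <- edges[order(edges$node_i, edges$node_j), , drop = FALSE]
  rownames(edges) <- NULL
  new("SemanticNetwork", nodes = nodes, edges = edges, provenance = provenance)
}

#' @describeIn semanticNetwork nodes of the network (sorted)
#' @param net,object a `SemanticNetwork`
#' @export
setGeneric("nodes", function(object) standardGeneric("nodes"))

#' @rdname semanticNetwork
#' @export
setMethod("nodes", "SemanticNetwork", function(object) object@nodes)

#' @describeIn semanticNetwork edge table (`node_i`, `node_j`, `weight`)
#' @export
setGeneric("edgeTable", function(object) standardGeneric("edgeTable"))

#' @rdname semanticNetwork
#' @export
setMethod("edgeTable", "SemanticNetwork", function(object) object@edges)

#' @describeIn semanticNetwork provenance tag
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))

#' @rdname semanticNetwork
#' @export
setMethod("provenance", "SemanticNetwork", function(object) object@provenance)

#' @describeIn semanticNetwork number of nodes
#' @export
numNodes <- function(net) length(net@nodes)

#' @describeIn semanticNetwork number of (undirected) edges
#' @export
numEdges <- function(net) nrow(net@edges)

#' @describeIn semanticNetwork total edge weight (each pair counted once)
#' @export
totalWeight <- function(net) sum(net@edges$weight)

#' @describeIn semanticNetwork weight of the pair (i, j); 0 if no edge
#' @param i,j node identifiers
#' @export
edgeWeight <- function(net, i, j) {
  stopifnot(is(net, "SemanticNetwork"))
  lo <- pmin(i, j); hi <- pmax(i, j)
  key <- paste(lo, hi, sep = "\r")
  w <- stats::setNames(net@edges$weight,
                       paste(net@edges$node_i, net@edges$node_j, sep = "\r"))
  out <- unname(w[key])
  out[is.na(out)] <- 0
  out
}

setMethod("show", "SemanticNetwork", function(object) {
  cat(sprintf("SemanticNetwork (%s): %d nodes, %d edges\n",
              object@provenance, numNodes(object), numEdges(object)))
  if (numEdges(object) > 0) {
    cat(sprintf("  weight range: [%.4g, %.4g], total %.4g\n",
                min(object@edges$weight), max(object@edges$weight),
                totalWeight(object)))
  }
})

setMethod("show", "Lexicon", function(object) {
  cat(sprintf("Lexicon: %d words, frequencies sum to %.6f\n",
              length(object@freq), sum(object@freq)))
})

setMethod("show", "CueSet", function(object) {
  cat(sprintf("CueSet (%s, seed %d): %d cues\n",
              object@type, object@seed, length(object@cues)))
  cat("  ", paste(utils::head(object@cues, 8), collapse = ", "),
      if (length(object@cues) > 8) ", ..." else "", "\n", sep = "")
})

setMethod("show", "MeasurePanel", function(object) {
  cat("MeasurePanel\n")
  cat(sprintf("  average strength: %s\n", format(object@averageStrength)))
  cat(sprintf("  ASPL:             %s\n", format(object@aspl)))
  cat(sprintf("  average CC:       %s\n", format(object@averageCC)))
  cat(sprintf("  modularity:       %s\n", format(object@modularity)))
  cat(sprintf("  %d edge weights, %d node strengths\n",
              length(object@edgeWeights), length(object@nodeStrengths)))
})

## ---- internal helpers -------------------------------------------------

## dense symmetric adjacency matrix, dimnames = nodes
.adjacency <- function(net) {
  n <- numNodes(net)
  A <- matrix(0, n, n, dimnames = list(net@nodes, net@nodes))
  if (numEdges(net) > 0) {
    ii <- match(net@edges$node_i, net@nodes)
    jj <- match(net@edges$node_j, net@nodes)
    A[cbind(ii, jj)] <- net@edges$weight
    A[cbind(jj, ii)] <- net@edges$weight
  }
  A
}

## build a SemanticNetwork from a symmetric adjacency matrix
.fromAdjacency <- function(A, provenance = "ground-truth") {
  nd <- rownames(A)
  ut <- upper.tri(A)
  keep <- which(ut & A != 0, arr.ind = TRUE)
  edges <- data.frame(
    node_i = nd[keep[, 1]], node_j = nd[keep[, 2]],
    weight = A[keep], stringsAsFactors = FALSE
  )
  semanticNetwork(edges, nodes = nd, provenance = provenance)
}

.asIgraph <- function(net) {
  g <- igraph::make_empty_graph(n = numNodes(net), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = net@nodes)
  if (numEdges(net) > 0) {
    g <- igraph::add_edges(g, rbind(net@edges$node_i, net@edges$node_j),
                           weight = net@edges$weight)
  }
  g
}

## neighbor lookup: named list node -> data.frame(neighbor, weight)
.neighborList <- function(net) {
  ed <- net@edges
  nb <- stats::setNames(vector("list", numNodes(net)), net@nodes)
  for (nm in net@nodes) nb[[nm]] <- list(neighbor = character(), weight = numeric())
  if (nrow(ed) > 0) {
    both <- data.frame(
      from = c(ed$node_i, ed$node_j), to = c(ed$node_j, ed$node_i),
      weight = c(ed$weight, ed$weight), stringsAsFactors = FALSE
    )
    sp <- split(both[c("to", "weight")], both$from)
    for (nm in names(sp)) {
      nb[[nm]] <- list(neighbor = sp[[nm]]$to, weight = sp[[nm]]$weight)
    }
  }
  nb
}

## sample() without the length-1 surprise
.resample <- function(x, size = 1, prob = NULL, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

## derive a child seed from a master seed and integer indices, < 2^31
.deriveSeed <- function(master, ...) {
  idx <- c(...)
  s <- as.double(master)
  for (k in seq_along(idx)) {
    s <- (s * 69069 + as.double(idx[k]) * 7919 + 1) %% 2147483629
  }
  as.integer(s)
}

## ---- subgraphs and triangle scores ------------------------------------

#' Induced subgraph on a node subset
#'
#' Restricts a network to the given nodes, keeping exactly the edges with both
#' endpoints in the subset, weights unchanged. Used to build the local
#' (cue-set) reference networks for recovery evaluation.
#'
#' @param net a [SemanticNetwork-class]
#' @param nodeSet character vector of node identifiers, all present in `net`
#' @return A [SemanticNetwork-class] on `nodeSet` (same provenance).
#' @export
inducedSubgraph <- function(net, nodeSet) {
  stopifnot(is(net, "SemanticNetwork"))
  nodeSet <- unique(as.character(nodeSet))
  unknown <- setdiff(nodeSet, net@nodes)
  if (length(unknown)) {
    stop("unknown node identifier(s): ", paste(unknown, collapse = ", "))
  }
  ed <- net@edges
  keep <- ed$node_i %in% nodeSet & ed$node_j %in% nodeSet
  semanticNetwork(ed[keep, , drop = FALSE], nodes = nodeSet,
                  provenance = net@provenance)
}

#' Per-edge triangle scores
#'
#' The triangle score of an edge is the sum, over all triangles the edge is
#' part of, of the product of the three edge weights of the triangle. It
#' quantifies how much an edge contributes to local clustering and steers the
#' individualization algorithm ([perturbNetwork()]) toward (or away from)
#' clustering-relevant edges. An edge in no triangle scores 0.
#'
#' @param net a [SemanticNetwork-class]
#' @return data.frame `node_i`, `node_j`, `score`, aligned with
#'   `edgeTable(net)`.
#' @export
triangleScores <- function(net) {
  stopifnot(is(net, "SemanticNetwork"))
  ed <- net@edges
  if (nrow(ed) == 0) {
    return(data.frame(node_i = character(), node_j = character(),
                      score = numeric()))
  }
  A <- .adjacency(net)
  ## sum over common neighbors h of w_ih * w_hj, times w_ij
  P <- A %*% A
  ii <- match(ed$node_i, net@nodes)
  jj <- match(ed$node_j, net@nodes)
  data.frame(node_i = ed$node_i, node_j = ed$node_j,
             score = ed$weight * P[cbind(ii, jj)])
}

## ---- file I/O ----------------------------------------------------------

#' Read / write weighted edge lists
#'
#' The canonical on-disk format is a CSV with header `node_i,node_j,weight`,
#' one row per unordered pair. Weights are written with 15 significant digits
#' so that a write/read round trip reproduces the network exactly. Symmetric
#' duplicate rows with identical weights collapse to one edge; self-loops,
#' non-numeric weights, and conflicting duplicates are format errors.
#'
#' @param path file path
#' @param provenance provenance tag to stamp on the network read
#' @return `readEdgelist` returns a [SemanticNetwork-class];
#'   `writeEdgelist` invisibly returns `path`.
#' @export
readEdgelist <- function(path, provenance = "ground-truth") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("edge list must have columns node_i, node_j, weight")
  w <- df[[3]]
  if (is.character(w)) {
    wn <- suppressWarnings(as.numeric(w))
    if (anyNA(wn) & !anyNA(w)) stop("non-numeric weight in edge list")
    df[[3]] <- wn
  }
  if (anyNA(df[[3]])) stop("non-numeric or missing weight in edge list")
  semanticNetwork(df, provenance = provenance)
}

#' @rdname readEdgelist
#' @param net a [SemanticNetwork-class]
#' @export
writeEdgelist <- function(net, path) {
  stopifnot(is(net, "SemanticNetwork"))
  ed <- net@edges
  out <- data.frame(node_i = ed$node_i, node_j = ed$node_j,
                    weight = sprintf("%.15g", ed$weight))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname readEdgelist
#' @details `writeGraphML` exports the network in GraphML for use in other
#'   tools, with the edge attribute `weight`. Isolated nodes are preserved.
#' @export
writeGraphML <- function(net, path) {
  stopifnot(is(net, "SemanticNetwork"))
  igraph::write_graph(.asIgraph(net), path, format = "graphml")
  invisible(path)
}
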