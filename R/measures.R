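#' Node strengths and average strength
#'
#' The strength of a node is the sum of its incident edge weights; isolated
#' nodes have strength 0. Average strength is the mean over all nodes of the
#' network.
#'
#' @param net a [SemanticNetwork-class]
#' @return `nodeStrengths`: named numeric vector over all nodes;
#'   `averageStrength`: length-1 numeric.
#' @export
nodeStrengths <- function(net) {
  stopifnot(is(net, "SemanticNetwork"))
  s <- stats::setNames(numeric(numNodes(net)), net@nodes)
  if (numEdges(net) > 0) {
    agg <- tapply(c(net@edges$weight, net@edges$weight),
                  c(net@edges$node_i, net@edges$node_j), sum)
    s[names(agg)] <- agg
  }
  s
}

#' @rdname nodeStrengths
#' @export
averageStrength <- function(net) mean(nodeStrengths(net))

#' Average shortest path length with similarity-based step costs
#'
#' Each step along a path costs `1 - w` (strong edges are short), the
#' distance between two nodes is the cost of the cheapest path, and ASPL is
#' the mean distance over all ordered node pairs connected by some path.
#' Pairs in different components are dropped from the average; if no
#' connected pair exists the measure is undefined and `NA` is returned.
#' Zero-cost edges (weight 1) are allowed.
#'
#' @param net a [SemanticNetwork-class]
#' @return length-1 numeric, or `NA` when undefined.
#' @export
aspl <- function(net) {
  stopifnot(is(net, "SemanticNetwork"))
  if (numEdges(net) == 0) return(NA_real_)
  if (any(net@edges$weight > 1)) {
    stop("aspl requires edge weights <= 1 (step cost 1 - w must be nonnegative)")
  }
  g <- .asIgraph(net)
  D <- igraph::distances(g, weights = 1 - igraph::E(g)$weight)
  vals <- D[row(D) != col(D)]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0) return(NA_real_)
  mean(vals)
}

#' Average weighted clustering coefficient on the strongest edges
#'
#' Local clustering of node `i` follows the strength-normalized weighted
#' form `cc_i = 1 / (s_i * (k_i - 1)) * sum_{j,h} ((w_ij + w_ih) / 2) *
#' a_ij * a_ih * a_jh` (sum over ordered neighbor pairs, `a` indicating
#' present edges). To avoid ceiling effects the network is first restricted
#' to its strongest edges: only edges with weight at or above the
#' `edgeQuantile` weight quantile (default the median, i.e. the 50% strongest
#' edges; ties kept; `edgeQuantile = 0` disables the filter) are retained,
#' and strengths and degrees are taken in the restricted graph. Nodes with
#' fewer than 2 retained neighbors are excluded from the average; if no node
#' qualifies the measure is undefined (`NA`).
#'
#' @param net a [SemanticNetwork-class]
#' @param edgeQuantile weight quantile below which edges are dropped
#'   (default 0.5)
#' @return length-1 numeric in `[0, 1]`, or `NA` when undefined.
#' @export
averageCC <- function(net, edgeQuantile = 0.5) {
  stopifnot(is(net, "SemanticNetwork"))
  if (numEdges(net) == 0) return(NA_real_)
  ed <- net@edges
  if (edgeQuantile > 0) {
    thr <- stats::quantile(ed$weight, edgeQuantile, names = FALSE)
    ed <- ed[ed$weight >= thr, , drop = FALSE]
  }
  sub <- semanticNetwork(ed, nodes = net@nodes, provenance = net@provenance)
  W <- .adjacency(sub)
  A <- (W > 0) * 1
  k <- rowSums(A)
  s <- rowSums(W)
  eligible <- k >= 2
  if (!any(eligible)) return(NA_real_)
  ## sum over ordered (j, h): ((w_ij + w_ih)/2) a_ij a_ih a_jh  ==  (W A A)_ii
  num <- diag(W %*% A %*% A)
  cc <- num[eligible] / (s[eligible] * (k[eligible] - 1))
  mean(cc)
}

## weighted modularity of a given membership vector:
## Q = 1/(2m) * sum_ij (a_ij - s_i s_j / 2m) delta(c_i, c_j),
## with a_ij the weight matrix and 2m the total weight counted both ways
.modularityQ <- function(W, membership) {
  two_m <- sum(W)
  if (two_m <= 0) stop("modularity undefined: no edge weight")
  s <- rowSums(W)
  same <- outer(membership, membership, "==")
  sum((W - outer(s, s) / two_m) * same) / two_m
}

#' Weighted modularity under Louvain communities
#'
#' Detects communities with the weighted Louvain algorithm (resolution 1) and
#' evaluates the weighted modularity
#' `Q = 1/(2m) * sum_ij (a_ij - s_i * s_j / (2m)) * delta(c_i, c_j)`
#' of the resulting partition, where `2m` is the total edge weight counted in
#' both directions. Louvain is stochastic, so the seed is part of the call;
#' with `nRestarts > 1` the best (max-Q) of several seeded runs is returned.
#'
#' @param net a [SemanticNetwork-class] with at least one edge
#' @param seed integer seed for the Louvain run(s)
#' @param nRestarts number of independent Louvain runs (default 1)
#' @param membership optional integer/character vector (named by node or in
#'   node order) fixing the partition; skips Louvain and just evaluates Q
#' @return length-1 numeric with attribute `"membership"`.
#' @export
modularityLouvain <- function(net, seed = 1, nRestarts = 1, membership = NULL) {
  stopifnot(is(net, "SemanticNetwork"))
  if (numEdges(net) == 0) stop("modularity undefined for an edgeless network")
  W <- .adjacency(net)
  if (!is.null(membership)) {
    if (!is.null(names(membership))) membership <- membership[net@nodes]
    if (length(membership) != numNodes(net) || anyNA(membership)) {
      stop("membership must cover every node")
    }
    q <- .modularityQ(W, membership)
    attr(q, "membership") <- stats::setNames(membership, net@nodes)
    return(q)
  }
  g <- .asIgraph(net)
  best_q <- -Inf
  best_mb <- NULL
  for (run in seq_len(nRestarts)) {
    mb <- withr::with_seed(.deriveSeed(seed, run), {
      igraph::membership(igraph::cluster_louvain(
        g, weights = igraph::E(g)$weight, resolution = 1
      ))
    })
    q <- .modularityQ(W, as.integer(mb))
    if (q > best_q) {
      best_q <- q
      best_mb <- mb
    }
  }
  out <- best_q
  attr(out, "membership") <- stats::setNames(as.integer(best_mb), net@nodes)
  out
}

#' Compute the full measure panel of a network
#'
#' Assembles the six structural measures with shared conventions: the
#' within-network measures edge weight and node strength, and the
#' between-network measures average strength, ASPL ([aspl()]), average
#' clustering ([averageCC()]), and Louvain modularity ([modularityLouvain()]).
#' Undefined measures are recorded as `NA` (including modularity of an
#' edgeless network).
#'
#' @param net a non-empty [SemanticNetwork-class]
#' @param seed seed for the Louvain run
#' @param ccQuantile edge-weight quantile filter for [averageCC()]
#' @param nRestarts Louvain restarts
#' @return A [MeasurePanel-class].
#' @export
measurePanel <- function(net, seed = 1, ccQuantile = 0.5, nRestarts = 1) {
  stopifnot(is(net, "SemanticNetwork"), numNodes(net) > 0)
  ew <- stats::setNames(
    net@edges$weight,
    paste(net@edges$node_i, net@edges$node_j, sep = "|")
  )
  ns <- nodeStrengths(net)
  q <- tryCatch(
    as.numeric(modularityLouvain(net, seed = seed, nRestarts = nRestarts)),
    error = function(e) NA_real_
  )
  new("MeasurePanel",
      edgeWeights = ew, nodeStrengths = ns,
      averageStrength = mean(ns), aspl = aspl(net),
      averageCC = averageCC(net, edgeQuantile = ccQuantile), modularity = q)
}

#' @describeIn measurePanel the four between-network measures as a named
#'   vector (`average_strength`, `aspl`, `average_cc`, `modularity`)
#' @param panel a `MeasurePanel`
#' @export
betweenMeasures <- function(panel) {
  stopifnot(is(panel, "MeasurePanel"))
  c(average_strength = panel@averageStrength, aspl = panel@aspl,
    average_cc = panel@averageCC, modularity = panel@modularity)
}
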