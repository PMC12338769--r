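# Independent brute-force oracles and fixture generators. Everything here is
# deliberately naive (triple loops, exhaustive path enumeration) and shares no
# code path with the package implementations it checks.

# random weighted undirected graph as a SemanticNetwork
rand_net <- function(n, p_edge = 0.5, seed = 1, wmin = 0.05, wmax = 1) {
  withr::with_seed(seed, {
    nodes <- sprintf("n%02d", seq_len(n))
    pairs <- t(combn(nodes, 2))
    keep <- runif(nrow(pairs)) < p_edge
    edges <- data.frame(
      node_i = pairs[keep, 1], node_j = pairs[keep, 2],
      weight = runif(sum(keep), wmin, wmax)
    )
    semanticNetwork(edges, nodes = nodes)
  })
}

# dense symmetric weight matrix from a network
adj_of <- function(net) {
  nd <- nodes(net)
  A <- matrix(0, length(nd), length(nd), dimnames = list(nd, nd))
  ed <- edgeTable(net)
  for (r in seq_len(nrow(ed))) {
    A[ed$node_i[r], ed$node_j[r]] <- ed$weight[r]
    A[ed$node_j[r], ed$node_i[r]] <- ed$weight[r]
  }
  A
}

# triangle scores by explicit enumeration of node triples
bf_triangle_scores <- function(net) {
  A <- adj_of(net)
  nd <- nodes(net)
  ed <- edgeTable(net)
  score <- numeric(nrow(ed))
  for (r in seq_len(nrow(ed))) {
    i <- ed$node_i[r]; j <- ed$node_j[r]
    for (h in setdiff(nd, c(i, j))) {
      if (A[i, h] > 0 && A[j, h] > 0) {
        score[r] <- score[r] + A[i, j] * A[i, h] * A[j, h]
      }
    }
  }
  cbind(ed[, c("node_i", "node_j")], score = score)
}

# all-pairs min path cost (cost 1 - w per step) by exhaustive simple-path DFS
bf_aspl <- function(net) {
  A <- adj_of(net)
  n <- nrow(A)
  best <- matrix(Inf, n, n)
  dfs <- function(path, cost, target) {
    v <- path[length(path)]
    if (v == target) {
      best[path[1], target] <<- min(best[path[1], target], cost)
      return(invisible())
    }
    for (u in seq_len(n)) {
      if (A[v, u] > 0 && !(u %in% path)) {
        dfs(c(path, u), cost + 1 - A[v, u], target)
      }
    }
  }
  for (s in seq_len(n)) for (t in seq_len(n)) if (s != t) dfs(s, 0, t)
  vals <- best[row(best) != col(best)]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0) NA_real_ else mean(vals)
}

# Barrat-style weighted clustering by direct triple loop (no edge filter)
bf_average_cc <- function(net) {
  W <- adj_of(net)
  A <- (W > 0) * 1
  n <- nrow(W)
  cc <- c()
  for (i in seq_len(n)) {
    k <- sum(A[i, ])
    if (k < 2) next
    s <- sum(W[i, ])
    acc <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j != h && A[i, j] == 1 && A[i, h] == 1 && A[j, h] == 1) {
        acc <- acc + (W[i, j] + W[i, h]) / 2
      }
    }
    cc <- c(cc, acc / (s * (k - 1)))
  }
  if (length(cc) == 0) NA_real_ else mean(cc)
}

# weighted modularity of a given membership by direct double loop
bf_modularity <- function(net, membership) {
  W <- adj_of(net)
  nd <- nodes(net)
  two_m <- sum(W)
  s <- rowSums(W)
  q <- 0
  for (i in seq_along(nd)) for (j in seq_along(nd)) {
    if (membership[nd[i]] == membership[nd[j]]) {
      q <- q + W[i, j] - s[i] * s[j] / two_m
    }
  }
  as.numeric(q / two_m)
}

# small clustered ground truth shared by several test files
fixture_truth <- function(n_words = 60, communities = 3, seed = 11) {
  cosineNetwork(
    synthEmbeddings(n_words, 12, communities, 0.35, seed = seed),
    cutoff = 0.2
  )
}
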