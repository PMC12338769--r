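#' Individualize a network by triangle-score-guided perturbation
#'
#' Derives one individualized network from a common ground truth by
#' redistributing edge weight. The algorithm targets clustering-relevant
#' edges through their triangle score ([triangleScores()]), which lets the
#' population vary in average clustering independently of average strength:
#'
#' 1. Sample `floor(E/2)` source edges: a proportion `p` from the half of
#'    edges with above-median triangle score (ties count as above), `1 - p`
#'    from the below-median half. If every score ties (e.g. a triangle-free
#'    graph), sources are drawn uniformly from all edges.
#' 2. Draw a weight fraction `k ~ Uniform(0, 1)` independently for each
#'    source edge.
#' 3. For a uniformly chosen fraction `1 - r` of the sources, reduce the
#'    weight by that fraction: `w <- w * (1 - k)`.
#' 4. For the remaining `floor(r * S)` sources, relocate `k * w` to a target
#'    edge drawn from the non-source edges with probability proportional to
#'    its current weight; the target is capped at `cap` (default 1, the
#'    cosine scale) and excess weight is discarded.
#' 5. Remove all edges with final weight below `cutoff`.
#'
#' `p` tilts the perturbation toward high-clustering edges (lowering average
#' CC); `r` trades pure weight loss against weight relocation (controlling
#' average strength).
#'
#' @param net a [SemanticNetwork-class] with at least 2 edges
#' @param p proportion of sources from the above-median triangle-score half,
#'   in `[0, 1]`
#' @param r proportion of sources whose weight is relocated rather than
#'   reduced, in `[0, 1]`
#' @param cutoff post-perturbation minimum edge weight (default 0.2; 0
#'   disables pruning)
#' @param cap maximum weight a relocation target may reach (default 1;
#'   `Inf` disables the cap)
#' @param seed integer seed; the function is a pure function of
#'   `(net, p, r, cutoff, cap, seed)`
#' @return A [SemanticNetwork-class] with provenance `"individualized"`.
#' @export
perturbNetwork <- function(net, p, r, cutoff = 0.2, cap = 1, seed = 1) {
  stopifnot(is(net, "SemanticNetwork"))
  E <- numEdges(net)
  if (E < 2) stop("need at least 2 edges to perturb")
  if (p < 0 || p > 1 || r < 0 || r > 1) stop("p and r must be in [0, 1]")
  if (cutoff < 0 || cutoff >= 1) stop("cutoff must be in [0, 1)")

  ts <- triangleScores(net)$score
  w <- net@edges$weight
  S <- E %/% 2L

  withr::with_seed(as.integer(seed), {
    med <- stats::median(ts)
    above <- which(ts >= med)
    below <- which(ts < med)
    if (length(below) == 0L || length(above) == 0L) {
      ## all scores tie: both halves are the full edge set, sample uniformly
      src <- sample.int(E, S)
    } else {
      n_hi <- round(p * S)
      n_hi <- min(n_hi, length(above))
      n_lo <- min(S - n_hi, length(below))
      n_hi <- S - n_lo  # backfill if the below half is too small
      src <- c(.resample(above, n_hi), .resample(below, n_lo))
    }
    k <- stats::runif(S)

    n_rel <- floor(r * S)
    rel_pos <- if (n_rel > 0) sample.int(S, n_rel) else integer()
    reducers <- setdiff(seq_len(S), rel_pos)

    ## step 3: reduction
    w[src[reducers]] <- w[src[reducers]] * (1 - k[reducers])

    ## step 4: sequential relocation onto non-source edges, prob ~ weight
    nonsrc <- setdiff(seq_len(E), src)
    if (n_rel > 0 && length(nonsrc) == 0L) {
      stop("no non-source edges available as relocation targets")
    }
    for (pos in rel_pos) {
      e <- src[pos]
      moved <- k[pos] * w[e]
      w[e] <- w[e] - moved
      tgt <- .resample(nonsrc, 1, prob = w[nonsrc])
      w[tgt] <- min(cap, w[tgt] + moved)
    }
  })

  ed <- net@edges
  ed$weight <- w
  ed <- ed[w >= cutoff & w > 0, , drop = FALSE]
  semanticNetwork(ed, nodes = net@nodes, provenance = "individualized")
}

#' Default perturbation parameter grid
#'
#' A 25-pair Cartesian grid `p` in `{0, 0.1875, 0.375, 0.5625, 0.75}` by
#' `r` in `{0, 0.25, 0.5, 0.75, 1}`, spanning the full documented ranges of
#' both parameters. Any data.frame with columns `p` and `r` can be supplied
#' instead; [decorrelationCheck()] helps select a grid on which average
#' strength and clustering are (close to) uncorrelated across the population.
#'
#' @return data.frame with columns `p`, `r` (25 rows).
#' @export
defaultPerturbationGrid <- function() {
  expand.grid(p = seq(0, 0.75, length.out = 5),
              r = seq(0, 1, length.out = 5),
              KEEP.OUT.ATTRS = FALSE)
}

#' Generate a population of individualized networks
#'
#' Runs [perturbNetwork()] `reps` times for every `(p, r)` pair of the grid,
#' each run with a distinct seed derived deterministically from `baseSeed`
#' and the (cell, rep) index. At the default grid and `reps = 10` this yields
#' a population of 250 structurally varying individuals.
#'
#' @param net the common ground-truth [SemanticNetwork-class]
#' @param grid data.frame with columns `p`, `r`
#'   (default [defaultPerturbationGrid()])
#' @param reps number of individuals per grid cell (default 10)
#' @param baseSeed integer master seed
#' @param cutoff,cap passed to [perturbNetwork()]
#' @return list of [SemanticNetwork-class], ordered by grid row then rep,
#'   with attribute `"manifest"`: data.frame
#'   `individual_id, p, r, rep, seed, n_nodes, n_edges`.
#' @export
generatePopulation <- function(net, grid = defaultPerturbationGrid(),
                               reps = 10, baseSeed = 1,
                               cutoff = 0.2, cap = 1) {
  grid <- as.data.frame(grid)
  if (!all(c("p", "r") %in% colnames(grid)) || nrow(grid) == 0) {
    stop("grid must be a non-empty data.frame with columns p and r")
  }
  if (reps < 1) stop("reps must be >= 1")
  n <- nrow(grid) * reps
  pop <- vector("list", n)
  manifest <- data.frame(
    individual_id = seq_len(n), p = NA_real_, r = NA_real_,
    rep = NA_integer_, seed = NA_integer_,
    n_nodes = NA_integer_, n_edges = NA_integer_
  )
  idx <- 0L
  for (g in seq_len(nrow(grid))) {
    for (rep in seq_len(reps)) {
      idx <- idx + 1L
      sd <- .deriveSeed(baseSeed, g, rep)
      pop[[idx]] <- perturbNetwork(net, grid$p[g], grid$r[g],
                                   cutoff = cutoff, cap = cap, seed = sd)
      manifest[idx, c("p", "r")] <- grid[g, c("p", "r")]
      manifest$rep[idx] <- rep
      manifest$seed[idx] <- sd
      manifest$n_nodes[idx] <- numNodes(pop[[idx]])
      manifest$n_edges[idx] <- numEdges(pop[[idx]])
    }
  }
  attr(pop, "manifest") <- manifest
  pop
}

#' Strength/clustering decorrelation diagnostic
#'
#' Pearson correlation between per-network average strength and average
#' clustering coefficient across a population. Used to check that a chosen
#' perturbation grid lets the two measures vary independently, so that
#' recovery of one can be evaluated without confounding by the other.
#'
#' @param population list of [SemanticNetwork-class] (>= 3)
#' @param ccQuantile edge-weight quantile filter passed to [averageCC()]
#' @return Pearson correlation (length-1 numeric) with attribute
#'   `"measures"`: the underlying data.frame.
#' @export
decorrelationCheck <- function(population, ccQuantile = 0.5) {
  if (length(population) < 3) stop("need at least 3 networks")
  st <- vapply(population, averageStrength, numeric(1))
  cc <- vapply(population, averageCC, numeric(1), edgeQuantile = ccQuantile)
  if (anyNA(cc)) stop("average CC undefined for some network(s)")
  if (stats::sd(st) == 0 || stats::sd(cc) == 0) {
    stop("undefined correlation: constant measure vector")
  }
  out <- stats::cor(st, cc)
  attr(out, "measures") <- data.frame(average_strength = st, average_cc = cc)
  out
}
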