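#' Recovery bias and resolution
#'
#' `recoveryBias()` scores systematic over-/underestimation as the geometric
#' mean of the inferred/truth ratios minus one (computed as
#' `exp(mean(log(ratio))) - 1` for numerical stability). A bias of -0.25
#' means the inferred measure underestimates the truth by 25% on average.
#' Pairs with a nonpositive inferred or truth value (possible for
#' modularity) are excluded and counted in the `"n_excluded"` attribute;
#' if every pair is excluded the bias is undefined (`NA`).
#'
#' `recoveryResolution()` scores how well a design separates individuals: the
#' tie-corrected Spearman rank correlation between inferred and truth values.
#'
#' @param inferred,truth equal-length numeric vectors, paired by individual
#' @return `recoveryBias`: length-1 numeric (or `NA`), attributes
#'   `"n_used"` and `"n_excluded"`; `recoveryResolution`: length-1 numeric in
#'   `[-1, 1]`.
#' @export
recoveryBias <- function(inferred, truth) {
  if (length(inferred) != length(truth)) stop("length mismatch")
  if (length(inferred) < 1) stop("need at least one pair")
  ratio <- inferred / truth
  ok <- is.finite(ratio) & ratio > 0
  out <- if (any(ok)) exp(mean(log(ratio[ok]))) - 1 else NA_real_
  attr(out, "n_used") <- sum(ok)
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' @rdname recoveryBias
#' @export
recoveryResolution <- function(inferred, truth) {
  if (length(inferred) != length(truth)) stop("length mismatch")
  ok <- is.finite(inferred) & is.finite(truth)
  if (sum(ok) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(inferred[ok]) == 0 || stats::sd(truth[ok]) == 0) {
    stop("undefined correlation: constant input")
  }
  stats::cor(inferred[ok], truth[ok], method = "spearman")
}

#' Mean within-network resolution across individuals
#'
#' For within-network measures (edge weights, node strengths) resolution is
#' computed inside each individual — Spearman correlation of the inferred and
#' truth vectors over the shared cue set — and then averaged across
#' individuals. Individuals with a constant vector on either side are skipped
#' and counted.
#'
#' @param perIndividualPairs list of `list(inferred = ..., truth = ...)`
#'   numeric vector pairs (absent inferred edges should enter as 0)
#' @return length-1 numeric (or `NA` if all skipped) with attributes
#'   `"n_used"` and `"n_skipped"`.
#' @export
withinNetworkResolution <- function(perIndividualPairs) {
  rs <- vapply(perIndividualPairs, function(pr) {
    if (length(pr$inferred) != length(pr$truth)) stop("length mismatch")
    ok <- is.finite(pr$inferred) & is.finite(pr$truth)
    if (sum(ok) < 3 ||
        stats::sd(pr$inferred[ok]) == 0 || stats::sd(pr$truth[ok]) == 0) {
      return(NA_real_)
    }
    stats::cor(pr$inferred[ok], pr$truth[ok], method = "spearman")
  }, numeric(1))
  out <- if (all(is.na(rs))) NA_real_ else mean(rs, na.rm = TRUE)
  attr(out, "n_used") <- sum(!is.na(rs))
  attr(out, "n_skipped") <- sum(is.na(rs))
  out
}

.BIAS_BAND <- 0.3        # |bias| <= 0.3: acceptable recovery
.RESOLUTION_FLOOR <- 0.5 # resolution >= 0.5: acceptable recovery

## all unordered pair keys "i|j" (i < j) of a node set, and the weight vector
## of a network over exactly those pairs (absent edge = 0)
.pairKeys <- function(nodeSet) {
  ns <- sort(nodeSet)
  if (length(ns) < 2) return(character())
  pr <- utils::combn(ns, 2)
  paste(pr[1, ], pr[2, ], sep = "|")
}

.edgeVector <- function(net, keys) {
  w <- stats::setNames(net@edges$weight,
                       paste(net@edges$node_i, net@edges$node_j, sep = "|"))
  out <- stats::setNames(numeric(length(keys)), keys)
  hit <- intersect(keys, names(w))
  out[hit] <- w[hit]
  out
}

#' Evaluate recovery for one design cell
#'
#' Compares inferred networks against the individualized ground truths for
#' every measure. The reference is either `"local"` — the truth network
#' restricted to the instantiation's cue set — or `"global"` — the full truth
#' network (the generalizability analysis). Between-network measures (average
#' strength, ASPL, average CC, modularity) are pooled over all individual x
#' instantiation pairs into one bias and one resolution per measure;
#' within-network measures (edge weight, node strength) are evaluated per
#' individual via [withinNetworkResolution()] and reported for the local
#' reference only, resolution only.
#'
#' @param truthPopulation list of individualized [SemanticNetwork-class]
#' @param inferredNetworks list over instantiations, each a list over
#'   individuals, of inferred [SemanticNetwork-class]
#' @param cuesets list over instantiations of [CueSet-class] (or character)
#' @param reference `"local"` or `"global"`
#' @param seed seed for the Louvain runs inside the measure panels
#' @param ccQuantile edge-weight quantile filter for [averageCC()]
#' @return data.frame with one row per measure: `measure, reference, bias,
#'   resolution, n_pairs, n_excluded, acceptable_bias, acceptable_resolution`.
#' @export
evaluateDesign <- function(truthPopulation, inferredNetworks, cuesets,
                           reference = c("local", "global"), seed = 1,
                           ccQuantile = 0.5) {
  reference <- match.arg(reference)
  nInst <- length(inferredNetworks)
  nInd <- length(truthPopulation)
  if (nInst != length(cuesets)) stop("one cue set per instantiation required")
  for (ii in seq_len(nInst)) {
    if (length(inferredNetworks[[ii]]) != nInd) {
      stop(sprintf("missing inferred network(s) in instantiation %d", ii))
    }
  }

  ## truth panels
  if (reference == "global") {
    truthPanels <- lapply(seq_len(nInd), function(di) {
      betweenMeasures(measurePanel(truthPopulation[[di]],
                                   seed = .deriveSeed(seed, 1, di),
                                   ccQuantile = ccQuantile))
    })
  }

  measures <- c("average_strength", "aspl", "average_cc", "modularity")
  inf_vals <- matrix(NA_real_, nInst * nInd, length(measures),
                     dimnames = list(NULL, measures))
  tru_vals <- inf_vals
  withinPairs <- list(edge_weight = vector("list", nInst * nInd),
                      node_strength = vector("list", nInst * nInd))

  row <- 0L
  for (ii in seq_len(nInst)) {
    cueVec <- .asCues(cuesets[[ii]])
    keys <- .pairKeys(cueVec)
    for (di in seq_len(nInd)) {
      row <- row + 1L
      inferred <- inferredNetworks[[ii]][[di]]
      if (is.null(inferred)) stop(sprintf(
        "missing inferred network: instantiation %d, individual %d", ii, di))
      infPanel <- measurePanel(inferred, seed = .deriveSeed(seed, 2, ii, di),
                               ccQuantile = ccQuantile)
      inf_vals[row, ] <- betweenMeasures(infPanel)
      if (reference == "global") {
        tru_vals[row, ] <- truthPanels[[di]]
      } else {
        truthLocal <- inducedSubgraph(truthPopulation[[di]], cueVec)
        tru_vals[row, ] <- betweenMeasures(measurePanel(
          truthLocal, seed = .deriveSeed(seed, 3, ii, di),
          ccQuantile = ccQuantile))
      }
      if (reference == "local") {
        withinPairs$edge_weight[[row]] <- list(
          inferred = .edgeVector(inferred, keys),
          truth = .edgeVector(truthLocal, keys)
        )
        sInf <- nodeStrengths(inferred)
        sTru <- nodeStrengths(truthLocal)
        withinPairs$node_strength[[row]] <- list(
          inferred = sInf[sort(cueVec)], truth = sTru[sort(cueVec)]
        )
      }
    }
  }

  res <- lapply(measures, function(m) {
    b <- recoveryBias(inf_vals[, m], tru_vals[, m])
    r <- tryCatch(recoveryResolution(inf_vals[, m], tru_vals[, m]),
                  error = function(e) NA_real_)
    data.frame(
      measure = m, reference = reference,
      bias = as.numeric(b), resolution = r,
      n_pairs = nInst * nInd, n_excluded = attr(b, "n_excluded"),
      acceptable_bias = !is.na(b) && abs(b) <= .BIAS_BAND,
      acceptable_resolution = !is.na(r) && r >= .RESOLUTION_FLOOR
    )
  })
  if (reference == "local") {
    res <- c(res, lapply(c("edge_weight", "node_strength"), function(m) {
      r <- withinNetworkResolution(withinPairs[[m]])
      data.frame(
        measure = m, reference = "local",
        bias = NA_real_, resolution = as.numeric(r),
        n_pairs = attr(r, "n_used"), n_excluded = attr(r, "n_skipped"),
        acceptable_bias = NA,
        acceptable_resolution = !is.na(r) && r >= .RESOLUTION_FLOOR
      )
    }))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Attenuation-based power simulation
#'
#' Estimates the power of a one-sided two-sample t-test when the measured
#' outcome is an attenuated version of the true score. Per replicate, two
#' groups of `nPerGroup` true scores are drawn with a separation of
#' `effectD` pooled standard deviations; observed scores add independent
#' Gaussian noise with variance `(1 - r^2) / r^2` (times the true-score
#' variance), so that `cor(observed, true) = resolution` and the observable
#' effect shrinks to `effectD * resolution`. The returned power is the
#' proportion of replicates in which the test rejects at level `alpha`.
#'
#' @param resolution truth-estimate correlation in `[0, 1]` (`0` means the
#'   measurement carries no signal; power collapses to `alpha`)
#' @param effectD true effect size (Cohen's d)
#' @param nPerGroup participants per group
#' @param alpha one-sided significance level (default 0.05)
#' @param nSims Monte-Carlo replicates (default 10000)
#' @param seed integer seed
#' @return length-1 numeric: the rejection proportion.
#' @export
powerSimulation <- function(resolution, effectD, nPerGroup, alpha = 0.05,
                            nSims = 10000, seed = 1) {
  stopifnot(resolution >= 0, resolution <= 1, nPerGroup >= 2, nSims >= 1)
  n <- as.integer(nPerGroup)
  noise_sd <- if (resolution == 0) Inf else sqrt(1 - resolution^2) / resolution
  crit <- stats::qt(1 - alpha, df = 2 * n - 2)
  withr::with_seed(as.integer(seed), {
    rej <- logical(nSims)
    chunk <- max(1L, min(nSims, floor(2e6 / n)))
    done <- 0L
    while (done < nSims) {
      b <- min(chunk, nSims - done)
      g1 <- matrix(stats::rnorm(n * b, mean = effectD), n, b)
      g2 <- matrix(stats::rnorm(n * b, mean = 0), n, b)
      if (resolution == 0) {
        g1 <- matrix(stats::rnorm(n * b), n, b)
        g2 <- matrix(stats::rnorm(n * b), n, b)
      } else if (resolution < 1) {
        g1 <- g1 + matrix(stats::rnorm(n * b, sd = noise_sd), n, b)
        g2 <- g2 + matrix(stats::rnorm(n * b, sd = noise_sd), n, b)
      }
      m1 <- colMeans(g1); m2 <- colMeans(g2)
      v1 <- colSums((g1 - rep(m1, each = n))^2) / (n - 1)
      v2 <- colSums((g2 - rep(m2, each = n))^2) / (n - 1)
      tstat <- (m1 - m2) / sqrt((v1 + v2) / n)
      rej[done + seq_len(b)] <- tstat > crit
      done <- done + b
    }
    mean(rej)
  })
}

## closed-form one-sided two-sample power under attenuation (noncentral t)
.powerClosedForm <- function(resolution, effectD, nPerGroup, alpha) {
  d_obs <- effectD * resolution
  ncp <- d_obs * sqrt(nPerGroup / 2)
  df <- 2 * nPerGroup - 2
  1 - stats::pt(stats::qt(1 - alpha, df), df, ncp = ncp)
}

#' Required sample size under attenuation
#'
#' Smallest per-group n at which a one-sided two-sample t-test detects a true
#' effect of `effectD` with probability `targetPower`, given that the
#' measured outcome correlates with the truth at `resolution` (so the
#' observable effect is `effectD * resolution`). Solved by bisection over the
#' closed-form noncentral-t power; [powerSimulation()] can verify the result.
#'
#' @inheritParams powerSimulation
#' @param targetPower desired power (default 0.8)
#' @param nMax search ceiling (default 1e7)
#' @return integer: per-group sample size.
#' @export
requiredN <- function(resolution, effectD, targetPower = 0.8, alpha = 0.05,
                      nMax = 1e7) {
  if (resolution <= 0) stop("unattainable: resolution must be > 0")
  stopifnot(effectD > 0, targetPower > 0, targetPower < 1)
  lo <- 2L
  hi <- 4L
  while (.powerClosedForm(resolution, effectD, hi, alpha) < targetPower) {
    hi <- hi * 2L
    if (hi > nMax) stop("required n exceeds nMax")
  }
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (.powerClosedForm(resolution, effectD, mid, alpha) >= targetPower) {
      hi <- mid
    } else {
      lo <- mid
    }
  }
  if (.powerClosedForm(resolution, effectD, lo, alpha) >= targetPower) lo else hi
}
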