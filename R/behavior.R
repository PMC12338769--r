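#' Response-model parameter bundles
#'
#' `faParams()` holds the free-association retrieval parameters: the
#' probability of producing response `i` to cue `j` is proportional to
#' `w_ij^gammaW * f_i^gammaF`, combining local semantic similarity (the edge
#' weight) with the global word frequency from a [Lexicon-class]. The
#' defaults `gammaW = 10`, `gammaF = 1` are the values at which simulated
#' response distributions best reproduce large-scale human free-association
#' norms.
#'
#' `rjParams()` holds the relatedness-judgment parameters: a rating for the
#' pair `(i, j)` is drawn from a truncated normal on the `[scaleMin,
#' scaleMax]` rating scale with location `scaleMin + (scaleMax - scaleMin) *
#' w_ij^gamma` and standard deviation `sigma`. The defaults `gamma = 1`,
#' `sigma = 3.85` (on the 1-20 scale) reproduce the inter-rater reliability
#' of published human relatedness norms.
#'
#' @param gammaW similarity sensitivity, >= 0 (default 10)
#' @param gammaF frequency sensitivity, >= 0 (default 1)
#' @param responsesPerTrial associations collected per cue presentation
#'   (default 3, the usual multi-response norming convention)
#' @return a named list of parameters.
#' @export
faParams <- function(gammaW = 10, gammaF = 1, responsesPerTrial = 3) {
  stopifnot(gammaW >= 0, gammaF >= 0, responsesPerTrial >= 1)
  list(gammaW = gammaW, gammaF = gammaF,
       responsesPerTrial = as.integer(responsesPerTrial))
}

#' @rdname faParams
#' @param gamma similarity sensitivity, >= 0 (default 1)
#' @param sigma rating noise SD on the rating scale, >= 0 (default 3.85)
#' @param scaleMin,scaleMax rating scale bounds (default 1 and 20)
#' @param round round ratings to integers (default `FALSE`; the generating
#'   distribution is continuous)
#' @export
rjParams <- function(gamma = 1, sigma = 3.85, scaleMin = 1, scaleMax = 20,
                     round = FALSE) {
  stopifnot(gamma >= 0, sigma >= 0, scaleMin < scaleMax)
  list(gamma = gamma, sigma = sigma, scaleMin = scaleMin,
       scaleMax = scaleMax, round = round)
}

#' Free-association response distribution for one cue
#'
#' The exact retrieval distribution: over the neighbors `i` of the cue `j`
#' that are not excluded, `P(i | j)` is proportional to
#' `w_ij^gammaW * f_i^gammaF`. Words without an edge to the cue have
#' probability 0 and are not in the support. With `gammaF = 0` the lexicon
#' is not consulted (frequency neutrality).
#'
#' @param net the individual's [SemanticNetwork-class]
#' @param cue a node of `net`
#' @param lex a [Lexicon-class] covering the cue's neighbors (may be `NULL`
#'   when `params$gammaF == 0`)
#' @param params see [faParams()]
#' @param exclude nodes removed from the support (e.g. earlier responses in
#'   the same trial)
#' @return named probability vector over the eligible neighbors (sums to 1).
#' @export
faDistribution <- function(net, cue, lex = NULL, params = faParams(),
                           exclude = character()) {
  stopifnot(is(net, "SemanticNetwork"))
  if (!cue %in% net@nodes) stop("unknown cue: ", cue)
  ed <- net@edges
  hit_i <- ed$node_i == cue
  hit_j <- ed$node_j == cue
  nbr <- c(ed$node_j[hit_i], ed$node_i[hit_j])
  w <- c(ed$weight[hit_i], ed$weight[hit_j])
  keep <- !(nbr %in% c(exclude, cue))
  nbr <- nbr[keep]; w <- w[keep]
  if (length(nbr) == 0) {
    stop("empty support: cue '", cue, "' has no eligible neighbor")
  }
  score <- w^params$gammaW
  if (params$gammaF > 0) {
    if (is.null(lex)) stop("a Lexicon is required when gammaF > 0")
    f <- frequencies(lex)[nbr]
    if (anyNA(f)) {
      stop("lexicon is missing frequencies for: ",
           paste(nbr[is.na(f)], collapse = ", "))
    }
    score <- score * unname(f)^params$gammaF
  }
  stats::setNames(score / sum(score), nbr)
}

#' Simulate a free-association session for one individual
#'
#' For each cue, responses are collected in trials of
#' `params$responsesPerTrial` responses. Within a trial the responses are
#' drawn sequentially from [faDistribution()] without replacement (the
#' support is renormalized after every draw, and a trial ends early if the
#' cue's neighborhood is exhausted); across trials the support resets, so the
#' same word can recur in different trials. Cues with no neighbors produce no
#' records and are reported in the `"skipped_cues"` attribute with a single
#' warning.
#'
#' @param net the individual's [SemanticNetwork-class]
#' @param cueset a [CueSet-class] or character vector of cues
#' @param nResponses responses to collect per cue; trials of
#'   `params$responsesPerTrial`, final partial trial allowed
#' @param lex a [Lexicon-class] (see [faDistribution()])
#' @param params see [faParams()]
#' @param seed integer seed
#' @return data.frame `cue, trial, position, response` with attribute
#'   `"skipped_cues"`.
#' @export
simulateFA <- function(net, cueset, nResponses, lex = NULL,
                       params = faParams(), seed = 1) {
  cueVec <- .asCues(cueset)
  stopifnot(length(cueVec) >= 1, nResponses >= 1)
  rpt <- params$responsesPerTrial
  recs <- vector("list", length(cueVec))
  skipped <- character()
  withr::with_seed(as.integer(seed), {
    for (ci in seq_along(cueVec)) {
      cue <- cueVec[ci]
      base <- tryCatch(faDistribution(net, cue, lex, params),
                       error = function(e) NULL)
      if (is.null(base)) {
        skipped <- c(skipped, cue)
        next
      }
      nTrials <- ceiling(nResponses / rpt)
      sizes <- rep(rpt, nTrials)
      sizes[nTrials] <- nResponses - rpt * (nTrials - 1L)
      out <- vector("list", nTrials)
      for (tr in seq_len(nTrials)) {
        prob <- base
        nDraw <- min(sizes[tr], length(base))
        resp <- character(nDraw)
        for (pos in seq_len(nDraw)) {
          pick <- .resample(names(prob), 1, prob = prob)
          resp[pos] <- pick
          prob <- prob[names(prob) != pick]
        }
        out[[tr]] <- data.frame(cue = cue, trial = tr,
                                position = seq_len(nDraw), response = resp)
      }
      recs[[ci]] <- do.call(rbind, out)
    }
  })
  if (length(skipped)) {
    warning(length(skipped), " cue(s) skipped for lack of neighbors")
  }
  res <- do.call(rbind, recs)
  if (is.null(res)) {
    res <- data.frame(cue = character(), trial = integer(),
                      position = integer(), response = character())
  }
  rownames(res) <- NULL
  attr(res, "skipped_cues") <- skipped
  res
}

## truncated-normal sampler by inverse CDF (exact seed reproducibility;
## degenerates to the clamped location when sigma == 0)
.rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(pmin(upper, pmax(lower, rep_len(mean, n))))
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(lo + stats::runif(n) * (hi - lo), mean, sd)
}

#' Simulate a relatedness-judgment session for one individual
#'
#' The judgment budget is `length(cues) * nResponses` ratings, allocated over
#' the `P = C(n, 2)` unordered cue pairs: every pair receives
#' `floor(budget / P)` ratings and a uniformly random subset of pairs one
#' extra; if the budget is smaller than `P`, a uniform random sample of
#' `budget` distinct pairs is rated once. Each rating is drawn from a
#' truncated normal on the rating scale with location
#' `scaleMin + (scaleMax - scaleMin) * w^gamma` (weight 0 for absent edges)
#' and SD `sigma`.
#'
#' @inheritParams simulateFA
#' @param params see [rjParams()]
#' @return data.frame `word_i, word_j, rating` (pairs stored with
#'   `word_i < word_j`).
#' @export
simulateRJ <- function(net, cueset, nResponses, params = rjParams(), seed = 1) {
  cueVec <- .asCues(cueset)
  if (length(cueVec) < 2) stop("need at least 2 cues")
  stopifnot(nResponses >= 1)
  pr <- t(utils::combn(sort(cueVec), 2))
  P <- nrow(pr)
  budget <- length(cueVec) * nResponses
  withr::with_seed(as.integer(seed), {
    if (budget < P) {
      counts <- integer(P)
      counts[sample.int(P, budget)] <- 1L
    } else {
      counts <- rep(budget %/% P, P)
      extra <- budget %% P
      if (extra > 0) {
        bump <- sample.int(P, extra)
        counts[bump] <- counts[bump] + 1L
      }
    }
    idx <- rep(seq_len(P), counts)
    w <- edgeWeight(net, pr[idx, 1], pr[idx, 2])
    mu <- params$scaleMin + (params$scaleMax - params$scaleMin) * w^params$gamma
    rating <- .rtruncnorm(length(idx), mu, params$sigma,
                          params$scaleMin, params$scaleMax)
    if (params$round) rating <- round(rating)
  })
  data.frame(word_i = pr[idx, 1], word_j = pr[idx, 2], rating = rating)
}

#' Grid search for response-model sensitivity parameters
#'
#' Generic tuning operation: evaluates a simulator over a parameter grid and
#' scores each point by the correlation between the simulated summary (e.g. a
#' first-response probability distribution, or a vector of mean ratings) and
#' a reference summary on the same support.
#'
#' @param simulator `function(params_row)` returning a numeric vector aligned
#'   with `reference` (a named list of one grid row is passed)
#' @param reference numeric vector; must not be constant
#' @param grid data.frame of parameter combinations, one row per candidate
#' @param metric `"pearson"` or `"spearman"`
#' @return list with `best` (the argmax row of `grid`), `surface` (`grid`
#'   plus a `score` column), and `metric`.
#' @export
sensitivityGridSearch <- function(simulator, reference, grid,
                                  metric = c("pearson", "spearman")) {
  metric <- match.arg(metric)
  grid <- as.data.frame(grid)
  if (nrow(grid) == 0) stop("empty parameter grid")
  if (stats::sd(reference) == 0) {
    stop("undefined correlation: constant reference")
  }
  method <- if (metric == "pearson") "pearson" else "spearman"
  score <- vapply(seq_len(nrow(grid)), function(i) {
    sim <- simulator(as.list(grid[i, , drop = FALSE]))
    if (length(sim) != length(reference)) {
      stop("simulator output length does not match the reference")
    }
    if (stats::sd(sim) == 0) return(NA_real_)
    stats::cor(sim, reference, method = method)
  }, numeric(1))
  if (all(is.na(score))) stop("all grid points produced constant output")
  surface <- cbind(grid, score = score)
  list(best = grid[which.max(score), , drop = FALSE],
       surface = surface, metric = metric)
}
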