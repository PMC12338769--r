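#' Cue-response frequency matrix
#'
#' Tabulates free-association records into a cues x responses count matrix.
#' Rows follow the cue-set order; columns are all words observed as responses
#' in the dataset (cues included when they occur as responses), in
#' lexicographic order. A cue absent from the data keeps an all-zero row (with
#' a warning), so node sets stay comparable across individuals.
#'
#' @param data data.frame with columns `cue` and `response`
#'   (see [simulateFA()])
#' @param cueset a [CueSet-class] or character vector of cues
#' @return integer matrix with dimnames `(cues, responses)`.
#' @export
cueResponseMatrix <- function(data, cueset) {
  cueVec <- .asCues(cueset)
  if (!all(c("cue", "response") %in% colnames(data))) {
    stop("data must have columns 'cue' and 'response'")
  }
  vocab <- sort(unique(as.character(data$response)))
  m <- matrix(0L, length(cueVec), max(length(vocab), 1L),
              dimnames = list(cueVec, if (length(vocab)) vocab else "<none>"))
  keep <- data$cue %in% cueVec
  absent <- setdiff(cueVec, unique(data$cue))
  if (length(absent)) {
    warning("cue(s) absent from the data, kept as all-zero rows: ",
            paste(absent, collapse = ", "))
  }
  if (any(keep) && length(vocab)) {
    tab <- table(factor(data$cue[keep], levels = cueVec),
                 factor(data$response[keep], levels = vocab))
    m[, vocab] <- as.integer(tab)
  }
  m
}

#' Positive pointwise mutual information transform
#'
#' Re-weights a count matrix cell-wise as
#' `max(0, log2(p(c, r) / (p(c) * p(r))))`, with all probabilities estimated
#' by maximum likelihood from the matrix totals (no smoothing). Cells with a
#' zero count map to 0, as do cells with negative pointwise mutual
#' information. PPMI sharpens the response distributions by discounting
#' responses that are frequent across all cues.
#'
#' @param m nonnegative count matrix with a positive total
#' @return real matrix of the same shape, everywhere >= 0.
#' @export
ppmiTransform <- function(m) {
  m <- as.matrix(m)
  N <- sum(m)
  if (N <= 0) stop("all-zero matrix")
  pc <- rowSums(m) / N
  pr <- colSums(m) / N
  expected <- outer(pc, pr)
  out <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
  nz <- m > 0
  out[nz] <- pmax(0, log2((m[nz] / N) / expected[nz]))
  out
}

#' Infer a semantic network from free-association data
#'
#' The standard association-based inference: build the cue-response frequency
#' matrix, optionally apply the PPMI transform (the default), and connect two
#' cues with an edge weighted by the cosine similarity of their (transformed)
#' response distributions. Rows are nonnegative, so weights lie in `[0, 1]`;
#' a cue with an all-zero row stays in the network as an isolated node.
#'
#' @param data free-association records (see [simulateFA()])
#' @param cueset a [CueSet-class] or character vector of cues
#' @param usePpmi apply [ppmiTransform()] before the cosine (default `TRUE`)
#' @return A [SemanticNetwork-class] with provenance `"inferred-FA"`.
#' @export
faInfer <- function(data, cueset, usePpmi = TRUE) {
  cueVec <- .asCues(cueset)
  m <- cueResponseMatrix(data, cueVec)
  if (usePpmi && sum(m) > 0) m <- ppmiTransform(m)
  nrm <- sqrt(rowSums(m^2))
  V <- m
  pos <- nrm > 0
  V[pos, ] <- m[pos, , drop = FALSE] / nrm[pos]
  S <- tcrossprod(V)
  S[!pos, ] <- 0
  S[, !pos] <- 0
  S[S > 1] <- 1
  diag(S) <- 0
  dimnames(S) <- list(cueVec, cueVec)
  S <- S[sort(cueVec), sort(cueVec), drop = FALSE]
  .fromAdjacency(S, provenance = "inferred-FA")
}

#' Infer a semantic network from relatedness-judgment data
#'
#' Ratings for the same unordered pair are averaged, then rescaled from the
#' rating scale to `[0, 1]`: `weight = (mean rating - scaleMin) / (scaleMax -
#' scaleMin)`. Unjudged pairs (and pairs whose rescaled weight is 0) get no
#' edge.
#'
#' @param data data.frame `word_i, word_j, rating` (see [simulateRJ()])
#' @param cueset a [CueSet-class] or character vector of cues
#' @param scaleMin,scaleMax rating scale bounds (default 1 and 20)
#' @return A [SemanticNetwork-class] with provenance `"inferred-RJ"`.
#' @export
rjInfer <- function(data, cueset, scaleMin = 1, scaleMax = 20) {
  cueVec <- .asCues(cueset)
  if (!all(c("word_i", "word_j", "rating") %in% colnames(data))) {
    stop("data must have columns word_i, word_j, rating")
  }
  if (nrow(data) > 0 &&
      (any(data$rating < scaleMin) || any(data$rating > scaleMax))) {
    stop(sprintf("rating(s) outside [%g, %g]", scaleMin, scaleMax))
  }
  bad <- setdiff(unique(c(data$word_i, data$word_j)), cueVec)
  if (length(bad)) {
    stop("judged word(s) outside the cue set: ", paste(bad, collapse = ", "))
  }
  lo <- pmin(data$word_i, data$word_j)
  hi <- pmax(data$word_i, data$word_j)
  key <- paste(lo, hi, sep = "\r")
  mean_rating <- tapply(data$rating, key, mean)
  parts <- strsplit(names(mean_rating), "\r", fixed = TRUE)
  edges <- data.frame(
    node_i = vapply(parts, `[[`, character(1), 1),
    node_j = vapply(parts, `[[`, character(1), 2),
    weight = as.numeric(mean_rating - scaleMin) / (scaleMax - scaleMin)
  )
  semanticNetwork(edges, nodes = cueVec, provenance = "inferred-RJ")
}
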