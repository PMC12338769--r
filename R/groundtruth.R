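#' Build a semantic network from word embeddings
#'
#' Constructs the common ground-truth network: nodes are words, edge weights
#' are cosine similarities between the words' embedding vectors, and pairs
#' with cosine below `cutoff` get no edge. Negative cosines never produce an
#' edge (they fall below any nonnegative cutoff; no absolute-value transform
#' is applied).
#'
#' @param emb numeric matrix of embeddings, one row per word, rownames = words
#' @param cutoff minimum edge weight retained, in `[0, 1)`; default 0.2
#' @return A [SemanticNetwork-class] with provenance `"ground-truth"`.
#' @examples
#' emb <- rbind(a = c(1, 0), b = c(1, 1))
#' edgeTable(cosineNetwork(emb, cutoff = 0.2))  # weight 1/sqrt(2)
#' @export
cosineNetwork <- function(emb, cutoff = 0.2) {
  emb <- as.matrix(emb)
  if (nrow(emb) < 2) stop("need at least 2 words")
  if (is.null(rownames(emb))) stop("embedding matrix must have word rownames")
  if (cutoff < 0 || cutoff >= 1) stop("cutoff must be in [0, 1)")
  nrm <- sqrt(rowSums(emb^2))
  if (any(nrm == 0)) {
    stop("zero-norm embedding vector(s): ",
         paste(rownames(emb)[nrm == 0], collapse = ", "))
  }
  V <- emb / nrm
  S <- tcrossprod(V)
  S[S < cutoff] <- 0
  S[S > 1] <- 1  # guard against fp overshoot on near-identical vectors
  diag(S) <- 0
  .fromAdjacency(S, provenance = "ground-truth")
}

#' Synthetic clustered word embeddings
#'
#' Download-free stand-in for a pre-trained embedding model. Words are
#' assigned round-robin to `nCommunities` community centers (random unit
#' vectors); each word vector is the unit-normalized sum of its center and
#' isotropic Gaussian noise of scale `withinNoise`. Small noise yields high
#' within-community and low between-community cosines, so the resulting
#' cosine network is modular, mimicking the clustered structure of lexical
#' semantic spaces.
#'
#' @param nWords vocabulary size (default 300)
#' @param dim embedding dimension (default 16)
#' @param nCommunities number of semantic clusters (default 6)
#' @param withinNoise isotropic noise scale, > 0 (default 0.35)
#' @param seed integer seed; identical seeds give identical tables
#' @return numeric matrix with rownames `w001 ...`.
#' @export
synthEmbeddings <- function(nWords = 300, dim = 16, nCommunities = 6,
                            withinNoise = 0.35, seed = 1) {
  if (nWords < nCommunities || nCommunities < 1) {
    stop("need nWords >= nCommunities >= 1")
  }
  if (dim < 2) stop("dim must be >= 2")
  if (withinNoise <= 0) stop("withinNoise must be > 0")
  withr::with_seed(as.integer(seed), {
    centers <- matrix(stats::rnorm(nCommunities * dim), nCommunities, dim)
    centers <- centers / sqrt(rowSums(centers^2))
    comm <- rep_len(seq_len(nCommunities), nWords)
    E <- centers[comm, , drop = FALSE] +
      matrix(stats::rnorm(nWords * dim, sd = withinNoise), nWords, dim)
    E <- E / sqrt(rowSums(E^2))
    rownames(E) <- sprintf("w%0*d", nchar(nWords), seq_len(nWords))
    attr(E, "community") <- stats::setNames(comm, rownames(E))
    E
  })
}

#' Lexicon constructors
#'
#' `lexicon()` validates and normalizes a named vector of frequencies or
#' counts. `synthFrequencies()` generates a Zipfian lexicon: the rank-k word
#' gets frequency proportional to `k^(-zipfExponent)`, ranks are assigned to
#' words at random, and frequencies are normalized to sum to 1.
#'
#' @param freq named numeric vector of positive frequencies or counts
#'   (normalized to sum 1)
#' @return A [Lexicon-class].
#' @export
lexicon <- function(freq) {
  if (is.null(names(freq))) stop("frequencies must be named by word")
  if (any(!is.finite(freq)) || any(freq <= 0)) {
    stop("frequencies must be positive and finite")
  }
  new("Lexicon", freq = freq / sum(freq))
}

#' @rdname lexicon
#' @param words character vector of words, or a single count (words are then
#'   named `w001 ...` to match [synthEmbeddings()])
#' @param zipfExponent Zipf exponent, >= 0 (0 = uniform; default 1)
#' @param seed integer seed for the random rank assignment
#' @export
synthFrequencies <- function(words, zipfExponent = 1, seed = 1) {
  if (is.numeric(words) && length(words) == 1) {
    words <- sprintf("w%0*d", nchar(words), seq_len(words))
  }
  n <- length(words)
  if (n < 1) stop("need at least one word")
  if (zipfExponent < 0) stop("zipfExponent must be >= 0")
  f <- seq_len(n)^(-zipfExponent)
  withr::with_seed(as.integer(seed), {
    f <- f[sample.int(n)]
  })
  lexicon(stats::setNames(f, words))
}

#' @describeIn lexicon accessor: named vector of relative frequencies
#' @param object a `Lexicon`
#' @export
setGeneric("frequencies", function(object) standardGeneric("frequencies"))

#' @rdname lexicon
#' @export
setMethod("frequencies", "Lexicon", function(object) object@freq)

#' Load embeddings in word2vec/fastText text format
#'
#' Reads the plain-text format whose first line is `n d` and whose remaining
#' lines are `word v1 ... vd`, restricted to a requested vocabulary. Words of
#' the vocabulary absent from the file are reported in the `"missing"`
#' attribute of the result (and with a warning).
#'
#' @param path file path
#' @param vocabulary character vector of words to keep; `NULL` keeps all
#' @return numeric matrix (rownames = words) with attribute `"missing"`.
#' @export
loadEmbeddings <- function(path, vocabulary = NULL) {
  lines <- readLines(path)
  if (length(lines) < 1) stop("empty embedding file")
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hdr) != 2 || anyNA(suppressWarnings(as.integer(hdr)))) {
    stop("malformed header line: expected 'n d'")
  }
  d <- as.integer(hdr[2])
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  parts <- strsplit(trimws(body), "\\s+")
  words <- vapply(parts, `[[`, character(1), 1)
  keep <- if (is.null(vocabulary)) seq_along(words) else which(words %in% vocabulary)
  vecs <- matrix(NA_real_, length(keep), d,
                 dimnames = list(words[keep], NULL))
  for (r in seq_along(keep)) {
    p <- parts[[keep[r]]]
    if (length(p) != d + 1) {
      stop(sprintf("dimension mismatch for word '%s': expected %d values, got %d",
                   p[1], d, length(p) - 1))
    }
    v <- suppressWarnings(as.numeric(p[-1]))
    if (anyNA(v)) stop(sprintf("malformed vector for word '%s'", p[1]))
    vecs[r, ] <- v
  }
  missing <- if (is.null(vocabulary)) character() else setdiff(vocabulary, words)
  if (length(missing)) {
    warning("words missing from embedding file: ",
            paste(missing, collapse = ", "))
  }
  attr(vecs, "missing") <- missing
  vecs
}

#' Read a word-frequency table
#'
#' Two-column CSV `word,count_or_frequency` (header optional in spirit but a
#' header row is expected); counts are normalized to relative frequencies.
#'
#' @param path file path
#' @param vocabulary optional character vector; restrict and renormalize
#' @return A [Lexicon-class].
#' @export
readFrequencies <- function(path, vocabulary = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("frequency table must have two columns: word, count")
  f <- stats::setNames(as.numeric(df[[2]]), as.character(df[[1]]))
  if (anyNA(f)) stop("non-numeric frequency value")
  if (!is.null(vocabulary)) {
    miss <- setdiff(vocabulary, names(f))
    if (length(miss)) {
      stop("words missing from frequency table: ", paste(miss, collapse = ", "))
    }
    f <- f[vocabulary]
  }
  lexicon(f)
}
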