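#' Cue-set generators
#'
#' Three ways of selecting the word list a simulated study probes, all
#' operating on the common ground-truth network and deterministic given a
#' seed:
#'
#' * `narrowCues()` grows one tight semantic neighborhood: starting from a
#'   uniformly drawn node, it repeatedly adds the not-yet-included neighbor
#'   of the current set with the highest average edge weight to the included
#'   nodes (averaging over existing edges to included nodes only; ties broken
#'   uniformly at random). Mimics single-category cue lists (animals,
#'   countries, ...).
#' * `broadCues()` takes a random walk: each step adds a uniformly random
#'   new neighbor of the most recently added node; when the walk gets stuck
#'   it restarts from a uniformly random already-included node. Mimics
#'   studies mapping wide portions of the lexicon.
#' * `mixedCues()` draws `floor(sqrt(size))` seeds by the broad procedure,
#'   then grows each seed into a tight neighborhood by the narrow procedure
#'   (batch sizes as equal as possible, remainder to the earliest seeds),
#'   never re-using an already-chosen cue. Mimics cue lists made of several
#'   groups of closely related words.
#'
#' If the reachable component is exhausted before `size` cues are found, an
#' error reports the achieved size rather than silently truncating.
#'
#' @param net the common ground-truth [SemanticNetwork-class]
#' @param size number of cues to select (>= 1)
#' @param seed integer seed
#' @return A [CueSet-class].
#' @export
narrowCues <- function(net, size, seed = 1) {
  stopifnot(is(net, "SemanticNetwork"), size >= 1)
  withr::with_seed(as.integer(seed), {
    nb <- .neighborList(net)
    start <- .resample(net@nodes, 1)
    cues <- .growNarrow(nb, start, size - 1L, exclude = character())
  })
  new("CueSet", cues = cues, type = "narrow", seed = as.integer(seed))
}

## greedy growth by highest average edge weight to the included set;
## `seedNodes` are already included, `nGrow` more are added. Assumes an
## active RNG state (callers wrap in with_seed).
.growNarrow <- function(nb, seedNodes, nGrow, exclude = character()) {
  cues <- seedNodes
  ## running sums of weight to included nodes per frontier candidate
  wsum <- numeric(0)
  wcnt <- integer(0)
  addNode <- function(node) {
    dat <- nb[[node]]
    for (idx in seq_along(dat$neighbor)) {
      v <- dat$neighbor[idx]
      if (v %in% cues || v %in% exclude) next
      if (is.na(wsum[v])) { wsum[v] <<- 0; wcnt[v] <<- 0L }
      wsum[v] <<- wsum[v] + dat$weight[idx]
      wcnt[v] <<- wcnt[v] + 1L
    }
    wsum <<- wsum[names(wsum) != node]
    wcnt <<- wcnt[names(wcnt) != node]
  }
  for (s in seedNodes) addNode(s)
  for (step in seq_len(nGrow)) {
    if (length(wsum) == 0) {
      stop(sprintf("component exhausted: achieved %d cue(s), requested %d",
                   length(cues), length(seedNodes) + nGrow))
    }
    avg <- wsum / wcnt
    best <- names(avg)[avg == max(avg)]
    pick <- if (length(best) > 1) .resample(best, 1) else best
    cues <- c(cues, pick)
    addNode(pick)
  }
  cues
}

#' @rdname narrowCues
#' @export
broadCues <- function(net, size, seed = 1) {
  stopifnot(is(net, "SemanticNetwork"), size >= 1)
  withr::with_seed(as.integer(seed), {
    nb <- .neighborList(net)
    start <- .resample(net@nodes, 1)
    cues <- .growBroad(nb, start, size - 1L)
  })
  new("CueSet", cues = cues, type = "broad", seed = as.integer(seed))
}

## random-walk growth; assumes active RNG state
.growBroad <- function(nb, start, nGrow) {
  cues <- start
  current <- start
  for (step in seq_len(nGrow)) {
    cand <- setdiff(nb[[current]]$neighbor, cues)
    while (length(cand) == 0) {
      ## walk is stuck: restart from a random included node with new neighbors
      open <- cues[vapply(cues, function(u) {
        length(setdiff(nb[[u]]$neighbor, cues)) > 0
      }, logical(1))]
      if (length(open) == 0) {
        stop(sprintf("component exhausted: achieved %d cue(s), requested %d",
                     length(cues), 1L + nGrow))
      }
      current <- .resample(open, 1)
      cand <- setdiff(nb[[current]]$neighbor, cues)
    }
    nxt <- .resample(cand, 1)
    cues <- c(cues, nxt)
    current <- nxt
  }
  cues
}

#' @rdname narrowCues
#' @export
mixedCues <- function(net, size, seed = 1) {
  stopifnot(is(net, "SemanticNetwork"), size >= 1)
  nBroad <- max(1L, floor(sqrt(size)))
  withr::with_seed(as.integer(seed), {
    nb <- .neighborList(net)
    start <- .resample(net@nodes, 1)
    seeds <- .growBroad(nb, start, nBroad - 1L)
    ## split the remaining cues into nBroad batches, remainder to the earliest
    remaining <- size - nBroad
    batch <- rep(remaining %/% nBroad, nBroad)
    if (remaining %% nBroad > 0) {
      batch[seq_len(remaining %% nBroad)] <- batch[seq_len(remaining %% nBroad)] + 1L
    }
    cues <- seeds
    for (b in seq_len(nBroad)) {
      if (batch[b] == 0) next
      grown <- .growNarrow(nb, seeds[b], batch[b],
                           exclude = setdiff(cues, seeds[b]))
      cues <- c(cues, setdiff(grown, seeds[b]))
    }
  })
  new("CueSet", cues = cues, type = "mixed", seed = as.integer(seed))
}

#' @describeIn narrowCues dispatch on the `type` string
#' @param type one of `"narrow"`, `"broad"`, `"mixed"`
#' @export
generateCues <- function(net, size, type, seed = 1) {
  switch(match.arg(type, c("narrow", "broad", "mixed")),
         narrow = narrowCues(net, size, seed),
         broad = broadCues(net, size, seed),
         mixed = mixedCues(net, size, seed))
}

#' @describeIn narrowCues accessor: the ordered cue words
#' @param object a `CueSet`
#' @export
setGeneric("cues", function(object) standardGeneric("cues"))

#' @rdname narrowCues
#' @export
setMethod("cues", "CueSet", function(object) object@cues)

## accept a CueSet or a plain character vector wherever cues are consumed
.asCues <- function(x) {
  if (is(x, "CueSet")) x@cues else as.character(x)
}

#' Enumerate the factorial study-design grid
#'
#' Full Cartesian product of the design axes in deterministic order
#' (paradigm varying slowest, responses per cue fastest). The default axes
#' reproduce the 2 paradigms x 3 cue set types x 3 cue set sizes x 3 response
#' counts = 54-cell grid.
#'
#' @param paradigms character, subset of
#'   `c("free_association", "relatedness_judgment")`
#' @param cueSetTypes character, subset of `c("narrow", "broad", "mixed")`
#' @param cueSetSizes integer vector of cue-set sizes (>= 2)
#' @param responsesPerCue integer vector of responses collected per cue
#' @param nInstantiations cue-set instantiations per design cell (default 10)
#' @param nParticipants simulated individuals per design cell (default 250)
#' @return data.frame, one row per design configuration, with a `design_id`
#'   column.
#' @examples
#' nrow(enumerateDesigns())  # 54
#' @export
enumerateDesigns <- function(paradigms = c("free_association", "relatedness_judgment"),
                             cueSetTypes = c("narrow", "broad", "mixed"),
                             cueSetSizes = c(10, 100, 1000),
                             responsesPerCue = c(3, 30, 300),
                             nInstantiations = 10,
                             nParticipants = 250) {
  if (!length(paradigms) || !length(cueSetTypes) ||
      !length(cueSetSizes) || !length(responsesPerCue)) {
    stop("every design axis must be non-empty")
  }
  if (any(cueSetSizes < 2)) stop("cue set sizes must be >= 2")
  if (any(responsesPerCue < 1)) stop("responses per cue must be >= 1")
  grid <- expand.grid(
    responses_per_cue = as.integer(responsesPerCue),
    cue_set_size = as.integer(cueSetSizes),
    cue_set_type = cueSetTypes,
    paradigm = paradigms,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid <- grid[, c("paradigm", "cue_set_type", "cue_set_size", "responses_per_cue")]
  grid$n_instantiations <- as.integer(nInstantiations)
  grid$n_participants <- as.integer(nParticipants)
  grid <- cbind(design_id = seq_len(nrow(grid)), grid)
  rownames(grid) <- NULL
  grid
}
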