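#' Default run configuration
#'
#' A desk-scale configuration for [runExperiment()]: a 300-word synthetic
#' ground truth, a small individualized population, and a reduced design
#' grid. Every field can be overridden through a YAML file
#' ([readRunConfig()]) or by passing a modified list.
#'
#' @return nested list of configuration defaults.
#' @export
defaultRunConfig <- function() {
  list(
    seed = 1,
    truth = list(
      source = "synthetic",       # or "embeddings"
      embeddings_path = NULL,     # word2vec/fastText text format
      frequencies_path = NULL,    # two-column CSV word,count
      n_words = 300, dim = 16, n_communities = 6, within_noise = 0.35,
      zipf_exponent = 1, cutoff = 0.2
    ),
    population = list(
      grid = NULL,                # data.frame p, r; NULL = default 25-pair grid
      reps = 10, cutoff = 0.2, cap = 1
    ),
    designs = list(
      paradigms = c("free_association", "relatedness_judgment"),
      cue_set_types = c("narrow", "broad", "mixed"),
      cue_set_sizes = c(10, 20),
      responses_per_cue = c(3, 30),
      n_instantiations = 2, n_participants = 10
    ),
    fa = list(gamma_w = 10, gamma_f = 1, responses_per_trial = 3,
              use_ppmi = TRUE),
    rj = list(gamma = 1, sigma = 3.85, scale_min = 1, scale_max = 20),
    cc_quantile = 0.5
  )
}

## overlay user values onto the defaults, recursively
.mergeConfig <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- .mergeConfig(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Read a run configuration from YAML
#'
#' Loads a YAML file and overlays it onto [defaultRunConfig()]; fields not
#' present in the file keep their defaults. `population$grid`, if given, must
#' be a list/table with columns `p` and `r`.
#'
#' @param path YAML file path
#' @return nested configuration list.
#' @export
readRunConfig <- function(path) {
  cfg <- .mergeConfig(defaultRunConfig(), yaml::read_yaml(path))
  if (!is.null(cfg$population$grid)) {
    cfg$population$grid <- as.data.frame(cfg$population$grid)
  }
  cfg
}

## build truth network + lexicon from a config
.buildTruth <- function(cfg, seed) {
  tc <- cfg$truth
  if (identical(tc$source, "embeddings")) {
    emb <- loadEmbeddings(tc$embeddings_path)
    lex <- if (!is.null(tc$frequencies_path)) {
      readFrequencies(tc$frequencies_path, vocabulary = rownames(emb))
    } else {
      synthFrequencies(rownames(emb), tc$zipf_exponent, seed = .deriveSeed(seed, 2))
    }
  } else {
    emb <- synthEmbeddings(tc$n_words, tc$dim, tc$n_communities,
                           tc$within_noise, seed = .deriveSeed(seed, 1))
    lex <- synthFrequencies(rownames(emb), tc$zipf_exponent,
                            seed = .deriveSeed(seed, 2))
  }
  list(net = cosineNetwork(emb, cutoff = tc$cutoff), lexicon = lex)
}

## simulate + infer one (design, instantiation, individual) cell
.inferOne <- function(paradigm, truth, cueset, nResponses, lex, cfg, seed) {
  if (paradigm == "free_association") {
    fa <- suppressWarnings(simulateFA(
      truth, cueset, nResponses, lex,
      params = faParams(cfg$fa$gamma_w, cfg$fa$gamma_f,
                        cfg$fa$responses_per_trial),
      seed = seed
    ))
    suppressWarnings(faInfer(fa, cueset, usePpmi = isTRUE(cfg$fa$use_ppmi)))
  } else {
    rj <- simulateRJ(
      truth, cueset, nResponses,
      params = rjParams(cfg$rj$gamma, cfg$rj$sigma,
                        cfg$rj$scale_min, cfg$rj$scale_max),
      seed = seed
    )
    rjInfer(rj, cueset, cfg$rj$scale_min, cfg$rj$scale_max)
  }
}

#' Run the full recovery simulation
#'
#' Executes the complete pipeline for every cell of the design grid: build
#' the common ground truth, individualize it into a population, draw cue-set
#' instantiations, simulate behavior for each individual, re-infer networks,
#' measure them, and score recovery locally and globally. All randomness is
#' derived deterministically from `config$seed`, so a rerun with the same
#' configuration reproduces the output files exactly. A failing design cell
#' is logged and skipped; the remaining cells still run.
#'
#' @param config nested list (see [defaultRunConfig()], [readRunConfig()])
#' @param outDir output directory; created if missing. Files written:
#'   `recovery_results.csv` (one row per design cell x measure x reference),
#'   `panels.csv` (per-individual between-network measures),
#'   `manifest.csv` (population manifest incl. perturbation seeds),
#'   `log.txt` (seeds, timings, skipped cells).
#' @return invisibly, the recovery results data.frame.
#' @export
runExperiment <- function(config = defaultRunConfig(), outDir = ".") {
  cfg <- .mergeConfig(defaultRunConfig(), config)
  seed <- as.integer(cfg$seed)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(outDir, "log.txt")
  logLines <- c(sprintf("run started; master seed %d", seed))

  truth <- .buildTruth(cfg, seed)
  logLines <- c(logLines, sprintf("ground truth: %d nodes, %d edges",
                                  numNodes(truth$net), numEdges(truth$net)))

  grid <- cfg$population$grid
  if (is.null(grid)) grid <- defaultPerturbationGrid()
  pop <- generatePopulation(truth$net, grid, reps = cfg$population$reps,
                            baseSeed = .deriveSeed(seed, 3),
                            cutoff = cfg$population$cutoff,
                            cap = cfg$population$cap)
  manifest <- attr(pop, "manifest")
  utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                   row.names = FALSE)

  designs <- enumerateDesigns(
    paradigms = cfg$designs$paradigms,
    cueSetTypes = cfg$designs$cue_set_types,
    cueSetSizes = cfg$designs$cue_set_sizes,
    responsesPerCue = cfg$designs$responses_per_cue,
    nInstantiations = cfg$designs$n_instantiations,
    nParticipants = cfg$designs$n_participants
  )
  nInd <- min(cfg$designs$n_participants, length(pop))
  individuals <- pop[seq_len(nInd)]

  results <- list()
  panels <- list()
  for (d in seq_len(nrow(designs))) {
    dc <- designs[d, ]
    cellLabel <- sprintf("design %d (%s/%s/size %d/%d responses)",
                         dc$design_id, dc$paradigm, dc$cue_set_type,
                         dc$cue_set_size, dc$responses_per_cue)
    cell <- tryCatch({
      cuesets <- lapply(seq_len(dc$n_instantiations), function(ii) {
        generateCues(truth$net, dc$cue_set_size, dc$cue_set_type,
                     seed = .deriveSeed(seed, 4, d, ii))
      })
      inferred <- lapply(seq_len(dc$n_instantiations), function(ii) {
        lapply(seq_len(nInd), function(di) {
          .inferOne(dc$paradigm, individuals[[di]], cuesets[[ii]],
                    dc$responses_per_cue, truth$lexicon, cfg,
                    seed = .deriveSeed(seed, 5, d, ii, di))
        })
      })
      loc <- evaluateDesign(individuals, inferred, cuesets, "local",
                            seed = .deriveSeed(seed, 6, d),
                            ccQuantile = cfg$cc_quantile)
      glob <- evaluateDesign(individuals, inferred, cuesets, "global",
                             seed = .deriveSeed(seed, 6, d),
                             ccQuantile = cfg$cc_quantile)
      res <- rbind(loc, glob)
      pan <- do.call(rbind, lapply(seq_len(dc$n_instantiations), function(ii) {
        do.call(rbind, lapply(seq_len(nInd), function(di) {
          bm <- betweenMeasures(measurePanel(
            inferred[[ii]][[di]], seed = .deriveSeed(seed, 7, d, ii, di),
            ccQuantile = cfg$cc_quantile))
          data.frame(design_id = dc$design_id, instantiation = ii,
                     individual_id = di, measure = names(bm),
                     value = as.numeric(bm), row.names = NULL)
        }))
      }))
      list(res = res, pan = pan)
    }, error = function(e) {
      logLines <<- c(logLines, sprintf("SKIPPED %s: %s", cellLabel,
                                       conditionMessage(e)))
      NULL
    })
    if (is.null(cell)) next
    cell$res <- cbind(dc[rep(1, nrow(cell$res)),
                         c("design_id", "paradigm", "cue_set_type",
                           "cue_set_size", "responses_per_cue")],
                      cell$res)
    results[[length(results) + 1L]] <- cell$res
    panels[[length(panels) + 1L]] <- cell$pan
    logLines <- c(logLines, sprintf("done %s", cellLabel))
  }

  out <- if (length(results)) do.call(rbind, results) else data.frame()
  rownames(out) <- NULL
  utils::write.csv(out, file.path(outDir, "recovery_results.csv"),
                   row.names = FALSE)
  if (length(panels)) {
    utils::write.csv(do.call(rbind, panels), file.path(outDir, "panels.csv"),
                     row.names = FALSE)
  }
  writeLines(logLines, logPath)
  invisible(out)
}
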