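test_that("bias is the geometric mean ratio minus one", {
  expect_equal(as.numeric(recoveryBias(c(1, 2, 3), c(1, 2, 3))), 0)
  expect_equal(as.numeric(recoveryBias(c(2, 4), c(1, 2))), 1)
  expect_equal(as.numeric(recoveryBias(c(2, 1), c(1, 2))), 0)  # 2 and 0.5 cancel
  # nonpositive ratios are excluded and counted
  b <- recoveryBias(c(2, -1, 0), c(1, 1, 1))
  expect_equal(as.numeric(b), 1)
  expect_equal(attr(b, "n_excluded"), 2)
  expect_true(is.na(recoveryBias(c(-1, 0), c(1, 1))))
  expect_error(recoveryBias(1:3, 1:2), "length mismatch")
  # scale consistency: inflating estimates by lambda maps bias exactly
  x <- c(1.2, 0.7, 2.2); y <- c(1.1, 0.9, 1.8)
  b0 <- as.numeric(recoveryBias(x, y))
  expect_equal(as.numeric(recoveryBias(3 * x, y)), (1 + b0) * 3 - 1,
               tolerance = 1e-12)
})

test_that("resolution is tie-corrected Spearman, monotone-invariant", {
  truth <- c(1, 2, 3, 4)
  expect_equal(recoveryResolution(exp(truth), truth), 1)
  expect_equal(recoveryResolution(rev(truth), truth), -1)
  expect_equal(recoveryResolution(c(1, 3, 2, 4), truth), 0.8)
  expect_error(recoveryResolution(c(1, 1, 1), truth[1:3]), "constant")
})

test_that("within-network resolution averages per-individual correlations", {
  perfect <- list(inferred = c(1, 2, 3, 4), truth = c(2, 4, 6, 8))
  null_r <- list(inferred = c(1, 2, 3, 4), truth = c(2, 4, 1, 3))  # rho = 0
  expect_equal(as.numeric(withinNetworkResolution(list(perfect, perfect))), 1)
  expect_equal(as.numeric(withinNetworkResolution(list(perfect, null_r))), 0.5)
  # constant vectors are skipped and counted
  flat <- list(inferred = c(0, 0, 0, 0), truth = c(1, 2, 3, 4))
  out <- withinNetworkResolution(list(perfect, flat))
  expect_equal(as.numeric(out), 1)
  expect_equal(attr(out, "n_skipped"), 1)
  expect_true(is.na(withinNetworkResolution(list(flat))))
  # agreement with direct computation on random fixtures
  withr::with_seed(5, {
    prs <- lapply(1:6, function(i) list(inferred = rnorm(10), truth = rnorm(10)))
  })
  direct <- mean(sapply(prs, function(p) cor(p$inferred, p$truth,
                                             method = "spearman")))
  expect_equal(as.numeric(withinNetworkResolution(prs)), direct,
               tolerance = 1e-12)
})

test_that("perfect recovery scores zero bias and unit resolution", {
  truth <- generatePopulation(fixture_truth(40, 2, seed = 71),
                              data.frame(p = c(0, 0.4, 0.75), r = c(0, 0.5, 1)),
                              reps = 2, baseSeed = 3)
  cs1 <- cues(broadCues(fixture_truth(40, 2, seed = 71), 8, seed = 1))
  cs2 <- cues(broadCues(fixture_truth(40, 2, seed = 71), 8, seed = 2))
  inferred <- lapply(list(cs1, cs2), function(cs) {
    lapply(truth, function(tn) inducedSubgraph(tn, cs))
  })
  res <- evaluateDesign(truth, inferred, list(cs1, cs2), "local", seed = 9)
  between <- res[res$measure %in% c("average_strength", "aspl"), ]
  expect_equal(between$bias, rep(0, 2), tolerance = 1e-9)
  expect_equal(between$resolution, rep(1, 2), tolerance = 1e-9)
  expect_true(all(between$acceptable_bias, between$acceptable_resolution))
  expect_equal(unique(res$n_pairs[res$measure == "aspl"]), 12)  # 2 inst x 6 ind
  # within-network rows appear only under the local reference
  expect_setequal(
    res$measure,
    c("average_strength", "aspl", "average_cc", "modularity",
      "edge_weight", "node_strength")
  )
  glob <- evaluateDesign(truth, inferred, list(cs1, cs2), "global", seed = 9)
  expect_setequal(glob$measure,
                  c("average_strength", "aspl", "average_cc", "modularity"))
  expect_equal(glob$reference, rep("global", 4))
})

test_that("evaluateDesign validates its pairing structure", {
  truth <- generatePopulation(fixture_truth(30, 2, seed = 73),
                              data.frame(p = 0.5, r = 0.5), reps = 3)
  cs <- cues(broadCues(fixture_truth(30, 2, seed = 73), 6, seed = 1))
  inferred <- list(lapply(truth[1:2], function(tn) inducedSubgraph(tn, cs)))
  expect_error(evaluateDesign(truth, inferred, list(cs), "local"),
               "missing inferred")
  expect_error(evaluateDesign(truth, list(), list(cs), "local"),
               "one cue set per instantiation")
})

test_that("null effects reject at the nominal rate", {
  pow <- powerSimulation(0.5, effectD = 0, nPerGroup = 100, alpha = 0.05,
                         nSims = 4000, seed = 2)
  se <- sqrt(0.05 * 0.95 / 4000)
  expect_lt(abs(pow - 0.05), 3 * se)
})

test_that("perfect measurement at d = 0.5, n = 200 is near-certain detection", {
  pow <- powerSimulation(1, 0.5, 200, 0.05, nSims = 4000, seed = 3)
  # closed-form normal approximation: Phi(0.5 * sqrt(100) - 1.645)
  expect_gt(pow, 0.995)
})

test_that("required sample sizes follow the attenuation closed form", {
  n_full <- requiredN(1, 0.5, 0.8, 0.05)
  expect_lte(abs(n_full - 50), 1)  # classic one-sided n for d = 0.5
  n_half <- requiredN(0.5, 0.5, 0.8, 0.05)
  # halving resolution quadruples the required n (d attenuates to d * r)
  expect_lt(abs(n_half / n_full - 4), 0.25)
  # monotonicity in resolution
  ns <- sapply(c(0.3, 0.5, 0.7, 1), function(r) requiredN(r, 0.5))
  expect_true(all(diff(ns) <= 0))
  expect_error(requiredN(0, 0.5), "unattainable")
  # simulated power at the returned n meets the target
  pow <- powerSimulation(0.5, 0.5, n_half, nSims = 4000, seed = 4)
  expect_gt(pow, 0.8 - 3 * sqrt(0.8 * 0.2 / 4000))
})

test_that("runExperiment writes a reproducible result set", {
  cfg <- defaultRunConfig()
  cfg$seed <- 11
  cfg$truth$n_words <- 60
  cfg$truth$n_communities <- 3
  cfg$population <- list(grid = data.frame(p = c(0, 0.5, 0.75),
                                           r = c(0.25, 0.5, 1)),
                         reps = 2, cutoff = 0.2, cap = 1)
  cfg$designs <- list(paradigms = c("free_association", "relatedness_judgment"),
                      cue_set_types = "mixed", cue_set_sizes = 8,
                      responses_per_cue = 3,
                      n_instantiations = 2, n_participants = 5)
  d1 <- withr::local_tempdir()
  res <- runExperiment(cfg, d1)
  # 2 design cells x (6 local rows + 4 global rows)
  expect_equal(nrow(res), 2 * 10)
  expect_true(all(c("recovery_results.csv", "panels.csv", "manifest.csv",
                    "log.txt") %in% list.files(d1)))
  pan <- read.csv(file.path(d1, "panels.csv"))
  expect_equal(sort(unique(pan$measure)),
               c("aspl", "average_cc", "average_strength", "modularity"))
  # rerun with the same config and seed is byte-identical
  d2 <- withr::local_tempdir()
  runExperiment(cfg, d2)
  for (f in c("recovery_results.csv", "panels.csv", "manifest.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("run configurations merge YAML overrides onto defaults", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("seed: 99", "truth:", "  n_words: 42", "designs:",
               "  cue_set_sizes: [5, 9]"), path)
  cfg <- readRunConfig(path)
  expect_equal(cfg$seed, 99)
  expect_equal(cfg$truth$n_words, 42)
  expect_equal(cfg$designs$cue_set_sizes, c(5, 9))
  expect_equal(cfg$truth$cutoff, 0.2)  # untouched default
})
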