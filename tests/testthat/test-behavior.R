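# cue "j" with two neighbors of weights 0.5 and 0.25
two_neighbor_net <- function() {
  semanticNetwork(data.frame(
    node_i = c("j", "j"), node_j = c("x", "y"), weight = c(0.5, 0.25)
  ))
}

test_that("faDistribution implements the similarity-frequency retrieval rule", {
  net <- two_neighbor_net()
  lexEq <- lexicon(c(j = 1, x = 1, y = 1))
  # similarity only, gammaW = 1: probabilities proportional to the weights
  p <- faDistribution(net, "j", lexEq, faParams(gammaW = 1, gammaF = 0))
  expect_equal(unname(p[c("x", "y")]), c(2, 1) / 3)
  # frequency only
  lexF <- lexicon(c(j = 0.97, x = 0.02, y = 0.01))
  pf <- faDistribution(net, "j", lexF, faParams(gammaW = 0, gammaF = 1))
  expect_equal(unname(pf[c("x", "y")]), c(2, 1) / 3)
  # gammaW = 10 sharpens a 2:1 weight ratio into 2^10 : 1 odds
  ps <- faDistribution(net, "j", NULL, faParams(gammaW = 10, gammaF = 0))
  expect_equal(unname(ps[c("x", "y")]), c(1024, 1) / 1025)
  # support excludes non-neighbors and the cue itself; sums to one
  expect_false("j" %in% names(p))
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_error(faDistribution(net, "j", lexEq, faParams(),
                              exclude = c("x", "y")), "empty support")
})

test_that("faDistribution normalizes over every cue of a realistic network", {
  net <- fixture_truth(40, 2, seed = 41)
  lex <- synthFrequencies(nodes(net), 1, seed = 5)
  for (cue in nodes(net)[1:15]) {
    p <- faDistribution(net, cue, lex)
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
})

test_that("the top response concentrates as similarity sensitivity grows", {
  net <- fixture_truth(30, 2, seed = 43)
  cue <- nodes(net)[1]
  pmax_at <- vapply(c(0.5, 1, 2, 5, 10, 20), function(gw) {
    max(faDistribution(net, cue, NULL, faParams(gammaW = gw, gammaF = 0)))
  }, numeric(1))
  expect_true(all(diff(pmax_at) >= -1e-12))
})

test_that("frequency neutrality: gammaF = 0 ignores the lexicon", {
  net <- two_neighbor_net()
  lexA <- lexicon(c(j = 0.1, x = 0.8, y = 0.1))
  lexB <- lexicon(c(j = 0.8, x = 0.1, y = 0.1))
  pA <- faDistribution(net, "j", lexA, faParams(gammaW = 3, gammaF = 0))
  pB <- faDistribution(net, "j", lexB, faParams(gammaW = 3, gammaF = 0))
  expect_equal(pA, pB)
})

test_that("simulateFA books trials and positions correctly", {
  net <- fixture_truth(40, 2, seed = 45)
  lex <- synthFrequencies(nodes(net), 1, seed = 5)
  cs <- nodes(net)[1:10]
  fa <- simulateFA(net, cs, 3, lex, seed = 2)
  expect_equal(nrow(fa), 30)  # 10 cues x 3 responses
  expect_true(all(fa$response != fa$cue))
  # positions within a trial are distinct
  expect_true(all(tapply(fa$position, paste(fa$cue, fa$trial),
                         anyDuplicated) == 0))
  # within a trial, responses are distinct (sampling without replacement)
  expect_true(all(tapply(fa$response, paste(fa$cue, fa$trial),
                         anyDuplicated) == 0))
  # determinism
  expect_identical(fa, simulateFA(net, cs, 3, lex, seed = 2),
                   ignore_attr = TRUE)
  # forced draw: single neighbor, one response
  pair <- semanticNetwork(data.frame(node_i = "a", node_j = "b", weight = 0.9))
  one <- simulateFA(pair, "a", 1, NULL, faParams(gammaF = 0), seed = 1)
  expect_equal(one$response, "b")
})

test_that("first-response frequencies match the exact distribution", {
  net <- two_neighbor_net()
  p <- faDistribution(net, "j", NULL, faParams(gammaW = 2, gammaF = 0))
  fa <- simulateFA(net, rep("j", 1), 10000, NULL,
                   faParams(gammaW = 2, gammaF = 0, responsesPerTrial = 1),
                   seed = 8)
  phat <- mean(fa$response == "x")
  se <- sqrt(p[["x"]] * (1 - p[["x"]]) / 10000)
  expect_lt(abs(phat - p[["x"]]), 3 * se)
})

test_that("cues without neighbors are skipped with a warning", {
  net <- semanticNetwork(data.frame(node_i = "a", node_j = "b", weight = 0.9),
                         nodes = c("a", "b", "lonely"))
  expect_warning(fa <- simulateFA(net, c("a", "lonely"), 3, NULL,
                                  faParams(gammaF = 0), seed = 1),
                 "skipped")
  expect_identical(attr(fa, "skipped_cues"), "lonely")
  expect_true(all(fa$cue == "a"))
})

test_that("simulateRJ allocates the judgment budget over pairs", {
  net <- fixture_truth(40, 2, seed = 47)
  cs <- nodes(net)[1:10]
  # budget 30 < 45 pairs: 30 distinct pairs rated once
  rj <- simulateRJ(net, cs, 3, seed = 3)
  expect_equal(nrow(rj), 30)
  expect_equal(anyDuplicated(paste(rj$word_i, rj$word_j)), 0)
  # budget 300 over 45 pairs: 6 or 7 ratings per pair, every pair judged
  rj2 <- simulateRJ(net, cs, 30, seed = 3)
  counts <- table(paste(rj2$word_i, rj2$word_j))
  expect_equal(length(counts), 45)
  expect_true(all(counts %in% c(6, 7)))
  expect_equal(sum(counts), 300)
  # ratings stay on the scale; runs are seed-deterministic
  expect_true(all(rj2$rating >= 1 & rj2$rating <= 20))
  expect_identical(rj2, simulateRJ(net, cs, 30, seed = 3))
})

test_that("noiseless judgments sit exactly at the mapped location", {
  net <- semanticNetwork(data.frame(node_i = "a", node_j = "b", weight = 1))
  # budget: 2 cues x 1 response = 2 ratings on the single pair
  rj <- simulateRJ(net, c("a", "b"), 1, rjParams(sigma = 0), seed = 1)
  expect_equal(rj$rating, c(20, 20))  # w = 1 maps to the top of the scale
  half <- semanticNetwork(data.frame(node_i = "a", node_j = "b", weight = 0.5))
  rjh <- simulateRJ(half, c("a", "b"), 1, rjParams(sigma = 0), seed = 1)
  expect_equal(rjh$rating, rep(1 + 19 * 0.5, 2))
})

test_that("grid search recovers generating parameters and scores identity as 1", {
  net <- fixture_truth(30, 2, seed = 49)
  cue <- nodes(net)[1]
  reference <- faDistribution(net, cue, NULL, faParams(gammaW = 5, gammaF = 0))
  sim <- function(par) {
    faDistribution(net, cue, NULL,
                   faParams(gammaW = par$gammaW, gammaF = 0))[names(reference)]
  }
  fit <- sensitivityGridSearch(sim, reference,
                               data.frame(gammaW = c(1, 5, 15)), "pearson")
  expect_equal(fit$best$gammaW, 5)
  expect_equal(max(fit$surface$score), 1, tolerance = 1e-9)
  # a one-point grid returns that point
  one <- sensitivityGridSearch(sim, reference, data.frame(gammaW = 2))
  expect_equal(one$best$gammaW, 2)
  expect_error(sensitivityGridSearch(sim, rep(1, length(reference)),
                                     data.frame(gammaW = 2)), "constant")
})

test_that("noisy grid search recovers the generating parameter modally", {
  net <- fixture_truth(30, 2, seed = 51)
  cueVec <- nodes(net)[1:8]
  grid <- data.frame(gammaW = c(2, 10, 25))
  hits <- 0L
  for (rep in 1:20) {
    fa <- suppressWarnings(simulateFA(
      net, cueVec, 60, NULL,
      faParams(gammaW = 10, gammaF = 0, responsesPerTrial = 1), seed = rep
    ))
    firsts <- fa[fa$position == 1 & fa$trial <= 60, ]
    obs <- table(factor(firsts$response, levels = nodes(net))) /
      max(nrow(firsts), 1)
    sim <- function(par) {
      p <- numeric(length(nodes(net)))
      names(p) <- nodes(net)
      for (cue in cueVec) {
        d <- faDistribution(net, cue, NULL,
                            faParams(gammaW = par$gammaW, gammaF = 0))
        p[names(d)] <- p[names(d)] + d / length(cueVec)
      }
      p
    }
    fit <- sensitivityGridSearch(sim, as.numeric(obs), grid, "pearson")
    hits <- hits + (fit$best$gammaW == 10)
  }
  expect_gt(hits, 10)  # modal argmax at the generating value
})
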