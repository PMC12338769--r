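---
title: "Measuring individual semantic networks: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring individual semantic networks: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semnetrecover)
```

## The problem

Semantic memory is often modeled as a weighted network: words are nodes,
edge weights encode relatedness. Empirical studies estimate such networks per
person from behavioral data — free associations (produce associates to a cue)
or relatedness judgments (rate a word pair on a numerical scale) — and then
compare structural measures between individuals or groups. Whether those
comparisons mean anything depends on the psychometrics of the whole pipeline:
is a measure estimated without systematic distortion (*bias*), does it
preserve the ordering of individuals (*resolution*), and does a measure taken
on the studied cue set speak for the network beyond it
(*generalizability*)?

`semnetrecover` answers these questions by recovery simulation: it generates
a population of individualized ground-truth networks, simulates behavioral
data from them under a configurable study design, re-infers networks from
that data exactly as an empirical study would, and scores the inferred
against the true measures. Because the ground truth is known, every
distortion observed is attributable to the design and inference method.

## Ground truth

The common ground truth is a cosine-similarity network over word embeddings:
edge weight = cosine of the two word vectors, pairs below a minimum weight
(default `cutoff = 0.2`) get no edge. The cutoff is applied once, at
construction; all downstream stages see only the thresholded network.
Negative cosines fall below any nonnegative cutoff and never produce edges;
no absolute-value transform is applied.

Two sources are supported. External word2vec/fastText-format vectors can be
loaded with `loadEmbeddings()`, paired with a word-frequency table
(`readFrequencies()`). The default, download-free source is
`synthEmbeddings()`: words are assigned round-robin to community centers
(random unit vectors) and each word vector is the unit-normalized center plus
isotropic Gaussian noise. The defaults — 300 words, dimension 16, 6
communities, noise scale 0.35 — were chosen once so that the 0.2-cutoff
network is connected and modular (Louvain modularity clearly above 0),
i.e. it has the clustered topology that makes narrow/broad/mixed cue sets
meaningfully different. What the generator does *not* emulate: hub words,
part-of-speech structure, the heavy-tailed degree profile of full-vocabulary
lexical networks, or any correlation between frequency and connectivity
(the Zipfian lexicon from `synthFrequencies()` assigns ranks to words at
random). Passing tests therefore certify the machinery and its directional
behavior, not quantitative recovery rates on real lexica.

## Individualization

`perturbNetwork()` derives one individual from the common truth. Each edge
carries a triangle score — the sum over all triangles through the edge of
the product of the three edge weights — so that perturbation can target
edges that carry clustering. Half of the edges are sampled as sources, a
proportion `p` of them from the above-median triangle-score half; each
source draws an independent weight fraction `k ~ Uniform(0, 1)`; a fraction
`1 - r` of sources simply lose `k` of their weight, the remaining `floor(r *
S)` relocate it to a non-source edge drawn proportionally to its current
weight; finally edges below the cutoff are pruned. `p` therefore lowers
average clustering, `r` preserves average strength (with `r = 1`, the cap
disabled and pruning off, total weight is conserved exactly).

Choices where the procedure was genuinely open:

* **One `k` per source edge**, not one shared draw — a single shared `k`
  would make the reduction step degenerate (every reduced edge scaled by the
  same factor).
* **Median ties go to the "above" half**; in a triangle-free graph all
  scores tie at 0 and source sampling falls back to uniform.
* **Relocation is sequential** and targets are capped at weight 1 (the
  cosine scale); excess is discarded. Relocated weight is drawn from the
  source *after* its own reduction would have applied — i.e. the moved mass
  is `k` times the source's current weight at relocation time.
* **The default grid** `p in {0, .1875, .375, .5625, .75} x r in {0, .25,
  .5, .75, 1}` spans the documented parameter ranges uniformly; with 10
  repetitions it yields a 250-individual population. A grid tuned to a
  specific ground truth can be selected with `decorrelationCheck()`, which
  reports the strength-clustering correlation across a candidate population.

## Behavioral simulation

**Free association** (`simulateFA()`): the probability of producing response
*i* to cue *j* is

\[
P(i \mid j) = \frac{w_{ij}^{\gamma_w} f_i^{\gamma_f}}
  {\sum_i w_{ij}^{\gamma_w} f_i^{\gamma_f}},
\]

combining edge weight (local similarity) and relative word frequency
(global availability). Defaults \(\gamma_w = 10\), \(\gamma_f = 1\) are the
values that best reproduce large public association norms. Responses come in
trials of 3 (the common norming convention); within a trial sampling is
without replacement with renormalization, across trials the support resets.
Only network neighbors of the cue are candidates — an absent edge means
probability zero — and a cue with no neighbors is skipped with a warning.

**Relatedness judgment** (`simulateRJ()`): a rating for pair *(i, j)* is
drawn from a truncated normal on the 1–20 scale with location
\(\mu = 1 + 19\, w_{ij}^{\gamma}\) and SD \(\sigma\), defaults
\(\gamma = 1\), \(\sigma = 3.85\). The location map is an explicit choice:
the generating model places a \([0, 1]\)-scale similarity on a 1–20 scale,
and the affine map of \([0,1]\) onto \([1,20]\) is the unique choice that
makes the inference rescaling (below) its exact inverse — with \(\sigma = 0\)
and full pair coverage, recovery is exact by construction, which the tests
verify end to end. An alternative reading of the noise scale
(\(\sigma = 0.15\) on the 0–1 scale, i.e. 2.85 rating points) can be
configured via `rjParams()`. Sampling uses the inverse-CDF construction so
results are exactly seed-reproducible, and ratings are continuous by default
(integer rounding is an option). The judgment budget (cues × responses) is
spread over pairs as evenly as possible; a budget below the number of pairs
rates a uniform random subset once.

`sensitivityGridSearch()` exposes the tuning procedure generically: any
simulator, any reference summary on the same support, Pearson or Spearman
scoring, returning the full score surface and argmax.

## Inference

Free associations: `faInfer()` builds the cue × response count matrix over
the responses observed in the dataset (column order lexicographic), applies
the PPMI transform by default (`max(0, log2 p(c,r)/(p(c)p(r)))`, maximum
likelihood estimates, no smoothing, base 2 fixed for determinism), and
connects cues by the cosine of their transformed rows. Cues never observed
stay in the network as isolated nodes so node sets remain comparable across
individuals. Relatedness judgments: `rjInfer()` averages repeated ratings
per pair and rescales to \([0, 1]\) by `(mean - 1) / 19`; unjudged pairs get
no edge.

## Network measures

`measurePanel()` computes, with shared conventions:

* **edge weight** and **node strength** (within-network measures),
* **average strength** — mean strength over all nodes, isolated nodes as 0;
* **ASPL** — step cost \(1 - w\), cheapest-path distances (Dijkstra; weight-1
  edges cost 0), averaged over connected ordered pairs only. Disconnected
  pairs are dropped rather than poisoning the mean, which keeps the measure
  defined on sparse inferred networks; with no connected pair it is `NA`;
* **average CC** — the strength-normalized weighted local clustering
  \(cc_i = \frac{1}{s_i (k_i - 1)} \sum_{j,h} \frac{w_{ij} + w_{ih}}{2}
  a_{ij} a_{ih} a_{jh}\), computed after restricting to the 50% strongest
  edges (weights at or above the median; ties kept; `edgeQuantile = 0`
  disables the filter) to avoid ceiling effects; nodes with fewer than two
  retained neighbors are excluded, and with no eligible node the measure is
  `NA`;
* **modularity** — weighted Louvain communities (resolution 1, seeded;
  optional best-of-`nRestarts`), scored by
  \(Q = \frac{1}{2m}\sum_{ij}(a_{ij} - \frac{s_i s_j}{2m})
  \delta(c_i, c_j)\) with \(2m\) the total edge weight counted in both
  directions. `m` is total *weight*, not edge count: the strength terms in
  the formula require the weighted null model, so the weighted reading is
  the consistent one.

## Recovery evaluation

`evaluateDesign()` compares inferred networks to the individualized truths.
Bias is the geometric mean of inferred/truth ratios minus one (computed as
`exp(mean(log ratio)) - 1`); ratios that are nonpositive — possible for
modularity — are excluded pairwise and counted, and an all-excluded cell is
`NA` rather than a number. Resolution is the tie-corrected Spearman
correlation. The local reference is the truth restricted to the cue set; the
global reference (the generalizability analysis) is the full truth network.
Between-network measures pool all individual × instantiation pairs into one
bias and one resolution per measure — at full scale 10 × 250 = 2,500 points
per cell — rather than averaging per-instantiation statistics; within-network
measures are evaluated per individual (absent inferred edges enter as weight
0, since they are absences by inference, not missing data) and averaged, for
the local reference only. Acceptability bands: |bias| ≤ 0.3 and resolution
≥ 0.5.

The resolution band connects to study planning through attenuation: if a
measure correlates with the truth at *r*, a true group difference *d* is
observable only as ≈ *d·r*. `powerSimulation()` implements this with
observed = true + independent Gaussian noise calibrated so that
corr(observed, truth) = *r* — the simplest model consistent with resolution
being a truth–estimate correlation — and a one-sided two-sample t-test. At
*r* = .5, *d* = 0.5, *n* = 200 per group, α = .05 the simulated power is
0.80, which is what motivates the resolution ≥ .5 band. `requiredN()`
inverts the closed-form noncentral-t power for sample-size planning; halving
resolution quadruples the required n.

## Orchestration and problem sizes

`runExperiment()` chains all stages over a factorial design grid from a
single configuration (R list or YAML via `readRunConfig()`), with every seed
derived deterministically from the master seed; identical configurations
yield byte-identical result files. The full published-scale grid (54 cells,
13,486-word truth, 250 individuals, 10 instantiations — 135,000 inferred
networks) is enumerable here but is a cluster-scale computation; the package
default configuration runs the same pipeline at desk scale (300-word truth,
reduced grid). The test suite exercises the directional findings on a
200-word truth with 20 individuals, 20-cue mixed sets, and 20 replicates,
and verifies the measure implementations against brute-force oracles on
small random graphs. These sizes are the package's validation conditions;
they demonstrate the machinery and the direction of the design effects, not
full-scale effect magnitudes.

## Known limitations

* The synthetic ground truth is far smaller and more regular than a real
  lexicon; absolute bias/resolution values at desk scale do not transfer.
* Retrieval parameters are constant across simulated individuals; real
  populations likely vary in both representation and process.
* One inference method per paradigm (PPMI+cosine; rescale+average). Variants
  such as random-walk similarity or response-word nodes are out of scope.
* Louvain is stochastic; modularity values are seed-dependent on graphs with
  ambiguous community structure (the seed is part of every call signature).
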