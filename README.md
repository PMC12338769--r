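# semnetrecover

Recovery simulation for individual semantic networks.

Studies of semantic memory estimate a weighted word network per person from
behavioral data — free associations (FA) or relatedness judgments (RJ) — and
compare structural measures between people. `semnetrecover` asks whether such
a study can work *before* it is run: it generates a population of
individualized ground-truth networks, simulates the behavioral data a given
study design would collect, re-infers networks from that data the way an
empirical study would, and scores the recovery. It is aimed at researchers
designing (or re-interpreting) individual-difference studies of semantic
networks.

## The model in brief

* **Ground truth.** A cosine-similarity network over word embeddings
  (synthetic clustered embeddings by default; external word2vec/fastText
  vectors optionally), thresholded at a minimum edge weight (default 0.2).
* **Individualization.** A graph perturbation algorithm redistributes edge
  weight guided by per-edge *triangle scores*
  (`ts_e = Σ_triangles Π w`): a proportion *p* of source edges is drawn from
  the above-median triangle-score half (controlling clustering), and a
  proportion *r* of sources relocates weight instead of losing it
  (controlling strength). Edges falling below the cutoff are pruned.
* **Behavior.** FA responses follow
  `P(i|j) ∝ w_ij^γw · f_i^γf` (defaults γw = 10, γf = 1, with Zipfian word
  frequencies `f`); RJ ratings follow a truncated normal on the 1–20 scale,
  `RJ(i,j) ~ TN(1 + 19·w_ij^γ, σ², 1, 20)` (defaults γ = 1, σ = 3.85).
* **Inference.** FA: cue-response counts → PPMI → cosine between cue rows.
  RJ: ratings averaged per pair and rescaled to [0, 1].
* **Measures.** Edge weight, node strength, average strength, ASPL (step
  cost 1 − w), Barrat-style weighted clustering on the 50% strongest edges,
  and weighted Louvain modularity.
* **Scoring.** *Bias* = geometric mean of inferred/truth ratios − 1
  (acceptable within ±0.3); *resolution* = Spearman correlation between
  inferred and true measures (acceptable at ≥ 0.5, which corresponds to 80%
  power for a d = 0.5 group difference at n = 200/group, one-sided α = .05);
  *generalizability* = both, referenced to the full truth network instead of
  the cue-set sub-network.

## Worked example

Build a 120-word clustered truth, individualize it, simulate a
free-association study (15 mixed cues, 30 responses per cue) for 10
individuals, and score the recovery:

```r
library(semnetrecover)

emb   <- synthEmbeddings(nWords = 120, nCommunities = 4, seed = 3)
truth <- cosineNetwork(emb, cutoff = 0.2)
truth
#> SemanticNetwork (ground-truth): 120 nodes, 2516 edges
#>   weight range: [0.2001, 0.8655], total 972.6

lex <- synthFrequencies(rownames(emb), zipfExponent = 1, seed = 4)
pop <- generatePopulation(truth, defaultPerturbationGrid()[1:10, ],
                          reps = 1, baseSeed = 5)
cs  <- mixedCues(truth, 15, seed = 6)

inferred <- lapply(seq_along(pop), function(i) {
  fa <- simulateFA(pop[[i]], cs, nResponses = 30, lex, seed = 10 + i)
  faInfer(fa, cs)
})
res <- evaluateDesign(pop, list(inferred), list(cs),
                      reference = "local", seed = 9)
print(res, digits = 3)
#>            measure reference   bias resolution n_pairs n_excluded
#> 1 average_strength     local -0.823      0.794      10          0
#> 2             aspl     local  1.107      0.382      10          0
#> 3       average_cc     local -0.188      0.636      10          0
#> 4       modularity     local  1.298      0.515      10          0
#> 5      edge_weight     local     NA      0.186      10          0
#> 6    node_strength     local     NA      0.204      10          0
```

Reading the output: this design *underestimates average strength by 82%*
(bias −0.823 — the characteristic FA signature: two cues rarely share
responses, so cosine edge weights are small), yet still *orders individuals
usefully* on strength and clustering (resolution 0.79 and 0.64, above the
0.5 acceptability bar). Edge-level resolution is poor (0.19) at 30
responses per cue. The power side of the 0.5 bar:

```r
powerSimulation(resolution = 0.5, effectD = 0.5, nPerGroup = 200, seed = 1)
#> [1] 0.8004
requiredN(resolution = 0.5, effectD = 0.5)
#> [1] 199
```

`runExperiment(defaultRunConfig(), "out/")` runs the whole factorial grid
from one (YAML-configurable) specification and writes
`recovery_results.csv`, `panels.csv`, `manifest.csv`, and a log; a thin CLI
over the same functions is installed at `inst/cli/semnetrecover.R`
(subcommands `truth`, `individualize`, `cues`, `simulate`, `infer`,
`evaluate`, `power`, `run`).

See `vignettes/recovery-simulation.Rmd` for the methods, parameter defaults,
and design choices.

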