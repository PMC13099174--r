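# encontext

Encounter-conditioned co-occurrence fusion for wildlife photo-identification.

## The problem

Photo-identification pipelines for individually recognizable animals
(killer whales and other cetaceans, primates, elephants, camera-trap
systems) increasingly rely on deep image classifiers that score each
photograph independently. But photographs are not independent: they are
collected in *encounters* — structured field observation events in which
several individuals are photographed together — and in socially structured
populations the probability that two individuals co-occur is highly
non-random (matrilines travel together for decades). Field experts use this
context routinely: when an image is ambiguous, the plausible identities are
constrained by who else is present.

`encontext` turns that informal practice into a deployable probabilistic
post-processing layer. It requires no retraining and no access to the image
model — only (a) an encounter table (who was recorded together, in
chronological order, with confirmed/uncertain flags) and (b) per-image
classifier posteriors over a closed identity set.

## The model

From **training encounters only** (temporal leakage control), the package
builds:

* **Global sighting priors** — `P_global(i) = n_i / |E|`, where `n_i` is the
  weighted count of encounters containing individual `i` (confirmed
  sighting = 1, uncertain "?" sighting = 0.5).
* **Co-occurrence log lift** — with weighted pair counts `n_ij` and
  `P(i,j) = n_ij / |E|`,

  `L(i,j) = log[ (P(i,j) + eps) / ((P(i) + eps)(P(j) + eps)) ]`,

  natural log, clipped to `[-6, 6]`, `eps = 1e-6`. Positive = above-chance
  association, negative = avoidance. Self-association is neutral
  (`L(i,i) = 0`; see the methods vignette).

Given the evolving set `Y` of identities confirmed or inferred present in
an encounter, the association score of candidate `y` is the mean lift to the
members, `a(y; Y) = (1/|Y|) * sum_{i in Y} L(i, y)` (0 when `Y` is empty),
and the three evidence channels combine log-linearly:

`log P_fuse(y | x, Y) = alpha * log P_ML(y | x) + beta * log P_global(y) + gamma * a(y; Y) - log Z(x, Y)`

Inference is a **single pass** per encounter: images are processed easiest
first (descending baseline confidence), each fused posterior is recorded,
and a prediction joins `Y` when its fused confidence strictly exceeds
`tau = 0.95`. `Y` can be seeded empty (`null_set`), with `n` expert-confirmed
members (`random_known`), with the model's own most confident predictions
(`top_unknown`), or randomly from the model's predictions
(`random_unknown`). Weights `(alpha, beta, gamma)` are selected on a
temporally held-out validation block by a staged lexicographic search
(maximize macro-F1; break ties by log loss, then Brier score).

Two controls probe whether gains are real: a **placebo** log lift rebuilt
from encounters whose identity membership was shuffled (preserving
encounter sizes and per-identity marginals), and **seed corruption**
(drop / swap / add) of the initial membership set. A synthetic encounter
simulator with matriline-like units and confusable-identity posteriors makes
the whole pipeline testable without field data.

## Worked example

```r
library(encontext)

# 1. Simulate a unit-structured encounter archive (matriline-like society)
sim <- simulate_archive(n_individuals = 20, n_units = 5, n_encounters = 1000,
                        within_unit_join_prob = 0.9, cross_unit_join_prob = 0.02,
                        rate_sdlog = 0, n_confusable_pairs = 5, seed = 7)

# 2. Temporal split: context statistics come from the training block only
split <- temporal_split(sim$encounters, t = 0.7)
train <- split_block(sim$encounters, split, "train")
test  <- split_block(sim$encounters, split, "test")
artifacts <- build_context(train, epsilon = 1e-6, clip = 6)
graph_diagnostics(artifacts$pair_counts)
#> <graph_diagnostics> density 0.995, mean degree 18.9, dyads at support >= 5: 61.6%

# 3. Classifier posteriors for the test images (0.55/0.40 confusable pairs)
post <- simulate_posteriors(test,
          posterior_config(confusable_pairs = sim$confusable_pairs), seed = 8)

# 4. Baseline vs encounter-context fusion (expert seeding, n = 1)
baseline_pred <- colnames(post$prob)[max.col(post$prob, "first")]
score_predictions(baseline_pred, post$prob, post$true_identity)
#> <metrics_report> acc 0.840 | macro-F1 0.837 | logloss 0.358 | Brier 0.209 (n_seeds=1)

cfg <- inference_config("random_known", n_init = 1, seed = 1, n_seeds = 10)
evaluate_strategy(post, artifacts, fusion_weights(1, 0.5, 1), cfg,
                  encounters = test, baseline_accuracy = 0.840)
#> <metrics_report> acc 0.973 | macro-F1 0.972 | logloss 0.118 | Brier 0.044 | rAER 0.832 | coverage 0.866 (n_seeds=10)

# 5. Placebo control: destroy associations, keep marginals
run_placebo_experiment(train, test, post, seed = 7)[,
  c("strategy", "macro_f1_real", "macro_f1_placebo", "macro_f1_gap")]
#>       strategy macro_f1_real macro_f1_placebo macro_f1_gap
#> 1     null_set     0.9369349        0.8175611    0.1193738
#> 2  top_unknown     0.9608193        0.8150384    0.1457809
#> 3 random_known     0.9730511        0.8227300    0.1503211
```

Reading: seeding a single expert-confirmed member and fusing with the real
co-occurrence structure lifts top-1 accuracy from 0.840 to 0.973 (rAER
0.83: 83% of the baseline's errors removed), while the same fixed-weight
update driven by an association-destroying placebo lift falls back to (or
below) the baseline — the gain comes from genuine social structure, not
from the mere presence of a context term. `coverage` is the fraction of
true encounter members recovered in the final inferred set `Y`.

## Command line

```sh
inst/cli/encontext simulate      --out simdir --seed 7 --n-encounters 500
inst/cli/encontext build-context --train-table simdir/encounters.csv --out context.json
inst/cli/encontext placebo       --train-table simdir/encounters.csv --out placebo.csv --seed 7
inst/cli/encontext infer         --artifacts context.json --posteriors simdir/posteriors.csv \
                                 --encounters simdir/encounters.csv --weights 1,0.5,1 --out results.csv
inst/cli/encontext evaluate      --results results.csv --out report.json
```

## Documentation

The methods vignette (`vignettes/encounter-context-fusion.Rmd`) documents
the model and its assumptions, every tunable parameter, what the synthetic
generator does and does not emulate, numerical choices, and known
limitations (including an honest analysis of when the placebo
weight-selection control cannot work).
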