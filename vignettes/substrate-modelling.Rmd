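---
title: "Modelling wood ear cultivation outcomes from substrate composition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling wood ear cultivation outcomes from substrate composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`woodear` models six cultivation outcomes of the wood ear mushroom
(*Auricularia cornea*) — spawn run period, days to pinhead formation,
days to first harvest, fresh yield, biological efficiency, and total
cultivation period — as functions of a four-component substrate
composition: beech sawdust, hornbeam sawdust, wheat bran and rice bran,
in percent of dry mass summing to 100. This vignette documents the
statistical model, the choices behind every tunable, and what the
package's tests do and do not establish.

## Data model and the synthetic generator

The package embeds the 16-formulation trial summary: per substrate, the
mean and standard error over n = 12 replicate bags of seven responses
(number of fruiting bodies is carried as data but not modelled). The
per-bag observations were never published, so all model fitting happens
on *synthetic* replicate tables drawn to match the summary:

* per substrate and response, replicates are independent Gaussian draws
  with the printed mean and standard deviation SE·√12 — the SD the
  printed standard error implies for the original replication;
* non-positive draws are rejected and redrawn (never clipped, to avoid
  point masses at zero);
* records violating the physical ordering SRP ≤ DPHF ≤ DFFH ≤ TCP have
  those four responses redrawn jointly (up to 1000 rounds, then an
  error). The printed means always satisfy the ordering;
* responses are drawn independently within a record. The summary carries
  no cross-response covariance and none is invented; consequently any
  metric sensitive to within-bag correlations will differ from the
  original data.

Two properties of this design deserve emphasis. First, rejection is a
conditioning operation: for substrates where the pinhead-formation SE is
large relative to the gap to the neighbouring period responses, the
ordering constraint shifts the conditional mean of the constrained
responses by up to about one printed SE (the property tests quantify
this: unconstrained responses converge to the printed means at the
law-of-large-numbers rate, and every cell stays within 1.25 printed SE).
Second, the residual noise floor implied by the printed SEs caps the
attainable out-of-sample R²; for yield the cap is near 0.985. Headline
accuracies on the synthetic study are therefore expected to sit slightly
below the values reported for the original (unpublished) data, and the
package treats the comparison *between* model families — not the
absolute numbers — as the reproducible quantity.

A second generator, `generate_linear_benchmark()`, produces tables with
a known linear ground truth for validating the sensitivity and selection
stages. By default its inputs lie on the 100% simplex like real
substrate data. On the simplex, however, any three components determine
the fourth, so coefficient vectors are identified only up to an additive
constant — a coefficient of zero is *not* distinguishable from its
nonzero reparameterizations, and no leave-one-input-out procedure can
be expected to single it out. Tests that need an identifiable irrelevant
input therefore use `compositional = FALSE`, which draws the four inputs
independently on [0, 100].

## Preprocessing

**Box-Cox.** Each response is normalized by a Box-Cox power transform
whose exponent maximizes the standard profile log-likelihood over the
grid [-5, 5] in steps of 0.01; exact ties break toward λ = 1 (no
transform). By default the exponent is fitted once on the full response
vector, reproducing the original procedure at the cost of a mild
information leak into the cross-validation folds; `boxcox = "per_fold"`
refits it on each training partition for a leak-free variant. Metrics
are reported in original response units (predictions are
back-transformed) unless `metrics_scale = "transformed"` is requested.
The inverse transform clamps `λz + 1` at `1e-12` so an unbounded network
extrapolation inverts to a vanishingly small positive value rather than
`NaN`.

**Outlier screen.** Records are scored by a Hotelling-style distance on
the principal components covering ≥ 95% of the variance of the
standardized responses; records beyond mean + 3 SD are flagged, never
dropped. With 192 records, about half a flag is expected from clean
Gaussian data, so an occasional single flag on the synthetic study is
chance, not structure; the screen exists to catch gross anomalies in
user-supplied tables.

**Scaling.** Inputs are min-max mapped to [-1, 1] (the tansig hidden
layer saturates outside roughly ±3) and the target is centred by its
mean and divided by its half-range — both fitted on the training
partition only; held-out values outside the training range pass through
unclipped. A constant target is a degenerate special case with an exact
bias-only solution, which `train_mlp()` returns directly instead of
training.

**Cross-validation.** One plan is used everywhere: 10 independent
shuffles of the record indices, each cut into 5 contiguous folds whose
sizes differ by at most one. The plan is a pure function of
`(n_records, seed)`; its md5 hash is recorded in every fit report so the
comparison between model families can assert byte-identical fold
memberships. Folds are unstratified (the plain reading of a
five-fold/ten-replicate scheme over 192 records); headline metrics pool
the held-out predictions across all folds and replicates, and per-fold
metrics are also emitted.

## The network and its trainer

The regressor is a three-layer perceptron: four inputs, one hidden layer
of `hidden_n` tansig units, one linear output. Training is full-batch
gradient descent with momentum 0.9 and an adaptive learning rate in the
style of MATLAB's batch backpropagation defaults: the rate (initially
0.01) is multiplied by 1.05 after an epoch that lowers the batch MSE and
a step that raises it by more than 4% is rejected, the rate multiplied
by 0.7 and the momentum reset. The adaptive rate was chosen over a fixed
or plateau-halved schedule because, on these tiny designed datasets, it
reaches the representability limit of the architecture (a noiseless
linear map is fitted to R² ≥ 0.999; four-point parity is fitted to
|error| < 0.1 by three hidden units) within the 2000-epoch budget, which
a fixed rate of 0.01 does not.

Early stopping monitors a 15% internal validation split (training sets
below 10 records train against their own loss) with patience 100; the
epoch-best weights by validation RMSE are kept, with a fallback to the
train-best epoch in the degenerate case where validation selection would
return something worse than the initial random network. Weights
initialize uniformly on ±0.5 scaled by 1/√fan-in; three seeded restarts
keep the best run. Everything is deterministic given the configuration
seed; fold-level training seeds derive from it.

Fewer than six training records per hidden neuron triggers a warning
(not an error — deliberately, since tiny representability checks like
the parity fixture are legitimate uses of an overparameterized net).

## Architecture search

The hidden-layer size is selected from 1-20 by an elitist genetic
algorithm with the study's settings: population 50, single-point
crossover at rate 0.85, per-bit mutation at 0.01, tournament-2
selection, one elite. The 5-bit gene decodes by modulo onto 1-20.
Fitness is the pooled held-out RMSE from cross-validation at the decoded
size, computed with a single CV replicate during the search (for cost)
and a fixed training seed (so fitness is deterministic within a run),
and cached per decoded size — each architecture is trained at most once
per search. The winner is taken from the full evaluation cache, with
exact fitness ties broken toward fewer neurons, then re-scored under the
complete 10-replicate plan and refit on all records for the sensitivity
stage.

The original schedule of 500 generations is available
(`full_ga_schedule = TRUE`, or `ga_config(generations = 500,
early_stop_generations = Inf)`), but on a 20-state search space it
evaluates nothing new after the first few generations — the cache makes
the long schedule nearly free, and the desk default of 40 generations
with early stopping after 15 stagnant generations selects the same
winner. The GA tunes architecture only; trainer hyperparameters stay
fixed, and weights are always learned by backpropagation.

## Sensitivity analysis (VSE/VSR)

For each response, the baseline is the all-records RMSE of the final
network trained on all data with all four inputs. The variable
sensitivity error of input *v* is the all-records RMSE of the model with
*v* "nonexistent"; the package implements both readings of nonexistence
and defaults to the stronger one:

* `retrain` (default): refit the network at the same hidden size on the
  remaining three inputs;
* `ablate`: keep the baseline network and clamp *v* to its training
  mean.

VSR(v) = VSE(v) / baseline RMSE, min-max rescaled to [0, 1] across the
four inputs, so each response's report contains exactly one 1.000 and
one 0.000 whenever the VSRs are not all equal. Two caveats are recorded
in the report itself: an `unstable` flag when the VSRs differ by less
than 5% (the rescaling then amplifies noise), and the compositional
caveat — because the inputs sum to 100, a retrained three-input model
retains all the information of four, so VSRs on compositional data
measure *how much the model leans on* a component rather than pure
information content. The original analysis applied no correction for
this and neither does the package.

## Stepwise baseline

The comparison baseline is bidirectional stepwise OLS on linear terms of
the four components: add the excluded variable with the smallest
partial-F p-value while ≤ 0.05, then drop any included variable with
p > 0.10 (never the one just added; 50-step safety cap). The entry and
removal thresholds are the conventional default pair; the original study
does not state its values. Candidate additions that would make the
design singular — the fourth component alongside the intercept — are
skipped rather than handled by dropping the intercept. Selection is
re-run inside every training fold, so the reported metrics include
selection variability, and a stability table records how often each
variable was retained. The stepwise response is left untransformed: the
normalization step in the original pipeline is described with the
machine-learning stage, and an interpretable linear baseline in original
units matches how its errors are reported.

## The study pipeline

`run_full_study()` chains the stages — simulate (or load) replicates,
screen, then per response: Box-Cox, GA search, cross-validated
evaluation of both families under one shared plan, sensitivity — and
writes `fit_metrics.csv`, `sensitivity.csv`, `predictions.csv`,
`replicates.csv`, `config.json` and `run_log.txt`, each CSV stamped with
the config hash and seed. All component seeds derive from the master
seed, so a config determines every byte of the outputs; the test suite
asserts byte-identity of repeated runs. Problem sizes used throughout:
16 substrates × 12 replicates (192 records), a 5-fold × 10-replicate
plan (50 fits per family per response), architecture search over 20
sizes with one CV replicate, and a 2000-epoch training budget — the full
study runs in a few minutes on one CPU.

```{r, eval = FALSE}
library(woodear)
result <- run_full_study(study_config(seed = 42, out_dir = "results/study"))
result$fit_metrics
```

## Limitations

* All fitting happens on synthetic replicates; the generator reproduces
  the summary's first two moments per cell but cannot recover
  within-bag correlations, distributional shape beyond Gaussian, or any
  structure the original raw data may have had. Absolute accuracies are
  therefore indicative; the family comparison and the sensitivity
  *rankings* are the robust outputs.
* The ordering and positivity rejections bias constrained cells by a
  bounded amount (worst case about one printed SE), quantified in the
  property tests.
* The compositional constraint caps the spread of retrain-mode VSRs;
  rankings near the `unstable` threshold should not be over-read.
* The original trainer is unspecified beyond "backpropagation"; RMSE
  magnitudes are not expected to match the original report exactly, and
  the package does not attempt to.
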