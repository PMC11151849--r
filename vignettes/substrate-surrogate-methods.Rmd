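---
title: "Modelling and optimizing shiitake substrate formulation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and optimizing shiitake substrate formulation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mycorun)
```

## The problem

Shiitake (*Lentinula edodes*) is grown on lignocellulosic substrates, and the
speed with which its mycelium colonizes ("runs" through) the substrate is a
production checkpoint: a slow spawn run delays fruiting and invites
contamination. Two quantities summarise the process on a substrate column:
the **running length** (RL, cm), the linear extent of colonization measured
at 5-day intervals up to day 40, and the **running rate** (RR, cm d⁻¹),
defined as running length divided by running time.

`mycorun` models both responses as functions of the growing-substrate
composition — percentages of bagasse (B), wheat bran (WB) and beech sawdust
(BS), each expressed as a fraction of a 10 g aliquot, so the three do **not**
sum to 100 — and, for RL, of the running time. The package ships the full
published 64-substrate design (compositions, day of highest RL, mean RL and
mean RR) as `shiitake_tables()`.

The modelling strategy is a surrogate-assisted evolutionary analysis:

1. a single-hidden-layer perceptron (tanh hidden units, linear output) is the
   surrogate for each response;
2. a genetic algorithm (GA) is used twice — as an integer-coded search over
   the hidden-layer width, and as a real-coded search over the substrate
   inputs of the trained surrogate;
3. five linear regressions (MLR, stepwise, OLSR, PCR, PLSR) provide the
   comparison under the identical repeated 8-fold cross-validation plan;
4. input importance is ranked by an ablation statistic (VSE/VSR).

## The synthetic replicate-level generator

No replicate-level or time-course raw data are published; only per-substrate
mean RL, mean RR and the day each substrate reaches its highest RL are
printed. The generator therefore reconstructs a *plausible* replicate-level
dataset exactly calibrated to those printed values:

* **Mean curve.** Each substrate's expected RL follows a linear ramp
  `plateau_cm * min(t, plateau_day) / plateau_day`: the simplest curve
  consistent with the reported monotone increase and with reaching the
  printed mean (`plateau_cm`, Table of mean RL) on the printed day
  (`plateau_day`). No curve-shape information is printed, so no richer shape
  (logistic, Gompertz) is identifiable; the ramp adds the fewest assumptions.
* **Replicate noise.** One Gaussian offset per substrate × replicate,
  `N(0, noise_sd_cm²)` with `noise_sd_cm = 0.30` cm by default, is applied to
  the plateau and scaled proportionally along the ramp. The default matches
  the spread reported for the validation culture (≈ ±0.35 cm). A single
  replicate-level level shift — rather than independent noise at every time
  point — keeps each replicate trajectory nondecreasing in time, which
  independent per-timepoint noise would violate; the true replicate variance
  is not printed anywhere, so `noise_sd_cm` is surfaced in `sim_config()` and
  never hard-coded downstream.
* **Structure.** 64 substrates × 8 observation days (5–40, step 5) × 4
  replicates = 2,048 RL rows; RR applies the rate definition to each
  replicate's RL at its substrate's plateau day, giving 256 rows. The
  non-growing control (0/0/0) has plateau 0 and rate 0. The full stream is
  drawn from the single seed in `sim_config()`, consumed substrate-by-
  substrate then replicate-by-replicate, so a seed reproduces a dataset
  byte-for-byte.

What the generator does **not** emulate: lag phases and deceleration before
the plateau, heteroscedastic or correlated replicate errors, contamination
or failed runs, and any excess variation between the printed cell means and
biological truth. Tests passing on this generator therefore demonstrate that
the pipeline recovers structure *of this kind* at the study's size and noise
scale — not that the biological system is this simple.

## Preprocessing

Responses are Box–Cox transformed before fitting. Both RL and RR contain
exact zeros (the control), which the plain power transform cannot accept, so
an additive offset of 1 is applied first. The power λ is estimated by
maximising the profile log-likelihood on a λ ∈ [−2, 2] grid (step 0.1)
followed by local refinement; ties within numerical resolution prefer λ = 1.
The transform is applied to outputs only — the inputs are designed factor
levels, not samples from a distribution. Inputs are min-max scaled to
[−1, 1], the operating range of the tanh hidden layer; predictions invert
the scaling and the transform, so all reported metrics are in cm or cm d⁻¹.

A PCA screen guards against gross data errors: the scaled input+output
matrix is projected onto the components explaining ≥ 90 % of variance, each
score is standardised by a robust SD (1.4826 × MAD), and a row is flagged
when its score distance exceeds 3·√m. On the default synthetic data no row
is flagged, matching the published analysis, and a planted 10× outlier is
caught.

## The perceptron surrogate and its training

The network is deliberately minimal: inputs → one tanh hidden layer → one
linear output, y = W₂ tanh(W₁x + b₁) + b₂. Weights start at Glorot-uniform
values; training is full-batch gradient descent with adaptive moment
estimates (step size 0.02, β₁ = 0.9, β₂ = 0.999) minimising MSE on the
transformed scale, with early stopping on a 15 % validation split (the only
regulariser) and restoration of the best validation weights. Everything is
deterministic given the seed.

The epoch budget scales inversely with dataset size
(`default_train_config()`: ≈10⁶ row-epochs, clamped to [600, 4000], patience
7.5 % of the budget). The rationale is symmetric: full-batch epochs on the
2,048-row RL table are expensive and converge quickly per epoch, while the
256-row RR table is cheap per epoch and needs more epochs to converge. With
these budgets a cross-validated RL surrogate reaches test R² ≈ 0.95 and an
RR surrogate ≈ 0.92–0.96 on default synthetic data, against ≈ 0.77 and
≈ 0.53 for the linear baselines — reproducing the published contrast
qualitatively (surrogate ≈ 0.97/0.92 vs regressions 0.71/0.52 there).

## Genetic algorithm

One engine serves both uses. Defaults follow the published configuration:
population 50, 500 generations, crossover 0.85, mutation 0.01,
roulette-wheel selection. Design choices the published description leaves
open, resolved here:

* **Fitness sign and shifting.** Roulette selection needs nonnegative
  weights, but the natural fitnesses (−RMSE, or a predicted response)
  can be negative; each generation's fitnesses are shifted by the population
  minimum plus a small epsilon so the least-fit individual keeps a nonzero
  selection weight.
* **Operators.** Real encoding: arithmetic (blend) crossover and Gaussian
  mutation with SD 10 % of the gene range, clipped to bounds — standard for
  continuous media-formulation searches. Integer encoding: single-point
  crossover and uniform redraw mutation.
* **Elitism.** One elite is copied unchanged per generation, making the
  best-so-far trace nondecreasing; the published flowchart's accept/iterate
  loop implies monotone progress but does not name elitism, so it is logged
  in the config echo.
* **Stopping.** The published "desired fitness" stopping rule is
  unquantified; the fixed generation count is the sole stop criterion.
* **Integer initialisation.** For a single integer gene, when the population
  is at least as large as the number of levels, every level is included once
  before random fill — full coverage of a small discrete space costs nothing
  and removes a needless failure mode of fitness-proportional drift.

## Architecture search and cross-validation

The hidden-layer width is searched over {1, …, 25} (the only published
constraint is that selected networks were *small*). The GA's fitness for a
width is −(mean test RMSE) under a reduced plan — 8 folds, 1 repeat — and is
cached per width, so at most 25 cross-validations run regardless of the GA
budget; a 500-generation GA over a 25-level gene would otherwise cost
hundreds of thousands of fits. The reported width then applies the
one-standard-error parsimony rule (the smallest width within 1 SE of the
best mean), and the selected architecture is re-evaluated under the full
8-fold × 10-repeat plan (80 splits) for reporting.

Folding is at the row (replicate) level, matching the published row counts.
Replicates and time points of one substrate can then appear in both training
and test folds, a known source of optimistic bias; `group_by_substrate =
TRUE` in `cross_validate()` keeps each composition's rows together for users
who want the conservative estimate. The default mirrors the original
analysis.

## Linear baselines

MLR and OLSR are the same least-squares estimator reported under both
customary labels (the published comparison lists both; they never differ).
Stepwise regression is bidirectional from the empty model with partial-F
entry/removal thresholds 0.05/0.10 (unstated in the source; conventional
defaults) and deterministic tie-breaking by smallest p-value then smallest
input index. PCR regresses on standardised principal components (default:
enough for 95 % of feature variance — with four standardised inputs on a
balanced design this retains all four, making PCR coincide with MLR, which
is itself informative). PLSR is NIPALS with the deterministic
cross-covariance initial direction; its default component count minimises an
internal 5-fold CV RMSE. All five fit the same Box–Cox-transformed response
as the perceptron, so the comparison isolates the model class.

## Sensitivity analysis

The variable sensitivity error (VSE) of input *i* is the full-dataset RMSE
of a surrogate retrained *without* input *i*, with identical architecture
and seed; the VSR is VSE divided by the full model's RMSE, min-max rescaled
to [0, 1]. "Input not available" could also be read as ablation (fixing the
input at its mean in the trained model); that variant is provided as
`mode = "ablate"`, but retraining is the default because a model in which an
input "was not available" is most naturally a model lacking that input.
On default synthetic RL data the ranking is running time (1.0) first and
wheat bran second in 20/20 seeds, matching the published ordering.

## Input optimization

The real-coded GA maximises the trained surrogate's original-units
prediction over the design box — components in [0, 100], time in [5, 40]
days; extrapolation beyond the design range is disallowed. The initial
population is seeded with the design grid (each composition at its recorded
plateau day for RL), ranked by predicted response; with elitism this
guarantees the returned optimum is at least as good as every design point.
Optimal times are reported both as fractional days and as a days + hours
rendering.

Two behaviours of this step deserve honesty. First, under the generator,
RL is nondecreasing in time by construction, so the RL-optimal time sits at
the upper time bound — unlike the published interior optimum (≈ 28 d 10 h),
which reflects structure in the real data that the printed tables do not
constrain. Second, the RR response surface implied by the printed means has
several near-tied maxima (0.393 at B 50/WB 100/BS 0 against 0.390 at BS 25
and 0.385 at B 100/WB 100/BS 50) whose separation is below the replicate-mean
standard error at the default noise level. The surrogate reproduces the 64
cell means essentially at the information limit (RMSE ≈ 0.006), but its
continuous maximum frequently lies between design levels — particularly in
the wide bagasse gap between 50 and 100 — so the optimized beech-sawdust
coordinate lands on the zero boundary only in a minority of seeds, while
high wheat bran (> 70) is recovered in a clear majority. A single published
run reporting BS = 0.00 is consistent with, but not implied by, this
distribution; treat optimized compositions as candidates for validation
culture, not as point estimates.

## Numerical choices and degenerate inputs

* Box–Cox forward/inverse round-trip to < 10⁻⁹; inverse inputs outside the
  forward image raise an error, and network predictions are clipped to the
  image boundary before inversion (a scaled output below the transform's
  range corresponds to a response at or below the zero floor).
* Constant features, constant responses, rank-deficient designs and
  degenerate covariance matrices raise immediate errors naming the offender.
* CSV round-trips preserve values to full double precision; datasets are
  validated row-by-row on read with errors naming row and column.
* Model serialisation uses JSON at 17 significant digits, enough to restore
  predictions bit-for-bit.

## Problem sizes used in the shipped analyses

The packaged analyses run at the study's own scale: 2,048/256-row datasets,
a {1..25} width search under the reduced (8 × 1) plan, 80-split evaluation
of the selected architecture and all baselines, and 500-generation GA
optimizations. Multi-seed distributional statements (sensitivity ordering,
optimum location) use 20 seeds.

## Known limitations

* The generator's ramp-to-plateau mean curve cannot inform time-response
  questions beyond monotone saturation; conclusions about *when* growth
  decelerates are outside its reach.
* Row-level folding inherits the original analysis's optimistic bias; use
  grouped folding for honest generalisation to unseen substrates.
* The GA provides no optimality certificate; with 500 generations on a
  4-dimensional box its known-optimum recovery error is ≈ 2 % of each
  gene's range on smooth test functions.
* MLR/OLSR duplication is reported, not resolved; the source never explains
  how they differ.
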