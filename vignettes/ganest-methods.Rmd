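---
title: "Methods: GA wrapper selection in nested CV for fatigue-outcome prediction"
author: "ganest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GA wrapper selection in nested CV}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The problem

Roughly 80% of rheumatoid arthritis (RA) patients report clinically relevant
fatigue, and clinicians currently have no objective marker to predict which
patients will improve. `ganest` implements a prediction pipeline for this
setting: given a baseline subject-by-feature table — structural MRI
morphometrics (596 features), diffusion tract metrics (304 features) or
clinical variables — and Chalder Fatigue Scale (CFS) scores at baseline and
6 months, it classifies each patient as a fatigue *improver*
(`ΔCFS = baseline − follow-up ≥ 2`) or *non-improver*, and reports which
features carry the signal.

The statistical challenge is the regime: ~54 subjects against hundreds of
correlated features. The pipeline therefore combines aggressive feature
selection with an estimation design whose only purpose is to not fool
itself: wrapper selection inside every training fold, nested
cross-validation (CV) for hyperparameters, and stability analysis across
repeated resampling.

## The model

### Least-squares linear discriminant (LSLD)

The core classifier is the linear decision function

$$y = \sum_{n=1}^{L} w_n x_n + b$$

fit by minimizing mean squared error against ±1 class targets (+1 =
improver). We chose the ±1 coding so that `sign(y)` is the class rule;
scores of exactly 0 deterministically predict the non-improver (majority)
class. Features are z-scored with training-fold statistics stored in the
model; a zero-variance training column is standardized to a column of zeros
and flagged. Because the design is often singular (the chromosome length
`L` can approach or exceed the fold size, and columns can be collinear),
the fit always returns the minimum-norm least-squares solution, computed
through the SVD pseudoinverse of the bias-augmented design. The test suite
cross-checks this against an independent `MASS::ginv` solve to 1e-8.

### Support vector machines

The soft-margin linear SVM and the RBF-kernel SVM are standard
maximum-margin classifiers; the quadratic program is solved by libsvm via
`e1071`, and this package owns the contracts around it: score orientation
(positive = improver), grids, and tuning. Hyperparameters are tuned on the
training partition only, by an inner stratified 5-fold CV over a grid of
integer powers of two from $2^{-4}$ to $2^{4}$ for the cost C (9
candidates) and, for the RBF kernel, the same grid for γ (81 pairs). The
grid range is fixed by the study design; the integer-exponent step and the
selection criterion — balanced accuracy of the pooled inner out-of-fold
predictions, ties broken toward smaller C then smaller γ — were open
choices, decided here in favour of the headline metric and of simpler
models.

### Genetic-algorithm wrapper selection

A *chromosome* is a set of exactly `L` distinct feature indices (default
`L = 8`); its *fitness* is the training mean squared error of the LSLD
restricted to those features (lower is fitter). Each generation:

1. rank the population by fitness (ranking selection) and keep the best
   10% as parents;
2. carry the single best individual unchanged (elitism);
3. refill the population with children made by uniform random crossover —
   each gene position inherited from either parent with probability ½,
   duplicates repaired from the unused union of the parents' genes;
4. mutate 1% of the non-elite gene slots (chosen uniformly without
   replacement), each mutated slot replaced by a uniformly chosen feature
   not already in that chromosome.

The population holds `10 × L` individuals and the search runs 100
generations at full scale, returning the best chromosome ever evaluated.

Several aspects of this scheme were genuinely open and are this package's
declared choices:

* **"10 times the number of dimensions"** is read as 10 × the chromosome
  length (80 individuals at `L = 8`), the GA rule of thumb for decision
  variables — not 10 × the total feature count, which would cost ~6,000
  LSLD fits per generation per fold. The larger reading remains available
  by setting `population_size` explicitly.
* **Elitism** (1 individual) is added so that best-so-far fitness is
  provably non-increasing — an invariant asserted on every run. Disable
  with `elitism = 0` for a strictly memoryless scheme.
* **Mutation floor.** The mutated-slot count is
  `round(rate × non-elite gene slots)`, but never 0 while the rate is
  positive. At small populations (e.g. 20 chromosomes of length 2 —
  40 slots) the rounded count is 0, the gene pool collapses onto the
  initial parents, and the search stalls far from the optimum; with the
  one-slot floor the GA matches exhaustive subset search on every small
  instance we test. At study scale (632 non-elite slots) the floor is
  inactive and the count is the expected 6.
* **Chromosomes are sets**: fitness is invariant to gene order, and the
  selected chromosome is reported sorted.

### Nested, repeated cross-validation

The outer loop is a stratified 5-fold CV: fold sizes differ by at most one
per class and overall (so the 22/32 cohort gives folds of 11, 11, 11, 11,
10 with 4–5 improvers each). Stratification is not stated in the study
design but the 22/32 imbalance occasionally yields degenerate unstratified
folds, so we stratify. The GA and all classifier fitting see only the
training rows of a fold; a leakage test perturbs held-out rows and asserts
that the selected chromosome and fitted parameters are unchanged. The whole
procedure is repeated with freshly randomized folds (100 repeats at full
scale), which we read as re-randomization per repeat.

Performance is summarized per repeat from that repeat's pooled out-of-fold
predictions (each subject predicted exactly once per repeat): sensitivity,
specificity, balanced accuracy `(Sens + Spec)/2` (the study's "accuracy"),
PPV, NPV, and trapezoidal AUC of the pooled decision scores. Overall values
are means over repeats with a 95% normal-approximation CI from the
across-repeat distribution (the CI construction for the published error
bars is unstated; a percentile band is available for the ROC).

ROC curves are averaged vertically on a fixed 101-point false-positive-rate
grid, with the averaged curve anchored at (0,0) and (1,1); the summary AUC
is the mean of per-repeat AUCs, and the trapezoidal AUC is
property-checked against the tie-adjusted rank statistic.

### Selection frequency

The stability/importance measure is the number of fold-fits (out of
`repeats × k` = 500 at full scale) whose selected chromosome contains a
feature. Counts conserve exactly (`Σ counts = L × repeats × k`), percentages
use the fold-fit denominator, and ranking ties break by feature order.
`chromosome_sweep()` repeats the whole analysis across chromosome lengths
(study range 1–20) to show which features persist.

## The synthetic cohort generator

No patient data ship with the package; `generate_cohort()` provides the
test bed, and its defaults are the study conditions: 22 improvers, 32
non-improvers. The generative model is deliberately the simplest structure
that exposes both signal recovery and correlated-feature selection
instability:

* per class, features are multivariate normal with equal covariance and
  unit marginal SD (`noise_sd = 1`);
* features sharing a schema group tag (the 8 statistics of a parcellation,
  the 4 measures of a tract, left/right volumes of a structure) share an
  exchangeable correlation, default 0.3 — a moderate within-region
  dependence of the kind real morphometrics show;
* planted features differ between classes by `effect_size` pooled SDs
  (Cohen's d, default 1.5), with deterministic alternating directions;
* baseline CFS scores are uniform integers on 4–11 (above the eligibility
  floor of 3), and follow-up scores are constructed so that
  `label_improvement()` reproduces the intended classes exactly;
* the clinical modality uses the same machinery with `sex` binarized 0/1.

What this emulates is location/scale/correlation structure only. Real
morphometric data have heavier tails, site and age effects, and
between-block correlations; chance-level and recovery results on synthetic
cohorts therefore validate the *machinery* (absence of leakage, ability to
find planted effects), not clinical performance. The published accuracies
were computed on an unreleased 54-patient cohort and are not reproducible
here; what is reproducible is the printed-arithmetic identity
`(67.3% + 61.2%)/2 = 64.25% ≈ 64.3%` and the design's behavioural
properties.

## Numerical and degenerate-input policy

* Minimum-norm SVD solve with tolerance `max(dim) × max(d) × eps`;
  zero-variance columns zeroed after centering.
* Score ties (exactly 0) predict non-improver.
* Inner-CV folds with a class smaller than `k` fall back to one member per
  fold for that class, with a message; outer folds treat this as an error.
* Crossover duplicate repair draws from the unused union of both parents'
  genes, which is always sufficient; a full-feature fallback pool is kept
  defensively.
* Missing values in feature tables are fatal by default
  (`drop_incomplete = TRUE` drops and names incomplete subjects); missing
  schema columns are fatal; extra columns are dropped with a warning.
* All randomness flows from one master seed through `derive_seed()`
  (a Lehmer-style integer hash), giving bitwise-reproducible reports and
  per-fold streams that are stable under re-ordering of work.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run the pipeline at desk scale,
chosen as: GA population 40 and 20 generations inside nested CV; 5 CV
repeats per null cohort (20 cohorts per classifier for calibration, 6 in
the acceptance script); 20 repeats for planted-recovery runs on 3 cohorts
(diffusion schema, 3 planted features at d = 1.5); 100 seeds for the
GA-vs-exhaustive check at D = 10, L = 2. Chance-level calibration is
expected in [45%, 55%] and planted recovery above 65% balanced accuracy
with the 3 planted features in the top 3 frequency ranks. Full-scale
settings (population 80, 100 generations, 100 repeats) are plain
configuration changes.

## Known limitations

* The generator does not emulate scanner physics, site effects, or
  realistic marginal distributions; it is a declared stand-in, not an
  inference about the study data.
* The chromosome length is fixed per run, not learned inside training
  (sweeping it is supported; learning it is future work).
* Continuous ΔCFS regression, alternative GA selection schemes
  (tournament, roulette), variable-length chromosomes, and probability
  calibration are out of scope.
* The exact clinical variable list of the study is not public; the
  clinical schema defaults to the documented eight variables and is
  user-configurable.

## A short worked example

```{r example, eval = FALSE}
library(ganest)

schema <- build_schema("dti")
coh <- generate_cohort(cohort_config(schema,
                                     planted_features = c(1, 50, 200),
                                     effect_size = 1.5, seed = 1))
report <- run_nested_cv(coh$table, coh$labels, "lsld",
                        ga_config = ga_config(population_size = 40,
                                              generations = 20),
                        repeats = 20, seed = 100 + 1)
print(report)
head(report$frequency)
```
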