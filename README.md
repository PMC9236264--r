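# ganest

Genetic-algorithm wrapper feature selection with nested cross-validation,
for predicting fatigue-outcome in rheumatoid arthritis from brain and
clinical features.

## The problem

Fatigue is one of the most burdensome symptoms of rheumatoid arthritis
(RA), and no objective marker predicts which patients will improve.
`ganest` implements a complete small-sample, high-dimensional
classification pipeline for this problem: given baseline subject-by-feature
tables — structural MRI morphometrics (596 features: 52 subcortical volumes
plus 8 statistics × 68 cortical parcellations), diffusion tract metrics
(304 features: 4 measures × 76 tracts) or clinical variables — and Chalder
Fatigue Scale (CFS) scores at baseline and 6 months, it labels each subject
an *improver* (ΔCFS = baseline − follow-up ≥ 2) or *non-improver* and asks
which baseline features predict that label.

## The method

* **Least-squares linear discriminant (LSLD).** The decision function
  `y = Σₙ wₙxₙ + b` over the `L` selected features, fit by minimizing mean
  squared error against ±1 class targets; singular designs get the
  minimum-norm (pseudoinverse) solution. Soft-margin linear and RBF SVMs
  are provided as alternative classifiers, tuned by an inner stratified
  5-fold grid search over C, γ ∈ {2⁻⁴, …, 2⁴}.
* **GA wrapper selection.** A chromosome is a set of `L = 8` distinct
  feature indices; fitness is the training MSE of the LSLD on those
  features. Ranking selection (top 10% as parents), uniform random
  crossover with duplicate repair, 1% gene mutation, elitism, 100
  generations, population `10 × L`.
* **Nested repeated CV.** Stratified 5-fold outer CV, re-randomized over
  100 repeats; the GA and all tuning see training rows only. Reports
  balanced accuracy (= (Sens+Spec)/2), sensitivity, specificity, PPV, NPV,
  vertically averaged ROC curves with 95% bands, and AUC.
* **Stability.** Selection frequency: how many of the repeats × folds = 500
  fold-fits selected each feature, with a chromosome-length sweep (1–20).
* **Synthetic cohorts.** A generator reproducing the study geometry
  (22 improvers / 32 non-improvers) with block-correlated Gaussian features
  and planted effects of configurable Cohen's d, so every stage is testable
  without patient data.

## Worked example

Plant 3 discriminative features (Cohen's d = 1.5) among the 304 diffusion
features of a synthetic 54-subject cohort, then run the scaled-down nested
CV with the LSLD:

```r
library(ganest)

schema <- build_schema("dti")
coh <- generate_cohort(cohort_config(schema,
                                     planted_features = c(1, 50, 200),
                                     effect_size = 1.5, seed = 1))
report <- run_nested_cv(coh$table, coh$labels, "lsld",
                        ga_config = ga_config(population_size = 40,
                                              generations = 20),
                        repeats = 20, seed = 101)
print(report)
head(report$frequency, 5)
```

```
<cv_report> lsld, 20 repeats x 5 folds (L = 8)
  Acc 81.3% [79.3, 83.3] | Sens 81.4% [78.6, 84.2] | Spec 81.2% [77.8, 84.7]
  AUC 0.893 | top feature: cc_frontal_pole_r_rd (75/100)
  feature                                      name count percentage
1     200                      cc_frontal_pole_r_rd    75         75
2       1                   arcuate_fasciculus_l_fa    64         64
3      50 inferior_fronto_occipital_fasciculus_l_md    57         57
4     228                          cc_temporal_l_rd    13         13
5      96                     stria_terminalis_r_rd    11         11
```

The three planted features dominate the selection-frequency ranking — they
were chosen in 75%, 64% and 57% of the 100 fold-fits while no noise feature
exceeds 13% — and out-of-fold balanced accuracy (81.3%) is far above the
~50% a null cohort gives. On a cohort with *no* planted effect the same pipeline stays
at chance, which is the leakage check that matters in this n ≪ p regime.

A thin command-line wrapper with `simulate` / `run` / `sweep` / `report`
subcommands is in `inst/cli/ganest-cli.R`.

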