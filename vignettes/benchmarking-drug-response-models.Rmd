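---
title: "Bias-aware benchmarking of drug response prediction models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bias-aware benchmarking of drug response prediction models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drbench)
library(dplyr)
```

## The evaluation problem

Models that predict the drug sensitivity of cancer cell lines map a
(cell line, drug) pair to a continuous response — typically ln IC50, but
also IC50, EC50, pEC50 or a viability AUC. Evaluating such models naively is
treacherous for three structural reasons:

1. **Mean-effect memorization.** Most of the variance in a large screen is
   explained by *which drug* was applied, not by any molecular feature of
   the cell line. A model that merely memorizes per-drug average potency
   appears excellent on global metrics.
2. **Simpson's paradox.** The global correlation between predictions and
   truth pools across drugs with very different mean potencies. It can be
   high while the correlation *within* each drug — the clinically relevant
   differential signal — is near zero.
3. **Pseudoreplication and leakage.** Hundreds of thousands of pairs derive
   from only hundreds of cell lines and drugs. Random splits leak entity
   identities between train and test, and the effective sample size for
   generalization is the number of entities, not pairs.

drbench is a harness built around these three failure modes: naive
baselines that quantify how much performance mean effects alone buy,
split designs matched to application scenarios, normalized metrics that
remove the mean effects, and rank-based statistics for honest model
comparison — all executable end to end on synthetic data with known
structure.

## Split designs

Cross-validation folds are formed by grouping records, shuffling the groups
with the seed, and dealing them round-robin to folds:

* **LPO** (leave-pairs-out) groups by (cell line, drug) pair — the
  imputation scenario. Replicates of one pair always share a fold.
* **LCO** (leave-cell-lines-out) — the personalized-medicine scenario:
  test cell lines are never seen in training.
* **LTO** (leave-tissues-out) — generalization to unseen tissue types.
* **LDO** (leave-drugs-out) — drug repurposing/design: test drugs are
  never seen in training.

Group-disjointness is asserted at runtime for every fold, not assumed.
Balancing is by group count (round-robin dealing), not record count: record
balancing is not needed for rank statistics, and group-count balancing
keeps the design simple and exactly reproducible. Requesting more folds
than there are groups (e.g. LTO with k greater than the number of tissues)
is an error rather than a silent merge.

Hyperparameter tuning uses a *single inner holdout* carved from the
training groups (default 10% of training groups), group-disjoint under the
same rules; models that need early stopping get a second disjoint holdout.
Grid search scores every configuration by validation RMSE and keeps the
minimizer, breaking ties by grid order. The winning fit is the one trained
on the inner-train part: the validation records stay untouched by the
returned model. This keeps grid-searched models comparable with
early-stopping models (which also never train on their validation data) at
the cost of a slightly smaller effective training set; models without a
grid are simply fit on the full training fold.

## The naive predictor family

With $\mu$ the overall training mean, $\mu_i^c$ the mean of cell line $i$
and $\mu_j^d$ the mean of drug $j$, the mean-effects baseline predicts

$$\hat{y}_{ij} = \mu_i^c + \mu_j^d - \mu,$$

falling back to $\mu_i^c = \mu$ or $\mu_j^d = \mu$ for entities unseen in
training (so under LDO it degrades gracefully to the cell-line mean). The
single-factor variants (overall, drug mean, cell-line mean, tissue mean)
isolate each source of memorizable variance; the tissue-mean variant falls
back to $\mu$ for unseen tissues, a symmetric choice we made since only the
drug/cell-line fallbacks are canonical. On a complete, noiseless additive
table the mean-effects predictor is exact — a property the test suite
verifies, along with agreement to $10^{-12}$ with a brute-force group-mean
oracle.

## Metrics and normalization

Per fold, drbench computes MSE, RMSE, MAE, $R^2 = 1 - \sum(y-\hat
y)^2/\sum(y-\bar y)^2$, and Pearson/Spearman/Kendall correlations.
Correlations are *undefined* (not zero) when either argument has zero
variance, and undefined values are excluded from averages with a count —
coercing them to zero would silently reward degenerate predictors.

**Normalized metrics** recompute the suite after subtracting the
predictions of a mean-effects baseline — fitted on the *same training
fold* as the evaluated model, so normalization is leakage-consistent — from
both truth and prediction. What survives is differential drug response:
the interaction between molecular features and drug properties. Negative
normalized $R^2$ values are stored unclipped in all CSV outputs; clipping
at zero happens only in the rendered summary.

**Stratified metrics** pool predictions across folds and compute the suite
within each drug (or cell line). Strata under 3 points are reported as
undefined with their size. Comparing global with mean per-drug correlation
is the Simpson's-paradox diagnostic; note that under LPO the per-drug
correlation of a drug-mean-like predictor carries a finite-resampling
artifact of order $-1/\sqrt{n_{\text{per drug per fold}}}$ (the fold's
test values are anti-correlated with the complementary training mean), so
the diagnostic needs enough records per drug to read cleanly.

**SSMD** between two models' per-fold metric values uses the paired form
$\mathrm{mean}(a-b)/\mathrm{sd}(a-b)$ (folds pair the values); an unpaired
variant is available behind a switch. Conventions: elementwise-equal
vectors give 0; constant nonzero differences give a signed infinity.

## Rank statistics

Models are ranked by MSE within each fold (average ranks for ties — ties
do occur with quantized metrics). The tie-corrected Friedman statistic

$$Q = (k-1)\,\frac{\sum_j (R_j - n(k+1)/2)^2}{A - C}, \qquad
A = \sum_{ij} r_{ij}^2,\; C = \tfrac{nk(k+1)^2}{4}$$

is referred to the upper tail of $\chi^2_{k-1}$. The Conover post-hoc
statistic $t = (R_i - R_j)/\sqrt{2n(A-B)/((n-1)(k-1))}$ with
$B = \sum_j R_j^2/n$ follows a t-distribution with $(n-1)(k-1)$ degrees of
freedom; two-sided p-values are Benjamini–Hochberg adjusted over the
$k(k-1)/2$ pairs at $\alpha = 0.05$. Degenerate cases are distinguished:
complete ties give all $p = 1$ (no evidence), while perfectly consistent
distinct rankings have zero residual rank variance and diverging evidence
($p \to 0$). The test suite checks the implementation against an
independently coded textbook formulation of the Conover denominator, against
`stats::friedman.test` on tie-free data, against a within-block permutation
null, and calibrates the type-I error by simulation.

Critical-difference groups are computed on contiguous runs in mean-rank
order: each model's bar is the maximal contiguous run containing it in
which every pair is non-significant; nested and duplicate bars are merged.
The omnibus and post-hoc results are always both computed; when the
omnibus test is non-significant the result carries a flag, since the
pairwise bars then localize no real differences.

## Dose-response preprocessing

Raw viability signals are normalized per replicate by that replicate's
control (no-drug) signal; values above 1 (growth stimulation) are kept.
Replicates are *not* aggregated before fitting: a single four-parameter
log-logistic curve

$$v(x) = \text{back} + \frac{\text{front} - \text{back}}
{1 + 10^{\,\text{slope}\,(x - \log_{10}\mathrm{EC50})}}$$

is fit jointly across all replicate points per (cell line, drug) pair, so
replicate disagreement inflates the residual and weakens the fit's
significance. Doses are in micromolar and pEC50 is reported as
$-\log_{10}(\mathrm{EC50}\,[\mu M])$; a molar convention is a constant
offset of 6. Significance is a plain nested-model F-test against the
constant-mean model. Fitting is multi-start Levenberg–Marquardt
(`minpack.lm`), EC50 initialized at five dose quantiles with a small
seeded jitter, plateaus at the viability extremes; with fewer than four
distinct doses the front plateau is fixed at 1 (a three-parameter fit) to
avoid overparameterization. Non-convergence across all starts flags the
curve unfit with $p = 1$. Under a flat truth with realistic noise the
F-test is mildly conservative (about 3–4% of fits fall below $p = 0.05$ in
our 1000-curve simulation), acceptable for a screening-quality filter.

Derived measures: IC50 is the closed-form solution of $v(x) = 0.5$ when
the plateaus bracket 0.5, otherwise missing; AUC is the mean fitted
viability over the measured $\log_{10}$ dose range (closed-form integral),
so lower AUC means more sensitive and a flat inert curve has AUC 1. The
AUC is over the *fitted* curve, normalized by the log-range width — a
documented choice, since conventions differ across screens. Validity
rules: an EC50 outside the measured dose range is flagged invalid; an IC50
outside $[d_{\min}/10,\; d_{\max}\cdot 10]$ (one order of magnitude beyond
the range, read literally) is set to missing. Because screens dose
different ranges, fits carry a dosage-group label and p-values should only
be compared within one group.

## Ablation and robustness

Three randomizers, each destroying specific information while preserving a
stated invariant:

* **Permutation** reassigns feature vectors across entities — the multiset
  of vectors is unchanged, only the entity link is destroyed.
* **Moment-preserving Gaussian** replaces each feature column with draws
  matching that column's mean and sd — only summary statistics survive.
  "Moments" are per feature column across entities (a per-entity variant
  exists behind a switch).
* **Degree-preserving edge shuffle** rewires graphs by double-edge swaps
  rejecting loops and multi-edges (via `igraph::rewire`), with the default
  effort of 10 swap attempts per edge; degree sequences are exactly
  preserved, and rigid graphs (paths of two edges, stars) return unchanged.

An ablation run retrains the model from scratch on the randomized features
— re-predicting with the old fit would understate reliance on the modality
— reusing the fold assignment and the hyperparameters chosen in the
unperturbed run. No re-tuning: the delta should isolate the feature
signal, not the tuner's ability to adapt. Results are per-fold $R^2$
deltas (ablated minus unperturbed) with a $\pm 1.96 \times$ SEM band.
Robustness refits measure the metric spread across seeds for stochastic
learners; deterministic models report zero spread.

## Cross-study evaluation

Fold-trained models predict external screens after excluding records the
model has, per its split mode, already seen: overlapping pairs under LPO,
cell lines under LCO, tissues under LTO, drugs under LDO. Exclusion is
against each fold's *own* training records (the union-over-folds variant
is available behind a switch): each fold model is an independent unit, and
per-fold exclusion matches that reading. A mean-effects reference is
fitted on the same training fold and evaluated on the same filtered
records, so the external naive baseline is always comparable. A useful
separation property, covered by tests: an affine assay shift in the
external study leaves Pearson untouched while degrading MSE — correlation
metrics measure transfer of ordering, error metrics measure calibration.

## The synthetic generator

`generate_response_dataset()` draws
$y_{ij} = \mu_0 + d_j + c_i + t_{tissue(i)} + I_{ij} + \varepsilon_{ij}$
with every component rescaled to its configured standard deviation
*exactly* (sample mean 0, sample sd as configured). The exact-share
construction matters: with plain i.i.d. draws the realized drug-variance
share of 150 drugs fluctuates by several points, which would swamp the
±0.02 recovery checks; rescaling makes the configured decomposition a
property of the generated population. The interaction is a bilinear form
$u_i^\top W v_j$ of the informative feature blocks, rescaled to its
configured sd over the sampled pairs, and the cell/drug effects are linear
reads of those same blocks — so feature-based learners can in principle
recover them, and ablating the informative block provably removes the
signal. Tissues are dealt round-robin to cell lines.

Default variance shares on unit total variance mirror the decomposition
of large public screens, where drug identity dominates: drug 0.675, cell
line 0.035, tissue 0.025, interaction 0.065, noise 0.200 — so a
drug-mean predictor should score $R^2 \approx 0.675$ under LPO, a
cell-line-mean predictor $\approx 0.060$ (cell + tissue), a tissue-mean
predictor $\approx 0.025$, and a mean-effects predictor $\approx 0.735$.
Default sizes are 200 cell lines × 100 drugs at completeness 0.25 (a
quarter of the grid measured), i.e. a desk-scale screen. All randomness
derives from one root seed through labelled sub-streams
(`derive_seed()`), so each generator is independently reproducible.

What the generator does **not** emulate: realistic omics marginal
distributions, chemical-space structure, batch effects, heteroscedastic
assay noise, or missingness that correlates with potency. Passing tests
on this synthetic structure therefore demonstrates correctness of the
harness's accounting — splits, baselines, normalization, statistics — not
that any model will transfer to real screens.

`generate_raw_viability()` simulates plate signals from known
four-parameter curves (front 1, back uniform on [0, 0.3], Hill slope on
[0.7, 2], EC50 log-uniform inside the dosed range, optional flat curves)
with Gaussian signal noise, returning the truth for recovery checks.

## Numerical and design choices

* Benchmark runs fix one output measure across all compared models; mixing
  measures across models is rejected by design.
* Records whose entities lack a required feature modality are dropped per
  model with reported counts, never imputed.
* Entity identifiers are opaque strings; no external identifier mapping.
* Fold assignment, tuning splits and model fits all derive seeds from the
  run seed via labelled hashing, so reruns are byte-identical for
  deterministic models.
* Test problem sizes: the test suite exercises the variance-share and
  Simpson diagnostics at 300×150 and 5000×20 entities respectively, the
  constant-predictor zero-$R^2$ check at 300×150 with complete
  measurement (its small-sample $R^2$ bias is $O(1/n_{\text{fold}})$,
  so fold sizes are chosen to push it beyond the third decimal), the
  curve recovery at 100 curves × 8 doses × 2 replicates, the F-test
  calibration at 1000 curves, and the Friedman type-I calibration at 2000
  simulated benchmarks — sizes chosen so each check's sampling error is
  well inside its tolerance.

## Known limitations

* The curve fit's F-test treats the nonlinear model as if it were linear
  in its parameters; the resulting p-values are approximate (empirically
  slightly conservative under the null) and are intended for filtering,
  not inference.
* The reference learners (penalized linear, random forest, per-drug
  linear) are deliberately simple harness exercisers; the model contract,
  not the shipped learners, is the extension point.
* Critical-difference bars use the standard contiguity convention on
  mean-rank order; non-contiguous non-significant pairs are representable
  only through overlapping bars.
* The graph modality ships with a degree-preserving null model only;
  graph-aware learners must bring their own featurization.

## A minimal run

```{r example, eval = FALSE}
cfg <- synthetic_config(n_cell_lines = 60, n_drugs = 20,
                        completeness = 0.5, seed = 1)
sim <- generate_response_dataset(cfg)
cv <- run_cross_validation(
  sim$dataset,
  models = list(naive_model("overall"), naive_model("drug_mean"),
                naive_model("mean_effects")),
  mode = "LPO", k = 5, seed = 1
)
glance(cv)
compare_models(fold_metrics(cv$predictions))
```
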