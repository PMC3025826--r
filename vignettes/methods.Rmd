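---
title: "Combined clinical and gene-expression-module prognostic modelling: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combined clinical and gene-expression-module prognostic modelling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prognomod)
```

## The problem

Dozens of breast-cancer gene-expression signatures predict outcome about
equally well, and clinical-pathological variables (tumor size, grade,
estrogen-receptor and HER2 status) remain independently prognostic. The
question this package operationalizes is whether a *combined* model —
standard clinical variables plus a large library of expression "modules"
entered as candidate covariates of a sparse multivariate model — improves
prognostication over either variable type alone, and whether the same
machinery predicts response to neoadjuvant chemotherapy.

A **module** is a named gene set summarized per sample by a single score,
so that hundreds of signatures become ordinary covariates. Four scoring
routes are supported, matching how published signatures are constructed:

* **median** — each member gene is centered by its cohort median, and the
  sample score is the median across member genes. Median centering makes
  scores location-free across array platforms; it can be disabled
  (`score_median(..., center = FALSE)`).
* **first principal component** — member genes are z-scored, and the score
  is the sample projection on the leading eigenvector of the gene–gene
  covariance matrix. The eigenvector's sign is arbitrary, so the score is
  oriented to correlate non-negatively with the mean member-gene profile
  (or per an explicit `direction_hint`), then standardized to unit
  variance.
* **centroid correlation** — the correlation between a sample's member-gene
  profile and one or more reference centroids (e.g. intrinsic-subtype
  centroids), one score row per centroid. Spearman rank correlation is the
  default, following the subtype-centroid literature; Pearson is available
  because original implementations vary and sources rarely say which was
  used.
* **published model** — a fixed linear model (per-gene weights plus
  offset); genes absent from the data contribute zero and are reported,
  because predictors applied across merged platforms always lose genes.

A module is scoreable when at least `min_fraction` (default 0.5) of its
genes are present; the threshold is a design choice — published analyses
are silent on how much gene loss they tolerated — and every match report
records the fraction so the consequence is visible.

## Cohort assembly

Merged microarray cohorts carry batch effects. `dwd_adjust()` implements
batch adjustment in the distance-weighted-discrimination (DWD) style: for
each batch against the largest batch as reference, it fits the separating
linear direction by minimizing a smoothed DWD objective — mean reciprocal
margin, with the convex linear extension below a unit margin to keep the
loss differentiable, plus a small ridge term — with L-BFGS-B, and then
translates the batch along that direction so the two batch means coincide
on it. The fit-and-translate step repeats only while the projected mean
difference exceeds four standard errors of a batch-mean difference along
the fitted direction; chasing shifts below that floor would be fitting
sampling noise, and stopping there makes the adjustment a fixed point
(re-running an adjusted matrix changes nothing). A per-gene per-batch
mean-centering fallback (`method = "mean_center"`) handles batches too
small for a discriminant.

The remaining assembly rules are deliberately mechanical and each is a
one-line contract:

* `complete_case_filter()` drops records missing any required clinical or
  outcome field and reports retention.
* `apply_followup_cutpoint()` administratively censors at the follow-up
  cut-point (default 7 years): times beyond it become the cut-point with
  the event indicator cleared.
* `her2_surrogate()` calls HER2-positive the top 20% of HER2 (ERBB2) mRNA
  expressers — the surrogate used when clinical HER2 status is
  unavailable. Exactly `ceiling(0.2 n)` samples are positive; boundary
  ties break by ascending sample id so the rule is reproducible.
* `assign_subtypes()` assigns each sample the centroid it correlates with
  best; centroids are always a user-supplied artifact (reference centroid
  values are proprietary to their publications and never bundled).
* `define_subgroup()` provides the standard clinical subgroups (ER+, ER−,
  HER2+, ER+/HER2−, Luminal = Luminal A ∪ B, Basal-like, HER2-enriched).

## Model building and validation

Candidate covariates are the encoded clinical variables (ER and HER2 as
0/1 positivity, size as 0/1 for ≥ 2 cm, grade ordinal 1–3) and the module
scores, in three families: clinical only, genomic only, combined.
`fit_lasso_cox()` maximizes the L1-penalized Cox partial likelihood
(via glmnet) over a descending λ grid, choosing λ by seeded 10-fold
cross-validated partial-likelihood deviance at the minimum-deviance rule
(a 1-SE rule is available by flag; with hundreds of correlated candidates
the 1-SE rule frequently returns the empty model, which would make the
success rule vacuous). Variables are standardized internally before
penalization, so coefficient magnitudes — and selection — are comparable
across modules and clinical variables.

The **risk score** is the fitted linear predictor centered at its
training-set mean: the log hazard ratio relative to the training-average
patient. Centering makes the conventional high/low cut-off of zero
meaningful on test data. A score exactly at the threshold is labelled
low risk; the tie has probability zero for continuous scores and the rule
is stated only for reproducibility.

Validation uses a stratified 2:1 train/test split
(`stratified_split()`): samples are cross-classified by data source,
platform and the clinical variables, and a seeded largest-remainder
allocation keeps every cell's training fraction within one sample of 2/3
while hitting the global target exactly (singleton cells go to training).
A model counts as a **success** only when the Cox p-value of its risk
score is below 0.05 on *both* the training and the testing set and the
model is non-empty; the test-set requirement is what controls false
successes.

Evaluation statistics follow standard conventions, stated explicitly
because they affect third-decimal comparisons: Kaplan–Meier and log-rank
use the events-before-censorings convention at tied times; the Cox refit
p-value is Wald by default (likelihood-ratio by flag); Harrell's C counts
pairs `(i, j)` with `t_i < t_j` and an event in `i` as comparable and
credits tied scores one half; AUC is the midrank Mann–Whitney form, which
handles tied predictions exactly.

## Resampling

`run_resampling()` repeats split → fit → evaluate with derived per-round
seeds (`base_seed + i`, so any round can be reproduced in isolation)
until a target number of rounds succeed for the primary family (default:
combined) or an attempt cap is reached — published descriptions of
"200 successful models" are ambiguous about whether all attempts
succeeded, so both counts are reported and an incomplete run is flagged
rather than silently truncated. Selection frequencies are tabulated among
successful rounds with each variable's direction of association
(positive coefficient = higher hazard = poor prognosis). Mean test-set
C-index per family averages over all evaluated rounds, and the
superiority matrix entry `M[f1, f2]` is the fraction of rounds in which
family `f1`'s test C-index strictly exceeds `f2`'s; ties count for
neither cell. Exclusion re-analyses (dropping well-known signatures such
as a 70-gene or 76-gene signature, a recurrence score and a
risk-of-relapse score before model building) are expressed through
`exclude_modules()`.

Module scoring constants are a potential leakage channel: gene medians,
principal axes and standardization constants computed on all samples let
the test set influence training features. `run_round()` therefore
supports split scoring mode (pass `expr` + `registry`), in which scoring
constants are re-derived on each training set and applied to the test
set; global mode (pass a precomputed score matrix) is retained because
whole-cohort scoring is how published module matrices are distributed,
and because for location/scale constants the leakage is second-order.

`run_pcr_experiment()` is the binary-response parallel: one stratified
150/75-style split (by response, ER and HER2; splits lacking a class are
re-drawn with the next seed, boundedly), an L1-penalized logistic model
per family, training and testing ROC AUC, and the selected variables with
their direction of association with response.

## The synthetic-data generator

`generate_expression_cohort()` produces cohorts with exactly the
structure the analysis assumes, so every downstream stage is testable
without the original cohorts:

* module blocks: member genes of module *m* are
  `sqrt(ρ)·z_m + sqrt(1−ρ)·ε`, giving expected pairwise within-module
  correlation ρ (`module_correlation`); background genes are independent
  standard normals;
* per-(batch, gene) additive location shifts with SD `batch_shift_sd`,
  batches assigned in rotation (default two, emulating a two-platform
  design);
* clinical covariates as thresholded latent Gaussians correlated with
  designated module scores (ER with module 1, size with module 2, grade
  with module 3, HER2 with module 4), which reproduces the confounding
  between ER status and module scores without extra machinery; marginal
  prevalences default to values typical of node-negative cohorts
  (ER+ 71.8%, size < 2 cm 56.2%, grade 17.8/33.1/49.1%, HER2+ 20% by the
  top-fraction rule);
* survival outcomes from an exponential baseline hazard
  (`baseline_hazard_rate`, default 0.08/year) multiplied by
  `exp(linear predictor)` on standardized covariates, with independent
  exponential censoring (`censoring_rate`, default 0.10/year) — the
  simplest forms with closed-form sanity checks (median event time
  `ln 2 / λ`); a Weibull hook is left open;
* binary response outcomes from a logistic model whose intercept
  (default −1.0, giving roughly the ~26% response prevalence typical of
  anthracycline/taxane neoadjuvant cohorts) controls prevalence.

Effect sizes of real prognostic modules are not published, so the default
planted coefficient (0.8 per SD) was chosen once to make an effect
detectable at a few hundred samples, and parameter-recovery tests are run
at those generator defaults rather than tuned per test. What the
generator does **not** emulate: probe-level artifacts, normalization
pipelines, realistic gene–gene networks beyond block correlation,
non-proportional hazards, or informative censoring. Passing tests
therefore demonstrate that the machinery is correct and powered under its
own assumptions, not that real cohorts satisfy those assumptions.

## Numerical choices and degenerate inputs

* First-PC scoring drops zero-variance genes with a warning and declares
  the module unscoreable if none remain or fewer than two genes / three
  samples are available.
* Centroid correlation of a constant sample profile is undefined and
  returned as `NA` with a warning.
* Constant covariates are dropped (with a warning) before penalized
  fitting; monotone-likelihood Cox fits are flagged.
* All tie rules (HER2 boundary, subtype-correlation ties, risk-score
  threshold, superiority ties) are deterministic and documented above.
* Identical seeds give byte-identical simulations, splits, fits and
  pipeline outputs; RNG state of the caller is never clobbered.

## Problem sizes used in the shipped checks

The package's test suite runs its heavier simulation-based checks at
sizes chosen to make the statistical assertions stable: 100 candidate
modules with 5 planted prognostic modules at n = 350 over 50 successful
resampling rounds for selection-frequency recovery, and 100 null rounds
at n = 300 for the success-rate error-control check. Larger cohorts only
sharpen the same comparisons.

## Known limitations

The DWD adjustment removes a single translation direction per batch pair;
batch effects that rescale variance or act nonlinearly are out of scope
(as is probe-to-gene mapping across platforms). The resampling rounds
reuse overlapping data, so selection frequencies and mean C-indexes are
dependent across rounds and should be read comparatively, not as
calibrated probabilities. Elastic-net/ridge variants, time-dependent
covariates, competing risks and time-dependent AUC are intentionally not
implemented.
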