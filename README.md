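# prognomod

Combined clinical + gene-expression-module prognostic modelling for
breast cancer cohorts.

## What problem this solves

Node-negative breast cancer patients are prognosticated both by
clinical-pathological variables (tumor size, histological grade, ER and
HER2 status) and by gene-expression signatures, of which hundreds have
been published. `prognomod` treats each signature as a **module** — a
named gene set summarized per sample by one score — and asks whether a
sparse multivariate model over *clinical variables + hundreds of module
scores* predicts relapse-free survival (or chemotherapy response) better
than either variable type alone.

The core procedure, for a cohort with expression matrix `X` (genes ×
samples), module registry `M` and survival outcome `(T, δ)`:

1. **Score modules**: each module `m` becomes a covariate
   `s_m(j)` per sample `j` via one of four routes — median of
   median-centered member genes, first principal component of the member
   submatrix (sign-oriented, unit variance), Spearman correlation to
   reference centroids, or a published linear model `w·x + b`.
2. **Fit**: an L1-penalized Cox model
   `argmax_β { ℓ_partial(β) − λ‖β‖₁ }` over a feature family
   (clinical / genomic / combined), λ chosen by seeded 10-fold
   cross-validated partial-likelihood deviance, on a training set from a
   stratified 2:1 split.
3. **Validate**: the risk score `η_j = x_jᵀβ̂ − mean_train(xᵀβ̂)`
   (log hazard ratio vs. the training average; threshold 0 splits
   high/low risk) is refit in a univariate Cox model on both sets; a
   model "succeeds" only if p < 0.05 on **both** training and testing
   sets.
4. **Resample**: the split–fit–validate round repeats with derived seeds
   until a target number of successes; variable **selection frequencies**
   (with direction of association), per-family mean test **Harrell
   C-index** and a pairwise **superiority matrix** summarize the rounds.

A parallel `LASSO + logistic` path predicts pathological complete
response (pCR) with training/testing ROC AUC. Supporting machinery:
DWD-style batch-effect adjustment, complete-case filtering, an
administrative follow-up cut-point, a top-20% HER2 mRNA surrogate,
nearest-centroid subtyping, clinical subgroup specs, and a fully
synthetic cohort generator with known truth so every stage is testable
without access to patient-level data. See `vignettes/methods.Rmd` for the
model details and design rationale.

## Worked example

Simulate a 300-patient cohort with 40 candidate modules of which two
(`MOD05`, `MOD06`) truly increase hazard, alongside grade and size
effects; score modules from the expression matrix; run 20 resampling
rounds:

```r
library(prognomod)

cfg <- simulation_config(
  n_samples = 300, n_genes = 400, n_modules = 40, genes_per_module = 8,
  module_correlation = 0.7,
  true_coefficients = c(MOD05 = 0.9, MOD06 = 0.9, grade = 0.5, size = 0.4),
  seed = 7)
sim    <- generate_expression_cohort(cfg)
cohort <- generate_survival_outcomes(truth_module_scores(sim$truth),
                                     sim$clinical, sim$truth, cfg)
cohort <- apply_followup_cutpoint(cohort, 7)

registry <- module_registry(lapply(names(sim$truth$module_memberships),
  function(m) module_definition(m, sim$truth$module_memberships[[m]])))
scores <- compute_all_scores(sim$expr, registry)

rs <- run_resampling(cohort, scores = scores$scores,
                     families = c("clinical", "genomic", "combined"),
                     n_target = 20, max_attempts = 60, base_seed = 1)
rs
#> resample_summary: 20 attempted rounds, 20/20 successes (combined)
#> mean test C-index:
#> clinical  genomic combined
#>   0.6249   0.7742   0.7918

head(rs$selection$combined, 5)
#>   variable count frequency direction
#> 3    MOD05    20      1.00      poor
#> 4    MOD06    20      1.00      poor
#> 1     size    19      0.95      poor
#> 2    grade    18      0.90      poor
#> 7    MOD38    17      0.85      good

round(rs$superiority, 3)
#>          clinical genomic combined
#> clinical       NA    0.00      0.0
#> genomic         1      NA      0.1
#> combined        1    0.85       NA
```

Reading the output: every round succeeded (p < 0.05 on both sets); both
planted modules were selected in all 20 successful models and tagged
poor-prognosis (positive log-hazard coefficient), with the planted
clinical effects close behind; the combined family's mean test C-index
(0.79) beats genomic-only (0.77) and clinical-only (0.62), and the
combined model's test C-index exceeded the genomic model's in 85% of
rounds. Null modules can recur in the table (`MOD38` here): rounds reuse
overlapping data, so a chance association persists across splits — one
reason frequencies should be read comparatively.

The same pipeline runs from a config file, end to end:

```r
run_pipeline(list(analysis = "survival",
                  simulate = list(n_samples = 200, n_genes = 80,
                                  n_modules = 6, genes_per_module = 6),
                  families = c("clinical", "combined"),
                  n_target = 5, seed = 42, out = "results/demo"))
```

writing `summary.json`, `selection_frequency.tsv`, `cindex.tsv`,
`superiority.tsv` and a rendered `report.md`. A thin command-line
wrapper lives at `inst/cli/prognomod.R`
(`Rscript prognomod.R {simulate|pipeline} --config cfg.json --seed 1 --out dir/`).

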