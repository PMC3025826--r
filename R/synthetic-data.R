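#' Simulation configuration for synthetic expression cohorts
#'
#' Defines a synthetic cohort with block-correlated gene modules, per-batch
#' location shifts, clinical covariates tied to designated module scores,
#' and outcome models (exponential-hazard survival with independent
#' exponential censoring, or Bernoulli response from a logistic model).
#'
#' @param n_samples number of samples.
#' @param n_genes total number of genes (module members plus background).
#' @param n_modules number of co-expressed gene blocks.
#' @param genes_per_module genes in each block.
#' @param module_correlation target average pairwise correlation between
#'   genes of the same module, in `[0, 1]`.
#' @param n_batches number of batches (default two, emulating a two-platform
#'   design); samples are assigned to batches in rotation.
#' @param batch_shift_sd standard deviation of the per-(batch, gene) additive
#'   location shift, in log-expression units.
#' @param true_coefficients named numeric vector of Cox log-hazard (or
#'   logistic log-odds) effects per standardized unit; names must resolve to
#'   module names (`"MOD01"`, ...) or clinical variables
#'   (`er`, `size`, `grade`, `her2`).
#' @param baseline_hazard_rate baseline event rate (events/year), > 0.
#' @param censoring_rate independent censoring rate (censorings/year), > 0.
#' @param followup_cutpoint_years administrative follow-up cut-point.
#' @param clinical_dependence strength in `[0, 1)` of the dependence of each
#'   clinical latent on its designated module score (ER on module 1, size on
#'   module 2, grade on module 3, HER2 on module 4, when present).
#' @param clinical_prevalence named list of marginal category frequencies
#'   (`er_pos`, `size_lt2cm`, `grade` length-3, `her2_top`).
#' @param pcr_intercept logistic intercept controlling response prevalence.
#' @param seed integer RNG seed; identical configs generate identical data.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_samples = 550,
                              n_genes = 1000,
                              n_modules = 20,
                              genes_per_module = 10,
                              module_correlation = 0.7,
                              n_batches = 2,
                              batch_shift_sd = 0.5,
                              true_coefficients = c(MOD01 = 0.8, grade = 0.4),
                              baseline_hazard_rate = 0.08,
                              censoring_rate = 0.10,
                              followup_cutpoint_years = 7,
                              clinical_dependence = 0.5,
                              clinical_prevalence = list(
                                er_pos = 0.718, size_lt2cm = 0.562,
                                grade = c(0.178, 0.331, 0.491),
                                her2_top = 0.20),
                              pcr_intercept = -1.0,
                              seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
              n_modules = as.integer(n_modules),
              genes_per_module = as.integer(genes_per_module),
              module_correlation = module_correlation,
              n_batches = as.integer(n_batches),
              batch_shift_sd = batch_shift_sd,
              true_coefficients = true_coefficients,
              baseline_hazard_rate = baseline_hazard_rate,
              censoring_rate = censoring_rate,
              followup_cutpoint_years = followup_cutpoint_years,
              clinical_dependence = clinical_dependence,
              clinical_prevalence = clinical_prevalence,
              pcr_intercept = pcr_intercept,
              seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  if (cfg$n_modules * cfg$genes_per_module > cfg$n_genes) {
    stop_config(
      "n_genes: n_modules * genes_per_module (%d) exceeds n_genes (%d)",
      cfg$n_modules * cfg$genes_per_module, cfg$n_genes)
  }
  if (cfg$module_correlation < 0 || cfg$module_correlation > 1) {
    stop_config("module_correlation: must lie in [0, 1], got %g",
                cfg$module_correlation)
  }
  if (cfg$batch_shift_sd < 0) stop_config("batch_shift_sd: must be >= 0")
  for (f in c("baseline_hazard_rate", "censoring_rate",
              "followup_cutpoint_years")) {
    if (cfg[[f]] <= 0) stop_config("%s: must be strictly positive", f)
  }
  if (cfg$n_batches < 1) stop_config("n_batches: must be >= 1")
  if (cfg$clinical_dependence < 0 || cfg$clinical_dependence >= 1) {
    stop_config("clinical_dependence: must lie in [0, 1)")
  }
  invisible(cfg)
}

module_name <- function(i) sprintf("MOD%02d", i)

#' Generate a synthetic expression cohort with known truth
#'
#' Member genes of module m are `sqrt(rho) * z_m + sqrt(1 - rho) * noise`
#' where `z_m` is the module's latent score, so the expected pairwise
#' within-module correlation equals `rho = module_correlation`. Background
#' genes are independent standard normals. Per-(batch, gene) additive shifts
#' with SD `batch_shift_sd` are then applied. Clinical categories are
#' thresholded latent Gaussians correlated with designated module scores;
#' HER2 status is assigned by the top-fraction rule on its latent.
#'
#' @param config a [simulation_config()].
#' @return list with `expr` (genes x samples log-expression matrix),
#'   `clinical` (data.frame: sample_id, er, size, grade, her2, source,
#'   platform), and `truth` (module memberships, latent module scores,
#'   batch shifts, true coefficients, the config).
#' @export
generate_expression_cohort <- function(config) {
  validate_simulation_config(config)
  n <- config$n_samples
  rho <- config$module_correlation
  samples <- sprintf("S%04d", seq_len(n))
  genes <- sprintf("G%05d", seq_len(config$n_genes))

  with_seed(config$seed, {
    latent <- matrix(stats::rnorm(config$n_modules * n),
                     nrow = config$n_modules,
                     dimnames = list(module_name(seq_len(config$n_modules)),
                                     samples))
    expr <- matrix(stats::rnorm(config$n_genes * n), nrow = config$n_genes,
                   dimnames = list(genes, samples))
    memberships <- list()
    for (m in seq_len(config$n_modules)) {
      idx <- (m - 1L) * config$genes_per_module + seq_len(config$genes_per_module)
      expr[idx, ] <- sqrt(rho) * matrix(latent[m, ], nrow = length(idx),
                                        ncol = n, byrow = TRUE) +
        sqrt(1 - rho) * expr[idx, , drop = FALSE]
      memberships[[module_name(m)]] <- genes[idx]
    }

    batch <- rep_len(seq_len(config$n_batches), n)
    shifts <- matrix(stats::rnorm(config$n_batches * config$n_genes,
                                  sd = config$batch_shift_sd),
                     nrow = config$n_batches,
                     dimnames = list(paste0("batch", seq_len(config$n_batches)),
                                     genes))
    expr <- expr + t(shifts)[, batch, drop = FALSE]

    clin <- draw_clinical(latent, config)
  })

  clinical <- data.frame(
    sample_id = samples,
    er = clin$er, size = clin$size, grade = clin$grade, her2 = clin$her2,
    source = paste0("Source", batch),
    platform = c("PlatformA", "PlatformB")[(batch - 1L) %% 2L + 1L],
    stringsAsFactors = FALSE)

  truth <- list(module_memberships = memberships,
                true_coefficients = as.list(config$true_coefficients),
                batch_shifts = shifts,
                latent_module_scores = latent,
                seed = config$seed)
  list(expr = expr, clinical = clinical, truth = truth)
}

## Clinical categories as thresholded latent Gaussians tied to designated
## module scores (ER ~ module 1, size ~ module 2, grade ~ module 3,
## HER2 ~ module 4 where available). Must be called inside with_seed().
draw_clinical <- function(latent, config) {
  n <- ncol(latent)
  a <- config$clinical_dependence
  prev <- config$clinical_prevalence
  latent_for <- function(k) {
    noise <- stats::rnorm(n)
    if (k <= nrow(latent)) a * latent[k, ] + sqrt(1 - a^2) * noise else noise
  }
  er_l <- latent_for(1L); size_l <- latent_for(2L)
  grade_l <- latent_for(3L); her2_l <- latent_for(4L)

  er <- ifelse(er_l > stats::qnorm(1 - prev$er_pos), "pos", "neg")
  size <- ifelse(size_l < stats::qnorm(prev$size_lt2cm), "lt2cm", "ge2cm")
  gcuts <- stats::qnorm(cumsum(prev$grade[1:2]) / sum(prev$grade))
  grade <- ifelse(grade_l < gcuts[1], 1L, ifelse(grade_l < gcuts[2], 2L, 3L))
  n_pos <- ceiling(prev$her2_top * n)
  her2 <- rep("neg", n)
  her2[order(-her2_l)[seq_len(n_pos)]] <- "pos"
  list(er = er, size = size, grade = grade, her2 = her2)
}

## Encode clinical categories numerically (er/size/her2 binary, grade 1-3)
## and bind with module-score rows into the covariate matrix used by the
## outcome generators; all covariates standardized.
outcome_design <- function(scores, clinical, coef_names) {
  clin_num <- cbind(er = as.numeric(clinical$er == "pos"),
                    size = as.numeric(clinical$size == "ge2cm"),
                    grade = as.numeric(clinical$grade),
                    her2 = as.numeric(clinical$her2 == "pos"))
  rownames(clin_num) <- clinical$sample_id
  avail <- c(rownames(scores), colnames(clin_num))
  unknown <- setdiff(coef_names, avail)
  if (length(unknown)) {
    stop_config("true_coefficients: unknown variable(s) %s",
                paste(unknown, collapse = ", "))
  }
  x <- sapply(coef_names, function(v) {
    col <- if (v %in% rownames(scores)) scores[v, clinical$sample_id]
           else clin_num[, v]
    s <- stats::sd(col)
    if (s == 0) rep(0, length(col)) else (col - mean(col)) / s
  })
  if (length(coef_names) == 0) x <- matrix(0, nrow(clinical), 0)
  x
}

#' Generate right-censored survival outcomes from a Cox model
#'
#' Event times are exponential with hazard
#' `baseline_hazard_rate * exp(lp)` where the linear predictor `lp` runs
#' over standardized covariates named in `true_coefficients`; censoring is
#' independent exponential with rate `censoring_rate`.
#'
#' @param scores module x sample score matrix (may have zero rows).
#' @param clinical clinical data.frame from [generate_expression_cohort()].
#' @param truth truth object from [generate_expression_cohort()].
#' @param config the [simulation_config()].
#' @param seed RNG seed for the outcome draw (default derived from config).
#' @return cohort data.frame: clinical columns plus `time` (years, > 0) and
#'   `event` (1 = relapse observed, 0 = censored).
#' @export
generate_survival_outcomes <- function(scores, clinical, truth, config,
                                       seed = config$seed + 1L) {
  beta <- unlist(truth$true_coefficients)
  x <- outcome_design(scores, clinical, names(beta))
  lp <- if (length(beta)) drop(x %*% beta) else rep(0, nrow(clinical))
  with_seed(seed, {
    t_event <- stats::rexp(nrow(clinical),
                           rate = config$baseline_hazard_rate * exp(lp))
    t_cens <- stats::rexp(nrow(clinical), rate = config$censoring_rate)
  })
  cohort <- clinical
  cohort$time <- pmin(t_event, t_cens)
  cohort$event <- as.integer(t_event <= t_cens)
  cohort
}

#' Generate binary treatment-response outcomes from a logistic model
#'
#' Response (e.g. pathological complete response) is Bernoulli with
#' probability `plogis(intercept + lp)` on standardized covariates.
#'
#' @inheritParams generate_survival_outcomes
#' @return cohort data.frame: clinical columns plus `response` (0/1).
#' @export
generate_pcr_outcomes <- function(scores, clinical, truth, config,
                                  seed = config$seed + 2L) {
  beta <- unlist(truth$true_coefficients)
  x <- outcome_design(scores, clinical, names(beta))
  lp <- if (length(beta)) drop(x %*% beta) else rep(0, nrow(clinical))
  p <- stats::plogis(config$pcr_intercept + lp)
  cohort <- clinical
  cohort$response <- with_seed(seed,
    as.integer(stats::rbinom(nrow(clinical), 1L, p)))
  cohort
}

#' Score modules directly from simulation truth
#'
#' Convenience scorer returning the latent module scores as the genomic
#' feature table; useful for outcome generation before (or independent of)
#' expression-based scoring.
#'
#' @param truth truth object from [generate_expression_cohort()].
#' @return module x sample matrix of latent scores.
#' @export
truth_module_scores <- function(truth) truth$latent_module_scores

#' Write a simulated cohort to disk
#'
#' Expression and clinical tables as TSV, truth as JSON (batch-shift matrix
#' flattened with dimension names preserved).
#'
#' @param sim result of [generate_expression_cohort()], optionally with an
#'   added `cohort` element.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(sim$expr, file.path(dir, "expression.tsv"))
  utils::write.table(sim$clinical, file.path(dir, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sim$cohort)) {
    utils::write.table(sim$cohort, file.path(dir, "cohort.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  truth <- sim$truth
  truth$batch_shifts <- list(values = as.vector(truth$batch_shifts),
                             batches = rownames(truth$batch_shifts),
                             genes = colnames(truth$batch_shifts))
  truth$latent_module_scores <- list(
    values = as.vector(truth$latent_module_scores),
    modules = rownames(truth$latent_module_scores),
    samples = colnames(truth$latent_module_scores))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
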