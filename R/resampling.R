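#' Stratified train/test split
#'
#' Samples are cross-classified by the strata fields; within each cell a
#' seeded shuffle allocates samples so that every cell's training fraction
#' is within one sample of the target ratio and the global training count
#' hits `round(n * ratio)` as closely as the cells allow (largest-remainder
#' allocation, ties broken by cell name). Singleton cells go to the
#' training set.
#'
#' @param cohort cohort data.frame with a `sample_id` column.
#' @param strata_fields columns to cross-classify on.
#' @param ratio target training fraction (default 2/3).
#' @param seed RNG seed; identical seeds give identical plans.
#' @return object of class `split_plan`: `assignment` (named
#'   `"train"`/`"test"` vector), `train_ids`, `test_ids`, plus metadata.
#' @export
stratified_split <- function(cohort, strata_fields, ratio = 2 / 3, seed = 1) {
  if (nrow(cohort) == 0) stop_config("stratified_split: empty cohort")
  missing_fields <- setdiff(strata_fields, names(cohort))
  if (length(missing_fields)) {
    stop_config("stratified_split: missing strata field(s) %s",
                paste(missing_fields, collapse = ", "))
  }
  cell <- if (length(strata_fields)) {
    do.call(paste, c(lapply(cohort[strata_fields], as.character), sep = "|"))
  } else rep("all", nrow(cohort))
  cells <- sort(unique(cell))
  k <- vapply(cells, function(cl) sum(cell == cl), 0L)
  target <- round(nrow(cohort) * ratio)

  n_train <- integer(length(cells))
  names(n_train) <- cells
  single <- k == 1
  n_train[single] <- 1L
  base <- floor(k * ratio)
  frac <- k * ratio - base
  n_train[!single] <- base[!single]
  need <- target - sum(n_train)
  if (need > 0) {
    elig <- which(!single & n_train < k)
    ord <- elig[order(-frac[elig], cells[elig])]
    bump <- utils::head(ord, need)
    n_train[bump] <- n_train[bump] + 1L
  } else if (need < 0) {
    elig <- which(!single & n_train >= 1)
    ord <- elig[order(frac[elig], cells[elig])]
    drop_ <- utils::head(ord, -need)
    n_train[drop_] <- n_train[drop_] - 1L
  }

  assignment <- stats::setNames(rep("test", nrow(cohort)), cohort$sample_id)
  with_seed(seed, {
    for (ci in seq_along(cells)) {
      idx <- which(cell == cells[ci])
      pick <- idx[sample.int(length(idx))][seq_len(n_train[ci])]
      assignment[pick] <- "train"
    }
  })
  structure(list(assignment = assignment,
                 train_ids = names(assignment)[assignment == "train"],
                 test_ids = names(assignment)[assignment == "test"],
                 ratio = ratio, strata_fields = strata_fields, seed = seed,
                 cell_sizes = stats::setNames(as.integer(k), cells),
                 cell_train = n_train),
            class = "split_plan")
}

default_strata <- function(cohort) {
  intersect(c("source", "platform", "er", "size", "grade", "her2"),
            names(cohort))
}

## Score train and test expression separately, re-deriving scoring
## constants on the training samples and applying them to the test
## samples; rows restricted to modules scoreable on the training set.
split_scores <- function(expr, registry, train_ids, test_ids,
                         min_fraction = 0.5) {
  tr <- compute_all_scores(expr[, train_ids, drop = FALSE], registry,
                           min_fraction)
  te <- compute_all_scores(expr[, test_ids, drop = FALSE], registry,
                           min_fraction, constants = tr$constants)
  common <- intersect(rownames(tr$scores), rownames(te$scores))
  list(train = tr$scores[common, , drop = FALSE],
       test = te$scores[common, , drop = FALSE])
}

#' One round of stratified model building and validation
#'
#' Splits the cohort, fits an L1-penalized Cox model per family on the
#' training set, and evaluates the resulting risk scores on both sets.
#' Training constants (variable encoding, scoring constants in split
#' scoring mode, the risk-score center) are derived on the training set
#' only and reused on the test set -- the test set never touches fitting
#' or lambda selection.
#'
#' @param cohort cohort data.frame (clinical columns + `time`, `event`).
#' @param scores precomputed module x sample score matrix (global scoring
#'   mode); or supply `expr` + `registry` for split scoring mode in which
#'   module scoring is re-derived on each training set.
#' @param expr,registry expression matrix and module registry (split mode).
#' @param families model families to fit.
#' @param seed round seed (split + CV folds).
#' @param strata_fields stratification fields (default: source, platform
#'   and the clinical variables present).
#' @param cv_folds cross-validation folds for lambda selection.
#' @param alpha significance level of the success rule.
#' @param min_fraction module scoreability threshold (split mode).
#' @return list (`round_result`): `seed`, `split`, and per-family `model`,
#'   `train_eval`, `test_eval`, `success`, `failed`.
#' @export
run_round <- function(cohort, scores = NULL, expr = NULL, registry = NULL,
                      families = c("clinical", "genomic", "combined"),
                      seed = 1, strata_fields = default_strata(cohort),
                      cv_folds = 10, alpha = 0.05, min_fraction = 0.5) {
  plan <- stratified_split(cohort, strata_fields, 2 / 3, seed)
  tr <- cohort[match(plan$train_ids, cohort$sample_id), , drop = FALSE]
  te <- cohort[match(plan$test_ids, cohort$sample_id), , drop = FALSE]

  if (is.null(scores)) {
    if (is.null(expr) || is.null(registry)) {
      stop_config("run_round: supply either scores or expr + registry")
    }
    ss <- split_scores(expr, registry, plan$train_ids, plan$test_ids,
                       min_fraction)
    sc_tr <- ss$train; sc_te <- ss$test
  } else {
    sc_tr <- scores[, plan$train_ids, drop = FALSE]
    sc_te <- scores[, plan$test_ids, drop = FALSE]
  }

  out <- list(seed = seed, split = plan, families = list())
  for (fam in families) {
    res <- tryCatch({
      f_tr <- build_feature_set(fam, clinical = tr, scores = sc_tr)
      f_te <- build_feature_set(fam, clinical = te, scores = sc_te)
      model <- suppressWarnings(
        fit_lasso_cox(f_tr, tr$time, tr$event, cv_folds = cv_folds,
                      seed = seed))
      s_tr <- predict_risk_score(model, f_tr)
      s_te <- predict_risk_score(model, f_te)
      ev_tr <- evaluate_survival(s_tr, tr$time, tr$event)
      ev_te <- evaluate_survival(s_te, te$time, te$event)
      list(model = model, train_eval = ev_tr, test_eval = ev_te,
           success = model_success(ev_tr$cox, ev_te$cox,
                                   length(model$selected), alpha),
           failed = FALSE)
    }, error = function(e) {
      list(model = NULL, train_eval = NULL, test_eval = NULL,
           success = FALSE, failed = TRUE, error = conditionMessage(e))
    })
    out$families[[fam]] <- res
  }
  class(out) <- "round_result"
  out
}

#' Repeated stratified resampling with selection-frequency tabulation
#'
#' Repeats the round procedure with derived seeds (`base_seed + i`, so any
#' round is re-runnable in isolation) until `n_target` rounds succeed for
#' the primary family or `max_attempts` is reached. Selection counts are
#' tabulated among each family's successful rounds, with the direction of
#' association (positive coefficient = higher hazard = poor prognosis).
#' Mean test-set concordance per family is averaged over all evaluated
#' rounds; the superiority matrix entry `M[f1, f2]` is the fraction of
#' rounds (both families evaluated) in which `C(f1) > C(f2)` strictly,
#' ties counting for neither cell.
#'
#' @inheritParams run_round
#' @param n_target number of successful rounds to accumulate.
#' @param max_attempts cap on attempted rounds.
#' @param base_seed base of the per-round seed sequence.
#' @param primary_family family whose successes drive the stopping rule
#'   (default `"combined"` when present).
#' @return object of class `resample_summary`.
#' @export
run_resampling <- function(cohort, scores = NULL, expr = NULL,
                           registry = NULL,
                           families = c("clinical", "genomic", "combined"),
                           n_target = 200, max_attempts = 1000,
                           base_seed = 1,
                           primary_family = NULL,
                           strata_fields = default_strata(cohort),
                           cv_folds = 10, alpha = 0.05,
                           min_fraction = 0.5) {
  primary_family <- primary_family %||%
    (if ("combined" %in% families) "combined" else families[1])
  rounds <- list()
  n_success <- 0L
  attempt <- 0L
  while (n_success < n_target && attempt < max_attempts) {
    attempt <- attempt + 1L
    rr <- run_round(cohort, scores = scores, expr = expr,
                    registry = registry, families = families,
                    seed = base_seed + attempt, strata_fields = strata_fields,
                    cv_folds = cv_folds, alpha = alpha,
                    min_fraction = min_fraction)
    rounds[[attempt]] <- rr
    if (isTRUE(rr$families[[primary_family]]$success)) {
      n_success <- n_success + 1L
    }
  }
  summarize_resampling(rounds, families, primary_family, n_target)
}

summarize_resampling <- function(rounds, families, primary_family,
                                 n_target) {
  n_attempted <- length(rounds)
  succ <- sapply(families, function(f) {
    sum(vapply(rounds, function(r) isTRUE(r$families[[f]]$success), TRUE))
  })
  cindex <- sapply(families, function(f) {
    vapply(rounds, function(r) {
      ev <- r$families[[f]]$test_eval
      if (is.null(ev)) NA_real_ else ev$c_index
    }, 0)
  })
  cindex <- matrix(cindex, nrow = n_attempted,
                   dimnames = list(NULL, families))

  selection <- lapply(stats::setNames(families, families), function(f) {
    ok <- vapply(rounds, function(r) isTRUE(r$families[[f]]$success), TRUE)
    counts <- list()
    signs <- list()
    for (r in rounds[ok]) {
      sel <- r$families[[f]]$model$selected
      for (v in names(sel)) {
        counts[[v]] <- (counts[[v]] %||% 0L) + 1L
        signs[[v]] <- (signs[[v]] %||% 0) + sign(sel[[v]])
      }
    }
    if (!length(counts)) {
      return(data.frame(variable = character(), count = integer(),
                        frequency = numeric(), direction = character(),
                        stringsAsFactors = FALSE))
    }
    df <- data.frame(variable = names(counts),
                     count = unlist(counts, use.names = FALSE),
                     frequency = unlist(counts, use.names = FALSE) / sum(ok),
                     direction = ifelse(unlist(signs, use.names = FALSE) >= 0,
                                        "poor", "good"),
                     stringsAsFactors = FALSE)
    df[order(-df$frequency, df$variable), , drop = FALSE]
  })

  superiority <- matrix(NA_real_, length(families), length(families),
                        dimnames = list(families, families))
  for (f1 in families) for (f2 in families) {
    if (f1 == f2) next
    both <- !is.na(cindex[, f1]) & !is.na(cindex[, f2])
    if (!any(both)) next
    superiority[f1, f2] <- mean(cindex[both, f1] > cindex[both, f2])
  }

  structure(list(n_attempted = n_attempted,
                 n_success = succ,
                 n_target = n_target,
                 primary_family = primary_family,
                 complete = unname(succ[primary_family]) >= n_target,
                 selection = selection,
                 cindex = cindex,
                 mean_test_cindex = colMeans(cindex, na.rm = TRUE),
                 superiority = superiority,
                 rounds = rounds),
            class = "resample_summary")
}

#' @export
print.resample_summary <- function(x, ...) {
  cat(sprintf("resample_summary: %d attempted rounds, %d/%d successes (%s)\n",
              x$n_attempted, x$n_success[x$primary_family], x$n_target,
              x$primary_family))
  cat("mean test C-index:\n")
  print(round(x$mean_test_cindex, 4))
  invisible(x)
}

#' Treatment-response (pCR) prediction experiment
#'
#' Splits a binary-response cohort (stratified by response, ER and HER2),
#' fits an L1-penalized logistic model per family on the training set, and
#' reports training/testing AUC plus the selected variables with their
#' direction of association (positive log-odds coefficient = associated
#' with response). Splits lacking a class in either set are re-drawn with
#' the next seed, up to `max_retries` times.
#'
#' @param cohort cohort data.frame with a 0/1 `response` column.
#' @param scores module x sample score matrix.
#' @param families model families to fit.
#' @param seed base split seed.
#' @param strata_fields stratification fields (default response, ER, HER2).
#' @param cv_folds cross-validation folds.
#' @param max_retries bounded re-draws when a split lacks a class.
#' @return list (`pcr_report`): split sizes, seed used, and per-family
#'   `model`, `auc_train`, `auc_test`, `selected` table.
#' @export
run_pcr_experiment <- function(cohort, scores,
                               families = c("clinical", "genomic",
                                            "combined"),
                               seed = 1,
                               strata_fields = intersect(
                                 c("response", "er", "her2"), names(cohort)),
                               cv_folds = 10, max_retries = 10) {
  plan <- NULL
  used_seed <- seed
  for (s in seed + 0:max_retries) {
    cand <- stratified_split(cohort, strata_fields, 2 / 3, s)
    resp_tr <- cohort$response[match(cand$train_ids, cohort$sample_id)]
    resp_te <- cohort$response[match(cand$test_ids, cohort$sample_id)]
    if (length(unique(resp_tr)) == 2 && length(unique(resp_te)) == 2) {
      plan <- cand; used_seed <- s
      break
    }
    message(sprintf("run_pcr_experiment: split seed %d lacks a class; re-drawing", s))
  }
  if (is.null(plan)) {
    stop_config("run_pcr_experiment: no valid split in %d retries",
                max_retries)
  }
  tr <- cohort[match(plan$train_ids, cohort$sample_id), , drop = FALSE]
  te <- cohort[match(plan$test_ids, cohort$sample_id), , drop = FALSE]
  sc_tr <- scores[, plan$train_ids, drop = FALSE]
  sc_te <- scores[, plan$test_ids, drop = FALSE]

  fams <- list()
  for (fam in families) {
    fams[[fam]] <- tryCatch({
      f_tr <- build_feature_set(fam, clinical = tr, scores = sc_tr)
      f_te <- build_feature_set(fam, clinical = te, scores = sc_te)
      model <- suppressWarnings(
        fit_lasso_logistic(f_tr, tr$response, cv_folds = cv_folds,
                           seed = used_seed))
      p_tr <- predict_response_prob(model, f_tr)
      p_te <- predict_response_prob(model, f_te)
      sel <- model$selected
      selected <- data.frame(
        variable = names(sel), coefficient = unname(sel),
        direction = ifelse(sel > 0, "pCR", "non-pCR"),
        stringsAsFactors = FALSE)
      selected <- selected[order(-abs(selected$coefficient)), , drop = FALSE]
      list(model = model,
           auc_train = roc_auc(p_tr, tr$response),
           auc_test = roc_auc(p_te, te$response),
           selected = selected, failed = FALSE)
    }, error = function(e) {
      list(model = NULL, auc_train = NA_real_, auc_test = NA_real_,
           selected = NULL, failed = TRUE, error = conditionMessage(e))
    })
  }
  structure(list(seed = used_seed, split = plan,
                 n_train = length(plan$train_ids),
                 n_test = length(plan$test_ids),
                 families = fams),
            class = "pcr_report")
}
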