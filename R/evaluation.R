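#' Kaplan-Meier product-limit estimate
#'
#' Wraps [survival::survfit()] (events precede censorings at tied times,
#' the standard convention) and returns one tidy table per group.
#'
#' @param time,event survival outcome.
#' @param group_labels optional grouping; `NULL` for a single curve.
#' @return named list of data.frames with columns `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv`.
#' @export
km_curve <- function(time, event, group_labels = NULL) {
  if (length(time) == 0) stop_config("km_curve: empty cohort/group")
  if (is.null(group_labels)) group_labels <- rep("all", length(time))
  d <- data.frame(time = time, event = event, g = as.character(group_labels))
  out <- lapply(split(d, d$g), function(di) {
    sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = di)
    data.frame(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
               n_censor = sf$n.censor, surv = sf$surv)
  })
  out
}

#' k-group log-rank test
#'
#' @param time,event survival outcome.
#' @param group_labels group membership (>= 2 groups).
#' @return list with `statistic` (chi-square), `df`, `p`.
#' @export
log_rank_test <- function(time, event, group_labels) {
  g <- as.factor(group_labels)
  if (nlevels(g) < 2) stop_config("log_rank_test: need >= 2 groups")
  if (sum(event) < 1) stop_config("log_rank_test: no events")
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ g)
  df <- nlevels(g) - 1
  list(statistic = sd_$chisq, df = df,
       p = stats::pchisq(sd_$chisq, df, lower.tail = FALSE))
}

#' Univariate Cox refit of a continuous risk score
#'
#' Fits a proportional-hazards model on the score alone; the hazard ratio
#' per unit score and its p-value (Wald by default, likelihood-ratio by
#' flag) quantify the score's prognostic strength on an independent set.
#' Monotone-likelihood (divergent coefficient) fits are flagged.
#'
#' @param time,event survival outcome.
#' @param scores continuous risk score.
#' @param test `"wald"` (default) or `"lrt"`.
#' @return list with `hr`, `beta`, `se`, `p`, `flagged`.
#' @export
cox_score_test <- function(time, event, scores, test = c("wald", "lrt")) {
  test <- match.arg(test)
  if (sum(event) < 2) stop_config("cox_score_test: need >= 2 events")
  if (stats::sd(scores) == 0) stop_config("cox_score_test: constant score")
  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ scores),
    warning = function(w) {
      flagged <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- unname(stats::coef(fit)[1])
  se <- sqrt(fit$var[1, 1])
  p <- if (test == "wald") {
    2 * stats::pnorm(-abs(beta / se))
  } else {
    stats::pchisq(2 * diff(fit$loglik), 1, lower.tail = FALSE)
  }
  if (abs(beta) > 15) flagged <- TRUE
  list(hr = exp(beta), beta = beta, se = se, p = p, flagged = flagged)
}

#' Harrell's concordance index
#'
#' The probability that of two comparable patients, the one with the worse
#' outcome carries the higher risk score. Comparable pairs are `(i, j)`
#' with `t_i < t_j` and `event_i = 1`; a pair is concordant when
#' `score_i > score_j`, tied scores count one half. Ranges from 0.5
#' (uninformative) to 1 (perfect).
#'
#' @param scores risk scores (higher = worse predicted outcome).
#' @param time,event survival outcome.
#' @return concordance in `[0, 1]`.
#' @export
concordance_index <- function(scores, time, event) {
  ev <- which(event == 1)
  conc <- 0; comp <- 0
  for (i in ev) {
    later <- time > time[i]
    n_i <- sum(later)
    if (n_i == 0) next
    comp <- comp + n_i
    conc <- conc + sum(scores[i] > scores[later]) +
      0.5 * sum(scores[i] == scores[later])
  }
  if (comp == 0) stop_config("concordance_index: no comparable pairs")
  conc / comp
}

#' Rank-based (Mann-Whitney) AUC
#'
#' Area under the ROC curve computed from midranks, which handles tied
#' predictions exactly (each tie contributes one half).
#'
#' @param predicted numeric predictions (probabilities or scores).
#' @param labels 0/1 class labels.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(predicted, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop_config("roc_auc: both classes required")
  r <- rank(predicted)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Train-and-test model success rule
#'
#' A model counts as successful only when its risk score is prognostic
#' (Cox p-value below `alpha`) on both the training and the testing set,
#' and the model selected at least one variable. The test-set requirement
#' is what controls false successes.
#'
#' @param train_report,test_report lists with a `p` element (e.g. from
#'   [cox_score_test()]).
#' @param n_nonzero number of nonzero model coefficients.
#' @param alpha significance level (default 0.05).
#' @return logical.
#' @export
model_success <- function(train_report, test_report, n_nonzero,
                          alpha = 0.05) {
  n_nonzero >= 1 &&
    is.finite(train_report$p) && train_report$p < alpha &&
    is.finite(test_report$p) && test_report$p < alpha
}

#' Evaluate a fitted survival risk model on one dataset
#'
#' Computes the Cox refit of the risk score, the log-rank test for the
#' zero-threshold high/low stratification, and Harrell's C-index.
#'
#' @param scores per-sample risk scores.
#' @param time,event survival outcome.
#' @return list (`evaluation_report`): `cox` (hr/beta/p), `log_rank`
#'   (statistic/p or NA when only one stratum), `c_index`, `n`, `n_events`.
#' @export
evaluate_survival <- function(scores, time, event) {
  cox <- tryCatch(cox_score_test(time, event, scores),
                  error = function(e) list(hr = NA, beta = NA, se = NA,
                                           p = NA_real_, flagged = TRUE))
  strata <- stratify_risk(scores)
  lr <- if (length(unique(strata)) == 2 && sum(event) >= 1) {
    log_rank_test(time, event, strata)
  } else {
    list(statistic = NA_real_, df = NA, p = NA_real_)
  }
  ci <- tryCatch(concordance_index(scores, time, event),
                 error = function(e) NA_real_)
  list(cox = cox, log_rank = lr, c_index = ci,
       n = length(time), n_events = sum(event))
}
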