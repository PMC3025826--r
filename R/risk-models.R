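#' Encode clinical categories as model covariates
#'
#' ER and HER2 become 0/1 indicators of positivity, tumor size a 0/1
#' indicator of >= 2 cm, and histological grade the ordinal 1-3 value --
#' the categories in which node-negative cohorts are conventionally
#' reported. Missing values are not allowed (filter first).
#'
#' @param clinical data.frame with `er`, `size`, `grade`, `her2` columns
#'   (any subset).
#' @return numeric samples x variables matrix.
#' @export
encode_clinical <- function(clinical) {
  cols <- list()
  if ("er" %in% names(clinical)) cols$er <- as.numeric(clinical$er == "pos")
  if ("size" %in% names(clinical)) {
    cols$size <- as.numeric(clinical$size == "ge2cm")
  }
  if ("grade" %in% names(clinical)) cols$grade <- as.numeric(clinical$grade)
  if ("her2" %in% names(clinical)) {
    cols$her2 <- as.numeric(clinical$her2 == "pos")
  }
  if (!length(cols)) stop_config("encode_clinical: no clinical columns found")
  x <- do.call(cbind, cols)
  if (anyNA(x)) stop_config("encode_clinical: missing values after encoding")
  rownames(x) <- clinical$sample_id
  x
}

#' Assemble the design matrix for a model family
#'
#' @param family `"clinical"`, `"genomic"` or `"combined"`.
#' @param clinical clinical data.frame (required unless family is genomic).
#' @param scores module x sample score matrix (required unless clinical).
#' @return list of class `feature_set`: `family`, `x` (samples x
#'   variables), `variables`.
#' @export
build_feature_set <- function(family = c("clinical", "genomic", "combined"),
                              clinical = NULL, scores = NULL) {
  family <- match.arg(family)
  parts <- list()
  if (family %in% c("clinical", "combined")) {
    parts$clin <- encode_clinical(clinical)
  }
  if (family %in% c("genomic", "combined")) {
    g <- t(scores)
    if (!is.null(clinical)) g <- g[clinical$sample_id, , drop = FALSE]
    parts$genomic <- g
  }
  x <- do.call(cbind, parts)
  if (anyNA(x)) stop_config("build_feature_set: missing values in features")
  structure(list(family = family, x = x, variables = colnames(x)),
            class = "feature_set")
}

drop_constant_columns <- function(x) {
  const <- apply(x, 2, function(v) stats::sd(v) == 0)
  if (any(const)) {
    warning(sprintf("dropping %d constant variable(s): %s", sum(const),
                    paste(utils::head(colnames(x)[const], 5), collapse = ", ")),
            call. = FALSE)
    x <- x[, !const, drop = FALSE]
  }
  x
}

finalize_model <- function(family_name, outcome, x, beta, intercept, lambda,
                           cv_folds, seed, rule) {
  nz <- beta[beta != 0]
  lp <- drop(x %*% beta)
  structure(list(
    family = family_name, outcome = outcome,
    coefficients = beta, selected = nz, intercept = intercept,
    lambda = lambda, cv_folds = cv_folds, seed = seed, lambda_rule = rule,
    train_ids = rownames(x), train_lp_mean = mean(lp)),
    class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("%s %s model: %d/%d nonzero coefficients (lambda = %.4g)\n",
              x$family, x$outcome, length(x$selected),
              length(x$coefficients), x$lambda))
  invisible(x)
}

#' Fit an L1-penalized Cox proportional hazards model
#'
#' Maximizes the L1-penalized Cox partial likelihood over a descending
#' lambda grid (via glmnet), choosing lambda by seeded k-fold
#' cross-validated partial-likelihood deviance. Variables are standardized
#' internally; coefficients are returned on the original scale.
#'
#' @param features a [build_feature_set()] object (or plain matrix).
#' @param time,event survival outcome (years, 0/1 indicator).
#' @param cv_folds number of cross-validation folds.
#' @param seed RNG seed controlling fold assignment (fits are reproducible
#'   given data, seed and grid).
#' @param lambda optional fixed lambda sequence/value, bypassing CV.
#' @param lambda_rule `"min"` (CV-deviance minimum, default) or `"1se"`.
#' @param standardize standardize variables before penalization.
#' @return object of class `risk_model` with the sparse coefficient map.
#' @export
fit_lasso_cox <- function(features, time, event, cv_folds = 10, seed = 1,
                          lambda = NULL, lambda_rule = c("min", "1se"),
                          standardize = TRUE) {
  lambda_rule <- match.arg(lambda_rule)
  x <- if (inherits(features, "feature_set")) features$x else features
  fam <- if (inherits(features, "feature_set")) features$family else "custom"
  if (sum(event) < 2) stop_config("fit_lasso_cox: need >= 2 events")
  x <- drop_constant_columns(x)
  y <- survival::Surv(time, event)

  if (!is.null(lambda)) {
    fit <- glmnet::glmnet(x, y, family = "cox", lambda = lambda,
                          standardize = standardize)
    lam <- min(lambda)
  } else {
    foldid <- with_seed(seed, sample(rep_len(seq_len(cv_folds), nrow(x))))
    cv <- glmnet::cv.glmnet(x, y, family = "cox", foldid = foldid,
                            standardize = standardize)
    fit <- cv$glmnet.fit
    lam <- if (lambda_rule == "min") cv$lambda.min else cv$lambda.1se
  }
  beta <- drop(as.matrix(stats::coef(fit, s = lam)))
  finalize_model(fam, "survival", x, beta, intercept = NULL, lambda = lam,
                 cv_folds = cv_folds, seed = seed, rule = lambda_rule)
}

#' Fit an L1-penalized logistic response model
#'
#' As [fit_lasso_cox()] but with a binomial likelihood, for binary
#' endpoints such as pathological complete response; lambda is chosen by
#' seeded cross-validated binomial deviance.
#'
#' @inheritParams fit_lasso_cox
#' @param response 0/1 outcome vector.
#' @return object of class `risk_model` with coefficients and intercept.
#' @export
fit_lasso_logistic <- function(features, response, cv_folds = 10, seed = 1,
                               lambda = NULL, lambda_rule = c("min", "1se"),
                               standardize = TRUE) {
  lambda_rule <- match.arg(lambda_rule)
  x <- if (inherits(features, "feature_set")) features$x else features
  fam <- if (inherits(features, "feature_set")) features$family else "custom"
  if (length(unique(response)) < 2) {
    stop_config("fit_lasso_logistic: both classes required in training data")
  }
  x <- drop_constant_columns(x)

  if (!is.null(lambda)) {
    fit <- glmnet::glmnet(x, response, family = "binomial", lambda = lambda,
                          standardize = standardize)
    lam <- min(lambda)
  } else {
    foldid <- with_seed(seed, sample(rep_len(seq_len(cv_folds), nrow(x))))
    cv <- glmnet::cv.glmnet(x, response, family = "binomial",
                            foldid = foldid, standardize = standardize,
                            type.measure = "deviance")
    fit <- cv$glmnet.fit
    lam <- if (lambda_rule == "min") cv$lambda.min else cv$lambda.1se
  }
  cf <- drop(as.matrix(stats::coef(fit, s = lam)))
  finalize_model(fam, "response", x, cf[-1], intercept = cf[1], lambda = lam,
                 cv_folds = cv_folds, seed = seed, rule = lambda_rule)
}

#' Risk score: log hazard ratio relative to the training average
#'
#' The linear predictor on the model's coefficients, centered at the
#' training-set mean, so a score of zero corresponds to the average hazard
#' of the training cohort and the conventional high/low cut-off of zero is
#' meaningful on test data.
#'
#' @param model a `risk_model` from [fit_lasso_cox()].
#' @param features [build_feature_set()] object or matrix containing every
#'   selected variable (encoded with the same conventions as training).
#' @return named per-sample numeric score.
#' @export
predict_risk_score <- function(model, features) {
  x <- if (inherits(features, "feature_set")) features$x else features
  missing_vars <- setdiff(names(model$selected), colnames(x))
  if (length(missing_vars)) {
    stop_config("predict_risk_score: missing selected variable(s) %s",
                paste(missing_vars, collapse = ", "))
  }
  vars <- intersect(names(model$coefficients), colnames(x))
  lp <- drop(x[, vars, drop = FALSE] %*% model$coefficients[vars])
  stats::setNames(lp - model$train_lp_mean, rownames(x))
}

#' Predicted response probability from a penalized logistic model
#'
#' @param model a `risk_model` from [fit_lasso_logistic()].
#' @inheritParams predict_risk_score
#' @return per-sample probabilities in (0, 1).
#' @export
predict_response_prob <- function(model, features) {
  x <- if (inherits(features, "feature_set")) features$x else features
  missing_vars <- setdiff(names(model$selected), colnames(x))
  if (length(missing_vars)) {
    stop_config("predict_response_prob: missing selected variable(s) %s",
                paste(missing_vars, collapse = ", "))
  }
  vars <- intersect(names(model$coefficients), colnames(x))
  lp <- model$intercept + drop(x[, vars, drop = FALSE] %*%
                                 model$coefficients[vars])
  stats::setNames(stats::plogis(lp), rownames(x))
}

#' Stratify risk scores into high and low groups
#'
#' High risk iff score strictly exceeds the threshold; a score exactly at
#' the threshold is low (documented tie rule).
#'
#' @param scores numeric risk scores.
#' @param threshold cut-off (default 0, the training-average hazard).
#' @return character vector of `"high"`/`"low"`.
#' @export
stratify_risk <- function(scores, threshold = 0) {
  out <- ifelse(scores > threshold, "high", "low")
  if (!is.null(names(scores))) names(out) <- names(scores)
  out
}

#' Save / load a fitted risk model as JSON
#'
#' @param model a `risk_model`.
#' @param path JSON file path.
#' @return the path (write) or the restored `risk_model` (read).
#' @export
write_risk_model <- function(model, path) {
  m <- unclass(model)
  m$coefficients <- as.list(m$coefficients)  # keep variable names in JSON
  m$selected <- as.list(m$selected)
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_risk_model
#' @export
read_risk_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$coefficients <- unlist(m$coefficients)
  m$selected <- unlist(m$selected)
  structure(m, class = "risk_model")
}
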