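## Smoothed DWD loss: reciprocal margin for u >= rho, with the convex
## quadratic-free linear extension below rho keeping it differentiable.
dwd_loss <- function(u, rho = 1) {
  ifelse(u >= rho, 1 / u, 2 / rho - u / rho^2)
}
dwd_loss_grad <- function(u, rho = 1) {
  ifelse(u >= rho, -1 / u^2, -1 / rho^2)
}

## Fit the DWD separating direction between two sample sets (columns of x1,
## x2) by minimizing mean(V(y * (w.x + b))) + lambda * ||w||^2 with L-BFGS-B.
## Returns the unit direction, or NULL when the class means coincide.
dwd_direction <- function(x1, x2, lambda = 1e-4, rho = 1, maxit = 200) {
  d <- rowMeans(x1) - rowMeans(x2)
  nd <- sqrt(sum(d^2))
  if (nd < 1e-10) return(NULL)
  x <- cbind(x1, x2)
  y <- c(rep(1, ncol(x1)), rep(-1, ncol(x2)))
  mid <- (rowMeans(x1) + rowMeans(x2)) / 2
  w0 <- 2 * d / nd^2                       # means project to +/- 1
  theta0 <- c(w0, -sum(w0 * mid))
  p <- nrow(x)
  fn <- function(theta) {
    u <- y * (drop(crossprod(x, theta[1:p])) + theta[p + 1])
    mean(dwd_loss(u, rho)) + lambda * sum(theta[1:p]^2)
  }
  gr <- function(theta) {
    u <- y * (drop(crossprod(x, theta[1:p])) + theta[p + 1])
    vp <- dwd_loss_grad(u, rho) * y / length(y)
    c(drop(x %*% vp) + 2 * lambda * theta[1:p], sum(vp))
  }
  fit <- stats::optim(theta0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit))
  w <- fit$par[1:p]
  nw <- sqrt(sum(w^2))
  if (nw < 1e-12) d / nd else w / nw
}

#' Batch-effect adjustment by distance-weighted discrimination
#'
#' For each batch (against the largest batch as reference), the separating
#' DWD direction between the two batches is fitted, and the batch is
#' translated along that direction so the two batch means coincide on it.
#' This removes the systematic between-batch direction while leaving
#' within-batch structure intact. A fallback mode (`method =
#' "mean_center"`) sets every gene's per-batch mean to its grand mean and
#' should be used for batches too small to fit a discriminant.
#'
#' @param expr genes x samples expression matrix.
#' @param batch_labels batch factor/character, one per sample (column).
#' @param method `"dwd"` (default) or `"mean_center"`.
#' @param lambda ridge penalty of the DWD objective.
#' @return adjusted matrix with identical dimnames.
#' @export
dwd_adjust <- function(expr, batch_labels, method = c("dwd", "mean_center"),
                       lambda = 1e-4) {
  method <- match.arg(method)
  batch_labels <- as.character(batch_labels)
  stopifnot(length(batch_labels) == ncol(expr))
  tab <- table(batch_labels)
  if (length(tab) < 2) stop_config("dwd_adjust: need >= 2 batches")

  if (method == "mean_center") {
    grand <- rowMeans(expr)
    out <- expr
    for (b in names(tab)) {
      j <- which(batch_labels == b)
      out[, j] <- expr[, j] - rowMeans(expr[, j, drop = FALSE]) + grand
    }
    return(out)
  }

  if (any(tab < 3)) {
    stop_config(paste("dwd_adjust: batch(es) %s have < 3 samples;",
                      "use method = 'mean_center'"),
                paste(names(tab)[tab < 3], collapse = ", "))
  }
  ref <- names(tab)[which.max(tab)]
  out <- expr
  jref <- which(batch_labels == ref)
  for (b in setdiff(names(sort(tab, decreasing = TRUE)), ref)) {
    jb <- which(batch_labels == b)
    ## fit-and-translate along the DWD direction; repeat only while the
    ## projected mean difference exceeds its own sampling noise (4 SE),
    ## so an already-adjusted matrix passes through unchanged
    for (it in seq_len(10)) {
      v <- dwd_direction(out[, jref, drop = FALSE], out[, jb, drop = FALSE],
                         lambda = lambda)
      if (is.null(v)) break                # batch means already coincide
      shift <- sum(v * (rowMeans(out[, jref, drop = FALSE]) -
                          rowMeans(out[, jb, drop = FALSE])))
      pr <- drop(crossprod(out[, jref, drop = FALSE], v))
      pb <- drop(crossprod(out[, jb, drop = FALSE], v))
      se <- sqrt(stats::var(pr) / length(pr) + stats::var(pb) / length(pb))
      if (!is.finite(se) || abs(shift) <= 4 * se) break
      out[, jb] <- out[, jb] + v * shift
    }
  }
  out
}

#' Remove records with missing required fields
#'
#' `NA` and the literal category `"missing"` both count as missing. The
#' retention count and percentage are reported via `message()`.
#'
#' @param cohort clinical/cohort data.frame.
#' @param required_fields columns that must be non-missing.
#' @return the complete-case subset.
#' @export
complete_case_filter <- function(cohort,
                                 required_fields = c("er", "size", "grade",
                                                     "time", "event")) {
  required_fields <- intersect(required_fields, names(cohort))
  if (length(required_fields) == 0) return(cohort)
  ok <- !Reduce(`|`, lapply(cohort[required_fields], is_missing_value))
  kept <- cohort[ok, , drop = FALSE]
  if (nrow(kept) == 0) stop_config("complete_case_filter: no complete cases")
  message(sprintf("complete_case_filter: retained %d of %d (%.0f%%)",
                  nrow(kept), nrow(cohort), 100 * nrow(kept) / nrow(cohort)))
  kept
}

#' Apply an administrative follow-up cut-point
#'
#' Records followed beyond the cut-point are truncated to it and their
#' event indicator cleared (administrative censoring) -- e.g. a 7-year
#' cut-point for relapse-free survival.
#'
#' @param cohort cohort data.frame with `time` (years) and `event` columns.
#' @param cutpoint_years the cut-point.
#' @return cohort with `time <= cutpoint_years` everywhere.
#' @export
apply_followup_cutpoint <- function(cohort, cutpoint_years = 7) {
  if (any(cohort$time <= 0)) {
    bad <- cohort$sample_id[cohort$time <= 0]
    stop_config("apply_followup_cutpoint: non-positive time for sample(s) %s",
                paste(utils::head(bad, 5), collapse = ", "))
  }
  over <- cohort$time > cutpoint_years
  cohort$event[over] <- 0L
  cohort$time[over] <- cutpoint_years
  cohort
}

#' HER2 status surrogate from HER2 (ERBB2) mRNA levels
#'
#' When clinical HER2 status is unavailable, tumors in the top
#' `top_fraction` of HER2 gene expression (rank order) are called positive.
#' Exactly `ceiling(top_fraction * n)` samples are labeled positive; ties
#' at the boundary are broken by ascending sample id (deterministic).
#'
#' @param erbb2_expression named per-sample expression of the HER2 gene.
#' @param top_fraction fraction called positive (default 0.20).
#' @return named character vector of `"pos"`/`"neg"` (`NA` where the
#'   expression value is missing).
#' @export
her2_surrogate <- function(erbb2_expression, top_fraction = 0.20) {
  ids <- names(erbb2_expression)
  if (is.null(ids)) ids <- as.character(seq_along(erbb2_expression))
  ok <- !is.na(erbb2_expression)
  if (sum(ok) < 5) stop_config("her2_surrogate: need >= 5 non-missing samples")
  x <- erbb2_expression[ok]
  nm <- ids[ok]
  n_pos <- ceiling(top_fraction * length(x))
  if (length(unique(x)) == 1) {
    warning("her2_surrogate: all expression values equal; labels set by the sample-id tie rule",
            call. = FALSE)
  }
  ord <- order(-x, nm)
  lab <- stats::setNames(rep(NA_character_, length(erbb2_expression)), ids)
  lab[nm] <- "neg"
  lab[nm[ord[seq_len(n_pos)]]] <- "pos"
  lab
}

#' Nearest-centroid subtype assignment
#'
#' Each sample is assigned the centroid with which its gene profile
#' correlates most strongly (same correlation flavor as
#' [score_centroid_correlation()]). Ties go to the lexicographically first
#' centroid with a warning.
#'
#' @param expr genes x samples expression matrix.
#' @param centroid_set named list: centroid name -> named per-gene values.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param min_fraction minimum fraction of centroid genes present.
#' @return named character vector of subtype labels.
#' @export
assign_subtypes <- function(expr, centroid_set,
                            method = c("spearman", "pearson"),
                            min_fraction = 0.5) {
  method <- match.arg(method)
  up <- toupper(rownames(expr))
  cors <- sapply(names(centroid_set), function(cn) {
    cen <- unlist(centroid_set[[cn]])
    names(cen) <- toupper(names(cen))
    idx <- which(up %in% names(cen))
    if (length(idx) / length(cen) < min_fraction) {
      stop_config("assign_subtypes: centroid '%s' overlap below %.2f",
                  cn, min_fraction)
    }
    apply(expr[idx, , drop = FALSE], 2, function(prof) {
      if (stats::sd(prof) == 0) return(NA_real_)
      stats::cor(prof, cen[up[idx]], method = method)
    })
  })
  cors <- matrix(cors, ncol = length(centroid_set),
                 dimnames = list(colnames(expr), names(centroid_set)))
  cols <- sort(colnames(cors))
  cors <- cors[, cols, drop = FALSE]
  labels <- apply(cors, 1, function(r) {
    best <- max(r, na.rm = TRUE)
    hits <- cols[!is.na(r) & r == best]
    if (length(hits) > 1) {
      warning("assign_subtypes: correlation tie; lexicographically first centroid used",
              call. = FALSE)
    }
    hits[1]
  })
  stats::setNames(labels, colnames(expr))
}

#' Built-in and custom clinical subgroup definitions
#'
#' Built-in specs: `all`, `ER+`, `ER-`, `HER2+`, `ER+/HER2-`, `Luminal`
#' (Luminal A or B), `Basal-like`, `HER2-enriched`. Intrinsic-subtype
#' groups require a `subtype` column with labels `LumA`, `LumB`, `Her2`,
#' `Basal`, `Normal`. A custom spec is a `list(name =, predicate =)` whose
#' predicate maps the cohort to a logical vector.
#'
#' @param cohort cohort data.frame.
#' @param spec a built-in name or a custom spec list.
#' @return integer vector of row indices belonging to the subgroup.
#' @export
define_subgroup <- function(cohort, spec) {
  builtin <- list(
    "all" = function(d) rep(TRUE, nrow(d)),
    "ER+" = function(d) !is_missing_value(d$er) & d$er == "pos",
    "ER-" = function(d) !is_missing_value(d$er) & d$er == "neg",
    "HER2+" = function(d) !is_missing_value(d$her2) & d$her2 == "pos",
    "ER+/HER2-" = function(d) {
      !is_missing_value(d$er) & d$er == "pos" &
        !is_missing_value(d$her2) & d$her2 == "neg"
    },
    "Luminal" = function(d) d$subtype %in% c("LumA", "LumB"),
    "Basal-like" = function(d) d$subtype %in% "Basal",
    "HER2-enriched" = function(d) d$subtype %in% "Her2")
  pred <- if (is.character(spec)) {
    if (!spec %in% names(builtin)) {
      stop_config("define_subgroup: unknown spec '%s' (built-ins: %s)",
                  spec, paste(names(builtin), collapse = ", "))
    }
    builtin[[spec]]
  } else spec$predicate
  needed <- switch(if (is.character(spec)) spec else "custom",
                   "ER+" = , "ER-" = "er",
                   "HER2+" = "her2",
                   "ER+/HER2-" = c("er", "her2"),
                   "Luminal" = , "Basal-like" = , "HER2-enriched" = "subtype",
                   character())
  missing_fields <- setdiff(needed, names(cohort))
  if (length(missing_fields)) {
    stop_config("define_subgroup: cohort lacks field(s) %s",
                paste(missing_fields, collapse = ", "))
  }
  which(pred(cohort))
}
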