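#' Match module genes against an expression matrix
#'
#' Symbols are compared case-insensitively. A module is scoreable when the
#' matched fraction reaches `min_fraction`; predictors applied across merged
#' microarray platforms routinely lose genes, so partial matches are the
#' norm rather than the exception.
#'
#' @param expr genes x samples expression matrix (rownames = symbols).
#' @param module a [module_definition()].
#' @param min_fraction minimum matched/total fraction for scoreability.
#' @return list with `matched` (rownames of `expr`, in module order),
#'   `n_matched`, `n_module`, `fraction`, `scoreable`.
#' @export
match_genes <- function(expr, module, min_fraction = 0.5) {
  up <- toupper(rownames(expr))
  idx <- match(module$genes, up)
  matched <- rownames(expr)[idx[!is.na(idx)]]
  n_matched <- length(matched)
  fraction <- n_matched / length(module$genes)
  scoreable <- n_matched > 0 && fraction >= min_fraction
  if (n_matched == 0) {
    warning(sprintf("module '%s': no genes matched; unscoreable",
                    module$name), call. = FALSE)
  }
  list(matched = matched, n_matched = n_matched,
       n_module = length(module$genes), fraction = fraction,
       scoreable = scoreable)
}

#' Median module score
#'
#' Each matched gene is first centered by its cohort median (making the
#' score location-free across platforms); the sample score is the median
#' across matched genes of the centered values. When `constants` from a
#' training cohort are supplied, its gene medians are reused instead of
#' recomputing them.
#'
#' @inheritParams match_genes
#' @param constants optional list with `center` (named per-gene medians)
#'   from a previous (training) call.
#' @param center logical; median-center genes before scoring.
#' @return list with `score` (named per-sample vector) and `constants`.
#' @export
score_median <- function(expr, module, min_fraction = 0.5, constants = NULL,
                         center = TRUE) {
  mg <- match_genes(expr, module, min_fraction)
  if (!mg$scoreable) return(NULL)
  x <- expr[mg$matched, , drop = FALSE]
  ctr <- if (!is.null(constants)) {
    constants$center[mg$matched]
  } else if (center) {
    apply(x, 1, stats::median)
  } else {
    stats::setNames(rep(0, nrow(x)), mg$matched)
  }
  score <- apply(x - ctr, 2, stats::median)
  list(score = score, constants = list(center = ctr))
}

#' First-principal-component module score
#'
#' Member genes are z-scored across samples; the score is the projection of
#' each sample onto the leading eigenvector of the gene-gene covariance
#' matrix of the member submatrix. The sign is oriented so the score
#' correlates non-negatively with the mean member-gene profile (or per
#' `direction_hint`), and the score is standardized to unit variance.
#' Training constants (gene means/SDs, loading vector, orientation, score
#' scale) are reusable on a test cohort.
#'
#' @inheritParams score_median
#' @return list with `score` and `constants`, or `NULL` if unscoreable.
#' @export
score_first_pc <- function(expr, module, min_fraction = 0.5,
                           constants = NULL) {
  mg <- match_genes(expr, module, min_fraction)
  if (!mg$scoreable) return(NULL)

  if (!is.null(constants)) {
    g <- intersect(names(constants$loading), mg$matched)
    z <- (expr[g, , drop = FALSE] - constants$mean[g]) / constants$sd[g]
    score <- drop(crossprod(z, constants$loading[g])) / constants$scale
    return(list(score = score, constants = constants))
  }

  x <- expr[mg$matched, , drop = FALSE]
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("module '%s': dropping %d zero-variance gene(s)",
                    module$name, sum(sds == 0)), call. = FALSE)
    x <- x[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (nrow(x) < 2 || ncol(x) < 3) return(NULL)
  mu <- rowMeans(x)
  z <- (x - mu) / sds

  cv <- stats::cov(t(z))                  # gene-gene covariance
  e <- eigen(cv, symmetric = TRUE)
  w <- e$vectors[, 1]
  names(w) <- rownames(z)
  score <- drop(crossprod(z, w))

  orient <- if (!is.null(module$direction_hint)) {
    sign(module$direction_hint)
  } else {
    ref <- colMeans(z)
    s <- sign(stats::cor(score, ref))
    if (is.na(s) || s == 0) 1 else s
  }
  w <- w * orient
  score <- score * orient
  scale <- stats::sd(score)
  if (scale == 0) return(NULL)
  list(score = score / scale,
       constants = list(mean = mu, sd = sds, loading = w, scale = scale))
}

#' Centroid-correlation module scores
#'
#' One score row per centroid: the correlation (Spearman rank by default,
#' the convention of the subtype-centroid literature; Pearson available)
#' between a sample's matched-gene profile and the centroid. Samples with a
#' constant profile get `NA` (undefined correlation).
#'
#' @inheritParams score_median
#' @param method correlation flavor, `"spearman"` or `"pearson"`.
#' @return list with `score` (centroids x samples matrix, rows named
#'   `module.centroid`), or `NULL` if unscoreable.
#' @export
score_centroid_correlation <- function(expr, module, min_fraction = 0.5,
                                       method = c("spearman", "pearson")) {
  method <- match.arg(method)
  mg <- match_genes(expr, module, min_fraction)
  if (!mg$scoreable) return(NULL)
  out <- matrix(NA_real_, length(module$centroids), ncol(expr),
                dimnames = list(paste(module$name, names(module$centroids),
                                      sep = "."),
                                colnames(expr)))
  warned <- FALSE
  for (k in seq_along(module$centroids)) {
    cen <- module$centroids[[k]]
    g <- mg$matched[toupper(mg$matched) %in% names(cen)]
    if (length(g) / length(module$genes) < min_fraction) next
    cv <- cen[toupper(g)]
    for (s in seq_len(ncol(expr))) {
      prof <- expr[g, s]
      if (stats::sd(prof) == 0) {
        if (!warned) {
          warning(sprintf("module '%s': constant sample profile(s); NA score",
                          module$name), call. = FALSE)
          warned <- TRUE
        }
        next
      }
      out[k, s] <- stats::cor(prof, cv, method = method)
    }
  }
  list(score = out, constants = list())
}

#' Published-model module score
#'
#' The score is the published linear model applied to the matched genes:
#' `offset + sum(weight_g * expression[g, sample])`. Genes missing from the
#' expression matrix contribute zero and are reported.
#'
#' @inheritParams score_median
#' @return list with `score`, `constants` and `missing_genes`.
#' @export
score_published_model <- function(expr, module, min_fraction = 0.5) {
  mg <- match_genes(expr, module, min_fraction)
  if (!mg$scoreable) return(NULL)
  w <- module$weights[toupper(mg$matched)]
  score <- module$offset + drop(crossprod(expr[mg$matched, , drop = FALSE], w))
  names(score) <- colnames(expr)
  list(score = score, constants = list(),
       missing_genes = setdiff(module$genes, toupper(mg$matched)))
}

#' Score every module in a registry
#'
#' Dispatches on each module's mode and stacks the per-sample scores into a
#' module x sample matrix (centroid modules expand to one row per centroid,
#' named `module.centroid`). Row order follows registry order. Modules
#' failing the match threshold are absent from the matrix and flagged in
#' the report. Pass `constants` from a training call to apply
#' training-derived centering/loadings to a test cohort.
#'
#' @param expr genes x samples expression matrix.
#' @param registry a `module_registry`.
#' @param min_fraction scoreability threshold, see [match_genes()].
#' @param constants optional constants from a previous call (its
#'   `$constants` element), reused per module.
#' @param centroid_method correlation flavor for centroid modules.
#' @return object of class `module_scores`: list with `scores` (matrix),
#'   `report` (data.frame: module, mode, n_module, n_matched, fraction,
#'   scoreable), and `constants`.
#' @export
compute_all_scores <- function(expr, registry, min_fraction = 0.5,
                               constants = NULL,
                               centroid_method = "spearman") {
  rows <- list()
  consts <- list()
  rep_rows <- vector("list", length(registry))
  for (i in seq_along(registry)) {
    m <- registry[[i]]
    res <- withCallingHandlers(
      switch(m$mode,
        median = score_median(expr, m, min_fraction,
                              constants = constants[[m$name]]),
        first_pc = score_first_pc(expr, m, min_fraction,
                                  constants = constants[[m$name]]),
        centroid_corr = score_centroid_correlation(expr, m, min_fraction,
                                                   method = centroid_method),
        published_model = score_published_model(expr, m, min_fraction)),
      warning = function(w) invokeRestart("muffleWarning"))
    mg <- suppressWarnings(match_genes(expr, m, min_fraction))
    rep_rows[[i]] <- data.frame(module = m$name, mode = m$mode,
                                n_module = mg$n_module,
                                n_matched = mg$n_matched,
                                fraction = mg$fraction,
                                scoreable = !is.null(res),
                                stringsAsFactors = FALSE)
    if (is.null(res)) next
    sc <- res$score
    if (is.matrix(sc)) {
      rows[[length(rows) + 1L]] <- sc
    } else {
      rows[[length(rows) + 1L]] <- matrix(sc, nrow = 1,
                                          dimnames = list(m$name, names(sc)))
    }
    consts[[m$name]] <- res$constants
  }
  if (!length(rows)) stop_config("no module was scoreable")
  structure(list(scores = do.call(rbind, rows),
                 report = do.call(rbind, rep_rows),
                 constants = consts),
            class = "module_scores")
}

#' @export
print.module_scores <- function(x, ...) {
  cat(sprintf("module_scores: %d score rows x %d samples (%d/%d modules scoreable)\n",
              nrow(x$scores), ncol(x$scores), sum(x$report$scoreable),
              nrow(x$report)))
  invisible(x)
}
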