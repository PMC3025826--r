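#' Define a gene-expression module
#'
#' A module is a named gene set summarized per sample by one of four scoring
#' modes: the median of (median-centered) member genes, the first principal
#' component of the member-gene submatrix, the correlation of the sample
#' profile to one or more reference centroids, or a published linear model
#' (fixed per-gene weights plus offset).
#'
#' @param name module name (unique within a registry).
#' @param genes non-empty character vector of gene symbols (stored uppercase).
#' @param mode one of `"median"`, `"first_pc"`, `"centroid_corr"`,
#'   `"published_model"`.
#' @param centroids (`centroid_corr` only) named list or matrix: one named
#'   per-gene numeric vector per centroid, gene names matching `genes`.
#' @param weights (`published_model` only) named per-gene numeric weights.
#' @param offset (`published_model` only) additive offset.
#' @param direction_hint optional +1/-1 sign override for `first_pc`
#'   orientation.
#' @param note free-text provenance note.
#' @return an object of class `module_definition`.
#' @export
module_definition <- function(name, genes,
                              mode = c("median", "first_pc", "centroid_corr",
                                       "published_model"),
                              centroids = NULL, weights = NULL, offset = 0,
                              direction_hint = NULL, note = "") {
  mode <- match.arg(mode)
  genes <- toupper(as.character(genes))
  if (length(genes) == 0) stop_config("module '%s': empty gene list", name)
  if (anyDuplicated(genes)) {
    stop_config("module '%s': duplicate gene symbols", name)
  }
  if (mode == "centroid_corr") {
    if (is.null(centroids)) {
      stop_config("module '%s': centroid_corr mode requires centroids", name)
    }
    centroids <- lapply(centroids, function(v) {
      v <- unlist(v)
      names(v) <- toupper(names(v))
      if (!all(is.finite(v))) {
        stop_config("module '%s': non-finite centroid values", name)
      }
      v
    })
  } else if (!is.null(centroids)) {
    stop_config("module '%s': centroids only allowed in centroid_corr mode",
                name)
  }
  if (mode == "published_model") {
    if (is.null(weights)) {
      stop_config("module '%s': published_model mode requires weights", name)
    }
    weights <- unlist(weights)
    names(weights) <- toupper(names(weights))
    if (!all(is.finite(weights)) || !all(is.finite(offset))) {
      stop_config("module '%s': non-finite weights/offset", name)
    }
  } else if (!is.null(weights)) {
    stop_config("module '%s': weights only allowed in published_model mode",
                name)
  }
  structure(list(name = name, mode = mode, genes = genes,
                 centroids = centroids, weights = weights, offset = offset,
                 direction_hint = direction_hint, note = note),
            class = "module_definition")
}

new_module_registry <- function(modules) {
  nms <- vapply(modules, `[[`, "", "name")
  if (anyDuplicated(nms)) {
    stop_config("duplicate module name(s): %s",
                paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  names(modules) <- nms
  structure(modules, class = "module_registry")
}

#' Build a module registry from module definitions
#'
#' @param ... [module_definition()] objects (or a single list of them).
#' @return an ordered `module_registry`.
#' @export
module_registry <- function(...) {
  mods <- list(...)
  if (length(mods) == 1 && !inherits(mods[[1]], "module_definition")) {
    mods <- mods[[1]]
  }
  new_module_registry(mods)
}

#' @export
print.module_registry <- function(x, ...) {
  cat(sprintf("module_registry with %d modules\n", length(x)))
  print(registry_mode_counts(x))
  invisible(x)
}

#' Count registry modules by scoring mode
#'
#' @param registry a `module_registry`.
#' @return named integer vector of counts per mode.
#' @export
registry_mode_counts <- function(registry) {
  modes <- vapply(registry, `[[`, "", "mode")
  table_modes <- table(factor(modes, levels = c("median", "first_pc",
                                                "centroid_corr",
                                                "published_model")))
  stats::setNames(as.integer(table_modes), names(table_modes))
}

#' Read a module registry from GMT with an optional JSON sidecar
#'
#' The GMT file follows the standard tab format (name, description,
#' genes...). The sidecar maps module names to scoring parameters:
#' `{"<module>": {"mode": ..., "centroids": ..., "weights": ...,
#' "offset": ..., "direction_hint": ...}}`. Modules without a sidecar
#' entry default to `median` mode.
#'
#' @param gmt_path path to the GMT file.
#' @param sidecar_json_path optional path to the parameter sidecar.
#' @return a `module_registry`.
#' @export
read_module_registry <- function(gmt_path, sidecar_json_path = NULL) {
  lines <- readLines(gmt_path)
  lines <- lines[nzchar(trimws(lines))]
  side <- if (!is.null(sidecar_json_path)) {
    jsonlite::read_json(sidecar_json_path)
  } else list()

  seen <- character()
  mods <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      stop_config("GMT line %d: fewer than 3 tab-separated fields", i)
    }
    nm <- f[1]
    if (nm %in% seen) stop_config("GMT line %d: duplicate module name '%s'",
                                  i, nm)
    seen <- c(seen, nm)
    p <- side[[nm]] %||% list()
    mods[[i]] <- module_definition(
      name = nm, genes = f[-(1:2)],
      mode = p$mode %||% "median",
      centroids = p$centroids,
      weights = p$weights,
      offset = p$offset %||% 0,
      direction_hint = p$direction_hint,
      note = f[2])
  }
  unknown <- setdiff(names(side), seen)
  if (length(unknown)) {
    stop_config("sidecar references unknown module(s): %s",
                paste(unknown, collapse = ", "))
  }
  new_module_registry(mods)
}

#' Write a module registry as GMT plus JSON sidecar
#'
#' Round-trips exactly with [read_module_registry()]: names, modes, genes
#' and mode-specific parameters are preserved.
#'
#' @param registry a `module_registry`.
#' @param gmt_path output GMT path.
#' @param sidecar_json_path output sidecar path (only written when some
#'   module needs non-default parameters, or when given explicitly).
#' @return `gmt_path`, invisibly.
#' @export
write_module_registry <- function(registry, gmt_path,
                                  sidecar_json_path = NULL) {
  lines <- vapply(registry, function(m) {
    paste(c(m$name, if (nzchar(m$note)) m$note else "na", m$genes),
          collapse = "\t")
  }, "")
  writeLines(lines, gmt_path)
  side <- list()
  for (m in registry) {
    entry <- list()
    if (m$mode != "median") entry$mode <- m$mode
    if (!is.null(m$centroids)) entry$centroids <- lapply(m$centroids, as.list)
    if (!is.null(m$weights)) entry$weights <- as.list(m$weights)
    if (!identical(m$offset, 0)) entry$offset <- m$offset
    if (!is.null(m$direction_hint)) entry$direction_hint <- m$direction_hint
    if (length(entry)) side[[m$name]] <- entry
  }
  if (!is.null(sidecar_json_path) && length(side)) {
    jsonlite::write_json(side, sidecar_json_path, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(gmt_path)
}

#' Remove named modules from a registry
#'
#' Used for the exclusion re-analyses in which well-known prognostic
#' signatures are dropped before model building (e.g. a 323-module registry
#' reduced to 319 or 318).
#'
#' @param registry a `module_registry`.
#' @param names modules to remove; every name must exist.
#' @return the reduced `module_registry`.
#' @export
exclude_modules <- function(registry, names) {
  unknown <- setdiff(names, names(registry))
  if (length(unknown)) {
    stop_config("unknown module(s): %s. Valid names: %s",
                paste(unknown, collapse = ", "),
                paste(utils::head(names(registry), 50), collapse = ", "))
  }
  keep <- setdiff(names(registry), names)
  new_module_registry(unname(registry[keep]))
}
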