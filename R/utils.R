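#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## Run code under a fixed RNG seed without clobbering the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

## Missingness convention shared by clinical tables: NA or the literal
## string "missing" both count as missing.
is_missing_value <- function(x) {
  is.na(x) | (as.character(x) == "missing")
}

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

#' Write a numeric matrix as a tab-delimited table
#'
#' First column holds the row identifiers (named by `id_col`), remaining
#' columns are the matrix columns.
#'
#' @param x numeric matrix with row and column names.
#' @param path output file path.
#' @param id_col name for the identifier column.
#' @export
write_matrix_tsv <- function(x, path, id_col = "gene_id") {
  df <- data.frame(id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-delimited matrix written by [write_matrix_tsv()]
#'
#' @param path input file path.
#' @return numeric matrix with row names taken from the first column.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
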