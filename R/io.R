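#' Read and write expression tables
#'
#' Expression matrices are exchanged as tab-separated text: a header row of
#' sample ids, the first column a feature id, and an optional leading comment
#' line `# scale: <tag>` recording the value scale. `write_expression()`
#' always emits the scale comment so a round trip preserves it.
#'
#' @param path File path of a TSV expression matrix.
#' @return `read_expression()` returns an [as_expr()] tibble.
#' @export
read_expression <- function(path) {
  first <- readLines(path, n = 1L)
  scale <- "log2"
  skip <- 0L
  if (startsWith(first, "#")) {
    m <- regmatches(first, regexec("scale:\\s*([a-z0-9-]+)", first))[[1L]]
    if (length(m) == 2L) scale <- m[2L]
    skip <- 1L
  }
  x <- readr::read_tsv(path, skip = skip, show_col_types = FALSE,
                       progress = FALSE, name_repair = "minimal")
  if (anyDuplicated(names(x)[-1L])) {
    abort(paste0("duplicated sample id in header of ", path))
  }
  for (j in seq_along(x)[-1L]) {
    if (!is.numeric(x[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(x[[j]]))) & !is.na(x[[j]]))[1L]
      abort(paste0("non-numeric expression value at row ", bad %||% NA,
                   ", column '", names(x)[j], "' in ", path))
    }
  }
  as_expr(x, scale = scale)
}

#' @rdname read_expression
#' @param x An expression table.
#' @export
write_expression <- function(x, path) {
  stopifnot(inherits(x, "expr_tbl"))
  writeLines(paste0("# scale: ", expr_scale(x)), path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

clinical_required_cols <- c("sample_id", "cohort", "age", "tumor_size", "grade",
                            "er_status", "node_status", "relapse_event", "time_years")

#' Read and write clinical tables
#'
#' Clinical/survival annotations are exchanged as CSV with columns
#' `sample_id, cohort, age, tumor_size, grade, er_status, node_status,
#' relapse_event, time_years`. Missing values stay missing; `relapse_event`
#' must be 0, 1 or missing. Extra columns are preserved with a warning.
#'
#' @param path File path of a CSV clinical table.
#' @return A tibble with typed columns.
#' @export
read_clinical <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(clinical_required_cols, names(x))
  if (length(miss)) abort(paste0("clinical table is missing column(s): ", paste(miss, collapse = ", ")))
  extra <- setdiff(names(x), clinical_required_cols)
  if (length(extra)) warn(paste0("clinical table has extra column(s), preserved: ", paste(extra, collapse = ", ")))
  bad <- !(x$relapse_event %in% c(0L, 1L) | is.na(x$relapse_event))
  if (any(bad)) abort(paste0("relapse_event must be 0, 1 or missing; offending row(s): ",
                             paste(which(bad)[1:5], collapse = ", ")))
  x$relapse_event <- as.integer(x$relapse_event)
  x
}

#' @rdname read_clinical
#' @param x A clinical table.
#' @export
write_clinical <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}
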