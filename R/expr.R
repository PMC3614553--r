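#' Expression tables
#'
#' Expression data travels through the pipeline as a wide tibble: the first
#' column holds the feature identifier (`probe_id` or `gene_id`) and every
#' remaining column is one sample. A `scale` attribute records which point of
#' the harmonization pipeline the values are on: `"raw-linear"` (original chip
#' intensities, strictly positive), `"log2"`, `"z"` (per-gene standardized
#' within cohort) or `"qnorm"` (quantile normalized across the merged
#' samples).
#'
#' @param x A data frame whose first column is a feature id and whose
#'   remaining columns are numeric sample values.
#' @param scale One of `"raw-linear"`, `"log2"`, `"z"`, `"qnorm"`.
#' @return A tibble with class `expr_tbl` and a `scale` attribute.
#' @export
as_expr <- function(x, scale = c("raw-linear", "log2", "z", "qnorm")) {
  scale <- match.arg(scale)
  x <- tibble::as_tibble(x)
  validate_expr(x, scale)
  structure(x, scale = scale, class = c("expr_tbl", class(tibble::tibble())))
}

#' @rdname as_expr
#' @export
expr_scale <- function(x) attr(x, "scale", exact = TRUE)

validate_expr <- function(x, scale) {
  if (ncol(x) < 2L) abort("expression table needs a feature id column and at least one sample")
  ids <- x[[1L]]
  if (anyDuplicated(ids)) {
    abort(paste0("duplicated feature ids: ", paste(unique(ids[duplicated(ids)])[1:5], collapse = ", ")))
  }
  samp <- names(x)[-1L]
  if (anyDuplicated(samp)) abort("duplicated sample ids")
  vals <- as.matrix(x[, -1L, drop = FALSE])
  if (!is.numeric(vals)) abort("sample columns must be numeric")
  if (any(!is.finite(vals))) abort("expression values must be finite")
  if (scale == "raw-linear" && any(vals <= 0)) {
    abort("raw-linear expression values must be strictly positive")
  }
  invisible(x)
}

# feature-id rownamed matrix view of an expr_tbl
expr_matrix <- function(x) {
  m <- as.matrix(x[, -1L, drop = FALSE])
  rownames(m) <- x[[1L]]
  m
}

# rebuild an expr_tbl from a matrix, keeping the id column name
expr_from_matrix <- function(m, id_col, scale) {
  out <- tibble::as_tibble(m)
  out <- tibble::add_column(out, !!id_col := rownames(m), .before = 1L)
  as_expr(out, scale = scale)
}

expr_id_col <- function(x) names(x)[1L]

#' @export
print.expr_tbl <- function(x, ...) {
  cat("# Expression table [", nrow(x), " features x ", ncol(x) - 1L,
      " samples], scale: ", expr_scale(x), "\n", sep = "")
  NextMethod()
}
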