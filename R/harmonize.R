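#' Affine-log conversion of a linear-intensity matrix
#'
#' Converts original chip intensities `X` onto the shared log2 scale with
#' `Y = log2(a*X + b)`, the per-cohort conversion used to make pooled cohorts
#' comparable in central tendency and dispersion (the identity case is
#' `a = 1, b = 0`, i.e. `Y = log2(X)`).
#'
#' @param x An expression table on the `"raw-linear"` scale.
#' @param params Named vector or list with elements `a` (positive multiplier)
#'   and `b` (additive offset in linear-intensity units).
#' @return The converted expression table, scale `"log2"`; shape and ids are
#'   preserved.
#' @export
apply_affine_log <- function(x, params) {
  stopifnot(inherits(x, "expr_tbl"))
  if (expr_scale(x) != "raw-linear") abort("apply_affine_log() expects a raw-linear matrix")
  a <- params[["a"]]; b <- params[["b"]]
  if (a <= 0) abort("affine multiplier a must be positive")
  m <- expr_matrix(x)
  arg <- a * m + b
  if (any(arg <= 0)) {
    bad <- which(arg <= 0, arr.ind = TRUE)[1L, ]
    abort(sprintf("a*x + b is non-positive for probe '%s', sample '%s' (value %g); no silent clipping",
                  rownames(m)[bad[1L]], colnames(m)[bad[2L]], arg[bad[1L], bad[2L]]))
  }
  expr_from_matrix(log2(arg), expr_id_col(x), "log2")
}

#' Estimate affine-log conversion parameters against a reference cohort
#'
#' Finds `(a, b)` such that the mean and standard deviation of
#' `log2(a*X + b)` over all cohort values match those of the reference log2
#' matrix, by derivative-free Nelder-Mead minimization of the squared
#' mean/SD distance from the starting point `(a = 1, b = 0)`. Deterministic
#' for fixed inputs.
#'
#' @param cohort An expression table on the `"raw-linear"` scale.
#' @param reference An expression table on the `"log2"` scale.
#' @return A named vector `c(a = , b = )`.
#' @export
estimate_affine_params <- function(cohort, reference) {
  stopifnot(inherits(cohort, "expr_tbl"), inherits(reference, "expr_tbl"))
  if (expr_scale(cohort) != "raw-linear") abort("cohort must be raw-linear")
  if (expr_scale(reference) != "log2") abort("reference must be log2")
  x <- as.numeric(expr_matrix(cohort))
  r <- as.numeric(expr_matrix(reference))
  if (sd(x) == 0 || sd(r) == 0) abort("degenerate input: zero standard deviation")
  m_ref <- mean(r); s_ref <- sd(r)
  obj <- function(p) {
    a <- p[1L]; b <- p[2L]
    if (a <= 0) return(1e10)
    arg <- a * x + b
    if (any(arg <= 0)) return(1e10)
    y <- log2(arg)
    (mean(y) - m_ref)^2 + (sd(y) - s_ref)^2
  }
  fit <- optim(c(1, 0), obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  if (obj(fit$par) >= 1e10) abort("no admissible (a, b) keeps all arguments positive")
  c(a = fit$par[1L], b = fit$par[2L])
}

#' Per-gene Z-standardization within a cohort
#'
#' Standardizes every gene (row) to mean 0 and sample standard deviation 1
#' (n - 1 denominator) within the given matrix, the within-cohort step that
#' makes gene values comparable across cohorts before merging.
#'
#' @param x An expression table on the `"log2"` scale (gene level).
#' @return The standardized table, scale `"z"`.
#' @export
z_standardize <- function(x) {
  stopifnot(inherits(x, "expr_tbl"))
  m <- expr_matrix(x)
  mu <- rowMeans(m)
  s <- apply(m, 1L, sd)
  if (any(s == 0)) {
    abort(paste0("zero-variance gene(s), cannot standardize: ",
                 paste(head(rownames(m)[s == 0], 10), collapse = ", ")))
  }
  expr_from_matrix((m - mu) / s, expr_id_col(x), "z")
}

#' Collapse probe values to gene values by the median rule
#'
#' Represents each gene, per sample, by the median of its probes' values;
#' an even probe count uses the arithmetic mean of the two middle values.
#' With 13 probes this picks the 7th-ranked probe value.
#'
#' @param x A probe-level expression table.
#' @param map A tibble with columns `probe_id`, `gene_id` covering every probe
#'   in `x`.
#' @return A gene-level expression table on the same scale.
#' @export
collapse_probes <- function(x, map) {
  stopifnot(inherits(x, "expr_tbl"))
  m <- expr_matrix(x)
  idx <- match(rownames(m), map$probe_id)
  if (anyNA(idx)) {
    abort(paste0("probes absent from the map: ",
                 paste(head(rownames(m)[is.na(idx)], 5), collapse = ", ")))
  }
  gene <- map$gene_id[idx]
  # group genes by probe count; per group, one radix sort gives all column
  # medians at once (k x (genes*samples) reshaping)
  counts <- table(gene)
  out <- matrix(NA_real_, length(counts), ncol(m),
                dimnames = list(names(counts), colnames(m)))
  ord <- order(gene)
  m_ord <- m[ord, , drop = FALSE]
  gene_ord <- gene[ord]
  row_start <- c(1L, cumsum(counts) + 1L)
  for (k in sort(unique(as.integer(counts)))) {
    gk <- names(counts)[counts == k]
    rows <- unlist(lapply(match(gk, names(counts)),
                          function(i) seq(row_start[i], length.out = k)))
    sub <- m_ord[rows, , drop = FALSE]                 # (gk*k) x n, probe-fastest
    if (k == 1L) {
      out[gk, ] <- sub
      next
    }
    b <- matrix(array(sub, dim = c(k, length(gk), ncol(m))), nrow = k)
    o <- order(col(b), b)
    bs <- matrix(b[o], nrow = k)
    med <- if (k %% 2L == 1L) bs[(k + 1L) / 2L, ] else
      (bs[k / 2L, ] + bs[k / 2L + 1L, ]) / 2
    out[gk, ] <- matrix(med, length(gk), ncol(m))
  }
  tbl <- expr_from_matrix(out, "gene_id", expr_scale(x))
  tbl
}

#' Quantile normalization across samples
#'
#' Forces every sample (column) to share an identical value distribution:
#' rank values within each sample and replace rank r by the mean of the r-th
#' order statistics across samples; ties receive the mean of the tied ranks'
#' reference values. Delegates to [limma::normalizeQuantiles()].
#'
#' @param x An expression table with at least 2 samples.
#' @return The normalized table, scale `"qnorm"`.
#' @export
quantile_normalize <- function(x) {
  stopifnot(inherits(x, "expr_tbl"))
  if (ncol(x) - 1L < 2L) abort("quantile normalization needs at least 2 samples")
  m <- expr_matrix(x)
  q <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(q) <- dimnames(m)
  expr_from_matrix(q, expr_id_col(x), "qnorm")
}

#' Apply the subject exclusion cascade
#'
#' Removes, in order: subjects with missing relapse status; subjects with
#' positive or missing lymph-node status; event-free subjects with follow-up
#' shorter than five years (subjects who relapsed within five years are
#' retained). Restricting to node-negative, adequately followed subjects
#' focuses the cohort on early-stage disease with a determinable five-year
#' outcome.
#'
#' @param clinical A clinical table (see [read_clinical()] for columns).
#' @return A list with `clinical` (the filtered table) and `report` (a tibble
#'   of cascade stages with removed/remaining counts).
#' @export
apply_exclusions <- function(clinical) {
  n0 <- nrow(clinical)
  s1 <- dplyr::filter(clinical, !is.na(.data$relapse_event))
  s2 <- dplyr::filter(s1, !is.na(.data$node_status) & .data$node_status == 0)
  s3 <- dplyr::filter(s2, .data$time_years >= 5 |
                        (.data$relapse_event == 1 & .data$time_years < 5))
  report <- tibble::tibble(
    stage = c("initial", "missing relapse status removed",
              "node-positive or node-missing removed",
              "follow-up shorter than 5 years removed"),
    n_removed = c(0L, n0 - nrow(s1), nrow(s1) - nrow(s2), nrow(s2) - nrow(s3)),
    n_remaining = c(n0, nrow(s1), nrow(s2), nrow(s3))
  )
  if (nrow(s3) == 0L) warn("exclusion cascade removed every subject")
  list(clinical = s3, report = report)
}

#' Harmonize pooled cohorts onto a common gene-level scale
#'
#' Runs the full cross-cohort preprocessing pipeline: (1) affine-log
#' conversion of each cohort's linear intensities, (2) median collapse of
#' probes to genes, (3) per-gene Z-standardization within cohort, (4) merge of
#' cohorts over the shared gene universe, (5) quantile normalization over the
#' merged samples, then the subject exclusion cascade. A `relapse5` column
#' (relapse within five years) is added to the retained clinical table.
#'
#' @param cohorts A list of `cohort_bundle`s (see [simulate_cohorts()]).
#' @param probe_map Probe-to-gene map tibble.
#' @param reference Index of the reference cohort (used when estimating
#'   transforms).
#' @param params `"given"` to use each bundle's stored transform, or
#'   `"estimate"` to fit `(a, b)` against the reference cohort with
#'   [estimate_affine_params()].
#' @return A list of class `harmonized_cohorts` with `expression` (gene-level,
#'   quantile-normalized, retained subjects only), `clinical`, `exclusions`
#'   (the cascade report) and `provenance` (per-cohort transforms applied).
#' @export
harmonize_cohorts <- function(cohorts, probe_map, reference = 1L,
                              params = c("given", "estimate")) {
  params <- match.arg(params)
  stopifnot(length(cohorts) >= 1L)
  gene_mats <- vector("list", length(cohorts))
  provenance <- vector("list", length(cohorts))

  ref_logged <- NULL
  if (params == "estimate") {
    ref_logged <- apply_affine_log(cohorts[[reference]]$expression,
                                   cohorts[[reference]]$transform)
  }
  for (i in seq_along(cohorts)) {
    b <- cohorts[[i]]
    tr <- if (params == "given" || i == reference) b$transform else
      estimate_affine_params(b$expression, ref_logged)
    logged <- if (expr_scale(b$expression) == "raw-linear")
      apply_affine_log(b$expression, tr) else b$expression
    genes <- collapse_probes(logged, probe_map)
    gene_mats[[i]] <- z_standardize(genes)
    provenance[[i]] <- list(cohort = b$cohort, a = unname(tr[["a"]]), b = unname(tr[["b"]]),
                            stages = c("affine_log", "collapse_probes", "z_standardize"))
  }

  shared <- Reduce(intersect, lapply(gene_mats, function(g) g$gene_id))
  if (length(shared) == 0L) abort("cohorts share no genes")
  merged <- Reduce(function(a, b) dplyr::inner_join(a, b, by = "gene_id"),
                   lapply(gene_mats, function(g) g[match(shared, g$gene_id), ]))
  merged <- as_expr(merged, "z")
  normalized <- quantile_normalize(merged)

  clinical <- dplyr::bind_rows(lapply(cohorts, function(b) b$clinical))
  excl <- apply_exclusions(clinical)
  if (nrow(excl$clinical) == 0L) abort("no subjects survive the exclusion cascade")
  keep <- excl$clinical$sample_id
  expression <- as_expr(normalized[, c("gene_id", keep)], "qnorm")
  clinical <- dplyr::mutate(excl$clinical,
                            relapse5 = as.integer(.data$relapse_event == 1 & .data$time_years < 5))

  structure(list(expression = expression, clinical = clinical,
                 exclusions = excl$report, provenance = provenance),
            class = "harmonized_cohorts")
}

#' @export
print.harmonized_cohorts <- function(x, ...) {
  cat("<harmonized_cohorts> ", nrow(x$expression), " genes x ", ncol(x$expression) - 1L,
      " retained subjects (scale ", expr_scale(x$expression), ")\n", sep = "")
  print(x$exclusions)
  invisible(x)
}
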