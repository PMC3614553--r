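#' Draw a random subject subsample for gene selection
#'
#' Uniform sample without replacement of `n` subjects, redrawn (up to
#' `max_attempts`) until both outcome classes are present.
#'
#' @param clinical Clinical table with a `relapse5` column.
#' @param n Subsample size.
#' @param seed Integer seed.
#' @param max_attempts Bounded number of redraws before giving up.
#' @return Character vector of `n` sample ids.
#' @export
subsample_subjects <- function(clinical, n = 200L, seed = 1L, max_attempts = 100L) {
  if (n > nrow(clinical)) abort("subsample size exceeds the number of subjects")
  if (length(unique(clinical$relapse5)) < 2L) abort("population contains a single outcome class")
  withr::local_seed(seed)
  for (i in seq_len(max_attempts)) {
    ids <- sample(clinical$sample_id, n)
    cls <- clinical$relapse5[match(ids, clinical$sample_id)]
    if (length(unique(cls)) == 2L) return(ids)
  }
  abort("could not draw a subsample containing both classes")
}

#' Two-sided Mann-Whitney U p-value
#'
#' Rank-sum test with midranks for ties. The p-value is exact (from the null
#' distribution of U) when both groups have at most 8 observations and there
#' are no ties; otherwise a normal approximation with tie correction and
#' continuity correction is used. Identical multisets give p = 1.
#'
#' @param x,y Numeric value vectors for the two groups.
#' @return A two-sided p-value in (0, 1].
#' @export
mannwhitney_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 1L || ny < 1L) abort("both groups need at least one observation")
  r <- rank(c(x, y))
  u1 <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  has_ties <- anyDuplicated(c(x, y)) > 0L
  if (nx <= 8L && ny <= 8L && !has_ties) {
    p <- 2 * min(pwilcox(u1, nx, ny), 1 - pwilcox(u1 - 1, nx, ny))
    return(min(1, p))
  }
  n <- nx + ny
  tie_term <- if (has_ties) {
    tt <- table(c(x, y))
    sum(tt^3 - tt) / (n * (n - 1))
  } else 0
  sigma2 <- nx * ny / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(1)                   # all values identical
  z <- (abs(u1 - nx * ny / 2) - 0.5) / sqrt(sigma2)
  z <- max(z, 0)
  min(1, max(2 * pnorm(-z), .Machine$double.xmin))
}

# Vectorized normal-approximation Mann-Whitney over the rows of a matrix.
# Used inside the bootstrap where thousands of genes are tested per round.
mw_p_rows <- function(m, labels) {
  na <- sum(labels == 1L); nb <- sum(labels == 0L)
  n <- na + nb
  rk <- t(apply(m, 1L, rank))
  u1 <- rowSums(rk[, labels == 1L, drop = FALSE]) - na * (na + 1) / 2
  tie_rows <- apply(m, 1L, anyDuplicated) > 0L
  tie_term <- numeric(nrow(m))
  if (any(tie_rows)) {
    tie_term[tie_rows] <- apply(m[tie_rows, , drop = FALSE], 1L, function(v) {
      tt <- table(v)
      sum(tt^3 - tt)
    }) / (n * (n - 1))
  }
  sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
  z <- (abs(u1 - na * nb / 2) - 0.5) / sqrt(pmax(sigma2, .Machine$double.eps))
  p <- 2 * pnorm(-pmax(z, 0))
  p[sigma2 <= 0] <- 1
  pmin(1, pmax(p, .Machine$double.xmin))
}

#' Bootstrap Mann-Whitney p-values per gene
#'
#' For each of `B` rounds, resamples the subjects with replacement (same
#' size), redrawing any single-class resample, and computes the two-sided
#' Mann-Whitney p-value of every gene between relapse and non-relapse
#' subjects.
#'
#' @param expr Gene-level expression table over the subsampled subjects.
#' @param labels Named (by sample id) or positionally aligned 0/1 relapse
#'   indicator.
#' @param b_rounds Number of bootstrap rounds.
#' @param seed Integer seed.
#' @return A genes x rounds matrix of p-values.
#' @export
bootstrap_pvalues <- function(expr, labels, b_rounds = 200L, seed = 1L) {
  if (b_rounds < 1L) abort("b_rounds must be at least 1")
  m <- expr_matrix(expr)
  if (!is.null(names(labels))) labels <- labels[colnames(m)]
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) abort("both classes must be present")
  n <- ncol(m)
  withr::local_seed(seed)
  out <- matrix(NA_real_, nrow(m), b_rounds,
                dimnames = list(rownames(m), paste0("b", seq_len(b_rounds))))
  for (b in seq_len(b_rounds)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(labels[idx])) == 2L) break
    }
    out[, b] <- mw_p_rows(m[, idx, drop = FALSE], labels[idx])
  }
  out
}

#' Symmetric trimmed mean
#'
#' Sorts the values, drops `floor(length(values) * trim)` from each end and
#' averages the remainder; with 200 values and a 5% trim exactly 180 values
#' remain.
#'
#' @param values Numeric vector (e.g. one gene's bootstrap p-values).
#' @param trim Fraction trimmed from each tail.
#' @return The trimmed mean.
#' @export
trimmed_mean <- function(values, trim = 0.05) {
  b <- length(values)
  drop_n <- floor(b * trim)
  if (b - 2L * drop_n < 1L) abort("trimming leaves no values")
  s <- sort(values)
  mean(s[seq(drop_n + 1L, b - drop_n)])
}

#' Rank genes by trimmed-mean p-value and select the top k
#'
#' Ascending sort by trimmed-mean p; ties are broken by gene id (lexicographic)
#' for reproducibility.
#'
#' @param trimmed_p Named numeric vector of per-gene trimmed-mean p-values.
#' @param top_k Number of genes to flag as selected.
#' @return A tibble with columns `gene_id`, `trimmed_p`, `rank`, `selected`.
#' @export
rank_genes <- function(trimmed_p, top_k = 100L) {
  if (top_k > length(trimmed_p)) abort("top_k exceeds the number of genes")
  ord <- order(trimmed_p, names(trimmed_p))
  tibble::tibble(
    gene_id = names(trimmed_p)[ord],
    trimmed_p = unname(trimmed_p[ord]),
    rank = seq_along(trimmed_p),
    selected = seq_along(trimmed_p) <= top_k
  )
}

#' Bootstrap trimmed-mean gene ranking
#'
#' End-to-end candidate-gene selection: draw a random subject subsample, run
#' `b_rounds` bootstrap rounds of per-gene Mann-Whitney tests between
#' five-year relapse classes, average each gene's p-values after trimming the
#' top and bottom `trim` fraction, and rank genes by the trimmed mean.
#'
#' @param harmonized A [harmonize_cohorts()] result.
#' @param subsample Size of the random subject subsample used for testing.
#' @param b_rounds Number of bootstrap rounds.
#' @param trim Trim fraction per tail.
#' @param top_k Number of genes selected.
#' @param seed Integer seed.
#' @return A `ranked_genes` tibble (see [rank_genes()]) with the bootstrap
#'   round count in attribute `b_rounds`.
#' @export
rank_candidate_genes <- function(harmonized, subsample = 200L, b_rounds = 200L,
                                 trim = 0.05, top_k = 100L, seed = 1L) {
  clin <- harmonized$clinical
  ids <- subsample_subjects(clin, n = subsample, seed = seed)
  expr <- as_expr(harmonized$expression[, c(expr_id_col(harmonized$expression), ids)],
                  expr_scale(harmonized$expression))
  labels <- setNames(clin$relapse5, clin$sample_id)[ids]
  pmat <- bootstrap_pvalues(expr, labels, b_rounds = b_rounds, seed = seed + 1L)
  tm <- apply(pmat, 1L, trimmed_mean, trim = trim)
  out <- rank_genes(tm, top_k = top_k)
  attr(out, "b_rounds") <- b_rounds
  attr(out, "subsample") <- ids
  class(out) <- c("ranked_genes", class(out))
  out
}
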