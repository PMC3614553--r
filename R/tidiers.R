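#' Tidy a fitted classifier
#'
#' One row per input variable with its importance score and within-model
#' rank (1 = most important).
#'
#' @param x A `recur_model`.
#' @param ... Unused.
#' @return A tibble with columns `model`, `variable`, `importance`, `rank`.
#' @export
tidy.recur_model <- function(x, ...) {
  tibble::tibble(model = x$kind, variable = names(x$importance),
                 importance = unname(x$importance),
                 rank = rank(-x$importance, ties.method = "min"))
}

#' @export
glance.recur_model <- function(x, ...) {
  tibble::tibble(model = x$kind, n_vars = length(x$vars),
                 n_used = sum(x$importance > 0), prevention_fraction = x$f)
}

#' Tidy a Cox fit
#'
#' One row per covariate: log hazard per SD, standard error, hazard ratio and
#' 95% confidence bounds.
#'
#' @param x A [cox_fit()] result.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std_error`, `hr`, `ci_low`,
#'   `ci_high`, `p`.
#' @export
tidy.recur_cox <- function(x, ...) {
  z <- x$coefficients / x$se
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients),
                 std_error = unname(x$se),
                 hr = exp(unname(x$coefficients)),
                 ci_low = exp(unname(x$coefficients - 1.96 * x$se)),
                 ci_high = exp(unname(x$coefficients + 1.96 * x$se)),
                 p = 2 * pnorm(-abs(unname(z))))
}

#' @export
glance.recur_cox <- function(x, ...) {
  s <- x$fit
  tibble::tibble(n = s$n, n_events = s$nevent,
                 concordance = unname(s$concordance["concordance"]),
                 converged = x$converged)
}

#' Tidy a risk signature
#'
#' One row per signature gene in importance order with its standardized Cox
#' coefficient.
#'
#' @param x A [incremental_signature()] result.
#' @param ... Unused.
#' @return A tibble with `gene_id`, `order`, `beta`, `hr`.
#' @export
tidy.risk_signature <- function(x, ...) {
  tibble::tibble(gene_id = x$genes, order = seq_along(x$genes),
                 beta = unname(x$fit$coefficients[x$genes]),
                 hr = exp(unname(x$fit$coefficients[x$genes])))
}

#' @export
glance.risk_signature <- function(x, ...) {
  tibble::tibble(k_star = x$k_star,
                 auc_train = x$curve$auc_train[x$k_star],
                 auc_test = x$curve$auc_test[x$k_star],
                 cutoff = x$cutoff,
                 min_sensitivity = x$min_sensitivity)
}

#' One-row summary of a pipeline run
#'
#' @param x A [run_recurrence_pipeline()] result.
#' @param ... Unused.
#' @return A one-row tibble with retained subject count, signature size and
#'   test AUC, univariate/multivariate hazard ratio of the risk grouping,
#'   log-rank statistic/p and NRI.
#' @export
glance.recurrence_pipeline <- function(x, ...) {
  hr_uni <- x$hazards$hr[x$hazards$model == "univariate" & x$hazards$term == "high_risk"]
  hr_multi <- x$hazards$hr[x$hazards$model == "multivariate" & x$hazards$term == "high_risk"]
  tibble::tibble(
    n_subjects = nrow(x$harmonized$clinical),
    n_candidate_genes = sum(x$ranked$selected),
    k_star = x$signature$k_star,
    auc_test = x$signature$curve$auc_test[x$signature$k_star],
    hr_univariate = hr_uni,
    hr_multivariate = hr_multi,
    logrank_chisq = x$logrank$statistic,
    logrank_p = x$logrank$p,
    nri = x$nri
  )
}
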