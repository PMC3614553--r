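#' Cox proportional-hazards fit on standardized covariates
#'
#' Partial-likelihood maximization with Efron tie handling (via
#' [survival::coxph()]). Covariates are standardized with their own mean/SD
#' unless `standardize = FALSE`, so coefficients are log hazard per SD.
#'
#' @param x Data frame of covariates.
#' @param time Follow-up times.
#' @param event 0/1 event indicator.
#' @param standardize Standardize columns before fitting.
#' @return A list of class `recur_cox` with the `coxph` fit, coefficients,
#'   standard errors and the standardization constants.
#' @export
cox_fit <- function(x, time, event, standardize = TRUE) {
  if (sum(event) < 1L) abort("at least one event is required")
  xm <- as.matrix(x)
  if (any(apply(xm, 2L, sd) == 0)) {
    abort(paste0("constant covariate(s): ",
                 paste(head(colnames(xm)[apply(xm, 2L, sd) == 0], 5), collapse = ", ")))
  }
  ctr <- if (standardize) colMeans(xm) else rep(0, ncol(xm))
  scl <- if (standardize) apply(xm, 2L, sd) else rep(1, ncol(xm))
  xs <- sweep(sweep(xm, 2L, ctr), 2L, scl, "/")
  df <- data.frame(xs, check.names = FALSE)
  fit <- survival::coxph(survival::Surv(time, event) ~ ., data = df,
                         ties = "efron", control = survival::coxph.control(iter.max = 50))
  if (any(!is.finite(coef(fit)))) {
    abort(paste0("Cox fit produced non-finite coefficients; score at exit: ",
                 paste(signif(colSums(survival::coxph.detail(fit)$score), 3), collapse = ", ")))
  }
  structure(list(fit = fit, coefficients = coef(fit),
                 se = sqrt(diag(fit$var)), center = ctr, scale = scl,
                 converged = fit$iter < 50),
            class = "recur_cox")
}

#' Linear risk score from a Cox fit
#'
#' `score = sum(beta_j * z_j)` with training-derived coefficients applied
#' unchanged; new subjects are standardized with the training means/SDs.
#'
#' @param fit A [cox_fit()] result.
#' @param newdata Data frame containing every fitted covariate.
#' @return Numeric vector of risk scores.
#' @export
risk_score <- function(fit, newdata) {
  vars <- names(fit$coefficients)
  miss <- setdiff(vars, colnames(newdata))
  if (length(miss)) abort(paste0("missing covariate(s): ", paste(head(miss, 5), collapse = ", ")))
  xm <- as.matrix(newdata[, vars, drop = FALSE])
  xs <- sweep(sweep(xm, 2L, fit$center[vars]), 2L, fit$scale[vars], "/")
  drop(xs %*% fit$coefficients)
}

#' Incremental Cox gene signature
#'
#' Adds genes one at a time in the supplied importance order; for each count
#' `k` fits a standardized Cox model on the training subjects, scores train
#' and test subjects, and computes the AUC of the score against the binary
#' five-year relapse label. The selected size `k*` maximizes the test AUC
#' (smallest `k` on ties); the risk-score cutoff is chosen on the training
#' scores by [choose_cutoff()].
#'
#' @param ordered_genes Character vector of gene columns, most important first.
#' @param train,test Tibbles with `sample_id`, gene columns, `relapse5`,
#'   `time_years`, `relapse_event`.
#' @param k_max Largest gene count examined.
#' @param min_sensitivity Sensitivity floor for the cutoff.
#' @return A list of class `risk_signature`: `genes` (the selected subset),
#'   `k_star`, `fit` (the Cox fit at `k*`), `cutoff`, `curve`
#'   (tibble `k`, `auc_train`, `auc_test`, `converged`).
#' @export
incremental_signature <- function(ordered_genes, train, test, k_max = 100L,
                                  min_sensitivity = 0.80) {
  k_max <- min(k_max, length(ordered_genes))
  curve <- tibble::tibble(k = seq_len(k_max), auc_train = NA_real_,
                          auc_test = NA_real_, converged = FALSE)
  fits <- vector("list", k_max)
  for (k in seq_len(k_max)) {
    gs <- ordered_genes[seq_len(k)]
    fit <- tryCatch(
      suppressWarnings(cox_fit(train[, gs, drop = FALSE],
                               train$time_years, train$relapse_event)),
      error = function(e) NULL)
    if (is.null(fit)) next
    fits[[k]] <- fit
    curve$auc_train[k] <- auc_rank(risk_score(fit, train), train$relapse5)
    curve$auc_test[k] <- auc_rank(risk_score(fit, test), test$relapse5)
    curve$converged[k] <- TRUE
  }
  if (!any(curve$converged)) abort("no gene count produced a convergent Cox fit")
  k_star <- curve$k[which.max(curve$auc_test)]   # which.max: smallest index on ties
  fit <- fits[[k_star]]
  train_scores <- risk_score(fit, train)
  cutoff <- choose_cutoff(train_scores, train$relapse5, min_sensitivity = min_sensitivity)
  structure(list(genes = ordered_genes[seq_len(k_star)], k_star = k_star,
                 fit = fit, cutoff = cutoff, curve = curve,
                 min_sensitivity = min_sensitivity),
            class = "risk_signature")
}

#' @export
print.risk_signature <- function(x, ...) {
  cat("<risk_signature> ", x$k_star, " genes; test AUC ",
      round(x$curve$auc_test[x$k_star], 4), "; cutoff ", signif(x$cutoff, 4), "\n", sep = "")
  invisible(x)
}

#' Classify subjects into high/low recurrence-risk groups
#'
#' @param signature A [incremental_signature()] result.
#' @param data Tibble containing the signature's gene columns.
#' @return Factor with levels `low`, `high` (`high` when score >= cutoff).
#' @export
classify_risk <- function(signature, data) {
  sc <- risk_score(signature$fit, data)
  factor(ifelse(sc >= signature$cutoff, "high", "low"), levels = c("low", "high"))
}

#' Risk-score cutoff at a sensitivity floor
#'
#' Candidate thresholds are the midpoints of adjacent sorted unique scores
#' (plus sentinels below the minimum and above the maximum); among candidates
#' whose training sensitivity is at least `min_sensitivity` (high risk =
#' score >= threshold), the one maximizing specificity is returned; among
#' equally specific thresholds the more sensitive one wins (perfectly
#' separated scores then classify everything correctly), and remaining ties
#' go to the higher threshold.
#'
#' @param scores Numeric risk scores.
#' @param labels 0/1 five-year relapse labels.
#' @param min_sensitivity Sensitivity floor in `[0, 1]`.
#' @return The cutoff value.
#' @export
choose_cutoff <- function(scores, labels, min_sensitivity = 0.80) {
  if (length(unique(labels)) < 2L) abort("both classes must be present")
  u <- sort(unique(scores))
  cand <- c(u[1L] - 1, if (length(u) > 1L) (u[-1L] + u[-length(u)]) / 2, u[length(u)] + 1)
  sens <- vapply(cand, function(ct) mean(scores[labels == 1] >= ct), numeric(1))
  spec <- vapply(cand, function(ct) mean(scores[labels == 0] < ct), numeric(1))
  ok <- sens >= min_sensitivity
  if (!any(ok)) abort(sprintf("no threshold attains sensitivity >= %.2f", min_sensitivity))
  best_spec <- max(spec[ok])
  ok <- ok & spec == best_spec
  best_sens <- max(sens[ok])
  max(cand[ok & sens == best_sens])
}

#' Kaplan-Meier survival curves
#'
#' Product-limit estimator per group; censored subjects leave the risk set
#' without a step.
#'
#' @param time Non-negative follow-up times.
#' @param event 0/1 event indicator.
#' @param group Optional grouping factor.
#' @return A tibble of class `km_curve` with columns `group`, `time`,
#'   `n_risk`, `n_event`, `surv`.
#' @export
km_curve <- function(time, event, group = NULL) {
  if (any(time < 0)) abort("times must be non-negative")
  if (is.null(group)) group <- factor(rep("all", length(time)))
  group <- as.factor(group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  strata <- if (is.null(fit$strata)) setNames(length(fit$time), levels(group)[1L]) else fit$strata
  out <- tibble::tibble(
    group = rep(sub("^group=", "", names(strata)), strata),
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event, surv = fit$surv
  )
  class(out) <- c("km_curve", class(out))
  out
}

#' Two-group log-rank test
#'
#' Observed-minus-expected events over the shared event times
#' (via [survival::survdiff()]).
#'
#' @inheritParams km_curve
#' @param group Grouping factor with at least 2 levels.
#' @return A list with `statistic` (chi-square), `df` and `p`.
#' @export
log_rank <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2L) abort("log-rank needs at least 2 groups")
  if (sum(event) == 0L) abort("log-rank needs at least one event")
  fit <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(fit$n) - 1L
  list(statistic = unname(fit$chisq), df = df,
       p = stats::pchisq(fit$chisq, df, lower.tail = FALSE))
}

#' Univariate and multivariate hazard ratios for a risk grouping
#'
#' Univariate Cox on the high/low risk indicator, then a multivariate Cox
#' adding age, tumor diameter, dichotomized histopathologic grade (high =
#' grade >= `grade_cut`) and estrogen-receptor status. `HR = exp(beta)`,
#' 95% CI `exp(beta +/- 1.96 SE)`.
#'
#' @param risk_group Factor with levels `low`, `high`.
#' @param clinical Clinical table aligned to `risk_group` (needs `age`,
#'   `tumor_size`, `grade`, `er_status`).
#' @param time,event Survival outcome.
#' @param grade_cut Grade value at or above which grade counts as high.
#' @return A tibble with columns `term`, `model`, `hr`, `ci_low`, `ci_high`,
#'   `p`.
#' @export
hazard_ratios <- function(risk_group, clinical, time, event, grade_cut = 3) {
  df <- data.frame(high_risk = as.integer(risk_group == "high"),
                   age = clinical$age,
                   tumor_size = clinical$tumor_size,
                   grade_high = as.integer(clinical$grade >= grade_cut),
                   er_status = clinical$er_status)
  uni <- survival::coxph(survival::Surv(time, event) ~ high_risk, data = df, ties = "efron")
  multi <- survival::coxph(survival::Surv(time, event) ~ high_risk + age + tumor_size +
                             grade_high + er_status, data = df, ties = "efron")
  row_of <- function(fit, model) {
    s <- summary(fit)
    tibble::tibble(term = rownames(s$coefficients), model = model,
                   hr = exp(s$coefficients[, "coef"]),
                   ci_low = exp(s$coefficients[, "coef"] - 1.96 * s$coefficients[, "se(coef)"]),
                   ci_high = exp(s$coefficients[, "coef"] + 1.96 * s$coefficients[, "se(coef)"]),
                   p = s$coefficients[, "Pr(>|z|)"])
  }
  dplyr::bind_rows(row_of(uni, "univariate"), row_of(multi, "multivariate"))
}

#' Net reclassification improvement
#'
#' `NRI = [P(up | event) - P(down | event)] + [P(down | non-event) -
#' P(up | non-event)]` for a move from an old to a new two-level risk
#' categorization of the same subjects (`up` = low to high, `down` = high to
#' low).
#'
#' @param old,new Factors (or values coercible to factor) with ordered levels
#'   `low`, `high` for the same subjects.
#' @param event 0/1 event indicator.
#' @return The NRI value.
#' @export
nri <- function(old, new, event) {
  old <- factor(old, levels = c("low", "high"))
  new <- factor(new, levels = c("low", "high"))
  if (length(old) != length(new) || length(old) != length(event)) {
    abort("old, new and event must describe the same subjects")
  }
  if (sum(event == 1) == 0L || sum(event == 0) == 0L) {
    abort("NRI needs both events and non-events")
  }
  up <- old == "low" & new == "high"
  down <- old == "high" & new == "low"
  ev <- event == 1
  (mean(up[ev]) - mean(down[ev])) + (mean(down[!ev]) - mean(up[!ev]))
}
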