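#' Plot the AUC-versus-gene-count curve of a risk signature
#'
#' Training and test AUC of the incremental Cox risk score as genes are added
#' in importance order, with the selected size `k*` marked. The test curve's
#' rise-then-fall shape is the visual signature of over-fitting past the
#' informative gene set.
#'
#' @param object A [incremental_signature()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.risk_signature <- function(object, ...) {
  d <- tidyr::pivot_longer(object$curve, c("auc_train", "auc_test"),
                           names_to = "set", values_to = "auc")
  d$set <- ifelse(d$set == "auc_train", "training", "test")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$k, y = .data$auc, colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$k_star, linetype = "dashed") +
    ggplot2::labs(x = "number of genes in the Cox risk score", y = "AUC",
                  colour = NULL,
                  title = sprintf("Incremental signature (k* = %d)", object$k_star)) +
    ggplot2::theme_minimal()
}

#' Plot Kaplan-Meier curves
#'
#' @param object A [km_curve()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.km_curve <- function(object, ...) {
  d <- dplyr::bind_rows(
    tibble::tibble(group = unique(object$group), time = 0, surv = 1),
    tibble::as_tibble(object)[, c("group", "time", "surv")]
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$surv, colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "years", y = "relapse-free proportion", colour = "risk group") +
    ggplot2::theme_minimal()
}

#' Extrapolation plot for a model suite
#'
#' Dot plot of mean training vs test performance per model; the horizontal
#' distance is the extrapolation difference (train minus test).
#'
#' @param suite A [fit_model_suite()] result.
#' @param metric `"acc"` or `"auc"`.
#' @return A ggplot object.
#' @export
plot_extrapolation <- function(suite, metric = c("acc", "auc")) {
  metric <- match.arg(metric)
  cols <- paste0(metric, c("_train", "_test"))
  d <- tidyr::pivot_longer(suite$summary[, c("model", cols)], dplyr::all_of(cols),
                           names_to = "set", values_to = "value")
  d$set <- ifelse(grepl("train", d$set), "training", "test")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value, y = .data$model,
                                  colour = .data$set)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = paste0(toupper(metric), " (%)"), y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
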