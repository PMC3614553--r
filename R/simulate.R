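#' Simulation configuration for multi-cohort expression data
#'
#' Builds the configuration for [simulate_cohorts()]. The defaults emulate the
#' structure of four pooled HG-U133A breast-cancer cohorts: four cohorts of
#' 198/189/249/286 subjects, genes covered by 1-14 probes each, a small set of
#' co-expressed recurrence-associated genes, right-censored follow-up, and
#' per-cohort affine distortions of a shared log2 expression scale (the
#' reference cohort and one other are stored as plain `2^Y` intensities, the
#' remaining two with multiplier/offset pairs (2.2, -8) and (2.65, -0.1)).
#'
#' @param n_cohorts Number of cohorts.
#' @param subjects_per_cohort Integer vector of per-cohort subject counts.
#' @param n_genes Number of genes on the simulated platform.
#' @param probes_per_gene_range Inclusive integer range of probes per gene;
#'   must lie within `[1, 14]`.
#' @param n_signal_genes Number of genes carrying a recurrence signal.
#' @param effect_size Target mean difference (log2 units) of each signal gene
#'   between subjects who do and do not relapse within five years.
#' @param signal_loading Loading of the signal genes on a shared latent factor
#'   (co-expression of the prognostic module); in (0, 1).
#' @param hazard_weights Optional per-signal-gene Cox log-hazard coefficients.
#'   When `NULL` a single common weight is calibrated by quadrature so the
#'   induced class separation equals `effect_size`.
#' @param baseline_hazard Baseline event rate (events per year).
#' @param censor_window Censoring times are uniform on `(0, censor_window)` years.
#' @param node_positive_fraction Proportion of lymph-node-positive subjects.
#' @param missing_fraction Proportion of missing values injected independently
#'   into lymph-node status and relapse status.
#' @param grade_hazard Optional log-hazard increment per unit of (centred)
#'   histopathologic grade; 0 keeps clinical covariates independent of outcome.
#' @param cohort_transforms List of `c(a = , b = )` affine parameters, one per
#'   cohort; the stored intensity matrix of cohort *c* is
#'   `X = (2^Y - b_c) / a_c` so that `Y = log2(a_c X + b_c)` recovers the
#'   latent log2 values.
#' @param probe_offset_sd SD of the fixed per-probe offset (log2 units).
#' @param noise_sd SD of per-probe, per-sample measurement noise (log2 units).
#' @param gene_mean_range Range of baseline gene means (log2 units).
#' @param gene_sd Between-subject SD of gene-level log2 expression.
#' @param seed Integer seed; identical configurations give identical output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cohorts = 4L,
                       subjects_per_cohort = c(198L, 189L, 249L, 286L),
                       n_genes = 2000L,
                       probes_per_gene_range = c(1L, 14L),
                       n_signal_genes = 20L,
                       effect_size = 1.0,
                       signal_loading = 0.8,
                       hazard_weights = NULL,
                       baseline_hazard = 0.06,
                       censor_window = 20,
                       node_positive_fraction = 0.135,
                       missing_fraction = 0.005,
                       grade_hazard = 0,
                       cohort_transforms = list(c(a = 1, b = 0),
                                                c(a = 2.2, b = -8),
                                                c(a = 2.65, b = -0.1),
                                                c(a = 1, b = 0)),
                       probe_offset_sd = 0.3,
                       noise_sd = 0.3,
                       gene_mean_range = c(4, 10),
                       gene_sd = 1,
                       seed = 1L) {
  cfg <- list(n_cohorts = as.integer(n_cohorts),
              subjects_per_cohort = as.integer(subjects_per_cohort),
              n_genes = as.integer(n_genes),
              probes_per_gene_range = as.integer(probes_per_gene_range),
              n_signal_genes = as.integer(n_signal_genes),
              effect_size = effect_size,
              signal_loading = signal_loading,
              hazard_weights = hazard_weights,
              baseline_hazard = baseline_hazard,
              censor_window = censor_window,
              node_positive_fraction = node_positive_fraction,
              missing_fraction = missing_fraction,
              grade_hazard = grade_hazard,
              cohort_transforms = cohort_transforms,
              probe_offset_sd = probe_offset_sd,
              noise_sd = noise_sd,
              gene_mean_range = gene_mean_range,
              gene_sd = gene_sd,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (length(subjects_per_cohort) != n_cohorts) abort("subjects_per_cohort must have n_cohorts entries")
    if (any(subjects_per_cohort < 2L)) abort("every cohort needs at least 2 subjects")
    if (probes_per_gene_range[1L] < 1L || probes_per_gene_range[2L] > 14L ||
        probes_per_gene_range[1L] > probes_per_gene_range[2L]) {
      abort("probes_per_gene_range must be an increasing integer interval within [1, 14]")
    }
    if (n_signal_genes > n_genes) abort("n_signal_genes must not exceed n_genes")
    for (p in c(node_positive_fraction, missing_fraction)) {
      if (p < 0 || p > 1) abort("proportions must lie in [0, 1]")
    }
    if (signal_loading <= 0 || signal_loading >= 1) abort("signal_loading must be in (0, 1)")
    if (length(cohort_transforms) != n_cohorts) abort("cohort_transforms must have n_cohorts entries")
    for (tr in cohort_transforms) {
      if (tr[["a"]] <= 0) abort("affine multiplier a must be positive")
    }
    if (baseline_hazard <= 0 || censor_window <= 0) abort("hazard and censor window must be positive")
  })
  invisible(cfg)
}

#' Assign probes to genes
#'
#' Draws an integer number of probes per gene uniformly on
#' `probes_per_gene_range`; the resulting map is total and surjective onto the
#' gene set (every probe maps to exactly one gene, every gene has at least one
#' probe), emulating a platform where genes are covered by 1-14 probe sets.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return A tibble with columns `probe_id`, `gene_id`.
#' @export
generate_probe_map <- function(config, seed = config$seed) {
  withr::local_seed(seed)
  gene_ids <- sprintf("g%04d", seq_len(config$n_genes))
  rng <- config$probes_per_gene_range
  n_probes <- if (rng[1L] == rng[2L]) rep(rng[1L], config$n_genes) else
    sample(seq(rng[1L], rng[2L]), config$n_genes, replace = TRUE)
  tibble::tibble(
    probe_id = sprintf("%s_p%02d", rep(gene_ids, n_probes), sequence(n_probes)),
    gene_id = rep(gene_ids, n_probes)
  )
}

# Mean difference of one signal gene between 5-year relapse classes, as a
# function of the common hazard weight w, under the generative model:
#   z_g = rho*u + sqrt(1-rho^2)*e_g,  eta = w * sum(z_g),  T ~ Exp(h0*e^eta).
# Evaluated by 2-D quadrature over (u, t = sum(e)/sqrt(K)).
signal_class_diff <- function(w, k, rho, h0, horizon = 5, nodes = 201) {
  g <- seq(-7, 7, length.out = nodes)
  wts <- dnorm(g)
  wts <- wts / sum(wts)
  u <- matrix(g, nodes, nodes)
  t <- matrix(g, nodes, nodes, byrow = TRUE)
  ww <- outer(wts, wts)
  eta <- w * (k * rho * u + sqrt(1 - rho^2) * sqrt(k) * t)
  eta <- pmin(eta, 30)                       # guard exp overflow
  pev <- 1 - exp(-horizon * h0 * exp(eta))   # P(relapse within horizon | u, t)
  zbar <- rho * u + sqrt(1 - rho^2) * t / sqrt(k)
  p <- sum(pev * ww)
  ezg <- sum(zbar * pev * ww)
  list(diff = ezg / (p * (1 - p)), prevalence = p)
}

#' Analytic five-year relapse prevalence of a simulation design
#'
#' Expected proportion of subjects whose latent event time falls within five
#' years, computed by quadrature from the exponential survival model (no
#' censoring); used to check observed prevalences against the design.
#'
#' @param config A [sim_config()].
#' @return A single probability.
#' @export
expected_relapse_prevalence <- function(config) {
  w <- resolve_hazard_weights(config)
  if (config$n_signal_genes == 0L || all(w == 0)) {
    return(1 - exp(-5 * config$baseline_hazard))
  }
  signal_class_diff(w[1L], config$n_signal_genes, config$signal_loading,
                    config$baseline_hazard)$prevalence
}

resolve_hazard_weights <- function(config) {
  k <- config$n_signal_genes
  if (k == 0L) return(numeric(0))
  if (!is.null(config$hazard_weights)) {
    if (length(config$hazard_weights) != k) abort("hazard_weights must have n_signal_genes entries")
    return(config$hazard_weights)
  }
  if (config$effect_size == 0) return(rep(0, k))
  rho <- config$signal_loading
  h0 <- config$baseline_hazard
  lim <- signal_class_diff(60 / k, k, rho, h0)$diff
  if (config$effect_size >= lim) {
    abort(sprintf("effect_size %.2f is unattainable for this design (limit %.2f); increase signal_loading",
                  config$effect_size, lim))
  }
  w <- uniroot(function(x) signal_class_diff(x, k, rho, h0)$diff - config$effect_size,
               lower = 1e-6, upper = 60 / k, tol = 1e-8)$root
  rep(w, k)
}

#' Generate synthetic multi-cohort probe-level expression data
#'
#' Draws gene-level log2 expression from a shared distribution, plants a
#' co-expressed module of recurrence-associated genes, generates survival
#' outcomes from an exponential model with hazard
#' `h0 * exp(sum(w_g * z_g))` over the standardized signal genes, censors
#' uniformly, derives the five-year relapse indicator, and stores every
#' cohort's probe matrix on its own distorted linear-intensity scale
#' `X = (2^Y - b_c) / a_c`. Probe values are the gene value plus a fixed
#' per-probe offset plus noise, so the median-probe collapse rule is
#' meaningful. Clinical covariates (age, tumor size, grade, estrogen-receptor
#' status, lymph-node status) are generated independently of expression except
#' for an optional grade-hazard link; missing values are injected into node
#' and relapse status only.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_cohorts` with elements `cohorts` (a list of
#'   `cohort_bundle`s, each holding `expression`, `clinical`, `cohort`,
#'   `transform`), `probe_map`, `truth` (signal gene ids, per-gene hazard
#'   coefficients, per-subject linear predictor and true five-year relapse
#'   probability/indicator) and `config`.
#' @export
simulate_cohorts <- function(config = sim_config()) {
  validate_sim_config(config)
  withr::local_seed(config$seed)

  probe_map <- generate_probe_map(config, seed = config$seed + 7919L)
  gene_ids <- unique(probe_map$gene_id)
  n_genes <- config$n_genes
  n_total <- sum(config$subjects_per_cohort)
  cohort_names <- sprintf("cohort%d", seq_len(config$n_cohorts))
  sample_ids <- sprintf("%s_s%03d", rep(cohort_names, config$subjects_per_cohort),
                        sequence(config$subjects_per_cohort))

  signal_ids <- if (config$n_signal_genes > 0L) sort(sample(gene_ids, config$n_signal_genes)) else character(0)
  w <- resolve_hazard_weights(config)
  rho <- config$signal_loading

  gene_mu <- runif(n_genes, config$gene_mean_range[1L], config$gene_mean_range[2L])
  names(gene_mu) <- gene_ids

  # latent standardized gene scores; signal genes share a factor u
  z <- matrix(rnorm(n_genes * n_total), n_genes, n_total,
              dimnames = list(gene_ids, sample_ids))
  u <- rnorm(n_total)
  if (length(signal_ids)) {
    z[signal_ids, ] <- rho * rep(u, each = length(signal_ids)) +
      sqrt(1 - rho^2) * z[signal_ids, , drop = FALSE]
  }

  # clinical covariates
  age <- round(pmin(pmax(rnorm(n_total, 54, 11), 25), 90))
  tumor_size <- round(pmin(rlnorm(n_total, log(2), 0.4), 10), 1)
  grade <- sample(1:3, n_total, replace = TRUE, prob = c(0.2, 0.45, 0.35))
  er_status <- rbinom(n_total, 1L, 0.7)
  node_status <- rbinom(n_total, 1L, config$node_positive_fraction)

  # survival from the exponential hazard model
  eta <- if (length(signal_ids)) colSums(w * z[signal_ids, , drop = FALSE]) else rep(0, n_total)
  eta <- eta + config$grade_hazard * (grade - 2)
  t_event <- rexp(n_total, rate = config$baseline_hazard * exp(pmin(eta, 30)))
  t_cens <- runif(n_total, 0, config$censor_window)
  time_years <- pmin(t_event, t_cens)
  relapse_event <- as.integer(t_event <= t_cens)

  if (config$missing_fraction > 0) {
    node_status[runif(n_total) < config$missing_fraction] <- NA_integer_
    relapse_event[runif(n_total) < config$missing_fraction] <- NA_integer_
  }

  # probe-level log2 values: gene value + fixed probe offset + noise
  probe_offset <- rnorm(nrow(probe_map), 0, config$probe_offset_sd)
  gene_log2 <- gene_mu[probe_map$gene_id] + config$gene_sd * z[probe_map$gene_id, , drop = FALSE]
  y <- gene_log2 + probe_offset +
    matrix(rnorm(nrow(probe_map) * n_total, 0, config$noise_sd), nrow(probe_map), n_total)
  rownames(y) <- probe_map$probe_id

  clinical <- tibble::tibble(
    sample_id = sample_ids,
    cohort = rep(cohort_names, config$subjects_per_cohort),
    age = age, tumor_size = tumor_size, grade = grade,
    er_status = er_status, node_status = node_status,
    relapse_event = relapse_event, time_years = time_years
  )

  col_of <- split(seq_len(n_total), rep(seq_len(config$n_cohorts), config$subjects_per_cohort))
  cohorts <- vector("list", config$n_cohorts)
  for (c_i in seq_len(config$n_cohorts)) {
    tr <- config$cohort_transforms[[c_i]]
    x_lin <- (2^y[, col_of[[c_i]], drop = FALSE] - tr[["b"]]) / tr[["a"]]
    if (any(x_lin <= 0)) {
      abort(sprintf("cohort %d: affine parameters (a=%g, b=%g) give non-positive linear intensities",
                    c_i, tr[["a"]], tr[["b"]]))
    }
    cohorts[[c_i]] <- new_cohort_bundle(
      expression = expr_from_matrix(x_lin, "probe_id", "raw-linear"),
      clinical = clinical[col_of[[c_i]], ],
      cohort = cohort_names[c_i],
      transform = c(a = unname(tr[["a"]]), b = unname(tr[["b"]]))
    )
  }

  truth <- list(
    signal_gene_ids = signal_ids,
    genes = tibble::tibble(gene_id = gene_ids,
                           hazard_coef = ifelse(gene_ids %in% signal_ids,
                                                w[match(gene_ids, signal_ids)], 0)),
    subjects = tibble::tibble(sample_id = sample_ids,
                              linear_predictor = eta,
                              relapse5_prob = 1 - exp(-5 * config$baseline_hazard * exp(pmin(eta, 30))),
                              true_event5 = as.integer(t_event < 5))
  )
  truth$genes$hazard_coef[is.na(truth$genes$hazard_coef)] <- 0

  structure(list(cohorts = cohorts, probe_map = probe_map, truth = truth, config = config),
            class = "sim_cohorts")
}

new_cohort_bundle <- function(expression, clinical, cohort, transform, provenance = character(0)) {
  structure(list(expression = expression, clinical = clinical, cohort = cohort,
                 transform = transform, provenance = provenance),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("<cohort_bundle> ", x$cohort, ": ", nrow(x$expression), " features x ",
      ncol(x$expression) - 1L, " subjects; transform a=", x$transform[["a"]],
      ", b=", x$transform[["b"]], "; scale ", expr_scale(x$expression), "\n", sep = "")
  invisible(x)
}

#' @export
print.sim_cohorts <- function(x, ...) {
  cat("<sim_cohorts> ", length(x$cohorts), " cohorts, ", x$config$n_genes, " genes (",
      length(x$truth$signal_gene_ids), " signal), ", nrow(x$probe_map), " probes\n", sep = "")
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Writes one probe-level TSV expression matrix per cohort, the probe-to-gene
#' map, per-cohort clinical CSV tables and ground-truth sidecar files.
#'
#' @param sim A [simulate_cohorts()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohorts <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(sim$probe_map, file.path(dir, "probe_map.tsv"))
  for (b in sim$cohorts) {
    write_expression(b$expression, file.path(dir, paste0(b$cohort, "_expression.tsv")))
    write_clinical(b$clinical, file.path(dir, paste0(b$cohort, "_clinical.csv")))
  }
  readr::write_tsv(sim$truth$genes, file.path(dir, "truth_genes.tsv"))
  readr::write_tsv(sim$truth$subjects, file.path(dir, "truth_subjects.tsv"))
  invisible(dir)
}
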