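# Shared fixtures, built in code.

# Small two-cohort design used across unit tests.
small_config <- function(seed = 11L, ...) {
  defaults <- list(n_cohorts = 2L, subjects_per_cohort = c(120L, 130L),
                   n_genes = 200L, n_signal_genes = 6L,
                   cohort_transforms = list(c(a = 1, b = 0), c(a = 2.2, b = -8)),
                   seed = seed)
  overrides <- list(...)
  do.call(sim_config, c(overrides, defaults[setdiff(names(defaults), names(overrides))]))
}

# Clinical table encoding the published exclusion cascade:
# 922 records -> 2 missing relapse -> 124 node-positive/missing -> 39 with
# event-free follow-up under five years -> 757 retained.
cascade_clinical <- function() {
  n <- 922L
  tbl <- tibble::tibble(
    sample_id = sprintf("s%03d", seq_len(n)),
    cohort = "pooled",
    age = 50, tumor_size = 2, grade = 2L, er_status = 1L,
    node_status = 0L,
    relapse_event = rep(c(0L, 1L), length.out = n),
    time_years = 8
  )
  tbl$relapse_event[1:2] <- NA_integer_              # missing outcome
  tbl$node_status[3:120] <- 1L                       # node positive
  tbl$node_status[121:126] <- NA_integer_            # node missing (124 total)
  tbl$relapse_event[127:165] <- 0L                   # short event-free follow-up
  tbl$time_years[127:165] <- 3.5                     # (39 records)
  tbl
}

# One deterministic pipeline run at the pooled desk-scale design, shared by
# the acceptance tests (cached across test files).
default_pipeline <- function() {
  if (!exists(".poolsig_pipeline_cache", envir = globalenv())) {
    assign(".poolsig_pipeline_cache",
           run_recurrence_pipeline(config = sim_config(), seed = 1L),
           envir = globalenv())
  }
  get(".poolsig_pipeline_cache", envir = globalenv())
}

# Brute-force two-sided Mann-Whitney p by enumerating all group assignments.
enumerate_mw_p <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(length(pooled), nx)
  u_all <- apply(combos, 2L, function(ix) sum(r[ix]) - nx * (nx + 1) / 2)
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Brute-force Cox partial likelihood (Breslow would differ under ties; the
# toys used are tie-free so Efron and Breslow coincide).
cox_partial_loglik <- function(beta, x, time, event) {
  eta <- drop(as.matrix(x) %*% beta)
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + eta[i] - log(sum(exp(eta[risk])))
  }
  ll
}
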