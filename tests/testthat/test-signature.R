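# survival toy data with a known hazard structure
surv_sim <- function(n, beta, seed = 91, h0 = 0.08, cens = 25) {
  withr::local_seed(seed)
  x <- matrix(rnorm(n * length(beta)), n, length(beta),
              dimnames = list(NULL, paste0("v", seq_along(beta))))
  t_ev <- rexp(n, h0 * exp(drop(x %*% beta)))
  t_c <- runif(n, 0, cens)
  list(x = as.data.frame(x), time = pmin(t_ev, t_c), event = as.integer(t_ev <= t_c))
}

test_that("Cox fit recovers planted coefficients and matches a brute-force oracle", {
  d <- surv_sim(400, c(0.5, -0.5, 0.3), seed = 92)
  fit <- cox_fit(d$x, d$time, d$event)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$coefficients - c(0.5, -0.5, 0.3))), 0.15)

  # independent covariate: coefficient near zero
  d0 <- surv_sim(600, 0, seed = 93)
  fit0 <- cox_fit(d0$x, d0$time, d0$event)
  expect_lt(abs(fit0$coefficients[1]), 0.12)

  # 6-subject toy: partial-likelihood grid search equals the fit to 1e-4
  toy_x <- data.frame(v1 = c(-1.2, 0.4, 1.1, -0.3, 0.8, -0.9))
  toy_t <- c(1.5, 2.3, 3.1, 4.8, 6.2, 7.9)           # distinct times: no ties
  toy_e <- c(1, 0, 1, 1, 0, 1)
  fit_toy <- cox_fit(toy_x, toy_t, toy_e, standardize = FALSE)
  grid <- seq(-3, 3, by = 1e-4)
  ll <- vapply(grid, cox_partial_loglik, numeric(1),
               x = toy_x, time = toy_t, event = toy_e)
  expect_lt(abs(fit_toy$coefficients[1] - grid[which.max(ll)]), 1e-4)

  expect_error(cox_fit(data.frame(v = rep(1, 6)), toy_t, toy_e), "constant")
  expect_error(cox_fit(toy_x, toy_t, rep(0, 6)), "at least one event")
})

test_that("risk scores are the linear predictor with training standardization", {
  fit <- structure(list(coefficients = c(a = 1, b = -1),
                        center = c(a = 0, b = 0), scale = c(a = 1, b = 1)),
                   class = "recur_cox")
  expect_equal(risk_score(fit, data.frame(a = 2, b = 1)), 1)
  expect_equal(risk_score(fit, data.frame(a = 0, b = 0)), 0)
  # linearity
  z1 <- data.frame(a = 1.3, b = -0.2); z2 <- data.frame(a = -0.4, b = 2)
  expect_equal(risk_score(fit, z1 + z2), risk_score(fit, z1) + risk_score(fit, z2))
  # monotone in a positive-coefficient gene
  expect_gt(risk_score(fit, data.frame(a = 2, b = 0)), risk_score(fit, data.frame(a = 1, b = 0)))
  expect_error(risk_score(fit, data.frame(a = 1)), "missing covariate")
})

test_that("incremental signature shows rise-then-fall and finds the planted size", {
  withr::local_seed(94)
  n <- 1000
  p <- 30
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("g%02d", 1:p)))
  beta <- c(rep(1, 3), rep(0, p - 3))                 # signal in the first 3 genes
  t_ev <- rexp(n, 0.08 * exp(drop(x %*% beta)))
  t_c <- runif(n, 0, 25)
  d <- tibble::tibble(sample_id = sprintf("s%04d", 1:n), as.data.frame(x),
                      time_years = pmin(t_ev, t_c),
                      relapse_event = as.integer(t_ev <= t_c))
  d$relapse5 <- as.integer(d$relapse_event == 1 & d$time_years < 5)
  d <- d[d$time_years >= 5 | d$relapse5 == 1, ]       # determinable outcome
  tr <- d[seq_len(floor(nrow(d) / 2)), ]
  te <- d[-seq_len(floor(nrow(d) / 2)), ]
  sig <- incremental_signature(sprintf("g%02d", 1:p), tr, te, k_max = p)
  expect_lte(abs(sig$k_star - 3), 5)
  # rise-then-fall: AUC at k* above both the first and the last point
  expect_gt(sig$curve$auc_test[sig$k_star], sig$curve$auc_test[1] - 1e-9)
  expect_gt(sig$curve$auc_test[sig$k_star], sig$curve$auc_test[p])
  # train AUC grows (up to fit noise) with added genes
  expect_gt(mean(diff(sig$curve$auc_train) > -0.005), 0.9)
  # k_max = 1: signature is the single top gene
  sig1 <- incremental_signature(sprintf("g%02d", 1:p), tr, te, k_max = 1)
  expect_identical(sig1$genes, "g01")
  # cutoff satisfies the sensitivity floor on training data
  sc <- risk_score(sig$fit, tr)
  expect_gte(mean(sc[tr$relapse5 == 1] >= sig$cutoff), sig$min_sensitivity)
})

test_that("cutoff selection maximizes specificity under the sensitivity floor", {
  scores <- 1:10
  labels <- as.integer(scores >= 7)                    # events at 7..10
  cut <- choose_cutoff(scores, labels, min_sensitivity = 0.8)
  # brute force over all thresholds
  cand <- seq(0, 11, by = 0.25)
  sens <- vapply(cand, function(ct) mean(scores[labels == 1] >= ct), numeric(1))
  spec <- vapply(cand, function(ct) mean(scores[labels == 0] < ct), numeric(1))
  best <- max(spec[sens >= 0.8])
  expect_equal(mean(scores[labels == 1] >= cut), 1)    # sens 1 attainable here
  expect_equal(mean(scores[labels == 0] < cut), best)

  # perfectly separated scores classify everything correctly
  sep_scores <- c(rnorm(20, -5), rnorm(20, 5))
  sep_labels <- rep(c(0L, 1L), each = 20)
  cut2 <- choose_cutoff(sep_scores, sep_labels, 0.8)
  expect_equal(mean(sep_scores[sep_labels == 1] >= cut2), 1)
  expect_equal(mean(sep_scores[sep_labels == 0] < cut2), 1)

  # sensitivity floor 0: specificity is maximized first, then sensitivity,
  # which here returns the perfect separator rather than a degenerate rule
  cut3 <- choose_cutoff(scores, labels, 0)
  expect_equal(mean(scores[labels == 0] < cut3), 1)
  expect_equal(mean(scores[labels == 1] >= cut3), 1)
  expect_error(choose_cutoff(scores, rep(1L, 10)), "both classes")
})

test_that("Kaplan-Meier estimator matches hand results and the empirical survivor", {
  km <- km_curve(c(1, 2), c(1, 0))
  expect_equal(km$surv[km$time == 1], 0.5)
  km_c <- km_curve(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km_c$surv == 1))
  # no censoring: product-limit equals the empirical survivor function
  withr::local_seed(95)
  t_all <- rexp(60, 0.2)
  km_e <- km_curve(t_all, rep(1, 60))
  emp <- vapply(km_e$time, function(tt) mean(t_all > tt), numeric(1))
  expect_equal(km_e$surv, emp, tolerance = 1e-12)
  expect_true(all(diff(km_e$surv) <= 0))
  expect_error(km_curve(c(-1, 2), c(1, 1)), "non-negative")
})

test_that("log-rank is null on identical groups, powerful on separated ones, symmetric", {
  tt <- c(1, 2, 3, 4, 6, 8, 9, 12)
  ev <- c(1, 0, 1, 1, 0, 1, 1, 0)
  two <- rep(c("a", "b"), each = 8)
  out <- log_rank(c(tt, tt), c(ev, ev), two)
  expect_equal(out$statistic, 0, tolerance = 1e-12)
  expect_equal(out$p, 1, tolerance = 1e-12)

  withr::local_seed(96)
  g <- rep(c("low", "high"), each = 200)
  t_ev <- c(rexp(200, 0.05), rexp(200, 0.05 * 3.5))   # planted HR 3.5
  t_c <- runif(400, 0, 25)
  out2 <- log_rank(pmin(t_ev, t_c), as.integer(t_ev <= t_c), g)
  expect_lt(out2$p, 0.001)
  out2b <- log_rank(pmin(t_ev, t_c), as.integer(t_ev <= t_c), rev(factor(g)))
  expect_equal(out2$statistic, out2b$statistic, tolerance = 1e-9)

  expect_error(log_rank(tt, rep(0, 8), rep(c("a", "b"), 4)), "at least one event")
  expect_error(log_rank(tt, ev, rep("a", 8)), "at least 2 groups")
})

test_that("hazard ratios recover a planted group effect and bracket the estimate", {
  withr::local_seed(97)
  n <- 760
  grp <- factor(rep(c("low", "high"), each = n / 2), levels = c("low", "high"))
  t_ev <- rexp(n, 0.05 * exp(1.26 * (grp == "high")))  # HR = e^1.26 ~ 3.5
  t_c <- runif(n, 0, 25)
  clin <- tibble::tibble(age = rnorm(n, 55, 10), tumor_size = rlnorm(n, log(2), 0.4),
                         grade = sample(1:3, n, TRUE), er_status = rbinom(n, 1, 0.7))
  hr <- hazard_ratios(grp, clin, pmin(t_ev, t_c), as.integer(t_ev <= t_c))
  uni <- hr[hr$model == "univariate" & hr$term == "high_risk", ]
  expect_lt(abs(uni$hr - 3.5) / 3.5, 0.25)
  expect_true(all(hr$ci_low <= hr$hr & hr$hr <= hr$ci_high))

  # grouping independent of survival: HR near 1, CI covers 1
  grp0 <- factor(sample(c("low", "high"), n, TRUE), levels = c("low", "high"))
  hr0 <- hazard_ratios(grp0, clin, pmin(t_ev, t_c), as.integer(t_ev <= t_c))
  uni0 <- hr0[hr0$model == "univariate" & hr0$term == "high_risk", ]
  expect_true(uni0$ci_low < 1 && 1 < uni0$ci_high)
})

test_that("net reclassification improvement follows its defining formula", {
  lv <- c("low", "high")
  same <- factor(rep(lv, 50), levels = lv)
  ev <- rep(c(1L, 0L), each = 50)
  expect_equal(nri(same, same, ev), 0)

  # 100 events: 10 up, 5 down; 100 non-events: 5 up, 10 down -> 0.10
  old <- factor(rep("low", 200), levels = lv)
  new <- factor(rep("low", 200), levels = lv)
  event <- rep(c(1L, 0L), each = 100)
  new[1:10] <- "high"                     # events moving up
  old[11:15] <- "high"                    # events moving down
  new[101:105] <- "high"                  # non-events moving up
  old[106:115] <- "high"                  # non-events moving down
  expect_equal(nri(old, new, event), 0.10)

  # swapping event labels negates the event-side term
  up_term <- function(o, n, e) mean((o == "low" & n == "high")[e == 1]) -
    mean((o == "high" & n == "low")[e == 1])
  expect_equal(up_term(old, new, event), 0.05)
  expect_equal(up_term(old, new, 1L - event), -0.05)

  expect_error(nri(old, new, rep(1L, 200)), "both events and non-events")
})
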