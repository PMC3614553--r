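# small labelled dataset with one informative variable among noise
toy_data <- function(n = 120, p = 6, shift = 2, seed = 61) {
  withr::local_seed(seed)
  y <- rep(c(0L, 1L), each = n / 2)
  x <- as.data.frame(matrix(rnorm(n * p), n, p))
  names(x) <- sprintf("g%02d", seq_len(p))
  x$g01 <- x$g01 + shift * y
  list(x = x, y = y)
}

test_that("splits partition the subjects and are seed-deterministic", {
  ids <- sprintf("s%03d", 1:757)
  sp <- make_splits(ids, rounds = 3, seed = 62)
  expect_length(sp[[1]]$train, 370L)
  expect_length(sp[[1]]$test, 387L)
  expect_length(intersect(sp[[1]]$train, sp[[1]]$test), 0L)
  expect_setequal(c(sp[[1]]$train, sp[[1]]$test), ids)
  sp2 <- make_splits(ids, rounds = 3, seed = 62)
  expect_identical(sp, sp2)
  expect_error(make_splits(ids, sizes = c(100, 100), rounds = 1), "sum")
  expect_error(make_splits(ids, sizes = c(0, 757), rounds = 1), "non-empty")
})

test_that("balance check flags separation, tolerates constants, matches null rate", {
  withr::local_seed(63)
  n <- 200
  data <- tibble::tibble(sample_id = sprintf("s%03d", 1:n),
                         v_const = 1,
                         v_sep = rep(c(0, 1), each = n / 2),
                         v_null = rnorm(n))
  split <- list(train = data$sample_id[1:(n / 2)], test = data$sample_id[(n / 2 + 1):n])
  rep1 <- balance_check(data, split, c("v_const", "v_sep", "v_null"))
  expect_equal(rep1$p_value[rep1$variable == "v_const"], 1)
  expect_true(rep1$flagged[rep1$variable == "v_const"])
  expect_lt(rep1$p_value[rep1$variable == "v_sep"], 1e-6)
  expect_gt(rep1$p_value[rep1$variable == "v_null"], 0.001)

  # identical train/test composition: duplicated toy cohort split into halves
  dup <- tibble::tibble(sample_id = sprintf("d%02d", 1:40),
                        v1 = rep(rnorm(20), 2), v2 = rep(sample(0:1, 20, TRUE), 2))
  split_dup <- list(train = dup$sample_id[1:20], test = dup$sample_id[21:40])
  rep2 <- balance_check(dup, split_dup, c("v1", "v2"))
  expect_true(all(rep2$p_value > 0.99))

  # ~5% of null variables significant at alpha = 0.05
  nv <- 106
  null_data <- tibble::tibble(sample_id = sprintf("n%03d", 1:n))
  for (j in seq_len(nv)) null_data[[paste0("x", j)]] <- rnorm(n)
  reps <- purrr::map(1:8, function(i) {
    sp <- make_splits(null_data$sample_id, sizes = c(100, 100), rounds = 1, seed = i)[[1]]
    sum(balance_check(null_data, sp, paste0("x", seq_len(nv)))$p_value < 0.05)
  })
  expect_lt(abs(mean(unlist(reps)) - 0.05 * nv), 4)
})

test_that("cross-validation sets are the best balanced, ties by index", {
  splits <- lapply(1:6, function(i) list(train = letters[1:3], test = letters[4:6]))
  reports <- lapply(c(5, 0, 3, 0, 1, 2), function(k) {
    tibble::tibble(p_value = c(rep(0.01, k), rep(0.5, 10 - k)))
  })
  sel <- select_cv_sets(splits, reports, m = 3)
  expect_identical(vapply(sel, attr, integer(1), "index"), c(2L, 4L, 5L))
  expect_identical(vapply(sel, attr, integer(1), "imbalance"), c(0L, 0L, 1L))
  expect_error(select_cv_sets(splits, reports, m = 10), "fewer")
})

test_that("decision tree separates, prunes noise to the root, zeroes unused importance", {
  td <- toy_data(shift = 4)
  dt <- fit_dt(td$x, td$y, seed = 64)
  expect_s3_class(dt, "recur_model")
  acc <- mean((predict_prob(dt, td$x) >= 0.5) == (td$y == 1))
  expect_gt(acc, 0.95)
  expect_gt(dt$importance[["g01"]], 0)
  used <- setdiff(names(dt$importance)[dt$importance > 0], "g01")
  # variables never split on have importance exactly 0
  frame_vars <- as.character(dt$fit$frame$var)
  expect_true(all(names(dt$importance)[dt$importance > 0] %in% frame_vars))
  expect_true(all(dt$importance[setdiff(names(dt$importance), frame_vars)] == 0))

  # pure noise with a majority class: cross-validated pruning collapses the
  # tree to the root and predictions are the constant majority rate
  withr::local_seed(1001)
  y0 <- sample(rep(0:1, times = c(200, 100)))
  x0 <- as.data.frame(matrix(rnorm(300 * 6), 300, 6))
  names(x0) <- sprintf("g%02d", 1:6)
  dt0 <- fit_dt(x0, y0, seed = 2001)
  expect_identical(nrow(dt0$fit$frame), 1L)            # pruned to the root
  expect_true(all(dt0$importance == 0))
  p0 <- predict_prob(dt0, x0)
  expect_identical(length(unique(p0)), 1L)             # majority-class constant
  expect_lt(p0[1], 0.5)

  expect_error(fit_dt(td$x, rep(1, nrow(td$x))), "single class")
})

test_that("ridge logistic regression matches glm and survives separation", {
  td <- toy_data(shift = 1.5, seed = 67)
  lr <- fit_lr(td$x, td$y)
  ref <- stats::glm(td$y ~ ., data = as.data.frame(scale(td$x)), family = stats::binomial())
  expect_equal(unname(lr$coefficients), unname(coef(ref)[-1]), tolerance = 0.01)
  expect_identical(names(which.max(lr$importance)), "g01")

  # all-null predictors: intercept near logit of prevalence, coefficients near 0
  null_d <- toy_data(shift = 0, seed = 68)
  y_skew <- rep(c(0L, 1L), times = c(90, 30))
  lr0 <- fit_lr(null_d$x[1:120, ], y_skew)
  expect_equal(unname(lr0$fit$beta[1]), stats::qlogis(0.25), tolerance = 0.35)
  expect_lt(max(abs(lr0$coefficients)), 0.5)

  # perfect separation: ridge keeps coefficients finite, training ACC 100
  sep <- data.frame(g01 = c(rnorm(30, -3), rnorm(30, 3)))
  ysep <- rep(c(0L, 1L), each = 30)
  lrs <- fit_lr(sep, ysep)
  expect_true(all(is.finite(lrs$coefficients)))
  expect_equal(mean((predict_prob(lrs, sep) >= 0.5) == (ysep == 1)), 1)
})

test_that("neural network learns separable data and is chance-level on null labels", {
  withr::local_seed(69)
  y <- rep(c(0L, 1L), each = 60)
  x <- as.data.frame(matrix(rnorm(120 * 4), 120, 4))
  names(x) <- sprintf("g%02d", 1:4)
  x$g01 <- ifelse(y == 1, runif(120, 1, 2), runif(120, -2, -1))  # separable margin
  ann <- fit_ann(x, y, f = 1, seed = 70)
  expect_equal(mean((predict_prob(ann, x) >= 0.5) == (y == 1)), 1)
  expect_identical(names(which.max(ann$importance)), "g01")
  expect_error(fit_ann(x, y, f = 0), "prevention fraction")

  withr::local_seed(71)
  null_d <- toy_data(shift = 0, seed = 72)
  y_rand <- sample(rep(c(0L, 1L), each = 60))
  ann0 <- fit_ann(null_d$x, y_rand, f = 0.8, seed = 73)
  x_new <- as.data.frame(matrix(rnorm(200 * 6), 200, 6))
  names(x_new) <- names(null_d$x)
  y_new <- sample(rep(c(0L, 1L), each = 100))
  auc <- getFromNamespace("auc_rank", "poolsig")(predict_prob(ann0, x_new), y_new)
  expect_lt(abs(auc - 0.5), 0.15)
})

test_that("over-training prevention shrinks the train-test accuracy gap on average", {
  gaps <- purrr::map_dfr(1:3, function(s) {
    withr::local_seed(80 + s)
    n <- 160; p <- 20
    y <- rep(c(0L, 1L), each = n / 2)
    x <- as.data.frame(matrix(rnorm(n * p), n, p))
    names(x) <- sprintf("g%02d", 1:p)
    x$g01 <- x$g01 + 0.8 * y                     # weak signal, mostly noise
    xt <- as.data.frame(matrix(rnorm(n * p), n, p)); names(xt) <- names(x)
    yt <- rep(c(0L, 1L), each = n / 2)
    xt$g01 <- xt$g01 + 0.8 * yt
    a80 <- evaluate_model(fit_ann(x, y, f = 0.8, seed = s), x, y, xt, yt)
    a100 <- evaluate_model(fit_ann(x, y, f = 1, seed = s), x, y, xt, yt)
    tibble::tibble(d80 = a80$d_acc, d100 = a100$d_acc)
  })
  expect_lt(mean(gaps$d80), mean(gaps$d100))
})

test_that("composite models use the tree-selected variables with a ranked fallback", {
  td <- toy_data(shift = 4, seed = 74)
  comp <- fit_composite(td$x, td$y, head = "lr", seed = 75)
  expect_identical(comp$kind, "DL")
  expect_true(all(comp$vars %in% comp$dt_selected))
  expect_true(all(comp$dt_selected %in% names(td$x)))

  # predictors carrying no split at all: the tree selects nothing and the
  # head falls back to the first fallback_k (ranked) columns
  flat <- as.data.frame(matrix(0, 80, 5))
  names(flat) <- sprintf("g%02d", 1:5)
  yflat <- rep(c(0L, 1L), each = 40)
  comp0 <- fit_composite(flat, yflat, head = "ann", f = 0.8,
                         fallback_k = 3, seed = 77)
  expect_identical(comp0$kind, "DA80")
  expect_identical(comp0$vars, names(flat)[1:3])       # fallback: first k columns

  # one perfectly separating variable -> univariate head
  one <- data.frame(g01 = c(rnorm(40, -4), rnorm(40, 4)),
                    g02 = rnorm(80))
  yone <- rep(c(0L, 1L), each = 40)
  comp1 <- fit_composite(one, yone, head = "lr", seed = 78)
  expect_identical(comp1$vars, "g01")
})

test_that("evaluation reports exact accuracy, AUC and extrapolation identities", {
  # linear model with identity standardization: prob = plogis(v - 0.5),
  # so the 0.5 probability threshold falls at v = 0.5
  fake <- structure(list(kind = "LR", vars = "v",
                         fit = list(beta = c(0, 1), center = 0.5, scale = 1),
                         importance = c(v = 1), f = NA_real_),
                    class = c("recur_lr", "recur_model"))
  train <- data.frame(v = c(0.9, 0.8, 0.2, 0.6))   # 3 of 4 correct at 0.5
  test <- data.frame(v = c(0.9, 0.8, 0.1, 0.2))
  ev <- evaluate_model(fake, train, c(1, 1, 0, 0), test, c(1, 1, 0, 0))
  expect_equal(ev$acc_train, 75)
  expect_equal(ev$acc_test, 100)
  expect_equal(ev$d_acc, ev$acc_train - ev$acc_test)
  expect_equal(ev$auc_test, 100)                      # perfect ordering
  expect_equal(ev$d_auc, ev$auc_train - ev$auc_test)
})

test_that("rank-formulation AUC equals trapezoidal ROC integration", {
  auc_rank <- getFromNamespace("auc_rank", "poolsig")
  withr::local_seed(79)
  for (i in 1:10) {
    sc <- rnorm(60)
    lab <- rbinom(60, 1, 0.4)
    if (length(unique(lab)) < 2) next
    r <- pROC::roc(lab, sc, quiet = TRUE, direction = "<")
    expect_equal(auc_rank(sc, lab), as.numeric(pROC::auc(r)), tolerance = 1e-10)
  }
})

test_that("importance integration is a Borda mean rank with documented ties", {
  imp <- tibble::tibble(
    model = rep(c("DT", "LR", "ANN80", "ANN100"), each = 3),
    variable = rep(c("a", "b", "c"), 4),
    importance = c(3, 2, 1, 3, 2, 1, 3, 2, 1, 3, 2, 1))
  out <- integrate_importance(imp)
  expect_identical(out$variable[order(out$integrated_rank)], c("a", "b", "c"))
  expect_identical(sort(out$integrated_rank), 1:3)

  # reversing every model ranking reverses the integration
  rev_imp <- dplyr::mutate(imp, importance = -importance)
  out_rev <- integrate_importance(rev_imp)
  expect_identical(out_rev$variable[order(out_rev$integrated_rank)], c("c", "b", "a"))

  # gene ranked first in 3 of 4 models wins when the dissenters disagree uniformly
  imp2 <- tibble::tibble(
    model = rep(c("m1", "m2", "m3", "m4"), each = 3),
    variable = rep(c("lmcd1", "x", "y"), 4),
    importance = c(9, 5, 1, 9, 5, 1, 9, 5, 1, 1, 9, 5))
  out2 <- integrate_importance(imp2)
  expect_identical(out2$variable[out2$integrated_rank == 1], "lmcd1")
})

test_that("a single-class test set yields missing AUC with a flag", {
  td <- toy_data(shift = 2, seed = 620)
  lr <- fit_lr(td$x, td$y)
  ev <- evaluate_model(lr, td$x, td$y, td$x[td$y == 1, ], td$y[td$y == 1])
  expect_true(is.na(ev$auc_test))
  expect_true(ev$auc_flag)
  expect_false(is.na(ev$acc_test))
})
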