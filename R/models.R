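#' Random train/test partitions
#'
#' Draws `rounds` independent uniform partitions of the subjects into a
#' training and a test set. The default sizes follow the 370/387 proportions
#' of a 757-subject pooled cohort, scaled to the available `n`.
#'
#' @param ids Character vector of subject ids.
#' @param sizes Integer vector `c(n_train, n_test)`; must sum to
#'   `length(ids)`. `NULL` scales the 370/387 split to `n`.
#' @param rounds Number of partitions.
#' @param seed Integer seed.
#' @return A list of `rounds` lists with elements `train` and `test`.
#' @export
make_splits <- function(ids, sizes = NULL, rounds = 400L, seed = 1L) {
  n <- length(ids)
  if (is.null(sizes)) {
    n_train <- round(n * 370 / 757)
    sizes <- c(n_train, n - n_train)
  }
  if (sum(sizes) != n) abort("split sizes must sum to the number of subjects")
  if (any(sizes < 1L)) abort("both the training and the test set must be non-empty")
  withr::local_seed(seed)
  lapply(seq_len(rounds), function(i) {
    tr <- sample(ids, sizes[1L])
    list(train = tr, test = setdiff(ids, tr))
  })
}

#' Train-vs-test balance check
#'
#' Tests every variable for a difference between the training and test sets:
#' continuous variables by the Mann-Whitney U test, categorical variables by
#' the chi-square test. Degenerate (constant) variables are recorded with
#' p = 1 and flagged.
#'
#' @param data Tibble of subjects (rows) with a `sample_id` column.
#' @param split One element of [make_splits()].
#' @param variables Character vector of column names to test.
#' @return A tibble with columns `variable`, `type`, `p_value`, `flagged`.
#' @export
balance_check <- function(data, split, variables) {
  miss <- setdiff(variables, names(data))
  if (length(miss)) abort(paste0("variables absent from data: ", paste(head(miss, 5), collapse = ", ")))
  in_train <- data$sample_id %in% split$train
  purrr::map_dfr(variables, function(v) {
    x <- data[[v]]
    constant <- length(unique(x[!is.na(x)])) < 2L
    if (constant) {
      return(tibble::tibble(variable = v, type = "degenerate", p_value = 1, flagged = TRUE))
    }
    if (is.numeric(x) && length(unique(x)) > 5L) {
      p <- mannwhitney_p(x[in_train], x[!in_train])
      tibble::tibble(variable = v, type = "continuous", p_value = p, flagged = p < 0.001)
    } else {
      tab <- table(factor(in_train, levels = c(TRUE, FALSE)), x)
      p <- tryCatch(suppressWarnings(chisq.test(tab, correct = FALSE)$p.value),
                    error = function(e) 1)
      if (is.na(p)) p <- 1
      tibble::tibble(variable = v, type = "categorical", p_value = p, flagged = p < 0.001)
    }
  })
}

#' Select the best-balanced splits as cross-validation sets
#'
#' Orders candidate splits by the number of variables showing a significant
#' train-vs-test difference (ascending, ties by split index) and returns the
#' first `m`.
#'
#' @param splits List of splits from [make_splits()].
#' @param reports List of [balance_check()] reports, one per split.
#' @param m Number of cross-validation sets to keep.
#' @param alpha Significance level defining an imbalanced variable.
#' @return The selected splits, each annotated with its imbalance count
#'   (attribute `imbalance`) and original index (attribute `index`).
#' @export
select_cv_sets <- function(splits, reports, m = 20L, alpha = 0.05) {
  if (length(splits) < m) abort("fewer candidate splits than requested cross-validation sets")
  counts <- vapply(reports, function(r) sum(r$p_value < alpha), integer(1))
  ord <- order(counts, seq_along(counts))[seq_len(m)]
  out <- splits[ord]
  for (i in seq_along(out)) {
    attr(out[[i]], "imbalance") <- counts[ord[i]]
    attr(out[[i]], "index") <- ord[i]
  }
  out
}

new_recur_model <- function(kind, fit, vars, importance, f = NA_real_, extra = list()) {
  structure(c(list(kind = kind, fit = fit, vars = vars,
                   importance = importance, f = f), extra),
            class = c(paste0("recur_", tolower(kind)), "recur_model"))
}

check_two_classes <- function(y) {
  if (length(unique(y)) < 2L) abort("training labels contain a single class")
}

#' Fit a classification decision tree
#'
#' CART-style binary recursive partitioning (Gini impurity, minimum leaf size
#' 5) with cost-complexity pruning chosen by internal 10-fold cross-validation
#' on the training set (1-SE rule). Variable importance is the total impurity
#' decrease over the tree's primary splits; variables the pruned tree never
#' uses score exactly 0.
#'
#' @param x Data frame of predictors.
#' @param y 0/1 outcome vector.
#' @param min_leaf Minimum leaf size.
#' @param xval Internal cross-validation folds for pruning.
#' @param seed Seed for the fold assignment.
#' @return A `recur_model` of kind `"DT"`.
#' @export
fit_dt <- function(x, y, min_leaf = 5L, xval = 10L, seed = 1L) {
  check_two_classes(y)
  df <- data.frame(x, check.names = FALSE)
  df$.y <- factor(y, levels = c(0, 1))
  withr::local_seed(seed)
  fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                      parms = list(split = "gini"),
                      control = rpart::rpart.control(minbucket = min_leaf, cp = 0,
                                                     xval = xval))
  cp_tab <- fit$cptable
  best <- which.min(cp_tab[, "xerror"])
  thresh <- cp_tab[best, "xerror"] + cp_tab[best, "xstd"]
  chosen <- which(cp_tab[, "xerror"] <= thresh)[1L]
  pruned <- rpart::prune(fit, cp = cp_tab[chosen, "CP"] * 1.0000001)
  imp <- primary_split_importance(pruned, colnames(x))
  new_recur_model("DT", pruned, colnames(x), imp)
}

# total Gini improvement of the primary split at each internal node
primary_split_importance <- function(fit, vars) {
  imp <- setNames(numeric(length(vars)), vars)
  if (is.null(fit$splits) || nrow(fit$frame) == 1L) return(imp)
  frame <- fit$frame
  splits <- fit$splits
  row_i <- 1L
  for (node in seq_len(nrow(frame))) {
    if (frame$var[node] == "<leaf>") next
    n_rows <- 1L + frame$ncompete[node] + frame$nsurrogate[node]
    v <- as.character(frame$var[node])
    imp[v] <- imp[v] + splits[row_i, "improve"] * frame$n[node]
    row_i <- row_i + n_rows
  }
  imp
}

#' @export
predict_prob <- function(model, newdata) UseMethod("predict_prob")

#' @export
predict_prob.recur_dt <- function(model, newdata) {
  unname(predict(model$fit, data.frame(newdata, check.names = FALSE), type = "prob")[, "1"])
}

#' Fit a ridge-penalized logistic regression
#'
#' Maximum-likelihood logistic fit on standardized inputs with a small ridge
#' penalty guarding against complete separation; iteratively reweighted least
#' squares, intercept unpenalized. Importance is the absolute coefficient on
#' the standardized scale.
#'
#' @param x Data frame or matrix of predictors.
#' @param y 0/1 outcome vector.
#' @param lambda Ridge penalty.
#' @param max_iter Maximum IRLS iterations.
#' @return A `recur_model` of kind `"LR"`.
#' @export
fit_lr <- function(x, y, lambda = 1e-4, max_iter = 200L) {
  check_two_classes(y)
  xm <- as.matrix(x)
  ctr <- colMeans(xm)
  scl <- apply(xm, 2L, sd)
  scl[scl == 0] <- 1
  xs <- sweep(sweep(xm, 2L, ctr), 2L, scl, "/")
  n <- nrow(xs); p <- ncol(xs)
  X <- cbind(`(Intercept)` = 1, xs)
  pen <- diag(c(0, rep(lambda, p)), p + 1L)
  beta <- numeric(p + 1L)
  beta[1L] <- stats::qlogis(mean(y))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    wdiag <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(X, y - mu)) - n * drop(pen %*% beta)
    hess <- crossprod(X * wdiag, X) + n * pen
    delta <- solve(hess, grad)
    beta <- beta + delta
    if (max(abs(delta)) < 1e-10) break
  }
  if (it == max_iter && max(abs(delta)) >= 1e-6) {
    abort(sprintf("logistic regression did not converge (max step %.3g after %d iterations)",
                  max(abs(delta)), max_iter))
  }
  coefs <- setNames(beta[-1L], colnames(xm))
  new_recur_model("LR", list(beta = beta, center = ctr, scale = scl),
                  colnames(xm), abs(coefs), extra = list(coefficients = coefs))
}

#' @export
predict_prob.recur_lr <- function(model, newdata) {
  xm <- as.matrix(newdata)[, model$vars, drop = FALSE]
  xs <- sweep(sweep(xm, 2L, model$fit$center), 2L, model$fit$scale, "/")
  drop(stats::plogis(model$fit$beta[1L] + xs %*% model$fit$beta[-1L]))
}

# ---- single-hidden-layer perceptron -----------------------------------------

mlp_forward <- function(W, X) {
  h <- stats::plogis(cbind(1, X) %*% W$w1)
  p <- stats::plogis(drop(cbind(1, h) %*% W$w2))
  list(h = h, p = p)
}

mlp_fit <- function(X, y, hidden, epochs, lr, momentum) {
  # full-batch gradient descent on cross-entropy; returns weight history hook
  p <- ncol(X)
  W <- list(w1 = matrix(runif((p + 1) * hidden, -0.5, 0.5) / sqrt(p + 1), p + 1, hidden),
            w2 = runif(hidden + 1, -0.5, 0.5) / sqrt(hidden + 1))
  v1 <- W$w1 * 0; v2 <- W$w2 * 0
  n <- nrow(X)
  step <- function(W) {
    fw <- mlp_forward(W, X)
    err <- fw$p - y                                    # d(loss)/d(logit)
    g2 <- drop(crossprod(cbind(1, fw$h), err)) / n
    dh <- outer(err, W$w2[-1]) * fw$h * (1 - fw$h)
    g1 <- crossprod(cbind(1, X), dh) / n
    list(g1 = g1, g2 = g2)
  }
  list(W = W, v1 = v1, v2 = v2, step = step)
}

#' Fit a feed-forward neural network with over-training prevention
#'
#' Single hidden layer, logistic activations, trained by full-batch gradient
#' descent (momentum) on cross-entropy. With prevention fraction `f < 1`, a
#' random fraction `f` of the training rows is used for weight updates and the
#' remaining `1 - f` as an internal validation set: training stops at the
#' epoch with the best internal-validation accuracy (patience `patience`
#' epochs) and those weights are returned. With `f = 1` the full epoch budget
#' is used with no internal validation. Importance is the mean decrease in
#' training accuracy under within-column permutation.
#'
#' @param x Data frame or matrix of predictors.
#' @param y 0/1 outcome vector.
#' @param f Over-training-prevention fraction in (0, 1].
#' @param hidden Hidden units.
#' @param epochs Epoch budget.
#' @param lr Learning rate.
#' @param momentum Momentum coefficient.
#' @param patience Early-stopping patience (epochs without improvement).
#' @param n_perm Permutations per variable for the importance score.
#' @param seed Integer seed (weight init, internal holdout, permutations).
#' @return A `recur_model` of kind `"ANN80"` (f = 0.8), `"ANN100"` (f = 1) or
#'   `"ANN<100f>"` in general.
#' @export
fit_ann <- function(x, y, f = 0.8, hidden = 10L, epochs = 300L, lr = 0.5,
                    momentum = 0.9, patience = 20L, n_perm = 10L, seed = 1L) {
  if (f <= 0 || f > 1) abort("prevention fraction f must be in (0, 1]")
  check_two_classes(y)
  xm <- as.matrix(x)
  ctr <- colMeans(xm); scl <- apply(xm, 2L, sd); scl[scl == 0] <- 1
  xs <- sweep(sweep(xm, 2L, ctr), 2L, scl, "/")
  n <- nrow(xs)
  withr::local_seed(seed)

  if (f < 1) {
    n_fit <- max(2L, floor(f * n))
    idx_fit <- sample.int(n, n_fit)
    idx_val <- setdiff(seq_len(n), idx_fit)
    if (length(idx_val) == 0L || length(unique(y[idx_fit])) < 2L) {
      idx_fit <- seq_len(n); idx_val <- integer(0)
    }
  } else {
    idx_fit <- seq_len(n); idx_val <- integer(0)
  }
  st <- mlp_fit(xs[idx_fit, , drop = FALSE], y[idx_fit], hidden, epochs, lr, momentum)
  W <- st$W; v1 <- st$v1; v2 <- st$v2
  best <- list(W = W, acc = -Inf, epoch = 0L)
  stale <- 0L
  for (ep in seq_len(epochs)) {
    g <- st$step(W)
    v1 <- momentum * v1 - lr * g$g1
    v2 <- momentum * v2 - lr * g$g2
    W$w1 <- W$w1 + v1
    W$w2 <- W$w2 + v2
    if (length(idx_val)) {
      pv <- mlp_forward(W, xs[idx_val, , drop = FALSE])$p
      acc <- mean((pv >= 0.5) == (y[idx_val] == 1))
      if (acc > best$acc + 1e-12) {
        best <- list(W = W, acc = acc, epoch = ep)
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= patience) break
      }
    }
  }
  if (length(idx_val)) W <- best$W

  kind <- paste0("ANN", round(100 * f))
  model <- new_recur_model(kind, list(W = W, center = ctr, scale = scl),
                           colnames(xm), setNames(rep(0, ncol(xm)), colnames(xm)),
                           f = f)
  class(model) <- c("recur_ann", "recur_model")

  base_acc <- mean((mlp_forward(W, xs)$p >= 0.5) == (y == 1))
  imp <- vapply(seq_len(ncol(xs)), function(j) {
    drops <- vapply(seq_len(n_perm), function(r) {
      xp <- xs
      xp[, j] <- xp[sample.int(n), j]
      base_acc - mean((mlp_forward(W, xp)$p >= 0.5) == (y == 1))
    }, numeric(1))
    mean(drops)
  }, numeric(1))
  model$importance <- setNames(pmax(imp, 0), colnames(xm))
  model
}

#' @export
predict_prob.recur_ann <- function(model, newdata) {
  xm <- as.matrix(newdata)[, model$vars, drop = FALSE]
  xs <- sweep(sweep(xm, 2L, model$fit$center), 2L, model$fit$scale, "/")
  mlp_forward(model$fit$W, xs)$p
}

#' Fit a composite model (decision tree as variable selector)
#'
#' Fits a decision tree, keeps the variables with positive importance and
#' passes them to a logistic-regression or neural-network head: kinds `DL`
#' (head LR), `DA80` (head ANN, f = 0.8) and `DA100` (head ANN, f = 1). If the
#' pruned tree selects no variable, the first `fallback_k` columns of `x`
#' (assumed ranked by relevance) are used instead.
#'
#' @param x Data frame of predictors, columns in ranked order.
#' @param y 0/1 outcome vector.
#' @param head `"lr"` or `"ann"`.
#' @param f Prevention fraction for an ANN head.
#' @param fallback_k Fallback variable count when the tree selects none.
#' @param seed Integer seed.
#' @param ... Passed to the head fitter.
#' @return A `recur_model` whose `vars` are the tree-selected subset.
#' @export
fit_composite <- function(x, y, head = c("lr", "ann"), f = 1, fallback_k = 10L,
                          seed = 1L, ...) {
  head <- match.arg(head)
  dt <- fit_dt(x, y, seed = seed)
  sel <- names(dt$importance)[dt$importance > 0]
  if (length(sel) == 0L) sel <- colnames(x)[seq_len(min(fallback_k, ncol(x)))]
  xs <- x[, sel, drop = FALSE]
  model <- if (head == "lr") fit_lr(xs, y, ...) else fit_ann(xs, y, f = f, seed = seed, ...)
  kind <- if (head == "lr") "DL" else paste0("DA", round(100 * f))
  model$kind <- kind
  model$dt_selected <- sel
  model$dt <- dt
  model
}

# rank-based (Mann-Whitney) AUC with midranks; returns [0, 1] or NA for a
# single-class label vector
auc_rank <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a fitted classifier on training and test sets
#'
#' Accuracy at probability threshold 0.5 and AUC by the rank (Mann-Whitney)
#' formulation, both as percentages, plus the extrapolation differences
#' `d_acc = acc_train - acc_test` and `d_auc = auc_train - auc_test`. A
#' single-class test set gives missing AUC with `auc_flag = TRUE`.
#'
#' @param model A `recur_model`.
#' @param train_x,test_x Predictor tables.
#' @param train_y,test_y 0/1 outcomes.
#' @return A one-row tibble (an EvalReport).
#' @export
evaluate_model <- function(model, train_x, train_y, test_x, test_y) {
  p_tr <- predict_prob(model, train_x)
  p_te <- predict_prob(model, test_x)
  acc_tr <- 100 * mean((p_tr >= 0.5) == (train_y == 1))
  acc_te <- 100 * mean((p_te >= 0.5) == (test_y == 1))
  auc_tr <- 100 * auc_rank(p_tr, train_y)
  auc_te <- 100 * auc_rank(p_te, test_y)
  tibble::tibble(
    model = model$kind,
    acc_train = acc_tr, acc_test = acc_te, d_acc = acc_tr - acc_te,
    auc_train = auc_tr, auc_test = auc_te, d_auc = auc_tr - auc_te,
    auc_flag = is.na(auc_tr) || is.na(auc_te)
  )
}

#' Integrate variable importance across models
#'
#' Ranks variables within each model (1 = most important) and integrates by
#' mean rank (Borda). Ties in the integrated score are broken by the
#' trimmed-mean p-value from the gene ranking when supplied, then by variable
#' name. Variables missing from a model are assigned that model's worst rank
#' and flagged.
#'
#' @param importances Long tibble with columns `model`, `variable`,
#'   `importance`.
#' @param tie_break Optional tibble with columns `gene_id`, `trimmed_p`.
#' @return A tibble with `variable`, `mean_rank`, `integrated_rank` (a
#'   permutation of 1..V, 1 = most important) and `missing_from` count.
#' @export
integrate_importance <- function(importances, tie_break = NULL) {
  vars <- unique(importances$variable)
  models <- unique(importances$model)
  rank_tbl <- purrr::map_dfr(models, function(mo) {
    sub <- importances[importances$model == mo, ]
    r <- rank(-sub$importance, ties.method = "average")
    full <- setNames(rep(length(vars), length(vars)), vars)  # worst rank default
    full[sub$variable] <- r
    tibble::tibble(model = mo, variable = vars, model_rank = unname(full[vars]),
                   missing = !(vars %in% sub$variable))
  })
  agg <- rank_tbl |>
    dplyr::group_by(.data$variable) |>
    dplyr::summarise(mean_rank = mean(.data$model_rank),
                     missing_from = sum(.data$missing), .groups = "drop")
  if (!is.null(tie_break)) {
    agg <- dplyr::left_join(agg, tie_break[, c("gene_id", "trimmed_p")],
                            by = c(variable = "gene_id"))
  } else {
    agg$trimmed_p <- NA_real_
  }
  agg <- agg[order(agg$mean_rank, agg$trimmed_p, agg$variable), ]
  agg$integrated_rank <- seq_len(nrow(agg))
  if (any(agg$missing_from > 0)) warn("some variables were missing from at least one model; assigned worst rank")
  agg
}

model_fitter <- function(kind) {
  switch(toupper(kind),
         DT = function(x, y, seed) fit_dt(x, y, seed = seed),
         LR = function(x, y, seed) fit_lr(x, y),
         ANN80 = function(x, y, seed) fit_ann(x, y, f = 0.8, seed = seed),
         ANN100 = function(x, y, seed) fit_ann(x, y, f = 1, seed = seed),
         DL = function(x, y, seed) fit_composite(x, y, head = "lr", seed = seed),
         DA80 = function(x, y, seed) fit_composite(x, y, head = "ann", f = 0.8, seed = seed),
         DA100 = function(x, y, seed) fit_composite(x, y, head = "ann", f = 1, seed = seed),
         abort(paste0("unknown model kind: ", kind)))
}

#' Fit and evaluate the classifier suite over cross-validation sets
#'
#' Fits the requested single (DT, LR, ANN80, ANN100) and composite (DL, DA80,
#' DA100) models on each cross-validation split using the supplied gene
#' profile, evaluates each on its train/test pair, and averages the reports
#' per model. Importances of the single models are averaged across splits and
#' integrated by mean rank.
#'
#' @param data Tibble of subjects with `sample_id`, outcome column
#'   `relapse5`, and one column per gene.
#' @param cv_sets List of splits (see [select_cv_sets()]).
#' @param genes Character vector of gene columns (ranked order).
#' @param models Character vector of model kinds.
#' @param tie_break Optional ranked-genes tibble for integration tie breaks.
#' @param seed Integer seed.
#' @return A list of class `model_suite` with `evaluations` (per set x model),
#'   `summary` (per-model means), `importance` (long, single models) and
#'   `integrated` (see [integrate_importance()]).
#' @export
fit_model_suite <- function(data, cv_sets, genes,
                            models = c("dt", "lr", "ann80", "ann100", "dl", "da80", "da100"),
                            tie_break = NULL, seed = 1L) {
  models <- toupper(models)
  evals <- list(); imps <- list()
  for (s in seq_along(cv_sets)) {
    sp <- cv_sets[[s]]
    tr <- data[data$sample_id %in% sp$train, ]
    te <- data[data$sample_id %in% sp$test, ]
    xtr <- tr[, genes, drop = FALSE]; xte <- te[, genes, drop = FALSE]
    for (mo in models) {
      fitter <- model_fitter(mo)
      fit <- fitter(xtr, tr$relapse5, seed = seed + 31L * s)
      ev <- evaluate_model(fit, xtr, tr$relapse5, xte, te$relapse5)
      ev$cv_set <- s
      evals[[length(evals) + 1L]] <- ev
      if (mo %in% c("DT", "LR", "ANN80", "ANN100")) {
        imps[[length(imps) + 1L]] <- tibble::tibble(
          model = mo, cv_set = s,
          variable = names(fit$importance), importance = unname(fit$importance))
      }
    }
  }
  evaluations <- dplyr::bind_rows(evals)
  summary <- evaluations |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(dplyr::across(c("acc_train", "acc_test", "d_acc",
                                     "auc_train", "auc_test", "d_auc"),
                                   ~ mean(.x, na.rm = TRUE)), .groups = "drop")
  importance <- dplyr::bind_rows(imps) |>
    dplyr::group_by(.data$model, .data$variable) |>
    dplyr::summarise(importance = mean(.data$importance), .groups = "drop")
  integrated <- if (nrow(importance)) integrate_importance(importance, tie_break) else NULL
  structure(list(evaluations = evaluations, summary = summary,
                 importance = importance, integrated = integrated),
            class = "model_suite")
}

#' @export
print.model_suite <- function(x, ...) {
  cat("<model_suite> mean performance over", length(unique(x$evaluations$cv_set)), "cross-validation sets\n")
  print(x$summary)
  invisible(x)
}
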