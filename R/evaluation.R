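#' Stratified k-fold cross-validation split plan
#'
#' Builds k folds stratified by class. Within each fold, the held-out fifth
#' is further split (stratified) into validation and test sets with ratio
#' `val_fraction : (1 - val_fraction)`; the remaining samples form the
#' training set.
#'
#' @param labels class labels, one per sample; every class needs >= k
#'   members.
#' @param k number of folds.
#' @param val_fraction fraction of each held-out fold used for validation
#'   (the rest is the final test set). Default 0.6 (a 60:40 split).
#' @param seed RNG seed; the plan is deterministic given the seed.
#' @return an object of class `split_plan`: a list of `k` folds, each with
#'   integer index vectors `train`, `validation`, `test`.
#' @export
stratified_cv_split <- function(labels, k = 5L, val_fraction = 0.6, seed = 1L) {
  y <- factor(labels)
  counts <- table(y)
  small <- names(counts)[counts < k]
  if (length(small) > 0) {
    stop(sprintf("class(es) with fewer than k=%d members: %s",
                 k, paste(small, collapse = ", ")))
  }
  set.seed(seed)
  fold_of <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold_of[idx] <- rep_len(seq_len(k), length(idx))
  }
  plan <- lapply(seq_len(k), function(f) {
    held <- which(fold_of == f)
    by_class <- lapply(levels(y), function(cl) held[y[held] == cl])
    m_c <- lengths(by_class)
    # largest-remainder allocation: hit the global 60:40 count exactly while
    # staying within +-1 of proportionality per class
    quota <- val_fraction * m_c
    n_val <- floor(quota)
    leftover <- round(val_fraction * length(held)) - sum(n_val)
    if (leftover > 0) {
      extra <- order(quota - n_val, decreasing = TRUE)[seq_len(leftover)]
      n_val[extra] <- n_val[extra] + 1L
    }
    # keep at least one validation and one test sample per class when possible
    n_val <- ifelse(m_c >= 2, pmin(pmax(n_val, 1L), m_c - 1L), n_val)
    val <- unlist(lapply(seq_along(by_class), function(i) {
      by_class[[i]][seq_len(n_val[i])]
    }))
    list(train = which(fold_of != f),
         validation = sort(val),
         test = sort(setdiff(held, val)))
  })
  structure(plan, class = "split_plan", seed = seed, k = k,
            val_fraction = val_fraction)
}

#' @export
print.split_plan <- function(x, ...) {
  sizes <- vapply(x, function(f) {
    c(length(f$train), length(f$validation), length(f$test))
  }, integer(3))
  cat(sprintf("split_plan: %d folds (train/val/test sizes below)\n", length(x)))
  print(t(sizes))
  invisible(x)
}

#' Multiclass confusion matrix
#'
#' @param y_true,y_pred label vectors of equal length, values in
#'   `0..n_classes-1` (or factors over the same levels).
#' @param n_classes number of classes K.
#' @return K x K count matrix; rows = true class, columns = predicted class.
#' @export
confusion_matrix <- function(y_true, y_pred, n_classes) {
  if (length(y_true) == 0) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  t_i <- as.integer(y_true)
  p_i <- as.integer(y_pred)
  if (is.factor(y_true)) t_i <- t_i - 1L
  if (is.factor(y_pred)) p_i <- p_i - 1L
  if (any(t_i < 0 | t_i >= n_classes | p_i < 0 | p_i >= n_classes)) {
    stop("labels out of range [0, n_classes)")
  }
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(t_i)) {
    cm[t_i[i] + 1L, p_i[i] + 1L] <- cm[t_i[i] + 1L, p_i[i] + 1L] + 1L
  }
  dimnames(cm) <- list(true = 0:(n_classes - 1), pred = 0:(n_classes - 1))
  cm
}

#' Multiclass classification metric suite
#'
#' Computes accuracy, balanced accuracy, macro/micro/weighted F1, the
#' Gorodkin K-category Matthews correlation coefficient, macro precision and
#' macro recall from the confusion matrix. Per-class precision, recall or F1
#' that are 0/0 follow the 0-convention with a warning.
#'
#' @inheritParams confusion_matrix
#' @return an object of class `metric_report` (a list of scalar metrics plus
#'   the `confusion` matrix).
#' @export
compute_metrics <- function(y_true, y_pred, n_classes) {
  cm <- confusion_matrix(y_true, y_pred, n_classes)
  s <- sum(cm)
  correct <- sum(diag(cm))
  t_k <- rowSums(cm) # true counts per class
  p_k <- colSums(cm) # predicted counts per class

  tp <- diag(cm)
  precision <- ifelse(p_k > 0, tp / p_k, 0)
  recall <- ifelse(t_k > 0, tp / t_k, 0)
  if (any(p_k == 0) || any(t_k == 0)) {
    warning("class(es) with no predictions or no truth: 0-convention applied")
  }
  denom <- precision + recall
  f1 <- ifelse(denom > 0, 2 * precision * recall / denom, 0)

  support <- t_k / s
  present <- t_k > 0
  mcc_denom <- sqrt((s^2 - sum(p_k^2)) * (s^2 - sum(t_k^2)))
  mcc <- if (mcc_denom == 0) 0 else (correct * s - sum(p_k * t_k)) / mcc_denom

  structure(list(
    accuracy = correct / s,
    balanced_accuracy = mean(recall[present]),
    f1_macro = mean(f1),
    f1_micro = correct / s, # pooled TP/(TP+FP) = accuracy for single-label
    f1_weighted = sum(support * f1),
    mcc = mcc,
    precision_macro = mean(precision),
    recall_macro = mean(recall[present]),
    confusion = cm
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(paste0(
    "accuracy %.4f | balanced acc %.4f | F1 macro %.4f | F1 micro %.4f | ",
    "F1 weighted %.4f\nMCC %.4f | precision macro %.4f | recall macro %.4f\n"),
    x$accuracy, x$balanced_accuracy, x$f1_macro, x$f1_micro, x$f1_weighted,
    x$mcc, x$precision_macro, x$recall_macro))
  invisible(x)
}

#' Row-normalize a confusion matrix
#'
#' Each row (true class) is divided by its total; zero rows are left at zero
#' with a warning.
#'
#' @param confusion K x K count matrix.
#' @return K x K matrix of row proportions.
#' @export
normalized_confusion <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (any(confusion < 0)) stop("confusion counts must be non-negative")
  rs <- rowSums(confusion)
  if (any(rs == 0)) warning("zero row(s) in confusion matrix left at zero")
  out <- confusion
  nz <- rs > 0
  out[nz, ] <- confusion[nz, , drop = FALSE] / rs[nz]
  out
}

#' L2-regularized multinomial logistic regression baseline
#'
#' The classical baseline: ridge-penalized multinomial logistic regression on
#' flattened per-run features. The regularization strength is chosen from a
#' grid by k-fold cross-validated accuracy on the training portion; the
#' reported accuracy comes from the untouched test split.
#'
#' @param x run-level feature matrix (rows = runs).
#' @param y class labels, one per run.
#' @param lambda_grid candidate ridge penalties.
#' @param k folds for the internal CV.
#' @param test_fraction fraction of runs held out (stratified) for the final
#'   test.
#' @param seed RNG seed.
#' @return list with `test_accuracy`, `chosen_lambda`, `cv_accuracy` (per
#'   grid value) and the fitted glmnet model.
#' @export
logistic_baseline <- function(x, y, lambda_grid = 10^seq(-4, 2, length.out = 13),
                              k = 5L, test_fraction = 0.2, seed = 1L) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("non-finite features")
  if (length(lambda_grid) == 0) stop("empty regularization grid")
  y <- factor(y)
  set.seed(seed)
  test <- integer(0)
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    test <- c(test, idx[seq_len(max(1L, round(test_fraction * length(idx))))])
  }
  train <- setdiff(seq_along(y), test)

  # internal CV over the grid, accuracy-scored
  folds <- integer(length(train))
  for (cl in levels(y)) {
    pos <- which(y[train] == cl)
    folds[sample(pos)] <- rep_len(seq_len(k), length(pos))
  }
  lambda_sorted <- sort(lambda_grid, decreasing = TRUE)
  cv_acc <- rep(0, length(lambda_sorted))
  for (f in seq_len(k)) {
    tr <- train[folds != f]
    va <- train[folds == f]
    fit <- glmnet::glmnet(x[tr, , drop = FALSE], y[tr], family = "multinomial",
                          alpha = 0, lambda = lambda_sorted)
    pred <- predict(fit, x[va, , drop = FALSE], type = "class",
                    s = lambda_sorted)
    cv_acc <- cv_acc + colMeans(pred == as.character(y[va]))
  }
  cv_acc <- cv_acc / k
  chosen <- lambda_sorted[which.max(cv_acc)]

  final <- glmnet::glmnet(x[train, , drop = FALSE], y[train],
                          family = "multinomial", alpha = 0,
                          lambda = lambda_sorted)
  pred_test <- predict(final, x[test, , drop = FALSE], type = "class",
                       s = chosen)
  list(
    test_accuracy = mean(pred_test == as.character(y[test])),
    chosen_lambda = chosen,
    cv_accuracy = stats::setNames(cv_acc, signif(lambda_sorted, 4)),
    model = final,
    test_indices = sort(test)
  )
}

#' Run-level pooled features for the logistic baseline
#'
#' @param runs list of runs from [simulate_dataset()].
#' @param mode `"mean_node_features"` pools the nine per-node statistical
#'   features by their node mean and standard deviation;
#'   `"connectivity"` uses the upper triangle of the Fisher-z connectivity.
#' @return matrix with one row per run.
#' @export
run_feature_table <- function(runs, mode = c("connectivity",
                                             "mean_node_features")) {
  mode <- match.arg(mode)
  rows <- lapply(runs, function(r) {
    if (mode == "connectivity") {
      z <- fisher_z(pearson_connectivity(r$series))
      z[upper.tri(z)]
    } else {
      f <- node_stat_features(r$series)
      c(colMeans(f), apply(f, 2, stats::sd))
    }
  })
  do.call(rbind, rows)
}

#' Nearest-centroid connectivity classifier MCC for one run of the harness
#'
#' A fast classifier used to exercise the repeated-run comparison harness
#' cheaply. Each invocation is one independent "training run": a random
#' subset of subjects is drawn (without replacement, so no run can appear on
#' both sides of the split), a random subset of connectivity features is
#' drawn (emulating the run-to-run stochasticity of a trained network, which
#' is what varies across the repeated runs of the protocol), runs are split
#' in half (stratified by class) into train/test, each class is summarized
#' by the centroid of its Fisher-z connectivity vectors, test runs are
#' assigned to the nearest centroid, and the multiclass MCC on the test half
#' is returned.
#'
#' @param runs list of runs from [simulate_dataset()].
#' @param seed per-run seed (controls subject subset, feature subset and
#'   split).
#' @param subject_fraction fraction of subjects used per run.
#' @param feature_fraction fraction of connectivity features used per run.
#' @return scalar MCC.
#' @export
connectivity_centroid_mcc <- function(runs, seed = 1L,
                                      subject_fraction = 0.7,
                                      feature_fraction = 0.3) {
  set.seed(seed)
  subjects <- unique(run_labels(runs, "subject"))
  draw <- sample(subjects, max(2L, floor(subject_fraction * length(subjects))))
  runs <- runs[run_labels(runs, "subject") %in% draw]
  y <- run_labels(runs, "class")
  x <- run_feature_table(runs, "connectivity")
  keep <- sample(ncol(x), max(2L, floor(feature_fraction * ncol(x))))
  x <- x[, keep, drop = FALSE]
  test <- integer(0)
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    test <- c(test, idx[seq_len(max(1L, floor(length(idx) / 2)))])
  }
  train <- setdiff(seq_along(y), test)
  classes <- sort(unique(y[train]))
  centroids <- t(vapply(classes, function(cl) {
    colMeans(x[train[y[train] == cl], , drop = FALSE])
  }, numeric(ncol(x))))
  d2 <- outer(rowSums(x[test, , drop = FALSE]^2), rep(1, length(classes))) -
    2 * x[test, , drop = FALSE] %*% t(centroids) +
    outer(rep(1, length(test)), rowSums(centroids^2))
  pred <- classes[max.col(-d2, ties.method = "first")]
  # subsampled test halves can miss a class; the 0-convention is intended here
  suppressWarnings(compute_metrics(y[test], pred, n_classes = max(y) + 1L)$mcc)
}

#' Repeated-run group-difference comparison
#'
#' Trains and evaluates a classifier independently `n_runs` times on each of
#' two datasets (fresh seed per run, recorded), collects the per-run MCC
#' samples, tests each sample for normality with Shapiro-Wilk, and compares
#' the two samples with Welch's two-sample two-sided t-test at level `alpha`.
#' The normality test is reported but does not gate the t-test.
#'
#' @param dataset_a,dataset_b lists of runs (e.g., the two groups of a
#'   [simulate_dataset()] split by `group_label`).
#' @param fit_fun `function(runs, seed)` returning a scalar MCC for one
#'   train/evaluate cycle. Default: [connectivity_centroid_mcc()]; use
#'   [gcn_pipeline_mcc()] for the full GCN pipeline.
#' @param n_runs repetitions per dataset (the reference protocol uses 35).
#' @param alpha significance level.
#' @param base_seed run r uses seed `base_seed + r` on dataset A and
#'   `base_seed + n_runs + r` on dataset B.
#' @return an object of class `group_comparison`.
#' @export
repeated_run_comparison <- function(dataset_a, dataset_b,
                                    fit_fun = connectivity_centroid_mcc,
                                    n_runs = 35L, alpha = 0.05,
                                    base_seed = 1L) {
  if (length(dataset_a) == 0 || length(dataset_b) == 0) {
    stop("both datasets must be non-empty")
  }
  seeds_a <- base_seed + seq_len(n_runs)
  seeds_b <- base_seed + n_runs + seq_len(n_runs)
  run_one <- function(data, seed, label, r) {
    tryCatch(fit_fun(data, seed), error = function(e) {
      stop(sprintf("run %d on dataset %s failed: %s", r, label,
                   conditionMessage(e)))
    })
  }
  mcc_a <- vapply(seq_len(n_runs), function(r) {
    run_one(dataset_a, seeds_a[r], "A", r)
  }, numeric(1))
  mcc_b <- vapply(seq_len(n_runs), function(r) {
    run_one(dataset_b, seeds_b[r], "B", r)
  }, numeric(1))
  sw_a <- tryCatch(stats::shapiro.test(mcc_a),
                   error = function(e) list(statistic = NA_real_, p.value = NA_real_))
  sw_b <- tryCatch(stats::shapiro.test(mcc_b),
                   error = function(e) list(statistic = NA_real_, p.value = NA_real_))
  tt <- stats::t.test(mcc_a, mcc_b, var.equal = FALSE)
  structure(list(
    mcc_a = mcc_a, mcc_b = mcc_b,
    seeds_a = seeds_a, seeds_b = seeds_b,
    shapiro_a = list(W = unname(sw_a$statistic), p = sw_a$p.value),
    shapiro_b = list(W = unname(sw_b$statistic), p = sw_b$p.value),
    t_statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    alpha = alpha,
    significant = tt$p.value < alpha
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group comparison over %d runs per dataset\n", length(x$mcc_a)))
  cat(sprintf("  MCC A: mean %.3f (sd %.3f) | MCC B: mean %.3f (sd %.3f)\n",
              mean(x$mcc_a), stats::sd(x$mcc_a),
              mean(x$mcc_b), stats::sd(x$mcc_b)))
  cat(sprintf("  Shapiro-Wilk W: A %.3f (p %.3g), B %.3f (p %.3g)\n",
              x$shapiro_a$W, x$shapiro_a$p, x$shapiro_b$W, x$shapiro_b$p))
  cat(sprintf("  Welch t = %.3f, df = %.1f, p = %.4g -> %s at alpha %.2f\n",
              x$t_statistic, x$df, x$p_value,
              if (x$significant) "significant" else "not significant",
              x$alpha))
  invisible(x)
}
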