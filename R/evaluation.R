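# The evaluation suite: accuracy, cross-entropy loss, per-class and
# support-weighted precision/recall/F1, class-specific and micro/macro ROC
# AUC, paired t-tests with Bonferroni adjustment, and thin adapters around
# off-the-shelf baseline classifiers so that every method is scored by the
# same metric code path.

#' ROC AUC via the rank (Mann-Whitney) statistic
#'
#' The probability that a randomly chosen positive outscores a randomly
#' chosen negative, ties counted one half — identical to the trapezoidal
#' area under the ROC curve.
#'
#' @param scores numeric per-sample scores
#' @param labels binary labels (logical or 0/1)
#' @return the AUC, or `NA` (with a warning) when only one label value is
#'   present — such classes are excluded from averaged AUCs
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    warning("roc_auc undefined: only one class present in labels")
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Micro-average ROC AUC
#'
#' Pools every (sample, class) pair into one binary problem — score =
#' predicted probability of the class, label = whether it is the true class
#' — and computes a single AUC over the pool.
#'
#' @param probs class-probability matrix (rows on the simplex)
#' @param labels integer true classes in 1..ncol(probs)
#' @return the pooled AUC
#' @export
micro_average_auc <- function(probs, labels) {
  probs <- as.matrix(probs)
  labels <- as.integer(labels)
  truth <- matrix(0, nrow(probs), ncol(probs))
  truth[cbind(seq_along(labels), labels)] <- 1
  roc_auc(as.numeric(probs), as.numeric(truth))
}

#' Full per-fold metric report
#'
#' Accuracy (argmax predictions, ties to the lowest class index),
#' cross-entropy loss (probabilities clipped to \[1e-15, 1\]), per-class
#' precision/recall/F1 with 0/0 defined as 0, support-weighted averages,
#' class-specific ROC AUCs, the pooled micro-average AUC, the
#' support-weighted mean of per-class AUCs (reported as
#' `macro_weighted_auc`), and the conventional unweighted mean
#' (`macro_unweighted_auc`).
#'
#' @param probs class-probability matrix
#' @param labels integer true classes in 1..ncol(probs), or a factor with
#'   class levels
#' @return a `metrics_report` list
#' @export
compute_metrics <- function(probs, labels) {
  probs <- as.matrix(probs)
  if (is.factor(labels)) labels <- as.integer(labels)
  labels <- as.integer(labels)
  if (length(labels) != nrow(probs)) stop_("labels length != number of probability rows")
  K <- ncol(probs)
  if (any(labels < 1 | labels > K)) stop_("labels out of range 1..", K)
  pred <- max.col(probs, ties.method = "first")
  accuracy <- mean(pred == labels)
  loss <- -mean(log(pmin(pmax(probs[cbind(seq_along(labels), labels)], 1e-15), 1)))
  support <- vapply(seq_len(K), function(k) sum(labels == k), 0)
  tp <- vapply(seq_len(K), function(k) sum(pred == k & labels == k), 0)
  pp <- vapply(seq_len(K), function(k) sum(pred == k), 0)
  safe_div <- function(a, b) ifelse(b == 0, 0, a / b)
  precision <- safe_div(tp, pp)
  recall <- safe_div(tp, support)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  auc <- vapply(seq_len(K), function(k) {
    if (support[k] == 0 || support[k] == length(labels)) return(NA_real_)
    roc_auc(probs[, k], labels == k)
  }, 0)
  w <- support / sum(support)
  ok <- !is.na(auc)
  classes <- if (K == length(RE_CLASSES)) RE_CLASSES else paste0("class_", seq_len(K))
  structure(list(
    accuracy = accuracy,
    cross_entropy_loss = loss,
    precision = stats::setNames(precision, classes),
    recall = stats::setNames(recall, classes),
    f1 = stats::setNames(f1, classes),
    auc = stats::setNames(auc, classes),
    support = stats::setNames(support, classes),
    weighted_precision = sum(w * precision),
    weighted_recall = sum(w * recall),
    weighted_f1 = sum(w * f1),
    micro_average_auc = micro_average_auc(probs, labels),
    macro_weighted_auc = if (any(ok)) sum(w[ok] * auc[ok]) / sum(w[ok]) else NA_real_,
    macro_unweighted_auc = if (any(ok)) mean(auc[ok]) else NA_real_),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.3f | loss %.3f | wP %.3f wR %.3f wF1 %.3f | micro-AUC %.3f | macro-AUC (weighted) %.3f\n",
              x$accuracy, x$cross_entropy_loss, x$weighted_precision,
              x$weighted_recall, x$weighted_f1, x$micro_average_auc,
              x$macro_weighted_auc))
  invisible(x)
}

#' Flatten a metrics report to a one-row data frame
#' @param report a `metrics_report`
#' @export
metrics_row <- function(report) {
  data.frame(accuracy = report$accuracy, loss = report$cross_entropy_loss,
             precision = report$weighted_precision, recall = report$weighted_recall,
             f1 = report$weighted_f1, micro_auc = report$micro_average_auc,
             macro_weighted_auc = report$macro_weighted_auc,
             macro_unweighted_auc = report$macro_unweighted_auc)
}

#' Paired comparison of two methods across folds
#'
#' Two-sided paired t-test on fold-wise score differences with Bonferroni
#' multiplication over the number of simultaneous comparisons. Identical
#' vectors give p = 1; a nonzero but zero-variance difference is flagged as
#' degenerate (the t statistic diverges; p is reported as 0, its limit).
#'
#' @param scores_a,scores_b per-fold scores for the two methods, paired by
#'   fold index (length >= 2)
#' @param n_comparisons number of simultaneous comparisons for Bonferroni
#' @param metric optional metric name carried through for reporting
#' @return a `method_comparison` with `t`, `p_value`, `p_adjusted`,
#'   `mean_difference` and a `degenerate` flag
#' @export
compare_methods <- function(scores_a, scores_b, n_comparisons = 1, metric = "") {
  if (length(scores_a) != length(scores_b)) stop_("score vectors must be paired")
  if (length(scores_a) < 2) stop_("need at least 2 folds for a paired t-test")
  d <- scores_a - scores_b
  degenerate <- FALSE
  if (all(d == 0)) {
    t_stat <- 0; p <- 1
  } else if (stats::sd(d) == 0) {
    degenerate <- TRUE
    t_stat <- sign(mean(d)) * Inf; p <- 0
  } else {
    tt <- stats::t.test(scores_a, scores_b, paired = TRUE)
    t_stat <- unname(tt$statistic); p <- tt$p.value
  }
  structure(list(metric = metric, scores_a = scores_a, scores_b = scores_b,
                 mean_difference = mean(d), t = t_stat, p_value = p,
                 p_adjusted = min(1, p * n_comparisons),
                 n_comparisons = n_comparisons, degenerate = degenerate),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("%s: mean diff %+.4f, t = %.3f, p = %.3g (Bonferroni x%d: %.3g)%s\n",
              if (nzchar(x$metric)) x$metric else "comparison",
              x$mean_difference, x$t, x$p_value, x$n_comparisons, x$p_adjusted,
              if (x$degenerate) " [degenerate: zero-variance difference]" else ""))
  invisible(x)
}

#' Fit and evaluate an off-the-shelf baseline classifier
#'
#' Thin adapters over established implementations — multinomial logistic
#' regression (`nnet::multinom`), random forest (`ranger`) and
#' gradient-boosted trees (`xgboost`) — evaluated with [compute_metrics()]
#' so MLP-vs-baseline comparisons share one metric code path.
#'
#' @param method `"logistic_regression"`, `"random_forest"` or `"gbdt"`
#' @param train_x,train_y training matrix and integer labels (1..4)
#' @param test_x,test_y held-out data
#' @param hyperparameters optional named list passed to the backend
#' @param seed integer seed
#' @return list with the `metrics_report`, the probability matrix `probs`
#'   and the backend `fit`
#' @export
baseline_harness <- function(method, train_x, train_y, test_x, test_y,
                             hyperparameters = list(), seed = 1) {
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  if (is.null(colnames(train_x))) {
    colnames(train_x) <- paste0("f", seq_len(ncol(train_x)))
    colnames(test_x) <- colnames(train_x)
  }
  train_y <- as.integer(train_y); test_y <- as.integer(test_y)
  K <- length(RE_CLASSES)
  yf <- factor(RE_CLASSES[train_y], levels = RE_CLASSES)
  probs <- switch(method,
    logistic_regression = {
      df <- as.data.frame(train_x)
      names(df) <- paste0("f", seq_len(ncol(train_x)))
      df$.y <- yf
      fit <- withr::with_seed(seed,
        nnet::multinom(.y ~ ., data = df, trace = FALSE,
                       maxit = hyperparameters$maxit %||% 200,
                       MaxNWts = 100000, decay = hyperparameters$decay %||% 0))
      nd <- as.data.frame(test_x)
      names(nd) <- paste0("f", seq_len(ncol(test_x)))
      p <- stats::predict(fit, newdata = nd, type = "probs")
      if (is.null(dim(p))) p <- matrix(p, nrow = 1, dimnames = list(NULL, names(p)))
      full <- matrix(0, nrow(test_x), K, dimnames = list(NULL, RE_CLASSES))
      full[, colnames(p)] <- p
      attr(full, "fit") <- fit
      full
    },
    random_forest = {
      if (!requireNamespace("ranger", quietly = TRUE))
        stop_("the random_forest baseline requires the 'ranger' package")
      fit <- ranger::ranger(x = train_x, y = yf, probability = TRUE,
                            num.trees = hyperparameters$num.trees %||% 200,
                            seed = seed, num.threads = 1)
      p <- stats::predict(fit, data = test_x, num.threads = 1)$predictions
      full <- matrix(0, nrow(test_x), K, dimnames = list(NULL, RE_CLASSES))
      full[, colnames(p)] <- p
      attr(full, "fit") <- fit
      full
    },
    gbdt = {
      if (!requireNamespace("xgboost", quietly = TRUE))
        stop_("the gbdt baseline requires the 'xgboost' package")
      fit <- withr::with_seed(seed,
        xgboost::xgboost(train_x, yf,
                         nrounds = hyperparameters$nrounds %||% 100,
                         max_depth = hyperparameters$max_depth %||% 6,
                         learning_rate = hyperparameters$eta %||% 0.3,
                         nthreads = 1, verbosity = 0))
      p <- stats::predict(fit, test_x)
      full <- matrix(0, nrow(test_x), K, dimnames = list(NULL, RE_CLASSES))
      full[, colnames(p)] <- p
      attr(full, "fit") <- fit
      full
    },
    stop_("unknown baseline method '", method,
          "'; use logistic_regression, random_forest or gbdt"))
  fit <- attr(probs, "fit"); attr(probs, "fit") <- NULL
  list(metrics = compute_metrics(probs, test_y), probs = probs, fit = fit)
}
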