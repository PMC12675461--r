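# Evaluation suite: confusion counts, ratio metrics, log loss, ROC / AUC by
# threshold sweep with trapezoidal integration, class-frequency-weighted
# AUC, and the one-sample t test used to compare a model's accuracy against
# a body of previously reported accuracies.

#' Binary confusion counts
#'
#' @param y_true,y_pred Equal-length binary label vectors (factor,
#'   character, or numeric; at most two distinct values between them).
#' @param positive The label treated as the positive class.
#' @return A `confusion_counts` list: `TP`, `TN`, `FP`, `FN`, `N`.
#' @export
confusion_counts <- function(y_true, y_pred, positive) {
  if (length(y_true) != length(y_pred)) {
    abort("`y_true` and `y_pred` must have equal length.", class = "sobelnet_error_validation")
  }
  lv <- unique(c(as.character(y_true), as.character(y_pred)))
  if (length(lv) > 2L) {
    abort("Labels are not binary.", class = "sobelnet_error_validation")
  }
  if (!as.character(positive) %in% lv) {
    abort(sprintf("Positive class '%s' not present in the labels.", positive),
      class = "sobelnet_error_validation")
  }
  tp <- sum(y_true == positive & y_pred == positive)
  tn <- sum(y_true != positive & y_pred != positive)
  fp <- sum(y_true != positive & y_pred == positive)
  fn <- sum(y_true == positive & y_pred != positive)
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn, N = tp + tn + fp + fn,
    positive = as.character(positive)), class = "confusion_counts")
}

safe_ratio <- function(num, den, warnings, what) {
  if (den == 0) {
    warnings <- c(warnings, sprintf("%s undefined (zero denominator); returned 0", what))
    list(value = 0, warnings = warnings)
  } else {
    list(value = num / den, warnings = warnings)
  }
}

#' Ratio metrics from confusion counts
#'
#' Accuracy `(TP+TN)/N`, precision `TP/(TP+FP)`, recall `TP/(TP+FN)`,
#' F1 `2PR/(P+R)`, Jaccard `TP/(TP+FP+FN)`. Ratios with a zero denominator
#' return 0 and are recorded in the `"warnings"` attribute (a warning is
#' also signalled), so batch evaluation never dies on a degenerate fold.
#'
#' @param counts A [confusion_counts()].
#' @return One-row tibble `accuracy`, `precision`, `recall`, `f1`,
#'   `jaccard`, with attribute `warnings`.
#' @export
basic_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (counts$N == 0) abort("No samples.", class = "sobelnet_error_validation")
  warns <- character()
  acc <- (counts$TP + counts$TN) / counts$N
  pr <- safe_ratio(counts$TP, counts$TP + counts$FP, warns, "precision")
  warns <- pr$warnings
  rc <- safe_ratio(counts$TP, counts$TP + counts$FN, warns, "recall")
  warns <- rc$warnings
  f1 <- safe_ratio(2 * pr$value * rc$value, pr$value + rc$value, warns, "f1")
  warns <- f1$warnings
  jc <- safe_ratio(counts$TP, counts$TP + counts$FP + counts$FN, warns, "jaccard")
  warns <- jc$warnings
  if (length(warns)) warn(paste(warns, collapse = "; "))
  out <- tibble(accuracy = acc, precision = pr$value, recall = rc$value,
    f1 = f1$value, jaccard = jc$value)
  attr(out, "warnings") <- warns
  out
}

#' Binary log loss
#'
#' Mean negative log-likelihood of binary labels under predicted
#' probabilities, with probabilities clipped to `[eps, 1 - eps]`.
#'
#' @param y Numeric 0/1 labels.
#' @param p Predicted probabilities of the positive class.
#' @param eps Clipping constant (default 1e-15).
#' @return Nonnegative scalar.
#' @export
log_loss <- function(y, p, eps = 1e-15) {
  if (length(y) != length(p)) {
    abort("`y` and `p` must have equal length.", class = "sobelnet_error_validation")
  }
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps thresholds over the unique scores (descending) and integrates the
#' resulting (FPR, TPR) polyline trapezoidally; tied scores move in blocks,
#' which reproduces midrank handling (identical scores for all samples give
#' AUC 0.5). The AUC equals the Mann-Whitney probability that a random
#' positive outscores a random negative.
#'
#' @param y Binary labels (0/1 numeric, or logical).
#' @param scores Classifier scores, higher meaning more positive.
#' @return List with `auc` and `curve` (tibble `threshold`, `fpr`, `tpr`).
#' @export
roc_auc <- function(y, scores) {
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) {
    abort("ROC requires both classes present.", class = "sobelnet_error_validation")
  }
  np <- sum(y == 1); nn <- sum(y == 0)
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  # block boundaries at the last element of each tied-score group
  last_of_block <- c(ss[-length(ss)] != ss[-1L], TRUE)
  ctp <- cumsum(ys)[last_of_block]
  cfp <- cumsum(1 - ys)[last_of_block]
  tpr <- c(0, ctp / np)
  fpr <- c(0, cfp / nn)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(auc = auc,
    curve = tibble(threshold = c(Inf, ss[last_of_block]), fpr = fpr, tpr = tpr))
}

#' Class-frequency-weighted AUC
#'
#' Convex combination of per-class one-vs-rest AUCs with weights
#' proportional to class counts.
#'
#' @param per_class_auc Numeric vector of per-class AUCs.
#' @param class_counts Same-length vector of class frequencies.
#' @return Scalar between the minimum and maximum per-class AUC.
#' @export
weighted_auc <- function(per_class_auc, class_counts) {
  if (length(per_class_auc) != length(class_counts)) {
    abort("AUC and count vectors must have equal length.", class = "sobelnet_error_validation")
  }
  total <- sum(class_counts)
  if (total == 0) abort("Zero total class count.", class = "sobelnet_error_validation")
  sum(per_class_auc * class_counts / total)
}

#' One-sample t test from summary statistics
#'
#' `t = (x_bar - mu) / (s / sqrt(n))`, `df = n - 1`: does a new result
#' `x_bar` differ from the mean `mu` of `n` previously reported values with
#' standard deviation `s`?
#'
#' @param x_bar Observed value under test.
#' @param mu Reference mean.
#' @param s Reference standard deviation (> 0).
#' @param n Reference sample size (>= 2).
#' @param alternative `"two.sided"`, `"greater"`, or `"less"`.
#' @return An object of class `htest` with `statistic`, `parameter` (df),
#'   and `p.value`.
#' @export
one_sample_t <- function(x_bar, mu, s, n, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (s <= 0) abort("`s` must be > 0.", class = "sobelnet_error_validation")
  if (n < 2) abort("`n` must be >= 2.", class = "sobelnet_error_validation")
  t <- (x_bar - mu) / (s / sqrt(n))
  df <- n - 1
  p <- switch(alternative,
    two.sided = 2 * stats::pt(-abs(t), df),
    greater = stats::pt(t, df, lower.tail = FALSE),
    less = stats::pt(t, df))
  structure(list(
    statistic = c(t = t), parameter = c(df = df), p.value = p,
    estimate = c(`x bar` = x_bar), null.value = c(mean = mu),
    alternative = alternative, method = "One sample t-test (summary statistics)",
    data.name = sprintf("x_bar = %g vs n = %d prior values", x_bar, n)
  ), class = "htest")
}

#' Full evaluation report
#'
#' Confusion counts (argmax labels), every ratio metric, log loss, per-class
#' one-vs-rest ROC/AUC, class-frequency-weighted AUC, and a per-class
#' classification report.
#'
#' @param truth Factor/character vector of true class names.
#' @param probs n x K probability matrix with class-name columns.
#' @param positive Positive class for the confusion counts (default: last
#'   class in sorted order, i.e. "tumor" for tumor/healthy).
#' @return A `sobelnet_report` list; see [tidy.sobelnet_report()] and
#'   [glance.sobelnet_report()].
#' @export
metrics_report <- function(truth, probs, positive = NULL) {
  classes <- colnames(probs)
  if (is.null(classes)) abort("`probs` must have class-name columns.",
    class = "sobelnet_error_validation")
  truth <- as.character(truth)
  positive <- positive %||% tail(sort(classes, method = "radix"), 1)
  pred <- classes[max.col(probs, ties.method = "first")]
  counts <- confusion_counts(truth, pred, positive)
  metrics <- basic_metrics(counts)

  y_pos <- as.numeric(truth == positive)
  ll <- log_loss(y_pos, probs[, positive])

  per_class <- lapply(classes, function(cl) {
    roc_auc(as.numeric(truth == cl), probs[, cl])
  })
  names(per_class) <- classes
  aucs <- vapply(per_class, function(r) r$auc, numeric(1))
  class_n <- vapply(classes, function(cl) sum(truth == cl), numeric(1))
  wauc <- weighted_auc(aucs, class_n)

  report <- purrr::map_dfr(classes, function(cl) {
    c2 <- confusion_counts(truth, pred, cl)
    m2 <- suppressWarnings(basic_metrics(c2))
    tibble(class = cl, precision = m2$precision, recall = m2$recall,
      f1 = m2$f1, support = sum(truth == cl))
  })

  structure(list(
    counts = counts, metrics = metrics, log_loss = ll,
    per_class_auc = aucs, class_counts = class_n, weighted_auc = wauc,
    roc = purrr::imap(per_class, function(r, cl) dplyr::mutate(r$curve, class = cl)),
    classification_report = report, positive = positive, classes = classes
  ), class = "sobelnet_report")
}

#' @export
print.sobelnet_report <- function(x, ...) {
  cat(sprintf("Evaluation report (positive class: %s)\n", x$positive))
  cat(sprintf("  confusion: TP %d  TN %d  FP %d  FN %d  (N = %d)\n",
    x$counts$TP, x$counts$TN, x$counts$FP, x$counts$FN, x$counts$N))
  m <- x$metrics
  cat(sprintf("  accuracy %.4f  precision %.4f  recall %.4f  f1 %.4f  jaccard %.4f\n",
    m$accuracy, m$precision, m$recall, m$f1, m$jaccard))
  cat(sprintf("  log loss %.4f  weighted AUC %.4f\n", x$log_loss, x$weighted_auc))
  print(x$classification_report)
  invisible(x)
}

#' Tidy an evaluation report
#'
#' @param x A `sobelnet_report`.
#' @param ... Unused.
#' @return Long tibble with `metric` and `value` columns.
#' @export
tidy.sobelnet_report <- function(x, ...) {
  m <- x$metrics
  tibble(
    metric = c("accuracy", "log_loss", "precision", "recall", "f1", "jaccard",
      paste0("auc_", names(x$per_class_auc)), "weighted_auc"),
    value = c(m$accuracy, x$log_loss, m$precision, m$recall, m$f1, m$jaccard,
      unname(x$per_class_auc), x$weighted_auc)
  )
}

#' Summarize an evaluation report in one row
#'
#' @param x A `sobelnet_report`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.sobelnet_report <- function(x, ...) {
  dplyr::bind_cols(x$metrics,
    tibble(log_loss = x$log_loss, weighted_auc = x$weighted_auc,
      n = x$counts$N))
}

#' Serialize a report to machine-readable JSON
#'
#' Full-precision JSON; identical reports serialize to identical bytes, so
#' reproducibility can be checked bit-for-bit.
#'
#' @param report A `sobelnet_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(report, path) {
  out <- list(
    positive = report$positive,
    confusion = report$counts[c("TP", "TN", "FP", "FN", "N")],
    metrics = as.list(report$metrics),
    log_loss = report$log_loss,
    per_class_auc = as.list(report$per_class_auc),
    weighted_auc = report$weighted_auc,
    classification_report = report$classification_report
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
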