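test_that("confusion counts partition the sample and flip symmetrically", {
  y <- c(rep("tumor", 376), rep("healthy", 313))
  cc <- confusion_counts(y, y, positive = "tumor")
  expect_equal(cc[c("TP", "TN", "FP", "FN")], list(TP = 376, TN = 313, FP = 0, FN = 0))
  flip <- ifelse(y == "tumor", "healthy", "tumor")
  cf <- confusion_counts(y, flip, positive = "tumor")
  expect_equal(cf$TP, 0); expect_equal(cf$FN, 376)
  expect_equal(cf$TN, 0); expect_equal(cf$FP, 313)

  truth <- withr::with_seed(1, sample(0:1, 200, TRUE))
  pred <- withr::with_seed(2, sample(0:1, 200, TRUE))
  cc2 <- confusion_counts(truth, pred, positive = 1)
  tp <- tn <- fp <- fn <- 0 # brute-force loop
  for (i in 1:200) {
    if (truth[i] == 1 && pred[i] == 1) tp <- tp + 1
    if (truth[i] == 0 && pred[i] == 0) tn <- tn + 1
    if (truth[i] == 0 && pred[i] == 1) fp <- fp + 1
    if (truth[i] == 1 && pred[i] == 0) fn <- fn + 1
  }
  expect_equal(cc2[c("TP", "TN", "FP", "FN")], list(TP = tp, TN = tn, FP = fp, FN = fn))
  expect_equal(cc2$N, 200)
  expect_error(confusion_counts(c(1, 2, 3), c(1, 2, 3), positive = 1),
    class = "sobelnet_error_validation")
})

test_that("ratio metrics follow their formulas, including degenerate cases", {
  perfect <- confusion_counts(c(rep(1, 376), rep(0, 313)),
    c(rep(1, 376), rep(0, 313)), positive = 1)
  m <- basic_metrics(perfect)
  expect_equal(unlist(m), c(accuracy = 1, precision = 1, recall = 1, f1 = 1, jaccard = 1))

  cc <- structure(list(TP = 1, TN = 0, FP = 1, FN = 0, N = 2, positive = "1"),
    class = "confusion_counts")
  m2 <- basic_metrics(cc)
  expect_equal(m2$precision, 0.5)
  expect_equal(m2$recall, 1)
  expect_equal(m2$f1, 2 / 3)
  expect_equal(m2$jaccard, 0.5)

  for (i in 1:20) {
    k <- withr::with_seed(i, sample(0:30, 4, TRUE))
    if (sum(k) == 0) k[1] <- 1
    cc3 <- structure(list(TP = k[1], TN = k[2], FP = k[3], FN = k[4],
      N = sum(k), positive = "1"), class = "confusion_counts")
    m3 <- suppressWarnings(basic_metrics(cc3))
    expect_equal(m3$accuracy, (k[1] + k[2]) / sum(k))
    if (k[1] + k[3] > 0) expect_equal(m3$precision, k[1] / (k[1] + k[3]))
    if (k[1] + k[3] + k[4] > 0) {
      expect_equal(m3$jaccard, k[1] / (k[1] + k[3] + k[4]))
      expect_lte(m3$jaccard, m3$f1 + 1e-12)
    }
  }

  # zero denominator: flagged, zero, and non-fatal
  none <- structure(list(TP = 0, TN = 5, FP = 0, FN = 0, N = 5, positive = "1"),
    class = "confusion_counts")
  expect_warning(mz <- basic_metrics(none))
  expect_equal(mz$precision, 0)
  expect_true(length(attr(mz, "warnings")) > 0)
})

test_that("log loss matches its closed form and brute-force sum", {
  expect_equal(log_loss(1, 0.5), log(2))
  expect_lt(log_loss(c(1, 0), c(1, 0)), 1e-12) # post-clip perfect predictions
  y <- withr::with_seed(3, sample(0:1, 50, TRUE))
  p <- withr::with_seed(4, runif(50, 0.01, 0.99))
  s <- 0 # brute force
  for (i in 1:50) s <- s - (y[i] * log(p[i]) + (1 - y[i]) * log(1 - p[i]))
  expect_equal(log_loss(y, p), s / 50)
  expect_gte(log_loss(y, p), 0)
  expect_error(log_loss(c(1, 0), 0.5), class = "sobelnet_error_validation")
})

test_that("constant predictors minimize log loss at the empirical rate", {
  y <- c(rep(1, 13), rep(0, 27))
  grid <- seq(0.01, 0.99, by = 0.005)
  losses <- vapply(grid, function(q) log_loss(y, rep(q, 40)), numeric(1))
  expect_equal(grid[which.min(losses)], 0.325, tolerance = 0.005)
})

test_that("AUC equals pairwise counting, handles ties, and is rank-invariant", {
  y <- c(rep(0, 10), rep(1, 10))
  expect_equal(roc_auc(y, c(runif(10), 5 + runif(10)))$auc, 1)
  expect_equal(roc_auc(y, rep(2, 20))$auc, 0.5) # all tied: chance by midranks

  for (i in 1:10) {
    yy <- withr::with_seed(i, sample(0:1, 30, TRUE))
    if (length(unique(yy)) < 2) yy[1:2] <- 0:1
    ss <- withr::with_seed(100 + i, round(rnorm(30), 1)) # rounding creates ties
    r <- roc_auc(yy, ss)
    expect_equal(r$auc, brute_auc(yy, ss))
    # invariance under a strictly monotone transform
    expect_equal(roc_auc(yy, exp(3 * ss))$auc, r$auc)
    # curve is a valid staircase from (0,0) to (1,1)
    expect_equal(r$curve$fpr[1], 0)
    expect_equal(utils::tail(r$curve$tpr, 1), 1)
  }
  expect_error(roc_auc(rep(1, 5), rnorm(5)), class = "sobelnet_error_validation")
})

test_that("our AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  for (i in 1:5) {
    y <- withr::with_seed(i, sample(0:1, 40, TRUE))
    if (length(unique(y)) < 2) y[1:2] <- 0:1
    s <- withr::with_seed(50 + i, rnorm(40))
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE, direction = "<")))
    expect_equal(roc_auc(y, s)$auc, ref)
  }
})

test_that("weighted AUC is the count-weighted convex combination", {
  expect_equal(weighted_auc(c(0.8, 1.0), c(5, 5)), 0.9)
  expect_equal(weighted_auc(c(0.6, 0.95), c(0, 7)), 0.95)
  for (i in 1:10) {
    a <- withr::with_seed(i, runif(4, 0.5, 1))
    n <- withr::with_seed(20 + i, sample(1:50, 4))
    expect_equal(weighted_auc(a, n), sum(a * n / sum(n)))
    expect_gte(weighted_auc(a, n), min(a))
    expect_lte(weighted_auc(a, n), max(a))
  }
  # uniform per-class AUC passes through regardless of weights
  expect_equal(weighted_auc(c(0.7, 0.7, 0.7), c(1, 10, 100)), 0.7)
  expect_error(weighted_auc(c(1, 1), c(0, 0)), class = "sobelnet_error_validation")
})

test_that("the one-sample t statistic reproduces the reference comparison", {
  ht <- one_sample_t(0.9958, 0.9634, 0.0366, 20)
  expect_equal(round(unname(ht$statistic), 2), 3.96)
  expect_equal(unname(ht$parameter), 19)
  expect_lt(one_sample_t(0.9958, 0.9634, 0.0366, 20, "greater")$p.value, 0.001)

  expect_equal(unname(one_sample_t(0.5, 0.5, 0.1, 10)$statistic), 0)
  for (i in 1:10) {
    v <- withr::with_seed(i, c(runif(2), runif(1, 0.01, 1), sample(2:50, 1)))
    ht2 <- one_sample_t(v[1], v[2], v[3], v[4])
    expect_equal(unname(ht2$statistic), (v[1] - v[2]) / (v[3] / sqrt(v[4])),
      tolerance = 1e-12)
    expect_equal(unname(ht2$parameter), v[4] - 1)
  }
  expect_error(one_sample_t(1, 0, 0, 10), class = "sobelnet_error_validation")
  expect_error(one_sample_t(1, 0, 1, 1), class = "sobelnet_error_validation")
})

test_that("the full report ties the pieces together coherently", {
  probs <- withr::with_seed(5, {
    p <- runif(60, 0.01, 0.99)
    cbind(healthy = 1 - p, tumor = p)
  })
  truth <- ifelse(probs[, "tumor"] + withr::with_seed(6, rnorm(60, 0, 0.3)) > 0.5,
    "tumor", "healthy")
  rep <- metrics_report(truth, probs)
  expect_s3_class(rep, "sobelnet_report")
  expect_equal(rep$positive, "tumor")
  td <- tidy(rep)
  expect_true(all(c("accuracy", "log_loss", "weighted_auc") %in% td$metric))
  expect_true(all(td$value[td$metric != "log_loss"] >= 0 &
    td$value[td$metric != "log_loss"] <= 1))
  g <- glance(rep)
  expect_equal(g$n, 60)
  # weighted AUC lies between the per-class AUCs
  expect_gte(rep$weighted_auc, min(rep$per_class_auc) - 1e-12)
  expect_lte(rep$weighted_auc, max(rep$per_class_auc) + 1e-12)
  # serialization is stable byte-for-byte
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_metrics_report(rep, f1)
  write_metrics_report(rep, f2)
  expect_identical(readLines(f1), readLines(f2))
})
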