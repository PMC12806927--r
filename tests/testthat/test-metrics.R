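test_that("confusion counts match direct tallies", {
  truth <- c(rep(1L, 5L), rep(0L, 5L))
  expect_equal(
    as.list(confusion_counts(truth, truth)),
    list(tp = 5L, fp = 0L, fn = 0L, tn = 5L)
  )
  expect_equal(
    as.list(confusion_counts(rep(1L, 10L), truth)),
    list(tp = 5L, fp = 5L, fn = 0L, tn = 0L)
  )
  expect_error(confusion_counts(c(0, 1), c(0, 1, 1)), "equal length")
  expect_error(confusion_counts(c(0, 2), c(0, 1)), "only 0 and 1")
})

test_that("confusion counts agree with element-wise counting on random vectors", {
  withr::with_seed(61L, {
    pred <- sample(0:1, 1000L, replace = TRUE)
    truth <- sample(0:1, 1000L, replace = TRUE)
  })
  cc <- confusion_counts(pred, truth)
  expect_equal(cc$tp, sum(pred & truth))
  expect_equal(cc$fp, sum(pred & !truth))
  expect_equal(cc$fn, sum(!pred & truth))
  expect_equal(cc$tn, sum(!pred & !truth))
  expect_equal(cc$tp + cc$fp + cc$fn + cc$tn, 1000L)
})

test_that("metric panel matches direct formula evaluation", {
  # counts (tp, fp, fn, tn) = (3, 1, 2, 4): accuracy 0.7, mcc = 10 / sqrt(600)
  m <- compute_metrics(tibble::tibble(tp = 3L, fp = 1L, fn = 2L, tn = 4L))
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$precision, 3 / 4)
  expect_equal(m$recall, 3 / 5)
  expect_equal(m$f1, 2 * (3 / 4) * (3 / 5) / (3 / 4 + 3 / 5))
  expect_equal(m$mcc, 10 / sqrt(600))

  # enumerated confusion matrices vs independent formulas
  grid <- expand.grid(tp = 0:3, fp = 0:3, fn = 0:3, tn = 0:3)
  grid <- grid[rowSums(grid) > 0, ]
  for (i in seq_len(nrow(grid))) {
    cc <- tibble::as_tibble(grid[i, ])
    m <- compute_metrics(cc)
    with(cc, {
      expect_equal(m$accuracy, (tp + tn) / (tp + fp + fn + tn))
      if (tp + fp > 0) expect_equal(m$precision, tp / (tp + fp))
      if (tp + fn > 0) expect_equal(m$recall, tp / (tp + fn))
      den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
      if (den > 0) expect_equal(m$mcc, (tp * tn - fp * fn) / den)
    })
  }
})

test_that("perfect and inverted predictions hit the metric extremes", {
  perfect <- compute_metrics(tibble::tibble(tp = 5L, fp = 0L, fn = 0L, tn = 5L))
  expect_equal(
    unlist(perfect[c("accuracy", "precision", "recall", "f1", "mcc")]),
    c(accuracy = 1, precision = 1, recall = 1, f1 = 1, mcc = 1)
  )
  inverted <- compute_metrics(tibble::tibble(tp = 0L, fp = 5L, fn = 5L, tn = 0L))
  expect_equal(inverted$mcc, -1)
  expect_equal(inverted$accuracy, 0)
})

test_that("0/0 metrics report 0 with a degenerate flag", {
  m <- compute_metrics(tibble::tibble(tp = 0L, fp = 0L, fn = 3L, tn = 7L))
  expect_equal(m$precision, 0)
  expect_match(m$degenerate, "precision")
  expect_match(m$degenerate, "f1")
})

test_that("rank-based AUC matches the all-pairs statistic on random scores", {
  withr::with_seed(71L, {
    truth <- sample(0:1, 200L, replace = TRUE, prob = c(0.6, 0.4))
    scores <- round(stats::runif(200L), 2) # rounding induces ties
  })
  expect_equal(roc_auc(scores, truth), bf_auc(scores, truth))
})

test_that("AUC endpoints: perfect separation gives 1, all ties give 0.5", {
  truth <- c(0, 0, 0, 1, 1)
  expect_equal(roc_auc(c(.1, .2, .3, .8, .9), truth), 1)
  expect_equal(roc_auc(rep(0.5, 5), truth), 0.5)
  expect_equal(roc_auc(c(.9, .8, .7, .2, .1), truth), 0)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUC is invariant under strictly monotone transforms of scores", {
  withr::with_seed(73L, {
    truth <- sample(0:1, 100L, replace = TRUE)
    truth[1:2] <- c(0L, 1L)
    scores <- stats::runif(100L)
  })
  a <- roc_auc(scores, truth)
  expect_equal(roc_auc(exp(3 * scores), truth), a)
  expect_equal(roc_auc(rank(scores), truth), a)
})

test_that("AUC agrees with an established reference implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(79L, {
    truth <- sample(0:1, 150L, replace = TRUE)
    truth[1:2] <- c(0L, 1L)
    scores <- stats::runif(150L)
  })
  ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE)))
  expect_equal(roc_auc(scores, truth), ref)
})

test_that("MCC flips sign under prediction inversion, magnitude preserved", {
  withr::with_seed(83L, {
    pred <- sample(0:1, 300L, replace = TRUE)
    truth <- sample(0:1, 300L, replace = TRUE)
  })
  m1 <- compute_metrics(confusion_counts(pred, truth))
  m2 <- compute_metrics(confusion_counts(1L - pred, truth))
  expect_equal(m2$mcc, -m1$mcc)
})

test_that("F1 lies between precision and recall when both are nonzero", {
  withr::with_seed(89L, {
    for (i in 1:20) {
      pred <- sample(0:1, 100L, replace = TRUE)
      truth <- sample(0:1, 100L, replace = TRUE)
      m <- compute_metrics(confusion_counts(pred, truth))
      if (m$precision > 0 && m$recall > 0) {
        expect_gte(m$f1, min(m$precision, m$recall))
        expect_lte(m$f1, max(m$precision, m$recall))
      }
    }
  })
})

test_that("precision-recall AUC matches a direct step-sum on small cases", {
  # three positives ranked 1st, 3rd, 4th of 5
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.5)
  truth <- c(1, 0, 1, 1, 0)
  # step sum: recall steps at each positive with precision 1/1, 2/3, 3/4
  expected <- (1 / 3) * (1 / 1) + (1 / 3) * (2 / 3) + (1 / 3) * (3 / 4)
  expect_equal(pr_auc(scores, truth), expected)
  expect_equal(pr_auc(c(.9, .8, .2, .1), c(1, 1, 0, 0)), 1)
})
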