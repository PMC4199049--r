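test_that("AUC follows the midrank pair-count convention", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(roc_auc(rep(0.3, 10), rep(0:1, 5)), 0.5)
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1)
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")

  for (i in 1:20) {
    n <- with_seed(400 + i, sample(10:120, 1))
    sc <- with_seed(500 + i, round(runif(n), 1))  # heavy ties
    y <- with_seed(600 + i, rbinom(n, 1, 0.4))
    if (!any(y == 1) || !any(y == 0)) next
    expect_equal(roc_auc(sc, y), pairwise_auc(sc, y), tolerance = 1e-12)
    expect_equal(roc_auc(-sc, y), 1 - roc_auc(sc, y), tolerance = 1e-12)
  }
})

test_that("ROC points integrate back to the AUC", {
  for (i in 1:10) {
    sc <- with_seed(700 + i, round(runif(60), 1))
    y <- with_seed(800 + i, rbinom(60, 1, 0.3))
    if (!any(y == 1) || !any(y == 0)) next
    rc <- roc_curve(sc, y)
    expect_true(all(diff(rc$fpr) >= 0) && all(diff(rc$tpr) >= 0))
    expect_equal(rc$fpr[1], 0); expect_equal(rc$tpr[nrow(rc)], 1)
    trap <- sum(diff(rc$fpr) * (head(rc$tpr, -1) + tail(rc$tpr, -1)) / 2)
    expect_equal(trap, roc_auc(sc, y), tolerance = 1e-12)
  }
  flat <- roc_curve(rep(0.2, 8), rep(0:1, 4))
  expect_equal(flat$fpr, c(0, 1)); expect_equal(flat$tpr, c(0, 1))
})

test_that("confusion metrics follow the standard definitions", {
  m <- confusion_metrics(c(0.6, 0.2, 0.7, 0.1), c(1, 1, 0, 0), 0.5)
  expect_equal(m$sensitivity, 0.5)
  expect_equal(m$specificity, 0.5)
  expect_equal(m$ppv, 0.5)
  expect_equal(m$npv, 0.5)
  expect_equal(m$classification_rate, 0.5)

  all_pos <- confusion_metrics(c(0.9, 0.8, 0.7), c(1, 0, 1), 0)
  expect_equal(all_pos$sensitivity, 1)
  expect_equal(all_pos$specificity, 0)
  expect_true(is.na(all_pos$npv))  # nothing called negative

  # consistency identities on random instances
  for (i in 1:10) {
    sc <- with_seed(900 + i, runif(80))
    y <- with_seed(950 + i, rbinom(80, 1, 0.3))
    if (!any(y == 1) || !any(y == 0)) next
    m <- confusion_metrics(sc, y, 0.5)
    n1 <- sum(y == 1); n0 <- sum(y == 0)
    expect_equal(m$sensitivity * n1 + m$specificity * n0, m$tp + m$tn)
    expect_equal(m$classification_rate,
                 (m$sensitivity * n1 + m$specificity * n0) / (n1 + n0))
  }
})

test_that("a model that calls no positives reports PPV as N/A", {
  m <- confusion_metrics(c(0.1, 0.2, 0.3, 0.2), c(0, 1, 0, 1), 0.9)
  expect_true(is.na(m$ppv))
  expect_identical(m$tp + m$fp, 0L)
  expect_output(print(m), "N/A")
})

test_that("Pearson chi-square matches the incidence comparison and a reference", {
  res <- pearson_chi2(matrix(c(99, 3165, 40, 1373), 2, byrow = TRUE))
  expect_equal(round(res$statistic, 2), 0.14)
  expect_equal(round(res$p.value, 2), 0.71)

  expect_equal(pearson_chi2(matrix(c(20, 10, 10, 20), 2,
                                   byrow = TRUE))$statistic,
               20 / 3, tolerance = 1e-12)
  prop <- pearson_chi2(matrix(c(10, 20, 30, 60), 2, byrow = TRUE))
  expect_equal(prop$statistic, 0)
  expect_equal(prop$p.value, 1)
  expect_error(pearson_chi2(matrix(c(0, 0, 3, 4), 2)), "margins")

  for (i in 1:15) {
    m <- matrix(with_seed(1200 + i, sample(1:200, 4)), 2)
    ref <- suppressWarnings(chisq.test(m, correct = FALSE))
    mine <- pearson_chi2(m)
    expect_equal(mine$statistic, unname(ref$statistic),
                 tolerance = 1e-10)
    expect_equal(mine$p.value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("prevalence prints the survey's headline rates", {
  expect_equal(sprintf("%.1f%%", 100 * 99 / 3264), "3.0%")
  tab <- sized_cohort(40, 1373)
  expect_equal(sprintf("%.1f%%", 100 * prevalence(tab)), "2.8%")
  expect_equal(prevalence(sized_cohort(1, 99)), 0.01)
  none <- sized_cohort(1, 9); none$outcome <- 0L
  expect_equal(prevalence(none), 0)
  expect_error(prevalence(none[0, ]), "empty")
})
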