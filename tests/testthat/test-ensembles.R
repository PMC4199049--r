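test_that("a degenerate forest reduces to a single unpruned tree", {
  tab <- random_table(150, seed = 11)
  fo <- fit_forest(outcome ~ ., tab, B = 1, mtry = 3, seed = 5,
                   bootstrap = FALSE)
  single <- cart(outcome ~ ., tab, cp = 0, minsplit = 2, minbucket = 1)
  expect_equal(predict(fo, tab), predict(single, tab))
  expect_length(fo$oob[[1]], 0)
})

test_that("forests are deterministic given the seed", {
  tab <- random_table(120, seed = 12)
  f1 <- fit_forest(outcome ~ ., tab, B = 15, seed = 3)
  f2 <- fit_forest(outcome ~ ., tab, B = 15, seed = 3)
  expect_identical(f1$oob, f2$oob)
  expect_identical(predict(f1, tab), predict(f2, tab))
  f3 <- fit_forest(outcome ~ ., tab, B = 15, seed = 4)
  expect_false(identical(f1$oob, f3$oob))
})

test_that("out-of-bag sets have the bootstrap's expected size", {
  n <- 300
  tab <- random_table(n, seed = 13)
  fo <- fit_forest(outcome ~ ., tab, B = 40, seed = 6)
  frac <- lengths(fo$oob) / n
  se <- sd(frac) / sqrt(length(frac))
  expect_lt(abs(mean(frac) - exp(-1)), 4 * se + 1e-12)
})

test_that("forest scores aggregate and bound per-tree leaf proportions", {
  tab <- random_table(100, seed = 14)
  fo <- fit_forest(outcome ~ ., tab, B = 12, seed = 7)
  per_tree <- sapply(fo$trees, function(root)
    imbcart:::route_leaf_values(root, tab, seq_len(nrow(tab)),
                                numeric(nrow(tab)),
                                function(nd) nd$p1, warn_unseen = FALSE))
  p <- predict(fo, tab)
  expect_equal(p, rowMeans(per_tree))
  expect_true(all(p >= apply(per_tree, 1, min) - 1e-12))
  expect_true(all(p <= apply(per_tree, 1, max) + 1e-12))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("balanced training data centres forest training scores near 0.5", {
  coh <- undersample(generate_cohort(3000, seed = 15), 1, seed = 16)
  fo <- fit_forest(outcome ~ ., coh, B = 60, seed = 17)
  expect_lt(abs(mean(predict(fo, coh)) - 0.5), 0.1)
})

test_that("forest ranks agree with an independent reference forest", {
  skip_if_not_installed("randomForest")
  coh <- undersample(generate_cohort(1500, seed = 18), 1, seed = 19)
  coh$education <- NULL; coh$marital <- NULL
  ours <- fit_forest(outcome ~ ., coh, B = 100, seed = 20)
  ref <- with_seed(21, randomForest::randomForest(
    factor(outcome) ~ gender + age + race + pir + bmi, data = coh,
    ntree = 100))
  p_ref <- predict(ref, coh, type = "prob")[, "1"]
  expect_gt(cor(predict(ours, coh), p_ref, method = "spearman"), 0.9)
})

test_that("an empty boosting model predicts the training prevalence", {
  tab <- random_table(90, seed = 22)
  bo <- fit_boost(outcome ~ ., tab, M = 0, seed = 1)
  expect_equal(predict(bo, tab), rep(mean(tab$outcome), nrow(tab)))
  expect_length(bo$trees, 0)
})

test_that("boosting runs the configured number of increments, reproducibly", {
  tab <- random_table(150, seed = 23)
  bo <- fit_boost(outcome ~ ., tab, M = 25, seed = 2)
  expect_length(bo$trees, 25)
  expect_identical(predict(bo, tab),
                   predict(fit_boost(outcome ~ ., tab, M = 25, seed = 2),
                           tab))
  expect_true(all(predict(bo, tab) > 0 & predict(bo, tab) < 1))
  # scores are monotone in the additive link
  expect_equal(order(predict(bo, tab)), order(predict(bo, tab,
                                                      type = "link")))
  expect_error(fit_boost(outcome ~ ., tab, shrinkage = 0), "shrinkage")
})

test_that("training deviance never rises without subsampling", {
  coh <- generate_cohort(500, seed = 24)
  bo <- fit_boost(outcome ~ ., coh, M = 40, bag_fraction = 1, seed = 3)
  expect_true(all(diff(bo$train_deviance) <= 1e-9))
})

test_that("boosting tracks an independent reference implementation on AUC", {
  skip_if_not_installed("xgboost")
  coh <- generate_cohort(500, cohort_config(target_prevalence = 0.2),
                         seed = 25)
  coh$education <- NULL; coh$marital <- NULL
  ours <- fit_boost(outcome ~ ., coh, M = 100, bag_fraction = 1, seed = 4)
  X <- model.matrix(~ gender + age + race + pir + bmi - 1, coh)
  dm <- xgboost::xgb.DMatrix(X, label = coh$outcome)
  ref <- with_seed(5, xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = 1,
                  eta = 0.1),
    data = dm, nrounds = 100, verbose = 0))
  auc_ours <- roc_auc(predict(ours, coh), coh$outcome)
  auc_ref <- roc_auc(predict(ref, dm), coh$outcome)
  expect_lt(abs(auc_ours - auc_ref), 0.05)
})

test_that("weighted boosting upweights the case class", {
  coh <- generate_cohort(800, seed = 26)
  wcoh <- class_weights(coh, 1)
  bw <- fit_boost(outcome ~ ., wcoh, M = 10, seed = 6)
  b0 <- fit_boost(outcome ~ ., coh, M = 10, seed = 6)
  # the weighted intercept starts at logit(0.5), the raw one near 3%
  expect_equal(bw$F0, 0, tolerance = 1e-9)
  expect_lt(b0$F0, -2)
})
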