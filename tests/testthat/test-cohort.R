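test_that("generated cohorts have the fixed schema at any size", {
  cols <- c("gender", "age", "race", "education", "marital", "pir",
            "bmi", "outcome", "weight")
  empty <- generate_cohort(0, seed = 1)
  expect_identical(names(empty), cols)
  expect_identical(nrow(empty), 0L)
  expect_true(is.factor(empty$race) && nlevels(empty$race) == 5)

  coh <- generate_cohort(250, seed = 1)
  expect_identical(names(coh), cols)
  expect_identical(nrow(coh), 250L)
  expect_true(all(coh$age >= 20 & coh$age <= 85))
  expect_true(all(coh$bmi >= 14 & coh$bmi <= 70))
  expect_true(all(coh$pir >= 0 & coh$pir <= 5))
  expect_true(all(coh$outcome %in% 0:1))
  expect_true(all(coh$weight > 0))
  expect_false(anyNA(coh))
})

test_that("regeneration with the same seed is bit-identical", {
  expect_identical(generate_cohort(300, seed = 42),
                   generate_cohort(300, seed = 42))
  expect_false(identical(generate_cohort(300, seed = 42),
                         generate_cohort(300, seed = 43)))
})

test_that("intercept calibration hits the target prevalence", {
  # null effects: outcomes are iid Bernoulli(0.03)
  cfg <- cohort_config(age_per_decade = 0, bmi_per_unit = 0,
                       race = c("Mexican American" = 0),
                       education_per_level = 0, pir_per_unit = 0)
  n <- 100000
  coh <- generate_cohort(n, cfg, seed = 5)
  sd4 <- 4 * sqrt(0.03 * 0.97 / n)
  expect_lt(abs(mean(coh$outcome) - 0.03), sd4)

  # default (signal-bearing) config at the replication size
  coh2 <- generate_cohort(4677, seed = 11)
  expect_lt(abs(sum(coh2$outcome) - 139), 4 * sqrt(4677 * 0.03 * 0.97))
})

test_that("generator errors on bad inputs", {
  expect_error(generate_cohort(-1, seed = 1), "nonnegative")
  expect_error(cohort_config(bmi_per_unit = Inf), "finite")
  expect_error(cohort_config(target_prevalence = 1.2), "inside")
})

test_that("raising the BMI effect never lowers expected prevalence", {
  coh <- generate_cohort(3000, seed = 8)
  cfgs <- lapply(c(0, 0.05, 0.1, 0.2, 0.4),
                 function(b) cohort_config(bmi_per_unit = b))
  prev <- vapply(cfgs, function(cfg)
    mean(plogis(-3.5 + cohort_linear_predictor(coh, cfg))), numeric(1))
  expect_true(all(diff(prev) >= 0))
})

test_that("missingness injection touches only eligible fields", {
  coh <- generate_cohort(4677, seed = 3)
  expect_identical(inject_missing(coh, c(education = 0, marital = 0)),
                   coh)
  all_gone <- inject_missing(coh, c(marital = 1))
  expect_true(all(is.na(all_gone$marital)))
  expect_false(anyNA(all_gone$education))
  # education rate from the survey's 9-in-4677: expect about 9 blanks
  sparse <- inject_missing(coh, c(education = 9 / 4677), seed = 2)
  expect_lt(abs(sum(is.na(sparse$education)) - 9), 4 * sqrt(9) + 1)
  expect_false(anyNA(sparse$outcome) || anyNA(sparse$age) ||
                 anyNA(sparse$bmi))
  expect_error(inject_missing(coh, c(bmi = 0.1)), "education and marital")
  expect_error(inject_missing(coh, c(education = 2)), "\\[0, 1\\]")
})

test_that("train/test split partitions the cohort exactly", {
  coh <- generate_cohort(4677, seed = 2)
  coh$id <- seq_len(nrow(coh))
  sp <- split_train_test(coh, 3264, seed = 9)
  expect_identical(nrow(sp$train), 3264L)
  expect_identical(nrow(sp$test), 1413L)
  expect_length(intersect(sp$train$id, sp$test$id), 0)
  expect_identical(sort(c(sp$train$id, sp$test$id)), coh$id)
  expect_identical(split_train_test(coh, 3264, seed = 9), sp)

  degenerate <- split_train_test(coh, nrow(coh), seed = 1)
  expect_identical(nrow(degenerate$test), 0L)
  expect_error(split_train_test(coh, nrow(coh) + 1), "n_train")
})

test_that("cohort CSV round trip preserves values and missingness", {
  coh <- inject_missing(generate_cohort(120, seed = 4),
                        c(education = 0.1, marital = 0.05), seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(back$bmi, coh$bmi, tolerance = 1e-12)
  expect_identical(back$outcome, coh$outcome)
  expect_identical(is.na(back$education), is.na(coh$education))
  expect_identical(as.character(back$race), as.character(coh$race))
})
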