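## Synthetic cohort generator: a low-prevalence binary outcome (evidence of
## undiagnosed diabetes) driven by mixed-type demographic predictors, shaped
## like an adult national health-survey sample.

cohort_columns <- c("gender", "age", "race", "education", "marital",
                    "pir", "bmi", "outcome", "weight")

gender_levels <- c("Male", "Female")
race_levels <- c("Mexican American", "Other Hispanic", "Non-Hispanic White",
                 "Non-Hispanic Black", "Other")
education_levels <- c("Less than 9th grade", "9th-11th grade", "High school",
                      "Some college", "College graduate or above")
marital_levels <- c("Married", "Widowed", "Divorced", "Separated",
                    "Never married", "Living with partner")

#' Configuration for the synthetic cohort generator
#'
#' Bundles the marginal distributions of the predictors and the log-odds
#' effect sizes that drive the binary outcome. Defaults emulate an adult
#' health-survey cohort with roughly 3% outcome prevalence in which risk
#' rises with age and BMI, is highest for Mexican American participants,
#' and falls with education and with the family poverty income ratio.
#'
#' Effects are on the log-odds scale. The intercept is not a free
#' parameter: it is calibrated at generation time so that the expected
#' prevalence given the drawn covariates equals `target_prevalence`.
#'
#' @param target_prevalence Expected outcome proportion, in (0, 1).
#' @param age_per_decade Log-odds increase per decade of age (centred at 50).
#' @param bmi_per_unit Log-odds increase per kg/m2 of BMI (centred at 28.77).
#' @param race Named log-odds contrasts versus Non-Hispanic White; names must
#'   be a subset of the race levels.
#' @param education_per_level Log-odds change per ordered education level
#'   (centred at the middle level); negative means more education is
#'   protective.
#' @param pir_per_unit Log-odds change per unit of poverty income ratio.
#' @param gender_female Log-odds contrast for female versus male.
#' @param missing_rates Default per-field missingness rates used by
#'   [inject_missing()]; only `education` and `marital` may be missing.
#' @return An object of class `"cohort_config"`.
#' @examples
#' cfg <- cohort_config()
#' cfg$target_prevalence
#' @export
cohort_config <- function(target_prevalence = 0.03,
                          age_per_decade = 0.55,
                          bmi_per_unit = 0.10,
                          race = c("Mexican American" = 0.90,
                                   "Other Hispanic" = 0.35,
                                   "Non-Hispanic Black" = 0.45,
                                   "Other" = 0.30),
                          education_per_level = -0.15,
                          pir_per_unit = -0.20,
                          gender_female = 0,
                          missing_rates = c(education = 9 / 4677,
                                            marital = 2 / 4677)) {
  effs <- c(target_prevalence, age_per_decade, bmi_per_unit, race,
            education_per_level, pir_per_unit, gender_female)
  if (!all(is.finite(effs)))
    stop("all effect terms and the target prevalence must be finite")
  if (target_prevalence <= 0 || target_prevalence >= 1)
    stop("target_prevalence must lie strictly inside (0, 1)")
  if (length(race) && !all(names(race) %in% race_levels))
    stop("race contrast names must be race levels")
  structure(list(
    target_prevalence = target_prevalence,
    age_per_decade = age_per_decade,
    bmi_per_unit = bmi_per_unit,
    race = race,
    education_per_level = education_per_level,
    pir_per_unit = pir_per_unit,
    gender_female = gender_female,
    missing_rates = missing_rates,
    ## marginals: survey-style frequencies for categorical predictors and
    ## age decades; moment-matched gamma (PIR) and normal (BMI) continuous
    ## marginals, independent by default
    marginals = list(
      gender = c(Male = 0.479, Female = 0.521),
      age_bands = c(`20` = 0.205, `30` = 0.195, `40` = 0.203,
                    `50` = 0.157, `60` = 0.141, `70` = 0.097),
      race = c(0.188, 0.104, 0.481, 0.172, 0.055),
      education = c(0.111, 0.158, 0.234, 0.283, 0.215),
      marital = c(0.518, 0.050, 0.107, 0.035, 0.196, 0.093),
      pir_mean = 2.46, pir_sd = 1.65, pir_cap = 5,
      bmi_mean = 28.77, bmi_sd = 6.67, bmi_range = c(14, 70)
    )
  ), class = "cohort_config")
}

empty_cohort <- function() {
  data.frame(
    gender = factor(character(), levels = gender_levels),
    age = integer(),
    race = factor(character(), levels = race_levels),
    education = factor(character(), levels = education_levels,
                       ordered = TRUE),
    marital = factor(character(), levels = marital_levels),
    pir = numeric(),
    bmi = numeric(),
    outcome = integer(),
    weight = numeric(),
    stringsAsFactors = FALSE
  )
}

#' Linear predictor of the cohort risk model
#'
#' The log-odds of the outcome for each row, excluding the calibrated
#' intercept. Useful for checking monotonicity properties of the generator
#' without resampling outcomes.
#'
#' @param table A cohort data frame (see [generate_cohort()]).
#' @param config A [cohort_config()].
#' @return Numeric vector, one value per row.
#' @export
cohort_linear_predictor <- function(table, config = cohort_config()) {
  m <- config$marginals
  lp <- config$age_per_decade * (table$age - 50) / 10 +
    config$bmi_per_unit * (table$bmi - m$bmi_mean) +
    config$pir_per_unit * (table$pir - m$pir_mean)
  if (length(config$race)) {
    rc <- config$race[as.character(table$race)]
    rc[is.na(rc)] <- 0
    lp <- lp + unname(rc)
  }
  edu <- as.integer(table$education)
  edu[is.na(edu)] <- 3L
  lp <- lp + config$education_per_level * (edu - 3L)
  lp + config$gender_female * (table$gender == "Female")
}

#' Generate a synthetic low-prevalence cohort
#'
#' Draws `n` independent participants: categorical predictors from
#' survey-style marginal frequencies, age uniform within sampled decade
#' bands (20--85 years), poverty income ratio from a moment-matched gamma
#' top-coded at 5, and BMI from a truncated normal. The binary outcome is
#' Bernoulli with probability `plogis(intercept + lp)`, where `lp` is the
#' configured log-odds linear predictor and the intercept is calibrated by
#' root finding so the mean outcome probability over the drawn covariates
#' equals `config$target_prevalence`.
#'
#' Predictors are generated complete; use [inject_missing()] to blank
#' education/marital cells. All weights are 1.
#'
#' @param n Number of rows (may be 0).
#' @param config A [cohort_config()].
#' @param seed Integer seed; the same seed regenerates the table exactly.
#' @return A data frame with columns gender, age, race, education, marital,
#'   pir, bmi, outcome (0/1 integer), weight.
#' @examples
#' coh <- generate_cohort(500, seed = 1)
#' mean(coh$outcome)
#' @export
generate_cohort <- function(n, config = cohort_config(), seed = 1) {
  stopifnot(inherits(config, "cohort_config"))
  if (length(n) != 1 || is.na(n) || n < 0)
    stop("n must be a single nonnegative count")
  n <- as.integer(n)
  if (n == 0L) return(empty_cohort())
  m <- config$marginals
  with_seed(child_seed(seed, "cohort"), {
    gender <- factor(sample(gender_levels, n, TRUE, prob = m$gender),
                     levels = gender_levels)
    band <- sample(as.integer(names(m$age_bands)), n, TRUE,
                   prob = m$age_bands)
    width <- ifelse(band == 70L, 16L, 10L)  # 70+ band runs to 85
    age <- band + as.integer(floor(stats::runif(n) * width))
    race <- factor(sample(race_levels, n, TRUE, prob = m$race),
                   levels = race_levels)
    education <- factor(sample(education_levels, n, TRUE,
                               prob = m$education),
                        levels = education_levels, ordered = TRUE)
    marital <- factor(sample(marital_levels, n, TRUE, prob = m$marital),
                      levels = marital_levels)
    shape <- (m$pir_mean / m$pir_sd)^2
    rate <- m$pir_mean / m$pir_sd^2
    pir <- pmin(stats::rgamma(n, shape = shape, rate = rate), m$pir_cap)
    bmi <- pmin(pmax(stats::rnorm(n, m$bmi_mean, m$bmi_sd),
                     m$bmi_range[1]), m$bmi_range[2])
    tab <- data.frame(gender, age, race, education, marital,
                      pir = pir, bmi = bmi, outcome = 0L, weight = 1,
                      stringsAsFactors = FALSE)
    lp <- cohort_linear_predictor(tab, config)
    ## calibrate the intercept so E[prevalence | covariates] hits target
    f <- function(b0) mean(stats::plogis(b0 + lp)) - config$target_prevalence
    b0 <- stats::uniroot(f, c(-40, 40), tol = 1e-10)$root
    tab$outcome <- stats::rbinom(n, 1L, stats::plogis(b0 + lp))
    tab
  })
}

#' Blank education/marital cells at given rates
#'
#' Emulates the sparse item nonresponse of survey cohorts: each eligible
#' cell is independently set to missing with its field's rate. Only the
#' `education` and `marital` fields may receive missingness; outcome, age
#' and BMI are never touched.
#'
#' @param table A cohort data frame.
#' @param rates Named numeric vector of rates in `[0, 1]`; names must be a
#'   subset of `c("education", "marital")`.
#' @param seed Integer seed.
#' @return The table with cells blanked.
#' @export
inject_missing <- function(table, rates = cohort_config()$missing_rates,
                           seed = 1) {
  if (is.null(names(rates)) || !all(names(rates) %in% c("education",
                                                        "marital")))
    stop("missingness rates may only be supplied for education and marital")
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  n <- nrow(table)
  if (n == 0L) return(table)
  with_seed(child_seed(seed, "missing"), {
    for (fld in names(rates)) {
      hit <- stats::runif(n) < rates[[fld]]
      table[[fld]][hit] <- NA
    }
  })
  table
}

#' Split a cohort into training and testing sets
#'
#' Unstratified simple random sampling without replacement: `n_train` rows
#' form the training set and the remainder the testing set; together they
#' partition the input exactly.
#'
#' @param table A cohort data frame.
#' @param n_train Training-set size; defaults to `floor(0.7 * nrow(table))`.
#' @param seed Integer seed.
#' @return A list with elements `train` and `test`.
#' @examples
#' sp <- split_train_test(generate_cohort(100, seed = 1), seed = 2)
#' nrow(sp$train); nrow(sp$test)
#' @export
split_train_test <- function(table, n_train = floor(0.7 * nrow(table)),
                             seed = 1) {
  n <- nrow(table)
  if (length(n_train) != 1 || is.na(n_train) || n_train < 0 || n_train > n)
    stop("n_train must lie in [0, nrow(table)]")
  n_train <- as.integer(n_train)
  idx <- with_seed(child_seed(seed, "split"), sample.int(n, n_train))
  list(train = table[sort(idx), , drop = FALSE],
       test = table[setdiff(seq_len(n), sort(idx)), , drop = FALSE])
}

#' Read / write a cohort as CSV
#'
#' Plain UTF-8 CSV with a header row and the fixed column set
#' `gender, age, race, education, marital, pir, bmi, outcome, weight`;
#' empty strings encode missing values.
#'
#' @param table A cohort data frame.
#' @param path File path.
#' @return `read_cohort` returns the cohort data frame; `write_cohort`
#'   returns `path` invisibly.
#' @export
write_cohort <- function(table, path) {
  stopifnot(all(cohort_columns %in% names(table)))
  utils::write.csv(table[cohort_columns], path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                         fileEncoding = "UTF-8")
  miss <- setdiff(cohort_columns, names(raw))
  if (length(miss))
    stop("cohort CSV is missing columns: ", paste(miss, collapse = ", "))
  lv <- function(x, canon) factor(x, levels = union(canon, unique(x[!is.na(x)])))
  data.frame(
    gender = lv(raw$gender, gender_levels),
    age = as.integer(raw$age),
    race = lv(raw$race, race_levels),
    education = factor(raw$education,
                       levels = union(education_levels,
                                      unique(raw$education[!is.na(raw$education)])),
                       ordered = TRUE),
    marital = lv(raw$marital, marital_levels),
    pir = as.numeric(raw$pir),
    bmi = as.numeric(raw$bmi),
    outcome = as.integer(raw$outcome),
    weight = if (all(is.na(raw$weight))) rep(1, nrow(raw))
             else as.numeric(raw$weight),
    stringsAsFactors = FALSE
  )
}
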