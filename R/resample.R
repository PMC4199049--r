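## Resampling designs for class-imbalanced training data: random
## oversampling of cases, random undersampling of controls, and class
## weighting, each to a target case-to-control ratio 1:r.

n_cases <- function(table) sum(table$outcome == 1L)
n_controls <- function(table) sum(table$outcome != 1L)

#' Target number of cases for a case-to-control ratio 1:r
#'
#' Fractional targets round up, so e.g. 3165 controls at ratio 1:2 call
#' for 1583 cases and at 1:4 for 792.
#'
#' @param n_control Number of control rows.
#' @param ratio Positive integer r in the target ratio 1:r.
#' @return Integer case count.
#' @examples
#' target_case_count(3165, 2)
#' @export
target_case_count <- function(n_control, ratio) {
  if (length(ratio) != 1 || is.na(ratio) || ratio <= 0)
    stop("ratio must be a positive integer")
  if (length(n_control) != 1 || is.na(n_control) || n_control < 0)
    stop("n_control must be a nonnegative count")
  as.integer(ceiling(n_control / ratio))
}

#' Randomly oversample the cases of an imbalanced cohort
#'
#' All control rows pass through unchanged; case rows are drawn uniformly
#' with replacement from the original cases until the case count reaches
#' `target_case_count(n_control, ratio)`. Output rows are ordered controls
#' first, then the sampled cases; all weights are reset to 1.
#'
#' @param table A cohort data frame with at least one case and one control.
#' @param ratio Target case-to-control ratio 1:ratio.
#' @param seed Integer seed.
#' @param include_originals If `TRUE`, every original case is included once
#'   before sampling the remainder (only when the target is at least the
#'   original case count). Default `FALSE`: pure uniform sampling.
#' @return The resampled cohort data frame.
#' @examples
#' coh <- generate_cohort(300, seed = 1)
#' table(oversample(coh, ratio = 2, seed = 1)$outcome)
#' @export
oversample <- function(table, ratio = 1, seed = 1,
                       include_originals = FALSE) {
  case_idx <- which(table$outcome == 1L)
  ctrl_idx <- which(table$outcome != 1L)
  if (!length(case_idx) || !length(ctrl_idx))
    stop("oversampling requires at least one case and one control")
  m <- target_case_count(length(ctrl_idx), ratio)
  draw <- with_seed(child_seed(seed, "oversample", ratio), {
    if (include_originals && m >= length(case_idx))
      c(case_idx, sample(case_idx, m - length(case_idx), replace = TRUE))
    else sample(case_idx, m, replace = TRUE)
  })
  out <- table[c(ctrl_idx, draw), , drop = FALSE]
  out$weight <- 1
  rownames(out) <- NULL
  out
}

#' Randomly undersample the controls of an imbalanced cohort
#'
#' All case rows pass through unchanged; exactly `ratio * n_case` controls
#' are drawn uniformly without replacement. All weights are reset to 1.
#'
#' @inheritParams oversample
#' @return The undersampled cohort data frame (cases first, then the
#'   selected controls in their original order).
#' @export
undersample <- function(table, ratio = 1, seed = 1) {
  case_idx <- which(table$outcome == 1L)
  ctrl_idx <- which(table$outcome != 1L)
  if (!length(case_idx) || !length(ctrl_idx))
    stop("undersampling requires at least one case and one control")
  k <- as.integer(ratio * length(case_idx))
  if (k > length(ctrl_idx))
    stop("too few controls for the requested case-to-control ratio")
  keep <- with_seed(child_seed(seed, "undersample", ratio),
                    sort(sample(ctrl_idx, k)))
  out <- table[c(case_idx, keep), , drop = FALSE]
  out$weight <- 1
  rownames(out) <- NULL
  out
}

#' Reweight classes to a target case-to-control ratio
#'
#' Leaves the rows untouched and sets control weights to 1 and each case
#' weight to `n_control / (ratio * n_case)`, so that total case weight :
#' total control weight = 1 : ratio exactly.
#'
#' @inheritParams oversample
#' @return The cohort with adjusted `weight` column.
#' @examples
#' coh <- generate_cohort(300, seed = 1)
#' unique(class_weights(coh)$weight)
#' @export
class_weights <- function(table, ratio = 1) {
  nc <- n_cases(table); n0 <- n_controls(table)
  if (!nc || !n0) stop("class weighting requires both classes nonempty")
  if (ratio <= 0) stop("ratio must be a positive integer")
  table$weight <- ifelse(table$outcome == 1L, n0 / (ratio * nc), 1)
  table
}

#' Resampling plan
#'
#' A small descriptor of how a training dataset is rebalanced: one of
#' `none` (leave as is), `weight`, `oversample`, `undersample`, together
#' with the target case-to-control ratio 1:ratio and a seed.
#'
#' @param method One of `"none"`, `"weight"`, `"oversample"`,
#'   `"undersample"`.
#' @param ratio Positive integer r (case:control = 1:r).
#' @param seed Integer seed for the stochastic methods.
#' @return An object of class `"resampling_plan"`.
#' @export
resampling_plan <- function(method = c("none", "weight", "oversample",
                                       "undersample"),
                            ratio = 1, seed = 1) {
  method <- match.arg(method)
  if (length(ratio) != 1 || is.na(ratio) || ratio < 1 ||
      ratio != as.integer(ratio))
    stop("ratio must be a positive integer")
  structure(list(method = method, ratio = as.integer(ratio),
                 seed = as.integer(seed)),
            class = "resampling_plan")
}

#' Apply a resampling plan to a training table
#'
#' @param table A cohort data frame.
#' @param plan A [resampling_plan()].
#' @return The rebalanced training table (`method = "none"` returns the
#'   input unchanged).
#' @export
apply_resampling <- function(table, plan) {
  stopifnot(inherits(plan, "resampling_plan"))
  switch(plan$method,
         none = table,
         weight = class_weights(table, plan$ratio),
         oversample = oversample(table, plan$ratio, plan$seed),
         undersample = undersample(table, plan$ratio, plan$seed))
}

#' @export
print.resampling_plan <- function(x, ...) {
  cat(sprintf("resampling plan: %s, case:control = 1:%d, seed %d\n",
              x$method, x$ratio, x$seed))
  invisible(x)
}
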