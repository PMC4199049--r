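## Random forest on the cart engine: bootstrap aggregation of unpruned
## Gini trees with a fresh random predictor subset at every node.

#' Fit a random forest of classification trees
#'
#' Grows `B` unpruned trees, each on a bootstrap resample of the rows
#' (n draws with replacement; with non-unit weights the draw probability
#' is proportional to weight, and trees are grown unweighted). At every
#' node the split search is restricted to `mtry` predictors drawn fresh.
#' Trees are grown to purity subject to `minbucket`.
#'
#' @inheritParams cart
#' @param B Number of trees.
#' @param mtry Predictors sampled per node; default `floor(sqrt(p))`.
#' @param minbucket Minimum child size (rows), default 1.
#' @param seed Integer seed; per-tree child seeds are derived from it.
#' @param bootstrap Set `FALSE` to grow every tree on the full data
#'   (useful only for degenerate single-tree checks).
#' @return An object of class `"cart_forest"` with `print` and `predict`
#'   methods; `$oob` holds each tree's out-of-bag row indices.
#' @examples
#' coh <- generate_cohort(200, seed = 1)
#' fit <- fit_forest(outcome ~ ., coh, B = 10, seed = 2)
#' summary(predict(fit, coh))
#' @export
fit_forest <- function(formula = outcome ~ ., data, weights = NULL,
                       B = 500, mtry = NULL, minbucket = 1, seed = 1,
                       bootstrap = TRUE) {
  if (B < 1) stop("B must be at least 1")
  inp <- resolve_cart_inputs(formula, data, weights)
  if (!any(inp$y == 1) || !any(inp$y == 0))
    stop("both classes must be present")
  n <- nrow(data)
  p <- length(inp$vars)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))
  if (mtry < 1 || mtry > p) stop("mtry must lie in [1, p]")
  prep <- tree_prep(data, inp$vars, inp$y, rep(1, n))
  trees <- vector("list", B)
  oob <- vector("list", B)
  for (b in seq_len(B)) {
    res <- with_seed(child_seed(seed, "tree", b), {
      idx <- if (bootstrap)
        sample.int(n, n, replace = TRUE,
                   prob = if (all(inp$w == inp$w[1])) NULL else inp$w)
      else seq_len(n)
      root_risk <- {
        w1 <- sum(prep$y[idx]); min(w1, length(idx) - w1)
      }
      list(root = grow_node(prep, idx, cp = 0, minsplit = 2 * minbucket,
                            minbucket = minbucket, root_risk = root_risk,
                            mtry = mtry),
           oob = setdiff(seq_len(n), idx))
    })
    trees[[b]] <- res$root
    oob[[b]] <- res$oob
  }
  structure(list(trees = trees, oob = oob, B = B, mtry = mtry,
                 seed = seed, vars = inp$vars, n = n,
                 prevalence = sum(inp$w * inp$y) / sum(inp$w),
                 call = match.call()),
            class = "cart_forest")
}

#' Predict from a random forest
#'
#' The forest score of a row is the mean over trees of the leaf case
#' proportion the row lands in.
#'
#' @param object A [fit_forest()] model.
#' @param newdata Data frame of rows to score.
#' @param type `"prob"` (default) or `"class"` at `threshold`.
#' @param threshold Cutoff for `type = "class"`; defaults to the training
#'   prevalence.
#' @param ... Unused.
#' @return Numeric scores in `[0, 1]`, or 0/1 calls.
#' @export
predict.cart_forest <- function(object, newdata,
                                type = c("prob", "class"),
                                threshold = NULL, ...) {
  type <- match.arg(type)
  n <- nrow(newdata)
  acc <- numeric(n)
  for (b in seq_along(object$trees))
    acc <- acc + route_leaf_values(object$trees[[b]], newdata,
                                   seq_len(n), numeric(n),
                                   function(nd) nd$p1,
                                   warn_unseen = (b == 1L))
  p <- acc / object$B
  if (type == "prob") return(p)
  if (is.null(threshold)) threshold <- object$prevalence
  as.integer(p >= threshold)
}

#' @export
print.cart_forest <- function(x, ...) {
  cat(sprintf(
    "Random forest: %d trees, mtry = %d of %d predictors, n = %d\n",
    x$B, x$mtry, length(x$vars), x$n))
  cat(sprintf("Mean out-of-bag fraction: %.3f\n",
              mean(lengths(x$oob)) / x$n))
  invisible(x)
}
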