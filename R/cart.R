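## Classification tree (CART) on the weighted Gini engine. Splits are
## chosen to maximise the Gini impurity decrease; a chosen split is kept
## only if it lowers the weighted misclassification risk by at least
## cp * (root risk), mirroring rpart's complexity scale. Growing therefore
## uses impurity while stopping and pruning use risk.

## Recursive growth over row indices. `mtry`, when given, samples that many
## predictors afresh at every node (used by the forest).
grow_node <- function(prep, idx, cp, minsplit, minbucket, root_risk,
                      mtry = NULL, maxdepth = Inf, depth = 0L) {
  w <- prep$w[idx]; y <- prep$y[idx]
  w1 <- sum(w * y); wt <- sum(w); w2 <- wt - w1
  node <- list(n = length(idx), w = wt, w1 = w1, w2 = w2,
               p1 = if (wt > 0) w1 / wt else 0,
               label = as.integer(w1 > w2),
               risk = min(w1, w2),
               split = NULL, left = NULL, right = NULL)
  if (wt < minsplit - .split_eps || w1 <= .split_eps || w2 <= .split_eps ||
      depth >= maxdepth)
    return(node)
  vars <- prep$vars
  if (!is.null(mtry) && mtry < length(vars))
    vars <- sort(sample(vars, mtry))
  s <- best_split_at(prep, idx, minbucket, vars)
  if (is.null(s)) return(node)
  xv <- prep$x[[s$var]][idx]
  if (s$type == "numeric") {
    gl <- xv < s$threshold
  } else {
    gl <- as.character(xv) %in% s$levels_left
    gl[is.na(xv)] <- isTRUE(s$missing_left)
    s$known_levels <- levels(prep$x[[s$var]])
  }
  lidx <- idx[gl]; ridx <- idx[!gl]
  l1 <- sum(prep$w[lidx] * prep$y[lidx]); lw <- sum(prep$w[lidx])
  r1 <- w1 - l1; rw <- wt - lw
  if (s$type == "numeric") s$missing_left <- lw >= rw
  ## risk gate: the split must cut weighted misclassification by
  ## cp * root risk
  risk_dec <- node$risk - (min(l1, lw - l1) + min(r1, rw - r1))
  if (risk_dec < cp * root_risk - .split_eps) return(node)
  node$split <- s
  node$left <- grow_node(prep, lidx, cp, minsplit, minbucket, root_risk,
                         mtry, maxdepth, depth + 1L)
  node$right <- grow_node(prep, ridx, cp, minsplit, minbucket, root_risk,
                          mtry, maxdepth, depth + 1L)
  node
}

## Route rows down a tree, filling each row's entry with leaf_fun(leaf).
route_leaf_values <- function(node, data, idx, out, leaf_fun,
                              warn_unseen = TRUE) {
  if (is.null(node$split)) {
    out[idx] <- leaf_fun(node)
    return(out)
  }
  gl <- rule_goes_left(node$split, data[[node$split$var]][idx], warn_unseen)
  out <- route_leaf_values(node$left, data, idx[gl], out, leaf_fun,
                           warn_unseen)
  route_leaf_values(node$right, data, idx[!gl], out, leaf_fun, warn_unseen)
}

resolve_cart_inputs <- function(formula, data, weights) {
  resp <- all.vars(formula[[2]])
  if (length(resp) != 1 || !resp %in% names(data))
    stop("the response must be a single column of `data`")
  tl <- attr(stats::terms(formula, data = data), "term.labels")
  if (!all(tl %in% names(data)))
    stop("predictors must be plain columns of `data` (no transformations)")
  vars <- setdiff(tl, c(resp, "weight"))
  if (!length(vars)) stop("no predictors in formula")
  yr <- data[[resp]]
  y <- if (is.factor(yr)) as.integer(yr == levels(yr)[2])
       else as.integer(yr)
  if (any(is.na(y)) || !all(y %in% c(0L, 1L)))
    stop("the response must be binary (0/1, logical, or a 2-level factor ",
         "whose second level is the case)")
  if (is.null(weights))
    weights <- if ("weight" %in% names(data)) data$weight
               else rep(1, nrow(data))
  if (length(weights) != nrow(data) || any(!is.finite(weights)) ||
      any(weights <= 0))
    stop("weights must be positive and finite, one per row")
  list(y = y, w = as.numeric(weights), vars = vars, response = resp)
}

#' Fit a classification tree by recursive Gini partitioning
#'
#' From-scratch CART for a binary outcome with case weights. Each node is
#' split by the predictor/threshold (or level subset) maximising the
#' decrease in weighted Gini impurity; a node is split only when its total
#' weight is at least `minsplit`, it is impure, and the chosen split
#' lowers the weighted misclassification risk by at least `cp` times the
#' root risk. Size constraints count total weight, so integer case
#' weights are exactly equivalent to replicated rows.
#'
#' @param formula Model formula, e.g. `outcome ~ .`; the `weight` column
#'   is never used as a predictor. The response must be 0/1, logical, or
#'   a two-level factor whose second level is the case.
#' @param data A data frame (typically a cohort from
#'   [generate_cohort()]).
#' @param weights Optional positive case weights; defaults to the
#'   `weight` column when present, else 1.
#' @param cp Complexity parameter: minimum risk decrease of a kept split,
#'   as a fraction of the root risk.
#' @param minsplit Minimum total node weight eligible for splitting.
#' @param minbucket Minimum total child weight.
#' @param maxdepth Maximum tree depth (root = depth 0).
#' @return An object of class `"cart"` with `print`, `summary`,
#'   `predict` and `residuals` methods.
#' @seealso [cart_1se()] for cross-validated complexity selection,
#'   [cost_complexity_prune()], [fit_forest()], [fit_boost()].
#' @examples
#' coh <- generate_cohort(600, seed = 1)
#' fit <- cart(outcome ~ ., data = undersample(coh, ratio = 1, seed = 2))
#' fit
#' @export
cart <- function(formula = outcome ~ ., data, weights = NULL, cp = 0.01,
                 minsplit = 20, minbucket = max(1, round(minsplit / 3)),
                 maxdepth = Inf) {
  if (!nrow(data)) stop("cannot grow a tree on an empty table")
  if (cp < 0) stop("cp must be nonnegative")
  if (minbucket > minsplit) stop("minbucket must not exceed minsplit")
  inp <- resolve_cart_inputs(formula, data, weights)
  prep <- tree_prep(data, inp$vars, inp$y, inp$w)
  root_risk <- min(sum(prep$w * prep$y), sum(prep$w * (1 - prep$y)))
  root <- grow_node(prep, seq_len(nrow(data)), cp, minsplit, minbucket,
                    root_risk, maxdepth = maxdepth)
  obj <- structure(list(
    root = root, call = match.call(), vars = inp$vars,
    response = inp$response, cp = cp, minsplit = minsplit,
    minbucket = minbucket, maxdepth = maxdepth,
    root_risk = root_risk, n = nrow(data),
    prevalence = root$p1, y = inp$y, w = inp$w
  ), class = "cart")
  obj$fitted <- route_leaf_values(root, data, seq_len(nrow(data)),
                                  numeric(nrow(data)),
                                  function(nd) nd$p1, warn_unseen = FALSE)
  obj
}

n_leaves <- function(node) {
  if (is.null(node$split)) 1L
  else n_leaves(node$left) + n_leaves(node$right)
}

n_nodes <- function(node) {
  if (is.null(node$split)) 1L
  else 1L + n_nodes(node$left) + n_nodes(node$right)
}

tree_depth <- function(node) {
  if (is.null(node$split)) 0L
  else 1L + max(tree_depth(node$left), tree_depth(node$right))
}

tree_vars_used <- function(node) {
  if (is.null(node$split)) character()
  else unique(c(node$split$var, tree_vars_used(node$left),
                tree_vars_used(node$right)))
}

subtree_leaf_risk <- function(node) {
  if (is.null(node$split)) node$risk
  else subtree_leaf_risk(node$left) + subtree_leaf_risk(node$right)
}

rule_text <- function(rule, left) {
  if (rule$type == "numeric") {
    sprintf("%s %s %.4g", rule$var, if (left) "<" else ">=", rule$threshold)
  } else {
    lv <- if (left) rule$levels_left
          else setdiff(rule$known_levels, rule$levels_left)
    sprintf("%s in {%s}", rule$var, paste(lv, collapse = ", "))
  }
}

render_node <- function(node, label, indent) {
  line <- sprintf("%s%s  n=%d, w=%.6g, case%%=%.1f%%%s",
                  strrep("  ", indent), label, node$n, node$w,
                  100 * node$p1,
                  if (is.null(node$split)) " *" else "")
  if (is.null(node$split)) return(line)
  c(line,
    render_node(node$left, rule_text(node$split, TRUE), indent + 1L),
    render_node(node$right, rule_text(node$split, FALSE), indent + 1L))
}

#' @export
print.cart <- function(x, ...) {
  cat(sprintf(
    "Classification tree (Gini): n=%d, %d leaves, depth %d, cp=%g\n",
    x$n, n_leaves(x$root), tree_depth(x$root), x$cp))
  cat("Leaves are marked '*'; case%% is the weighted case proportion.\n")
  cat(render_node(x$root, "root", 0L), sep = "\n")
  invisible(x)
}

#' @export
summary.cart <- function(object, ...) {
  r <- object$root
  res <- list(
    n = object$n, leaves = n_leaves(r), nodes = n_nodes(r),
    depth = tree_depth(r), variables = sort(tree_vars_used(r)),
    prevalence = object$prevalence,
    root_risk = object$root_risk,
    tree_risk = subtree_leaf_risk(r),
    cp = object$cp
  )
  class(res) <- "summary.cart"
  res
}

#' @export
print.summary.cart <- function(x, ...) {
  cat(sprintf("Classification tree: n=%d, %d leaves (%d nodes), depth %d\n",
              x$n, x$leaves, x$nodes, x$depth))
  cat(sprintf("Training case proportion (weighted): %.4f\n", x$prevalence))
  cat(sprintf("Risk: %.6g at root -> %.6g at leaves (cp=%g)\n",
              x$root_risk, x$tree_risk, x$cp))
  cat("Splitting variables:",
      if (length(x$variables)) paste(x$variables, collapse = ", ")
      else "(none - root-only tree)", "\n")
  invisible(x)
}

#' Predict from a classification tree
#'
#' Routes each row down the tree; rows with a missing (or unseen) split
#' value follow the split's stored majority-weight direction, with a
#' warning for unseen categorical levels.
#'
#' @param object A fitted [cart()] tree.
#' @param newdata Data frame of rows to score.
#' @param type `"prob"` for the leaf's weighted case proportion,
#'   `"class"` for a 0/1 call at `threshold`.
#' @param threshold Score cutoff for `type = "class"`; defaults to the
#'   weighted training prevalence (see the package vignette for why a 0.5
#'   cutoff is uninformative on imbalanced training data).
#' @param ... Unused.
#' @return Numeric vector of probabilities, or integer 0/1 calls.
#' @export
predict.cart <- function(object, newdata, type = c("prob", "class"),
                         threshold = NULL, ...) {
  type <- match.arg(type)
  p <- route_leaf_values(object$root, newdata, seq_len(nrow(newdata)),
                         numeric(nrow(newdata)), function(nd) nd$p1)
  if (type == "prob") return(p)
  if (is.null(threshold)) threshold <- object$prevalence
  as.integer(p >= threshold)
}

#' @export
residuals.cart <- function(object, ...) object$y - object$fitted
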