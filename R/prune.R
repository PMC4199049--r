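## Cost-complexity (weakest-link) pruning and cross-validated complexity
## selection by the 1-SE rule. Risk is the weighted misclassification
## count under majority-vote labelling; alpha is the per-leaf risk price,
## and cp = alpha / (root risk) is the normalised complexity scale.

.risk_eps <- 1e-9

## Optimal subtree at penalty alpha, by bottom-up collapse of every
## internal node whose weakest-link value g = (risk gain)/(leaves - 1)
## does not exceed alpha.
prune_node_at <- function(node, alpha) {
  if (is.null(node$split)) return(node)
  node$left <- prune_node_at(node$left, alpha)
  node$right <- prune_node_at(node$right, alpha)
  g <- (node$risk - subtree_leaf_risk(node)) / (n_leaves(node) - 1L)
  if (g <= alpha + .risk_eps) {
    node$split <- NULL; node$left <- NULL; node$right <- NULL
  }
  node
}

min_weak_link <- function(node) {
  if (is.null(node$split)) return(Inf)
  g <- (node$risk - subtree_leaf_risk(node)) / (n_leaves(node) - 1L)
  min(g, min_weak_link(node$left), min_weak_link(node$right))
}

#' Cost-complexity prune sequence of a tree
#'
#' Weakest-link pruning: starting from the fitted tree, repeatedly
#' collapse the internal node(s) with the smallest risk increase per leaf
#' removed, recording the complexity threshold alpha at each collapse.
#' The result is a nested sequence of subtrees ending at the root-only
#' tree, with strictly increasing alphas.
#'
#' @param object A fitted [cart()] tree.
#' @return An object of class `"prune_sequence"`: a list with `table`
#'   (columns `alpha`, `cp`, `leaves`, `risk`) and `trees`, the
#'   corresponding subtree roots.
#' @export
cost_complexity_prune <- function(object) {
  stopifnot(inherits(object, "cart"))
  cur <- prune_node_at(object$root, 0)
  alphas <- 0
  trees <- list(cur)
  while (!is.null(cur$split)) {
    g <- min_weak_link(cur)
    cur <- prune_node_at(cur, g)
    alphas <- c(alphas, g)
    trees <- c(trees, list(cur))
  }
  rr <- object$root_risk
  tab <- data.frame(
    alpha = alphas,
    cp = if (rr > 0) alphas / rr else alphas,
    leaves = vapply(trees, n_leaves, integer(1)),
    risk = vapply(trees, subtree_leaf_risk, numeric(1))
  )
  structure(list(table = tab, trees = trees, root_risk = rr),
            class = "prune_sequence")
}

#' @export
print.prune_sequence <- function(x, ...) {
  cat("Cost-complexity prune sequence (risk = weighted misclassification):\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Prune a fitted tree at a complexity threshold
#'
#' @param object A fitted [cart()] tree.
#' @param alpha Complexity threshold on the risk scale; alternatively give
#'   `cp = alpha / root risk`.
#' @param cp Normalised complexity parameter (used when `alpha` is NULL).
#' @return The pruned `"cart"` object (fitted values are dropped).
#' @export
prune_tree <- function(object, alpha = NULL, cp = NULL) {
  stopifnot(inherits(object, "cart"))
  if (is.null(alpha)) {
    if (is.null(cp)) stop("supply alpha or cp")
    alpha <- cp * object$root_risk
  }
  object$root <- prune_node_at(object$root, alpha)
  object$pruned_alpha <- alpha
  object$fitted <- NULL
  object
}

## Stratified fold assignment; re-deals with successive seeds until every
## training complement contains both classes.
stratified_folds <- function(y, w, folds, seed, max_attempts = 10) {
  n <- length(y)
  for (a in seq_len(max_attempts)) {
    f <- integer(n)
    with_seed(child_seed(seed + a - 1L, "folds"), {
      for (cls in unique(y)) {
        id <- which(y == cls)
        f[id] <- sample(rep_len(seq_len(folds), length(id)))
      }
    })
    ok <- all(vapply(seq_len(folds), function(k) {
      tr <- y[f != k]
      length(tr) > 0 && any(tr == 1) && any(tr == 0) && any(f == k)
    }, logical(1)))
    if (ok) return(f)
  }
  stop("could not deal ", folds,
       "-fold split with both classes in every training fold")
}

## The 1-SE pick: index of the largest alpha whose cv risk is within one
## standard error of the minimum. `cv_risk` must be ordered by increasing
## alpha.
pick_1se <- function(cv_risk, cv_se) {
  imin <- which.min(cv_risk)
  max(which(cv_risk <= cv_risk[imin] + cv_se[imin] + .risk_eps))
}

#' Select the complexity parameter by the 1-SE rule
#'
#' Grows an unpenalised tree, computes its cost-complexity prune
#' sequence, estimates each subtree's misclassification risk by
#' stratified K-fold cross-validation (evaluating at the geometric means
#' of consecutive alphas), and returns the largest alpha whose
#' cross-validated risk is within one standard error of the minimum —
#' i.e. the simplest statistically indistinguishable subtree.
#'
#' @inheritParams cart
#' @param folds Number of cross-validation folds (>= 2).
#' @param seed Integer seed for the fold deal.
#' @return An object of class `"cp_selection"`: list with `cp`, `alpha`,
#'   and `table` (per-subtree alpha, leaves, relative cv risk and SE).
#' @export
select_cp_1se <- function(formula = outcome ~ ., data, weights = NULL,
                          folds = 10, seed = 1, minsplit = 20,
                          minbucket = max(1, round(minsplit / 3))) {
  if (folds < 2) stop("folds must be at least 2")
  inp <- resolve_cart_inputs(formula, data, weights)
  if (!any(inp$y == 1) || !any(inp$y == 0))
    stop("both classes must be present")
  master <- cart(formula, data, weights = inp$w, cp = 0,
                 minsplit = minsplit, minbucket = minbucket)
  ps <- cost_complexity_prune(master)
  alphas <- ps$table$alpha
  K <- length(alphas)
  rr <- master$root_risk
  if (K == 1L || rr <= 0) {
    tab <- data.frame(alpha = alphas, cp = ps$table$cp,
                      leaves = ps$table$leaves,
                      cv_risk = NA_real_, cv_se = NA_real_)
    return(structure(list(cp = ps$table$cp[K], alpha = alphas[K],
                          table = tab, folds = folds, seed = seed),
                     class = "cp_selection"))
  }
  eval_a <- c(sqrt(alphas[-K] * alphas[-1]), alphas[K])
  f <- stratified_folds(inp$y, inp$w, folds, seed)
  loss <- numeric(K)
  for (k in seq_len(folds)) {
    tr <- f != k
    fit <- cart(formula, data[tr, , drop = FALSE], weights = inp$w[tr],
                cp = 0, minsplit = minsplit, minbucket = minbucket)
    te <- data[!tr, , drop = FALSE]
    yte <- inp$y[!tr]; wte <- inp$w[!tr]
    for (j in seq_len(K)) {
      sub <- prune_node_at(fit$root, eval_a[j])
      lab <- route_leaf_values(sub, te, seq_len(nrow(te)),
                               numeric(nrow(te)),
                               function(nd) as.numeric(nd$w1 > nd$w2),
                               warn_unseen = FALSE)
      loss[j] <- loss[j] + sum(wte * (lab != yte))
    }
  }
  W <- sum(inp$w)
  p_err <- loss / W
  cv_se_abs <- sqrt(pmax(p_err * (1 - p_err), 0) * W)
  cv_risk <- loss / rr
  cv_se <- cv_se_abs / rr
  sel <- pick_1se(cv_risk, cv_se)
  tab <- data.frame(alpha = alphas, cp = ps$table$cp,
                    leaves = ps$table$leaves,
                    cv_risk = cv_risk, cv_se = cv_se)
  structure(list(cp = ps$table$cp[sel], alpha = alphas[sel], table = tab,
                 folds = folds, seed = seed),
            class = "cp_selection")
}

#' @export
print.cp_selection <- function(x, ...) {
  cat(sprintf("1-SE complexity selection (%d-fold CV): cp = %.6g, alpha = %.6g\n",
              x$folds, x$cp, x$alpha))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Fit a classification tree with 1-SE complexity selection
#'
#' Convenience wrapper: grows an unpenalised tree, selects the
#' complexity threshold by [select_cp_1se()], and returns the pruned
#' tree.
#'
#' @inheritParams select_cp_1se
#' @return A `"cart"` object, with the selection stored as
#'   `$cp_selection`.
#' @export
cart_1se <- function(formula = outcome ~ ., data, weights = NULL,
                     folds = 10, seed = 1, minsplit = 20,
                     minbucket = max(1, round(minsplit / 3))) {
  sel <- select_cp_1se(formula, data, weights, folds, seed, minsplit,
                       minbucket)
  master <- cart(formula, data, weights, cp = 0, minsplit = minsplit,
                 minbucket = minbucket)
  fit <- prune_tree(master, alpha = sel$alpha)
  fit$cp <- sel$cp
  fit$cp_selection <- sel
  fit
}
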