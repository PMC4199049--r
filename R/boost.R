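## Gradient boosting of the Bernoulli deviance with shallow least-squares
## regression trees and one-step Newton leaf updates (the classic
## stagewise additive logistic model).

## Least-squares split search: maximise the between-child sum of squares
## (equivalently the drop in weighted SSE of the response z).
reg_best_split_at <- function(xlist, idx, z, w, minbucket, vars) {
  Wt <- sum(w[idx]); St <- sum(w[idx] * z[idx])
  best <- NULL
  for (v in vars) {
    xv <- xlist[[v]][idx]
    if (is.numeric(xv)) {
      o <- order(xv)
      xs <- xv[o]; ws <- w[idx][o]; zs <- z[idx][o]
      nn <- length(xs)
      if (nn < 2L || xs[1] == xs[nn]) next
      cw <- cumsum(ws); cs <- cumsum(ws * zs)
      b <- which(xs[-nn] < xs[-1])
      lw <- cw[b]; ls <- cs[b]; rw <- Wt - lw; rs <- St - ls
      ok <- lw >= minbucket - .split_eps & rw >= minbucket - .split_eps
      if (!any(ok)) next
      dec <- ls^2 / lw + rs^2 / rw - St^2 / Wt
      dec[!ok] <- -Inf
      i <- which.max(dec)
      if (dec[i] > .split_eps &&
          (is.null(best) || dec[i] > best$decrease + .split_eps)) {
        pos <- b[i]
        best <- list(var = v, type = "numeric",
                     threshold = (xs[pos] + xs[pos + 1]) / 2,
                     levels_left = NULL, missing_left = lw[i] >= rw[i],
                     decrease = dec[i])
      }
    } else {
      obs <- !is.na(xv)
      if (!any(obs)) next
      fo <- factor(xv[obs])
      if (nlevels(fo) < 2L) next
      wo <- w[idx][obs]; zo <- z[idx][obs]
      lw_ <- rowsum(wo, fo)[, 1]
      ls_ <- rowsum(wo * zo, fo)[, 1]
      ord <- order(ls_ / lw_, names(lw_))
      lev <- levels(fo)[ord]
      cw <- unname(cumsum(lw_[ord])); cs <- unname(cumsum(ls_[ord]))
      Wo <- cw[length(cw)]; So <- cs[length(cs)]
      wm <- Wt - Wo
      k <- length(lev)
      j <- seq_len(k - 1L)
      lw <- cw[j]; ls <- cs[j]; rw <- Wo - lw; rs <- So - ls
      miss_left <- lw >= rw
      lfin <- lw + ifelse(miss_left, wm, 0)
      rfin <- rw + ifelse(miss_left, 0, wm)
      ok <- lfin >= minbucket - .split_eps & rfin >= minbucket - .split_eps
      if (!any(ok)) next
      dec <- (ls^2 / lw + rs^2 / rw - So^2 / Wo) * (Wo / Wt)
      dec[!ok] <- -Inf
      i <- which.max(dec)
      if (dec[i] > .split_eps &&
          (is.null(best) || dec[i] > best$decrease + .split_eps)) {
        best <- list(var = v, type = "categorical",
                     threshold = NA_real_,
                     levels_left = lev[seq_len(i)],
                     missing_left = miss_left[i],
                     decrease = dec[i],
                     known_levels = levels(xlist[[v]]))
      }
    }
  }
  best
}

grow_reg_node <- function(xlist, idx, z, w, minbucket, maxdepth, vars,
                          depth = 0L) {
  node <- list(split = NULL, left = NULL, right = NULL,
               gamma = NA_real_, n = length(idx))
  if (depth >= maxdepth || length(idx) < 2L) return(node)
  s <- reg_best_split_at(xlist, idx, z, w, minbucket, vars)
  if (is.null(s)) return(node)
  gl <- rule_goes_left(s, xlist[[s$var]][idx], warn_unseen = FALSE)
  node$split <- s
  node$left <- grow_reg_node(xlist, idx[gl], z, w, minbucket, maxdepth,
                             vars, depth + 1L)
  node$right <- grow_reg_node(xlist, idx[!gl], z, w, minbucket, maxdepth,
                              vars, depth + 1L)
  node
}

assign_leaf_ids <- function(node, counter) {
  if (is.null(node$split)) {
    counter$k <- counter$k + 1L
    node$leaf_id <- counter$k
    return(node)
  }
  node$left <- assign_leaf_ids(node$left, counter)
  node$right <- assign_leaf_ids(node$right, counter)
  node
}

set_leaf_gammas <- function(node, gammas) {
  if (is.null(node$split)) {
    node$gamma <- gammas[node$leaf_id]
    return(node)
  }
  node$left <- set_leaf_gammas(node$left, gammas)
  node$right <- set_leaf_gammas(node$right, gammas)
  node
}

bernoulli_deviance <- function(y, p, w) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -2 * sum(w * (y * log(p) + (1 - y) * log(1 - p)))
}

#' Fit gradient-boosted trees (Bernoulli deviance)
#'
#' Stagewise additive logistic boosting: the model starts at
#' `F0 = logit(weighted prevalence)`; at each of `M` steps a
#' depth-limited least-squares regression tree is fitted to the negative
#' gradient `y - p` on a `bag_fraction` row subsample, its terminal
#' values are set by a one-step Newton update
#' `sum(w (y - p)) / sum(w p (1 - p))`, and `shrinkage` times the
#' increment is added. Case weights enter both the gradient fit and the
#' Newton updates.
#'
#' @inheritParams cart
#' @param M Number of boosting iterations (trees).
#' @param depth Maximum depth of each regression tree (1 = stumps).
#' @param shrinkage Learning rate in (0, 1].
#' @param bag_fraction Fraction of rows subsampled (without replacement)
#'   at each step.
#' @param min_node Minimum total weight per terminal node.
#' @param seed Integer seed; per-step child seeds are derived from it.
#' @return An object of class `"cart_boost"` with `print` and `predict`
#'   methods; `$train_deviance` traces the weighted training deviance
#'   after each step.
#' @examples
#' coh <- generate_cohort(300, seed = 1)
#' fit <- fit_boost(outcome ~ ., coh, M = 20, seed = 2)
#' range(predict(fit, coh))
#' @export
fit_boost <- function(formula = outcome ~ ., data, weights = NULL,
                      M = 100, depth = 1, shrinkage = 0.1,
                      bag_fraction = 0.5, min_node = 10, seed = 1) {
  if (shrinkage <= 0 || shrinkage > 1)
    stop("shrinkage must lie in (0, 1]")
  if (bag_fraction <= 0 || bag_fraction > 1)
    stop("bag_fraction must lie in (0, 1]")
  if (M < 0) stop("M must be nonnegative")
  if (depth < 1) stop("depth must be at least 1")
  inp <- resolve_cart_inputs(formula, data, weights)
  if (!any(inp$y == 1) || !any(inp$y == 0))
    stop("both classes must be present")
  n <- nrow(data)
  y <- inp$y; w <- inp$w
  prep <- tree_prep(data, inp$vars, y, w)
  F0 <- stats::qlogis(sum(w * y) / sum(w))
  Fv <- rep(F0, n)
  trees <- vector("list", M)
  dev <- numeric(M)
  for (m in seq_len(M)) {
    res <- with_seed(child_seed(seed, "boost", m), {
      bag <- if (bag_fraction < 1)
        sort(sample.int(n, max(1L, floor(bag_fraction * n))))
      else seq_len(n)
      p <- stats::plogis(Fv)
      z <- y - p
      root <- grow_reg_node(prep$x, bag, z, w, min_node, depth,
                            sort(inp$vars))
      counter <- new.env(); counter$k <- 0L
      root <- assign_leaf_ids(root, counter)
      leaf_of_bag <- route_leaf_values(root, data, bag, numeric(n),
                                       function(nd) nd$leaf_id,
                                       warn_unseen = FALSE)[bag]
      num <- rowsum(w[bag] * z[bag], leaf_of_bag)
      den <- rowsum(w[bag] * p[bag] * (1 - p[bag]), leaf_of_bag)
      gammas <- rep(0, counter$k)
      gammas[as.integer(rownames(num))] <-
        num[, 1] / pmax(den[, 1], 1e-12)
      set_leaf_gammas(root, gammas)
    })
    leaf_all <- route_leaf_values(res, data, seq_len(n), numeric(n),
                                  function(nd) nd$gamma,
                                  warn_unseen = FALSE)
    Fv <- Fv + shrinkage * leaf_all
    trees[[m]] <- res
    dev[m] <- bernoulli_deviance(y, stats::plogis(Fv), w)
  }
  structure(list(trees = trees, F0 = F0, M = M, depth = depth,
                 shrinkage = shrinkage, bag_fraction = bag_fraction,
                 min_node = min_node, seed = seed, vars = inp$vars,
                 n = n, prevalence = sum(w * y) / sum(w),
                 train_deviance = dev, call = match.call()),
            class = "cart_boost")
}

#' Predict from a boosted-tree model
#'
#' @param object A [fit_boost()] model.
#' @param newdata Data frame of rows to score.
#' @param type `"prob"` (inverse-logit of the additive score, default),
#'   `"link"` for the raw score, or `"class"` at `threshold`.
#' @param threshold Cutoff for `type = "class"`; defaults to the training
#'   prevalence.
#' @param ... Unused.
#' @return Numeric vector.
#' @export
predict.cart_boost <- function(object, newdata,
                               type = c("prob", "link", "class"),
                               threshold = NULL, ...) {
  type <- match.arg(type)
  n <- nrow(newdata)
  Fv <- rep(object$F0, n)
  for (tr in object$trees)
    Fv <- Fv + object$shrinkage *
      route_leaf_values(tr, newdata, seq_len(n), numeric(n),
                        function(nd) nd$gamma, warn_unseen = FALSE)
  if (type == "link") return(Fv)
  p <- stats::plogis(Fv)
  if (type == "prob") return(p)
  if (is.null(threshold)) threshold <- object$prevalence
  as.integer(p >= threshold)
}

#' @export
print.cart_boost <- function(x, ...) {
  cat(sprintf(
    "Boosted trees (Bernoulli deviance): %d trees, depth %d, shrinkage %g, bag %g\n",
    x$M, x$depth, x$shrinkage, x$bag_fraction))
  if (x$M > 0)
    cat(sprintf("Training deviance: %.4f -> %.4f\n",
                x$train_deviance[1], x$train_deviance[x$M]))
  invisible(x)
}
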