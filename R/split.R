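## Exhaustive Gini split search over numeric and categorical predictors
## with case weights. Numeric candidates are midpoints between consecutive
## distinct observed values; categorical candidates are the contiguous
## subsets of levels ordered by weighted case proportion (optimal for
## two-class Gini). All size constraints are on total node weight, so a
## case of integer weight k behaves exactly like k replicated rows.

.split_eps <- 1e-12

## Precompute fitting columns once per tree/forest fit.
tree_prep <- function(data, vars, y, w) {
  x <- lapply(data[vars], function(col) {
    if (is.numeric(col) || is.integer(col)) as.numeric(col)
    else if (is.logical(col)) as.numeric(col)
    else factor(col, ordered = FALSE)  # splits treat ordered as nominal sets
  })
  list(y = as.numeric(y), w = as.numeric(w), x = x, vars = sort(vars))
}

## Best split for the rows `idx`, searching `vars` (already sorted for the
## lexicographic tie-break). Returns NULL when no candidate both respects
## minbucket (weight) and strictly decreases the Gini impurity.
best_split_at <- function(prep, idx, minbucket, vars = prep$vars) {
  w <- prep$w[idx]; y <- prep$y[idx]
  Wt <- sum(w); W1 <- sum(w * y)
  if (W1 <= 0 || W1 >= Wt) return(NULL)
  parent_g <- gini(W1, Wt - W1)
  best <- NULL
  for (v in vars) {
    xv <- prep$x[[v]][idx]
    if (is.numeric(xv)) {
      o <- order(xv)
      xs <- xv[o]; ws <- w[o]; ys <- y[o]
      nn <- length(xs)
      if (nn < 2L || xs[1] == xs[nn]) next
      cw <- cumsum(ws); c1 <- cumsum(ws * ys)
      b <- which(xs[-nn] < xs[-1])
      lw <- cw[b]; l1 <- c1[b]; rw <- Wt - lw; r1 <- W1 - l1
      ok <- lw >= minbucket - .split_eps & rw >= minbucket - .split_eps
      if (!any(ok)) next
      pl <- l1 / lw; pr <- r1 / rw
      child <- (lw * (1 - pl^2 - (1 - pl)^2) +
                rw * (1 - pr^2 - (1 - pr)^2)) / Wt
      dec <- parent_g - child
      dec[!ok] <- -Inf
      i <- which.max(dec)  # first max: smallest threshold on ties
      if (dec[i] > .split_eps &&
          (is.null(best) || dec[i] > best$decrease + .split_eps)) {
        pos <- b[i]
        best <- list(var = v, type = "numeric",
                     threshold = (xs[pos] + xs[pos + 1]) / 2,
                     levels_left = NULL, missing_left = NA,
                     decrease = dec[i])
      }
    } else {
      obs <- !is.na(xv)
      wm <- sum(w[!obs])
      if (!any(obs)) next
      fo <- factor(xv[obs])
      if (nlevels(fo) < 2L) next
      lw1 <- rowsum(w[obs] * y[obs], fo)[, 1]
      lwt <- rowsum(w[obs], fo)[, 1]
      p1 <- lw1 / lwt
      ord <- order(p1, names(lwt))
      lev <- levels(fo)[ord]
      cw <- unname(cumsum(lwt[ord])); c1 <- unname(cumsum(lw1[ord]))
      Wo <- cw[length(cw)]; W1o <- c1[length(c1)]
      k <- length(lev)
      j <- seq_len(k - 1L)
      lw <- cw[j]; l1 <- c1[j]; rw <- Wo - lw; r1 <- W1o - l1
      miss_left <- lw >= rw  # missing rows follow the heavier child
      lfin <- lw + ifelse(miss_left, wm, 0)
      rfin <- rw + ifelse(miss_left, 0, wm)
      ok <- lfin >= minbucket - .split_eps & rfin >= minbucket - .split_eps
      if (!any(ok)) next
      pl <- l1 / lw; pr <- r1 / rw
      g_obs <- gini(W1o, Wo - W1o)
      child <- (lw * (1 - pl^2 - (1 - pl)^2) +
                rw * (1 - pr^2 - (1 - pr)^2)) / Wo
      dec <- (Wo / Wt) * (g_obs - child)  # scale by observed-weight share
      dec[!ok] <- -Inf
      i <- which.max(dec)  # first max: smallest subset on ties
      if (dec[i] > .split_eps &&
          (is.null(best) || dec[i] > best$decrease + .split_eps)) {
        best <- list(var = v, type = "categorical",
                     threshold = NA_real_,
                     levels_left = lev[seq_len(i)],
                     missing_left = miss_left[i],
                     decrease = dec[i])
      }
    }
  }
  best
}

## Logical go-left vector for a rule applied to a prediction column.
rule_goes_left <- function(rule, col, warn_unseen = TRUE) {
  if (rule$type == "numeric") {
    gl <- as.numeric(col) < rule$threshold
    gl[is.na(gl)] <- isTRUE(rule$missing_left)
  } else {
    chr <- as.character(col)
    known <- chr %in% rule$known_levels
    if (warn_unseen && any(!known & !is.na(chr)))
      warning("unseen level(s) in '", rule$var,
              "' routed in the majority direction: ",
              paste(unique(chr[!known & !is.na(chr)]), collapse = ", "))
    gl <- chr %in% rule$levels_left
    gl[is.na(chr) | !known] <- isTRUE(rule$missing_left)
  }
  gl
}

#' Find the best Gini split of a cohort node
#'
#' Exhaustive weighted Gini split search over all predictors: numeric
#' predictors are searched over midpoints between consecutive distinct
#' observed values; categorical predictors over contiguous subsets of the
#' levels ordered by weighted case proportion (which is optimal for
#' two-class Gini). Rows with a missing categorical value are routed to
#' the majority-weight child. Both children must carry at least
#' `minbucket` total weight.
#'
#' @param table A cohort data frame with an `outcome` column (0/1) and an
#'   optional `weight` column; all other columns are predictors.
#' @param minbucket Minimum total weight allowed in a child.
#' @param predictors Optional character vector restricting the search.
#' @return `NULL` if no split strictly decreases the impurity; otherwise a
#'   list with elements `var`, `type` (`"numeric"` go left iff value <
#'   `threshold`; `"categorical"` go left iff level in `levels_left`),
#'   `threshold`, `levels_left`, `missing_left`, and `decrease`, the drop
#'   in size-weighted Gini impurity.
#' @examples
#' coh <- generate_cohort(200, seed = 1)
#' best_split(coh)$var
#' @export
best_split <- function(table, minbucket = 1, predictors = NULL) {
  if (!nrow(table)) stop("best_split requires a nonempty table")
  vars <- setdiff(names(table), c("outcome", "weight"))
  if (!is.null(predictors)) vars <- intersect(vars, predictors)
  w <- if ("weight" %in% names(table)) table$weight else rep(1, nrow(table))
  prep <- tree_prep(table, vars, table$outcome, w)
  best_split_at(prep, seq_len(nrow(table)), minbucket)
}
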