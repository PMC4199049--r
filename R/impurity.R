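## Gini impurity for two-class nodes with nonnegative case weights.

#' Gini impurity of a two-class node
#'
#' `1 - p1^2 - p2^2`, where `p1 = w1 / (w1 + w2)` is the (weighted)
#' proportion of the first class. Zero for a pure node, maximal (0.5) at a
#' 50/50 mix. Vectorised over parallel `w1`, `w2`.
#'
#' @param w1,w2 Nonnegative total class weights (e.g. case and control
#'   counts).
#' @return Numeric impurity in `[0, 0.5]`.
#' @examples
#' gini(31, 2228)   # 0.0271
#' gini(997, 2228)  # 0.4272
#' @export
gini <- function(w1, w2) {
  tot <- w1 + w2
  if (any(tot <= 0)) stop("gini is undefined for an empty node")
  p1 <- w1 / tot
  1 - p1^2 - (1 - p1)^2
}

#' Size-weighted impurity of a binary split
#'
#' The weighted average of the two children's Gini impurities, with
#' weights proportional to the children's total weights. By concavity of
#' the Gini index this never exceeds the parent's impurity.
#'
#' @param left,right Length-2 numeric vectors `c(w1, w2)` of class weights
#'   in each child.
#' @return Numeric impurity.
#' @examples
#' split_impurity(c(13, 1718), c(18, 510))   # 0.0268
#' split_impurity(c(431, 1718), c(566, 510)) # 0.3801
#' @export
split_impurity <- function(left, right) {
  wl <- sum(left); wr <- sum(right)
  if (wl <= 0 || wr <= 0) stop("both children must be nonempty")
  (wl * gini(left[1], left[2]) + wr * gini(right[1], right[2])) / (wl + wr)
}
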