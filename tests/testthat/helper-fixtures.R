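# Fixtures built in code: worked-example node tables, random mixed-type
# tables for oracle checks, and brute-force reference implementations
# (exhaustive split enumeration, pair-count AUC, exhaustive subtree
# search) kept deliberately independent of the package's engine.

# A one-split node: `left` and `right` are c(cases, controls); the only
# informative predictor is age (left child age 50, right child age 65),
# so the optimal split is "age < 57.5". A constant bmi column is included
# so the search has an uninformative competitor.
worked_fixture <- function(left, right) {
  n <- sum(left) + sum(right)
  data.frame(
    age = rep(c(50, 65), c(sum(left), sum(right))),
    bmi = rep(30, n),
    outcome = c(rep(c(1L, 0L), left), rep(c(1L, 0L), right)),
    weight = 1
  )
}

# Mixed-type random table for oracle equivalence: two tying-prone
# numerics, one categorical, optional non-unit integer weights.
random_table <- function(n, seed, weighted = FALSE, k_levels = 4) {
  with_seed(seed, data.frame(
    x1 = round(runif(n), 2),
    x2 = sample(5L, n, replace = TRUE),
    g = factor(sample(letters[seq_len(k_levels)], n, replace = TRUE)),
    outcome = rbinom(n, 1L, 0.4),
    weight = if (weighted) sample(3L, n, replace = TRUE) else rep(1, n)
  ))
}

# Brute force over EVERY numeric threshold and EVERY proper nonempty
# categorical subset (not just contiguous ones); minbucket on weight.
brute_force_split <- function(table, minbucket = 1) {
  y <- table$outcome
  w <- table$weight
  W1 <- sum(w * y); Wt <- sum(w)
  parent <- gini(W1, Wt - W1)
  best <- -Inf
  eval_split <- function(go_left) {
    lw <- sum(w[go_left]); rw <- Wt - lw
    if (lw < minbucket || rw < minbucket || lw == 0 || rw == 0)
      return(invisible())
    l1 <- sum(w[go_left] * y[go_left]); r1 <- W1 - l1
    dec <- parent - split_impurity(c(l1, lw - l1), c(r1, rw - r1))
    if (dec > best) best <<- dec
  }
  for (v in setdiff(names(table), c("outcome", "weight"))) {
    x <- table[[v]]
    if (is.numeric(x)) {
      for (t in sort(unique(x))[-1]) eval_split(x < t)
    } else {
      lev <- levels(droplevels(x))
      k <- length(lev)
      if (k < 2) next
      for (code in seq_len(2^k - 2)) {
        inset <- as.logical(bitwAnd(code, 2^(seq_len(k) - 1)))
        eval_split(x %in% lev[inset])
      }
    }
  }
  best
}

# Recompute the impurity decrease a returned rule actually achieves.
rule_decrease <- function(table, rule) {
  y <- table$outcome; w <- table$weight
  gl <- if (rule$type == "numeric") table[[rule$var]] < rule$threshold
        else table[[rule$var]] %in% rule$levels_left
  W1 <- sum(w * y); Wt <- sum(w)
  l1 <- sum(w[gl] * y[gl]); lw <- sum(w[gl])
  gini(W1, Wt - W1) -
    split_impurity(c(l1, lw - l1), c(W1 - l1, Wt - lw - (W1 - l1)))
}

# Pair-count AUC oracle: loop over all case-control pairs, ties 1/2.
pairwise_auc <- function(scores, labels) {
  cs <- scores[labels == 1]; ct <- scores[labels == 0]
  tot <- 0
  for (a in cs) tot <- tot + sum(a > ct) + 0.5 * sum(a == ct)
  tot / (length(cs) * length(ct))
}

# Structure signature ignoring raw row counts (weights carry the size),
# used for node-for-node tree comparison.
tree_signature <- function(node) {
  sig <- list(w1 = node$w1, w2 = node$w2, p1 = node$p1)
  if (!is.null(node$split)) {
    s <- node$split
    sig$rule <- list(var = s$var, type = s$type,
                     threshold = s$threshold,
                     levels_left = s$levels_left)
    sig$left <- tree_signature(node$left)
    sig$right <- tree_signature(node$right)
  }
  sig
}

# All rooted subtrees of a tree (every internal node independently
# collapsed or expanded), as (risk, leaves) pairs.
all_subtree_costs <- function(node) {
  collapsed <- list(risk = node$risk, leaves = 1L)
  if (is.null(node$split)) return(list(collapsed))
  out <- list(collapsed)
  for (l in all_subtree_costs(node$left))
    for (r in all_subtree_costs(node$right))
      out <- c(out, list(list(risk = l$risk + r$risk,
                              leaves = l$leaves + r$leaves)))
  out
}

# Cohort-shaped table with an exact case/control count and weak signal,
# for resampling size checks that need the printed class sizes.
sized_cohort <- function(n_case, n_control, seed = 1) {
  n <- n_case + n_control
  with_seed(seed, {
    tab <- data.frame(
      age = sample(20:85, n, replace = TRUE),
      bmi = round(rnorm(n, 29, 6), 1),
      race = factor(sample(c("Mexican American", "Non-Hispanic White",
                             "Other"), n, replace = TRUE)),
      outcome = rep(c(1L, 0L), c(n_case, n_control)),
      weight = 1
    )
    tab$id <- seq_len(n)
    tab[sample(n), ]
  })
}
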