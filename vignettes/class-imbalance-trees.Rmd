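---
title: "Resampling class-imbalanced cohorts for tree-based classifiers: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resampling class-imbalanced cohorts for tree-based classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imbcart)
```

## The experiment this package implements

A binary-outcome cohort is *class-imbalanced* when one class dominates;
the motivating setting is a cross-sectional health-survey cohort in
which roughly 3% of adults show biochemical evidence of undiagnosed
diabetes. `imbcart` implements, end to end, the experiment of fitting
tree-based classifiers to such a cohort after rebalancing the training
data in eight ways — unchanged, class-weighted 1:1, randomly
oversampled at case:control ratios 1:1, 1:2 and 1:4, and randomly
undersampled at the same three ratios — and scoring every fit on a
single untouched held-out split. The resampling always applies to the
training split only; reweighting or resampling the test split would
change the estimand.

Three design commitments run through the package:

1. **The tree engine is first-party.** Split search, pruning,
   cross-validated complexity selection, bagging and boosting are all
   implemented in the package, so the interaction between imbalance and
   each algorithmic ingredient is inspectable. Established packages
   (`rpart`, `randomForest`, `xgboost`) appear only as independent
   cross-checks in the test suite, never inside the implementation.
2. **Weights are first-class.** Every size rule counts total case
   weight rather than rows, which makes a case of integer weight k
   exactly equivalent to k replicated case rows (asserted node-for-node
   in the tests). The class-weighted design is therefore the
   continuous-weight limit of the oversampled one.
3. **Everything is seeded through one tree of child seeds.** A global
   seed expands into named per-stage seeds (`child_seed(seed, "cell",
   method, ratio, model)`), so any grid cell can be rerun in isolation
   and adding cells never perturbs existing ones.

## The cohort generator

`generate_cohort()` draws survey-like participants: gender, age 20–85,
five race groups, five ordered education levels, six marital statuses,
family poverty income ratio (PIR), and BMI. Categorical marginals and
the age-decade frequencies follow published cohort tables for this
setting; PIR uses a moment-matched gamma (mean 2.46, SD 1.65) top-coded
at 5, as survey PIR is; BMI a normal (mean 28.77, SD 6.67) truncated to
a physiologic 14–70 kg/m². The outcome is Bernoulli through a logistic
risk model whose default log-odds effects carry the directions reported
for undiagnosed diabetes — risk rising with age (+0.55/decade) and BMI
(+0.10 per kg/m²), highest for Mexican American participants (+0.90 vs
Non-Hispanic White), falling with education (−0.15/level) and PIR
(−0.20/unit). The magnitudes are the package's own choice: moderate
values a logistic fit on a cohort of this shape would plausibly return,
fixed once and not tuned. The intercept is never set by hand: it is
calibrated by root finding so the expected prevalence over the drawn
covariates equals `target_prevalence` (default 0.03).

What the generator deliberately does **not** emulate: predictor
correlations (marginals are independent; age–education–PIR dependence
in real surveys is substantial), multistage survey design and
examination weights, informative missingness (education/marital cells
are blanked completely at random at the observed sparse rates, about
0.2% of cells), and any nonlinearity or interaction in the true risk.
Passing tests therefore demonstrate that the machinery behaves
correctly under a known low-prevalence logistic truth — not that any
particular AUC will be attained on real data, whose printed headline
values depend on row-level records this package does not ship.

Ages are generated and modelled as continuous years; decade bands in
descriptive tables are reporting conventions, and the trees are free to
split at any observed age midpoint.

## Resampling semantics

For `n_control` controls at target ratio 1:r the case target is
`ceiling(n_control / r)` — forced by the combinatorics of the reference
design (3165 controls give 3165, 1583 and 792 cases at r = 1, 2, 4).
Oversampling passes every control through untouched and draws the case
multiset uniformly with replacement; it does not guarantee every
original case appears (an `include_originals` flag offers that
variant). Undersampling keeps every case and draws `r * n_case`
controls without replacement, with no covariate matching. Class
weighting sets control weights to 1 and case weights to
`n_control / (r * n_case)`, making the weight ratio exactly 1:r while
keeping the effective control count interpretable.

## The tree engine

**Split search.** Numeric candidates are midpoints between consecutive
distinct observed values (a data-derived cutpoint reported
deterministically). Categorical levels are ordered by weighted case
proportion and only contiguous subsets in that order are scored, which
is exactly optimal for two-class Gini; the test suite checks the
search against brute-force enumeration of *every* subset. Both
children must carry at least `minbucket` weight (default
`round(minsplit/3)` = 7).

**Acceptance rule.** Splits are *selected* by Gini decrease but *kept*
by risk: a split survives only if it lowers the weighted
misclassification count (majority-vote labelling) by at least
`cp × root risk`, with `cp = 0.01` and `minsplit = 20` as defaults.
This greedy risk gate is applied during growth, which is deliberately
simpler than growing on impurity and cost-complexity-pruning to `cp`
afterwards: the two differ exactly when a risk-neutral split enables a
risk-reducing descendant. On heavily imbalanced data the consequence is
visible and intended — no split flips a majority label, so the
full-data tree at cp = 0.01 is typically root-only, the clearest
possible exhibit of why rebalancing is needed. The worked two-node
example (31/2228 vs the oversampled 997/2228) behaves accordingly: the
same age split is rejected on the imbalanced node and accepted on the
oversampled one, where its impurity drop is amplified from 0.0003 to
0.0471.

**Missing values and unseen levels.** Only education and marital
status may be missing. Candidate categorical splits are scored on the
non-missing rows with the impurity decrease scaled by the observed
weight share; missing rows then follow the majority-weight child. The
same direction is stored on every split and reused at prediction time
for missing values and (with a warning) for factor levels never seen in
training. This is a documented simplification of surrogate splits,
confined to the ~0.2% of cells that are ever missing.

**Ties.** Predictors are scanned in lexicographic name order and a
later candidate replaces the incumbent only when it improves the
decrease by more than 1e-12; within a predictor the smallest threshold
or smallest level subset wins. Tie behaviour is thus deterministic
across platforms. All floating-point comparisons against size and risk
thresholds use absolute slacks of 1e-12 (weights) and 1e-9 (risk), far
below one observation.

**Pruning and the 1-SE rule.** `cost_complexity_prune()` performs
weakest-link pruning, collapsing bottom-up every internal node whose
risk increase per removed leaf is at most the current alpha; the
recorded alphas increase strictly and the sequence ends at the root
(verified against exhaustive subtree search). `select_cp_1se()` grows
an unpenalised master tree, cross-validates the sequence with
stratified K folds (default 10; the fold deal re-deals up to 10 times
if a training complement lacks a class, then errors), evaluates each
interval at the geometric mean of its bounding alphas, and picks the
largest alpha whose CV risk is within one SE of the minimum — the
simplest statistically indistinguishable subtree. The SE uses the
binomial approximation `sqrt(p(1-p)·W)` on the weighted error count.

## Ensembles

The forest bags `B` unpruned trees (default 500) grown to purity with
`minbucket = 1`, sampling `mtry = floor(sqrt(p))` predictors afresh at
every node; with non-unit weights the bootstrap draws rows with
probability proportional to weight and grows unweighted, so the
weighted design enters through the resample. Scores are the plain mean
of leaf case proportions. Boosting (default 100 trees) is stagewise
logistic: `F0 = logit(weighted prevalence)`, then depth-limited
least-squares trees (default stumps, `min_node = 10`) fitted to
`y − p` on a 50% bag, one-step Newton leaf values
`Σw(y−p) / Σwp(1−p)` (denominator floored at 1e-12), shrinkage 0.1.
Only the ensemble sizes are externally fixed; the remaining
hyperparameters follow the conventional defaults of the field's
reference implementations and are all exposed as arguments. With
`bag_fraction = 1` the training deviance is non-increasing, which the
tests assert.

## Evaluation choices

AUC uses the midrank convention (ties count ½), identical to the
Mann-Whitney pair count; `roc_curve()` emits one point per distinct
score plus the endpoints, and its trapezoidal integral equals the AUC
exactly. The 2×2 incidence comparison uses the Pearson chi-square
*without* continuity correction — with Yates correction the reference
incidence table (99/3165 vs 40/1373) gives ≈0.06 rather than the
printed 0.14, so the uncorrected statistic is the one the design
implies. Ratios with empty denominators (PPV with no positive calls,
NPV with no negative calls) are reported as `N/A`, never coerced to 0.

The operating threshold behind published sensitivity/specificity
batteries of this kind is generally not recoverable: a fixed 0.5
cutoff is inconsistent with any leaf of a low-prevalence tree being
called positive. The package's default — the weighted training
prevalence of the dataset the model was fitted on, hence 0.5 for
balanced resamples and ≈0.03 for the full data — is an interpretive
choice, flagged here and overridable everywhere via `threshold`.

## Problem sizes in the shipped tests

The suite regenerates all fixtures in code. Oracle equivalence runs on
50 random mixed-type tables of up to 200 rows (split search), 50
score vectors (AUC) and exhaustive subtree enumeration on 50-row trees
(pruning). The directional replication uses 20 synthetic cohorts of
n = 4677 at 3% prevalence split 3264/1413, comparing CART on the
undersampled 1:1 training set against the full one and counting how
often the 1-SE full-data tree collapses to a stump. Ensemble
cross-checks use 100-tree forests on ~200-row balanced tables and
100-round boosting on 500-row cohorts; these sizes give stable
rank-level agreement while keeping the whole suite inside a coffee
break.

## Known limitations

* No surrogate splits, loss matrices, multiclass outcomes or
  regression trees; no SMOTE-style synthetic or informed resampling,
  and no combined over+under designs.
* The greedy risk gate (above) makes cp = 0.01 trees on raw imbalanced
  data smaller than an engine that prunes after growing; use `cp = 0`
  with `cart_1se()` when that distinction matters.
* Forest and boosting variable importance, partial dependence and
  early stopping are out of scope.
* AUC confidence intervals are not computed.
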