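# imbcart

Resampling methods and classification trees for class-imbalanced cohort
data.

## The problem

Many clinical prediction targets are rare. In a cross-sectional adult
cohort, undiagnosed diabetes affects about 3% of participants: 97 of
every 100 rows are controls, so a classifier tuned for overall accuracy
learns to call everyone negative and looks deceptively good while
detecting nothing. `imbcart` is a workbench for studying the standard
remedies on tree-based classifiers:

* **random oversampling** — draw the cases with replacement until the
  case:control ratio reaches a target 1:r,
* **random undersampling** — draw a without-replacement subset of the
  controls of size r × (number of cases),
* **class weighting** — leave the rows alone and give each case weight
  `n_control / (r * n_case)`,

each crossed with four model types: a classification tree, the same
tree with cross-validated complexity selection, a random forest, and
gradient-boosted trees. All tree machinery is implemented from scratch
in the package so that every splitting and pruning decision is
inspectable.

## The model

A tree is grown by recursive binary partitioning. The impurity of a
node with class proportions p₁ (cases) and p₂ (controls) is the Gini
index

    G = 1 − p₁² − p₂²,

and a candidate split of a node into children L, R of total weight w_L,
w_R is scored by the size-weighted impurity
(w_L·G_L + w_R·G_R)/(w_L + w_R). The split search is exhaustive:
midpoints between consecutive distinct values for numeric predictors,
and case-proportion-ordered level subsets for categorical ones (optimal
for two-class Gini). A chosen split is kept only when it lowers the
weighted misclassification risk by at least `cp` × (root risk); nodes
below `minsplit` total weight, or producing a child below `minbucket`,
are not split. Cost-complexity (weakest-link) pruning and a stratified
K-fold 1-SE rule select the final subtree when cross-validated
complexity selection is requested. Ensembles are built on the same
engine: bagged trees with a fresh random predictor subset at every node
(random forest), and stagewise logistic boosting of shallow
least-squares trees with one-step Newton leaf updates.

Because the imbalance is the point, all size constraints count *weight*
rather than rows: a case carrying integer weight k behaves exactly like
k replicated case rows, which ties the weighted design to the
oversampled one.

Test-set performance is reported as AUC, sensitivity, specificity,
PPV, NPV and classification rate. The default operating threshold is
the weighted training prevalence of the dataset the model was fitted on
(0.5 for balanced resamples); with a 3% prevalence a fixed 0.5 cutoff
would call almost nothing positive.

## Worked example

```r
library(imbcart)

cohort <- inject_missing(generate_cohort(4677, seed = 1), seed = 1)
sp <- split_train_test(cohort, n_train = 3264, seed = 2)

un  <- undersample(sp$train, ratio = 1, seed = 3)   # 101 cases + 101 controls
fit <- cart(outcome ~ ., data = un)                  # cp = 0.01, minsplit = 20
fit
#> Classification tree (Gini): n=202, 6 leaves, depth 5, cp=0.01
#> root  n=202, w=202, case%=50.0%
#>   age < 66.5  n=145, w=145, case%=37.2%
#>     bmi < 28.92  n=66, w=66, case%=15.2% *
#>     ...
#>   age >= 66.5  n=57, w=57, case%=82.5% *

confusion_metrics(predict(fit, sp$test), sp$test$outcome, threshold = 0.5)
#> AUC                 0.67
#> Sensitivity         63.2%
#> Specificity         68.7%
#> PPV                 5.3%
#> NPV                 98.5%
#> Classification rate 68.6%
```

The tree learned on the balanced 202-row undersample splits on age,
BMI, race and marital status and ranks held-out participants with AUC
0.67. The same CART fitted on the full imbalanced training split is a
root-only tree (no split changes any majority label, so none passes the
risk gate at cp = 0.01) and scores AUC 0.50 — the resampling is doing
the work. The low PPV (5.3%) is what a 2.7% test-set prevalence implies
at this sensitivity/specificity; the NPV of 98.5% is the useful number
for ruling out.

The whole grid — eight training datasets by four model types, the
metric battery per cell — is one call:

```r
res <- run_experiment(replication_config(seed = 1))
res$tables$cart   # metrics x {full, weighted, over 1:1/1:2/1:4, under 1:1/1:2/1:4}
```

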