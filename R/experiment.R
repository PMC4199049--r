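## Experiment driver: the full resampling-by-model grid on one
## train/test split, plus a replicate summariser. Every cell draws its
## randomness from a child seed derived from (global seed, plan, ratio,
## model), so cells are independently reproducible and adding cells never
## perturbs existing ones.

default_plans <- function() {
  list(
    list(method = "none", ratio = 1L, label = "full"),
    list(method = "weight", ratio = 1L, label = "weighted"),
    list(method = "oversample", ratio = 1L, label = "over_1_1"),
    list(method = "oversample", ratio = 2L, label = "over_1_2"),
    list(method = "oversample", ratio = 4L, label = "over_1_4"),
    list(method = "undersample", ratio = 1L, label = "under_1_1"),
    list(method = "undersample", ratio = 2L, label = "under_1_2"),
    list(method = "undersample", ratio = 4L, label = "under_1_4")
  )
}

#' Configure a resampling-by-model experiment
#'
#' Describes one end-to-end run: cohort source, train/test split size,
#' the grid of resampling plans and model types, and all model
#' hyperparameters. The defaults encode the replication design: a
#' 4677-row cohort split 3264/1413, eight training datasets (full,
#' weighted 1:1, over- and undersampled at 1:1, 1:2, 1:4) by four model
#' types (CART at cp = 0.01, CART with 1-SE pruning, a 500-tree random
#' forest, 100 boosted trees).
#'
#' @param n Cohort size to generate (ignored when `cohort` is given).
#' @param n_train Training split size.
#' @param generator A [cohort_config()] for synthetic cohorts.
#' @param cohort Optional cohort data frame (or CSV path) to use instead
#'   of generating one.
#' @param plans List of plans, each `list(method, ratio, label)`.
#' @param models Character subset of `c("cart", "cart_1se", "forest",
#'   "boost")`.
#' @param cp,minsplit CART growth parameters.
#' @param folds CV folds for the 1-SE selection.
#' @param forest_trees,mtry Random-forest size and per-split predictor
#'   count (`NULL` = `floor(sqrt(p))`).
#' @param boost_trees,boost_depth,shrinkage,bag_fraction Boosting
#'   hyperparameters.
#' @param seed Global seed; all stage seeds derive from it.
#' @return An object of class `"experiment_config"`.
#' @export
experiment_config <- function(n = 4677, n_train = 3264,
                              generator = cohort_config(), cohort = NULL,
                              plans = default_plans(),
                              models = c("cart", "cart_1se", "forest",
                                         "boost"),
                              cp = 0.01, minsplit = 20, folds = 10,
                              forest_trees = 500, mtry = NULL,
                              boost_trees = 100, boost_depth = 1,
                              shrinkage = 0.1, bag_fraction = 0.5,
                              seed = 1) {
  models <- match.arg(models, several.ok = TRUE)
  for (pl in plans)
    if (!pl$method %in% c("none", "weight", "oversample", "undersample"))
      stop("unknown plan method: ", pl$method)
  structure(list(n = n, n_train = n_train, generator = generator,
                 cohort = cohort, plans = plans, models = models,
                 cp = cp, minsplit = minsplit, folds = folds,
                 forest_trees = forest_trees, mtry = mtry,
                 boost_trees = boost_trees, boost_depth = boost_depth,
                 shrinkage = shrinkage, bag_fraction = bag_fraction,
                 seed = seed),
            class = "experiment_config")
}

#' @rdname experiment_config
#' @export
replication_config <- function(seed = 1, ...) {
  experiment_config(seed = seed, ...)
}

fit_and_score <- function(model, train, test, cfg, mseed) {
  fit <- switch(model,
    cart = cart(outcome ~ ., train, cp = cfg$cp,
                minsplit = cfg$minsplit),
    cart_1se = cart_1se(outcome ~ ., train, folds = cfg$folds,
                        seed = mseed, minsplit = cfg$minsplit),
    forest = fit_forest(outcome ~ ., train, B = cfg$forest_trees,
                        mtry = cfg$mtry, seed = mseed),
    boost = fit_boost(outcome ~ ., train, M = cfg$boost_trees,
                      depth = cfg$boost_depth,
                      shrinkage = cfg$shrinkage,
                      bag_fraction = cfg$bag_fraction, seed = mseed),
    stop("unknown model type: ", model))
  predict(fit, test)
}

#' Run a resampling-by-model experiment grid
#'
#' For every (plan, model) cell: rebalance the training split per the
#' plan, fit the model, score the untouched held-out test split, and
#' compute the metric battery at a threshold equal to the weighted
#' training prevalence of the rebalanced dataset (0.5 for balanced
#' resamples, roughly the raw prevalence for the full data). A failing
#' cell is logged and reported as failed without aborting the grid.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional directory; when given, per-model metric tables
#'   (CSV), the full cell list (JSON) and a run log are written there.
#' @return An object of class `"experiment_result"`: `cells` (one entry
#'   per grid cell with metrics, child seed, and any warnings or error),
#'   `tables` (one metric-by-dataset data frame per model type), `train`
#'   and `test` (the split actually used), and `config`.
#' @examples
#' cfg <- experiment_config(n = 400, n_train = 280, models = "cart",
#'   plans = list(list(method = "none", ratio = 1L, label = "full")),
#'   seed = 7)
#' res <- run_experiment(cfg)
#' res$tables$cart
#' @export
run_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  cohort <- config$cohort
  if (is.null(cohort)) {
    cohort <- generate_cohort(config$n, config$generator,
                              seed = child_seed(config$seed, "cohort"))
    cohort <- inject_missing(cohort, config$generator$missing_rates,
                             seed = child_seed(config$seed, "missing"))
  } else if (is.character(cohort)) {
    cohort <- read_cohort(cohort)
  }
  sp <- split_train_test(cohort, config$n_train,
                         seed = child_seed(config$seed, "split"))
  log_lines <- character()
  cells <- list()
  for (pl in config$plans) {
    pseed <- child_seed(config$seed, "plan", pl$method, pl$ratio)
    train_var <- tryCatch(
      apply_resampling(sp$train,
                       resampling_plan(pl$method, pl$ratio, pseed)),
      error = function(e) structure(conditionMessage(e),
                                    class = "resample_error"))
    if (inherits(train_var, "resample_error")) {
      for (model in config$models) {
        key <- paste(pl$label, model, sep = "::")
        cells[[key]] <- list(plan = pl, model = model, seed = NA_integer_,
                             n_train = NA_integer_, threshold = NA_real_,
                             metrics = NULL, warnings = character(),
                             error = as.character(train_var))
        log_lines <- c(log_lines, sprintf(
          "cell %s model=%s FAILED: %s", pl$label, model,
          as.character(train_var)))
      }
      next
    }
    thr <- sum(train_var$weight * (train_var$outcome == 1L)) /
      sum(train_var$weight)
    for (model in config$models) {
      mseed <- child_seed(config$seed, "cell", pl$method, pl$ratio, model)
      key <- paste(pl$label, model, sep = "::")
      warns <- character()
      cell <- tryCatch({
        scores <- withCallingHandlers(
          fit_and_score(model, train_var, sp$test, config, mseed),
          warning = function(w) {
            warns <<- c(warns, conditionMessage(w))
            invokeRestart("muffleWarning")
          })
        list(plan = pl, model = model, seed = mseed,
             n_train = nrow(train_var), threshold = thr,
             metrics = confusion_metrics(scores, sp$test$outcome, thr),
             warnings = warns, error = NULL)
      }, error = function(e) {
        list(plan = pl, model = model, seed = mseed,
             n_train = nrow(train_var), threshold = thr,
             metrics = NULL, warnings = warns,
             error = conditionMessage(e))
      })
      cells[[key]] <- cell
      log_lines <- c(log_lines, sprintf(
        "cell %s model=%s seed=%d n_train=%d %s", pl$label, model,
        mseed, nrow(train_var),
        if (is.null(cell$error)) "ok" else paste("FAILED:", cell$error)))
    }
  }
  metric_names <- c("auc", "sensitivity", "specificity", "ppv", "npv",
                    "classification_rate")
  labels <- vapply(config$plans, `[[`, character(1), "label")
  tables <- lapply(stats::setNames(config$models, config$models),
                   function(model) {
    tab <- sapply(labels, function(lb) {
      cell <- cells[[paste(lb, model, sep = "::")]]
      if (is.null(cell$metrics)) rep(NA_real_, length(metric_names))
      else unlist(cell$metrics[metric_names])
    })
    tab <- as.data.frame(tab)
    rownames(tab) <- metric_names
    tab
  })
  res <- structure(list(cells = cells, tables = tables,
                        train = sp$train, test = sp$test,
                        config = config, log = log_lines),
                   class = "experiment_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (model in names(tables))
      utils::write.csv(tables[[model]],
                       file.path(out_dir, paste0("metrics_", model,
                                                 ".csv")))
    cell_json <- lapply(cells, function(cl) {
      cl$metrics <- if (is.null(cl$metrics)) NULL
                    else unclass(cl$metrics)
      cl
    })
    jsonlite::write_json(cell_json, file.path(out_dir, "cells.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  res
}

#' @export
print.experiment_result <- function(x, ...) {
  for (model in names(x$tables)) {
    cat(sprintf("== %s ==\n", model))
    tab <- x$tables[[model]]
    out <- tab
    out["auc", ] <- sprintf("%.2f", unlist(tab["auc", ]))
    for (rn in setdiff(rownames(tab), "auc"))
      out[rn, ] <- ifelse(is.na(unlist(tab[rn, ])), "N/A",
                          sprintf("%.1f%%", 100 * unlist(tab[rn, ])))
    print(out)
    cat("\n")
  }
  invisible(x)
}

#' Summarise metric tables over replicate experiment runs
#'
#' Cell-wise order statistics across replicates of the same grid:
#' per-cell median and interquartile range of every metric, and, per
#' model type, the count of replicates in which each resampled cell beat
#' the full-data cell on AUC.
#'
#' @param results A list of [run_experiment()] results with identical
#'   grid shapes.
#' @return A list of class `"replicate_summary"` with `median`, `iqr`
#'   (lists of per-model data frames) and `auc_wins` (data frame of
#'   beat-the-full-data counts, with the replicate count as attribute).
#' @export
summarize_replicates <- function(results) {
  if (!length(results)) stop("need at least one replicate")
  tabs0 <- results[[1]]$tables
  for (r in results)
    if (!identical(lapply(r$tables, dim), lapply(tabs0, dim)) ||
        !identical(lapply(r$tables, names), lapply(tabs0, names)))
      stop("replicates have different grid shapes")
  models <- names(tabs0)
  stat_tab <- function(model, f) {
    arr <- simplify2array(lapply(results, function(r)
      as.matrix(r$tables[[model]])))
    out <- apply(arr, c(1, 2), f, na.rm = TRUE)
    as.data.frame(out)
  }
  med <- lapply(stats::setNames(models, models), stat_tab,
                f = stats::median)
  iqr <- lapply(stats::setNames(models, models), stat_tab, f = stats::IQR)
  labels <- colnames(tabs0[[1]])
  wins <- sapply(stats::setNames(models, models), function(model) {
    sapply(labels, function(lb) {
      sum(vapply(results, function(r) {
        a <- r$tables[[model]]["auc", lb]
        f <- r$tables[[model]]["auc", labels[1]]
        isTRUE(as.numeric(a) > as.numeric(f))
      }, logical(1)))
    })
  })
  structure(list(median = med, iqr = iqr,
                 auc_wins = as.data.frame(wins),
                 n_replicates = length(results)),
            class = "replicate_summary")
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat(sprintf("Summary over %d replicates\n", x$n_replicates))
  for (model in names(x$median)) {
    cat(sprintf("== %s (median) ==\n", model))
    print(round(x$median[[model]], 3))
  }
  cat("AUC wins versus the full-data cell:\n")
  print(x$auc_wins)
  invisible(x)
}

#' Read an experiment configuration from YAML or JSON
#'
#' The file may set any argument of [experiment_config()]; a `generator`
#' block is passed to [cohort_config()]. Unknown keys are an error.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  known <- names(formals(experiment_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(raw$generator))
    raw$generator <- do.call(cohort_config, raw$generator)
  if (!is.null(raw$plans))
    raw$plans <- lapply(raw$plans, function(pl)
      list(method = pl$method, ratio = as.integer(pl$ratio),
           label = pl$label))
  do.call(experiment_config, raw)
}
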