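#' Downstream evaluation configuration
#'
#' Settings for the leakage-safe cross-validated evaluation of a selected
#' feature set: stratified 10-fold cross-validation repeated over 10 seeds,
#' with a fixed random-forest evaluator of 100 trees at library defaults
#' (no class-weight balancing, majority-vote prediction).
#'
#' @param k Number of top-ranked features handed to the evaluator (default 20).
#' @param n_folds Folds per repetition (default 10).
#' @param seeds Integer seeds, one per repetition; each seed drives both the
#'   fold split and the evaluator forest (default 0:9).
#' @param evaluator_trees Trees in the evaluator forest (default 100).
#' @param evaluator_class_weight_balanced Balance class weights in the
#'   evaluator (default FALSE: the evaluator runs at library defaults, with
#'   no reweighting, so differences reflect the selected features alone).
#' @return A list of class `eval_config`. The positive class is fixed at 1.
#' @export
eval_config <- function(k = 20, n_folds = 10, seeds = 0:9,
                        evaluator_trees = 100,
                        evaluator_class_weight_balanced = FALSE) {
  stopifnot(k >= 1, n_folds >= 2, length(seeds) >= 1, evaluator_trees >= 1)
  structure(list(k = as.integer(k), n_folds = as.integer(n_folds),
                 seeds = as.integer(seeds),
                 evaluator_trees = as.integer(evaluator_trees),
                 evaluator_class_weight_balanced =
                   evaluator_class_weight_balanced,
                 positive_class = 1L),
            class = "eval_config")
}

#' Stratified fold assignment
#'
#' Assigns every sample to exactly one of `n_folds` folds such that per-fold
#' positive counts differ by at most one (and likewise for negatives). The
#' assignment is a pure function of `(outcome, n_folds, seed)`: the ambient
#' RNG state is untouched.
#'
#' @param outcome 0/1 vector with both classes present.
#' @param n_folds Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..n_folds`, one per sample.
#' @export
stratified_folds <- function(outcome, n_folds, seed) {
  outcome <- as.integer(outcome)
  n <- length(outcome)
  if (n_folds > n) stop("n_folds exceeds the number of samples")
  if (length(unique(outcome)) < 2) stop("both outcome classes must be present")
  n_min <- min(table(outcome))
  if (n_folds > n_min) {
    warning("n_folds (", n_folds, ") exceeds the minority class count (",
            n_min, "); some folds will lack positives")
  }
  with_local_seed(seed, {
    fold <- integer(n)
    for (cls in c(1L, 0L)) {
      idx <- which(outcome == cls)
      idx <- idx[sample.int(length(idx))]
      labels <- sample.int(n_folds)
      fold[idx] <- rep_len(labels, length(idx))
    }
    fold
  })
}

#' Per-fold feature selection on training rows only
#'
#' For each fold, fits the scorer on the training portion (all rows outside
#' the fold) and returns its top-k feature names. This is the selection step
#' used inside [evaluate_selector()]; exposing it makes the leakage guarantee
#' directly auditable: held-out rows can be perturbed arbitrarily without
#' changing any fold's selected set.
#'
#' @param table A [feature_table()].
#' @param scorer_id Registered scorer identifier.
#' @param scorer_config A [scorer_config()].
#' @param k Selection size.
#' @param folds Fold assignment vector from [stratified_folds()].
#' @return Named list `fold<j>` -> character vector of selected features.
#' @export
fold_selections <- function(table, scorer_id, scorer_config, k, folds) {
  stopifnot(inherits(table, "feature_table"),
            length(folds) == nrow(table$values))
  out <- list()
  for (j in sort(unique(folds))) {
    train <- subset_samples(table, folds != j)
    res <- compute_importance(train, scorer_id, scorer_config)
    out[[paste0("fold", j)]] <-
      rank_top_k(res, k, train$column_order)$ordered_features
  }
  out
}

#' Confusion-count metrics
#'
#' Accuracy, sensitivity (recall of the positive class), and binary F1 from
#' confusion counts, with the zero-division convention that sensitivity is 0
#' when no positives are present and F1 is 0 when its denominator is 0.
#'
#' @param tp,fp,tn,fn Confusion counts.
#' @return Named numeric vector `accuracy`, `sensitivity`, `f1`.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  total <- tp + fp + tn + fn
  acc <- if (total > 0) (tp + tn) / total else 0
  sens <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
  c(accuracy = acc, sensitivity = sens, f1 = f1)
}

#' Leakage-safe cross-validated evaluation of a scorer's selections
#'
#' For every seed and fold: the scorer is fitted on the training rows only,
#' its top-k features are selected, a random-forest evaluator is trained on
#' the training rows restricted to those features (randomness driven by the
#' seed), and the held-out fold is predicted by majority vote. Feature
#' selection is recomputed inside each training fold, so held-out data never
#' influences which features are used.
#'
#' Aggregates are the mean and SD over all seed x fold cells (flat
#' convention, stamped in `aggregation_tag`); alternative nestings can be
#' computed from `per_cell`.
#'
#' @param table A [feature_table()].
#' @param scorer_id Registered scorer identifier.
#' @param scorer_config A [scorer_config()].
#' @param config An [eval_config()].
#' @return An object of class `eval_metrics` with `per_cell` (data.frame of
#'   seed, fold, TP/FP/TN/FN, accuracy, sensitivity, f1), the six aggregate
#'   fields, `selected` (per-cell selected feature sets), and
#'   `aggregation_tag`.
#' @export
evaluate_selector <- function(table, scorer_id,
                              scorer_config = rankstab::scorer_config(),
                              config = eval_config()) {
  stopifnot(inherits(table, "feature_table"), inherits(config, "eval_config"))
  rows <- list()
  selected <- list()
  zero_div <- FALSE
  for (s in config$seeds) {
    folds <- stratified_folds(table$outcome, config$n_folds, s)
    for (j in sort(unique(folds))) {
      test_idx <- folds == j
      train <- subset_samples(table, !test_idx)
      if (length(unique(train$outcome)) < 2) {
        stop("training fold with a single outcome class at seed ", s,
             ", fold ", j)
      }
      res <- compute_importance(train, scorer_id, scorer_config)
      sel <- rank_top_k(res, config$k, train$column_order)$ordered_features
      selected[[sprintf("seed%d_fold%d", s, j)]] <- sel

      yf <- factor(train$outcome, levels = c(0L, 1L))
      cw <- if (config$evaluator_class_weight_balanced) {
        as.numeric(length(yf) / (2 * table(yf)))
      } else NULL
      fit <- ranger::ranger(x = train$values[, sel, drop = FALSE], y = yf,
                            num.trees = config$evaluator_trees,
                            class.weights = cw, seed = forest_seed(s),
                            num.threads = 1)
      pred <- stats::predict(fit,
                             data = table$values[test_idx, sel, drop = FALSE],
                             seed = forest_seed(s),
                             num.threads = 1)$predictions
      truth <- table$outcome[test_idx]
      phat <- as.integer(as.character(pred))
      tp <- sum(phat == 1 & truth == 1)
      fp <- sum(phat == 1 & truth == 0)
      tn <- sum(phat == 0 & truth == 0)
      fn <- sum(phat == 0 & truth == 1)
      met <- confusion_metrics(tp, fp, tn, fn)
      if ((tp + fn) == 0 || (2 * tp + fp + fn) == 0) zero_div <- TRUE
      rows[[length(rows) + 1]] <- data.frame(
        seed = s, fold = j, tp = tp, fp = fp, tn = tn, fn = fn,
        accuracy = met["accuracy"], sensitivity = met["sensitivity"],
        f1 = met["f1"], row.names = NULL)
    }
  }
  if (zero_div) {
    warning("some folds contained no positive samples or no positive ",
            "predictions; sensitivity/F1 set to 0 there")
  }
  per_cell <- do.call(rbind, rows)
  agg <- function(col) c(mean = mean(per_cell[[col]]),
                         sd = stats::sd(per_cell[[col]]))
  a <- agg("accuracy"); se <- agg("sensitivity"); f <- agg("f1")
  structure(list(scorer_id = scorer_id, per_cell = per_cell,
                 selected = selected,
                 accuracy_mean = a[["mean"]], accuracy_sd = a[["sd"]],
                 sensitivity_mean = se[["mean"]], sensitivity_sd = se[["sd"]],
                 f1_mean = f[["mean"]], f1_sd = f[["sd"]],
                 aggregation_tag = "flat_mean_sd_over_all_seed_fold_cells"),
            class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf(
    "<eval_metrics> %s: accuracy %.4f +/- %.4f, sensitivity %.4f +/- %.4f, F1 %.4f +/- %.4f (%d cells)\n",
    x$scorer_id, x$accuracy_mean, x$accuracy_sd, x$sensitivity_mean,
    x$sensitivity_sd, x$f1_mean, x$f1_sd, nrow(x$per_cell)))
  invisible(x)
}

#' Comparison table across methods
#'
#' Merges each method's aggregate metrics and (optionally) its consistency
#' verdict into one row per method, with 1-based dense ranks per metric
#' (higher metric = rank 1; equal values share a rank, flagged in `tied`).
#'
#' @param metrics_by_method Named list of `eval_metrics` (>= 2 methods).
#' @param verdicts Optional named list of `consistency_verdict` or
#'   `stability_report` objects aligned with the methods.
#' @return A data.frame with one row per method: consistency label, the three
#'   metric means and SDs, their dense ranks, and a `tied` flag.
#' @export
rank_methods <- function(metrics_by_method, verdicts = NULL) {
  if (length(metrics_by_method) < 2) stop("need at least two methods")
  ids <- names(metrics_by_method)
  get_label <- function(id) {
    v <- verdicts[[id]]
    if (is.null(v)) return(NA_character_)
    if (inherits(v, "stability_report")) v <- v$verdict
    v$label
  }
  df <- data.frame(
    method = ids,
    consistency = vapply(ids, get_label, character(1)),
    accuracy_mean = vapply(metrics_by_method, `[[`, 0, "accuracy_mean"),
    accuracy_sd = vapply(metrics_by_method, `[[`, 0, "accuracy_sd"),
    sensitivity_mean = vapply(metrics_by_method, `[[`, 0, "sensitivity_mean"),
    sensitivity_sd = vapply(metrics_by_method, `[[`, 0, "sensitivity_sd"),
    f1_mean = vapply(metrics_by_method, `[[`, 0, "f1_mean"),
    f1_sd = vapply(metrics_by_method, `[[`, 0, "f1_sd"),
    row.names = NULL, stringsAsFactors = FALSE)
  df$accuracy_rank <- dense_rank_desc(df$accuracy_mean)
  df$sensitivity_rank <- dense_rank_desc(df$sensitivity_mean)
  df$f1_rank <- dense_rank_desc(df$f1_mean)
  df$tied <- duplicated(df$accuracy_rank) | duplicated(df$accuracy_rank,
                                                       fromLast = TRUE) |
    duplicated(df$sensitivity_rank) | duplicated(df$sensitivity_rank,
                                                 fromLast = TRUE) |
    duplicated(df$f1_rank) | duplicated(df$f1_rank, fromLast = TRUE)
  df
}
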