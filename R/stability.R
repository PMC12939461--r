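#' Top-k ranking with deterministic tie-breaking
#'
#' Sorts features by descending score; features with equal scores are ordered
#' by ascending original column index (a stable, fully deterministic rule, so
#' repeated runs and different scorers break ties identically).
#'
#' @param result An `importance_result`.
#' @param k Positive ranking size; the ranking is truncated to
#'   `min(k, n_features)`.
#' @param column_order Named integer vector mapping feature names to original
#'   0-based column indices (the `column_order` of the scored table).
#' @return An object of class `ranking` with fields `ordered_features`,
#'   `scores` (of the ranked features), `k`, `tie_policy`, `source_scorer`.
#' @export
rank_top_k <- function(result, k, column_order) {
  stopifnot(inherits(result, "importance_result"))
  if (k < 1) stop("k must be >= 1")
  fn <- names(result$scores)
  orig <- column_order[fn]
  if (anyNA(orig)) stop("column_order must cover every scored feature")
  ord <- order(-result$scores, orig)
  take <- seq_len(min(k, length(fn)))
  sel <- ord[take]
  structure(list(ordered_features = fn[sel],
                 scores = unname(result$scores[sel]),
                 k = as.integer(k),
                 tie_policy = "stable_by_original_column_order",
                 source_scorer = result$scorer_id),
            class = "ranking")
}

#' @export
print.ranking <- function(x, ...) {
  cat(sprintf("<ranking> %s top-%d: %s\n", x$source_scorer, x$k,
              paste(utils::head(x$ordered_features, 5), collapse = ", ")))
  invisible(x)
}

#' Strict order-preservation consistency verdict
#'
#' After removing the top-m features and re-ranking, a scorer is
#' `Consistent` only under a uniform rank shift: the ordered sequence of
#' features originally ranked (m+1)..k must be element-wise identical to the
#' perturbed ranking's positions 1..(k-m). Any substituted feature or any
#' reordering yields `Inconsistent`. This is deliberately stricter than
#' overlap indices (Jaccard, Kuncheva), which see only the sets.
#'
#' @param original The `ranking` on the full table (length k).
#' @param perturbed The `ranking` after removal (length >= k - m).
#' @param m Number of top features removed before re-ranking.
#' @return An object of class `consistency_verdict` with fields `label`
#'   (`"Consistent"` / `"Inconsistent"`), `first_divergence` (1-based position
#'   in the compared windows, or `NA`), `set_difference` (features in exactly
#'   one window), and `order_preserved`.
#' @export
strict_consistency <- function(original, perturbed, m) {
  stopifnot(inherits(original, "ranking"), inherits(perturbed, "ranking"))
  k <- length(original$ordered_features)
  if (m < 0 || m >= k) stop("need 0 <= m < k")
  if (length(perturbed$ordered_features) < k - m) {
    stop("perturbed ranking shorter than k - m = ", k - m)
  }
  a <- original$ordered_features[(m + 1):k]
  b <- perturbed$ordered_features[seq_len(k - m)]
  set_diff <- c(setdiff(a, b), setdiff(b, a))
  mism <- which(a != b)
  first_div <- if (length(mism)) mism[1] else NA_integer_
  common <- intersect(a, b)
  order_preserved <- identical(a[a %in% common], b[b %in% common])
  label <- if (length(set_diff) == 0 && order_preserved && is.na(first_div)) {
    "Consistent"
  } else {
    "Inconsistent"
  }
  structure(list(label = label, first_divergence = first_div,
                 set_difference = set_diff,
                 order_preserved = order_preserved),
            class = "consistency_verdict")
}

#' @export
print.consistency_verdict <- function(x, ...) {
  cat(sprintf("<consistency_verdict> %s", x$label))
  if (!is.na(x$first_divergence)) {
    cat(sprintf(" (first divergence at position %d", x$first_divergence))
    if (length(x$set_difference)) {
      cat("; set difference: ", paste(x$set_difference, collapse = ", "))
    }
    cat(")")
  }
  cat("\n")
  invisible(x)
}

#' Overlap contrast metrics for two ranking windows
#'
#' Computes set-overlap diagnostics on the same windows compared by
#' [strict_consistency()]: the Jaccard index `|A n B| / |A u B|` and the
#' fraction of positions holding identical occupants. These are reported only
#' as a contrast: a window pair can have Jaccard 1.0 (perfect set overlap)
#' while the strict verdict is Inconsistent because the order changed.
#'
#' @inheritParams strict_consistency
#' @return Named numeric vector with `jaccard` and `positional_agreement`.
#' @export
overlap_metrics <- function(original, perturbed, m) {
  k <- length(original$ordered_features)
  if (m < 0 || m >= k) stop("need 0 <= m < k")
  a <- original$ordered_features[(m + 1):k]
  b <- perturbed$ordered_features[seq_len(k - m)]
  uni <- union(a, b)
  jac <- if (length(uni)) length(intersect(a, b)) / length(uni) else 1
  pos <- if (length(a)) mean(a == b) else 1
  c(jaccard = jac, positional_agreement = pos)
}

#' Leave-top-features-out perturbation run
#'
#' The perturbation protocol: (1) score the full table and take the top-k
#' ranking; (2) remove the top-m features of that ranking; (3) re-score the
#' reduced table with the identical configuration and seed (isolating the
#' effect of the perturbation from sampling noise); (4) re-rank; (5) apply
#' the strict consistency criterion and the overlap contrast metrics.
#'
#' By default the top-m features of the *original* ranking are removed
#' jointly. With `iterative = TRUE` the top-1 feature is removed and the
#' table re-scored m times, an exploratory variant.
#'
#' @param table A [feature_table()] with more than `k` features.
#' @param scorer_id Registered scorer identifier.
#' @param config A [scorer_config()].
#' @param k Ranking size (default 20).
#' @param m Perturbation depth, `1 <= m < k` (default 1).
#' @param iterative Remove-and-re-rank one feature at a time instead of the
#'   joint removal (default FALSE).
#' @return An object of class `stability_report` with the original and
#'   perturbed rankings, the removed features, the `consistency_verdict`,
#'   and the contrast metrics.
#' @export
run_perturbation <- function(table, scorer_id, config = scorer_config(),
                             k = 20, m = 1, iterative = FALSE) {
  stopifnot(inherits(table, "feature_table"))
  if (m < 1 || m >= k) stop("need 1 <= m < k")
  if (ncol(table$values) <= k) stop("table must have more than k features")
  res0 <- compute_importance(table, scorer_id, config)
  original <- rank_top_k(res0, k, table$column_order)

  if (iterative) {
    removed <- character(0)
    reduced <- table
    for (i in seq_len(m)) {
      res_i <- compute_importance(reduced, scorer_id, config)
      top1 <- rank_top_k(res_i, 1, reduced$column_order)$ordered_features
      removed <- c(removed, top1)
      reduced <- drop_features(reduced, top1)
    }
  } else {
    removed <- original$ordered_features[seq_len(m)]
    reduced <- drop_features(table, removed)
  }
  res1 <- compute_importance(reduced, scorer_id, config)
  perturbed <- rank_top_k(res1, k, reduced$column_order)
  verdict <- strict_consistency(original, perturbed, m)
  contrast <- overlap_metrics(original, perturbed, m)
  structure(list(scorer_id = scorer_id, original_ranking = original,
                 removed_features = removed, perturbed_ranking = perturbed,
                 m = as.integer(m), k = as.integer(k),
                 iterative = iterative, verdict = verdict,
                 contrast_metrics = as.list(contrast)),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> %s, k=%d, m=%d: %s (Jaccard %.3f)\n",
              x$scorer_id, x$k, x$m, x$verdict$label,
              x$contrast_metrics$jaccard))
  invisible(x)
}

#' Side-by-side ranking table for a stability report
#'
#' Renders the two rankings in the two-column layout used for reporting:
#' "Ranking (Original Set)" next to "Ranking (W/O Top m)", with the first m
#' perturbed cells holding a horizontal bar so both columns align by rank
#' position.
#'
#' @param report A `stability_report`.
#' @param placeholder String for the removed positions (default `"―"`).
#' @return A data.frame with columns `rank`, `original`, `perturbed`.
#' @export
format_ranking_table <- function(report, placeholder = "―") {
  stopifnot(inherits(report, "stability_report"))
  orig <- report$original_ranking$ordered_features
  pert <- report$perturbed_ranking$ordered_features
  k <- length(orig)
  pert_col <- c(rep(placeholder, report$m),
                utils::head(pert, k - report$m))
  length(pert_col) <- k
  data.frame(rank = seq_len(k), original = orig, perturbed = pert_col,
             stringsAsFactors = FALSE)
}
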