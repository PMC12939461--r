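#' Scorer configuration
#'
#' Hyperparameters shared by the importance scorers. Defaults follow the
#' minimally tuned settings used throughout the benchmark: a mild LASSO
#' penalty (`lasso_alpha = 0.01`) with a generous iteration budget, 100 trees
#' with class-weight balancing for the random-forest scorer, and all principal
#' components for the PCA scorer.
#'
#' @param lasso_alpha Positive L1 penalty, on the scale
#'   `(1/2n)||y - Xb||^2 + alpha * ||b||_1` (default 0.01).
#' @param lasso_max_iter Coordinate-descent iteration limit (default 1e5).
#' @param n_trees Number of trees for the forest and boosted-tree scorers
#'   (default 100).
#' @param class_weight_balanced Balance class weights in the forest scorer,
#'   weighting each class by `n / (2 * n_class)` (default TRUE).
#' @param n_components `"all"` (= `min(n_samples - 1, n_features)`) or a
#'   positive integer count of principal components.
#' @param seed Integer seed consumed only by stochastic scorers (default 0).
#' @return A list of class `scorer_config`.
#' @export
scorer_config <- function(lasso_alpha = 0.01, lasso_max_iter = 1e5,
                          n_trees = 100, class_weight_balanced = TRUE,
                          n_components = "all", seed = 0) {
  stopifnot(lasso_alpha > 0, lasso_max_iter >= 1, n_trees >= 1)
  if (!identical(n_components, "all")) {
    stopifnot(is.numeric(n_components), n_components >= 1)
  }
  structure(list(lasso_alpha = lasso_alpha,
                 lasso_max_iter = as.integer(lasso_max_iter),
                 n_trees = as.integer(n_trees),
                 class_weight_balanced = class_weight_balanced,
                 n_components = n_components, seed = as.integer(seed)),
            class = "scorer_config")
}

importance_result <- function(scorer_id, scores, deterministic,
                              seed = NULL, metadata = list()) {
  stopifnot(!is.null(names(scores)), all(is.finite(scores)), all(scores >= 0))
  structure(list(scorer_id = scorer_id, scores = scores,
                 deterministic = deterministic, seed = seed,
                 metadata = metadata),
            class = "importance_result")
}

#' @export
print.importance_result <- function(x, ...) {
  cat(sprintf("<importance_result> %s: %d features, %s\n", x$scorer_id,
              length(x$scores),
              if (x$deterministic) "deterministic"
              else sprintf("stochastic (seed %s)", x$seed)))
  invisible(x)
}

check_table <- function(table, min_n = 1, need_both_classes = FALSE) {
  stopifnot(inherits(table, "feature_table"))
  if (ncol(table$values) < 1) stop("table has no features")
  if (nrow(table$values) < min_n) {
    stop("need at least ", min_n, " samples")
  }
  if (need_both_classes && length(unique(table$outcome)) < 2) {
    stop("both outcome classes must be present")
  }
}

#' Ordinary-least-squares coefficient importance
#'
#' Regresses the 0/1 outcome on all features jointly (with intercept) and
#' scores each feature by the absolute value of its coefficient. On
#' rank-deficient tables (p > n, collinear columns) the minimum-norm
#' least-squares solution is used, computed from the SVD of the centered
#' design; the convention is recorded in the result metadata.
#'
#' @param table A [feature_table()].
#' @param config Unused; present for the uniform scorer signature.
#' @return An `importance_result`.
#' @export
score_ols <- function(table, config = scorer_config()) {
  check_table(table, min_n = 2)
  X <- table$values
  Xc <- sweep(X, 2, colMeans(X))
  yc <- table$outcome - mean(table$outcome)
  sv <- svd(Xc)
  tol <- max(dim(Xc)) * .Machine$double.eps * max(sv$d, 0)
  pos <- sv$d > tol
  beta <- if (any(pos)) {
    drop(sv$v[, pos, drop = FALSE] %*%
           (crossprod(sv$u[, pos, drop = FALSE], yc) / sv$d[pos]))
  } else {
    rep(0, ncol(X))
  }
  importance_result("ols_abs_coef",
                    stats::setNames(abs(beta), table$feature_names),
                    deterministic = TRUE,
                    metadata = list(solution = "minimum_norm_svd_pseudoinverse"))
}

#' LASSO coefficient importance
#'
#' Fits an L1-penalized least-squares regression of the 0/1 outcome on all
#' features (coordinate descent, no standardization, with intercept) at the
#' fixed penalty `config$lasso_alpha`, and scores each feature by the
#' absolute value of its coefficient. Non-convergence within
#' `lasso_max_iter` is recorded as a warning in the result metadata, not an
#' error.
#'
#' @inheritParams score_ols
#' @param config A [scorer_config()]; uses `lasso_alpha`, `lasso_max_iter`.
#' @return An `importance_result`.
#' @export
score_lasso <- function(table, config = scorer_config()) {
  check_table(table, min_n = 2)
  X <- table$values
  y <- as.numeric(table$outcome)
  warns <- character()
  if (ncol(X) == 1L) {
    # glmnet requires >= 2 columns; the single-variable coordinate-descent
    # update has a closed form: soft-threshold the centered covariance.
    xc <- X[, 1] - mean(X[, 1])
    yc <- y - mean(y)
    z <- mean(xc * yc)
    denom <- mean(xc^2)
    beta <- if (denom > 0) {
      sign(z) * max(abs(z) - config$lasso_alpha, 0) / denom
    } else 0
  } else {
    fit <- withCallingHandlers(
      glmnet::glmnet(X, y, family = "gaussian", alpha = 1,
                     lambda = config$lasso_alpha, standardize = FALSE,
                     intercept = TRUE, maxit = config$lasso_max_iter,
                     thresh = 1e-10),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    beta <- as.numeric(stats::coef(fit))[-1]
  }
  importance_result("lasso_abs_coef",
                    stats::setNames(abs(beta), table$feature_names),
                    deterministic = TRUE,
                    metadata = list(penalty = config$lasso_alpha,
                                    warnings = warns))
}

#' Random-forest Gini importance
#'
#' Fits a random-forest classifier (`config$n_trees` trees, optional balanced
#' class weights, randomness fully determined by `config$seed`) and scores
#' each feature by the mean decrease in Gini impurity, normalized to sum
#' to 1 whenever any split occurred.
#'
#' @inheritParams score_ols
#' @param config A [scorer_config()]; uses `n_trees`,
#'   `class_weight_balanced`, `seed`.
#' @return An `importance_result` with `deterministic = FALSE`.
#' @export
score_forest_impurity <- function(table, config = scorer_config()) {
  check_table(table, min_n = 2, need_both_classes = TRUE)
  yf <- factor(table$outcome, levels = c(0L, 1L))
  cw <- if (config$class_weight_balanced) {
    as.numeric(length(yf) / (2 * table(yf)))
  } else NULL
  fit <- ranger::ranger(x = table$values, y = yf,
                        num.trees = config$n_trees,
                        importance = "impurity",
                        class.weights = cw,
                        seed = forest_seed(config$seed), num.threads = 1)
  imp <- fit$variable.importance[table$feature_names]
  imp[imp < 0] <- 0
  total <- sum(imp)
  if (total > 0) imp <- imp / total
  importance_result("forest_impurity", imp, deterministic = FALSE,
                    seed = config$seed,
                    metadata = list(class_weights = cw))
}

#' Gradient-boosted-tree gain importance
#'
#' Fits gradient-boosted decision trees with the binary logistic objective at
#' the implementation's default hyperparameters (`config$n_trees` boosting
#' rounds) and scores each feature by its share of the total split gain.
#' Features never used in any split score 0. Without row/column subsampling
#' the greedy split search is deterministic, but the scorer is conservatively
#' flagged stochastic and records its seed.
#'
#' @inheritParams score_ols
#' @param config A [scorer_config()]; uses `n_trees`, `seed`.
#' @return An `importance_result`.
#' @export
score_gbt_gain <- function(table, config = scorer_config()) {
  check_table(table, min_n = 2, need_both_classes = TRUE)
  dtrain <- xgboost::xgb.DMatrix(table$values, label = table$outcome,
                                 nthread = 1)
  fit <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", nthread = 1,
                  seed = config$seed),
    data = dtrain, nrounds = config$n_trees, verbose = 0)
  imp <- xgboost::xgb.importance(model = fit)
  scores <- stats::setNames(rep(0, ncol(table$values)), table$feature_names)
  if (!is.null(imp) && nrow(imp) > 0) {
    scores[imp$Feature] <- imp$Gain
  }
  importance_result("gbt_gain", scores, deterministic = FALSE,
                    seed = config$seed,
                    metadata = list(gain_aggregation =
                                      "total_gain_normalized_share"))
}

#' PCA loading-sum importance
#'
#' Mean-centers the feature matrix (no variance scaling), computes the
#' principal components, and scores each feature by the sum of the absolute
#' values of its loadings across all retained components. With
#' `n_components = "all"`, `min(n_samples - 1, n_features)` components are
#' requested and components with numerically zero variance are discarded.
#' The outcome is never read.
#'
#' @inheritParams score_ols
#' @param config A [scorer_config()]; uses `n_components`.
#' @return An `importance_result`.
#' @export
score_pca_loading_sum <- function(table, config = scorer_config()) {
  check_table(table, min_n = 2)
  X <- table$values
  max_comp <- min(nrow(X) - 1L, ncol(X))
  ncomp <- if (identical(config$n_components, "all")) max_comp
           else min(as.integer(config$n_components), max_comp)
  pr <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = ncomp)
  keep <- pr$sdev[seq_len(ncol(pr$rotation))] > pr$sdev[1] * 1e-9 &
    pr$sdev[seq_len(ncol(pr$rotation))] > 0
  load <- pr$rotation[, keep, drop = FALSE]
  scores <- stats::setNames(rowSums(abs(load)), table$feature_names)
  importance_result("pca_loading_sum", scores, deterministic = TRUE,
                    metadata = list(n_components_retained = sum(keep)))
}

#' Feature-wise variance importance (highly-variable selection)
#'
#' Scores each feature by its sample variance (denominator n - 1), the
#' variance-based filtering strategy used for highly-variable gene selection
#' in transcriptomics. The outcome is never read, and each feature's score
#' depends only on its own column, making the scorer provably stable under
#' removal of other features.
#'
#' @inheritParams score_ols
#' @return An `importance_result`.
#' @export
score_variance <- function(table, config = scorer_config()) {
  check_table(table, min_n = 2)
  X <- table$values
  n <- nrow(X)
  v <- colSums(sweep(X, 2, colMeans(X))^2) / (n - 1)
  v[v < 0] <- 0
  importance_result("variance", stats::setNames(v, table$feature_names),
                    deterministic = TRUE,
                    metadata = list(denominator = "n_minus_1"))
}

#' Absolute Spearman correlation importance
#'
#' Scores each feature by the absolute Spearman rank correlation with the
#' outcome: the Pearson correlation of the average-rank transforms of the
#' feature and of the outcome (ties receive average ranks). A constant
#' feature scores 0 by convention. Univariate: each feature's score depends
#' only on its own column and the outcome.
#'
#' @inheritParams score_ols
#' @return An `importance_result`.
#' @export
score_spearman <- function(table, config = scorer_config()) {
  check_table(table, min_n = 3, need_both_classes = TRUE)
  r <- suppressWarnings(
    as.numeric(stats::cor(table$values, table$outcome, method = "spearman")))
  r[is.na(r)] <- 0
  importance_result("spearman_abs",
                    stats::setNames(abs(r), table$feature_names),
                    deterministic = TRUE,
                    metadata = list(constant_feature_convention = 0))
}

# ---- scorer registry --------------------------------------------------------

.scorers <- new.env(parent = emptyenv())

#' Register an importance scorer
#'
#' User-supplied scorers plug into the perturbation and evaluation harnesses
#' by registering a function `(feature_table, scorer_config) ->
#' importance_result` (or a bare named score vector, which is wrapped).
#'
#' @param id Scorer identifier string.
#' @param fn Scoring function.
#' @param deterministic Whether the scorer is fully deterministic under fixed
#'   data and hyperparameters.
#' @param univariate Whether each feature's score depends only on its own
#'   column (and the outcome); univariate scorers are provably consistent
#'   under feature removal.
#' @param overwrite Allow replacing an existing registration.
#' @export
register_scorer <- function(id, fn, deterministic, univariate,
                            overwrite = FALSE) {
  stopifnot(is.character(id), length(id) == 1, is.function(fn))
  if (!overwrite && exists(id, envir = .scorers, inherits = FALSE)) {
    stop("scorer '", id, "' already registered")
  }
  assign(id, list(id = id, fn = fn, deterministic = deterministic,
                  univariate = univariate), envir = .scorers)
  invisible(id)
}

#' List registered scorer ids
#' @return Character vector of scorer identifiers.
#' @export
list_scorers <- function() sort(ls(.scorers))

get_scorer <- function(id) {
  if (!exists(id, envir = .scorers, inherits = FALSE)) {
    stop("unknown scorer '", id, "'; registered: ",
         paste(list_scorers(), collapse = ", "))
  }
  get(id, envir = .scorers)
}

#' Is a scorer univariate?
#' @param id Scorer identifier.
#' @return Logical flag as declared at registration.
#' @export
scorer_is_univariate <- function(id) isTRUE(get_scorer(id)$univariate)

#' Compute importance scores by scorer id
#'
#' Uniform entry point used by the perturbation protocol, the evaluation
#' harness, and the command-line driver.
#'
#' @param table A [feature_table()].
#' @param scorer_id Registered scorer identifier (see [list_scorers()]).
#' @param config A [scorer_config()].
#' @return An `importance_result`.
#' @export
compute_importance <- function(table, scorer_id, config = scorer_config()) {
  sc <- get_scorer(scorer_id)
  res <- sc$fn(table, config)
  if (!inherits(res, "importance_result")) {
    res <- importance_result(scorer_id, res, deterministic = sc$deterministic,
                             seed = config$seed)
  }
  if (!setequal(names(res$scores), table$feature_names)) {
    stop("scorer '", scorer_id, "' did not score every feature exactly once")
  }
  res$scores <- res$scores[table$feature_names]
  res
}

register_scorer("ols_abs_coef", score_ols, deterministic = TRUE,
                univariate = FALSE)
register_scorer("lasso_abs_coef", score_lasso, deterministic = TRUE,
                univariate = FALSE)
register_scorer("forest_impurity", score_forest_impurity,
                deterministic = FALSE, univariate = FALSE)
register_scorer("gbt_gain", score_gbt_gain, deterministic = FALSE,
                univariate = FALSE)
register_scorer("pca_loading_sum", score_pca_loading_sum,
                deterministic = TRUE, univariate = FALSE)
register_scorer("variance", score_variance, deterministic = TRUE,
                univariate = TRUE)
register_scorer("spearman_abs", score_spearman, deterministic = TRUE,
                univariate = TRUE)
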