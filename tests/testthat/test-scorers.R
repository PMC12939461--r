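fx <- fixture_suite()

test_that("closed-form oracles: OLS slope, Spearman rho, variance, PCA loadings", {
  # simple-regression slope sum((x-xbar)(y-ybar)) / sum((x-xbar)^2) = 0.4
  expect_equal(unname(score_ols(fx$worked_example)$scores), 0.4,
               tolerance = 1e-12)
  # average ranks (1,2,3,4) vs (1.5,1.5,3.5,3.5): Pearson = 4/sqrt(20)
  expect_equal(unname(score_spearman(fx$worked_example)$scores),
               4 / sqrt(20), tolerance = 1e-12)
  # sample variance of (0,0,1,1) with n-1 denominator
  expect_equal(unname(score_variance(fx$binary_step)$scores), 1 / 3,
               tolerance = 1e-12)
  # exactly uncorrelated columns: components are the coordinate axes,
  # so each feature's absolute-loading sum is 1
  expect_equal(unname(score_pca_loading_sum(fx$axis_aligned)$scores),
               c(1, 1), tolerance = 1e-12)
})

test_that("OLS scores a perfect predictor 1 and a constant feature 0", {
  tab <- make_table(cbind(x = c(0, 1, 0, 1, 1, 0)), c(0, 1, 0, 1, 1, 0))
  expect_equal(unname(score_ols(tab)$scores), 1, tolerance = 1e-12)
  tab2 <- make_table(cbind(const = rep(2, 6), x = c(0, 1, 0, 1, 1, 0)),
                     c(0, 1, 0, 1, 1, 0))
  s <- score_ols(tab2)$scores
  expect_equal(unname(s["const"]), 0, tolerance = 1e-12)
  expect_gt(s[["x"]], 0.5)
  expect_error(
    score_ols(feature_table(matrix(numeric(0), 2, 0,
                                   dimnames = list(NULL, character(0))),
                            c(0, 1))),
    "no features")
})

test_that("OLS returns finite minimum-norm coefficients when p >> n", {
  s <- score_ols(fx$wide)$scores
  expect_length(s, 300)
  expect_true(all(is.finite(s)) && all(s >= 0))
})

test_that("LASSO shrinks noise to zero and approaches OLS as the penalty vanishes", {
  set.seed(11)
  y <- rep(c(0L, 1L), 25)
  tab <- make_table(cbind(sig = y + rnorm(50, sd = 0.1),
                          noise = rnorm(50)), y)
  s <- score_lasso(tab, scorer_config(lasso_alpha = 0.2))$scores
  expect_identical(unname(s["noise"]), 0)

  set.seed(12)
  tab2 <- make_table(matrix(rnorm(30), 10, 3), rep(c(0L, 1L), 5))
  near0 <- score_lasso(tab2, scorer_config(lasso_alpha = 1e-7))$scores
  expect_equal(near0, score_ols(tab2)$scores, tolerance = 1e-3)
})

test_that("LASSO splits a duplicated column's coefficient across the pair", {
  tab <- fx$duplicated_columns
  single <- drop_features(tab, "info_b")
  cfg <- scorer_config(lasso_alpha = 0.01)
  s_pair <- score_lasso(tab, cfg)$scores
  s_one <- score_lasso(single, cfg)$scores
  expect_equal(unname(s_pair["info_a"] + s_pair["info_b"]),
               unname(s_one["info_a"]), tolerance = 1e-4)
})

test_that("forest impurity importance is normalized and finds a separating feature", {
  s <- score_forest_impurity(fx$separable, scorer_config(seed = 0))$scores
  expect_equal(sum(s), 1, tolerance = 1e-9)
  expect_equal(names(which.max(s)), "sep")
  expect_error(
    score_forest_impurity(make_table(matrix(rnorm(20), 10, 2), rep(0L, 10))),
    "both outcome classes")
})

test_that("forest importance on pure noise shows no dominant feature over seeds", {
  set.seed(5)
  X <- matrix(rnorm(200 * 20), 200, 20,
              dimnames = list(NULL, paste0("f", 1:20)))
  y <- rep(c(0L, 1L), 100)  # independent of all features
  tab <- feature_table(X, y)
  for (sd in 0:4) {
    s <- score_forest_impurity(tab, scorer_config(seed = sd))$scores
    expect_lt(max(s), 3 * mean(s))
  }
})

test_that("boosted-tree gain is zero for unused features and tops the separator", {
  s <- score_gbt_gain(fx$separable, scorer_config(seed = 0))$scores
  expect_equal(names(which.max(s)), "sep")
  tab <- make_table(cbind(const = rep(1, 40), fx$separable$values),
                    fx$separable$outcome)
  s2 <- score_gbt_gain(tab, scorer_config(seed = 0))$scores
  expect_identical(unname(s2["const"]), 0)
})

test_that("boosted-tree rankings are identical across seeds without subsampling", {
  tab <- random_table(80, 25, seed = 21)
  ranks <- lapply(0:3, function(sd) {
    r <- compute_importance(tab, "gbt_gain", scorer_config(seed = sd))
    rank_top_k(r, 10, tab$column_order)$ordered_features
  })
  for (i in 2:4) expect_identical(ranks[[i]], ranks[[1]])
})

test_that("PCA loading sums ignore constant columns and the outcome", {
  tab <- make_table(cbind(const = rep(3, 6),
                          a = c(1, 2, 3, 4, 5, 6),
                          b = c(2, 1, 4, 3, 6, 5)),
                    c(0, 1, 0, 1, 0, 1))
  s <- score_pca_loading_sum(tab)$scores
  expect_equal(unname(s["const"]), 0, tolerance = 1e-12)
  flipped <- feature_table(tab$values, 1L - tab$outcome)
  expect_identical(score_pca_loading_sum(flipped)$scores, s)
})

test_that("variance scales quadratically and never reads the outcome", {
  tab <- random_table(25, 6, seed = 31)
  s <- score_variance(tab)$scores
  scaled <- tab$values
  scaled[, "f3"] <- 5 * scaled[, "f3"]
  s2 <- score_variance(feature_table(scaled, tab$outcome))$scores
  expect_equal(unname(s2["f3"]), 25 * unname(s["f3"]), tolerance = 1e-12)
  permuted <- feature_table(tab$values, sample(tab$outcome))
  expect_identical(score_variance(permuted)$scores, s)
})

test_that("Spearman importance is symmetric in direction and monotone-invariant", {
  inc <- make_table(cbind(x = c(1, 2, 3, 4)), c(0, 0, 1, 1))
  dec <- make_table(cbind(x = c(4, 3, 2, 1)), c(0, 0, 1, 1))
  expect_equal(score_spearman(inc)$scores, score_spearman(dec)$scores)
  expect_equal(unname(score_spearman(make_table(cbind(x = c(0, 1, 0, 1)),
                                                c(0, 1, 0, 1)))$scores), 1)
  tab <- random_table(30, 5, seed = 41)
  s <- score_spearman(tab)$scores
  transformed <- tab$values
  transformed[, "f2"] <- exp(transformed[, "f2"])  # strictly increasing
  s2 <- score_spearman(feature_table(transformed, tab$outcome))$scores
  expect_identical(s2[["f2"]], s[["f2"]])
  const <- make_table(cbind(c1 = rep(1, 10), x = rnorm(10)),
                      rep(c(0L, 1L), 5))
  expect_identical(unname(score_spearman(const)$scores["c1"]), 0)
})

test_that("univariate scorers are local: removing other columns leaves scores bit-identical", {
  for (seed in 1:5) {
    tab <- random_table(40, 12, seed = seed, ties = TRUE)
    reduced <- drop_features(tab, c("f1", "f7"))
    for (id in c("variance", "spearman_abs")) {
      full <- compute_importance(tab, id)$scores
      part <- compute_importance(reduced, id)$scores
      expect_identical(part, full[names(part)])
    }
  }
})

test_that("deterministic scorers reproduce bit-identical scores across calls", {
  tab <- random_table(50, 15, seed = 9, ties = TRUE)
  for (id in c("ols_abs_coef", "lasso_abs_coef", "pca_loading_sum",
               "variance", "spearman_abs")) {
    r1 <- compute_importance(tab, id)
    r2 <- compute_importance(tab, id)
    expect_true(r1$deterministic, info = id)
    expect_identical(r1$scores, r2$scores)
  }
})

test_that("the scorer registry accepts user scorers and rejects collisions", {
  register_scorer("test_range", function(table, config) {
    apply(table$values, 2, function(col) diff(range(col)))
  }, deterministic = TRUE, univariate = TRUE, overwrite = TRUE)
  tab <- random_table(20, 5, seed = 3)
  r <- compute_importance(tab, "test_range")
  expect_s3_class(r, "importance_result")
  expect_length(r$scores, 5)
  expect_true(scorer_is_univariate("test_range"))
  expect_error(register_scorer("variance", identity, TRUE, TRUE),
               "already registered")
  expect_error(compute_importance(tab, "no_such_scorer"), "unknown scorer")
})
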