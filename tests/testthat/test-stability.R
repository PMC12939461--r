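test_that("rank_top_k sorts descending, truncates, and breaks ties by column order", {
  co <- c(a = 0L, b = 1L, c = 2L)
  r <- rank_top_k(
    structure(list(scorer_id = "t", scores = c(a = 3, b = 5, c = 4),
                   deterministic = TRUE, seed = NULL, metadata = list()),
              class = "importance_result"), 3, co)
  expect_equal(r$ordered_features, c("b", "c", "a"))
  tied <- structure(list(scorer_id = "t", scores = c(a = 2, b = 2, c = 2),
                         deterministic = TRUE, seed = NULL,
                         metadata = list()),
                    class = "importance_result")
  expect_equal(rank_top_k(tied, 2, co)$ordered_features, c("a", "b"))
  expect_length(rank_top_k(tied, 10, co)$ordered_features, 3)
  expect_error(rank_top_k(tied, 0, co), "k must be")
})

test_that("a uniform rank shift is Consistent; reorderings and substitutions are not", {
  orig <- make_ranking(c("A", "B", "C", "D", "E"))
  shift <- make_ranking(c("B", "C", "D", "E", "F"))
  v <- strict_consistency(orig, shift, m = 1)
  expect_equal(v$label, "Consistent")
  expect_true(is.na(v$first_divergence))
  expect_length(v$set_difference, 0)
  expect_true(v$order_preserved)

  swapped <- make_ranking(c("C", "B", "D", "E", "F"))
  v2 <- strict_consistency(orig, swapped, m = 1)
  expect_equal(v2$label, "Inconsistent")
  expect_equal(v2$first_divergence, 1L)
  expect_length(v2$set_difference, 0)
  expect_false(v2$order_preserved)

  subst <- make_ranking(c("B", "G", "H"))
  v3 <- strict_consistency(make_ranking(c("A", "B", "C")), subst, m = 1)
  expect_equal(v3$label, "Inconsistent")
  expect_setequal(v3$set_difference, c("C", "G"))

  expect_error(strict_consistency(orig, make_ranking(c("B", "C")), m = 1),
               "shorter")
})

test_that("overlap metrics are blind to reorderings the strict criterion catches", {
  # windows [B,C,D] vs [C,B,D]: perfect set overlap, broken order
  orig <- make_ranking(c("A", "B", "C", "D"))
  pert <- make_ranking(c("C", "B", "D"))
  om <- overlap_metrics(orig, pert, m = 1)
  expect_equal(unname(om["jaccard"]), 1.0)
  expect_lt(om[["positional_agreement"]], 1.0)
  expect_equal(strict_consistency(orig, pert, m = 1)$label, "Inconsistent")

  ident <- overlap_metrics(orig, make_ranking(c("B", "C", "D")), m = 1)
  expect_equal(unname(ident), c(1.0, 1.0))
  disj <- overlap_metrics(orig, make_ranking(c("X", "Y", "Z")), m = 1)
  expect_equal(unname(disj["jaccard"]), 0.0)
})

test_that("shuffling a perturbed window of length > 1 always breaks consistency", {
  set.seed(77)
  for (i in 1:25) {
    k <- sample(3:12, 1)
    feats <- paste0("g", sample(1000, k + 1))
    orig <- make_ranking(feats[1:k])
    window <- feats[2:(k + 1)]
    repeat {
      shuf <- sample(window)
      if (!identical(shuf, window)) break
    }
    expect_equal(strict_consistency(orig, make_ranking(shuf), 1)$label,
                 "Inconsistent")
  }
})

test_that("run_perturbation is Consistent for univariate scorers and ties out", {
  tab <- random_table(60, 40, seed = 13, ties = TRUE)
  for (id in c("variance", "spearman_abs")) {
    for (m in c(1, 3)) {
      rep <- run_perturbation(tab, id, k = 20, m = m)
      expect_equal(rep$verdict$label, "Consistent")
      expect_equal(rep$removed_features,
                   rep$original_ranking$ordered_features[seq_len(m)])
      # Consistent implies perfect overlap (one-way implication)
      expect_equal(rep$contrast_metrics$jaccard, 1.0)
      expect_equal(rep$contrast_metrics$positional_agreement, 1.0)
    }
  }
  ties <- fixture_suite()$ties_everywhere
  # all scores equal: the criterion still applies mechanically
  rep <- run_perturbation(ties, "variance", k = 5, m = 1)
  expect_equal(rep$verdict$label, "Consistent")
  expect_error(run_perturbation(ties, "variance", k = 5, m = 5), "m < k")
  expect_error(run_perturbation(ties, "variance", k = 20, m = 1),
               "more than k")
})

test_that("an inconsistent forest run records faithful diagnostics", {
  # duplicated informative columns + interaction structure destabilize
  # impurity importance; the instance is frozen at a seed found by search
  found <- NULL
  for (seed in 1:30) {
    set.seed(seed)
    n <- 120
    z1 <- rnorm(n); z2 <- rnorm(n)
    y <- as.integer(z1 * z2 > 0)  # pure interaction
    X <- cbind(a1 = z1, a2 = z1, b1 = z2, b2 = z2,
               matrix(rnorm(n * 26), n, 26,
                      dimnames = list(NULL, paste0("f", 1:26))))
    tab <- feature_table(X, y)
    rep <- run_perturbation(tab, "forest_impurity",
                            scorer_config(seed = 0), k = 10, m = 1)
    if (rep$verdict$label == "Inconsistent") { found <- rep; break }
  }
  expect_false(is.null(found))
  # verdict must match an independent re-implementation of the window check
  a <- found$original_ranking$ordered_features[2:10]
  b <- found$perturbed_ranking$ordered_features[1:9]
  expect_false(identical(a, b))
  expect_equal(found$verdict$label, "Inconsistent")
  expect_length(found$original_ranking$ordered_features, 10)
  expect_length(found$perturbed_ranking$ordered_features, 10)
  expect_false(found$removed_features %in% found$perturbed_ranking$ordered_features)
})

test_that("run_perturbation is deterministic: identical inputs give identical reports", {
  tab <- random_table(80, 30, seed = 17)
  for (id in c("forest_impurity", "gbt_gain", "lasso_abs_coef")) {
    r1 <- run_perturbation(tab, id, scorer_config(seed = 2), k = 15, m = 2)
    r2 <- run_perturbation(tab, id, scorer_config(seed = 2), k = 15, m = 2)
    expect_identical(r1$original_ranking, r2$original_ranking)
    expect_identical(r1$perturbed_ranking, r2$perturbed_ranking)
    expect_identical(r1$verdict, r2$verdict)
    expect_identical(r1$contrast_metrics, r2$contrast_metrics)
  }
})

test_that("iterative removal matches joint removal for univariate scorers", {
  tab <- random_table(50, 35, seed = 19, ties = TRUE)
  joint <- run_perturbation(tab, "variance", k = 20, m = 4)
  iter <- run_perturbation(tab, "variance", k = 20, m = 4, iterative = TRUE)
  expect_identical(joint$removed_features, iter$removed_features)
  expect_identical(joint$perturbed_ranking$ordered_features,
                   iter$perturbed_ranking$ordered_features)
})

test_that("the two-column rendering shifts the perturbed ranking under a bar", {
  tab <- random_table(40, 30, seed = 23)
  rep <- run_perturbation(tab, "variance", k = 10, m = 1)
  ft <- format_ranking_table(rep)
  expect_equal(ft$perturbed[1], "―")
  expect_equal(ft$perturbed[2:10], ft$original[1:9 + 1])
  expect_equal(nrow(ft), 10)
})
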