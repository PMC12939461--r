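# Fixture builders used across the suite. Everything is generated in code
# under fixed seeds.

make_table <- function(values, outcome) {
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("f", seq_len(ncol(values)))
  }
  feature_table(values, outcome)
}

# Random table with both outcome classes and, optionally, heavy ties
# (quantized values and a few exactly duplicated columns).
random_table <- function(n, p, seed, ties = FALSE) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  if (ties) {
    quant <- sample(p, ceiling(p / 2))
    X[, quant] <- round(X[, quant], 1)
    ndup <- min(3, floor(p / 10))
    if (ndup > 0) {
      src <- sample(p, ndup)
      dst <- sample(setdiff(seq_len(p), src), ndup)
      X[, dst] <- X[, src]
    }
  }
  y <- integer(n)
  y[sample.int(n, max(2, round(n * 0.25)))] <- 1L
  feature_table(X, y)
}

# Build a ranking object directly, for unit tests of the consistency
# criterion that do not involve a scorer.
make_ranking <- function(features, scores = NULL, scorer = "test") {
  structure(list(ordered_features = features,
                 scores = scores %||% rev(seq_along(features)),
                 k = length(features),
                 tie_policy = "stable_by_original_column_order",
                 source_scorer = scorer),
            class = "ranking")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
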