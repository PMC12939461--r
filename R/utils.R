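# Internal helpers shared across modules.

# Run `expr` under a fixed, fully specified RNG state and restore the
# caller's state afterwards. The generator is pinned (Mersenne-Twister /
# Inversion / Rejection) so results are bit-identical across platforms and
# sessions regardless of ambient RNGkind.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  old_kind <- RNGkind()
  on.exit({
    do.call(RNGkind, as.list(old_kind))
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  suppressWarnings(set.seed(as.integer(seed), kind = "Mersenne-Twister",
                            normal.kind = "Inversion",
                            sample.kind = "Rejection"))
  expr
}

# 1-based dense rank, larger value = rank 1.
dense_rank_desc <- function(x) {
  match(x, sort(unique(x), decreasing = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# The forest backend reserves seed 0 for "unseeded" operation, so user seeds
# are offset by one before being handed down; determinism tests cover seed 0.
forest_seed <- function(seed) as.integer(seed) + 1L
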