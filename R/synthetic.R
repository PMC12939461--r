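#' Specification for a synthetic multi-omics-like table
#'
#' Describes a samples x features table emulating the statistical structure
#' of a multi-omics survival cohort: a rare positive class (defaults mirror a
#' 705-patient cohort with 13.3% deceased and 1936 mixed-modality features),
#' planted outcome-associated features (class-conditional Gaussian shifts),
#' planted high-variance outcome-independent features, exactly duplicated
#' column pairs, equicorrelated feature blocks, pure-noise features, and
#' missing entries inserted before preprocessing so the zero-imputation path
#' is exercised end to end.
#'
#' @param n_samples Number of samples (default 705).
#' @param n_features Number of features (default 1936).
#' @param prevalence Positive-class fraction in (0,1); the positive count is
#'   exactly `round(prevalence * n_samples)` (default 0.133).
#' @param n_signal Number of planted outcome-associated features (default 10).
#' @param signal_effect Mean shift of signal features in the positive class,
#'   in within-class SD units (default 1).
#' @param n_high_variance Number of planted high-variance, outcome-independent
#'   features (default 10).
#' @param variance_boost Variance multiplier (> 1) for high-variance features
#'   (default 5).
#' @param n_duplicate_pairs Number of exactly duplicated column pairs
#'   (default 5).
#' @param block_correlation Pairwise correlation within declared noise blocks,
#'   in `[0, 1)` (default 0.5); blocks of 5 features covering roughly 10% of
#'   the noise features are declared when positive.
#' @param missing_rate Fraction of feature entries set missing before
#'   preprocessing (default 0.02).
#' @param modality_mix Named proportions over prefixes `rs_`, `cn_`, `mu_`,
#'   `pp_`. Prefixes affect names and marginal distributions only (`mu_`
#'   features are sparse binary); planted structure is assigned to
#'   continuous-modality features.
#' @param seed Integer seed; generation is bit-identical given the seed.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples = 705, n_features = 1936,
                           prevalence = 0.133, n_signal = 10,
                           signal_effect = 1, n_high_variance = 10,
                           variance_boost = 5, n_duplicate_pairs = 5,
                           block_correlation = 0.5, missing_rate = 0.02,
                           modality_mix = c(rs_ = 0.65, cn_ = 0.20,
                                            mu_ = 0.10, pp_ = 0.05),
                           seed = 1) {
  stopifnot(n_samples >= 2, n_features >= 1,
            prevalence > 0, prevalence < 1,
            n_signal >= 0, signal_effect >= 0,
            n_high_variance >= 0, variance_boost >= 1,
            n_duplicate_pairs >= 0,
            block_correlation >= 0, block_correlation < 1,
            missing_rate >= 0, missing_rate < 1,
            all(c("rs_", "cn_", "mu_", "pp_") %in% names(modality_mix)))
  if (n_signal + n_high_variance + 2 * n_duplicate_pairs > n_features) {
    stop("n_signal + n_high_variance + 2*n_duplicate_pairs exceeds n_features")
  }
  if (round(prevalence * n_samples) < 1) {
    stop("prevalence * n_samples must be at least 1")
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_features = as.integer(n_features),
                 prevalence = prevalence, n_signal = as.integer(n_signal),
                 signal_effect = signal_effect,
                 n_high_variance = as.integer(n_high_variance),
                 variance_boost = variance_boost,
                 n_duplicate_pairs = as.integer(n_duplicate_pairs),
                 block_correlation = block_correlation,
                 missing_rate = missing_rate,
                 modality_mix = modality_mix / sum(modality_mix),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic table with known ground truth
#'
#' Draws a table per the spec. The outcome has exactly
#' `round(prevalence * n_samples)` positives. Signal features are standard
#' normal in the negative class and shifted by `signal_effect` in the
#' positive class; high-variance features are outcome-independent normals
#' with variance multiplied by `variance_boost`; duplicate pairs are
#' bit-identical columns; declared blocks share pairwise correlation
#' `block_correlation` via a common latent factor; `mu_`-modality noise
#' features are sparse binary. Missing entries are inserted into the raw
#' table, which is then zero-imputed by [preprocess()].
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `table` (the preprocessed [feature_table()]), `raw`
#'   (the raw data.frame including missing values and the `vital.status`
#'   column with levels Alive/Deceased), and `truth` (a `ground_truth` list:
#'   `signal_features` with their generating shifts, `high_variance_features`,
#'   `duplicate_pairs`, `correlated_blocks`, `noise_features`).
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_samples
  p <- spec$n_features
  with_local_seed(spec$seed, {
    n_pos <- as.integer(round(spec$prevalence * n))
    y <- integer(n)
    y[sample.int(n, n_pos)] <- 1L

    # modality assignment and names
    counts <- floor(spec$modality_mix * p)
    rem <- p - sum(counts)
    if (rem > 0) {
      top <- order(spec$modality_mix * p - counts, decreasing = TRUE)
      counts[top[seq_len(rem)]] <- counts[top[seq_len(rem)]] + 1
    }
    mods <- sample(rep(names(counts), counts))
    names_v <- paste0(mods, "F", formatC(seq_len(p), width = nchar(p),
                                         flag = "0"))

    # planted roles go to continuous-modality columns (mu_ is binary)
    cont <- which(mods != "mu_")
    need <- spec$n_signal + spec$n_high_variance + 2 * spec$n_duplicate_pairs
    if (length(cont) < need) {
      stop("not enough continuous-modality features for the planted structure")
    }
    role_cols <- sample(cont, need)
    sig_idx <- role_cols[seq_len(spec$n_signal)]
    hv_idx <- role_cols[spec$n_signal + seq_len(spec$n_high_variance)]
    dup_idx <- role_cols[spec$n_signal + spec$n_high_variance +
                           seq_len(2 * spec$n_duplicate_pairs)]
    dup_a <- dup_idx[seq_len(spec$n_duplicate_pairs)]
    dup_b <- dup_idx[spec$n_duplicate_pairs + seq_len(spec$n_duplicate_pairs)]
    noise_idx <- setdiff(seq_len(p), c(sig_idx, hv_idx, dup_a, dup_b))

    # base marginals per modality
    X <- matrix(0, n, p)
    for (j in seq_len(p)) {
      X[, j] <- switch(mods[j],
                       "mu_" = as.numeric(stats::rbinom(n, 1, 0.05)),
                       "cn_" = stats::rnorm(n, 0, 0.7),
                       stats::rnorm(n))
    }

    effects <- stats::setNames(rep(spec$signal_effect, spec$n_signal),
                               names_v[sig_idx])
    for (j in sig_idx) X[, j] <- stats::rnorm(n) + spec$signal_effect * y
    for (j in hv_idx) X[, j] <- stats::rnorm(n, 0, sqrt(spec$variance_boost))
    for (i in seq_along(dup_a)) X[, dup_b[i]] <- X[, dup_a[i]]

    # equicorrelated blocks of 5 over ~10% of the continuous noise features
    blocks <- list()
    if (spec$block_correlation > 0) {
      cont_noise <- intersect(noise_idx, cont)
      n_blocks <- min(floor(length(cont_noise) / 5),
                      max(1, floor(0.10 * p / 5)))
      if (length(cont_noise) >= 5 && n_blocks >= 1) {
        pool <- sample(cont_noise, 5 * n_blocks)
        rho <- spec$block_correlation
        for (b in seq_len(n_blocks)) {
          members <- pool[(b - 1) * 5 + 1:5]
          z <- stats::rnorm(n)
          for (j in members) {
            X[, j] <- sqrt(rho) * z + sqrt(1 - rho) * stats::rnorm(n)
          }
          blocks[[b]] <- names_v[members]
        }
      }
    }

    colnames(X) <- names_v
    # missingness inserted pre-preprocessing
    if (spec$missing_rate > 0) {
      na_at <- which(stats::runif(n * p) < spec$missing_rate)
      X[na_at] <- NA_real_
    }
    raw_df <- as.data.frame(X, check.names = FALSE)
    raw_df[["vital.status"]] <- ifelse(y == 1L, "Deceased", "Alive")

    raw <- raw_table(raw_df[, names_v, drop = FALSE],
                     raw_df[["vital.status"]])
    table <- preprocess(raw, preprocess_config(positive_label = "Deceased"))

    truth <- structure(list(
      signal_features = names_v[sig_idx],
      signal_effects = effects,
      high_variance_features = names_v[hv_idx],
      duplicate_pairs = Map(c, names_v[dup_a], names_v[dup_b]),
      correlated_blocks = blocks,
      noise_features = names_v[noise_idx]), class = "ground_truth")

    list(table = table, raw = raw_df, truth = truth)
  })
}

#' Deterministic fixture tables
#'
#' Small tables used throughout the test surface, all built in code:
#' \describe{
#'   \item{worked_example}{4 samples, one feature `x = (0,1,2,3)` with
#'     outcome `(0,0,1,1)`: the least-squares slope is 0.4 and the absolute
#'     Spearman correlation is `4/sqrt(20)`.}
#'   \item{binary_step}{4 samples, one feature `(0,0,1,1)`: sample variance
#'     1/3.}
#'   \item{axis_aligned}{4 samples, two exactly uncorrelated features with
#'     unequal variances: principal components align with the axes, so each
#'     feature's loading sum is 1.}
#'   \item{separable}{40 samples: one binary feature equal to the outcome
#'     plus 9 noise features.}
#'   \item{ties_everywhere}{6 samples x 8 identical columns: every scorer
#'     ties all features.}
#'   \item{duplicated_columns}{60 samples: an informative column, its exact
#'     duplicate, and 6 noise columns.}
#'   \item{wide}{30 samples x 300 features (p >> n), exercising the
#'     rank-deficient least-squares path.}
#' }
#'
#' @return Named list of [feature_table()] objects.
#' @export
fixture_suite <- function() {
  out <- list()
  out$worked_example <- feature_table(
    matrix(c(0, 1, 2, 3), 4, 1, dimnames = list(NULL, "x")),
    c(0, 0, 1, 1))
  out$binary_step <- feature_table(
    matrix(c(0, 0, 1, 1), 4, 1, dimnames = list(NULL, "b")),
    c(0, 1, 0, 1))
  out$axis_aligned <- feature_table(
    cbind(f1 = c(1, 1, -1, -1), f2 = c(2, -2, -2, 2)),
    c(0, 1, 0, 1))
  out$separable <- with_local_seed(101, {
    y <- rep(c(0L, 1L), each = 20)
    X <- cbind(sep = as.numeric(y),
               matrix(stats::rnorm(40 * 9), 40, 9,
                      dimnames = list(NULL, paste0("n", 1:9))))
    feature_table(X, y)
  })
  out$ties_everywhere <- feature_table(
    matrix(rep(c(0, 1, 0, 1, 1, 0), 8), 6, 8,
           dimnames = list(NULL, paste0("t", 1:8))),
    c(0, 1, 0, 1, 1, 0))
  out$duplicated_columns <- with_local_seed(102, {
    y <- rep(c(0L, 1L), 30)
    info <- stats::rnorm(60) + 1.5 * y
    X <- cbind(info_a = info, info_b = info,
               matrix(stats::rnorm(60 * 6), 60, 6,
                      dimnames = list(NULL, paste0("n", 1:6))))
    feature_table(X, y)
  })
  out$wide <- with_local_seed(103, {
    y <- rep(c(0L, 1L), 15)
    X <- matrix(stats::rnorm(30 * 300), 30, 300,
                dimnames = list(NULL, paste0("w", 1:300)))
    feature_table(X, y)
  })
  out
}
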