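#' Benchmark configuration
#'
#' Bundles every knob of an end-to-end run: the input (a [feature_table()],
#' a [synthetic_spec()], or a file path plus outcome column), the scorer set,
#' the scorer and evaluation configurations, the ranking size `k`, and the
#' perturbation depth `m`.
#'
#' @param input A `feature_table`, a `synthetic_spec`, or a file path string.
#' @param scorers Character vector of registered scorer ids (>= 1).
#' @param scorer_config A [scorer_config()].
#' @param k Ranking size (default 20); must exceed `m`.
#' @param m Perturbation depth (default 1).
#' @param eval_cfg An [eval_config()]; its `k` is forced to match `k`.
#' @param outcome_column Outcome column name when `input` is a path.
#' @param positive_label Positive outcome level when `input` is a path.
#' @param output_dir Directory for rendered reports, or `NULL` to skip
#'   writing.
#' @param formats Subset of `c("csv", "json", "markdown")`.
#' @return A list of class `benchmark_config`.
#' @export
benchmark_config <- function(input, scorers = list_scorers(),
                             scorer_config = rankstab::scorer_config(),
                             k = 20, m = 1, eval_cfg = eval_config(k = k),
                             outcome_column = "vital.status",
                             positive_label = NULL,
                             output_dir = NULL,
                             formats = c("csv", "json")) {
  if (length(scorers) < 1) stop("at least one scorer required")
  if (m >= k) stop("perturbation depth m must be smaller than k")
  bad <- setdiff(formats, c("csv", "json", "markdown"))
  if (length(bad)) stop("unknown format(s): ", paste(bad, collapse = ", "))
  missing_sc <- setdiff(scorers, list_scorers())
  if (length(missing_sc)) {
    stop("unregistered scorer(s): ", paste(missing_sc, collapse = ", "))
  }
  eval_cfg$k <- as.integer(k)
  structure(list(input = input, scorers = scorers,
                 scorer_config = scorer_config, k = as.integer(k),
                 m = as.integer(m), eval_cfg = eval_cfg,
                 outcome_column = outcome_column,
                 positive_label = positive_label,
                 output_dir = output_dir, formats = formats),
            class = "benchmark_config")
}

resolve_input <- function(config) {
  input <- config$input
  if (inherits(input, "feature_table")) return(input)
  if (inherits(input, "synthetic_spec")) return(generate_synthetic(input)$table)
  if (is.character(input) && length(input) == 1) {
    raw <- load_table(input, config$outcome_column)
    return(preprocess(raw,
                      preprocess_config(positive_label =
                                          config$positive_label)))
  }
  stop("input must be a feature_table, a synthetic_spec, or a file path")
}

# Stable hash of the semantically meaningful configuration fields.
config_hash <- function(config) {
  semantic <- config[c("scorers", "k", "m", "outcome_column",
                       "positive_label")]
  semantic$scorer_config <- unclass(config$scorer_config)
  semantic$eval_cfg <- unclass(config$eval_cfg)
  semantic$input <- if (inherits(config$input, "synthetic_spec")) {
    unclass(config$input)
  } else if (is.character(config$input)) {
    config$input
  } else {
    c(dim(config$input$values), sum(config$input$outcome))
  }
  js <- jsonlite::toJSON(semantic, auto_unbox = TRUE, digits = NA,
                         null = "null")
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeChar(as.character(js), tmp, eos = NULL)
  unname(tools::md5sum(tmp))
}

#' Run the full stability-and-accuracy benchmark
#'
#' Executes, for every configured scorer, the perturbation protocol
#' ([run_perturbation()]) and the leakage-safe downstream evaluation
#' ([evaluate_selector()]), then assembles the cross-method comparison table
#' ([rank_methods()]). If `output_dir` is set, reports are rendered in every
#' configured format. Timestamps are isolated in the run metadata so repeated
#' runs with identical configuration produce byte-identical reports.
#'
#' @param config A [benchmark_config()].
#' @return An object of class `benchmark_result` with `stability` (named list
#'   of `stability_report`), `evaluation` (named list of `eval_metrics`),
#'   `comparison` (the [rank_methods()] table), and `metadata`.
#' @export
run_benchmark <- function(config) {
  stopifnot(inherits(config, "benchmark_config"))
  table <- resolve_input(config)
  if (ncol(table$values) <= config$k) {
    stop("input has too few features for k = ", config$k)
  }
  stability <- list()
  evaluation <- list()
  for (id in config$scorers) {
    message("[rankstab] perturbation: ", id)
    stability[[id]] <- run_perturbation(table, id, config$scorer_config,
                                        k = config$k, m = config$m)
    message("[rankstab] evaluation: ", id)
    evaluation[[id]] <- evaluate_selector(table, id, config$scorer_config,
                                          config$eval_cfg)
  }
  comparison <- if (length(config$scorers) >= 2) {
    rank_methods(evaluation, stability)
  } else NULL
  result <- structure(list(
    stability = stability, evaluation = evaluation, comparison = comparison,
    metadata = list(
      config_hash = config_hash(config),
      scorers = config$scorers, k = config$k, m = config$m,
      eval_seeds = config$eval_cfg$seeds,
      package_version = as.character(utils::packageVersion("rankstab")),
      r_version = R.version.string,
      timestamp = format(Sys.time(), tz = "UTC"))),
    class = "benchmark_result")
  if (!is.null(config$output_dir)) {
    for (fmt in config$formats) {
      render_tables(result, fmt, config$output_dir)
    }
  }
  result
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("<benchmark_result>\n")
  if (!is.null(x$comparison)) {
    print(x$comparison[, c("method", "consistency", "accuracy_mean",
                           "sensitivity_mean", "f1_mean")])
  }
  invisible(x)
}

result_as_list <- function(result) {
  list(
    stability = lapply(result$stability, function(r) list(
      scorer_id = r$scorer_id, k = r$k, m = r$m,
      original_ranking = r$original_ranking$ordered_features,
      removed_features = r$removed_features,
      perturbed_ranking = r$perturbed_ranking$ordered_features,
      verdict = list(label = r$verdict$label,
                     first_divergence = r$verdict$first_divergence,
                     set_difference = r$verdict$set_difference,
                     order_preserved = r$verdict$order_preserved),
      contrast_metrics = r$contrast_metrics)),
    evaluation = lapply(result$evaluation, function(e) list(
      scorer_id = e$scorer_id,
      accuracy_mean = e$accuracy_mean, accuracy_sd = e$accuracy_sd,
      sensitivity_mean = e$sensitivity_mean, sensitivity_sd = e$sensitivity_sd,
      f1_mean = e$f1_mean, f1_sd = e$f1_sd,
      aggregation_tag = e$aggregation_tag,
      per_cell = e$per_cell)),
    comparison = result$comparison,
    metadata = result$metadata[setdiff(names(result$metadata), "timestamp")])
}

#' Render benchmark reports to files
#'
#' Writes (a) one two-column rankings table per scorer, with the first `m`
#' perturbed cells holding a horizontal bar, and (b) the aggregate comparison
#' table with consistency labels, metric means and SDs, and dense ranks. JSON
#' output additionally contains the full report (per-cell metrics included).
#' The run timestamp is written only to `run_metadata.json`, keeping every
#' other artifact byte-identical across repeated runs.
#'
#' @param result A `benchmark_result`.
#' @param format One of `"csv"`, `"json"`, `"markdown"`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
render_tables <- function(result, format = c("csv", "json", "markdown"),
                          dir = ".") {
  stopifnot(inherits(result, "benchmark_result"))
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)

  if (format == "json") {
    p <- file.path(dir, "report.json")
    jsonlite::write_json(result_as_list(result), p, auto_unbox = TRUE,
                         digits = NA, null = "null", na = "null",
                         dataframe = "rows")
    pm <- file.path(dir, "run_metadata.json")
    jsonlite::write_json(result$metadata, pm, auto_unbox = TRUE, digits = NA)
    return(invisible(c(p, pm)))
  }

  for (id in names(result$stability)) {
    tab <- format_ranking_table(result$stability[[id]])
    names(tab) <- c("Rank", "Ranking (Original Set)",
                    sprintf("Ranking (W/O Top %d)", result$stability[[id]]$m))
    p <- file.path(dir, sprintf("rankings_%s.%s", id,
                                if (format == "csv") "csv" else "md"))
    if (format == "csv") {
      utils::write.csv(tab, p, row.names = FALSE, fileEncoding = "UTF-8")
    } else {
      writeLines(markdown_table(tab), p, useBytes = TRUE)
    }
    paths <- c(paths, p)
  }
  if (!is.null(result$comparison)) {
    p <- file.path(dir, paste0("comparison.",
                               if (format == "csv") "csv" else "md"))
    if (format == "csv") {
      utils::write.csv(result$comparison, p, row.names = FALSE,
                       fileEncoding = "UTF-8")
    } else {
      writeLines(markdown_table(result$comparison), p, useBytes = TRUE)
    }
    paths <- c(paths, p)
  }
  invisible(paths)
}

markdown_table <- function(df) {
  fmt_cell <- function(x) {
    if (is.numeric(x)) formatC(x, digits = 6, format = "g") else as.character(x)
  }
  cells <- vapply(df, function(col) as.character(sapply(col, fmt_cell)),
                  character(nrow(df)))
  if (nrow(df) == 1) cells <- matrix(cells, nrow = 1)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep(" --- ", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "),
                                             " |"))
  c(header, sep, body)
}
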