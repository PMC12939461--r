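#' Construct a feature table
#'
#' A `feature_table` holds a fully numeric samples x features matrix, a
#' binary outcome vector, and the *original* column order of every feature.
#' The original order is frozen when the table is first built and survives
#' feature removal, because it is the deterministic tie-break used by all
#' ranking operations downstream.
#'
#' @param values Numeric matrix (samples x features) with unique column names.
#' @param outcome Vector of 0/1 outcome labels, one per row (1 = positive,
#'   e.g. deceased).
#' @param column_order Optional named integer vector mapping each feature name
#'   to its original 0-based column index. Defaults to the current positions.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(values, outcome, column_order = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  fn <- colnames(values)
  if (is.null(fn) && ncol(values) == 0) fn <- character(0)
  if (is.null(fn) || anyNA(fn) || any(fn == "")) {
    stop("`values` must have non-empty column names")
  }
  if (anyDuplicated(fn)) {
    stop("duplicate feature names: ",
         paste(unique(fn[duplicated(fn)]), collapse = ", "))
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("`values` must contain only finite entries (preprocess first)")
  }
  outcome <- as.integer(outcome)
  if (length(outcome) != nrow(values)) {
    stop("`outcome` length must equal the number of rows")
  }
  if (!all(outcome %in% c(0L, 1L))) {
    stop("`outcome` must contain only 0 and 1")
  }
  if (is.null(column_order)) {
    column_order <- stats::setNames(seq_along(fn) - 1L, fn)
  }
  column_order <- column_order[fn]
  if (anyNA(column_order)) stop("`column_order` must cover every feature")
  structure(
    list(values = values, feature_names = fn,
         column_order = column_order, outcome = outcome),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d features, %d positive (%.1f%%)\n",
              nrow(x$values), ncol(x$values), sum(x$outcome),
              100 * mean(x$outcome)))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Modality tag of a feature name
#'
#' Feature names in the multi-omics convention carry a data-layer prefix:
#' `rs_` (expression/SNP identifiers), `cn_` (copy number), `mu_` (mutation),
#' `pp_` (phosphoprotein). Anything else is tagged `other`.
#'
#' @param names Character vector of feature names.
#' @return Character vector of tags in `{rs_, cn_, mu_, pp_, other}`.
#' @export
modality <- function(names) {
  tags <- c("rs_", "cn_", "mu_", "pp_")
  out <- rep("other", length(names))
  for (t in tags) out[startsWith(names, t)] <- t
  out
}

#' Load a delimited samples x features table
#'
#' Reads a CSV or TSV file (delimiter auto-detected from the extension,
#' comma by default) with a mandatory header row, separating the outcome
#' column from the feature columns. No type coercion or imputation happens
#' here; see [preprocess()].
#'
#' @param path Path to the delimited file.
#' @param outcome_column Name of the outcome column (default `"vital.status"`).
#' @return A list of class `raw_table` with elements `features` (data.frame,
#'   columns in file order), `outcome` (raw vector), `n_rows`, `n_cols`.
#' @export
load_table <- function(path, outcome_column = "vital.status") {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""),
                          quote = "\"", comment.char = "", fileEncoding = "UTF-8")
  nm <- names(df)
  if (anyDuplicated(nm)) {
    stop("duplicate column names in ", path, ": ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  if (!outcome_column %in% nm) {
    stop("outcome column '", outcome_column, "' not found in ", path)
  }
  feats <- df[, setdiff(nm, outcome_column), drop = FALSE]
  structure(
    list(features = feats, outcome = df[[outcome_column]],
         n_rows = nrow(df), n_cols = ncol(feats)),
    class = "raw_table"
  )
}

#' Raw table from in-memory data
#'
#' Convenience constructor building the same structure as [load_table()]
#' from a data.frame, for programmatic use and fixtures.
#'
#' @param features Data frame of feature columns (mixed types allowed).
#' @param outcome Raw outcome vector.
#' @return A `raw_table`.
#' @export
raw_table <- function(features, outcome) {
  if (anyDuplicated(names(features))) {
    stop("duplicate column names: ",
         paste(unique(names(features)[duplicated(names(features))]),
               collapse = ", "))
  }
  if (length(outcome) != nrow(features)) stop("outcome length mismatch")
  structure(list(features = features, outcome = outcome,
                 n_rows = nrow(features), n_cols = ncol(features)),
            class = "raw_table")
}

#' Preprocessing configuration
#'
#' @param missing_fill_value Finite number substituted for missing numeric
#'   entries (default 0).
#' @param one_hot Expand categorical columns into indicator columns
#'   (default TRUE).
#' @param positive_label Raw outcome level mapped to 1. May be `NULL` when
#'   the outcome is already coded 0/1.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(missing_fill_value = 0, one_hot = TRUE,
                              positive_label = NULL) {
  stopifnot(is.numeric(missing_fill_value), is.finite(missing_fill_value))
  structure(list(missing_fill_value = missing_fill_value,
                 one_hot = one_hot, positive_label = positive_label),
            class = "preprocess_config")
}

#' Preprocess a raw table into a feature table
#'
#' Missing numeric entries are replaced by `missing_fill_value` (zero by
#' default); categorical columns are one-hot encoded into indicator columns
#' named `"<col>=<level>"` inserted at the original column position, with
#' missing categorical entries yielding all-zero indicator rows; the outcome
#' is mapped to 1 for `positive_label` and 0 otherwise. No scaling or
#' normalization is applied.
#'
#' @param raw A `raw_table` from [load_table()] or [raw_table()].
#' @param config A [preprocess_config()].
#' @return A [feature_table()].
#' @export
preprocess <- function(raw, config = preprocess_config()) {
  stopifnot(inherits(raw, "raw_table"))
  y <- encode_outcome(raw$outcome, config$positive_label)

  cols <- list()
  for (nm in names(raw$features)) {
    col <- raw$features[[nm]]
    if (is.numeric(col) || is.logical(col)) {
      col <- as.numeric(col)
      bad <- !is.na(col) & !is.finite(col)
      if (any(bad)) stop("non-finite values in numeric column '", nm, "'")
      col[is.na(col)] <- config$missing_fill_value
      cols[[nm]] <- col
    } else if (config$one_hot) {
      col <- as.character(col)
      levs <- sort(unique(col[!is.na(col)]))
      for (lv in levs) {
        cols[[paste0(nm, "=", lv)]] <- as.numeric(!is.na(col) & col == lv)
      }
    } else {
      stop("categorical column '", nm, "' with one_hot = FALSE")
    }
  }
  values <- do.call(cbind, cols)
  colnames(values) <- names(cols)
  feature_table(values, y)
}

encode_outcome <- function(outcome, positive_label) {
  if (is.numeric(outcome) && all(stats::na.omit(outcome) %in% c(0, 1))) {
    if (anyNA(outcome)) stop("missing values in outcome")
    if (!is.null(positive_label) && !identical(positive_label, "1")) {
      stop("positive_label given but outcome already coded 0/1")
    }
    return(as.integer(outcome))
  }
  levs <- sort(unique(as.character(stats::na.omit(outcome))))
  if (length(levs) != 2L) {
    stop("outcome must take exactly two levels, observed: ",
         paste(levs, collapse = ", "))
  }
  if (anyNA(outcome)) stop("missing values in outcome")
  if (is.null(positive_label)) {
    stop("positive_label required for a non-numeric outcome with levels: ",
         paste(levs, collapse = ", "))
  }
  if (!positive_label %in% levs) {
    stop("positive_label '", positive_label, "' not an observed outcome level")
  }
  as.integer(as.character(outcome) == positive_label)
}

#' Remove features from a table
#'
#' Surviving columns keep their relative order and retain their original
#' column-order indices, so tie-breaking downstream is unchanged by removal.
#'
#' @param table A `feature_table`.
#' @param names Character vector of feature names to remove (may be empty).
#' @return A `feature_table` without the named columns.
#' @export
drop_features <- function(table, names) {
  stopifnot(inherits(table, "feature_table"))
  names <- unique(as.character(names))
  unknown <- setdiff(names, table$feature_names)
  if (length(unknown)) {
    stop("unknown feature name(s): ", paste(unknown, collapse = ", "))
  }
  keep <- !(table$feature_names %in% names)
  feature_table(table$values[, keep, drop = FALSE], table$outcome,
                column_order = table$column_order[keep])
}

#' Subset the rows (samples) of a feature table
#'
#' @param table A `feature_table`.
#' @param rows Integer or logical index of rows to keep.
#' @return A `feature_table` with the selected rows; column order unchanged.
#' @export
subset_samples <- function(table, rows) {
  stopifnot(inherits(table, "feature_table"))
  feature_table(table$values[rows, , drop = FALSE], table$outcome[rows],
                column_order = table$column_order)
}

#' Write a feature table to CSV
#'
#' Round-trip writer used for fixtures: the outcome is written under the
#' given column name, followed by the feature columns in their current order.
#'
#' @param table A `feature_table`.
#' @param path Output CSV path.
#' @param outcome_column Column name for the outcome (default `"vital.status"`).
#' @export
write_feature_table <- function(table, path, outcome_column = "vital.status") {
  stopifnot(inherits(table, "feature_table"))
  df <- data.frame(table$outcome, table$values, check.names = FALSE)
  names(df)[1] <- outcome_column
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
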