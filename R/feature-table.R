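#' Read a protein feature table
#'
#' Reads a delimited text file with one row per protein: an identifier
#' column plus a fixed-width numeric feature vector (85 dimensions in the
#' motivating blood-secretory use case, but any width is accepted). The
#' result is a tibble whose first column is `id` (character) and whose
#' remaining columns are numeric features, the in-memory feature-table
#' format used throughout the package.
#'
#' Missing values are a hard error: the feature vectors this package was
#' designed for are complete, and silent imputation would corrupt the
#' distance geometry every downstream stage depends on.
#'
#' @param path Path to a TSV (default) or CSV file.
#' @param delim Field delimiter, `"tab"` or `"comma"`.
#' @param header Does the file carry a header row? If `FALSE`, columns are
#'   named `id`, `f1`, `f2`, ...
#' @param id_column Name or 1-based index of the identifier column
#'   (default: first column).
#'
#' @return A feature-table tibble: column `id` plus numeric feature columns.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("id\tf1\tf2", "a\t0\t0", "b\t3\t4", "c\t1\t1"), tf)
#' read_feature_table(tf)
#' @export
read_feature_table <- function(path, delim = c("tab", "comma"), header = TRUE,
                               id_column = 1L) {
  delim <- match.arg(delim)
  sep <- if (delim == "tab") "\t" else ","
  if (!file.exists(path)) {
    stop_validation(paste0("feature table not found: ", path))
  }
  raw <- suppressWarnings(readr::read_delim(
    path,
    delim = sep,
    col_names = header,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE,
    lazy = FALSE
  ))
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    stop_validation(paste0(
      "malformed feature table: line ", probs$row[1], " of ", path,
      " does not have the expected number of fields (", probs$expected[1],
      " expected, ", probs$actual[1], " found)"
    ))
  }
  if (is.character(id_column)) {
    if (!id_column %in% names(raw)) {
      stop_validation(paste0("id column '", id_column, "' not found in ", path))
    }
    id_idx <- match(id_column, names(raw))
  } else {
    id_idx <- as.integer(id_column)
    if (id_idx < 1L || id_idx > ncol(raw)) {
      stop_validation(paste0("id column index ", id_idx, " out of range"))
    }
  }
  ids <- raw[[id_idx]]
  feat <- raw[-id_idx]
  if (!header) {
    names(feat) <- paste0("f", seq_len(ncol(feat)))
  } else if ("id" %in% names(feat)) {
    # the identifier column claims the name "id" in the output tibble
    names(feat)[names(feat) == "id"] <- "id.feature"
  }
  parsed <- purrr::map(feat, function(col) {
    suppressWarnings(as.numeric(col))
  })
  for (j in seq_along(parsed)) {
    bad <- which(is.na(parsed[[j]]))
    if (length(bad) > 0) {
      i <- bad[1]
      cell <- feat[[j]][i]
      what <- if (is.na(cell) || cell %in% c("", "NA", "na", "NaN")) {
        "missing value"
      } else {
        paste0("non-numeric value '", cell, "'")
      }
      stop_validation(paste0(
        what, " at row ", i, ", feature column '", names(feat)[j],
        "' of ", path
      ))
    }
  }
  out <- tibble(id = as.character(ids))
  out[names(feat)] <- parsed
  validate_feature_table(out)
}

#' Write a feature table
#'
#' Inverse of [read_feature_table()]: writes the tibble as delimited text
#' with full double precision, so a write/read roundtrip preserves values.
#'
#' @param data A feature-table tibble (see [read_feature_table()]).
#' @param path Output path.
#' @param delim `"tab"` or `"comma"`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(data, path, delim = c("tab", "comma")) {
  delim <- match.arg(delim)
  data <- validate_feature_table(data)
  sep <- if (delim == "tab") "\t" else ","
  header <- paste(names(data), collapse = sep)
  feat <- as.matrix(data[-1])
  rows <- apply(format(feat, digits = 17, trim = TRUE, scientific = TRUE),
                1, paste, collapse = sep)
  writeLines(c(header, paste(data$id, rows, sep = sep)), path)
  invisible(path)
}

#' Validate a feature-table tibble
#'
#' Checks the invariants every stage relies on: unique character ids in the
#' first column, all remaining columns numeric and finite, at least two
#' rows and one feature.
#'
#' @param data A data frame to validate.
#' @param min_rows Minimum acceptable number of rows.
#' @return The validated tibble, invisibly usable in pipes.
#' @export
validate_feature_table <- function(data, min_rows = 2L) {
  data <- as_tibble(data)
  if (ncol(data) < 2L) {
    stop_validation("feature table needs an id column plus at least one feature column")
  }
  if (names(data)[1] != "id") names(data)[1] <- "id"
  data$id <- as.character(data$id)
  dup <- data$id[duplicated(data$id)]
  if (length(dup) > 0) {
    stop_validation(paste0(
      "duplicate identifiers in feature table: ",
      paste(unique(dup), collapse = ", ")
    ))
  }
  if (nrow(data) < min_rows) {
    stop_validation(paste0("feature table needs at least ", min_rows, " rows"))
  }
  for (j in seq(2L, ncol(data))) {
    if (!is.numeric(data[[j]])) {
      stop_validation(paste0("feature column '", names(data)[j], "' is not numeric"))
    }
    if (any(!is.finite(data[[j]]))) {
      i <- which(!is.finite(data[[j]]))[1]
      stop_validation(paste0(
        "non-finite value at row ", i, ", feature column '", names(data)[j], "'"
      ))
    }
  }
  data
}

# Feature matrix (rows = samples, rownames = ids) from a feature table.
feature_matrix <- function(data) {
  data <- validate_feature_table(data)
  X <- as.matrix(data[-1])
  rownames(X) <- data$id
  X
}

#' Standardise feature columns
#'
#' Optional z-score scaling (mean 0, sd 1 per feature) before distance
#' computation. Off by default throughout the package: the ranking method
#' is defined on raw feature-space distances, but heterogeneous feature
#' scales can dominate the Euclidean metric, so the flag is exposed.
#' Constant columns are left at zero rather than dividing by a zero sd.
#'
#' @param data A feature-table tibble.
#' @return The tibble with each feature column centred and scaled.
#' @export
zscore_features <- function(data) {
  data <- validate_feature_table(data)
  dplyr::mutate(data, dplyr::across(
    -"id",
    function(x) {
      s <- stats::sd(x)
      if (s == 0) x - mean(x) else (x - mean(x)) / s
    }
  ))
}
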