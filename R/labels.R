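#' Build a label assignment for a feature table
#'
#' In the positive-unlabeled setting the input splits into known positives
#' (the queries — here, experimentally validated blood-secretory proteins),
#' optionally known negatives (used only by the universal ranking variant),
#' and an unlabeled background. The assignment is a tibble with one row per
#' feature-table row, in table order, with a `status` column in
#' `{"positive", "negative", "unlabeled"}`.
#'
#' @param data A feature-table tibble (see [read_feature_table()]).
#' @param positives Character vector of ids of known positives (queries).
#' @param negatives Optional character vector of ids of known negatives.
#' @return A tibble with columns `id` and `status`, one row per sample.
#' @examples
#' tbl <- tibble::tibble(id = c("a", "b", "c"), f1 = c(0, 1, 2))
#' assign_labels(tbl, positives = "a", negatives = "b")
#' @export
assign_labels <- function(data, positives, negatives = character()) {
  data <- validate_feature_table(data)
  positives <- as.character(positives)
  negatives <- as.character(negatives)
  unknown <- setdiff(c(positives, negatives), data$id)
  if (length(unknown) > 0) {
    stop_validation(paste0(
      "labelled ids not present in the feature table: ",
      paste(unknown, collapse = ", ")
    ))
  }
  if (length(positives) == 0) {
    stop_validation("at least one positive (query) id is required")
  }
  both <- intersect(positives, negatives)
  if (length(both) > 0) {
    stop_validation(paste0(
      "ids labelled both positive and negative: ", paste(both, collapse = ", ")
    ))
  }
  if (all(data$id %in% positives)) {
    stop_validation("every sample is a query; nothing is left to rank")
  }
  status <- rep("unlabeled", nrow(data))
  status[data$id %in% positives] <- "positive"
  status[data$id %in% negatives] <- "negative"
  tibble(id = data$id, status = status)
}

#' Read a query (label) file
#'
#' Reads a one- or two-column delimited file of labelled ids. A single
#' column lists positives; an optional second column gives the status
#' (`positive` or `negative`) per id, for the universal variant. All ids
#' absent from the file become unlabeled; counts are reported via a
#' message.
#'
#' @param path Path to the label file (TSV; no header).
#' @param data The feature table the labels refer to.
#' @return A label tibble as produced by [assign_labels()].
#' @export
read_labels <- function(path, data) {
  if (!file.exists(path)) {
    stop_validation(paste0("label file not found: ", path))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, function(p) trimws(p[[1]]), character(1))
  status <- vapply(parts, function(p) {
    if (length(p) >= 2) trimws(p[[2]]) else "positive"
  }, character(1))
  bad <- setdiff(unique(status), c("positive", "negative"))
  if (length(bad) > 0) {
    stop_validation(paste0(
      "unrecognised status values in ", path, ": ", paste(bad, collapse = ", ")
    ))
  }
  labels <- assign_labels(
    data,
    positives = ids[status == "positive"],
    negatives = ids[status == "negative"]
  )
  counts <- table(factor(labels$status, c("positive", "negative", "unlabeled")))
  inform(paste0(
    "labels: ", counts[["positive"]], " positive, ", counts[["negative"]],
    " negative, ", counts[["unlabeled"]], " unlabeled"
  ))
  labels
}

# Initial score vectors in table order: y (1 for positives, else 0),
# y_plus (= y) and y_minus (-1 for negatives, else 0).
label_vectors <- function(labels) {
  stopifnot(all(c("id", "status") %in% names(labels)))
  y <- as.numeric(labels$status == "positive")
  if (sum(y) == 0) stop_validation("label assignment has no positives")
  list(
    y = y,
    y_plus = y,
    y_minus = -as.numeric(labels$status == "negative")
  )
}

#' Write a ranking to a delimited file
#'
#' Writes the top `top_n` samples as `id<TAB>rank<TAB>score`, in
#' descending score order, scores printed with 6 significant digits.
#' Score ties keep input row order (stable), so output is deterministic.
#'
#' @param result A ranking result (from [manifold_rank()] or the low-level
#'   solvers), or any tibble with `id` and `score` columns.
#' @param path Output path.
#' @param top_n Number of top-ranked rows to write; values above the
#'   sample count are clamped with a warning; `0` writes a header only.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(result, path, top_n = Inf) {
  scores <- if (inherits(result, "secrank_ranking")) tidy(result) else as_tibble(result)
  stopifnot(all(c("id", "score") %in% names(scores)))
  n <- nrow(scores)
  if (top_n > n) {
    if (is.finite(top_n)) {
      warn(paste0("top_n = ", top_n, " exceeds sample count ", n, "; clamping"))
    }
    top_n <- n
  }
  ord <- order(-scores$score, seq_len(n))
  sel <- scores[ord, ][seq_len(top_n), , drop = FALSE]
  lines <- "id\trank\tscore"
  if (top_n > 0) {
    lines <- c(lines, paste(
      sel$id, seq_len(top_n),
      formatC(sel$score, format = "g", digits = 6),
      sep = "\t"
    ))
  }
  writeLines(lines, path)
  invisible(path)
}
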