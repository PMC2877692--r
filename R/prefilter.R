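#' Nearest-positive distance per sample
#'
#' For every sample, the Euclidean distance to its nearest known positive
#' (query). Positives are at distance 0 from themselves. This single
#' statistic drives both the prefilter (drop the farthest unlabeled
#' samples before the O(n^3) ranking) and the nearest-distance baseline
#' ranker.
#'
#' @param data A feature-table tibble.
#' @param labels A label tibble from [assign_labels()].
#' @return A tibble with columns `id`, `status`,
#'   `nearest_positive_distance`, one row per sample in table order.
#' @export
nearest_positive_distance <- function(data, labels) {
  data <- validate_feature_table(data)
  check_labels_match(data, labels)
  X <- feature_matrix(data)
  pos <- labels$status == "positive"
  if (!any(pos)) stop_validation("no positive samples to measure distance to")
  Xp <- X[pos, , drop = FALSE]
  # squared cross-distances via the expansion ||x||^2 + ||p||^2 - 2 x.p
  d2 <- outer(rowSums(X^2), rowSums(Xp^2), "+") - 2 * tcrossprod(X, Xp)
  d2[d2 < 0] <- 0
  nd <- unname(sqrt(apply(d2, 1, min)))
  nd[pos] <- 0
  tibble(
    id = data$id,
    status = labels$status,
    nearest_positive_distance = nd
  )
}

check_labels_match <- function(data, labels) {
  if (!all(c("id", "status") %in% names(labels)) ||
      nrow(labels) != nrow(data) ||
      !identical(labels$id, data$id)) {
    stop_validation("labels do not match the feature table (same ids, same order, required)")
  }
  invisible(TRUE)
}

#' Prefilter: drop the k least query-like unlabeled samples
#'
#' Ranks unlabeled samples by nearest-positive distance and removes the
#' `k` farthest before graph construction, keeping the cubic-cost ranking
#' tractable on large candidate pools. Positives are never dropped; known
#' negatives are protected by default (the filter targets unknown samples
#' only) but can be exposed with `protect_negatives = FALSE`. Ties in
#' distance are broken by input row order. Row order among retained
#' samples is preserved.
#'
#' @param data A feature-table tibble.
#' @param labels A label tibble from [assign_labels()].
#' @param k Number of samples to drop (non-negative integer).
#' @param protect_negatives Keep known negatives regardless of distance?
#' @return A list with elements `data` (retained feature table), `labels`
#'   (retained label rows), and `report`: a tibble (`id`,
#'   `nearest_positive_distance`, `dropped`) over all input samples.
#' @examples
#' tbl <- tibble::tibble(id = c("p", "u1", "u2", "u3"), f1 = c(0, 1, 5, 9))
#' lab <- assign_labels(tbl, positives = "p")
#' filter_bottom_k(tbl, lab, k = 2)$report
#' @export
filter_bottom_k <- function(data, labels, k, protect_negatives = TRUE) {
  data <- validate_feature_table(data)
  check_labels_match(data, labels)
  k <- as.integer(k)
  if (k < 0) stop_validation("k must be non-negative")
  nd <- nearest_positive_distance(data, labels)
  droppable <- labels$status == "unlabeled" |
    (!protect_negatives & labels$status == "negative")
  k_max <- sum(droppable)
  if (k > k_max) {
    stop_validation(paste0(
      "k = ", k, " exceeds the number of filterable samples; maximum is ", k_max
    ))
  }
  dropped <- rep(FALSE, nrow(data))
  if (k > 0) {
    cand <- which(droppable)
    ord <- cand[order(-nd$nearest_positive_distance[cand], cand)]
    dropped[ord[seq_len(k)]] <- TRUE
  }
  report <- tibble(
    id = data$id,
    nearest_positive_distance = nd$nearest_positive_distance,
    dropped = dropped
  )
  list(
    data = data[!dropped, , drop = FALSE],
    labels = labels[!dropped, , drop = FALSE],
    report = report
  )
}

#' Write a prefilter report
#'
#' @param report The `report` tibble from [filter_bottom_k()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  lines <- c(
    "id\tnearest_positive_distance\tdropped",
    paste(report$id,
          formatC(report$nearest_positive_distance, format = "g", digits = 6),
          ifelse(report$dropped, "yes", "no"),
          sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}
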