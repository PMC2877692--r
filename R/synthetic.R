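#' Simulate a positive-unlabeled feature dataset
#'
#' Seeded generator emulating, at desk scale, the structure of a
#' secretory-protein screen: a small set of labelled positives (queries),
#' a pool of hidden positives sharing their feature-space structure, and
#' a majority of negatives (defaults keep roughly the 1:20
#' positive:negative imbalance of the motivating 305-versus-14,770
#' screen, with the same 85-dimensional feature space).
#'
#' Two layouts:
#' * `"gaussian_clusters"`: positives and negatives are isotropic
#'   Gaussian clouds whose centres sit `separation * noise_sd` apart
#'   along a random direction in the m-dimensional space — the simple
#'   geometry where any reasonable ranker succeeds once separation is
#'   large.
#' * `"curved_manifold"`: positives lie along a one-dimensional arc
#'   embedded in the first two coordinates, negatives along a parallel
#'   (concentric) arc a gap of `separation * noise_sd` away, both with
#'   isotropic noise in all `m` coordinates. Queries cover only part of
#'   the arc by chance, so plain nearest-query distance confuses
#'   far-along-the-arc positives with nearby negatives, while
#'   propagation along the densely sampled arc does not — the geometry
#'   that motivates transductive ranking.
#'
#' @param n_query Number of labelled positives (queries); at least 1.
#' @param n_hidden_pos Number of unlabeled true positives.
#' @param n_neg Number of unlabeled negatives.
#' @param m Feature dimension (default 85).
#' @param separation Class separation in units of `noise_sd`.
#' @param noise_sd Isotropic noise standard deviation (> 0).
#' @param layout `"gaussian_clusters"` or `"curved_manifold"`.
#' @param seed Integer seed; the output is a deterministic function of it.
#' @return A list with `data` (feature-table tibble, rows in randomised
#'   order), `labels` (queries marked positive, everything else
#'   unlabeled), and `truth` (tibble `id`, `is_positive` marking all true
#'   positives, hidden and query alike).
#' @examples
#' sim <- simulate_pu_data(n_query = 5, n_hidden_pos = 10, n_neg = 40,
#'                         m = 10, seed = 7)
#' dplyr::count(dplyr::left_join(sim$labels, sim$truth, by = "id"),
#'              status, is_positive)
#' @export
simulate_pu_data <- function(n_query = 10L, n_hidden_pos = 40L, n_neg = 200L,
                             m = 85L, separation = 6, noise_sd = 1,
                             layout = c("gaussian_clusters", "curved_manifold"),
                             seed = NULL) {
  layout <- match.arg(layout)
  if (n_query < 1L) stop_validation("n_query must be at least 1")
  if (n_hidden_pos < 0L || n_neg < 0L) stop_validation("counts must be non-negative")
  if (separation < 0) stop_validation("separation must be non-negative")
  if (noise_sd <= 0) stop_validation("noise_sd must be positive")
  if (m < 2L) stop_validation("at least 2 feature dimensions required")
  if (!is.null(seed)) set.seed(as.integer(seed))

  n_pos <- n_query + n_hidden_pos
  n <- n_pos + n_neg
  if (n < 2L) stop_validation("need at least 2 samples in total")

  if (layout == "gaussian_clusters") {
    u <- rnorm(m)
    u <- u / sqrt(sum(u^2))
    centre_neg <- separation * noise_sd * u
    X <- matrix(rnorm(n * m, sd = noise_sd), n, m)
    if (n_neg > 0) {
      X[(n_pos + 1):n, ] <- X[(n_pos + 1):n, , drop = FALSE] +
        matrix(centre_neg, n_neg, m, byrow = TRUE)
    }
  } else {
    gap <- separation * noise_sd
    radius <- 4 * gap # arc long relative to the class gap: chords between
    # distant arc points exceed the gap, which is what defeats
    # point-to-query distance
    t_pos <- runif(n_pos, 0, pi)
    t_neg <- runif(n_neg, 0, pi)
    X <- matrix(rnorm(n * m, sd = noise_sd), n, m)
    X[seq_len(n_pos), 1] <- X[seq_len(n_pos), 1] + radius * cos(t_pos)
    X[seq_len(n_pos), 2] <- X[seq_len(n_pos), 2] + radius * sin(t_pos)
    if (n_neg > 0) {
      idx <- (n_pos + 1):n
      X[idx, 1] <- X[idx, 1] + (radius + gap) * cos(t_neg)
      X[idx, 2] <- X[idx, 2] + (radius + gap) * sin(t_neg)
    }
  }

  is_pos <- c(rep(TRUE, n_pos), rep(FALSE, n_neg))
  query <- rep(FALSE, n)
  query[sample(seq_len(n_pos), n_query)] <- TRUE
  perm <- sample(n)
  X <- X[perm, , drop = FALSE]
  is_pos <- is_pos[perm]
  query <- query[perm]

  ids <- sprintf("prot%04d", seq_len(n))
  data <- as_tibble(as.data.frame(X))
  names(data) <- paste0("f", seq_len(m))
  data <- dplyr::bind_cols(tibble(id = ids), data)
  labels <- tibble(
    id = ids,
    status = ifelse(query, "positive", "unlabeled")
  )
  truth <- tibble(id = ids, is_positive = is_pos)
  list(data = data, labels = labels, truth = truth, layout = layout)
}

#' The six-sample worked example
#'
#' A fixed 6-sample, 2-feature toy dataset used throughout the
#' documentation and tests: one labelled query (`s1`) in a tight cluster
#' of three, and a second cluster of three far away. Every intermediate
#' quantity of the pipeline on this dataset (pairwise distances, sigma,
#' W, L, and the closed-form scores at alpha = 0.5) is stored as
#' plain-text fixtures under `inst/extdata/worked_example/`, computed by
#' the straight-line script `generate.R` alongside them — an independent
#' reference path the test suite checks the package against.
#'
#' @return A list with `data` (feature table) and `labels` (one positive,
#'   `s1`).
#' @export
worked_example <- function() {
  data <- tibble(
    id = c("s1", "s2", "s3", "s4", "s5", "s6"),
    f1 = c(0.0, 0.4, 1.0, 4.0, 4.6, 5.0),
    f2 = c(0.0, 0.3, -0.2, 3.0, 3.4, 2.6)
  )
  labels <- assign_labels(data, positives = "s1")
  list(data = data, labels = labels)
}

#' Write a simulated dataset to disk
#'
#' Writes the feature table, the query/label file and the hidden truth as
#' tab-separated text, the on-disk form consumed by the command-line
#' interface.
#'
#' @param sim A list from [simulate_pu_data()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  features <- file.path(dir, "features.tsv")
  queries <- file.path(dir, "queries.tsv")
  truth <- file.path(dir, "truth.tsv")
  write_feature_table(sim$data, features)
  lab <- sim$labels[sim$labels$status != "unlabeled", ]
  writeLines(paste(lab$id, lab$status, sep = "\t"), queries)
  writeLines(c("id\tis_positive",
               paste(sim$truth$id, as.integer(sim$truth$is_positive), sep = "\t")),
             truth)
  invisible(c(features = features, queries = queries, truth = truth))
}
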