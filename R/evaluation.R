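#' Recall-precision curve and its area
#'
#' Sweeps the score threshold down the ranking of the evaluated samples;
#' each prefix of the descending-score order yields a
#' `(recall, precision)` point with `precision = TP / (TP + FP)` and
#' `recall = TP / (TP + FN)`. The area under the curve is computed as
#' average precision — the mean, over the true positives, of the
#' precision at each true positive's rank — i.e. step integration without
#' interpolation. Query samples must be excluded (`exclude`): the
#' protocol measures retrieval of held-out positives, and queries would
#' trivially inflate the top of the ranking.
#'
#' Score ties are resolved by input order (stable), so the curve is
#' deterministic; if all scores are tied a warning is emitted.
#'
#' @param scores Numeric score vector (higher = more positive-like).
#' @param truth Binary (0/1 or logical) truth vector, same length.
#' @param exclude Integer indices to drop before evaluation (the queries).
#' @return A `pr_curve` object: list with `points` (tibble `rank`,
#'   `recall`, `precision`, `is_positive`) and `auc`.
#' @examples
#' pr_curve(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))$auc # (1 + 2/3) / 2
#' @export
pr_curve <- function(scores, truth, exclude = integer()) {
  truth <- as.integer(as.logical(truth))
  if (length(scores) != length(truth)) {
    stop_validation("scores and truth must have the same length")
  }
  if (length(exclude) > 0) {
    scores <- scores[-exclude]
    truth <- truth[-exclude]
  }
  n <- length(scores)
  n_pos <- sum(truth)
  if (n_pos == 0) {
    stop_validation("no true positives among the evaluated samples")
  }
  if (n > 1 && length(unique(scores)) == 1L) {
    warn("all scores are tied; recall-precision curve uses the stable input order")
  }
  ord <- order(-scores, seq_len(n))
  hits <- truth[ord]
  tp <- cumsum(hits)
  precision <- tp / seq_len(n)
  recall <- tp / n_pos
  auc <- sum(precision[hits == 1L]) / n_pos
  structure(
    list(
      points = tibble(
        rank = seq_len(n),
        recall = recall,
        precision = precision,
        is_positive = hits == 1L
      ),
      auc = auc,
      n = n,
      n_pos = n_pos
    ),
    class = "pr_curve"
  )
}

#' @export
print.pr_curve <- function(x, ...) {
  cat("<pr_curve> ", x$n_pos, "/", x$n, " positives, AUC = ",
      format(x$auc, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Recall-precision AUC
#'
#' Shortcut for `pr_curve(...)$auc`.
#'
#' @inheritParams pr_curve
#' @return The average-precision AUC, a scalar in `(0, 1]`.
#' @export
pr_auc <- function(scores, truth, exclude = integer()) {
  pr_curve(scores, truth, exclude = exclude)$auc
}

#' @rdname pr_curve
#' @param x A `pr_curve` object.
#' @param ... Unused.
#' @method tidy pr_curve
#' @export
tidy.pr_curve <- function(x, ...) {
  x$points
}

#' Plot a recall-precision curve
#'
#' @param object A `pr_curve`.
#' @param ... Unused.
#' @return A ggplot object (step curve, AUC in the subtitle).
#' @method autoplot pr_curve
#' @export
autoplot.pr_curve <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      title = "Recall-precision curve",
      subtitle = paste0("AUC (average precision) = ", format(object$auc, digits = 4)),
      x = "recall", y = "precision"
    ) +
    ggplot2::theme_minimal()
}

#' Nearest-distance baseline ranker
#'
#' Scores every sample by the negated distance to its nearest query:
#' purely local, no propagation. This is the prefilter criterion reused
#' as a ranking baseline; manifold ranking should beat it whenever the
#' positives live on a curved structure that point-to-query distance
#' cannot follow.
#'
#' @param data A feature-table tibble.
#' @param labels A label tibble (positives = queries).
#' @return Numeric score vector in table order (higher = closer to a
#'   query; queries score 0, the maximum).
#' @export
nearest_distance_ranker <- function(data, labels) {
  -nearest_positive_distance(data, labels)$nearest_positive_distance
}

#' SVM baseline rankers
#'
#' Scores samples by signed distance to a trained max-margin boundary,
#' the comparison strategy used against manifold ranking. Two strategies:
#' `"binary"` trains a C-SVM on the queries versus `negative_multiple`
#' times as many sampled negatives (known negatives when available,
#' otherwise — flagged by a message — sampled unlabeled background, the
#' usual PU surrogate); `"one_class"` trains a one-class SVM on the
#' queries only. Radial-basis kernel with bandwidth tied to the graph
#' sigma so the baseline shares the ranking's feature geometry.
#'
#' @param data A feature-table tibble.
#' @param labels A label tibble (positives = queries).
#' @param strategy `"binary"` or `"one_class"`.
#' @param negative_multiple For `"binary"`: negatives sampled per query
#'   (the N-times-negatives heuristic; default 100).
#' @param seed Integer seed for negative sampling.
#' @param sigma Kernel bandwidth; default [estimate_sigma()] on `data`.
#' @return Numeric decision-value score vector in table order.
#' @export
svm_ranker <- function(data, labels, strategy = c("binary", "one_class"),
                       negative_multiple = 100L, seed = 1L, sigma = NULL) {
  strategy <- match.arg(strategy)
  data <- validate_feature_table(data)
  check_labels_match(data, labels)
  X <- feature_matrix(data)
  pos_idx <- which(labels$status == "positive")
  q <- length(pos_idx)
  if (q == 0) stop_validation("no positive (query) samples to train on")
  sigma <- sigma %||% estimate_sigma(pairwise_distances(data))
  kernel_gamma <- 1 / (2 * sigma^2)

  if (strategy == "one_class") {
    if (q < 2) stop_validation("one-class SVM needs at least 2 queries")
    fit <- e1071::svm(
      x = X[pos_idx, , drop = FALSE],
      type = "one-classification",
      kernel = "radial", gamma = kernel_gamma,
      scale = FALSE
    )
    dv <- attr(predict(fit, X, decision.values = TRUE), "decision.values")
    return(as.numeric(dv))
  }

  neg_pool <- which(labels$status == "negative")
  if (length(neg_pool) == 0) {
    inform("no known negatives: sampling unlabeled background as the negative class")
    neg_pool <- which(labels$status == "unlabeled")
  }
  if (length(neg_pool) == 0) {
    stop_validation("binary SVM strategy needs negatives or unlabeled background")
  }
  set.seed(seed)
  n_neg <- min(length(neg_pool), negative_multiple * q)
  neg_idx <- sort(sample(neg_pool, n_neg))
  train_idx <- c(pos_idx, neg_idx)
  yf <- factor(c(rep("positive", q), rep("negative", n_neg)),
               levels = c("positive", "negative"))
  fit <- e1071::svm(
    x = X[train_idx, , drop = FALSE], y = yf,
    type = "C-classification",
    kernel = "radial", gamma = kernel_gamma,
    scale = FALSE
  )
  dv <- as.numeric(attr(predict(fit, X, decision.values = TRUE),
                        "decision.values"))
  # orient so queries sit on the high side regardless of level bookkeeping
  if (mean(dv[pos_idx]) < mean(dv[neg_idx])) dv <- -dv
  dv
}

ranker_registry <- function(alpha = 0.5, svm_negative_multiple = 100L) {
  list(
    manifold = function(data, labels, sigma, seed) {
      tidy(manifold_rank(data, labels, alpha = alpha, sigma = sigma))$score
    },
    nearest = function(data, labels, sigma, seed) {
      nearest_distance_ranker(data, labels)
    },
    svm_binary = function(data, labels, sigma, seed) {
      svm_ranker(data, labels, strategy = "binary",
                 negative_multiple = svm_negative_multiple,
                 seed = seed, sigma = sigma)
    },
    svm_one_class = function(data, labels, sigma, seed) {
      svm_ranker(data, labels, strategy = "one_class", sigma = sigma)
    }
  )
}

#' Query-subsampling benchmark
#'
#' The evaluation protocol for comparing rankers without a labelled test
#' split: for each query size and repeat, a random subset of the known
#' positives becomes the queries; every registered method ranks all
#' samples from those same queries; PR-AUC is computed over the non-query
#' samples with the remaining positives as truth; results are averaged
#' over repeats. Default sizes 10/20/30 with five repeats.
#'
#' @param data A feature-table tibble.
#' @param labels A label tibble whose positives form the sampling pool.
#' @param query_sizes Integer vector of query-set sizes.
#' @param repeats Repeats per size.
#' @param methods Methods to run; any of `"manifold"`, `"nearest"`,
#'   `"svm_binary"`, `"svm_one_class"`.
#' @param seed Integer seed; the whole report is a deterministic function
#'   of it.
#' @param alpha Propagation strength for the manifold method.
#' @param svm_negative_multiple Negatives-per-query for the binary SVM.
#' @return A `benchmark_report`: list with `results` (tibble `method`,
#'   `query_size`, `repeat`, `auc`), `summary` (mean AUC per method and
#'   size) and the protocol parameters.
#' @export
run_benchmark <- function(data, labels, query_sizes = c(10L, 20L, 30L),
                          repeats = 5L,
                          methods = c("manifold", "nearest"),
                          seed = 1L, alpha = 0.5,
                          svm_negative_multiple = 100L) {
  data <- validate_feature_table(data)
  check_labels_match(data, labels)
  registry <- ranker_registry(alpha, svm_negative_multiple)
  unknown <- setdiff(methods, names(registry))
  if (length(unknown) > 0) {
    stop_validation(paste0(
      "unknown method(s): ", paste(unknown, collapse = ", "),
      "; registered methods are: ", paste(names(registry), collapse = ", ")
    ))
  }
  pos_idx <- which(labels$status == "positive")
  if (max(query_sizes) > length(pos_idx)) {
    stop_validation(paste0(
      "largest query size ", max(query_sizes), " exceeds the ",
      length(pos_idx), " available positives"
    ))
  }
  sigma <- estimate_sigma(pairwise_distances(data))
  set.seed(seed)
  draws <- list()
  for (r in seq_len(repeats)) {
    for (s in query_sizes) {
      draws[[paste(r, s)]] <- sort(sample(pos_idx, s))
    }
  }
  rows <- list()
  for (r in seq_len(repeats)) {
    for (s in query_sizes) {
      queries <- draws[[paste(r, s)]]
      lab_q <- labels
      lab_q$status[setdiff(pos_idx, queries)] <- "unlabeled"
      truth <- rep(0L, nrow(data))
      truth[setdiff(pos_idx, queries)] <- 1L
      for (meth in methods) {
        scores <- registry[[meth]](data, lab_q, sigma, seed + r)
        rows[[length(rows) + 1L]] <- tibble(
          method = meth, query_size = s, `repeat` = r,
          auc = pr_auc(scores, truth, exclude = queries)
        )
      }
    }
  }
  results <- dplyr::bind_rows(rows)
  summary <- results |>
    dplyr::group_by(.data$method, .data$query_size) |>
    dplyr::summarise(mean_auc = mean(.data$auc), .groups = "drop")
  structure(
    list(results = results, summary = summary,
         query_sizes = query_sizes, repeats = repeats, seed = seed),
    class = "benchmark_report"
  )
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("<benchmark_report> ", x$repeats, " repeats, query sizes ",
      paste(x$query_sizes, collapse = "/"), ", seed ", x$seed, "\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @rdname run_benchmark
#' @param x A `benchmark_report`.
#' @param ... Unused.
#' @method tidy benchmark_report
#' @export
tidy.benchmark_report <- function(x, ...) {
  x$results
}

#' @rdname run_benchmark
#' @method glance benchmark_report
#' @export
glance.benchmark_report <- function(x, ...) {
  tidyr::pivot_wider(x$summary, names_from = "method",
                     values_from = "mean_auc")
}

#' Plot a benchmark report
#'
#' Mean PR-AUC per method against query-set size, individual repeats as
#' faint points.
#'
#' @param object A `benchmark_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot benchmark_report
#' @export
autoplot.benchmark_report <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$query_size, y = .data$mean_auc,
                               colour = .data$method)) +
    ggplot2::geom_point(data = object$results,
                        ggplot2::aes(y = .data$auc), alpha = 0.35, size = 1) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "number of queries", y = "PR-AUC",
                  colour = NULL, title = "Query-subsampling benchmark") +
    ggplot2::theme_minimal()
}
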