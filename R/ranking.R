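#' Iterative manifold-ranking propagation
#'
#' Starting from the initial evidence vector `f0 = y` (1 at queries, 0
#' elsewhere), repeats `f <- alpha * L %*% f + (1 - alpha) * y` until the
#' max-norm change drops below `tol` or the iteration cap is reached.
#' Because the spectral radius of the normalised graph operator `L` is at
#' most 1, the residual contracts geometrically with ratio `alpha`, and
#' the iteration converges to the closed-form fixed point
#' `(1 - alpha) (I - alpha L)^-1 y`.
#'
#' @param ngraph A `normalized_graph` from [normalize_affinity()].
#' @param y Initial score vector (length n; 1 at queries, 0 elsewhere).
#' @param alpha Propagation strength in `[0, 1)`: 0 disables propagation
#'   (ranking returns the queries themselves), values near 1 weight graph
#'   structure heavily.
#' @param tol Max-norm convergence tolerance.
#' @param max_iter Iteration cap; hitting it flags the result
#'   `converged = FALSE` with a warning, never silently.
#' @return A `secrank_ranking` object; see [tidy.secrank_ranking()].
#' @export
rank_iterative <- function(ngraph, y, alpha = 0.5, tol = 1e-9,
                           max_iter = 10000L) {
  check_rank_inputs(ngraph, y, alpha)
  L <- ngraph$L
  f <- y
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    f_new <- alpha * as.vector(L %*% f) + (1 - alpha) * y
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(paste0(
      "manifold ranking iteration did not converge in ", max_iter,
      " steps (alpha = ", alpha, ", tol = ", tol, ")"
    ))
  }
  new_ranking(f, ngraph$ids, mode = "positive_only", solver = "iterative",
              alpha = alpha, gamma = NA_real_,
              iterations = it, converged = converged)
}

#' Closed-form manifold ranking
#'
#' Solves the propagation fixed point directly:
#' `f* = (1 - alpha) (I - alpha L)^-1 y`, via a single linear solve (no
#' explicit inverse). For `alpha < 1` the system is non-singular because
#' the spectral radius of `L` is at most 1. This is the default solver:
#' exact, and one factorisation instead of hundreds of iterations. The
#' `(1 - alpha)` factor is a positive scale and cannot change the
#' ordering; it is kept so the two solvers agree numerically.
#'
#' @inheritParams rank_iterative
#' @return A `secrank_ranking` object with `converged = TRUE`,
#'   `iterations = 0`.
#' @export
rank_closed_form <- function(ngraph, y, alpha = 0.5) {
  check_rank_inputs(ngraph, y, alpha)
  f <- propagation_solve(ngraph$L, y, alpha)
  new_ranking(f, ngraph$ids, mode = "positive_only", solver = "closed_form",
              alpha = alpha, gamma = NA_real_,
              iterations = 0L, converged = TRUE)
}

propagation_solve <- function(L, y, alpha) {
  n <- nrow(L)
  A <- diag(n) - alpha * L
  f <- tryCatch(
    solve(A, y),
    error = function(e) {
      stop_numerical(paste0(
        "linear solve for (I - alpha L) failed: ", conditionMessage(e)
      ))
    }
  )
  (1 - alpha) * as.vector(f)
}

#' Universal manifold ranking (positive and negative queries)
#'
#' When known negatives are available, both evidence vectors propagate
#' through the same operator `A = (1 - alpha)(I - alpha L)^-1`; the
#' negative contribution is damped by `gamma` in `(0, 1]` because
#' distance from the positives is informative in a way distance from
#' negatives is not. The combined score is computed as one linear solve
#' on `y_plus + gamma * y_minus`. `gamma = 0` is accepted as the
#' degenerate input reproducing the positive-only ranking exactly.
#'
#' @inheritParams rank_iterative
#' @param y_plus Non-negative evidence vector (1 at positive queries).
#' @param y_minus Non-positive evidence vector (-1 at negative queries);
#'   supports must be disjoint from `y_plus`.
#' @param gamma Negative-evidence damping in `[0, 1]`.
#' @return A `secrank_ranking` object.
#' @export
rank_universal <- function(ngraph, y_plus, y_minus, alpha = 0.5, gamma = 0.5) {
  check_rank_inputs(ngraph, y_plus, alpha)
  if (length(y_minus) != length(y_plus)) {
    stop_validation("y_plus and y_minus must have the same length")
  }
  if (any(y_plus < 0) || any(y_minus > 0)) {
    stop_validation("y_plus must be non-negative and y_minus non-positive")
  }
  if (any(y_plus != 0 & y_minus != 0)) {
    stop_validation("y_plus and y_minus supports must be disjoint")
  }
  if (gamma < 0 || gamma > 1) {
    stop_validation("gamma must lie in [0, 1]")
  }
  f <- propagation_solve(ngraph$L, y_plus + gamma * y_minus, alpha)
  new_ranking(f, ngraph$ids, mode = "universal", solver = "closed_form",
              alpha = alpha, gamma = gamma,
              iterations = 0L, converged = TRUE)
}

check_rank_inputs <- function(ngraph, y, alpha) {
  stopifnot(inherits(ngraph, "normalized_graph"))
  if (length(y) != nrow(ngraph$L)) {
    stop_validation("initial score vector length does not match the graph")
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha >= 1) {
    stop_validation("alpha must lie in [0, 1)")
  }
  invisible(TRUE)
}

new_ranking <- function(scores, ids, mode, solver, alpha, gamma,
                        iterations, converged) {
  n <- length(scores)
  ord <- order(-scores, seq_len(n)) # stable: ties keep input order
  rank <- integer(n)
  rank[ord] <- seq_len(n)
  structure(
    list(
      scores = tibble(id = ids, score = as.numeric(scores), rank = rank),
      order = ord,
      mode = mode,
      solver = solver,
      alpha = alpha,
      gamma = gamma,
      iterations = iterations,
      converged = converged
    ),
    class = "secrank_ranking"
  )
}

#' @export
print.secrank_ranking <- function(x, n = 5L, ...) {
  cat("<secrank_ranking> ", nrow(x$scores), " samples, mode = ", x$mode,
      ", solver = ", x$solver, ", alpha = ", x$alpha,
      if (!is.na(x$gamma)) paste0(", gamma = ", x$gamma) else "",
      if (!x$converged) " [NOT CONVERGED]" else "", "\n", sep = "")
  print(head(x$scores[x$order, ], n))
  invisible(x)
}

#' Tidy a ranking result
#'
#' @param x A `secrank_ranking`.
#' @param ... Unused.
#' @return Tibble (`id`, `score`, `rank`), one row per sample in input
#'   order; `rank` 1 is the highest score, ties resolved by input order.
#' @method tidy secrank_ranking
#' @export
tidy.secrank_ranking <- function(x, ...) {
  x$scores
}

#' One-line summary of a ranking result
#'
#' @param x A `secrank_ranking`.
#' @param ... Unused.
#' @return One-row tibble with sample count, solver settings, iteration
#'   count and convergence flag.
#' @method glance secrank_ranking
#' @export
glance.secrank_ranking <- function(x, ...) {
  tibble(
    n = nrow(x$scores),
    mode = x$mode,
    solver = x$solver,
    alpha = x$alpha,
    gamma = x$gamma,
    iterations = x$iterations,
    converged = x$converged
  )
}

#' Rank candidates by manifold ranking, end to end
#'
#' High-level interface: builds the Gaussian affinity graph from the
#' feature table, optionally sparsifies it by b-matching, normalises it,
#' and propagates query evidence to every sample. Queries float to the
#' top of the returned ranking; evaluation utilities exclude them.
#'
#' @param data A feature-table tibble.
#' @param labels A label tibble from [assign_labels()] /
#'   [read_labels()].
#' @param alpha Propagation strength in `[0, 1)`; default 0.5 (the value
#'   the cross-validation tuner selects on well-structured data; see
#'   [tune_alpha()]).
#' @param mode `"positive_only"` (default; negatives, if present, are
#'   ignored) or `"universal"` (negative queries damped by `gamma`).
#' @param gamma Negative-evidence damping for universal mode.
#' @param solver `"closed_form"` (default) or `"iterative"`.
#' @param sigma Optional kernel bandwidth override; default is the mean
#'   pairwise distance of `data`.
#' @param sparsify_b Optional b-matching degree budget; `NULL` (default)
#'   keeps the dense graph.
#' @param zscore Standardise features before distances?
#' @param tol,max_iter Iterative-solver controls.
#' @return A `secrank_ranking` whose tibble also carries the label
#'   `status` column; attributes record `sigma` and the graph.
#' @examples
#' sim <- simulate_pu_data(n_query = 5, n_hidden_pos = 10, n_neg = 30,
#'                         m = 5, seed = 1)
#' r <- manifold_rank(sim$data, sim$labels)
#' tidy(r)
#' @export
manifold_rank <- function(data, labels, alpha = 0.5,
                          mode = c("positive_only", "universal"),
                          gamma = 0.5,
                          solver = c("closed_form", "iterative"),
                          sigma = NULL, sparsify_b = NULL, zscore = FALSE,
                          tol = 1e-9, max_iter = 10000L) {
  mode <- match.arg(mode)
  solver <- match.arg(solver)
  data <- validate_feature_table(data)
  check_labels_match(data, labels)
  graph <- build_graph(data, sigma = sigma, zscore = zscore)
  pattern <- NULL
  if (!is.null(sparsify_b)) {
    pattern <- solve_bmatching(graph, sparsify_b)
    graph <- apply_sparsification(graph, pattern)
  }
  ngraph <- suppressWarnings(normalize_affinity(graph))
  yv <- label_vectors(labels)
  result <- if (mode == "universal") {
    rank_universal(ngraph, yv$y_plus, yv$y_minus, alpha = alpha, gamma = gamma)
  } else if (solver == "iterative") {
    rank_iterative(ngraph, yv$y, alpha = alpha, tol = tol, max_iter = max_iter)
  } else {
    rank_closed_form(ngraph, yv$y, alpha = alpha)
  }
  result$scores$status <- labels$status
  result$sigma <- graph$sigma
  result$graph <- graph
  result$pattern <- pattern
  result
}

#' Plot a ranking
#'
#' Scores against rank position, coloured by label status — a quick view
#' of how far the queries' evidence reaches into the unlabeled pool.
#'
#' @param object A `secrank_ranking` (ideally from [manifold_rank()], so
#'   status is attached).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot secrank_ranking
#' @export
autoplot.secrank_ranking <- function(object, ...) {
  d <- tidy(object)
  if (is.null(d$status)) d$status <- "unlabeled"
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$score,
                                  colour = .data$status)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "rank", y = "propagated score", colour = NULL,
                  title = "Manifold-ranking scores") +
    ggplot2::theme_minimal()
}

#' Tune the propagation strength by query cross-validation
#'
#' Splits the known positives into `folds` folds; each fold in turn plays
#' the queries while the other folds' positives are the held-out truth.
#' All non-query samples are ranked and scored by recall-precision AUC;
#' the grid value with the highest mean AUC wins, ties going to the
#' smaller `alpha` (less propagation, more conservative). Grid values at
#' or above 1 are clamped to `1 - 1e-6` with a warning, since the closed
#' form requires `alpha < 1`.
#'
#' The affinity graph does not depend on the queries, so it is built once
#' and factorised per grid value with all folds as right-hand sides.
#'
#' @param data A feature-table tibble.
#' @param labels A label tibble; its positives are cross-validated.
#' @param grid Candidate `alpha` values.
#' @param folds Number of folds (default 10).
#' @param seed Integer seed for the fold split.
#' @param sigma,zscore Passed to graph construction.
#' @return An `alpha_tuning` object: list with the chosen `alpha` and a
#'   `table` tibble (`alpha`, `mean_auc`).
#' @export
tune_alpha <- function(data, labels, grid = seq(0.1, 0.9, by = 0.1),
                       folds = 10L, seed = 1L, sigma = NULL, zscore = FALSE) {
  data <- validate_feature_table(data)
  check_labels_match(data, labels)
  if (any(grid <= 0)) stop_validation("alpha grid values must be positive")
  if (any(grid >= 1)) {
    warn("alpha grid values >= 1 clamped to 1 - 1e-6 (closed form requires alpha < 1)")
    grid[grid >= 1] <- 1 - 1e-6
  }
  pos_idx <- which(labels$status == "positive")
  q <- length(pos_idx)
  if (q < folds) {
    stop_validation(paste0(
      "only ", q, " positives for ", folds,
      "-fold tuning; use fewer folds"
    ))
  }
  set.seed(seed)
  fold_of <- sample(rep(seq_len(folds), length.out = q))
  graph <- build_graph(data, sigma = sigma, zscore = zscore)
  L <- suppressWarnings(normalize_affinity(graph))$L
  n <- nrow(L)
  # fold f's positives as queries (columns of Y)
  Y <- matrix(0, n, folds)
  for (f in seq_len(folds)) Y[pos_idx[fold_of == f], f] <- 1
  rows <- purrr::map_dfr(grid, function(a) {
    Fstar <- (1 - a) * solve(diag(n) - a * L, Y)
    aucs <- vapply(seq_len(folds), function(f) {
      queries <- pos_idx[fold_of == f]
      truth <- rep(0L, n)
      truth[setdiff(pos_idx, queries)] <- 1L
      pr_auc(Fstar[, f], truth, exclude = queries)
    }, numeric(1))
    tibble(alpha = a, mean_auc = mean(aucs))
  })
  best <- rows$alpha[order(-rows$mean_auc, rows$alpha)][1]
  structure(
    list(alpha = best, table = rows, folds = folds, seed = seed),
    class = "alpha_tuning"
  )
}

#' @export
print.alpha_tuning <- function(x, ...) {
  cat("<alpha_tuning> selected alpha = ", x$alpha, " (", x$folds,
      "-fold query cross-validation)\n", sep = "")
  print(x$table)
  invisible(x)
}

#' @rdname tune_alpha
#' @param x An `alpha_tuning` object.
#' @param ... Unused.
#' @method tidy alpha_tuning
#' @export
tidy.alpha_tuning <- function(x, ...) {
  x$table
}
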