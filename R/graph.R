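#' Euclidean pairwise distance matrix
#'
#' Computes the full symmetric matrix of Euclidean distances between all
#' sample pairs in a feature table — the geometry every downstream stage
#' (kernel bandwidth, affinity weights, prefilter, baselines) is built on.
#'
#' @param data A feature-table tibble.
#' @return An n x n symmetric numeric matrix with zero diagonal, dimnames
#'   set to the sample ids.
#' @export
pairwise_distances <- function(data) {
  X <- feature_matrix(data)
  D <- as.matrix(dist(X, method = "euclidean"))
  dimnames(D) <- list(rownames(X), rownames(X))
  D
}

#' Kernel bandwidth heuristic
#'
#' The Gaussian kernel bandwidth sigma is set to the mean of all pairwise
#' distances in the dataset at hand (the n(n-1)/2 off-diagonal pairs).
#' Duplicated points contribute their zero distances, shrinking sigma;
#' this follows directly from the mean-over-all-pairs definition.
#'
#' @param distances A symmetric distance matrix (see [pairwise_distances()]).
#' @return The bandwidth, a positive scalar in feature-space distance units.
#' @export
estimate_sigma <- function(distances) {
  stopifnot(is.matrix(distances), nrow(distances) == ncol(distances))
  if (nrow(distances) < 2L) {
    stop_validation("sigma heuristic needs at least two samples")
  }
  sigma <- mean(distances[upper.tri(distances)])
  if (sigma <= 0) {
    stop_numerical("degenerate dataset: all points identical (mean pairwise distance is 0)")
  }
  sigma
}

#' Build the Gaussian affinity graph
#'
#' Edge weights are the Gaussian kernel of squared Euclidean distance,
#' `W_ij = exp(-d_ij^2 / (2 sigma^2))`, with the diagonal forced to zero
#' (no self-edges: a sample must not propagate evidence to itself).
#'
#' @param distances A symmetric distance matrix.
#' @param sigma Kernel bandwidth; defaults to [estimate_sigma()] of
#'   `distances`.
#' @return An `affinity_graph` object: list with the weight matrix `W`,
#'   `sigma`, and the node `ids`.
#' @export
build_affinity <- function(distances, sigma = NULL) {
  stopifnot(is.matrix(distances), nrow(distances) == ncol(distances))
  sigma <- sigma %||% estimate_sigma(distances)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop_validation("sigma must be a positive scalar")
  }
  W <- exp(-distances^2 / (2 * sigma^2))
  diag(W) <- 0
  new_affinity_graph(W, sigma, rownames(distances) %||% as.character(seq_len(nrow(W))))
}

new_affinity_graph <- function(W, sigma, ids) {
  dimnames(W) <- list(ids, ids)
  structure(
    list(W = W, sigma = sigma, ids = ids, degrees = rowSums(W)),
    class = "affinity_graph"
  )
}

#' @export
print.affinity_graph <- function(x, ...) {
  n_edges <- sum(x$W[upper.tri(x$W)] > 0)
  cat("<affinity_graph> ", length(x$ids), " nodes, ", n_edges,
      " weighted edges, sigma = ", format(x$sigma, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Tidy an affinity graph into an edge list
#'
#' @param x An `affinity_graph`.
#' @param ... Unused.
#' @return A tibble with columns `from`, `to`, `weight`, one row per
#'   retained (nonzero) undirected edge, upper triangle only.
#' @method tidy affinity_graph
#' @export
tidy.affinity_graph <- function(x, ...) {
  idx <- which(upper.tri(x$W) & x$W > 0, arr.ind = TRUE)
  tibble(
    from = x$ids[idx[, 1]],
    to = x$ids[idx[, 2]],
    weight = x$W[idx]
  )
}

#' Symmetric normalisation of an affinity graph
#'
#' Computes `L = D^-1/2 W D^-1/2`, with `D` the diagonal degree matrix
#' `D_ii = sum_j W_ij`. The spectral radius of `L` is at most 1, which is
#' what guarantees convergence of the propagation iteration and
#' invertibility of `I - alpha L` for `alpha < 1`. Isolated nodes
#' (degree 0, possible after aggressive sparsification) get an all-zero
#' row and column: they neither emit nor receive evidence; a warning is
#' issued rather than an error.
#'
#' @param graph An `affinity_graph`.
#' @return A `normalized_graph` object: list with matrix `L`, the source
#'   `graph`, and `ids`.
#' @export
normalize_affinity <- function(graph) {
  stopifnot(inherits(graph, "affinity_graph"))
  d <- graph$degrees
  isolated <- d <= 0
  if (any(isolated)) {
    warn(paste0(
      sum(isolated), " isolated node(s) in the affinity graph; ",
      "their rows in L are zero and they take no part in propagation"
    ))
  }
  inv_sqrt <- ifelse(isolated, 0, 1 / sqrt(d))
  L <- graph$W * tcrossprod(inv_sqrt)
  structure(
    list(L = L, graph = graph, ids = graph$ids),
    class = "normalized_graph"
  )
}

#' @export
print.normalized_graph <- function(x, ...) {
  cat("<normalized_graph> ", length(x$ids),
      " nodes, L = D^-1/2 W D^-1/2\n", sep = "")
  invisible(x)
}

#' Build graph straight from a feature table
#'
#' Convenience wrapper chaining [pairwise_distances()], [estimate_sigma()]
#' and [build_affinity()].
#'
#' @param data A feature-table tibble.
#' @param sigma Optional bandwidth override.
#' @param zscore Standardise features first? See [zscore_features()].
#' @return An `affinity_graph`.
#' @export
build_graph <- function(data, sigma = NULL, zscore = FALSE) {
  if (zscore) data <- zscore_features(data)
  build_affinity(pairwise_distances(data), sigma = sigma)
}

#' Dump a graph as an edge-list text file
#'
#' Writes `from<TAB>to<TAB>weight` rows (upper triangle, nonzero edges)
#' for inspection.
#'
#' @param graph An `affinity_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graph_edges <- function(graph, path) {
  edges <- tidy(graph)
  lines <- c("from\tto\tweight", paste(
    edges$from, edges$to,
    formatC(edges$weight, format = "g", digits = 6), sep = "\t"
  ))
  writeLines(lines, path)
  invisible(path)
}
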