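#' Maximum-weight b-matching by loopy belief propagation
#'
#' Selects a sparse edge subset of the affinity graph: a binary symmetric
#' pattern `P` with zero diagonal and exactly `b` selected edges per node,
#' maximising the retained weight `sum_ij W_ij P_ij`. The max-product
#' messages are iterated synchronously with damping until the largest
#' message change falls below `tol`; edges are then selected where both
#' endpoints rank each other in their top `b` beliefs. If the mutual
#' selection is not exactly b-regular (possible when belief propagation
#' oscillates or the optimum is fractional), the pattern is completed by a
#' deterministic greedy/repair pass over the beliefs, and the result is
#' always polished with degree-preserving alternating-cycle exchanges —
#' so the returned pattern satisfies the exact-degree invariant by
#' construction. Non-convergence of the messages triggers a warning and a
#' greedy mutual-selection fallback seeded directly on the weights.
#'
#' Feasibility requires `1 <= b <= n - 1` and `n * b` even (a b-regular
#' simple graph has `n * b / 2` edges, which must be an integer).
#'
#' @param graph An `affinity_graph`.
#' @param b Per-node degree budget (positive integer).
#' @param damping Message damping in `[0, 1)`; 0.5 stabilises the
#'   synchronous schedule.
#' @param tol Convergence tolerance on the max message change.
#' @param max_iter Message-iteration cap.
#' @return A `sparsity_pattern`: list with binary matrix `P`, `b`, the
#'   achieved `objective`, `converged`, `iterations`, and `ids`.
#' @seealso [bmatching_oracle()] for the exhaustive reference solver,
#'   [apply_sparsification()] to re-weight the graph.
#' @export
solve_bmatching <- function(graph, b, damping = 0.5, tol = 1e-6,
                            max_iter = 1000L) {
  stopifnot(inherits(graph, "affinity_graph"))
  W <- graph$W
  n <- nrow(W)
  b <- as.integer(b)
  check_bmatching_feasible(n, b)

  bp <- bmatching_bp_messages(W, b, damping, tol, max_iter)
  if (!bp$converged) {
    warn(paste0(
      "b-matching belief propagation did not converge in ", max_iter,
      " iterations; completing via the greedy mutual-selection heuristic ",
      "on the last beliefs"
    ))
  }
  beliefs <- W + bp$M + t(bp$M)
  P <- mutual_topb_selection(beliefs, b)
  if (!is_b_regular(P, b)) {
    P <- greedy_bmatching(beliefs, b)
  }
  P <- improve_bmatching(W, P, b)
  new_sparsity_pattern(P, b, W, graph$ids,
                       converged = bp$converged, iterations = bp$iterations,
                       method = if (bp$converged) "belief_propagation" else "greedy_fallback")
}

check_bmatching_feasible <- function(n, b) {
  if (b < 1L || b > n - 1L) {
    stop_validation(paste0(
      "infeasible degree budget b = ", b, ": must satisfy 1 <= b <= n - 1 = ", n - 1L
    ))
  }
  if ((n * b) %% 2L != 0L) {
    stop_validation(paste0(
      "infeasible degree budget: n * b = ", n * b,
      " is odd, but a b-regular graph has n*b/2 edges"
    ))
  }
  invisible(TRUE)
}

# Synchronous max-product messages for exact-degree b-matching:
# m[i,j] = -(b-th largest of W[i,k] + m[k,i], k != i,j). The damped
# update loop lives in compiled code (src/bmatching.cpp); message
# matrices are dense and the update is the inner loop of the solver.
bmatching_bp_messages <- function(W, b, damping, tol, max_iter) {
  bp_messages_cpp(W, as.integer(b), damping, tol, as.integer(max_iter))
}

# P[i,j] = 1 iff j is in i's top-b beliefs AND i in j's top-b.
mutual_topb_selection <- function(beliefs, b) {
  n <- nrow(beliefs)
  diag(beliefs) <- -Inf
  pick <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    pick[i, order(beliefs[i, ], decreasing = TRUE)[seq_len(b)]] <- TRUE
  }
  P <- (pick & t(pick)) * 1L
  storage.mode(P) <- "integer"
  P
}

is_b_regular <- function(P, b) {
  all(rowSums(P) == b) && all(P == t(P)) && all(diag(P) == 0)
}

# Deterministic exact-degree construction: greedy on descending scores,
# then degree repair. `scores` ranks the edges (weights or beliefs).
greedy_bmatching <- function(scores, b) {
  n <- nrow(scores)
  P <- matrix(0L, n, n)
  deg <- integer(n)
  ut <- which(upper.tri(scores), arr.ind = TRUE)
  ord <- order(-scores[ut], ut[, 1], ut[, 2])
  for (e in ord) {
    i <- ut[e, 1]; j <- ut[e, 2]
    if (deg[i] < b && deg[j] < b) {
      P[i, j] <- P[j, i] <- 1L
      deg[i] <- deg[i] + 1L
      deg[j] <- deg[j] + 1L
    }
  }
  repair_degrees(scores, P, b)
}

# Bring every node up to degree exactly b via additions and exchanges.
# Each step reduces total deficiency by 2; caps guard against pathological
# inputs.
repair_degrees <- function(scores, P, b) {
  n <- nrow(P)
  deg <- rowSums(P)
  guard <- 0L
  while (any(deg < b)) {
    guard <- guard + 1L
    if (guard > n * n) {
      stop_numerical("b-matching degree repair failed to terminate")
    }
    def <- which(deg < b)
    # best direct addition between two deficient endpoints
    added <- FALSE
    if (length(def) >= 2) {
      best <- c(NA_integer_, NA_integer_); best_s <- -Inf
      for (a in seq_along(def)) {
        for (c in seq_along(def)) {
          if (c <= a) next
          i <- def[a]; j <- def[c]
          if (P[i, j] == 0L && scores[i, j] > best_s) {
            best <- c(i, j); best_s <- scores[i, j]
          }
        }
      }
      if (is.finite(best_s)) {
        P[best[1], best[2]] <- P[best[2], best[1]] <- 1L
        deg <- rowSums(P)
        added <- TRUE
      }
    }
    if (added) next
    # exchange: remove a selected edge (k,l) away from the deficient nodes
    # and connect its endpoints to them
    done <- FALSE
    if (length(def) == 1L || (length(def) >= 2 && P[def[1], def[2]] == 1L)) {
      i <- def[1]
      j <- if (length(def) >= 2) def[2] else def[1]
      sel <- which(upper.tri(P) & P == 1L, arr.ind = TRUE)
      for (e in seq_len(nrow(sel))) {
        k <- sel[e, 1]; l <- sel[e, 2]
        if (k %in% c(i, j) || l %in% c(i, j)) next
        if (i == j) { # one node short by >= 2
          if (P[i, k] == 0L && P[i, l] == 0L) {
            P[k, l] <- P[l, k] <- 0L
            P[i, k] <- P[k, i] <- 1L
            P[i, l] <- P[l, i] <- 1L
            done <- TRUE
          }
        } else if (P[i, k] == 0L && P[j, l] == 0L) {
          P[k, l] <- P[l, k] <- 0L
          P[i, k] <- P[k, i] <- 1L
          P[j, l] <- P[l, j] <- 1L
          done <- TRUE
        } else if (P[i, l] == 0L && P[j, k] == 0L) {
          P[k, l] <- P[l, k] <- 0L
          P[i, l] <- P[l, i] <- 1L
          P[j, k] <- P[k, j] <- 1L
          done <- TRUE
        }
        if (done) break
      }
      if (!done) {
        stop_numerical("b-matching degree repair found no feasible exchange")
      }
      deg <- rowSums(P)
    } else {
      stop_numerical("b-matching degree repair stalled")
    }
  }
  P
}

# Degree-preserving local search. A cheap pairwise-exchange pass
# (alternating 4-cycles) runs at every size; on small instances a
# general alternating-closed-walk search follows, which can realise any
# exchange between two b-regular patterns whose symmetric difference
# fits the depth cap. On desk-scale instances this closes the gap
# between the message fixed point and the exact optimum whenever belief
# propagation stalls on a fractional relaxation.
improve_bmatching <- function(W, P, b, max_moves = 500L, walk_n_cap = 16L,
                              walk_depth = 8L) {
  n <- nrow(P)
  for (move in seq_len(max_moves)) {
    mv <- find_four_cycle_move(W, P)
    if (is.null(mv) && n <= walk_n_cap) {
      mv <- find_alternating_walk(W, P, max_len = walk_depth)
    }
    if (is.null(mv)) break
    for (r in seq_len(nrow(mv))) {
      i <- mv[r, 1]; j <- mv[r, 2]
      P[i, j] <- P[j, i] <- 1L - P[i, j]
    }
  }
  P
}

# Best exchange of two selected edges (i_a,j_a), (i_c,j_c) for two
# unselected ones on the same four nodes, vectorised over all edge
# pairs so the pass stays usable at pipeline scale. Returns the four
# edges to toggle, or NULL when no exchange improves the objective.
find_four_cycle_move <- function(W, P) {
  sel <- which(upper.tri(P) & P == 1L, arr.ind = TRUE)
  ne <- nrow(sel)
  if (ne < 2) return(NULL)
  i <- sel[, 1]; j <- sel[, 2]
  w_sel <- W[sel]
  admissible <- upper.tri(matrix(0, ne, ne)) &
    outer(i, i, "!=") & outer(i, j, "!=") &
    outer(j, i, "!=") & outer(j, j, "!=")
  w_old <- outer(w_sel, w_sel, "+")
  # variant 1: add (i_a, i_c) and (j_a, j_c)
  g1 <- W[i, i] + W[j, j] - w_old
  g1[!(admissible & P[i, i] == 0L & P[j, j] == 0L)] <- -Inf
  # variant 2: add (i_a, j_c) and (j_a, i_c)
  g2 <- W[i, j] + W[j, i] - w_old
  g2[!(admissible & P[i, j] == 0L & P[j, i] == 0L)] <- -Inf
  m1 <- max(g1); m2 <- max(g2)
  if (max(m1, m2) <= 1e-12) return(NULL)
  if (m1 >= m2) {
    ac <- which(g1 == m1, arr.ind = TRUE)[1, ]
    rbind(sel[ac[1], ], sel[ac[2], ],
          c(i[ac[1]], i[ac[2]]), c(j[ac[1]], j[ac[2]]))
  } else {
    ac <- which(g2 == m2, arr.ind = TRUE)[1, ]
    rbind(sel[ac[1], ], sel[ac[2], ],
          c(i[ac[1]], j[ac[2]]), c(j[ac[1]], i[ac[2]]))
  }
}

# First positive-gain alternating closed walk (edges alternately added
# and removed, each edge used once, closing at the start node), found by
# depth-first search. Toggling its edges preserves every node degree.
# Any closed alternating walk can be rooted at its smallest node with an
# addition first, so the search restricts walks to nodes >= the root and
# prunes branches whose optimistic remaining gain cannot go positive.
find_alternating_walk <- function(W, P, max_len = 8L) {
  n <- nrow(P)
  used <- matrix(FALSE, n, n)
  walk <- matrix(0L, max_len, 2L)
  res <- NULL
  maxW <- max(W)
  dfs <- function(u0, pos, gain, depth) {
    if (!is.null(res) || depth > max_len) return(invisible(NULL))
    adding <- depth %% 2L == 1L
    adds_left <- (max_len - depth) %/% 2L + as.integer(adding)
    if (gain + adds_left * maxW <= 1e-12) return(invisible(NULL))
    for (w in seq_len(n)) {
      if (!is.null(res)) return(invisible(NULL))
      if (w == pos || w < u0 || used[pos, w]) next
      if (P[pos, w] == as.integer(adding)) next
      g2 <- if (adding) gain + W[pos, w] else gain - W[pos, w]
      used[pos, w] <<- used[w, pos] <<- TRUE
      walk[depth, ] <<- c(pos, w)
      if (!adding && w == u0 && g2 > 1e-12) {
        res <<- walk[seq_len(depth), , drop = FALSE]
      } else {
        dfs(u0, w, g2, depth + 1L)
      }
      if (is.null(res)) used[pos, w] <<- used[w, pos] <<- FALSE
    }
    invisible(NULL)
  }
  for (u0 in seq_len(n)) {
    dfs(u0, u0, 0, 1L)
    if (!is.null(res)) break
  }
  res
}

new_sparsity_pattern <- function(P, b, W, ids, converged, iterations, method) {
  dimnames(P) <- list(ids, ids)
  structure(
    list(
      P = P, b = b,
      objective = sum(W * P) / 2,
      n_edges = sum(P[upper.tri(P)]),
      converged = converged,
      iterations = iterations,
      method = method,
      ids = ids
    ),
    class = "sparsity_pattern"
  )
}

#' @export
print.sparsity_pattern <- function(x, ...) {
  cat("<sparsity_pattern> b = ", x$b, ", ", x$n_edges, " edges, objective = ",
      format(x$objective, digits = 6), " (", x$method, ")\n", sep = "")
  invisible(x)
}

#' Tidy a sparsity pattern into an edge list
#'
#' @param x A `sparsity_pattern`.
#' @param ... Unused.
#' @return Tibble of retained undirected edges (`from`, `to`).
#' @method tidy sparsity_pattern
#' @export
tidy.sparsity_pattern <- function(x, ...) {
  idx <- which(upper.tri(x$P) & x$P == 1L, arr.ind = TRUE)
  tibble(from = x$ids[idx[, 1]], to = x$ids[idx[, 2]])
}

#' Exhaustive b-matching reference solver
#'
#' Enumerates all symmetric binary patterns with exact row degree `b`
#' (depth-first over the edge list in lexicographic order, with degree
#' feasibility pruning) and returns a maximiser of the retained weight.
#' Ties are broken toward the lexicographically smallest edge set. Used as
#' the independent correctness oracle for [solve_bmatching()] on small
#' instances; refuses `n > 10` because the search space is combinatorial.
#'
#' @inheritParams solve_bmatching
#' @return A `sparsity_pattern` (with `method = "exhaustive"`).
#' @export
bmatching_oracle <- function(graph, b) {
  stopifnot(inherits(graph, "affinity_graph"))
  W <- graph$W
  n <- nrow(W)
  b <- as.integer(b)
  if (n > 10L) {
    stop_validation("exhaustive b-matching oracle is limited to n <= 10")
  }
  check_bmatching_feasible(n, b)

  ut <- which(upper.tri(W), arr.ind = TRUE)
  ord <- order(ut[, 1], ut[, 2])
  edges <- ut[ord, , drop = FALSE]
  ne <- nrow(edges)
  # residual capacity: edges at position >= e that touch node v
  remaining <- matrix(0L, ne + 1L, n)
  for (e in rev(seq_len(ne))) {
    remaining[e, ] <- remaining[e + 1L, ]
    remaining[e, edges[e, 1]] <- remaining[e, edges[e, 1]] + 1L
    remaining[e, edges[e, 2]] <- remaining[e, edges[e, 2]] + 1L
  }

  best <- new.env(parent = emptyenv())
  best$obj <- -Inf
  best$sel <- NULL

  recurse <- function(e, deg, weight, chosen) {
    if (any(deg + remaining[e, ] < b)) return(invisible(NULL))
    if (e > ne) {
      if (all(deg == b) && weight > best$obj) {
        best$obj <- weight
        best$sel <- chosen
      }
      return(invisible(NULL))
    }
    i <- edges[e, 1]; j <- edges[e, 2]
    if (deg[i] < b && deg[j] < b) {
      deg2 <- deg
      deg2[i] <- deg2[i] + 1L
      deg2[j] <- deg2[j] + 1L
      recurse(e + 1L, deg2, weight + W[i, j], c(chosen, e))
    }
    recurse(e + 1L, deg, weight, chosen)
  }
  recurse(1L, integer(n), 0, integer(0))

  if (is.null(best$sel) && best$obj == -Inf) {
    stop_numerical("no feasible b-regular pattern exists for this instance")
  }
  P <- matrix(0L, n, n)
  for (e in best$sel) {
    P[edges[e, 1], edges[e, 2]] <- 1L
    P[edges[e, 2], edges[e, 1]] <- 1L
  }
  new_sparsity_pattern(P, b, W, graph$ids,
                       converged = TRUE, iterations = 0L, method = "exhaustive")
}

#' Re-weight a graph through a sparsity pattern
#'
#' Retained edges keep their Gaussian kernel weight, removed edges drop to
#' zero: `W' = W * P` elementwise. The result is again a valid affinity
#' graph (symmetric, zero diagonal, weights in `[0, 1]`), now highly
#' sparse.
#'
#' @param graph An `affinity_graph`.
#' @param pattern A `sparsity_pattern` for the same nodes.
#' @return A sparsified `affinity_graph` (same `sigma`).
#' @export
apply_sparsification <- function(graph, pattern) {
  stopifnot(inherits(graph, "affinity_graph"), inherits(pattern, "sparsity_pattern"))
  if (!identical(dim(graph$W), dim(pattern$P))) {
    stop_validation("graph and sparsity pattern have different sizes")
  }
  new_affinity_graph(graph$W * pattern$P, graph$sigma, graph$ids)
}
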