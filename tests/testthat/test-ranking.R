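test_that("alpha = 0 disables propagation and returns the queries", {
  ng <- random_ngraph(10, seed = 21)
  y <- as.numeric(seq_len(10) <= 2)
  expect_equal(tidy(rank_closed_form(ng, y, alpha = 0))$score, y)
  it <- rank_iterative(ng, y, alpha = 0)
  expect_equal(tidy(it)$score, y)
  expect_true(all(tidy(it)$rank[1:2] <= 2))
})

test_that("zero evidence propagates to zero scores", {
  ng <- random_ngraph(8, seed = 22)
  expect_true(all(tidy(rank_iterative(ng, rep(0, 8)))$score == 0))
  expect_true(all(tidy(rank_closed_form(ng, rep(0, 8)))$score == 0))
})

test_that("scores decay with graph distance on a path graph", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.9
  W[2, 3] <- W[3, 2] <- 0.9
  ng <- normalize_affinity(graph_from_W(W))
  y <- c(1, 0, 0)
  f_cf <- tidy(rank_closed_form(ng, y, alpha = 0.5))$score
  expect_true(f_cf[1] > f_cf[2] && f_cf[2] > f_cf[3])
  # hand linear solve as the oracle
  expected <- 0.5 * solve(diag(3) - 0.5 * ng$L, y)
  expect_equal(f_cf, as.vector(expected), tolerance = 1e-12)
  f_it <- tidy(rank_iterative(ng, y, alpha = 0.5, tol = 1e-12))$score
  expect_equal(f_it, f_cf, tolerance = 1e-9)
})

test_that("iterative and closed-form solvers agree on random graphs", {
  for (seed in 1:10) {
    ng <- random_ngraph(30, seed = seed)
    y <- as.numeric(seq_len(30) <= 3)
    for (a in c(0.1, 0.5, 0.9)) {
      f1 <- tidy(rank_closed_form(ng, y, alpha = a))$score
      f2 <- tidy(rank_iterative(ng, y, alpha = a, tol = 1e-12,
                                max_iter = 20000))$score
      expect_lt(max(abs(f1 - f2)), 1e-8)
    }
  }
})

test_that("the empty graph returns the damped evidence vector", {
  W <- matrix(0, 4, 4)
  ng <- suppressWarnings(normalize_affinity(graph_from_W(W)))
  y <- c(0.2, 1, 0, 0.5)
  r <- rank_closed_form(ng, y, alpha = 0.3)
  expect_equal(tidy(r)$score, (1 - 0.3) * y)
  expect_identical(tidy(r)$rank, c(3L, 1L, 4L, 2L))
})

test_that("iteration cap trips a warning and flags non-convergence", {
  ng <- random_ngraph(12, seed = 4)
  y <- as.numeric(seq_len(12) == 1)
  expect_warning(r <- rank_iterative(ng, y, alpha = 0.9, tol = 1e-14,
                                     max_iter = 3), "converge")
  expect_false(r$converged)
})

test_that("iterative residual contracts at least geometrically with ratio alpha", {
  ng <- random_ngraph(20, seed = 17)
  y <- as.numeric(seq_len(20) <= 2)
  a <- 0.7
  fstar <- tidy(rank_closed_form(ng, y, alpha = a))$score
  err <- vapply(c(5, 10, 15), function(k) {
    f <- suppressWarnings(tidy(
      rank_iterative(ng, y, alpha = a, tol = 1e-300, max_iter = k)
    )$score)
    max(abs(f - fstar))
  }, numeric(1))
  expect_lt(err[2] / err[1], a^5 * 1.05)
  expect_lt(err[3] / err[2], a^5 * 1.05)
})

test_that("positive rescaling of the evidence leaves the ordering fixed", {
  ng <- random_ngraph(15, seed = 9)
  y <- as.numeric(seq_len(15) <= 2)
  base <- tidy(rank_closed_form(ng, y, alpha = 0.5))$rank
  scaled <- tidy(rank_closed_form(ng, 37.5 * y, alpha = 0.5))$rank
  expect_identical(base, scaled)
})

test_that("adding a positive never decreases any score", {
  for (seed in 1:5) {
    ng <- random_ngraph(15, seed = 100 + seed)
    y1 <- as.numeric(seq_len(15) == 1)
    y2 <- as.numeric(seq_len(15) %in% c(1, 7))
    f1 <- tidy(rank_closed_form(ng, y1, alpha = 0.6))$score
    f2 <- tidy(rank_closed_form(ng, y2, alpha = 0.6))$score
    expect_true(all(f2 - f1 >= -1e-12))
  }
})

test_that("universal ranking reduces to positive-only without negatives", {
  ng <- random_ngraph(12, seed = 41)
  y_plus <- as.numeric(seq_len(12) <= 2)
  zero <- rep(0, 12)
  pos_only <- tidy(rank_closed_form(ng, y_plus, alpha = 0.5))$score
  # gamma = 0 accepted as the degenerate reduction, bitwise
  expect_identical(tidy(rank_universal(ng, y_plus, -as.numeric(seq_len(12) == 5),
                                       alpha = 0.5, gamma = 0))$score, pos_only)
  # empty negative set, any gamma
  expect_identical(tidy(rank_universal(ng, y_plus, zero,
                                       alpha = 0.5, gamma = 0.8))$score, pos_only)
})

test_that("universal scores equal the combined-evidence linear solve", {
  ng <- random_ngraph(4, seed = 43)
  y_plus <- c(1, 0, 0, 0)
  y_minus <- c(0, 0, 0, -1)
  r <- rank_universal(ng, y_plus, y_minus, alpha = 0.5, gamma = 1)
  expected <- 0.5 * solve(diag(4) - 0.5 * ng$L, y_plus + y_minus)
  expect_equal(tidy(r)$score, as.vector(expected), tolerance = 1e-12)
  # the known negative carries the most negative contribution
  delta <- tidy(r)$score -
    tidy(rank_closed_form(ng, y_plus, alpha = 0.5))$score
  expect_equal(which.min(delta), 4L)

  expect_error(rank_universal(ng, y_plus, c(0, 0, 0, 1)),
               class = "secrank_validation_error")
  expect_error(rank_universal(ng, y_plus, -y_plus),
               "disjoint", class = "secrank_validation_error")
})

test_that("alpha tuning returns the argmax of its own mean-AUC table", {
  sim <- simulate_pu_data(n_query = 15, n_hidden_pos = 15, n_neg = 60,
                          m = 8, separation = 5, seed = 6)
  labels <- sim$labels
  labels$status[sim$truth$is_positive] <- "positive"
  single <- tune_alpha(sim$data, labels, grid = 0.5, folds = 5, seed = 1)
  expect_equal(single$alpha, 0.5)

  tuned <- tune_alpha(sim$data, labels, folds = 5, seed = 1)
  expect_equal(tuned$alpha,
               tuned$table$alpha[which.max(tuned$table$mean_auc)])
  expect_identical(nrow(tidy(tuned)), 9L)

  expect_warning(tune_alpha(sim$data, labels, grid = c(0.5, 1), folds = 5,
                            seed = 1), "clamp")
  few <- assign_labels(sim$data, positives = sim$data$id[1])
  expect_error(tune_alpha(sim$data, few, folds = 10),
               "fewer folds", class = "secrank_validation_error")
})

test_that("manifold_rank floats queries to the top and echoes settings", {
  sim <- simulate_pu_data(n_query = 4, n_hidden_pos = 8, n_neg = 40,
                          m = 6, separation = 6, seed = 13)
  r <- manifold_rank(sim$data, sim$labels)
  d <- tidy(r)
  expect_true(all(d$rank[d$status == "positive"] <= 8))
  g <- glance(r)
  expect_identical(g$mode, "positive_only")
  expect_equal(g$alpha, 0.5)
  expect_s3_class(autoplot(r), "ggplot")
})
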