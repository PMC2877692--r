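test_that("pairwise distances are Euclidean, symmetric, zero-diagonal", {
  D <- pairwise_distances(tiny_table())
  expect_equal(D["a", "b"], 5) # 3-4-5 triangle
  expect_equal(D, t(D))
  expect_equal(diag(D), setNames(rep(0, 3), c("a", "b", "c")))

  dup <- tibble::tibble(id = c("a", "b"), f1 = c(2, 2), f2 = c(-1, -1))
  expect_equal(pairwise_distances(dup)["a", "b"], 0)

  one_d <- tibble::tibble(id = c("a", "b"), f1 = c(0, 3))
  expect_equal(pairwise_distances(one_d)["a", "b"], 3)
})

test_that("sigma heuristic is the mean off-diagonal distance", {
  one_pair <- tibble::tibble(id = c("a", "b"), f1 = c(0, 2))
  expect_equal(estimate_sigma(pairwise_distances(one_pair)), 2)

  three <- tibble::tibble(id = c("a", "b", "c"), f1 = c(0, 1, 2))
  expect_equal(estimate_sigma(pairwise_distances(three)), 4 / 3)

  # duplicating every point adds zero distances and shrinks sigma
  six <- tibble::tibble(id = letters[1:6], f1 = c(0, 0, 1, 1, 2, 2))
  expect_lt(estimate_sigma(pairwise_distances(six)), 4 / 3)

  same <- tibble::tibble(id = c("a", "b"), f1 = c(1, 1))
  expect_error(estimate_sigma(pairwise_distances(same)), "degenerate",
               class = "secrank_numerical_error")
})

test_that("affinity weights follow the Gaussian kernel", {
  sigma <- 1.7
  D <- matrix(c(0, sigma * sqrt(2), sigma * sqrt(2), 0), 2, 2)
  g <- build_affinity(D, sigma = sigma)
  expect_equal(g$W[1, 2], exp(-1))
  expect_equal(diag(g$W), setNames(c(0, 0), g$ids)) # forced even though exp(0)=1
  g0 <- build_affinity(matrix(0, 2, 2) + diag(0, 2), sigma = 1)
  expect_equal(g0$W[1, 2], 1) # coincident points: full-strength edge
  expect_error(build_affinity(D, sigma = -1), class = "secrank_validation_error")
})

test_that("normalisation D^-1/2 W D^-1/2 has unit spectral bound", {
  # two nodes, one edge: L_12 = w / sqrt(w * w) = 1 for any w
  W <- matrix(c(0, 0.37, 0.37, 0), 2, 2)
  ng <- normalize_affinity(graph_from_W(W))
  expect_equal(ng$L[1, 2], 1)

  for (seed in 1:5) {
    ng <- random_ngraph(20, m = 4, seed = seed)
    ev <- eigen(ng$L, symmetric = TRUE, only.values = TRUE)$values
    expect_lt(max(abs(ev)), 1 + 1e-9)
    expect_lt(max(abs(ng$L - t(ng$L))), 1e-12)
  }
})

test_that("normalisation cancels any constant rescaling of W", {
  tbl <- random_table(15, 4, seed = 3)
  g <- build_graph(tbl)
  L1 <- normalize_affinity(g)$L
  g2 <- secrank:::new_affinity_graph(g$W * 7.3, g$sigma, g$ids)
  L2 <- normalize_affinity(g2)$L
  expect_equal(L1, L2, tolerance = 1e-12)
})

test_that("isolated nodes yield zero rows with a warning, not an error", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.5
  expect_warning(ng <- normalize_affinity(graph_from_W(W)), "isolated")
  expect_equal(ng$L[3, ], setNames(rep(0, 3), ng$ids))
  expect_equal(ng$L[, 3], setNames(rep(0, 3), ng$ids))

  # fully disconnected graph: all-zero L
  expect_warning(ng0 <- normalize_affinity(graph_from_W(matrix(0, 2, 2))))
  expect_true(all(ng0$L == 0))
})

test_that("graph edge lists tidy into from/to/weight tibbles", {
  g <- build_graph(tiny_table())
  edges <- tidy(g)
  expect_identical(nrow(edges), 3L) # complete graph on 3 nodes
  expect_true(all(edges$weight > 0 & edges$weight <= 1))
  path <- withr::local_tempfile()
  write_graph_edges(g, path)
  expect_length(readLines(path), 4L)
})
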