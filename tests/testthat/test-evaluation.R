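test_that("average precision matches hand-enumerated prefixes", {
  # perfect ranking: every true positive arrives with precision 1
  expect_equal(pr_auc(c(5, 4, 3, 2, 1), c(1, 1, 0, 0, 0)), 1)
  # single positive ranked last of 5
  expect_equal(pr_auc(5:1, c(0, 0, 0, 0, 1)), 1 / 5)
  # the four-sample worked case: precisions 1/1 and 2/3 at the hits
  curve <- pr_curve(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))
  expect_equal(curve$auc, 5 / 6)
  expect_equal(curve$points$recall, c(0.5, 0.5, 1, 1))
  expect_equal(curve$points$precision, c(1, 1 / 2, 2 / 3, 2 / 4))
  # recall is non-decreasing, precision within [0, 1]
  expect_true(all(diff(curve$points$recall) >= 0))
  expect_true(all(curve$points$precision >= 0 & curve$points$precision <= 1))
  expect_s3_class(autoplot(curve), "ggplot")
})

test_that("query exclusion removes samples before the curve is built", {
  scores <- c(10, 0.9, 0.8, 0.7, 0.6)
  truth <- c(1, 1, 0, 1, 0)
  expect_equal(pr_auc(scores, truth, exclude = 1L),
               pr_auc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)))
})

test_that("pr_auc is invariant to sample permutation", {
  set.seed(50)
  scores <- rnorm(40)
  truth <- sample(c(rep(1, 8), rep(0, 32)))
  base <- pr_auc(scores, truth)
  for (i in 1:5) {
    p <- sample(40)
    expect_equal(pr_auc(scores[p], truth[p]), base)
  }
})

test_that("degenerate score vectors are handled explicitly", {
  expect_error(pr_auc(c(1, 2), c(0, 0)), class = "secrank_validation_error")
  expect_warning(pr_auc(c(1, 1, 1), c(1, 0, 0)), "tied")
})

test_that("random scores average at the random-ranking calibration point", {
  # Average precision of a uniformly random ranking is slightly above
  # prevalence at finite n. For a random positive at rank r the expected
  # number of positives at or above it is 1 + (P-1)(r-1)/(n-1), and r is
  # uniform on 1..n, giving the closed form
  #   E[AP] = (H_n + (P-1)/(n-1) * (n - H_n)) / n,
  # which tends to the prevalence P/n as n grows.
  set.seed(60)
  n <- 60; n_pos <- 12
  h_n <- sum(1 / seq_len(n))
  expected <- (h_n + (n_pos - 1) / (n - 1) * (n - h_n)) / n
  truth <- c(rep(1, n_pos), rep(0, n - n_pos))
  aucs <- vapply(1:50, function(i) pr_auc(rnorm(n), truth), numeric(1))
  se <- sd(aucs) / sqrt(length(aucs))
  expect_lt(abs(mean(aucs) - expected), 3 * se)
  expect_lt(abs(mean(aucs) - n_pos / n), 0.05)
})

test_that("the nearest-distance baseline negates the prefilter distances", {
  tbl <- random_table(20, 3, seed = 77)
  lab <- assign_labels(tbl, positives = tbl$id[1:3])
  expect_equal(nearest_distance_ranker(tbl, lab),
               -nearest_positive_distance(tbl, lab)$nearest_positive_distance)
})

test_that("SVM baselines separate a linearly separable toy problem", {
  sim <- simulate_pu_data(n_query = 8, n_hidden_pos = 12, n_neg = 60,
                          m = 5, separation = 8, seed = 3)
  q <- which(sim$labels$status == "positive")
  truth <- as.integer(sim$truth$is_positive); truth[q] <- 0L

  s_bin <- suppressMessages(svm_ranker(sim$data, sim$labels,
                                       strategy = "binary", seed = 1))
  expect_gt(pr_auc(s_bin, truth, exclude = q), 0.9)
  s_one <- svm_ranker(sim$data, sim$labels, strategy = "one_class")
  expect_gt(pr_auc(s_one, truth, exclude = q), 0.9)

  # one-class support containment: cluster members outscore far outliers
  neg_scores <- s_one[!sim$truth$is_positive]
  expect_gt(mean(s_one[q]), mean(neg_scores))

  # same seed, same scores
  expect_identical(s_bin, suppressMessages(
    svm_ranker(sim$data, sim$labels, strategy = "binary", seed = 1)
  ))

  one_pos <- assign_labels(sim$data, positives = sim$data$id[1])
  expect_error(svm_ranker(sim$data, one_pos, strategy = "one_class"),
               class = "secrank_validation_error")
})

test_that("the benchmark protocol fills every cell deterministically", {
  sim <- simulate_pu_data(n_query = 12, n_hidden_pos = 12, n_neg = 60,
                          m = 6, separation = 5, seed = 8)
  labels <- sim$labels
  labels$status[sim$truth$is_positive] <- "positive"
  rep1 <- run_benchmark(sim$data, labels, query_sizes = c(4, 6, 8),
                        repeats = 5, methods = "manifold", seed = 2)
  expect_identical(nrow(tidy(rep1)), 15L)
  expect_identical(nrow(rep1$summary), 3L)
  means <- dplyr::summarise(
    dplyr::group_by(tidy(rep1), .data$query_size),
    m = mean(.data$auc)
  )
  expect_equal(sort(rep1$summary$mean_auc), sort(means$m))

  rep2 <- run_benchmark(sim$data, labels, query_sizes = c(4, 6, 8),
                        repeats = 5, methods = "manifold", seed = 2)
  expect_identical(tidy(rep1), tidy(rep2))

  one <- run_benchmark(sim$data, labels, query_sizes = 4, repeats = 1,
                       methods = "nearest", seed = 3)
  expect_equal(one$summary$mean_auc, one$results$auc)

  expect_error(run_benchmark(sim$data, labels, methods = "oracle"),
               "registered", class = "secrank_validation_error")
  expect_error(run_benchmark(sim$data, labels, query_sizes = 1000),
               class = "secrank_validation_error")
  expect_s3_class(autoplot(rep1), "ggplot")
  expect_identical(ncol(glance(rep1)), 2L)
})
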