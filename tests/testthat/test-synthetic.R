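test_that("generation is a deterministic function of the seed", {
  a <- simulate_pu_data(n_query = 4, n_hidden_pos = 6, n_neg = 20, m = 6,
                        seed = 9)
  b <- simulate_pu_data(n_query = 4, n_hidden_pos = 6, n_neg = 20, m = 6,
                        seed = 9)
  expect_identical(a, b)
  c <- simulate_pu_data(n_query = 4, n_hidden_pos = 6, n_neg = 20, m = 6,
                        seed = 10)
  expect_false(identical(a$data, c$data))
})

test_that("counts, labels and truth are consistent", {
  sim <- simulate_pu_data(n_query = 5, n_hidden_pos = 7, n_neg = 30, m = 10,
                          seed = 2)
  expect_identical(nrow(sim$data), 42L)
  expect_identical(sum(sim$labels$status == "positive"), 5L)
  expect_identical(sum(sim$truth$is_positive), 12L)
  # every query is a true positive
  q <- sim$labels$id[sim$labels$status == "positive"]
  expect_true(all(sim$truth$is_positive[match(q, sim$truth$id)]))
  expect_error(simulate_pu_data(n_query = 0), class = "secrank_validation_error")
  expect_error(simulate_pu_data(noise_sd = 0), class = "secrank_validation_error")
})

test_that("without negatives every ranking is perfect", {
  sim <- simulate_pu_data(n_query = 3, n_hidden_pos = 9, n_neg = 0, m = 5,
                          seed = 4)
  q <- which(sim$labels$status == "positive")
  truth <- as.integer(sim$truth$is_positive); truth[q] <- 0L
  scores <- tidy(manifold_rank(sim$data, sim$labels))$score
  expect_equal(pr_auc(scores, truth, exclude = q), 1)
})

test_that("planted structure puts hidden positives nearer the queries", {
  check_margin <- function(sim) {
    nd <- nearest_positive_distance(sim$data, sim$labels)
    hidden <- sim$truth$is_positive & sim$labels$status != "positive"
    negs <- !sim$truth$is_positive
    expect_lt(mean(nd$nearest_positive_distance[hidden]),
              mean(nd$nearest_positive_distance[negs]))
  }
  # low dimension: any separation above 2 noise-sd leaves a clear margin
  for (seed in 1:5) {
    check_margin(simulate_pu_data(n_query = 6, n_hidden_pos = 20, n_neg = 80,
                                  m = 5, separation = 3, seed = seed))
  }
  # default study conditions (85 dimensions, separation 6)
  check_margin(simulate_pu_data(seed = 1))
})

test_that("curved layout bends the positives along an arc", {
  sim <- simulate_pu_data(n_query = 10, n_hidden_pos = 30, n_neg = 100,
                          m = 10, layout = "curved_manifold", seed = 11)
  X <- as.matrix(sim$data[-1])
  pos <- sim$truth$is_positive
  # positives sit near radius 4*gap in the first two coordinates,
  # negatives near radius 4*gap + gap
  r <- sqrt(X[, 1]^2 + X[, 2]^2)
  expect_lt(abs(mean(r[pos]) - 24), 2)
  expect_lt(abs(mean(r[!pos]) - 30), 2)
})

test_that("the worked example reproduces its independent fixtures", {
  we <- worked_example()
  fixture_dir <- system.file("extdata", "worked_example", package = "secrank")

  D <- pairwise_distances(we$data)
  fixture_D <- as.matrix(read.delim(file.path(fixture_dir, "distances.tsv"),
                                    row.names = 1))
  expect_equal(unname(D), unname(fixture_D), tolerance = 1e-12)

  # sigma is the mean of the 15 distinct pairwise distances
  sigma <- estimate_sigma(D)
  expect_equal(sigma, mean(D[upper.tri(D)]))
  fixture_sigma <- scan(file.path(fixture_dir, "sigma.tsv"), skip = 1,
                        quiet = TRUE)
  expect_equal(sigma, fixture_sigma, tolerance = 1e-14)

  fixture_f <- read.delim(file.path(fixture_dir, "fstar.tsv"))$fstar
  scores <- tidy(manifold_rank(we$data, we$labels, alpha = 0.5))$score
  expect_lt(max(abs(scores - fixture_f)), 1e-10)
})

test_that("re-running the fixture generator reproduces the files bitwise", {
  fixture_dir <- system.file("extdata", "worked_example", package = "secrank")
  out <- withr::local_tempdir()
  rscript <- file.path(R.home("bin"), "Rscript")
  status <- system2(rscript, c(file.path(fixture_dir, "generate.R"), out),
                    stdout = FALSE, stderr = FALSE)
  expect_identical(status, 0L)
  for (f in c("distances.tsv", "sigma.tsv", "W.tsv", "L.tsv", "fstar.tsv")) {
    expect_identical(readLines(file.path(out, f)),
                     readLines(file.path(fixture_dir, f)),
                     label = f)
  }
})

test_that("simulations write loadable feature/label/truth files", {
  sim <- simulate_pu_data(n_query = 3, n_hidden_pos = 3, n_neg = 10, m = 4,
                          seed = 5)
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, dir)
  back <- read_feature_table(paths[["features"]])
  expect_equal(as.matrix(back[-1]), as.matrix(sim$data[-1]),
               tolerance = 1e-12, ignore_attr = TRUE)
  lab <- suppressMessages(read_labels(paths[["queries"]], back))
  expect_identical(lab$status, sim$labels$status)
})
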