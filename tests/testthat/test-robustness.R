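# Bootstrap tests run at deliberately small B; the B < 100 warning is
# expected and silenced where the check is about something else.
quiet_boot <- function(...) suppressWarnings(edge_ci_bootstrap(...))
quiet_cs <- function(...) suppressWarnings(case_dropping_bootstrap(...))

test_that("edge bootstrap is reproducible under a fixed seed", {
  sim <- simulate_dataset(synthetic_spec(n = 150, seed = 91,
                                         community_sizes = c(3L, 2L)))
  b1 <- quiet_boot(sim$data, B = 2, seed = 11)
  b2 <- quiet_boot(sim$data, B = 2, seed = 11)
  expect_identical(b1$replicates, b2$replicates)
  expect_identical(b1$lower, b2$lower)
})

test_that("duplicating the sample shrinks bootstrap interval widths", {
  sim <- simulate_dataset(synthetic_spec(n = 150, seed = 93,
                                         community_sizes = c(3L, 2L),
                                         density = 0.4))
  b_small <- quiet_boot(sim$data, B = 60, seed = 5)
  big <- sim$data$values[rep(seq_len(150), 100), ]
  b_big <- quiet_boot(big, B = 60, seed = 5)
  expect_lt(mean(b_big$upper - b_big$lower),
            mean(b_small$upper - b_small$lower))
})

test_that("a strong planted edge has an interval excluding zero", {
  sim <- simulate_dataset(bivariate_spec(0.5, n = 1000, seed = 95))
  b <- quiet_boot(sim$data, B = 60, seed = 7)
  expect_gt(b$lower[[1]], 0)
})

test_that("perfectly collinear items give maximal stability", {
  # five near-copies of one base column; item j carries j units of noise,
  # giving a centrality ordering that any large subsample reproduces
  set.seed(97)
  base <- sample(1:5, 240, replace = TRUE)
  values <- sapply(1:5, function(j) {
    v <- base
    flip <- sample(240, 16 * j)
    v[flip] <- pmin(5, pmax(1, v[flip] + sample(c(-1, 1), 16 * j, TRUE)))
    v
  })
  colnames(values) <- paste0("v", 1:5)
  cs <- quiet_cs(values, statistic = "expected_influence",
                 drop_fractions = seq(0.1, 0.5, by = 0.1),
                 B = 40, seed = 15)
  expect_equal(cs$cs_coefficient, 0.5)
})

test_that("pure-noise data yields an unstable centrality ordering", {
  sim <- simulate_dataset(synthetic_spec(n = 200, density = 0, seed = 99))
  cs <- quiet_cs(sim$data, statistic = "expected_influence",
                 B = 40, seed = 23)
  expect_lte(cs$cs_coefficient, 0.25)
})

test_that("the CS coefficient is recomputable from the stored draws", {
  sim <- simulate_dataset(synthetic_spec(n = 200, seed = 101,
                                         community_sizes = c(4L, 3L),
                                         density = 0.3))
  cs <- quiet_cs(sim$data, statistic = "expected_influence",
                 drop_fractions = c(0.1, 0.3, 0.5), B = 40, seed = 29)
  # independent quantile routine: 2.5th percentile as a sorted order stat
  q025 <- apply(cs$correlations, 2, function(v) {
    v <- sort(v[!is.na(v)])
    v[max(1, ceiling(0.025 * length(v)))]
  })
  ok <- q025 >= cs$r_threshold
  oracle <- if (any(ok)) max(cs$drop_fractions[ok]) else 0
  expect_identical(cs$cs_coefficient, oracle)
})

test_that("subsamples smaller than p + 1 are skipped with a warning", {
  sim <- simulate_dataset(synthetic_spec(n = 40, seed = 103,
                                         community_sizes = c(10L, 9L),
                                         density = 0.1))
  expect_warning(
    expect_warning(
      cs <- case_dropping_bootstrap(sim$data,
                                    statistic = "expected_influence",
                                    drop_fractions = c(0.2, 0.9), B = 30,
                                    seed = 31),
      "skipped"),
    "small")
  expect_identical(cs$drop_fractions, 0.2)
})

test_that("difference tests flag separated edges and respect symmetry", {
  # truth: one strong edge (v1-v2), one absent edge (v1-v3)
  sp <- synthetic_spec(n = 1000, community_sizes = c(2L, 1L),
                       category_counts = c(5L, 5L),
                       category_start = c(1L, 1L),
                       density = 0, seed = 107)
  truth <- make_ground_truth(sp)
  truth$partial[1, 2] <- truth$partial[2, 1] <- 0.5
  truth$precision <- diag(3) - truth$partial
  sigma <- true_to_covariance(truth)
  set.seed(108)
  z <- matrix(rnorm(1000 * 3), 1000) %*% chol(sigma$matrix)
  data <- ordinalize(z, sp$thresholds, labels = sp$labels)

  b <- quiet_boot(data, B = 60, seed = 43)
  dt <- difference_test(b, alpha = 0.05)
  expect_true(isSymmetric(dt$significant))
  expect_false(any(diag(dt$significant)))
  expect_true(dt$significant["C1I1--C1I2", "C1I1--C2I1"])

  # identical replicate values: difference interval [0, 0], never significant
  b2 <- b
  b2$replicates[, 2] <- b2$replicates[, 1]
  dt2 <- difference_test(b2, alpha = 0.05)
  expect_false(dt2$significant[1, 2])
  expect_equal(dt2$lower[1, 2], 0)
  expect_equal(dt2$upper[1, 2], 0)

  expect_error(difference_test(b, alpha = 0.001), "too small")
})
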