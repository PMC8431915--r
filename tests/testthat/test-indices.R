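# A small handmade network: w12 = 0.5, w13 = -0.2, w23 = 0.1
toy_weights <- function() {
  w <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  w["a", "b"] <- w["b", "a"] <- 0.5
  w["a", "c"] <- w["c", "a"] <- -0.2
  w["b", "c"] <- w["c", "b"] <- 0.1
  w
}

test_that("expected influence sums signed edge weights", {
  expect_equal(expected_influence(matrix(0, 4, 4)), rep(0, 4),
               ignore_attr = TRUE)
  ei <- expected_influence(toy_weights())
  expect_equal(unname(ei), c(0.3, 0.6, -0.1))
})

test_that("bridge expected influence counts only cross-community edges", {
  part <- community_partition(c("a", "b", "c"), c("g1", "g1", "g2"))
  bei <- bridge_expected_influence(toy_weights(), part)
  expect_equal(unname(bei), c(-0.2, 0.1, -0.1))

  # no cross-community edges -> all zero
  w <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  w[1, 2] <- w[2, 1] <- 0.4
  w[3, 4] <- w[4, 3] <- 0.2
  part2 <- community_partition(letters[1:4], c("x", "x", "y", "y"))
  expect_equal(unname(bridge_expected_influence(w, part2)), rep(0, 4))

  # unassigned node is an error naming it
  expect_error(
    bridge_expected_influence(toy_weights(),
                              community_partition(c("a", "b"), c("x", "y"))),
    "c")
})

test_that("EI decomposes exactly into bridge and within-community parts", {
  sim <- simulate_dataset(synthetic_spec(n = 400, seed = 51))
  net <- fit_from_values(sim$data$values)
  part <- default_partition()
  ei <- expected_influence(net)
  bei <- bridge_expected_influence(net, part)
  comm <- unclass(part)[net$labels]
  within <- outer(comm, comm, `==`)
  diag(within) <- FALSE
  wei <- rowSums(net$weights * within)
  expect_equal(ei, bei + wei, tolerance = 1e-12)
})

test_that("centralities scale linearly and commute with relabeling", {
  w <- toy_weights()
  part <- community_partition(c("a", "b", "c"), c("g1", "g1", "g2"))
  expect_equal(expected_influence(3 * w), 3 * expected_influence(w))
  expect_equal(bridge_expected_influence(3 * w, part),
               3 * bridge_expected_influence(w, part))
  perm <- c(3, 1, 2)
  wp <- w[perm, perm]
  expect_equal(expected_influence(wp), expected_influence(w)[perm])
  expect_equal(bridge_expected_influence(wp, part),
               bridge_expected_influence(w, part)[perm])
})

test_that("z-scores standardize and flag degenerate input", {
  expect_equal(unname(zscore(c(1, 2, 3))), c(-1, 0, 1))
  z <- zscore(rep(4, 5))
  expect_equal(unname(z), rep(0, 5), ignore_attr = TRUE)
  expect_true(attr(z, "degenerate"))
  set.seed(61)
  x <- rnorm(10)
  expect_equal(mean(zscore(x)), 0, tolerance = 1e-12)
  expect_equal(sd(zscore(x)), 1, tolerance = 1e-12)
  expect_error(zscore(1), "at least 2")
})

test_that("predictability reflects how well neighbours explain a node", {
  # independent items: R^2 near zero
  sim0 <- simulate_dataset(synthetic_spec(n = 5000, density = 0, seed = 71))
  pr0 <- predictability(sim0$data)
  expect_lt(max(pr0), 0.05)

  # a duplicated column is fully predictable
  set.seed(72)
  x <- matrix(sample(1:5, 300, TRUE), 100, 3)
  x <- cbind(x, x[, 1])
  colnames(x) <- paste0("v", 1:4)
  pr <- predictability(x)
  expect_gt(pr[["v1"]], 0.999)
  expect_gt(pr[["v4"]], 0.999)

  expect_error(predictability(matrix(sample(1:3, 12, TRUE), 3, 4)),
               "n > p")
})

test_that("bivariate predictability matches a brute-force regression", {
  sp <- bivariate_spec(0.6, n = 20000, seed = 81)
  sim <- simulate_dataset(sp)
  pr <- predictability(sim$data)
  # oracle: plain lm on a fresh draw from the same truth
  sim2 <- simulate_dataset(bivariate_spec(0.6, n = 20000, seed = 82))
  oracle <- summary(lm(sim2$data$values[, 1] ~ sim2$data$values[, 2]))$r.squared
  expect_lt(abs(pr[[1]] - oracle), 0.03)
})
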