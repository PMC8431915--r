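test_that("identity input gives an identity precision at any penalty", {
  for (lam in c(0.01, 0.1, 1)) {
    K <- glasso_fit(diag(4), lam)
    expect_equal(unname(K), diag(4), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("unpenalized fits reproduce the direct inverse", {
  for (seed in 1:3) {
    set.seed(seed)
    for (p in 2:5) {
      A <- crossprod(matrix(rnorm(20 * p), 20, p)) + diag(p)
      S <- stats::cov2cor(A)
      K <- glasso_fit(S, 0)
      expect_lt(max(abs(K - solve(S))), 1e-6)
    }
  }
})

test_that("bivariate solution equals the closed-form soft threshold", {
  # off-diagonal r, penalty lambda < r: implied covariance off-diagonal is
  # soft-thresholded to r - lambda, which is the resulting edge weight
  for (r in c(0.5, -0.4)) {
    lam <- 0.2
    S <- matrix(c(1, r, r, 1), 2)
    K <- glasso_fit(S, lam)
    w <- precision_to_partial(K)[1, 2]
    expect_equal(w, sign(r) * (abs(r) - lam), tolerance = 1e-6)
  }
  # lambda >= |r| kills the edge
  S <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(precision_to_partial(glasso_fit(S, 0.5))[1, 2], 0)
})

test_that("penalty paths are log-spaced from the empty-graph threshold", {
  S <- matrix(c(1, 0.6, 0.6, 1), 2)
  expect_equal(penalty_path(S, n_points = 2, min_ratio = 0.01),
               c(0.6, 0.006))
  lams <- penalty_path(S, n_points = 100, min_ratio = 0.01)
  # constant adjacent ratios, matching independent logarithmic spacing
  expect_equal(lams, exp(seq(log(0.6), log(0.006), length.out = 100)),
               tolerance = 1e-12)
  expect_lt(diff(range(lams[-100] / lams[-1])), 1e-10)
  # the first path point always yields an empty network
  K <- glasso_fit(S, lams[1])
  expect_equal(K[1, 2], 0)
})

test_that("EBIC matches its hand-evaluated formula and penalty behaviour", {
  # p = 2, S = K = I: L = (n/2)(0 - 2) = -n, E = 0
  expect_equal(ebic_score(diag(2), diag(2), n = 100, gamma = 0.5), 200)
  # E = 0: gamma has no effect
  expect_equal(ebic_score(diag(3), diag(3), n = 50, gamma = 0),
               ebic_score(diag(3), diag(3), n = 50, gamma = 10))
  # E > 0: strictly increasing in gamma
  K <- matrix(c(2, -1, -1, 2), 2)
  S <- matrix(c(1, 0.2, 0.2, 1), 2)
  scores <- vapply(c(0, 0.5, 1), function(g) ebic_score(K, S, 100, g),
                   numeric(1))
  expect_true(all(diff(scores) > 0))
  expect_error(ebic_score(matrix(c(1, 2, 2, 1), 2), diag(2), 10, 0.5),
               "positive definite")
})

test_that("precision-to-partial conversion follows the scaling formula", {
  expect_equal(precision_to_partial(diag(3)), matrix(0, 3, 3))
  K <- matrix(c(2, -1, -1, 2), 2)
  expect_equal(precision_to_partial(K)[1, 2], 0.5)
  expect_error(precision_to_partial(matrix(c(-1, 0, 0, 1), 2)),
               "diagonal")
  # weights of PD precisions stay inside (-1, 1)
  set.seed(21)
  for (i in 1:5) {
    A <- crossprod(matrix(rnorm(49), 7)) + diag(7)
    w <- precision_to_partial(A)
    expect_true(all(abs(w[upper.tri(w)]) < 1))
  }
})

test_that("model selection returns an empty network for identity input", {
  for (g in c(0, 0.5, 1)) {
    net <- select_network(correlation_matrix(diag(6)), n = 200, gamma = g)
    expect_identical(net$edge_count, 0L)
    expect_equal(net$weights, matrix(0, 6, 6,
                                     dimnames = dimnames(net$weights)))
  }
})

test_that("the penalty path spans empty through dense models", {
  # Edge counts are not exactly nested along a glasso path (active sets
  # can shed an edge as lambda falls); the reliable structure is an
  # empty model at lambda_max densifying toward the path's foot.
  sim <- simulate_dataset(synthetic_spec(n = 300, seed = 31))
  net <- fit_from_values(sim$data$values)
  ec <- net$path$edge_count
  expect_identical(ec[1], 0L)
  expect_gt(ec[length(ec)], ec[1])
  expect_gte(stats::cor(seq_along(ec), ec, method = "spearman"), 0.5)
  expect_true(all(net$path$lambda == sort(net$path$lambda,
                                          decreasing = TRUE)))
})

test_that("selected networks are bit-identical across repeated runs", {
  sim <- simulate_dataset(synthetic_spec(n = 250, seed = 37))
  co <- suppressMessages(nearest_pd_repair(spearman_matrix(sim$data)))
  n1 <- select_network(co)
  n2 <- select_network(co)
  expect_identical(n1$weights, n2$weights)
  expect_identical(n1$penalty, n2$penalty)
  # the network model keeps its bookkeeping invariants
  expect_equal(n1$weights, t(n1$weights))
  expect_equal(diag(n1$weights), rep(0, 19), ignore_attr = TRUE)
  ut <- upper.tri(n1$weights)
  expect_identical(n1$edge_count, sum(n1$weights[ut] != 0))
  nz <- which(n1$precision != 0 & row(n1$precision) != col(n1$precision))
  expect_true(all(sign(n1$weights[nz]) == -sign(n1$precision[nz])))
})

test_that("estimation demands a positive-definite input", {
  bad <- matrix(c(1, 0.9, 0.9, 0.9, 1, -0.9, 0.9, -0.9, 1), 3)
  expect_error(glasso_fit(bad, 0.1), "positive definite")
  cm <- correlation_matrix(bad)
  expect_error(select_network(cm, n = 100), "positive definite")
  expect_error(select_network(correlation_matrix(diag(3))),
               "sample size")
})
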