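test_that("sum-of-squares cost matches hand arithmetic", {
  expect_equal(cost_sse(c(7, 7, 7)), 0)
  expect_equal(cost_sse(c(1, 2, 3)), 2)
  expect_equal(cost_sse(5), 0)
  set.seed(3)
  y <- matrix(rnorm(30), ncol = 3)
  expect_equal(cost_sse(y), oracle_cost_sse(y))
})

test_that("Mahalanobis cost reduces correctly for special precisions", {
  set.seed(4)
  y <- matrix(rnorm(40), ncol = 2)
  crit <- split_criterion(y, "mahalanobis")
  # identity precision: plain column-summed SSE
  crit$lambda_inv <- diag(2)
  expect_equal(cost_mahalanobis(y, crit), cost_sse(y))
  # scalar case: sse / sigma^2
  y1 <- matrix(rnorm(15), ncol = 1)
  c1 <- split_criterion(y1, "mahalanobis")
  expect_equal(cost_mahalanobis(y1, c1), cost_sse(y1) * c1$lambda_inv[1, 1])
  # two symmetric points, correlated precision, hand-computed quadratic form
  y2 <- rbind(c(1, 2), c(3, 4))   # deviations (+-1, +-1)
  c2 <- split_criterion(y2, "mahalanobis")
  rho <- 0.5
  c2$lambda_inv <- solve(matrix(c(1, rho, rho, 1), 2))
  expect_equal(cost_mahalanobis(y2, c2), 4 / (1 + rho))  # 8/3
  # oracle equality on a random node
  crit2 <- split_criterion(y, "mahalanobis")
  expect_equal(cost_mahalanobis(y, crit2),
               oracle_cost_mahalanobis(y, crit2$lambda_inv))
})

test_that("copula cost decomposes into D1 and D2 as specified", {
  set.seed(5)
  y <- matrix(rnorm(60), ncol = 2)
  crit <- split_criterion(y, "copula", alpha = 1.5, grid_size = 4)
  # whole training set: no copula distortion
  cc <- cost_copula(y, crit)
  expect_equal(cc[["d1"]], 0)
  expect_equal(cc[["cost"]], 1.5 * cc[["d2"]])
  # D1 bounded by node size for a bivariate response
  for (seed in 1:5) {
    set.seed(seed)
    node <- y[sample(30, 12), ]
    expect_lte(cost_copula(node, crit)[["d1"]],
               12 * (1 + 1 / 12 + 1 / 30))
  }
  # brute-force oracle on a 4-row fixture
  node <- y[c(2, 9, 17, 25), ]
  expect_equal(
    unname(cost_copula(node, crit)),
    unname(oracle_cost_copula(node, oracle_ecop_grid(y, 4), 4,
                              crit$sigma2, 1.5)))
  # degenerate nodes and univariate responses carry no copula term
  expect_equal(cost_copula(y[1:2, ], crit)[["d1"]], 0)
  y1 <- matrix(rnorm(20), ncol = 1)
  c1 <- split_criterion(y1, "copula", alpha = 2)
  expect_equal(cost_copula(y1, c1)[["d1"]], 0)
})

test_that("best split recovers a perfectly separating partition", {
  x <- cbind(c(1, 2, 3, 4), c(5, 5, 5, 5))
  y <- matrix(c(0, 0, 10, 10), ncol = 1)
  crit <- split_criterion(y, "sse")
  sp <- best_split(x, y, crit)
  # parent SSE = 4 * 25 = 100, both children pure
  expect_equal(sp$feature, 1)
  expect_equal(sp$threshold, 2)
  expect_equal(sp$gain, 100)
  expect_equal(sp$left, 1:2)
  # constant features admit no partition
  x0 <- matrix(1, 4, 2)
  expect_null(best_split(x0, y, crit))
})

test_that("best split agrees with the exhaustive oracle for all criteria", {
  for (seed in 1:10) {
    fx <- make_fixture(n = sample(6:25, 1), M = sample(2:5, 1),
                       r = sample(1:3, 1), seed = 500 + seed)
    K <- 4
    crits <- list(
      sse = list(crit = split_criterion(fx$y, "sse"),
                 fun = oracle_cost_sse))
    cm <- split_criterion(fx$y, "mahalanobis")
    crits$mahalanobis <- list(
      crit = cm, fun = function(y) oracle_cost_mahalanobis(y, cm$lambda_inv))
    cc_ <- split_criterion(fx$y, "copula", alpha = 0.8, grid_size = K)
    root_grid <- oracle_ecop_grid(fx$y, K)
    crits$copula <- list(
      crit = cc_,
      fun = function(y) oracle_cost_copula(y, root_grid, K, cc_$sigma2,
                                           0.8)[["cost"]])
    for (nm in names(crits)) {
      got <- best_split(fx$x, fx$y, crits[[nm]]$crit)
      want <- oracle_best_split(fx$x, fx$y, seq_len(ncol(fx$x)),
                                crits[[nm]]$fun)
      expect_equal(got$feature, want$feature, label = nm)
      expect_equal(got$threshold, want$threshold, label = nm)
      expect_equal(got$gain, want$gain, tolerance = 1e-9, label = nm)
    }
  }
})

test_that("variance-decomposition gains are nonnegative for sse/Mahalanobis", {
  for (seed in 1:5) {
    fx <- make_fixture(12, 3, 2, seed = 900 + seed)
    for (kind in c("sse", "mahalanobis")) {
      crit <- split_criterion(fx$y, kind)
      cand <- split_candidates(fx$x, fx$y, crit)
      expect_true(all(cand$gain >= -1e-9))
    }
  }
})

test_that("best split is invariant to row order and unused-feature warps", {
  fx <- make_fixture(18, 4, 2, seed = 77)
  crit <- split_criterion(fx$y, "copula", alpha = 1, grid_size = 5)
  sp <- best_split(fx$x, fx$y, crit)
  set.seed(1)
  perm <- sample(18)
  sp_perm <- best_split(fx$x[perm, ], fx$y[perm, ], crit)
  expect_equal(sp_perm$feature, sp$feature)
  expect_equal(sp_perm$threshold, sp$threshold)
  expect_equal(sp_perm$gain, sp$gain)
  # strictly increasing transform of a feature that is not selected
  x2 <- fx$x
  unused <- setdiff(1:4, sp$feature)[1]
  x2[, unused] <- exp(x2[, unused])
  sp_warp <- best_split(x2, fx$y, crit)
  expect_equal(sp_warp$feature, sp$feature)
  expect_equal(sp_warp$threshold, sp$threshold)
  expect_equal(sp_warp$gain, sp$gain)
  # repeated calls agree exactly
  expect_identical(best_split(fx$x, fx$y, crit), sp)
})

test_that("minimum child size restricts the candidate set", {
  fx <- make_fixture(14, 3, 2, seed = 31)
  crit <- split_criterion(fx$y, "sse")
  cand <- split_candidates(fx$x, fx$y, crit, min_child = 4)
  expect_true(all(cand$n_left >= 4 & (14 - cand$n_left) >= 4))
  sp <- best_split(fx$x, fx$y, crit, min_child = 4)
  want <- oracle_best_split(fx$x, fx$y, 1:3, oracle_cost_sse, min_child = 4)
  expect_equal(sp$feature, want$feature)
  expect_equal(sp$gain, want$gain, tolerance = 1e-9)
})
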