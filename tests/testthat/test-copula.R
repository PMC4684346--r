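test_that("pseudo-observations are ranks over n, with averaged ties", {
  expect_equal(drop(pseudo_observations(c(10, 30, 20))), c(1/3, 1, 2/3))
  expect_equal(drop(pseudo_observations(c(5, 5, 9))), c(0.5, 0.5, 1))
  # invariance under strictly increasing transforms
  set.seed(1)
  y <- rnorm(25)
  expect_equal(pseudo_observations(y^3), pseudo_observations(y))
  # bias-reduced denominator variant stays strictly inside (0, 1)
  u <- pseudo_observations(y, denominator = "n_plus_1")
  expect_true(all(u > 0 & u < 1))
  expect_equal(drop(u), drop(pseudo_observations(y)) * 25 / 26)
})

test_that("empirical copula grid matches hand counts and closed forms", {
  # two points with pseudo-obs (0.5, 1) and (1, 0.5)
  y <- cbind(c(1, 2), c(2, 1))
  ec <- empirical_copula(y, grid_size = 2)
  expect_equal(ec$values[1, 1], 0)    # u = (0.5, 0.5)
  expect_equal(ec$values[2, 1], 0.5)  # u = (1, 0.5)
  expect_equal(ec$values[1, 2], 0.5)
  expect_equal(ec$values[2, 2], 1)

  # comonotone pairs follow the upper Frechet bound within 1/p
  p <- 40
  y <- cbind(seq_len(p), exp(seq_len(p) / 7))
  ec <- empirical_copula(y, grid_size = 8)
  pts <- as.matrix(expand.grid(u1 = (1:8) / 8, u2 = (1:8) / 8))
  expect_true(all(abs(as.numeric(ec$values) - pmin(pts[, 1], pts[, 2]))
                  <= 1 / p + 1e-12))

  # antimonotone pairs follow the lower Frechet bound within 1/p
  y <- cbind(seq_len(p), -seq_len(p))
  ec <- empirical_copula(y, grid_size = 8)
  expect_true(all(abs(as.numeric(ec$values) -
                        pmax(pts[, 1] + pts[, 2] - 1, 0)) <= 1 / p + 1e-12))
})

test_that("empirical copula grids obey bounds, monotonicity and 2-increase", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(5:40, 1)
    r <- sample(2:3, 1)
    y <- matrix(rnorm(n * r) + rt(n * r, df = 3), n, r)
    K <- 6
    ec <- empirical_copula(y, grid_size = K)
    expect_equal(as.numeric(ec$values), as.numeric(oracle_ecop_grid(y, K)))
    v <- ec$values
    expect_true(all(v >= 0 & v <= 1))
    # upper corner is exactly 1 with the rank/n convention
    expect_equal(as.numeric(v)[length(v)], 1)
    # Frechet bounds up to empirical resolution: each margin contributes
    # up to 1/n of discretisation slack on the lower side
    pts <- as.matrix(expand.grid(rep(list((1:K) / K), r)))
    lo <- pmax(rowSums(pts) - (r - 1), 0) - r / n - 1e-12
    hi <- apply(pts, 1, min) + 1 / n + 1e-12
    expect_true(all(as.numeric(v) >= lo & as.numeric(v) <= hi))
    # monotone nondecreasing along every axis
    for (ax in seq_len(r)) {
      d <- apply(v, setdiff(seq_len(r), ax), diff)
      expect_true(all(d >= -1e-12))
    }
    # rectangle inequality on the first axis pair
    if (r == 2) {
      rect <- v[-1, -1] - v[-K, -1] - v[-1, -K] + v[-K, -K]
      expect_true(all(rect >= -1 / n - 1e-12))
    }
  }
})

test_that("copula distance is a pseudometric bounded by the Frechet gap", {
  set.seed(42)
  ya <- matrix(rnorm(24), ncol = 2)
  yb <- matrix(rt(30, df = 2), ncol = 2)
  yc <- matrix(rnorm(16), ncol = 2)
  ca <- empirical_copula(ya, 10)
  cb <- empirical_copula(yb, 10)
  cc_ <- empirical_copula(yc, 10)
  expect_equal(copula_distance(ca, ca), 0)
  expect_equal(copula_distance(ca, cb), copula_distance(cb, ca))
  expect_lte(copula_distance(ca, cb),
             copula_distance(ca, cc_) + copula_distance(cc_, cb) + 1e-12)
  expect_lte(copula_distance(ca, cb), 1 / 6 + 1 / nrow(ya) + 1 / nrow(yb))
  expect_error(copula_distance(ca, empirical_copula(ya, 5)), "resolution")
})

test_that("copula distance equals a brute-force grid sum on small samples", {
  set.seed(7)
  root <- matrix(rnorm(12), ncol = 2)
  node <- matrix(rnorm(6), ncol = 2)
  K <- 4
  d <- copula_distance(empirical_copula(node, K), empirical_copula(root, K))
  expect_equal(d, mean(abs(oracle_ecop_grid(node, K) -
                             oracle_ecop_grid(root, K))))
})

test_that("reference copulas return their closed forms", {
  expect_equal(reference_copula_value("independence", c(0.5, 0.5)), 0.25)
  expect_equal(reference_copula_value("upper_frechet", c(0.3, 0.7)), 0.3)
  expect_equal(reference_copula_value("lower_frechet", c(0.3, 0.7)), 0)
  expect_equal(reference_copula_value("lower_frechet", c(0.8, 0.9)),
               0.7, tolerance = 1e-12)
  expect_equal(reference_copula_value("clayton", c(0.4, 0.6), xi = 2),
               (0.4^-2 + 0.6^-2 - 1)^(-1/2))
  # Clayton approaches independence as xi -> 0
  u <- cbind(runif(20), runif(20))
  expect_equal(reference_copula_value("clayton", u, xi = 1e-6),
               reference_copula_value("independence", u), tolerance = 1e-4)
  expect_error(reference_copula_value("clayton", c(0.5, 0.5, 0.5), xi = 1),
               "dimension 2")
  expect_error(reference_copula_value("clayton", c(0.5, 0.5), xi = 0))
})

test_that("Clayton sampler matches its Kendall tau and is reproducible", {
  u <- sample_clayton(4000, xi = 2, seed = 11)
  expect_true(all(u > 0 & u < 1))
  # population tau = xi / (xi + 2) = 0.5
  expect_equal(cor(u[, 1], u[, 2], method = "kendall"), 0.5,
               tolerance = 0.05)
  u0 <- sample_clayton(4000, xi = 1e-6, seed = 11)
  expect_lt(abs(cor(u0[, 1], u0[, 2], method = "kendall")), 0.05)
  expect_identical(sample_clayton(50, 2, seed = 3),
                   sample_clayton(50, 2, seed = 3))
  expect_error(sample_clayton(10, xi = -1), "positive")
})

test_that("empirical Clayton copulas converge to the analytic grid", {
  K <- 10
  pts <- as.matrix(expand.grid((1:K) / K, (1:K) / K))
  analytic <- array(reference_copula_value("clayton", pts, xi = 2),
                    dim = c(K, K))
  dists <- vapply(c(50, 500, 5000), function(p) {
    u <- sample_clayton(p, xi = 2, seed = 99)
    mean(abs(empirical_copula(u, K)$values - analytic))
  }, numeric(1))
  expect_true(all(diff(dists) < 0))
  expect_lt(dists[3], 0.01)
})

test_that("Frechet gap integrals approach their analytic values", {
  g2 <- frechet_gap_integrals(2, "grid", resolution = 200)
  expect_equal(unname(g2), c(1/6, 1/12, 1/3), tolerance = 1e-3)
  g3 <- frechet_gap_integrals(3, "grid", resolution = 100)
  expect_equal(unname(g3), c(1/4 - 1/24, 1/4 - 1/8, 1/4), tolerance = 2e-3)
  gm <- frechet_gap_integrals(4, "monte_carlo", samples = 2e5, seed = 5)
  expect_equal(unname(gm), c(1/5 - 1/120, 1/5 - 1/16, 1/5), tolerance = 5e-3)
  expect_identical(frechet_gap_integrals(3, "monte_carlo", samples = 1e4,
                                         seed = 2),
                   frechet_gap_integrals(3, "monte_carlo", samples = 1e4,
                                         seed = 2))
  # finer grids get closer to the analytic value
  err <- vapply(c(25, 50, 100), function(K) {
    abs(frechet_gap_integrals(2, "grid", resolution = K)[["cu"]] - 1/3)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("each diagonal region of the bivariate gap contributes 1/24", {
  reg <- bivariate_gap_by_region(300)
  expect_lt(max(abs(reg - 1/24)), 1e-3)
  expect_lt(abs(sum(reg) - 1/6), 1e-3)
})

test_that("high-dimensional copulas fall back to low-discrepancy points", {
  set.seed(8)
  y <- matrix(rnorm(40 * 4), 40, 4)
  ec <- empirical_copula(y, grid_size = 40, max_grid = 1e5)
  expect_identical(ec$eval, "points")
  expect_equal(length(ec$values), 2048)
  expect_error(empirical_copula(y, grid_size = 40, eval = "lattice",
                                max_grid = 1e5), "points")
})
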