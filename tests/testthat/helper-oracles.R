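# Plain-loop reference implementations used as independent oracles.
# Deliberately written with naive R loops / apply over explicit grids, with
# no reliance on the package's C++ code paths.

oracle_pseudo <- function(y) {
  y <- as.matrix(y)
  apply(y, 2, function(col) rank(col) / length(col))
}

# empirical copula tabulated at the upper-corner lattice (k/K)^r
oracle_ecop_grid <- function(y, K) {
  u <- oracle_pseudo(y)
  r <- ncol(u)
  pts <- as.matrix(expand.grid(rep(list(seq_len(K) / K), r)))
  vals <- apply(pts, 1, function(pt) {
    mean(apply(u, 1, function(row) all(row <= pt + 1e-12)))
  })
  array(vals, dim = rep(K, r))
}

oracle_cost_sse <- function(y) {
  y <- as.matrix(y)
  tot <- 0
  for (j in seq_len(ncol(y))) {
    mu <- mean(y[, j])
    for (i in seq_len(nrow(y))) tot <- tot + (y[i, j] - mu)^2
  }
  tot
}

oracle_cost_mahalanobis <- function(y, prec) {
  y <- as.matrix(y)
  mu <- colMeans(y)
  tot <- 0
  for (i in seq_len(nrow(y))) {
    d <- y[i, ] - mu
    tot <- tot + drop(t(d) %*% prec %*% d)
  }
  tot
}

oracle_cost_copula <- function(y, root_grid, K, sigma2, alpha) {
  y <- as.matrix(y)
  p <- nrow(y)
  d2 <- 0
  for (j in seq_len(ncol(y)))
    d2 <- d2 + oracle_cost_sse(y[, j, drop = FALSE]) / sigma2[j]
  d1 <- 0
  if (ncol(y) >= 2 && p >= 3)
    d1 <- 6 * p * mean(abs(oracle_ecop_grid(y, K) - root_grid))
  c(cost = d1 + alpha * d2, d1 = d1, d2 = d2)
}

# exhaustive enumeration of every (feature, threshold) partition; gains
# within a parent-scaled tolerance count as ties resolved to the earlier
# candidate, mirroring the package's documented tie rule
oracle_best_split <- function(x, y, features, cost_fun, min_child = 1) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  parent <- cost_fun(y)
  tie_tol <- 1e-9 * (1 + abs(parent))
  best <- NULL
  for (f in sort(features)) {
    for (z in sort(unique(x[, f]))) {
      left <- x[, f] <= z
      nl <- sum(left)
      if (nl == 0 || nl == nrow(x)) next
      if (nl < min_child || nrow(x) - nl < min_child) next
      gain <- parent - cost_fun(y[left, , drop = FALSE]) -
        cost_fun(y[!left, , drop = FALSE])
      if (is.null(best) || gain > best$gain + tie_tol)
        best <- list(feature = f, threshold = z, gain = gain)
    }
  }
  best
}

# O(n^2) dominance filter: i is dominated by j when j is at least as small
# in both coordinates and strictly smaller in one
oracle_pareto <- function(d1, d2) {
  keep <- !duplicated(cbind(d1, d2))
  d1 <- d1[keep]
  d2 <- d2[keep]
  id <- which(keep)
  n <- length(d1)
  dominated <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      a <- d1[i] > d1[j] && d2[i] >= d2[j]
      b <- d1[i] >= d1[j] && d2[i] > d2[j]
      if (a || b) {
        dominated[i] <- TRUE
        break
      }
    }
  }
  out <- data.frame(d1 = d1[!dominated], d2 = d2[!dominated],
                    id = id[!dominated])
  out[order(out$d1), ]
}

# random regression fixture
make_fixture <- function(n, M, r, seed) {
  set.seed(seed)
  x <- matrix(rnorm(n * M), n, M)
  b <- matrix(rnorm(M * r), M, r)
  y <- x %*% b + matrix(rnorm(n * r, sd = 0.5), n, r)
  list(x = x, y = y)
}
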