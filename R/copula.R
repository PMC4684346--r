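#' Rank-based pseudo-observations
#'
#' Transforms each column of a response matrix to its within-sample marginal
#' ranks divided by the number of rows (average ranks for ties), yielding
#' values in (0, 1]. Pseudo-observations are invariant under strictly
#' increasing transformations of any column, which is what makes the
#' empirical copula a marginal-free summary of the joint dependence.
#'
#' @param y numeric matrix (or vector, treated as a one-column matrix) of
#'   responses, one row per sample.
#' @param denominator either `"n"` (default; ranks divided by the number of
#'   rows, so the largest value maps exactly to 1 and the empirical copula
#'   reaches 1 at the upper corner) or `"n_plus_1"` (the classical
#'   bias-reducing variant with values strictly inside (0, 1)).
#' @return numeric matrix of the same shape with entries in (0, 1].
#' @examples
#' pseudo_observations(cbind(c(10, 30, 20), c(5, 5, 9)))
#' @export
pseudo_observations <- function(y, denominator = c("n", "n_plus_1")) {
  denominator <- match.arg(denominator)
  y <- as.matrix(y)
  if (!is.numeric(y)) stop("'y' must be numeric")
  if (nrow(y) < 1L) stop("'y' must have at least one row")
  u <- .pseudo_obs_cpp(y)
  if (denominator == "n_plus_1") u <- u * nrow(y) / (nrow(y) + 1)
  dimnames(u) <- dimnames(y)
  u
}

#' Deterministic low-discrepancy points in the unit hypercube
#'
#' Halton sequence used as the default evaluation set for copula-distance
#' integrals in dimensions where a full lattice is too large.
#' @param n number of points.
#' @param dim dimension.
#' @return an `n` x `dim` matrix in (0, 1).
#' @keywords internal
halton_points <- function(n, dim) {
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37)
  if (dim > length(primes)) stop("dimension too large for Halton sequence")
  out <- matrix(0, n, dim)
  for (j in seq_len(dim)) {
    b <- primes[j]
    for (i in seq_len(n)) {
      f <- 1 / b
      k <- i
      x <- 0
      while (k > 0) {
        x <- x + f * (k %% b)
        k <- k %/% b
        f <- f / b
      }
      out[i, j] <- x
    }
  }
  out
}

#' Empirical copula tabulated on a grid
#'
#' Estimates the copula of a multivariate sample by first converting each
#' margin to pseudo-observations (see [pseudo_observations()]) and then
#' counting, for each grid point u, the fraction of samples dominated by u
#' componentwise: `C(u) = #\{i : U[i, j] <= u[j] for all j\} / n`.
#'
#' For dimension at most 3 (by default) the copula is tabulated on the full
#' lattice `\{(k1/K, ..., kr/K)\}`; for higher dimensions, where `K^r`
#' explodes, it is evaluated at a fixed set of 2048 low-discrepancy
#' (Halton) points instead, which is sufficient for the distance integrals
#' the tree-growing code needs.
#'
#' @param y numeric matrix of responses (rows = samples).
#' @param grid_size lattice resolution `K` per axis (default 10).
#' @param eval `"lattice"` or `"points"`; default `"auto"` picks the lattice
#'   when `grid_size^ncol(y)` does not exceed `max_grid` and Halton points
#'   otherwise.
#' @param n_points number of low-discrepancy points in `"points"` mode.
#' @param max_grid largest permissible lattice size before `"auto"` switches
#'   to point evaluation (an explicit `eval = "lattice"` beyond this budget
#'   is an error suggesting point mode).
#' @param denominator passed to [pseudo_observations()].
#' @return an object of class `"empirical_copula"`: a list with elements
#'   `dim`, `n`, `pseudo_obs`, `grid_size`, `eval`, `values` (an array of
#'   dimension `rep(K, r)` in lattice mode, a vector in point mode) and
#'   `eval_points` (point mode only).
#' @examples
#' y <- cbind(1:20, (1:20)^3)          # comonotone pair
#' ec <- empirical_copula(y, grid_size = 5)
#' ec$values[5, 5]                     # upper corner equals 1
#' @export
empirical_copula <- function(y, grid_size = 10,
                             eval = c("auto", "lattice", "points"),
                             n_points = 2048, max_grid = 1e6,
                             denominator = c("n", "n_plus_1")) {
  eval <- match.arg(eval)
  y <- as.matrix(y)
  r <- ncol(y)
  if (nrow(y) < 1L) stop("'y' must have at least one row")
  if (grid_size < 2L) stop("'grid_size' must be at least 2")
  g <- grid_size^r
  if (eval == "auto") eval <- if (g <= max_grid) "lattice" else "points"
  if (eval == "lattice" && g > max_grid) {
    stop("lattice of ", grid_size, "^", r, " points exceeds the memory ",
         "budget; use eval = \"points\" (Monte-Carlo/low-discrepancy mode)")
  }
  u <- pseudo_observations(y, denominator = match.arg(denominator))
  if (eval == "lattice") {
    values <- array(.lattice_copula_cpp(u, as.integer(grid_size)),
                    dim = rep(grid_size, r))
    ep <- NULL
  } else {
    ep <- halton_points(n_points, r)
    values <- .copula_values_cpp(u, ep)
  }
  structure(
    list(dim = r, n = nrow(y), pseudo_obs = u, grid_size = grid_size,
         eval = eval, values = values, eval_points = ep),
    class = "empirical_copula"
  )
}

#' @export
print.empirical_copula <- function(x, ...) {
  cat("Empirical copula: dim =", x$dim, ", n =", x$n,
      ", eval =", x$eval,
      if (x$eval == "lattice") paste0("(K = ", x$grid_size, ")")
      else paste0("(", length(x$values), " points)"), "\n")
  invisible(x)
}

#' Integrated absolute difference between two empirical copulas
#'
#' The distance used by the copula node cost: the integral over the unit
#' hypercube of `|C1(u) - C2(u)|`, approximated as the mean absolute
#' difference over the shared evaluation grid. It is a pseudometric on
#' copulas tabulated on the same grid, bounded by the integral of the
#' Frechet-Hoeffding gap for the dimension (1/6 for bivariate copulas).
#'
#' @param a,b `"empirical_copula"` objects with identical dimension and
#'   evaluation grid.
#' @return a nonnegative scalar.
#' @export
copula_distance <- function(a, b) {
  stopifnot(inherits(a, "empirical_copula"), inherits(b, "empirical_copula"))
  if (a$dim != b$dim) stop("copulas have different dimensions")
  if (a$eval != b$eval) stop("copulas use different evaluation modes")
  if (a$eval == "lattice" && a$grid_size != b$grid_size)
    stop("copulas tabulated at different grid resolutions")
  if (a$eval == "points" && length(a$values) != length(b$values))
    stop("copulas evaluated at different point sets")
  mean(abs(as.numeric(a$values) - as.numeric(b$values)))
}

#' Reference copulas: Frechet bounds, independence, Clayton
#'
#' Closed-form copulas used as anchors and test oracles: the upper Frechet
#' bound (comonotone) `min(u)`, the lower Frechet bound (countermonotone for
#' r = 2) `max(sum(u) - (r - 1), 0)`, the independence copula `prod(u)`, and
#' the bivariate Clayton copula
#' `(u1^-xi + u2^-xi - 1)^(-1/xi)` with parameter `xi > 0`.
#'
#' @param family one of `"upper_frechet"`, `"lower_frechet"`,
#'   `"independence"`, `"clayton"`.
#' @param u a point in the unit hypercube (numeric vector), or a matrix with
#'   one point per row.
#' @param xi Clayton dependence parameter, required positive; the family is
#'   defined here for dimension 2 only and approaches independence as
#'   `xi -> 0` and comonotonicity as `xi -> Inf`.
#' @return copula value(s) at `u`.
#' @examples
#' reference_copula_value("independence", c(0.5, 0.5))  # 0.25
#' reference_copula_value("upper_frechet", c(0.3, 0.7)) # 0.3
#' @export
reference_copula_value <- function(family = c("upper_frechet", "lower_frechet",
                                              "independence", "clayton"),
                                   u, xi = NULL) {
  family <- match.arg(family)
  u <- if (is.matrix(u)) u else matrix(u, nrow = 1)
  if (any(u < 0 | u > 1)) stop("'u' must lie in the unit hypercube")
  r <- ncol(u)
  out <- switch(family,
    upper_frechet = apply(u, 1, min),
    lower_frechet = pmax(rowSums(u) - (r - 1), 0),
    independence  = apply(u, 1, prod),
    clayton = {
      if (r != 2) stop("the Clayton copula is defined here for dimension 2")
      if (is.null(xi) || xi <= 0) stop("Clayton requires xi > 0")
      (pmax(u[, 1], .Machine$double.xmin)^(-xi) +
         pmax(u[, 2], .Machine$double.xmin)^(-xi) - 1)^(-1 / xi)
    })
  unname(out)
}

#' Sample from the bivariate Clayton copula
#'
#' Conditional-inverse sampler: draw `u1` uniform, draw `w` uniform, and set
#' `u2 = (u1^-xi * (w^(-xi/(1+xi)) - 1) + 1)^(-1/xi)`, which inverts the
#' conditional distribution of `u2` given `u1`. The population Kendall's tau
#' of the family is `xi / (xi + 2)`.
#'
#' @param n number of pairs to draw.
#' @param xi Clayton parameter, must be positive.
#' @param seed optional integer seed for reproducible draws.
#' @return an `n` x 2 matrix with entries in (0, 1).
#' @export
sample_clayton <- function(n, xi, seed = NULL) {
  if (xi <= 0) stop("'xi' must be positive")
  if (!is.null(seed)) set.seed(seed)
  u1 <- runif(n)
  w <- runif(n)
  u2 <- (u1^(-xi) * (w^(-xi / (1 + xi)) - 1) + 1)^(-1 / xi)
  cbind(u1, u2)
}

#' Integrals of Frechet-Hoeffding gap functions over the unit hypercube
#'
#' Estimates the three integrals that calibrate the copula node cost: the
#' integral of `C_U - C_L` (the widest possible gap between two copulas of
#' that dimension), of `C_U - C_I`, and of `C_U` alone, where `C_U = min(u)`,
#' `C_L = max(sum(u) - (r-1), 0)` and `C_I = prod(u)`. Analytic values are
#' `1/(r+1) - 1/(r+1)!`, `1/(r+1) - 2^-r` and `1/(r+1)`; in dimension 2 these
#' are 1/6, 1/12 and 1/3. The bound 1/6 motivates the factor 6 in the
#' copula node cost, which rescales the distance integral to at most
#' (roughly) 1 per sample for a bivariate response.
#'
#' @param dim dimension, at least 2.
#' @param method `"grid"` (midpoint rule on `resolution^dim` cells,
#'   deterministic) or `"monte_carlo"` (mean over `samples` uniform points,
#'   seeded). Default: grid for `dim <= 3`, Monte Carlo above.
#' @param resolution cells per axis for the grid method.
#' @param samples number of Monte-Carlo points.
#' @param seed seed for the Monte-Carlo method.
#' @return named numeric vector `c(cu_minus_cl, cu_minus_ci, cu)`.
#' @examples
#' frechet_gap_integrals(2, "grid", resolution = 200)  # ~ (1/6, 1/12, 1/3)
#' @export
frechet_gap_integrals <- function(dim,
                                  method = if (dim <= 3) "grid" else "monte_carlo",
                                  resolution = 200, samples = 1e6,
                                  seed = NULL) {
  method <- match.arg(method, c("grid", "monte_carlo"))
  if (dim < 2) stop("'dim' must be at least 2")
  if (method == "grid") {
    mids <- (seq_len(resolution) - 0.5) / resolution
    u1 <- rep(mids, times = resolution)
    u2 <- rep(mids, each = resolution)
    base_min <- pmin(u1, u2)
    base_sum <- u1 + u2
    base_prod <- u1 * u2
    if (dim == 2) {
      rest <- matrix(numeric(0), nrow = 1, ncol = 0)
    } else {
      rest <- as.matrix(expand.grid(rep(list(mids), dim - 2)))
    }
    s_gap <- s_ind <- s_cu <- 0
    for (k in seq_len(nrow(rest))) {
      cc <- rest[k, ]
      mn <- if (length(cc)) pmin(base_min, min(cc)) else base_min
      sm <- base_sum + sum(cc)
      pr <- base_prod * prod(cc)
      cl <- pmax(sm - (dim - 1), 0)
      s_gap <- s_gap + sum(mn - cl)
      s_ind <- s_ind + sum(mn - pr)
      s_cu <- s_cu + sum(mn)
    }
    ncell <- resolution^2 * nrow(rest)
    out <- c(s_gap, s_ind, s_cu) / ncell
  } else {
    if (!is.null(seed)) set.seed(seed)
    u <- matrix(runif(samples * dim), ncol = dim)
    mn <- u[, 1]
    pr <- u[, 1]
    sm <- u[, 1]
    for (j in 2:dim) {
      mn <- pmin(mn, u[, j])
      pr <- pr * u[, j]
      sm <- sm + u[, j]
    }
    cl <- pmax(sm - (dim - 1), 0)
    out <- c(mean(mn - cl), mean(mn - pr), mean(mn))
  }
  names(out) <- c("cu_minus_cl", "cu_minus_ci", "cu")
  out
}

#' Bivariate Frechet gap split by diagonal region
#'
#' The unit square splits along its two diagonals (`u = v`, `u + v = 1`)
#' into four triangles on which `C_U - C_L` reduces to a linear function;
#' each triangle contributes exactly 1/24 to the total 1/6. Computed by the
#' midpoint rule at the requested resolution. Region 1 is
#' `\{u > v, u + v > 1\}`, region 2 `\{u > v, u + v <= 1\}`, region 3
#' `\{u <= v, u + v <= 1\}`, region 4 `\{u <= v, u + v > 1\}`.
#'
#' @param resolution cells per axis (default 400).
#' @return named numeric vector of the four regional integrals.
#' @export
bivariate_gap_by_region <- function(resolution = 400) {
  mids <- (seq_len(resolution) - 0.5) / resolution
  u <- rep(mids, times = resolution)
  v <- rep(mids, each = resolution)
  gap <- pmin(u, v) - pmax(u + v - 1, 0)
  cell <- 1 / resolution^2
  r1 <- u > v & u + v > 1
  r2 <- u > v & u + v <= 1
  r3 <- u <= v & u + v <= 1
  r4 <- u <= v & u + v > 1
  c(region1 = sum(gap[r1]), region2 = sum(gap[r2]),
    region3 = sum(gap[r3]), region4 = sum(gap[r4])) * cell
}
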