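#' Synthetic quadratic-dependence benchmark data
#'
#' Generates the illustrative multi-response dataset used throughout the
#' package's tests: a feature matrix of iid standard normals and two
#' responses
#' `Y1 = 2 x1 + 5 x2 - 1.5 x3 + x4` and `Y2 = (Y1 - E(Y1))^2`,
#' so that only four of the features are informative and the two responses
#' have a purely quadratic (near-zero correlation) relationship that a
#' covariance-based node cost cannot see but a copula-based one can. By
#' default `E(Y1)` is the realised sample mean of the generated `Y1`
#' (`center = "analytic"` uses the population value 0 instead); the
#' construction is noise-free unless `noise_sd > 0` adds Gaussian noise to
#' both responses.
#'
#' @param n number of samples (default 50).
#' @param n_features number of features, at least 4 (default 10).
#' @param noise_sd standard deviation of additive response noise
#'   (default 0).
#' @param center `"sample"` (default) or `"analytic"`.
#' @param seed optional integer seed.
#' @return a `"cmrf_data"` list with elements `x` (n x n_features), `y`
#'   (n x 2, columns `Y1`, `Y2`), `sample_ids`, `feature_names`,
#'   `response_names`.
#' @examples
#' d <- sim_quadratic_example(seed = 7)
#' dim(d$x); dim(d$y); min(d$y[, "Y2"]) >= 0
#' @export
sim_quadratic_example <- function(n = 50, n_features = 10, noise_sd = 0,
                                  center = c("sample", "analytic"),
                                  seed = NULL) {
  center <- match.arg(center)
  if (n_features < 4) stop("'n_features' must be at least 4")
  if (!is.null(seed)) set.seed(seed)
  x <- matrix(rnorm(n * n_features), n, n_features,
              dimnames = list(paste0("sample_", seq_len(n)),
                              paste0("X", seq_len(n_features))))
  y1 <- 2 * x[, 1] + 5 * x[, 2] - 1.5 * x[, 3] + x[, 4]
  if (noise_sd > 0) y1 <- y1 + rnorm(n, sd = noise_sd)
  mu <- if (center == "sample") mean(y1) else 0
  y2 <- (y1 - mu)^2
  if (noise_sd > 0) y2 <- y2 + rnorm(n, sd = noise_sd)
  y <- cbind(Y1 = y1, Y2 = y2)
  rownames(y) <- rownames(x)
  new_cmrf_data(x, y)
}

#' Synthetic response pairs with controllable dependence
#'
#' Generators for contrasting node-cost behaviours on known dependence
#' structures, all seeded and feature matrix iid standard normal:
#'
#' * `"linear"` — `Y1 = 2 x1 + 5 x2 - 1.5 x3 + x4 + noise`,
#'   `Y2 = slope * Y1 + noise`: strongly correlated pair.
#' * `"clayton"` — responses built from a Clayton(`xi`)-coupled uniform
#'   pair mapped through the requested marginal quantile functions:
#'   monotone, nonlinear, lower-tail-heavy dependence with Kendall's tau
#'   `xi / (xi + 2)`. The features are uninformative here; this model is a
#'   dependence fixture for the copula machinery.
#' * `"independent"` — `Y1 = 2 x1 + x2`, `Y2 = x3 - x4`: both predictable
#'   from disjoint features, mutually independent.
#'
#' @param model `"linear"`, `"clayton"`, or `"independent"`.
#' @param n,n_features sample and feature counts (features at least 4).
#' @param slope linear-pair coefficient of `Y2` on `Y1`.
#' @param xi Clayton dependence parameter.
#' @param marginal marginal distribution for the Clayton pair: `"normal"`,
#'   `"exponential"` or `"uniform"`.
#' @param noise_sd additive Gaussian response noise (linear model only;
#'   default 0).
#' @param seed optional integer seed.
#' @return a `"cmrf_data"` list (see [sim_quadratic_example()]).
#' @export
sim_response_pair <- function(model = c("linear", "clayton", "independent"),
                              n = 100, n_features = 10, slope = 1, xi = 2,
                              marginal = c("normal", "exponential", "uniform"),
                              noise_sd = 0, seed = NULL) {
  model <- match.arg(model)
  marginal <- match.arg(marginal)
  if (n_features < 4) stop("'n_features' must be at least 4")
  if (!is.null(seed)) set.seed(seed)
  x <- matrix(rnorm(n * n_features), n, n_features,
              dimnames = list(paste0("sample_", seq_len(n)),
                              paste0("X", seq_len(n_features))))
  y <- switch(model,
    linear = {
      y1 <- 2 * x[, 1] + 5 * x[, 2] - 1.5 * x[, 3] + x[, 4]
      if (noise_sd > 0) y1 <- y1 + rnorm(n, sd = noise_sd)
      y2 <- slope * y1
      if (noise_sd > 0) y2 <- y2 + rnorm(n, sd = noise_sd)
      cbind(Y1 = y1, Y2 = y2)
    },
    clayton = {
      u <- sample_clayton(n, xi)
      qf <- switch(marginal, normal = stats::qnorm,
                   exponential = stats::qexp, uniform = identity)
      cbind(Y1 = qf(u[, 1]), Y2 = qf(u[, 2]))
    },
    independent = cbind(Y1 = 2 * x[, 1] + x[, 2], Y2 = x[, 3] - x[, 4])
  )
  rownames(y) <- rownames(x)
  new_cmrf_data(x, y)
}

#' Diagnose the quadratic response relationship
#'
#' For a two-response dataset, reports the Pearson correlation between the
#' responses (near zero for a symmetric quadratic link, where covariance is
#' blind) and a flag for whether the squared-response dependence is
#' detectable: the correlation between `Y2` and `(Y1 - mean(Y1))^2` exceeds
#' 0.9.
#'
#' @param y two-column response matrix, or a `"cmrf_data"` object.
#' @return list with `pearson_r` and logical `quadratic_dependence`.
#' @export
quadratic_dependence_check <- function(y) {
  if (inherits(y, "cmrf_data")) y <- y$y
  y <- as.matrix(y)
  if (ncol(y) != 2) stop("expected exactly two responses")
  r <- cor(y[, 1], y[, 2])
  sq <- (y[, 1] - mean(y[, 1]))^2
  flag <- sd(sq) > 0 && sd(y[, 2]) > 0 && cor(y[, 2], sq) > 0.9
  list(pearson_r = r, quadratic_dependence = flag)
}
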