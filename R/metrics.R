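#' Pearson correlation between observed and predicted responses
#'
#' Thin wrapper around [stats::cor()] that returns `NA` with a warning when
#' either vector has zero variance (where the correlation is undefined),
#' which happens for degenerate folds or constant predictions.
#'
#' @param y,yhat numeric vectors of equal length (at least 2).
#' @return correlation in \[-1, 1\], or `NA`.
#' @export
pearson_r <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("'y' and 'yhat' differ in length")
  if (length(y) < 2) stop("need at least two observations")
  if (sd(y) == 0 || sd(yhat) == 0) {
    warning("zero variance: Pearson correlation undefined, returning NA")
    return(NA_real_)
  }
  cor(y, yhat)
}

#' Mean absolute error
#'
#' @param y,yhat numeric vectors of equal length.
#' @return `mean(abs(y - yhat))`.
#' @export
mae <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("'y' and 'yhat' differ in length")
  mean(abs(y - yhat))
}

#' Normalised root mean squared error
#'
#' `sqrt( sum((y - yhat)^2) / sum((y - mean(y))^2) )`: 0 for perfect
#' prediction and exactly 1 for always predicting the response mean, which
#' makes values below 1 directly interpretable as beating the mean
#' predictor. `square_root = FALSE` returns the squared-error ratio itself.
#'
#' @param y,yhat numeric vectors of equal length (at least 2).
#' @param square_root take the square root of the quotient (default `TRUE`).
#' @return nonnegative scalar.
#' @export
nrmse <- function(y, yhat, square_root = TRUE) {
  if (length(y) != length(yhat)) stop("'y' and 'yhat' differ in length")
  if (length(y) < 2) stop("need at least two observations")
  den <- sum((y - mean(y))^2)
  if (den == 0) stop("'y' has zero variance: NRMSE undefined")
  q <- sum((y - yhat)^2) / den
  if (square_root) sqrt(q) else q
}

# per-response metrics table for a prediction matrix
.metrics_table <- function(y, yhat, response_names = colnames(y)) {
  if (is.null(response_names))
    response_names <- paste0("response_", seq_len(ncol(y)))
  data.frame(
    response = response_names,
    pearson_r = vapply(seq_len(ncol(y)), function(j)
      tryCatch(pearson_r(y[, j], yhat[, j]), warning = function(w) NA_real_),
      numeric(1)),
    mae = vapply(seq_len(ncol(y)), function(j) mae(y[, j], yhat[, j]),
                 numeric(1)),
    nrmse = vapply(seq_len(ncol(y)), function(j) nrmse(y[, j], yhat[, j]),
                   numeric(1)),
    stringsAsFactors = FALSE
  )
}

#' k-fold cross-validation of multivariate random forests
#'
#' Assigns rows to `k` balanced folds (seeded), trains a forest on each
#' training fold — optionally re-selecting the copula weight alpha inside
#' the fold by the grid or Pareto procedure — predicts the held-out rows,
#' and scores the pooled out-of-fold predictions per response with Pearson
#' correlation, MAE and NRMSE. Pooling (rather than averaging per-fold
#' metrics) matches computing each metric once per response over all
#' cross-validated predictions.
#'
#' @param x,y feature and response matrices.
#' @param k number of folds (default 5).
#' @param criterion `"copula"`, `"mahalanobis"`, `"sse"`, or `"rf"`
#'   (independent univariate SSE forests, one per response column).
#' @param ntree,mtry,nodesize,sample_frac,grid_size forest hyperparameters.
#' @param alpha a number (fixed weight), `"grid"`, or `"pareto"`; the
#'   selection variants re-run inside each training fold and may pick a
#'   different alpha per fold.
#' @param seed integer seed driving fold assignment, per-fold forests and
#'   any alpha selection.
#' @param alpha_args optional list of extra arguments for the selection
#'   procedure (e.g. `list(ntree = 30)`).
#' @return an object of class `"cmrf_cv"`: list with `metrics` (per-response
#'   data frame), `predictions` (out-of-fold matrix aligned with `y`),
#'   `folds` (assignment vector), `alphas` (per-fold values used), `k`,
#'   `seed` and the forest parameters.
#' @examples
#' d <- sim_quadratic_example(n = 30, seed = 1)
#' cv <- cross_validate(d$x, d$y, k = 3, criterion = "copula", ntree = 5,
#'                      seed = 1)
#' cv$metrics
#' @export
cross_validate <- function(x, y, k = 5,
                           criterion = c("copula", "mahalanobis", "sse", "rf"),
                           ntree = 150, mtry = 10, nodesize = 5,
                           sample_frac = 1, grid_size = 10, alpha = 1,
                           seed = NULL, alpha_args = list()) {
  criterion <- match.arg(criterion)
  x <- as.matrix(x)
  y <- as.matrix(y)
  n <- nrow(x)
  if (k < 2) stop("'k' must be at least 2")
  if (n < k) stop("more folds than samples; use a smaller k")
  if (is.null(colnames(y))) colnames(y) <- paste0("response_", seq_len(ncol(y)))
  if (!is.null(seed)) set.seed(seed)
  folds <- sample(rep_len(seq_len(k), n))
  fold_seeds <- sample.int(.Machine$integer.max - 1L, k)
  preds <- matrix(NA_real_, n, ncol(y), dimnames = list(rownames(y), colnames(y)))
  alphas <- rep(NA_real_, k)
  for (f in seq_len(k)) {
    test <- folds == f
    xtr <- x[!test, , drop = FALSE]
    ytr <- y[!test, , drop = FALSE]
    a_use <- if (is.numeric(alpha)) alpha else NA_real_
    if (criterion == "copula" && is.character(alpha)) {
      sel <- if (alpha == "grid") {
        do.call(select_alpha_grid,
                c(list(x = xtr, y = ytr, mtry = mtry, nodesize = nodesize,
                       sample_frac = sample_frac, grid_size = grid_size,
                       seed = fold_seeds[f]), alpha_args))
      } else if (alpha == "pareto") {
        do.call(select_alpha_pareto,
                c(list(x = xtr, y = ytr, mtry = mtry, nodesize = nodesize,
                       sample_frac = sample_frac, grid_size = grid_size,
                       seed = fold_seeds[f]), alpha_args))
      } else stop("unknown alpha policy '", alpha, "'")
      a_use <- sel$alpha
    }
    alphas[f] <- a_use
    if (criterion == "rf") {
      for (j in seq_len(ncol(y))) {
        fit <- cmrf(xtr, ytr[, j, drop = FALSE], criterion = "sse",
                    ntree = ntree, mtry = mtry, nodesize = nodesize,
                    sample_frac = sample_frac, seed = fold_seeds[f])
        preds[test, j] <- predict(fit, x[test, , drop = FALSE])
      }
    } else {
      fit <- cmrf(xtr, ytr, criterion = criterion, ntree = ntree,
                  mtry = mtry, nodesize = nodesize,
                  alpha = if (is.na(a_use)) 1 else a_use,
                  sample_frac = sample_frac, grid_size = grid_size,
                  seed = fold_seeds[f])
      preds[test, ] <- predict(fit, x[test, , drop = FALSE])
    }
  }
  structure(
    list(metrics = .metrics_table(y, preds), predictions = preds,
         folds = folds, alphas = alphas, k = k, seed = seed,
         params = list(criterion = criterion, ntree = ntree, mtry = mtry,
                       nodesize = nodesize, sample_frac = sample_frac,
                       grid_size = grid_size, alpha = alpha)),
    class = "cmrf_cv"
  )
}

#' @export
print.cmrf_cv <- function(x, ...) {
  cat(x$k, "-fold cross-validation, ", x$params$criterion,
      " criterion, T = ", x$params$ntree, "\n", sep = "")
  print(x$metrics, row.names = FALSE)
  invisible(x)
}
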