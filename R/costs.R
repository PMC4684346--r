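#' Frozen root-level statistics for a node-splitting criterion
#'
#' Builds the split criterion used throughout one forest: which node cost to
#' apply and the quantities that are computed once from the full training
#' responses and then shared read-only by every node evaluation — the
#' response precision matrix for the Mahalanobis cost, and the root-node
#' variances plus the root empirical copula for the copula cost.
#'
#' The covariance matrix is that of the complete training responses (a
#' per-node covariance would be singular at small nodes); it is inverted
#' directly when well conditioned and otherwise through a ridge of
#' `1e-8 * trace` on the diagonal. Root variances use the population
#' denominator `n`, so a node that preserves the root variance contributes
#' about r times the node size to the normalised-SSE term `D2`.
#'
#' @param y numeric training response matrix (rows = samples).
#' @param kind `"copula"`, `"mahalanobis"` or `"sse"`.
#' @param alpha weight of the normalised-SSE term in the copula cost
#'   `D_C = D1 + alpha * D2`; nonnegative, copula kind only.
#' @param grid_size copula lattice resolution `K` (copula kind only).
#' @param max_grid lattice budget forwarded to [empirical_copula()].
#' @param node_marginals `"rerank"` (default): node copulas re-rank the
#'   responses within the node, making them marginal-free in the spirit of
#'   Sklar's theorem; `"root"`: node copula values are counted on the root
#'   pseudo-observations of the node's rows instead, so a node also pays
#'   for concentrating in a sub-range of the marginals.
#' @return an object of class `"split_criterion"`.
#' @seealso [cost_copula()], [cost_mahalanobis()], [best_split()]
#' @export
split_criterion <- function(y, kind = c("copula", "mahalanobis", "sse"),
                            alpha = 1, grid_size = 10, max_grid = 1e6,
                            node_marginals = c("rerank", "root")) {
  kind <- match.arg(kind)
  node_marginals <- match.arg(node_marginals)
  y <- as.matrix(y)
  n <- nrow(y)
  r <- ncol(y)
  if (n < 2) stop("need at least two training samples")
  if (alpha < 0) stop("'alpha' must be nonnegative")
  sigma2 <- lambda_inv <- root_copula <- NULL
  if (kind == "copula") {
    sigma2 <- colMeans(sweep(y, 2, colMeans(y))^2)
    if (any(sigma2 <= 0))
      stop("constant response column: root variance must be positive ",
           "for the copula criterion")
    root_copula <- empirical_copula(y, grid_size = grid_size,
                                    max_grid = max_grid)
  }
  if (kind == "mahalanobis") {
    lambda <- cov(y)
    lambda_inv <- tryCatch({
      li <- solve(lambda)
      if (!all(is.finite(li))) stop("non-finite inverse")
      li
    }, error = function(e) {
      ridge <- 1e-8 * sum(diag(lambda))
      if (ridge <= 0) ridge <- 1e-8
      solve(lambda + diag(ridge, r))
    })
    lambda_inv <- (lambda_inv + t(lambda_inv)) / 2
  }
  structure(
    list(kind = kind, alpha = alpha, grid_size = grid_size,
         sigma2 = sigma2, lambda_inv = lambda_inv,
         root_copula = root_copula, node_marginals = node_marginals,
         n_root = n, dim = r),
    class = "split_criterion"
  )
}

#' @export
print.split_criterion <- function(x, ...) {
  cat("Split criterion:", x$kind,
      if (x$kind == "copula")
        paste0("(alpha = ", signif(x$alpha, 4), ", K = ", x$grid_size, ")"),
      "\n")
  invisible(x)
}

#' Sum-of-squares node cost
#'
#' The classical regression-tree node cost: the sum of squared deviations of
#' the response(s) from the node mean, columns summed for a matrix input.
#'
#' @param y numeric vector or matrix of node responses.
#' @return a nonnegative scalar; 0 for a constant or single-sample node.
#' @examples
#' cost_sse(c(1, 2, 3))  # 2
#' @export
cost_sse <- function(y) {
  y <- as.matrix(y)
  sum(sweep(y, 2, colMeans(y))^2)
}

#' Mahalanobis node cost
#'
#' Sum over node samples of the squared Mahalanobis distance from the node
#' mean, `sum_i (y_i - mu) Lambda^-1 (y_i - mu)^T`, with the precision
#' matrix `Lambda^-1` frozen from the full training responses (see
#' [split_criterion()]). With a diagonal covariance this reduces to the
#' variance-normalised Euclidean SSE; with one response it is `cost_sse / sigma^2`.
#'
#' @param y numeric matrix of node responses.
#' @param criterion a `"split_criterion"` of kind `"mahalanobis"`.
#' @return a nonnegative scalar.
#' @export
cost_mahalanobis <- function(y, criterion) {
  stopifnot(inherits(criterion, "split_criterion"),
            criterion$kind == "mahalanobis")
  y <- as.matrix(y)
  dev <- sweep(y, 2, colMeans(y))
  sum((dev %*% criterion$lambda_inv) * dev)
}

#' Copula node cost
#'
#' The copula-based node cost `D_C = D1 + alpha * D2` where
#' `D1 = 6 * N_P * Psi` penalises distortion of the training dependence
#' structure (`Psi` is the integrated absolute difference between the node's
#' empirical copula, re-ranked within the node, and the root copula; the
#' factor 6 rescales by the bivariate Frechet gap integral 1/6 so `D1` is at
#' most about `N_P` for a bivariate response) and
#' `D2 = sum_j SSE_j / sigma_j^2` is the per-response SSE normalised by the
#' root-node variances. `D1` is defined as 0 for nodes of fewer than 3
#' samples (their empirical copula is vacuous) and for univariate responses
#' (a 1-D copula carries no dependence information).
#'
#' @param y numeric matrix of node responses.
#' @param criterion a `"split_criterion"` of kind `"copula"`.
#' @return named numeric vector `c(cost, d1, d2)` with
#'   `cost = d1 + alpha * d2`.
#' @export
cost_copula <- function(y, criterion) {
  stopifnot(inherits(criterion, "split_criterion"),
            criterion$kind == "copula")
  y <- as.matrix(y)
  p <- nrow(y)
  d2 <- sum(colSums(sweep(y, 2, colMeans(y))^2) / criterion$sigma2)
  d1 <- 0
  if (ncol(y) >= 2 && p >= 3) {
    root <- criterion$root_copula
    node <- empirical_copula(y, grid_size = criterion$grid_size,
                             eval = root$eval)
    d1 <- 6 * p * copula_distance(node, root)
  }
  c(cost = d1 + criterion$alpha * d2, d1 = d1, d2 = d2)
}

# marshal a split_criterion into the argument list of the C++ search
.crit_cpp_args <- function(criterion) {
  dummy_mat <- matrix(0, 1, 1)
  root_vals <- numeric(1)
  eval_pts <- dummy_mat
  use_lattice <- TRUE
  if (criterion$kind == "copula" && !is.null(criterion$root_copula)) {
    root_vals <- as.numeric(criterion$root_copula$values)
    if (criterion$root_copula$eval == "points") {
      use_lattice <- FALSE
      eval_pts <- criterion$root_copula$eval_points
    }
  }
  list(
    kind = match(criterion$kind, c("sse", "mahalanobis", "copula")) - 1L,
    alpha = if (is.null(criterion$alpha)) 0 else criterion$alpha,
    rootC = root_vals,
    K = as.integer(criterion$grid_size %||% 10L),
    sigma2 = if (is.null(criterion$sigma2)) numeric(1) else criterion$sigma2,
    prec = if (is.null(criterion$lambda_inv)) dummy_mat else criterion$lambda_inv,
    evalPts = eval_pts,
    useLattice = use_lattice
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# pseudo-observation matrix for root-marginal node copulas (internal)
.node_pseudo_arg <- function(criterion, node_pseudo, p) {
  use <- identical(criterion$node_marginals, "root") &&
    criterion$kind == "copula"
  if (use && is.null(node_pseudo))
    stop("criterion uses root marginals: supply 'node_pseudo' (root ",
         "pseudo-observations of the node rows)")
  if (use && nrow(node_pseudo) != p)
    stop("'node_pseudo' must align with the node rows")
  list(mat = if (use) node_pseudo else matrix(0, 1, 1), use = use)
}

#' Exhaustive best-split search at a node
#'
#' Enumerates, for every feature in `features`, a candidate threshold at
#' each observed in-node value of that feature (samples with
#' `x <= threshold` go left), skips partitions with an empty side, and
#' returns the candidate maximising the cost reduction
#' `gain = cost(parent) - cost(left) - cost(right)` under the supplied
#' criterion. Ties resolve to the smallest feature index, then the smallest
#' threshold, making the search deterministic.
#'
#' @param x numeric feature matrix of the node's samples (bootstrap
#'   multiplicities expanded into rows).
#' @param y numeric response matrix aligned with `x`.
#' @param criterion a [split_criterion()].
#' @param features integer vector of candidate feature columns (default all).
#' @param min_child smallest admissible child size (default 1, i.e. children
#'   need only be nonempty; the drug-sensitivity protocol's "minimum leaf
#'   size" reading sets this to the leaf size).
#' @param node_pseudo root pseudo-observations of the node rows; required
#'   only when the criterion uses `node_marginals = "root"`.
#' @return `NULL` when no valid partition exists, otherwise a list with
#'   `feature`, `threshold`, `gain`, `left` / `right` (row indices into the
#'   node), and the parent cost (plus its `d1` / `d2` components for the
#'   copula criterion).
#' @export
best_split <- function(x, y, criterion, features = NULL,
                       min_child = 1L, node_pseudo = NULL) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  if (nrow(x) < 2) return(NULL)
  if (is.null(features)) features <- seq_len(ncol(x))
  features <- sort(unique(as.integer(features)))
  if (any(features < 1 | features > ncol(x))) stop("invalid feature index")
  a <- .crit_cpp_args(criterion)
  nu <- .node_pseudo_arg(criterion, node_pseudo, nrow(x))
  res <- .split_search_cpp(x, y, features - 1L, a$kind, a$alpha, a$rootC,
                           a$K, a$sigma2, a$prec, a$evalPts, a$useLattice,
                           FALSE, as.integer(min_child), nu$mat, nu$use)
  if (!res$found) return(NULL)
  left <- which(x[, res$feature] <= res$threshold)
  list(feature = res$feature, threshold = res$threshold, gain = res$gain,
       left = left, right = setdiff(seq_len(nrow(x)), left),
       parent_cost = res$parent_cost, parent_d1 = res$parent_d1,
       parent_d2 = res$parent_d2)
}

#' All candidate partitions of a node with their cost components
#'
#' Enumerates every (feature, threshold) partition that [best_split()] would
#' consider and reports, for each, the gain and — under the copula
#' criterion — the `(D1, D2)` pair of both children. These per-child pairs
#' are the two-objective points from which the Pareto-frontier procedure
#' for choosing `alpha` is built (see [select_alpha_pareto()]).
#'
#' @inheritParams best_split
#' @return a data frame with columns `feature`, `threshold`, `gain`,
#'   `n_left`, `d1_left`, `d2_left`, `d1_right`, `d2_right` (the d1/d2
#'   columns are zero for non-copula criteria).
#' @export
split_candidates <- function(x, y, criterion, features = NULL,
                             min_child = 1L, node_pseudo = NULL) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  if (is.null(features)) features <- seq_len(ncol(x))
  features <- sort(unique(as.integer(features)))
  a <- .crit_cpp_args(criterion)
  nu <- .node_pseudo_arg(criterion, node_pseudo, nrow(x))
  res <- .split_search_cpp(x, y, features - 1L, a$kind, a$alpha, a$rootC,
                           a$K, a$sigma2, a$prec, a$evalPts, a$useLattice,
                           TRUE, as.integer(min_child), nu$mat, nu$use)
  as.data.frame(res$candidates)
}
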