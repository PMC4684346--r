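#' Copula-based multivariate random forest
#'
#' Fits an ensemble of multivariate regression trees for jointly predicting
#' several real-valued responses from a common feature matrix. Each tree is
#' grown on a bootstrap draw of the training rows; at every node a fresh
#' random subset of `mtry` features is considered and the partition
#' maximising the reduction in the chosen node cost is taken. Three costs
#' are available:
#'
#' * `"sse"` — the classical sum of squared deviations (summed over
#'   response columns); with a single response this is univariate random
#'   forest regression.
#' * `"mahalanobis"` — the covariance-normalised cost
#'   `sum_i (y_i - mu) Lambda^-1 (y_i - mu)^T`, suited to linearly related
#'   responses (the VMRF of the drug-sensitivity literature).
#' * `"copula"` — `D1 + alpha * D2`, where `D1 = 6 N_P Psi` measures how far
#'   the node's empirical copula drifts from the training copula and `D2` is
#'   the variance-normalised SSE; designed to preserve nonlinear dependence
#'   between responses (CMRF).
#'
#' Nodes with fewer than `nodesize` samples become leaves, as do nodes whose
#' best candidate partition no longer reduces the cost (set
#' `allow_negative_gain = TRUE` to keep splitting to `nodesize` regardless).
#' Predictions are convex combinations of training responses through the
#' leaf-membership weight representation (see [predict.cmrf()]).
#'
#' Randomness is reproducible: the seed spawns one substream per tree, so
#' growing a larger forest with the same seed leaves the earlier trees
#' unchanged.
#'
#' @param x numeric feature matrix or data frame, one row per sample.
#' @param y numeric response vector or matrix aligned with `x`.
#' @param criterion node cost, see above.
#' @param ntree number of trees `T` (default 150).
#' @param mtry number of features sampled (without replacement) at each
#'   node (default 10, capped at `ncol(x)`).
#' @param nodesize minimum node size still eligible for splitting
#'   (default 5); smaller nodes become leaves.
#' @param min_bucket smallest admissible child (leaf) size: candidate
#'   partitions leaving a child below this are skipped. Default 1
#'   reproduces the "node smaller than nodesize is not partitioned" rule;
#'   setting `min_bucket = nodesize` reproduces the stricter
#'   "minimum leaf size" reading of the same protocol.
#' @param alpha weight of the normalised-SSE term in the copula cost.
#' @param sample_frac bootstrap fraction: each tree sees
#'   `ceiling(sample_frac * n)` rows drawn with replacement (default 1).
#' @param grid_size copula lattice resolution `K` (default 10).
#' @param seed optional integer seed.
#' @param node_marginals how node copulas treat marginals, see
#'   [split_criterion()].
#' @param allow_negative_gain if `TRUE`, split on the arg-max partition even
#'   when its gain is nonpositive (the copula cost's `D1` can grow in the
#'   children, so gains may be negative for every candidate).
#' @param keep_data store the training matrices in the fit (needed by
#'   `predict`; default `TRUE`).
#' @return an object of class `"cmrf"`: a list with the grown `trees`, the
#'   frozen `criterion`, `params`, and the training data.
#' @examples
#' d <- sim_quadratic_example(n = 40, seed = 1)
#' fit <- cmrf(d$x, d$y, criterion = "copula", ntree = 10, mtry = 10,
#'             seed = 1)
#' head(predict(fit, d$x))
#' variable_importance(fit)
#' @export
cmrf <- function(x, y, criterion = c("copula", "mahalanobis", "sse"),
                 ntree = 150, mtry = 10, nodesize = 5, min_bucket = 1,
                 alpha = 1, sample_frac = 1, grid_size = 10, seed = NULL,
                 node_marginals = c("rerank", "root"),
                 allow_negative_gain = FALSE, keep_data = TRUE) {
  criterion <- match.arg(criterion)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.matrix(y)
  storage.mode(y) <- "double"
  n <- nrow(x)
  if (nrow(y) != n) stop("'x' and 'y' must have the same number of rows")
  if (n < 2) stop("need at least two training samples")
  if (anyNA(y)) stop("'y' contains missing values; apply complete_case_filter() first")
  if (ntree < 1) stop("'ntree' must be at least 1")
  if (sample_frac <= 0 || sample_frac > 1) stop("'sample_frac' must be in (0, 1]")
  mtry <- min(as.integer(mtry), ncol(x))
  if (mtry < 1) stop("'mtry' must be at least 1")
  if (is.null(colnames(x))) colnames(x) <- paste0("feature_", seq_len(ncol(x)))
  if (is.null(colnames(y))) colnames(y) <- paste0("response_", seq_len(ncol(y)))

  crit <- split_criterion(y, kind = criterion, alpha = alpha,
                          grid_size = grid_size,
                          node_marginals = match.arg(node_marginals))
  if (!is.null(seed)) set.seed(seed)
  tree_seeds <- sample.int(.Machine$integer.max - 1L, ntree)
  nboot <- ceiling(sample_frac * n)
  trees <- vector("list", ntree)
  for (t in seq_len(ntree)) {
    set.seed(tree_seeds[t])
    rows <- sample.int(n, nboot, replace = TRUE)
    trees[[t]] <- grow_tree(x, y, rows, crit, mtry, nodesize, min_bucket,
                            allow_negative_gain)
  }
  structure(
    list(trees = trees, criterion = crit,
         params = list(criterion = criterion, ntree = ntree, mtry = mtry,
                       nodesize = nodesize, min_bucket = min_bucket,
                       alpha = alpha,
                       sample_frac = sample_frac, grid_size = grid_size,
                       seed = seed,
                       allow_negative_gain = allow_negative_gain),
         tree_seeds = tree_seeds, n = n,
         feature_names = colnames(x), response_names = colnames(y),
         x = if (keep_data) x else NULL, y = y,
         call = match.call()),
    class = "cmrf"
  )
}

# Grow one tree on the bootstrap multiset `rows` (indices into x/y, with
# multiplicity). Flat representation: parallel vectors over node ids plus a
# list of leaf member multisets, which serialises cleanly to JSON.
grow_tree <- function(x, y, rows, crit, mtry, nodesize, min_bucket,
                      allow_negative_gain) {
  M <- ncol(x)
  feature <- integer(0)
  threshold <- numeric(0)
  left <- integer(0)
  right <- integer(0)
  members <- list()
  a <- .crit_cpp_args(crit)

  use_root_u <- identical(crit$node_marginals, "root") &&
    crit$kind == "copula"
  root_u <- if (use_root_u) crit$root_copula$pseudo_obs else matrix(0, 1, 1)

  recurse <- function(rws) {
    id <- length(feature) + 1L
    feature[id] <<- NA_integer_
    threshold[id] <<- NA_real_
    left[id] <<- NA_integer_
    right[id] <<- NA_integer_
    members[[id]] <<- integer(0)
    if (length(rws) < max(nodesize, 2 * min_bucket)) {
      members[[id]] <<- rws
      return(id)
    }
    feats <- sort(sample.int(M, mtry))
    res <- .split_search_cpp(x[rws, , drop = FALSE], y[rws, , drop = FALSE],
                             feats - 1L, a$kind, a$alpha, a$rootC, a$K,
                             a$sigma2, a$prec, a$evalPts, a$useLattice,
                             FALSE, as.integer(min_bucket),
                             if (use_root_u) root_u[rws, , drop = FALSE]
                             else root_u,
                             use_root_u)
    if (!res$found || (!allow_negative_gain && res$gain <= 0)) {
      members[[id]] <<- rws
      return(id)
    }
    go_left <- x[rws, res$feature] <= res$threshold
    feature[id] <<- as.integer(res$feature)
    threshold[id] <<- res$threshold
    left[id] <<- recurse(rws[go_left])
    right[id] <<- recurse(rws[!go_left])
    id
  }
  recurse(rows)
  list(feature = feature, threshold = threshold, left = left, right = right,
       members = members, bootstrap_rows = rows)
}

# leaf id reached by one test sample
descend <- function(tree, xrow) {
  id <- 1L
  while (!is.na(tree$feature[id])) {
    id <- if (xrow[tree$feature[id]] <= tree$threshold[id])
      tree$left[id] else tree$right[id]
  }
  id
}

#' Per-tree prediction weights over the training rows
#'
#' A single tree predicts a test point as a weighted mean of the training
#' responses: the weight of training row `i` is its multiplicity in the
#' bootstrap leaf containing the test point, divided by the leaf size.
#' Weights are nonnegative and sum to 1; rows out of the tree's bootstrap
#' sample get weight 0.
#'
#' @param object a fitted [cmrf()] forest.
#' @param newx a single feature vector (or one-row matrix).
#' @param tree index of the tree.
#' @return numeric weight vector of length `n` (training rows).
#' @export
tree_weights <- function(object, newx, tree = 1L) {
  stopifnot(inherits(object, "cmrf"))
  tr <- object$trees[[tree]]
  newx <- as.numeric(newx)
  leaf <- descend(tr, newx)
  mem <- tr$members[[leaf]]
  tabulate(mem, nbins = object$n) / length(mem)
}

#' Predict from a copula-based multivariate random forest
#'
#' Averages the per-tree leaf-membership weights over the forest and applies
#' the averaged weights to each training response column; this equals the
#' mean over trees of the per-tree leaf means, and every prediction is a
#' convex combination of training responses.
#'
#' @param object a fitted [cmrf()] forest.
#' @param newdata feature matrix or data frame of test samples; defaults to
#'   the training features.
#' @param type `"response"` for predictions (default) or `"weights"` for the
#'   forest-averaged weight matrix (test rows x training rows).
#' @param ... unused.
#' @return a matrix of predictions (test rows x responses), or the weight
#'   matrix when `type = "weights"`.
#' @export
predict.cmrf <- function(object, newdata = NULL,
                         type = c("response", "weights"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    if (is.null(object$x)) stop("fit stored no training data; supply 'newdata'")
    newdata <- object$x
  }
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$feature_names))
    stop("'newdata' must have ", length(object$feature_names), " columns")
  ntest <- nrow(newdata)
  n <- object$n
  W <- matrix(0, ntest, n)
  ntree <- length(object$trees)
  for (tr in object$trees) {
    for (i in seq_len(ntest)) {
      leaf <- descend(tr, newdata[i, ])
      mem <- tr$members[[leaf]]
      W[i, ] <- W[i, ] + tabulate(mem, nbins = n) / length(mem)
    }
  }
  W <- W / ntree
  if (type == "weights") {
    rownames(W) <- rownames(newdata)
    return(W)
  }
  pred <- W %*% object$y
  colnames(pred) <- object$response_names
  rownames(pred) <- rownames(newdata)
  pred
}

#' Selection-frequency variable importance
#'
#' Counts how many internal nodes across the forest split on each feature
#' and normalises by the total number of splits, so the scores are
#' nonnegative and sum to 1. Features that drive the responses are selected
#' often and score high; under the copula criterion this ranking tracks
#' nonlinear as well as linear response dependence.
#'
#' @param object a fitted [cmrf()] forest.
#' @return named numeric vector of length `M` summing to 1 (all zeros, with
#'   a warning, for a forest of stumps).
#' @export
variable_importance <- function(object) {
  stopifnot(inherits(object, "cmrf"))
  M <- length(object$feature_names)
  counts <- numeric(M)
  for (tr in object$trees) {
    f <- tr$feature[!is.na(tr$feature)]
    if (length(f)) counts <- counts + tabulate(f, nbins = M)
  }
  tot <- sum(counts)
  if (tot == 0) {
    warning("forest contains no splits; importance is identically zero")
    return(setNames(counts, object$feature_names))
  }
  setNames(counts / tot, object$feature_names)
}

#' @export
print.cmrf <- function(x, ...) {
  p <- x$params
  cat("Multivariate random forest (", p$criterion, " node cost)\n", sep = "")
  cat("  trees:", p$ntree, " mtry:", p$mtry, " nodesize:", p$nodesize, "\n")
  if (p$criterion == "copula")
    cat("  alpha:", signif(p$alpha, 4), " copula grid K:", p$grid_size, "\n")
  cat("  training samples:", x$n, " features:", length(x$feature_names),
      " responses:", length(x$response_names), "\n")
  invisible(x)
}

#' @export
summary.cmrf <- function(object, ...) {
  vim <- variable_importance(object)
  splits <- sum(vapply(object$trees,
                       function(tr) sum(!is.na(tr$feature)), integer(1)))
  depth1 <- function(tr) {
    d <- integer(length(tr$feature))
    d[1] <- 1L
    for (id in seq_along(tr$feature)) {
      if (!is.na(tr$feature[id])) {
        d[tr$left[id]] <- d[id] + 1L
        d[tr$right[id]] <- d[id] + 1L
      }
    }
    max(d)
  }
  out <- list(params = object$params, n = object$n,
              n_splits = splits,
              mean_depth = mean(vapply(object$trees, depth1, integer(1))),
              importance = sort(vim, decreasing = TRUE))
  class(out) <- "summary.cmrf"
  out
}

#' @export
print.summary.cmrf <- function(x, ...) {
  cat("Forest of", x$params$ntree, "trees,", x$n_splits, "splits, mean depth",
      round(x$mean_depth, 2), "\n")
  cat("Top features by selection frequency:\n")
  print(round(head(x$importance, 10), 4))
  invisible(x)
}

#' Plot variable importance of a fitted forest
#'
#' @param x a fitted [cmrf()] forest.
#' @param n_features number of top features to show.
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, the plotted importance vector.
#' @export
plot.cmrf <- function(x, n_features = 20, ...) {
  vim <- sort(variable_importance(x), decreasing = TRUE)
  vim <- head(vim, n_features)
  graphics::barplot(rev(vim), horiz = TRUE, las = 1,
                    xlab = "selection frequency", ...)
  invisible(vim)
}

#' @export
fitted.cmrf <- function(object, ...) predict(object)

#' @export
residuals.cmrf <- function(object, ...) object$y - predict(object)

#' Serialise a fitted forest to a self-describing JSON document
#'
#' Writes hyperparameters, training responses, and every tree's bootstrap
#' rows, split nodes and leaf member multisets as portable JSON, so models
#' are diffable in tests and loadable without R-specific binary formats.
#'
#' @param object a fitted [cmrf()] forest.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_cmrf()]
#' @export
write_cmrf <- function(object, path) {
  stopifnot(inherits(object, "cmrf"))
  doc <- list(
    format = "cmrf-model", format_version = 1L,
    params = object$params,
    n = object$n,
    feature_names = object$feature_names,
    response_names = object$response_names,
    y = unname(object$y),
    tree_seeds = object$tree_seeds,
    trees = lapply(object$trees, function(tr) {
      list(bootstrap_rows = tr$bootstrap_rows,
           feature = tr$feature, threshold = tr$threshold,
           left = tr$left, right = tr$right,
           members = tr$members)
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null")
  invisible(path)
}

#' Load a forest serialised by [write_cmrf()]
#'
#' @param path JSON file written by [write_cmrf()].
#' @return a `"cmrf"` object (without the training feature matrix; supply
#'   `newdata` to `predict`).
#' @export
read_cmrf <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format, "cmrf-model"))
    stop("'", path, "' is not a cmrf model file")
  num1 <- function(v, empty) {
    vapply(v, function(e) if (is.null(e)) empty else as.numeric(e),
           numeric(1))
  }
  y <- matrix(unlist(lapply(doc$y, as.numeric)),
              nrow = length(doc$y), byrow = TRUE)
  colnames(y) <- unlist(doc$response_names)
  trees <- lapply(doc$trees, function(tl) {
    list(feature = as.integer(num1(tl$feature, NA_real_)),
         threshold = num1(tl$threshold, NA_real_),
         left = as.integer(num1(tl$left, NA_real_)),
         right = as.integer(num1(tl$right, NA_real_)),
         members = lapply(tl$members, function(m) as.integer(unlist(m))),
         bootstrap_rows = as.integer(unlist(tl$bootstrap_rows)))
  })
  params <- doc$params
  crit <- split_criterion(y, kind = params$criterion,
                          alpha = params$alpha %||% 1,
                          grid_size = params$grid_size %||% 10)
  structure(
    list(trees = trees, criterion = crit, params = params,
         tree_seeds = as.integer(unlist(doc$tree_seeds)), n = doc$n,
         feature_names = unlist(doc$feature_names),
         response_names = unlist(doc$response_names),
         x = NULL, y = y, call = NULL),
    class = "cmrf"
  )
}
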