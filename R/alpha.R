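#' Candidate grids for the copula-cost weight alpha
#'
#' Ten values spanning \[0.1, 10\] by default; logarithmic spacing covers the
#' regimes alpha < 1 (dependence-dominated cost) and alpha > 1
#' (SSE-dominated cost) symmetrically. Linear spacing is available.
#'
#' @param n number of candidates.
#' @param range two-element range.
#' @param spacing `"log"` (default) or `"linear"`.
#' @return numeric vector of candidate alpha values.
#' @export
alpha_grid <- function(n = 10, range = c(0.1, 10),
                       spacing = c("log", "linear")) {
  spacing <- match.arg(spacing)
  if (spacing == "log") exp(seq(log(range[1]), log(range[2]), length.out = n))
  else seq(range[1], range[2], length.out = n)
}

# mean per-response Pearson correlation between predictions and truth;
# zero-variance responses are skipped with a warning
.mean_pearson <- function(y, yhat) {
  r <- ncol(y)
  cors <- numeric(0)
  for (j in seq_len(r)) {
    if (sd(y[, j]) == 0 || sd(yhat[, j]) == 0) {
      warning("response ", j, " has zero variance; skipped in scoring")
      next
    }
    cors <- c(cors, cor(y[, j], yhat[, j]))
  }
  if (!length(cors)) return(NA_real_)
  mean(cors)
}

#' Choose alpha by evaluating a grid of candidates on a secondary split
#'
#' The training data are sub-divided once into secondary training and
#' secondary testing parts; for each candidate alpha a copula-criterion
#' forest is fitted on the secondary training rows (all candidates share the
#' same forest seed, so the comparison is paired) and scored by the mean
#' per-response Pearson correlation on the secondary test rows. The
#' candidate with the highest score wins.
#'
#' @param x,y training features and responses.
#' @param grid candidate alpha values (default [alpha_grid()]).
#' @param split_frac fraction of rows in the secondary training part
#'   (default 0.7).
#' @param ntree,mtry,nodesize,sample_frac,grid_size forest hyperparameters
#'   for the evaluation forests (a lighter `ntree` than the final forest
#'   keeps the search cheap).
#' @param seed integer seed controlling the secondary split and the shared
#'   forest substream.
#' @return an object of class `"alpha_choice"`: list with `alpha` (the
#'   winner), `method = "grid"`, and `scores` (a data frame of every
#'   candidate and its correlation score).
#' @export
select_alpha_grid <- function(x, y, grid = alpha_grid(), split_frac = 0.7,
                              ntree = 50, mtry = 10, nodesize = 5,
                              sample_frac = 1, grid_size = 10, seed = NULL) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  if (!length(grid)) stop("'grid' must be nonempty")
  if (split_frac <= 0 || split_frac >= 1) stop("'split_frac' must be in (0, 1)")
  n <- nrow(x)
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(n, floor(split_frac * n))
  if (length(idx) < 2 * nodesize)
    stop("secondary split leaves fewer than 2 * nodesize training rows; ",
         "increase split_frac or the sample size")
  forest_seed <- sample.int(.Machine$integer.max - 1L, 1)
  scores <- vapply(grid, function(a) {
    fit <- cmrf(x[idx, , drop = FALSE], y[idx, , drop = FALSE],
                criterion = "copula", ntree = ntree, mtry = mtry,
                nodesize = nodesize, alpha = a, sample_frac = sample_frac,
                grid_size = grid_size, seed = forest_seed)
    yhat <- predict(fit, x[-idx, , drop = FALSE])
    .mean_pearson(y[-idx, , drop = FALSE], yhat)
  }, numeric(1))
  best <- which.max(scores)
  structure(
    list(alpha = grid[best], method = "grid",
         scores = data.frame(alpha = grid, score = scores),
         seed = seed),
    class = "alpha_choice"
  )
}

#' @export
print.alpha_choice <- function(x, ...) {
  cat("alpha =", signif(x$alpha, 5), "selected by", x$method, "method\n")
  print(x$scores, row.names = FALSE)
  invisible(x)
}

#' Pareto frontier of candidate split costs
#'
#' Given the `(D1, D2)` pairs of candidate node partitions (both objectives
#' to be minimised), returns the non-dominated points: a point is dominated
#' when another point is at least as good in both coordinates and strictly
#' better in one. Exact duplicates are kept once. The result is sorted by
#' increasing `d1`, along which `d2` is strictly decreasing.
#'
#' @param d1,d2 numeric vectors of the two cost components, or `d1` may be a
#'   matrix / data frame whose first two columns are taken.
#' @return a data frame with columns `d1`, `d2` and `id` (row index of the
#'   point in the input).
#' @export
pareto_frontier <- function(d1, d2 = NULL) {
  if (is.null(d2)) {
    m <- as.matrix(as.data.frame(d1)[, 1:2])
    d1 <- m[, 1]
    d2 <- m[, 2]
  }
  if (!length(d1)) stop("'d1' must be nonempty")
  keep <- !duplicated(cbind(d1, d2))
  id <- which(keep)
  d1 <- d1[keep]
  d2 <- d2[keep]
  ord <- order(d1, d2)
  best <- Inf
  sel <- logical(length(ord))
  for (k in seq_along(ord)) {
    i <- ord[k]
    if (d2[i] < best) {
      sel[k] <- TRUE
      best <- d2[i]
    }
  }
  pick <- ord[sel]
  data.frame(d1 = d1[pick], d2 = d2[pick], id = id[pick])
}

#' Fit straight lines to a Pareto frontier and convert slopes to alphas
#'
#' The frontier in the `(D1, D2)` plane is approximated by two straight
#' lines (one steeper than -1, one shallower), found as the two-segment
#' piecewise-linear least-squares fit of `d2` on `d1` over all breakpoints
#' that leave at least two points per segment; frontiers of two or three
#' points get a single line. Each segment with negative slope `rho` yields
#' a candidate `alpha = -1 / rho`; a steep segment (`|rho| > 1`) gives
#' `alpha < 1` and a shallow one gives `alpha > 1`. Candidates landing in
#' the same bucket are averaged; segments with nonnegative slope yield
#' nothing.
#'
#' @param frontier data frame with columns `d1`, `d2` sorted by `d1`
#'   (as returned by [pareto_frontier()]).
#' @return list with `alpha_gt1` and `alpha_lt1` (each a scalar or `NA`),
#'   `slopes` of the fitted segment(s) and the `breakpoint` index (last
#'   point of the first segment; `NA` for a single-line fit).
#' @export
fit_frontier_alphas <- function(frontier) {
  d1 <- frontier$d1
  d2 <- frontier$d2
  n <- length(d1)
  if (n < 2)
    return(list(alpha_gt1 = NA_real_, alpha_lt1 = NA_real_,
                slopes = numeric(0), breakpoint = NA_integer_))
  slope_fit <- function(i) {
    # least squares of d2 on d1; NA slope for a vertical segment
    xm <- mean(d1[i]); ym <- mean(d2[i])
    sxx <- sum((d1[i] - xm)^2)
    if (sxx == 0) return(c(NA_real_, Inf))
    b <- sum((d1[i] - xm) * (d2[i] - ym)) / sxx
    rss <- sum((d2[i] - ym - b * (d1[i] - xm))^2)
    c(b, rss)
  }
  if (n < 4) {
    sf <- slope_fit(seq_len(n))
    slopes <- sf[1]
    bp <- NA_integer_
  } else {
    best_rss <- Inf
    slopes <- c(NA_real_, NA_real_)
    bp <- NA_integer_
    for (k in 2:(n - 2)) {
      s1 <- slope_fit(1:k)
      s2 <- slope_fit((k + 1):n)
      rss <- s1[2] + s2[2]
      if (rss < best_rss) {
        best_rss <- rss
        slopes <- c(s1[1], s2[1])
        bp <- k
      }
    }
  }
  alphas <- -1 / slopes[!is.na(slopes) & slopes < 0]
  gt1 <- alphas[alphas > 1]
  lt1 <- alphas[alphas <= 1]
  list(alpha_gt1 = if (length(gt1)) mean(gt1) else NA_real_,
       alpha_lt1 = if (length(lt1)) mean(lt1) else NA_real_,
       slopes = slopes, breakpoint = bp)
}

#' Choose alpha from Pareto frontiers of first-split candidates
#'
#' Grows `n_trees_probe` probe trees (bootstrap draw plus random feature
#' subset, exactly as in forest training) and, for each, enumerates every
#' candidate first split, collects the `(D1, D2)` pairs of both children,
#' extracts the Pareto frontier of each child's point cloud and fits the
#' two-line approximation of [fit_frontier_alphas()]. The resulting alphas
#' are pooled across trees into an alpha > 1 group and an alpha < 1 group;
#' the two pooled means are then scored against each other by the secondary
#' split procedure of [select_alpha_grid()] and the better one is returned.
#' `D1` and `D2` do not depend on alpha, so the probe needs no prior weight.
#'
#' @inheritParams select_alpha_grid
#' @param n_trees_probe number of probe trees (default 100).
#' @param ntree_eval trees per forest in the final head-to-head scoring.
#' @return an `"alpha_choice"` with `method = "pareto"`, the pooled means,
#'   the per-tree alpha values, and the head-to-head `scores` table. When
#'   both groups are empty (for example `D1` identically zero for a
#'   univariate response) the choice falls back to `alpha = 1` with a
#'   warning.
#' @export
select_alpha_pareto <- function(x, y, n_trees_probe = 100, mtry = 10,
                                nodesize = 5, sample_frac = 1,
                                grid_size = 10, split_frac = 0.7,
                                ntree_eval = 50, seed = NULL) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  if (n_trees_probe < 1) stop("'n_trees_probe' must be at least 1")
  n <- nrow(x)
  M <- ncol(x)
  mtry <- min(mtry, M)
  crit <- split_criterion(y, kind = "copula", alpha = 1,
                          grid_size = grid_size)
  if (!is.null(seed)) set.seed(seed)
  probe_seeds <- sample.int(.Machine$integer.max - 1L, n_trees_probe)
  eval_seed <- sample.int(.Machine$integer.max - 1L, 1)
  nboot <- ceiling(sample_frac * n)
  alphas <- numeric(0)
  for (t in seq_len(n_trees_probe)) {
    set.seed(probe_seeds[t])
    rows <- sample.int(n, nboot, replace = TRUE)
    feats <- sort(sample.int(M, mtry))
    cand <- split_candidates(x[rows, , drop = FALSE],
                             y[rows, , drop = FALSE], crit, feats)
    if (!nrow(cand)) next
    for (side in c("left", "right")) {
      # drop children too small to carry dependence information: their
      # empirical copula is vacuous (D1 = 0 by convention), which would
      # collapse the frontier onto a degenerate corner point
      size <- if (side == "left") cand$n_left else nboot - cand$n_left
      use <- size >= 3
      if (sum(use) < 2) next
      fr <- pareto_frontier(cand[[paste0("d1_", side)]][use],
                            cand[[paste0("d2_", side)]][use])
      fa <- fit_frontier_alphas(fr)
      alphas <- c(alphas, fa$alpha_gt1, fa$alpha_lt1)
    }
  }
  alphas <- alphas[!is.na(alphas)]
  gt1 <- alphas[alphas > 1]
  lt1 <- alphas[alphas <= 1]
  if (!length(gt1) && !length(lt1)) {
    warning("no usable frontier slopes (D1 may be identically zero); ",
            "falling back to alpha = 1")
    return(structure(
      list(alpha = 1, method = "pareto",
           scores = data.frame(alpha = 1, score = NA_real_),
           mean_gt1 = NA_real_, mean_lt1 = NA_real_, alphas = alphas,
           seed = seed),
      class = "alpha_choice"))
  }
  cand_means <- c(if (length(lt1)) mean(lt1), if (length(gt1)) mean(gt1))
  pick <- select_alpha_grid(x, y, grid = cand_means,
                            split_frac = split_frac, ntree = ntree_eval,
                            mtry = mtry, nodesize = nodesize,
                            sample_frac = sample_frac,
                            grid_size = grid_size, seed = eval_seed)
  structure(
    list(alpha = pick$alpha, method = "pareto", scores = pick$scores,
         mean_gt1 = if (length(gt1)) mean(gt1) else NA_real_,
         mean_lt1 = if (length(lt1)) mean(lt1) else NA_real_,
         alphas = alphas, seed = seed),
    class = "alpha_choice"
  )
}
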