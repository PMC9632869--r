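#' Default parameters of the missing-value dissimilarity
#'
#' Per-feature scales are set to twice the observed variance and the
#' missing-value penalty to `a = 1`. The factor two comes from the
#' identity \eqn{E[(X - Y)^2] = 2V} for i.i.d. X, Y with variance V: with
#' this scale a typical observed squared difference contributes about
#' 1/2, and a missing coordinate (contribution `a = 1`) acts as a maximal
#' disagreement.
#'
#' @param m Numeric matrix, observations in rows, `NA` for missing.
#' @param penalty Missing-value penalty `a`, in `[0.25, 1]`. Values below
#'   1/4 break the triangle inequality of the neighbour metric.
#' @param var_type `"population"` (divide by n, the default) or
#'   `"sample"` (divide by n - 1) variance for the scales.
#' @return List with `scales` (length `ncol(m)`) and `penalty`.
#' @export
default_metric_params <- function(m, penalty = 1, var_type = c("population", "sample")) {
  var_type <- match.arg(var_type)
  m <- as.matrix(m)
  if (penalty < 0.25 || penalty > 1)
    stop("penalty must lie in [0.25, 1]")
  n_obs <- colSums(!is.na(m))
  if (any(n_obs < 2))
    stop("features with fewer than 2 observed values: ",
         paste(which(n_obs < 2), collapse = ", "))
  v <- apply(m, 2, stats::var, na.rm = TRUE)  # sample variance
  if (var_type == "population") v <- v * (n_obs - 1) / n_obs
  if (any(v <= 0))
    stop("constant features have zero variance: ",
         paste(which(v <= 0), collapse = ", "))
  list(scales = 2 * v, penalty = penalty)
}

#' Missing-value dissimilarity between two feature vectors
#'
#' \eqn{D(x, y) = \sum_i f(x_i, y_i)} with
#' \eqn{f = (x_i - y_i)^2 / (s_i + (x_i - y_i)^2)} when both coordinates
#' are observed and the penalty `a` when either is missing. Each
#' coordinate contributes at most 1 (strictly below 1 when observed), so
#' D is bounded by the number of features.
#'
#' @param x,y Numeric vectors with `NA` for missing.
#' @param params As from [default_metric_params()].
#' @return Scalar in `[0, n]`.
#' @export
pair_dissimilarity <- function(x, y, params) {
  if (length(x) != length(y) || length(x) != length(params$scales))
    stop("x, y and params must cover the same features")
  miss <- is.na(x) | is.na(y)
  d2 <- (x[!miss] - y[!miss])^2
  sum(d2 / (params$scales[!miss] + d2)) + params$penalty * sum(miss)
}

#' Neighbour metric: square root of the dissimilarity
#'
#' The quantity used for nearest-neighbour queries. Per coordinate,
#' \eqn{\sqrt{f}} is a concave increasing transform of the absolute
#' difference and hence a metric; the root of the coordinate sum is then
#' an L2-type composition. The missing-value case requires
#' `penalty >= 1/4`: the supremum observed-coordinate distance is 1 and
#' the detour through a missing value has length \eqn{2\sqrt{a}}.
#'
#' @inheritParams pair_dissimilarity
#' @return Non-negative scalar.
#' @export
tree_metric <- function(x, y, params) {
  sqrt(pair_dissimilarity(x, y, params))
}

#' Pairwise neighbour metric matrix
#'
#' @param m Numeric matrix with `NA` for missing.
#' @param params As from [default_metric_params()].
#' @param squared Return the raw dissimilarity D instead of its root.
#' @return Symmetric `nrow(m) x nrow(m)` matrix.
#' @export
dissimilarity_matrix <- function(m, params, squared = FALSE) {
  m <- as.matrix(m)
  d <- cpp_pairwise_dissimilarity(m, params$scales, params$penalty)
  if (squared) d else sqrt(d)
}

#' Search for the smallest penalty preserving the triangle inequality
#'
#' For each candidate penalty, hunts for triples (x, y, z) violating the
#' triangle inequality of [tree_metric()], combining randomized triples
#' (random values, random missingness) with the adversarial family of a
#' widely separated observed pair bridged by an all-missing intermediate
#' — the family whose detour length \eqn{2\sqrt{a}} against the direct
#' distance (approaching 1) pins the threshold at `a = 1/4`.
#'
#' @param a_grid Ascending penalties to test.
#' @param n_random Random triples per penalty.
#' @param seed Integer seed.
#' @param n_features Dimension of the random vectors.
#' @return List with `threshold` (smallest penalty with no violation
#'   found), and `violations`, a logical vector along `a_grid`.
#' @export
triangle_threshold_search <- function(a_grid, n_random = 1e4, seed = 1,
                                      n_features = 3) {
  if (length(a_grid) == 0) stop("a_grid must be non-empty")
  if (is.unsorted(a_grid)) stop("a_grid must be ascending")
  set.seed(seed)
  p <- n_features
  scales <- rep(1, p)
  # Random triples: heavy-tailed values so large separations occur, and
  # independent missingness per coordinate.
  draw <- function(n) {
    v <- matrix(stats::rcauchy(n * p), n, p)
    v[matrix(stats::runif(n * p) < 0.35, n, p)] <- NA
    v
  }
  x <- draw(n_random); y <- draw(n_random); z <- draw(n_random)
  f_sum <- function(a_mat, b_mat, penalty) {
    miss <- is.na(a_mat) | is.na(b_mat)
    d2 <- (a_mat - b_mat)^2
    contrib <- d2 / (matrix(scales, nrow(a_mat), p, byrow = TRUE) + d2)
    contrib[miss] <- penalty
    rowSums(contrib)
  }
  # Adversarial family: observed pair at +-c, all-missing intermediate.
  adv <- function(penalty) {
    c_vals <- 10^(1:8)
    dxz <- sqrt(p * c_vals^2 * 4 / (1 + c_vals^2 * 4))
    dxy <- sqrt(p * penalty)
    any(dxz > 2 * dxy + 1e-12)
  }
  violated <- vapply(a_grid, function(a) {
    dxy <- sqrt(f_sum(x, y, a)); dyz <- sqrt(f_sum(y, z, a))
    dxz <- sqrt(f_sum(x, z, a))
    rnd <- any(dxz > dxy + dyz + 1e-12) ||
      any(dxy > dxz + dyz + 1e-12) ||
      any(dyz > dxy + dxz + 1e-12)
    rnd || adv(a)
  }, logical(1))
  ok <- which(!violated)
  if (length(ok) == 0) stop("every candidate penalty admitted a violation")
  list(threshold = a_grid[min(ok)], violations = violated, a_grid = a_grid)
}

#' k-nearest-neighbour matrix completion
#'
#' Each missing entry is replaced by the mean of that feature over the
#' `k` nearest neighbours (by [tree_metric()], i.e. with missing
#' coordinates contributing the penalty) that observe the feature,
#' falling back to the feature's global observed mean when none of the
#' `k` neighbours observes it. Observed entries are never modified.
#' Neighbours are drawn from the full observation pool.
#'
#' @param m Numeric matrix with `NA` for missing.
#' @param k Number of neighbours (default 10).
#' @param params Metric parameters; default [default_metric_params()] of `m`.
#' @param weighted Use inverse-distance weights over the contributing
#'   neighbours instead of an unweighted mean.
#' @return Completed numeric matrix.
#' @export
knn_impute <- function(m, k = 10, params = NULL, weighted = FALSE) {
  m <- as.matrix(m)
  n <- nrow(m)
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < nrow(m)")
  if (!anyNA(m)) return(m)
  if (is.null(params)) params <- default_metric_params(m)
  d <- dissimilarity_matrix(m, params)
  feat_means <- colMeans(m, na.rm = TRUE)
  out <- m
  rows_missing <- which(rowSums(is.na(m)) > 0)
  for (i in rows_missing) {
    ord <- order(d[i, -i])
    nb <- seq_len(n)[-i][ord[seq_len(k)]]
    for (j in which(is.na(m[i, ]))) {
      vals <- m[nb, j]
      obs <- !is.na(vals)
      if (!any(obs)) {
        out[i, j] <- feat_means[j]
      } else if (weighted) {
        w <- 1 / pmax(d[i, nb[obs]], 1e-12)
        out[i, j] <- sum(w * vals[obs]) / sum(w)
      } else {
        out[i, j] <- mean(vals[obs])
      }
    }
  }
  out
}

#' Per-feature mean imputation (baseline)
#'
#' @param m Numeric matrix with `NA` for missing.
#' @return Completed matrix with missing entries set to the feature's
#'   observed mean.
#' @export
mean_impute <- function(m) {
  m <- as.matrix(m)
  if (!anyNA(m)) return(m)
  feat_means <- colMeans(m, na.rm = TRUE)
  idx <- which(is.na(m), arr.ind = TRUE)
  m[idx] <- feat_means[idx[, 2]]
  m
}

#' Root sum of squared errors over originally missing entries
#'
#' @param completed,truth Matrices of identical shape.
#' @param mask Logical matrix: TRUE where the entry was missing before
#'   completion.
#' @return Non-negative scalar.
#' @export
rsse <- function(completed, truth, mask) {
  if (!all(dim(completed) == dim(truth)) || !all(dim(completed) == dim(mask)))
    stop("shapes disagree")
  sqrt(sum((completed[mask] - truth[mask])^2))
}

#' Drop features with excessive missingness
#'
#' @param m Numeric matrix with `NA` for missing.
#' @param threshold Features whose missing fraction strictly exceeds this
#'   are removed (default 0.9).
#' @return Matrix with offending columns dropped; attribute `dropped`
#'   records their indices.
#' @export
drop_high_missing <- function(m, threshold = 0.9) {
  m <- as.matrix(m)
  frac <- colMeans(is.na(m))
  drop <- which(frac > threshold)
  out <- if (length(drop)) m[, -drop, drop = FALSE] else m
  attr(out, "dropped") <- drop
  out
}
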