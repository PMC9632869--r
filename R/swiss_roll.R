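#' Swiss-roll matrix-completion benchmark
#'
#' Generates a 3-D Swiss roll, embeds it into higher dimensions with a
#' random orthonormal map (Gram-Schmidt, here via QR, of a uniformly
#' random matrix), removes a fraction of the entries uniformly at
#' random, and compares mean imputation against kNN completion under the
#' missing-value metric by RSSE on the masked entries.
#'
#' @param n_points Number of points on the roll.
#' @param dims Embedding dimensions to test (each >= 3).
#' @param missing_frac Fraction of entries removed, in (0, 1).
#' @param seed Integer seed.
#' @param k Neighbours for [knn_impute()].
#' @return Data frame with columns `dim`, `rsse_mean`, `rsse_knn`,
#'   `masked_frac`.
#' @export
swiss_roll_benchmark <- function(n_points = 2000, dims = c(3, 10, 100),
                                 missing_frac = 0.7, seed = 1, k = 10) {
  if (missing_frac <= 0 || missing_frac >= 1)
    stop("missing_frac must lie in (0, 1)")
  if (any(dims < 3)) stop("embedding dimensions must be >= 3")
  set.seed(seed)
  x3 <- swiss_roll_points(n_points)
  out <- lapply(dims, function(d) {
    q <- random_orthonormal_map(3, d)
    x <- x3 %*% t(q)                     # n x d, columns interdependent
    mask <- matrix(stats::runif(length(x)) < missing_frac, nrow(x), ncol(x))
    # keep every feature estimable
    for (j in which(colSums(!mask) < 2)) mask[1:2, j] <- FALSE
    xm <- x
    xm[mask] <- NA
    params <- default_metric_params(xm)
    data.frame(
      dim = d,
      rsse_mean = rsse(mean_impute(xm), x, mask),
      rsse_knn = rsse(knn_impute(xm, k = k, params = params), x, mask),
      masked_frac = mean(mask)
    )
  })
  do.call(rbind, out)
}

# Classic Swiss roll: angle t on [1.5*pi, 4.5*pi], height uniform.
swiss_roll_points <- function(n) {
  t <- stats::runif(n, 1.5 * pi, 4.5 * pi)
  h <- stats::runif(n, 0, 21)
  cbind(t * cos(t), h, t * sin(t))
}

#' Random orthonormal embedding map
#'
#' Orthonormalizes a `d_out x d_in` matrix of uniform draws; the result
#' satisfies `t(Q) %*% Q = I` so the embedding is an isometry.
#'
#' @param d_in Source dimension.
#' @param d_out Target dimension, `>= d_in`.
#' @return `d_out x d_in` matrix with orthonormal columns.
#' @export
random_orthonormal_map <- function(d_in, d_out) {
  if (d_out < d_in) stop("d_out must be >= d_in")
  a <- matrix(stats::runif(d_out * d_in, -1, 1), d_out, d_in)
  qr.Q(qr(a))[, seq_len(d_in), drop = FALSE]
}
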