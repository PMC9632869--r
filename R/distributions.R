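#' Fixed support grid for categorical return distributions
#'
#' Constructs the atom grid \eqn{z_1 < \dots < z_N} on which all categorical
#' return distributions live. The default is 51 equally spaced atoms on
#' \eqn{[-100, 100]}, matching terminal rewards of +100 (recovery) and
#' -100 (death).
#'
#' @param v_min Smallest atom (return units).
#' @param v_max Largest atom.
#' @param n_atoms Number of atoms, at least 2.
#' @return An object of class `support_grid` with elements `atoms`,
#'   `v_min`, `v_max`, `n_atoms`.
#' @examples
#' g <- make_support(-100, 100, 51)
#' diff(g$atoms)[1]  # 4
#' @export
make_support <- function(v_min = -100, v_max = 100, n_atoms = 51) {
  if (!is.numeric(v_min) || !is.numeric(v_max) || v_min >= v_max)
    stop("v_min must be strictly smaller than v_max")
  if (n_atoms < 2) stop("n_atoms must be at least 2")
  support_grid(seq(v_min, v_max, length.out = n_atoms))
}

#' Support grid from explicit atoms
#'
#' @param atoms Strictly increasing numeric vector of length >= 2.
#' @return A `support_grid`.
#' @export
support_grid <- function(atoms) {
  atoms <- as.numeric(atoms)
  if (length(atoms) < 2) stop("need at least 2 atoms")
  if (any(diff(atoms) <= 0)) stop("atoms must be strictly increasing")
  structure(
    list(atoms = atoms, v_min = atoms[1], v_max = atoms[length(atoms)],
         n_atoms = length(atoms)),
    class = "support_grid"
  )
}

#' @export
print.support_grid <- function(x, ...) {
  cat(sprintf("<support_grid> %d atoms on [%g, %g]\n",
              x$n_atoms, x$v_min, x$v_max))
  invisible(x)
}

is_support_grid <- function(x) inherits(x, "support_grid")

same_grid <- function(a, b) {
  is_support_grid(a) && is_support_grid(b) &&
    a$n_atoms == b$n_atoms && all(a$atoms == b$atoms)
}

#' Categorical projection onto a fixed support
#'
#' Projects a finitely supported distribution (point masses at arbitrary
#' `locations`) onto the grid atoms: every location is clipped into
#' \eqn{[v_{\min}, v_{\max}]} and its mass split between the two bracketing
#' atoms in proportion to proximity. This is the standard categorical
#' projection operator \eqn{\Pi_C}; it conserves total mass exactly and
#' preserves the mean for locations inside the support range.
#'
#' @param grid A `support_grid`.
#' @param locations Numeric vector of point-mass locations.
#' @param masses Probabilities attached to the locations; must be
#'   non-negative and sum to 1 (tolerance 1e-6).
#' @return Numeric probability vector of length `grid$n_atoms`.
#' @examples
#' g <- support_grid(c(0, 1, 2))
#' project_categorical(g, 0.5, 1)  # 0.5, 0.5, 0
#' @export
project_categorical <- function(grid, locations, masses) {
  stopifnot(is_support_grid(grid))
  if (length(locations) != length(masses))
    stop("locations and masses must have the same length")
  if (any(masses < -1e-12))
    stop("masses must be non-negative")
  if (abs(sum(masses) - 1) > 1e-6)
    stop("masses must sum to 1")
  w <- projection_weights(grid, locations)
  p <- as.numeric(crossprod(w, masses))
  p
}

# Rows = locations, columns = atoms: row i is the projection of a unit
# point mass at locations[i]. Shared by project_categorical and the
# precomputed shift operator used inside the training sweeps.
projection_weights <- function(grid, locations) {
  z <- grid$atoms
  n <- grid$n_atoms
  loc <- pmin(pmax(locations, grid$v_min), grid$v_max)
  lo <- findInterval(loc, z, rightmost.closed = TRUE)
  lo <- pmin(pmax(lo, 1L), n - 1L)
  hi <- lo + 1L
  frac <- (loc - z[lo]) / (z[hi] - z[lo])  # in [0, 1]
  w <- matrix(0, nrow = length(loc), ncol = n)
  idx <- seq_along(loc)
  w[cbind(idx, lo)] <- 1 - frac
  w[cbind(idx, hi)] <- w[cbind(idx, hi)] + frac
  w
}

#' Expectation of a categorical distribution
#'
#' @param pmf Probability (or signed weight) vector aligned to `grid`.
#' @param grid A `support_grid`.
#' @return \eqn{\sum_i p_i z_i}.
#' @export
expectation <- function(pmf, grid) {
  stopifnot(is_support_grid(grid))
  if (length(pmf) != grid$n_atoms)
    stop("pmf length does not match the grid")
  sum(pmf * grid$atoms)
}

#' Cramér distance between two categorical distributions
#'
#' The L2 distance between cumulative distribution functions, evaluated
#' with the general non-uniform-spacing sum
#' \eqn{(\sum_{i=1}^{N-1} (z_{i+1}-z_i)(F_a(z_i)-F_b(z_i))^2)^{1/2}}.
#' A metric on distributions over a fixed grid.
#'
#' @param a,b Weight vectors aligned to `grid`.
#' @param grid A `support_grid`.
#' @return Non-negative scalar.
#' @export
cramer_distance <- function(a, b, grid) {
  stopifnot(is_support_grid(grid))
  n <- grid$n_atoms
  if (length(a) != n || length(b) != n)
    stop("pmf length does not match the grid")
  fa <- cumsum(a)
  fb <- cumsum(b)
  sqrt(sum(diff(grid$atoms) * (fa[-n] - fb[-n])^2))
}

#' Return-distribution table
#'
#' Holds one categorical distribution per valid (state, action) pair on a
#' shared support grid. Probabilities are stored as a dense matrix with
#' one row per pair; `index[s, a]` gives the row for state `s` and action
#' `a` (NA for invalid pairs). During speedy training rows may carry
#' signed weights summing to 1; [readout_pmfs()] clips and renormalizes.
#'
#' @param n_states Number of non-terminal states.
#' @param valid Logical matrix `n_states x n_actions` of valid actions.
#' @param grid A `support_grid`.
#' @param probs Optional matrix of initial weights (rows = valid pairs in
#'   row-major state order). Defaults to a point mass at the atom nearest 0.
#' @return An object of class `return_table`.
#' @export
return_table <- function(n_states, valid, grid, probs = NULL) {
  stopifnot(is_support_grid(grid), is.matrix(valid), nrow(valid) == n_states)
  index <- matrix(NA_integer_, n_states, ncol(valid))
  sa <- which(valid, arr.ind = TRUE)
  sa <- sa[order(sa[, 1], sa[, 2]), , drop = FALSE]
  index[sa] <- seq_len(nrow(sa))
  if (is.null(probs)) {
    probs <- matrix(0, nrow(sa), grid$n_atoms)
    probs[, which.min(abs(grid$atoms))] <- 1
  }
  stopifnot(nrow(probs) == nrow(sa), ncol(probs) == grid$n_atoms)
  structure(
    list(grid = grid, states = sa[, 1], actions = sa[, 2],
         index = index, probs = probs),
    class = "return_table"
  )
}

#' @export
print.return_table <- function(x, ...) {
  cat(sprintf("<return_table> %d (state, action) pairs, %d atoms on [%g, %g]\n",
              nrow(x$probs), x$grid$n_atoms, x$grid$v_min, x$grid$v_max))
  invisible(x)
}

#' Look up one distribution in a return table
#'
#' @param eta A `return_table`.
#' @param state,action Integer ids.
#' @return Weight vector over the grid atoms.
#' @export
rt_pmf <- function(eta, state, action) {
  i <- eta$index[state, action]
  if (is.na(i)) stop(sprintf("(%d, %d) is not a valid pair", state, action))
  eta$probs[i, ]
}

#' Expectations of every distribution in a return table
#'
#' @param eta A `return_table`.
#' @return Matrix `n_states x n_actions` of expected returns, NA at
#'   invalid pairs.
#' @export
rt_expectations <- function(eta) {
  ev <- as.numeric(eta$probs %*% eta$grid$atoms)
  out <- matrix(NA_real_, nrow(eta$index), ncol(eta$index))
  out[cbind(eta$states, eta$actions)] <- ev
  out
}

# Row-wise cumulative sums (CDFs when columns are atoms). Matrix
# multiplication keeps the shape stable for single-column inputs, where
# apply() would collapse dimensions.
row_cdfs <- function(p) {
  n <- ncol(p)
  u <- matrix(0, n, n)
  u[upper.tri(u, diag = TRUE)] <- 1
  p %*% u
}

#' Maximum Cramér distance between two return tables
#'
#' \eqn{\bar\ell_2(\eta, \xi)}: the supremum over (state, action) pairs of
#' the per-pair Cramér distance. Used as the training stop criterion.
#'
#' @param a,b `return_table`s over the same key set and grid.
#' @return Non-negative scalar.
#' @export
sup_cramer <- function(a, b) {
  stopifnot(inherits(a, "return_table"), inherits(b, "return_table"))
  if (!same_grid(a$grid, b$grid)) stop("grids differ")
  if (nrow(a$probs) != nrow(b$probs) ||
      !all(a$states == b$states) || !all(a$actions == b$actions))
    stop("key sets differ")
  sup_cramer_rows(a$probs, b$probs, a$grid)
}

sup_cramer_rows <- function(pa, pb, grid) {
  n <- grid$n_atoms
  fdiff <- row_cdfs(pa - pb)[, -n, drop = FALSE]
  dz <- diff(grid$atoms)
  sqrt(max(as.numeric(fdiff^2 %*% dz)))
}

#' Clip-renormalize signed weights into valid PMFs
#'
#' Training with the speedy combination can leave small negative weights;
#' at readout these are clipped to zero and each row renormalized. The
#' total clipped mass is reported for diagnostics.
#'
#' @param eta A `return_table`.
#' @return A `return_table` whose rows are valid PMFs, with attribute
#'   `clipped_mass` (largest negative mass removed from any row).
#' @export
readout_pmfs <- function(eta) {
  p <- eta$probs
  neg <- pmin(p, 0)
  clipped <- max(-rowSums(neg), 0)
  p <- pmax(p, 0)
  p <- p / rowSums(p)
  eta$probs <- p
  attr(eta, "clipped_mass") <- clipped
  eta
}
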