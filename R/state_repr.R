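#' Standardize a completed feature matrix
#'
#' Centers and scales every feature to zero mean and unit standard
#' deviation (population convention, matching the metric-scale choice).
#' Constant features become zero columns with a warning.
#'
#' @param m Completed numeric matrix (no missing entries).
#' @param params Optional list with `mean` and `sd` from a previous call
#'   (to map new data into an existing standardized space).
#' @return List with `x` (standardized matrix) and `params`.
#' @export
standardize <- function(m, params = NULL) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("standardize requires a completed matrix")
  if (is.null(params)) {
    mu <- colMeans(m)
    sdv <- sqrt(colMeans(sweep(m, 2, mu)^2))   # population sd
    if (any(sdv == 0)) {
      warning("constant features standardized to zero: ",
              paste(which(sdv == 0), collapse = ", "))
    }
    params <- list(mean = mu, sd = sdv)
  }
  sdv <- ifelse(params$sd > 0, params$sd, 1)
  x <- sweep(sweep(m, 2, params$mean), 2, sdv, "/")
  x[, params$sd == 0] <- 0
  list(x = x, params = params)
}

#' Fit a family of k-means state representations
#'
#' Runs standard k-means once per (K, restart) combination, each with
#' its own recorded seed, producing `length(k_grid) * n_restarts`
#' candidate discretizations.
#'
#' @param x Standardized feature matrix.
#' @param k_grid Cluster counts (each >= 2; values above `nrow(x)` are
#'   skipped with a warning).
#' @param n_restarts Independent fits per K.
#' @param seed Master seed; candidate seeds are derived from it.
#' @param iter_max k-means iteration cap.
#' @return List of `representation` objects (fields `centers`, `k`,
#'   `seed`).
#' @export
fit_candidates <- function(x, k_grid, n_restarts = 50, seed = 1,
                           iter_max = 50) {
  stopifnot(all(k_grid >= 2))
  usable <- k_grid[k_grid <= nrow(x)]
  if (length(usable) < length(k_grid))
    warning("skipping cluster counts exceeding the number of observations")
  out <- list()
  i <- 0L
  for (k in usable) {
    for (r in seq_len(n_restarts)) {
      i <- i + 1L
      cand_seed <- (seed * 1000L + i) %% .Machine$integer.max
      set.seed(cand_seed)
      out[[i]] <- fit_kmeans_rep(x, k, cand_seed, iter_max)
    }
  }
  out
}

# k-means robust to degenerate (noise-free) inputs: when the data hold
# at most k distinct rows, those rows already are the exact centers.
fit_kmeans_rep <- function(x, k, cand_seed, iter_max = 50) {
  ux <- unique(x)
  centers <- if (nrow(ux) <= k) {
    ux
  } else {
    stats::kmeans(x, centers = k, iter.max = iter_max, nstart = 1)$centers
  }
  structure(list(centers = centers, k = nrow(centers), seed = cand_seed),
            class = "representation")
}

#' @export
print.representation <- function(x, ...) {
  cat(sprintf("<representation> K = %d, %d features, seed %d\n",
              x$k, ncol(x$centers), x$seed))
  invisible(x)
}

#' Map feature rows to discrete states
#'
#' Nearest cluster center in standardized space (Euclidean); ties go to
#' the lowest center index. Idempotent under re-assignment.
#'
#' @param x Standardized feature matrix.
#' @param rep A `representation`.
#' @return Integer state ids in `1..rep$k`.
#' @export
assign_states <- function(x, rep) {
  x <- as.matrix(x)
  cen <- rep$centers
  if (ncol(x) != ncol(cen)) stop("feature dimension mismatch")
  # squared distances via the expansion |x|^2 - 2 x.c + |c|^2
  d2 <- outer(rowSums(x^2), rep(1, nrow(cen))) - 2 * x %*% t(cen) +
    outer(rep(1, nrow(x)), rowSums(cen^2))
  max.col(-d2, ties.method = "first")
}

#' Empirical clinician policy from discretized trajectories
#'
#' Action probabilities proportional to observed counts per state.
#' States never visited get `NA` rows.
#'
#' @param traj Trajectory data frame with `state` and `action`.
#' @param n_states Number of states.
#' @param n_actions Size of the action grid.
#' @return Policy matrix `n_states x n_actions`.
#' @export
extract_policy <- function(traj, n_states, n_actions = 25) {
  if (nrow(traj) == 0) stop("empty trajectory table")
  cnt <- matrix(tabulate((traj$action - 1L) * n_states + traj$state,
                         nbins = n_states * n_actions),
                nrow = n_states)
  tot <- rowSums(cnt)
  pol <- cnt / ifelse(tot > 0, tot, 1)
  pol[tot == 0, ] <- NA_real_
  pol
}

#' Coverage of one value function by another
#'
#' The fraction of states whose values agree to within `threshold`
#' (default 15 on the [-100, 100] return scale) between two evaluations.
#'
#' @param v1,v2 State-value vectors over the same states (`NA`s in
#'   either are excluded).
#' @param threshold Agreement margin.
#' @return Fraction in `[0, 1]`.
#' @export
coverage <- function(v1, v2, threshold = 15) {
  if (length(v1) != length(v2)) stop("value vectors differ in length")
  keep <- !is.na(v1) & !is.na(v2)
  if (!any(keep)) stop("no states shared by both value functions")
  mean(abs(v1[keep] - v2[keep]) < threshold)
}

#' Select a state representation by the coverage heuristic
#'
#' For every candidate clustering: split patients into two halves,
#' discretize both halves, extract the clinician policy from the first,
#' evaluate that policy by dynamic programming on each half's empirical
#' MDP, and score the candidate by the coverage of the two value
#' functions (restricted to states visited in both halves). The
#' candidate with the highest coverage wins; ties break to smaller K,
#' then smaller candidate seed.
#'
#' @param x Standardized feature matrix, rows aligned with `traj`.
#' @param traj Trajectory data frame (`patient_id`, `t`, `action`,
#'   `outcome`; `next_state` is re-derived per candidate).
#' @param candidates List of `representation`s from [fit_candidates()].
#' @param gamma Discount for policy evaluation.
#' @param threshold Coverage margin (default 15).
#' @param n_actions Action-grid size.
#' @param seed Seed for the patient split (shared by all candidates).
#' @return List with `report` (data frame `k`, `seed`, `coverage`) and
#'   `selected` (the winning `representation`).
#' @export
select_representation <- function(x, traj, candidates, gamma = 0.99,
                                  threshold = 15, n_actions = 25, seed = 1) {
  if (length(candidates) == 0) stop("no candidates")
  set.seed(seed)
  ids <- unique(traj$patient_id)
  half1 <- sample(ids, floor(length(ids) / 2))
  in1 <- traj$patient_id %in% half1
  if (!any(in1) || all(in1)) stop("a half has no episodes")
  scores <- vapply(candidates, function(cand) {
    candidate_coverage(x, traj, cand, half1_ids = half1, gamma = gamma,
                       threshold = threshold, n_actions = n_actions)
  }, numeric(1))
  k_vals <- vapply(candidates, `[[`, numeric(1), "k")
  seeds <- vapply(candidates, `[[`, numeric(1), "seed")
  ord <- order(-scores, k_vals, seeds)
  report <- data.frame(k = k_vals, seed = seeds, coverage = scores)[ord, ]
  rownames(report) <- NULL
  list(report = report, selected = candidates[[ord[1]]])
}

#' Coverage score of one candidate representation
#'
#' The inner step of [select_representation()] with an explicit patient
#' split: discretize both halves under the candidate, extract the
#' clinician policy from the first half, evaluate it by dynamic
#' programming on each half's empirical MDP, and return the coverage of
#' the two value functions over states visited in both halves.
#'
#' @inheritParams select_representation
#' @param rep A `representation`.
#' @param half1_ids Patient ids forming the first half.
#' @return Coverage fraction in `[0, 1]` (`NA` if the halves share no
#'   states).
#' @export
candidate_coverage <- function(x, traj, rep, half1_ids, gamma = 0.99,
                               threshold = 15, n_actions = 25) {
  in1 <- traj$patient_id %in% half1_ids
  if (!any(in1) || all(in1)) stop("a half has no episodes")
  st <- assign_states(x, rep)
  t1 <- discretize_trajectories(traj[in1, , drop = FALSE], st[in1], rep$k)
  t2 <- discretize_trajectories(traj[!in1, , drop = FALSE], st[!in1], rep$k)
  m1 <- build_empirical_mdp(t1, rep$k, n_actions)
  m2 <- build_empirical_mdp(t2, rep$k, n_actions)
  pol <- extract_policy(t1, rep$k, n_actions)
  v1 <- dp_policy_evaluation(m1, pol, gamma = gamma)
  v2 <- dp_policy_evaluation(m2, pol, gamma = gamma)
  shared <- rowSums(m1$valid) > 0 & rowSums(m2$valid) > 0
  if (!any(shared)) return(NA_real_)
  coverage(v1[shared], v2[shared], threshold)
}

#' Rewrite trajectories in a candidate's discrete state space
#'
#' Replaces `state` with the candidate assignment and re-derives
#' `next_state` within each episode; the final transition of an episode
#' points to the absorbing outcome matching its label (censored episodes
#' keep a self-loop-free truncation: their last row's successor is the
#' assigned state of the following hour, which does not exist, so the
#' row is dropped).
#'
#' @param traj Trajectory rows (one episode segment per patient, ordered
#'   by `t`).
#' @param states Assigned state ids aligned with `traj` rows.
#' @param n_states Number of states in the representation.
#' @return Trajectory data frame in the discrete space.
#' @export
discretize_trajectories <- function(traj, states, n_states) {
  ord <- order(traj$patient_id, traj$t)
  traj <- traj[ord, , drop = FALSE]
  states <- states[ord]
  n <- nrow(traj)
  last <- c(traj$patient_id[-1] != traj$patient_id[-n], TRUE)
  nxt <- integer(n)
  nxt[!last] <- states[c(FALSE, !last[-n])]
  out <- data.frame(patient_id = traj$patient_id, t = traj$t,
                    state = states, action = traj$action,
                    next_state = nxt, outcome = traj$outcome)
  term <- ifelse(traj$outcome == "recovered", n_states + 1L,
                 ifelse(traj$outcome == "died", n_states + 2L, NA_integer_))
  out$next_state[last] <- term[last]
  out[!(last & is.na(out$next_state)), , drop = FALSE]  # drop censored tails
}
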