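#' Tabular MDP with absorbing recovery/death outcomes
#'
#' Internal constructor shared by the empirical simulator and the
#' synthetic ground truth. Non-terminal states are `1..n_states`; the two
#' absorbing outcomes are coded `n_states + 1` (recovered, terminal
#' reward +100) and `n_states + 2` (died, terminal reward -100). Rewards
#' attach to the transition into an absorbing state and are zero
#' elsewhere, so a length-L recovery episode has discounted return
#' `100 * gamma^(L-1)`.
#'
#' @param probs Array `n_states x n_actions x (n_states + 2)`; rows of
#'   valid (state, action) pairs sum to 1.
#' @param valid Logical `n_states x n_actions` matrix of valid actions.
#' @param init Initial-state distribution over non-terminal states.
#' @param counts Optional transition counts of the same shape as `probs`.
#' @return An object of class `mdp_model`.
#' @export
mdp_model <- function(probs, valid, init, counts = NULL) {
  k <- dim(probs)[1]
  n_actions <- dim(probs)[2]
  stopifnot(dim(probs)[3] == k + 2, all(dim(valid) == c(k, n_actions)),
            length(init) == k)
  rs <- apply(probs, c(1, 2), sum)
  if (any(abs(rs[valid] - 1) > 1e-9))
    stop("transition rows of valid pairs must sum to 1")
  if (any(valid) == FALSE) stop("at least one valid pair required")
  init <- init / sum(init)
  m <- structure(
    list(n_states = k, n_actions = n_actions, probs = probs, valid = valid,
         init = init, counts = counts,
         recovered_id = k + 1L, died_id = k + 2L),
    class = "mdp_model"
  )
  m$trans_cum <- flat_cum_probs(m)
  m
}

#' @export
print.mdp_model <- function(x, ...) {
  cat(sprintf("<mdp_model> %d states, %d actions, %d valid pairs\n",
              x$n_states, x$n_actions, sum(x$valid)))
  invisible(x)
}

# Flattened cumulative transition matrix, row (a - 1) * K + s.
flat_cum_probs <- function(mdp) {
  k <- mdp$n_states
  pm <- matrix(mdp$probs, nrow = k * mdp$n_actions)
  row_cdfs(pm)
}

pair_row <- function(mdp, state, action) (action - 1L) * mdp$n_states + state

#' Estimate an empirical MDP from discretized trajectories
#'
#' Accumulates transition counts per (state, action, next state), with
#' the final transition of each episode directed into the absorbing
#' outcome matching its label (`"recovered"` or `"died"`; censored
#' episodes keep their last observed non-terminal transition, if any).
#' Valid actions are those observed at least once in a state; the
#' initial-state distribution is proportional to episode-start counts.
#'
#' @param traj Data frame with columns `patient_id`, `t`, `state`,
#'   `action`, `next_state` (terminal codes `n_states + 1` / `+ 2`
#'   allowed), and `outcome`.
#' @param n_states Number of non-terminal states.
#' @param n_actions Size of the action grid (default 25 = 5 x 5 doses).
#' @return An `mdp_model` carrying counts.
#' @export
build_empirical_mdp <- function(traj, n_states, n_actions = 25) {
  if (nrow(traj) == 0) stop("empty trajectory table")
  need <- c("patient_id", "t", "state", "action", "next_state")
  if (!all(need %in% names(traj))) stop("missing trajectory columns")
  k <- as.integer(n_states)
  if (any(traj$state > k) || any(traj$next_state > k + 2))
    stop("state ids exceed n_states")
  li <- (traj$next_state - 1L) * k * n_actions +
    (traj$action - 1L) * k + traj$state
  cnt <- array(tabulate(li, nbins = k * n_actions * (k + 2)),
               dim = c(k, n_actions, k + 2))
  tot <- apply(cnt, c(1, 2), sum)
  valid <- tot > 0
  if (!any(valid)) stop("no observed transitions")
  probs <- cnt / ifelse(array(tot, dim(cnt)) > 0, array(tot, dim(cnt)), 1)
  # episode starts: first row per patient
  first <- !duplicated(traj$patient_id)
  init <- tabulate(traj$state[first], nbins = k)
  mdp_model(probs, valid, init, counts = cnt)
}

#' Sample an initial state
#'
#' @param mdp An `mdp_model`.
#' @return List with `state` and its `valid_actions`.
#' @export
mdp_reset <- function(mdp) {
  s <- sample.int(mdp$n_states, 1, prob = mdp$init)
  list(state = s, valid_actions = which(mdp$valid[s, ]))
}

#' Advance the simulator by one transition
#'
#' @param mdp An `mdp_model`.
#' @param state Current non-terminal state.
#' @param action Action id; must be valid in `state`.
#' @return List with `next_state`, `reward` (+100 entering recovery,
#'   -100 entering death, 0 otherwise), `done`, and `valid_actions` of
#'   the successor (empty when terminal).
#' @export
mdp_step <- function(mdp, state, action) {
  if (state < 1 || state > mdp$n_states) stop("state out of range")
  if (action < 1 || action > mdp$n_actions || !mdp$valid[state, action])
    stop(sprintf("action %d invalid in state %d; valid: %s", action, state,
                 paste(which(mdp$valid[state, ]), collapse = " ")))
  nxt <- sample.int(mdp$n_states + 2L, 1, prob = mdp$probs[state, action, ])
  reward <- if (nxt == mdp$recovered_id) 100 else if (nxt == mdp$died_id) -100 else 0
  done <- nxt > mdp$n_states
  va <- if (done) integer(0) else which(mdp$valid[nxt, ])
  list(next_state = nxt, reward = reward, done = done, valid_actions = va)
}

# Sample one index per row of a cumulative-probability matrix.
sample_rows <- function(cum_rows, u) {
  max.col(cum_rows >= u, ties.method = "first")
}

# Policy as matrix K x n_actions (stochastic) or integer vector length K
# (deterministic). Returns cumulative matrix + accessor closure.
policy_cum <- function(policy, mdp) {
  if (is.matrix(policy)) {
    stopifnot(nrow(policy) == mdp$n_states, ncol(policy) == mdp$n_actions)
    p <- policy
    p[is.na(p)] <- 0
    p[!mdp$valid] <- 0          # never roll an action the MDP cannot take
    row_cdfs(p)
  } else {
    NULL
  }
}

#' Batch episode rollout
#'
#' Simulates `n_episodes` episodes under a policy, stepping all live
#' episodes synchronously (vectorized over episodes). Episodes end on
#' absorption, at the horizon cap (censored), or on entering a state
#' with no usable action (also censored).
#'
#' @param mdp An `mdp_model`.
#' @param policy Stochastic policy matrix (`n_states x n_actions`, rows
#'   summing to 1 over valid actions) or a deterministic integer vector.
#' @param n_episodes Number of episodes.
#' @param h_max Horizon cap (default 500).
#' @param gamma Discount used for the reported returns.
#' @param record Also return the per-transition table (used by the
#'   synthetic-cohort sampler).
#' @param init_states Optional fixed initial states (recycled).
#' @return List with `episodes` (data frame: `patient_id`, `length`,
#'   `outcome`, `return_discounted`) and, if requested, `transitions`.
#' @export
rollout_batch <- function(mdp, policy, n_episodes, h_max = 500, gamma = 0.99,
                          record = FALSE, init_states = NULL) {
  k <- mdp$n_states
  pc <- policy_cum(policy, mdp)
  deterministic <- is.null(pc)
  if (deterministic) stopifnot(length(policy) == k)
  state <- if (is.null(init_states)) {
    sample.int(k, n_episodes, replace = TRUE, prob = mdp$init)
  } else {
    rep_len(init_states, n_episodes)
  }
  alive <- rep(TRUE, n_episodes)
  len <- integer(n_episodes)
  outcome <- rep("censored", n_episodes)
  ret <- numeric(n_episodes)
  rec <- if (record) vector("list", h_max) else NULL
  for (t in seq_len(h_max)) {
    idx <- which(alive)
    if (length(idx) == 0) break
    s <- state[idx]
    # states with no usable action end the episode as censored
    if (deterministic) {
      a <- policy[s]
      bad <- is.na(a) | !mdp$valid[cbind(s, a)]
    } else {
      rows <- pc[s, , drop = FALSE]
      tot <- rows[, ncol(rows)]
      bad <- tot <= 0
      a <- rep(NA_integer_, length(s))
      if (any(!bad)) {
        u <- stats::runif(sum(!bad)) * tot[!bad]
        a[!bad] <- sample_rows(rows[!bad, , drop = FALSE], u)
      }
    }
    if (any(bad)) {
      alive[idx[bad]] <- FALSE
      idx <- idx[!bad]; s <- s[!bad]; a <- a[!bad]
      if (length(idx) == 0) next
    }
    nxt <- sample_rows(mdp$trans_cum[pair_row(mdp, s, a), , drop = FALSE],
                       stats::runif(length(idx)))
    len[idx] <- len[idx] + 1L
    if (record)
      rec[[t]] <- data.frame(patient_id = idx, t = len[idx], state = s,
                             action = a, next_state = nxt)
    recov <- nxt == mdp$recovered_id
    died <- nxt == mdp$died_id
    done <- recov | died
    ret[idx[recov]] <- 100 * gamma^(len[idx[recov]] - 1)
    ret[idx[died]] <- -100 * gamma^(len[idx[died]] - 1)
    outcome[idx[recov]] <- "recovered"
    outcome[idx[died]] <- "died"
    alive[idx[done]] <- FALSE
    state[idx[!done]] <- nxt[!done]
  }
  episodes <- data.frame(patient_id = seq_len(n_episodes), length = len,
                         outcome = outcome, return_discounted = ret)
  out <- list(episodes = episodes)
  if (record) {
    tr <- do.call(rbind, rec[!vapply(rec, is.null, logical(1))])
    tr <- tr[order(tr$patient_id, tr$t), , drop = FALSE]
    tr$outcome <- episodes$outcome[tr$patient_id]
    rownames(tr) <- NULL
    out$transitions <- tr
  }
  out
}

#' Roll out a single episode
#'
#' @inheritParams rollout_batch
#' @return List with `states`, `actions`, `rewards`, `outcome`,
#'   `length`, `return_discounted`.
#' @export
sample_episode <- function(mdp, policy, h_max = 500, gamma = 0.99) {
  s <- mdp_reset(mdp)$state
  states <- integer(0); actions <- integer(0); rewards <- numeric(0)
  outcome <- "censored"
  for (t in seq_len(h_max)) {
    if (is.matrix(policy)) {
      pr <- policy[s, ]
      pr[is.na(pr) | !mdp$valid[s, ]] <- 0
      if (sum(pr) <= 0) break
      a <- sample.int(mdp$n_actions, 1, prob = pr)
    } else {
      a <- policy[s]
      if (is.na(a) || !mdp$valid[s, a]) break
    }
    st <- mdp_step(mdp, s, a)
    states <- c(states, s); actions <- c(actions, a)
    rewards <- c(rewards, st$reward)
    if (st$done) {
      outcome <- if (st$next_state == mdp$recovered_id) "recovered" else "died"
      break
    }
    s <- st$next_state
  }
  l <- length(states)
  list(states = states, actions = actions, rewards = rewards,
       outcome = outcome, length = l,
       return_discounted = if (l) sum(gamma^(seq_len(l) - 1) * rewards) else 0)
}

#' Split trajectories into train and test by patient
#'
#' @param traj Trajectory data frame with `patient_id`.
#' @param train_frac Fraction of patients assigned to training (default 0.8).
#' @return List with data frames `train` and `test`.
#' @export
split_patients <- function(traj, train_frac = 0.8) {
  ids <- unique(traj$patient_id)
  n_train <- max(1, round(train_frac * length(ids)))
  tr_ids <- sample(ids, n_train)
  list(train = traj[traj$patient_id %in% tr_ids, , drop = FALSE],
       test = traj[!traj$patient_id %in% tr_ids, , drop = FALSE])
}

#' Dynamic-programming policy evaluation
#'
#' Iterates the Bellman expectation backup
#' \eqn{v(x) = \sum_a \pi(a|x) \sum_{x'} p(x'|x,a) (r(x') + \gamma v(x'))}
#' until the sup-norm change drops below `tol`. Policy rows are
#' renormalized over the MDP's valid actions; states whose policy row has
#' no mass on any valid action fall back to uniform over valid actions,
#' and states with no valid action get value 0 (they censor).
#'
#' @param mdp An `mdp_model`.
#' @param policy Stochastic policy matrix or deterministic vector.
#' @param gamma Discount factor.
#' @param tol Sup-norm convergence tolerance.
#' @param max_iter Iteration cap; non-convergence is an error.
#' @return Numeric state-value vector of length `n_states`.
#' @export
dp_policy_evaluation <- function(mdp, policy, gamma = 0.99, tol = 1e-8,
                                 max_iter = 100000) {
  k <- mdp$n_states
  pol <- normalize_policy(policy, mdp)
  pm <- matrix(mdp$probs, nrow = k * mdp$n_actions)  # row (a-1)*K + s
  v <- numeric(k)
  for (i in seq_len(max_iter)) {
    target <- c(gamma * v, 100, -100)
    q <- matrix(pm %*% target, nrow = k)             # K x n_actions
    v_new <- rowSums(pol * q)
    if (max(abs(v_new - v)) < tol) return(v_new)
    v <- v_new
  }
  stop(sprintf("policy evaluation did not converge in %d iterations (last delta %.3g)",
               max_iter, max(abs(v_new - v))))
}

# Policy matrix renormalized over valid actions; uniform fallback.
normalize_policy <- function(policy, mdp) {
  k <- mdp$n_states
  if (!is.matrix(policy)) {
    m <- matrix(0, k, mdp$n_actions)
    ok <- !is.na(policy) & policy >= 1
    m[cbind(which(ok), policy[ok])] <- 1
    policy <- m
  }
  pol <- policy
  pol[is.na(pol)] <- 0
  pol[!mdp$valid] <- 0
  rs <- rowSums(pol)
  fallback <- rs <= 0 & rowSums(mdp$valid) > 0
  pol[fallback, ] <- mdp$valid[fallback, , drop = FALSE] /
    rowSums(mdp$valid[fallback, , drop = FALSE])
  rs <- rowSums(pol)
  pol[rs > 0, ] <- pol[rs > 0, , drop = FALSE] / rs[rs > 0]
  pol
}

#' Exact value iteration (expected-value oracle)
#'
#' Classical value iteration on the tabular model:
#' \eqn{q(x,a) = \sum_{x'} p(x'|x,a)(r(x') + \gamma v(x'))},
#' \eqn{v(x) = \max_{a \in A(x)} q(x,a)}. Serves as the independent
#' expected-value route against which the distributional learners are
#' checked.
#'
#' @param mdp An `mdp_model`.
#' @param gamma Discount factor.
#' @param tol Sup-norm tolerance.
#' @param max_iter Iteration cap.
#' @return List with `v`, `q` (NA at invalid pairs), and the greedy
#'   `policy` (ties to the lowest action index; NA where no valid action).
#' @export
value_iteration <- function(mdp, gamma = 0.99, tol = 1e-10, max_iter = 100000) {
  k <- mdp$n_states
  pm <- matrix(mdp$probs, nrow = k * mdp$n_actions)
  v <- numeric(k)
  has_action <- rowSums(mdp$valid) > 0
  for (i in seq_len(max_iter)) {
    q <- matrix(pm %*% c(gamma * v, 100, -100), nrow = k)
    q[!mdp$valid] <- NA
    v_new <- ifelse(has_action, apply(q, 1, max, na.rm = TRUE), 0)
    if (max(abs(v_new - v)) < tol) {
      pol <- apply(q, 1, function(r) if (all(is.na(r))) NA_integer_ else which.max(r))
      return(list(v = v_new, q = q, policy = as.integer(pol)))
    }
    v <- v_new
  }
  stop("value iteration did not converge")
}
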