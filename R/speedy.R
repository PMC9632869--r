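#' Training configuration for categorical distributional learning
#'
#' Defaults follow the tabular ICU setup: 51 equally spaced atoms on
#' `[-100, 100]`, discount 0.99, at most 1000 synchronous sweeps,
#' sup-Cramér stop threshold 0.05, and learning rate
#' \eqn{\alpha_k = 1/(k+1)}.
#'
#' @param gamma Discount factor in (0, 1].
#' @param v_min,v_max Support range.
#' @param n_atoms Number of atoms.
#' @param max_iter Maximum sweeps T.
#' @param delta Sup-Cramér stop threshold (control only).
#' @param seed Integer seed for the per-sweep transition samples.
#' @return A `train_config` list (includes the `support_grid`).
#' @export
train_config <- function(gamma = 0.99, v_min = -100, v_max = 100,
                         n_atoms = 51, max_iter = 1000, delta = 0.05,
                         seed = 1) {
  stopifnot(gamma > 0, gamma <= 1, delta >= 0, max_iter >= 1)
  structure(
    list(gamma = gamma, grid = make_support(v_min, v_max, n_atoms),
         max_iter = max_iter, delta = delta, seed = seed),
    class = "train_config"
  )
}

#' Greedy policy of a return table
#'
#' Per state, the valid action maximizing the expected return; ties go
#' to the lowest action index.
#'
#' @param eta A `return_table`.
#' @return Integer action vector (NA for states without valid actions).
#' @export
greedy_policy <- function(eta) {
  ev <- rt_expectations(eta)
  apply(ev, 1, function(r) {
    if (all(is.na(r))) NA_integer_ else which.max(r)
  })
}

#' One distributional Bellman backup for a sampled transition
#'
#' Shifts and scales the successor distribution by `r + gamma * z` and
#' projects it back onto the grid — applied to both the current and the
#' previous return table with the *same* sampled transition and the same
#' successor action (the pairing the speedy combination requires). A
#' terminal successor contributes the point mass at the terminal reward.
#'
#' @param eta_k,eta_km1 Current and previous `return_table`s.
#' @param x_next Sampled successor state (terminal codes allowed).
#' @param reward Sampled reward.
#' @param a_next Successor action (ignored for terminal successors).
#' @param gamma Discount factor.
#' @param terminal Is the successor absorbing?
#' @return List with projected weight vectors `t_k` and `t_km1`.
#' @export
bellman_backup_pair <- function(eta_k, eta_km1, x_next, reward, a_next,
                                gamma, terminal = FALSE) {
  grid <- eta_k$grid
  if (!same_grid(grid, eta_km1$grid)) stop("grids differ")
  if (terminal) {
    t_r <- project_categorical(grid, reward, 1)
    return(list(t_k = t_r, t_km1 = t_r))
  }
  locs <- reward + gamma * grid$atoms
  w <- projection_weights(grid, locs)
  list(t_k = as.numeric(crossprod(w, rt_pmf(eta_k, x_next, a_next))),
       t_km1 = as.numeric(crossprod(w, rt_pmf(eta_km1, x_next, a_next))))
}

# Shared synchronous training engine.
#
# rule: "speedy"  -> eta_{k+1} = (1-a_k) eta_k + a_k [k P T eta_k - (k-1) P T eta_{k-1}]
#       "plain"   -> eta_{k+1} = (1-a_k) eta_k + a_k  P T eta_k
# mode: "control" (greedy successor action, early stop at delta) or
#       "evaluation" (successor action sampled from a fixed policy, no
#       early stop).
run_categorical <- function(env, config, rule = c("speedy", "plain"),
                            mode = c("control", "evaluation"),
                            policy = NULL) {
  rule <- match.arg(rule)
  mode <- match.arg(mode)
  stopifnot(inherits(env, "mdp_model"), inherits(config, "train_config"))
  grid <- config$grid
  gamma <- config$gamma
  k_states <- env$n_states
  set.seed(config$seed)

  eta <- return_table(k_states, env$valid, grid)
  p_k <- eta$probs
  p_km1 <- p_k
  n_pairs <- nrow(p_k)
  pair_rows <- pair_row(env, eta$states, eta$actions)

  shift_op <- projection_weights(grid, gamma * grid$atoms)  # r = 0 targets
  t_recovered <- projection_weights(grid, 100)[1, ]
  t_died <- projection_weights(grid, -100)[1, ]
  t_censor <- projection_weights(grid, 0)[1, ]              # dead-end states

  pol_norm <- if (mode == "evaluation") {
    if (is.null(policy)) stop("evaluation mode needs a policy")
    normalize_policy(policy, env)
  } else NULL
  pol_cum <- if (!is.null(pol_norm)) row_cdfs(pol_norm) else NULL

  trace <- numeric(config$max_iter)
  iters <- config$max_iter
  row_sum_err <- 0
  min_weight <- 0
  for (k in seq_len(config$max_iter) - 1L) {
    alpha <- 1 / (k + 1)
    # successor action choice per state
    a_next_by_state <- if (mode == "control") {
      ev <- as.numeric(p_k %*% grid$atoms)
      evm <- matrix(NA_real_, k_states, env$n_actions)
      evm[cbind(eta$states, eta$actions)] <- ev
      apply(evm, 1, function(r) if (all(is.na(r))) NA_integer_ else which.max(r))
    } else {
      sample_rows(pol_cum, stats::runif(k_states))  # one draw per state/sweep
    }
    # one sampled transition per (x, a), shared by both Bellman targets
    x_next <- sample_rows(env$trans_cum[pair_rows, , drop = FALSE],
                          stats::runif(n_pairs))
    target_rows <- rep(NA_integer_, n_pairs)
    nonterm <- x_next <= k_states
    if (any(nonterm))
      target_rows[nonterm] <- eta$index[cbind(x_next[nonterm],
                                              a_next_by_state[x_next[nonterm]])]
    t_k <- matrix(0, n_pairs, grid$n_atoms)
    t_km1 <- t_k
    ok <- !is.na(target_rows)
    if (any(ok)) {
      t_k[ok, ] <- p_k[target_rows[ok], , drop = FALSE] %*% shift_op
      t_km1[ok, ] <- p_km1[target_rows[ok], , drop = FALSE] %*% shift_op
    }
    dead_end <- nonterm & !ok   # successor has no valid action: return 0
    if (any(dead_end)) {
      t_k[dead_end, ] <- matrix(t_censor, sum(dead_end), grid$n_atoms, byrow = TRUE)
      t_km1[dead_end, ] <- t_k[dead_end, , drop = FALSE]
    }
    if (any(x_next == env$recovered_id)) {
      rows <- x_next == env$recovered_id
      t_k[rows, ] <- matrix(t_recovered, sum(rows), grid$n_atoms, byrow = TRUE)
      t_km1[rows, ] <- t_k[rows, , drop = FALSE]
    }
    if (any(x_next == env$died_id)) {
      rows <- x_next == env$died_id
      t_k[rows, ] <- matrix(t_died, sum(rows), grid$n_atoms, byrow = TRUE)
      t_km1[rows, ] <- t_k[rows, , drop = FALSE]
    }
    p_new <- if (rule == "speedy") {
      (1 - alpha) * p_k + alpha * (k * t_k - (k - 1) * t_km1)
    } else {
      (1 - alpha) * p_k + alpha * t_k
    }
    if (any(!is.finite(p_new))) stop("non-finite weights during training")
    row_sum_err <- max(row_sum_err, abs(rowSums(p_new) - 1))
    min_weight <- min(min_weight, p_new)
    delta_k <- sup_cramer_rows(p_new, p_k, grid)
    trace[k + 1L] <- delta_k
    p_km1 <- p_k
    p_k <- p_new
    if (mode == "control" && delta_k <= config$delta) {
      iters <- k + 1L
      break
    }
  }
  eta$probs <- p_k
  eta_out <- readout_pmfs(eta)
  pol <- greedy_policy(eta_out)
  list(eta = eta_out, policy = pol,
       diagnostics = list(iterations = iters,
                          sup_cramer_trace = trace[seq_len(iters)],
                          clipped_mass = attr(eta_out, "clipped_mass"),
                          max_row_sum_err = row_sum_err,
                          min_weight = min_weight))
}

#' Synchronous speedy categorical policy control
#'
#' Per sweep k, for every valid (state, action) pair: sample one
#' transition, form both Bellman targets (against the current and the
#' previous return table, sharing the sample and the greedy successor
#' action), combine them as
#' \eqn{D_k = k \Pi_C T \eta_k - (k-1) \Pi_C T \eta_{k-1}} and update
#' \eqn{\eta_{k+1} = (1-\alpha_k)\eta_k + \alpha_k D_k} with
#' \eqn{\alpha_k = 1/(k+1)}. Stops when the sup-Cramér change drops to
#' `config$delta` or after `config$max_iter` sweeps. The extrapolated
#' combination can carry transient negative weights; rows always sum to
#' 1, and the returned table is clip-renormalized to valid PMFs.
#'
#' @param env An `mdp_model`.
#' @param config A `train_config`.
#' @return List with `eta` (the return table), `policy` (greedy,
#'   deterministic), and `diagnostics` (iterations, sup-Cramér trace,
#'   clipped mass at readout).
#' @export
speedy_control <- function(env, config = train_config()) {
  run_categorical(env, config, rule = "speedy", mode = "control")
}

#' Speedy categorical policy evaluation
#'
#' Same engine as [speedy_control()] but the successor action is drawn
#' from the fixed policy instead of being greedy, and the loop never
#' breaks early.
#'
#' @param env An `mdp_model`.
#' @param policy Stochastic policy matrix or deterministic vector.
#' @param config A `train_config`.
#' @return As [speedy_control()] (the returned `policy` is the greedy
#'   readout, for reference only).
#' @export
speedy_policy_evaluation <- function(env, policy, config = train_config()) {
  run_categorical(env, config, rule = "speedy", mode = "evaluation",
                  policy = policy)
}

#' Plain categorical Q-learning (baseline)
#'
#' The unaccelerated update
#' \eqn{\eta_{k+1} = (1-\alpha_k)\eta_k + \alpha_k \Pi_C T \eta_k};
#' shares fixed points with the speedy rule and serves as its speed
#' baseline.
#'
#' @inheritParams speedy_control
#' @return As [speedy_control()].
#' @export
categorical_q_control <- function(env, config = train_config()) {
  run_categorical(env, config, rule = "plain", mode = "control")
}
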