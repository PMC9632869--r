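# Shared fixtures and independent oracles. Everything here is built in
# code at test time; no stored data.

# Deterministic (or slightly slippery) chain: states 1..L, one action,
# state s -> s+1, state L -> recovered. slip = self-loop probability.
make_chain_mdp <- function(L, slip = 0) {
  probs <- array(0, dim = c(L, 1, L + 2))
  for (s in seq_len(L - 1)) {
    probs[s, 1, s + 1] <- 1 - slip
    probs[s, 1, s] <- slip
  }
  probs[L, 1, L + 1] <- 1 - slip
  probs[L, 1, L] <- slip
  mdp_model(probs, matrix(TRUE, L, 1), c(1, rep(0, L - 1)))
}

# One state, one action: recovery with probability p, death otherwise.
make_two_point_mdp <- function(p) {
  probs <- array(0, dim = c(1, 1, 3))
  probs[1, 1, 2] <- p
  probs[1, 1, 3] <- 1 - p
  mdp_model(probs, matrix(TRUE, 1, 1), 1)
}

# Random MDP whose actions genuinely differ in value: per state the
# recovery and death hazards are a permutation of well-separated
# levels, so optimal actions are identifiable at finite sampling.
make_suite_mdp <- function(seed, k = 10, n_actions = 3) {
  set.seed(seed)
  probs <- array(0, dim = c(k, n_actions, k + 2))
  for (s in seq_len(k)) {
    h_rec <- sample(c(0.05, 0.16, 0.30), n_actions)
    h_die <- sample(c(0.00, 0.04, 0.08), n_actions)
    for (a in seq_len(n_actions)) {
      w <- stats::rexp(k)
      w <- w / sum(w) * (1 - h_rec[a] - h_die[a])
      probs[s, a, ] <- c(w, h_rec[a], h_die[a])
    }
  }
  mdp_model(probs, matrix(TRUE, k, n_actions), stats::rexp(k))
}

# Exact policy evaluation by linear solve (independent of the iterative
# implementation): v = (I - gamma * P_pi)^(-1) r_pi.
exact_policy_values <- function(mdp, policy, gamma = 0.99) {
  k <- mdp$n_states
  pol <- sepsisrl:::normalize_policy(policy, mdp)
  p_pi <- matrix(0, k, k)
  r_pi <- numeric(k)
  for (s in seq_len(k)) {
    for (a in which(pol[s, ] > 0)) {
      p_pi[s, ] <- p_pi[s, ] + pol[s, a] * mdp$probs[s, a, seq_len(k)]
      r_pi[s] <- r_pi[s] + pol[s, a] *
        (100 * mdp$probs[s, a, mdp$recovered_id] -
         100 * mdp$probs[s, a, mdp$died_id])
    }
  }
  solve(diag(k) - gamma * p_pi, r_pi)
}

# Exact absorption (recovery) probability under a policy, by linear
# algebra: r = (I - P_pi)^(-1) p_recover.
exact_recovery_prob <- function(mdp, policy) {
  k <- mdp$n_states
  pol <- sepsisrl:::normalize_policy(policy, mdp)
  p_pi <- matrix(0, k, k)
  p_rec <- numeric(k)
  for (s in seq_len(k)) {
    for (a in which(pol[s, ] > 0)) {
      p_pi[s, ] <- p_pi[s, ] + pol[s, a] * mdp$probs[s, a, seq_len(k)]
      p_rec[s] <- p_rec[s] + pol[s, a] * mdp$probs[s, a, mdp$recovered_id]
    }
  }
  as.numeric(solve(diag(k) - p_pi, p_rec) %*% mdp$init)
}

# Naive scalar projection oracle: distributes each point mass by an
# explicit loop over atoms (independent of the vectorized operator).
naive_project <- function(atoms, locations, masses) {
  n <- length(atoms)
  out <- numeric(n)
  for (i in seq_along(locations)) {
    loc <- min(max(locations[i], atoms[1]), atoms[n])
    if (loc <= atoms[1]) { out[1] <- out[1] + masses[i]; next }
    j <- max(which(atoms <= loc))
    if (j == n) { out[n] <- out[n] + masses[i]; next }
    frac <- (loc - atoms[j]) / (atoms[j + 1] - atoms[j])
    out[j] <- out[j] + masses[i] * (1 - frac)
    out[j + 1] <- out[j + 1] + masses[i] * frac
  }
  out
}

# Random PMF over n atoms.
random_pmf <- function(n) {
  p <- stats::rexp(n)
  p / sum(p)
}

# The representation whose centers are the ground truth's centroids,
# mapped into the standardized feature space.
true_representation <- function(mdp, std_params) {
  sdv <- ifelse(std_params$sd > 0, std_params$sd, 1)
  cen <- sweep(sweep(mdp$centroids, 2, std_params$mean), 2, sdv, "/")
  structure(list(centers = cen, k = nrow(cen), seed = 0L),
            class = "representation")
}
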