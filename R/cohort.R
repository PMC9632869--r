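#' Configuration of the synthetic ICU cohort
#'
#' Describes the stated world the generator emulates: hourly
#' cluster-structured continuous features (default 53), a 5 x 5
#' intravenous-fluid x vasopressor dose grid (25 actions) with per-state
#' valid subsets, absorbing recovery/death outcomes with terminal
#' rewards of +-100, an overall missing-value rate of 0.39, and
#' episode-length distributions with geometric-type long tails arising
#' from absorption hazards.
#'
#' @param n_patients Number of patient episodes.
#' @param n_features Continuous feature channels (default 53).
#' @param k_true Latent (ground-truth) states, at least 2.
#' @param n_iv_bins,n_vaso_bins Dose bins per drug (default 5 each).
#' @param missing_rate Overall fraction of masked feature entries.
#' @param noise_sd Isotropic feature noise around the state centroid.
#' @param centroid_scale Standard deviation of centroid coordinates;
#'   with the default noise this keeps latent states well separated.
#' @param episode_cap Horizon cap; cap-hit episodes are censored.
#' @param behavior_quality Mixing weight in `[0, 1]` of the optimal
#'   policy in the clinician (behavior) policy; 0 = uniform over valid
#'   actions.
#' @param action_prob Probability that an action is valid in a state.
#' @param seed Master seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 500, n_features = 53, k_true = 8,
                          n_iv_bins = 5, n_vaso_bins = 5,
                          missing_rate = 0.39, noise_sd = 1,
                          centroid_scale = 5, episode_cap = 500,
                          behavior_quality = 0.6, action_prob = 0.5,
                          seed = 1) {
  stopifnot(n_patients >= 1, n_features >= 1, k_true >= 2,
            missing_rate >= 0, missing_rate < 1, noise_sd >= 0,
            behavior_quality >= 0, behavior_quality <= 1,
            action_prob > 0, action_prob <= 1, episode_cap >= 1)
  structure(
    list(n_patients = n_patients, n_features = n_features, k_true = k_true,
         n_iv_bins = n_iv_bins, n_vaso_bins = n_vaso_bins,
         n_actions = n_iv_bins * n_vaso_bins, missing_rate = missing_rate,
         noise_sd = noise_sd, centroid_scale = centroid_scale,
         episode_cap = episode_cap, behavior_quality = behavior_quality,
         action_prob = action_prob, seed = seed),
    class = "cohort_config"
  )
}

#' Draw a ground-truth latent MDP
#'
#' Per (state, action): a recovery hazard in (0.02, 0.30) and a death
#' hazard in (0, 0.08) drawn uniformly — so actions genuinely differ in
#' value — with the remaining mass spread over latent states by a
#' Dirichlet(1) draw. Valid-action subsets are sampled per state
#' (forced non-empty); the initial-state distribution is Dirichlet(1).
#' Absorption hazards of this size give recovery-heavy outcomes and
#' geometric-tailed episode lengths.
#'
#' @param config A `cohort_config`.
#' @return An `mdp_model` with extra fields `centroids`
#'   (`k_true x n_features`) and `optimal` (the value-iteration solution).
#' @export
generate_latent_mdp <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$k_true < 2) stop("k_true must be at least 2")
  set.seed(config$seed)
  k <- config$k_true
  na <- config$n_actions
  valid <- matrix(stats::runif(k * na) < config$action_prob, k, na)
  none <- rowSums(valid) == 0
  valid[cbind(which(none), sample.int(na, sum(none), replace = TRUE))] <- TRUE
  probs <- array(0, dim = c(k, na, k + 2))
  for (s in seq_len(k)) {
    for (a in which(valid[s, ])) {
      h_rec <- stats::runif(1, 0.02, 0.30)
      h_die <- stats::runif(1, 0, 0.08)
      w <- stats::rexp(k)                       # Dirichlet(1) over states
      w <- w / sum(w) * (1 - h_rec - h_die)
      probs[s, a, ] <- c(w, h_rec, h_die)
    }
  }
  init <- stats::rexp(k)
  centroids <- matrix(stats::rnorm(k * config$n_features,
                                   sd = config$centroid_scale),
                      k, config$n_features)
  m <- mdp_model(probs, valid, init)
  m$centroids <- centroids
  m$optimal <- value_iteration(m, gamma = 0.99)
  class(m) <- c("ground_truth_mdp", class(m))
  m
}

#' Clinician-like behavior policy
#'
#' Mixture of the ground truth's optimal policy (weight `quality`) and
#' the uniform distribution over valid actions (weight `1 - quality`).
#'
#' @param mdp A `ground_truth_mdp` (or any `mdp_model`; the optimal
#'   policy is computed if absent).
#' @param quality Mixing weight in `[0, 1]`.
#' @param gamma Discount used if the optimal policy must be computed.
#' @return Stochastic policy matrix `n_states x n_actions`.
#' @export
behavior_policy <- function(mdp, quality = 0.6, gamma = 0.99) {
  stopifnot(quality >= 0, quality <= 1)
  opt <- if (!is.null(mdp$optimal)) mdp$optimal$policy
         else value_iteration(mdp, gamma = gamma)$policy
  k <- mdp$n_states
  unif <- mdp$valid / rowSums(mdp$valid)
  greedy <- matrix(0, k, mdp$n_actions)
  greedy[cbind(seq_len(k), opt)] <- 1
  quality * greedy + (1 - quality) * unif
}

#' Sample patient trajectories from a ground-truth MDP
#'
#' @param mdp An `mdp_model`.
#' @param policy Stochastic policy matrix (e.g. [behavior_policy()]).
#' @param n_patients Number of episodes.
#' @param cap Horizon cap; cap-hit episodes are labelled `"censored"`.
#' @param seed Integer seed.
#' @return Trajectory data frame: `patient_id`, `t`, `state`, `action`,
#'   `next_state` (terminal codes included), `outcome`.
#' @export
sample_trajectories <- function(mdp, policy, n_patients, cap = 500, seed = 1) {
  set.seed(seed)
  rollout_batch(mdp, policy, n_patients, h_max = cap, record = TRUE)$transitions
}

#' Emit continuous features for visited states
#'
#' The inverse of discretization: every visited latent state emits its
#' centroid plus isotropic Gaussian noise, one row per (patient, hour).
#'
#' @param traj Trajectory data frame from [sample_trajectories()].
#' @param mdp The `ground_truth_mdp` carrying centroids.
#' @param config The `cohort_config` (noise scale, feature count).
#' @param seed Integer seed.
#' @return List with `features` (matrix, rows aligned to `traj` rows)
#'   and `alignment` (data frame `patient_id`, `t`, `state`).
#' @export
emit_features <- function(traj, mdp, config, seed = 1) {
  set.seed(seed)
  n <- nrow(traj)
  p <- config$n_features
  x <- mdp$centroids[traj$state, , drop = FALSE] +
    matrix(stats::rnorm(n * p, sd = config$noise_sd), n, p)
  colnames(x) <- sprintf("f%02d", seq_len(p))
  list(features = x,
       alignment = data.frame(patient_id = traj$patient_id, t = traj$t,
                              state = traj$state))
}

#' Mask feature entries completely at random
#'
#' @param m Numeric feature matrix.
#' @param rate Masking probability per entry, in `[0, 1)`.
#' @param seed Integer seed.
#' @return Matrix with masked entries set to `NA`; attribute `mask`
#'   holds the logical mask.
#' @export
apply_missingness <- function(m, rate = 0.39, seed = 1) {
  if (rate < 0 || rate >= 1) stop("rate must lie in [0, 1)")
  set.seed(seed)
  mask <- matrix(stats::runif(length(m)) < rate, nrow(m), ncol(m))
  out <- m
  out[mask] <- NA
  attr(out, "mask") <- mask
  out
}

#' Generate a complete synthetic cohort
#'
#' Convenience wrapper: latent MDP, behavior policy, trajectories,
#' features, missingness — all driven by the config's seed.
#'
#' @param config A `cohort_config`.
#' @return List with `mdp`, `policy`, `traj`, `features` (with `NA`s if
#'   `missing_rate > 0`), `features_complete`, and `alignment`.
#' @export
generate_cohort <- function(config) {
  mdp <- generate_latent_mdp(config)
  pol <- behavior_policy(mdp, config$behavior_quality)
  traj <- sample_trajectories(mdp, pol, config$n_patients,
                              cap = config$episode_cap,
                              seed = config$seed + 1L)
  emit <- emit_features(traj, mdp, config, seed = config$seed + 2L)
  feats <- emit$features
  if (config$missing_rate > 0)
    feats <- apply_missingness(feats, config$missing_rate,
                               seed = config$seed + 3L)
  list(mdp = mdp, policy = pol, traj = traj, features = feats,
       features_complete = emit$features, alignment = emit$alignment,
       config = config)
}
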