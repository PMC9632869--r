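#' Ranked stochastic deployment policy
#'
#' Ranks the valid actions of every state by expected return (ties to
#' the lower action index) and assigns geometric weights
#' \eqn{2^{-\mathrm{rank}}}, renormalized over the valid set — so with
#' many valid actions the best gets probability ~0.5 and the second-best
#' ~0.25. Randomizing over near-best actions prevents the deterministic
#' loops that a purely greedy policy can fall into on an empirical
#' simulator.
#'
#' @param eta A `return_table`.
#' @return Stochastic policy matrix `n_states x n_actions` (zero rows
#'   for states without valid actions).
#' @export
ranked_stochastic_policy <- function(eta) {
  ev <- rt_expectations(eta)
  k <- nrow(ev)
  pol <- matrix(0, k, ncol(ev))
  for (s in seq_len(k)) {
    va <- which(!is.na(ev[s, ]))
    if (length(va) == 0) next
    ranks <- rank(-ev[s, va], ties.method = "first")
    w <- 2^(-ranks)
    pol[s, va] <- w / sum(w)
  }
  pol
}

#' Monte-Carlo rollout metrics of a policy
#'
#' Simulates episodes on the empirical simulator and reports the mean
#' discounted return (discounted terminal reward; censored episodes
#' contribute 0 and count as non-recovered) and the recovery rate.
#'
#' @param env An `mdp_model`.
#' @param policy Stochastic policy matrix or deterministic vector.
#' @param n_episodes Number of simulated episodes (default 10000).
#' @param gamma Discount factor.
#' @param h_max Horizon cap.
#' @param seed Integer seed.
#' @return List of class `eval_report`: `mean_return`, `recovery_rate`,
#'   `n_episodes`, `n_censored`, `mean_length`, `seed`.
#' @export
rollout_metrics <- function(env, policy, n_episodes = 10000, gamma = 0.99,
                            h_max = 500, seed = 1) {
  stopifnot(n_episodes >= 1)
  set.seed(seed)
  ep <- rollout_batch(env, policy, n_episodes, h_max = h_max,
                      gamma = gamma)$episodes
  structure(
    list(mean_return = mean(ep$return_discounted),
         recovery_rate = mean(ep$outcome == "recovered"),
         n_episodes = n_episodes,
         n_censored = sum(ep$outcome == "censored"),
         mean_length = mean(ep$length), seed = seed),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n = %d | mean return %.2f | recovery rate %.4f | censored %d\n",
              x$n_episodes, x$mean_return, x$recovery_rate, x$n_censored))
  invisible(x)
}

#' Classify a return distribution by outcome risk
#'
#' Death probability is the mass on negative atoms, recovery probability
#' the mass on positive atoms (an atom at exactly 0 contributes half to
#' each). Classes, checked in order: `negative` (death > 0.5), `safe`
#' (recovery > 0.95), `bimodal` (min(death, recovery) >= `bimodal_min`),
#' else `positive`. The rule is total and exclusive.
#'
#' @param pmf Probability vector over `grid` atoms.
#' @param grid A `support_grid`.
#' @param bimodal_min Minimum two-sided mass for `bimodal` (default 0.4,
#'   operationalizing "a positive outcome almost as likely as a negative
#'   one").
#' @return One of `"negative"`, `"safe"`, `"bimodal"`, `"positive"`.
#' @export
classify_return_distribution <- function(pmf, grid, bimodal_min = 0.4) {
  stopifnot(length(pmf) == grid$n_atoms)
  zero <- sum(pmf[grid$atoms == 0])
  p_death <- sum(pmf[grid$atoms < 0]) + zero / 2
  p_recover <- sum(pmf[grid$atoms > 0]) + zero / 2
  if (p_death > 0.5) return("negative")
  if (p_recover > 0.95) return("safe")
  if (min(p_death, p_recover) >= bimodal_min) return("bimodal")
  "positive"
}

#' Train/test generalization experiment
#'
#' For each repeat: a fresh patient-level 80/20 split of one synthetic
#' cohort, then for each cluster count K a k-means discretization fitted
#' on the training rows, empirical simulators for both halves, speedy
#' policy control on the training simulator, and Monte-Carlo evaluation
#' of the ranked stochastic policy on both simulators.
#'
#' @param config A `cohort_config` (features are imputed with
#'   [knn_impute()] first when the cohort carries missing values).
#' @param k_grid Cluster counts to test.
#' @param n_repeats Random splits per K.
#' @param n_eval Episodes per Monte-Carlo evaluation.
#' @param train_cfg A `train_config`.
#' @param seed Master seed.
#' @return Data frame: `k`, `repeat`, `train_recovery`, `test_recovery`,
#'   `train_return`, `test_return`.
#' @export
generalization_experiment <- function(config, k_grid, n_repeats = 10,
                                      n_eval = 2000,
                                      train_cfg = train_config(), seed = 1) {
  cohort <- generate_cohort(config)
  feats <- cohort$features
  if (anyNA(feats)) feats <- knn_impute(feats)
  std <- standardize(feats)
  traj <- cohort$traj
  out <- list()
  row <- 0L
  for (r in seq_len(n_repeats)) {
    set.seed(seed + 97L * r)
    sp <- split_patients(traj, 0.8)
    in_train <- traj$patient_id %in% unique(sp$train$patient_id)
    for (k in k_grid) {
      row <- row + 1L
      set.seed(seed + 97L * r + k)
      rep_k <- fit_kmeans_rep(std$x[in_train, , drop = FALSE], k,
                              seed + 97L * r + k)
      k <- rep_k$k
      st <- assign_states(std$x, rep_k)
      d_train <- discretize_trajectories(traj[in_train, , drop = FALSE],
                                         st[in_train], k)
      d_test <- discretize_trajectories(traj[!in_train, , drop = FALSE],
                                        st[!in_train], k)
      m_train <- build_empirical_mdp(d_train, k, config$n_actions)
      m_test <- build_empirical_mdp(d_test, k, config$n_actions)
      cfg <- train_cfg
      cfg$seed <- seed + 1000L * r + k
      fit <- speedy_control(m_train, cfg)
      pol <- ranked_stochastic_policy(fit$eta)
      ev_tr <- rollout_metrics(m_train, pol, n_eval, gamma = cfg$gamma,
                               seed = cfg$seed + 1L)
      ev_te <- rollout_metrics(m_test, pol, n_eval, gamma = cfg$gamma,
                               seed = cfg$seed + 2L)
      out[[row]] <- data.frame(k = k, rep = r,
                               train_recovery = ev_tr$recovery_rate,
                               test_recovery = ev_te$recovery_rate,
                               train_return = ev_tr$mean_return,
                               test_return = ev_te$mean_return)
    }
  }
  do.call(rbind, out)
}

#' Run the full pipeline on a synthetic cohort
#'
#' Generate (or accept) a cohort, impute missing features, standardize,
#' fit and select a state representation by the coverage heuristic,
#' split patients 80/20, build train and test simulators, run speedy
#' policy control on the training simulator, and evaluate the ranked
#' stochastic policy and the clinician (behavior) policy on both
#' simulators.
#'
#' @param config A `cohort_config`.
#' @param k_grid Candidate cluster counts.
#' @param n_restarts k-means restarts per count.
#' @param train_cfg A `train_config`.
#' @param n_eval Episodes per evaluation.
#' @param knn_k Neighbours for imputation.
#' @param seed Master seed for split/selection/training.
#' @return List with the cohort, the selected representation and
#'   coverage report, both simulators, the trained return table and
#'   policies, and an evaluation summary data frame.
#' @export
run_full_pipeline <- function(config, k_grid = config$k_true,
                              n_restarts = 1, train_cfg = train_config(),
                              n_eval = 2000, knn_k = 10, seed = 1) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  cohort <- stage("synth", generate_cohort(config))
  feats <- cohort$features
  if (anyNA(feats)) feats <- stage("impute", knn_impute(feats, k = knn_k))
  std <- stage("standardize", standardize(feats))
  cands <- stage("cluster",
                 fit_candidates(std$x, k_grid, n_restarts = n_restarts,
                                seed = seed))
  sel <- stage("select",
               select_representation(std$x, cohort$traj, cands,
                                     gamma = train_cfg$gamma,
                                     n_actions = config$n_actions,
                                     seed = seed))
  st <- stage("assign", assign_states(std$x, sel$selected))
  set.seed(seed)
  sp <- stage("split", split_patients(cohort$traj, 0.8))
  in_train <- cohort$traj$patient_id %in% unique(sp$train$patient_id)
  k <- sel$selected$k
  d_train <- discretize_trajectories(cohort$traj[in_train, , drop = FALSE],
                                     st[in_train], k)
  d_test <- discretize_trajectories(cohort$traj[!in_train, , drop = FALSE],
                                    st[!in_train], k)
  m_train <- stage("simulator",
                   build_empirical_mdp(d_train, k, config$n_actions))
  m_test <- stage("simulator",
                  build_empirical_mdp(d_test, k, config$n_actions))
  cfg <- train_cfg
  cfg$seed <- seed
  fit <- stage("train", speedy_control(m_train, cfg))
  agent_pol <- ranked_stochastic_policy(fit$eta)
  clin_pol <- extract_policy(d_train, k, config$n_actions)
  evals <- stage("evaluate", {
    rows <- list(
      agent_train = rollout_metrics(m_train, agent_pol, n_eval,
                                    gamma = cfg$gamma, seed = seed + 1L),
      agent_test = rollout_metrics(m_test, agent_pol, n_eval,
                                   gamma = cfg$gamma, seed = seed + 2L),
      clinician_train = rollout_metrics(m_train, clin_pol, n_eval,
                                        gamma = cfg$gamma, seed = seed + 3L),
      clinician_test = rollout_metrics(m_test, clin_pol, n_eval,
                                       gamma = cfg$gamma, seed = seed + 4L)
    )
    data.frame(policy = c("agent", "agent", "clinician", "clinician"),
               env = c("train", "test", "train", "test"),
               mean_return = vapply(rows, `[[`, numeric(1), "mean_return"),
               recovery_rate = vapply(rows, `[[`, numeric(1), "recovery_rate"),
               row.names = NULL)
  })
  list(cohort = cohort, representation = sel$selected,
       coverage_report = sel$report, mdp_train = m_train, mdp_test = m_test,
       eta = fit$eta, diagnostics = fit$diagnostics,
       agent_policy = agent_pol, clinician_policy = clin_pol,
       summary = evals)
}
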