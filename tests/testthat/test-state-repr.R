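test_that("standardize centers and scales with the population convention", {
  m <- cbind(c(0, 2), c(10, 30))
  s <- standardize(m)
  expect_equal(s$x[, 1], c(-1, 1))
  expect_equal(s$x[, 2], c(-1, 1))
  # already standardized input passes through
  s2 <- standardize(s$x)
  expect_equal(s2$x, s$x, tolerance = 1e-9)
  expect_warning(standardize(cbind(c(1, 1), c(0, 2))), "constant")
  expect_error(standardize(cbind(c(1, NA))), "completed")
  # params reuse maps new data into the same space
  s3 <- standardize(rbind(c(1, 20)), params = s$params)
  expect_equal(s3$x[1, ], c(0, 0))
})

test_that("fit_candidates enumerates K x restarts reproducibly", {
  set.seed(1)
  x <- rbind(matrix(stats::rnorm(40, -5), 20, 2),
             matrix(stats::rnorm(40, 5), 20, 2))
  cands <- fit_candidates(x, k_grid = c(2, 3), n_restarts = 3, seed = 10)
  expect_length(cands, 6)
  expect_equal(sort(unique(vapply(cands, `[[`, numeric(1), "k"))), c(2, 3))
  cands_b <- fit_candidates(x, k_grid = c(2, 3), n_restarts = 3, seed = 10)
  expect_equal(cands[[4]]$centers, cands_b[[4]]$centers)
  # two separated blobs recovered at K = 2
  st <- assign_states(x, cands[[1]])
  expect_equal(length(unique(st[1:20])), 1)
  expect_equal(length(unique(st[21:40])), 1)
  expect_warning(fit_candidates(x, k_grid = c(2, 100), n_restarts = 1),
                 "skipping")
})

test_that("assign_states maps to the nearest center with low-index ties", {
  rep <- structure(list(centers = rbind(c(0, 0), c(2, 0), c(4, 0)),
                        k = 3, seed = 1L), class = "representation")
  expect_equal(assign_states(rbind(c(2, 0)), rep), 2L)
  expect_equal(assign_states(rbind(c(1, 0)), rep), 1L)   # tie 1 vs 2
  expect_equal(assign_states(rbind(c(3, 0)), rep), 2L)   # tie 2 vs 3
  x <- matrix(stats::rnorm(20), 10, 2)
  st <- assign_states(x, rep)
  expect_identical(assign_states(rep$centers[st, , drop = FALSE], rep), st)
  expect_error(assign_states(matrix(0, 1, 3), rep), "dimension")
})

test_that("extract_policy normalizes observed action counts", {
  traj <- data.frame(patient_id = 1, t = 1:4, state = c(1, 1, 1, 1),
                     action = c(2, 2, 3, 4))
  pol <- extract_policy(traj, n_states = 2, n_actions = 4)
  expect_equal(pol[1, ], c(0, 0.5, 0.25, 0.25))
  expect_true(all(is.na(pol[2, ])))
  expect_equal(sum(pol[1, ]), 1)
  one <- extract_policy(data.frame(patient_id = 1, t = 1, state = 1, action = 3),
                        n_states = 1, n_actions = 4)
  expect_equal(one[1, 3], 1)
  expect_error(extract_policy(traj[0, ], 2, 4), "empty")
})

test_that("dp_policy_evaluation matches closed forms and the linear solve", {
  expect_equal(dp_policy_evaluation(make_two_point_mdp(1), matrix(1, 1, 1)),
               100, tolerance = 1e-5)
  chain <- make_chain_mdp(3)
  v <- dp_policy_evaluation(chain, rep(1L, 3), gamma = 0.99)
  expect_equal(v[1], 100 * 0.99^2, tolerance = 1e-5)
  expect_equal(dp_policy_evaluation(make_two_point_mdp(0.5), matrix(1, 1, 1)),
               0, tolerance = 1e-5)
  # oracle equivalence on random 10-state MDPs
  for (s in 1:5) {
    mdp <- make_suite_mdp(s)
    pol <- behavior_policy(mdp, 0.4)
    expect_equal(dp_policy_evaluation(mdp, pol, tol = 1e-10),
                 exact_policy_values(mdp, pol), tolerance = 1e-6)
  }
  expect_error(dp_policy_evaluation(make_two_point_mdp(1), matrix(1, 1, 1),
                                    gamma = 1, tol = 0, max_iter = 5),
               "did not converge")
})

test_that("coverage counts deviations under the threshold", {
  expect_equal(coverage(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(coverage(c(0, 50), c(10, 80)), 0.5)
  expect_equal(coverage(c(1, 2), c(1, 3), threshold = 0), 0)
  v1 <- c(0, 10, 40); v2 <- c(20, 11, 41)
  for (th in c(30, 15, 5, 1))
    expect_gte(coverage(v1, v2, 30), coverage(v1, v2, th))
  expect_error(coverage(c(NA, NA), c(1, 2)), "no states")
  expect_error(coverage(1:3, 1:2), "length")
})

test_that("discretize_trajectories rewires successors and terminals", {
  traj <- data.frame(patient_id = c(1, 1, 2), t = c(1, 2, 1),
                     action = c(1, 2, 1),
                     outcome = c("recovered", "recovered", "died"))
  st <- c(3L, 1L, 2L)
  d <- discretize_trajectories(traj, st, n_states = 3)
  expect_equal(d$next_state, c(1L, 4L, 5L))  # within-episode, then terminals
  expect_equal(d$state, st)
  # censored tails are dropped
  traj$outcome <- "censored"
  d2 <- discretize_trajectories(traj, st, n_states = 3)
  expect_equal(nrow(d2), 1)                  # only the 1 -> 2 hop of patient 1
})

test_that("select_representation ranks by coverage and is reproducible", {
  cfg <- cohort_config(n_patients = 120, k_true = 4, n_features = 6,
                       missing_rate = 0, noise_sd = 0.3, seed = 40)
  cohort <- generate_cohort(cfg)
  std <- standardize(cohort$features)
  good <- true_representation(cohort$mdp, std$params)
  cands <- list(good)
  sel <- select_representation(std$x, cohort$traj, cands, seed = 3)
  expect_identical(sel$selected, good)       # single candidate wins
  expect_true(all(sel$report$coverage >= 0 & sel$report$coverage <= 1))
  sel2 <- select_representation(std$x, cohort$traj, cands, seed = 3)
  expect_identical(sel2$report, sel$report)
})
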