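test_that("generate_latent_mdp is seeded and row-stochastic", {
  cfg <- cohort_config(n_patients = 10, k_true = 5, seed = 21)
  m1 <- generate_latent_mdp(cfg)
  m2 <- generate_latent_mdp(cfg)
  expect_identical(m1$probs, m2$probs)
  expect_identical(m1$valid, m2$valid)
  rs <- apply(m1$probs, c(1, 2), sum)
  expect_true(all(abs(rs[m1$valid] - 1) < 1e-12))
  expect_true(all(rowSums(m1$valid) >= 1))
  expect_error(generate_latent_mdp(cohort_config(k_true = 1)), "k_true")
})

test_that("an always-recovering action dominates under value iteration", {
  cfg <- cohort_config(n_patients = 10, k_true = 4, n_iv_bins = 2,
                       n_vaso_bins = 2, seed = 8)
  mdp <- generate_latent_mdp(cfg)
  # force action 1 to recover immediately in every state
  mdp$probs[, 1, ] <- 0
  mdp$probs[, 1, mdp$recovered_id] <- 1
  mdp$valid[, 1] <- TRUE
  mdp <- mdp_model(mdp$probs, mdp$valid, mdp$init)
  vi <- value_iteration(mdp, gamma = 0.99)
  expect_equal(vi$policy, rep(1L, 4))
  expect_equal(vi$v, rep(100, 4), tolerance = 1e-8)
})

test_that("behavior_policy mixes optimal and uniform as stated", {
  probs <- array(0, dim = c(1, 2, 3))
  probs[1, 1, 2] <- 1            # action 1: certain recovery (optimal)
  probs[1, 2, 3] <- 1            # action 2: certain death
  mdp <- mdp_model(probs, matrix(TRUE, 1, 2), 1)
  expect_equal(behavior_policy(mdp, 1)[1, ], c(1, 0))
  expect_equal(behavior_policy(mdp, 0)[1, ], c(0.5, 0.5))
  expect_equal(behavior_policy(mdp, 0.5)[1, ], c(0.75, 0.25))
})

test_that("sample_trajectories terminates, labels outcomes, reproduces", {
  # certain immediate recovery: every episode has length 1
  rec <- make_two_point_mdp(1)
  tr <- sample_trajectories(rec, matrix(1, 1, 1), 50, seed = 2)
  expect_equal(nrow(tr), 50)
  expect_true(all(tr$t == 1 & tr$outcome == "recovered"))
  # seeded reproducibility on a generated cohort
  cfg <- cohort_config(n_patients = 40, k_true = 4, seed = 5)
  mdp <- generate_latent_mdp(cfg)
  pol <- behavior_policy(mdp, 0.5)
  t1 <- sample_trajectories(mdp, pol, 40, seed = 9)
  t2 <- sample_trajectories(mdp, pol, 40, seed = 9)
  expect_identical(t1, t2)
})

test_that("episode lengths under a constant hazard are geometric", {
  p <- 0.3
  probs <- array(0, dim = c(1, 1, 3))
  probs[1, 1, 1] <- 1 - p                    # stay
  probs[1, 1, 2] <- p                        # recover
  mdp <- mdp_model(probs, matrix(TRUE, 1, 1), 1)
  tr <- sample_trajectories(mdp, matrix(1, 1, 1), 5000, cap = 200, seed = 31)
  lens <- tabulate(tr$patient_id)
  obs <- tabulate(pmin(lens, 15), nbins = 15)
  probs_geom <- stats::dgeom(0:13, p)
  expected <- 5000 * c(probs_geom, 1 - sum(probs_geom))
  chi2 <- sum((obs - expected)^2 / expected)
  expect_lt(chi2, stats::qchisq(0.99, df = 14))
})

test_that("emit_features places rows on centroids plus noise", {
  cfg <- cohort_config(n_patients = 30, k_true = 4, n_features = 6,
                       noise_sd = 0, seed = 12)
  mdp <- generate_latent_mdp(cfg)
  pol <- behavior_policy(mdp, 0.5)
  tr <- sample_trajectories(mdp, pol, 30, seed = 13)
  em <- emit_features(tr, mdp, cfg, seed = 14)
  expect_equal(nrow(em$features), nrow(tr))
  expect_equal(em$features[5, ], mdp$centroids[tr$state[5], ],
               ignore_attr = TRUE)
  # small noise: k-means at K_true recovers the partition exactly
  cfg2 <- cohort_config(n_patients = 60, k_true = 4, n_features = 6,
                        noise_sd = 0.3, seed = 12)
  em2 <- emit_features(tr, mdp, cfg2, seed = 15)
  set.seed(16)
  km <- stats::kmeans(em2$features, centers = 4, nstart = 5)
  tab <- table(km$cluster, tr$state)
  expect_true(all(rowSums(tab > 0) == 1))   # clusters pure
  expect_true(all(colSums(tab > 0) == 1))   # states unsplit
})

test_that("apply_missingness masks at the requested MCAR rate", {
  m <- matrix(stats::rnorm(1e5), 1000, 100)
  out0 <- apply_missingness(m, 0, seed = 1)
  expect_false(anyNA(out0))
  out <- apply_missingness(m, 0.39, seed = 2)
  expect_equal(mean(is.na(out)), 0.39, tolerance = 0.01)
  out_b <- apply_missingness(m, 0.39, seed = 2)
  expect_identical(attr(out, "mask"), attr(out_b, "mask"))
  expect_error(apply_missingness(m, 1), "rate")
})

test_that("generate_cohort is a pure function of config and seed", {
  cfg <- cohort_config(n_patients = 25, k_true = 3, n_features = 5,
                       missing_rate = 0.2, seed = 77)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$traj, b$traj)
  expect_identical(a$features, b$features)
  expect_lt(abs(mean(is.na(a$features)) - 0.2), 0.05)
})
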