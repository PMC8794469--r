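test_that("obtained and chance reward rates are computed per session", {
  sched <- constant_schedule(0.2, 0.8, 5000)
  s <- simulate_session(function(ch, rw) 1, sched, seed = 1)  # best arm
  rv <- reward_vs_chance(s)
  expect_equal(rv[["chance"]], 0.5)
  expect_lt(abs(rv[["obtained"]] - 0.8), 3 * sqrt(0.8 * 0.2 / 5000))

  zero <- bandit_session(c(0, 1), c(0, 0), schedule = constant_schedule(0.5, 0.5, 2))
  expect_equal(reward_vs_chance(zero)[["obtained"]], 0)
  noschedule <- bandit_session(c(0, 1), c(0, 0))
  expect_error(reward_vs_chance(noschedule), "schedule")
})

test_that("win-stay and lose-shift rates match hand counts", {
  s <- bandit_session(c(0, 0, 1), c(1, 0, 0))
  w <- wsls_rates(s)
  expect_equal(w[["win_stay"]], 1)   # trial 2 stayed after a win
  expect_equal(w[["lose_shift"]], 1) # trial 3 shifted after a loss

  det <- bandit_session(c(0, 0, 1, 1), c(1, 0, 1, 1))
  wd <- wsls_rates(det)
  expect_equal(wd[["win_stay"]], 1)
  expect_equal(wd[["lose_shift"]], 1)

  set.seed(2)
  iid <- bandit_session(sample(0:1, 20000, replace = TRUE),
                        sample(0:1, 20000, replace = TRUE))
  wi <- wsls_rates(iid)
  expect_lt(abs(wi[["win_stay"]] - 0.5), 0.02)
  expect_lt(abs(wi[["lose_shift"]] - 0.5), 0.02)
})

test_that("state-conditioned rates use the outcome trial's label", {
  s <- bandit_session(c(0, 0, 1), c(1, 0, 0))
  st <- structure(list(binary_explore = c(1, 0, 0)),
                  class = "state_sequence")
  w <- wsls_rates(s, st)
  expect_equal(w[["win_stay_explore"]], 1)  # the win happened at trial 1 (explore)
  expect_true(is.na(w[["win_stay_exploit"]]))  # no wins during exploit
  expect_equal(w[["lose_shift_exploit"]], 1)
  expect_true(is.na(w[["lose_shift_explore"]]))
})

test_that("conditional mutual information hits its analytic anchors", {
  # exact independent joint: 0 bits
  grid <- expand.grid(ct = 0:1, ct1 = 0:1, r = 0:1)
  expect_equal(conditional_mutual_info(grid), 0)

  # deterministic WSLS with uniform margins: 1 bit
  ct1 <- rep(0:1, each = 4)
  r <- rep(rep(0:1, each = 2), 2)
  ct <- ifelse(r == 1, ct1, 1 - ct1)
  expect_equal(conditional_mutual_info(list(ct = ct, ct1 = ct1, r = r)), 1)

  # plug-in bias stays small for iid choices at large n
  set.seed(3)
  s <- bandit_session(sample(0:1, 2e5, replace = TRUE),
                      sample(0:1, 2e5, replace = TRUE))
  expect_lt(conditional_mutual_info(s), 0.01)
  expect_gte(conditional_mutual_info(s), 0)

  # invariant to relabeling the arms
  set.seed(4)
  s1 <- bandit_session(sample(0:1, 500, replace = TRUE),
                       sample(0:1, 500, replace = TRUE))
  s2 <- bandit_session(1L - s1$choices, s1$rewards)
  expect_equal(conditional_mutual_info(s1), conditional_mutual_info(s2),
               tolerance = 1e-12)
})

test_that("tetrachoric correlation matches the latent-normal oracle", {
  expect_equal(tetrachoric_corr(matrix(c(25, 25, 25, 25), 2)), 0,
               tolerance = 1e-6)
  # odds ratio 16: cos-approximation gives cos(pi / (1 + sqrt(16))) = 0.809
  r <- tetrachoric_corr(matrix(c(40, 10, 10, 40), 2))
  expect_equal(r, cos(pi / 5), tolerance = 0.01)
  expect_gt(tetrachoric_corr(matrix(c(50, 1, 1, 50), 2)), 0.95)
  # sign symmetry
  expect_equal(tetrachoric_corr(matrix(c(10, 40, 40, 10), 2)),
               -tetrachoric_corr(matrix(c(40, 10, 10, 40), 2)),
               tolerance = 1e-6)
  # degenerate margin undefined
  expect_true(is.na(tetrachoric_corr(rep(1L, 20), rep(c(0L, 1L), 10))))
})

test_that("AUC follows the concordant-pair arithmetic", {
  expect_equal(auc_separability(c(1, 2, 3), c(4, 5, 6))$auc, 1)
  expect_equal(auc_separability(c(1, 3), c(2, 4))$auc, 0.75)
  a <- auc_separability(c(1, 3), c(2, 4))
  b <- auc_separability(c(2, 4), c(1, 3))
  expect_equal(a$auc + b$auc, 1)
  deg <- auc_separability(rep(1, 3), rep(1, 3))
  expect_true(deg$degenerate)
  expect_equal(deg$auc, 0.5)
  set.seed(5)
  null <- replicate(40, auc_separability(rnorm(10), rnorm(10))$auc)
  expect_lt(abs(mean(null) - 0.5), 0.1)
})

test_that("latency regressions quantify state-linked response times", {
  ex <- rep(c(1, 0), each = 25)
  s <- bandit_session(rep(0, 50), rep(0, 50),
                      response_time = 1 + 0.5 * ex)
  out <- latency_by_state(s, ex)
  expect_equal(out$rt_explore, 1.5)
  expect_equal(out$rt_exploit, 1.0)
  expect_equal(out$r_squared, 1, tolerance = 1e-10)

  flat <- bandit_session(rep(0, 50), rep(0, 50),
                         response_time = rep(2, 50))
  expect_equal(latency_by_state(flat, ex)$r_squared, 0)

  # two label sets ranked by how much latency they explain
  set.seed(6)
  rt <- 1 + 0.5 * ex + rnorm(50, 0, 0.1)
  noisy_labels <- ex; noisy_labels[sample(50, 20)] <- 1 - noisy_labels[sample(50, 20)]
  s2 <- bandit_session(rep(0, 50), rep(0, 50), response_time = pmax(rt, 0.1))
  out2 <- latency_by_state(s2, ex, noisy_labels)
  expect_equal(out2$labels, c("hmm", "rl"))
  expect_gt(out2$r_squared[1], out2$r_squared[2])
})

test_that("explore choices from an HMM agent are value-orthogonal", {
  set.seed(7)
  sp <- hmm_spec("tied2", list(a = 0.9, d = 0.85))
  sims <- lapply(1:6, function(i)
    simulate_hmm_agent(sp, generate_reward_walk(300)))
  sessions <- lapply(sims, `[[`, "session")
  states <- lapply(sims, function(x) x$states$binary_explore)
  f <- fit_rl("rl", sessions, n_restarts = 5, seed = 8)
  delta <- explore_value_orthogonality(sessions, states, f)
  expect_lt(abs(delta), 0.05)

  # a greedy agent mislabeled all-explore scores positive by construction
  pol <- rl_policy("rl", list(alpha = 0.7, beta = 15))
  sg <- simulate_session(pol, generate_reward_walk(300))
  fg <- structure(list(model_id = "rl", params = list(alpha = 0.7, beta = 15)),
                  class = "rl_fit")
  expect_gt(explore_value_orthogonality(sg, list(rep(1L, 300)), fg), 0)

  # empty conditioning set flagged undefined
  expect_true(is.na(explore_value_orthogonality(sg, list(rep(0L, 300)), fg)))
})

test_that("matching-law points land on their definitions", {
  corner <- bandit_session(rep(1, 10), rep(1, 10))
  mp <- matching_law_points(corner)
  expect_equal(mp$reward_fraction, 1)
  expect_equal(mp$choice_fraction, 1)

  none <- bandit_session(c(0, 1), c(0, 0))
  expect_true(is.na(matching_law_points(none)$reward_fraction))

  # matching agents correlate choice and reward allocation
  set.seed(9)
  pol_fn <- function() rl_policy("rlck", list(alpha = 0.4, beta = 4,
                                              alpha_c = 0.3, beta_c = 1))
  ss <- lapply(1:12, function(i)
    simulate_session(pol_fn(), generate_reward_walk(300)))
  pts <- matching_law_points(ss)
  expect_gt(cor(pts$reward_fraction, pts$choice_fraction), 0.3)
})
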