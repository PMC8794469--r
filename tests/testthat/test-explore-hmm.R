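test_that("transition matrices match hand arithmetic and are stochastic", {
  sp <- hmm_spec("tied2", list(a = 0.921, d = 0.835))
  P <- build_transition_matrix(sp)
  expect_equal(unname(P[1, ]), c(0.921, 0.0395, 0.0395))
  expect_equal(unname(P[2, ]), c(0.165, 0.835, 0))
  expect_equal(unname(P[3, ]), c(0.165, 0, 0.835))

  for (a in c(0.3, 0.7, 1)) for (d in c(0.2, 0.9, 1)) {
    P <- build_transition_matrix(hmm_spec("tied2", list(a = a, d = d)))
    expect_equal(rowSums(P), c(explore = 1, exploit_L = 1, exploit_R = 1),
                 tolerance = 1e-12)
    expect_equal(P[2, 3], 0)  # exploit states never touch each other
    expect_equal(P[3, 2], 0)
  }

  Pn <- build_transition_matrix(
    hmm_spec("nt4", list(q_L = 0.1, q_R = 0.3, d_L = 0.8, d_R = 0.6)))
  expect_equal(unname(Pn[1, ]), c(0.6, 0.1, 0.3))
  expect_error(hmm_spec("nt4", list(q_L = 0.6, q_R = 0.6, d_L = 0.5,
                                    d_R = 0.5)), "q_L \\+ q_R")
  expect_error(build_transition_matrix(
    hmm_spec("io4", list(a_win = .9, a_loss = .8, d_win = .9, d_loss = .7))),
    "prev_reward")
})

test_that("analytically forced likelihood values hold for any parameters", {
  for (a in c(0.2, 0.6, 0.95)) for (d in c(0.3, 0.835)) {
    sp <- hmm_spec("tied2", list(a = a, d = d))
    expect_equal(hmm_loglik(sp, bandit_session(1, 0)), log(0.5))
    # two repeated choices: explore emission 1/2, then a/2 + (1-a)/2 * 1 = 1/2
    expect_equal(hmm_loglik(sp, bandit_session(c(0, 0), c(1, 0))), log(0.25))
    expect_equal(hmm_loglik(sp, bandit_session(c(1, 1), c(0, 0))), log(0.25))
  }
})

test_that("forward likelihood equals exhaustive path enumeration", {
  specs <- list(
    hmm_spec("tied2", list(a = 0.8, d = 0.8)),
    hmm_spec("tied2", list(a = 0.921, d = 0.835)),
    hmm_spec("io4", list(a_win = 0.95, a_loss = 0.7, d_win = 0.9,
                         d_loss = 0.6)),
    hmm_spec("nt4", list(q_L = 0.05, q_R = 0.15, d_L = 0.9, d_R = 0.7)))
  for (sp in specs) {
    for (seed in 1:8) {
      T <- 3 + (seed %% 6)
      s <- random_session(T, seed * 100)
      expect_equal(hmm_loglik(sp, s), oracle_loglik(sp, s),
                   tolerance = 1e-10)
    }
  }
  # the documented 5-trial case
  sp <- hmm_spec("tied2", list(a = 0.8, d = 0.8))
  s <- bandit_session(c(0, 0, 1, 1, 0), c(1, 0, 1, 0, 1))
  expect_equal(hmm_loglik(sp, s), oracle_loglik(sp, s), tolerance = 1e-10)
})

test_that("viterbi path attains the enumerated maximum path probability", {
  specs <- list(hmm_spec("tied2", list(a = 0.9, d = 0.9)),
                hmm_spec("io4", list(a_win = 0.95, a_loss = 0.6,
                                     d_win = 0.85, d_loss = 0.7)))
  for (sp in specs) {
    for (seed in 1:15) {
      T <- 3 + (seed %% 6)
      s <- random_session(T, seed * 31)
      st <- viterbi_decode(sp, s)
      expect_equal(decoded_path_prob(sp, s, st),
                   oracle_best_path_prob(sp, s), tolerance = 1e-12)
      expect_equal(as.character(st$labels[1]), "explore")
    }
  }
})

test_that("viterbi labels match the forced decoding patterns", {
  sp <- hmm_spec("tied2", list(a = 0.9, d = 0.9))
  alt <- bandit_session(rep(c(0, 1), 5), rep(0, 10))
  expect_true(all(viterbi_decode(sp, alt)$binary_explore == 1))

  run7 <- bandit_session(rep(0, 7), rep(1, 7))
  labs <- as.character(viterbi_decode(sp, run7)$labels)
  expect_equal(labs, c("explore", rep("exploit_L", 6)))
})

test_that("decoded sequences never jump between the two exploit states", {
  sp <- hmm_spec("tied2", list(a = 0.7, d = 0.95))
  for (seed in 1:10) {
    s <- random_session(40, seed + 500)
    labs <- as.integer(viterbi_decode(sp, s)$labels)
    jumps <- any((labs[-1] == 2 & labs[-length(labs)] == 3) |
                   (labs[-1] == 3 & labs[-length(labs)] == 2))
    expect_false(jumps)
  }
})

test_that("EM log-likelihood is non-decreasing and recovers parameters", {
  set.seed(42)
  sp <- hmm_spec("tied2", list(a = 0.921, d = 0.835))
  sessions <- lapply(1:4, function(i)
    simulate_hmm_agent(sp, constant_schedule(0.5, 0.5, 250))$session)
  fit <- fit_hmm(sessions, "tied2", n_restarts = 8, seed = 1)
  expect_true(all(diff(fit$loglik_trace) > -1e-7))
  expect_lt(abs(fit$spec$params$a - 0.921), 0.08)
  expect_lt(abs(fit$spec$params$d - 0.835), 0.12)
  expect_equal(fit$total_loglik, sum(fit$per_session_loglik))
  expect_lte(fit$total_loglik, 0)
})

test_that("alternating choices drive the explore state to saturation", {
  alt <- bandit_session(rep(c(0, 1), 60), rep(0, 120))
  fit <- fit_hmm(alt, "tied2", n_restarts = 5, seed = 2)
  st <- viterbi_decode(fit, alt)
  expect_equal(explore_fraction(st), 1)
  expect_gt(fit$spec$params$a, 0.9)
})

test_that("io variant with tied inputs reproduces the two-parameter model", {
  sp2 <- hmm_spec("tied2", list(a = 0.88, d = 0.77))
  sp4 <- hmm_spec("io4", list(a_win = 0.88, a_loss = 0.88,
                              d_win = 0.77, d_loss = 0.77))
  for (seed in 1:6) {
    s <- random_session(30, seed + 90)
    expect_equal(hmm_loglik(sp2, s), hmm_loglik(sp4, s), tolerance = 1e-12)
  }
})

test_that("information criteria reproduce the worked arithmetic", {
  fits <- list(io4 = structure(list(total_loglik = -1430.5,
                                    n_free_params = 128),
                               class = "hmm_fit"))
  ic <- information_criteria(fits, n_obs = 70912)
  expect_equal(ic$AIC, 3117)

  same <- structure(list(total_loglik = -100, n_free_params = 3),
                    class = "hmm_fit")
  ic2 <- information_criteria(list(m1 = same, m2 = same), n_obs = 500)
  expect_equal(ic2$delta_AIC, c(0, 0))
  expect_equal(ic2$rel_lik_AIC, c(1, 1))
  expect_error(information_criteria(list(m1 = same), n_obs = 0), "positive")
})

test_that("per-subject fits aggregate their parameter counts", {
  mk <- function(ll) structure(list(total_loglik = ll, n_free_params = 2),
                               class = "hmm_fit")
  fits <- list(tied2 = list(mk(-50), mk(-60), mk(-70)))
  ic <- information_criteria(fits, n_obs = 900)
  expect_equal(ic$k, 6)
  expect_equal(ic$loglik, -180)
  expect_equal(ic$AIC, 2 * 6 + 360)
})

test_that("model selection prefers the tied model on tied-generated data", {
  set.seed(7)
  sp <- hmm_spec("tied2", list(a = 0.9, d = 0.8))
  wins <- 0
  n_subj <- 8
  for (i in seq_len(n_subj)) {
    sessions <- lapply(1:2, function(j)
      simulate_hmm_agent(sp, constant_schedule(0.5, 0.5, 300))$session)
    fits <- list(
      tied2 = fit_hmm(sessions, "tied2", n_restarts = 6),
      io4 = fit_hmm(sessions, "io4", n_restarts = 6),
      nt4 = fit_hmm(sessions, "nt4", n_restarts = 6))
    ic <- information_criteria(fits, n_obs = 600)
    if (ic$model[which.min(ic$AIC)] == "tied2") wins <- wins + 1
  }
  expect_gte(wins, ceiling(0.75 * n_subj))
})

test_that("explore fraction counts labels overall and per bin", {
  st <- structure(list(binary_explore = c(1, 1, 0, 0)),
                  class = "state_sequence")
  expect_equal(explore_fraction(st), 0.5)
  expect_equal(explore_fraction(rep(1, 10)), 1)
  expect_equal(explore_fraction(c(1, 1, 0, 0), bins = 2), c(1, 0))
  expect_error(explore_fraction(c(1, 0), bins = 5), "bins")
})

test_that("long simulations approach the stationary explore fraction", {
  sp <- hmm_spec("tied2", list(a = 0.921, d = 0.835))
  set.seed(13)
  sim <- simulate_hmm_agent(sp, constant_schedule(0.5, 0.5, 20000))
  target <- stationary_distribution(sp)$pi2[["explore"]]
  expect_lt(abs(explore_fraction(sim$states) - target), 0.03)
})
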