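test_that("likelihoods match hand recursions for the simple models", {
  # delta-rule + softmax, two left choices, first rewarded:
  # trial 1 p = 1/2; Q_L -> 0.75; trial 2 p = logistic(beta * 0.25)
  s <- bandit_session(c(0, 0), c(1, 1))
  nll <- rl_nll("rl", list(alpha = 0.5, beta = 1), s)
  expect_equal(nll, -(log(0.5) + log(plogis(0.25))), tolerance = 1e-10)

  # noisy WSLS: rewarded stay has probability 1 - eps/2
  s2 <- bandit_session(c(0, 0), c(1, 0))
  expect_equal(rl_nll("wsls", list(eps = 0.2), s2),
               log(2) - log(0.9), tolerance = 1e-10)
  # lose-shift followed: choices L then R after a loss
  s3 <- bandit_session(c(0, 1), c(0, 0))
  expect_equal(rl_nll("wsls", list(eps = 0.2), s3),
               log(2) - log(0.9), tolerance = 1e-10)

  # pure bias model: T * log 2 at b = 0.5
  s4 <- bandit_session(sample(0:1, 25, replace = TRUE), rep(0, 25))
  expect_equal(rl_nll("random", list(b = 0.5), s4), 25 * log(2))
})

test_that("per-trial trace probabilities multiply back to the NLL", {
  set.seed(3)
  s <- bandit_session(sample(0:1, 80, replace = TRUE),
                      sample(0:1, 80, replace = TRUE))
  for (m in c("rl", "rl_eps", "rlck", "rlck_gamma", "rlck_eta")) {
    pars <- switch(m,
                   rl = list(alpha = 0.3, beta = 2),
                   rl_eps = list(alpha = 0.3, beta = 2, eps = 0.1),
                   rlck = list(alpha = 0.3, beta = 2, alpha_c = 0.4,
                               beta_c = 1),
                   rlck_gamma = list(alpha = 0.3, beta = 2, alpha_c = 0.4,
                                     beta_c = 1, gamma = 0.5),
                   rlck_eta = list(alpha = 0.3, beta = 2, alpha_c = 0.4,
                                   beta_c = 1, eta = 0.7))
    res <- rl_nll(m, pars, s, trace = TRUE)
    p <- res$trace[[1]]$p
    pc <- p[cbind(seq_along(s$choices), s$choices + 1)]
    expect_equal(-sum(log(pc)), res$nll, tolerance = 1e-10)
    expect_true(all(p > 0 & p < 1))
    expect_equal(rowSums(p), rep(1, 80), tolerance = 1e-12)
    # Q stays in the convex hull of initial value and rewards
    expect_true(all(res$trace[[1]]$Q >= 0 & res$trace[[1]]$Q <= 1))
  }
})

test_that("nested models collapse onto their parents", {
  set.seed(4)
  s <- bandit_session(sample(0:1, 100, replace = TRUE),
                      sample(0:1, 100, replace = TRUE))
  expect_equal(rl_nll("rl_eps", list(alpha = 0.4, beta = 3, eps = 0), s),
               rl_nll("rl", list(alpha = 0.4, beta = 3), s),
               tolerance = 1e-10)
  # eta model at eta = 1 discards the kernel; with beta doubled it
  # reproduces the plain RL model (beta enters as eta * beta)
  expect_equal(rl_nll("rlck_eta", list(alpha = 0.4, beta = 6, alpha_c = 0.3,
                                       beta_c = 2, eta = 0.5), s),
               rl_nll("rlck", list(alpha = 0.4, beta = 3, alpha_c = 0.3,
                                   beta_c = 1), s),
               tolerance = 1e-10)
  # gamma = 1 removes the loss asymmetry
  expect_equal(rl_nll("rlck_gamma", list(alpha = 0.4, beta = 3,
                                         alpha_c = 0.3, beta_c = 2,
                                         gamma = 1), s),
               rl_nll("rlck", list(alpha = 0.4, beta = 3, alpha_c = 0.3,
                                   beta_c = 2), s),
               tolerance = 1e-10)
})

test_that("parameter bounds are enforced", {
  s <- bandit_session(c(0, 1), c(0, 1))
  expect_error(rl_nll("rl", list(alpha = 1.2, beta = 1), s), "bounds")
  expect_error(rl_nll("wsls", list(eps = 0.7), s), "bounds")
  expect_error(rl_nll("rlck_gamma",
                      list(alpha = 0.9, beta = 1, alpha_c = 0.1, beta_c = 1,
                           gamma = 1.5), s), "gamma")
  expect_error(rl_nll("rl", list(alpha = 0.5), s), "needs parameters")
})

test_that("fitted NLL of a nesting model never exceeds the nested one", {
  set.seed(5)
  pol <- rl_policy("rl", list(alpha = 0.4, beta = 3))
  sessions <- lapply(1:2, function(i)
    simulate_session(pol, generate_reward_walk(300)))
  f_rl <- fit_rl("rl", sessions, n_restarts = 6, seed = 11)
  f_eps <- fit_rl("rl_eps", sessions, n_restarts = 6, seed = 12)
  f_ck <- fit_rl("rlck", sessions, n_restarts = 6, seed = 13)
  expect_lte(f_eps$nll, f_rl$nll + 0.01)
  expect_lte(f_ck$nll, f_rl$nll + 0.01)
})

test_that("maximum likelihood recovers generating parameters", {
  set.seed(6)
  # closed-form check: bias model reduces to the binomial MLE
  pol <- rl_policy("random", list(b = 0.7))
  ss <- lapply(1:10, function(i)
    simulate_session(pol, constant_schedule(0.5, 0.5, 1000)))
  f <- fit_rl("random", ss, n_restarts = 4, seed = 21)
  n <- 10000
  expect_lt(abs(f$params$b - 0.7), 3 * sqrt(0.7 * 0.3 / n))
  emp <- mean(unlist(lapply(ss, function(s) s$choices == 0)))
  expect_equal(f$params$b, emp, tolerance = 1e-3)

  # learning-rate recovery for the choice-kernel model
  hits <- 0
  reps <- 10
  for (r in seq_len(reps)) {
    truth <- list(alpha = 0.35, beta = 4, alpha_c = 0.3, beta_c = 1.5)
    pol <- rl_policy("rlck", truth)
    ss <- lapply(1:4, function(i)
      simulate_session(pol, generate_reward_walk(300)))
    fr <- fit_rl("rlck", ss, n_restarts = 6)
    if (abs(fr$params$alpha - truth$alpha) < 0.1) hits <- hits + 1
  }
  expect_gte(hits, ceiling(0.8 * reps))
})

test_that("refitting with the same seed reproduces the fit exactly", {
  set.seed(8)
  pol <- rl_policy("rl", list(alpha = 0.3, beta = 2))
  ss <- lapply(1:2, function(i)
    simulate_session(pol, generate_reward_walk(200)))
  a <- fit_rl("rl", ss, n_restarts = 5, seed = 99)
  b <- fit_rl("rl", ss, n_restarts = 5, seed = 99)
  expect_identical(a$params, b$params)
  expect_identical(a$nll, b$nll)
})

test_that("model agreement counts majority-rate and perfect predictions", {
  s <- bandit_session(c(rep(0, 7), rep(1, 3)), rep(0, 10))
  f <- structure(list(model_id = "random", params = list(b = 0.7)),
                 class = "rl_fit")
  expect_equal(model_agreement(f, s), 0.7)

  # near-deterministic WSLS agent scored by the matching WSLS model
  set.seed(9)
  polw <- rl_policy("wsls", list(eps = 0.001))
  sw <- simulate_session(polw, constant_schedule(0.5, 0.5, 400))
  fw <- structure(list(model_id = "wsls", params = list(eps = 0.001)),
                  class = "rl_fit")
  expect_gt(model_agreement(fw, sw), 0.99)

  # kernel model beats the bias-only model on its own data
  set.seed(10)
  better <- 0
  for (r in 1:8) {
    pol <- rl_policy("rlck", list(alpha = 0.35, beta = 4, alpha_c = 0.3,
                                  beta_c = 1.5))
    ss <- lapply(1:2, function(i)
      simulate_session(pol, generate_reward_walk(300)))
    fck <- fit_rl("rlck", ss, n_restarts = 5)
    frand <- fit_rl("random", ss, n_restarts = 3)
    if (model_agreement(fck, ss) > model_agreement(frand, ss))
      better <- better + 1
  }
  expect_gte(better, 7)
})

test_that("explore labels mark choices against the decision variable", {
  # hand-constructed: after a rewarded left, Q favors left; choosing
  # right is explore, choosing left is exploit
  s <- bandit_session(c(0, 1, 0), c(1, 0, 0))
  f <- structure(list(model_id = "rl", params = list(alpha = 0.5, beta = 2)),
                 class = "rl_fit")
  labs <- rl_explore_labels(f, s)[[1]]
  expect_equal(labs, c(0L, 1L, 0L))  # tie at trial 1 counts as exploit

  # greedy agent: explore fraction collapses toward zero
  set.seed(11)
  pol <- rl_policy("rl", list(alpha = 0.7, beta = 20))
  sg <- simulate_session(pol, generate_reward_walk(400))
  fg <- structure(list(model_id = "rl", params = list(alpha = 0.7, beta = 20)),
                  class = "rl_fit")
  expect_lt(mean(rl_explore_labels(fg, sg)[[1]]), 0.12)
})

test_that("a maximal learning rate behaves like win-stay lose-shift", {
  set.seed(12)
  pol <- rl_policy("rl", list(alpha = 1, beta = 10))
  s <- simulate_session(pol, generate_reward_walk(2000))
  w <- wsls_rates(s)
  expect_gt(w[["win_stay"]], 1 - w[["lose_shift"]])  # stay|win > stay|loss
  expect_gt(w[["win_stay"]], 0.9)
})

test_that("the exploration regression recovers a planted coefficient", {
  set.seed(13)
  n <- 800
  alpha <- exp(runif(n, log(0.05), log(1)))
  beta <- exp(runif(n, log(0.1), log(10)))
  zb <- as.numeric(scale(log(beta)))
  noise <- rnorm(n, 0, 0.05)
  tab <- data.frame(agent = 1:n, alpha = alpha, beta = beta,
                    p_explore = 0.5 - 0.1 * zb + noise,
                    reward_rate = NA)
  co <- exploration_glm(tab)
  b1 <- co$estimate[co$term == "beta1"]
  se1 <- co$std_error[co$term == "beta1"]
  expect_lt(abs(b1 - (-0.1)), 3 * se1)

  flat <- tab; flat$p_explore <- 0.4
  co0 <- suppressWarnings(exploration_glm(flat))  # zero-residual fit
  expect_equal(co0$estimate, rep(0, 3), tolerance = 1e-10)

  degen <- tab; degen$alpha <- 0.5
  expect_error(exploration_glm(degen), "degenerate")
})

test_that("a small agent grid shows the no-learning exploration ceiling", {
  grid <- exploration_grid_experiment(n_agents = 24, trials = 150, seed = 14,
                                      alpha_range = c(0.01, 1),
                                      beta_range = c(0.5, 8),
                                      n_restarts = 3)
  expect_equal(nrow(grid), 24)
  expect_true(all(is.finite(grid$p_explore)))
  expect_true(all(grid$p_explore >= 0 & grid$p_explore <= 1))
  low_alpha <- grid$alpha < quantile(grid$alpha, 0.25)
  expect_gt(mean(grid$p_explore[low_alpha]),
            mean(grid$p_explore[!low_alpha]))
})
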