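# Independent brute-force oracles used across the HMM tests. These
# deliberately avoid the package's forward/Viterbi code paths: they
# enumerate every latent state path explicitly.

# transition probability i -> j under a spec, given the previous reward
oracle_trans <- function(spec, i, j, prev_reward) {
  P <- if (spec$variant == "io4") build_transition_matrix(spec, prev_reward)
       else build_transition_matrix(spec)
  P[i, j]
}

oracle_emit <- function(state, choice) {
  if (state == 1) return(0.5)
  if (state == 2) return(if (choice == 0) 1 else 0)
  if (choice == 1) 1 else 0
}

# all 3^T state paths with trial 1 forced to explore
oracle_paths <- function(T) {
  if (T == 1) return(matrix(1, 1, 1))
  grid <- do.call(expand.grid, c(list(1), rep(list(1:3), T - 1)))
  as.matrix(grid)
}

oracle_path_prob <- function(spec, session, path) {
  ch <- session$choices; rw <- session$rewards
  p <- oracle_emit(path[1], ch[1])
  if (length(ch) > 1) {
    for (t in 2:length(ch)) {
      p <- p * oracle_trans(spec, path[t - 1], path[t], rw[t - 1]) *
        oracle_emit(path[t], ch[t])
    }
  }
  p
}

# exhaustive-path log-likelihood
oracle_loglik <- function(spec, session) {
  paths <- oracle_paths(length(session$choices))
  log(sum(apply(paths, 1, function(pp) oracle_path_prob(spec, session, pp))))
}

# probability of the single best path (for checking Viterbi optimality)
oracle_best_path_prob <- function(spec, session) {
  paths <- oracle_paths(length(session$choices))
  max(apply(paths, 1, function(pp) oracle_path_prob(spec, session, pp)))
}

# probability of a decoded state_sequence under the model
decoded_path_prob <- function(spec, session, states) {
  path <- as.integer(states$labels)
  oracle_path_prob(spec, session, path)
}

random_session <- function(T, seed) {
  set.seed(seed)
  bandit_session(sample(0:1, T, replace = TRUE),
                 sample(0:1, T, replace = TRUE))
}

# constant two-arm schedule helper
constant_schedule <- function(p_left, p_right, n) {
  structure(list(n_trials = n,
                 p_reward = cbind(rep(p_left, n), rep(p_right, n)),
                 step_prob = 0, step_size = 0.1, bounds = c(0, 1),
                 seed = NULL),
            class = "reward_schedule")
}
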