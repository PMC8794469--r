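#' Generate a restless two-armed reward walk
#'
#' Each arm's reward probability performs an independent random walk: on
#' every trial there is a `step_prob` chance that the arm's probability
#' moves by `step_size` (up or down with equal probability), reflecting at
#' the bounds so probabilities never reach 0 or 1. Whole candidate walks
#' are drawn and rejected until three constraints hold: (1) the two arms'
#' time-averaged probabilities are within 0.02 of each other, (2) neither
#' arm ever leaves the open unit interval (guaranteed by the reflecting
#' bounds), and (3) there is no window of 30 consecutive trials in which
#' both arms are below 0.20.
#'
#' @param n_trials Number of trials (>= 1).
#' @param step_prob Per-trial, per-arm probability of a step (default 0.10).
#' @param step_size Size of a probability step (default 0.10; must be in
#'   (0, 0.5)).
#' @param seed Integer seed making generation deterministic.
#' @param bounds Reflecting bounds for the walk, default `c(0.1, 0.9)`: a
#'   proposed step that would leave the interval is cancelled and the value
#'   stays, which keeps the walk on the grid implied by `step_size`.
#' @param start_values Optional length-2 vector of starting probabilities
#'   (left, right). By default each arm starts uniformly on the
#'   `step_size` grid spanning `[0.2, 0.8]`.
#' @param max_rejections Rejection-sampling budget (default 10000).
#' @param constrained If `FALSE`, the first candidate walk is returned
#'   without constraint checking (useful for studying the raw step
#'   process).
#'
#' @return A `reward_schedule` object: list with `n_trials`, `p_reward`
#'   (an `n_trials` x 2 matrix, column 1 = left arm), `step_prob`,
#'   `step_size`, `bounds`, `seed`.
#' @export
generate_reward_walk <- function(n_trials, step_prob = 0.10, step_size = 0.10,
                                 seed = NULL, bounds = c(0.1, 0.9),
                                 start_values = NULL, max_rejections = 10000,
                                 constrained = TRUE) {
  stopifnot(n_trials >= 1, step_prob >= 0, step_prob <= 1,
            step_size > 0, step_size < 0.5,
            length(bounds) == 2, bounds[1] < bounds[2])
  if (!is.null(seed)) set.seed(seed)

  draw_walk <- function() {
    p <- matrix(NA_real_, n_trials, 2)
    if (is.null(start_values)) {
      grid <- seq(0.2, 0.8, by = step_size)
      p0 <- c(sample(grid, 1), sample(grid, 1))
    } else {
      p0 <- start_values
    }
    p[1, ] <- p0
    if (n_trials > 1) {
      for (t in 2:n_trials) {
        for (arm in 1:2) {
          cur <- p[t - 1, arm]
          if (stats::runif(1) < step_prob) {
            prop <- cur + sample(c(-1, 1), 1) * step_size
            # reflecting bounds: a step that would exit is cancelled
            if (prop >= bounds[1] - 1e-9 && prop <= bounds[2] + 1e-9) cur <- prop
          }
          p[t, arm] <- cur
        }
      }
    }
    p
  }

  mk <- function(p) {
    structure(list(n_trials = n_trials, p_reward = p,
                   step_prob = step_prob, step_size = step_size,
                   bounds = bounds, seed = seed),
              class = "reward_schedule")
  }

  if (!constrained) return(mk(draw_walk()))

  last_violation <- NULL
  for (k in seq_len(max_rejections)) {
    sched <- mk(draw_walk())
    v <- validate_schedule(sched)
    if (length(v) == 0) return(sched)
    last_violation <- v[[1]]$constraint
  }
  stop("failed to generate a valid reward walk within ", max_rejections,
       " candidates; last violated constraint: ", last_violation)
}

#' Check a reward schedule against the walk constraints
#'
#' Diagnostic companion to [generate_reward_walk()]: returns an empty list
#' when the schedule satisfies all constraints, otherwise one descriptor
#' per violated constraint with the first offending trial index.
#'
#' @param schedule A `reward_schedule`.
#' @param mean_tol Maximum allowed difference between the arms'
#'   time-averaged probabilities (default 0.02).
#' @param low_window Length of the disallowed both-arms-low window
#'   (default 30 trials).
#' @param low_threshold Probability below which an arm counts as "low"
#'   (default 0.20).
#' @return List of violations, each a list with `constraint` and `trial`.
#' @export
validate_schedule <- function(schedule, mean_tol = 0.02, low_window = 30,
                              low_threshold = 0.20) {
  p <- schedule$p_reward
  out <- list()

  bad <- which(p <= 0 | p >= 1, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    out[[length(out) + 1]] <- list(
      constraint = "probability at or beyond 0/1 bound",
      trial = min(bad[, 1]))
  }

  gap <- abs(mean(p[, 1]) - mean(p[, 2]))
  if (gap > mean_tol + 1e-12) {
    out[[length(out) + 1]] <- list(
      constraint = sprintf("means differ by > %.2f (gap %.3f)", mean_tol, gap),
      trial = 1L)
  }

  if (nrow(p) >= low_window) {
    low <- p[, 1] < low_threshold & p[, 2] < low_threshold
    runs <- rle(low)
    if (any(runs$values & runs$lengths >= low_window)) {
      idx <- which(runs$values & runs$lengths >= low_window)[1]
      first <- if (idx == 1) 1L else sum(runs$lengths[seq_len(idx - 1)]) + 1L
      out[[length(out) + 1]] <- list(
        constraint = sprintf("%d-trial low-reward window", low_window),
        trial = first)
    }
  }
  out
}

#' @export
print.reward_schedule <- function(x, ...) {
  cat(sprintf("reward_schedule: %d trials, step_prob %.2f, step_size %.2f\n",
              x$n_trials, x$step_prob, x$step_size))
  cat(sprintf("  mean p(left) %.3f, mean p(right) %.3f\n",
              mean(x$p_reward[, 1]), mean(x$p_reward[, 2])))
  invisible(x)
}

#' Construct a session record
#'
#' The universal per-subject-per-session interchange record: choices,
#' rewards, optional latencies, and the generating schedule when known.
#'
#' @param choices Integer vector of arm choices (0 = left, 1 = right).
#' @param rewards Integer vector of 0/1 outcomes, same length.
#' @param subject_id,group,session_index Identifiers.
#' @param response_time,retrieval_time Optional nonnegative latency
#'   vectors (seconds).
#' @param schedule Optional `reward_schedule` with matching `n_trials`.
#' @return A `bandit_session` object.
#' @export
bandit_session <- function(choices, rewards, subject_id = "s1", group = NA,
                           session_index = 1L, response_time = NULL,
                           retrieval_time = NULL, schedule = NULL) {
  choices <- as.integer(choices)
  rewards <- as.integer(rewards)
  stopifnot(length(choices) == length(rewards),
            all(choices %in% c(0L, 1L)), all(rewards %in% c(0L, 1L)))
  if (!is.null(schedule))
    stopifnot(schedule$n_trials == length(choices))
  if (!is.null(response_time))
    stopifnot(length(response_time) == length(choices), all(response_time >= 0))
  if (!is.null(retrieval_time))
    stopifnot(length(retrieval_time) == length(choices), all(retrieval_time >= 0))
  structure(list(subject_id = subject_id, group = group,
                 session_index = as.integer(session_index),
                 choices = choices, rewards = rewards,
                 response_time = response_time,
                 retrieval_time = retrieval_time,
                 schedule = schedule),
            class = "bandit_session")
}

#' @export
print.bandit_session <- function(x, ...) {
  cat(sprintf("bandit_session: subject %s (group %s), session %d, %d trials, reward rate %.3f\n",
              x$subject_id, as.character(x$group), x$session_index,
              length(x$choices), mean(x$rewards)))
  invisible(x)
}

#' Run a choice policy against a reward schedule
#'
#' The policy is called once per trial with the history of prior choices
#' and rewards (both empty on trial 1) and must return the probability of
#' choosing arm 1 (right). The choice is drawn from that probability and
#' the reward from the chosen arm's scheduled probability.
#'
#' @param policy `function(choices, rewards)` returning P(choose right).
#'   Stateful closures are supported; the function is called exactly once
#'   per trial in order.
#' @param schedule A `reward_schedule`.
#' @param seed Integer seed; the same seed, policy and schedule give an
#'   identical session.
#' @param ... Passed to [bandit_session()] (identifiers).
#' @return A `bandit_session` with the schedule attached.
#' @export
simulate_session <- function(policy, schedule, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- schedule$n_trials
  choices <- integer(n)
  rewards <- integer(n)
  for (t in seq_len(n)) {
    p1 <- policy(choices[seq_len(t - 1)], rewards[seq_len(t - 1)])
    if (!is.numeric(p1) || length(p1) != 1 || is.na(p1) || p1 < 0 || p1 > 1)
      stop("policy must return a single probability in [0, 1]")
    choices[t] <- as.integer(stats::runif(1) < p1)
    rewards[t] <- as.integer(stats::runif(1) < schedule$p_reward[t, choices[t] + 1])
  }
  bandit_session(choices, rewards, schedule = schedule, ...)
}

#' Chance reward rate of a schedule
#'
#' The expected reward rate of a policy that chooses uniformly at random:
#' the mean over trials of the two arms' average probability.
#'
#' @param schedule A `reward_schedule`.
#' @return A probability.
#' @export
chance_reward_rate <- function(schedule) {
  mean(rowMeans(schedule$p_reward))
}

#' Write a reward schedule as a delimited table
#'
#' Columns: `trial` (1-based), `p_left`, `p_right`.
#' @param schedule A `reward_schedule`.
#' @param path Output file path (tab-separated).
#' @export
write_schedule <- function(schedule, path) {
  df <- data.frame(trial = seq_len(schedule$n_trials),
                   p_left = schedule$p_reward[, 1],
                   p_right = schedule$p_reward[, 2])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
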