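#' Specify an explore/exploit hidden Markov model
#'
#' Three latent states drive observed choices: an explore state emitting
#' either arm with probability 1/2, and one exploit state per arm emitting
#' that arm deterministically. Exploit states can only be entered and left
#' through exploration, so the transition matrix has structural zeros
#' between the two exploit states. Three variants are supported:
#'
#' * `tied2` — two free parameters: `a` = P(explore -> explore) and
#'   `d` = P(exploit_i -> exploit_i), tied across exploit states; leaving
#'   exploration splits equally between the two exploit states.
#' * `io4` — input-output variant, four parameters `a_win`, `a_loss`,
#'   `d_win`, `d_loss`: the stay probabilities condition on whether the
#'   previous trial was rewarded.
#' * `nt4` — no parameter tying, four parameters: `q_L`, `q_R` =
#'   P(explore -> exploit left/right) and `d_L`, `d_R` = per-arm exploit
#'   stay probabilities (requires `q_L + q_R <= 1`).
#'
#' @param variant One of `"tied2"`, `"io4"`, `"nt4"`.
#' @param params Named list/vector of the variant's parameters.
#' @param n_arms Number of arms; only 2 is exercised.
#' @return An `hmm_spec` object.
#' @export
hmm_spec <- function(variant = c("tied2", "io4", "nt4"), params, n_arms = 2L) {
  variant <- match.arg(variant)
  params <- as.list(params)
  need <- hmm_param_names(variant)
  if (!setequal(names(params), need))
    stop("variant ", variant, " needs parameters: ", paste(need, collapse = ", "))
  vals <- unlist(params[need])
  if (any(vals < 0 | vals > 1)) stop("all HMM parameters must lie in [0, 1]")
  if (variant == "nt4" && params$q_L + params$q_R > 1 + 1e-12)
    stop("nt4 requires q_L + q_R <= 1")
  structure(list(variant = variant, params = params[need],
                 n_arms = as.integer(n_arms)),
            class = "hmm_spec")
}

hmm_param_names <- function(variant) {
  switch(variant,
         tied2 = c("a", "d"),
         io4 = c("a_win", "a_loss", "d_win", "d_loss"),
         nt4 = c("q_L", "q_R", "d_L", "d_R"))
}

#' Build the 3x3 transition matrix of an explore/exploit HMM
#'
#' Rows and columns are ordered explore, exploit-left, exploit-right.
#' For the input-output variant the matrix depends on the previous
#' trial's reward.
#'
#' @param spec An [hmm_spec()].
#' @param prev_reward 0/1, required iff `variant == "io4"`.
#' @return Row-stochastic 3x3 matrix.
#' @export
build_transition_matrix <- function(spec, prev_reward = NULL) {
  p <- spec$params
  if (spec$variant == "io4") {
    if (is.null(prev_reward)) stop("io4 transitions require prev_reward")
    a <- if (prev_reward == 1) p$a_win else p$a_loss
    d <- if (prev_reward == 1) p$d_win else p$d_loss
  } else if (spec$variant == "tied2") {
    a <- p$a; d <- p$d
  }
  if (spec$variant == "nt4") {
    P <- rbind(c(1 - p$q_L - p$q_R, p$q_L, p$q_R),
               c(1 - p$d_L, p$d_L, 0),
               c(1 - p$d_R, 0, p$d_R))
  } else {
    P <- rbind(c(a, (1 - a) / 2, (1 - a) / 2),
               c(1 - d, d, 0),
               c(1 - d, 0, d))
  }
  dimnames(P) <- list(c("explore", "exploit_L", "exploit_R"),
                      c("explore", "exploit_L", "exploit_R"))
  P
}

# Win/loss transition matrices for the C++ kernels (identical matrices
# for reward-independent variants).
transition_pair <- function(spec) {
  if (spec$variant == "io4") {
    list(win = build_transition_matrix(spec, 1),
         loss = build_transition_matrix(spec, 0))
  } else {
    P <- build_transition_matrix(spec)
    list(win = P, loss = P)
  }
}

#' Forward-algorithm log-likelihood of a session under an HMM
#'
#' Scaled forward recursion over the choice sequence, with the initial
#' distribution fixed at explore (sessions start with no knowledge of the
#' arms, so the first trial is exploratory by assumption).
#'
#' @param spec An [hmm_spec()].
#' @param session A [bandit_session()].
#' @return Log-likelihood in nats (<= 0).
#' @export
hmm_loglik <- function(spec, session) {
  P <- transition_pair(spec)
  hmm_forward_cpp(session$choices, session$rewards, P$win, P$loss)
}

#' Fit an explore/exploit HMM by Baum-Welch with random restarts
#'
#' Expectation-maximization on one subject's sessions pooled: each session
#' contributes its own forward-backward pass (starting in explore), and
#' expected transition counts are pooled across sessions — and across tied
#' entries — before the M-step. Emissions and the initial distribution are
#' fixed, so only the transition parameters are estimated. The fit is
#' repeated from `n_restarts` random initializations (stay parameters
#' uniform on (0.5, 0.99)) and the restart with the highest observed-data
#' log-likelihood wins.
#'
#' @param sessions A `bandit_session` or list of them (one subject).
#' @param variant HMM variant, see [hmm_spec()].
#' @param n_restarts Number of random restarts (default 20).
#' @param tol Convergence tolerance on the log-likelihood (nats,
#'   default 1e-6).
#' @param max_iter Maximum EM iterations per restart (default 500).
#' @param seed Integer seed for the restart initializations.
#' @return An `hmm_fit`: list with `spec`, `total_loglik`,
#'   `per_session_loglik`, `n_free_params`, `n_restarts`, `best_restart`,
#'   `converged`, `n_iterations`, `loglik_trace` (best restart's EM trace).
#' @export
fit_hmm <- function(sessions, variant = c("tied2", "io4", "nt4"),
                    n_restarts = 20, tol = 1e-6, max_iter = 500,
                    seed = NULL) {
  variant <- match.arg(variant)
  if (inherits(sessions, "bandit_session")) sessions <- list(sessions)
  stopifnot(length(sessions) >= 1)
  if (!is.null(seed)) set.seed(seed)

  n_free <- if (variant == "tied2") 2L else 4L
  best <- NULL

  for (r in seq_len(n_restarts)) {
    init <- random_hmm_init(variant)
    res <- try(baum_welch(sessions, variant, init, tol, max_iter),
               silent = TRUE)
    if (inherits(res, "try-error")) next
    if (is.null(best) || res$loglik > best$loglik) {
      best <- res
      best$restart <- r
    }
  }
  if (is.null(best)) stop("all EM restarts failed")

  spec <- hmm_spec(variant, best$params)
  per_ll <- vapply(sessions, function(s) hmm_loglik(spec, s), numeric(1))
  structure(list(spec = spec,
                 total_loglik = sum(per_ll),
                 per_session_loglik = per_ll,
                 n_free_params = n_free,
                 n_obs = sum(vapply(sessions, function(s) length(s$choices),
                                    integer(1))),
                 n_restarts = n_restarts,
                 best_restart = best$restart,
                 converged = best$converged,
                 n_iterations = best$n_iter,
                 loglik_trace = best$trace),
            class = "hmm_fit")
}

random_hmm_init <- function(variant) {
  u <- function() stats::runif(1, 0.5, 0.99)
  switch(variant,
         tied2 = list(a = u(), d = u()),
         io4 = list(a_win = u(), a_loss = u(), d_win = u(), d_loss = u()),
         nt4 = {
           a <- u(); w <- stats::runif(1, 0.3, 0.7)
           list(q_L = (1 - a) * w, q_R = (1 - a) * (1 - w),
                d_L = u(), d_R = u())
         })
}

# One EM run from a given initialization. Expected transition counts from
# the forward-backward pass are pooled across sessions; tied entries are
# pooled before re-estimation.
baum_welch <- function(sessions, variant, init, tol, max_iter) {
  params <- init
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0

  for (iter in seq_len(max_iter)) {
    spec <- hmm_spec(variant, params)
    P <- transition_pair(spec)
    xw <- matrix(0, 3, 3); xl <- matrix(0, 3, 3)
    ll <- 0
    for (s in sessions) {
      fb <- hmm_fb_counts_cpp(s$choices, s$rewards, P$win, P$loss)
      ll <- ll + fb$loglik
      xw <- xw + fb$xi_win
      xl <- xl + fb$xi_loss
    }
    trace <- c(trace, ll)

    if (is.finite(ll_old) && ll - ll_old < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll

    params <- switch(variant,
      tied2 = {
        x <- xw + xl
        list(a = safe_ratio(x[1, 1], sum(x[1, ])),
             d = safe_ratio(x[2, 2] + x[3, 3], sum(x[2, ]) + sum(x[3, ])))
      },
      io4 = list(
        a_win  = safe_ratio(xw[1, 1], sum(xw[1, ])),
        a_loss = safe_ratio(xl[1, 1], sum(xl[1, ])),
        d_win  = safe_ratio(xw[2, 2] + xw[3, 3], sum(xw[2, ]) + sum(xw[3, ])),
        d_loss = safe_ratio(xl[2, 2] + xl[3, 3], sum(xl[2, ]) + sum(xl[3, ]))),
      nt4 = {
        x <- xw + xl
        er <- sum(x[1, ])
        list(q_L = safe_ratio(x[1, 2], er), q_R = safe_ratio(x[1, 3], er),
             d_L = safe_ratio(x[2, 2], sum(x[2, ])),
             d_R = safe_ratio(x[3, 3], sum(x[3, ])))
      })
  }
  list(params = params, loglik = trace[length(trace)], trace = trace,
       converged = converged, n_iter = iter)
}

# Ratio of expected counts, guarded against an unvisited conditioning
# state (keeps the parameter interior instead of producing NaN).
safe_ratio <- function(num, den) {
  if (den <= 0) return(0.5)
  min(max(num / den, 1e-6), 1 - 1e-6)
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat(sprintf("hmm_fit (%s): logLik %.2f over %d trials, %s after %d iterations\n",
              x$spec$variant, x$total_loglik, x$n_obs,
              if (x$converged) "converged" else "not converged",
              x$n_iterations))
  cat("  params:", paste(sprintf("%s = %.3f", names(x$spec$params),
                                 unlist(x$spec$params)), collapse = ", "), "\n")
  invisible(x)
}

#' Decode the most probable explore/exploit state path
#'
#' Viterbi decoding under a given or fitted model, with trial 1
#' constrained to explore and ties broken toward explore.
#'
#' @param spec An [hmm_spec()] or `hmm_fit`.
#' @param session A [bandit_session()].
#' @return A `state_sequence`: list with `labels` (factor with levels
#'   explore, exploit_L, exploit_R) and `binary_explore` (0/1 vector).
#' @export
viterbi_decode <- function(spec, session) {
  if (inherits(spec, "hmm_fit")) spec <- spec$spec
  P <- transition_pair(spec)
  path <- hmm_viterbi_cpp(session$choices, session$rewards, P$win, P$loss)
  lv <- c("explore", "exploit_L", "exploit_R")
  structure(list(labels = factor(lv[path + 1], levels = lv),
                 binary_explore = as.integer(path == 0)),
            class = "state_sequence")
}

#' Information criteria and relative likelihoods for a set of fits
#'
#' AIC = 2k - 2LL and BIC = k log(n_obs) - 2LL, where for per-subject
#' fits the free-parameter count aggregates across subjects
#' (k = parameters-per-subject x n_subjects) and the log-likelihood sums
#' across subjects. The relative likelihood (Akaike weight against the
#' best model) of model m is exp((AIC_best - AIC_m) / 2), and analogously
#' for BIC.
#'
#' @param fits Named list. Each element is either a single fit or a list
#'   of per-subject fits (objects carrying `total_loglik`/`nll` and
#'   `n_free_params`).
#' @param n_obs Total number of observations (trials) across all fits'
#'   data; used by BIC.
#' @return Data frame with model, loglik, k, AIC, BIC, delta_AIC,
#'   rel_lik_AIC (relative likelihood vs the AIC-best model),
#'   rel_lik_BIC.
#' @export
information_criteria <- function(fits, n_obs) {
  if (n_obs <= 0) stop("n_obs must be positive")
  one <- function(f) {
    if (inherits(f, c("hmm_fit", "rl_fit"))) f <- list(f)
    ll <- sum(vapply(f, function(x) {
      if (!is.null(x$total_loglik)) x$total_loglik else -x$nll
    }, numeric(1)))
    k <- sum(vapply(f, function(x) x$n_free_params, numeric(1)))
    c(loglik = ll, k = k)
  }
  m <- t(vapply(fits, one, numeric(2)))
  aic <- 2 * m[, "k"] - 2 * m[, "loglik"]
  bic <- m[, "k"] * log(n_obs) - 2 * m[, "loglik"]
  data.frame(model = names(fits), loglik = m[, "loglik"], k = m[, "k"],
             AIC = aic, BIC = bic,
             delta_AIC = aic - min(aic),
             rel_lik_AIC = exp((min(aic) - aic) / 2),
             rel_lik_BIC = exp((min(bic) - bic) / 2),
             row.names = NULL)
}

#' Fraction of trials labeled exploratory
#'
#' @param states A `state_sequence` (or 0/1 vector of explore labels).
#' @param bins Optional number of equal-width within-session bins; when
#'   given, returns the per-bin explore fraction instead of the overall
#'   one.
#' @return A fraction, or a numeric vector of per-bin fractions.
#' @export
explore_fraction <- function(states, bins = NULL) {
  b <- if (inherits(states, "state_sequence")) states$binary_explore else states
  stopifnot(length(b) >= 1)
  if (is.null(bins)) return(mean(b))
  if (bins > length(b)) stop("more bins than trials")
  idx <- cut(seq_along(b), breaks = bins, labels = FALSE)
  as.numeric(tapply(b, idx, mean))
}

#' Simulate choices from an explore/exploit HMM agent
#'
#' Generative counterpart of the fitted model: latent states evolve by
#' the spec's transition matrix (starting in explore), choices are
#' emitted uniformly during exploration and deterministically during
#' exploitation, and rewards are drawn from the schedule.
#'
#' @param spec An [hmm_spec()].
#' @param schedule A `reward_schedule`.
#' @param seed Integer seed.
#' @param ... Identifiers passed to [bandit_session()].
#' @return List with `session` (a `bandit_session`) and `states` (the
#'   ground-truth `state_sequence`).
#' @export
simulate_hmm_agent <- function(spec, schedule, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- schedule$n_trials
  states <- integer(n)
  choices <- integer(n)
  rewards <- integer(n)
  states[1] <- 0L
  for (t in seq_len(n)) {
    if (t > 1) {
      P <- if (spec$variant == "io4")
        build_transition_matrix(spec, rewards[t - 1])
      else build_transition_matrix(spec)
      states[t] <- sample(0:2, 1, prob = P[states[t - 1] + 1, ])
    }
    choices[t] <- switch(states[t] + 1L,
                         as.integer(stats::runif(1) < 0.5),  # explore
                         0L,                                  # exploit left
                         1L)                                  # exploit right
    rewards[t] <- as.integer(stats::runif(1) <
                             schedule$p_reward[t, choices[t] + 1])
  }
  lv <- c("explore", "exploit_L", "exploit_R")
  list(session = bandit_session(choices, rewards, schedule = schedule, ...),
       states = structure(list(labels = factor(lv[states + 1], levels = lv),
                               binary_explore = as.integer(states == 0)),
                          class = "state_sequence"))
}
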