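#' @useDynLib exploreExploit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Registry of the seven candidate likelihood models: integer code used by
# the compiled kernel, parameter names, and box bounds for fitting.
rl_model_table <- function() {
  list(
    random     = list(code = 1L, pars = "b",
                      lower = 0,                 upper = 1),
    wsls       = list(code = 2L, pars = "eps",
                      lower = 0,                 upper = 0.5),
    rl         = list(code = 3L, pars = c("alpha", "beta"),
                      lower = c(0, 0),           upper = c(1, 20)),
    rl_eps     = list(code = 4L, pars = c("alpha", "beta", "eps"),
                      lower = c(0, 0, 0),        upper = c(1, 20, 0.5)),
    rlck       = list(code = 5L, pars = c("alpha", "beta", "alpha_c", "beta_c"),
                      lower = c(0, 0, 0, 0),     upper = c(1, 20, 1, 20)),
    rlck_gamma = list(code = 6L,
                      pars = c("alpha", "beta", "alpha_c", "beta_c", "gamma"),
                      lower = c(0, 0, 0, 0, 0),  upper = c(1, 20, 1, 20, 2)),
    rlck_eta   = list(code = 7L,
                      pars = c("alpha", "beta", "alpha_c", "beta_c", "eta"),
                      lower = c(0, 0, 0, 0, 0),  upper = c(1, 20, 1, 20, 1)))
}

#' Names and bounds of the RL model family
#'
#' @return Character vector of the seven model identifiers: `random`
#'   (side bias only), `wsls` (noisy win-stay/lose-shift), `rl`
#'   (delta-rule values + softmax), `rl_eps` (adds a lapse rate), `rlck`
#'   (adds a choice kernel), `rlck_gamma` (adds asymmetric learning from
#'   losses), `rlck_eta` (adds a value-vs-kernel policy mixing weight).
#' @export
rl_models <- function() names(rl_model_table())

check_rl_params <- function(model_id, params) {
  info <- rl_model_table()[[model_id]]
  if (is.null(info)) stop("unknown model: ", model_id)
  if (!setequal(names(params), info$pars))
    stop(model_id, " needs parameters: ", paste(info$pars, collapse = ", "))
  v <- unlist(params[info$pars])
  if (any(v < info$lower - 1e-9) || any(v > info$upper + 1e-9))
    stop("parameter out of bounds for ", model_id)
  if (model_id == "rlck_gamma" && v["gamma"] * v["alpha"] > 1 + 1e-9)
    stop("rlck_gamma requires gamma * alpha <= 1")
  v
}

#' Negative log-likelihood of sessions under an RL model
#'
#' Per-trial choice probabilities under the named model; values and
#' choice kernels reset at each session start (Q at 0.5 per arm, kernel
#' at 0). Only the chosen arm's value updates (delta rule); the kernel
#' updates for every arm toward its chosen indicator.
#'
#' @param model_id One of [rl_models()].
#' @param params Named parameter list/vector for the model.
#' @param sessions A `bandit_session` or list of them.
#' @param trace If `TRUE`, also return the per-trial latent trace.
#' @return The NLL in nats; with `trace = TRUE`, a list with `nll` and
#'   `trace` (per session: matrices `Q`, `CK`, `p` of per-arm values,
#'   kernels and choice probabilities as they stood entering each trial).
#' @export
rl_nll <- function(model_id, params, sessions, trace = FALSE) {
  v <- check_rl_params(model_id, params)
  code <- rl_model_table()[[model_id]]$code
  if (inherits(sessions, "bandit_session")) sessions <- list(sessions)
  stopifnot(length(sessions) >= 1)
  total <- 0
  traces <- if (trace) vector("list", length(sessions)) else NULL
  for (i in seq_along(sessions)) {
    s <- sessions[[i]]
    res <- rl_nll_cpp(code, v, s$choices, s$rewards, trace)
    total <- total + res$nll
    if (trace) traces[[i]] <- res[c("Q", "CK", "p")]
  }
  if (trace) list(nll = total, trace = traces) else total
}

#' Fit an RL model by bounded maximum likelihood with restarts
#'
#' L-BFGS-B on the model's box constraints, restarted from
#' `n_restarts` uniform-random initializations; the best optimum wins.
#' The `gamma * alpha <= 1` constraint of the asymmetric-learning model
#' is enforced by a smooth penalty inside the objective.
#'
#' @param model_id One of [rl_models()].
#' @param sessions A `bandit_session` or list of them.
#' @param n_restarts Number of random restarts (default 10).
#' @param seed Integer seed for the initializations.
#' @param fit_unit `"subject"` pools all sessions into one fit;
#'   `"session"` returns a list of per-session fits (for drift-of-
#'   parameters analyses).
#' @return An `rl_fit`: `model_id`, `params`, `nll`, `n_free_params`,
#'   `n_obs`, `aic`, `bic`, `converged`, `n_restarts`, plus `agreement`
#'   (filled by [model_agreement()]). With `fit_unit = "session"`, a list
#'   of `rl_fit`s.
#' @export
fit_rl <- function(model_id, sessions, n_restarts = 10, seed = NULL,
                   fit_unit = c("subject", "session")) {
  fit_unit <- match.arg(fit_unit)
  if (inherits(sessions, "bandit_session")) sessions <- list(sessions)
  if (!is.null(seed)) set.seed(seed)
  if (fit_unit == "session")
    return(lapply(sessions, function(s)
      fit_rl_once(model_id, list(s), n_restarts)))
  fit_rl_once(model_id, sessions, n_restarts)
}

fit_rl_once <- function(model_id, sessions, n_restarts) {
  info <- rl_model_table()[[model_id]]
  code <- info$code
  np <- length(info$pars)
  lower <- rep_len(info$lower, np)
  upper <- rep_len(info$upper, np)

  obj <- function(x) {
    total <- 0
    for (s in sessions)
      total <- total + rl_nll_cpp(code, x, s$choices, s$rewards, FALSE)$nll
    if (model_id == "rlck_gamma") {
      excess <- x[5] * x[1] - 1
      if (excess > 0) total <- total + 1e4 * excess^2
    }
    total
  }

  best <- NULL
  converged <- FALSE
  for (r in seq_len(n_restarts)) {
    x0 <- stats::runif(np, lower + 0.01 * (upper - lower),
                       upper - 0.01 * (upper - lower))
    o <- try(stats::optim(x0, obj, method = "L-BFGS-B",
                          lower = lower, upper = upper,
                          control = list(maxit = 300)), silent = TRUE)
    if (inherits(o, "try-error")) next
    if (o$convergence == 0) converged <- TRUE
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) stop("all optimizer restarts failed for ", model_id)

  pars <- as.list(best$par)
  names(pars) <- info$pars
  if (model_id == "rlck_gamma" && pars$gamma * pars$alpha > 1)
    pars$gamma <- 1 / pars$alpha
  n_obs <- sum(vapply(sessions, function(s) length(s$choices), integer(1)))
  structure(list(model_id = model_id, params = pars, nll = best$value,
                 n_free_params = np, n_obs = n_obs,
                 aic = 2 * np + 2 * best$value,
                 bic = np * log(n_obs) + 2 * best$value,
                 converged = converged, n_restarts = n_restarts,
                 agreement = NA_real_),
            class = "rl_fit")
}

#' @export
print.rl_fit <- function(x, ...) {
  cat(sprintf("rl_fit (%s): NLL %.2f over %d trials, AIC %.1f%s\n",
              x$model_id, x$nll, x$n_obs, x$aic,
              if (isTRUE(x$converged)) "" else " [not converged]"))
  cat("  params:", paste(sprintf("%s = %.3f", names(x$params),
                                 unlist(x$params)), collapse = ", "), "\n")
  invisible(x)
}

#' Fraction of choices correctly predicted by a fitted model
#'
#' A trial counts as correctly predicted when the model's
#' higher-probability arm (under the fitted parameters) matches the
#' observed choice; exact ties earn half credit.
#'
#' @param fit An `rl_fit`.
#' @param sessions The sessions to score.
#' @return A fraction in \[0, 1\].
#' @export
model_agreement <- function(fit, sessions) {
  if (inherits(sessions, "bandit_session")) sessions <- list(sessions)
  res <- rl_nll(fit$model_id, fit$params, sessions, trace = TRUE)
  hits <- 0; n <- 0
  for (i in seq_along(sessions)) {
    p <- res$trace[[i]]$p
    ch <- sessions[[i]]$choices
    pred_right <- p[, 2] - p[, 1]
    score <- ifelse(pred_right == 0, 0.5,
                    as.numeric((pred_right > 0) == (ch == 1)))
    hits <- hits + sum(score)
    n <- n + length(ch)
  }
  hits / n
}

# Combined decision variable per arm (the quantity inside the softmax)
# for a fitted model, one matrix per session.
decision_variables <- function(fit, sessions) {
  res <- rl_nll(fit$model_id, fit$params, sessions, trace = TRUE)
  p <- fit$params
  lapply(res$trace, function(tr) {
    switch(fit$model_id,
           random = , wsls = log(pmax(tr$p, 1e-12)),
           rl = , rl_eps = p$beta * tr$Q,
           rlck = p$beta * tr$Q + p$beta_c * tr$CK,
           rlck_gamma = p$beta * tr$Q + p$beta_c * tr$CK,
           rlck_eta = p$eta * p$beta * tr$Q +
             (1 - p$eta) * p$beta_c * tr$CK)
  })
}

#' Label exploratory choices from a fitted RL model
#'
#' A trial is labeled exploratory when the chosen arm's combined decision
#' variable (value plus any kernel term, as weighted by the fitted
#' model) is strictly lower than the unchosen arm's — i.e. the choice
#' deviates from the model's value-maximizing prediction. Ties count as
#' exploitation.
#'
#' @param fit An `rl_fit`.
#' @param sessions The sessions to label.
#' @return List of per-session 0/1 vectors (1 = explore).
#' @export
rl_explore_labels <- function(fit, sessions) {
  if (inherits(sessions, "bandit_session")) sessions <- list(sessions)
  dv <- decision_variables(fit, sessions)
  lapply(seq_along(sessions), function(i) {
    ch <- sessions[[i]]$choices
    z <- dv[[i]]
    chosen <- z[cbind(seq_along(ch), ch + 1)]
    other <- z[cbind(seq_along(ch), 2 - ch)]
    as.integer(chosen < other)
  })
}

#' Policy closure for simulating an RL agent
#'
#' Returns a stateful policy suitable for [simulate_session()]: it tracks
#' its own values/kernel incrementally from the history it is shown.
#'
#' @param model_id One of [rl_models()].
#' @param params Named parameters for the model.
#' @return `function(choices, rewards)` returning P(choose right).
#' @export
rl_policy <- function(model_id, params) {
  check_rl_params(model_id, params)
  p <- params
  Q <- c(0.5, 0.5)
  CK <- c(0, 0)
  prev_t <- 0L
  function(choices, rewards) {
    t <- length(choices) + 1L
    if (t == 1L) { Q <<- c(0.5, 0.5); CK <<- c(0, 0); prev_t <<- 0L }
    if (t > 1L && prev_t == t - 1L) {
      c_prev <- choices[t - 1]; r_prev <- rewards[t - 1]
      if (model_id %in% c("rl", "rl_eps", "rlck", "rlck_gamma", "rlck_eta")) {
        lr <- p$alpha
        if (model_id == "rlck_gamma" && r_prev == 0) lr <- p$gamma * p$alpha
        Q[c_prev + 1] <<- Q[c_prev + 1] + lr * (r_prev - Q[c_prev + 1])
      }
      if (model_id %in% c("rlck", "rlck_gamma", "rlck_eta")) {
        ind <- c(c_prev == 0, c_prev == 1)
        CK <<- CK + p$alpha_c * (ind - CK)
      }
    }
    prev_t <<- t
    switch(model_id,
           random = 1 - p$b,
           wsls = {
             if (t == 1L) 0.5
             else {
               favored <- if (rewards[t - 1] == 1) choices[t - 1]
                          else 1 - choices[t - 1]
               if (favored == 1) 1 - p$eps / 2 else p$eps / 2
             }
           },
           {
             z <- switch(model_id,
                         rl = , rl_eps = p$beta * Q,
                         rlck = , rlck_gamma = p$beta * Q + p$beta_c * CK,
                         rlck_eta = p$eta * p$beta * Q +
                           (1 - p$eta) * p$beta_c * CK)
             pr <- 1 / (1 + exp(z[1] - z[2]))  # P(right)
             if (model_id == "rl_eps") pr <- p$eps + (1 - 2 * p$eps) * pr
             pr
           })
  }
}

#' Grid simulation: how learning rate and decision noise drive exploration
#'
#' Simulates delta-rule softmax agents at random (learning rate, inverse
#' temperature) combinations, each on a fresh restless schedule, then
#' fits the tied explore/exploit HMM to each agent's choices and decodes
#' its explore fraction. Also records each agent's obtained reward rate.
#' Both parameters are drawn log-uniformly over their ranges: each spans
#' more than a decade and the behaviorally distinct regimes (e.g. the
#' slow-learning region where decision noise stops mattering) live at
#' the low end, which uniform sampling would barely visit.
#'
#' @param n_agents Number of agents (the full experiment uses 10000; a
#'   few hundred suffice for the qualitative pattern).
#' @param alpha_range,beta_range Ranges from which each agent's learning
#'   rate and inverse temperature are drawn log-uniformly.
#' @param trials Trials per agent (default 300).
#' @param seed Integer seed.
#' @param n_restarts HMM fitting restarts per agent (default 5; each
#'   agent is a single session so the likelihood surface is simple).
#' @return Data frame: `agent`, `alpha`, `beta`, `p_explore`,
#'   `reward_rate`.
#' @export
exploration_grid_experiment <- function(n_agents = 10000,
                                        alpha_range = c(0.01, 1),
                                        beta_range = c(0.1, 10),
                                        trials = 300, seed = NULL,
                                        n_restarts = 5) {
  if (!is.null(seed)) set.seed(seed)
  alphas <- exp(stats::runif(n_agents, log(alpha_range[1]),
                             log(alpha_range[2])))
  betas <- exp(stats::runif(n_agents, log(beta_range[1]),
                            log(beta_range[2])))
  p_explore <- rep(NA_real_, n_agents)
  reward_rate <- rep(NA_real_, n_agents)
  for (i in seq_len(n_agents)) {
    res <- try({
      sched <- generate_reward_walk(trials)
      pol <- rl_policy("rl", list(alpha = alphas[i], beta = betas[i]))
      s <- simulate_session(pol, sched)
      fit <- fit_hmm(s, "tied2", n_restarts = n_restarts)
      st <- viterbi_decode(fit, s)
      c(explore_fraction(st), mean(s$rewards))
    }, silent = TRUE)
    if (!inherits(res, "try-error")) {
      p_explore[i] <- res[1]
      reward_rate[i] <- res[2]
    }
  }
  data.frame(agent = seq_len(n_agents), alpha = alphas, beta = betas,
             p_explore = p_explore, reward_rate = reward_rate)
}

#' Regress exploration on learning rate and decision noise
#'
#' Ordinary least squares of the per-agent explore fraction on z-scored
#' log inverse temperature, z-scored log learning rate, and their
#' product, as a compact summary of the grid experiment. Standardizing
#' on the log scale matches how the agents are sampled and spreads the
#' decades of each parameter evenly.
#'
#' @param grid_table Output of [exploration_grid_experiment()].
#' @return Data frame with `term` (`beta1` = inverse temperature,
#'   `beta2` = learning rate, `beta3` = interaction), `estimate`,
#'   `std_error`, `p_value`.
#' @export
exploration_glm <- function(grid_table) {
  g <- grid_table[stats::complete.cases(grid_table[, c("alpha", "beta",
                                                       "p_explore")]), ]
  if (nrow(g) == 0) stop("empty grid table")
  if (stats::sd(g$alpha) == 0 || stats::sd(g$beta) == 0)
    stop("degenerate (constant) predictor")
  zb <- as.numeric(scale(log(g$beta)))
  za <- as.numeric(scale(log(g$alpha)))
  fit <- stats::lm(g$p_explore ~ zb + za + I(zb * za))
  sm <- summary(fit)$coefficients
  data.frame(term = c("beta1", "beta2", "beta3"),
             estimate = sm[2:4, 1], std_error = sm[2:4, 2],
             p_value = sm[2:4, 4], row.names = NULL)
}
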