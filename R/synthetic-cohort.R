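#' Configuration for a synthetic behavioral cohort
#'
#' Describes a two-group cohort of simulated agents performing the
#' restless bandit: group sizes, session structure, the generating model
#' and its per-group parameter distributions (truncated normal), and a
#' log-normal latency model. The default preset mirrors the qualitative
#' group structure the downstream analyses are designed to detect: group
#' "F" has a higher learning rate (or, for the HMM generator, lower
#' explore-state stickiness) than group "M", responds faster, and both
#' groups respond slower during exploration than exploitation. Retrieval
#' times are state-independent.
#'
#' @param model_id Generating model: one of [rl_models()] or
#'   `"hmm_tied"`. Default `"rlck"` (value learning plus a choice
#'   kernel).
#' @param n_per_group Subjects per group (default 16).
#' @param sessions_per_subject Sessions per subject (default 8).
#' @param trials_per_session Trials per session (default 300).
#' @param group_labels Two group labels (default `c("F", "M")`).
#' @param param_means Named list per group of named parameter means; a
#'   built-in preset is used when `NULL`.
#' @param param_sds Named list per group of parameter SDs (>= 0); preset
#'   when `NULL`.
#' @param latency List with `rt_exploit` (named per-group mean RT during
#'   exploitation, seconds), `rt_explore_gap` (added mean RT during
#'   exploration), `rt_sdlog` (log-normal shape; 0 = noiseless),
#'   `retrieval_mean`, `retrieval_sdlog`.
#' @param schedule Walk settings passed to [generate_reward_walk()]
#'   (`step_prob`, `step_size`).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(model_id = "rlck", n_per_group = 16,
                          sessions_per_subject = 8,
                          trials_per_session = 300,
                          group_labels = c("F", "M"),
                          param_means = NULL, param_sds = NULL,
                          latency = NULL, schedule = NULL) {
  stopifnot(n_per_group >= 1, sessions_per_subject >= 1,
            trials_per_session >= 1, length(group_labels) == 2)
  if (is.null(param_means)) param_means <- cohort_preset(model_id, group_labels)$means
  if (is.null(param_sds)) param_sds <- cohort_preset(model_id, group_labels)$sds
  if (is.null(latency)) {
    latency <- list(rt_exploit = stats::setNames(c(1.0, 1.5), group_labels),
                    rt_explore_gap = 0.5, rt_sdlog = 0.3,
                    retrieval_mean = 2.0, retrieval_sdlog = 0.3)
  }
  stopifnot(all(unlist(latency[c("rt_exploit", "retrieval_mean")]) > 0),
            latency$rt_explore_gap >= 0, latency$rt_sdlog >= 0)
  if (is.null(schedule)) schedule <- list(step_prob = 0.10, step_size = 0.10)
  structure(list(model_id = model_id, n_per_group = n_per_group,
                 sessions_per_subject = sessions_per_subject,
                 trials_per_session = trials_per_session,
                 group_labels = group_labels,
                 param_means = param_means, param_sds = param_sds,
                 latency = latency, schedule = schedule),
            class = "cohort_config")
}

# Default per-group parameter distributions. The HMM preset uses the
# stay-probability group means the tied model is meant to recover
# (explore-stay 0.921/0.831, exploit-stay 0.835/0.797, group M deeper in
# exploration); the RL presets put the group difference in learning rate
# only, with shared decision noise and choice-kernel settings.
cohort_preset <- function(model_id, group_labels) {
  g1 <- group_labels[1]; g2 <- group_labels[2]  # F, M by default
  if (model_id == "hmm_tied") {
    means <- list(list(a = 0.831, d = 0.797), list(a = 0.921, d = 0.835))
    sds <- list(list(a = 0.08, d = 0.08), list(a = 0.034, d = 0.037))
  } else if (model_id %in% c("rl", "rl_eps")) {
    base <- list(alpha = 0.25, beta = 3)
    m1 <- base; m1$alpha <- 0.45
    means <- list(m1, base)
    if (model_id == "rl_eps") {
      means[[1]]$eps <- 0.05; means[[2]]$eps <- 0.05
    }
    sds <- lapply(means, function(m) lapply(m, function(x) 0.05))
  } else if (model_id %in% c("rlck", "rlck_gamma", "rlck_eta")) {
    base <- list(alpha = 0.25, beta = 3, alpha_c = 0.3, beta_c = 1.5)
    if (model_id == "rlck_gamma") base$gamma <- 0.8
    if (model_id == "rlck_eta") base$eta <- 0.6
    m1 <- base; m1$alpha <- 0.45
    means <- list(m1, base)
    sds <- lapply(means, function(m) lapply(m, function(x) 0.05))
  } else if (model_id == "random") {
    means <- list(list(b = 0.5), list(b = 0.5))
    sds <- list(list(b = 0.05), list(b = 0.05))
  } else if (model_id == "wsls") {
    means <- list(list(eps = 0.2), list(eps = 0.3))
    sds <- list(list(eps = 0.05), list(eps = 0.05))
  } else stop("no preset for model ", model_id)
  list(means = stats::setNames(means, c(g1, g2)),
       sds = stats::setNames(sds, c(g1, g2)))
}

param_bounds <- function(model_id, par) {
  if (model_id == "hmm_tied") return(c(0.01, 0.99))
  info <- rl_model_table()[[model_id]]
  i <- match(par, info$pars)
  c(rep_len(info$lower, length(info$pars))[i],
    rep_len(info$upper, length(info$pars))[i])
}

rtruncnorm1 <- function(mean, sd, lo, hi) {
  if (mean < lo - 10 * max(sd, 1e-12) || mean > hi + 10 * max(sd, 1e-12))
    stop("parameter distribution has essentially no mass inside bounds [",
         lo, ", ", hi, "]")
  if (sd == 0) return(min(max(mean, lo), hi))
  for (i in 1:1000) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  min(max(mean, lo), hi)
}

#' Draw per-subject generating parameters for a cohort
#'
#' Each subject's parameters are drawn from its group's truncated-normal
#' distribution (truncation at the model's legal bounds).
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return List of `agent_params`: `subject_id`, `group`, `model_id`,
#'   `params` (named list).
#' @export
sample_cohort_params <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  agents <- list()
  sid <- 0
  for (g in config$group_labels) {
    mu <- config$param_means[[g]]
    sds <- config$param_sds[[g]]
    for (i in seq_len(config$n_per_group)) {
      sid <- sid + 1
      pars <- lapply(names(mu), function(par) {
        b <- param_bounds(config$model_id, par)
        rtruncnorm1(mu[[par]], sds[[par]], b[1], b[2])
      })
      names(pars) <- names(mu)
      if (config$model_id == "rlck_gamma" &&
          pars$gamma * pars$alpha > 1)
        pars$gamma <- 1 / pars$alpha
      agents[[sid]] <- structure(
        list(subject_id = sprintf("%s%02d", g, i), group = g,
             model_id = config$model_id, params = pars),
        class = "agent_params")
    }
  }
  agents
}

#' Generate a full synthetic cohort
#'
#' For every subject and session, draws a fresh reward walk and simulates
#' the configured generative model against it, then attaches latencies.
#' Ground truth (generating parameters and, where defined, per-trial
#' explore states) is retained so recovery can be scored downstream. For
#' HMM agents the true states are the simulated latent states; for RL
#' agents they are the trials on which the agent's own decision variable
#' favored the unchosen arm.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; the full cohort is deterministic given it.
#' @return List with `sessions` (list of `bandit_session`), `agents`
#'   (list of `agent_params`), `true_states` (list aligned with
#'   `sessions` of 0/1 explore vectors), and `config`.
#' @export
generate_cohort <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  agents <- sample_cohort_params(config)
  sessions <- list()
  true_states <- list()
  k <- 0
  for (ag in agents) {
    for (si in seq_len(config$sessions_per_subject)) {
      k <- k + 1
      sched <- generate_reward_walk(config$trials_per_session,
                                    step_prob = config$schedule$step_prob,
                                    step_size = config$schedule$step_size)
      if (config$model_id == "hmm_tied") {
        sim <- simulate_hmm_agent(hmm_spec("tied2", ag$params), sched,
                                  subject_id = ag$subject_id,
                                  group = ag$group, session_index = si)
        s <- sim$session
        ts <- sim$states$binary_explore
      } else {
        pol <- rl_policy(ag$model_id, ag$params)
        s <- simulate_session(pol, sched, subject_id = ag$subject_id,
                              group = ag$group, session_index = si)
        pseudo_fit <- structure(list(model_id = ag$model_id,
                                     params = ag$params), class = "rl_fit")
        ts <- rl_explore_labels(pseudo_fit, s)[[1]]
      }
      sessions[[k]] <- s
      true_states[[k]] <- ts
    }
  }
  sessions <- attach_latencies(sessions, true_states, config)
  list(sessions = sessions, agents = agents, true_states = true_states,
       config = config)
}

#' Attach response and retrieval latencies to sessions
#'
#' Response times are log-normal with a state- and group-dependent mean:
#' the configured exploit-state mean per group, plus a fixed gap during
#' exploration. Retrieval times are log-normal and state-independent.
#' With `rt_sdlog = 0` the latencies equal the configured means exactly.
#'
#' @param sessions List of `bandit_session`.
#' @param true_states List of aligned 0/1 explore vectors (or
#'   `state_sequence`s).
#' @param config A [cohort_config()] supplying the latency model.
#' @param seed Optional integer seed.
#' @return The sessions with `response_time` and `retrieval_time` filled.
#' @export
attach_latencies <- function(sessions, true_states, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lat <- config$latency
  lapply(seq_along(sessions), function(i) {
    s <- sessions[[i]]
    ex <- true_states[[i]]
    if (inherits(ex, "state_sequence")) ex <- ex$binary_explore
    stopifnot(length(ex) == length(s$choices))
    base <- lat$rt_exploit[[as.character(s$group)]]
    if (is.null(base) || is.na(base)) base <- mean(unlist(lat$rt_exploit))
    mu <- base + lat$rt_explore_gap * ex
    s$response_time <- draw_lognormal(mu, lat$rt_sdlog)
    s$retrieval_time <- draw_lognormal(rep(lat$retrieval_mean, length(ex)),
                                       lat$retrieval_sdlog)
    s
  })
}

# log-normal draws parameterized by their arithmetic mean
draw_lognormal <- function(means, sdlog) {
  if (sdlog == 0) return(means)
  meanlog <- log(means) - sdlog^2 / 2
  stats::rlnorm(length(means), meanlog, sdlog)
}
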