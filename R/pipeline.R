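#' Write sessions as one tidy per-trial table
#'
#' Tab-separated columns: subject, group, session, trial (1-based),
#' choice (0 = left), reward, response_time, retrieval_time, p_left,
#' p_right, and optionally hmm_state (E/L/R) and rl_explore (0/1).
#'
#' @param sessions List of `bandit_session`.
#' @param path Output path; when `NULL`, the data frame is returned
#'   instead of written.
#' @param hmm_states,rl_explore Optional lists aligned with `sessions`
#'   (`state_sequence`s / 0-1 vectors) appended as label columns.
#' @return The path (invisibly) or the data frame.
#' @export
write_sessions <- function(sessions, path = NULL, hmm_states = NULL,
                           rl_explore = NULL) {
  if (inherits(sessions, "bandit_session")) sessions <- list(sessions)
  rows <- lapply(seq_along(sessions), function(i) {
    s <- sessions[[i]]
    n <- length(s$choices)
    df <- data.frame(subject = s$subject_id,
                     group = as.character(s$group),
                     session = s$session_index,
                     trial = seq_len(n),
                     choice = s$choices, reward = s$rewards,
                     response_time = if (is.null(s$response_time)) NA_real_
                                     else s$response_time,
                     retrieval_time = if (is.null(s$retrieval_time)) NA_real_
                                      else s$retrieval_time,
                     p_left = if (is.null(s$schedule)) NA_real_
                              else s$schedule$p_reward[, 1],
                     p_right = if (is.null(s$schedule)) NA_real_
                               else s$schedule$p_reward[, 2])
    if (!is.null(hmm_states)) {
      lab <- hmm_states[[i]]$labels
      df$hmm_state <- c(explore = "E", exploit_L = "L",
                        exploit_R = "R")[as.character(lab)]
    }
    if (!is.null(rl_explore)) df$rl_explore <- rl_explore[[i]]
    df
  })
  out <- do.call(rbind, rows)
  if (is.null(path)) return(out)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read sessions from a per-trial table
#'
#' Inverse of [write_sessions()]: splits the table into one
#' `bandit_session` per (subject, session) pair, validating the schema.
#' Rows must have contiguous 1-based trial numbers within each pair and
#' choices/rewards in \{0, 1\}.
#'
#' @param path File path, or a data frame already in the schema.
#' @return List of `bandit_session` (empty, with a warning, for an empty
#'   file).
#' @export
read_sessions <- function(path) {
  df <- if (is.data.frame(path)) path
        else utils::read.table(path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    warning("no rows found; returning an empty session list")
    return(list())
  }
  need <- c("subject", "session", "trial", "choice", "reward")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("missing columns: ", paste(miss, collapse = ", "))
  bad <- which(!(df$choice %in% c(0, 1)) | !(df$reward %in% c(0, 1)))
  if (length(bad) > 0)
    stop("invalid choice/reward value at row ", bad[1])

  keys <- unique(df[, c("subject", "session")])
  lapply(seq_len(nrow(keys)), function(i) {
    rows <- df[df$subject == keys$subject[i] & df$session == keys$session[i], ]
    rows <- rows[order(rows$trial), ]
    if (!identical(as.integer(rows$trial), seq_len(nrow(rows))))
      stop("non-contiguous trials for subject ", keys$subject[i],
           " session ", keys$session[i])
    sched <- NULL
    if (all(c("p_left", "p_right") %in% names(rows)) &&
        !anyNA(rows$p_left)) {
      sched <- structure(list(n_trials = nrow(rows),
                              p_reward = cbind(rows$p_left, rows$p_right),
                              step_prob = NA, step_size = NA,
                              bounds = c(0, 1), seed = NULL),
                         class = "reward_schedule")
    }
    rt <- if ("response_time" %in% names(rows) && !anyNA(rows$response_time))
      rows$response_time else NULL
    rv <- if ("retrieval_time" %in% names(rows) && !anyNA(rows$retrieval_time))
      rows$retrieval_time else NULL
    bandit_session(rows$choice, rows$reward,
                   subject_id = as.character(keys$subject[i]),
                   group = if ("group" %in% names(rows)) rows$group[1] else NA,
                   session_index = keys$session[i],
                   response_time = rt, retrieval_time = rv,
                   schedule = sched)
  })
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' End-to-end orchestration: generate (or accept) a cohort, fit the
#' explore/exploit HMM variants per subject and compare them, decode
#' explore states, fit the requested RL models and score agreement,
#' characterize run-length switching dynamics, build the group energy
#' landscape, and compute the behavioral metrics table. Deterministic
#' given `seed`.
#'
#' @param config A [cohort_config()] (ignored when `sessions` given).
#' @param seed Integer master seed.
#' @param sessions Optional pre-loaded list of `bandit_session` (e.g.
#'   from [read_sessions()]); skips cohort generation.
#' @param hmm_variants Character vector of HMM variants to fit and
#'   compare (first is used for decoding).
#' @param rl_model_ids RL models to fit (default the four non-trivial
#'   ones; use [rl_models()] for all seven).
#' @param hmm_restarts,rl_restarts Restart counts for the two fitters.
#' @param out_dir Optional directory; when given, tables are written
#'   there (sessions.tsv, metrics.tsv, ic_hmm.tsv, ic_rl.tsv,
#'   landscape.tsv, mixture.tsv, report.md).
#' @return List with `sessions`, `hmm_fits` (per subject, first
#'   variant), `hmm_ic`, `states` (decoded), `rl_fits` (per subject,
#'   per model), `rl_ic`, `mixture`, `landscape`, `metrics`,
#'   `group_summary`.
#' @export
run_pipeline <- function(config = cohort_config(), seed = 1,
                         sessions = NULL,
                         hmm_variants = c("tied2", "io4", "nt4"),
                         rl_model_ids = c("random", "wsls", "rl", "rlck"),
                         hmm_restarts = 20, rl_restarts = 10,
                         out_dir = NULL) {
  set.seed(seed)
  if (is.null(sessions)) {
    cohort <- generate_cohort(config, seed = seed)
    sessions <- cohort$sessions
  }
  subjects <- unique(vapply(sessions, function(s) s$subject_id, character(1)))
  by_subj <- lapply(subjects, function(id)
    sessions[vapply(sessions, function(s) s$subject_id == id, logical(1))])
  groups <- vapply(by_subj, function(ss) as.character(ss[[1]]$group),
                   character(1))
  n_obs <- sum(vapply(sessions, function(s) length(s$choices), integer(1)))

  # --- HMM stage ------------------------------------------------------
  hmm_fits_all <- lapply(hmm_variants, function(v)
    lapply(by_subj, function(ss) fit_hmm(ss, v, n_restarts = hmm_restarts)))
  names(hmm_fits_all) <- hmm_variants
  hmm_ic <- information_criteria(hmm_fits_all, n_obs)
  hmm_fits <- hmm_fits_all[[1]]

  states <- vector("list", length(sessions))
  for (i in seq_along(subjects)) {
    idx <- which(vapply(sessions, function(s)
      s$subject_id == subjects[i], logical(1)))
    for (j in idx)
      states[[j]] <- viterbi_decode(hmm_fits[[i]], sessions[[j]])
  }

  # --- RL stage -------------------------------------------------------
  rl_fits <- lapply(rl_model_ids, function(m)
    lapply(by_subj, function(ss) {
      f <- fit_rl(m, ss, n_restarts = rl_restarts)
      f$agreement <- model_agreement(f, ss)
      f
    }))
  names(rl_fits) <- rl_model_ids
  rl_ic <- information_criteria(rl_fits, n_obs)

  best_rl <- rl_ic$model[which.min(rl_ic$AIC)]
  rl_labels <- vector("list", length(sessions))
  for (i in seq_along(subjects)) {
    idx <- which(vapply(sessions, function(s)
      s$subject_id == subjects[i], logical(1)))
    labs <- rl_explore_labels(rl_fits[[best_rl]][[i]], sessions[idx])
    for (k in seq_along(idx)) rl_labels[[idx[k]]] <- labs[[k]]
  }

  # --- switching dynamics ---------------------------------------------
  lengths_all <- unlist(lapply(sessions, run_lengths))
  mixture <- mixture_model_selection(lengths_all, max_components = 3)

  # --- energy landscape -----------------------------------------------
  landscape <- if (hmm_variants[1] == "io4") NULL
               else landscape_summary(hmm_fits, groups)

  # --- metrics --------------------------------------------------------
  metrics <- do.call(rbind, lapply(seq_along(subjects), function(i) {
    idx <- which(vapply(sessions, function(s)
      s$subject_id == subjects[i], logical(1)))
    ss <- sessions[idx]
    st <- states[idx]
    rvc <- vapply(ss, function(s)
      if (is.null(s$schedule)) c(NA, NA) else reward_vs_chance(s), numeric(2))
    wsls_mat <- vapply(seq_along(ss), function(k)
      wsls_rates(ss[[k]], st[[k]]), numeric(6))
    w <- rowMeans(wsls_mat, na.rm = TRUE)
    cmi <- mean(vapply(ss, conditional_mutual_info, numeric(1)))
    expl <- mean(vapply(st, explore_fraction, numeric(1)))
    has_rt <- !is.null(ss[[1]]$response_time)
    if (has_rt) {
      lat <- do.call(rbind, lapply(seq_along(ss), function(k)
        latency_by_state(ss[[k]], st[[k]], rl_labels[[idx[k]]])))
      rt_e <- mean(lat$rt_explore[lat$labels == "hmm"], na.rm = TRUE)
      rt_x <- mean(lat$rt_exploit[lat$labels == "hmm"], na.rm = TRUE)
      r2_h <- mean(lat$r_squared[lat$labels == "hmm"], na.rm = TRUE)
      r2_r <- mean(lat$r_squared[lat$labels == "rl"], na.rm = TRUE)
    } else rt_e <- rt_x <- r2_h <- r2_r <- NA_real_
    rtet <- tetrachoric_corr(unlist(lapply(st, function(x) x$binary_explore)),
                             unlist(rl_labels[idx]))
    data.frame(subject = subjects[i], group = groups[i],
               p_reward_obtained = mean(rvc[1, ], na.rm = TRUE),
               p_reward_chance = mean(rvc[2, ], na.rm = TRUE),
               explore_fraction = expl,
               win_stay = w[["win_stay"]], lose_shift = w[["lose_shift"]],
               win_stay_explore = w[["win_stay_explore"]],
               win_stay_exploit = w[["win_stay_exploit"]],
               lose_shift_explore = w[["lose_shift_explore"]],
               lose_shift_exploit = w[["lose_shift_exploit"]],
               cmi_bits = cmi, r_tet = rtet,
               rt_explore = rt_e, rt_exploit = rt_x,
               rt_r2_hmm = r2_h, rt_r2_rl = r2_r,
               explore_stay = if (hmm_fits[[i]]$spec$variant == "tied2")
                 hmm_fits[[i]]$spec$params$a else NA_real_,
               exploit_stay = if (hmm_fits[[i]]$spec$variant == "tied2")
                 hmm_fits[[i]]$spec$params$d else NA_real_)
  }))

  g1 <- metrics[metrics$group == unique(groups)[1], ]
  g2 <- metrics[metrics$group == unique(groups)[2], ]
  auc_expl <- if (nrow(g1) >= 2 && nrow(g2) >= 2)
    auc_separability(g1$explore_fraction, g2$explore_fraction) else NULL

  group_summary <- do.call(rbind, lapply(split(metrics, metrics$group),
    function(m) {
      num <- vapply(m[, -(1:2)], mean, numeric(1), na.rm = TRUE)
      cbind(data.frame(group = m$group[1], n = nrow(m)), t(num))
    }))

  result <- list(sessions = sessions, hmm_fits = hmm_fits, hmm_ic = hmm_ic,
                 states = states, rl_fits = rl_fits, rl_ic = rl_ic,
                 rl_labels = rl_labels, mixture = mixture,
                 landscape = landscape, metrics = metrics,
                 auc_explore = auc_expl, group_summary = group_summary,
                 seed = seed)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_sessions(sessions, file.path(out_dir, "sessions.tsv"),
                   hmm_states = states, rl_explore = rl_labels)
    wt <- function(x, f) utils::write.table(
      x, file.path(out_dir, f), sep = "\t", row.names = FALSE, quote = FALSE)
    wt(metrics, "metrics.tsv"); wt(hmm_ic, "ic_hmm.tsv")
    wt(rl_ic, "ic_rl.tsv"); wt(mixture, "mixture.tsv")
    if (!is.null(landscape)) wt(landscape, "landscape.tsv")
    writeLines(make_report(result), file.path(out_dir, "report.md"))
  }
  result
}

#' Render a human-readable summary of a pipeline run
#'
#' @param result Output of [run_pipeline()] (sections with missing
#'   components are omitted).
#' @return Character vector of markdown lines.
#' @export
make_report <- function(result) {
  if (length(result) == 0 || is.null(result$metrics))
    return("# Pipeline report\n\nno outputs found")
  fmt_tab <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) signif(x, 4))
    c(paste(names(df), collapse = " | "),
      paste(rep("---", ncol(df)), collapse = " | "),
      apply(df, 1, paste, collapse = " | "))
  }
  lines <- c("# Explore/exploit pipeline report", "",
             sprintf("Seed: %d. Subjects: %d. Sessions: %d.",
                     result$seed, nrow(result$metrics),
                     length(result$sessions)), "")
  if (!is.null(result$hmm_ic))
    lines <- c(lines, "## HMM model comparison", "",
               fmt_tab(result$hmm_ic), "")
  if (!is.null(result$rl_ic))
    lines <- c(lines, "## RL model comparison", "", fmt_tab(result$rl_ic), "")
  if (!is.null(result$mixture))
    lines <- c(lines, "## Run-length mixture selection", "",
               fmt_tab(result$mixture), "")
  if (!is.null(result$landscape))
    lines <- c(lines, "## Energy landscape by group", "",
               fmt_tab(result$landscape), "")
  if (!is.null(result$auc_explore))
    lines <- c(lines, sprintf(
      "Explore-fraction group separability: AUC = %.2f (p = %.3g)",
      result$auc_explore$auc, result$auc_explore$p_value), "")
  lines <- c(lines, "## Group means", "", fmt_tab(result$group_summary), "")
  lines
}
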