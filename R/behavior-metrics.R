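#' Obtained vs chance reward rate of a session
#'
#' Chance is the expected reward rate of a uniformly random policy on the
#' session's schedule; obtained is the empirical reward rate.
#'
#' @param session A `bandit_session` with its schedule attached.
#' @return Named vector `c(obtained, chance)`.
#' @export
reward_vs_chance <- function(session) {
  if (is.null(session$schedule))
    stop("session has no schedule; chance rate is undefined")
  c(obtained = mean(session$rewards),
    chance = chance_reward_rate(session$schedule))
}

#' Win-stay and lose-shift rates
#'
#' Win-stay is the probability of repeating the previous choice given the
#' previous trial was rewarded; lose-shift the probability of switching
#' given it was not. When a state sequence is supplied, the rates are
#' additionally split by the latent state of the *outcome* trial (t - 1,
#' the trial being learned from). Conditioning sets that never occur
#' yield `NA` rather than 0.
#'
#' @param session A `bandit_session` (>= 2 trials).
#' @param states Optional `state_sequence` (or 0/1 explore vector)
#'   aligned with the session.
#' @return Named vector: `win_stay`, `lose_shift`, and with states also
#'   `win_stay_explore`, `win_stay_exploit`, `lose_shift_explore`,
#'   `lose_shift_exploit`.
#' @export
wsls_rates <- function(session, states = NULL) {
  ch <- session$choices; rw <- session$rewards
  stopifnot(length(ch) >= 2)
  t2 <- 2:length(ch)
  stay <- ch[t2] == ch[t2 - 1]
  won <- rw[t2 - 1] == 1

  rate <- function(x) if (length(x) == 0) NA_real_ else mean(x)
  out <- c(win_stay = rate(stay[won]), lose_shift = rate(!stay[!won]))

  if (!is.null(states)) {
    ex <- if (inherits(states, "state_sequence")) states$binary_explore
          else states
    ex_prev <- ex[t2 - 1] == 1
    out <- c(out,
             win_stay_explore = rate(stay[won & ex_prev]),
             win_stay_exploit = rate(stay[won & !ex_prev]),
             lose_shift_explore = rate(!stay[!won & ex_prev]),
             lose_shift_exploit = rate(!stay[!won & !ex_prev]))
  }
  out
}

#' Conditional mutual information between consecutive choices given reward
#'
#' Plug-in estimate of I(C_t ; C_(t-1) | R_(t-1)) in bits from the
#' empirical joint distribution of (current choice, previous choice,
#' previous reward); cells with zero probability contribute zero. This
#' measures how much the previous choice still predicts the current one
#' after the intervening outcome is accounted for.
#'
#' @param session A `bandit_session` (>= 2 trials), or a data frame /
#'   list with columns `ct`, `ct1`, `r` giving the joint sample directly.
#' @return Mutual information in bits (>= 0).
#' @export
conditional_mutual_info <- function(session) {
  if (inherits(session, "bandit_session")) {
    ch <- session$choices; rw <- session$rewards
    stopifnot(length(ch) >= 2)
    t2 <- 2:length(ch)
    ct <- ch[t2]; ct1 <- ch[t2 - 1]; r <- rw[t2 - 1]
  } else {
    ct <- session$ct; ct1 <- session$ct1; r <- session$r
  }
  n <- length(ct)
  joint <- table(factor(ct, levels = 0:1), factor(ct1, levels = 0:1),
                 factor(r, levels = 0:1)) / n
  cmi <- 0
  for (r0 in 1:2) {
    pr <- sum(joint[, , r0])
    if (pr == 0) next
    for (a in 1:2) for (b in 1:2) {
      pj <- joint[a, b, r0]
      if (pj == 0) next
      pa <- sum(joint[a, , r0]); pb <- sum(joint[, b, r0])
      cmi <- cmi + pj * log2(pr * pj / (pa * pb))
    }
  }
  max(cmi, 0)
}

#' Tetrachoric correlation between two binary label sets
#'
#' Assumes each binary variable is a thresholded latent standard normal
#' and estimates the latent correlation from the 2x2 contingency table:
#' thresholds come from the margins and the correlation is solved so the
#' bivariate-normal orthant probability matches the observed (1,1) cell.
#' Zero cells receive a +0.5 continuity correction. A margin that is
#' entirely one-valued leaves the correlation undefined (`NA`).
#'
#' @param labels_a,labels_b Equal-length 0/1 vectors, or a 2x2 table
#'   passed as `labels_a` (rows = a, columns = b, level order 0, 1).
#' @return Estimated latent correlation in (-1, 1), or `NA`.
#' @export
tetrachoric_corr <- function(labels_a, labels_b = NULL) {
  if (is.matrix(labels_a) || is.table(labels_a)) {
    tab <- as.matrix(labels_a)
  } else {
    stopifnot(length(labels_a) == length(labels_b))
    tab <- table(factor(labels_a, levels = 0:1),
                 factor(labels_b, levels = 0:1))
    tab <- matrix(as.numeric(tab), 2, 2)
  }
  # an entirely one-valued margin leaves the threshold (and so the
  # correlation) undefined; check before the continuity correction
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(NA_real_)
  if (any(tab == 0)) tab <- tab + 0.5
  n <- sum(tab)
  pa <- sum(tab[2, ]) / n  # P(a = 1)
  pb <- sum(tab[, 2]) / n  # P(b = 1)
  if (pa <= 0 || pa >= 1 || pb <= 0 || pb >= 1) return(NA_real_)
  p11 <- tab[2, 2] / n
  h <- stats::qnorm(1 - pa)  # threshold: P(X > h) = pa
  k <- stats::qnorm(1 - pb)

  # upper-right orthant probability of a standard bivariate normal
  orthant <- function(rho) {
    if (abs(rho) < 1e-12) return((1 - stats::pnorm(h)) * (1 - stats::pnorm(k)))
    f <- function(x) stats::dnorm(x) *
      stats::pnorm((k - rho * x) / sqrt(1 - rho^2), lower.tail = FALSE)
    stats::integrate(f, h, Inf, rel.tol = 1e-10)$value
  }
  g <- function(rho) orthant(rho) - p11
  lo <- -0.9999; hi <- 0.9999
  glo <- g(lo); ghi <- g(hi)
  if (glo * ghi > 0) return(sign(ghi) * 0.9999)
  stats::uniroot(g, c(lo, hi), tol = 1e-8)$root
}

#' Rank-based group separability (ROC AUC)
#'
#' Mann-Whitney AUC for discriminating group b from group a: the
#' probability that a random draw from `values_b` exceeds one from
#' `values_a` (ties count half). Standard error by Hanley-McNeil; the
#' p-value comes from the two-sided Mann-Whitney test.
#'
#' @param values_a,values_b Numeric vectors (>= 2 each).
#' @return List: `auc`, `se`, `ci` (95%), `p_value`, `degenerate` flag
#'   (all pooled values identical).
#' @export
auc_separability <- function(values_a, values_b) {
  stopifnot(length(values_a) >= 2, length(values_b) >= 2)
  na <- length(values_a); nb <- length(values_b)
  if (stats::sd(c(values_a, values_b)) == 0)
    return(list(auc = 0.5, se = NA_real_, ci = c(NA_real_, NA_real_),
                p_value = 1, degenerate = TRUE))
  r <- rank(c(values_b, values_a))
  U <- sum(r[seq_len(nb)]) - nb * (nb + 1) / 2
  auc <- U / (na * nb)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (nb - 1) * (q1 - auc^2) +
                (na - 1) * (q2 - auc^2)) / (na * nb))
  wt <- stats::wilcox.test(values_b, values_a, exact = FALSE)
  list(auc = auc, se = se,
       ci = pmin(pmax(auc + c(-1, 1) * 1.96 * se, 0), 1),
       p_value = wt$p.value, degenerate = FALSE)
}

#' Response time by latent state
#'
#' Mean response time per explore/exploit label and, for each supplied
#' label set, a simple regression of z-scored response time on the
#' binary explore label: the standardized coefficient and variance
#' explained (R^2) quantify how much behavioral latency each labeling
#' method accounts for.
#'
#' @param session A `bandit_session` with `response_time`.
#' @param states_hmm `state_sequence` or 0/1 explore labels.
#' @param states_rl Optional second label set (e.g. RL-derived labels).
#' @return Data frame with one row per label set: `labels`, `rt_explore`,
#'   `rt_exploit`, `std_coef`, `r_squared`.
#' @export
latency_by_state <- function(session, states_hmm, states_rl = NULL) {
  rt <- session$response_time
  if (is.null(rt)) stop("session has no response times")
  one <- function(lab, name) {
    ex <- if (inherits(lab, "state_sequence")) lab$binary_explore else lab
    stopifnot(length(ex) == length(rt))
    if (stats::sd(rt) == 0 || stats::sd(ex) == 0) {
      coef <- 0; r2 <- 0
    } else {
      fit <- stats::lm(scale(rt) ~ scale(ex))
      coef <- unname(stats::coef(fit)[2])
      # noiseless latencies give a legitimately perfect fit
      r2 <- suppressWarnings(summary(fit)$r.squared)
    }
    data.frame(labels = name,
               rt_explore = mean(rt[ex == 1]),
               rt_exploit = mean(rt[ex == 0]),
               std_coef = coef, r_squared = r2)
  }
  out <- one(states_hmm, "hmm")
  if (!is.null(states_rl)) out <- rbind(out, one(states_rl, "rl"))
  out
}

#' Value difference of explore-labeled choices
#'
#' Mean over explore-labeled trials of Q(chosen) - Q(unchosen) under a
#' fitted value trace. A value near zero says exploratory choices are
#' orthogonal to learned value (not systematically directed at the
#' better or worse arm).
#'
#' @param sessions A `bandit_session` or list of them.
#' @param states List of per-session 0/1 explore labels (or
#'   `state_sequence`s), aligned with `sessions`.
#' @param fit An `rl_fit` supplying the value trace.
#' @return Mean relative value of explore choices, or `NA` if no trial
#'   is labeled explore.
#' @export
explore_value_orthogonality <- function(sessions, states, fit) {
  if (inherits(sessions, "bandit_session")) sessions <- list(sessions)
  if (!is.list(states) || inherits(states, "state_sequence"))
    states <- list(states)
  res <- rl_nll(fit$model_id, fit$params, sessions, trace = TRUE)
  deltas <- numeric(0)
  for (i in seq_along(sessions)) {
    ch <- sessions[[i]]$choices
    ex <- states[[i]]
    if (inherits(ex, "state_sequence")) ex <- ex$binary_explore
    Q <- res$trace[[i]]$Q
    dq <- Q[cbind(seq_along(ch), ch + 1)] - Q[cbind(seq_along(ch), 2 - ch)]
    deltas <- c(deltas, dq[ex == 1])
  }
  if (length(deltas) == 0) return(NA_real_)
  mean(deltas)
}

#' Matching-law points for a set of sessions
#'
#' Per session, the fraction of obtained rewards earned on arm 1 and the
#' fraction of choices allocated to arm 1; under strict matching the
#' points fall on the diagonal.
#'
#' @param sessions A `bandit_session` or list of them.
#' @return Data frame: `subject`, `session`, `reward_fraction`,
#'   `choice_fraction`. Sessions with no rewards give `NA` reward
#'   fractions.
#' @export
matching_law_points <- function(sessions) {
  if (inherits(sessions, "bandit_session")) sessions <- list(sessions)
  do.call(rbind, lapply(sessions, function(s) {
    tot <- sum(s$rewards)
    data.frame(subject = s$subject_id, session = s$session_index,
               reward_fraction = if (tot == 0) NA_real_
                                 else sum(s$rewards[s$choices == 1]) / tot,
               choice_fraction = mean(s$choices == 1))
  }))
}
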