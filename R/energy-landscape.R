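#' Stationary distribution of a transition matrix
#'
#' The equilibrium state-occupancy probabilities: the normalized left
#' eigenvector of the row-stochastic matrix with eigenvalue 1. For the
#' three-state explore/exploit models the two exploit states are also
#' reported summed into a single "exploit" mass.
#'
#' @param P Row-stochastic transition matrix (or an [hmm_spec()] /
#'   `hmm_fit`, whose reward-independent transition matrix is used).
#' @param collapse_exploit If `TRUE` (default) and `P` is 3x3, also
#'   return the two-state collapse.
#' @return List with `pi` (full stationary vector) and, for 3x3 inputs,
#'   `pi2` = c(explore, exploit).
#' @export
stationary_distribution <- function(P, collapse_exploit = TRUE) {
  if (inherits(P, "hmm_fit")) P <- P$spec
  if (inherits(P, "hmm_spec")) {
    if (P$variant == "io4")
      stop("io4 has reward-dependent transitions; supply an explicit matrix")
    P <- build_transition_matrix(P)
  }
  stopifnot(is.matrix(P), nrow(P) == ncol(P))
  if (any(abs(rowSums(P) - 1) > 1e-8)) stop("matrix is not row-stochastic")

  e <- eigen(t(P))
  unit <- which(abs(e$values - 1) < 1e-8)
  if (length(unit) == 0) stop("no unit eigenvalue: chain is not stochastic")
  if (length(unit) > 1)
    stop("non-ergodic chain: unit eigenvalue is not unique (reducible or absorbing)")
  # periodic chains have other eigenvalues on the unit circle
  others <- abs(e$values)[-unit]
  if (any(others > 1 - 1e-10))
    stop("non-ergodic chain: eigenvalue modulus 1 off the stationary mode (periodic)")
  v <- Re(e$vectors[, unit])
  pi_full <- v / sum(v)
  if (any(pi_full < -1e-10)) stop("negative stationary mass; matrix invalid")
  pi_full <- pmax(pi_full, 0); pi_full <- pi_full / sum(pi_full)
  names(pi_full) <- rownames(P)
  out <- list(pi = pi_full)
  if (collapse_exploit && length(pi_full) == 3)
    out$pi2 <- c(explore = unname(pi_full[1]),
                 exploit = unname(pi_full[2] + pi_full[3]))
  out
}

#' Relative energetic depth of two states
#'
#' Boltzmann inversion of equilibrium occupancy: with k_B T as the unit
#' of energy, E_exploit - E_explore = ln(p_explore / p_exploit), so the
#' more occupied state is the deeper (lower-energy) one.
#'
#' @param stationary Length-2 probability vector `c(explore, exploit)`
#'   (strictly positive), or the output of [stationary_distribution()].
#' @param kBT Energy scale (default 1; energies are then in natural-log
#'   units and only differences are meaningful).
#' @return `E_exploit - E_explore` in units of `kBT`.
#' @export
state_energies <- function(stationary, kBT = 1) {
  if (is.list(stationary)) stationary <- stationary$pi2
  stopifnot(length(stationary) == 2)
  if (any(stationary <= 0)) stop("stationary probabilities must be positive")
  kBT * log(stationary[[1]] / stationary[[2]])
}

#' Arrhenius activation energy of leaving a state
#'
#' The escape rate from a state with stay probability s is k = 1 - s;
#' with unit pre-exponential factor and k_B T = 1 the barrier is
#' Ea = -ln(k).
#'
#' @param stay_prob Stay probability in \[0, 1).
#' @param A Pre-exponential factor (default 1).
#' @param kBT Energy scale (default 1).
#' @return Activation energy (>= 0 for A = 1).
#' @export
activation_energy <- function(stay_prob, A = 1, kBT = 1) {
  stopifnot(stay_prob >= 0)
  if (any(stay_prob >= 1)) stop("stay probability 1: infinite barrier (no escape)")
  -log((1 - stay_prob) / A) * kBT
}

#' Group-level energy landscape from fitted HMMs
#'
#' Computes each subject's stationary distribution, averages those
#' distributions within group (the average of per-subject equilibria,
#' not the equilibrium of average parameters — the two differ), and
#' derives the group landscape: state depths from the group-mean
#' occupancies and activation barriers from the group-mean stay
#' probabilities. Subjects whose chain is non-ergodic (e.g. an absorbing
#' state at a parameter boundary) are excluded and listed.
#'
#' @param fits List of `hmm_fit` objects (reward-independent variants).
#' @param groups Vector of group labels, one per fit (default one group).
#' @return A data frame with one row per group: `group`, `n`,
#'   `pi_explore`, `pi_exploit`, `sd_pi_explore`, `mean_explore_stay`,
#'   `mean_exploit_stay`, `depth_difference` (E_exploit - E_explore),
#'   `barrier_from_explore`, `barrier_from_exploit`. Excluded subjects
#'   are reported in the `excluded` attribute.
#' @export
landscape_summary <- function(fits, groups = NULL) {
  if (inherits(fits, "hmm_fit")) fits <- list(fits)
  if (is.null(groups)) groups <- rep("all", length(fits))
  stopifnot(length(groups) == length(fits))

  pis <- matrix(NA_real_, length(fits), 2)
  stays <- matrix(NA_real_, length(fits), 2)
  excluded <- integer(0)
  for (i in seq_along(fits)) {
    f <- fits[[i]]
    sd_i <- try(stationary_distribution(f), silent = TRUE)
    if (inherits(sd_i, "try-error")) { excluded <- c(excluded, i); next }
    pis[i, ] <- sd_i$pi2
    prm <- f$spec$params
    stays[i, ] <- switch(f$spec$variant,
                         tied2 = c(prm$a, prm$d),
                         nt4 = c(1 - prm$q_L - prm$q_R,
                                 (prm$d_L + prm$d_R) / 2))
  }

  rows <- lapply(unique(groups), function(g) {
    keep <- which(groups == g & !is.na(pis[, 1]))
    if (length(keep) == 0) return(NULL)
    pi_bar <- colMeans(pis[keep, , drop = FALSE])
    stay_bar <- colMeans(stays[keep, , drop = FALSE])
    data.frame(group = g, n = length(keep),
               pi_explore = pi_bar[1], pi_exploit = pi_bar[2],
               sd_pi_explore = stats::sd(pis[keep, 1]),
               mean_explore_stay = stay_bar[1],
               mean_exploit_stay = stay_bar[2],
               depth_difference = state_energies(pi_bar),
               barrier_from_explore = activation_energy(stay_bar[1]),
               barrier_from_exploit = activation_energy(stay_bar[2]),
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  attr(out, "excluded") <- excluded
  out
}

#' Three-point landscape profile for plotting
#'
#' The landscape is only defined at three points — the explore well, the
#' barrier peak, and the exploit well. The peak is placed at
#' `barrier_from_explore` above the explore well (the zero of energy is a
#' plotting convention; only differences are meaningful).
#'
#' @param summary_row One row of [landscape_summary()].
#' @return Data frame with `position` in \{explore, barrier, exploit\}
#'   and `energy`.
#' @export
landscape_profile <- function(summary_row) {
  e_explore <- 0
  e_peak <- summary_row$barrier_from_explore
  e_exploit <- e_peak - summary_row$barrier_from_exploit
  data.frame(position = c("explore", "barrier", "exploit"),
             energy = c(e_explore, e_peak, e_exploit))
}
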