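#' Inter-switch run lengths of a choice sequence
#'
#' Lengths of maximal constant-choice runs, in order, counting the first
#' trial of each run (so strict alternation yields runs of length 1 and
#' i.i.d. equal-probability choices have mean run length 2). The final,
#' right-censored run is included by default; runs never span sessions.
#'
#' @param choices 0/1 choice vector or a `bandit_session`.
#' @param drop_final If `TRUE`, drop the final (censored) run.
#' @return Integer vector of run lengths.
#' @export
run_lengths <- function(choices, drop_final = FALSE) {
  if (inherits(choices, "bandit_session")) choices <- choices$choices
  stopifnot(length(choices) >= 1)
  r <- rle(choices)$lengths
  if (drop_final && length(r) > 1) r <- r[-length(r)]
  as.integer(r)
}

#' Sample from a mixture of geometric distributions
#'
#' Support \{1, 2, ...\}: P(x | p) = (1 - p)^(x - 1) p, so a component's
#' mean run length is 1/p.
#'
#' @param n Number of draws.
#' @param weights Mixture weights (summing to 1).
#' @param means Component means (1/p, each >= 1).
#' @param seed Optional integer seed.
#' @return Integer vector of lengths.
#' @export
rgeom_mixture <- function(n, weights, means, seed = NULL) {
  stopifnot(length(weights) == length(means), all(means >= 1),
            abs(sum(weights) - 1) < 1e-8)
  if (!is.null(seed)) set.seed(seed)
  comp <- sample.int(length(weights), n, replace = TRUE, prob = weights)
  # stats::rgeom counts failures before the first success (support 0, 1, ...)
  stats::rgeom(n, prob = 1 / means[comp]) + 1L
}

#' Fit a mixture of geometric distributions by EM
#'
#' Expectation-maximization for a K-component geometric mixture on
#' support \{1, 2, ...\}. Components are reported sorted by mean
#' ascending (fast-switching regime first).
#'
#' @param lengths Positive integer run lengths.
#' @param n_components Number of components K (>= 1).
#' @param n_restarts Random restarts (default 10).
#' @param tol Log-likelihood convergence tolerance (default 1e-8 per
#'   observation).
#' @param max_iter Maximum EM iterations (default 1000).
#' @param seed Optional integer seed for the restarts.
#' @return A `geom_mix_fit`: `n_components`, `weights`, `success_probs`,
#'   `means` (1/p), `loglik`, `n_iter`, `converged`, `loglik_trace`.
#' @export
geometric_mixture_em <- function(lengths, n_components, n_restarts = 10,
                                 tol = 1e-8, max_iter = 1000, seed = NULL) {
  x <- as.numeric(lengths)
  if (length(x) == 0) stop("no run lengths supplied")
  stopifnot(all(x >= 1), n_components >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- length(x)
  K <- n_components

  if (K == 1) {
    p <- 1 / mean(x)
    ll <- sum(stats::dgeom(x - 1, p, log = TRUE))
    return(structure(list(n_components = 1L, weights = 1,
                          success_probs = p, means = 1 / p, loglik = ll,
                          n_iter = 1L, converged = TRUE, loglik_trace = ll),
                     class = "geom_mix_fit"))
  }

  run_em <- function(p0, w0) {
    p <- p0; w <- w0
    ll_old <- -Inf; trace <- numeric(0); converged <- FALSE; it <- 0
    for (it in seq_len(max_iter)) {
      # E-step: responsibilities (log space for stability)
      lg <- vapply(seq_len(K), function(k)
        log(w[k]) + stats::dgeom(x - 1, p[k], log = TRUE), numeric(n))
      m <- lg[, 1]
      for (k in seq_len(K)[-1]) m <- pmax(m, lg[, k])
      lse <- m + log(rowSums(exp(lg - m)))
      ll <- sum(lse)
      trace <- c(trace, ll)
      if (is.finite(ll_old) && ll - ll_old < tol * n) { converged <- TRUE; break }
      ll_old <- ll
      resp <- exp(lg - lse)
      # M-step: weighted geometric MLE per component
      nk <- colSums(resp)
      w <- nk / n
      p <- pmin(pmax(nk / colSums(resp * x), 1e-8), 1 - 1e-8)
    }
    list(p = p, w = w, loglik = trace[length(trace)], trace = trace,
         converged = converged, n_iter = it)
  }

  best <- NULL
  for (r in seq_len(n_restarts)) {
    # initialize component means spread over the observed quantiles
    q <- stats::quantile(x, probs = stats::runif(K, 0.05, 0.95))
    p0 <- pmin(pmax(1 / pmax(as.numeric(q), 1), 1e-4), 1 - 1e-6)
    w0 <- stats::runif(K, 0.2, 1); w0 <- w0 / sum(w0)
    res <- run_em(p0, w0)
    if (is.null(best) || res$loglik > best$loglik) best <- res
  }

  ord <- order(1 / best$p)
  structure(list(n_components = as.integer(K),
                 weights = best$w[ord],
                 success_probs = best$p[ord],
                 means = 1 / best$p[ord],
                 loglik = best$loglik,
                 n_iter = best$n_iter,
                 converged = best$converged,
                 loglik_trace = best$trace),
            class = "geom_mix_fit")
}

#' @export
print.geom_mix_fit <- function(x, ...) {
  cat(sprintf("geom_mix_fit: %d component(s), logLik %.1f\n",
              x$n_components, x$loglik))
  for (k in seq_len(x$n_components))
    cat(sprintf("  component %d: weight %.3f, mean %.2f trials (p = %.3f)\n",
                k, x$weights[k], x$means[k], x$success_probs[k]))
  invisible(x)
}

#' Sequential model selection for geometric mixtures
#'
#' Fits mixtures with K = 1 .. `max_components` components and performs
#' sequential likelihood-ratio tests of K against K - 1 (chi-squared
#' with 2 degrees of freedom per added component: one weight, one rate;
#' the usual boundary caveat for mixture LRTs applies and makes the test
#' conservative in the accept direction). Components with weight below
#' 3% are flagged as negligible.
#'
#' @param lengths Positive integer run lengths.
#' @param max_components Largest K to fit (>= 2).
#' @param seed Optional integer seed.
#' @param n_restarts Restarts per K (default 10).
#' @return Data frame: `K`, `loglik`, `n_params`, `lrt_stat`, `p_value`
#'   (vs K - 1), `min_weight`, `negligible_components`, plus a `fits`
#'   attribute holding the fitted mixtures.
#' @export
mixture_model_selection <- function(lengths, max_components = 4, seed = NULL,
                                    n_restarts = 10) {
  stopifnot(max_components >= 2)
  if (!is.null(seed)) set.seed(seed)
  fits <- lapply(seq_len(max_components), function(K)
    geometric_mixture_em(lengths, K, n_restarts = n_restarts))
  ll <- vapply(fits, function(f) f$loglik, numeric(1))
  npar <- 2 * seq_len(max_components) - 1
  lrt <- c(NA, 2 * diff(ll))
  pval <- c(NA, stats::pchisq(2 * diff(ll), df = 2, lower.tail = FALSE))
  minw <- vapply(fits, function(f) min(f$weights), numeric(1))
  negl <- vapply(fits, function(f) sum(f$weights < 0.03), integer(1))
  out <- data.frame(K = seq_len(max_components), loglik = ll,
                    n_params = npar, lrt_stat = lrt, p_value = pval,
                    min_weight = minw, negligible_components = negl)
  attr(out, "fits") <- fits
  out
}
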