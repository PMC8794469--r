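#include <Rcpp.h>
using namespace Rcpp;

// Discrete explore/exploit HMM over three latent states:
//   0 = explore (uniform emission over the two arms)
//   1 = exploit left (emits left with probability 1)
//   2 = exploit right (emits right with probability 1)
// The initial distribution is fixed: sessions start in explore.
// Transitions may depend on the previous trial's reward (input-output
// variant): the matrix used between trials t and t+1 is Pwin if
// rewards[t] == 1 and Ploss otherwise. Reward-independent variants pass
// the same matrix twice.

static inline double emit_prob(int state, int choice) {
  if (state == 0) return 0.5;
  if (state == 1) return choice == 0 ? 1.0 : 0.0;
  return choice == 1 ? 1.0 : 0.0;
}

// [[Rcpp::export]]
double hmm_forward_cpp(const IntegerVector& choices,
                       const IntegerVector& rewards,
                       const NumericMatrix& Pwin,
                       const NumericMatrix& Ploss) {
  const int T = choices.size();
  double alpha[3], anew[3];
  double loglik = 0.0;

  // t = 1: start in explore with probability 1
  alpha[0] = emit_prob(0, choices[0]);
  alpha[1] = 0.0;
  alpha[2] = 0.0;
  double c = alpha[0];
  if (c <= 0.0) return R_NegInf;
  loglik += std::log(c);
  alpha[0] /= c;

  for (int t = 1; t < T; ++t) {
    const NumericMatrix& P = rewards[t - 1] == 1 ? Pwin : Ploss;
    for (int j = 0; j < 3; ++j) {
      double s = 0.0;
      for (int i = 0; i < 3; ++i) s += alpha[i] * P(i, j);
      anew[j] = s * emit_prob(j, choices[t]);
    }
    c = anew[0] + anew[1] + anew[2];
    if (c <= 0.0) return R_NegInf;
    loglik += std::log(c);
    for (int j = 0; j < 3; ++j) alpha[j] = anew[j] / c;
  }
  return loglik;
}

// Forward-backward pass returning scaled log-likelihood plus expected
// transition counts, split by the previous trial's reward so the M-step
// of the input-output variant can condition on it.
// [[Rcpp::export]]
List hmm_fb_counts_cpp(const IntegerVector& choices,
                       const IntegerVector& rewards,
                       const NumericMatrix& Pwin,
                       const NumericMatrix& Ploss) {
  const int T = choices.size();
  NumericMatrix alpha(T, 3);
  NumericVector cs(T);
  double loglik = 0.0;

  alpha(0, 0) = emit_prob(0, choices[0]);
  cs[0] = alpha(0, 0);
  if (cs[0] <= 0.0) stop("zero forward probability at trial 1");
  loglik += std::log(cs[0]);
  alpha(0, 0) /= cs[0];

  for (int t = 1; t < T; ++t) {
    const NumericMatrix& P = rewards[t - 1] == 1 ? Pwin : Ploss;
    double c = 0.0;
    for (int j = 0; j < 3; ++j) {
      double s = 0.0;
      for (int i = 0; i < 3; ++i) s += alpha(t - 1, i) * P(i, j);
      alpha(t, j) = s * emit_prob(j, choices[t]);
      c += alpha(t, j);
    }
    if (c <= 0.0) stop("zero forward probability (impossible choice sequence)");
    cs[t] = c;
    loglik += std::log(c);
    for (int j = 0; j < 3; ++j) alpha(t, j) /= c;
  }

  NumericMatrix xi_win(3, 3), xi_loss(3, 3);
  double beta[3], bnew[3];
  beta[0] = beta[1] = beta[2] = 1.0;

  for (int t = T - 2; t >= 0; --t) {
    const bool win = rewards[t] == 1;
    const NumericMatrix& P = win ? Pwin : Ploss;
    NumericMatrix& xi = win ? xi_win : xi_loss;
    for (int i = 0; i < 3; ++i) {
      double s = 0.0;
      for (int j = 0; j < 3; ++j) {
        double term = P(i, j) * emit_prob(j, choices[t + 1]) * beta[j];
        xi(i, j) += alpha(t, i) * term / cs[t + 1];
        s += term;
      }
      bnew[i] = s / cs[t + 1];
    }
    for (int i = 0; i < 3; ++i) beta[i] = bnew[i];
  }

  return List::create(_["loglik"] = loglik,
                      _["xi_win"] = xi_win,
                      _["xi_loss"] = xi_loss);
}

// Most probable state path, trial 1 constrained to explore, ties broken
// toward the lower state index (explore first).
// [[Rcpp::export]]
IntegerVector hmm_viterbi_cpp(const IntegerVector& choices,
                              const IntegerVector& rewards,
                              const NumericMatrix& Pwin,
                              const NumericMatrix& Ploss) {
  const int T = choices.size();
  NumericMatrix delta(T, 3);
  IntegerMatrix psi(T, 3);
  const double NEG = R_NegInf;

  for (int j = 0; j < 3; ++j) {
    double e = emit_prob(j, choices[0]);
    delta(0, j) = (j == 0 && e > 0.0) ? std::log(e) : NEG;
  }

  for (int t = 1; t < T; ++t) {
    const NumericMatrix& P = rewards[t - 1] == 1 ? Pwin : Ploss;
    for (int j = 0; j < 3; ++j) {
      double e = emit_prob(j, choices[t]);
      if (e <= 0.0) { delta(t, j) = NEG; psi(t, j) = 0; continue; }
      double best = NEG;
      int arg = 0;
      for (int i = 0; i < 3; ++i) {
        double v = delta(t - 1, i) +
          (P(i, j) > 0.0 ? std::log(P(i, j)) : NEG);
        if (v > best) { best = v; arg = i; }
      }
      delta(t, j) = best + std::log(e);
      psi(t, j) = arg;
    }
  }

  IntegerVector path(T);
  double best = NEG;
  int arg = 0;
  for (int j = 0; j < 3; ++j)
    if (delta(T - 1, j) > best) { best = delta(T - 1, j); arg = j; }
  path[T - 1] = arg;
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  return path;
}

// ---------------------------------------------------------------------
// Reinforcement-learning likelihood models for a two-armed bandit.
// Model codes: 1 random, 2 noisy WSLS, 3 RL, 4 RL+lapse, 5 RLCK,
// 6 RLCK+gamma (asymmetric learning), 7 RLCK+eta (policy mixing).
// Choices coded 0 = left, 1 = right; rewards 0/1. Q initialized at 0.5
// per arm, choice kernel at 0. Only the chosen arm's Q updates; the
// kernel updates for both arms toward the chosen indicator.

static inline double clamp_prob(double p) {
  const double lo = 1e-12;
  if (p < lo) return lo;
  if (p > 1.0 - lo) return 1.0 - lo;
  return p;
}

// [[Rcpp::export]]
List rl_nll_cpp(const int model,
                const NumericVector& params,
                const IntegerVector& choices,
                const IntegerVector& rewards,
                const bool trace) {
  const int T = choices.size();
  double nll = 0.0;

  NumericMatrix Qm, CKm, Pm;
  if (trace) {
    Qm = NumericMatrix(T, 2);
    CKm = NumericMatrix(T, 2);
    Pm = NumericMatrix(T, 2);
  }

  if (model == 1) {            // random: fixed bias b for the left arm
    const double b = params[0];
    for (int t = 0; t < T; ++t) {
      double pl = clamp_prob(b);
      double p = choices[t] == 0 ? pl : 1.0 - pl;
      nll -= std::log(clamp_prob(p));
      if (trace) { Pm(t, 0) = pl; Pm(t, 1) = 1.0 - pl;
                   Qm(t, 0) = Qm(t, 1) = 0.5; }
    }
  } else if (model == 2) {     // noisy win-stay lose-shift
    const double eps = params[0];
    for (int t = 0; t < T; ++t) {
      double p_stay_policy = 1.0 - eps / 2.0; // prob of following WSLS
      double pl;
      if (t == 0) {
        pl = 0.5;
      } else {
        int favored; // arm the WSLS policy points at
        if (rewards[t - 1] == 1) favored = choices[t - 1];
        else favored = 1 - choices[t - 1];
        pl = favored == 0 ? p_stay_policy : 1.0 - p_stay_policy;
      }
      double p = choices[t] == 0 ? pl : 1.0 - pl;
      nll -= std::log(clamp_prob(p));
      if (trace) { Pm(t, 0) = pl; Pm(t, 1) = 1.0 - pl;
                   Qm(t, 0) = Qm(t, 1) = 0.5; }
    }
  } else {                     // value / choice-kernel family
    double alpha = params[0], beta = params[1];
    double alpha_c = 0.0, beta_c = 0.0, eps = 0.0, gamma = 1.0, eta = 1.0;
    bool use_ck = false, use_eps = false;
    if (model == 4) { eps = params[2]; use_eps = true; }
    if (model >= 5) { alpha_c = params[2]; beta_c = params[3]; use_ck = true; }
    if (model == 6) gamma = params[4];
    double wq = 1.0, wc = 1.0;
    if (model == 7) { eta = params[4]; wq = eta; wc = 1.0 - eta; }

    double Q[2] = {0.5, 0.5};
    double CK[2] = {0.0, 0.0};

    for (int t = 0; t < T; ++t) {
      double z0 = wq * beta * Q[0], z1 = wq * beta * Q[1];
      if (use_ck) { z0 += wc * beta_c * CK[0]; z1 += wc * beta_c * CK[1]; }
      double m = z0 > z1 ? z0 : z1;
      double e0 = std::exp(z0 - m), e1 = std::exp(z1 - m);
      double p0 = e0 / (e0 + e1);
      if (use_eps) p0 = eps + (1.0 - 2.0 * eps) * p0;
      double p = choices[t] == 0 ? p0 : 1.0 - p0;
      nll -= std::log(clamp_prob(p));

      if (trace) {
        Qm(t, 0) = Q[0]; Qm(t, 1) = Q[1];
        CKm(t, 0) = CK[0]; CKm(t, 1) = CK[1];
        Pm(t, 0) = p0; Pm(t, 1) = 1.0 - p0;
      }

      int c = choices[t];
      double lr = alpha;
      if (model == 6 && rewards[t] == 0) lr = gamma * alpha;
      Q[c] += lr * ((double)rewards[t] - Q[c]);
      if (use_ck) {
        CK[0] += alpha_c * ((c == 0 ? 1.0 : 0.0) - CK[0]);
        CK[1] += alpha_c * ((c == 1 ? 1.0 : 0.0) - CK[1]);
      }
    }
  }

  if (trace)
    return List::create(_["nll"] = nll, _["Q"] = Qm, _["CK"] = CKm,
                        _["p"] = Pm);
  return List::create(_["nll"] = nll);
}
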