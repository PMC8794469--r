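---
title: "Models and methods for labeling exploration in restless bandit behavior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for labeling exploration in restless bandit behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exploreExploit)
```

## The problem

In a restless two-armed bandit, each arm's reward probability drifts over
trials, so a decision maker must keep balancing exploitation of the arm it
currently believes is better against exploration of the alternative. Neither
goal is directly observable: the only data are the sequence of choices,
outcomes, and latencies. This package implements a complete analysis chain
for such data — task simulation, latent-state labeling of exploration,
reinforcement-learning (RL) model fitting, switching-dynamics analysis,
energy-landscape summaries, and model-free behavioral metrics — together
with a synthetic-cohort generator that provides ground truth for validating
every stage.

## Task simulation

`generate_reward_walk()` produces the drifting schedules. Each arm is an
independent random walk on the probability scale: per trial, with
probability `step_prob` (default 0.10) the arm's reward probability moves by
`step_size` (default 0.10), up or down with equal probability. Three
constraints are enforced by whole-walk rejection sampling (budget 10,000
candidates): the arms' time-averaged probabilities must agree within 0.02
(neither arm is globally better), probabilities never reach 0 or 1, and
there is no 30-trial window with both arms below 0.20 (which would make a
real subject disengage).

Two details are deliberate choices where the task description is silent.
The walk reflects at bounds of 0.1 and 0.9: a proposed step that would
leave that interval is cancelled, which keeps every value on the 0.1 grid
implied by the step size. Start values are drawn uniformly from the grid
between 0.2 and 0.8 per arm, so walks begin well inside the legal range.

## The tied explore/exploit hidden Markov model

The labeling model has three latent states: one *explore* state and one
*exploit* state per arm. Emissions are fixed, not estimated: exploration
emits either arm with probability 1/2 (the maximum-entropy choice
distribution, which does not assume exploratory choice is random — only
that it is unconstrained), and exploit states emit their own arm with
probability 1. A switch of arms therefore *must* pass through exploration,
which is also why every session is constrained to begin in the explore
state rather than spending a parameter on the initial distribution.

With tying across the two exploit states, the transition matrix has two
free parameters: the explore-stay probability $a$ and the exploit-stay
probability $d$,

$$
A = \begin{pmatrix}
a & (1-a)/2 & (1-a)/2 \\
1-d & d & 0 \\
1-d & 0 & d
\end{pmatrix}.
$$

Two four-parameter variants relax the model: the input-output variant
(`io4`) lets both stay probabilities depend on whether the previous trial
was rewarded (the transition into trial $t$ conditions on the reward at
$t-1$; trial 1 has no transition), and the untied variant (`nt4`) gives
each exploit state its own entry and exit probability, allowing biased
exploitation. Structural zeros between the exploit states are kept in all
variants.

`fit_hmm()` runs Baum–Welch per subject with that subject's sessions
pooled: each session contributes a forward–backward pass, and expected
transition counts are summed across sessions and across tied entries
before the M-step. Because emissions and the initial distribution are
fixed, the M-step is a ratio of expected counts. Numerical choices: 20
random restarts with stay parameters initialized uniform on (0.5, 0.99)
(stay probabilities below one half are implausible for either regime and
make early EM iterations unstable), convergence at a log-likelihood gain
below $10^{-6}$ nats, at most 500 iterations, and count ratios guarded so
a never-visited conditioning state yields an interior parameter rather
than 0/0. `viterbi_decode()` returns the most probable state path with
trial 1 forced to explore and ties broken toward explore — the
lower-commitment label. The forward, backward, and Viterbi inner loops
are compiled (Rcpp); everything around them is plain R.

Model comparison uses `information_criteria()`: per-subject fits are
pooled by summing log-likelihoods and free-parameter counts (so a cohort
of 32 subjects contributes $k = 2 \times 32$ for the tied model), AIC
$= 2k - 2\,\mathrm{LL}$, BIC $= k\ln n - 2\,\mathrm{LL}$ with $n$ the
total trial count, and the relative likelihood of model $m$ is
$\exp((\mathrm{AIC}_{best} - \mathrm{AIC}_m)/2)$.

## Switching dynamics as geometric mixtures

If choice runs end probabilistically at a constant per-trial rate, run
lengths are geometric; if distinct regimes (fast-switching exploration,
slow-switching exploitation) coexist, run lengths are a mixture of
geometrics. `run_lengths()` extracts maximal constant-choice runs — a run
includes its first trial, so strict alternation gives runs of length 1 and
i.i.d. fair choices give mean 2 — and `geometric_mixture_em()` fits the
mixture on support $\{1, 2, \dots\}$ by EM. The final, right-censored run
of each session is kept uncensored (runs never span sessions; at ~300
trials per session the bias is negligible), components are reported sorted
by mean, and `mixture_model_selection()` performs sequential
likelihood-ratio tests with 2 degrees of freedom per added component
(weight + rate), flagging components below 3% weight as negligible. The
usual caveat applies: the LRT's boundary irregularity for mixtures makes
these p-values approximate; they are used directionally, for a decisive
one-vs-two comparison, not for fine-grained inference.

## Energy landscapes

A fitted transition matrix defines dynamics; the stationary distribution
$\pi$ (the normalized left unit-eigenvector, `stationary_distribution()`)
summarizes its equilibrium. Treating occupancy as a Boltzmann distribution
with $k_BT = 1$ turns occupancy ratios into energy differences,
$E_{exploit} - E_{explore} = \ln(\pi_{explore}/\pi_{exploit})$, and the
Arrhenius relation turns escape rates into barriers,
$E_a = -\ln(1 - \text{stay})$ with unit pre-exponential factor. Only
differences of these energies are meaningful; the plotting zero in
`landscape_profile()` is a convention.

Group summaries (`landscape_summary()`) average *per-subject stationary
distributions* within group, then derive depths from the group-mean
occupancies — not the equilibrium of the group-mean parameters. The two
differ (Jensen's inequality), which is why a group's mean occupancy is not
reproducible from its mean stay probabilities alone. Chains with an
absorbing state (a stay probability estimated at 1) have no unique
stationary distribution; such subjects are excluded and listed rather than
propagating an error.

## The reinforcement-learning model suite

Seven likelihood models are implemented (`rl_nll()`, `fit_rl()`), from a
pure side bias upward:

1. `random` — constant probability $b$ of choosing left.
2. `wsls` — noisy win-stay/lose-shift: the policy-consistent choice has
   probability $1 - \epsilon/2$.
3. `rl` — delta-rule value learning,
   $Q^k_{t+1} = Q^k_t + \alpha (r_t - Q^k_t)$ for the chosen arm only,
   with softmax choice $p^k_t \propto e^{\beta Q^k_t}$.
4. `rl_eps` — adds a lapse rate: $p = \epsilon + (1 - 2\epsilon)\,
   \mathrm{softmax}$.
5. `rlck` — adds a choice kernel $CK^k_{t+1} = CK^k_t + \alpha_c
   (\mathbb{1}[a_t = k] - CK^k_t)$ (updated for every arm) entering the
   softmax as $\beta Q + \beta_c CK$.
6. `rlck_gamma` — scales the learning rate by $\gamma$ on unrewarded
   trials (asymmetric learning; bounds $\gamma \in [0, 2]$ with
   $\gamma\alpha \le 1$ so the unrewarded update cannot overshoot).
7. `rlck_eta` — mixes the two policies: $\eta \beta Q + (1 - \eta)
   \beta_c CK$.

Values start at 0.5 per arm (the midpoint of the reward scale) and the
kernel at 0; both reset at session starts. Parameter bounds:
$b, \alpha, \alpha_c, \eta \in [0,1]$, $\epsilon \in [0, 0.5]$,
$\beta, \beta_c \in [0, 20]$. Fitting is bounded L-BFGS-B from 10
uniform-random starts; the $\gamma\alpha \le 1$ constraint is a smooth
penalty inside the objective.

One identifiability fact matters for model recovery: `rlck_eta` is an
exact reparameterization of `rlck` ($\eta\beta \to \beta'$,
$(1-\eta)\beta_c \to \beta_c'$), so data generated from it is always
selected as `rlck` by AIC. Recovery analyses treat \{`rlck`,
`rlck_eta`\} as one family; the variant is retained because its $\eta$
parameterization is interpretable when *fixed*, not because it is
separately identifiable.

`rl_explore_labels()` marks a trial exploratory when the chosen arm's
combined decision variable is strictly below the unchosen arm's (ties are
exploitation): exploration as deviation from the model's
value-maximizing prediction. `model_agreement()` scores the fraction of
trials on which the model's preferred arm matches the observed choice,
with half credit for exact ties.

## The grid experiment

`exploration_grid_experiment()` asks which RL parameters drive
exploration: agents with random $(\alpha, \beta)$ each play a fresh
schedule, the tied HMM is fit to each agent, and the decoded explore
fraction is regressed on the parameters (`exploration_glm()`).

Both parameters are sampled **log-uniformly**, and the regression
standardizes $\log\alpha$ and $\log\beta$. This is a deliberate design
choice: each parameter spans more than a decade, and the behaviorally
distinct regime in which learning is too slow for decision noise to
matter at all lives at the low end of the $\alpha$ range. Uniform linear
sampling concentrates on the fast-learning region, where the
$\alpha$-slope of exploration is non-monotone in $\beta$; there the
bilinear interaction term averages to approximately zero and its sign is
seed noise. On the log scale the three effects — more decision noise,
slower learning, and their interaction all increasing exploration — are
stable and visible at a few hundred agents. The full experiment uses
10,000 agents; the packaged tests use 400, which is already decisive for
the sign pattern (coefficient magnitudes then carry standard errors of
about 0.01).

The companion observation, that obtained reward peaks at a *moderate*
learning rate, holds among low-noise agents: at $\alpha = 1$ value
updating collapses onto win-stay/lose-shift, which tracks the drifting
arms too jerkily, while at very small $\alpha$ agents cannot track them
at all. At near-random decision noise the value signal is swamped and the
comparison is uninformative, so tests condition on $\beta > 2$.

## Model-free metrics

`wsls_rates()` computes win-stay and lose-shift rates; when a state
sequence is supplied the split uses the label of trial $t-1$ — the trial
whose outcome is being learned from, which is the alignment that makes
"learning during exploration" interpretable. Empty conditioning sets
return `NA`, never 0. `conditional_mutual_info()` is the plug-in estimate
of $I(C_t; C_{t-1} \mid R_{t-1})$ in bits (base 2 — the natural unit for
binary choices; no normalized "percentage" variant is computed because no
defensible normalizer presents itself). `tetrachoric_corr()` estimates
the latent bivariate-normal correlation between two binary label sets
from their 2×2 table, thresholds fixed by the margins and the correlation
solved so the model orthant probability matches the observed (1,1) cell
(orthant probabilities by one-dimensional Gaussian quadrature; +0.5
continuity correction for empty cells; degenerate margins return `NA`).
`auc_separability()` is the rank-based (Mann-Whitney) AUC with
Hanley-McNeil standard errors. First trials of sessions are excluded from
all lagged statistics.

## The synthetic cohort

`cohort_config()` / `generate_cohort()` produce cohorts with the
structure the analyses assume: 2 groups × 16 subjects × 8 sessions × 300
trials by default. Per-subject parameters are truncated-normal around
group means. The HMM preset uses explore-stay 0.921/0.831 and
exploit-stay 0.835/0.797 for the two groups (group M the stickier
explorer) with within-group SDs of a few percentage points; the RL
presets put the group difference in the learning rate only (F 0.45 vs M
0.25, shared $\beta = 3$, $\alpha_c = 0.3$, $\beta_c = 1.5$), since that
is the kind of difference the pipeline is meant to detect. The default
generating model is `rlck`. These numeric values are a modeling choice —
they fix a known ground truth with realistic effect sizes, and the
recovery tests are statements about the pipeline at *these* operating
points, not about any particular dataset.

Latencies are log-normal (parameterized by their arithmetic mean, so a
zero-noise configuration reproduces the configured means exactly):
response times average 1.0 s (group F) / 1.5 s (group M) during
exploitation plus 0.5 s during exploration, with `sdlog` 0.3; retrieval
times are state- and group-independent at 2.0 s. What the generator does
*not* emulate: satiety and session truncation, within-session engagement
drift, trial-level autocorrelation in latencies, and individual
differences beyond the parameter dispersion. Passing recovery tests on
these cohorts therefore demonstrates correctness of the estimators under
the stated generative assumptions — not robustness to every way real
behavior violates them.

## Problem sizes used in the packaged checks

The test suite runs parameter recovery at the full published operating
points where the quantity under test demands it — 24,836 run lengths for
the mixture refit, 16 subjects × 8 × 300 trials for the tied-HMM group
means — and at reduced sizes (a few subjects, a few hundred trials, 400
grid agents) for property checks where the property is size-independent.
Exhaustive-enumeration oracles cover all sessions up to 10 trials, where
$3^{10}$ paths are still cheap.

## Known limitations

- The Viterbi tie-break (toward explore) and the explore-label tie-break
  (toward exploit) are conventions; ties have measure zero under
  continuous parameters but occur at parameter bounds.
- Mixture LRT p-values inherit the boundary irregularity noted above.
- The `io4` variant has no single stationary distribution (its transition
  matrix is input-dependent), so landscape summaries apply only to the
  reward-independent variants.
- Only two arms are exercised; interfaces carry an `n_arms` field for
  forward compatibility but the emission structure is two-arm.
- Per-session RL fits (`fit_unit = "session"`) at 300 trials carry
  substantial estimation noise, as parameter-drift analyses on real data
  would; nothing in the package shrinks or pools them.
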