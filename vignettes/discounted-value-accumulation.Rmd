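---
title: "Discounted value accumulation: models, estimation and design choices"
author: "valba"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discounted value accumulation: models, estimation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

When people choose between a small immediate reward ($10 now) and a larger
delayed one ($R in D days), two modelling traditions describe the outcome.
Temporal-discounting models summarise *what* is chosen: the delayed reward's
subjective value is discounted, most commonly hyperbolically,
$V = R/(1 + kD)$, and a softmax (logistic) rule maps the value difference
into a choice probability, $P(\text{delayed}) = 1/(1 + e^{-m(V_D - V_I)})$.
Sequential-sampling models describe *how* the choice unfolds in time,
jointly predicting choices and response times (RTs). This package links the
two: intertemporal choice is modelled as a race between two linear ballistic
accumulators (LBA) — one per option — whose mean evidence-accumulation rates
(drift rates) are tied to discounted subjective value. `valba` implements
the complete analysis pipeline: two-session task emulation, discounting and
softmax fits, hierarchical Bayesian LBA estimation, variant comparison by
the Bayesian predictive information criterion (BPIC), and the linkage
analyses connecting drift rates and non-decision times to value.

## Task structure emulated by the synthetic generator

The generator (`generate_cohort()`) emulates a two-session design:

* **Session 1** estimates each subject's discount rate with a 60-trial
  staircase. Each trial offers $R = 10(1+\hat k D)$ at a delay $D$ against
  $10 now, so indifference implies rate $\hat k$ exactly. Chosen-delayed
  moves $\hat k$ down a step, chosen-immediate up; at every second choice
  reversal falling within five consecutive trials the step shrinks by 5%.
  Initial values ($\hat k_0 = 0.01$/day, step $0.005$/day) are defaults of
  this implementation, chosen at the typical human discount-rate scale; the
  staircase is self-correcting, so their exact values matter little. A
  floor of $10^{-6}$/day keeps the rate positive.
* **Session 2** presents offers constructed from the subject's discounting
  and softmax parameters so that the model-implied probability of choosing
  the delayed option equals one of five targets (0.1, 0.3, 0.5, 0.7, 0.9):
  the required value is $V_D = 10 + \mathrm{logit}(p)/m$ and the amount is
  the inverse value function at a delay drawn uniformly from 30–45 days.
  An EEG-like arm completes 30 trials per target (60 at 0.5; 180 total), an
  fMRI-like arm 40 (80 at 0.5; 240 total). Responses are collected inside a
  4-second decision window; trials answered in under 200 ms or outside the
  window are discarded by `filter_trials()` before modelling.

Session-2 behaviour is generated from the LBA itself, with each condition's
delayed drift rate solved numerically so the model-implied choice
probability equals the target (`linkage = "exact"`), or perturbed on the
logit scale (`linkage = "noisy"`). Trials slower than the window are
emitted with their true RT and removed downstream by the filter — the
discard rule is applied to the data, exactly as in the protocol being
emulated, rather than being built into the likelihood as censoring.

### Ground-truth population values

Where the emulated protocol fixes a quantity (targets, counts, delays,
window, staircase length) the generator uses it. The remaining population
values are this package's own choices, set once on realism grounds:

* discount rate $k \sim \mathrm{lognormal}(\log 0.01, 0.5)$ per day and
  softmax sensitivity $m \sim \mathrm{lognormal}(\log 2.5, 0.3)$ per dollar
  — typical scales for human delay discounting over week-to-month horizons;
* LBA start-point range $A \approx 0.45$, threshold gap
  $\chi = b - A \approx 0.5$, drift sd $s \approx 0.3$, non-decision time
  $t_0 \approx 0.30$ s (each lognormal with 10–15% coefficient of
  variation). These put median RTs at 1.2–1.4 s with roughly 1–2% of
  simulated responses exceeding the 4 s window — the regime expected from
  practised subjects under a response deadline — and place the threshold
  well above the start-point range, which is what produces *slow* errors
  (value-inconsistent choices slower than consistent ones);
* under the M2 generating variant, non-decision time carries a positive
  quadratic value profile $t_0 + 0.5\,(p - 0.5)^2$ seconds, i.e. an
  80 ms swing between the hardest and easiest conditions.

What the generator does **not** emulate: sequential presentation of delay
and amount within a trial, inter-trial-interval effects, session-order or
button-mapping effects, attentional lapses, and any RT contamination
process. Passing recovery tests on these cohorts therefore demonstrates
that the estimation machinery works when the model family is (nearly)
correct — the one deliberate misspecification is the unmodelled 4 s
truncation — not that the LBA is the true model of any given dataset.

## The LBA likelihood

Each accumulator starts a trial at an independent uniform start point on
$[0, A]$, accumulates evidence at a rate drawn from
$\mathcal N(\nu, s^2)$, and triggers its response on reaching threshold
$b$. Observed RT is the winning finishing time plus a non-decision offset
$t_0$. The finishing-time distribution of one accumulator has closed-form
density and CDF (`lba_node_pdf()`, `lba_node_cdf()`); the probability
density of responding with option $c$ at time $t$ is the *defective*
density: the density that accumulator $c$ finishes at $t - t_0$ times the
probability the other has not yet finished. Scale is fixed by the
constraint that the two mean drifts sum to one, so only the delayed drift
$\nu_d$ is estimated, per condition.

Numerical conventions:

* the threshold is parameterised as $b = A + \chi$ with $\chi > 0$, so the
  threshold always exceeds the start-point range;
* trials on which both sampled drifts are negative are redrawn in the
  simulator; the analytic defective density is left un-renormalised (its
  total mass is $1 - \Phi(-\nu_a/s)\Phi(-\nu_d/s)$), the standard LBA
  convention, and model-implied choice probabilities normalise by that
  mass;
* per-trial log densities below $-700$ (including the zero-density region
  $t \le t_0$) are clamped at $-700$ so sampler arithmetic stays finite;
* exact finishing ties are measure-zero; the simulator breaks them toward
  the delayed accumulator;
* times are seconds throughout, RT measured from decision-period onset.

The data log-likelihood loop is implemented in C++ (evaluated for all
MCMC chains of one subject in a single call); a pure-R reference path
implements the same formulas and the two are cross-checked in the test
suite.

## Hierarchical estimation

Subject parameters are sampled on transformed scales — log for the
positive parameters ($A$, $\chi$, $s$, $t_0$), logit for drifts — where
each has a normal group-level prior with mean $\mu_p$ and dispersion
$\sigma_p$. Group means get conjugate normal hyperpriors
$\mathcal N(0, 1)$; group *variances* get inverse-gamma IG(4, 9.96)
priors. The IG prior is deliberately skewed: mean 3.32 with an
approximate 95% set of (1.14, 9.05), encoding that between-subject
variability below 1 (transformed scale) was considered unlikely and very
large values increasingly so. Placing the inverse gamma on the variance
(rather than the sd) is what conditional conjugacy requires; the exact
normal-mean hyperprior values are this implementation's defaults and are
configurable via `hlba_prior()`.

Sampling alternates, per iteration:

1. **Subject level, DE-MCMC.** For every subject, each of $C$ chains
   proposes $\theta^* = \theta_i + \gamma(\theta_m - \theta_n) + U(-10^{-3},
   10^{-3})$ from two other chains' states and accepts by Metropolis. Two
   refinements to the textbook sweep proved necessary for short runs:
   proposals are made *block-wise* (structural parameters $A, \chi, s,
   t_0$ in one block, the five drifts in another), each block with its own
   dimension-scaled factor $\gamma = 2.38/\sqrt{2d_{\text{block}}}$, and
   $\gamma$ is randomised per sweep (uniform on 0.5–1 times the base
   value, with a 10% chance of a near-unit "mode-jumping" move). Both are
   standard DE-MCMC practice and markedly improve mixing with small chain
   populations; no migration or crossover steps are used.
2. **Group level, Gibbs.** Every chain carries its own group-level state,
   updated by exact conjugate draws from that chain's current subject
   parameters — first $\mu_p \mid \sigma_p^2$, then $\sigma_p^2 \mid
   \mu_p$. Per-chain group states are what the across-chain BPIC spread is
   computed over.

Chains initialise at a cheap penalised-ML point per subject (heuristic
start anchored at data moments: $t_0$ near half the fastest response,
drifts at a normal-approximation inverse of each condition's observed
choice fraction), jittered with sd 0.25; initialisation retries from the
mildly informative pre-coupling prior $\mathcal N(0, 2)$ if a chain
starts with a fully clamped likelihood (cap: 100 retries). The default
configuration (24 chains, 5,000 burn-in + 5,000 kept, thinned by 4)
retains 30,000 draws; every run is reproducible from its single seed.
Split-$\hat R$ and a crude effective-sample-size estimate are reported by
`summary()` as warnings, not hard failures.

MAP estimates are the retained draw with the highest joint log posterior
for that subject, back-transformed.

## Model variants and BPIC

The delayed drift rates always vary across the five value conditions. M1
frees nothing else (9 subject parameters); M2 additionally frees $t_0$
(13); M3/M4/M5 instead free $A$, the threshold gap, or $s$ (13); M6/M7/M8
combine $t_0$ with one of those (17). The assignment of the M3–M5 labels
to $A$/threshold/$s$ is arbitrary metadata. BPIC is operationalised in
its deviance form: with $D(\theta) = -2\sum_s \log L_s$,
$p_D = \bar D - D(\bar\theta)$ and $\mathrm{BPIC} = \bar D + 2 p_D$ —
twice the DIC penalty — with $\bar\theta$ the posterior mean taken on the
transformed scale, where posteriors are closer to Gaussian. The forward
search (`model_search()`) starts from M1, fits the four single
extensions, and completes the winner's extensions only if BPIC improved,
so at most eight variants are ever fitted.

A caution from our own simulations: with few subjects and short runs the
plug-in deviance $D(\bar\theta)$ is fragile, because the structural LBA
parameters ($A$, $\chi$, $s$, $t_0$) are weakly identified and their
joint posterior is ridge-shaped — the posterior mean can fall off the
ridge, driving $p_D$ negative. BPIC comparisons should use configurations
long enough for the deviance trace to stabilise; the comparison report
includes the across-chain sd as an instability diagnostic.

## Linkage analyses

If drift rates encode discounted value linearly, the logistic description
of choice in drift space, $P = \mathrm{logistic}(\beta_0 + \beta_1\nu_d)$,
and in value space, $P = \mathrm{logistic}(m(V_D - 10))$, must be the same
function, so $m(V_D - 10) = \beta_0 + \beta_1 \nu_d$ across conditions —
testable as a regression with slope one, with every component estimated
independently ($\beta_0, \beta_1$ from a per-subject trial-level logistic
fit of choices on MAP drifts; $m$ and the value model from the
discounting fits). The package runs this identity test for hyperbolic,
exponential ($V = Re^{-kD}$) and quasi-hyperbolic ($V = R\beta\delta^D$,
days as the exponent period) value functions. Supporting analyses:
per-condition rank tests of consistent versus inconsistent median RTs
(consistency defined by the session-1 value model: delayed is consistent
where the target probability exceeds 0.5), and regressions of MAP
non-decision times on the quadratic value regressor $(p - 0.5)^2$ and on
condition-wise minimum and median RT.

The regressions use random subject intercepts via `nlme::lme` where it
converges, falling back to fixed per-subject intercepts; the contract is
the coefficient/se/p triple, not the engine. The drift-on-choice logistic
regression is two-stage (per-subject ML fits, then a group-level t-test
on slopes) with the drift regressor centred within subject — the linear
predictor is unchanged by centring, which only stabilises the numerics.
Eq.-level ambiguity about trial- versus condition-level fitting is
resolved trial-level (each trial contributes a Bernoulli term).

## Problem sizes used by the test suite

The automated checks run at desk scale, as their own design choice:
recovery uses 8 subjects × 180 trials with 12 chains and 1,500 + 1,500
iterations (4,500 retained draws); BPIC selection replicates use 5
subjects with 8 chains and a long burn-in relative to the kept window;
the linkage identity cohort uses 20 subjects. The full-protocol
configuration (24 × 10,000) is the package default for real analyses.

## Known limitations

* The likelihood ignores the 4 s truncation that the discard rule
  introduces; at the ~1–2% discard rates of the emulated design this
  biases $s$ slightly downward and $A$ upward, visible in the recovery
  reports. Modelling the censoring would remove the bias but depart from
  the emulated protocol.
* $A$, $\chi$, $s$ and $t_0$ are individually weakly identified at a few
  hundred trials per subject; their MAP-truth correlations are modest
  even when drift rates recover excellently. Conclusions should rest on
  drift rates (and group-level patterns), not on individual structural
  parameters.
* No across-trial drift autocorrelation, collapsing bounds, urgency
  signals, or within-trial parameter drift; variational or ML fitting of
  the hierarchical model is out of scope.
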