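---
title: "Models and methods in hexlearn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in hexlearn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hexlearn)
```

hexlearn re-implements, as a tested pipeline, an analysis of how people learn
hostile expectations in a probabilistic shooting task and how the fitted
learning parameters relate to latent antisociality traits. This vignette is
the package's own account of the science: the models and their assumptions,
the tunable parameters and their defaults, what the synthetic cohorts emulate
(and what they deliberately do not), and the numerical choices made where the
design was genuinely open. Every empirical statement here is computed by the
package's test suite or acceptance script; nothing is asserted that the code
does not check.

## The task

Two opponents draw a gun with complementary probabilities (0.8 vs 0.2) that
flip after blocks of 40, 15, 25, 25, 15 and 40 trials — 160 trials with five
reversals. The subject must shoot when expecting a gun and withhold otherwise.
Environmental threat (whether points can be lost) alternates in regular
20-trial blocks.

`build_schedule()` encodes this design. Two layout choices were open:

* **Threat phase.** The sources state only that threat blocks were regular,
  predictable and *orthogonal* to the gun probabilities. A 20-trial
  alternation starting with a full high-threat block has a phi coefficient of
  0.375 with the probability blocks — far from orthogonal — because the
  probability block lengths (odd multiples of 5 after the first) never align
  with the threat grid. The default therefore uses a half-period phase offset
  (10 low-threat trials, then full 20-trial blocks starting with high
  threat): this is exactly orthogonal (phi = 0) and gives both condition
  streams the same number (five) of experienced probability switches.
  `threat_phase = 0` restores the unshifted layout.
* **Opponent interleaving.** Not stated in the sources; the default
  alternates deterministically (ABAB...), preserving equal counts per block;
  a seed-controlled random interleaving is available.

Outcome sequences are drawn per trial (`bernoulli`) or with exact per-block
gun counts (`exact_proportion`); both are seed-reproducible.

## Observer models

All five models map each trial's *prediction* of a gun to a shoot
probability; they differ in how the prediction is updated.

**Two-level Hierarchical Gaussian Filter (binary).** The second-level belief
$x_2$ follows a Gaussian random walk with step variance $e^{\omega}$; the
predicted gun probability is $\hat\mu_1 = s(\mu_2)$ with $s$ the logistic
sigmoid. The per-trial update is

$$
\hat\pi_2 = \frac{1}{\sigma_2 + e^{\omega}},\qquad
\pi_2 = \hat\pi_2 + \hat\mu_1(1-\hat\mu_1),\qquad
\varepsilon = \frac{u - \hat\mu_1}{\pi_2},\qquad
\mu_2 \leftarrow \mu_2 + \varepsilon,\qquad
\sigma_2 = \frac{1}{\pi_2}.
$$

Five quantities summarise a subject: the volatility $\omega$ (speed of belief
updating), the mean belief $\mu_2$ (average expected hostility), the
uncertainty $\sigma_2$, the precision-weighted prediction error
$\varepsilon$, and the response parameter $\zeta$. Only $\omega$ and $\zeta$
are free parameters of the generative model; $\mu$, $\sigma$ and
$\varepsilon$ are trajectory summaries, which matters for how couplings can be
induced in synthetic cohorts (below).

**Three-level HGF.** Adds a volatility level: the level-2 step variance is
$e^{\kappa\mu_3 + \omega_2}$ and $\mu_3$ follows its own random walk with
variance $e^{\theta}$, updated by volatility prediction errors. With
$\kappa \to 0$ it reduces exactly to the two-level filter (tested to
$10^{-8}$). $\kappa$ is fixed at 1 by default: freeing it alongside $\theta$
on 160 binary trials leaves both essentially unidentified. The canonical
level-3 precision update can turn negative for extreme volatility
trajectories; this raises a trial-indexed error rather than being silently
clamped.

One caveat the test suite documents: the level-3 volatility estimate tracks
*surprise relative to current uncertainty*, so a confident agent in a
stationary-but-stochastic world (p = 0.8) receives regular strong surprises
and can hold volatility beliefs as high as an agent in a switching world. The
regime test therefore contrasts near-deterministic stable blocks (p = 0.95)
with reversals, averaged over outcome realisations.

**Rescorla-Wagner, K1, Kalman.** Fixed learning rate; Sutton's incremental
delta-bar-delta meta-learning rate (learning rate capped at 1 for stability);
and a scalar Kalman filter with process noise $q$ and observation noise
$r_{obs}$. Each reduces to a documented limit that the tests exercise
(K1 with $\mu_{meta}=0$ is Rescorla-Wagner; the Kalman gain at $r_{obs}\to 0$
tracks the input; its posterior variance satisfies the steady-state fixed
point).

**Response model.** The printed shoot-probability expression in the source
material (a sum of two $\zeta$-powered terms with an outer exponent) does not
reduce to a probability for general $\zeta$; the text names "a unit square
sigmoid", whose canonical form

$$p(\text{shoot}) = \frac{\hat\mu_1^{\zeta}}{\hat\mu_1^{\zeta} + (1-\hat\mu_1)^{\zeta}}$$

is implemented. $\zeta = 1$ is probability matching; $\zeta \to \infty$ is
argmax responding; the function is strictly increasing in both arguments and
satisfies $p(m) + p(1-m) = 1$.

**Per-opponent beliefs.** Each subject carries two parallel trajectories (one
per opponent) sharing $\omega$ and $\zeta$, because the task defines
contingencies per opponent. A pooled single-stream variant is available
(`pool_opponents = TRUE`). All probabilities are clamped to
$[10^{-12}, 1-10^{-12}]$ before logs.

## Estimation

Parameters are estimated per subject by MAP in an unconstrained space
($\omega$ native; $\zeta$, variances, rates log- or logit-transformed) with
Gaussian priors, multi-start BFGS (default 8 jittered starts, objective
tolerance $10^{-8}$), and Laplace log model evidence
$-\mathcal{L}_{min} + \tfrac{d}{2}\log 2\pi - \tfrac12\log|H|$ with a
nearest-positive-definite fallback (flagged) for the numerical Hessian. The
Laplace evidence is validated against brute-force quadrature on a
one-parameter model to 0.1 nats.

Two prior presets exist per model. For the two-level HGF the defaults are
$\omega \sim N(-3, 2^2)$, $\log\zeta \sim N(0, 1)$, and the `wide` preset
$\omega \sim N(-3, 4^2)$, $\log\zeta \sim N(0, 2^2)$ — used to refit the
winning model so individual differences are less shrunk. The exact wide
values used in the original toolbox analysis are not published; these are
surrogates, exposed in `model_priors()`. Initial beliefs default to
$\mu_2^0 = 0,\ \sigma_2^0 = 1$ (agnostic prior).

Condition-specific parameters are obtained by *refitting* the model to each
threat condition's trial subsequence (per-opponent streams preserved). The
alternative — splitting one fit's trajectory — cannot make $\omega$ and
$\zeta$ condition-specific, which the downstream contrasts require.

Exclusion rules mirror the published analysis: subjects with more than 25% of
trials missing (strictly greater; a 50% sensitivity threshold is available),
and subjects with any screened parameter outside mean ± 2 SD, with the mean
and SD computed once on the full sample. Which parameters entered the
original ±2 SD screen is not enumerated; the pipeline screens the union of
fitted parameters and condition summaries, configurable.

## Model selection

Random-effects Bayesian model selection (variational Dirichlet scheme,
uniform prior $\alpha_0 = 1$) with exceedance probabilities from $10^5$
Monte-Carlo Dirichlet draws. For two models the exceedance probability is
checked against the closed-form Beta tail; invariances (column permutation,
per-subject evidence shifts) are property-tested. Bayesian omnibus risk and
protected exceedance probabilities are documented extension points, not
implemented.

## Recovery studies: the stated worlds

Two distinct generator regimes are used deliberately:

* **Recovery studies** (model identification, parameter recovery) draw agents
  from the *fitting prior itself* ($\omega \sim N(-3,4)$,
  $\log\zeta \sim N(0,1)$) — the canonical self-consistency design. This
  choice is substantive: in a narrow regime (e.g. $\omega$ SD 0.7 around -3,
  $\zeta \approx 2$) the five models are nearly likelihood-equivalent on 160
  binary trials, and selection results hinge on noise. With prior-spanning
  agents the acceptance suite obtains exceedance probability $\ge 0.9$ for
  the generating two-level HGF at 50 agents and recovery correlations of
  about 0.85 ($\omega$) and 0.91 ($\zeta$) at 100 agents, with median
  trajectory correlations above 0.99.
* **Cohort emulation** (`population_spec()`) states the emulated experiment
  once: $\omega$ centred at -3.2 under low threat with a +0.8 high-threat
  shift (the published direction; the magnitude is not printed), SD 0.7
  between subjects, trait coupling -0.3 per trait SD into $\omega$; $\zeta$
  log-normal around 2; initial beliefs coupled positively to the trait; 2%
  missing responses; aggression and psychopathy traits correlated 0.639;
  questionnaire subscales as linear indicators with loadings 0.6-0.86.

Because $\mu$, $\sigma$ and $\varepsilon$ are trajectory summaries rather
than free parameters, the cohort generator induces their trait couplings only
*indirectly* (through $\omega$ and the initial beliefs); recovery tests on
agent-based cohorts therefore target signs and the directly coupled
$\omega$, not magnitudes.

The condition streams necessarily traverse different outcome orderings, which
produced a small systematic null difference in mean $\mu_2$. The generator
counterbalances the threat phase across subjects (as the corresponding real
experiment would), cancelling the asymmetry. The null-calibration study uses
48-subject cohorts (the source study analysed 241): the JZS Bayes factor is
consistent under the null, so its false-alarm rate falls with cohort size,
and at this scale at least 90% of 50 null cohorts show no dual-criterion
condition effect.

What the synthetic cohorts do **not** emulate: real response-time
distributions, demographic structure, questionnaire item-level data (only
subscale scores), non-MCAR missingness, or any drift in attention or
strategy over the session. A green recovery test therefore establishes that
the pipeline recovers the stated generative structure — not that the
published participant-level estimates are reproduced, which is impossible
without the restricted raw data.

## Behavioural statistics

For the 2x2 within-subject ANOVA every effect is exactly a paired contrast
(F = t² to $10^{-8}$, cross-checked against `stats::aov`), so per-effect
Bayes factors are JZS one-sample Bayes factors on the contrast scores —
exact for two-level factors, and preferred here over a BIC approximation.
"Default flat priors" is interpreted as the conventional defaults of the
reference software: a Cauchy($\sqrt2/2$) prior on the standardised effect for
t-tests and a stretched-beta ($\kappa = 1/3$) prior on $\rho$ for
correlations (truly flat priors yield no finite Bayes factor). Both are
validated against printed reference values — BF = 0.799 for t(240) = 2.21
and BF ≈ 54.98 for r = 0.238 at n = 207 — and against independent
quadrature oracles ($10^{-4}$ relative). The dual-criterion convention
(significant iff p < 0.05 **and** BF > 3) is exposed as
`significant_both()`.

Correlation power uses the Fisher-z formula. At n = 188 it gives 78.7% for
r = 0.2 and 98.8% for r = 0.3; the published figures (78%, 98%) are evidently
floor-reported, so the acceptance check asserts agreement within one
percentage point rather than nearest-percent rounding, which the formula
cannot meet.

McDonald's omega comes from a one-factor ML fit. With no common factor the
one-factor solution is identified only up to a ridge (one item can absorb an
arbitrary loading with compensating residual), so omega near zero reliability
is unstable; the tests bound it loosely there.

## The SEM engine

`fit_ml_sem()` minimises
$F_{ML} = \log|\Sigma(\theta)| + \mathrm{tr}(S\Sigma^{-1}) - \log|S| - P$
with loadings and regressions unconstrained, residual variances on the log
scale (Heywood cases cannot go negative; estimates collapsing to zero are
flagged), and latent covariances through tanh. Identification follows the
unit-latent-variance convention (all latent residual variances fixed to 1,
all loadings free), with the sign fixed so each latent's first indicator
loads positively. Observed covariates are fixed exogenous (their covariance
is the sample one and not counted as free moments): the aggression MIMIC
model — four subscales loading on a latent trait regressed on the five
learning parameters — then has 17 degrees of freedom, matching the published
chi-square. Indicator variables are z-scored first by default.

Fit indices: $\chi^2 = (n-1)F_{ML}$; CFI against the independence baseline
(saturated covariate block); RMSEA $= \sqrt{\max(\chi^2-df,0)/(df(n-1))}$;
SRMR over standardised residuals including the diagonal. The perfect-fit
identity ($\chi^2 = 0$, CFI = 1, RMSEA = 0 on a model-implied covariance) is
tested exactly. Factor scores use the regression method
$\hat\eta = \Psi\Lambda'\Sigma_{yy}^{-1}(y-\bar y)$ and are zero-mean by
construction.

The published credible intervals came from MCMC; as a deliberate surrogate,
the second decision criterion here is a nonparametric bootstrap percentile
interval (default 2000 draws; the acceptance suite uses 1000 per replicate to
stay within its time budget, stated there). Bootstrap refits warm-start from
the full-sample solution and use the analytic gradient of $F_{ML}$, which is
verified against central finite differences in the test suite.

**The direct MIMIC generator.** The published standardised path pattern
(-0.24, 0.72, 0.45, 0.78, -0.01 for $\omega,\mu,\sigma,\varepsilon,\zeta$)
implies $b'Rb > 1$ for *independent* predictors, so no unit-variance latent
can carry those coefficients unless the predictors are correlated.
`mimic_predictor_corr()` freezes one admissible positive-definite correlation
matrix (chosen once; $b'Rb \approx 0.32$), and `generate_mimic_cohort()`
builds cohorts whose true standardised coefficients equal the published
pattern exactly. Large-sample recovery (n = $10^4$) reproduces the
coefficients within ±0.05, and across 50 replicate cohorts of n = 500 the
four non-null paths are flagged by both criteria, with the null $\zeta$ path's
interval covering zero, in at least 90% of replicates.

## Numerical choices, in one place

* Probability floor $10^{-12}$ before all logs and precisions.
* MAP: BFGS, 8 starts (4 in the acceptance studies, 2 in the null-calibration
  study — scaled down and stated there), objective reltol $10^{-8}$
  ($10^{-12}$ for SEM, whose objective is cheap).
* Laplace Hessian: nearest-PD eigenvalue clamp at $10^{-8}$, flagged.
* BMS convergence: max $|\Delta\alpha| < 10^{-6}$, $10^4$ iteration cap.
* JZS Bayes factors: `integrate()` with relative tolerance $10^{-9}$ on the
  log-scaled integrand; correlation Bayes factors use the exact sampling
  density of r with a direct-series Gauss hypergeometric.
* Ties and degenerate input: identical paired samples return t = 0, p = 1
  (a flat zero effect), while a noiseless nonzero shift raises a
  degenerate-data error; BH q-values are computed by the step-up rule with
  enforced monotonicity; zero-variance variables raise named errors rather
  than NaNs.
* Seeds: every stochastic stage takes an explicit seed; the pipeline derives
  per-stage seeds from one master seed and records them in its manifest.

## Known limitations

* The variational scheme of the original toolbox is replaced by MAP + Laplace
  (the sources describe the two as comparable); evidence enters only
  rank-based model selection.
* No hierarchical (empirical-Bayes) pooling across subjects; no
  continuous-outcome HGF; no reaction-time modelling.
* Bayesian SEM (MCMC posterior predictive p-values) is out of scope; the
  bootstrap interval is a surrogate with different small-sample behaviour.
* The three-level HGF's level-3 update can lose positive-definiteness for
  extreme parameters; this errors loudly instead of being repaired.
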