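---
title: "Methods: diffusion modelling of dot-probe data and the structural layer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diffusion modelling of dot-probe data and the structural layer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(driftsem)
```

This vignette documents the models the package implements, the tunable
parameters and their defaults, the numerical choices, and what the
synthetic studies can and cannot show.

## The diffusion model and its likelihood

Each dot-probe trial is modelled as a Wiener process with unit diffusion
coefficient starting at `a/2` between an upper (correct) and lower
(incorrect) absorbing boundary.  The five free parameters are the drift
rate `v` (evidence/s), threshold separation `a`, nondecision time `t0`
(s), the range `st0` of uniform across-trial variability in `t0`, and the
SD `sv` of Gaussian across-trial variability in drift.  The start point is
fixed at `a/2` because the boundaries code response correctness, not
response identity, so no bias between them is meaningful; with that
constraint the probability of a correct response for constant drift is
`1/(1 + exp(-v a))`.  The unit diffusion convention is used throughout:
printed drift rates near 4 and nondecision times near 0.35 s are on this
scale (on the 0.1 convention the same data would give drifts near 0.4).

The defective first-passage density at each boundary is evaluated with the
standard small-time and large-time series expansions, choosing per
evaluation whichever needs fewer terms for an absolute truncation error of
`1e-7`.  Gaussian drift variability has a closed form (a rescaled
exponential-quadratic factor), so only the uniform `t0` window is
integrated numerically, by composite 10-point Gauss–Legendre quadrature.
The panel count scales with the ratio of the window width to the mean
decision time `a/(2|v|) tanh(|v|a/2)` (capped at 8 panels): when decisions
are much faster than the nondecision variability — small thresholds — the
decision-time density is a narrow spike inside the window, and a single
panel integrates it poorly while leaving the total choice probability
exact (linearity), an error mode invisible to normalization checks and
caught only by the simulation oracle.  The density is exactly zero for
`t <= t0 - st0/2`.  In the likelihood each
trial's density is floored at `1e-29` before the log so that sampler
excursions into regions where some trial is impossible produce a very
unfavourable, but finite, posterior value; the induced bias is negligible
because accepted states never sit on the floor.

Correct responses are scored against the upper boundary and errors against
the lower, with no contaminant-mixture component: the preprocessing rules
already remove the fast guesses a contaminant component would absorb.

### The simulator as an independent oracle

`simulate_ddm()` is deliberately not derived from the series density.  It
simulates the process forward with Gaussian increments (exact for this
constant-coefficient SDE) at `dt = 5e-4` s, with a Brownian-bridge
correction for within-step boundary crossings
(`P(cross) = exp(-2 d0 d1 / dt)` for distances `d0`, `d1` at the step's
ends), and assigns the decision time at the midpoint of the crossing step.
The only neglected event — crossing both boundaries within one step — has
probability of order `exp(-a^2/(2 dt))`, which is negligible for every
realistic threshold.  The test suite uses this simulator as the
Monte-Carlo oracle for the density, comparing equal-mass bins of the
defective distribution at one million trials per parameter set.

## The DE-MCMC sampler

Each participant-condition data set is fit independently by
differential-evolution MCMC: 15 chains (three per parameter), 2000
iterations, 1000 burn-in; the proposal for chain `k` is
`theta_k + gamma (theta_m - theta_n) + U(-0.001, 0.001)` with `m != n != k`
and `gamma = 2.38/sqrt(2 d)`, accepted by Metropolis on the log posterior.
Priors are bounded uniforms — `v` in (−10, 10), `a` in (0.2, 5), `t0` in
(0.05, 1), `st0` in (0, 0.5), `sv` in (0, 5), jointly constrained by
`t0 - st0/2 > 0.05` — which keep the posterior proper without informative
content.  Two details depart from a textbook minimal implementation, both
standard in the differential-evolution literature and adopted after
observing stranded chains in recovery runs:

* with probability 0.1 a proposal uses `gamma = 1` (the mode-jumping move
  of the original DE-MC scheme), and
* each chain starts at the best of 25 prior draws rather than a single
  draw.

The reason is geometric: once most chains contract onto the posterior
mode, difference vectors between them are small, so a chain that started
inside a far-away, negligible-mass local basin (for rare-error data the
likelihood has a high-`v`/high-`a`/high-`sv` ridge) can only take small
local steps and never rejoins the population.  Filtering the starts makes
such a stranded start very unlikely while keeping the initial population
overdispersed and independent; no migration or snooker extensions are
used.

Even so, a chain can occasionally wander onto the ridge mid-run and stay
there (roughly one fit in sixty on default synthetic panels).  Because a
single outlier cannot be recovered by difference-vector proposals,
`fit_ddm_all()` re-runs any fit whose diagnostic fails with fresh chains
(up to twice, seeds derived deterministically) and reports the final
diagnostic either way — the refit-on-failed-diagnostic workflow an analyst
would apply by hand.

Convergence is summarized by the Brooks–Gelman multivariate potential
scale reduction factor on the post-burn-in samples,
`MPSF^2 = (n-1)/n + ((m+1)/m) lambda_1` with `lambda_1` the largest
eigenvalue of `W^{-1} B/n`; the same formula per coordinate gives the
univariate PSRFs, so the one-parameter case reduces exactly.  Values are
floored at 1: the raw statistic dips to `sqrt((n-1)/n)` when chains agree
perfectly, and the floor makes "1 means converged, larger means not"
literal.  The convergence criterion is MPSF < 1.15.  Point estimates are
posterior means pooled across chains; the mean was chosen over the mode
for stability under MCMC noise.

## Preprocessing rules

Within each participant and condition, in one pass: trials without a
response are removed, then responses faster than 200 ms, then trials whose
RT lies outside mean ± 2 SD, where the mean and SD are computed on the
trials surviving the first two rules.  The window is closed (a value
exactly at a limit survives), and a zero-SD group keeps all values equal
to the mean.  One pass rather than iterative re-trimming makes the
operation deterministic and idempotent.  Participants answering fewer than
50% of all presented trials (both runs, strictly below) are removed
entirely before trial filtering.  The 2-SD trim operates on raw RTs, not
log-RTs.

## Split-half reliability

Trials are split by the parity of their original (pre-filter) trial index,
so filtering cannot move a trial between halves; each half is fit with the
same sampler (callers typically halve the iteration budget), and ICC(2,1)
— two-way random effects, single measure, absolute agreement — is computed
across participants between the halves:
`ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))` with `k = 2`.
Absolute agreement is the right variant here because a constant offset
between odd and even halves is a real disagreement of the two estimators,
not noise.

## The structural layer

The measurement model puts four indicators (MiniPONS, PENN ER-40, RMET,
Hinting) on a social-cognitive-capacity factor and two (DACOBS AB, AIHQ
BS) on a social-cognitive-bias factor, identified by fixing each first
loading to 1 (the degrees of freedom are invariant to this choice versus
fixing latent variances).  The overt model regresses observed PSI and OSI
on both factors with SCC~~SCB and PSI~~OSI residual covariances: 8
observed variables, 36 moments, 20 free parameters, df = 16.  The
extended models add the condition's `t0` and `v` as correlated observed
exogenous predictors of all four endogenous quantities: 10 observed
variables, 55 moments, 31 free parameters, df = 24.  Exogenous variances
and their covariance are free parameters because nothing in the model can
explain them.

Estimation minimizes the maximum-likelihood discrepancy
`F = log|Sigma(theta)| + tr(S Sigma(theta)^{-1}) - log|S| - p`
with `nlminb` from a deterministic start (loadings 1, paths and
covariances 0, residual variances at half the observed variances).  The
optimization runs on SD-standardized variables — the raw problem mixes
variances of order `1e-3` (t0) and `1e2` (questionnaire totals), which
cripples quasi-Newton steps — and the estimates are mapped back to the raw
metric exactly afterwards; the discrepancy itself is invariant to this
rescaling.  A BFGS route over the same objective is kept as an independent
cross-check and agrees with the default to ~1e-11 on `F` in the test
suite.  `chi^2 = (n-1) F` (Wishart convention; users preferring `n F` can
rescale), `RMSEA = sqrt(max(chi^2 - df, 0)/(df (n-1)))`, and CFI uses the
independence baseline whose discrepancy is `-log|R|` for the sample
correlation matrix `R`.  Standard errors come from the inverse expected
information `(n-1)/2 tr(Sigma^{-1} dSigma_i Sigma^{-1} dSigma_j)` with
numerically differentiated `dSigma`; Heywood cases (negative residual
variances) are flagged as warnings, not errors.  Indirect effects are
products of two path coefficients with delta-method standard errors
`sqrt(b^2 Var(a) + a^2 Var(b) + 2ab Cov(a,b))`; suppression is flagged
when a direct path and the indirect chain through a mediator are both
significant with opposite signs.  Estimation is complete-case throughout.

## The synthetic-data generator

The generator is the package's definition of the study conditions.  Its
latent layer draws SCC and SCB from a bivariate standard normal with
correlation −0.32.  Each diffusion parameter has a unit-variance
condition-shared participant trait — a linear combination of the latents
(default couplings: v~SCC 0.33, t0~SCB 0.20) plus unique noise — and
condition-specific deviations whose cross-condition correlations default
to 0.758 (v), 0.738 (t0); parameter values are population mean + SD ×
deviation, redrawn (up to 1000 times, then clipped) to keep
`t0 - st0/2 > 0.05` and `a > 0.2`.  Population means for `t0`
(0.347/0.343 s) and `v` (4.098/4.003) and SDs (0.039; 0.443/0.483) are the
printed condition statistics; the remaining parameters are not printed
anywhere and were fixed once at realistic values: `a = 1.0` (SD 0.15),
`st0 = 0.15` (SD 0.04), `sv = 0.8` (SD 0.25).  The threshold choice is the
one place realism had to be traded explicitly: with drift near 4, `a = 1`
puts simulated accuracy near 97–98%, matching an easy probe
discrimination, whereas larger thresholds push accuracy to a ceiling where
`v` and `a` are jointly unidentifiable from 160 trials.

Observed indicators are loading × latent + Gaussian residual with default
loadings (0.60, 0.55, 0.50, 0.40; 0.65, 0.60) and residual SDs
`sqrt(1 - loading^2)`, then linearly rescaled to realistic questionnaire
means and SDs.  PSI and OSI are built from standardized structural paths
(defaults: SCB→PSI 0.56, SCC→PSI 0, SCB→OSI 0.31, SCC→OSI −0.26, t0→PSI
−0.16) applied to the latents and the shared diffusion traits, plus
residuals correlated at 0.45 and scaled for unit variance.  Because every
layer is standardized, the generating numbers are directly the
standardized coefficients a correct analysis should recover.  Item-level
matrices (20 UCLA-R items, 6 SNS items) come from one-factor models with
loadings 0.66 and 0.68, chosen to reproduce the reported reliabilities
(α ≈ 0.94 and 0.84); items are clipped to their response scales, which
slightly attenuates item covariances, so the score table uses the
unclipped linear scores.

### What the synthetic studies do not show

The generator emulates the *statistical* structure the analysis assumes —
it cannot validate the substantive model against real behaviour.  It has
no attentional-cueing micro-mechanism (condition effects are just
different DDM populations), no response deadlines other than a simple
1.5 s censoring rule, no practice, fatigue or sequential effects, and
Gaussian measurement throughout.  Passing recovery tests therefore shows
the pipeline is correct and well-calibrated, not that the model is true of
real dot-probe data.

### An information limit worth knowing about

At 160 trials per condition with all five parameters free, the Fisher
information of the Wiener likelihood at the default population values
bounds the standard error of `v̂` below by roughly 0.5–0.7 (numerically
inverted 5×5 per-trial information; the accuracy channel saturates near
`1/(a sqrt(n p q))` and the RT-shape channel mostly informs `a/v` and
`t0`).  Since the between-participant SD of `v` is only 0.443, no
estimator can exceed a true-score correlation of about 0.65 under these
conditions, and the package's recovery suite reports the corresponding
red result honestly rather than relaxing it.  Nondecision time is in a
different regime: its posterior SD is ~0.01 s, so `t0` recovers with mean
absolute bias well under 0.02 s and high split-half reliability.

## Problem sizes used by the test suite

The suite runs synthetic panels of 12–30 participants at 40–160 trials per
condition for sampler recovery, 20 parameter sets × 10^6 trials for the
density–simulator oracle, and SEM studies of n = 300–2000; these sizes
were chosen as the smallest that make each property statistically
decidable at the stated tolerances.
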