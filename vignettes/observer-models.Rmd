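---
title: "Two resource-limited observers for rapid numerosity estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two resource-limited observers for rapid numerosity estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sebtim)
```

## The estimation problem

An observer is flashed 1–15 dots for between 40 and 640 ms (or at one of
five Weber contrasts at a fixed 200 ms) and types an integer estimate.
`sebtim` implements two observers that both minimize the expected squared
error of the estimate under a resource constraint, but locate that
constraint at opposite ends of the processing chain: in *sensing* (SEB)
or in *acting* (TIM). Because both carry exactly the parameters
`R` (rate), `B` (bound) and `g` (lapse rate) — plus `mu`, `sigma` when
the prior is fitted — any difference in fit quality reflects mechanism,
not flexibility.

## The SEB observer

Numerosity is represented on a log scale: the sensory evidence is a
Brownian path whose drift is an affine function of `log n`, accumulated
for `tau = min(t, tmax)` seconds. Averaging the path gives a Gaussian
representation `r ~ N(m(n), nu^2(t))` with

    nu(t) = 1 / G,   G = min(R * sqrt(t) / sigma_eff, B).

The `sqrt(t)` is the diffusion law: averaging independent increments for
time `tau` shrinks the noise SD as `1/sqrt(tau)`. `R` is the ratio of the
drift power bound to the instantaneous diffusion noise; only this ratio
is identifiable, so the two underlying quantities are never separate
parameters. `B` is the largest attainable precision, equivalently a
largest useful accumulation time `tmax = (B * sigma_eff / R)^2`.
`sigma_eff` is the prior's `sigma` for a log-normal prior; under the
fixed power-law prior it is set to 1 and `R` absorbs the scale, keeping
the fixed-prior observer at three parameters. The implied Gaussian
channel capacity `0.5 * log(1 + R^2 * tau)` is exposed as
`channel_capacity()` for diagnostics; the likelihood never uses it.

Decoding is Bayesian MMSE. With a log-normal prior
`log n ~ N(mu, sigma^2)` and shrinkage weight
`lambda = sigma^2 / (sigma^2 + nu^2)`, the estimate is log-normal:

    log n_hat | n ~ N(lambda*log n + (1-lambda)*mu + lambda*nu^2/2,
                      lambda^2 * nu^2)

With the improper power-law prior `p(n) ∝ n^-alpha` (its log-scale
density `exp(-(alpha-1)x)` carries the change-of-variables Jacobian;
`lambda = 1`), the mean becomes `log n - (alpha-1)*nu^2 + nu^2/2`; at
`alpha = 2` the corrections cancel and the decoder is conditionally
unbiased, `E[n_hat | n] = n`. The estimate CV, `sqrt(exp(s2) - 1)`,
does not involve `n`: scalar variability is a theorem here, not a fit.

Two response conventions are provided. The *continuous* variant
evaluates the analytic log-normal density at the integers 1..`Nmax` and
normalizes (the density-at-integers reading of the integer-range
likelihood; integrating over unit bins is a near-identical alternative we
did not adopt as default). The *discrete* variant restricts encoding and
decoding to the integers: for each representation value `r` on a
quadrature grid the integer posterior mean is computed and rounded (half
away from zero), and the rounding probabilities are accumulated under the
`N(log n, nu^2)` weights.

## The TIM observer

TIM perceives `n` noiselessly but pays for precise responding: the
response pmf minimizes `sum_k p(k) (n-k)^2` subject to
`KL(p || q) <= C(t) = min(R*t, B)` nats, where `q` is the default state
(the discretized prior). The optimum is the exponential tilt
`p(k) ∝ q(k) exp(-b (n-k)^2)`; the per-stimulus multiplier is solved so
the budget binds. Any constant factor in the loss (such as a `q(n)`
weight) is absorbed into the solved multiplier, which is exactly
equivalent under the per-stimulus constraint; the per-stimulus reading of
the budget is the one implemented. TIM's `R` and `B` are nats/second and
nats — different units from SEB's, and the two models' values are never
compared numerically.

As `t -> 0` the two observers separate qualitatively: SEB's estimate
distribution collapses (its variance falls to zero as the decode shrinks
onto the prior mean) while TIM's falls back on `q`, the maximally
variable state. This zero-time contrast, the flat-vs-inflated CV profile,
and the earlier decay of SEB's bias with viewing time form the
qualitative signature suite.

## Numerical choices

* **Multiplier solve.** `KL(p_b || q)` is strictly increasing in `b`
  (derivative `b * Var_pb[(n-k)^2]`), so the budget equation is solved by
  bracketing plus safeguarded Newton to `1e-8` nats. When the budget
  exceeds `-log q(n)` — the supremum of attainable divergence — the point
  mass at `n` is returned with `b = Inf`. For budgets below `1e-10` nats
  the small-`b` expansion `KL ≈ (b^2/2) Var_q[(n-k)^2]` sets `b`
  directly; a finite-tolerance root search cannot resolve the multiplier
  there, and this keeps the zero-time fallback onto `q` exact to ~1e-11
  rather than ~1e-4.
* **Quadrature.** The discrete-variant grid spans `log n ± 6 nu` with
  8001 points and trapezoid weights. The rounded-posterior-mean map is a
  step function of `r`, so the pmf converges linearly in the grid step;
  8001 points hold the total-variation error against a 10x finer grid
  near 3e-4. (A 2001-point grid leaves ~1.4e-3.)
* **Log-space throughout.** Priors, densities and posteriors are
  normalized via log-sum-exp so that the extreme corners of the fitting
  box (`|mu|` up to 50, `sigma` up to 100) neither overflow nor
  underflow; per-trial likelihoods are floored at `1e-300` before taking
  logs.
* **Degenerate laws.** When the estimate variance is exactly zero the
  continuous pmf is a point mass at `round(exp(mu_hat))` before the
  guessing mixture; the discrete variant likewise degenerates to the
  stimulus itself at zero noise.
* **Continuous vs discrete agreement.** The two conventions agree
  (TV < 5e-2) once `nu` is small against the log spacing `~1/n` of
  neighbouring integers; at `nu = 0.05` and `n` near 15 they still
  differ by ~0.08 because they split boundary mass differently. The
  agreement test therefore runs at `nu ≈ 0.015`.

## Fitting

Each participant is fit by maximizing the summed log-likelihood of the
guessing mixture `(1-g) p_model(response | n, t) + g q(response)` (the
mixture is applied once, in the likelihood; model pmfs are computed at
`g = 0`). Responses above the support (1..100) are removed during
cleaning, alongside the strict rules `response > 10 n` and `rt > 10 s`.
The optimizer is the package's own differential evolution
(rand/1/bin, population `10*dim`, `CR = 0.9`, `F` dithered in
\[0.5, 1\], 100 generations by default) over the box `R ∈ (0.1, 200)`,
`B ∈ (0.1, 20)`, `g ∈ (0.0001, 0.5)`, and `mu ∈ (-50, 50)`,
`sigma ∈ (0.1, 100)` for free priors. The population size, strategy and
dither range are package defaults, surfaced as arguments; only the
iteration count is treated as canonical. Fits are bit-reproducible given
data and seed. AIC is `2k - 2 loglik` with `k ∈ {3, 5}`; cohort
comparisons report per-participant AIC differences, their sum, a
percentile bootstrap CI over participants (default 10,000 resamples, a
declared package default), a two-sided paired t-test and the paired
Cohen's `d` (mean over SD of differences; undefined and reported as `NA`
for constant differences).

## The synthetic-data generator

`simulate_cohort()` reproduces the experiments' structure exactly: per
participant a full factorial of 15 numerosities x 5 evidence levels x 2
repetitions (150 trials), shuffled; durations 40/80/160/320/640 ms for
experiments 1–3, Weber contrasts 10–160% at 200 ms for experiment 4,
pooled onto effective durations (10%→40 ms ... 160%→640 ms) for
modeling. Responses are forward samples of the chosen observer with a
lapse process drawing from the prior. Generating parameters for recovery
studies are drawn uniformly from `R ∈ [5, 100]`, `B ∈ [2, 15]`,
`g ∈ [0.001, 0.1]` (and `mu ∈ [0.5, 2.5]`, `sigma ∈ [0.3, 1.2]` for free
priors) — deliberately interior to the fitting box; the ranges are a
documented convention, not estimates. A placeholder log-normal response
time (~0.9 s median) is attached purely so the cleaning rule can be
exercised; response times are not modeled. What the generator does *not*
emulate: sequential dependencies between trials, stimulus-level visual
controls (dot size/density/area are design labels only), participant
drop-out, or any adaptation of the prior within a session. Passing
recovery tests therefore shows the pipeline is self-consistent, not that
real behavior satisfies the models' independence assumptions.

## Qualitative signature defaults

The signature suite runs at fixed desk-scale parameter sets chosen once:
SEB discrete `(R = 15, B = 10, g = 0)` and TIM `(R = 5, B = 3, g = 0.05)`
with the fixed `1/n^2` prior. The SEB set carries no lapses because
scalar variability is a property of the encoder/decoder itself; the TIM
set carries a small lapse rate because TIM's low-`n` CV inflation is a
fitted-parameter signature — fitted TIM accounts lean on guessing, and
with `g = 0` the pure tilt actually shows the opposite CV trend. The
"bias decays no later for SEB" claim is scored as
`|bias_SEB| <= |bias_TIM|` at matched `(n, t)`: the power-law SEB
observer is already near-unbiased at 40 ms, so normalizing each model's
bias by its own initial value would divide rounding noise by rounding
noise.

## Problem sizes

Desk-scale study sizes used by the test-suite and the acceptance script:
Monte-Carlo checks at 1e5–1e6 draws; parameter recovery at 20–100
simulated participants (150 trials each, 100 DE generations); model
recovery at 6–12 seeded replicates of 8 participants with 40 DE
generations (the summed AIC gap between generating and competing model is
large enough that the shortened optimization does not affect the sign).
These sizes are the package's own choices for routine runs; all of them
scale up by changing the corresponding arguments.

## Known limitations

* The continuous likelihood reads "normalized over the integer range" as
  density-at-integers; unit-bin integration would differ slightly at
  large `nu`.
* Whether the fixed-prior SEB fit should keep a prior-scale divisor
  inside `G` is not decidable from the model's behavior (the scale is
  absorbed by `R`); `sigma_eff = 1` is the implemented convention.
* TIM's expected-KL (averaged over stimuli) variant is not implemented;
  only the per-stimulus budget.
* Hierarchical (shared-parameter) fitting, BIC/AICc reporting, and
  random-effects model selection are out of scope; the per-participant
  tables expose everything needed to compute them downstream.
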