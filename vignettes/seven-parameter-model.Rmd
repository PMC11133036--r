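---
title: "The seven-parameter diffusion model: density, simulation and calibrated Bayesian fitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The seven-parameter diffusion model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wiener7)
```

## The model

The diffusion model describes a two-alternative forced choice as noisy
evidence accumulation: a Wiener process with drift $v$ and unit diffusion
coefficient starts at a fraction $w$ of the distance between two absorbing
boundaries separated by $a$, and the first boundary hit (upper = response 1,
lower = response 0) determines the response.  The observed reaction time is
the first-passage time plus a non-decision time.  The *seven-parameter*
version adds inter-trial variability: on each trial the drift is drawn from
$\mathcal N(v, s_v^2)$, the starting point uniformly from
$w \pm s_w/2$, and the non-decision time uniformly from
$[t_0, t_0 + s_{t_0}]$.  These variabilities let the model produce slow
and fast errors that the four-parameter version cannot.

Throughout, `w` is the starting fraction measured **from the lower
boundary** (0.5 = unbiased), and the diffusion coefficient is fixed at 1,
which sets the scale of $a$, $v$ and $s_v$.

## Density evaluation

The boundary-specific ("defective") reaction-time density is a triple
integral over the trial-level drift, starting point and non-decision time.
The package evaluates it as follows.

* **Drift integral in closed form.**  The normal mixture over trial drift
  has an analytic solution: a multiplicative factor
  $M(t; a, v, \omega, s_v)$ such that $M \cdot p_3(t \mid a, v, \omega)$
  equals the drift-mixed density, where $p_3$ is the four-parameter
  density.  When $s_v = 0$ the exponents cancel algebraically and
  $M \equiv 1$.
* **Series kernels.**  $p_3$ reduces to the zero-drift unit-boundary
  kernel $f(t^* \mid 0, 1, w)$ at scaled time $t^* = t/a^2$, which has two
  classical series representations: a large-time sine series and a
  small-time Gaussian-image series.  Both converge everywhere; the code
  picks whichever needs fewer terms for the requested absolute tolerance.
  Truncation counts come from explicit tail bounds — a geometric-ratio
  envelope for the large-time series and a Gaussian-tail integral envelope
  for the small-time series — validated in the tests against 200-term
  brute-force sums.
* **Outer quadrature.**  The remaining two-dimensional integral over the
  uniform starting-point and non-decision-time boxes is computed with
  fixed-order Gauss–Legendre rules (default order 8 per dimension),
  accumulated in log space with a max shift so that integrands spanning
  hundreds of orders of magnitude cannot underflow.  The integrands are
  smooth on their boxes, with one exception: when the reaction time falls
  inside the non-decision-time support ($t_0 < y < t_0 + s_{t_0}$), the
  integral is clipped at $y$ and the integrand develops a sharp vanishing
  layer; the code detects this and doubles the node count in that
  dimension.  The exported density additionally refines by doubling the
  order (twice at most) until successive values differ by less than the
  tolerance.
* **Precision semantics.**  The `tol` of `precision_spec()` is an absolute
  tolerance on the density kernel, applied to both the series truncation
  and the quadrature refinement stop.  The default `1e-6` keeps cost
  bounded inside MCMC; `1e-9`–`1e-12` are used in tests and oracles.
  Truncated series can come out infinitesimally negative right at the
  support boundary; such values are clamped to zero (and counted, see
  `kernel_clamp_count()`).
* **Support handling.**  `y <= t0` returns `-Inf` rather than raising, so
  samplers reject gracefully; errors are reserved for structurally invalid
  parameters.  With $s_{t_0} > 0$ the upper integration limit is
  $\min(y, t_0 + s_{t_0})$ while the $1/s_{t_0}$ normalizer is kept, so
  the probability mass of trials whose non-decision time exceeds $y$ is
  correctly lost rather than renormalized away.
* **Boundary convention.**  The series kernel written above integrates to
  $1 - w$ over time, i.e. it describes the boundary *opposite* the
  reference point of $w$.  With `w` measured from the lower boundary the
  upper-boundary density is therefore evaluated at $(-v,\, 1-w)$ and the
  lower-boundary density at $(v,\, w)$.  This is verified against the
  simulator (choice probabilities and distributional tests at asymmetric
  starting points); the user-facing mirroring identity — the lower-boundary
  log-density at $(v, w)$ equals the upper-boundary log-density at
  $(-v, 1-w)$ — holds exactly by construction.

### Gradients

Hamiltonian Monte Carlo needs $\partial \log p / \partial \theta$.  The
package differentiates its own computation analytically: the series terms,
the drift factor $M$, and the quadrature node positions and weights
(including their dependence on $t_0$, $s_{t_0}$, $w$, $s_w$) all have
exact derivatives, which are assembled through the log-sum-exp weights.
The result is consistent with the returned log-density to series-truncation
accuracy and matches plain central finite differences to better than
$10^{-4}$ relative error on random interior points (an acceptance check).
Derivatives for parameters on a constraint boundary (e.g. $s_v = 0$) are
two-sided-undefined and flagged instead of silently returned.

## Simulator

Trials are simulated by first drawing the trial-level parameters from the
mixing distributions and then running the within-trial process with
Euler–Maruyama steps (`dt = 1e-4` s by default) augmented by an exact
Brownian-bridge boundary-crossing correction: after each interior step the
probability that the continuous path crossed either boundary *between*
the step endpoints is evaluated in closed form and a crossing is resolved
by an extra uniform draw.  This removes the leading
$O(\sqrt{dt})$ underestimation of crossings of naive Euler; crossing
times get a uniform within-step jitter, removing the half-step bias and
the step-grid ties.  The remaining bias is of order `dt` and is validated
distributionally: simulated reaction times per boundary pass
Kolmogorov–Smirnov tests at $\alpha = .01$ against the numerically
normalized density at $5\times10^4$ draws, and empirical choice
probabilities match the numeric integral of the boundary densities.

What the generator deliberately does **not** emulate: contaminant
responses, lapses, or any non-diffusion process.  Passing tests therefore
certify the internal consistency of density, simulator and sampler — not
robustness of the model on messy empirical data.

## Priors and ground truths

The simulation studies use the mildly informative priors
`a ~ N(1,1) T[0.5,3]`, `v ~ N(2,3) T[0,5]`, `w ~ N(0.5,0.1) T[0.3,0.7]`,
`t0 ~ N(0.435,0.12) T[0.2,1]`, `sv ~ N(1,3) T[0,3]`, `sw ~ Beta(1,3)`,
`st0 ~ N(0.183,0.09) T[0,0.5]`.  Two interpretation decisions are worth
making explicit:

* The scale argument of every normal prior is a **standard deviation**
  (the convention of the Bayesian software these priors are drawn from),
  not a variance.
* Independent draws of `w` and `sw` can violate the joint constraint
  $0 < w - s_w/2$, $w + s_w/2 < 1$ (e.g. `w = 0.3`, `sw = 0.7`).  The
  generator redraws the pair jointly until the constraint holds, and the
  fitted model restricts its parameterization to the same region, so
  generator and prior stay identical — a prerequisite for the calibration
  study to be meaningful.

The two-condition design draws the drift twice and negates the second
draw, so condition 1 drifts towards the upper boundary and condition 2
towards the lower one; all other parameters are shared, giving eight
estimated parameters.

## Posterior sampling

`fit_dm()` runs a No-U-Turn sampler (multinomial variant, diagonal metric
with expanding estimation windows, dual-averaging step size, maximum tree
depth 5, divergence threshold at an energy error of 1000) on an
unconstrained scale: every parameter maps to its prior truncation interval
through a scaled logit, and `sw` is parameterized as a fraction of its
feasible range $\min(1, 2w, 2(1-w))$ so the joint constraint holds at
every reachable point.  `t0`'s interval is additionally capped just below
the smallest reaction time — the likelihood is zero beyond it, so this
restriction leaves the posterior unchanged while sparing the sampler a
cliff.  All transform Jacobians are included; chains initialize from
jittered prior draws.

Convergence is judged by rank-normalized split $\hat R$ and bulk effective
sample size (checked against an independent implementation of the same
published definitions to $10^{-6}$ on fixture chains), the relative
effective sample size, and the divergence count.  The reference protocol
is: four chains; strict thresholds $N_{\mathrm{eff}} > 400$,
$N_{\mathrm{eff}}/N_{\mathrm{samp}} > 0.1$, $\hat R < 1.01$, zero
divergences; warmup escalation 150 → 1000 → 3000 with 500 then 1000
sampling iterations; and after the schedule is exhausted a soft-pass tier
accepting $\hat R < 1.05$.  All thresholds are configuration fields, which
the batch studies below deliberately rescale.

## Validation studies and the sizes used here

Two batch drivers validate the whole pipeline under the self-consistency
design (truth drawn from the same priors used in fitting):

* `recovery_study()` aggregates truth–median Pearson correlations, 50%
  and 95% highest-density-interval coverage, mean Monte-Carlo standard
  errors and bias samples.  Under self-consistency, q% HDIs must cover the
  truth q% of the time regardless of the number of trials — that identity,
  not a particular correlation value, is the sharp check.
* `sbc_study()` computes, per dataset, the tie-randomized rank of the
  truth within `L` uniformly thinned posterior draws for nine test
  quantities (the eight parameters and the joint log-likelihood of the
  data — the prior term is deliberately excluded from this data-space
  quantity), then tests rank uniformity per quantity with a $\chi^2$ test
  on `B` bins and aggregates the p-values with Fisher's combined
  probability test.  The reference protocol uses `L = 399` and `B = 100`
  bins at 2000 datasets (20 expected per bin, critical value 123.23 at
  $df = 99$); a deliberately broken fitter (prior draws shifted in `a`)
  must fail these tests, and does.

The package's own test suite and acceptance script run these studies at
reduced sizes chosen so a complete run fits in minutes on one CPU: 10–12
datasets of 100 trials, two chains with a 150 → 400 warmup schedule and
400/500 sampling iterations, thinning to `L = 79`, `B = 4` rank bins
(so each bin still expects a handful of counts), and correspondingly rescaled
diagnostic gates ($N_{\mathrm{eff}} > 80$, relative
$N_{\mathrm{eff}} > 0.05$, $\hat R < 1.02$, soft 1.05).  Tolerances in
those tests are the Monte-Carlo 3-SE bands implied by these sizes.
Coverage bands use the observed between-dataset spread of the per-dataset
coverage proportions (which respects their within-dataset correlation).
Truth–median correlations are guarded one-sidedly — no degradation below
the reference pattern beyond 3 SE on the Fisher-z scale — because at a
dozen datasets the two-sided normal band is not valid for the skewed,
bounded variability-parameter marginals (their observed correlations
fluctuate on both sides of the reference, occasionally above it).  The
smaller-information arm used for directional comparisons has 6 datasets
of 24 trials.  Datasets that still fail
diagnostics after escalation are excluded from aggregates and counted in
the reports.

## Numerical choices and degenerate inputs

* Ties in the rank statistic are randomized uniformly on
  $\{0, \dots, r_{\mathrm{equal}}\}$, matching exhaustive enumeration on
  small cases.
* `hdi()` returns the shortest window of the sorted draws containing
  $\lceil q n \rceil$ draws; width ties resolve to the lowest start, and a
  point-mass sample yields a zero-width interval.
* `thin_to_independent()` uses stride $\lfloor N/L \rfloor$ and refuses to
  thin when the effective sample size is below $L + 1$.
* Zero-trial datasets are valid (the fit reproduces the prior); datasets
  whose reaction times all sit below the smallest admissible non-decision
  time raise an error.
* Per-dataset and per-chain seeds derive deterministically from one root
  seed, so any dataset of a study can be reproduced in isolation.

## Known limitations

* The sampler is a single-threaded R implementation; the reference
  protocol (4 chains, thousands of warmup iterations, hundreds of
  datasets) is hours of compute, which is why the bundled studies are
  scaled down.  The identities they test are size-invariant.
* The first-passage sampler is exact only in the `dt -> 0` limit; at the
  default `dt = 1e-4` the residual bias is far below the resolution of
  $5\times10^4$-draw distributional tests, but applications needing exact
  tail quantiles at extreme precision should reduce `dt`.
* Only the non-hierarchical, two-condition (or single-condition /
  restricted) design is implemented; hierarchical multi-participant
  extensions are out of scope.
* The $\chi^2$ uniformity p-values use the conventional upper tail.
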