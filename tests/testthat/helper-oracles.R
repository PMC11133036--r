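# Brute-force oracles used across the test files.  These are written
# independently of the package's evaluation path: plain 200-term series
# sums, direct quadrature/Monte-Carlo integrals, and plain central finite
# differences.

# zero-drift unit-boundary kernel: 200-term large-time series
oracle_f_large <- function(tstar, w, K = 200) {
  k <- seq_len(K)
  sum(k * pi * exp(-k^2 * pi^2 * tstar / 2) * sin(k * pi * w))
}

# same kernel: 200-term symmetric small-time series
oracle_f_small <- function(tstar, w, K = 200) {
  k <- -K:K
  sum((w + 2 * k) * exp(-(w + 2 * k)^2 / (2 * tstar))) /
    sqrt(2 * pi * tstar^3)
}

# log-density of one observation by plain central differences in each
# parameter (step h = max(1e-6, 1e-6 |param|)), high-precision evaluation
oracle_grad_fd <- function(y, response, pv,
                           prec = precision_spec(tol = 1e-12,
                                                 quad_order = 16L,
                                                 refine = FALSE)) {
  f <- function(p) {
    wiener7_logdensity(y, response,
                       dm_params(a = p[1], v = p[2], w = p[3], t0 = p[4],
                                 sv = p[5], sw = p[6], st0 = p[7]), prec)
  }
  vapply(seq_len(7), function(k) {
    h <- max(1e-6, 1e-6 * abs(pv[k]))
    up <- pv; up[k] <- pv[k] + h
    dn <- pv; dn[k] <- pv[k] - h
    (f(up) - f(dn)) / (2 * h)
  }, numeric(1))
}

# time beyond which the density tail is negligible: the slowest decay mode
# of the first-passage density has rate >= pi^2 / (2 a^2) regardless of
# drift, so 6 a^2 past the non-decision support leaves mass < 1e-9
tail_horizon <- function(params) {
  params$t0 + params$st0 + 6 * params$a^2 + 1
}

# numeric integral of the density over rt for one boundary
oracle_boundary_mass <- function(params, response,
                                 prec = precision_spec(tol = 1e-7)) {
  integrate(function(y)
    exp(wiener7_logdensity(y, response, params, prec)),
    params$t0, tail_horizon(params), rel.tol = 1e-5,
    subdivisions = 400L)$value
}

# random valid parameter set drawn wide across the admissible region
random_params <- function(variabilities = TRUE) {
  w <- runif(1, 0.3, 0.7)
  dm_params(
    a = runif(1, 0.6, 2.5),
    v = runif(1, -4, 4),
    w = w,
    t0 = runif(1, 0.1, 0.6),
    sv = if (variabilities) runif(1, 0.05, 2) else 0,
    sw = if (variabilities) runif(1, 0.02, 2 * min(w, 1 - w) * 0.9) else 0,
    st0 = if (variabilities) runif(1, 0.02, 0.4) else 0
  )
}

# conditional reaction-time CDF of one boundary (normalized), for KS tests
oracle_boundary_cdf <- function(params, response,
                                prec = precision_spec(tol = 1e-9)) {
  mass <- oracle_boundary_mass(params, response, prec)
  function(q) {
    vapply(q, function(qq)
      integrate(function(y) exp(wiener7_logdensity(y, response, params, prec)),
                params$t0, qq, rel.tol = 1e-6, subdivisions = 400L)$value,
      numeric(1)) / mass
  }
}

# quick reduced fit configuration for smoke tests
tiny_config <- function(seed = 1) {
  fit_config(n_chains = 2, warmup = c(60L, 120L), sampling = c(80L, 120L),
             seed = seed, neff_min = 10, releff_min = 0.005,
             rhat_max = 1.2, rhat_soft = 1.5)
}

# fast conditional CDF for KS tests: cumulative trapezoid of the density on
# a fine grid, linearly interpolated
# log-spaced grid: dense over the sharp rise just past t0, coarse in the
# exponential tail
grid_boundary_cdf <- function(params, response, upper_t = NULL,
                              n_grid = 4000L,
                              prec = precision_spec(tol = 1e-7)) {
  if (is.null(upper_t)) upper_t <- tail_horizon(params)
  g <- params$t0 + exp(seq(log(1e-5), log(upper_t - params$t0),
                           length.out = n_grid))
  dens <- exp(wiener7_logdensity(g, response, params, prec))
  cdf <- c(0, cumsum((dens[-1] + dens[-n_grid]) / 2 * diff(g)))
  cdf <- cdf / cdf[n_grid]
  approxfun(g, cdf, yleft = 0, yright = 1)
}

# simulate full-model trials (with inter-trial variability) for one condition
simulate_condition <- function(params, n, dt = 1e-4) {
  eff <- draw_trial_effective_params(params, n)
  fp <- sample_fpt(params$a, eff$nu, eff$omega, dt = dt)
  data.frame(rt = fp$t + eff$tau0, response = fp$response)
}
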