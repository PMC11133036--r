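#' Draw trial-level effective parameters
#'
#' One trial of the seven-parameter model runs a basic diffusion process
#' with parameters drawn from the inter-trial distributions:
#' drift `nu ~ Normal(v, sv^2)`, starting point
#' `omega ~ Uniform(w - sw/2, w + sw/2)` and non-decision time
#' `tau0 ~ Uniform(t0, t0 + st0)`; each collapses to its center when the
#' corresponding variability is zero.
#'
#' @param params a [dm_params()].
#' @param n number of trials.
#' @return Data frame with columns `nu`, `omega`, `tau0`.
#' @export
draw_trial_effective_params <- function(params, n = 1) {
  if (!inherits(params, "dm_params"))
    params <- do.call(dm_params, as.list(params)[c("a", "v", "w", "t0", "sv", "sw", "st0")])
  data.frame(
    nu = if (params$sv > 0) rnorm(n, params$v, params$sv) else rep(params$v, n),
    omega = if (params$sw > 0)
      runif(n, params$w - params$sw / 2, params$w + params$sw / 2)
      else rep(params$w, n),
    tau0 = if (params$st0 > 0) runif(n, params$t0, params$t0 + params$st0)
      else rep(params$t0, n)
  )
}

#' Sample first-passage times of the basic diffusion process
#'
#' Simulates the within-trial Wiener process (diffusion coefficient 1)
#' between boundaries 0 and `a`, starting at `omega * a`, with drift `nu`,
#' and returns the first boundary hit and its time.  The scheme is
#' Euler-Maruyama with an exact Brownian-bridge boundary-crossing
#' correction at every step plus uniform within-step crossing-time jitter,
#' which removes the leading discretization bias of plain Euler; the
#' remaining bias is of order `dt` and is validated against the density
#' module by Kolmogorov-Smirnov tests.
#'
#' @param a boundary separation (scalar or length-`n`).
#' @param nu drift rate(s).
#' @param omega relative starting point(s) in (0,1).
#' @param n number of draws (when the parameters are scalars).
#' @param dt Euler step in seconds.
#' @return Data frame with columns `t` (decision time, > 0) and `response`
#'   (0 lower, 1 upper).
#' @export
sample_fpt <- function(a, nu, omega, n = max(length(a), length(nu), length(omega)),
                       dt = 1e-4) {
  if (any(a <= 0)) stop("'a' must be > 0")
  if (any(omega <= 0 | omega >= 1)) stop("'omega' must be in (0,1)")
  a <- rep_len(a, n); nu <- rep_len(nu, n); omega <- rep_len(omega, n)
  s <- .sim_fpt_cpp(a, nu, omega, dt)
  data.frame(t = s$t, response = s$response)
}

#' Simulate a two-condition trial-level dataset
#'
#' Splits `n_trials` equally across the two conditions (condition 1 uses
#' drift `v1`, condition 2 uses `v2`), draws per-trial effective
#' parameters, simulates the first-passage process, and returns reaction
#' times `rt = t + tau0`.
#'
#' @param truth a `ground_truth` (see [sample_ground_truth()]).
#' @param n_trials total trial count; must be even.
#' @param dt Euler step for the first-passage sampler.
#' @return Data frame with columns `rt`, `response`, `condition`.
#' @export
simulate_dataset <- function(truth, n_trials, dt = 1e-4) {
  if (n_trials %% 2L != 0L)
    stop("'n_trials' must be even (equal split across 2 conditions)")
  half <- n_trials / 2
  out <- vector("list", 2)
  for (cond in 1:2) {
    p <- truth_params(truth, cond)
    eff <- draw_trial_effective_params(p, half)
    fp <- sample_fpt(p$a, eff$nu, eff$omega, dt = dt)
    out[[cond]] <- data.frame(rt = fp$t + eff$tau0,
                              response = fp$response,
                              condition = cond)
  }
  validate_dataset(do.call(rbind, out))
}

# deterministic per-dataset child seed from a root seed (kept below 2^31)
child_seed <- function(root_seed, index) {
  (as.numeric(root_seed) * 48271 + index * 104729) %% 2147483629 + 1
}
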