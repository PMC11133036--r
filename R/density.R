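#' Large-time series kernel of the first-passage density
#'
#' Zero-drift, unit-boundary first-passage density kernel
#' `f(t* | 0, 1, w)` evaluated with the large-time series
#' `sum_k k pi exp(-k^2 pi^2 t*/2) sin(k pi w)`, truncated at the smallest
#' number of terms whose geometric tail envelope is below `tol`.
#'
#' @param tstar scaled time `t / a^2`, > 0.
#' @param w relative starting point in (0,1).
#' @param tol absolute truncation tolerance.
#' @return Kernel value (may be infinitesimally negative before clamping in
#'   downstream density code; returned raw here).
#' @seealso [f_small()], [choose_expansion()]
#' @export
f_large <- function(tstar, w, tol = 1e-9) {
  stopifnot(length(tstar) == 1L, length(w) == 1L)
  if (!is.finite(tstar) || tstar <= 0) stop("'tstar' must be > 0")
  if (w <= 0 || w >= 1) stop("'w' must be in (0,1)")
  .fl_cpp(tstar, w, tol)
}

#' Small-time series kernel of the first-passage density
#'
#' Same kernel as [f_large()], via the small-time series
#' `(2 pi t*^3)^(-1/2) sum_k (w + 2k) exp(-(w + 2k)^2 / (2 t*))` with
#' symmetric truncation `|k| <= K`, `K` chosen from a Gaussian-tail
#' envelope so the absolute tail is below `tol`.
#'
#' @inheritParams f_large
#' @return Kernel value.
#' @export
f_small <- function(tstar, w, tol = 1e-9) {
  stopifnot(length(tstar) == 1L, length(w) == 1L)
  if (!is.finite(tstar) || tstar <= 0) stop("'tstar' must be > 0")
  if (w <= 0 || w >= 1) stop("'w' must be in (0,1)")
  .fs_cpp(tstar, w, tol)
}

#' Choose between the small- and large-time series
#'
#' Both series converge for every `t* > 0`; the evaluation uses whichever
#' needs fewer terms to guarantee the requested absolute precision.
#'
#' @inheritParams f_large
#' @return List with `method` (`"small"` or `"large"`), `terms` (term count
#'   of the selected series), and the per-series truncation indices
#'   `K_small`, `K_large`.
#' @export
choose_expansion <- function(tstar, w = 0.5, tol = 1e-6) {
  if (!is.finite(tstar) || tstar <= 0) stop("'tstar' must be > 0")
  .choose_expansion_cpp(tstar, w, tol)
}

#' Four-parameter first-passage density (no inter-trial variability)
#'
#' The kernel-form defective density
#' `p3(t | a, v, w) = a^-2 exp(-a v w - v^2 t / 2) f(t/a^2 | 0, 1, w)`
#' with `t = y - t0`; zero for `y <= t0`.  With `w` the starting fraction
#' measured from the lower boundary and drift `v` directed towards the
#' upper one, `p3(y | a, v, w)` is the density of hitting the *lower*
#' boundary (it integrates to that choice probability, `1 - w` at
#' `v = 0`); the upper-boundary density is `p3(y | a, -v, 1-w)`.  The two
#' together integrate to 1 over `y`.
#'
#' @param y reaction time(s) in seconds (vectorized).
#' @param a,v,w,t0 model parameters, see [dm_params()].
#' @param tol kernel tolerance.
#' @param log logical; return the log-density.
#' @return Vector of (log-)density values.
#' @export
wiener4_density <- function(y, a, v, w, t0, tol = 1e-9, log = FALSE) {
  dm_params(a = a, v = v, w = w, t0 = t0)   # validation
  lp <- .logp3_cpp(y - t0, a, v, w, tol)
  if (log) lp else exp(lp)
}

#' Drift-variability integration factor
#'
#' Closed-form factor `M(t; a, v, omega, sv)` with the property that
#' `M * p3(t | a, v, omega)` equals the integral of `p3(t | a, nu, omega)`
#' over trial-level drift `nu ~ Normal(v, sv^2)`.  Equals 1 exactly when
#' `sv = 0`; as `t -> 0` it tends to `exp(sv^2 a^2 omega^2 / 2)` (the
#' kernel's drift dependence does not vanish at `t = 0`).
#'
#' @param t decision time (> 0).
#' @param a,v,sv model parameters.
#' @param omega trial-level starting point.
#' @param log logical; return `log(M)`.
#' @return Scalar factor (or its log).
#' @export
m_factor <- function(t, a, v, omega, sv, log = FALSE) {
  if (sv < 0) stop("'sv' must be >= 0")
  lm <- .logM_cpp(t, a, v, omega, sv)
  if (log) lm else exp(lm)
}

#' Log first-passage-time density of the seven-parameter diffusion model
#'
#' Evaluates the log-density of observing reaction time `y` at the given
#' boundary under the full model: trial drift is integrated out in closed
#' form (the `M` factor); the uniform starting-point and non-decision-time
#' variabilities are integrated by Gauss-Legendre quadrature on their
#' boxes, accumulated in log space.  `response = 1` is the upper boundary
#' and `response = 0` the lower one (with `w` measured from the lower
#' boundary); one boundary is evaluated from the other by the substitution
#' `(-v, 1 - w)`, so the mirroring identity
#' `logdensity(y, 0 | v, w) == logdensity(y, 1 | -v, 1-w)` is exact by
#' construction.  With `sw = 0`
#' and/or `st0 = 0` the corresponding integral collapses to a point
#' evaluation (the `1/sw`, `1/st0` normalizers cancel), and with all three
#' variabilities zero the value equals `log(wiener4_density(...))` exactly.
#'
#' Support: the density is zero (`-Inf` returned, not an error) whenever
#' `y <= t0`.  With `st0 > 0` and `t0 < y < t0 + st0` the inner
#' non-decision-time integral runs only up to `min(y, t0 + st0)` while the
#' `1/st0` normalizer is kept, so probability mass of trials whose
#' non-decision time exceeds `y` is correctly lost.
#'
#' @param y reaction time(s), seconds; vectorized together with `response`.
#' @param response 0 = lower boundary, 1 = upper boundary.
#' @param params a [dm_params()] object (or list with the seven fields).
#' @param prec a [precision_spec()].
#' @return Vector of log-density values (`-Inf` off support).
#' @examples
#' p <- dm_params(a = 1.2, v = 1.5, w = 0.4, t0 = 0.3, sv = 0.5, sw = 0.1, st0 = 0.1)
#' wiener7_logdensity(0.8, 1, p)
#' @export
wiener7_logdensity <- function(y, response, params, prec = precision_spec()) {
  if (!inherits(params, "dm_params"))
    params <- do.call(dm_params, as.list(params)[c("a", "v", "w", "t0", "sv", "sw", "st0")])
  if (length(response) == 1L) response <- rep(response, length(y))
  if (length(y) != length(response)) stop("'y' and 'response' lengths differ")
  if (any(!response %in% c(0, 1))) stop("'response' must be 0 or 1")
  if (any(!is.finite(y) | y <= 0)) stop("'y' must be positive and finite")
  .w7_lpdf_cpp(y, as.integer(response), params$a, params$v, params$w,
               params$t0, params$sv, params$sw, params$st0,
               prec$tol, prec$quad_order, prec$refine)
}

#' Total log-likelihood of a trial-level dataset
#'
#' Sums [wiener7_logdensity()] over the trials of a dataset, looking up the
#' parameter set of each trial's condition.  Returns `-Inf` as soon as any
#' trial has zero density.
#'
#' @param data data frame with columns `rt`, `response`, `condition`
#'   (see [validate_dataset()]).
#' @param params_by_condition list of [dm_params()] indexed by condition
#'   (condition labels are 1-based indices into this list).
#' @param prec a [precision_spec()].
#' @return Scalar log-likelihood (0 for an empty dataset).
#' @export
loglik_dataset <- function(data, params_by_condition, prec = precision_spec()) {
  data <- validate_dataset(data)
  if (!nrow(data)) return(0)
  if (is.null(names(params_by_condition)) &&
      inherits(params_by_condition, "dm_params"))
    params_by_condition <- list(params_by_condition)
  ncond <- length(params_by_condition)
  if (any(data$condition > ncond))
    stop("no parameter set for condition ",
         min(data$condition[data$condition > ncond]))
  pm <- t(vapply(params_by_condition, as_params_vector, numeric(7)))
  .w7_loglik_cpp(data$rt, data$response, data$condition, pm,
                 prec$tol, prec$quad_order, prec$refine)
}

#' Gradient of the log-density with respect to the seven parameters
#'
#' Partial derivatives of [wiener7_logdensity()] with respect to
#' `(a, v, w, t0, sv, sw, st0)`.  The gradient is the exact derivative of
#' the series-plus-quadrature computation itself (the series terms, the
#' drift-integration factor, the quadrature node positions and weights are
#' all differentiated analytically), so it is consistent with the returned
#' log-density to the accuracy of the series truncation and matches
#' central finite differences of the log-density.  Components for
#' parameters sitting on a constraint boundary (for example `sv = 0`) are
#' returned as `NA` and flagged, since a two-sided derivative is not
#' defined there.
#'
#' @param y reaction time (scalar).
#' @param response 0 or 1.
#' @param params a [dm_params()] object strictly inside the constraint
#'   region for every component whose derivative is requested.
#' @param prec a [precision_spec()]; the internal evaluation tightens
#'   `tol` to at most `1e-10` and uses a fixed quadrature order of at
#'   least 16.
#' @return Named numeric vector of length 7; attribute `"on_boundary"`
#'   names any components flagged as undefined.
#' @export
grad_logdensity <- function(y, response, params, prec = precision_spec()) {
  if (!inherits(params, "dm_params"))
    params <- do.call(dm_params, as.list(params)[c("a", "v", "w", "t0", "sv", "sw", "st0")])
  stopifnot(length(y) == 1L, length(response) == 1L)
  pv <- as_params_vector(params)
  r <- .w7_grad_cpp(y, as.integer(response), pv[1], pv[2], pv[3], pv[4],
                    pv[5], pv[6], pv[7], min(prec$tol, 1e-10),
                    max(prec$quad_order, 16L))
  g <- setNames(r[2:8], names(pv))
  on_bnd <- character(0)
  if (pv["sv"] == 0) on_bnd <- c(on_bnd, "sv")
  if (pv["sw"] == 0) on_bnd <- c(on_bnd, "sw")
  if (pv["st0"] == 0) on_bnd <- c(on_bnd, "st0")
  if (pv["t0"] == 0) on_bnd <- c(on_bnd, "t0")
  g[on_bnd] <- NA_real_
  attr(g, "on_boundary") <- on_bnd
  attr(g, "logdensity") <- r[1]
  g
}

#' Count of kernel evaluations clamped at zero
#'
#' The truncated series can come out infinitesimally negative right at the
#' support boundary; such values are clamped to zero before logs are
#' taken.  This counter reports how often that happened in the current
#' session (monotone, never reset).
#'
#' @return Number of clamping events so far.
#' @export
kernel_clamp_count <- function() .clamp_count_cpp()
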