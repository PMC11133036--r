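#' Prior specification for one model parameter
#'
#' Two families are supported: a normal distribution truncated to
#' `[lo, hi]` (the `N(mean, sd) T[lo, hi]` notation; the second argument
#' is a standard deviation), and a beta distribution on \[0, 1).
#'
#' @param family `"tnorm"` or `"beta"`.
#' @param mean,sd location and SD of the untruncated normal (tnorm only).
#' @param lo,hi truncation bounds (tnorm only), `lo < hi`.
#' @param shape1,shape2 beta shape parameters (beta only).
#' @return Object of class `prior_spec`.
#' @export
prior_spec <- function(family = c("tnorm", "beta"), mean = NULL, sd = NULL,
                       lo = NULL, hi = NULL, shape1 = NULL, shape2 = NULL) {
  family <- match.arg(family)
  if (family == "tnorm") {
    stopifnot(is.numeric(mean), is.numeric(sd), sd > 0,
              is.numeric(lo), is.numeric(hi), lo < hi)
    structure(list(family = "tnorm", mean = mean, sd = sd, lo = lo, hi = hi),
              class = "prior_spec")
  } else {
    stopifnot(is.numeric(shape1), shape1 > 0, is.numeric(shape2), shape2 > 0)
    structure(list(family = "beta", shape1 = shape1, shape2 = shape2,
                   lo = 0, hi = 1), class = "prior_spec")
  }
}

#' Default priors for the simulation studies
#'
#' The set of mildly informative priors used throughout: `a ~ N(1,1)
#' T[0.5,3]`, `v ~ N(2,3) T[0,5]` (drawn per condition; the second
#' condition's drift is the negative of an independent draw), `w ~
#' N(0.5,0.1) T[0.3,0.7]`, `t0 ~ N(0.435,0.12) T[0.2,1]`, `sv ~ N(1,3)
#' T[0,3]`, `sw ~ Beta(1,3)`, `st0 ~ N(0.183,0.09) T[0,0.5]`.  All normal
#' scale arguments are standard deviations.
#'
#' @return Named list of [prior_spec()] objects
#'   (`a, v, w, t0, sv, sw, st0`).
#' @export
default_priors <- function() {
  list(
    a   = prior_spec("tnorm", mean = 1,     sd = 1,    lo = 0.5, hi = 3),
    v   = prior_spec("tnorm", mean = 2,     sd = 3,    lo = 0,   hi = 5),
    w   = prior_spec("tnorm", mean = 0.5,   sd = 0.1,  lo = 0.3, hi = 0.7),
    t0  = prior_spec("tnorm", mean = 0.435, sd = 0.12, lo = 0.2, hi = 1),
    sv  = prior_spec("tnorm", mean = 1,     sd = 3,    lo = 0,   hi = 3),
    sw  = prior_spec("beta",  shape1 = 1,   shape2 = 3),
    st0 = prior_spec("tnorm", mean = 0.183, sd = 0.09, lo = 0,   hi = 0.5)
  )
}

#' Draw from a prior
#'
#' Truncated normals are sampled by inverse-CDF on the truncated uniform;
#' betas via `rbeta`.
#'
#' @param spec a [prior_spec()].
#' @param n number of draws.
#' @return Numeric vector of `n` draws.
#' @export
sample_prior <- function(spec, n = 1) {
  if (spec$family == "tnorm") {
    plo <- pnorm(spec$lo, spec$mean, spec$sd)
    phi <- pnorm(spec$hi, spec$mean, spec$sd)
    qnorm(runif(n, plo, phi), spec$mean, spec$sd)
  } else {
    rbeta(n, spec$shape1, spec$shape2)
  }
}

#' Prior log-density (truncation renormalization included)
#'
#' @param spec a [prior_spec()].
#' @param x value(s) to evaluate.
#' @return Log-density; `-Inf` outside the truncation bounds.
#' @export
dprior <- function(spec, x) {
  if (spec$family == "tnorm") {
    lz <- log(pnorm(spec$hi, spec$mean, spec$sd) -
                pnorm(spec$lo, spec$mean, spec$sd))
    out <- dnorm(x, spec$mean, spec$sd, log = TRUE) - lz
    out[x < spec$lo | x > spec$hi] <- -Inf
    out
  } else {
    dbeta(x, spec$shape1, spec$shape2, log = TRUE)
  }
}

# derivative of the prior log-density wrt x (interior points)
dprior_grad <- function(spec, x) {
  if (spec$family == "tnorm") -(x - spec$mean) / spec$sd^2
  else (spec$shape1 - 1) / x - (spec$shape2 - 1) / (1 - x)
}

#' Sample a ground truth for the two-condition design
#'
#' Draws the shared parameters and two drift rates from the priors.  The
#' drift is drawn twice; the second draw is negated, giving a positive
#' drift (towards the upper boundary) in condition 1 and a negative drift
#' in condition 2.  The starting-point pair `(w, sw)` is redrawn jointly
#' until `0 < w - sw/2` and `w + sw/2 < 1` hold, so the generator and the
#' prior used in fitting describe the same (constrained) distribution — a
#' prerequisite for simulation-based calibration.
#'
#' @param priors named list of [prior_spec()], as [default_priors()].
#' @return Object of class `ground_truth`: list with `a, v1, v2, w, t0,
#'   sv, sw, st0`.
#' @export
sample_ground_truth <- function(priors = default_priors()) {
  need <- c("a", "v", "w", "t0", "sv", "sw", "st0")
  miss <- setdiff(need, names(priors))
  if (length(miss)) stop("missing prior(s): ", paste(miss, collapse = ", "))
  repeat {
    w <- sample_prior(priors$w)
    sw <- sample_prior(priors$sw)
    if (w - sw / 2 > 0 && w + sw / 2 < 1) break
  }
  structure(list(
    a = sample_prior(priors$a),
    v1 = sample_prior(priors$v),
    v2 = -sample_prior(priors$v),
    w = w,
    t0 = sample_prior(priors$t0),
    sv = sample_prior(priors$sv),
    sw = sw,
    st0 = sample_prior(priors$st0)
  ), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Ground truth (two-condition design, 8 parameters):\n")
  print(unlist(x))
  invisible(x)
}

#' Per-condition parameter set of a ground truth
#'
#' @param truth a `ground_truth`.
#' @param condition 1 or 2.
#' @return A [dm_params()] with the condition's drift rate.
#' @export
truth_params <- function(truth, condition) {
  v <- if (condition == 1) truth$v1 else truth$v2
  dm_params(a = truth$a, v = v, w = truth$w, t0 = truth$t0,
            sv = truth$sv, sw = truth$sw, st0 = truth$st0)
}

#' Joint log prior density of a ground truth
#'
#' Sum of the per-parameter truncated log densities; the second condition's
#' drift is evaluated as the density of its (negated) parent draw.  Returns
#' `-Inf` outside any truncation bound or when the joint starting-point
#' constraint fails.  The normalizing constant of the joint `(w, sw)`
#' rejection region is omitted (constant across parameter values).
#'
#' @param truth a `ground_truth` (or list with the 8 fields).
#' @param priors named prior list.
#' @return Scalar log prior density (up to the joint-constraint constant).
#' @export
log_prior <- function(truth, priors = default_priors()) {
  if (truth$w - truth$sw / 2 <= 0 || truth$w + truth$sw / 2 >= 1) return(-Inf)
  dprior(priors$a, truth$a) + dprior(priors$v, truth$v1) +
    dprior(priors$v, -truth$v2) + dprior(priors$w, truth$w) +
    dprior(priors$t0, truth$t0) + dprior(priors$sv, truth$sv) +
    dprior(priors$sw, truth$sw) + dprior(priors$st0, truth$st0)
}
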