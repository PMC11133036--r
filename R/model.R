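# Internal model machinery: the 8-parameter two-condition posterior on an
# unconstrained scale.
#
# Parameters (natural scale): a, v1, v2, w, t0, sv, sw, st0.  Each maps to
# an unconstrained coordinate via a scaled-logit onto its prior truncation
# interval; sw is parameterized as a fraction u of its feasible range
# m(w) = min(1, 2w, 2(1-w)), so that the joint starting-point constraint
# holds for every point the sampler can reach.  t0's upper limit is
# additionally capped just below the smallest reaction time, since the
# likelihood is zero beyond it; that restriction does not change the
# posterior.  All Jacobians are included, so the target in z-space is
# proportional to prior x likelihood in natural space.

PAR_NAMES <- c("a", "v1", "v2", "w", "t0", "sv", "sw", "st0")

logistic <- function(z) 1 / (1 + exp(-z))
logit <- function(p) log(p) - log1p(-p)

sw_range <- function(w) pmin(1, 2 * w, 2 * (1 - w))
sw_range_d <- function(w) ifelse(w < 0.5, 2, ifelse(w > 0.5, -2, 0))

# build the model object: bounds, free/fixed bookkeeping, prior lookups
build_model <- function(data, priors, fixed = list(), prec = precision_spec(refine = FALSE)) {
  data <- validate_dataset(data)
  ncond <- max(data$condition, 1L)
  if (ncond > 2L) stop("at most 2 conditions are supported")
  min_rt <- if (nrow(data)) min(data$rt) else Inf

  bounds <- list(
    a   = c(priors$a$lo, priors$a$hi),
    v1  = c(priors$v$lo, priors$v$hi),
    v2  = c(-priors$v$hi, -priors$v$lo),
    w   = c(priors$w$lo, priors$w$hi),
    t0  = c(priors$t0$lo, min(priors$t0$hi, min_rt * (1 - 1e-9))),
    sv  = c(priors$sv$lo, priors$sv$hi),
    sw  = c(0, 1),                       # as fraction u of m(w)
    st0 = c(priors$st0$lo, priors$st0$hi)
  )
  if (bounds$t0[2] <= bounds$t0[1])
    stop("degenerate dataset: all reaction times are at or below the ",
         "smallest possible non-decision time")

  pars <- if (ncond == 2L) PAR_NAMES else setdiff(PAR_NAMES, "v2")
  bad <- setdiff(names(fixed), pars)
  if (length(bad)) stop("unknown fixed parameter(s): ", paste(bad, collapse = ", "))
  free <- setdiff(pars, names(fixed))
  if (!length(free)) stop("no free parameters")

  list(data = data, priors = priors, fixed = fixed, free = free,
       pars = pars, bounds = bounds, ncond = ncond, prec = prec)
}

# z (free coords) -> full named natural parameter vector
z_to_params <- function(model, z) {
  x <- numeric(length(model$pars))
  names(x) <- model$pars
  zi <- 1L
  for (nm in model$pars) {
    if (nm %in% names(model$fixed)) { x[nm] <- model$fixed[[nm]]; next }
    if (nm == "sw") { x["sw"] <- NA; zi <- zi + 1L; next }  # fill after w known
    b <- model$bounds[[nm]]
    x[nm] <- b[1] + (b[2] - b[1]) * logistic(z[zi])
    zi <- zi + 1L
  }
  if ("sw" %in% model$pars) {
    if ("sw" %in% names(model$fixed)) x["sw"] <- model$fixed$sw
    else {
      u <- logistic(z[match("sw", model$free)])
      x["sw"] <- u * sw_range(x[["w"]])
    }
  }
  x
}

# natural parameter vector -> z; inverse of z_to_params for free coords
params_to_z <- function(model, x) {
  z <- numeric(length(model$free))
  for (k in seq_along(model$free)) {
    nm <- model$free[k]
    if (nm == "sw") {
      u <- x[["sw"]] / sw_range(x[["w"]])
      z[k] <- logit(min(max(u, 1e-12), 1 - 1e-12))
    } else {
      b <- model$bounds[[nm]]
      p <- (x[[nm]] - b[1]) / (b[2] - b[1])
      z[k] <- logit(min(max(p, 1e-12), 1 - 1e-12))
    }
  }
  z
}

params_matrix <- function(model, x) {
  v2 <- if (model$ncond == 2L) x[["v2"]] else NULL
  m <- rbind(c(x[["a"]], x[["v1"]], x[["w"]], x[["t0"]],
               x[["sv"]], x[["sw"]], x[["st0"]]))
  if (!is.null(v2))
    m <- rbind(m, c(x[["a"]], v2, x[["w"]], x[["t0"]],
                    x[["sv"]], x[["sw"]], x[["st0"]]))
  m
}

# prior log density and its natural-scale gradient for the full vector
prior_terms <- function(model, x) {
  pr <- model$priors
  lp <- 0; g <- setNames(numeric(length(model$pars)), model$pars)
  add <- function(nm, spec, val, neg = FALSE) {
    xx <- if (neg) -val else val
    lp <<- lp + dprior(spec, xx)
    g[nm] <<- dprior_grad(spec, xx) * (if (neg) -1 else 1)
  }
  add("a", pr$a, x[["a"]])
  add("v1", pr$v, x[["v1"]])
  if ("v2" %in% model$pars) add("v2", pr$v, x[["v2"]], neg = TRUE)
  add("w", pr$w, x[["w"]])
  add("t0", pr$t0, x[["t0"]])
  add("sv", pr$sv, x[["sv"]])
  add("sw", pr$sw, x[["sw"]])
  add("st0", pr$st0, x[["st0"]])
  list(lp = lp, grad = g)
}

# full log posterior (z-space, Jacobians included) with gradient
log_posterior <- function(model, z, gradient = TRUE) {
  x <- z_to_params(model, z)
  pm <- params_matrix(model, x)
  d <- model$data
  prec <- model$prec
  if (gradient) {
    lk <- .w7_loglik_grad_cpp(d$rt, d$response, d$condition, pm,
                              prec$tol, prec$quad_order)
    if (!lk$ok) return(list(lp = -Inf, grad = rep(0, length(z))))
    ll <- lk$loglik
    # map per-condition 7-grads onto the 8 natural parameters
    gl <- setNames(numeric(length(model$pars)), model$pars)
    cidx <- c(a = 1, v = 2, w = 3, t0 = 4, sv = 5, sw = 6, st0 = 7)
    for (nm in c("a", "w", "t0", "sv", "sw", "st0"))
      gl[nm] <- sum(lk$grad[, cidx[nm]])
    gl["v1"] <- lk$grad[1, 2]
    if ("v2" %in% model$pars) gl["v2"] <- lk$grad[2, 2]
  } else {
    ll <- .w7_loglik_cpp(d$rt, d$response, d$condition, pm,
                         prec$tol, prec$quad_order, prec$refine)
    if (!is.finite(ll)) return(list(lp = -Inf))
    gl <- NULL
  }
  pt <- prior_terms(model, x)
  if (!is.finite(pt$lp)) return(list(lp = -Inf, grad = rep(0, length(z))))

  lp <- ll + pt$lp
  # Jacobian terms
  jac <- 0
  sig <- list()
  for (k in seq_along(model$free)) {
    nm <- model$free[k]
    s <- logistic(z[k]); sig[[nm]] <- s
    if (nm == "sw") {
      jac <- jac + log(sw_range(x[["w"]])) + log(s) + log1p(-s)
    } else {
      b <- model$bounds[[nm]]
      jac <- jac + log(b[2] - b[1]) + log(s) + log1p(-s)
    }
  }
  lp <- lp + jac
  if (!gradient) return(list(lp = lp))

  gnat <- gl + pt$grad   # d(loglik + logprior)/dx
  gz <- numeric(length(model$free))
  for (k in seq_along(model$free)) {
    nm <- model$free[k]
    s <- sig[[nm]]
    if (nm == "sw") {
      m <- sw_range(x[["w"]])
      gz[k] <- gnat[["sw"]] * m * s * (1 - s) + (1 - 2 * s)
    } else {
      b <- model$bounds[[nm]]
      dxdz <- (b[2] - b[1]) * s * (1 - s)
      gz[k] <- gnat[[nm]] * dxdz + (1 - 2 * s)
      if (nm == "w" && "sw" %in% model$free) {
        # sw = u * m(w): w also moves sw and the log m(w) Jacobian term
        u <- sig[["sw"]]
        mp <- sw_range_d(x[["w"]])
        gz[k] <- gz[k] + (gnat[["sw"]] * u * mp + mp / sw_range(x[["w"]])) * dxdz
      }
    }
  }
  list(lp = lp, grad = gz)
}

# initial z from a jittered prior draw restricted to the model's bounds
init_z <- function(model) {
  repeat {
    gt <- sample_ground_truth(model$priors)
    x <- unlist(gt)[model$pars]
    for (nm in names(model$fixed)) x[nm] <- model$fixed[[nm]]
    b <- model$bounds$t0
    if (x[["t0"]] >= b[2]) x["t0"] <- b[1] + 0.9 * (b[2] - b[1]) * runif(1)
    z <- params_to_z(model, as.list(x))
    z <- z + rnorm(length(z), 0, 0.1)
    if (is.finite(log_posterior(model, z, gradient = FALSE)$lp)) return(z)
  }
}
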