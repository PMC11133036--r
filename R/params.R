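#' Seven-parameter diffusion-model parameter set
#'
#' Bundles and validates the seven parameters of the full diffusion model:
#' boundary separation `a`, drift rate `v`, relative starting point `w`,
#' (lower bound of the) non-decision time `t0`, and the inter-trial
#' variabilities `sv` (normal SD of drift), `sw` (uniform range of starting
#' point) and `st0` (uniform range of non-decision time).  The within-trial
#' diffusion coefficient is fixed at 1, so `a`, `v` and `sv` are expressed
#' on that evidence scale.
#'
#' Validity requires `a > 0`, `w` in (0,1), `t0 >= 0`, `sv >= 0`,
#' `sw` in \[0,1) and `st0 >= 0`, plus the joint starting-point constraint
#' `0 < w - sw/2` and `w + sw/2 < 1` so that every trial-level starting
#' point stays strictly between the boundaries.
#'
#' @param a boundary separation (> 0).
#' @param v drift rate (any real).
#' @param w relative starting point, fraction of `a` in (0,1).
#' @param t0 non-decision time lower bound in seconds (>= 0).
#' @param sv inter-trial SD of drift (>= 0).
#' @param st0 inter-trial range of non-decision time in seconds (>= 0).
#' @param sw inter-trial range of starting point (in \[0,1)).
#' @return An object of class `dm_params` (named list of the seven values).
#' @examples
#' dm_params(a = 1, v = 2, w = 0.5, t0 = 0.3)
#' @export
dm_params <- function(a, v, w, t0, sv = 0, sw = 0, st0 = 0) {
  p <- list(a = a, v = v, w = w, t0 = t0, sv = sv, sw = sw, st0 = st0)
  for (nm in names(p)) {
    x <- p[[nm]]
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("parameter '", nm, "' must be a single finite numeric value")
  }
  if (a <= 0) stop("boundary separation 'a' must be > 0")
  if (w <= 0 || w >= 1) stop("relative starting point 'w' must be in (0,1)")
  if (t0 < 0) stop("non-decision time 't0' must be >= 0")
  if (sv < 0) stop("drift variability 'sv' must be >= 0")
  if (sw < 0 || sw >= 1) stop("starting-point variability 'sw' must be in [0,1)")
  if (st0 < 0) stop("non-decision variability 'st0' must be >= 0")
  if (w - sw / 2 <= 0 || w + sw / 2 >= 1)
    stop("joint constraint violated: need 0 < w - sw/2 and w + sw/2 < 1")
  structure(p, class = "dm_params")
}

#' @export
print.dm_params <- function(x, ...) {
  cat("Diffusion-model parameters (diffusion coefficient fixed at 1):\n")
  print(unlist(x))
  invisible(x)
}

as_params_vector <- function(p) {
  unlist(p[c("a", "v", "w", "t0", "sv", "sw", "st0")])
}

#' Numerical precision settings for density evaluation
#'
#' @param tol absolute tolerance on the density kernel; applied to the
#'   series truncation and to the quadrature refinement stopping rule.
#' @param quad_order Gauss-Legendre node count per outer integral dimension
#'   (starting order when refinement is on).
#' @param refine logical; if `TRUE`, the quadrature order is doubled (up to
#'   two times) until successive density values differ by less than `tol`.
#' @return An object of class `precision_spec`.
#' @export
precision_spec <- function(tol = 1e-6, quad_order = 8L, refine = TRUE) {
  if (!is.numeric(tol) || tol <= 0) stop("'tol' must be > 0")
  quad_order <- as.integer(quad_order)
  if (quad_order < 1L) stop("'quad_order' must be >= 1")
  structure(list(tol = tol, quad_order = quad_order, refine = isTRUE(refine)),
            class = "precision_spec")
}

#' Validate a trial-level dataset
#'
#' A dataset is a data frame with columns `rt` (reaction time in seconds,
#' > 0), `response` (0 = lower boundary, 1 = upper boundary) and `condition`
#' (positive integer label).
#'
#' @param data data frame to validate.
#' @return The validated data frame (invisibly unchanged), with integer
#'   `response` and `condition` columns.
#' @export
validate_dataset <- function(data) {
  need <- c("rt", "response", "condition")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("dataset is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(data)) {
    bad <- which(!is.finite(data$rt) | data$rt <= 0)
    if (length(bad)) stop("non-positive or missing rt at row ", bad[1])
    bad <- which(!(data$response %in% c(0, 1)))
    if (length(bad)) stop("response not in {0,1} at row ", bad[1])
    bad <- which(!is.finite(data$condition) | data$condition < 1 |
                   data$condition != floor(data$condition))
    if (length(bad)) stop("condition must be a positive integer; bad row ", bad[1])
    if (stats::median(data$rt) > 100)
      warning("median rt exceeds 100: reaction times must be in seconds, ",
              "not milliseconds (no automatic conversion is applied)")
  }
  data$response <- as.integer(data$response)
  data$condition <- as.integer(data$condition)
  data
}
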