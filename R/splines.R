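#' B-spline specification
#'
#' Describes a clamped B-spline basis used for the log-baseline hazard or a
#' time-dependent covariate effect: degree, strictly increasing internal
#' knots, and boundary knots.  The boundary knots are repeated `degree + 1`
#' times, so the basis has `degree + 1 + length(knots)` functions, is a
#' partition of unity, and spans constants (no separate intercept is needed
#' in the hazard model).
#'
#' @param degree spline degree, one of 1 (linear), 2 (quadratic), 3 (cubic).
#' @param knots numeric vector of internal knots (possibly empty), strictly
#'   increasing and strictly inside `boundary`.
#' @param boundary length-2 numeric: lower (>= 0) and upper boundary knot.
#' @return object of class `spline_spec`.
#' @export
#' @examples
#' spline_spec(3, knots = c(1, 5), boundary = c(0, 10))
spline_spec <- function(degree = 3, knots = numeric(0), boundary = c(0, 10)) {
  degree <- as.integer(degree)
  if (!degree %in% 1:3) stop("degree must be 1, 2 or 3")
  knots <- as.numeric(knots)
  boundary <- as.numeric(boundary)
  if (length(boundary) != 2 || boundary[1] < 0 || boundary[2] <= boundary[1])
    stop("boundary must be c(lower, upper) with 0 <= lower < upper")
  if (length(knots)) {
    if (any(diff(knots) <= 0)) stop("internal knots must be strictly increasing")
    if (min(knots) <= boundary[1] || max(knots) >= boundary[2])
      stop("internal knots must lie strictly inside the boundary")
  }
  structure(list(degree = degree, knots = knots, boundary = boundary),
            class = "spline_spec")
}

#' @export
print.spline_spec <- function(x, ...) {
  cat(sprintf("B-spline spec: degree %d, %d internal knot(s)%s, boundary [%g, %g]\n",
              x$degree, length(x$knots),
              if (length(x$knots)) paste0(" at {", paste(x$knots, collapse = ", "), "}") else "",
              x$boundary[1], x$boundary[2]))
  invisible(x)
}

# number of basis functions
nbasis <- function(spec) spec$degree + 1L + length(spec$knots)

# full clamped knot vector
full_knots <- function(spec) {
  c(rep(spec$boundary[1], spec$degree + 1), spec$knots,
    rep(spec$boundary[2], spec$degree + 1))
}

#' Evaluate a clamped B-spline basis
#'
#' Returns the basis matrix of the clamped B-spline family described by
#' `spec`, evaluated at times `t`.  Rows sum to one (partition of unity) and
#' all entries are non-negative.  Times outside the boundary raise an error:
#' the hazard model never extrapolates silently.
#'
#' @param t numeric vector of times within `spec$boundary`.
#' @param spec a [spline_spec()].
#' @return matrix with `length(t)` rows and `degree + 1 + #knots` columns.
#' @export
bspline_basis <- function(t, spec) {
  if (!inherits(spec, "spline_spec")) stop("spec must be a spline_spec")
  t <- as.numeric(t)
  if (!length(t)) return(matrix(0, 0, nbasis(spec)))
  if (any(!is.finite(t))) stop("times must be finite")
  lo <- spec$boundary[1]; hi <- spec$boundary[2]
  if (any(t < lo | t > hi))
    stop(sprintf("times outside the spline boundary [%g, %g]; refit with a wider boundary rather than extrapolating", lo, hi))
  B <- splines::splineDesign(full_knots(spec), t, ord = spec$degree + 1L)
  dimnames(B) <- NULL
  B
}

#' Knots at empirical quantiles of event times
#'
#' Computes internal knots as empirical quantiles (type-7, linear
#' interpolation of the empirical CDF) of observed event times; used e.g. to
#' place cubic-spline knots at the 33rd and 66th percentile of all times to
#' event.
#'
#' @param event_times positive event times (nonempty).
#' @param probs probabilities strictly inside (0, 1).
#' @return numeric vector of knots.
#' @export
quantile_knots <- function(event_times, probs = c(0.33, 0.66)) {
  if (!length(event_times)) stop("event_times is empty")
  if (any(probs <= 0 | probs >= 1)) stop("probs must be in (0, 1)")
  k <- unname(stats::quantile(event_times, probs = probs, type = 7))
  if (anyDuplicated(k))
    stop("quantile knots are not distinct; reduce the number of knots")
  k
}
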