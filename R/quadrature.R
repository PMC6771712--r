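#' Gauss-Legendre quadrature rule
#'
#' Nodes and weights of the K-point Gauss-Legendre rule on \eqn{[-1, 1]}.
#' The weights sum to 2 and the nodes are symmetric about 0.  Rules are used
#' throughout the package to evaluate cumulative hazards and cumulative
#' probabilities, whose integrals have no closed form under spline
#' log-hazards.
#'
#' @param K integer node count (>= 2).
#' @return object of class `gl_rule`: list with `K`, `nodes`, `weights`.
#' @export
#' @examples
#' r <- gl_rule(5)
#' sum(r$weights)  # 2
gl_rule <- function(K) {
  K <- as.integer(K)
  if (K < 2) stop("K must be at least 2")
  gl <- pracma::gaussLegendre(K, -1, 1)
  structure(list(K = K, nodes = gl$x, weights = gl$w), class = "gl_rule")
}

#' Integrate a function on a bounded interval by Gauss-Legendre quadrature
#'
#' Approximates \eqn{\int_a^b f(t)\,dt} by the transformed K-point rule
#' \eqn{(b-a)/2 \sum_k w_k f((a+b)/2 + (b-a)/2\, z_k)}.  Exact for
#' polynomials of degree up to \eqn{2K-1}.
#'
#' @param f vectorized integrand.
#' @param a,b interval limits, `a <= b`.
#' @param rule a [gl_rule()].
#' @return scalar approximation of the integral (0 when `a == b`).
#' @export
gl_integrate <- function(f, a, b, rule = gl_rule(20)) {
  if (!inherits(rule, "gl_rule")) stop("rule must be a gl_rule")
  if (a > b) stop("require a <= b")
  if (a == b) return(0)
  h <- (b - a) / 2
  sum(rule$weights * f((a + b) / 2 + h * rule$nodes)) * h
}
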