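#' Cauchy similarity law of a ratio of Gaussian linear forms
#'
#' For standard Gaussian features \eqn{x \sim N_p(0, I)} the ratio
#' \eqn{(x^\top a)/(x^\top b)} of two linear forms is Cauchy distributed with
#' location \eqn{\delta = a^\top b / \|b\|^2} and scale
#' \eqn{\gamma = \|b\|^{-2} \sqrt{\|b\|^2 \|a\|^2 - (a^\top b)^2}}.
#' This is the law of the random effect \eqn{\beta = g(\theta_T, x) /
#' f(\theta_S, x)} linking a target linear model to a source linear model:
#' \eqn{\delta = 1, \gamma = 0} means source and target are identical.
#'
#' The discriminant under the square root is nonnegative by Cauchy-Schwarz;
#' negative floating-point round-off (e.g. `a` proportional to `b`) is
#' clamped to zero so that identical directions give exactly `gamma = 0`.
#'
#' @param a,b numeric vectors of equal length; `b` must be nonzero (a zero
#'   source form means there is no link between the domains).
#' @return list of class `cauchy_law` with elements `delta` and `gamma`.
#' @examples
#' cauchy_similarity(c(1, 2), c(1, 2))   # identical: delta 1, gamma 0
#' cauchy_similarity(c(1, 0), c(0, 1))   # orthonormal: delta 0, gamma 1
#' @export
cauchy_similarity <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) != length(b)) stop("a and b must have equal length")
  nb2 <- sum(b^2)
  if (nb2 == 0)
    stop("b is the zero vector: no link between the source and target domains")
  ab <- sum(a * b)
  disc <- nb2 * sum(a^2) - ab^2
  structure(
    list(delta = ab / nb2, gamma = sqrt(max(disc, 0)) / nb2),
    class = "cauchy_law"
  )
}

#' @export
print.cauchy_law <- function(x, ...) {
  cat(sprintf("Cauchy similarity law: delta = %.6g, gamma = %.6g\n",
              x$delta, x$gamma))
  invisible(x)
}

#' Draw from a (possibly degenerate) Cauchy law
#'
#' `gamma = 0` denotes the point mass at `delta`, used in limits and tests;
#' draws are then the constant `delta`.
#'
#' @param n number of draws.
#' @param delta location; may also be a `cauchy_law`, in which case `gamma`
#'   is taken from it.
#' @param gamma nonnegative scale.
#' @return numeric vector of length `n`. Uses R's global RNG stream, so draws
#'   are reproducible under [set.seed()].
#' @export
cauchy_rng <- function(n, delta, gamma = NULL) {
  if (inherits(delta, "cauchy_law")) {
    gamma <- delta$gamma
    delta <- delta$delta
  }
  stopifnot(n >= 1, gamma >= 0)
  if (gamma == 0) rep(delta, n) else rcauchy(n, location = delta, scale = gamma)
}

#' Cauchy log-density
#'
#' @param beta evaluation point(s).
#' @param delta location; may be a `cauchy_law`.
#' @param gamma positive scale (the degenerate `gamma = 0` law has no
#'   density and raises an error).
#' @return log density \eqn{\log\{\gamma / (\pi[(\beta-\delta)^2 +
#'   \gamma^2])\}}.
#' @export
cauchy_logpdf <- function(beta, delta, gamma = NULL) {
  if (inherits(delta, "cauchy_law")) {
    gamma <- delta$gamma
    delta <- delta$delta
  }
  if (!is.numeric(gamma) || gamma <= 0)
    stop("gamma must be positive: the degenerate law has no density")
  dcauchy(beta, location = delta, scale = gamma, log = TRUE)
}
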