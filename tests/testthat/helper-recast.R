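# Shared fixtures and slow-object cache (studies are reused across test
# blocks within a session).
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache, inherits = FALSE)
}

# A recast object with an (almost) point-mass posterior, for closed-form
# predictive checks.
degenerate_fit <- function(delta = 1, gamma = 1e-300, sigma = 1,
                           family = "gaussian", ndraws = 500) {
  draws <- cbind(delta = rep(delta, ndraws), gamma = rep(gamma, ndraws))
  if (family == "gaussian") draws <- cbind(draws, sigma = rep(sigma, ndraws))
  structure(list(draws = draws, family = family, n = 0L,
                 acceptance_rate = NA_real_),
            class = "recast")
}

# Composite adaptive-quadrature oracle in the untransformed beta coordinate:
# same integral, different variable and different integrator than the
# package's kernel.
oracle_term_continuous <- function(y, f, delta, gamma, sigma) {
  m <- y / f
  a <- sigma / abs(f)
  br <- sort(unique(c(delta - 1e4 * gamma, delta + 1e4 * gamma, delta,
                      m, m - 12 * a, m + 12 * a)))
  g <- function(b) dnorm(y, b * f, sigma) * dcauchy(b, delta, gamma)
  tot <- 0
  for (i in seq_len(length(br) - 1)) {
    tot <- tot + integrate(g, br[i], br[i + 1], rel.tol = 1e-12,
                           abs.tol = 1e-320, subdivisions = 4000L,
                           stop.on.error = FALSE)$value
  }
  log(tot)
}

# Brute-force trapezoid oracle over a dense beta grid. The Gaussian factor
# confines the integrand to [y/f +- 13 sigma/|f|]; the grid is refined until
# the Cauchy spike (width gamma) spans many grid steps.
trapezoid_term_continuous <- function(y, f, delta, gamma, sigma) {
  m <- y / f
  a <- sigma / abs(f)
  lo <- m - 13 * a
  hi <- m + 13 * a
  n <- min(2e7, max(2e6, ceiling((hi - lo) / (gamma / 50))))
  b <- seq(lo, hi, length.out = n)
  v <- dnorm(y, b * f, sigma) * dcauchy(b, delta, gamma)
  log(sum((v[-1] + v[-n]) / 2) * (b[2] - b[1]))
}

trapezoid_term_binary <- function(y, f, delta, gamma, n = 2e6) {
  # endpoints included: tan saturates at +-1.6e16 and expit at 0/1
  u <- seq(-pi / 2, pi / 2, length.out = n)
  b <- delta + gamma * tan(u)
  p <- plogis(if (y == 1) f * b else -f * b)
  log(sum((p[-1] + p[-n]) / 2) * (u[2] - u[1]) / pi)
}
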