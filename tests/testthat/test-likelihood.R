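test_that("the truncation bound is the standard-normal underflow point", {
  expect_identical(integral_bound(), 39)
  expect_gt(dnorm(38), 0)           # still a positive subnormal
  expect_identical(dnorm(39), 0)    # exact underflow
  # smallest such integer
  z <- 1:39
  expect_identical(min(z[dnorm(z) == 0]), 39L)
})

test_that("a degenerate Cauchy collapses the continuous term to the normal density", {
  got <- loglik_term_continuous(y = 1, f = 2, delta = 0.5, gamma = 1e-12,
                                sigma = 1)
  expect_equal(got, dnorm(1, mean = 0.5 * 2, sd = 1, log = TRUE),
               tolerance = 1e-6)
})

test_that("the continuous term matches a brute-force trapezoid at the reference point", {
  got <- loglik_term_continuous(0.7, -1.3, delta = 1.1, gamma = 0.4,
                                sigma = 0.9)
  expect_equal(got, trapezoid_term_continuous(0.7, -1.3, 1.1, 0.4, 0.9),
               tolerance = 1e-8)
})

test_that("the continuous term agrees with an independent adaptive oracle on random points", {
  set.seed(21)
  for (i in 1:100) {
    y <- rnorm(1, 0, 3)
    f <- rnorm(1, 0, 2); if (abs(f) < 0.1) f <- 0.5
    delta <- rnorm(1, 1, 1)
    gamma <- exp(rnorm(1, -1, 1))
    sigma <- exp(rnorm(1, -0.5, 0.7))
    got <- loglik_term_continuous(y, f, delta, gamma, sigma)
    expect_equal(got, oracle_term_continuous(y, f, delta, gamma, sigma),
                 tolerance = 1e-8)
    # halving both tolerances moves the value by less than 1e-9
    tight <- loglik_term_continuous(y, f, delta, gamma, sigma,
                                    atol = 5e-11, rtol = 5e-9)
    expect_lt(abs(got - tight), 1e-9)
  }
})

test_that("the continuous term is symmetric under joint sign flip and finite in the far tail", {
  set.seed(22)
  for (i in 1:20) {
    y <- rnorm(1, 0, 5); f <- rnorm(1, 0, 2); if (abs(f) < 0.1) f <- 1
    d <- rnorm(1); g <- runif(1, 0.05, 2); s <- runif(1, 0.2, 2)
    expect_equal(loglik_term_continuous(y, f, d, g, s),
                 loglik_term_continuous(-y, -f, d, g, s), tolerance = 1e-10)
  }
  # far beyond the Gaussian truncation range the heavy Cauchy tail keeps the
  # term finite and monotonically decreasing in |y|
  ys <- c(60, 120, 240, 480, 960)
  terms <- vapply(ys, function(y)
    loglik_term_continuous(y, f = 1, delta = 0, gamma = 0.3, sigma = 0.5),
    numeric(1))
  expect_true(all(is.finite(terms)))
  expect_true(all(diff(terms) < 0))
})

test_that("the binary term has its closed-form special cases and matches a trapezoid oracle", {
  expect_equal(loglik_term_binary(1, f = 0, delta = 2, gamma = 0.7), log(0.5))
  expect_equal(loglik_term_binary(0, f = 0, delta = 2, gamma = 0.7), log(0.5))
  # delta = 0 makes the random-effect law symmetric, so labels are exchangeable
  expect_equal(loglik_term_binary(1, f = 1.4, delta = 0, gamma = 0.6),
               loglik_term_binary(0, f = 1.4, delta = 0, gamma = 0.6),
               tolerance = 1e-10)
  got <- loglik_term_binary(1, f = 0.8, delta = 1, gamma = 0.5)
  expect_equal(got, trapezoid_term_binary(1, 0.8, 1, 0.5), tolerance = 1e-8)
  set.seed(23)
  for (i in 1:25) {
    y <- rbinom(1, 1, 0.5)
    f <- rnorm(1, 0, 2); if (abs(f) < 0.05) f <- 0.3
    d <- rnorm(1, 1, 1); g <- exp(rnorm(1, -1, 1))
    t1 <- loglik_term_binary(y, f, d, g)
    expect_lte(t1, 0)
    expect_equal(t1, trapezoid_term_binary(y, f, d, g), tolerance = 1e-7)
  }
})

test_that("the binary term is bounded below by the Cauchy mass where the label is certain", {
  # for y = 1 and f > 0, expit(beta f) -> 1 on the far right Cauchy tail
  d <- 2; g <- 0.5; f <- 3
  lower <- log(1 - pcauchy(40 / f, location = d, scale = g))
  expect_gt(loglik_term_binary(1, f, d, g), lower)
})

test_that("the log posterior composes prior and per-observation terms", {
  prior <- recast_prior()
  # empty data: the prior alone, in closed form
  lp0 <- log_posterior(list(delta = 0.8, gamma = 0.6, sigma = 1.2),
                       numeric(0), numeric(0), "gaussian", prior)
  expect_equal(lp0,
               dnorm(0.8, 1, 10, log = TRUE) + dlnorm(0.6, 0, 2, log = TRUE) +
                 dlnorm(1.2, 0, 2, log = TRUE))
  # three-point compositional check
  y <- c(0.5, -1.2, 2)
  f <- c(1.1, -0.7, 2.3)
  pars <- list(delta = 0.9, gamma = 0.4, sigma = 0.8)
  terms <- mapply(loglik_term_continuous, y, f,
                  MoreArgs = list(delta = 0.9, gamma = 0.4, sigma = 0.8))
  prior_part <- log_posterior(pars, numeric(0), numeric(0), "gaussian", prior)
  expect_equal(log_posterior(pars, y, f, "gaussian", prior),
               prior_part + sum(terms), tolerance = 1e-10)
  # doubling the data doubles the likelihood part exactly
  lp1 <- log_posterior(pars, y, f, "gaussian", prior)
  lp2 <- log_posterior(pars, c(y, y), c(f, f), "gaussian", prior)
  expect_equal(lp2 - prior_part, 2 * (lp1 - prior_part), tolerance = 1e-9)
  # invalid scales are rejected softly, to serve Metropolis-Hastings
  expect_identical(log_posterior(list(delta = 1, gamma = -1, sigma = 1),
                                 y, f, "gaussian", prior), -Inf)
  expect_identical(log_posterior(list(delta = 1, gamma = 1, sigma = 0),
                                 y, f, "gaussian", prior), -Inf)
  # binary posterior drops the sigma factor
  yb <- c(1, 0, 1)
  lpb <- log_posterior(list(delta = 1, gamma = 0.5), yb, f, "binomial", prior)
  termsb <- mapply(loglik_term_binary, yb, f,
                   MoreArgs = list(delta = 1, gamma = 0.5))
  expect_equal(lpb, dnorm(1, 1, 10, log = TRUE) +
                 dlnorm(0.5, 0, 2, log = TRUE) + sum(termsb),
               tolerance = 1e-10)
})
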