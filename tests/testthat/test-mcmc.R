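test_that("starting values follow the robust-statistics rules", {
  f <- c(1, -2, 0.5, 3, -1.5)
  init <- initial_params(2 * f, f, "gaussian")
  expect_equal(init$delta, 2)
  expect_equal(init$gamma, 0.01)  # exact ratios: MAD floor kicks in
  set.seed(31)
  r <- rcauchy(501, 1.3, 0.6)
  f2 <- runif(501, 0.5, 2)
  init2 <- initial_params(r * f2, f2, "gaussian")
  expect_equal(init2$delta, median(r))
  expect_equal(init2$gamma, mad(r, constant = 1))
  expect_identical(initial_params(c(0, 1), c(1, -1), "binomial"),
                   list(delta = 1, gamma = 0.5))
  expect_error(initial_params(c(1, 2), c(0, 1), "gaussian"), "nonzero")
})

test_that("proposal-scale adaptation pushes the acceptance rate towards 0.3", {
  s <- c(0.1, 0.2)
  expect_true(all(adapt_scales(1, s) > s))
  expect_true(all(adapt_scales(0, s) < s))
  expect_equal(adapt_scales(0.3, s), s, tolerance = 1e-12)
})

test_that("the sampler is deterministic given a seed and respects the config", {
  set.seed(32)
  theta <- make_theta_source(10)
  d <- simulate_recast_data(theta, 400, "gaussian", noise_sd = 0.5)
  src <- recast_source(d$X, d$y)
  tr <- simulate_recast_data(theta, 40, "gaussian", noise_sd = 0.5)
  ctl <- recast_control(iterations = 800, burn_in = 300, thin = 2)
  fit1 <- recast(src, tr$X, tr$y, control = ctl, seed = 7)
  fit2 <- recast(src, tr$X, tr$y, control = ctl, seed = 7)
  expect_identical(fit1$draws, fit2$draws)
  expect_identical(fit1$acceptance_rate, fit2$acceptance_rate)
  fit3 <- recast(src, tr$X, tr$y, control = ctl, seed = 8)
  expect_false(identical(fit1$draws, fit3$draws))
  expect_identical(nrow(fit1$draws), (800L - 300L) %/% 2L)
  expect_true(all(fit1$draws[, "gamma"] > 0))
  expect_true(all(fit1$draws[, "sigma"] > 0))
  expect_gte(fit1$acceptance_rate, 0)
  expect_lte(fit1$acceptance_rate, 1)
})

test_that("with no data the chain samples the prior", {
  prior <- recast_prior(sd_delta = 10, sdlog_gamma = 2)
  set.seed(33)
  mh <- recast:::run_mh(numeric(0), numeric(0), "binomial", prior,
                        recast_control(iterations = 30000, burn_in = 5000,
                                       proposal_scales = c(8, 2)))
  expect_equal(mean(mh$draws[, "delta"]), 1, tolerance = 1.5)
  expect_equal(sd(mh$draws[, "delta"]), 10, tolerance = 2)
  expect_equal(median(log(mh$draws[, "gamma"])), 0, tolerance = 0.6)
})

test_that("the posterior concentrates on the similarity ratio as the target sample grows", {
  # repeated fixed feature vector: the location must approach the ratio of
  # target to source structural values and the Cauchy scale must vanish
  set.seed(34)
  p <- 8
  theta_S <- rnorm(p, 2, 0.5)
  theta_T <- theta_S + rnorm(p, 0, 0.2)
  xtilde <- rnorm(p)
  ratio <- sum(xtilde * theta_T) / sum(xtilde * theta_S)
  src <- as_recast_source(function(M) drop(M %*% theta_S), "gaussian", p)
  sigma <- 0.4
  res <- lapply(c(50, 500), function(n_T) {
    X <- matrix(rep(xtilde, each = n_T), nrow = n_T)
    y <- sum(xtilde * theta_T) + sigma * rnorm(n_T)
    fit <- recast(src, X, y, seed = 35,
                  control = recast_control(iterations = 2500, burn_in = 800))
    c(delta = mean(fit$draws[, "delta"]),
      dsd = sd(fit$draws[, "delta"]),
      gamma = mean(fit$draws[, "gamma"]))
  })
  err <- vapply(res, function(r) abs(r[["delta"]] - ratio), numeric(1))
  expect_lt(err[2], 0.05)
  expect_lt(err[2], err[1] + 0.02)
  expect_lt(res[[2]][["gamma"]], res[[1]][["gamma"]])
  expect_lt(res[[2]][["dsd"]], res[[1]][["dsd"]])
})

test_that("the chain's equilibrium matches direct normalisation of the posterior", {
  # two binary observations: cheap likelihood, 2-d (delta, gamma) posterior
  y <- c(1, 0)
  f <- c(1.5, -0.7)
  prior <- recast_prior(mean_delta = 1, sd_delta = 1.5,
                        meanlog_gamma = 0, sdlog_gamma = 0.75)
  set.seed(36)
  mh <- recast:::run_mh(y, f, "binomial", prior,
                        recast_control(iterations = 110000, burn_in = 10000,
                                       thin = 50))
  draws <- mh$draws
  # direct numerical normalisation over a fine grid in (delta, log gamma)
  dg <- seq(quantile(draws[, "delta"], 0.005),
            quantile(draws[, "delta"], 0.995), length.out = 160)
  lg <- seq(quantile(log(draws[, "gamma"]), 0.005),
            quantile(log(draws[, "gamma"]), 0.995), length.out = 160)
  dens <- outer(dg, lg, Vectorize(function(d, l)
    exp(log_posterior(list(delta = d, gamma = exp(l)), y, f, "binomial",
                      prior) + l)))
  # coarse 4 x 4 histogram comparison inside the grid window
  db <- dg[round(seq(1, 160, length.out = 5))]
  lb <- lg[round(seq(1, 160, length.out = 5))]
  inside <- draws[, "delta"] >= db[1] & draws[, "delta"] <= db[5] &
    log(draws[, "gamma"]) >= lb[1] & log(draws[, "gamma"]) <= lb[5]
  ix <- findInterval(draws[inside, "delta"], db, all.inside = TRUE)
  iy <- findInterval(log(draws[inside, "gamma"]), lb, all.inside = TRUE)
  obs <- table(factor(ix, 1:4), factor(iy, 1:4))
  gx <- findInterval(dg, db, all.inside = TRUE)
  gy <- findInterval(lg, lb, all.inside = TRUE)
  expc <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4)
    expc[i, j] <- sum(dens[gx == i, gy == j])
  expc <- expc / sum(expc) * sum(obs)
  chi2 <- sum((obs - expc)^2 / expc)
  pval <- pchisq(chi2, df = 15, lower.tail = FALSE)
  expect_gt(pval, 0.01)
})
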