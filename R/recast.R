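#' Calibrate a frozen source model to a target sample
#'
#' Fits the transfer-calibration model: each target response is linked to the
#' frozen source structural value \eqn{f_i = f(\hat\theta_S, x_i)} through a
#' per-observation Cauchy random effect \eqn{\beta_i \sim
#' \mathrm{Cauchy}(\delta, \gamma)},
#' \deqn{Y_i = \beta_i f_i + \sigma U_i \quad (U_i \sim N(0,1))}
#' for a continuous response, or
#' \deqn{Y_i \sim \mathrm{Bernoulli}\{\mathrm{expit}(\beta_i f_i)\}}
#' for a binary one. \eqn{\delta \approx 1, \gamma \approx 0} means the
#' source model already describes the target population; \eqn{\gamma}
#' quantifies source-target dissimilarity. The posterior of
#' \eqn{(\delta, \gamma[, \sigma])}, with the random effects marginalised out
#' by quadrature, is sampled by random-walk Metropolis-Hastings.
#'
#' Only the source model's structural function is used: the source data
#' themselves are never required.
#'
#' @param source a [recast_source()] / [as_recast_source()] object.
#' @param X target feature matrix, `n_T x p`.
#' @param y target response vector (numeric, or 0/1 for a binary source).
#' @param prior a [recast_prior()].
#' @param control a [recast_control()].
#' @param seed optional integer seed for the sampler.
#' @return An object of class `recast`: a list with the posterior `draws`
#'   matrix (columns `delta`, `gamma` and, for a continuous response,
#'   `sigma`), `acceptance_rate`, the `source` model, cached structural
#'   values `f`, the data, and the settings used. Methods:
#'   [predict.recast()], `print`, `summary`, `coef`, `plot`,
#'   [simulate.recast()], `residuals`.
#' @examples
#' set.seed(42)
#' Xs <- cbind(1, matrix(rnorm(400), 200, 2))
#' ys <- drop(Xs %*% c(1, 2, -1)) + rnorm(200, sd = 0.5)
#' src <- recast_source(Xs, ys)
#' Xt <- cbind(1, matrix(rnorm(80), 40, 2))
#' yt <- drop(Xt %*% c(1.1, 1.9, -1.2)) + rnorm(40, sd = 0.5)
#' fit <- recast(src, Xt, yt, seed = 1,
#'               control = recast_control(iterations = 1500, burn_in = 500))
#' summary(fit)
#' @export
recast <- function(source, X, y, prior = recast_prior(),
                   control = recast_control(), seed = NULL) {
  stopifnot(inherits(source, "recast_source"),
            inherits(prior, "recast_prior"),
            inherits(control, "recast_control"))
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  if (!length(y)) stop("target sample is empty")
  family <- source$family
  f <- structural_values(source, X)
  if (family == "gaussian" && any(f == 0))
    stop("structural value f(theta_S, x) is zero for observation(s) ",
         paste(which(f == 0), collapse = ", "),
         "; the calibration ratio is undefined there")
  if (family == "binomial" && !all(y %in% c(0, 1)))
    stop("binary source model requires a 0/1 response")
  if (!is.null(seed)) set.seed(seed)
  mh <- run_mh(y, f, family, prior, control)
  structure(
    list(draws = mh$draws, acceptance_rate = mh$acceptance_rate,
         family = family, source = source, f = f, y = y,
         prior = prior, control = control, init = mh$init,
         proposal_scales = mh$proposal_scales, seed = seed,
         n = length(y)),
    class = "recast"
  )
}

#' @export
print.recast <- function(x, ...) {
  cat("RECaST calibration fit (", x$family, " response)\n", sep = "")
  cat("  target observations:", x$n, "\n")
  cat("  posterior draws:", nrow(x$draws),
      sprintf(" (acceptance rate %.2f)\n", x$acceptance_rate))
  cat("  posterior means:\n")
  print(round(colMeans(x$draws), 4))
  invisible(x)
}

#' @export
summary.recast <- function(object, probs = c(0.025, 0.25, 0.5, 0.75, 0.975),
                           ...) {
  qs <- t(apply(object$draws, 2, quantile, probs = probs))
  out <- cbind(mean = colMeans(object$draws),
               sd = apply(object$draws, 2, sd), qs)
  structure(list(table = out, n = object$n, family = object$family,
                 acceptance_rate = object$acceptance_rate,
                 draws = nrow(object$draws)),
            class = "summary.recast")
}

#' @export
print.summary.recast <- function(x, ...) {
  cat("RECaST calibration fit (", x$family, " response), n_T = ", x$n,
      "\n", sep = "")
  cat(x$draws, "posterior draws, acceptance rate",
      sprintf("%.2f", x$acceptance_rate), "\n\n")
  print(round(x$table, 4))
  cat("\ndelta near 1 and gamma near 0 indicate a target population",
      "\nwell described by the frozen source model.\n")
  invisible(x)
}

#' @export
coef.recast <- function(object, ...) colMeans(object$draws)

#' @export
plot.recast <- function(x, ...) {
  k <- ncol(x$draws)
  op <- par(mfrow = c(k, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  for (j in seq_len(k)) {
    nm <- colnames(x$draws)[j]
    plot(x$draws[, j], type = "l", xlab = "draw", ylab = nm,
         main = paste("trace:", nm))
    hist(x$draws[, j], breaks = 50, freq = FALSE, xlab = nm,
         main = paste("posterior:", nm))
  }
  invisible(x)
}

#' @export
residuals.recast <- function(object, ...) {
  delta_hat <- median(object$draws[, "delta"])
  if (object$family == "gaussian") {
    object$y - delta_hat * object$f
  } else {
    object$y - plogis(delta_hat * object$f)
  }
}

#' Posterior-predictive replicates of the training responses
#'
#' Draws `nsim` full replicates of the target training response vector from
#' the fitted posterior predictive: for each replicate one posterior draw
#' \eqn{(\delta, \gamma[, \sigma])} is taken, then a fresh random effect
#' \eqn{\beta_i} per observation, then the response. Useful for posterior
#' predictive checks.
#'
#' @param object a fitted [recast()] model.
#' @param nsim number of replicated response vectors.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return a data.frame with `nsim` columns, each a replicate of `object$y`.
#' @export
simulate.recast <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- object$n
  idx <- sample.int(nrow(object$draws), nsim, replace = TRUE)
  sims <- vapply(idx, function(i) {
    d <- object$draws[i, ]
    beta <- cauchy_rng(n, d[["delta"]], d[["gamma"]])
    if (object$family == "gaussian") {
      beta * object$f + d[["sigma"]] * rnorm(n)
    } else {
      as.numeric(runif(n) < plogis(beta * object$f))
    }
  }, numeric(n))
  as.data.frame(sims, col.names = paste0("sim_", seq_len(nsim)))
}
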