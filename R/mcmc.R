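#' Metropolis-Hastings sampler settings
#'
#' @param iterations total chain length (default 10000).
#' @param burn_in iterations discarded from the front (default 2000);
#'   proposal-scale adaptation happens only here, so the retained chain is a
#'   valid time-homogeneous Metropolis-Hastings chain.
#' @param thin keep every `thin`-th retained draw.
#' @param proposal_scales positive numeric vector of random-walk standard
#'   deviations on the transformed coordinates `(delta, log gamma[, log
#'   sigma])`; recycled to the number of coordinates. Default 0.1 each.
#' @param adapt adapt a global factor on the proposal scales towards an
#'   acceptance rate of 0.3 during burn-in (Robbins-Monro on the log scale).
#' @param atol,rtol quadrature tolerances passed to the likelihood.
#' @return object of class `recast_control`.
#' @export
recast_control <- function(iterations = 10000L, burn_in = 2000L, thin = 1L,
                           proposal_scales = 0.1, adapt = TRUE,
                           atol = 1e-10, rtol = 1e-8) {
  iterations <- as.integer(iterations)
  burn_in <- as.integer(burn_in)
  thin <- as.integer(thin)
  stopifnot(iterations >= 1, burn_in >= 0, burn_in < iterations, thin >= 1,
            all(proposal_scales > 0))
  structure(
    list(iterations = iterations, burn_in = burn_in, thin = thin,
         proposal_scales = proposal_scales, adapt = isTRUE(adapt),
         atol = atol, rtol = rtol),
    class = "recast_control"
  )
}

#' Robust starting values for the calibration parameters
#'
#' Cauchy-parameter posteriors are heavy tailed, so the chain is started from
#' robust data statistics rather than a prior draw. Continuous response: the
#' location starts at the median of the per-observation ratios `y/f`, the
#' scale at their (unscaled) median absolute deviation floored at 0.01, and
#' the noise scale at the standard deviation of the residuals `y - delta0 f`
#' floored at 0.01. Binary response: fixed at `delta = 1`, `gamma = 0.5`.
#'
#' @param y response vector.
#' @param f structural values.
#' @param family `"gaussian"` or `"binomial"`.
#' @return list with `delta`, `gamma` and, for gaussian, `sigma`.
#' @export
initial_params <- function(y, f, family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  if (family == "binomial") return(list(delta = 1, gamma = 0.5))
  if (!length(y)) return(list(delta = 1, gamma = 0.5, sigma = 1))
  if (any(f == 0)) stop("continuous response requires nonzero structural values")
  r <- y / f
  delta0 <- median(r)
  gamma0 <- max(mad(r, constant = 1), 0.01)
  sigma0 <- max(sd(y - delta0 * f), 0.01, na.rm = TRUE)
  if (!is.finite(sigma0)) sigma0 <- 1
  list(delta = delta0, gamma = gamma0, sigma = sigma0)
}

#' Multiplicative proposal-scale update
#'
#' Drives the acceptance rate towards the 0.3 centre of the healthy
#' random-walk range (roughly 0.15-0.5): scales increase when acceptance is
#' above target and decrease when below, and are unchanged exactly at 0.3.
#'
#' @param acceptance observed acceptance fraction in the last window.
#' @param scales current positive scales.
#' @param step Robbins-Monro step size.
#' @return updated scales.
#' @export
adapt_scales <- function(acceptance, scales, step = 1) {
  stopifnot(acceptance >= 0, acceptance <= 1, all(scales > 0))
  scales * exp(step * (acceptance - 0.3))
}

# Random-walk MH on (delta, log gamma[, log sigma]).  The log-target in the
# transformed coordinates carries the Jacobian log gamma (+ log sigma), which
# keeps the positivity constraints structural rather than rejection-based.
run_mh <- function(y, f, family, prior, control, init = NULL) {
  gaussian <- family == "gaussian"
  k <- if (gaussian) 3L else 2L
  if (is.null(init)) init <- initial_params(y, f, family)
  theta <- c(init$delta, log(init$gamma), if (gaussian) log(init$sigma))

  lp_trans <- function(th) {
    pars <- list(delta = th[1], gamma = exp(th[2]),
                 sigma = if (gaussian) exp(th[3]) else NULL)
    log_posterior(pars, y, f, family, prior,
                  atol = control$atol, rtol = control$rtol) +
      sum(th[-1])  # Jacobian of the log transforms
  }

  lp <- lp_trans(theta)
  if (!is.finite(lp))
    stop("log posterior is not finite at the initial parameters")

  scales <- rep_len(control$proposal_scales, k)
  n_iter <- control$iterations
  burn <- control$burn_in
  keep_n <- (n_iter - burn) %/% control$thin
  draws <- matrix(NA_real_, keep_n, k)
  accepted_total <- 0L
  kept <- 0L
  window <- 50L
  acc_window <- 0L
  consec_reject <- 0L
  warned <- FALSE

  for (it in seq_len(n_iter)) {
    prop <- theta + rnorm(k) * scales
    lp_prop <- lp_trans(prop)
    if (is.finite(lp_prop) && log(runif(1)) < lp_prop - lp) {
      theta <- prop
      lp <- lp_prop
      acc_window <- acc_window + 1L
      consec_reject <- 0L
      if (it > burn) accepted_total <- accepted_total + 1L
    } else {
      consec_reject <- consec_reject + 1L
      if (!control$adapt && consec_reject >= 1000L && !warned) {
        warning("1000 consecutive rejected proposals; ",
                "consider smaller proposal_scales")
        warned <- TRUE
      }
    }
    if (control$adapt && it <= burn && it %% window == 0L) {
      step <- min(1, 5 / sqrt(it / window))
      scales <- adapt_scales(acc_window / window, scales, step = step)
      acc_window <- 0L
    }
    if (it == burn) acc_window <- 0L
    if (it > burn && (it - burn) %% control$thin == 0L) {
      kept <- kept + 1L
      draws[kept, ] <- theta
    }
  }

  draws <- draws[seq_len(kept), , drop = FALSE]
  out <- cbind(delta = draws[, 1], gamma = exp(draws[, 2]))
  if (gaussian) out <- cbind(out, sigma = exp(draws[, 3]))
  list(draws = out,
       acceptance_rate = accepted_total / (n_iter - burn),
       proposal_scales = scales,
       init = init)
}
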