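#' Draw the fixed source coefficient vector for the synthetic study
#'
#' The source coefficients are built as \eqn{\theta_S = (-a, b)} with the
#' components of \eqn{a, b \in R^{p/2}} drawn independently from
#' Uniform(0.75, 5): the first half of the vector is negative, the second
#' positive, and every magnitude lies in \[0.75, 5\]. In a study this vector
#' is drawn once and then held fixed across replicates.
#'
#' @param p even feature dimension (default 50, counting the intercept
#'   column whose coefficient is the first component).
#' @return numeric vector of length `p`. Uses the global RNG stream.
#' @export
make_theta_source <- function(p = 50) {
  p <- as.integer(p)
  if (p < 2 || p %% 2 != 0)
    stop("the study design requires an even feature dimension p >= 2; ",
         "supply a custom coefficient vector for other shapes")
  c(-runif(p / 2, 0.75, 5), runif(p / 2, 0.75, 5))
}

#' Perturb the source coefficients into target coefficients
#'
#' \eqn{\theta_T = \theta_S + \epsilon}, \eqn{\epsilon \sim N_p(0,
#' \sigma_{TL}^2 I)}. The variance \eqn{\sigma_{TL}^2} is the study's
#' source-target dissimilarity knob; 0 returns `theta_S` unchanged
#' (identical populations).
#'
#' @param theta_S source coefficient vector.
#' @param sigma_TL2 nonnegative perturbation variance.
#' @return numeric vector of the same length.
#' @export
make_theta_target <- function(theta_S, sigma_TL2) {
  stopifnot(is.numeric(sigma_TL2), length(sigma_TL2) == 1, sigma_TL2 >= 0)
  if (sigma_TL2 == 0) return(theta_S)
  theta_S + rnorm(length(theta_S), sd = sqrt(sigma_TL2))
}

#' Generate a synthetic source or target data set
#'
#' Features are standard Gaussian, \eqn{N_{p-1}(0, I)}, with a leading
#' intercept column of ones (so the total dimension matches
#' `length(theta)`); with `intercept = FALSE` all `p` columns are Gaussian.
#' The response follows the forward model: continuous
#' \eqn{y = x^\top\theta + \mathrm{sd}\cdot U}, \eqn{U \sim N(0,1)}; binary
#' \eqn{y = 1\{U < \mathrm{expit}(x^\top\theta)\}}, \eqn{U \sim
#' \mathrm{Uniform}(0,1)}.
#'
#' @param theta coefficient vector (length `p`).
#' @param n number of observations.
#' @param family `"gaussian"` or `"binomial"`.
#' @param noise_sd continuous-response noise standard deviation. The default
#'   0.5 reproduces the residual scale of the reference synthetic study (see
#'   the methods vignette).
#' @param intercept prepend a ones column (default) or draw all coordinates
#'   Gaussian.
#' @return list with elements `X` (`n x p` matrix) and `y`.
#' @export
simulate_recast_data <- function(theta, n, family = c("gaussian", "binomial"),
                                 noise_sd = 0.5, intercept = TRUE) {
  family <- match.arg(family)
  stopifnot(n >= 1, noise_sd >= 0)
  p <- length(theta)
  X <- if (intercept) {
    cbind(1, matrix(rnorm(n * (p - 1)), n, p - 1))
  } else {
    matrix(rnorm(n * p), n, p)
  }
  eta <- drop(X %*% theta)
  y <- if (family == "gaussian") {
    eta + noise_sd * rnorm(n)
  } else {
    as.numeric(runif(n) < plogis(eta))
  }
  list(X = X, y = y)
}

# Minimum-norm least squares for the target-only baseline; with n < p the
# ordinary solution does not exist and the generalized inverse is used.
min_norm_ols <- function(X, y) {
  sv <- svd(X)
  keep <- sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1]
  drop(sv$v[, keep, drop = FALSE] %*%
         ((crossprod(sv$u[, keep, drop = FALSE], y)) / sv$d[keep]))
}

#' Replicated synthetic transfer-learning study
#'
#' Runs the full pipeline `n_replicates` times for one design cell: draw
#' fresh source data from fixed \eqn{\theta_S} and fit the source model;
#' draw fresh target coefficients \eqn{\theta_T = \theta_S + \epsilon};
#' draw target training (`n_T`) and test (`n_test`) sets; calibrate with
#' [recast()]; and score prediction sets and point predictions on the test
#' set. Continuous cells report empirical interval coverage, RECaST RMSE and
#' a target-only least-squares baseline RMSE; binary cells report label-set
#' coverage and AUC of the predictive success probabilities.
#'
#' The master `seed` fixes \eqn{\theta_S} and spawns one sub-seed per
#' replicate, so studies replay exactly and per-replicate streams are
#' independent of the number of replicates consumed.
#'
#' @param family `"gaussian"` or `"binomial"`.
#' @param n_T target training-sample size.
#' @param sigma_TL2 source-target dissimilarity variance.
#' @param n_replicates number of independent source/target replicates.
#' @param n_S,p,n_test,noise_sd design constants (defaults: 1000, 50, 250,
#'   0.5).
#' @param alpha miscoverage level for the scored prediction sets.
#' @param prior,control passed to [recast()]; the default control shortens
#'   the chain to 4000 iterations / 1500 burn-in, adequate for this
#'   3-parameter posterior (see the methods vignette).
#' @param npost,nbeta,ny predictive sample sizes.
#' @param seed master seed (required, for exact replay).
#' @param ridge passed to the logistic source fit.
#' @return data.frame of class `recast_study` with one row per replicate:
#'   `replicate`, `seed`, `coverage`, and `rmse`/`rmse_baseline`
#'   (continuous) or `auc`/`set_size` (binary), plus `acceptance_rate`,
#'   `delta_mean`, `gamma_mean`. Failed replicates are recorded as `NA` rows
#'   with a warning naming the replicate, never dropped silently.
#'   `theta_S` and the design are attached as attributes.
#' @export
recast_study <- function(family = c("gaussian", "binomial"), n_T, sigma_TL2,
                         n_replicates = 30, n_S = 1000, p = 50, n_test = 250,
                         noise_sd = 0.5, alpha = 0.05,
                         prior = recast_prior(),
                         control = recast_control(iterations = 4000,
                                                  burn_in = 1500),
                         npost = 1000, nbeta = 10, ny = 10,
                         seed, ridge = TRUE) {
  family <- match.arg(family)
  stopifnot(!missing(seed))
  set.seed(seed)
  theta_S <- make_theta_source(p)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)

  gaussian <- family == "gaussian"
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    rows[[r]] <- tryCatch(
      study_replicate(family, theta_S, n_T, sigma_TL2, n_S, n_test,
                      noise_sd, alpha, prior, control, npost, nbeta, ny,
                      rep_seeds[r], ridge),
      error = function(e) {
        warning("replicate ", r, " failed and was skipped: ",
                conditionMessage(e))
        if (gaussian) {
          list(coverage = NA_real_, rmse = NA_real_,
               rmse_baseline = NA_real_, acceptance_rate = NA_real_,
               delta_mean = NA_real_, gamma_mean = NA_real_)
        } else {
          list(coverage = NA_real_, auc = NA_real_, set_size = NA_real_,
               acceptance_rate = NA_real_, delta_mean = NA_real_,
               gamma_mean = NA_real_)
        }
      })
  }
  out <- data.frame(replicate = seq_len(n_replicates), seed = rep_seeds,
                    do.call(rbind, lapply(rows, as.data.frame)))
  attr(out, "design") <- list(family = family, n_T = n_T,
                              sigma_TL2 = sigma_TL2, n_S = n_S, p = p,
                              n_test = n_test, noise_sd = noise_sd,
                              alpha = alpha, seed = seed)
  attr(out, "theta_S") <- theta_S
  class(out) <- c("recast_study", "data.frame")
  out
}

study_replicate <- function(family, theta_S, n_T, sigma_TL2, n_S, n_test,
                            noise_sd, alpha, prior, control, npost, nbeta,
                            ny, rep_seed, ridge) {
  set.seed(rep_seed)
  src_data <- simulate_recast_data(theta_S, n_S, family, noise_sd)
  source <- recast_source(src_data$X, src_data$y, family = family,
                          ridge = ridge)
  theta_T <- make_theta_target(theta_S, sigma_TL2)
  train <- simulate_recast_data(theta_T, n_T, family, noise_sd)
  test <- simulate_recast_data(theta_T, n_test, family, noise_sd)
  fit <- recast(source, train$X, train$y, prior = prior, control = control)

  base <- list(acceptance_rate = fit$acceptance_rate,
               delta_mean = mean(fit$draws[, "delta"]),
               gamma_mean = mean(fit$draws[, "gamma"]))
  if (family == "gaussian") {
    pr <- predict(fit, test$X, type = "interval", alpha = alpha,
                  npost = npost, nbeta = nbeta, ny = ny)
    theta_base <- min_norm_ols(train$X, train$y)
    pred_base <- drop(test$X %*% theta_base)
    c(list(coverage = empirical_coverage(pr[, c("lower", "upper")], test$y),
           rmse = rmse(pr$point, test$y),
           rmse_baseline = rmse(pred_base, test$y)),
      base)
  } else {
    p_tilde <- predict(fit, test$X, type = "prob", npost = npost,
                       nbeta = nbeta)
    sets <- binary_prediction_set(p_tilde, alpha)
    c(list(coverage = empirical_coverage(sets, test$y),
           auc = auc(p_tilde, test$y),
           set_size = mean(rowSums(sets))),
      base)
  }
}

#' @export
print.recast_study <- function(x, ...) {
  d <- attr(x, "design")
  if (is.null(d)) return(NextMethod())  # subset lost the design metadata
  cat(sprintf(
    "Synthetic transfer study: %s response, n_T = %d, sigma_TL2 = %g\n",
    d$family, d$n_T, d$sigma_TL2))
  cat(sprintf("  %d replicates (n_S = %d, p = %d, n_test = %d)\n",
              nrow(x), d$n_S, d$p, d$n_test))
  fmt <- function(v) sprintf("%.3g (%.2g)", mean(v, na.rm = TRUE),
                             sd(v, na.rm = TRUE))
  cat("  coverage at", 1 - d$alpha, "nominal:", fmt(x$coverage), "\n")
  if (!is.null(x$rmse)) {
    cat("  RMSE:", fmt(x$rmse), " [target-only LS baseline:",
        fmt(x$rmse_baseline), "]\n")
  }
  if (!is.null(x$auc)) cat("  AUC:", fmt(x$auc), "\n")
  if (anyNA(x$coverage))
    cat("  note:", sum(is.na(x$coverage)), "replicate(s) failed\n")
  invisible(x)
}
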