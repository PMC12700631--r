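#' Fit and freeze a reference source model
#'
#' Fits the source prediction model on source-domain data and freezes its
#' structural component \eqn{f(\hat\theta_S, x)} for use in transfer
#' calibration. Two reference families are provided: ordinary least squares
#' for a continuous response and logistic regression (IRLS maximum
#' likelihood) for a binary response. In both cases the frozen structural
#' value is the *linear predictor* \eqn{x^\top \hat\theta_S}; for the binary
#' family the inverse-logit is applied downstream, inside the random-effect
#' composition \eqn{\mathrm{expit}(\beta\, f)}.
#'
#' The design matrix is used exactly as supplied: no intercept is added
#' implicitly. Include a constant column if an intercept is wanted.
#'
#' @param X numeric matrix of source features, `n_S x p`.
#' @param y numeric response vector of length `n_S`; for
#'   `family = "binomial"` it must contain only 0 and 1, with both present.
#' @param family `"gaussian"` (continuous response, OLS) or `"binomial"`
#'   (binary response, logistic MLE).
#' @param ridge logical; for the binomial family only, fall back to a weakly
#'   penalised fit (L2 strength `1e-6`) when the data are separable and the
#'   unpenalised MLE diverges. The default `FALSE` raises an error instead.
#' @return An object of class `recast_source`: a list with elements `theta`
#'   (estimated coefficients), `family`, and `p` (feature dimension).
#' @examples
#' set.seed(1)
#' X <- cbind(1, matrix(rnorm(200), 100, 2))
#' y <- drop(X %*% c(0.5, 2, -1)) + rnorm(100, sd = 0.3)
#' src <- recast_source(X, y, family = "gaussian")
#' coef(src)
#' @seealso [as_recast_source()] to wrap an arbitrary frozen prediction
#'   function, [recast()] for the target-domain calibration.
#' @export
recast_source <- function(X, y, family = c("gaussian", "binomial"),
                          ridge = FALSE) {
  family <- match.arg(family)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  if (nrow(X) < ncol(X))
    stop("need at least as many source observations as features (n_S >= p)")
  if (anyNA(X) || anyNA(y)) stop("X and y must not contain missing values")
  theta <- switch(family,
    gaussian = fit_ols(X, y),
    binomial = fit_logistic(X, y, ridge = ridge)
  )
  structure(
    list(theta = unname(theta), family = family, p = ncol(X)),
    class = "recast_source"
  )
}

fit_ols <- function(X, y) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- setdiff(seq_len(ncol(X)), qx$pivot[seq_len(qx$rank)])
    stop("design matrix is rank deficient (column(s) ",
         paste(bad, collapse = ", "),
         " linearly dependent on the others); refusing a pseudo-inverse fit")
  }
  drop(qr.coef(qx, y))
}

fit_logistic <- function(X, y, ridge = FALSE) {
  if (!all(y %in% c(0, 1))) stop("binomial response must be coded 0/1")
  if (length(unique(y)) < 2L)
    stop("binary response is constant: both classes must be present")
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("design matrix is rank deficient; logistic fit is not identified")
  fit <- suppressWarnings(glm.fit(X, y, family = binomial()))
  # saturated fitted probabilities are expected under a strong signal; the
  # MLE fails to exist only when a hyperplane classifies every point
  # correctly (complete/quasi-complete separation)
  eta <- drop(X %*% fit$coefficients)
  separated <- !fit$converged || all((2 * y - 1) * eta >= 0)
  if (!separated) return(fit$coefficients)
  if (!ridge)
    stop("complete or quasi-complete separation detected: the logistic MLE ",
         "does not exist; refit with ridge = TRUE for a weakly penalised fit")
  ridge_logistic(X, y, lambda = 1e-6)
}

# Newton iterations on the L2-penalised logistic log-likelihood; the penalty
# only needs to be large enough to make the Hessian invertible under
# separation.
ridge_logistic <- function(X, y, lambda = 1e-6, maxit = 100L, tol = 1e-10) {
  p <- ncol(X)
  beta <- numeric(p)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    grad <- drop(crossprod(X, y - mu)) - lambda * beta
    H <- crossprod(X * w, X) + diag(lambda, p)
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta
}

#' Wrap an arbitrary frozen prediction function as a source model
#'
#' The transfer calibration only needs the source model's structural
#' component evaluated at target feature vectors; any deterministic scalar
#' function of a length-`p` feature vector qualifies (a linear predictor, a
#' network output before the link, ...). For a binary-response source model
#' the function must return the *linear scale* value: the inverse-logit is
#' applied downstream.
#'
#' @param fn function taking a numeric matrix (rows = observations, `p`
#'   columns) and returning a numeric vector of structural values, one per
#'   row. Must be deterministic.
#' @param family `"gaussian"` or `"binomial"`.
#' @param p feature dimension the function expects.
#' @return An object of class `recast_source`.
#' @export
as_recast_source <- function(fn, family = c("gaussian", "binomial"), p) {
  family <- match.arg(family)
  stopifnot(is.function(fn), is.numeric(p), p >= 1)
  structure(
    list(fn = fn, family = family, p = as.integer(p)),
    class = "recast_source"
  )
}

#' Evaluate the frozen structural component at feature vectors
#'
#' @param object a `recast_source`.
#' @param X numeric matrix with `object$p` columns (or a single feature
#'   vector).
#' @return numeric vector of structural values \eqn{f(\hat\theta_S, x_i)}.
#' @export
structural_values <- function(object, X) {
  stopifnot(inherits(object, "recast_source"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  if (ncol(X) != object$p)
    stop("feature matrix has ", ncol(X), " columns; source model expects ",
         object$p)
  if (!is.null(object$theta)) drop(X %*% object$theta) else {
    v <- object$fn(X)
    if (length(v) != nrow(X)) stop("structural function returned wrong length")
    as.numeric(v)
  }
}

#' @export
coef.recast_source <- function(object, ...) object$theta

#' @export
print.recast_source <- function(x, ...) {
  kind <- if (x$family == "gaussian") "continuous (linear)" else
    "binary (logistic)"
  cat("Frozen source model:", kind, "\n")
  cat("  features:", x$p,
      if (is.null(x$theta)) " (user-supplied structural function)" else "",
      "\n", sep = "")
  invisible(x)
}

#' Centre and scale feature columns
#'
#' Standardises each column to mean zero and unit variance, with the standard
#' deviation computed with denominator `n` (the population convention, so a
#' standardised column has exactly unit mean square). When `stats` from a
#' previous call is supplied (e.g. transforming held-out target data with the
#' target-training statistics), the stored affine transform is applied
#' instead of recomputing.
#'
#' @param X numeric matrix.
#' @param stats optional list with elements `mean` and `sd` as returned by a
#'   previous call.
#' @return list with the transformed matrix `X` and the `stats` used.
#' @export
standardize_features <- function(X, stats = NULL) {
  X <- as.matrix(X)
  if (is.null(stats)) {
    mu <- colMeans(X)
    s <- sqrt(colMeans(sweep(X, 2, mu)^2))
    zero <- which(s == 0)
    if (length(zero))
      stop("zero-variance column(s): ", paste(zero, collapse = ", "))
    stats <- list(mean = mu, sd = s)
  } else {
    if (length(stats$mean) != ncol(X) || length(stats$sd) != ncol(X))
      stop("supplied stats do not match the number of columns")
  }
  Z <- sweep(sweep(X, 2, stats$mean), 2, stats$sd, `/`)
  list(X = Z, stats = stats)
}
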