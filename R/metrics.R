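#' Empirical coverage of prediction sets
#'
#' The fraction of truths contained in their prediction sets. Intervals are
#' closed (a truth on an endpoint counts as covered); label sets cover when
#' the true label is a member.
#'
#' @param sets either a two-column numeric matrix/data.frame of interval
#'   `lower`/`upper` bounds, or a logical label-set matrix with columns
#'   `"0"` and `"1"` as returned by [binary_prediction_set()].
#' @param truths numeric vector, one truth per set.
#' @return the coverage fraction in \[0, 1\].
#' @export
empirical_coverage <- function(sets, truths) {
  sets <- as.matrix(sets)
  if (nrow(sets) != length(truths))
    stop("number of sets (", nrow(sets), ") does not match number of truths (",
         length(truths), ")")
  if (is.logical(sets)) {
    mean(ifelse(truths == 1, sets[, "1"], sets[, "0"]))
  } else {
    mean(truths >= sets[, 1] & truths <= sets[, 2])
  }
}

#' Nominal-versus-empirical coverage (reliability) curve
#'
#' Re-cuts the same predictive material at each nominal level and reports
#' empirical coverage: for a continuous response, equal-tailed intervals
#' from each observation's predictive sample; for a binary response, label
#' sets from each observation's predictive success probability. Calibrated
#' predictions put the curve on the diagonal.
#'
#' @param predictive for continuous responses, a list of numeric predictive
#'   sample vectors (one per observation, e.g.
#'   `predict(fit, X, type = "sample")`); for binary responses, a numeric
#'   vector of predictive success probabilities.
#' @param truths observed responses, aligned with `predictive`.
#' @param levels nominal coverage levels in (0, 1).
#' @return data.frame with columns `nominal` and `empirical`.
#' @export
reliability_curve <- function(predictive, truths,
                              levels = seq(0.5, 0.99, by = 0.07)) {
  stopifnot(all(levels > 0), all(levels < 1))
  if (is.list(predictive)) {
    stopifnot(length(predictive) == length(truths))
    emp <- vapply(levels, function(lv) {
      a <- 1 - lv
      ci <- t(vapply(predictive, quantile, numeric(2),
                     probs = c(a / 2, 1 - a / 2), names = FALSE))
      empirical_coverage(ci, truths)
    }, numeric(1))
  } else {
    emp <- vapply(levels, function(lv) {
      empirical_coverage(binary_prediction_set(predictive, 1 - lv), truths)
    }, numeric(1))
  }
  structure(data.frame(nominal = levels, empirical = emp),
            class = c("recast_reliability", "data.frame"))
}

#' @export
plot.recast_reliability <- function(x, ...) {
  plot(x$nominal, x$empirical, type = "b", pch = 19,
       xlim = c(0, 1), ylim = c(0, 1),
       xlab = "nominal coverage", ylab = "empirical coverage", ...)
  abline(0, 1, lty = 2, col = "grey50")
  invisible(x)
}

#' Root mean squared prediction error
#'
#' @param predictions,truths aligned numeric vectors.
#' @return `sqrt(mean((predictions - truths)^2))`.
#' @export
rmse <- function(predictions, truths) {
  if (length(predictions) != length(truths))
    stop("predictions and truths must have equal length")
  sqrt(mean((predictions - truths)^2))
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a randomly chosen positive outscores a randomly
#' chosen negative, with ties counting one half — computed from midranks, so
#' it is exact and invariant under strictly increasing score transforms.
#'
#' @param scores numeric ranking scores (higher means more likely positive).
#' @param labels 0/1 vector with both classes present.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length")
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present to compute AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
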