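#' Integrated Calibration Index
#'
#' Mean absolute difference between predicted probabilities and the
#' smoothed observed event rate at those predictions: a local (loess)
#' regression of the binary outcome on the predicted probability is
#' fitted, and the ICI is the average of
#' `|smoothed(p_i) - p_i|` over the observations. Averaging over
#' observations weights the discrepancy by the density of the predictions,
#' so regions holding most of the sample dominate. 0 means perfect
#' calibration.
#'
#' @param p_pred Predicted probabilities in `[0, 1]`.
#' @param y Binary outcomes (0/1), both classes present.
#' @param span,degree Loess smoothing parameters (defaults 0.75 and 2, the
#'   `stats::loess` defaults).
#' @param grid If `TRUE`, average over an equally spaced grid on the range
#'   of `p_pred` instead of over observations (sensitivity variant).
#' @return Non-negative scalar.
#' @export
ici <- function(p_pred, y, span = 0.75, degree = 2, grid = FALSE) {
  stopifnot(length(p_pred) == length(y), all(y %in% 0:1))
  if (any(p_pred < 0 | p_pred > 1))
    stop("predicted probabilities must lie in [0, 1]")
  if (length(unique(y)) < 2) stop("both outcome classes must be present")
  if (sd(p_pred) < 1e-12) {
    warning("constant predictions; ICI computed against mean(y)")
    return(mean(abs(mean(y) - p_pred)))
  }
  fit <- loess(y ~ p_pred, span = span, degree = degree,
               family = "gaussian")
  if (grid) {
    at <- seq(min(p_pred), max(p_pred), length.out = 100)
    return(mean(abs(predict(fit, newdata = data.frame(p_pred = at)) - at),
                na.rm = TRUE))
  }
  mean(abs(fitted(fit) - p_pred))
}

#' Calibration slope and intercept
#'
#' Ordinary least squares of the outcome on the prediction. A
#' well-calibrated predictor has slope 1 and intercept 0.
#'
#' @param pred Predictions (probabilities, or a PGS for untransformed
#'   scores); must be non-constant.
#' @param y Outcome (binary status, or a standardized status for
#'   observed-scale PGS evaluation).
#' @return Named vector `c(slope, intercept)`.
#' @export
calibration_slope_intercept <- function(pred, y) {
  stopifnot(length(pred) == length(y))
  if (sd(pred) < 1e-12) stop("predictions are constant; slope undefined")
  b <- coef(lm(y ~ pred))
  c(slope = unname(b[2]), intercept = unname(b[1]))
}

#' Empirical AUC (Mann-Whitney)
#'
#' Rank-based area under the ROC curve: the proportion of case/control
#' pairs in which the case scores higher, ties counted one half.
#'
#' @param scores Continuous scores.
#' @param y Binary outcomes (0/1), both classes present.
#' @return AUC in `[0, 1]`.
#' @examples
#' auc_empirical(c(2, 3, 1, 2), c(1, 1, 0, 0)) # 0.875
#' @export
auc_empirical <- function(scores, y) {
  stopifnot(length(scores) == length(y), all(y %in% 0:1))
  n1 <- as.numeric(sum(y == 1)) # double: n1 * n0 overflows integers
  n0 <- as.numeric(sum(y == 0))
  if (n1 == 0 || n0 == 0) stop("both outcome classes must be present")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Liability-scale R2 by regression in a case/control sample
#'
#' Squared correlation between disorder status and the PGS on the observed
#' 0/1 scale in an ascertained sample with case fraction `P`, converted to
#' the liability scale with the Lee et al. transformation
#' ([r2_observed_to_liability()]).
#'
#' @param pgs PGS values.
#' @param y Binary status (0/1).
#' @param K Population lifetime prevalence.
#' @param P Case fraction of the sample (defaults to `mean(y)`).
#' @return Liability-scale R2.
#' @export
r2_liability_regression <- function(pgs, y, K, P = mean(y)) {
  stopifnot(length(pgs) == length(y), all(y %in% 0:1))
  if (length(unique(y)) < 2) stop("both outcome classes must be present")
  r2o <- cor(pgs, y)^2
  r2_observed_to_liability(r2o, K, P)
}
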