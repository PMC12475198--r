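#' Quantile-based probability conversion (Pain et al. style)
#'
#' Re-implementation of the published quantile approach that converts PGS
#' Z-values into disorder probabilities, together with an adjusted variant.
#' The method (i) converts an R2 estimate to an AUC and hence to a
#' separation `d = sqrt(2) * qnorm(AUC)` between unit-variance normal PGS
#' distributions for cases and controls, (ii) divides the case/control
#' mixture into `n_quantiles` quantiles, (iii) computes the disorder
#' probability at each quantile midpoint from the prior and the two
#' densities, and (iv) assigns each individual the probability of the
#' quantile containing its Z-value (standardized against the population
#' reference distribution).
#'
#' In faithful mode (`adjusted = FALSE`) the case/control means are
#' centered with the mixture weights `(prior, 1 - prior)` while the
#' Z-values are standardized against the full population. When the target
#' sample is over-ascertained for cases relative to the population
#' prevalence, the Z-values therefore sit systematically to the right of
#' the assumed mixture and the probabilities are overestimated — the
#' documented calibration defect of this approach. The adjusted variant
#' (`adjusted = TRUE`) instead centers the means with the population
#' weights `(K, 1 - K)` while keeping the prior as mixture weight in the
#' Bayes step, which removes that bias (equal case/control variances are
#' still assumed).
#'
#' @param pgs PGS values of the target sample (any scale; they are
#'   standardized internally).
#' @param prior Prior disorder probability (target-sample case fraction).
#' @param r2_liability Estimate of the PGS R2 on the liability scale (the
#'   original method obtains it from lassosum; the reference-panel variance
#'   estimator of [bpc()] can be used instead).
#' @param K Population lifetime prevalence.
#' @param reference_mean,reference_sd Standardization constants taken from
#'   the PGS distribution in the population reference sample.
#' @param n_quantiles Number of quantiles (default 1000).
#' @param adjusted Use the prevalence-adjusted centering (default `FALSE`).
#' @param continuous Skip the quantile discretization and evaluate the
#'   continuous equal-variance Bayes formula directly (the
#'   `n_quantiles -> Inf` limit).
#' @return Predicted disorder probabilities.
#' @export
pain_probability <- function(pgs, prior, r2_liability, K,
                             reference_mean = 0, reference_sd = 1,
                             n_quantiles = 1000, adjusted = FALSE,
                             continuous = FALSE) {
  check_prob(prior, "prior")
  check_prob(K, "K")
  if (r2_liability < 0 || r2_liability > 1)
    stop("r2_liability must lie in [0, 1]")
  if (n_quantiles < 10) stop("n_quantiles must be at least 10")
  if (reference_sd <= 0) stop("reference_sd must be positive")
  if (r2_liability == 0) return(rep(prior, length(pgs)))

  zval <- (pgs - reference_mean) / reference_sd
  auc <- auc_from_r2(r2_liability, K)
  d <- sqrt(2) * qnorm(auc)
  if (adjusted) {
    mu1 <- (1 - K) * d
    mu0 <- -K * d
  } else {
    mu1 <- (1 - prior) * d
    mu0 <- -prior * d
  }
  post <- function(z)
    prior * dnorm(z, mu1, 1) /
      (prior * dnorm(z, mu1, 1) + (1 - prior) * dnorm(z, mu0, 1))
  if (continuous) return(post(zval))

  # mixture CDF of the assumed case/control distribution
  pmix <- function(z) prior * pnorm(z, mu1, 1) + (1 - prior) * pnorm(z, mu0, 1)
  grid <- seq(min(mu0, mu1) - 8, max(mu0, mu1) + 8, length.out = 8192)
  cdf <- pmix(grid)
  # quantile midpoints of the mixture
  mid <- stats::approx(cdf, grid, xout = (seq_len(n_quantiles) - 0.5) /
                         n_quantiles, rule = 2, ties = "ordered")$y
  prob_q <- post(mid)
  idx <- pmin(pmax(ceiling(pmix(zval) * n_quantiles), 1L), n_quantiles)
  prob_q[idx]
}
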