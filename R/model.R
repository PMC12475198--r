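#' Fit a Bayesian probability-conversion model for a polygenic score
#'
#' Builds the model that converts a liability-scale polygenic score (PGS)
#' into an absolute disorder probability. The PGS must be well-calibrated
#' on the liability scale (posterior-mean effect sizes converted with
#' [beta_liability()]), in which case its variance in a population sample
#' equals the variance it explains in the liability. The model therefore
#' estimates `R2_liability` as the sample variance of the PGS in an
#' ancestry-matched population reference panel (no phenotypes needed),
#' derives the normal-theory PGS distribution in cases and controls from
#' `R2_liability` and the population lifetime prevalence `K`
#' ([casecontrol_moments()]), and applies Bayes' theorem to update the
#' prior disorder probability given an individual's PGS value.
#'
#' @param reference_pgs Numeric vector of liability-scale PGS values in a
#'   population (non-ascertained) reference sample. Ignored when
#'   `r2_liability` is supplied directly.
#' @param K Population lifetime prevalence of the disorder.
#' @param prior Prior disorder probability of the target individual(s) —
#'   for example the case fraction of the clinic population they come
#'   from. May differ from `K`.
#' @param r2_liability Optional: supply the liability-scale R2 directly
#'   instead of a reference panel.
#' @return An object of class `"bpc"` with components `K`, `prior`,
#'   `r2_liability`, `moments` (a [casecontrol_moments()] object with
#'   mixing proportion `prior`), `source` (`"theory"`) and `n_reference`.
#' @seealso [predict.bpc()], [bpc_tuned()], [linear_rescale()]
#' @examples
#' ref <- rnorm(503, 0, sqrt(0.05))   # reference PGS with variance ~ 0.05
#' fit <- bpc(ref, K = 0.01, prior = 0.5)
#' predict(fit, pgs = c(-0.2, 0, 0.2))
#' @export
bpc <- function(reference_pgs = NULL, K, prior = 0.5, r2_liability = NULL) {
  check_prob(K, "K")
  check_prob(prior, "prior")
  n_ref <- NA_integer_
  if (is.null(r2_liability)) {
    if (is.null(reference_pgs))
      stop("supply either reference_pgs or r2_liability")
    if (length(reference_pgs) < 2)
      stop("reference_pgs needs at least 2 individuals")
    r2_liability <- var(reference_pgs) # n - 1 denominator
    n_ref <- length(reference_pgs)
  }
  if (r2_liability < 0 || r2_liability > 1)
    stop("r2_liability must lie in [0, 1]")
  out <- list(K = K, prior = prior, r2_liability = r2_liability,
              moments = casecontrol_moments(r2_liability, K, p_case = prior),
              source = "theory", n_reference = n_ref)
  class(out) <- "bpc"
  out
}

#' Probability-conversion model with moments estimated from a tuning sample
#'
#' Variant of [bpc()] that replaces the normal-theory case/control PGS
#' distributions with empirical means and variances estimated from a
#' tuning sample carrying both PGS and phenotype data (skipping the
#' reference-panel and scale-conversion steps).
#'
#' @param tuning_pgs Numeric vector of PGS values in the tuning sample.
#' @param tuning_status Binary disorder status (0/1) of the tuning sample;
#'   at least two cases and two controls are required.
#' @param prior Prior disorder probability for the target individuals.
#' @param K Population lifetime prevalence (retained for reporting; the
#'   empirical moments already reflect it). Optional.
#' @return An object of class `c("bpc_tuned", "bpc")`.
#' @export
bpc_tuned <- function(tuning_pgs, tuning_status, prior = 0.5, K = NULL) {
  check_prob(prior, "prior")
  stopifnot(length(tuning_pgs) == length(tuning_status),
            all(tuning_status %in% 0:1))
  n1 <- sum(tuning_status == 1)
  n0 <- sum(tuning_status == 0)
  if (n1 < 2 || n0 < 2)
    stop("tuning sample must contain at least 2 cases and 2 controls")
  m <- list(mu_case = mean(tuning_pgs[tuning_status == 1]),
            var_case = var(tuning_pgs[tuning_status == 1]),
            mu_control = mean(tuning_pgs[tuning_status == 0]),
            var_control = var(tuning_pgs[tuning_status == 0]),
            p_case = prior, r2_liability = NA_real_,
            K = if (is.null(K)) NA_real_ else K)
  class(m) <- "pgs_moments"
  out <- list(K = m$K, prior = prior, r2_liability = NA_real_, moments = m,
              source = "tuned", n_reference = NA_integer_,
              n_tuning = c(cases = n1, controls = n0))
  class(out) <- c("bpc_tuned", "bpc")
  out
}

#' Posterior disorder probabilities from a fitted conversion model
#'
#' Applies Bayes' theorem to each PGS value:
#' `P(case | PGS) = prior * f1(PGS) / (prior * f1(PGS) + (1 - prior) * f0(PGS))`
#' where `f1`, `f0` are the normal densities of the PGS in cases and
#' controls held by the model.
#'
#' @param object A `"bpc"` model.
#' @param pgs Numeric vector of liability-scale PGS values (the same scale
#'   the model was built on).
#' @param type `"posterior"` (default) for disorder probabilities,
#'   `"likelihood_ratio"` for `P(PGS | case) / P(PGS)` where `P(PGS)` is
#'   the prior-weighted mixture density.
#' @param prior Optional prior(s) overriding the model's; either a scalar
#'   or one value per individual (for context-specific priors such as age
#'   or sex strata).
#' @param ... Unused.
#' @return Numeric vector, same length as `pgs`.
#' @export
predict.bpc <- function(object, pgs,
                        type = c("posterior", "likelihood_ratio"),
                        prior = NULL, ...) {
  type <- match.arg(type)
  if (is.null(prior)) prior <- object$prior
  if (!all(prior > 0 & prior < 1)) stop("priors must lie strictly in (0, 1)")
  if (length(prior) != 1L && length(prior) != length(pgs))
    stop("prior must be a scalar or one value per individual")
  m <- object$moments
  if (m$var_case <= 0 || m$var_control <= 0) {
    if (m$var_case == 0 && m$var_control == 0 &&
        isTRUE(all.equal(m$mu_case, m$mu_control))) {
      # degenerate null model: the PGS carries no information
      return(switch(type,
                    posterior = rep(prior, length.out = length(pgs)),
                    likelihood_ratio = rep(1, length(pgs))))
    }
    stop("case/control PGS variances must be positive")
  }
  # log-space evaluation keeps the posterior finite far into the tails
  lf1 <- dnorm(pgs, m$mu_case, sqrt(m$var_case), log = TRUE)
  lf0 <- dnorm(pgs, m$mu_control, sqrt(m$var_control), log = TRUE)
  lodds <- log(prior) - log1p(-prior) + lf1 - lf0
  switch(type,
         posterior = stats::plogis(lodds),
         likelihood_ratio = 1 / (prior + (1 - prior) * exp(lf0 - lf1)))
}

#' Dispersion of the likelihood ratio across a target sample
#'
#' Standard deviation over individuals of
#' `P(PGS_i | case) / P(PGS_i)`. Values near 0 mean the posterior
#' probabilities are dominated by the prior; larger values mean the PGS
#' moves the posterior materially away from the prior.
#'
#' @param object A `"bpc"` model.
#' @param pgs PGS values of the target sample.
#' @param prior Optional prior override.
#' @return Non-negative scalar.
#' @export
likelihood_ratio_sd <- function(object, pgs, prior = NULL) {
  sd(predict(object, pgs, type = "likelihood_ratio", prior = prior))
}

#' @export
print.bpc <- function(x, ...) {
  cat("Polygenic score probability-conversion model\n")
  cat(sprintf("  source: %s\n", x$source))
  if (!is.na(x$K)) cat(sprintf("  population lifetime prevalence K = %g\n", x$K))
  cat(sprintf("  prior disorder probability = %g\n", x$prior))
  if (!is.na(x$r2_liability))
    cat(sprintf("  R2_liability = %.4f%s\n", x$r2_liability,
                if (!is.na(x$n_reference))
                  sprintf(" (variance of %d reference PGSs)", x$n_reference)
                else ""))
  m <- x$moments
  cat(sprintf("  PGS | case:    N(%.4f, %.5f)\n", m$mu_case, m$var_case))
  cat(sprintf("  PGS | control: N(%.4f, %.5f)\n", m$mu_control, m$var_control))
  invisible(x)
}

#' @export
summary.bpc <- function(object, ...) {
  m <- object$moments
  structure(list(model = object,
                 auc = if (!is.na(object$r2_liability) && !is.na(object$K))
                   auc_from_r2(object$r2_liability, object$K) else NA_real_,
                 separation = (m$mu_case - m$mu_control) /
                   sqrt((m$var_case + m$var_control) / 2)),
            class = "summary.bpc")
}

#' @export
print.summary.bpc <- function(x, ...) {
  print(x$model)
  cat(sprintf("  standardized case/control separation: %.3f\n", x$separation))
  if (!is.na(x$auc)) cat(sprintf("  implied AUC: %.3f\n", x$auc))
  invisible(x)
}

#' @export
coef.bpc <- function(object, ...) {
  m <- object$moments
  c(mu_case = m$mu_case, var_case = m$var_case,
    mu_control = m$mu_control, var_control = m$var_control,
    prior = object$prior, r2_liability = object$r2_liability)
}

#' Plot the case/control PGS densities and the posterior curve
#'
#' @param x A `"bpc"` model.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.bpc <- function(x, ...) {
  m <- x$moments
  lim <- range(m$mu_case + c(-4, 4) * sqrt(m$var_case),
               m$mu_control + c(-4, 4) * sqrt(m$var_control))
  g <- seq(lim[1], lim[2], length.out = 400)
  f1 <- dnorm(g, m$mu_case, sqrt(m$var_case))
  f0 <- dnorm(g, m$mu_control, sqrt(m$var_control))
  post <- predict(x, g)
  graphics::plot(g, f0 / max(f0), type = "l", col = "steelblue",
                 xlab = "liability-scale PGS",
                 ylab = "scaled density / probability", ylim = c(0, 1), ...)
  graphics::lines(g, f1 / max(f1), col = "firebrick")
  graphics::lines(g, post, lwd = 2)
  graphics::abline(h = x$prior, lty = 3)
  graphics::legend("topleft", bty = "n", lwd = c(1, 1, 2),
                   col = c("steelblue", "firebrick", "black"),
                   legend = c("controls", "cases", "P(case | PGS)"))
  invisible(x)
}

#' Linear rescaling of a liability-scale PGS to the probability scale
#'
#' Alternative to the Bayes update: rescales the liability-scale PGS so
#' that its variance in the ascertained target sample equals the
#' observed-scale R2 (Lee et al. conversion at case fraction `prior`), then
#' affine-maps it to the 0/1 scale,
#' `prob = PGS' * sqrt(prior (1 - prior)) + prior`. Values outside
#' `[0, 1]` are truncated, which is why this approach degrades when the
#' prevalence is low and R2 is large.
#'
#' @param pgs Liability-scale PGS values of the target sample.
#' @param object A `"bpc"` model (its `prior` is the target-sample case
#'   fraction).
#' @param truncate Truncate to `[0, 1]` (default `TRUE`, matching how the
#'   probabilities are evaluated).
#' @return Predicted disorder probabilities.
#' @export
linear_rescale <- function(pgs, object, truncate = TRUE) {
  stopifnot(inherits(object, "bpc"))
  P <- object$prior
  m <- object$moments
  # moments of the PGS in the ascertained sample (mixture with weight P)
  mu_asc <- P * m$mu_case + (1 - P) * m$mu_control
  v_asc <- P * (m$var_case + m$mu_case^2) +
    (1 - P) * (m$var_control + m$mu_control^2) - mu_asc^2
  if (is.na(object$r2_liability))
    stop("linear_rescale needs a theory-based model with a known R2")
  if (object$r2_liability == 0 || v_asc <= 0)
    return(rep(P, length(pgs)))
  r2o <- r2_liability_to_observed(object$r2_liability, object$K, P)
  pgs_std <- (pgs - mu_asc) * sqrt(r2o / v_asc)
  out <- pgs_std * sqrt(P * (1 - P)) + P
  if (truncate) out <- pmin(1, pmax(0, out))
  out
}

#' Probability conversion by logistic regression in a tuning sample
#'
#' Fits `status ~ PGS` by logistic regression in a tuning sample and
#' applies the fitted intercept and slope to the testing PGS values,
#' returning inverse-logit probabilities.
#'
#' @param tuning_pgs,tuning_status Tuning sample (binary status, both
#'   classes present).
#' @param testing_pgs PGS values to convert.
#' @return Predicted disorder probabilities for `testing_pgs`.
#' @export
logit_tuned <- function(tuning_pgs, tuning_status, testing_pgs) {
  stopifnot(length(tuning_pgs) == length(tuning_status),
            all(tuning_status %in% 0:1))
  if (length(unique(tuning_status)) < 2)
    stop("tuning sample must contain both classes")
  fit <- suppressWarnings(
    glm(tuning_status ~ tuning_pgs, family = binomial()))
  if (fit$deviance < 1e-6)
    stop("(near-)perfect separation in the tuning sample; the logistic ",
         "slope is unbounded. Use a larger or less extreme tuning sample")
  b <- unname(coef(fit))
  if (is.na(b[2])) b[2] <- 0 # constant PGS: intercept-only model
  eta <- b[1] + b[2] * testing_pgs
  1 / (1 + exp(-eta))
}
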