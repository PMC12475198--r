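#' Liability threshold and normal density height for a prevalence
#'
#' Under the liability threshold model a binary disorder with population
#' lifetime prevalence `K` corresponds to a standard-normal liability
#' exceeding the threshold `T = qnorm(1 - K)`; `z = dnorm(T)` is the height
#' of the standard normal density at that threshold. Both quantities appear
#' throughout the scale conversions of this package.
#'
#' @param K Population lifetime prevalence, in (0, 1).
#' @return A list with components `threshold` (T) and `density` (z).
#' @examples
#' liability_threshold(0.01)
#' @export
liability_threshold <- function(K) {
  check_prob(K, "K")
  t <- qnorm(1 - K)
  list(threshold = t, density = dnorm(t))
}

#' Convert effect sizes from the standardized 50/50 observed scale to the
#' liability scale
#'
#' Multiplies effect sizes on the standardized observed scale with case
#' fraction `p` by the scalar `K (1 - K) / (z p)`, where `z` is the height
#' of the standard normal density at the liability threshold for prevalence
#' `K`. With `p = 0.5` this is the conversion applied to posterior-mean
#' betas before constructing a liability-scale PGS. For a GWAS standardized
#' at a general case fraction `P`, pass `p = sqrt(P * (1 - P))` (which
#' equals 0.5 at `P = 0.5`).
#'
#' @param beta_5050 Numeric vector of per-SNP effects on the standardized
#'   observed scale.
#' @param K Population lifetime prevalence.
#' @param p Case-fraction scale constant of the observed scale
#'   (default 0.5).
#' @return Numeric vector of liability-scale effects.
#' @export
beta_liability <- function(beta_5050, K, p = 0.5) {
  check_prob(K, "K")
  stopifnot(is.numeric(beta_5050), p > 0)
  z <- liability_threshold(K)$density
  beta_5050 * K * (1 - K) / (z * p)
}

#' Lee et al. conversion of R2 between the liability and observed scales
#'
#' Converts a coefficient of determination between the liability scale and
#' the 0/1 observed scale in a (possibly case-ascertained) sample with case
#' fraction `P`, for a disorder with population lifetime prevalence `K`
#' (Lee et al. 2012). The two functions are exact inverses of each other.
#'
#' @param r2_liability,r2_observed The R2 to convert.
#' @param K Population lifetime prevalence.
#' @param P Case fraction of the ascertained sample.
#' @return The converted R2.
#' @examples
#' r2o <- r2_liability_to_observed(0.10, K = 0.01, P = 0.5)
#' r2_observed_to_liability(r2o, K = 0.01, P = 0.5) # 0.10
#' @export
r2_liability_to_observed <- function(r2_liability, K, P) {
  lc <- lee_constants(K, P)
  stopifnot(r2_liability >= 0, r2_liability <= 1)
  out <- r2_liability / (lc$C * (1 - lc$theta * r2_liability))
  if (any(out < 0 | out > 1))
    stop("converted R2 falls outside [0, 1]; check K, P and the input R2")
  out
}

#' @rdname r2_liability_to_observed
#' @export
r2_observed_to_liability <- function(r2_observed, K, P) {
  lc <- lee_constants(K, P)
  stopifnot(r2_observed >= 0, r2_observed <= 1)
  out <- lc$C * r2_observed / (1 + lc$C * lc$theta * r2_observed)
  if (any(out < 0 | out > 1))
    stop("converted R2 falls outside [0, 1]; check K, P and the input R2")
  out
}

# C and theta of the Lee et al. (2012) ascertainment-corrected conversion
lee_constants <- function(K, P) {
  check_prob(K, "K")
  check_prob(P, "P")
  lt <- liability_threshold(K)
  t <- lt$threshold
  z <- lt$density
  m <- z / K # mean liability of cases
  C <- K * (1 - K) / z^2 * K * (1 - K) / (P * (1 - P))
  d <- m * (P - K) / (1 - K)
  list(C = C, theta = d * (d - t))
}

#' Normal-theory moments of a liability-scale PGS in cases and controls
#'
#' For a liability-scale PGS with population variance `r2_liability` that is
#' jointly bivariate normal with the liability (correlation
#' `sqrt(r2_liability)`), returns the exact mean and variance of the PGS
#' conditional on disorder status, obtained from truncated bivariate normal
#' theory:
#' \deqn{\mu_{case} = R^2 z/K, \quad
#'       \sigma^2_{case} = R^2 (1 - R^2 (z/K)(z/K - T))}
#' and analogously for controls with `-z/(1-K)` in place of `z/K` and
#' `z/(1-K) + T` in place of `z/K - T`. For `K < 0.5` the case variance is
#' strictly smaller than the control variance, a feature the probability
#' conversion exploits.
#'
#' @param r2_liability PGS coefficient of determination on the liability
#'   scale, in `[0, 1]`.
#' @param K Population lifetime prevalence.
#' @param p_case Mixing proportion of cases in the target sample
#'   (defaults to `K`, the population mixture).
#' @return An object of class `"pgs_moments"`: a list with `mu_case`,
#'   `var_case`, `mu_control`, `var_control`, `p_case`, `r2_liability`, `K`.
#' @examples
#' casecontrol_moments(0.05, K = 0.01)
#' @export
casecontrol_moments <- function(r2_liability, K, p_case = K) {
  check_prob(K, "K")
  if (r2_liability < 0 || r2_liability > 1)
    stop("r2_liability must lie in [0, 1]")
  check_prob_incl(p_case, "p_case")
  lt <- liability_threshold(K)
  t <- lt$threshold
  i1 <- lt$density / K        # E[L | case]
  i0 <- lt$density / (1 - K)  # -E[L | control]
  out <- list(
    mu_case     = r2_liability * i1,
    var_case    = r2_liability * (1 - r2_liability * i1 * (i1 - t)),
    mu_control  = -r2_liability * i0,
    var_control = r2_liability * (1 - r2_liability * i0 * (i0 + t)),
    p_case      = p_case,
    r2_liability = r2_liability,
    K = K
  )
  class(out) <- "pgs_moments"
  out
}

#' @export
print.pgs_moments <- function(x, ...) {
  cat("Case/control PGS moments (liability scale)\n")
  cat(sprintf("  K = %g, R2_liability = %g, case mixing proportion = %g\n",
              x$K, x$r2_liability, x$p_case))
  cat(sprintf("  cases:    mean %.6f, variance %.6f\n", x$mu_case, x$var_case))
  cat(sprintf("  controls: mean %.6f, variance %.6f\n",
              x$mu_control, x$var_control))
  invisible(x)
}

#' AUC implied by a liability-scale R2
#'
#' Converts the variance explained by a PGS on the liability scale into the
#' area under the ROC curve implied by the normal-theory case/control PGS
#' distributions: `AUC = pnorm((mu_case - mu_control) /
#' sqrt(var_case + var_control))`, i.e. the probability that a random
#' case's PGS exceeds a random control's.
#'
#' @inheritParams casecontrol_moments
#' @return AUC in `[0.5, 1)`.
#' @examples
#' auc_from_r2(0.10, K = 0.15)
#' @export
auc_from_r2 <- function(r2_liability, K) {
  m <- casecontrol_moments(r2_liability, K)
  if (r2_liability == 0) return(0.5)
  pnorm((m$mu_case - m$mu_control) / sqrt(m$var_case + m$var_control))
}

# --- small validators shared across the package ---

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x >= 1)
    stop(sprintf("%s must be a single probability strictly inside (0, 1)",
                 name), call. = FALSE)
  invisible(x)
}

check_prob_incl <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("%s must be a single probability in [0, 1]", name),
         call. = FALSE)
  invisible(x)
}
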