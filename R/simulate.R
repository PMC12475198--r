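#' Define a simulation condition
#'
#' Bundles the parameters of one liability-threshold simulation condition:
#' prevalence, target liability-scale R2 of the PGS, SNP heritability,
#' number of LE SNPs, reference-panel size, testing-sample composition,
#' number of replicates and the prior disorder probability used by the
#' conversion methods.
#'
#' @param K Population lifetime prevalence.
#' @param r2_target Target PGS R2 on the liability scale (must be below
#'   `h2`); the training-sample size is solved to reach it.
#' @param h2 SNP heritability on the liability scale (default 0.2).
#' @param M Number of causal SNPs in linkage equilibrium (default 1000).
#' @param n_reference Size of the population reference panel (default 503).
#' @param n_test_cases,n_test_controls Testing-sample composition for
#'   ascertained evaluation (defaults 1000/1000).
#' @param n_runs Number of simulation replicates (default 100).
#' @param prior Prior disorder probability supplied to the conversion
#'   methods (default 0.5).
#' @param n_test_random Testing-sample size used under random
#'   (population) ascertainment (default 20000), where case counts follow
#'   the prevalence.
#' @return An object of class `"sim_condition"`.
#' @export
sim_condition <- function(K, r2_target, h2 = 0.2, M = 1000,
                          n_reference = 503, n_test_cases = 1000,
                          n_test_controls = 1000, n_runs = 100,
                          prior = 0.5, n_test_random = 20000) {
  check_prob(K, "K")
  check_prob(prior, "prior")
  if (r2_target < 0 || r2_target > h2)
    stop("r2_target must lie in [0, h2]")
  stopifnot(h2 > 0, h2 < 1, M >= 2, n_reference >= 2,
            n_test_cases >= 1, n_test_controls >= 1, n_runs >= 1)
  out <- list(K = K, r2_target = r2_target, h2 = h2, M = as.integer(M),
              n_reference = as.integer(n_reference),
              n_test_cases = as.integer(n_test_cases),
              n_test_controls = as.integer(n_test_controls),
              n_runs = as.integer(n_runs), prior = prior,
              n_test_random = as.integer(n_test_random))
  class(out) <- "sim_condition"
  out
}

#' @export
print.sim_condition <- function(x, ...) {
  cat(sprintf(
    "Simulation condition: K = %g, R2_liability target = %g, h2 = %g, M = %d\n",
    x$K, x$r2_target, x$h2, x$M))
  cat(sprintf("  reference N = %d, testing %d/%d, runs = %d, prior = %g\n",
              x$n_reference, x$n_test_cases, x$n_test_controls,
              x$n_runs, x$prior))
  invisible(x)
}

#' Simulate a population cohort under the liability threshold model
#'
#' Draws `n` individuals with `M` SNPs in linkage equilibrium: allele
#' counts `g_ij ~ Binomial(2, f_j)`, liability
#' `L_i = sum_j beta_j g_ij^std + e_i` with `e ~ N(0, 1 - h2)`, and status
#' `1{L > qnorm(1 - K)}`. Effects are on the standardized-genotype scale,
#' so `sum(effects^2)` is the realized SNP heritability.
#'
#' @param n Number of individuals.
#' @param effects Per-SNP liability effects on the standardized-genotype
#'   scale (for heritability `h2`, draw `rnorm(M, 0, sqrt(h2/M))`).
#' @param freqs Per-SNP allele frequencies.
#' @param h2 SNP heritability on the liability scale.
#' @param K Population lifetime prevalence.
#' @return An object of class `"cohort"`: a list with `dosages` (integer
#'   N x M), `liability`, `status`, `freqs`, `effects`, `h2`, `K`, `role`.
#' @export
simulate_population <- function(n, effects, freqs, h2, K) {
  if (n <= 0) stop("n must be positive")
  check_prob(K, "K")
  stopifnot(length(effects) == length(freqs), h2 >= 0, h2 < 1)
  M <- length(effects)
  X <- matrix(rbinom(n * M, 2L, rep(freqs, each = n)), n, M)
  g <- drop(standardize_dosages(X, freqs) %*% effects)
  liab <- g + rnorm(n, 0, sqrt(1 - h2))
  new_cohort(X, liab, K, freqs, effects, h2, role = "population")
}

#' Simulate an ascertained case/control cohort
#'
#' Draws exactly `n_cases` cases and `n_controls` controls from the
#' liability threshold model, using a sequential conditional genotype
#' sampler (genotype-by-genotype factorization of the genotype distribution
#' given disorder status, with the not-yet-sampled SNPs plus the
#' non-genetic residual treated as a normal remainder whose variance is
#' tracked exactly). This makes heavy case oversampling (for example cases
#' at prevalence 0.01) run in time proportional to the number of retained
#' individuals rather than the number of population draws; the sampler is
#' validated against brute-force rejection sampling in the test suite.
#'
#' @inheritParams simulate_population
#' @param n_cases,n_controls Requested counts (either may be 0).
#' @return A `"cohort"` with cases stacked above controls.
#' @export
simulate_ascertained <- function(n_cases, n_controls, effects, freqs, h2, K) {
  check_prob(K, "K")
  stopifnot(n_cases >= 0, n_controls >= 0, n_cases + n_controls > 0,
            length(effects) == length(freqs), h2 >= 0, h2 < 1)
  parts <- list()
  if (n_cases > 0)
    parts$case <- .sample_status_cohort(as.integer(n_cases), effects, freqs,
                                        h2, K, TRUE)
  if (n_controls > 0)
    parts$control <- .sample_status_cohort(as.integer(n_controls), effects,
                                           freqs, h2, K, FALSE)
  X <- do.call(rbind, lapply(parts, `[[`, "dosages"))
  liab <- unlist(lapply(parts, `[[`, "liability"), use.names = FALSE)
  new_cohort(X, liab, K, freqs, effects, h2, role = "ascertained")
}

new_cohort <- function(X, liability, K, freqs, effects, h2, role) {
  t <- qnorm(1 - K)
  out <- list(dosages = X, liability = liability,
              status = as.integer(liability > t), freqs = freqs,
              effects = effects, h2 = h2, K = K, role = role)
  class(out) <- "cohort"
  out
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Cohort (%s): %d individuals, %d SNPs, %d cases (K = %g)\n",
              x$role, nrow(x$dosages), ncol(x$dosages), sum(x$status), x$K))
  invisible(x)
}

#' Ascertain exact case/control counts from an existing cohort
#'
#' Draws the requested numbers of cases and controls uniformly without
#' replacement from a simulated cohort, preserving each individual's
#' genotype/liability/status pairing.
#'
#' @param cohort A `"cohort"` object.
#' @param n_cases,n_controls Requested counts.
#' @return A `"cohort"` with exactly the requested composition.
#' @export
ascertain <- function(cohort, n_cases, n_controls) {
  stopifnot(inherits(cohort, "cohort"))
  ca <- which(cohort$status == 1L)
  co <- which(cohort$status == 0L)
  if (n_cases > length(ca) || n_controls > length(co))
    stop(sprintf(
      "requested %d cases / %d controls but only %d / %d available",
      n_cases, n_controls, length(ca), length(co)))
  idx <- c(sample(ca, n_cases), sample(co, n_controls))
  new_cohort(cohort$dosages[idx, , drop = FALSE], cohort$liability[idx],
             cohort$K, cohort$freqs, cohort$effects, cohort$h2,
             role = "ascertained")
}

#' GWAS on the standardized observed scale
#'
#' Runs a marginal association scan of disorder status on each SNP:
#' `z_j = sqrt(n) * cor(g_j, status)`. Betas are reported on the
#' standardized observed scale with 50% case ascertainment via
#' `beta_5050 = z / sqrt(N_eff)` with `N_eff = 4 P (1 - P) n` for sample
#' case fraction `P` (`N_eff = n` in a balanced sample). Monomorphic SNPs
#' get `z = 0` with a warning.
#'
#' @param cohort A `"cohort"` with both cases and controls.
#' @return A data frame with columns `snp`, `af`, `z`, `beta_5050`,
#'   `n_eff`; attributes `scale_tag = "obs5050"`, `n` and `case_fraction`.
#' @export
gwas_obs5050 <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  y <- cohort$status
  n <- length(y)
  P <- mean(y)
  if (P == 0 || P == 1) stop("cohort must contain both cases and controls")
  X <- cohort$dosages
  yc <- y - P
  sy <- sqrt(mean(yc^2))
  if (is.integer(X)) {
    st <- .col_assoc_stats(X, yc)
    xm <- st$sum_x / n
    xs <- sqrt(pmax(st$sum_x2 / n - xm^2, 0))
    sxy <- st$sum_xy / n
  } else {
    xm <- colMeans(X)
    xs <- sqrt(colMeans(X^2) - xm^2)
    sxy <- as.vector(crossprod(X, yc)) / n
  }
  mono <- xs == 0
  if (any(mono)) {
    warning(sprintf("%d monomorphic SNP(s); their z set to 0", sum(mono)))
    xs[mono] <- 1
  }
  z <- sqrt(n) * sxy / (xs * sy)
  z[mono] <- 0
  n_eff <- 4 * P * (1 - P) * n
  out <- data.frame(snp = paste0("snp", seq_along(z)), af = xm / 2,
                    z = z, beta_5050 = z / sqrt(n_eff), n_eff = n_eff)
  attr(out, "scale_tag") <- "obs5050"
  attr(out, "n") <- n
  attr(out, "case_fraction") <- P
  out
}

#' Heritability on the standardized observed scale
#'
#' Converts SNP heritability from the liability scale to the standardized
#' observed scale of a sample with case fraction `P`:
#' `h2_obs = h2 z^2 P (1 - P) / (K (1 - K))^2`.
#'
#' @param h2 Liability-scale SNP heritability.
#' @param K Population lifetime prevalence.
#' @param P Case fraction of the GWAS sample (default 0.5).
#' @return Observed-scale heritability.
#' @export
h2_observed <- function(h2, K, P = 0.5) {
  check_prob(K, "K")
  check_prob(P, "P")
  z <- liability_threshold(K)$density
  h2 * z^2 * P * (1 - P) / (K * (1 - K))^2
}

#' Expected liability-scale R2 of a PGS from training-sample size
#'
#' Closed-form expectation of the liability-scale coefficient of
#' determination of a PGS built from marginal GWAS effects on `M`
#' independent SNPs estimated in a case/control sample of size `n` with
#' case fraction `P`:
#' \deqn{R^2 = \frac{h^2 \, h^2_{obs}}{h^2_{obs} + M (1 - h^2_{obs}/M)/n}}
#' with `h2_obs` the observed-scale heritability. The per-SNP sampling
#' variance `(1 - h2_obs/M)/n` accounts for the residual phenotypic
#' variance left by each SNP.
#'
#' @param n Training-sample size.
#' @inheritParams h2_observed
#' @param M Number of independent SNPs.
#' @return Expected liability-scale R2.
#' @export
expected_r2_liability <- function(n, K, h2, M, P = 0.5) {
  h2o <- h2_observed(h2, K, P)
  h2 * h2o / (h2o + M * (1 - h2o / M) / n)
}

#' Training-sample size required for a target liability-scale R2
#'
#' Inverts [expected_r2_liability()] and returns the smallest integer
#' training-sample size whose expected PGS R2 on the liability scale
#' reaches `r2_target`, for a case/control GWAS with case fraction `P` on
#' `M` independent markers.
#'
#' @param r2_target Target liability-scale R2 (strictly below `h2`).
#' @inheritParams expected_r2_liability
#' @return Integer sample size.
#' @examples
#' required_training_n(0.10, K = 0.01, h2 = 0.2, M = 1000) # 2759
#' @export
required_training_n <- function(r2_target, K, h2 = 0.2, M = 1000, P = 0.5) {
  if (r2_target <= 0) stop("r2_target must be positive")
  if (r2_target >= h2)
    stop("r2_target must be strictly below h2; the required sample size ",
         "diverges as the target approaches h2")
  h2o <- h2_observed(h2, K, P)
  n <- M * (1 - h2o / M) / (h2o * (h2 / r2_target - 1))
  as.integer(ceiling(n))
}
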