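#' Run one simulation condition and evaluate conversion methods
#'
#' For each replicate: draw SNP effects and allele frequencies, solve the
#' training-sample size for the condition's target R2
#' ([required_training_n()]), simulate a case/control training sample and
#' run the GWAS on the standardized observed scale ([gwas_obs5050()]),
#' shrink the betas to posterior means ([bpred_shrink()], infinitesimal
#' prior by default), convert them to the liability scale
#' ([beta_liability()]), score a population reference panel and a testing
#' sample, convert the testing PGSs to probabilities with each requested
#' method, and evaluate calibration and discrimination.
#'
#' Ascertainment modes: `"balanced"` trains on a 50/50 case/control sample
#' and tests on the condition's `n_test_cases`/`n_test_controls`
#' composition; `"random"` trains and tests on population (randomly
#' ascertained) samples, the design under which untransformed
#' observed-scale PGSs are themselves calibrated.
#'
#' @param cond A [sim_condition()].
#' @param methods Character vector from `"bpc"`, `"pain"`,
#'   `"pain_adjusted"`, `"pain_adjusted_refvar"`, `"linear"`,
#'   `"bpc_tuned"`, `"logit_tuned"`, `"untransformed"`. The quantile
#'   comparators use the reference-panel variance as their R2 estimate, so
#'   `"pain_adjusted_refvar"` coincides with `"pain_adjusted"` here.
#' @param seed Master seed; per-run child seeds are drawn from it, so a
#'   report is bit-reproducible given (`cond`, `methods`, `seed`).
#' @param ascertainment `"balanced"` (default) or `"random"`.
#' @param n_runs Number of replicates; defaults to `cond$n_runs`.
#' @param n_tuning_cases,n_tuning_controls Size of the tuning sample
#'   simulated for the tuned methods (0 unless those methods are
#'   requested).
#' @param n_quantiles Quantile count for the quantile comparators.
#' @param p_causal Prior causal fraction passed to [bpred_shrink()].
#' @return An object of class `"calibration_report"`: a list with
#'   `metrics` (per run x method: ICI, slope, intercept, AUC), `diagnostics`
#'   (per run: reference-panel R2 estimate, regression-based testing R2,
#'   likelihood-ratio SD, training N), `summary` and `diag_summary`
#'   (means with standard errors of the mean), plus the inputs.
#' @export
run_condition <- function(cond, methods = c("bpc", "pain"), seed = 1L,
                          ascertainment = c("balanced", "random"),
                          n_runs = cond$n_runs,
                          n_tuning_cases = 0L, n_tuning_controls = 0L,
                          n_quantiles = 1000L, p_causal = 1) {
  stopifnot(inherits(cond, "sim_condition"))
  ascertainment <- match.arg(ascertainment)
  known <- c("bpc", "pain", "pain_adjusted", "pain_adjusted_refvar",
             "linear", "bpc_tuned", "logit_tuned", "untransformed")
  if (!all(methods %in% known))
    stop("unknown method(s): ", paste(setdiff(methods, known), collapse = ", "))
  needs_tuning <- any(methods %in% c("bpc_tuned", "logit_tuned"))
  if (needs_tuning && (n_tuning_cases < 2 || n_tuning_controls < 2))
    stop("tuned methods need n_tuning_cases and n_tuning_controls >= 2")

  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max, n_runs)
  metrics <- vector("list", n_runs)
  diags <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    set.seed(run_seeds[r])
    one <- simulate_run(cond, methods, ascertainment,
                        n_tuning_cases, n_tuning_controls,
                        n_quantiles, p_causal)
    one$metrics$run <- r
    one$diagnostics$run <- r
    metrics[[r]] <- one$metrics
    diags[[r]] <- one$diagnostics
  }
  metrics <- do.call(rbind, metrics)
  diags <- do.call(rbind, diags)

  sem <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 2) return(NA_real_)
    sd(x) / sqrt(length(x))
  }
  agg <- function(df, by) {
    num <- setdiff(names(df)[vapply(df, is.numeric, TRUE)], c("run"))
    means <- aggregate(df[num], df[by], function(x) mean(x, na.rm = TRUE))
    sems <- aggregate(df[num], df[by], sem)
    names(sems)[-1] <- paste0("sem_", names(sems)[-1])
    names(means)[-1] <- paste0("mean_", names(means)[-1])
    cbind(means, sems[-1])
  }
  out <- list(condition = cond, methods = methods, seed = seed,
              ascertainment = ascertainment, n_runs = n_runs,
              metrics = metrics, diagnostics = diags,
              summary = agg(metrics, "method"),
              diag_summary = {
                num <- names(diags)[vapply(diags, is.numeric, TRUE)]
                num <- setdiff(num, "run")
                data.frame(metric = num,
                           mean = vapply(diags[num], function(x)
                             mean(x, na.rm = TRUE), 0),
                           sem = vapply(diags[num], sem, 0),
                           row.names = NULL)
              })
  class(out) <- "calibration_report"
  out
}

# one simulation replicate; RNG state is set by the caller
simulate_run <- function(cond, methods, ascertainment,
                         n_tuning_cases, n_tuning_controls,
                         n_quantiles, p_causal) {
  K <- cond$K
  h2 <- cond$h2
  M <- cond$M
  prior <- cond$prior
  effects <- rnorm(M, 0, sqrt(h2 / M))
  freqs <- runif(M, 0.05, 0.5)

  if (ascertainment == "balanced") {
    n_train <- required_training_n(cond$r2_target, K, h2, M, P = 0.5)
    n_ca <- ceiling(n_train / 2)
    training <- simulate_ascertained(n_ca, n_train - n_ca, effects, freqs,
                                     h2, K)
    testing <- simulate_ascertained(cond$n_test_cases, cond$n_test_controls,
                                    effects, freqs, h2, K)
  } else {
    n_train <- required_training_n(cond$r2_target, K, h2, M, P = K)
    training <- simulate_population(n_train, effects, freqs, h2, K)
    testing <- simulate_population(cond$n_test_random, effects, freqs, h2, K)
    if (length(unique(training$status)) < 2 ||
        length(unique(testing$status)) < 2)
      stop("random-ascertainment draw produced a single-class sample; ",
           "increase the sample sizes")
  }

  ss <- gwas_obs5050(training)
  P_train <- attr(ss, "case_fraction")
  n <- attr(ss, "n")

  # posterior means on the 50/50 observed scale, then the liability scale
  post_5050 <- bpred_shrink(ss$beta_5050, n_eff = ss$n_eff[1],
                            h2 = h2_observed(h2, K, P = 0.5), M = M,
                            p_causal = p_causal)
  beta_l <- beta_liability(post_5050, K, p = 0.5)

  reference <- simulate_population(cond$n_reference, effects, freqs, h2, K)
  ref_pgs <- pgs_score(standardize_dosages(reference$dosages, freqs),
                       beta_l, standardized = TRUE)
  test_pgs <- pgs_score(standardize_dosages(testing$dosages, freqs),
                        beta_l, standardized = TRUE)
  y <- testing$status

  fit <- bpc(ref_pgs, K = K, prior = prior)

  tuning <- NULL
  if (any(methods %in% c("bpc_tuned", "logit_tuned"))) {
    tuning <- simulate_ascertained(n_tuning_cases, n_tuning_controls,
                                   effects, freqs, h2, K)
    tun_pgs <- pgs_score(standardize_dosages(tuning$dosages, freqs),
                         beta_l, standardized = TRUE)
  }

  rows <- list()
  for (m in methods) {
    p <- NULL
    if (m == "bpc") {
      p <- predict(fit, test_pgs)
    } else if (m == "pain") {
      p <- pain_probability(test_pgs, prior, fit$r2_liability, K,
                            reference_mean = mean(ref_pgs),
                            reference_sd = sd(ref_pgs),
                            n_quantiles = n_quantiles)
    } else if (m %in% c("pain_adjusted", "pain_adjusted_refvar")) {
      # in simulations the adjusted variant already uses the reference-panel
      # variance as its R2 source, so the two names share one computation
      p <- pain_probability(test_pgs, prior, fit$r2_liability, K,
                            reference_mean = mean(ref_pgs),
                            reference_sd = sd(ref_pgs),
                            n_quantiles = n_quantiles, adjusted = TRUE)
    } else if (m == "linear") {
      p <- linear_rescale(test_pgs, fit)
    } else if (m == "bpc_tuned") {
      p <- predict(bpc_tuned(tun_pgs, tuning$status, prior = prior, K = K),
                   test_pgs)
    } else if (m == "logit_tuned") {
      p <- logit_tuned(tun_pgs, tuning$status, test_pgs)
    } else if (m == "untransformed") {
      # PGS on the training sample's standardized observed scale, evaluated
      # against the testing status standardized the same way
      post_obs <- bpred_shrink(ss$z / sqrt(n), n_eff = n,
                               h2 = h2_observed(h2, K, P = P_train), M = M,
                               p_causal = p_causal)
      pgs_obs <- pgs_score(standardize_dosages(testing$dosages, freqs),
                           post_obs, standardized = TRUE)
      y_std <- (y - mean(y)) / sd(y)
      si <- calibration_slope_intercept(pgs_obs, y_std)
      rows[[m]] <- data.frame(method = m, ici = NA_real_,
                              slope = si["slope"],
                              intercept = si["intercept"],
                              auc = auc_empirical(pgs_obs, y),
                              row.names = NULL)
      next
    }
    si <- calibration_slope_intercept(p, y)
    rows[[m]] <- data.frame(method = m, ici = ici(p, y),
                            slope = si["slope"], intercept = si["intercept"],
                            auc = auc_empirical(p, y), row.names = NULL)
  }
  list(metrics = do.call(rbind, rows),
       diagnostics = data.frame(
         r2_reference = fit$r2_liability,
         r2_regression = r2_liability_regression(test_pgs, y, K),
         lr_sd = likelihood_ratio_sd(fit, test_pgs),
         n_training = n_train))
}

#' @export
print.calibration_report <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Calibration report: %d runs, %s ascertainment, seed %d\n",
    x$n_runs, x$ascertainment, x$seed))
  print(x$condition)
  s <- x$summary
  num <- vapply(s, is.numeric, TRUE)
  s[num] <- lapply(s[num], round, digits)
  print(s, row.names = FALSE)
  cat("Diagnostics (per-run means):\n")
  d <- x$diag_summary
  d$mean <- round(d$mean, digits)
  d$sem <- round(d$sem, digits)
  print(d, row.names = FALSE)
  invisible(x)
}

#' @importFrom stats aggregate
#' @export
summary.calibration_report <- function(object, ...) object$summary
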