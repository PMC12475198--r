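test_that("an uninformative PGS returns the prior", {
  fit <- bpc(K = 0.1, prior = 0.3, r2_liability = 0)
  pgs <- c(-1, 0, 0.5, 2)
  expect_equal(predict(fit, pgs), rep(0.3, 4))
  expect_equal(predict(fit, pgs, type = "likelihood_ratio"), rep(1, 4))
  expect_equal(likelihood_ratio_sd(fit, pgs), 0)
})

test_that("posterior is 0.5 at the equal-density point with an even prior", {
  fit <- bpc(K = 0.05, prior = 0.5, r2_liability = 0.08)
  m <- fit$moments
  x <- uniroot(function(x) dnorm(x, m$mu_case, sqrt(m$var_case)) -
                 dnorm(x, m$mu_control, sqrt(m$var_control)),
               c(m$mu_control, m$mu_case), tol = 1e-12)$root
  expect_equal(predict(fit, x), 0.5, tolerance = 1e-6)
})

test_that("posterior matches a hand evaluation of the two normal densities", {
  # moments for r2 = 0.05, K = 0.01, frozen from the integration oracle
  mu1 <- 0.13326071; v1 <- 0.04774212
  mu0 <- -0.00134607; v0 <- 0.04984162
  f1 <- dnorm(mu1, mu1, sqrt(v1))
  f0 <- dnorm(mu1, mu0, sqrt(v0))
  by_hand <- 0.5 * f1 / (0.5 * f1 + 0.5 * f0)
  fit <- bpc(K = 0.01, prior = 0.5, r2_liability = 0.05)
  expect_equal(predict(fit, mu1), by_hand, tolerance = 1e-6)
  expect_equal(by_hand, 0.5506, tolerance = 1e-3)
})

test_that("posterior is invariant to a common affine rescaling", {
  fit <- bpc(K = 0.02, prior = 0.4, r2_liability = 0.12)
  pgs <- seq(-0.8, 0.8, length.out = 41)
  a <- 3.7; b <- -0.9
  fit2 <- fit
  fit2$moments$mu_case <- a * fit$moments$mu_case + b
  fit2$moments$mu_control <- a * fit$moments$mu_control + b
  fit2$moments$var_case <- a^2 * fit$moments$var_case
  fit2$moments$var_control <- a^2 * fit$moments$var_control
  expect_equal(predict(fit2, a * pgs + b), predict(fit, pgs),
               tolerance = 1e-12)
})

test_that("the posterior averaged over the mixture equals the prior", {
  for (prior in c(0.25, 0.5, 0.75)) {
    fit <- bpc(K = 0.01, prior = prior, r2_liability = 0.1)
    m <- fit$moments
    mix <- function(x) prior * dnorm(x, m$mu_case, sqrt(m$var_case)) +
      (1 - prior) * dnorm(x, m$mu_control, sqrt(m$var_control))
    avg <- integrate(function(x) predict(fit, x) * mix(x), -Inf, Inf,
                     rel.tol = 1e-12)$value
    expect_equal(avg, prior, tolerance = 1e-8)
  }
})

test_that("reference-panel variance estimates the generating R2", {
  set.seed(21)
  ref <- rnorm(503, 0, sqrt(0.07))
  fit <- bpc(ref, K = 0.01, prior = 0.5)
  se <- 0.07 * sqrt(2 / 502)
  expect_lt(abs(fit$r2_liability - 0.07), 3 * se)
  expect_error(bpc(ref[1], K = 0.1), "at least 2")
  expect_error(bpc(K = 0.1), "reference_pgs or r2_liability")
})

test_that("tuned moments recover generating values and degrade gracefully", {
  set.seed(22)
  mu1 <- 0.3; s1 <- 0.2; mu0 <- -0.05; s0 <- 0.25
  n <- 1e5
  pgs <- c(rnorm(n, mu1, s1), rnorm(n, mu0, s0))
  status <- rep(1:0, each = n)
  fit <- bpc_tuned(pgs, status, prior = 0.5)
  expect_lt(abs(fit$moments$mu_case - mu1), 3 * s1 / sqrt(n))
  expect_lt(abs(fit$moments$var_case - s1^2), 3 * s1^2 * sqrt(2 / n))
  expect_lt(abs(fit$moments$mu_control - mu0), 3 * s0 / sqrt(n))

  # identical case/control distributions: posterior equals the prior
  same <- bpc_tuned(c(rnorm(5e4), rnorm(5e4)), rep(1:0, each = 5e4),
                    prior = 0.3)
  expect_equal(predict(same, seq(-2, 2, 0.5)), rep(0.3, 9), tolerance = 0.02)
  expect_error(bpc_tuned(rnorm(10), rep(1, 10), prior = 0.5), "2 cases")
})

test_that("theory-based and tuning-based conversions agree on shared data", {
  set.seed(23)
  K <- 0.05; r2 <- 0.1; prior <- 0.5
  theory <- bpc(K = K, prior = prior, r2_liability = r2)
  m <- theory$moments
  n <- 5e4
  tun_pgs <- c(rnorm(n, m$mu_case, sqrt(m$var_case)),
               rnorm(n, m$mu_control, sqrt(m$var_control)))
  tuned <- bpc_tuned(tun_pgs, rep(1:0, each = n), prior = prior)
  test_pgs <- tun_pgs[sample(2 * n, 2000)]
  expect_lt(mean(abs(predict(tuned, test_pgs) - predict(theory, test_pgs))),
            0.02)
})

test_that("linear rescaling centers on the prior and truncates extremes", {
  fit0 <- bpc(K = 0.1, prior = 0.4, r2_liability = 0)
  expect_equal(linear_rescale(c(-1, 0, 1), fit0), rep(0.4, 3))

  set.seed(24)
  K <- 0.01; r2 <- 0.15; prior <- 0.5
  fit <- bpc(K = K, prior = prior, r2_liability = r2)
  m <- fit$moments
  n <- 4000
  pgs <- c(rnorm(n, m$mu_case, sqrt(m$var_case)),
           rnorm(n, m$mu_control, sqrt(m$var_control)))
  raw <- linear_rescale(pgs, fit, truncate = FALSE)
  expect_equal(mean(raw), prior, tolerance = 0.02)
  cut <- linear_rescale(pgs, fit)
  expect_true(all(cut >= 0 & cut <= 1))
  # low prevalence and large R2 push a positive fraction outside [0, 1]
  expect_gt(mean(raw > 1 | raw < 0), 0)
})

test_that("logistic tuning recovers generating coefficients", {
  set.seed(25)
  a <- -0.5; b <- 2
  n <- 5e4
  pgs <- rnorm(n)
  status <- rbinom(n, 1, plogis(a + b * pgs))
  fit <- glm(status ~ pgs, family = binomial())
  # generating coefficients recovered within 3 standard errors
  se <- summary(fit)$coefficients[, "Std. Error"]
  expect_lt(abs(coef(fit)[1] - a), 3 * se[1])
  expect_lt(abs(coef(fit)[2] - b), 3 * se[2])
  # at the fitted 50% point the converted probability is exactly 0.5
  p50 <- -coef(fit)[1] / coef(fit)[2]
  expect_equal(logit_tuned(pgs, status, unname(p50)), 0.5, tolerance = 1e-10)
  # constant tuning PGS collapses to the case fraction
  expect_equal(logit_tuned(rep(1, 100), rep(0:1, 50), c(0, 5)),
               rep(0.5, 2), tolerance = 1e-6)
  expect_error(logit_tuned(c(rep(0, 50), rep(10, 50)), rep(0:1, each = 50),
                           1), "separation")
})

test_that("calibration-in-the-large holds when the prior matches the sample", {
  set.seed(26)
  K <- 0.05; r2 <- 0.1
  for (prior in c(0.25, 0.5)) {
    fit <- bpc(K = K, prior = prior, r2_liability = r2)
    m <- fit$moments
    n1 <- round(4000 * prior); n0 <- 4000 - n1
    pgs <- c(rnorm(n1, m$mu_case, sqrt(m$var_case)),
             rnorm(n0, m$mu_control, sqrt(m$var_control)))
    expect_equal(mean(predict(fit, pgs)), prior, tolerance = 0.02)
  }
})

test_that("print, summary, coef and plot methods run", {
  fit <- bpc(K = 0.01, prior = 0.5, r2_liability = 0.05)
  expect_output(print(fit), "prevalence K = 0.01")
  expect_output(print(summary(fit)), "implied AUC")
  expect_named(coef(fit), c("mu_case", "var_case", "mu_control",
                            "var_control", "prior", "r2_liability"))
  tf <- tempfile(fileext = ".pdf")
  grDevices::pdf(tf)
  expect_invisible(plot(fit))
  grDevices::dev.off()
  expect_true(file.exists(tf))
})
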