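test_that("population cohorts recover prevalence, liability variance and h2", {
  set.seed(11)
  M <- 300; h2 <- 0.2
  eff <- rnorm(M, 0, sqrt(h2 / M))
  fr <- runif(M, 0.05, 0.5)
  pop <- simulate_population(2e4, eff, fr, h2, K = 0.5)
  expect_lt(abs(mean(pop$status) - 0.5), 3 * 0.5 / sqrt(2e4))
  expect_lt(abs(var(pop$liability) - 1), 0.03)
  g <- drop(sweep(sweep(pop$dosages + 0, 2, 2 * fr), 2,
                  sqrt(2 * fr * (1 - fr)), "/") %*% eff)
  expect_lt(abs(var(g) - sum(eff^2)), 0.01)

  pop2 <- simulate_population(3000, eff, fr, h2, K = 0.05)
  expect_lt(abs(mean(pop2$status) - 0.05), 3 * sqrt(0.05 * 0.95 / 3000))
  expect_error(simulate_population(0, eff, fr, h2, 0.1), "positive")
})

test_that("null-model GWAS z-scores are standard normal", {
  set.seed(12)
  M <- 400
  eff <- rep(0, M)
  fr <- runif(M, 0.1, 0.5)
  pop <- simulate_population(4000, eff, fr, h2 = 0, K = 0.3)
  ss <- gwas_obs5050(pop)
  expect_gt(stats::ks.test(ss$z, "pnorm")$p.value, 0.001)
  expect_equal(mean(ss$z), 0, tolerance = 3 / sqrt(M))
  expect_equal(var(ss$z), 1, tolerance = 0.2)
})

test_that("conditional ascertained sampler agrees with rejection sampling", {
  set.seed(13)
  M <- 80; h2 <- 0.2; K <- 0.2
  eff <- rnorm(M, 0, sqrt(h2 / M))
  fr <- runif(M, 0.05, 0.5)
  n <- 12000
  fast <- simulate_ascertained(n, 0, eff, fr, h2, K)
  slow <- oracle_ascertained(n, eff, fr, h2, K, case = TRUE)
  sc <- function(X) sweep(sweep(X + 0, 2, 2 * fr), 2,
                          sqrt(2 * fr * (1 - fr)), "/")
  g_fast <- drop(sc(fast$dosages) %*% eff)
  g_slow <- drop(sc(slow$dosages) %*% eff)
  # genetic-score distribution among cases
  se_m <- sd(g_slow) / sqrt(n)
  expect_lt(abs(mean(g_fast) - mean(g_slow)), 4 * sqrt(2) * se_m)
  expect_lt(abs(var(g_fast) - var(g_slow)), 0.1 * var(g_slow))
  expect_lt(abs(mean(fast$liability) - mean(slow$liability)), 0.03)
  # per-SNP case allele frequencies
  expect_lt(max(abs(colMeans(fast$dosages) - colMeans(slow$dosages))), 0.05)
  # all cases really are above the threshold
  expect_true(all(fast$liability > qnorm(1 - K)))
  expect_true(all(fast$status == 1L))

  ctrl <- simulate_ascertained(0, 500, eff, fr, h2, K)
  expect_true(all(ctrl$liability <= qnorm(1 - K)))
  expect_true(all(ctrl$status == 0L))
})

test_that("ascertainment returns exact counts and preserves pairings", {
  set.seed(14)
  eff <- rnorm(50, 0, sqrt(0.2 / 50)); fr <- runif(50, 0.1, 0.5)
  pop <- simulate_population(4000, eff, fr, 0.2, K = 0.3)
  asc <- ascertain(pop, 300, 100)
  expect_equal(sum(asc$status), 300)
  expect_equal(sum(1 - asc$status), 100)
  expect_equal(mean(asc$status), 0.75)
  t <- qnorm(1 - 0.3)
  expect_true(all((asc$liability > t) == (asc$status == 1L)))
  expect_error(ascertain(pop, 4000, 100), "available")

  both <- simulate_ascertained(250, 750, eff, fr, 0.2, 0.3)
  expect_equal(mean(both$status), 0.25)
})

test_that("GWAS is deterministic and recovers single-SNP effects", {
  set.seed(15)
  eff <- c(0.4, rep(0, 9))
  fr <- rep(0.3, 10)
  coh <- simulate_ascertained(2000, 2000, eff, fr, h2 = 0.2, K = 0.2)
  ss1 <- gwas_obs5050(coh)
  ss2 <- gwas_obs5050(coh)
  expect_identical(ss1, ss2)
  # z^2 / n equals the observed-scale R2 of an OLS of status on genotype
  r2_ols <- summary(lm(coh$status ~ coh$dosages[, 1]))$r.squared
  expect_equal(ss1$z[1]^2 / attr(ss1, "n"), r2_ols, tolerance = 1e-10)
  expect_equal(ss1$n_eff[1], 4000)

  coh$dosages[, 2] <- 1L # monomorphic
  expect_warning(ss3 <- gwas_obs5050(coh), "monomorphic")
  expect_equal(ss3$z[2], 0)
})

test_that("training-size solver hits the published worked example", {
  expect_equal(required_training_n(0.10, K = 0.01, h2 = 0.2, M = 1000), 2759L)
  # monotone in the target and diverging towards h2
  ns <- vapply(c(0.01, 0.05, 0.1, 0.15, 0.19, 0.199),
               required_training_n, 0L, K = 0.01, h2 = 0.2, M = 1000)
  expect_true(all(diff(ns) > 0))
  expect_gt(ns[6], 50 * ns[1])
  expect_error(required_training_n(0.25, K = 0.01, h2 = 0.2), "below h2")
  # solving then evaluating the expectation recovers the target
  for (K in c(0.01, 0.15)) {
    n <- required_training_n(0.05, K = K, h2 = 0.2, M = 1000)
    expect_equal(expected_r2_liability(n, K, 0.2, 1000), 0.05,
                 tolerance = 0.001)
  }
})

test_that("solver-sized training samples realize the target R2 in simulation", {
  cond <- sim_condition(K = 0.15, r2_target = 0.05, n_runs = 12)
  rep <- run_condition(cond, methods = "bpc", seed = 99)
  r2_real <- mean(rep$diagnostics$r2_regression)
  expect_equal(r2_real, 0.05, tolerance = 0.015)
})

test_that("reports are bit-reproducible under a fixed seed", {
  cond <- sim_condition(K = 0.15, r2_target = 0.04, M = 200,
                        n_test_cases = 200, n_test_controls = 200,
                        n_reference = 100, n_runs = 2)
  a <- run_condition(cond, methods = c("bpc", "pain"), seed = 5)
  b <- run_condition(cond, methods = c("bpc", "pain"), seed = 5)
  expect_identical(a$metrics, b$metrics)
  expect_identical(a$diagnostics, b$diagnostics)
  c <- run_condition(cond, methods = c("bpc", "pain"), seed = 6)
  expect_false(identical(a$metrics, c$metrics))
})
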