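test_that("liability threshold and density height match the normal law", {
  lt <- liability_threshold(0.5)
  expect_equal(lt$threshold, 0)
  expect_equal(lt$density, dnorm(0))

  lt <- liability_threshold(0.01)
  expect_equal(lt$threshold, 2.3263, tolerance = 1e-4)
  expect_equal(lt$density, 0.026652, tolerance = 1e-4)

  expect_equal(liability_threshold(0.15)$threshold, 1.0364, tolerance = 1e-4)

  expect_error(liability_threshold(0), "inside \\(0, 1\\)")
  expect_error(liability_threshold(1.2), "inside \\(0, 1\\)")
})

test_that("observed-to-liability effect conversion is the documented scalar", {
  expect_identical(beta_liability(0, K = 0.3), 0)
  # K = 0.5: 0.25 / (dnorm(0) * 0.5)
  expect_equal(beta_liability(1, K = 0.5), 1.253314, tolerance = 1e-6)
  expect_equal(beta_liability(1, K = 0.01), 0.742905, tolerance = 1e-6)
  # linear and order preserving
  b <- c(-0.2, 0, 0.1, 0.3)
  out <- beta_liability(b, K = 0.1)
  expect_equal(out, b * beta_liability(1, K = 0.1))
  expect_true(all(diff(out) > 0))
  # factor positive and continuous in K
  Ks <- seq(0.001, 0.999, length.out = 4000)
  f <- vapply(Ks, function(K) beta_liability(1, K), 0)
  expect_true(all(f > 0))
  # no jumps: successive differences shrink in proportion to the grid step
  expect_lt(max(abs(diff(f))), 0.05)
  f2 <- vapply(seq(0.001, 0.999, length.out = 8000),
               function(K) beta_liability(1, K), 0)
  expect_lt(max(abs(diff(f2))), max(abs(diff(f))) * 0.6)
})

test_that("Lee R2 conversion round-trips and matches simulation", {
  for (K in c(0.001, 0.01, 0.15, 0.5))
    for (P in c(0.25, 0.5, 0.75))
      for (r2 in c(0, 0.01, 0.1, 0.4)) {
        r2o <- r2_liability_to_observed(r2, K, P)
        expect_equal(r2_observed_to_liability(r2o, K, P), r2,
                     tolerance = 1e-10)
      }
  expect_equal(r2_liability_to_observed(0, 0.05, 0.3), 0)

  # simulation oracle: ascertained linear regression of status on a normal
  # score carrying liability R2 = 0.10
  set.seed(101)
  K <- 0.01; r2 <- 0.10
  n <- 4e5
  L <- rnorm(n)
  pgs <- r2 * L + rnorm(n, 0, sqrt(r2 - r2^2))
  y <- as.integer(L > qnorm(1 - K))
  ca <- which(y == 1)
  co <- sample(which(y == 0), length(ca))
  idx <- c(ca, co)
  r2o_sim <- cor(pgs[idx], y[idx])^2
  expect_equal(r2_liability_to_observed(r2, K, P = 0.5), r2o_sim,
               tolerance = 0.03)
})

test_that("case/control PGS moments equal the numerical-integration oracle", {
  for (K in c(0.001, 0.01, 0.15, 0.5))
    for (r2 in c(0.01, 0.05, 0.15, 0.6)) {
      m <- casecontrol_moments(r2, K)
      o <- oracle_moments(r2, K)
      expect_equal(m$mu_case, unname(o$mu_case), tolerance = 1e-8)
      expect_equal(m$var_case, unname(o$var_case), tolerance = 1e-8)
      expect_equal(m$mu_control, unname(o$mu_control), tolerance = 1e-8)
      expect_equal(m$var_control, unname(o$var_control), tolerance = 1e-8)
      # population mixture has mean 0 and total variance r2
      expect_equal(K * m$mu_case + (1 - K) * m$mu_control, 0,
                   tolerance = 1e-10)
      mix_var <- K * (m$var_case + m$mu_case^2) +
        (1 - K) * (m$var_control + m$mu_control^2) -
        (K * m$mu_case + (1 - K) * m$mu_control)^2
      expect_equal(mix_var, r2, tolerance = 1e-8)
      if (K < 0.5) expect_lt(m$var_case, m$var_control)
    }
})

test_that("moment formulas reproduce frozen spot values and symmetries", {
  m <- casecontrol_moments(0.05, K = 0.01)
  expect_equal(m$mu_case, 0.1333, tolerance = 1e-3)
  expect_equal(m$var_case, 0.04774, tolerance = 1e-4)

  m <- casecontrol_moments(0.2, K = 0.5)
  expect_equal(m$mu_case, -m$mu_control)
  expect_equal(m$var_case, m$var_control)

  m <- casecontrol_moments(0, K = 0.1)
  expect_equal(unlist(m[c("mu_case", "var_case", "mu_control",
                          "var_control")]),
               c(mu_case = 0, var_case = 0, mu_control = 0, var_control = 0))
  expect_error(casecontrol_moments(1.2, K = 0.1), "\\[0, 1\\]")
})

test_that("R2-to-AUC conversion matches Monte Carlo and is monotone", {
  expect_equal(auc_from_r2(0, K = 0.2), 0.5)
  aucs <- vapply(c(0.01, 0.05, 0.1, 0.2, 0.4), auc_from_r2, 0, K = 0.15)
  expect_true(all(diff(aucs) > 0))
  expect_true(all(aucs > 0.5 & aucs < 1))

  set.seed(7)
  m <- casecontrol_moments(0.10, K = 0.15)
  s1 <- rnorm(2e5, m$mu_case, sqrt(m$var_case))
  s0 <- rnorm(2e5, m$mu_control, sqrt(m$var_control))
  emp <- mean(outer(s1[1:400], s0[1:400], ">")) # coarse pair estimate
  expect_equal(auc_from_r2(0.10, K = 0.15),
               auc_empirical(c(s1, s0), rep(1:0, each = 2e5)),
               tolerance = 0.005)
  expect_equal(auc_from_r2(0.10, K = 0.15), emp, tolerance = 0.05)
})
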