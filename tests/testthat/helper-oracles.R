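# Independent oracles used across the test files. These deliberately avoid
# the package's own closed forms: moments come from 1-D numerical
# integration over the liability, posterior means from quadrature over the
# point-normal prior, and ascertained cohorts from brute-force rejection
# sampling.

# E and Var of the PGS given status by integrating over the liability:
# PGS | L ~ N(r2 * L, r2 - r2^2), L ~ N(0, 1), case = {L > t}.
oracle_moments <- function(r2, K) {
  t <- qnorm(1 - K)
  mom <- function(lower, upper, mass) {
    m <- integrate(function(L) r2 * L * dnorm(L), lower, upper,
                   rel.tol = 1e-12, abs.tol = 1e-14)$value / mass
    s <- integrate(function(L) ((r2 - r2^2) + (r2 * L)^2) * dnorm(L),
                   lower, upper, rel.tol = 1e-12, abs.tol = 1e-14)$value / mass
    c(mean = m, var = s - m^2)
  }
  ca <- mom(t, Inf, K)
  co <- mom(-Inf, t, 1 - K)
  list(mu_case = ca["mean"], var_case = ca["var"],
       mu_control = co["mean"], var_control = co["var"])
}

# posterior mean under the point-normal prior by quadrature
oracle_bpred <- function(beta_hat, n_eff, h2, M, p_causal) {
  s2c <- h2 / (M * p_causal)
  s2e <- 1 / n_eff
  vapply(beta_hat, function(b) {
    num <- p_causal * integrate(function(beta)
      beta * dnorm(b, beta, sqrt(s2e)) * dnorm(beta, 0, sqrt(s2c)),
      -Inf, Inf, rel.tol = 1e-10, abs.tol = 1e-14)$value
    den <- p_causal * dnorm(b, 0, sqrt(s2c + s2e)) +
      (1 - p_causal) * dnorm(b, 0, sqrt(s2e))
    num / den
  }, 0)
}

# brute-force rejection sampling of an ascertained cohort
oracle_ascertained <- function(n_keep, effects, freqs, h2, K, case = TRUE,
                               block = 20000L) {
  t <- qnorm(1 - K)
  M <- length(effects)
  dos <- list(); liab <- c()
  got <- 0L
  while (got < n_keep) {
    X <- matrix(rbinom(block * M, 2L, rep(freqs, each = block)), block, M)
    Xs <- sweep(sweep(X + 0, 2, 2 * freqs), 2, sqrt(2 * freqs * (1 - freqs)), "/")
    L <- drop(Xs %*% effects) + rnorm(block, 0, sqrt(1 - h2))
    keep <- if (case) which(L > t) else which(L <= t)
    keep <- keep[seq_len(min(length(keep), n_keep - got))]
    dos[[length(dos) + 1]] <- X[keep, , drop = FALSE]
    liab <- c(liab, L[keep])
    got <- got + length(keep)
  }
  list(dosages = do.call(rbind, dos), liability = liab)
}

# grid used for the main simulation study
grid_conditions <- function(n_runs, ...) {
  out <- list()
  for (K in c(0.01, 0.15))
    for (r2 in c(0.01, 0.05, 0.10, 0.15))
      out[[sprintf("K%g_r2%g", K, r2)]] <-
        sim_condition(K = K, r2_target = r2, n_runs = n_runs, ...)
  out
}
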