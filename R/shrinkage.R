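#' Effective sample size of a case/control GWAS meta-analysis
#'
#' Sums the per-cohort effective sample sizes
#' `N_eff = 4 / (1/N_case + 1/N_control)` over all cohorts contributing to
#' a meta-analysis. For a balanced cohort this equals the total sample
#' size.
#'
#' @param case_counts,control_counts Integer vectors of per-cohort case and
#'   control counts (equal length, all positive).
#' @return Total effective sample size (numeric scalar).
#' @examples
#' neff_from_cohorts(1000, 3000)                 # 3000
#' neff_from_cohorts(c(1000, 1000), c(1000, 3000)) # 5000
#' @export
neff_from_cohorts <- function(case_counts, control_counts) {
  if (length(case_counts) == 0L || length(control_counts) == 0L)
    stop("case_counts and control_counts must be non-empty")
  stopifnot(length(case_counts) == length(control_counts),
            all(case_counts > 0), all(control_counts > 0))
  sum(4 / (1 / case_counts + 1 / control_counts))
}

#' Analytic per-SNP effective sample size from allele frequency and SE
#'
#' Computes `N_eff = 4 / (2 AF (1 - AF) SE^2)` per SNP and returns a
#' quantile across SNPs (the 90th percentile by default, because the
#' analytic formula can produce large outliers).
#'
#' @param af Effect-allele frequencies, strictly inside (0, 1).
#' @param se Standard errors of the per-SNP effect estimates (positive).
#' @param quantile Quantile across SNPs to report (default 0.9). Computed
#'   with the default linear-interpolation quantile definition
#'   (`type = 7`); pass `quantile_type` to change it.
#' @param quantile_type Passed to [stats::quantile()] (default 7).
#' @return The requested quantile of the per-SNP `N_eff` values.
#' @export
neff_analytic <- function(af, se, quantile = 0.9, quantile_type = 7) {
  if (any(af <= 0 | af >= 1)) stop("allele frequencies must be inside (0, 1)")
  if (any(se <= 0)) stop("standard errors must be positive")
  n <- 4 / (2 * af * (1 - af) * se^2)
  unname(stats::quantile(n, probs = quantile, type = quantile_type))
}

#' Posterior-mean effect sizes under a point-normal prior in linkage
#' equilibrium
#'
#' Closed-form per-SNP posterior means for marginal GWAS effects on the
#' standardized observed scale, assuming `M` independent SNPs of which a
#' fraction `p_causal` are causal with effects drawn from
#' `N(0, h2 / (M p_causal))`, and sampling noise `N(0, 1/N_eff)`:
#' \deqn{E[\beta | \hat\beta] = \bar p_j \cdot
#'   \frac{h2/p}{h2/p + M/N_{eff}} \hat\beta_j}
#' where `p_j` is the per-SNP posterior probability of being causal. With
#' `p_causal = 1` this is the infinitesimal shrinkage
#' `h2 / (h2 + M/N_eff)` applied uniformly. `h2` must be on the same scale
#' as the betas (for 50/50 observed-scale betas, supply the observed-scale
#' heritability).
#'
#' @param beta Numeric vector of marginal effect estimates (standardized
#'   observed scale).
#' @param n_eff Effective GWAS sample size.
#' @param h2 Heritability captured by the `M` SNPs, on the betas' scale.
#' @param M Number of SNPs (defaults to `length(beta)`).
#' @param p_causal Prior fraction of causal SNPs, in (0, 1].
#' @return Numeric vector of posterior-mean effects (same scale).
#' @examples
#' bpred_shrink(rep(0.01, 5), n_eff = 4000, h2 = 0.2, M = 1000)
#' @export
bpred_shrink <- function(beta, n_eff, h2, M = length(beta), p_causal = 1) {
  if (h2 <= 0) stop("h2 must be positive")
  stopifnot(n_eff > 0, M > 0, p_causal > 0, p_causal <= 1)
  s2c <- h2 / (M * p_causal)  # causal effect variance
  s2e <- 1 / n_eff            # sampling variance
  shrink <- s2c / (s2c + s2e)
  if (p_causal == 1) return(shrink * beta)
  num <- p_causal * dnorm(beta, 0, sqrt(s2c + s2e))
  den <- num + (1 - p_causal) * dnorm(beta, 0, sqrt(s2e))
  pbar <- ifelse(den > 0, num / den, 0)
  pbar * shrink * beta
}

#' Score individuals from a dosage matrix
#'
#' Computes per-individual polygenic scores with centered-sum semantics:
#' `PGS_i = sum_j beta_j (g_ij - 2 f_j)` for raw allele-count dosages, or
#' `PGS_i = sum_j beta_j g_ij` when `standardized = TRUE` (dosages already
#' centered/scaled). When both the dosage columns and the betas are named,
#' they are aligned by SNP id and any mismatch is an error.
#'
#' @param dosages N x M matrix of allele counts in `[0, 2]` (or
#'   standardized genotypes).
#' @param betas Per-SNP effects; optionally named by SNP id.
#' @param freqs Per-SNP effect-allele frequencies used for centering
#'   (required unless `standardized = TRUE`).
#' @param standardized If `TRUE`, `dosages` are used as-is.
#' @return Numeric vector of per-individual scores.
#' @examples
#' pgs_score(matrix(c(2, 0), 1), betas = c(1, 1), freqs = c(0.5, 0.5)) # 0
#' @export
pgs_score <- function(dosages, betas, freqs = NULL, standardized = FALSE) {
  dosages <- as.matrix(dosages)
  if (!is.null(colnames(dosages)) && !is.null(names(betas))) {
    missing_in_dos <- setdiff(names(betas), colnames(dosages))
    missing_in_bet <- setdiff(colnames(dosages), names(betas))
    if (length(missing_in_dos) || length(missing_in_bet))
      stop("SNP sets are misaligned; offending ids: ",
           paste(unique(c(missing_in_dos, missing_in_bet)), collapse = ", "))
    dosages <- dosages[, names(betas), drop = FALSE]
  }
  if (ncol(dosages) != length(betas))
    stop("number of dosage columns must equal number of betas")
  if (standardized) return(drop(dosages %*% betas))
  if (is.null(freqs)) stop("freqs is required for raw dosages")
  if (length(freqs) != length(betas))
    stop("freqs must have one entry per SNP")
  drop(dosages %*% betas) - sum(betas * 2 * freqs)
}

# standardize allele counts to mean 0, variance 1 under HWE frequencies
standardize_dosages <- function(dosages, freqs) {
  sweep(sweep(as.matrix(dosages) + 0.0, 2, 2 * freqs),
        2, sqrt(2 * freqs * (1 - freqs)), "/")
}

#' Read and write GWAS summary statistics
#'
#' Whitespace- or tab-delimited text with a header. Column names are
#' matched case-insensitively against common aliases: SNP/ID/RSID (snp),
#' A1/EA/EFFECT_ALLELE (a1), A2/OA/OTHER_ALLELE (a2), Z/ZSCORE (z),
#' BETA/B (beta), SE (se), FRQ/AF/FREQ/MAF (af), N_EFF/NEFF (n_eff),
#' CHR (chr), BP/POS (pos), INFO (info). `write_sumstats()` emits
#' tab-delimited text with the canonical lower-case names.
#'
#' @param path File path.
#' @param x Data frame of summary statistics.
#' @return `read_sumstats()` returns a data frame with canonical column
#'   names; unrecognized columns are kept as-is.
#' @export
read_sumstats <- function(path) {
  x <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                         check.names = FALSE)
  names(x) <- canonical_sumstat_names(names(x))
  if (!is.null(x$z) && !is.null(x$n_eff) && is.null(x$beta_5050))
    x$beta_5050 <- x$z / sqrt(x$n_eff)
  x
}

#' @rdname read_sumstats
#' @export
write_sumstats <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

canonical_sumstat_names <- function(nm) {
  aliases <- list(
    snp = c("snp", "id", "rsid", "variant_id", "markername"),
    a1 = c("a1", "ea", "effect_allele", "allele1"),
    a2 = c("a2", "oa", "other_allele", "allele2"),
    z = c("z", "zscore", "z_score"),
    beta = c("beta", "b", "effect"),
    se = c("se", "stderr"),
    af = c("frq", "af", "freq", "eaf", "maf"),
    n_eff = c("n_eff", "neff"),
    chr = c("chr", "chromosome"),
    pos = c("bp", "pos", "position"),
    info = c("info", "imputation_info")
  )
  low <- tolower(nm)
  for (canon in names(aliases)) {
    hit <- which(low %in% aliases[[canon]])
    if (length(hit)) nm[hit[1]] <- canon
  }
  nm
}
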