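---
title: "Converting polygenic scores to calibrated disorder probabilities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Converting polygenic scores to calibrated disorder probabilities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bpc)
```

## The problem

A polygenic score (PGS) for a binary disorder is a weighted sum of allele
dosages whose weights come from a case/control GWAS. Scores rank people
well, but clinical use needs an absolute statement: *given this score and
this person's context, how likely is the disorder?* Two obstacles stand in
the way. First, GWAS effect sizes live on an observed 0/1 scale that
depends on the case fraction of the discovery sample; a score built from
them has an arbitrary scale. Second, the people to whom such a conversion
is applied are rarely a random population draw — help-seeking individuals
carry a prior risk well above the lifetime prevalence — and
ascertainment changes both the mean and the variance of the score
distribution in the target group.

The package implements a Bayesian conversion that handles both issues
with closed-form liability-threshold theory, requiring no tuning sample
with phenotypes, together with the comparator methods and the simulation
and evaluation machinery used to validate it.

## Model and assumptions

The liability threshold model posits a latent liability
$L \sim N(0, 1)$ with the disorder occurring when $L > T = \Phi^{-1}(1-K)$,
where $K$ is the population lifetime prevalence and $z = \varphi(T)$ the
normal density height at the threshold. The conversion assumes:

* the PGS, after conversion to the liability scale, is *well-calibrated*:
  regressing liability on the PGS has slope 1. Bayesian posterior-mean
  effect sizes have this property, which is why the pipeline starts from
  them;
* PGS and liability are bivariate normal — hence the PGS is normal within
  cases and within controls. This fails for scores dominated by a few
  large-effect common variants (e.g. APOE in Alzheimer's disease); such
  variants should be removed before conversion;
* effect sizes are age-independent, and the prior is not informed by
  variables correlated with the PGS (family history cannot be folded into
  the prior without also changing the explained variance).

The four steps:

1. **Scale.** GWAS effects are taken as $\beta_{50/50} = z_j/\sqrt{N_{eff}}$
   — the standardized observed scale of a balanced case/control design —
   and shrunk to posterior means. `bpred_shrink()` provides the
   linkage-equilibrium point-normal posterior mean; with causal fraction 1
   it reduces to the infinitesimal factor $h^2/(h^2 + M/N_{eff})$, where
   $h^2$ must be on the same observed scale as the betas
   (`h2_observed()`).
2. **Liability scale.** $\beta_{liability} = \beta_{50/50} \cdot
   K(1-K)/(z\,p)$ with $p = 0.5$; for a GWAS standardized at case
   fraction $P$ the same formula applies with $p = \sqrt{P(1-P)}$.
3. **Score distributions.** Since a well-calibrated liability-scale PGS
   satisfies $R^2_{liability} = \mathrm{var}(PGS)$, the variance of the
   score in an ancestry-matched population reference panel estimates
   $R^2_{liability}$ without phenotypes ($n-1$ denominator; at the usual
   panel size of ~500 the choice of denominator is immaterial).
   Truncated bivariate-normal theory then yields the exact conditional
   moments, implemented in `casecontrol_moments()`:
   $\mu_{case} = R^2 z/K$,
   $\sigma^2_{case} = R^2(1 - R^2 (z/K)(z/K - T))$,
   $\mu_{ctrl} = -R^2 z/(1-K)$,
   $\sigma^2_{ctrl} = R^2(1 - R^2 (z/(1-K))(z/(1-K) + T))$.
   These formulas are certified against numerical integration of the
   truncated bivariate normal in the test suite (tolerance 1e-8) rather
   than transcribed from anywhere; the case variance is strictly below
   the control variance for $K < 0.5$, a second-order effect the Bayes
   update exploits and equal-variance comparators miss.
4. **Bayes.** The posterior
   $P(case \mid PGS) = prior \cdot f_1 / (prior \cdot f_1 + (1-prior) f_0)$
   is evaluated in log space so that extreme scores stay numerically
   finite. Averaged over the prior-weighted mixture the posterior equals
   the prior exactly (law of total probability; tested by quadrature).

## Parameters that matter

* `K` — lifetime prevalence, in (0, 1). Drives the threshold, all scale
  conversions, and the case/control moment asymmetry.
* `prior` — disorder probability before seeing the score; the case mix of
  the target context, often far above `K`. Misspecifying the prior shifts
  all posteriors; a vector of per-individual priors (age/sex strata) is
  accepted by `predict.bpc()`.
* `r2_liability` — explained liability variance; estimated from the
  reference panel by default. Everything degrades gracefully to
  "posterior = prior" as it approaches 0.
* `n_quantiles` (comparators) — 1000 by default; the quantile
  discretization converges to the continuous equal-variance Bayes rule,
  and a `continuous = TRUE` flag provides the limit directly.
* `p_causal` (`bpred_shrink()`) — prior causal fraction; default 1
  (infinitesimal). The point-normal path is quadrature-tested but the
  simulation study does not depend on it, and the discovery-GWAS causal
  fraction is rarely known in practice.

## The simulator

`run_condition()` reproduces a desk-scale calibration study: per
replicate it draws `M = 1000` linkage-equilibrium SNPs (allele
frequencies uniform on 0.05–0.5, a deliberate choice matching a 10%
MAF-filtered analysis while still exercising frequency variation; effects
$N(0, h^2/M)$ on the standardized-genotype scale so the frequency
distribution does not alter per-SNP variance), simulates a 50/50
case/control training GWAS of the size returned by
`required_training_n()`, a population reference panel (N = 503), and an
ascertained testing sample (1000/1000 by default), then converts and
evaluates. One master seed drives deterministic per-run child seeds, so
every report is bit-reproducible.

**Training-size solver.** The expected liability-scale $R^2$ of a PGS
built from marginal effects on $M$ independent SNPs estimated in $n$
individuals at case fraction $P$ is
$R^2(n) = h^2 h^2_{obs} / (h^2_{obs} + M (1 - h^2_{obs}/M)/n)$ with
$h^2_{obs} = h^2 z^2 P(1-P)/(K(1-K))^2$; the solver returns the smallest
integer $n$ reaching the target (2759 for a target of 0.10 at
$K = 0.01$, $h^2 = 0.2$, $M = 1000$). The $(1 - h^2_{obs}/M)$ term is the
residual phenotypic variance left to each SNP; simulation confirms the
realized $R^2$ within ±0.015 of the target.

**Ascertained sampling.** Drawing 1000 cases at $K = 0.01$ by rejection
costs ~100× oversampling of full genotype matrices. Cohorts of fixed
case/control counts are instead drawn by a sequential conditional
sampler: genotypes are sampled SNP by SNP from
$P(g_j \mid g_{1..j-1}, status)$, treating the liability contribution of
the not-yet-sampled SNPs plus the non-genetic residual as a normal
remainder whose variance is tracked exactly, and the residual is finally
drawn from the exact truncated normal. The only approximation is the
normal shape of the genotype part of the remainder — excellent for
hundreds of small-effect SNPs, and dominated by the exactly-normal
residual ($1 - h^2 = 0.8$). The inner loop is C++ with an interpolated
normal-CDF table (absolute error < 3e-8). The sampler is validated
against brute-force rejection sampling in the test suite, and
`ascertain()` still provides the rejection path for population cohorts.

**Random-ascertainment experiment.** Untransformed observed-scale PGSs
are themselves calibrated (slope 1) only when neither training nor
testing is enriched for cases. At $K = 0.01$ and a target $R^2$ of 0.15
this requires a training sample of ~209,000; since the PGS $R^2$ depends
on $M/N$, the package runs this condition at $M = 100$ with $N$ re-solved
(~20,900) and a testing sample of 20,000 population draws — the same
condition at a tractable genotype volume.

**What the simulator does not emulate:** linkage disequilibrium (scores
aggregate SNP effects, so LD does not change the PGS scale, but
LD-induced correlation between estimated effects is absent), covariates
and age structure, allele-frequency mismatch between GWAS and target
ancestry, imputation error, and lassosum-style $R^2$ estimation noise in
the comparator (the quantile comparator receives the reference-panel
variance as its $R^2$ input). Passing simulations therefore demonstrate
the scale conversions and the probability update, not robustness to
those real-data complications.

## Evaluation metrics

The Integrated Calibration Index smooths the outcome on the predicted
probability with R's `loess` (span 0.75, degree 2 — the `loess`
defaults; both are arguments and a grid-averaged variant exists as a
sensitivity check) and averages the absolute difference between the
smoothed observed rate and the prediction over the observations, i.e.
weighted by the density of the predictions. Constant predictions fall
back to comparison with the outcome mean, with a warning. With 2000
testing individuals the smoother itself contributes an ICI noise floor
of roughly 0.01–0.02, which is why even a perfectly calibrated method
does not reach 0. Calibration slope and intercept come from OLS of the
outcome on the prediction — evaluated on probabilities for converted
methods and on the raw score (against standardized status) for the
untransformed method. AUC is the Mann–Whitney statistic with half-weight
ties; because all conversions here are monotone, every method shares the
AUC of the underlying score.

The regression-based $R^2_{liability}$ used to validate the
reference-panel estimator converts the observed-scale OLS $R^2$ with the
ascertainment-corrected Lee et al. transformation
(`r2_observed_to_liability()`), whose forward and inverse forms
round-trip to 1e-10.

## Numerical and design choices

* Quantile midpoints for the comparator are taken in probability space
  (midpoint of each quantile of the assumed mixture CDF, inverted on an
  8192-point grid); individuals are assigned by the mixture CDF of their
  Z-value. Convergence to the continuous rule is the correctness anchor,
  since the original method's binning convention is not fully specified.
* The linear rescaling truncates to [0, 1] *after* the probabilities are
  formed, and the truncation is applied before evaluation — outputs
  outside the unit interval are a documented weakness of that approach,
  most frequent at low prevalence and high $R^2$.
* `logit_tuned()` refuses (near-)separated tuning samples (unbounded
  slope) and collapses to the tuning case fraction for constant scores.
* Degenerate inputs: `r2_liability = 0` yields "posterior = prior"
  everywhere by construction; monomorphic SNPs get `z = 0` with a
  warning; harmonization errors out when no SNP survives.
* Duplicate SNP ids keep the first occurrence; strand-ambiguous SNPs are
  always dropped rather than frequency-inferred; the MHC exclusion window
  is hg19 chr6:28,000,000–34,000,000, 1-based inclusive.
* Test-suite and acceptance problem sizes: the full grid runs 100
  replicates per condition in the acceptance script, while the test suite
  uses 40 (grid) and 30 (single-condition checks) replicates with
  tolerance bands that carry an explicit three-standard-error sampling
  allowance.

## Known limitations

Calibration inherits every upstream misspecification: a wrong `N_eff`, a
wrong prevalence, or a prior that does not match the target context all
shift the posteriors (a prior off by 0.25 is far more damaging than any
approximation in the conversion itself). The approach applies to
polygenic architectures only; scores with outlying large-effect variants
violate the normality assumption. Ancestry mismatch between GWAS,
reference panel and target individual is not modelled. Probabilities are
lifetime risks, not age-conditional hazards.
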