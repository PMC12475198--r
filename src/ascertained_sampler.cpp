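#include <Rcpp.h>
using namespace Rcpp;

// Piecewise-linear interpolation table for the standard normal CDF.
// Grid step 1e-3 on [-8.5, 8.5] keeps the absolute interpolation error
// below ~3e-8, far inside the Monte Carlo noise of any cohort draw.
namespace {
struct PhiTable {
  std::vector<double> y;
  double lo, step;
  PhiTable(double lo_ = -8.5, double hi = 8.5, int n = 17001) : lo(lo_) {
    step = (hi - lo) / (n - 1);
    y.resize(n);
    for (int i = 0; i < n; ++i) y[i] = R::pnorm(lo + i * step, 0.0, 1.0, 1, 0);
  }
  inline double cdf(double x) const {
    if (x <= lo) return 0.0;
    double t = (x - lo) / step;
    std::size_t i = (std::size_t)t;
    if (i >= y.size() - 1) return 1.0;
    double f = t - i;
    return y[i] + f * (y[i + 1] - y[i]);
  }
};
}

// Draw n individuals conditional on disorder status under the liability
// threshold model with M SNPs in linkage equilibrium.
//
// Liability L = sum_j beta_j * (g_j - 2 f_j) / sqrt(2 f_j (1 - f_j)) + e,
// e ~ N(0, 1 - h2), status = 1{L > qnorm(1 - K)}. Genotypes are sampled
// one SNP at a time from P(g_j | g_1..g_{j-1}, status), where the
// contribution of the not-yet-sampled SNPs plus the residual is treated
// as a single normal remainder (its variance is tracked exactly; only its
// shape is approximated, which is excellent because the residual variance
// 1 - h2 is itself normal and dominates). The residual e is finally drawn
// from the exact truncated normal, so every returned liability respects
// the threshold.
//
// [[Rcpp::export(name = ".sample_status_cohort")]]
List sample_status_cohort(int n, NumericVector effects, NumericVector freqs,
                          double h2, double K, bool is_case) {
  int M = effects.size();
  if (freqs.size() != M) stop("effects and freqs must have equal length");
  double Tthr = R::qnorm(1.0 - K, 0.0, 1.0, 1, 0);
  double ve = 1.0 - h2;
  if (ve <= 0) stop("h2 must be < 1");
  double sde = std::sqrt(ve);
  static PhiTable tab;

  // sd of the normal remainder after SNP j has been assigned
  std::vector<double> sj(M);
  double acc = ve;
  for (int j = M - 1; j >= 0; --j) {
    sj[j] = std::sqrt(acc);
    acc += effects[j] * effects[j];
  }

  IntegerMatrix X(n, M);
  NumericVector u(n); // running genetic score (standardized-genotype scale)
  for (int j = 0; j < M; ++j) {
    double f = freqs[j];
    double sdg = std::sqrt(2.0 * f * (1.0 - f));
    double x0 = (0.0 - 2.0 * f) / sdg;
    double x1 = (1.0 - 2.0 * f) / sdg;
    double x2 = (2.0 - 2.0 * f) / sdg;
    double q0 = (1.0 - f) * (1.0 - f), q1 = 2.0 * f * (1.0 - f), q2 = f * f;
    double b = effects[j], s = sj[j];
    int* col = &X(0, j);
    for (int i = 0; i < n; ++i) {
      double c = Tthr - u[i];
      double p0 = tab.cdf((c - b * x0) / s);
      double p1 = tab.cdf((c - b * x1) / s);
      double p2 = tab.cdf((c - b * x2) / s);
      double w0, w1, w2;
      if (is_case) {
        w0 = q0 * (1.0 - p0); w1 = q1 * (1.0 - p1); w2 = q2 * (1.0 - p2);
      } else {
        w0 = q0 * p0; w1 = q1 * p1; w2 = q2 * p2;
      }
      double r = unif_rand() * (w0 + w1 + w2);
      int g = (r > w0) + (r > w0 + w1);
      col[i] = g;
      u[i] += b * ((double)g - 2.0 * f) / sdg;
    }
  }

  NumericVector liab(n);
  for (int i = 0; i < n; ++i) {
    double a = (Tthr - u[i]) / sde;
    double e;
    if (is_case) {
      e = sde * R::qnorm(unif_rand() * R::pnorm(a, 0.0, 1.0, 0, 0), 0.0, 1.0, 0, 0);
    } else {
      e = sde * R::qnorm(unif_rand() * R::pnorm(a, 0.0, 1.0, 1, 0), 0.0, 1.0, 1, 0);
    }
    liab[i] = u[i] + e;
  }
  return List::create(_["dosages"] = X, _["liability"] = liab, _["gvalue"] = u);
}

// One-pass per-SNP sufficient statistics for the marginal association scan:
// sums of x, x^2 and x * y_centered per column of an integer dosage matrix.
//
// [[Rcpp::export(name = ".col_assoc_stats")]]
List col_assoc_stats(IntegerMatrix X, NumericVector yc) {
  int n = X.nrow(), M = X.ncol();
  if (yc.size() != n) stop("yc must have one entry per row of X");
  NumericVector sx(M), sx2(M), sxy(M);
  for (int j = 0; j < M; ++j) {
    const int* col = &X(0, j);
    double a = 0.0, b = 0.0, c = 0.0;
    for (int i = 0; i < n; ++i) {
      double g = (double)col[i];
      a += g;
      b += g * g;
      c += g * yc[i];
    }
    sx[j] = a; sx2[j] = b; sxy[j] = c;
  }
  return List::create(_["sum_x"] = sx, _["sum_x2"] = sx2, _["sum_xy"] = sxy);
}
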