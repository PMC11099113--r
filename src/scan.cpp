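#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Per-variant logistic association scans over a dosage matrix
// (variants in rows, samples in columns; missing dosage = NA_INTEGER).
//
// Because each single-SNV model has a discrete predictor with at most three
// levels, the data collapse to a 2 x 3 outcome-by-dosage count table and the
// logistic fit runs on <= 3 support points regardless of sample size.  This
// is what makes 1000-permutation FDR estimation tractable.

static inline double wald_p(double z) {
  return 2.0 * R::pnorm(-std::fabs(z), 0.0, 1.0, 1, 0);
}

// Newton fit of logit P(y=1 | x) = b0 + b1*x on K weighted support points.
// n0[k]/n1[k]: counts of y=0 / y=1 at x = xs[k].  Returns false on
// non-convergence or divergence (separation); se1 is the Wald SE of b1
// evaluated at the converged estimate.
static bool fit_collapsed(const double* xs, const double* n0, const double* n1,
                          int K, double& b0, double& b1, double& se1) {
  b0 = 0.0; b1 = 0.0; se1 = NA_REAL;
  for (int it = 0; it < 50; ++it) {
    double u0 = 0, u1 = 0, i00 = 0, i01 = 0, i11 = 0;
    for (int k = 0; k < K; ++k) {
      double n = n0[k] + n1[k];
      if (n <= 0) continue;
      double eta = b0 + b1 * xs[k];
      double mu = 1.0 / (1.0 + std::exp(-eta));
      double w = n * mu * (1.0 - mu);
      double r = n1[k] - n * mu;
      u0 += r;            u1 += r * xs[k];
      i00 += w;           i01 += w * xs[k];   i11 += w * xs[k] * xs[k];
    }
    double det = i00 * i11 - i01 * i01;
    if (det < 1e-300 || !std::isfinite(det)) return false;
    if (std::fabs(u0) < 1e-10 && std::fabs(u1) < 1e-10) {
      se1 = std::sqrt(i00 / det);
      return std::isfinite(se1);
    }
    b0 += ( i11 * u0 - i01 * u1) / det;
    b1 += (-i01 * u0 + i00 * u1) / det;
    // divergence guard: genotype predictors live on [0,2], so |b1| > 15
    // means odds ratios beyond e^15 per allele -- quasi-separation.
    if (std::fabs(b1) > 15.0 || std::fabs(b0) > 30.0) return false;
  }
  return false;
}

// Dosage-to-predictor maps for the three inheritance codings.
static const double CODE_ADD[3] = {0.0, 1.0, 2.0};
static const double CODE_DOM[3] = {0.0, 1.0, 1.0};
static const double CODE_REC[3] = {0.0, 0.0, 1.0};

// [[Rcpp::export(name = ".scan_engine")]]
NumericMatrix scan_engine(IntegerMatrix dosage, IntegerVector y, int min_count) {
  const int m = dosage.nrow();
  const int n = dosage.ncol();
  if (y.size() != n) stop("length(y) must equal ncol(dosage)");
  // columns: beta, se, z, p for additive, dominant, recessive (12 total)
  NumericMatrix out(m, 12);
  const double* codes[3] = {CODE_ADD, CODE_DOM, CODE_REC};

  for (int j = 0; j < m; ++j) {
    double c0[3] = {0, 0, 0}, c1[3] = {0, 0, 0};
    for (int i = 0; i < n; ++i) {
      int g = dosage(j, i);
      if (g == NA_INTEGER) continue;
      if (g < 0 || g > 2) stop("dosage values must be 0, 1, 2 or NA");
      int yi = y[i];
      if (yi == NA_INTEGER) continue;
      if (yi) c1[g] += 1.0; else c0[g] += 1.0;
    }
    for (int k = 0; k < 3; ++k) {
      double beta = NA_REAL, se = NA_REAL, z = NA_REAL, p = 1.0;
      const double* cd = codes[k];
      // collapse dosage levels sharing an encoded value
      double xs[3], n0[3], n1[3];
      int K = 0;
      for (int g = 0; g < 3; ++g) {
        double ng = c0[g] + c1[g];
        if (ng <= 0) continue;
        int hit = -1;
        for (int q = 0; q < K; ++q) if (xs[q] == cd[g]) hit = q;
        if (hit < 0) { xs[K] = cd[g]; n0[K] = c0[g]; n1[K] = c1[g]; ++K; }
        else { n0[hit] += c0[g]; n1[hit] += c1[g]; }
      }
      // minor-category floor: total minus the modal encoded-value count
      double tot = 0, mx = 0;
      for (int q = 0; q < K; ++q) { double nq = n0[q] + n1[q]; tot += nq; if (nq > mx) mx = nq; }
      bool skip = (K < 2) || (tot - mx < (double)min_count);
      if (!skip) {
        double b0, b1, s1;
        if (fit_collapsed(xs, n0, n1, K, b0, b1, s1)) {
          beta = b1; se = s1; z = b1 / s1; p = wald_p(z);
          if (p <= 0.0) p = 1e-300;
        }
      }
      out(j, 4 * k + 0) = beta;
      out(j, 4 * k + 1) = se;
      out(j, 4 * k + 2) = z;
      out(j, 4 * k + 3) = p;
    }
  }
  return out;
}

// Best p-value per variant (min over the three codings) for permuted
// outcomes; returns an m x n_perm matrix.  The permutations themselves are
// drawn in R so that all randomness flows through R's RNG / seeds.
// [[Rcpp::export(name = ".scan_perm_best_p")]]
NumericMatrix scan_perm_best_p(IntegerMatrix dosage, IntegerMatrix perms,
                               int min_count) {
  const int m = dosage.nrow();
  const int B = perms.ncol();
  NumericMatrix best(m, B);
  for (int b = 0; b < B; ++b) {
    IntegerVector yb = perms(_, b);
    NumericMatrix sc = scan_engine(dosage, yb, min_count);
    for (int j = 0; j < m; ++j) {
      double p = sc(j, 3);
      if (sc(j, 7) < p) p = sc(j, 7);
      if (sc(j, 11) < p) p = sc(j, 11);
      best(j, b) = p;
    }
  }
  return best;
}
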