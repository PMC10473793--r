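#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <numeric>
#include <algorithm>
using namespace Rcpp;

// Template-match pair counts for sample entropy, Richman-Moorman convention:
// both the length-m and length-(m+1) pools use start indices 0..N-m-1, so a
// constant series yields A == B and SampEn 0.  Chebyshev distance, self-matches
// excluded.  Counts are over unordered pairs; the A/B ratio is unchanged.
// Templates are visited in order of their first coordinate so that the inner
// loop can stop once the first-coordinate gap exceeds r; the counted pair set
// is identical to the naive double loop.
static void sampen_count_pairs(const double* x, int n, int m, double r,
                               double& A, double& B) {
  const int ntemp = n - m;
  A = 0.0; B = 0.0;
  if (ntemp < 2) return;
  std::vector<int> idx(ntemp);
  std::iota(idx.begin(), idx.end(), 0);
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return x[a] < x[b]; });
  for (int a_i = 0; a_i < ntemp - 1; ++a_i) {
    const int i = idx[a_i];
    const double xi = x[i];
    for (int b_i = a_i + 1; b_i < ntemp && x[idx[b_i]] - xi <= r; ++b_i) {
      const int j = idx[b_i];
      bool match = true;
      for (int k = 1; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) > r) { match = false; break; }
      }
      if (!match) continue;
      B += 1.0;
      if (std::fabs(x[i + m] - x[j + m]) <= r) A += 1.0;
    }
  }
}

// [[Rcpp::export(name = ".sampen_counts")]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  double A, B;
  sampen_count_pairs(x.begin(), x.size(), m, r, A, B);
  return NumericVector::create(_["A"] = A, _["B"] = B);
}

static double sampen_value(const std::vector<double>& x, int m, double r) {
  double A, B;
  sampen_count_pairs(x.data(), (int)x.size(), m, r, A, B);
  if (A == 0.0 || B == 0.0) return NA_REAL;
  return -std::log(A / B);
}

// SampEn of the coarse-grained series at scales 1..a in one pass.
// tol_mode 0: fixed r_abs (Costa convention, caller supplies r_ref);
// tol_mode 1: r_frac times the population SD of each coarse-grained series.
// [[Rcpp::export(name = ".mse_profile")]]
NumericVector mse_profile(NumericVector x, int m, int a,
                          double r_ref, double r_frac, int tol_mode) {
  const int n = x.size();
  NumericVector out(a, NA_REAL);
  std::vector<double> cg;
  for (int s = 1; s <= a; ++s) {
    const int nb = n / s;
    if (nb < m + 2) continue;
    cg.assign(nb, 0.0);
    for (int b = 0; b < nb; ++b) {
      double acc = 0.0;
      for (int k = 0; k < s; ++k) acc += x[b * s + k];
      cg[b] = acc / s;
    }
    double r = r_ref;
    if (tol_mode == 1) {
      double mean = 0.0;
      for (int b = 0; b < nb; ++b) mean += cg[b];
      mean /= nb;
      double ss = 0.0;
      for (int b = 0; b < nb; ++b) ss += (cg[b] - mean) * (cg[b] - mean);
      r = r_frac * std::sqrt(ss / nb);
    }
    if (r == 0.0) {
      // constant coarse series: all templates match, SampEn 0 by convention
      bool constant = true;
      for (int b = 1; b < nb; ++b)
        if (cg[b] != cg[0]) { constant = false; break; }
      out[s - 1] = constant ? 0.0 : NA_REAL;
      continue;
    }
    out[s - 1] = sampen_value(cg, m, r);
  }
  return out;
}
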