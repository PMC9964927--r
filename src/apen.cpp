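#include <Rcpp.h>
using namespace Rcpp;

// Approximate entropy Phi_m(r) - Phi_{m+1}(r) with Chebyshev distance and
// self-match included, so every neighbor count is >= 1 and the log is
// finite.  One fused pairwise pass accumulates the neighbor counts for
// dimensions m and m+1 together.
// [[Rcpp::export(name = ".apen_impl")]]
double apen_impl(NumericVector xr, int m, int tau, double r) {
  const int N = xr.size();
  const int M = N - (m - 1) * tau;   // vectors of dimension m
  const int M1 = N - m * tau;        // vectors of dimension m + 1
  const double *x = REAL(xr);
  std::vector<int> cnt_m(M, 0), cnt_m1(M1, 0);

  for (int i = 0; i < M; ++i) {
    cnt_m[i] += 1;  // self
    if (i < M1) cnt_m1[i] += 1;
    for (int j = i + 1; j < M; ++j) {
      double d = 0.0;
      const double *xi = x + i, *xj = x + j;
      bool within_m = true;
      for (int k = 0; k < m; ++k) {
        double dd = std::fabs(xi[k * tau] - xj[k * tau]);
        if (dd > d) d = dd;
        if (d > r) { within_m = false; break; }
      }
      if (!within_m) continue;
      cnt_m[i] += 1; cnt_m[j] += 1;
      if (i < M1 && j < M1) {
        double dd = std::fabs(xi[m * tau] - xj[m * tau]);
        if (dd <= r && d <= r) { cnt_m1[i] += 1; cnt_m1[j] += 1; }
      }
    }
  }
  double phi_m = 0.0, phi_m1 = 0.0;
  for (int i = 0; i < M; ++i) {
    phi_m += std::log((double)cnt_m[i] / (double)M);
  }
  phi_m /= (double)M;
  for (int i = 0; i < M1; ++i) {
    phi_m1 += std::log((double)cnt_m1[i] / (double)M1);
  }
  phi_m1 /= (double)M1;
  return phi_m - phi_m1;
}
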