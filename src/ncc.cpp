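#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Zero-normalized cross-correlation of a template against every integer lag
// of a search region (template fully inside). Region window sums come from
// integral images so each lag costs one pass over the template for the cross
// term only. Windows with (numerically) zero variance get coefficient 0.
// [[Rcpp::export(name = ".ncc_surface_cpp")]]
NumericMatrix ncc_surface_cpp(NumericMatrix tmpl, NumericMatrix region) {
  const int kr = tmpl.nrow(), kc = tmpl.ncol();
  const int rr = region.nrow(), rc = region.ncol();
  const int nr = rr - kr + 1, nc = rc - kc + 1;
  if (nr < 1 || nc < 1)
    stop("search region must be at least as large as the template");
  const double* T = tmpl.begin();
  const double* R = region.begin();

  // template statistics
  const double kn = (double)kr * (double)kc;
  double tsum = 0.0, tsum2 = 0.0;
  for (int k = 0; k < kr * kc; ++k) {
    tsum += T[k];
    tsum2 += T[k] * T[k];
  }
  const double tss = tsum2 - tsum * tsum / kn;  // sum of squared deviations

  // integral images of region and region^2, (rr+1) x (rc+1)
  const int ld = rr + 1;
  std::vector<double> S((rr + 1) * (rc + 1), 0.0);
  std::vector<double> S2((rr + 1) * (rc + 1), 0.0);
  for (int j = 1; j <= rc; ++j) {
    const double* rcol = R + (j - 1) * rr;
    double* s0 = &S[(j - 1) * ld];
    double* s1 = &S[j * ld];
    double* q0 = &S2[(j - 1) * ld];
    double* q1 = &S2[j * ld];
    for (int i = 1; i <= rr; ++i) {
      const double v = rcol[i - 1];
      s1[i] = v + s1[i - 1] + s0[i] - s0[i - 1];
      q1[i] = v * v + q1[i - 1] + q0[i] - q0[i - 1];
    }
  }

  NumericMatrix out(nr, nc);
  const double eps = 1e-12;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      const int i1 = i + kr, j1 = j + kc;
      const double rsum = S[i1 + j1 * ld] - S[i + j1 * ld]
                          - S[i1 + j * ld] + S[i + j * ld];
      const double rsum2 = S2[i1 + j1 * ld] - S2[i + j1 * ld]
                           - S2[i1 + j * ld] + S2[i + j * ld];
      const double rss = rsum2 - rsum * rsum / kn;
      double cross = 0.0;
      for (int jj = 0; jj < kc; ++jj) {
        const double* tcol = T + jj * kr;
        const double* rwin = R + (j + jj) * rr + i;
        for (int ii = 0; ii < kr; ++ii)
          cross += tcol[ii] * rwin[ii];
      }
      const double num = cross - tsum * rsum / kn;
      const double den2 = tss * rss;
      out(i, j) = (den2 > eps * kn * kn) ? num / std::sqrt(den2) : 0.0;
    }
  }
  return out;
}
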