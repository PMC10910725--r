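#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// First-order partial correlation with a guard for |r_xz| or |r_yz| = 1.
static inline double partial_cor(double rxy, double rxz, double ryz) {
  double den = (1.0 - rxz * rxz) * (1.0 - ryz * ryz);
  if (den <= 0.0) return 0.0;
  return (rxy - rxz * ryz) / std::sqrt(den);
}

// PCIT trio elimination. For every trio (x, y, z) the information-theoretic
// tolerance is the mean of |partial / direct| over the trio's edges with
// non-zero direct correlation; an edge is flagged non-significant when both
// of its comparisons against the other two edges fall below the tolerance.
// Returns a logical matrix of retained edges (diagonal FALSE).
// [[Rcpp::export]]
LogicalMatrix pcit_keep_cpp(NumericMatrix R) {
  const int n = R.nrow();
  LogicalMatrix keep(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      keep(i, j) = (i != j);
  for (int x = 0; x < n - 2; ++x) {
    for (int y = x + 1; y < n - 1; ++y) {
      const double rxy = R(x, y);
      for (int z = y + 1; z < n; ++z) {
        const double rxz = R(x, z);
        const double ryz = R(y, z);
        const double pxy = partial_cor(rxy, rxz, ryz);
        const double pxz = partial_cor(rxz, rxy, ryz);
        const double pyz = partial_cor(ryz, rxy, rxz);
        double s = 0.0;
        int m = 0;
        if (rxy != 0.0) { s += std::fabs(pxy / rxy); ++m; }
        if (rxz != 0.0) { s += std::fabs(pxz / rxz); ++m; }
        if (ryz != 0.0) { s += std::fabs(pyz / ryz); ++m; }
        if (m == 0) continue;  // all three direct correlations zero
        const double eps = s / m;
        const double axy = std::fabs(rxy), axz = std::fabs(rxz),
                     ayz = std::fabs(ryz);
        if (axy < eps * axz && axy < eps * ayz)
          keep(x, y) = keep(y, x) = false;
        if (axz < eps * axy && axz < eps * ayz)
          keep(x, z) = keep(z, x) = false;
        if (ayz < eps * axy && ayz < eps * axz)
          keep(y, z) = keep(z, y) = false;
      }
    }
  }
  return keep;
}
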