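#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Masked Gaussian smoothing: normalized convolution over valid (non-NA)
// bins; invalid bins stay NA.
// [[Rcpp::export]]
NumericMatrix smooth_masked_cpp(NumericMatrix m, double sigma) {
  int nr = m.nrow(), nc = m.ncol();
  NumericMatrix out(nr, nc);
  if (sigma <= 0) { std::copy(m.begin(), m.end(), out.begin()); return out; }
  int h = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * h + 1);
  for (int i = -h; i <= h; ++i)
    k[i + h] = std::exp(-0.5 * i * i / (sigma * sigma));
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      if (!R_finite(m(r, c))) { out(r, c) = NA_REAL; continue; }
      double num = 0, den = 0;
      for (int dr = -h; dr <= h; ++dr) {
        int rr = r + dr;
        if (rr < 0 || rr >= nr) continue;
        for (int dc = -h; dc <= h; ++dc) {
          int cc = c + dc;
          if (cc < 0 || cc >= nc) continue;
          double v = m(rr, cc);
          if (!R_finite(v)) continue;
          double kk = k[dr + h] * k[dc + h];
          num += kk * v; den += kk;
        }
      }
      out(r, c) = den > 0 ? num / den : NA_REAL;
    }
  return out;
}

// Spatial autocorrelogram: Pearson r of overlapping valid bins at each 2-D
// lag up to max_lag bins; lags with fewer than min_overlap valid pairs are NA.
// [[Rcpp::export]]
NumericMatrix autocorr_cpp(NumericMatrix m, int max_lag, int min_overlap) {
  int nr = m.nrow(), nc = m.ncol();
  int L = max_lag;
  NumericMatrix out(2 * L + 1, 2 * L + 1);
  std::fill(out.begin(), out.end(), NA_REAL);
  for (int dr = -L; dr <= L; ++dr) {
    for (int dc = 0; dc <= L; ++dc) { // use point symmetry for dc < 0
      if (dc == 0 && dr < 0) continue;
      double sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0;
      int n = 0;
      int r0 = std::max(0, -dr), r1 = std::min(nr, nr - dr);
      int c0 = std::max(0, -dc), c1 = std::min(nc, nc - dc);
      for (int r = r0; r < r1; ++r)
        for (int c = c0; c < c1; ++c) {
          double a = m(r, c), b = m(r + dr, c + dc);
          if (!R_finite(a) || !R_finite(b)) continue;
          sx += a; sy += b; sxx += a * a; syy += b * b; sxy += a * b;
          ++n;
        }
      if (n >= min_overlap) {
        double vx = sxx - sx * sx / n, vy = syy - sy * sy / n;
        double cov = sxy - sx * sy / n;
        double r = (vx > 1e-12 && vy > 1e-12) ? cov / std::sqrt(vx * vy)
                                              : NA_REAL;
        out(dr + L, dc + L) = r;
        out(-dr + L, -dc + L) = r;
      }
    }
  }
  return out;
}

// Occupancy-weighted accumulation of a rate series into 2-D bins.
// [[Rcpp::export]]
List bin_rates_cpp(IntegerVector bx, IntegerVector by, NumericVector rate,
                   double dt, int nx, int ny) {
  NumericMatrix num(nx, ny), occ(nx, ny);
  int n = bx.size();
  for (int i = 0; i < n; ++i) {
    int x = bx[i], y = by[i];
    if (x < 1 || x > nx || y < 1 || y > ny) continue;
    occ(x - 1, y - 1) += dt;
    num(x - 1, y - 1) += rate[i] * dt;
  }
  return List::create(_["num"] = num, _["occ"] = occ);
}
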