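// Performance kernels for the permutation pipeline: per-pixel tail order
// statistics across map stacks, tail counts for p-values, and sparse
// Gaussian-basis assembly.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Row-wise k most extreme values of X (sorted, most extreme first).
// decreasing = true -> k largest; false -> k smallest.
// [[Rcpp::export]]
NumericMatrix topk_rows(NumericMatrix X, int k, bool decreasing) {
  const int n = X.nrow(), m = X.ncol();
  if (k > m) k = m;
  NumericMatrix out(n, k);
  std::vector<double> row(m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) row[j] = X(i, j);
    if (decreasing) {
      std::partial_sort(row.begin(), row.begin() + k, row.end(),
                        std::greater<double>());
    } else {
      std::partial_sort(row.begin(), row.begin() + k, row.end());
    }
    for (int j = 0; j < k; ++j) out(i, j) = row[j];
  }
  return out;
}

// Per-row counts of X values >= v and <= v (one pass, no large logicals).
// [[Rcpp::export]]
List count_extremes(NumericMatrix X, NumericVector v) {
  const int n = X.nrow(), m = X.ncol();
  IntegerVector ge(n), le(n);
  for (int j = 0; j < m; ++j) {
    for (int i = 0; i < n; ++i) {
      const double x = X(i, j);
      if (x >= v[i]) ++ge[i];
      if (x <= v[i]) ++le[i];
    }
  }
  return List::create(_["ge"] = ge, _["le"] = le);
}

// Triplets (pixel index, fixation index, value) of the truncated isotropic
// Gaussian kernel of each fixation evaluated at all pixel centers.
// gx, gy are the (ascending, equally spaced) pixel-center coordinates.
// [[Rcpp::export]]
List gaussian_basis_triplets(NumericVector x, NumericVector y,
                             NumericVector gx, NumericVector gy,
                             double sigma, double trunc_sd) {
  const int n = x.size(), nx = gx.size(), ny = gy.size();
  const double r = trunc_sd * sigma;
  const double cell_x0 = gx[0], cell_y0 = gy[0];
  const double cell = nx > 1 ? gx[1] - gx[0] : 1.0;
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  const double norm = 1.0 / (2.0 * M_PI * sigma * sigma);
  std::vector<int> ti, tj;
  std::vector<double> tv;
  std::vector<double> wx(nx), wy(ny);
  for (int f = 0; f < n; ++f) {
    // pixel-center window [x - r, x + r], matching the R-side comparison
    int ix0 = (int)std::ceil((x[f] - r - cell_x0) / cell - 1e-9);
    int ix1 = (int)std::floor((x[f] + r - cell_x0) / cell + 1e-9);
    int iy0 = (int)std::ceil((y[f] - r - cell_y0) / cell - 1e-9);
    int iy1 = (int)std::floor((y[f] + r - cell_y0) / cell + 1e-9);
    if (ix0 < 0) ix0 = 0;
    if (iy0 < 0) iy0 = 0;
    if (ix1 > nx - 1) ix1 = nx - 1;
    if (iy1 > ny - 1) iy1 = ny - 1;
    if (ix0 > ix1 || iy0 > iy1) continue;
    for (int i = ix0; i <= ix1; ++i) {
      const double dx = gx[i] - x[f];
      wx[i] = std::exp(-dx * dx * inv2s2);
    }
    for (int j = iy0; j <= iy1; ++j) {
      const double dy = gy[j] - y[f];
      wy[j] = std::exp(-dy * dy * inv2s2);
    }
    for (int j = iy0; j <= iy1; ++j) {
      for (int i = ix0; i <= ix1; ++i) {
        ti.push_back(j * nx + i + 1);  // 1-based linear pixel index
        tj.push_back(f + 1);
        tv.push_back(norm * wx[i] * wy[j]);
      }
    }
  }
  return List::create(_["i"] = wrap(ti), _["j"] = wrap(tj),
                      _["v"] = wrap(tv));
}
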