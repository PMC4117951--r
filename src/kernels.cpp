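#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// kernel families: 0 = triangle, 1 = gaussian, 2 = laplace
static inline double kernel_value(double d, int family, double d0) {
  switch (family) {
  case 0:
    return d >= d0 ? 0.0 : 1.0 - d / d0;
  case 1:
    return std::exp(-0.5 * (d / d0) * (d / d0));
  default:
    return std::exp(-d / d0);
  }
}

// Kernel-weighted local methylation level for every site of one chromosome.
// pos must be sorted ascending; w is the per-site weight (read count, or an
// indicator), val the per-site corrected fraction.  K(0) = 0: the focal
// site and any site at zero distance are excluded.  mode 0: all sites
// within the kernel support (triangle: d0; other families truncated at
// trunc * d0).  mode 1: the k nearest sites with w > 0; when d0 <= 0 the
// bandwidth adapts to the farthest selected neighbour + 1 bp.
// Sites whose window carries no weight get NA (caller substitutes the
// global level).
// [[Rcpp::export]]
NumericVector local_levels_cpp(NumericVector pos, NumericVector w,
                               NumericVector val, int family, double d0,
                               int mode, int k, double trunc_mult) {
  int n = pos.size();
  NumericVector out(n, NA_REAL);

  if (mode == 0) {
    double radius = (family == 0) ? d0 : trunc_mult * d0;
    int lo = 0, hi = -1;
    for (int i = 0; i < n; ++i) {
      while (lo < n && pos[lo] < pos[i] - radius) ++lo;
      while (hi + 1 < n && pos[hi + 1] <= pos[i] + radius) ++hi;
      double num = 0.0, den = 0.0;
      for (int j = lo; j <= hi; ++j) {
        if (j == i || w[j] <= 0.0) continue;
        double d = std::fabs(pos[j] - pos[i]);
        if (d <= 0.0) continue;
        double kk = kernel_value(d, family, d0);
        if (kk <= 0.0) continue;
        num += kk * w[j] * val[j];
        den += kk * w[j];
      }
      if (den > 0.0) out[i] = num / den;
    }
    return out;
  }

  // k-nearest mode over covered sites only
  std::vector<int> cov;
  cov.reserve(n);
  for (int i = 0; i < n; ++i)
    if (w[i] > 0.0) cov.push_back(i);
  int m = (int)cov.size();
  std::vector<int> sel;
  sel.reserve(k > 0 ? k : 1);
  int ptr = 0;
  for (int i = 0; i < n; ++i) {
    while (ptr < m && pos[cov[ptr]] < pos[i]) ++ptr;
    int left = ptr - 1, right = ptr;
    sel.clear();
    while ((int)sel.size() < k && (left >= 0 || right < m)) {
      if (right < m && cov[right] == i) { ++right; continue; }
      double dl = left >= 0 ? pos[i] - pos[cov[left]] : R_PosInf;
      double dr = right < m ? pos[cov[right]] - pos[i] : R_PosInf;
      if (dl <= dr) {
        sel.push_back(cov[left]);
        --left;
      } else {
        sel.push_back(cov[right]);
        ++right;
      }
    }
    if (sel.empty()) continue;
    double dmax = 0.0;
    for (size_t s = 0; s < sel.size(); ++s) {
      double d = std::fabs(pos[sel[s]] - pos[i]);
      if (d > dmax) dmax = d;
    }
    double d0_eff = d0 > 0.0 ? d0 : dmax + 1.0;
    double num = 0.0, den = 0.0;
    for (size_t s = 0; s < sel.size(); ++s) {
      int j = sel[s];
      double d = std::fabs(pos[j] - pos[i]);
      if (d <= 0.0) continue; // K(0) = 0
      double kk = kernel_value(d, family, d0_eff);
      if (kk <= 0.0) continue;
      num += kk * w[j] * val[j];
      den += kk * w[j];
    }
    if (den > 0.0) out[i] = num / den;
  }
  return out;
}

// Kernel-smoothed methylation level on a regular grid (no focal-site
// exclusion: a site at zero distance from a grid point gets full weight).
// [[Rcpp::export]]
NumericVector grid_smooth_cpp(NumericVector grid, NumericVector pos,
                              NumericVector w, NumericVector val, int family,
                              double d0, double trunc_mult) {
  int ng = grid.size(), n = pos.size();
  NumericVector out(ng, NA_REAL);
  double radius = (family == 0) ? d0 : trunc_mult * d0;
  int lo = 0, hi = -1;
  for (int g = 0; g < ng; ++g) {
    while (lo < n && pos[lo] < grid[g] - radius) ++lo;
    while (hi + 1 < n && pos[hi + 1] <= grid[g] + radius) ++hi;
    double num = 0.0, den = 0.0;
    for (int j = lo; j <= hi; ++j) {
      if (w[j] <= 0.0) continue;
      double d = std::fabs(pos[j] - grid[g]);
      double kk = kernel_value(d, family, d0);
      if (kk <= 0.0) continue;
      num += kk * w[j] * val[j];
      den += kk * w[j];
    }
    if (den > 0.0) out[g] = num / den;
  }
  return out;
}
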