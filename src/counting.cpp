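#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Cumulative ordered pair counts: for each threshold t in thr (ascending),
// the number of ordered pairs (i, j) with distance(i, j) <= t, summed over
// all focal points i. exclude_self drops j == i and requires both point sets
// to be the same vectors in the same order.
// [[Rcpp::export(name = ".cumPairCounts")]]
NumericVector cum_pair_counts(NumericVector xi, NumericVector yi,
                              NumericVector xj, NumericVector yj,
                              NumericVector thr, bool exclude_self) {
  const int ni = xi.size(), nj = xj.size(), nt = thr.size();
  std::vector<double> thr2(nt);
  for (int k = 0; k < nt; ++k)
    thr2[k] = thr[k] < 0 ? -1.0 : thr[k] * thr[k];
  std::vector<double> hist(nt + 1, 0.0);
  for (int i = 0; i < ni; ++i) {
    const double px = xi[i], py = yi[i];
    for (int j = 0; j < nj; ++j) {
      if (exclude_self && j == i) continue;
      const double dx = xj[j] - px, dy = yj[j] - py;
      const double d2 = dx * dx + dy * dy;
      // first bin k with d2 <= thr2[k]
      int lo = 0, hi = nt;
      while (lo < hi) {
        int mid = (lo + hi) / 2;
        if (d2 <= thr2[mid]) hi = mid; else lo = mid + 1;
      }
      hist[lo] += 1.0;
    }
  }
  NumericVector out(nt);
  double acc = 0.0;
  for (int k = 0; k < nt; ++k) { acc += hist[k]; out[k] = acc; }
  return out;
}

// Per focal point, the number of grid-cell centers lying inside the window
// and within distance thr[k]; returned as an n x nt matrix of cell counts
// (multiply by cell^2 for areas). Cells tile the window from (x0, y0) with
// side `cell`.
// [[Rcpp::export(name = ".cumCellCounts")]]
NumericMatrix cum_cell_counts(NumericVector x, NumericVector y,
                              NumericVector thr,
                              double x0, double x1, double y0, double y1,
                              double cell) {
  const int n = x.size(), nt = thr.size();
  const int mx = (int) std::floor((x1 - x0) / cell + 1e-9);
  const int my = (int) std::floor((y1 - y0) / cell + 1e-9);
  double tmax = 0.0;
  std::vector<double> thr2(nt);
  for (int k = 0; k < nt; ++k) {
    thr2[k] = thr[k] < 0 ? -1.0 : thr[k] * thr[k];
    if (thr[k] > tmax) tmax = thr[k];
  }
  NumericMatrix out(n, nt);
  std::vector<double> hist(nt + 1);
  for (int i = 0; i < n; ++i) {
    std::fill(hist.begin(), hist.end(), 0.0);
    const double px = x[i], py = y[i];
    int ax = (int) std::floor((px - tmax - x0) / cell);
    int bx = (int) std::floor((px + tmax - x0) / cell);
    int ay = (int) std::floor((py - tmax - y0) / cell);
    int by = (int) std::floor((py + tmax - y0) / cell);
    if (ax < 0) ax = 0;
    if (bx > mx - 1) bx = mx - 1;
    if (ay < 0) ay = 0;
    if (by > my - 1) by = my - 1;
    for (int cx = ax; cx <= bx; ++cx) {
      const double dx = x0 + (cx + 0.5) * cell - px;
      const double dx2 = dx * dx;
      if (dx2 > tmax * tmax) continue;
      for (int cy = ay; cy <= by; ++cy) {
        const double dy = y0 + (cy + 0.5) * cell - py;
        const double d2 = dx2 + dy * dy;
        int lo = 0, hi = nt;
        while (lo < hi) {
          int mid = (lo + hi) / 2;
          if (d2 <= thr2[mid]) hi = mid; else lo = mid + 1;
        }
        hist[lo] += 1.0;
      }
    }
    double acc = 0.0;
    for (int k = 0; k < nt; ++k) { acc += hist[k]; out(i, k) = acc; }
  }
  return out;
}

// Bin index matrix for a joint pattern: entry (i, j) is the smallest k
// (1-based) with distance(i, j) <= thr[k], or nt + 1 if beyond all
// thresholds; the diagonal is set to nt + 1 so self pairs never count.
// [[Rcpp::export(name = ".pairBinMatrix")]]
IntegerMatrix pair_bin_matrix(NumericVector x, NumericVector y,
                              NumericVector thr) {
  const int n = x.size(), nt = thr.size();
  std::vector<double> thr2(nt);
  for (int k = 0; k < nt; ++k)
    thr2[k] = thr[k] < 0 ? -1.0 : thr[k] * thr[k];
  IntegerMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    out(i, i) = nt + 1;
    for (int j = i + 1; j < n; ++j) {
      const double dx = x[j] - x[i], dy = y[j] - y[i];
      const double d2 = dx * dx + dy * dy;
      int lo = 0, hi = nt;
      while (lo < hi) {
        int mid = (lo + hi) / 2;
        if (d2 <= thr2[mid]) hi = mid; else lo = mid + 1;
      }
      out(i, j) = lo + 1;
      out(j, i) = lo + 1;
    }
  }
  return out;
}

// Given the precomputed bin matrix of a joint pattern and a case/control
// labeling, cumulative ordered pair counts split by the label of the
// neighbour: row 1 = case -> case, row 2 = case -> control.
// [[Rcpp::export(name = ".labelPairCum")]]
NumericMatrix label_pair_cum(IntegerMatrix bins, LogicalVector is_case,
                             int nt) {
  const int n = bins.nrow();
  std::vector<double> hist_cc(nt + 1, 0.0), hist_cj(nt + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    if (!is_case[i]) continue;
    for (int j = 0; j < n; ++j) {
      const int b = bins(j, i) - 1;  // column-major friendly: bins symmetric
      if (b >= nt) continue;
      if (is_case[j]) hist_cc[b] += 1.0; else hist_cj[b] += 1.0;
    }
  }
  NumericMatrix out(2, nt);
  double acc_cc = 0.0, acc_cj = 0.0;
  for (int k = 0; k < nt; ++k) {
    acc_cc += hist_cc[k]; acc_cj += hist_cj[k];
    out(0, k) = acc_cc; out(1, k) = acc_cj;
  }
  return out;
}
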