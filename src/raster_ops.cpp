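#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <limits>
#include <vector>
using namespace Rcpp;

// Separable convolution with replicate (clamp-to-edge) padding.
// kx runs along columns (horizontal pass), ky along rows (vertical pass).
// [[Rcpp::export]]
NumericMatrix conv_sep_cpp(const NumericMatrix& img, const NumericVector& kx,
                           const NumericVector& ky) {
  const int nr = img.nrow(), nc = img.ncol();
  const int rx = (kx.size() - 1) / 2, ry = (ky.size() - 1) / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      double acc = 0.0;
      for (int k = -rx; k <= rx; ++k) {
        int jj = j + k;
        if (jj < 0) jj = 0; else if (jj >= nc) jj = nc - 1;
        acc += img(i, jj) * kx[k + rx];
      }
      tmp(i, j) = acc;
    }
  }
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int k = -ry; k <= ry; ++k) {
        int ii = i + k;
        if (ii < 0) ii = 0; else if (ii >= nr) ii = nr - 1;
        acc += tmp(ii, j) * ky[k + ry];
      }
      out(i, j) = acc;
    }
  }
  return out;
}

// Square-window median filter using Huang's running histogram on values
// quantized to nbins over the image range.  Border handled by index clamping.
// [[Rcpp::export]]
NumericMatrix median_filter_cpp(const NumericMatrix& img, int radius,
                                int nbins = 1024) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  double lo = R_PosInf, hi = R_NegInf;
  for (int i = 0; i < nr * nc; ++i) {
    double v = img[i];
    if (v < lo) lo = v;
    if (v > hi) hi = v;
  }
  if (!(hi > lo)) { std::fill(out.begin(), out.end(), lo); return out; }
  const double scale = (nbins - 1) / (hi - lo);
  // precompute bin index per pixel
  std::vector<int> bin(nr * nc);
  for (int i = 0; i < nr * nc; ++i)
    bin[i] = (int)std::lround((img[i] - lo) * scale);
  std::vector<int> hist(nbins);
  const int w = 2 * radius + 1, half = (w * w) / 2; // median = (half+1)-th value
  auto clampi = [&](int v, int n) { return v < 0 ? 0 : (v >= n ? n - 1 : v); };
  for (int i = 0; i < nr; ++i) {
    std::fill(hist.begin(), hist.end(), 0);
    // initialize window at column 0
    for (int dj = -radius; dj <= radius; ++dj) {
      int jj = clampi(dj, nc);
      for (int di = -radius; di <= radius; ++di) {
        int ii = clampi(i + di, nr);
        ++hist[bin[ii + (size_t)jj * nr]];
      }
    }
    int med = 0, below = 0; // below = count of elements in bins < med
    for (int j = 0; j < nc; ++j) {
      if (j > 0) {
        int jout = clampi(j - 1 - radius, nc), jin = clampi(j + radius, nc);
        for (int di = -radius; di <= radius; ++di) {
          int ii = clampi(i + di, nr);
          int bo = bin[ii + (size_t)jout * nr], bi = bin[ii + (size_t)jin * nr];
          --hist[bo]; if (bo < med) --below;
          ++hist[bi]; if (bi < med) ++below;
        }
      }
      // move med so that below <= half < below + hist[med]
      while (below > half) { --med; below -= hist[med]; }
      while (below + hist[med] <= half) { below += hist[med]; ++med; }
      out(i, j) = lo + med / scale;
    }
  }
  return out;
}

// 4- or 8-connected component labelling; labels 1..K in scan order.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(const LogicalMatrix& mask, bool eight = true) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<std::pair<int, int>> stack;
  int next = 0;
  const int dx8[] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dy8[] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dx4[] = {-1, 1, 0, 0};
  const int dy4[] = {0, 0, -1, 1};
  const int nd = eight ? 8 : 4;
  const int* dx = eight ? dx8 : dx4;
  const int* dy = eight ? dy8 : dy4;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      lab(i, j) = ++next;
      stack.clear();
      stack.emplace_back(i, j);
      while (!stack.empty()) {
        auto [ci, cj] = stack.back();
        stack.pop_back();
        for (int d = 0; d < nd; ++d) {
          int ni = ci + dx[d], nj = cj + dy[d];
          if (ni < 0 || nj < 0 || ni >= nr || nj >= nc) continue;
          if (mask(ni, nj) && !lab(ni, nj)) {
            lab(ni, nj) = next;
            stack.emplace_back(ni, nj);
          }
        }
      }
    }
  }
  return lab;
}

static void edt_1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// Exact Euclidean distance (in pixels) from each true pixel to the nearest
// false pixel (Felzenszwalb & Huttenlocher two-pass).  False pixels get 0.
// Pixels outside the image border are treated as false.
// [[Rcpp::export]]
NumericMatrix distance_transform_cpp(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const double INF = 1e18;
  // pad by one so the border counts as background
  const int pr = nr + 2, pc = nc + 2;
  std::vector<double> g(pr * pc);
  for (int j = 0; j < pc; ++j)
    for (int i = 0; i < pr; ++i) {
      bool inside = i > 0 && j > 0 && i <= nr && j <= nc && mask(i - 1, j - 1);
      g[i + (size_t)j * pr] = inside ? INF : 0.0;
    }
  std::vector<double> f(std::max(pr, pc)), d(std::max(pr, pc));
  for (int j = 0; j < pc; ++j) {
    for (int i = 0; i < pr; ++i) f[i] = g[i + (size_t)j * pr];
    edt_1d(f, d, pr);
    for (int i = 0; i < pr; ++i) g[i + (size_t)j * pr] = d[i];
  }
  for (int i = 0; i < pr; ++i) {
    for (int j = 0; j < pc; ++j) f[j] = g[i + (size_t)j * pr];
    edt_1d(f, d, pc);
    for (int j = 0; j < pc; ++j) g[i + (size_t)j * pr] = d[j];
  }
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = std::sqrt(g[(i + 1) + (size_t)(j + 1) * pr]);
  return out;
}

// Zhang-Suen thinning to a 1-px skeleton.
// [[Rcpp::export]]
LogicalMatrix thin_cpp(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  std::vector<unsigned char> img(nr * nc);
  for (int i = 0; i < nr * nc; ++i) img[i] = mask[i] ? 1 : 0;
  auto at = [&](int i, int j) -> int {
    if (i < 0 || j < 0 || i >= nr || j >= nc) return 0;
    return img[i + (size_t)j * nr];
  };
  bool changed = true;
  std::vector<std::pair<int, int>> del;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      del.clear();
      for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
          if (!img[i + (size_t)j * nr]) continue;
          // neighbours P2..P9 clockwise from north
          int p2 = at(i - 1, j), p3 = at(i - 1, j + 1), p4 = at(i, j + 1),
              p5 = at(i + 1, j + 1), p6 = at(i + 1, j), p7 = at(i + 1, j - 1),
              p8 = at(i, j - 1), p9 = at(i - 1, j - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          del.emplace_back(i, j);
        }
      }
      for (auto& pr : del) img[pr.first + (size_t)pr.second * nr] = 0;
      if (!del.empty()) changed = true;
    }
  }
  LogicalMatrix out(nr, nc);
  for (int i = 0; i < nr * nc; ++i) out[i] = img[i] != 0;
  return out;
}
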