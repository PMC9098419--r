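// Per-slice Canny edge detection and 8-connected labeling.
//
// Matrices arrive column-major from R with dimensions (rows, cols);
// pixel (r, c) (0-based here) lives at index r + c * nr.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static inline int reflect_idx(int i, int n) {
  // mirror without edge repeat: -1 -> 1, n -> n-2
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * n - 2 - i;
  }
  return i;
}

static void gaussian_smooth(const NumericMatrix& src, NumericMatrix& dst,
                            double sigma) {
  int nr = src.nrow(), nc = src.ncol();
  int radius = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> w(2 * radius + 1);
  double s = 0.0;
  for (int i = -radius; i <= radius; ++i) {
    w[i + radius] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += w[i + radius];
  }
  for (auto& x : w) x /= s;

  NumericMatrix tmp(nr, nc);
  // along rows
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double acc = 0.0;
      for (int i = -radius; i <= radius; ++i)
        acc += w[i + radius] * src(reflect_idx(r + i, nr), c);
      tmp(r, c) = acc;
    }
  // along cols
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double acc = 0.0;
      for (int i = -radius; i <= radius; ++i)
        acc += w[i + radius] * tmp(r, reflect_idx(c + i, nc));
      dst(r, c) = acc;
    }
}

// Canny on one slice. high threshold is a fraction of the slice's maximum
// gradient magnitude (normalized 0-1 scale); low = low_ratio * high.
// Returns a logical matrix of edge pixels.
// [[Rcpp::export(name = ".canny_slice_cpp")]]
LogicalMatrix canny_slice_cpp(NumericMatrix image, double high_frac,
                              double sigma, double low_ratio) {
  int nr = image.nrow(), nc = image.ncol();
  NumericMatrix sm(nr, nc);
  gaussian_smooth(image, sm, sigma);

  NumericMatrix gx(nr, nc), gy(nr, nc), mag(nr, nc);
  double max_mag = 0.0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      // Sobel with mirrored borders
      int rm = reflect_idx(r - 1, nr), rp = reflect_idx(r + 1, nr);
      int cm = reflect_idx(c - 1, nc), cp = reflect_idx(c + 1, nc);
      double a = sm(rm, cm), b = sm(rm, c), d = sm(rm, cp);
      double e = sm(r, cm),                 f = sm(r, cp);
      double g = sm(rp, cm), h = sm(rp, c), i2 = sm(rp, cp);
      double dx = (g + 2.0 * h + i2) - (a + 2.0 * b + d);  // along rows
      double dy = (d + 2.0 * f + i2) - (a + 2.0 * e + g);  // along cols
      gx(r, c) = dx;
      gy(r, c) = dy;
      double m = std::sqrt(dx * dx + dy * dy);
      mag(r, c) = m;
      if (m > max_mag) max_mag = m;
    }

  LogicalMatrix edges(nr, nc);
  if (max_mag <= 0.0) return edges;  // constant image: no edges

  double high = high_frac * max_mag;
  double low = low_ratio * high;

  // non-maximum suppression: quantize gradient direction to 4 bins; the
  // >= / > asymmetry keeps exactly one pixel of an equal-magnitude pair.
  std::vector<unsigned char> nms(nr * nc, 0);
  for (int c = 1; c < nc - 1; ++c)
    for (int r = 1; r < nr - 1; ++r) {
      double m = mag(r, c);
      if (m < low) continue;
      double dx = gx(r, c), dy = gy(r, c);
      int dr, dc;
      double ang = std::atan2(dy, dx);  // in (-pi, pi]
      if (ang < 0) { ang += M_PI; dx = -dx; dy = -dy; }
      if (ang < M_PI / 8.0 || ang >= 7.0 * M_PI / 8.0) { dr = 1; dc = 0; }
      else if (ang < 3.0 * M_PI / 8.0) { dr = 1; dc = 1; }
      else if (ang < 5.0 * M_PI / 8.0) { dr = 0; dc = 1; }
      else { dr = -1; dc = 1; }
      double m_plus = mag(r + dr, c + dc);
      double m_minus = mag(r - dr, c - dc);
      if (m >= m_plus && m > m_minus) nms[r + c * nr] = 1;
    }

  // hysteresis: BFS from strong pixels over weak 8-neighbors
  std::vector<int> stack;
  std::vector<unsigned char> vis(nr * nc, 0);
  for (int c = 1; c < nc - 1; ++c)
    for (int r = 1; r < nr - 1; ++r) {
      int idx = r + c * nr;
      if (nms[idx] && mag(r, c) >= high && !vis[idx]) {
        vis[idx] = 1;
        stack.push_back(idx);
      }
    }
  while (!stack.empty()) {
    int idx = stack.back(); stack.pop_back();
    int r = idx % nr, c = idx / nr;
    edges(r, c) = true;
    for (int dc = -1; dc <= 1; ++dc)
      for (int dr = -1; dr <= 1; ++dr) {
        if (dr == 0 && dc == 0) continue;
        int rr = r + dr, cc = c + dc;
        if (rr < 1 || rr >= nr - 1 || cc < 1 || cc >= nc - 1) continue;
        int j = rr + cc * nr;
        if (!vis[j] && nms[j] && mag(rr, cc) >= low) {
          vis[j] = 1;
          stack.push_back(j);
        }
      }
  }
  return edges;
}

// 8-connected component labeling of a logical mask. Labels are assigned in
// order of each component's lexicographically smallest (row, col) pixel,
// starting at 1; background is 0.
// [[Rcpp::export(name = ".label8_cpp")]]
IntegerMatrix label8_cpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  for (int r = 0; r < nr; ++r)        // row-major scan => smallest (row, col) first
    for (int c = 0; c < nc; ++c) {
      if (!mask(r, c) || lab(r, c)) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int rr = idx % nr, cc = idx / nr;
        for (int dc = -1; dc <= 1; ++dc)
          for (int dr = -1; dr <= 1; ++dr) {
            int r2 = rr + dr, c2 = cc + dc;
            if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
            if (mask(r2, c2) && !lab(r2, c2)) {
              lab(r2, c2) = next;
              stack.push_back(r2 + c2 * nr);
            }
          }
      }
    }
  return lab;
}

// Fill the interior of a pixel ring: 4-connected flood from the image
// border over non-ring pixels; everything not reached (plus the ring) is
// interior. Robust to ring thickness and spurs; leaks only through true
// gaps wider than a diagonal step.
// [[Rcpp::export(name = ".fill_ring_cpp")]]
LogicalMatrix fill_ring_cpp(LogicalMatrix ring) {
  int nr = ring.nrow(), nc = ring.ncol();
  std::vector<unsigned char> outside(nr * nc, 0);
  std::vector<int> stack;
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      if (r == 0 || r == nr - 1 || c == 0 || c == nc - 1) {
        int idx = r + c * nr;
        if (!ring(r, c) && !outside[idx]) {
          outside[idx] = 1;
          stack.push_back(idx);
        }
      }
    }
  const int dr[4] = { 1, -1, 0, 0 };
  const int dc[4] = { 0, 0, 1, -1 };
  while (!stack.empty()) {
    int idx = stack.back(); stack.pop_back();
    int r = idx % nr, c = idx / nr;
    for (int k = 0; k < 4; ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      int j = rr + cc * nr;
      if (!outside[j] && !ring(rr, cc)) {
        outside[j] = 1;
        stack.push_back(j);
      }
    }
  }
  LogicalMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      out(r, c) = !outside[r + c * nr];
  return out;
}
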