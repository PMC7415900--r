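#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <queue>
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// 3x3 median with replicated edges; matrices are row = image row.
// [[Rcpp::export]]
NumericMatrix median3x3_cpp(NumericMatrix img) {
  int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  double buf[9];
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      int n = 0;
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di)
          buf[n++] = img(clampi(i + di, 0, H - 1), clampi(j + dj, 0, W - 1));
      std::nth_element(buf, buf + 4, buf + 9);
      out(i, j) = buf[4];
    }
  }
  return out;
}

// Separable (1,2,1)/4 binomial smoothing (the 3x3 Gaussian approximation),
// replicated edges.
// [[Rcpp::export]]
NumericMatrix binom3_cpp(NumericMatrix img) {
  int H = img.nrow(), W = img.ncol();
  NumericMatrix tmp(H, W), out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      tmp(i, j) = 0.25 * img(clampi(i - 1, 0, H - 1), j) + 0.5 * img(i, j) +
                  0.25 * img(clampi(i + 1, 0, H - 1), j);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      out(i, j) = 0.25 * tmp(i, clampi(j - 1, 0, W - 1)) + 0.5 * tmp(i, j) +
                  0.25 * tmp(i, clampi(j + 1, 0, W - 1));
  return out;
}

// Central-difference gradient magnitude; one-pixel border left at zero.
// [[Rcpp::export]]
NumericMatrix gradmag_cpp(NumericMatrix img) {
  int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  for (int j = 1; j < W - 1; ++j) {
    for (int i = 1; i < H - 1; ++i) {
      double gx = 0.5 * (img(i, j + 1) - img(i, j - 1));
      double gy = 0.5 * (img(i + 1, j) - img(i - 1, j));
      out(i, j) = std::sqrt(gx * gx + gy * gy);
    }
  }
  return out;
}

// Separable Gaussian blur, radius ceil(3*sigma), replicated edges.
// [[Rcpp::export]]
NumericMatrix gauss_blur_cpp(NumericMatrix img, double sigma) {
  int H = img.nrow(), W = img.ncol();
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int t = -r; t <= r; ++t) {
    k[t + r] = std::exp(-0.5 * t * t / (sigma * sigma));
    s += k[t + r];
  }
  for (size_t q = 0; q < k.size(); ++q) k[q] /= s;
  NumericMatrix tmp(H, W), out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double a = 0.0;
      for (int t = -r; t <= r; ++t) a += k[t + r] * img(clampi(i + t, 0, H - 1), j);
      tmp(i, j) = a;
    }
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double a = 0.0;
      for (int t = -r; t <= r; ++t) a += k[t + r] * tmp(i, clampi(j + t, 0, W - 1));
      out(i, j) = a;
    }
  return out;
}

// Stamp line segments with a Gaussian cross-section (sigma = width) onto a
// canvas by max-blending. Coordinates: x = column, y = row, origin at the
// top-left pixel corner, pixel (i, j) center at (j - 0.5, i - 0.5) in
// 1-based R indexing.
// [[Rcpp::export]]
NumericMatrix draw_segments_cpp(int H, int W,
                                NumericVector x0, NumericVector y0,
                                NumericVector x1, NumericVector y1,
                                NumericVector width, NumericVector intensity,
                                Nullable<NumericMatrix> base = R_NilValue) {
  NumericMatrix out = base.isNotNull() ? NumericMatrix(base) : NumericMatrix(H, W);
  int n = x0.size();
  for (int s = 0; s < n; ++s) {
    double ax = x0[s], ay = y0[s], bx = x1[s], by = y1[s];
    double w = width[s], A = intensity[s];
    double reach = 3.0 * w + 1.0;
    int jlo = clampi((int)std::floor(std::min(ax, bx) - reach), 0, W - 1);
    int jhi = clampi((int)std::ceil(std::max(ax, bx) + reach), 0, W - 1);
    int ilo = clampi((int)std::floor(std::min(ay, by) - reach), 0, H - 1);
    int ihi = clampi((int)std::ceil(std::max(ay, by) + reach), 0, H - 1);
    double dx = bx - ax, dy = by - ay, L2 = dx * dx + dy * dy;
    for (int j = jlo; j <= jhi; ++j) {
      for (int i = ilo; i <= ihi; ++i) {
        double px = j + 0.5, py = i + 0.5;
        double t = L2 > 0 ? ((px - ax) * dx + (py - ay) * dy) / L2 : 0.0;
        t = t < 0 ? 0 : (t > 1 ? 1 : t);
        double ddx = px - (ax + t * dx), ddy = py - (ay + t * dy);
        double v = A * std::exp(-0.5 * (ddx * ddx + ddy * ddy) / (w * w));
        if (v > out(i, j)) out(i, j) = v;
      }
    }
  }
  return out;
}

// 4-connected component labels of a logical mask (0 = background).
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  const int di[4] = {-1, 1, 0, 0};
  const int dj[4] = {0, 0, -1, 1};
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int, int> p = q.front();
        q.pop();
        for (int d = 0; d < 4; ++d) {
          int ii = p.first + di[d], jj = p.second + dj[d];
          if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
          if (mask(ii, jj) && lab(ii, jj) == 0) {
            lab(ii, jj) = next;
            q.push(std::make_pair(ii, jj));
          }
        }
      }
    }
  }
  return lab;
}
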