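// Low-level image operations for sperm-head detection and tracking:
// separable Gaussian blur, pyramid downsampling, min-eigenvalue corner
// response (Shi-Tomasi), and iterative Lucas-Kanade flow at one pyramid
// level. Images are R matrices indexed (row, col) = (y, x); all point
// coordinates are 0-based pixel centers with x along columns.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// bilinear interpolation with border clamping
static inline double bilin(const NumericMatrix& I, double x, double y) {
  int nr = I.nrow(), nc = I.ncol();
  x = clampd(x, 0.0, nc - 1.0);
  y = clampd(y, 0.0, nr - 1.0);
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  if (x0 > nc - 2) x0 = nc - 2;
  if (y0 > nr - 2) y0 = nr - 2;
  if (x0 < 0) x0 = 0;
  if (y0 < 0) y0 = 0;
  double ax = x - x0, ay = y - y0;
  double v00 = I(y0, x0), v01 = I(y0, x0 + 1);
  double v10 = I(y0 + 1, x0), v11 = I(y0 + 1, x0 + 1);
  return (1 - ay) * ((1 - ax) * v00 + ax * v01) + ay * ((1 - ax) * v10 + ax * v11);
}

// [[Rcpp::export]]
NumericMatrix cv_gauss_blur(const NumericMatrix& I, double sigma) {
  int nr = I.nrow(), nc = I.ncol();
  if (sigma <= 0) return clone(I);
  int rad = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * rad + 1);
  double s = 0.0;
  for (int i = -rad; i <= rad; ++i) {
    k[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + rad];
  }
  for (auto& v : k) v /= s;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  // horizontal pass (along columns = x), reflect borders; columns are
  // contiguous in R's column-major layout, so accumulate column by column
  for (int x = 0; x < nc; ++x) {
    double* tcol = &tmp(0, x);
    for (int i = -rad; i <= rad; ++i) {
      int xx = x + i;
      if (xx < 0) xx = -xx;
      if (xx > nc - 1) xx = 2 * (nc - 1) - xx;
      const double* icol = &I(0, xx);
      double kv = k[i + rad];
      for (int y = 0; y < nr; ++y) tcol[y] += kv * icol[y];
    }
  }
  // vertical pass within each column
  for (int x = 0; x < nc; ++x) {
    const double* tcol = &tmp(0, x);
    double* ocol = &out(0, x);
    for (int y = 0; y < nr; ++y) {
      double acc = 0.0;
      for (int i = -rad; i <= rad; ++i) {
        int yy = y + i;
        if (yy < 0) yy = -yy;
        if (yy > nr - 1) yy = 2 * (nr - 1) - yy;
        acc += k[i + rad] * tcol[yy];
      }
      ocol[y] = acc;
    }
  }
  return out;
}

// blur (sigma ~ 1) then decimate by 2
// [[Rcpp::export]]
NumericMatrix cv_pyr_down(const NumericMatrix& I) {
  NumericMatrix B = cv_gauss_blur(I, 1.0);
  int nr2 = (I.nrow() + 1) / 2, nc2 = (I.ncol() + 1) / 2;
  NumericMatrix out(nr2, nc2);
  for (int y = 0; y < nr2; ++y)
    for (int x = 0; x < nc2; ++x)
      out(y, x) = B(std::min(2 * y, (int)I.nrow() - 1), std::min(2 * x, (int)I.ncol() - 1));
  return out;
}

// Shi-Tomasi min-eigenvalue of the structure tensor summed over a
// (2*half+1)^2 block; gradients by central differences.
// [[Rcpp::export]]
NumericMatrix cv_corner_response(const NumericMatrix& I, int half) {
  int nr = I.nrow(), nc = I.ncol();
  NumericMatrix Ix(nr, nc), Iy(nr, nc), out(nr, nc);
  for (int y = 0; y < nr; ++y)
    for (int x = 0; x < nc; ++x) {
      int xm = std::max(0, x - 1), xp = std::min(nc - 1, x + 1);
      int ym = std::max(0, y - 1), yp = std::min(nr - 1, y + 1);
      Ix(y, x) = 0.5 * (I(y, xp) - I(y, xm));
      Iy(y, x) = 0.5 * (I(yp, x) - I(ym, x));
    }
  // box sums of Ix^2, Iy^2, IxIy via running accumulation per pixel
  for (int y = 0; y < nr; ++y) {
    int y0 = std::max(0, y - half), y1 = std::min(nr - 1, y + half);
    for (int x = 0; x < nc; ++x) {
      int x0 = std::max(0, x - half), x1 = std::min(nc - 1, x + half);
      double sxx = 0, syy = 0, sxy = 0;
      for (int yy = y0; yy <= y1; ++yy)
        for (int xx = x0; xx <= x1; ++xx) {
          double gx = Ix(yy, xx), gy = Iy(yy, xx);
          sxx += gx * gx;
          syy += gy * gy;
          sxy += gx * gy;
        }
      double tr = sxx + syy;
      double dd = std::sqrt((sxx - syy) * (sxx - syy) + 4.0 * sxy * sxy);
      out(y, x) = 0.5 * (tr - dd);
    }
  }
  return out;
}

// One pyramid level of iterative Lucas-Kanade. pts are (x, y) at this
// level's scale; guess is the initial displacement carried down from the
// coarser level. Returns the refined total displacement and a per-point
// success flag (false when the spatial-gradient matrix is degenerate or
// the tracked point leaves the image).
// [[Rcpp::export]]
List cv_lk_level(const NumericMatrix& prev, const NumericMatrix& nxt,
                 const NumericMatrix& pts, const NumericMatrix& guess,
                 int half_win, int max_iter, double eps) {
  int n = pts.nrow();
  int nr = prev.nrow(), nc = prev.ncol();
  NumericMatrix flow(n, 2);
  LogicalVector ok(n);
  int w = 2 * half_win + 1, npix = w * w;
  std::vector<double> Iv(npix), Gx(npix), Gy(npix);

  for (int i = 0; i < n; ++i) {
    double px = pts(i, 0), py = pts(i, 1);
    if (!R_finite(px) || !R_finite(py)) {
      ok[i] = false;
      continue;
    }
    double G11 = 0, G12 = 0, G22 = 0;
    int j = 0;
    for (int dy = -half_win; dy <= half_win; ++dy)
      for (int dx = -half_win; dx <= half_win; ++dx, ++j) {
        double x = px + dx, y = py + dy;
        Iv[j] = bilin(prev, x, y);
        Gx[j] = 0.5 * (bilin(prev, x + 1, y) - bilin(prev, x - 1, y));
        Gy[j] = 0.5 * (bilin(prev, x, y + 1) - bilin(prev, x, y - 1));
        G11 += Gx[j] * Gx[j];
        G12 += Gx[j] * Gy[j];
        G22 += Gy[j] * Gy[j];
      }
    double tr = G11 + G22;
    double mineig = 0.5 * (tr - std::sqrt((G11 - G22) * (G11 - G22) + 4.0 * G12 * G12));
    double det = G11 * G22 - G12 * G12;
    if (mineig <= 1e-12 + 1e-7 * tr || det <= 0) {
      flow(i, 0) = guess(i, 0);
      flow(i, 1) = guess(i, 1);
      ok[i] = false;
      continue;
    }
    double vx = guess(i, 0), vy = guess(i, 1);
    for (int it = 0; it < max_iter; ++it) {
      double b1 = 0, b2 = 0;
      j = 0;
      for (int dy = -half_win; dy <= half_win; ++dy)
        for (int dx = -half_win; dx <= half_win; ++dx, ++j) {
          double diff = Iv[j] - bilin(nxt, px + dx + vx, py + dy + vy);
          b1 += diff * Gx[j];
          b2 += diff * Gy[j];
        }
      double dvx = (G22 * b1 - G12 * b2) / det;
      double dvy = (G11 * b2 - G12 * b1) / det;
      vx += dvx;
      vy += dvy;
      if (dvx * dvx + dvy * dvy < eps * eps) break;
    }
    flow(i, 0) = vx;
    flow(i, 1) = vy;
    double qx = px + vx, qy = py + vy;
    ok[i] = (qx >= 0 && qx <= nc - 1.0 && qy >= 0 && qy <= nr - 1.0);
  }
  return List::create(Named("flow") = flow, Named("ok") = ok);
}
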