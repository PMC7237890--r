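// Pyramidal iterative Lucas-Kanade dense optical flow, plus bilinear
// footprint sampling used when advecting superpixel centroids.
// Matrices follow R's column-major layout; (r, c) zero-based -> r + c * H.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

static inline double bilinear(const std::vector<double>& img, int H, int W,
                              double r, double c) {
  r = clampd(r, 0.0, H - 1.0);
  c = clampd(c, 0.0, W - 1.0);
  int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
  int r1 = r0 + 1 < H ? r0 + 1 : r0;
  int c1 = c0 + 1 < W ? c0 + 1 : c0;
  double fr = r - r0, fc = c - c0;
  return (1 - fr) * (1 - fc) * img[r0 + c0 * H] +
         (1 - fr) * fc       * img[r0 + c1 * H] +
         fr       * (1 - fc) * img[r1 + c0 * H] +
         fr       * fc       * img[r1 + c1 * H];
}

// 2x2 block-average downsample
static void downsample(const std::vector<double>& src, int H, int W,
                       std::vector<double>& dst, int& H2, int& W2) {
  H2 = H / 2; W2 = W / 2;
  dst.assign((size_t)H2 * W2, 0.0);
  for (int c = 0; c < W2; ++c)
    for (int r = 0; r < H2; ++r)
      dst[r + (size_t)c * H2] = 0.25 * (src[2 * r + (size_t)(2 * c) * H] +
                                        src[2 * r + 1 + (size_t)(2 * c) * H] +
                                        src[2 * r + (size_t)(2 * c + 1) * H] +
                                        src[2 * r + 1 + (size_t)(2 * c + 1) * H]);
}

// windowed box sum via integral image (window clipped at borders)
static void boxsum(const std::vector<double>& src, int H, int W, int w,
                   std::vector<double>& out,
                   std::vector<double>& integral /* scratch (H+1)x(W+1) */) {
  int HI = H + 1, WI = W + 1;
  integral.assign((size_t)HI * WI, 0.0);
  for (int c = 1; c < WI; ++c) {
    double colsum = 0.0;
    for (int r = 1; r < HI; ++r) {
      colsum += src[(r - 1) + (size_t)(c - 1) * H];
      integral[r + (size_t)c * HI] = integral[r + (size_t)(c - 1) * HI] + colsum;
    }
  }
  out.assign((size_t)H * W, 0.0);
  for (int c = 0; c < W; ++c) {
    int c0 = c - w < 0 ? 0 : c - w;
    int c1 = c + w + 1 > W ? W : c + w + 1;
    for (int r = 0; r < H; ++r) {
      int r0 = r - w < 0 ? 0 : r - w;
      int r1 = r + w + 1 > H ? H : r + w + 1;
      out[r + (size_t)c * H] = integral[r1 + (size_t)c1 * HI] -
                               integral[r0 + (size_t)c1 * HI] -
                               integral[r1 + (size_t)c0 * HI] +
                               integral[r0 + (size_t)c0 * HI];
    }
  }
}

// one pyramid level of iterative LK; u, v are modified in place (px)
static void lk_level(const std::vector<double>& A, const std::vector<double>& B,
                     int H, int W, int win, int iters,
                     std::vector<double>& u, std::vector<double>& v) {
  size_t n = (size_t)H * W;
  std::vector<double> warp(n), Ix(n), Iy(n), It(n);
  std::vector<double> sxx, sxy, syy, sxt, syt, scratch, prod(n);
  const double reg = 1e-6;

  for (int it = 0; it < iters; ++it) {
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r) {
        size_t i = r + (size_t)c * H;
        warp[i] = bilinear(B, H, W, r + v[i], c + u[i]);
      }
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r) {
        size_t i = r + (size_t)c * H;
        int cp = c + 1 < W ? c + 1 : c, cm = c > 0 ? c - 1 : 0;
        int rp = r + 1 < H ? r + 1 : r, rm = r > 0 ? r - 1 : 0;
        double denc = (cp - cm) > 0 ? (double)(cp - cm) : 1.0;
        double denr = (rp - rm) > 0 ? (double)(rp - rm) : 1.0;
        Ix[i] = 0.5 * ((A[r + (size_t)cp * H] - A[r + (size_t)cm * H]) / denc +
                       (warp[r + (size_t)cp * H] - warp[r + (size_t)cm * H]) / denc);
        Iy[i] = 0.5 * ((A[rp + (size_t)c * H] - A[rm + (size_t)c * H]) / denr +
                       (warp[rp + (size_t)c * H] - warp[rm + (size_t)c * H]) / denr);
        It[i] = warp[i] - A[i];
      }
    for (size_t i = 0; i < n; ++i) prod[i] = Ix[i] * Ix[i];
    boxsum(prod, H, W, win, sxx, scratch);
    for (size_t i = 0; i < n; ++i) prod[i] = Ix[i] * Iy[i];
    boxsum(prod, H, W, win, sxy, scratch);
    for (size_t i = 0; i < n; ++i) prod[i] = Iy[i] * Iy[i];
    boxsum(prod, H, W, win, syy, scratch);
    for (size_t i = 0; i < n; ++i) prod[i] = Ix[i] * It[i];
    boxsum(prod, H, W, win, sxt, scratch);
    for (size_t i = 0; i < n; ++i) prod[i] = Iy[i] * It[i];
    boxsum(prod, H, W, win, syt, scratch);
    for (size_t i = 0; i < n; ++i) {
      double a = sxx[i] + reg, bb = sxy[i], d = syy[i] + reg;
      double det = a * d - bb * bb;
      if (det < 1e-12) continue;
      double du = (-d * sxt[i] + bb * syt[i]) / det;
      double dv = (bb * sxt[i] - a * syt[i]) / det;
      // limit per-iteration update to the window radius for stability
      du = clampd(du, -(double)win, (double)win);
      dv = clampd(dv, -(double)win, (double)win);
      u[i] += du;
      v[i] += dv;
    }
  }
}

// [[Rcpp::export(name = ".lk_flow")]]
List lk_flow_cpp(NumericMatrix a, NumericMatrix b, int levels = 3,
                 int win = 7, int iters = 3) {
  int H = a.nrow(), W = a.ncol();
  if (b.nrow() != H || b.ncol() != W)
    stop("frames must have identical dimensions");
  std::vector<std::vector<double> > pyrA, pyrB;
  std::vector<int> Hs, Ws;
  pyrA.emplace_back(a.begin(), a.end());
  pyrB.emplace_back(b.begin(), b.end());
  Hs.push_back(H); Ws.push_back(W);
  for (int l = 1; l < levels; ++l) {
    if (Hs.back() < 16 || Ws.back() < 16) break;
    std::vector<double> da, db; int h2, w2;
    downsample(pyrA.back(), Hs.back(), Ws.back(), da, h2, w2);
    downsample(pyrB.back(), Hs.back(), Ws.back(), db, h2, w2);
    pyrA.push_back(da); pyrB.push_back(db);
    Hs.push_back(h2); Ws.push_back(w2);
  }
  int top = (int)pyrA.size() - 1;
  std::vector<double> u((size_t)Hs[top] * Ws[top], 0.0),
                      v((size_t)Hs[top] * Ws[top], 0.0);
  for (int l = top; l >= 0; --l) {
    lk_level(pyrA[l], pyrB[l], Hs[l], Ws[l], win, iters, u, v);
    if (l > 0) {
      // upscale flow to the next finer level (values doubled)
      int Hf = Hs[l - 1], Wf = Ws[l - 1];
      std::vector<double> uf((size_t)Hf * Wf), vf((size_t)Hf * Wf);
      for (int c = 0; c < Wf; ++c)
        for (int r = 0; r < Hf; ++r) {
          double rs = (r + 0.5) / 2.0 - 0.5, cs = (c + 0.5) / 2.0 - 0.5;
          uf[r + (size_t)c * Hf] = 2.0 * bilinear(u, Hs[l], Ws[l], rs, cs);
          vf[r + (size_t)c * Hf] = 2.0 * bilinear(v, Hs[l], Ws[l], rs, cs);
        }
      u.swap(uf); v.swap(vf);
    }
  }
  NumericMatrix fx(H, W), fy(H, W);
  std::copy(u.begin(), u.end(), fx.begin());
  std::copy(v.begin(), v.end(), fy.begin());
  return List::create(_["dx"] = fx, _["dy"] = fy);
}

// mean flow over a square footprint of `side` px centred on each (cx, cy),
// sampled at unit spacing with bilinear interpolation; coordinates are
// zero-based pixel positions (col = x, row = y)
// [[Rcpp::export(name = ".footprint_mean_flow")]]
NumericMatrix footprint_mean_flow_cpp(NumericMatrix fx, NumericMatrix fy,
                                      NumericVector cx, NumericVector cy,
                                      int side) {
  int H = fx.nrow(), W = fx.ncol();
  int n = cx.size();
  if (side < 1) stop("side must be >= 1");
  double half = (side - 1) / 2.0;
  std::vector<double> u(fx.begin(), fx.end()), v(fy.begin(), fy.end());
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    double sx = 0.0, sy = 0.0;
    for (int a = 0; a < side; ++a)
      for (int bb = 0; bb < side; ++bb) {
        double r = cy[i] - half + a, c = cx[i] - half + bb;
        sx += bilinear(u, H, W, r, c);
        sy += bilinear(v, H, W, r, c);
      }
    out(i, 0) = sx / (side * side);
    out(i, 1) = sy / (side * side);
  }
  return out;
}
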