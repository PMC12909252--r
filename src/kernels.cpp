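// Dense numeric kernels for the growth-prediction network and the volume I/O
// layer. All feature maps are channel-first R arrays laid out (C, D, H, W)
// (column-major, so the channel index is fastest); convolution weights are
// (Cin*k^3) x Cout matrices with row index ci + Cin*(kd + k*(kh + k*kw)).
#include <RcppArmadillo.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
# define FCONE
#endif
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_dim(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// im2col: columns indexed by output voxel (d fastest), rows by (ci, kd, kh, kw)
static void im2col(const double* x, int C, int D, int H, int W,
                   int k, int stride, int pad, arma::mat& col) {
  const int Do = out_dim(D, k, stride, pad);
  const int Ho = out_dim(H, k, stride, pad);
  const int Wo = out_dim(W, k, stride, pad);
  col.zeros(C * k * k * k, (arma::uword)Do * Ho * Wo);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      for (int d0 = 0; d0 < Do; ++d0) {
        const arma::uword j = (arma::uword)d0 + (arma::uword)Do * (ho + (arma::uword)Ho * wo);
        double* cj = col.colptr(j);
        for (int kw = 0; kw < k; ++kw) {
          const int wi = wo * stride - pad + kw;
          if (wi < 0 || wi >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            const int hi = ho * stride - pad + kh;
            if (hi < 0 || hi >= H) continue;
            for (int kd = 0; kd < k; ++kd) {
              const int di = d0 * stride - pad + kd;
              if (di < 0 || di >= D) continue;
              const double* src = x + (size_t)C * (di + (size_t)D * (hi + (size_t)H * wi));
              double* dst = cj + (size_t)C * (kd + k * (kh + k * kw));
              std::memcpy(dst, src, C * sizeof(double));
            }
          }
        }
      }
    }
  }
}

// adjoint of im2col: scatter-add columns back into the input grid
static void col2im(const arma::mat& col, int C, int D, int H, int W,
                   int k, int stride, int pad, double* gx) {
  const int Do = out_dim(D, k, stride, pad);
  const int Ho = out_dim(H, k, stride, pad);
  const int Wo = out_dim(W, k, stride, pad);
  std::fill(gx, gx + (size_t)C * D * H * W, 0.0);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      for (int d0 = 0; d0 < Do; ++d0) {
        const arma::uword j = (arma::uword)d0 + (arma::uword)Do * (ho + (arma::uword)Ho * wo);
        const double* cj = col.colptr(j);
        for (int kw = 0; kw < k; ++kw) {
          const int wi = wo * stride - pad + kw;
          if (wi < 0 || wi >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            const int hi = ho * stride - pad + kh;
            if (hi < 0 || hi >= H) continue;
            for (int kd = 0; kd < k; ++kd) {
              const int di = d0 * stride - pad + kd;
              if (di < 0 || di >= D) continue;
              double* dst = gx + (size_t)C * (di + (size_t)D * (hi + (size_t)H * wi));
              const double* src = cj + (size_t)C * (kd + k * (kh + k * kw));
              for (int c = 0; c < C; ++c) dst[c] += src[c];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv3d_fwd")]]
NumericVector conv3d_fwd(NumericVector x, IntegerVector xdim,
                         NumericMatrix w, int k, int stride, int pad) {
  const int C = xdim[0], D = xdim[1], H = xdim[2], W = xdim[3];
  const int Co = w.ncol();
  const int Do = out_dim(D, k, stride, pad);
  const int Ho = out_dim(H, k, stride, pad);
  const int Wo = out_dim(W, k, stride, pad);
  arma::mat col;
  im2col(REAL(x), C, D, H, W, k, stride, pad, col);
  const arma::mat wm(const_cast<double*>(w.begin()), w.nrow(), w.ncol(), false, true);
  arma::mat y = wm.t() * col;  // Co x Nout, Co fastest when flattened column-major
  NumericVector out(y.begin(), y.end());
  out.attr("dim") = IntegerVector::create(Co, Do, Ho, Wo);
  return out;
}

// [[Rcpp::export(name = ".conv3d_bwd")]]
List conv3d_bwd(NumericVector x, IntegerVector xdim, NumericMatrix w,
                NumericVector gy, int k, int stride, int pad,
                bool need_gx, bool need_gw) {
  const int C = xdim[0], D = xdim[1], H = xdim[2], W = xdim[3];
  const int Co = w.ncol();
  const int Do = out_dim(D, k, stride, pad);
  const int Ho = out_dim(H, k, stride, pad);
  const int Wo = out_dim(W, k, stride, pad);
  const arma::uword Nout = (arma::uword)Do * Ho * Wo;
  const arma::mat wm(const_cast<double*>(w.begin()), w.nrow(), w.ncol(), false, true);
  const arma::mat gym(const_cast<double*>(REAL(gy)), Co, Nout, false, true);

  NumericVector gx;
  if (need_gx) {
    arma::mat gcol = wm * gym;
    gx = NumericVector((size_t)C * D * H * W);
    col2im(gcol, C, D, H, W, k, stride, pad, REAL(gx));
    gx.attr("dim") = xdim;
  }
  NumericMatrix gw;
  NumericVector gb;
  if (need_gw) {
    arma::mat col;
    im2col(REAL(x), C, D, H, W, k, stride, pad, col);
    arma::mat gwm = col * gym.t();
    gw = NumericMatrix(w.nrow(), w.ncol());
    std::copy(gwm.begin(), gwm.end(), gw.begin());
    arma::vec gbv = arma::sum(gym, 1);
    gb = NumericVector(gbv.begin(), gbv.end());
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// ---- fast path for the common 3x3x3 / stride 1 / pad 1 convolution --------
// The input is copied once into a zero-padded grid; each of the 27 kernel
// offsets is then a pure column shift of that (C x Np) matrix, so the whole
// convolution is 27 dense GEMM accumulations with no im2col buffer.

static void pad_grid(const double* x, int C, int D, int H, int W,
                     std::vector<double>& xp, int& Dp, int& Hp, int& Wp) {
  Dp = D + 2; Hp = H + 2; Wp = W + 2;
  xp.assign((size_t)C * Dp * Hp * Wp, 0.0);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      const double* src = x + (size_t)C * D * (h + (size_t)H * w);
      double* dst = &xp[(size_t)C * (1 + (size_t)Dp * ((h + 1) + (size_t)Hp * (w + 1)))];
      std::memcpy(dst, src, (size_t)C * D * sizeof(double));
    }
}

static void crop_grid(const std::vector<double>& yp, int C, int D, int H, int W,
                      double* y) {
  const int Dp = D + 2, Hp = H + 2;
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      const double* src = &yp[(size_t)C * (1 + (size_t)Dp * ((h + 1) + (size_t)Hp * (w + 1)))];
      double* dst = y + (size_t)C * D * (h + (size_t)H * w);
      std::memcpy(dst, src, (size_t)C * D * sizeof(double));
    }
}

// offset of kernel tap (kd, kh, kw) in flattened padded coordinates
static inline int tap_shift(int kd, int kh, int kw, int Dp, int Hp) {
  return (kd - 1) + Dp * ((kh - 1) + Hp * (kw - 1));
}

// [[Rcpp::export(name = ".conv3d_s1_fwd")]]
NumericVector conv3d_s1_fwd(NumericVector x, IntegerVector xdim,
                            NumericMatrix w) {
  const int C = xdim[0], D = xdim[1], H = xdim[2], W = xdim[3];
  const int Co = w.ncol();
  const int ldw = w.nrow();  // C * 27
  int Dp, Hp, Wp;
  std::vector<double> xp;
  pad_grid(REAL(x), C, D, H, W, xp, Dp, Hp, Wp);
  const int Np = Dp * Hp * Wp;
  std::vector<double> yp((size_t)Co * Np, 0.0);
  const double one = 1.0;
  int tap = 0;
  for (int kw = 0; kw < 3; ++kw)
    for (int kh = 0; kh < 3; ++kh)
      for (int kd = 0; kd < 3; ++kd, ++tap) {
        const int sh = tap_shift(kd, kh, kw, Dp, Hp);
        const int lo = std::max(0, -sh);
        const int hi = std::min(Np - 1, Np - 1 - sh);
        const int n = hi - lo + 1;
        if (n <= 0) continue;
        // yp[:, lo..hi] += Wtap' * xp[:, lo+sh .. hi+sh]
        F77_CALL(dgemm)("T", "N", &Co, &n, &C, &one,
                        &w[0] + (size_t)tap * C, &ldw,
                        xp.data() + (size_t)C * (lo + sh), &C, &one,
                        yp.data() + (size_t)Co * lo, &Co FCONE FCONE);
      }
  NumericVector out((size_t)Co * D * H * W);
  crop_grid(yp, Co, D, H, W, REAL(out));
  out.attr("dim") = IntegerVector::create(Co, D, H, W);
  return out;
}

// [[Rcpp::export(name = ".conv3d_s1_bwd")]]
List conv3d_s1_bwd(NumericVector x, IntegerVector xdim, NumericMatrix w,
                   NumericVector gy, bool need_gx, bool need_gw) {
  const int C = xdim[0], D = xdim[1], H = xdim[2], W = xdim[3];
  const int Co = w.ncol();
  const int ldw = w.nrow();
  int Dp, Hp, Wp;
  std::vector<double> gyp;
  pad_grid(REAL(gy), Co, D, H, W, gyp, Dp, Hp, Wp);
  const int Np = Dp * Hp * Wp;
  const double one = 1.0, zero = 0.0;
  NumericVector gx;
  if (need_gx) {
    std::vector<double> gxp((size_t)C * Np, 0.0);
    int tap = 0;
    for (int kw = 0; kw < 3; ++kw)
      for (int kh = 0; kh < 3; ++kh)
        for (int kd = 0; kd < 3; ++kd, ++tap) {
          const int sh = tap_shift(kd, kh, kw, Dp, Hp);
          const int lo = std::max(0, -sh);
          const int hi = std::min(Np - 1, Np - 1 - sh);
          const int n = hi - lo + 1;
          if (n <= 0) continue;
          // gxp[:, lo+sh .. ] += Wtap * gyp[:, lo..hi]
          F77_CALL(dgemm)("N", "N", &C, &n, &Co, &one,
                          &w[0] + (size_t)tap * C, &ldw,
                          gyp.data() + (size_t)Co * lo, &Co, &one,
                          gxp.data() + (size_t)C * (lo + sh), &C FCONE FCONE);
        }
    gx = NumericVector((size_t)C * D * H * W);
    crop_grid(gxp, C, D, H, W, REAL(gx));
    gx.attr("dim") = xdim;
  }
  NumericMatrix gw;
  NumericVector gb;
  if (need_gw) {
    std::vector<double> xp;
    int Dp2, Hp2, Wp2;
    pad_grid(REAL(x), C, D, H, W, xp, Dp2, Hp2, Wp2);
    gw = NumericMatrix(w.nrow(), w.ncol());
    int tap = 0;
    for (int kw = 0; kw < 3; ++kw)
      for (int kh = 0; kh < 3; ++kh)
        for (int kd = 0; kd < 3; ++kd, ++tap) {
          const int sh = tap_shift(kd, kh, kw, Dp, Hp);
          const int lo = std::max(0, -sh);
          const int hi = std::min(Np - 1, Np - 1 - sh);
          const int n = hi - lo + 1;
          if (n <= 0) continue;
          // gW_tap (C x Co) = xp[:, lo+sh..] * gyp[:, lo..hi]'
          F77_CALL(dgemm)("N", "T", &C, &Co, &n, &one,
                          xp.data() + (size_t)C * (lo + sh), &C,
                          gyp.data() + (size_t)Co * lo, &Co, &zero,
                          &gw[0] + (size_t)tap * C, &ldw FCONE FCONE);
        }
    const double* g = REAL(gy);
    gb = NumericVector(Co);
    const size_t nvox = (size_t)D * H * W;
    for (size_t p = 0; p < nvox; ++p)
      for (int c = 0; c < Co; ++c) gb[c] += g[c + (size_t)Co * p];
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Trilinear warp: out(c, p) = vol_c(p + u(p)), border-clamped sampling.
// u is (3, D, H, W) with components ordered (du, dh, dw) in voxel units.
// [[Rcpp::export(name = ".warp_fwd")]]
NumericVector warp_fwd(NumericVector vol, IntegerVector vdim, NumericVector u) {
  const int C = vdim[0], D = vdim[1], H = vdim[2], W = vdim[3];
  const double* v = REAL(vol);
  const double* uu = REAL(u);
  NumericVector out((size_t)C * D * H * W);
  double* o = REAL(out);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int d = 0; d < D; ++d) {
        const size_t p = (size_t)d + (size_t)D * (h + (size_t)H * w);
        const double sd = clampd(d + uu[3 * p], 0.0, D - 1.0);
        const double sh = clampd(h + uu[3 * p + 1], 0.0, H - 1.0);
        const double sw = clampd(w + uu[3 * p + 2], 0.0, W - 1.0);
        const int d0 = (int)std::floor(sd), h0 = (int)std::floor(sh), w0 = (int)std::floor(sw);
        const int d1 = std::min(d0 + 1, D - 1), h1 = std::min(h0 + 1, H - 1), w1 = std::min(w0 + 1, W - 1);
        const double fd = sd - d0, fh = sh - h0, fw = sw - w0;
        for (int c = 0; c < C; ++c) {
          #define V(dd, hh, ww) v[c + (size_t)C * ((dd) + (size_t)D * ((hh) + (size_t)H * (ww)))]
          const double c00 = V(d0, h0, w0) * (1 - fd) + V(d1, h0, w0) * fd;
          const double c10 = V(d0, h1, w0) * (1 - fd) + V(d1, h1, w0) * fd;
          const double c01 = V(d0, h0, w1) * (1 - fd) + V(d1, h0, w1) * fd;
          const double c11 = V(d0, h1, w1) * (1 - fd) + V(d1, h1, w1) * fd;
          #undef V
          const double c0 = c00 * (1 - fh) + c10 * fh;
          const double c1 = c01 * (1 - fh) + c11 * fh;
          o[c + C * p] = c0 * (1 - fw) + c1 * fw;
        }
      }
  out.attr("dim") = vdim;
  return out;
}

// [[Rcpp::export(name = ".warp_bwd")]]
List warp_bwd(NumericVector vol, IntegerVector vdim, NumericVector u,
              NumericVector gy) {
  const int C = vdim[0], D = vdim[1], H = vdim[2], W = vdim[3];
  const double* v = REAL(vol);
  const double* uu = REAL(u);
  const double* g = REAL(gy);
  NumericVector gvol((size_t)C * D * H * W);
  NumericVector gu((size_t)3 * D * H * W);
  double* gv = REAL(gvol);
  double* gud = REAL(gu);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int d = 0; d < D; ++d) {
        const size_t p = (size_t)d + (size_t)D * (h + (size_t)H * w);
        const double rd = d + uu[3 * p], rh = h + uu[3 * p + 1], rw = w + uu[3 * p + 2];
        const bool in_d = rd > 0.0 && rd < D - 1.0;
        const bool in_h = rh > 0.0 && rh < H - 1.0;
        const bool in_w = rw > 0.0 && rw < W - 1.0;
        const double sd = clampd(rd, 0.0, D - 1.0);
        const double sh = clampd(rh, 0.0, H - 1.0);
        const double sw = clampd(rw, 0.0, W - 1.0);
        const int d0 = (int)std::floor(sd), h0 = (int)std::floor(sh), w0 = (int)std::floor(sw);
        const int d1 = std::min(d0 + 1, D - 1), h1 = std::min(h0 + 1, H - 1), w1 = std::min(w0 + 1, W - 1);
        const double fd = sd - d0, fh = sh - h0, fw = sw - w0;
        double gsd = 0, gsh = 0, gsw = 0;
        for (int c = 0; c < C; ++c) {
          const double go = g[c + C * p];
          if (go == 0) continue;
          #define IDX(dd, hh, ww) (c + (size_t)C * ((dd) + (size_t)D * ((hh) + (size_t)H * (ww))))
          const double w000 = (1 - fd) * (1 - fh) * (1 - fw), w100 = fd * (1 - fh) * (1 - fw);
          const double w010 = (1 - fd) * fh * (1 - fw), w110 = fd * fh * (1 - fw);
          const double w001 = (1 - fd) * (1 - fh) * fw, w101 = fd * (1 - fh) * fw;
          const double w011 = (1 - fd) * fh * fw, w111 = fd * fh * fw;
          gv[IDX(d0, h0, w0)] += go * w000; gv[IDX(d1, h0, w0)] += go * w100;
          gv[IDX(d0, h1, w0)] += go * w010; gv[IDX(d1, h1, w0)] += go * w110;
          gv[IDX(d0, h0, w1)] += go * w001; gv[IDX(d1, h0, w1)] += go * w101;
          gv[IDX(d0, h1, w1)] += go * w011; gv[IDX(d1, h1, w1)] += go * w111;
          const double v000 = v[IDX(d0, h0, w0)], v100 = v[IDX(d1, h0, w0)];
          const double v010 = v[IDX(d0, h1, w0)], v110 = v[IDX(d1, h1, w0)];
          const double v001 = v[IDX(d0, h0, w1)], v101 = v[IDX(d1, h0, w1)];
          const double v011 = v[IDX(d0, h1, w1)], v111 = v[IDX(d1, h1, w1)];
          #undef IDX
          gsd += go * ((v100 - v000) * (1 - fh) * (1 - fw) + (v110 - v010) * fh * (1 - fw) +
                       (v101 - v001) * (1 - fh) * fw + (v111 - v011) * fh * fw);
          gsh += go * ((v010 - v000) * (1 - fd) * (1 - fw) + (v110 - v100) * fd * (1 - fw) +
                       (v011 - v001) * (1 - fd) * fw + (v111 - v101) * fd * fw);
          gsw += go * ((v001 - v000) * (1 - fd) * (1 - fh) + (v101 - v100) * fd * (1 - fh) +
                       (v011 - v010) * (1 - fd) * fh + (v111 - v110) * fd * fh);
        }
        gud[3 * p] = in_d ? gsd : 0.0;
        gud[3 * p + 1] = in_h ? gsh : 0.0;
        gud[3 * p + 2] = in_w ? gsw : 0.0;
      }
  gvol.attr("dim") = vdim;
  gu.attr("dim") = IntegerVector::create(3, D, H, W);
  return List::create(_["gvol"] = gvol, _["gu"] = gu);
}

// Separable (2r+1)^3 box-window sum with zero padding; self-adjoint, so the
// backward pass is the same operation applied to the output gradient.
// [[Rcpp::export(name = ".boxsum3d")]]
NumericVector boxsum3d(NumericVector x, IntegerVector xdim, int r) {
  const int C = xdim[0], D = xdim[1], H = xdim[2], W = xdim[3];
  const size_t n = (size_t)C * D * H * W;
  std::vector<double> a(REAL(x), REAL(x) + n), b(n, 0.0);
  // pass along D
  for (size_t w = 0; w < (size_t)W; ++w)
    for (size_t h = 0; h < (size_t)H; ++h)
      for (int d = 0; d < D; ++d) {
        const int lo = std::max(0, d - r), hi = std::min(D - 1, d + r);
        double* dst = &b[(size_t)C * (d + (size_t)D * (h + (size_t)H * w))];
        std::fill(dst, dst + C, 0.0);
        for (int dd = lo; dd <= hi; ++dd) {
          const double* src = &a[(size_t)C * (dd + (size_t)D * (h + (size_t)H * w))];
          for (int c = 0; c < C; ++c) dst[c] += src[c];
        }
      }
  // pass along H
  a.swap(b);
  for (size_t w = 0; w < (size_t)W; ++w)
    for (int h = 0; h < H; ++h) {
      const int lo = std::max(0, h - r), hi = std::min(H - 1, h + r);
      for (size_t d = 0; d < (size_t)D; ++d) {
        double* dst = &b[(size_t)C * (d + (size_t)D * (h + (size_t)H * w))];
        std::fill(dst, dst + C, 0.0);
        for (int hh = lo; hh <= hi; ++hh) {
          const double* src = &a[(size_t)C * (d + (size_t)D * (hh + (size_t)H * w))];
          for (int c = 0; c < C; ++c) dst[c] += src[c];
        }
      }
    }
  // pass along W
  a.swap(b);
  for (int w = 0; w < W; ++w) {
    const int lo = std::max(0, w - r), hi = std::min(W - 1, w + r);
    for (size_t h = 0; h < (size_t)H; ++h)
      for (size_t d = 0; d < (size_t)D; ++d) {
        double* dst = &b[(size_t)C * (d + (size_t)D * (h + (size_t)H * w))];
        std::fill(dst, dst + C, 0.0);
        for (int ww = lo; ww <= hi; ++ww) {
          const double* src = &a[(size_t)C * (d + (size_t)D * (h + (size_t)H * ww))];
          for (int c = 0; c < C; ++c) dst[c] += src[c];
        }
      }
  }
  NumericVector out(b.begin(), b.end());
  out.attr("dim") = xdim;
  return out;
}

// Grid resampling for preprocessing: sample output voxel centres (0-based,
// voxel i at physical i*spacing) in the input grid; border-clamped.
// [[Rcpp::export(name = ".resample3d")]]
NumericVector resample3d(NumericVector img, IntegerVector idim,
                         NumericVector sp_in, NumericVector sp_out,
                         IntegerVector odim, bool nearest) {
  const int D = idim[0], H = idim[1], W = idim[2];
  const int Do = odim[0], Ho = odim[1], Wo = odim[2];
  const double* v = REAL(img);
  NumericVector out((size_t)Do * Ho * Wo);
  double* o = REAL(out);
  for (int w = 0; w < Wo; ++w)
    for (int h = 0; h < Ho; ++h)
      for (int d = 0; d < Do; ++d) {
        const double sd = clampd(d * sp_out[0] / sp_in[0], 0.0, D - 1.0);
        const double sh = clampd(h * sp_out[1] / sp_in[1], 0.0, H - 1.0);
        const double sw = clampd(w * sp_out[2] / sp_in[2], 0.0, W - 1.0);
        double val;
        if (nearest) {
          val = v[(size_t)std::lround(sd) + (size_t)D * ((size_t)std::lround(sh) + (size_t)H * (size_t)std::lround(sw))];
        } else {
          const int d0 = (int)std::floor(sd), h0 = (int)std::floor(sh), w0 = (int)std::floor(sw);
          const int d1 = std::min(d0 + 1, D - 1), h1 = std::min(h0 + 1, H - 1), w1 = std::min(w0 + 1, W - 1);
          const double fd = sd - d0, fh = sh - h0, fw = sw - w0;
          #define V(dd, hh, ww) v[(size_t)(dd) + (size_t)D * ((hh) + (size_t)H * (ww))]
          const double c00 = V(d0, h0, w0) * (1 - fd) + V(d1, h0, w0) * fd;
          const double c10 = V(d0, h1, w0) * (1 - fd) + V(d1, h1, w0) * fd;
          const double c01 = V(d0, h0, w1) * (1 - fd) + V(d1, h0, w1) * fd;
          const double c11 = V(d0, h1, w1) * (1 - fd) + V(d1, h1, w1) * fd;
          #undef V
          val = (c00 * (1 - fh) + c10 * fh) * (1 - fw) + (c01 * (1 - fh) + c11 * fh) * fw;
        }
        o[(size_t)d + (size_t)Do * (h + (size_t)Ho * w)] = val;
      }
  out.attr("dim") = odim;
  return out;
}
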