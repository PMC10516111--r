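// Dense numeric kernels for the lat-long spherical grid.
#include <cstring>
// Array layout follows R column-major conventions:
//   feature/activation tensors: [H, W, C, N]  (H = latitude rows)
//   per-sample images:          [H, W, C]
//   displacement fields:        [H, W, 2]  (channel 1 = lat, 2 = lon)
// Longitude (W axis) is periodic; latitude (H axis) is clamped/replicated —
// the grid is cell-centered and excludes the exact poles.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int clampi(int i, int lo, int hi) {
  return i < lo ? lo : (i > hi ? hi : i);
}
static inline int wrapi(int j, int W) {
  j %= W;
  if (j < 0) j += W;
  return j;
}

// ---------------------------------------------------------------------------
// 3x3 convolution, stride 1, wrap-in-longitude / replicate-in-latitude padding.
// Implemented as im2col + GEMM per sample.
// ---------------------------------------------------------------------------

// The batched im2col matrix holds all N samples stacked row-wise so each
// layer runs a single sgemm. Activations move through the network in double
// precision at the R level; the GEMM runs in single precision (the usual
// arithmetic for network training — accumulation effects are orders of
// magnitude below the optimization noise floor).
static void im2col_sphere_f(const double* x, int H, int W, int C, int N,
                            arma::fmat& M) {
  // M: (H*W*N) x (9*C), column q = tap*C + c, tap = a*3 + b
  size_t HW = (size_t)H * W;
  for (int c = 0; c < C; ++c) {
    for (int a = 0; a < 3; ++a) {
      int di = a - 1;
      for (int b = 0; b < 3; ++b) {
        int dj = b - 1;
        float* Mc = M.colptr((a * 3 + b) * C + c);
        for (int n = 0; n < N; ++n) {
          const double* xch = x + HW * (c + (size_t)C * n);
          float* Mn = Mc + HW * n;
          for (int j = 0; j < W; ++j) {
            int jj = wrapi(j + dj, W);
            const double* src = xch + (size_t)H * jj;
            float* dst = Mn + (size_t)H * j;
            if (di == 0) {
              for (int i = 0; i < H; ++i) dst[i] = (float)src[i];
            } else if (di < 0) {  // row -1 replicates row 0
              dst[0] = (float)src[0];
              for (int i = 1; i < H; ++i) dst[i] = (float)src[i - 1];
            } else {  // row H replicates row H-1
              for (int i = 0; i < H - 1; ++i) dst[i] = (float)src[i + 1];
              dst[H - 1] = (float)src[H - 1];
            }
          }
        }
      }
    }
  }
}

static arma::fmat weights_as_fmat(const NumericVector& w, int C, int Cout) {
  // w dims [3, 3, C, Cout]; returns (9*C) x Cout with rows matching im2col.
  arma::fmat Wm(9 * C, Cout);
  const double* wp = w.begin();
  for (int o = 0; o < Cout; ++o)
    for (int c = 0; c < C; ++c)
      for (int a = 0; a < 3; ++a)
        for (int b = 0; b < 3; ++b)
          Wm((a * 3 + b) * C + c, o) =
              (float)wp[a + 3 * b + 9 * c + (size_t)9 * C * o];
  return Wm;
}

// `slope`: negative-side slope of a fused leaky-rectifier applied to the
// output; pass NA (or any negative sentinel via R wrapper) to disable.
// [[Rcpp::export]]
NumericVector conv2d_sphere_fwd(NumericVector x, NumericVector w,
                                NumericVector bias,
                                double slope = -1.0) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3], Cout = wd[3];
  if (wd[2] != C) stop("channel mismatch between input and kernel");
  arma::fmat Wm = weights_as_fmat(w, C, Cout);
  NumericVector out((size_t)H * W * Cout * N);
  out.attr("dim") = IntegerVector::create(H, W, Cout, N);
  size_t HWN = (size_t)H * W * N;
  static thread_local std::vector<float> Mbuf, Obuf;
  if (Mbuf.size() < HWN * 9 * C) Mbuf.resize(HWN * 9 * C);
  if (Obuf.size() < HWN * Cout) Obuf.resize(HWN * Cout);
  arma::fmat M(Mbuf.data(), HWN, 9 * C, false, true);
  arma::fmat O(Obuf.data(), HWN, Cout, false, true);
  im2col_sphere_f(x.begin(), H, W, C, N, M);
  O = M * Wm;
  size_t HW = (size_t)H * W;
  double* op = out.begin();
  for (int n = 0; n < N; ++n)
    for (int o = 0; o < Cout; ++o) {
      const float* src = O.colptr(o) + HW * n;
      double* dst = op + HW * (o + (size_t)Cout * n);
      double bo = bias[o];
      if (slope >= 0) {
        for (size_t q = 0; q < HW; ++q) {
          double v = (double)src[q] + bo;
          dst[q] = v > 0 ? v : slope * v;
        }
      } else {
        for (size_t q = 0; q < HW; ++q) dst[q] = (double)src[q] + bo;
      }
    }
  return out;
}

// When the forward pass fused a leaky rectifier (slope >= 0), pass the node
// output (`act`): since the rectifier preserves sign, out > 0 identifies the
// positive branch and the incoming gradient is scaled accordingly.
// [[Rcpp::export]]
List conv2d_sphere_bwd(NumericVector x, NumericVector w, NumericVector gout,
                       Nullable<NumericVector> act = R_NilValue,
                       double slope = -1.0) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3], Cout = wd[3];
  arma::fmat Wm = weights_as_fmat(w, C, Cout);
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = xd;
  NumericVector gw(w.size());
  gw.attr("dim") = wd;
  NumericVector gb(Cout);
  size_t HW = (size_t)H * W;
  size_t HWN = HW * N;
  static thread_local std::vector<float> Mbuf2, Gbuf, GCbuf;
  if (Mbuf2.size() < HWN * 9 * C) Mbuf2.resize(HWN * 9 * C);
  if (Gbuf.size() < HWN * Cout) Gbuf.resize(HWN * Cout);
  if (GCbuf.size() < HWN * 9 * C) GCbuf.resize(HWN * 9 * C);
  arma::fmat M(Mbuf2.data(), HWN, 9 * C, false, true);
  arma::fmat G(Gbuf.data(), HWN, Cout, false, true);
  arma::fmat Gcols(GCbuf.data(), HWN, 9 * C, false, true);
  im2col_sphere_f(x.begin(), H, W, C, N, M);
  // gout [H,W,Cout,N] -> G (HW*N) x Cout, sample-major rows like M
  const double* ap = act.isNotNull() ?
      NumericVector(act.get()).begin() : (const double*)nullptr;
  for (int n = 0; n < N; ++n)
    for (int o = 0; o < Cout; ++o) {
      const double* src = gout.begin() + HW * (o + (size_t)Cout * n);
      float* dst = G.colptr(o) + HW * n;
      if (slope >= 0 && ap) {
        const double* av = ap + HW * (o + (size_t)Cout * n);
        for (size_t q = 0; q < HW; ++q)
          dst[q] = (float)(av[q] > 0 ? src[q] : slope * src[q]);
      } else {
        for (size_t q = 0; q < HW; ++q) dst[q] = (float)src[q];
      }
    }
  arma::fmat GWm = M.t() * G;
  arma::frowvec gbv = arma::sum(G, 0);
  // gx as a convolution of gout with the adjoint (flipped) kernel. The
  // adjoint of replicate-latitude padding adds the out-of-range taps back
  // onto the edge rows; longitude stays a plain (negated) wrap.
  static thread_local std::vector<float> M2buf;
  if (M2buf.size() < HWN * 9 * Cout) M2buf.resize(HWN * 9 * Cout);
  arma::fmat M2(M2buf.data(), HWN, 9 * Cout, false, true);
  for (int o = 0; o < Cout; ++o)
    for (int a = 0; a < 3; ++a) {
      int di = a - 1;
      for (int b = 0; b < 3; ++b) {
        int dj = b - 1;
        float* Mc = M2.colptr((a * 3 + b) * Cout + o);
        for (int n = 0; n < N; ++n) {
          const float* gch = G.colptr(o) + HW * n;
          float* Mn = Mc + HW * n;
          for (int j = 0; j < W; ++j) {
            int jj = wrapi(j - dj, W);  // adjoint: gather from j - dj
            const float* src = gch + (size_t)H * jj;
            float* dst = Mn + (size_t)H * j;
            if (di == 0) {
              std::memcpy(dst, src, H * sizeof(float));
            } else if (di < 0) {  // fwd tap di=-1: gx[k] <- gout[k+1]
              for (int i = 0; i < H - 1; ++i) dst[i] = src[i + 1];
              dst[H - 1] = 0.0f;
              dst[0] += src[0];  // replicate-pad adjoint at the north edge
            } else {  // fwd tap di=+1: gx[k] <- gout[k-1]
              dst[0] = 0.0f;
              for (int i = 1; i < H; ++i) dst[i] = src[i - 1];
              dst[H - 1] += src[H - 1];  // south edge
            }
          }
        }
      }
    }
  // Wadj[(tap)*Cout + o, c] = w[tap, c, o]
  arma::fmat Wadj(9 * Cout, C);
  {
    const double* wp = w.begin();
    for (int c = 0; c < C; ++c)
      for (int o = 0; o < Cout; ++o)
        for (int a = 0; a < 3; ++a)
          for (int b = 0; b < 3; ++b)
            Wadj((a * 3 + b) * Cout + o, c) =
                (float)wp[a + 3 * b + 9 * c + (size_t)9 * C * o];
  }
  static thread_local std::vector<float> GXbuf;
  if (GXbuf.size() < HWN * C) GXbuf.resize(HWN * C);
  arma::fmat GX(GXbuf.data(), HWN, C, false, true);
  GX = M2 * Wadj;
  double* gxp = gx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const float* src = GX.colptr(c) + HW * n;
      double* dst = gxp + HW * (c + (size_t)C * n);
      for (size_t q = 0; q < HW; ++q) dst[q] = (double)src[q];
    }
  double* gwp = gw.begin();
  for (int o = 0; o < Cout; ++o) {
    for (int c = 0; c < C; ++c)
      for (int a = 0; a < 3; ++a)
        for (int b = 0; b < 3; ++b)
          gwp[a + 3 * b + 9 * c + (size_t)9 * C * o] =
              (double)GWm((a * 3 + b) * C + c, o);
    gb[o] = (double)gbv[o];
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
NumericVector lrelu_fwd(NumericVector x, double slope) {
  NumericVector out(x.size());
  out.attr("dim") = x.attr("dim");
  const double* xp = x.begin();
  double* op = out.begin();
  for (R_xlen_t q = 0; q < x.size(); ++q)
    op[q] = xp[q] > 0 ? xp[q] : slope * xp[q];
  return out;
}

// [[Rcpp::export]]
NumericVector lrelu_bwd(NumericVector x, NumericVector g, double slope) {
  NumericVector gx(x.size());
  gx.attr("dim") = x.attr("dim");
  const double* xp = x.begin();
  const double* gp = g.begin();
  double* op = gx.begin();
  for (R_xlen_t q = 0; q < x.size(); ++q)
    op[q] = xp[q] > 0 ? gp[q] : slope * gp[q];
  return gx;
}

// ---------------------------------------------------------------------------
// 2x2 max pooling (stride 2) with argmax cache, and nearest 2x upsampling.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List maxpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector out((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      size_t xoff = (size_t)H * W * (c + (size_t)C * n);
      size_t ooff = (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int jo = 0; jo < Wo; ++jo)
        for (int io = 0; io < Ho; ++io) {
          double best = -1e300;
          int bi = 0;
          for (int b = 0; b < 2; ++b)
            for (int a = 0; a < 2; ++a) {
              double v = xp[xoff + (2 * io + a) + (size_t)H * (2 * jo + b)];
              if (v > best) {
                best = v;
                bi = a + 2 * b;
              }
            }
          out[ooff + io + (size_t)Ho * jo] = best;
          idx[ooff + io + (size_t)Ho * jo] = bi;
        }
    }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd(IntegerVector idx, NumericVector gout, int H,
                           int W) {
  IntegerVector gd = gout.attr("dim");
  int Ho = gd[0], Wo = gd[1], C = gd[2], N = gd[3];
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      size_t xoff = (size_t)H * W * (c + (size_t)C * n);
      size_t ooff = (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int jo = 0; jo < Wo; ++jo)
        for (int io = 0; io < Ho; ++io) {
          int bi = idx[ooff + io + (size_t)Ho * jo];
          int a = bi % 2, b = bi / 2;
          gx[xoff + (2 * io + a) + (size_t)H * (2 * jo + b)] +=
              gout[ooff + io + (size_t)Ho * jo];
        }
    }
  return gx;
}

// [[Rcpp::export]]
NumericVector upsample2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector out((size_t)Ho * Wo * C * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      size_t xoff = (size_t)H * W * (c + (size_t)C * n);
      size_t ooff = (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) {
          double v = x[xoff + i + (size_t)H * j];
          for (int b = 0; b < 2; ++b)
            for (int a = 0; a < 2; ++a)
              out[ooff + (2 * i + a) + (size_t)Ho * (2 * j + b)] = v;
        }
    }
  return out;
}

// [[Rcpp::export]]
NumericVector upsample2_bwd(NumericVector gout) {
  IntegerVector gd = gout.attr("dim");
  int Ho = gd[0], Wo = gd[1], C = gd[2], N = gd[3];
  int H = Ho / 2, W = Wo / 2;
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      size_t xoff = (size_t)H * W * (c + (size_t)C * n);
      size_t ooff = (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) {
          double s = 0.0;
          for (int b = 0; b < 2; ++b)
            for (int a = 0; a < 2; ++a)
              s += gout[ooff + (2 * i + a) + (size_t)Ho * (2 * j + b)];
          gx[xoff + i + (size_t)H * j] = s;
        }
    }
  return gx;
}

// ---------------------------------------------------------------------------
// Bilinear warping: out(x) = img(x + u(x)); longitude wraps, latitude clamps.
// ---------------------------------------------------------------------------

struct Corner {
  int i0, i1, j0, j1;
  double fy, fx, dy;  // dy = 0 when the latitude sample is clamped
};

static inline Corner corner_at(int i, int j, int H, int W, const double* u1,
                               const double* u2) {
  Corner cr;
  size_t p = i + (size_t)H * j;
  double y = i + u1[p];
  cr.dy = 1.0;
  if (y <= 0.0) {
    y = 0.0;
    cr.dy = 0.0;
  } else if (y >= H - 1.0) {
    y = H - 1.0;
    cr.dy = 0.0;
  }
  double xr = j + u2[p];
  double x = xr - W * std::floor(xr / W);  // wrap into [0, W)
  if (x >= W) x = 0.0;
  cr.i0 = (int)std::floor(y);
  if (cr.i0 > H - 1) cr.i0 = H - 1;
  cr.i1 = cr.i0 + 1 > H - 1 ? H - 1 : cr.i0 + 1;
  cr.fy = y - cr.i0;
  cr.j0 = (int)std::floor(x);
  if (cr.j0 > W - 1) cr.j0 = W - 1;
  cr.j1 = (cr.j0 + 1) % W;
  cr.fx = x - cr.j0;
  return cr;
}

// [[Rcpp::export]]
NumericVector warp_img_fwd(NumericVector img, NumericVector u) {
  IntegerVector id = img.attr("dim");
  int H = id[0], W = id[1], C = id[2];
  NumericVector out((size_t)H * W * C);
  out.attr("dim") = id;
  const double* u1 = u.begin();
  const double* u2 = u.begin() + (size_t)H * W;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      Corner cr = corner_at(i, j, H, W, u1, u2);
      for (int c = 0; c < C; ++c) {
        const double* im = img.begin() + (size_t)H * W * c;
        double v00 = im[cr.i0 + (size_t)H * cr.j0];
        double v01 = im[cr.i0 + (size_t)H * cr.j1];
        double v10 = im[cr.i1 + (size_t)H * cr.j0];
        double v11 = im[cr.i1 + (size_t)H * cr.j1];
        out[i + (size_t)H * j + (size_t)H * W * c] =
            (1 - cr.fy) * ((1 - cr.fx) * v00 + cr.fx * v01) +
            cr.fy * ((1 - cr.fx) * v10 + cr.fx * v11);
      }
    }
  return out;
}

// [[Rcpp::export]]
List warp_img_bwd(NumericVector img, NumericVector u, NumericVector gout) {
  IntegerVector id = img.attr("dim");
  int H = id[0], W = id[1], C = id[2];
  NumericVector gimg((size_t)H * W * C);
  gimg.attr("dim") = id;
  NumericVector gu((size_t)H * W * 2);
  gu.attr("dim") = IntegerVector::create(H, W, 2);
  const double* u1 = u.begin();
  const double* u2 = u.begin() + (size_t)H * W;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      Corner cr = corner_at(i, j, H, W, u1, u2);
      size_t p = i + (size_t)H * j;
      double gy = 0.0, gx2 = 0.0;
      for (int c = 0; c < C; ++c) {
        const double* im = img.begin() + (size_t)H * W * c;
        double* gi = gimg.begin() + (size_t)H * W * c;
        double g = gout[p + (size_t)H * W * c];
        double v00 = im[cr.i0 + (size_t)H * cr.j0];
        double v01 = im[cr.i0 + (size_t)H * cr.j1];
        double v10 = im[cr.i1 + (size_t)H * cr.j0];
        double v11 = im[cr.i1 + (size_t)H * cr.j1];
        gi[cr.i0 + (size_t)H * cr.j0] += g * (1 - cr.fy) * (1 - cr.fx);
        gi[cr.i0 + (size_t)H * cr.j1] += g * (1 - cr.fy) * cr.fx;
        gi[cr.i1 + (size_t)H * cr.j0] += g * cr.fy * (1 - cr.fx);
        gi[cr.i1 + (size_t)H * cr.j1] += g * cr.fy * cr.fx;
        gy += g * ((1 - cr.fx) * (v10 - v00) + cr.fx * (v11 - v01));
        gx2 += g * ((1 - cr.fy) * (v01 - v00) + cr.fy * (v11 - v10));
      }
      gu[p] = gy * cr.dy;
      gu[p + (size_t)H * W] = gx2;
    }
  return List::create(_["gimg"] = gimg, _["gu"] = gu);
}

// ---------------------------------------------------------------------------
// Fused scaling-and-squaring: u0 = v / 2^n, then n self-compositions.
// Intermediates are returned so the backward pass can rerun the recursion.
// ---------------------------------------------------------------------------

static void warp_disp_raw(const double* img, const double* u, double* out,
                          int H, int W, int C) {
  const double* u1 = u;
  const double* u2 = u + (size_t)H * W;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      Corner cr = corner_at(i, j, H, W, u1, u2);
      for (int c = 0; c < C; ++c) {
        const double* im = img + (size_t)H * W * c;
        out[i + (size_t)H * j + (size_t)H * W * c] =
            (1 - cr.fy) * ((1 - cr.fx) * im[cr.i0 + (size_t)H * cr.j0] +
                           cr.fx * im[cr.i0 + (size_t)H * cr.j1]) +
            cr.fy * ((1 - cr.fx) * im[cr.i1 + (size_t)H * cr.j0] +
                     cr.fx * im[cr.i1 + (size_t)H * cr.j1]);
      }
    }
}

static void warp_bwd_raw(const double* img, const double* u,
                         const double* gout, double* gimg, double* gu, int H,
                         int W, int C) {
  const double* u1 = u;
  const double* u2 = u + (size_t)H * W;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      Corner cr = corner_at(i, j, H, W, u1, u2);
      size_t p = i + (size_t)H * j;
      double gy = 0.0, gx2 = 0.0;
      for (int c = 0; c < C; ++c) {
        const double* im = img + (size_t)H * W * c;
        double* gi = gimg + (size_t)H * W * c;
        double g = gout[p + (size_t)H * W * c];
        double v00 = im[cr.i0 + (size_t)H * cr.j0];
        double v01 = im[cr.i0 + (size_t)H * cr.j1];
        double v10 = im[cr.i1 + (size_t)H * cr.j0];
        double v11 = im[cr.i1 + (size_t)H * cr.j1];
        gi[cr.i0 + (size_t)H * cr.j0] += g * (1 - cr.fy) * (1 - cr.fx);
        gi[cr.i0 + (size_t)H * cr.j1] += g * (1 - cr.fy) * cr.fx;
        gi[cr.i1 + (size_t)H * cr.j0] += g * cr.fy * (1 - cr.fx);
        gi[cr.i1 + (size_t)H * cr.j1] += g * cr.fy * cr.fx;
        gy += g * ((1 - cr.fx) * (v10 - v00) + cr.fx * (v11 - v01));
        gx2 += g * ((1 - cr.fy) * (v01 - v00) + cr.fy * (v11 - v10));
      }
      gu[p] += gy * cr.dy;
      gu[p + (size_t)H * W] += gx2;
    }
}

// [[Rcpp::export]]
List svf_exp_fwd(NumericVector v, int n_steps) {
  IntegerVector vd = v.attr("dim");
  int H = vd[0], W = vd[1];
  size_t L = (size_t)H * W * 2;
  // all intermediate fields u_0 .. u_{n-1} in one block for the backward pass
  NumericVector steps((size_t)n_steps * L);
  NumericVector u(L);
  u.attr("dim") = vd;
  double sc = std::pow(2.0, -n_steps);
  for (size_t q = 0; q < L; ++q) u[q] = v[q] * sc;
  for (int s = 0; s < n_steps; ++s) {
    double* us = steps.begin() + (size_t)s * L;
    std::memcpy(us, u.begin(), L * sizeof(double));
    warp_disp_raw(us, us, u.begin(), H, W, 2);
    for (size_t q = 0; q < L; ++q) u[q] += us[q];
  }
  return List::create(_["u"] = u, _["steps"] = steps,
                      _["H"] = H, _["W"] = W);
}

// [[Rcpp::export]]
NumericVector svf_exp_bwd(NumericVector steps, NumericVector gout,
                          int n_steps, int H, int W) {
  size_t L = (size_t)H * W * 2;
  NumericVector g(clone(gout));
  static thread_local std::vector<double> gimg, gu;
  if (gimg.size() < L) gimg.resize(L);
  if (gu.size() < L) gu.resize(L);
  for (int s = n_steps - 1; s >= 0; --s) {
    const double* us = steps.begin() + (size_t)s * L;
    std::fill_n(gimg.begin(), L, 0.0);
    std::fill_n(gu.begin(), L, 0.0);
    warp_bwd_raw(us, us, g.begin(), gimg.data(), gu.data(), H, W, 2);
    for (size_t q = 0; q < L; ++q) g[q] += gimg[q] + gu[q];
  }
  double sc = std::pow(2.0, -n_steps);
  for (size_t q = 0; q < L; ++q) g[q] *= sc;
  g.attr("dim") = gout.attr("dim");
  return g;
}

// ---------------------------------------------------------------------------
// Jacobian determinant of phi = Id + u, central differences (one-sided at
// latitude edges, wrapped in longitude).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix jacobian_det_cpp(NumericVector u) {
  IntegerVector ud = u.attr("dim");
  int H = ud[0], W = ud[1];
  const double* u1 = u.begin();
  const double* u2 = u.begin() + (size_t)H * W;
  NumericMatrix det(H, W);
  for (int j = 0; j < W; ++j) {
    int jm = wrapi(j - 1, W), jp = wrapi(j + 1, W);
    for (int i = 0; i < H; ++i) {
      int im = i > 0 ? i - 1 : 0, ip = i < H - 1 ? i + 1 : H - 1;
      double hi = (ip - im) > 0 ? (double)(ip - im) : 1.0;
      double d11 = 1.0 + (u1[ip + (size_t)H * j] - u1[im + (size_t)H * j]) / hi;
      double d21 = (u2[ip + (size_t)H * j] - u2[im + (size_t)H * j]) / hi;
      double d12 = (u1[i + (size_t)H * jp] - u1[i + (size_t)H * jm]) / 2.0;
      double d22 = 1.0 + (u2[i + (size_t)H * jp] - u2[i + (size_t)H * jm]) / 2.0;
      det(i, j) = d11 * d22 - d12 * d21;
    }
  }
  return det;
}

// ---------------------------------------------------------------------------
// Scattered-to-grid interpolation: inverse-great-circle-distance over the k
// nearest unit-sphere vertices (brute force; vertex clouds here are small).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix knn_idw_sphere(NumericMatrix cells, NumericMatrix verts,
                             NumericMatrix vals, int k) {
  int M = cells.nrow(), V = verts.nrow(), C = vals.ncol();
  if (k > V) k = V;
  NumericMatrix out(M, C);
  std::vector<double> bestd(k);
  std::vector<int> besti(k);
  for (int m = 0; m < M; ++m) {
    for (int t = 0; t < k; ++t) {
      bestd[t] = -2.0;
      besti[t] = -1;
    }
    double cx = cells(m, 0), cy = cells(m, 1), cz = cells(m, 2);
    for (int v = 0; v < V; ++v) {
      double d = cx * verts(v, 0) + cy * verts(v, 1) + cz * verts(v, 2);
      if (d > bestd[k - 1]) {
        int t = k - 1;
        while (t > 0 && bestd[t - 1] < d) {
          bestd[t] = bestd[t - 1];
          besti[t] = besti[t - 1];
          --t;
        }
        bestd[t] = d;
        besti[t] = v;
      }
    }
    double wsum = 0.0;
    std::vector<double> wk(k);
    bool exact = false;
    for (int t = 0; t < k; ++t) {
      double dot = bestd[t] > 1.0 ? 1.0 : (bestd[t] < -1.0 ? -1.0 : bestd[t]);
      double ang = std::acos(dot);
      if (ang < 1e-9) {  // exact hit: take that vertex alone
        for (int c = 0; c < C; ++c) out(m, c) = vals(besti[t], c);
        exact = true;
        break;
      }
      wk[t] = 1.0 / ang;
      wsum += wk[t];
    }
    if (exact) continue;
    for (int c = 0; c < C; ++c) {
      double s = 0.0;
      for (int t = 0; t < k; ++t) s += wk[t] * vals(besti[t], c);
      out(m, c) = s / wsum;
    }
  }
  return out;
}
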