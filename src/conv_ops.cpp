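// Compiled tensor kernels for the autograd engine: grouped/dilated 2-D
// convolution (im2col + GEMM) and max-pooling, forward and backward.
// Array layout throughout: feature maps are (H, W, C, N) column-major,
// convolution weights are (kh, kw, Cin/groups, Cout).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad, int dil) {
  return (in + 2 * pad - (dil * (k - 1) + 1)) / stride + 1;
}

// Gather one (sample, group) block into cols: (Ho*Wo) x (kh*kw*Cg).
// Column index q = i + kh*j + kh*kw*c matches the column-major flattening
// of a (kh, kw, Cg) weight block.
static void im2col(const double* x, int H, int W,
                   int c0, int Cg, int kh, int kw,
                   int stride, int pad, int dil,
                   int Ho, int Wo, arma::mat& cols) {
  const int plane = H * W;
  for (int c = 0; c < Cg; ++c) {
    const double* src = x + (size_t)(c0 + c) * plane;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        double* col = cols.colptr(i + kh * j + kh * kw * c);
        for (int ow = 0; ow < Wo; ++ow) {
          const int wi = ow * stride - pad + j * dil;
          double* dst = col + (size_t)Ho * ow;
          if (wi < 0 || wi >= W) {
            for (int oh = 0; oh < Ho; ++oh) dst[oh] = 0.0;
            continue;
          }
          const double* sc = src + (size_t)wi * H;
          for (int oh = 0; oh < Ho; ++oh) {
            const int hi = oh * stride - pad + i * dil;
            dst[oh] = (hi >= 0 && hi < H) ? sc[hi] : 0.0;
          }
        }
      }
    }
  }
}

// Scatter-add the columns gradient back onto the input gradient.
static void col2im(const arma::mat& dcols, double* gx, int H, int W,
                   int c0, int Cg, int kh, int kw,
                   int stride, int pad, int dil,
                   int Ho, int Wo) {
  const int plane = H * W;
  for (int c = 0; c < Cg; ++c) {
    double* dstp = gx + (size_t)(c0 + c) * plane;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const double* col = dcols.colptr(i + kh * j + kh * kw * c);
        for (int ow = 0; ow < Wo; ++ow) {
          const int wi = ow * stride - pad + j * dil;
          if (wi < 0 || wi >= W) continue;
          double* dc = dstp + (size_t)wi * H;
          const double* sc = col + (size_t)Ho * ow;
          for (int oh = 0; oh < Ho; ++oh) {
            const int hi = oh * stride - pad + i * dil;
            if (hi >= 0 && hi < H) dc[hi] += sc[oh];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericVector w,
                            Nullable<NumericVector> bias,
                            int stride, int pad, int dil, int groups) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cg = wd[2], Cout = wd[3];
  if (Cg * groups != C) stop("conv2d: channels %d incompatible with groups %d x %d", C, groups, Cg);
  if (Cout % groups != 0) stop("conv2d: out channels not divisible by groups");
  const int Ho = out_size(H, kh, stride, pad, dil);
  const int Wo = out_size(W, kw, stride, pad, dil);
  if (Ho < 1 || Wo < 1) stop("conv2d: non-positive output size");
  const int Og = Cout / groups;
  const int K = kh * kw * Cg;

  NumericVector out = no_init((R_xlen_t)Ho * Wo * Cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat cols((size_t)Ho * Wo, K);
  arma::mat wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  double* op = out.begin();
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      im2col(xp + (size_t)n * H * W * C, H, W, g * Cg, Cg, kh, kw,
             stride, pad, dil, Ho, Wo, cols);
      arma::mat om(op + ((size_t)n * Cout + (size_t)g * Og) * Ho * Wo,
                   (size_t)Ho * Wo, Og, false, true);
      om = cols * wm.cols(g * Og, (g + 1) * Og - 1);
    }
  }
  if (bias.isNotNull()) {
    NumericVector b(bias);
    const size_t hw = (size_t)Ho * Wo;
    for (int n = 0; n < N; ++n)
      for (int co = 0; co < Cout; ++co) {
        const double bv = b[co];
        double* pp = op + ((size_t)n * Cout + co) * hw;
        for (size_t t = 0; t < hw; ++t) pp[t] += bv;
      }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, NumericVector w, NumericVector gout,
                   int stride, int pad, int dil, int groups,
                   bool need_gx, bool has_bias) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  IntegerVector gd = gout.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cg = wd[2], Cout = wd[3];
  const int Ho = gd[0], Wo = gd[1];
  const int Og = Cout / groups;
  const int K = kh * kw * Cg;

  NumericVector gw((size_t)K * Cout);
  gw.attr("dim") = wd;
  arma::mat gwm(gw.begin(), K, Cout, false, true);
  arma::mat wm(const_cast<double*>(w.begin()), K, Cout, false, true);

  NumericVector gx;
  double* gxp = nullptr;
  if (need_gx) {
    gx = NumericVector((size_t)H * W * C * N);  // zero-initialised
    gx.attr("dim") = xd;
    gxp = gx.begin();
  }

  arma::mat cols((size_t)Ho * Wo, K);
  const double* xp = x.begin();
  double* gp = gout.begin();
  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      im2col(xp + (size_t)n * H * W * C, H, W, g * Cg, Cg, kh, kw,
             stride, pad, dil, Ho, Wo, cols);
      arma::mat gom(gp + ((size_t)n * Cout + (size_t)g * Og) * Ho * Wo,
                    (size_t)Ho * Wo, Og, false, true);
      gwm.cols(g * Og, (g + 1) * Og - 1) += cols.t() * gom;
      if (need_gx) {
        arma::mat dcols = gom * wm.cols(g * Og, (g + 1) * Og - 1).t();
        col2im(dcols, gxp + (size_t)n * H * W * C, H, W, g * Cg, Cg,
               kh, kw, stride, pad, dil, Ho, Wo);
      }
    }
  }

  List res = List::create(_["gx"] = need_gx ? (SEXP)gx : R_NilValue,
                          _["gw"] = gw, _["gb"] = R_NilValue);
  if (has_bias) {
    NumericVector gb(Cout);
    const size_t hw = (size_t)Ho * Wo;
    for (int n = 0; n < N; ++n)
      for (int co = 0; co < Cout; ++co) {
        const double* pp = gp + ((size_t)n * Cout + co) * hw;
        double s = 0.0;
        for (size_t t = 0; t < hw; ++t) s += pp[t];
        gb[co] += s;
      }
    res["gb"] = gb;
  }
  return res;
}

// [[Rcpp::export]]
List cpp_maxpool2d_fw(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = out_size(H, k, stride, pad, 1);
  const int Wo = out_size(W, k, stride, pad, 1);
  NumericVector out = no_init((R_xlen_t)Ho * Wo * C * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector arg = no_init((R_xlen_t)Ho * Wo * C * N);  // 0-based into x
  const double* xp = x.begin();
  double* op = out.begin();
  int* ap = arg.begin();
  size_t t = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)n * C + c) * H * W;
      const double* plane = xp + base;
      for (int ow = 0; ow < Wo; ++ow)
        for (int oh = 0; oh < Ho; ++oh) {
          double best = -HUGE_VAL;
          int besti = -1;
          for (int j = 0; j < k; ++j) {
            const int wi = ow * stride - pad + j;
            if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < k; ++i) {
              const int hi = oh * stride - pad + i;
              if (hi < 0 || hi >= H) continue;
              const double v = plane[hi + (size_t)wi * H];
              if (v > best) { best = v; besti = hi + wi * H; }
            }
          }
          // output is column-major (Ho, Wo) within the plane
          const size_t o = ((size_t)n * C + c) * Ho * Wo + oh + (size_t)Ho * ow;
          op[o] = best;
          ap[o] = (int)(base + besti);
          ++t;
        }
    }
  (void)t;
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2d_bw(IntegerVector argmax, NumericVector gout,
                               IntegerVector xdim) {
  size_t nx = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector gx(nx);
  gx.attr("dim") = xdim;
  double* gp = gx.begin();
  const double* go = gout.begin();
  const int* ap = argmax.begin();
  const size_t m = gout.size();
  for (size_t i = 0; i < m; ++i) gp[ap[i]] += go[i];
  return gx;
}

// Bilinear x2 upsampling (half-pixel centers, clamped borders) given the
// per-axis source indices (0-based lo/hi) and hi-side fractions.
// [[Rcpp::export]]
NumericVector cpp_upsample2x_fw(NumericVector x,
                                IntegerVector rlo, IntegerVector rhi,
                                NumericVector rfr,
                                IntegerVector clo, IntegerVector chi,
                                NumericVector cfr) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int H2 = rlo.size(), W2 = clo.size();
  NumericVector out = no_init((R_xlen_t)H2 * W2 * C * N);
  out.attr("dim") = IntegerVector::create(H2, W2, C, N);
  const double* xp = x.begin();
  double* op = out.begin();
  const int planes = C * N;
  for (int p = 0; p < planes; ++p) {
    const double* src = xp + (size_t)p * H * W;
    double* dst = op + (size_t)p * H2 * W2;
    for (int oc = 0; oc < W2; ++oc) {
      const double* s0 = src + (size_t)clo[oc] * H;
      const double* s1 = src + (size_t)chi[oc] * H;
      const double wc = cfr[oc];
      double* dcol = dst + (size_t)oc * H2;
      for (int orow = 0; orow < H2; ++orow) {
        const double wr = rfr[orow];
        const double a = (1 - wr) * s0[rlo[orow]] + wr * s0[rhi[orow]];
        const double b = (1 - wr) * s1[rlo[orow]] + wr * s1[rhi[orow]];
        dcol[orow] = (1 - wc) * a + wc * b;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2x_bw(NumericVector g, IntegerVector xdim,
                                IntegerVector rlo, IntegerVector rhi,
                                NumericVector rfr,
                                IntegerVector clo, IntegerVector chi,
                                NumericVector cfr) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int H2 = rlo.size(), W2 = clo.size();
  NumericVector gx((R_xlen_t)H * W * C * N);
  gx.attr("dim") = xdim;
  const double* gp = g.begin();
  double* xp = gx.begin();
  const int planes = C * N;
  for (int p = 0; p < planes; ++p) {
    double* dst = xp + (size_t)p * H * W;
    const double* src = gp + (size_t)p * H2 * W2;
    for (int oc = 0; oc < W2; ++oc) {
      double* d0 = dst + (size_t)clo[oc] * H;
      double* d1 = dst + (size_t)chi[oc] * H;
      const double wc = cfr[oc];
      const double* scol = src + (size_t)oc * H2;
      for (int orow = 0; orow < H2; ++orow) {
        const double wr = rfr[orow];
        const double gv = scol[orow];
        d0[rlo[orow]] += (1 - wc) * (1 - wr) * gv;
        d0[rhi[orow]] += (1 - wc) * wr * gv;
        d1[rlo[orow]] += wc * (1 - wr) * gv;
        d1[rhi[orow]] += wc * wr * gv;
      }
    }
  }
  return gx;
}
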