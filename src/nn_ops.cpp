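// Low-level numerical kernels for the CNN engine and the PSF blur.
//
// Tensor layout: R arrays with dim (H, W, C, N), column-major, so element
// (h, w, c, n) sits at h + H*(w + W*(c + C*n)).  Convolution weights have
// dim (kh, kw, Cin, Cout).  im2col row order matches the column-major
// flattening of the first three weight dimensions, so the GEMM is
// W_mat (Cout x kh*kw*Cin) %*% col (kh*kw*Cin x Ho*Wo).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void get_dims4(const NumericVector &x, int &H, int &W, int &C, int &N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d tensor (H, W, C, N)");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

static void im2col(const double *x, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, arma::mat &col) {
  // col: (kh*kw*C) x (Ho*Wo)
  for (int c = 0; c < C; ++c) {
    const double *xc = x + (size_t)H * W * c;
    for (int q = 0; q < kw; ++q) {
      for (int p = 0; p < kh; ++p) {
        int row = p + kh * (q + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + q;
          double *dst = col.colptr(0) + row; // strided writes below
          if (wi < 0 || wi >= W) {
            for (int ho = 0; ho < Ho; ++ho)
              col(row, ho + Ho * wo) = 0.0;
            continue;
          }
          const double *xcol = xc + (size_t)H * wi;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + p;
            col(row, ho + Ho * wo) = (hi >= 0 && hi < H) ? xcol[hi] : 0.0;
          }
          (void)dst;
        }
      }
    }
  }
}

static void col2im(const arma::mat &col, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, double *gx) {
  for (int c = 0; c < C; ++c) {
    double *xc = gx + (size_t)H * W * c;
    for (int q = 0; q < kw; ++q) {
      for (int p = 0; p < kh; ++p) {
        int row = p + kh * (q + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + q;
          if (wi < 0 || wi >= W) continue;
          double *xcol = xc + (size_t)H * wi;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + p;
            if (hi >= 0 && hi < H)
              xcol[hi] += col(row, ho + Ho * wo);
          }
        }
      }
    }
  }
}

// [[Rcpp::export(rng = false)]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericVector w,
                            int stride, int pad) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("input channels do not match weight channels");
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (W + 2 * pad - kw) / stride + 1;

  arma::mat wmat(const_cast<double *>(w.begin()), (size_t)kh * kw * Cin, Cout, false, true);
  NumericVector y((R_xlen_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);

  arma::mat col((size_t)kh * kw * Cin, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, stride, pad, Ho, Wo, col);
    arma::mat ymat(y.begin() + (size_t)Ho * Wo * Cout * n, (size_t)Ho * Wo, Cout, false, true);
    ymat = col.t() * wmat;
  }
  return y;
}

// [[Rcpp::export(rng = false)]]
List cpp_conv2d_bw(NumericVector x, NumericVector w, NumericVector gy,
                   int stride, int pad) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (W + 2 * pad - kw) / stride + 1;

  arma::mat wmat(const_cast<double *>(w.begin()), (size_t)kh * kw * Cin, Cout, false, true);
  NumericVector gx((R_xlen_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector gw((R_xlen_t)kh * kw * Cin * Cout);
  gw.attr("dim") = IntegerVector::create(kh, kw, Cin, Cout);
  arma::mat gwmat(gw.begin(), (size_t)kh * kw * Cin, Cout, false, true);

  arma::mat col((size_t)kh * kw * Cin, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, stride, pad, Ho, Wo, col);
    arma::mat gymat(const_cast<double *>(gy.begin()) + (size_t)Ho * Wo * Cout * n,
                    (size_t)Ho * Wo, Cout, false, true);
    gwmat += col * gymat;
    arma::mat gcol = wmat * gymat.t();
    col2im(gcol, H, W, C, kh, kw, stride, pad, Ho, Wo,
           gx.begin() + (size_t)H * W * C * n);
  }
  return List::create(_["gx"] = gx, _["gw"] = gw);
}

// [[Rcpp::export(rng = false)]]
List cpp_maxpool2_fw(NumericVector x) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  if (H % 2 || W % 2) stop("maxpool2 requires even spatial dimensions");
  int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector arg((R_xlen_t)Ho * Wo * C * N); // linear index into x
  const double *xp = x.begin();
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double *xs = xp + (size_t)H * W * cn;
    size_t base = (size_t)H * W * cn;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        int h0 = 2 * ho, w0 = 2 * wo;
        size_t i00 = h0 + (size_t)H * w0, i10 = i00 + 1;
        size_t i01 = i00 + H, i11 = i01 + 1;
        size_t best = i00;
        if (xs[i10] > xs[best]) best = i10;
        if (xs[i01] > xs[best]) best = i01;
        if (xs[i11] > xs[best]) best = i11;
        size_t o = ho + (size_t)Ho * wo + (size_t)Ho * Wo * cn;
        y[o] = xs[best];
        arg[o] = (int)(base + best);
      }
    }
  }
  return List::create(_["y"] = y, _["arg"] = arg);
}

// [[Rcpp::export(rng = false)]]
NumericVector cpp_maxpool2_bw(NumericVector gy, IntegerVector arg, IntegerVector xdim) {
  NumericVector gx((R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  gx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < gy.size(); ++i) gx[arg[i]] += gy[i];
  return gx;
}

// In-place additive stamping of `patch` (scaled) at 1-based centres
// (rs, cs); used by the synthetic-slide rasteriser. The caller owns `plane`
// exclusively.
// [[Rcpp::export(rng = false)]]
void cpp_stamp_add_many(NumericMatrix plane, IntegerVector rs, IntegerVector cs,
                        NumericMatrix patch, NumericVector scale) {
  int H = plane.nrow(), W = plane.ncol();
  int ph = patch.nrow(), pw = patch.ncol();
  int hr = (ph - 1) / 2, hc = (pw - 1) / 2;
  for (int k = 0; k < rs.size(); ++k) {
    int r = rs[k], c = cs[k];
    double s = scale[k % scale.size()];
    int r1 = std::max(1, r - hr), r2 = std::min(H, r - hr + ph - 1);
    int c1 = std::max(1, c - hc), c2 = std::min(W, c - hc + pw - 1);
    if (r1 > r2 || c1 > c2) continue;
    for (int cc = c1; cc <= c2; ++cc)
      for (int rr = r1; rr <= r2; ++rr)
        plane(rr - 1, cc - 1) += s * patch(rr - (r - hr), cc - (c - hc));
  }
}

// Reflect-padded 2-D convolution of one plane with an arbitrary kernel
// (used for PSF blur; kernel centre at ((kh-1)/2, (kw-1)/2)).
// [[Rcpp::export(rng = false)]]
NumericMatrix cpp_conv2_reflect(NumericMatrix img, NumericMatrix ker) {
  int H = img.nrow(), W = img.ncol();
  int kh = ker.nrow(), kw = ker.ncol();
  int ch = (kh - 1) / 2, cw = (kw - 1) / 2;
  NumericMatrix out(H, W);
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      double acc = 0.0;
      for (int q = 0; q < kw; ++q) {
        int wi = w + q - cw;
        if (wi < 0) wi = -wi - 1;           // reflect without edge repeat? use edge-inclusive reflect
        if (wi >= W) wi = 2 * W - wi - 1;
        if (wi < 0) wi = 0; if (wi >= W) wi = W - 1;
        for (int p = 0; p < kh; ++p) {
          int hi = h + p - ch;
          if (hi < 0) hi = -hi - 1;
          if (hi >= H) hi = 2 * H - hi - 1;
          if (hi < 0) hi = 0; if (hi >= H) hi = H - 1;
          acc += img(hi, wi) * ker(p, q);
        }
      }
      out(h, w) = acc;
    }
  }
  return out;
}
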