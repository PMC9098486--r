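// Numerical kernels for the network core: stride-1 2-D convolution
// (im2col + GEMM), 2x2 max pooling and factor-2 bilinear upsampling,
// each with its adjoint for reverse-mode differentiation.
//
// Tensor layout everywhere: R array dim c(H, W, C, N), column-major.
// Weight layout: dim c(kh, kw, Cin, Cout).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::uword idx4(int h, int w, int c, int n,
                               int H, int W, int C) {
  return (arma::uword)h + (arma::uword)H * ((arma::uword)w + (arma::uword)W * ((arma::uword)c + (arma::uword)C * (arma::uword)n));
}

// Gather the padded receptive fields of sample n into colT (P x K),
// K = kh*kw*Cin, P = Hout*Wout, so both the reads from x and the writes
// into each column of colT are contiguous. Zero padding.
static void im2col(const double* x, int n, int H, int W, int C,
                   int kh, int kw, int ph, int pw,
                   int Hout, int Wout, arma::mat& colT) {
  colT.zeros();
  for (int c = 0; c < C; ++c) {
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        const int kcol = dh + kh * (dw + kw * c);
        double* dst = colT.colptr(kcol);
        for (int ow = 0; ow < Wout; ++ow) {
          const int iw = ow - pw + dw;
          if (iw < 0 || iw >= W) continue;
          const int oh0 = std::max(0, ph - dh);
          const int oh1 = std::min(Hout, H + ph - dh);
          if (oh1 <= oh0) continue;
          const double* src = x + idx4(oh0 - ph + dh, iw, c, n, H, W, C);
          std::copy(src, src + (oh1 - oh0), dst + oh0 + Hout * ow);
        }
      }
    }
  }
}

static void col2im_add(double* gx, int n, int H, int W, int C,
                       int kh, int kw, int ph, int pw,
                       int Hout, int Wout, const arma::mat& gcolT) {
  for (int c = 0; c < C; ++c) {
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        const int kcol = dh + kh * (dw + kw * c);
        const double* src = gcolT.colptr(kcol);
        for (int ow = 0; ow < Wout; ++ow) {
          const int iw = ow - pw + dw;
          if (iw < 0 || iw >= W) continue;
          const int oh0 = std::max(0, ph - dh);
          const int oh1 = std::min(Hout, H + ph - dh);
          double* dst = gx + idx4(oh0 - ph + dh, iw, c, n, H, W, C);
          const double* s = src + oh0 + Hout * ow;
          for (int k = 0; k < oh1 - oh0; ++k) dst[k] += s[k];
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".cpp_conv2d_fw")]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericVector w, NumericVector b,
                            int ph, int pw) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels but kernel expects %d", C, Cin);
  const int Hout = H + 2 * ph - kh + 1, Wout = W + 2 * pw - kw + 1;
  if (Hout < 1 || Wout < 1) stop("conv2d: kernel larger than padded input");
  const int K = kh * kw * C, P = Hout * Wout;

  NumericVector y((R_xlen_t)Hout * Wout * Cout * N);
  y.attr("dim") = IntegerVector::create(Hout, Wout, Cout, N);
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat colT(P, K);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin(), n, H, W, C, kh, kw, ph, pw, Hout, Wout, colT);
    arma::mat ym(y.begin() + (R_xlen_t)P * Cout * n, P, Cout, false, true);
    ym = colT * Wm;
    for (int c = 0; c < Cout; ++c) ym.col(c) += b[c];
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_conv2d_bw")]]
List cpp_conv2d_bw(NumericVector x, NumericVector w, NumericVector gy,
                   int ph, int pw) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int Hout = H + 2 * ph - kh + 1, Wout = W + 2 * pw - kw + 1;
  const int K = kh * kw * C, P = Hout * Wout;

  NumericVector gx((R_xlen_t)H * W * C * N);
  gx.attr("dim") = xd;
  NumericVector gw((R_xlen_t)K * Cout);
  gw.attr("dim") = wd;
  NumericVector gb(Cout);

  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat gWm(gw.begin(), K, Cout, false, true);
  arma::mat colT(P, K);
  for (int n = 0; n < N; ++n) {
    arma::mat gym(const_cast<double*>(gy.begin()) + (R_xlen_t)P * Cout * n,
                  P, Cout, false, true);
    im2col(x.begin(), n, H, W, C, kh, kw, ph, pw, Hout, Wout, colT);
    gWm += colT.t() * gym;
    arma::mat gcolT = gym * Wm.t();           // P x K
    col2im_add(gx.begin(), n, H, W, C, kh, kw, ph, pw, Hout, Wout, gcolT);
    for (int c = 0; c < Cout; ++c) gb[c] += arma::accu(gym.col(c));
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export(name = ".cpp_maxpool2_fw")]]
List cpp_maxpool2_fw(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (H % 2 || W % 2) stop("maxpool2: spatial size (%d x %d) not even", H, W);
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  NumericVector idx(y.size());   // 1-based flat index into x, stored as double
  idx.attr("dim") = y.attr("dim");
  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int ow = 0; ow < Wo; ++ow)
        for (int oh = 0; oh < Ho; ++oh, ++o) {
          double best = -INFINITY; arma::uword bi = 0;
          for (int dw = 0; dw < 2; ++dw)
            for (int dh = 0; dh < 2; ++dh) {
              arma::uword i = idx4(2 * oh + dh, 2 * ow + dw, c, n, H, W, C);
              if (x[i] > best) { best = x[i]; bi = i; }
            }
          y[o] = best; idx[o] = (double)bi + 1.0;
        }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".cpp_maxpool2_bw")]]
NumericVector cpp_maxpool2_bw(NumericVector idx, NumericVector gy,
                              IntegerVector xdim) {
  NumericVector gx((R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  gx.attr("dim") = xdim;
  for (R_xlen_t o = 0; o < gy.size(); ++o)
    gx[(R_xlen_t)idx[o] - 1] += gy[o];
  return gx;
}

// Factor-2 bilinear interpolation, half-pixel-centre convention:
// output index i samples input coordinate (i + 0.5)/2 - 0.5, edges clamped.
static void up2_coeffs(int Hin, std::vector<int>& i0, std::vector<int>& i1,
                       std::vector<double>& t) {
  const int Hout = 2 * Hin;
  i0.resize(Hout); i1.resize(Hout); t.resize(Hout);
  for (int i = 0; i < Hout; ++i) {
    double src = (i + 0.5) / 2.0 - 0.5;
    int lo = (int)std::floor(src);
    double tt = src - lo;
    int hi = lo + 1;
    if (lo < 0) { lo = 0; hi = 0; tt = 0.0; }
    if (hi > Hin - 1) { hi = Hin - 1; lo = Hin - 1; tt = 0.0; }
    i0[i] = lo; i1[i] = hi; t[i] = tt;
  }
}

// [[Rcpp::export(name = ".cpp_up2_fw")]]
NumericVector cpp_up2_fw(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = 2 * H, Wo = 2 * W;
  std::vector<int> r0, r1, c0, c1; std::vector<double> tr, tc;
  up2_coeffs(H, r0, r1, tr);
  up2_coeffs(W, c0, c1, tc);
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int ow = 0; ow < Wo; ++ow)
        for (int oh = 0; oh < Ho; ++oh, ++o) {
          const double a = tr[oh], b = tc[ow];
          y[o] =
            (1 - a) * (1 - b) * x[idx4(r0[oh], c0[ow], c, n, H, W, C)] +
            a       * (1 - b) * x[idx4(r1[oh], c0[ow], c, n, H, W, C)] +
            (1 - a) * b       * x[idx4(r0[oh], c1[ow], c, n, H, W, C)] +
            a       * b       * x[idx4(r1[oh], c1[ow], c, n, H, W, C)];
        }
  return y;
}

// [[Rcpp::export(name = ".cpp_up2_bw")]]
NumericVector cpp_up2_bw(NumericVector gy, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = 2 * H, Wo = 2 * W;
  std::vector<int> r0, r1, c0, c1; std::vector<double> tr, tc;
  up2_coeffs(H, r0, r1, tr);
  up2_coeffs(W, c0, c1, tc);
  NumericVector gx((R_xlen_t)H * W * C * N);
  gx.attr("dim") = xdim;
  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int ow = 0; ow < Wo; ++ow)
        for (int oh = 0; oh < Ho; ++oh, ++o) {
          const double a = tr[oh], b = tc[ow], g = gy[o];
          gx[idx4(r0[oh], c0[ow], c, n, H, W, C)] += (1 - a) * (1 - b) * g;
          gx[idx4(r1[oh], c0[ow], c, n, H, W, C)] += a       * (1 - b) * g;
          gx[idx4(r0[oh], c1[ow], c, n, H, W, C)] += (1 - a) * b       * g;
          gx[idx4(r1[oh], c1[ow], c, n, H, W, C)] += a       * b       * g;
        }
  return gx;
}

// Batch normalisation over (H, W, N) per channel, operating directly on
// the (H, W, C, N) layout. Channel c of sample n is the contiguous block
// starting at H*W*(c + C*n).

// [[Rcpp::export(name = ".cpp_bn_stats")]]
List cpp_bn_stats(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const R_xlen_t hw = (R_xlen_t)H * W;
  NumericVector mean(C), var(C);
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + hw * ((R_xlen_t)c + (R_xlen_t)C * n);
      for (R_xlen_t k = 0; k < hw; ++k) { s += p[k]; s2 += p[k] * p[k]; }
    }
    const double m = s / (hw * N);
    mean[c] = m;
    var[c] = s2 / (hw * N) - m * m;   // biased, as used for normalisation
    if (var[c] < 0) var[c] = 0;
  }
  return List::create(_["mean"] = mean, _["var"] = var);
}

// [[Rcpp::export(name = ".cpp_bn_fw")]]
NumericVector cpp_bn_fw(NumericVector x, NumericVector gamma,
                        NumericVector beta, NumericVector mean,
                        NumericVector var, double eps) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const R_xlen_t hw = (R_xlen_t)H * W;
  NumericVector y(x.size());
  y.attr("dim") = xd;
  for (int c = 0; c < C; ++c) {
    const double invstd = 1.0 / std::sqrt(var[c] + eps);
    const double a = gamma[c] * invstd;
    const double b = beta[c] - a * mean[c];
    for (int n = 0; n < N; ++n) {
      const R_xlen_t off = hw * ((R_xlen_t)c + (R_xlen_t)C * n);
      const double* p = x.begin() + off;
      double* q = y.begin() + off;
      for (R_xlen_t k = 0; k < hw; ++k) q[k] = a * p[k] + b;
    }
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_bn_bw")]]
List cpp_bn_bw(NumericVector x, NumericVector gy, NumericVector gamma,
               NumericVector mean, NumericVector var, double eps,
               bool training) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const R_xlen_t hw = (R_xlen_t)H * W;
  const double m = (double)hw * N;
  NumericVector gx(x.size()), ggamma(C), gbeta(C);
  gx.attr("dim") = xd;
  for (int c = 0; c < C; ++c) {
    const double invstd = 1.0 / std::sqrt(var[c] + eps);
    double s1 = 0, s2 = 0;   // sum gy, sum gy*xhat
    for (int n = 0; n < N; ++n) {
      const R_xlen_t off = hw * ((R_xlen_t)c + (R_xlen_t)C * n);
      const double* px = x.begin() + off;
      const double* pg = gy.begin() + off;
      for (R_xlen_t k = 0; k < hw; ++k) {
        s1 += pg[k];
        s2 += pg[k] * (px[k] - mean[c]) * invstd;
      }
    }
    gbeta[c] = s1; ggamma[c] = s2;
    const double a = gamma[c] * invstd;
    for (int n = 0; n < N; ++n) {
      const R_xlen_t off = hw * ((R_xlen_t)c + (R_xlen_t)C * n);
      const double* px = x.begin() + off;
      const double* pg = gy.begin() + off;
      double* pq = gx.begin() + off;
      if (training) {
        for (R_xlen_t k = 0; k < hw; ++k) {
          const double xhat = (px[k] - mean[c]) * invstd;
          pq[k] = a * (pg[k] - s1 / m - xhat * s2 / m);
        }
      } else {
        for (R_xlen_t k = 0; k < hw; ++k) pq[k] = a * pg[k];
      }
    }
  }
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma,
                      _["gbeta"] = gbeta);
}
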