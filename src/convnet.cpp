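// Dense kernels for the stacked-hourglass localizer: stride-1 "same"
// convolution (im2col + GEMM) with hand-derived backward passes, 2x2 max
// pooling and nearest-neighbour upsampling. Tensors are R arrays with dim
// (H, W, C, N), column-major. Weights have dim (kh, kw, Cin, Cout), so the
// flat weight matrix is (kh*kw*Cin) x Cout with no copying.

#include <RcppArmadillo.h>
using namespace Rcpp;

// [[Rcpp::depends(RcppArmadillo)]]

static arma::mat im2col(const double* x, int H, int W, int C, int N,
                        int kh, int kw, int pad) {
  // rows: h + H*w + H*W*n ; cols: dh + kh*dw + kh*kw*c
  arma::mat col((size_t)H * W * N, (size_t)kh * kw * C, arma::fill::zeros);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* src = x + ((size_t)n * C + c) * H * W;
      for (int dw = 0; dw < kw; ++dw)
        for (int dh = 0; dh < kh; ++dh) {
          double* dst = col.colptr(dh + (size_t)kh * dw + (size_t)kh * kw * c);
          for (int w = 0; w < W; ++w) {
            int iw = w + dw - pad;
            if (iw < 0 || iw >= W) continue;
            const double* s2 = src + (size_t)H * iw;
            double* d2 = dst + (size_t)H * w + (size_t)H * W * n;
            int h0 = std::max(0, pad - dh), h1 = std::min(H, H + pad - dh);
            for (int h = h0; h < h1; ++h) d2[h] = s2[h + dh - pad];
          }
        }
    }
  return col;
}

static void col2im(const arma::mat& col, double* gx, int H, int W, int C, int N,
                   int kh, int kw, int pad) {
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* dst = gx + ((size_t)n * C + c) * H * W;
      for (int dw = 0; dw < kw; ++dw)
        for (int dh = 0; dh < kh; ++dh) {
          const double* src = col.colptr(dh + (size_t)kh * dw + (size_t)kh * kw * c);
          for (int w = 0; w < W; ++w) {
            int iw = w + dw - pad;
            if (iw < 0 || iw >= W) continue;
            double* d2 = dst + (size_t)H * iw;
            const double* s2 = src + (size_t)H * w + (size_t)H * W * n;
            int h0 = std::max(0, pad - dh), h1 = std::min(H, H + pad - dh);
            for (int h = h0; h < h1; ++h) d2[h + dh - pad] += s2[h];
          }
        }
    }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd(NumericVector x, NumericVector wt, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = wt.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  int pad = (kh - 1) / 2;
  arma::mat col = im2col(x.begin(), H, W, C, N, kh, kw, pad);
  arma::mat Wm(const_cast<double*>(wt.begin()), (size_t)kh * kw * C, Cout, false, true);
  arma::mat Y = col * Wm;  // (H*W*N) x Cout
  NumericVector y((size_t)H * W * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  double* yp = y.begin();
  for (int co = 0; co < Cout; ++co) {
    const double* ycol = Y.colptr(co);
    double bias = b[co];
    for (int n = 0; n < N; ++n) {
      const double* srcn = ycol + (size_t)H * W * n;
      double* dstn = yp + ((size_t)n * Cout + co) * H * W;
      for (size_t i = 0; i < (size_t)H * W; ++i) dstn[i] = srcn[i] + bias;
    }
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd(NumericVector x, NumericVector wt, NumericVector gy) {
  IntegerVector xd = x.attr("dim"), wd = wt.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  int pad = (kh - 1) / 2;
  arma::mat col = im2col(x.begin(), H, W, C, N, kh, kw, pad);
  // permute gy (H,W,Cout,N) -> gY (H*W*N) x Cout
  arma::mat gY((size_t)H * W * N, Cout);
  const double* gp = gy.begin();
  for (int co = 0; co < Cout; ++co) {
    double* dcol = gY.colptr(co);
    for (int n = 0; n < N; ++n) {
      const double* srcn = gp + ((size_t)n * Cout + co) * H * W;
      double* dstn = dcol + (size_t)H * W * n;
      for (size_t i = 0; i < (size_t)H * W; ++i) dstn[i] = srcn[i];
    }
  }
  arma::mat Wm(const_cast<double*>(wt.begin()), (size_t)kh * kw * C, Cout, false, true);
  arma::mat gW = col.t() * gY;
  arma::rowvec gb = arma::sum(gY, 0);
  arma::mat gcol = gY * Wm.t();
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  col2im(gcol, gx.begin(), H, W, C, N, kh, kw, pad);
  NumericVector gWv(gW.begin(), gW.end());
  gWv.attr("dim") = IntegerVector::create(kh, kw, C, Cout);
  return List::create(_["gx"] = gx, _["gW"] = gWv,
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}

// [[Rcpp::export]]
List maxpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N);  // 0-based flat index into x
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      size_t base = ((size_t)n * C + c) * H * W;
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          size_t i00 = base + (size_t)H * (2 * w) + 2 * h;
          size_t best = i00;
          double bv = xp[i00];
          size_t cand[3] = {i00 + 1, i00 + (size_t)H, i00 + (size_t)H + 1};
          for (int k = 0; k < 3; ++k)
            if (xp[cand[k]] > bv) { bv = xp[cand[k]]; best = cand[k]; }
          yp[o] = bv;
          ip[o] = (int)best;
          ++o;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd(NumericVector gy, IntegerVector idx, IntegerVector xdim) {
  NumericVector gx((size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  gx.attr("dim") = xdim;
  double* gp = gx.begin();
  const double* gyp = gy.begin();
  const int* ip = idx.begin();
  size_t n = gy.size();
  for (size_t i = 0; i < n; ++i) gp[ip[i]] += gyp[i];
  return gx;
}

// [[Rcpp::export]]
NumericVector upsample2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      size_t bi = ((size_t)n * C + c) * H * W;
      size_t bo = ((size_t)n * C + c) * Ho * Wo;
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h)
          yp[bo + (size_t)Ho * w + h] = xp[bi + (size_t)H * (w / 2) + h / 2];
    }
  return y;
}

// [[Rcpp::export]]
NumericVector upsample2_bwd(NumericVector gy) {
  IntegerVector yd = gy.attr("dim");
  int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  int H = Ho / 2, W = Wo / 2;
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double* gp = gy.begin();
  double* xp = gx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      size_t bi = ((size_t)n * C + c) * H * W;
      size_t bo = ((size_t)n * C + c) * Ho * Wo;
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h)
          xp[bi + (size_t)H * (w / 2) + h / 2] += gp[bo + (size_t)Ho * w + h];
    }
  return gx;
}
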