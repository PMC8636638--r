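// Minimal conv-net kernels: batched 2-D convolution via im2col + BLAS gemm,
// and a bilinear affine resampler used by the label-preserving augmentation.
//
// Tensor layout is R column-major throughout:
//   activations x : (H, W, C, N)
//   filters     w : (k, k, Cin, Cout)   (square kernels only)
//   outputs     y : (Ho, Wo, Cout, N)
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// Fill K (k*k*Cin x Ho*Wo) with patches of image n. Row index is
// kh + k*kw + k*k*ci; column index is ho + Ho*wo.
static void im2col(const double* x, int H, int W, int Cin,
                   int k, int stride, int pad, int Ho, int Wo,
                   arma::mat& K) {
  K.zeros();
  for (int ci = 0; ci < Cin; ++ci) {
    const double* xc = x + (size_t)H * W * ci;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const int col = ho + Ho * wo;
        double* Kcol = K.colptr(col);
        const int h0 = ho * stride - pad;
        const int w0 = wo * stride - pad;
        for (int kw = 0; kw < k; ++kw) {
          const int wi = w0 + kw;
          if (wi < 0 || wi >= W) continue;
          const double* xcol = xc + (size_t)H * wi;
          double* Krow = Kcol + k * kw + k * k * ci;
          for (int kh = 0; kh < k; ++kh) {
            const int hi = h0 + kh;
            if (hi < 0 || hi >= H) continue;
            Krow[kh] = xcol[hi];
          }
        }
      }
    }
  }
}

// Scatter-add of dK (k*k*Cin x Ho*Wo) back into image gradient dx.
static void col2im(const arma::mat& dK, int H, int W, int Cin,
                   int k, int stride, int pad, int Ho, int Wo,
                   double* dx) {
  for (int ci = 0; ci < Cin; ++ci) {
    double* xc = dx + (size_t)H * W * ci;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const int col = ho + Ho * wo;
        const double* Kcol = dK.colptr(col);
        const int h0 = ho * stride - pad;
        const int w0 = wo * stride - pad;
        for (int kw = 0; kw < k; ++kw) {
          const int wi = w0 + kw;
          if (wi < 0 || wi >= W) continue;
          double* xcol = xc + (size_t)H * wi;
          const double* Krow = Kcol + k * kw + k * k * ci;
          for (int kh = 0; kh < k; ++kh) {
            const int hi = h0 + kh;
            if (hi < 0 || hi >= H) continue;
            xcol[hi] += Krow[kh];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(const NumericVector& x, const NumericVector& w,
                             const NumericVector& b, int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  if (wd[1] != k || wd[2] != Cin) stop("filter dimensions inconsistent with input");
  const int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  if (Ho <= 0 || Wo <= 0) stop("convolution output would be empty");

  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  const arma::mat Wm(const_cast<double*>(w.begin()), k * k * Cin, Cout, false, true);
  const arma::rowvec bias(const_cast<double*>(b.begin()), Cout, false, true);
  arma::mat K(k * k * Cin, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * Cin * n, H, W, Cin, k, stride, pad, Ho, Wo, K);
    // (Ho*Wo x Cout), column-major: exactly the (Ho,Wo,Cout) slice layout
    arma::mat Y(y.begin() + (size_t)Ho * Wo * Cout * n, Ho * Wo, Cout, false, true);
    Y = K.t() * Wm;
    Y.each_row() += bias;
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(const NumericVector& x, const NumericVector& w,
                    const NumericVector& dy, int stride, int pad,
                    bool need_dx) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  const int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);

  arma::mat dWm(k * k * Cin, Cout, arma::fill::zeros);
  arma::rowvec db(Cout, arma::fill::zeros);
  const arma::mat Wm(const_cast<double*>(w.begin()), k * k * Cin, Cout, false, true);

  NumericVector dx;
  if (need_dx) {
    dx = NumericVector((size_t)H * W * Cin * N);
    dx.attr("dim") = IntegerVector::create(H, W, Cin, N);
  }
  arma::mat K(k * k * Cin, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    const arma::mat dY(const_cast<double*>(dy.begin()) + (size_t)Ho * Wo * Cout * n,
                       Ho * Wo, Cout, false, true);
    im2col(x.begin() + (size_t)H * W * Cin * n, H, W, Cin, k, stride, pad, Ho, Wo, K);
    dWm += K * dY;
    db += arma::sum(dY, 0);
    if (need_dx) {
      arma::mat dK = Wm * dY.t();
      col2im(dK, H, W, Cin, k, stride, pad, Ho, Wo,
             dx.begin() + (size_t)H * W * Cin * n);
    }
  }
  NumericVector dwv(dWm.begin(), dWm.end());
  dwv.attr("dim") = IntegerVector::create(k, k, Cin, Cout);
  NumericVector dbv(db.begin(), db.end());
  if (need_dx) return List::create(_["dw"] = dwv, _["db"] = dbv, _["dx"] = dx);
  return List::create(_["dw"] = dwv, _["db"] = dbv);
}

// Bilinear resampling under an affine map from output to input coordinates:
//   (ri, ci) = A %*% (ro, co) + b, all in 1-based pixel coordinates.
// Samples falling outside the input are filled with `fill`.
// [[Rcpp::export]]
NumericMatrix cpp_affine_sample(const NumericMatrix& img,
                                const NumericVector& A, const NumericVector& b,
                                int out_h, int out_w, double fill) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(out_h, out_w);
  const double a11 = A[0], a21 = A[1], a12 = A[2], a22 = A[3];
  for (int co = 0; co < out_w; ++co) {
    const double xo = co + 1.0;
    for (int ro = 0; ro < out_h; ++ro) {
      const double yo = ro + 1.0;
      const double yi = a11 * yo + a12 * xo + b[0];
      const double xi = a21 * yo + a22 * xo + b[1];
      const int r0 = (int)std::floor(yi), c0 = (int)std::floor(xi);
      const double fr = yi - r0, fc = xi - c0;
      double v = 0.0;
      // corners, 1-based; zero-weight corners may fall outside
      for (int dr = 0; dr <= 1; ++dr) {
        for (int dc = 0; dc <= 1; ++dc) {
          const double wgt = (dr ? fr : 1.0 - fr) * (dc ? fc : 1.0 - fc);
          if (wgt == 0.0) continue;
          const int r = r0 + dr, c = c0 + dc;
          v += wgt * ((r >= 1 && r <= H && c >= 1 && c <= W) ? img(r - 1, c - 1) : fill);
        }
      }
      out(ro, co) = v;
    }
  }
  return out;
}
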