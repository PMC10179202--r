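// Minimal conv-net primitives for the residual autoencoder: stride-1
// convolution via im2col + BLAS, 2x2 average pooling, 2x nearest
// upsampling, each with its backward pass. Tensors are R arrays in
// (H, W, C, B) column-major layout; weights are (Cin*kh*kw) x Cout with
// patch row index c*kh*kw + j*kh + i.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static void im2col(const double* x, int H, int W, int C, int kh, int kw,
                   int pad, arma::mat& M) {
  int Ho = H + 2 * pad - kh + 1, Wo = W + 2 * pad - kw + 1;
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < kw; ++j)
      for (int i = 0; i < kh; ++i) {
        int row = c * kh * kw + j * kh + i;
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo - pad + j;
          bool wok = (wi >= 0 && wi < W);
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho - pad + i;
            double val = 0.0;
            if (wok && hi >= 0 && hi < H)
              val = x[hi + (size_t)H * (wi + (size_t)W * c)];
            M(row, wo * Ho + ho) = val;
          }
        }
      }
}

static void col2im(const arma::mat& M, int H, int W, int C, int kh, int kw,
                   int pad, double* x) {
  int Ho = H + 2 * pad - kh + 1, Wo = W + 2 * pad - kw + 1;
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < kw; ++j)
      for (int i = 0; i < kh; ++i) {
        int row = c * kh * kw + j * kh + i;
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo - pad + j;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho - pad + i;
            if (hi < 0 || hi >= H) continue;
            x[hi + (size_t)H * (wi + (size_t)W * c)] += M(row, wo * Ho + ho);
          }
        }
      }
}

// [[Rcpp::export(name = ".conv2d_fw_cpp")]]
NumericVector conv2d_fw_cpp(NumericVector x, IntegerVector dims,
                            NumericMatrix Wm, NumericVector bias, int kh,
                            int kw, int pad) {
  int H = dims[0], W = dims[1], C = dims[2], B = dims[3];
  int Ho = H + 2 * pad - kh + 1, Wo = W + 2 * pad - kw + 1;
  int Cout = Wm.ncol();
  arma::mat Wmat(Wm.begin(), Wm.nrow(), Cout, false);
  NumericVector y((size_t)Ho * Wo * Cout * B);
  arma::mat M(C * kh * kw, Ho * Wo);
  for (int b = 0; b < B; ++b) {
    im2col(x.begin() + (size_t)H * W * C * b, H, W, C, kh, kw, pad, M);
    arma::mat Y = Wmat.t() * M;  // Cout x (Ho*Wo)
    double* yp = y.begin() + (size_t)Ho * Wo * Cout * b;
    for (int co = 0; co < Cout; ++co) {
      double bb = bias[co];
      for (int p = 0; p < Ho * Wo; ++p)
        yp[(size_t)Ho * Wo * co + p] = Y(co, p) + bb;
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, B);
  return y;
}

// [[Rcpp::export(name = ".conv2d_bw_cpp")]]
List conv2d_bw_cpp(NumericVector x, IntegerVector dims, NumericMatrix Wm,
                   NumericVector dy, int kh, int kw, int pad) {
  int H = dims[0], W = dims[1], C = dims[2], B = dims[3];
  int Ho = H + 2 * pad - kh + 1, Wo = W + 2 * pad - kw + 1;
  int Cout = Wm.ncol();
  arma::mat Wmat(Wm.begin(), Wm.nrow(), Cout, false);
  NumericVector dx((size_t)H * W * C * B);
  arma::mat dW(Wm.nrow(), Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat M(C * kh * kw, Ho * Wo);
  arma::mat dY(Cout, Ho * Wo);
  for (int b = 0; b < B; ++b) {
    const double* dyp = dy.begin() + (size_t)Ho * Wo * Cout * b;
    for (int co = 0; co < Cout; ++co)
      for (int p = 0; p < Ho * Wo; ++p)
        dY(co, p) = dyp[(size_t)Ho * Wo * co + p];
    im2col(x.begin() + (size_t)H * W * C * b, H, W, C, kh, kw, pad, M);
    dW += M * dY.t();
    db += arma::sum(dY, 1);
    arma::mat dM = Wmat * dY;  // rows x (Ho*Wo)
    col2im(dM, H, W, C, kh, kw, pad, dx.begin() + (size_t)H * W * C * b);
  }
  dx.attr("dim") = IntegerVector::create(H, W, C, B);
  return List::create(_["dx"] = dx, _["dW"] = wrap(dW), _["db"] = wrap(db));
}

// [[Rcpp::export(name = ".avgpool2_fw_cpp")]]
NumericVector avgpool2_fw_cpp(NumericVector x, IntegerVector dims) {
  int H = dims[0], W = dims[1], C = dims[2], B = dims[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * B);
  for (int cb = 0; cb < C * B; ++cb) {
    const double* xp = x.begin() + (size_t)H * W * cb;
    double* yp = y.begin() + (size_t)Ho * Wo * cb;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        int h = 2 * ho, w = 2 * wo;
        yp[ho + (size_t)Ho * wo] =
            0.25 * (xp[h + (size_t)H * w] + xp[h + 1 + (size_t)H * w] +
                    xp[h + (size_t)H * (w + 1)] +
                    xp[h + 1 + (size_t)H * (w + 1)]);
      }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  return y;
}

// [[Rcpp::export(name = ".avgpool2_bw_cpp")]]
NumericVector avgpool2_bw_cpp(NumericVector dy, IntegerVector dims) {
  int Ho = dims[0], Wo = dims[1], C = dims[2], B = dims[3];
  int H = Ho * 2, W = Wo * 2;
  NumericVector dx((size_t)H * W * C * B);
  for (int cb = 0; cb < C * B; ++cb) {
    const double* dyp = dy.begin() + (size_t)Ho * Wo * cb;
    double* dxp = dx.begin() + (size_t)H * W * cb;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        double g = 0.25 * dyp[ho + (size_t)Ho * wo];
        int h = 2 * ho, w = 2 * wo;
        dxp[h + (size_t)H * w] += g;
        dxp[h + 1 + (size_t)H * w] += g;
        dxp[h + (size_t)H * (w + 1)] += g;
        dxp[h + 1 + (size_t)H * (w + 1)] += g;
      }
  }
  dx.attr("dim") = IntegerVector::create(H, W, C, B);
  return dx;
}

// [[Rcpp::export(name = ".upsample2_fw_cpp")]]
NumericVector upsample2_fw_cpp(NumericVector x, IntegerVector dims) {
  int H = dims[0], W = dims[1], C = dims[2], B = dims[3];
  int Ho = H * 2, Wo = W * 2;
  NumericVector y((size_t)Ho * Wo * C * B);
  for (int cb = 0; cb < C * B; ++cb) {
    const double* xp = x.begin() + (size_t)H * W * cb;
    double* yp = y.begin() + (size_t)Ho * Wo * cb;
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        double v = xp[h + (size_t)H * w];
        int ho = 2 * h, wo = 2 * w;
        yp[ho + (size_t)Ho * wo] = v;
        yp[ho + 1 + (size_t)Ho * wo] = v;
        yp[ho + (size_t)Ho * (wo + 1)] = v;
        yp[ho + 1 + (size_t)Ho * (wo + 1)] = v;
      }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  return y;
}

// [[Rcpp::export(name = ".upsample2_bw_cpp")]]
NumericVector upsample2_bw_cpp(NumericVector dy, IntegerVector dims) {
  int Ho = dims[0], Wo = dims[1], C = dims[2], B = dims[3];
  int H = Ho / 2, W = Wo / 2;
  NumericVector dx((size_t)H * W * C * B);
  for (int cb = 0; cb < C * B; ++cb) {
    const double* dyp = dy.begin() + (size_t)Ho * Wo * cb;
    double* dxp = dx.begin() + (size_t)H * W * cb;
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        int ho = 2 * h, wo = 2 * w;
        dxp[h + (size_t)H * w] = dyp[ho + (size_t)Ho * wo] +
                                 dyp[ho + 1 + (size_t)Ho * wo] +
                                 dyp[ho + (size_t)Ho * (wo + 1)] +
                                 dyp[ho + 1 + (size_t)Ho * (wo + 1)];
      }
  }
  dx.attr("dim") = IntegerVector::create(H, W, C, B);
  return dx;
}
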