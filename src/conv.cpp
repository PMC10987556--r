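// Convolution forward/backward kernels for the tiny multibox detector.
// Layout contract (column-major, matching the R arrays):
//   activations: [H, W, N, C]   weights: [k, k, Cin, Cout]
// im2col row index r = di + k*dj + k*k*ci, column index = ho + Ho*(wo + Wo*n),
// so the weight array flattens directly into the (k*k*Cin) x Cout matrix.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static arma::mat im2col_pad(const double *x, int H, int W, int N, int Cin,
                            int k, int stride, int pad, int Ho, int Wo) {
  arma::mat cols(k * k * Cin, (arma::uword)Ho * Wo * N, arma::fill::zeros);
  for (int ci = 0; ci < Cin; ++ci) {
    for (int n = 0; n < N; ++n) {
      const double *xs = x + ((arma::uword)ci * N + n) * H * W;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          arma::uword col = ho + (arma::uword)Ho * (wo + (arma::uword)Wo * n);
          double *dst = cols.colptr(col) + (arma::uword)k * k * ci;
          for (int dj = 0; dj < k; ++dj) {
            int wi = wo * stride + dj - pad;
            if (wi < 0 || wi >= W) continue;
            const double *xcol = xs + (arma::uword)wi * H;
            for (int di = 0; di < k; ++di) {
              int hi = ho * stride + di - pad;
              if (hi < 0 || hi >= H) continue;
              dst[di + k * dj] = xcol[hi];
            }
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
NumericVector conv_fw_cpp(NumericVector x, IntegerVector xdim,
                          NumericVector w, IntegerVector wdim,
                          NumericVector b, int stride, int pad) {
  int H = xdim[0], W = xdim[1], N = xdim[2], Cin = xdim[3];
  int k = wdim[0], Cout = wdim[3];
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  arma::mat cols = im2col_pad(x.begin(), H, W, N, Cin, k, stride, pad, Ho, Wo);
  arma::mat wm(w.begin(), k * k * Cin, Cout, false, true);
  arma::mat out = cols.t() * wm;
  out.each_row() += arma::rowvec(b.begin(), Cout);
  NumericVector res(out.begin(), out.end());
  res.attr("dim") = IntegerVector::create(Ho, Wo, N, Cout);
  return res;
}

// [[Rcpp::export]]
List conv_bw_cpp(NumericVector x, IntegerVector xdim,
                 NumericVector w, IntegerVector wdim,
                 NumericVector dout, int stride, int pad) {
  int H = xdim[0], W = xdim[1], N = xdim[2], Cin = xdim[3];
  int k = wdim[0], Cout = wdim[3];
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  arma::uword ncol = (arma::uword)Ho * Wo * N;
  arma::mat cols = im2col_pad(x.begin(), H, W, N, Cin, k, stride, pad, Ho, Wo);
  arma::mat dm(dout.begin(), ncol, Cout, false, true);
  arma::mat wm(w.begin(), k * k * Cin, Cout, false, true);
  arma::mat dW = cols * dm;                 // (k*k*Cin) x Cout
  arma::rowvec db = arma::sum(dm, 0);
  arma::mat dcols = wm * dm.t();            // (k*k*Cin) x ncol
  NumericVector dx(x.size());
  double *dxp = dx.begin();
  for (int ci = 0; ci < Cin; ++ci) {
    for (int n = 0; n < N; ++n) {
      double *xs = dxp + ((arma::uword)ci * N + n) * H * W;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          arma::uword col = ho + (arma::uword)Ho * (wo + (arma::uword)Wo * n);
          const double *src = dcols.colptr(col) + (arma::uword)k * k * ci;
          for (int dj = 0; dj < k; ++dj) {
            int wi = wo * stride + dj - pad;
            if (wi < 0 || wi >= W) continue;
            double *xcol = xs + (arma::uword)wi * H;
            for (int di = 0; di < k; ++di) {
              int hi = ho * stride + di - pad;
              if (hi < 0 || hi >= H) continue;
              xcol[hi] += src[di + k * dj];
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = xdim;
  NumericVector dWv(dW.begin(), dW.end());
  dWv.attr("dim") = wdim;
  return List::create(_["dx"] = dx, _["dW"] = dWv,
                      _["db"] = NumericVector(db.begin(), db.end()));
}
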