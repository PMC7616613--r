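// Armadillo-backed 2D convolution primitives for the built-in autodiff
// engine. Layout matches R column-major arrays: activations (H, W, C, N),
// kernels (k, k, Cin, Cout), "same" zero padding, stride 1, odd k.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// M: (H*W) x (k*k*C) patch matrix for one sample
static void im2col(const double* x, int H, int W, int C, int k, arma::mat& M) {
  const int p = k / 2;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        double* Mq = M.colptr(ki + k * (kj + k * c));
        for (int w = 0; w < W; ++w) {
          const int wi = w + kj - p;
          double* Mcol = Mq + (size_t)H * w;
          if (wi < 0 || wi >= W) {
            std::fill(Mcol, Mcol + H, 0.0);
            continue;
          }
          const double* xcol = xc + (size_t)H * wi;
          for (int h = 0; h < H; ++h) {
            const int hi = h + ki - p;
            Mcol[h] = (hi < 0 || hi >= H) ? 0.0 : xcol[hi];
          }
        }
      }
    }
  }
}

// scatter-add transpose of im2col
static void col2im(const arma::mat& M, int H, int W, int C, int k, double* gx) {
  const int p = k / 2;
  for (int c = 0; c < C; ++c) {
    double* gc = gx + (size_t)H * W * c;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const double* Mq = M.colptr(ki + k * (kj + k * c));
        for (int w = 0; w < W; ++w) {
          const int wi = w + kj - p;
          if (wi < 0 || wi >= W) continue;
          double* gcol = gc + (size_t)H * wi;
          const double* Mcol = Mq + (size_t)H * w;
          for (int h = 0; h < H; ++h) {
            const int hi = h + ki - p;
            if (hi >= 0 && hi < H) gcol[hi] += Mcol[h];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fw(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector dx = x.attr("dim"), dw = w.attr("dim");
  const int H = dx[0], W = dx[1], Cin = dx[2], N = dx[3];
  const int k = dw[0], Cout = dw[3];
  arma::mat Wmat(const_cast<double*>(w.begin()), (size_t)k * k * Cin, Cout, false, true);
  NumericVector y((size_t)H * W * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat M((size_t)H * W, (size_t)k * k * Cin);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * Cin * n, H, W, Cin, k, M);
    arma::mat Y(y.begin() + (size_t)H * W * Cout * n, (size_t)H * W, Cout, false, true);
    Y = M * Wmat;
    for (int c = 0; c < Cout; ++c) Y.col(c) += b[c];
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bw(NumericVector x, NumericVector w, NumericVector gy,
               bool need_gx) {
  IntegerVector dx = x.attr("dim"), dw = w.attr("dim");
  const int H = dx[0], W = dx[1], Cin = dx[2], N = dx[3];
  const int k = dw[0], Cout = dw[3];
  arma::mat Wmat(const_cast<double*>(w.begin()), (size_t)k * k * Cin, Cout, false, true);
  NumericVector gxv(need_gx ? x.size() : R_xlen_t(1));
  if (need_gx) gxv.attr("dim") = IntegerVector::create(H, W, Cin, N);
  NumericVector gwv(w.size());
  gwv.attr("dim") = dw;
  NumericVector gbv(Cout);
  arma::mat GW(gwv.begin(), (size_t)k * k * Cin, Cout, false, true);
  arma::mat M((size_t)H * W, (size_t)k * k * Cin);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * Cin * n, H, W, Cin, k, M);
    arma::mat GY(const_cast<double*>(gy.begin()) + (size_t)H * W * Cout * n,
                 (size_t)H * W, Cout, false, true);
    GW += M.t() * GY;
    for (int c = 0; c < Cout; ++c) gbv[c] += arma::accu(GY.col(c));
    if (need_gx) {
      arma::mat GM = GY * Wmat.t();
      col2im(GM, H, W, Cin, k, gxv.begin() + (size_t)H * W * Cin * n);
    }
  }
  return List::create(_["gx"] = need_gx ? SEXP(gxv) : R_NilValue,
                      _["gw"] = gwv, _["gb"] = gbv);
}
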