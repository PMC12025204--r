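// 3x3 same-zero-padding convolution kernels for the autoencoder. Per-sample
// im2col into a reused buffer plus one BLAS GEMM; the pure-R implementation
// in R/nn.R is kept as the reference these are tested against.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Patch matrix P (HW x 9C) for one H x W x C sample; column (k*C + c) holds
// the channel-c plane shifted by offset k (dj outer, di inner, -1..1).
static void im2col3(const double* x, int H, int W, int C, arma::mat& P) {
  const int HW = H * W;
  int k = 0;
  for (int dj = -1; dj <= 1; ++dj) {
    for (int di = -1; di <= 1; ++di) {
      for (int c = 0; c < C; ++c) {
        double* col = P.colptr((std::size_t)k * C + c);
        const double* xc = x + (std::size_t)c * HW;
        for (int j = 0; j < W; ++j) {
          int jj = j + dj;
          double* outcol = col + (std::size_t)j * H;
          if (jj < 0 || jj >= W) {
            std::fill(outcol, outcol + H, 0.0);
            continue;
          }
          const double* incol = xc + (std::size_t)jj * H;
          int i0 = std::max(0, -di);
          int i1 = std::min(H, H - di);
          if (i0 > 0) std::fill(outcol, outcol + i0, 0.0);
          std::copy(incol + i0 + di, incol + i1 + di, outcol + i0);
          if (i1 < H) std::fill(outcol + i1, outcol + H, 0.0);
        }
      }
      ++k;
    }
  }
}

// Weight tensor (3, 3, C, F) [di, dj, c, f] -> stacked (9C x F) matrix with
// rows ordered to match im2col3 columns.
static arma::mat stack_weights(const NumericVector& Wt, int C, int F) {
  arma::mat Wm(9 * C, F);
  for (int f = 0; f < F; ++f) {
    for (int c = 0; c < C; ++c) {
      for (int dj = 0; dj < 3; ++dj) {
        for (int di = 0; di < 3; ++di) {
          Wm((std::size_t)(dj * 3 + di) * C + c, f) =
            Wt[di + 3 * (dj + 3 * ((std::size_t)c + (std::size_t)C * f))];
        }
      }
    }
  }
  return Wm;
}

// [[Rcpp::export(name = ".conv3_forward_cpp")]]
NumericVector conv3_forward_cpp(NumericVector X, NumericVector Wt,
                                NumericVector b) {
  IntegerVector dx = X.attr("dim");
  int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  IntegerVector dw = Wt.attr("dim");
  int F = dw[3];
  const int HW = H * W;
  arma::mat Wm = stack_weights(Wt, C, F);
  NumericVector Y((R_xlen_t)HW * F * N);
  Y.attr("dim") = IntegerVector::create(H, W, F, N);
  arma::mat P(HW, 9 * C);
  const double* xp = REAL(X);
  double* yp = REAL(Y);
  for (int n = 0; n < N; ++n) {
    im2col3(xp + (std::size_t)n * HW * C, H, W, C, P);
    arma::mat Yn = P * Wm;
    double* yout = yp + (std::size_t)n * HW * F;
    for (int f = 0; f < F; ++f) {
      const double* src = Yn.colptr(f);
      double* dst = yout + (std::size_t)f * HW;
      const double bb = b[f];
      for (int p = 0; p < HW; ++p) dst[p] = src[p] + bb;
    }
  }
  return Y;
}

// Weight and bias gradients; the input gradient is obtained in R by a
// forward pass of dY through the spatially flipped weights.
// [[Rcpp::export(name = ".conv3_backward_cpp")]]
List conv3_backward_cpp(NumericVector dY, NumericVector X, NumericVector Wt) {
  IntegerVector dx = X.attr("dim");
  int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  IntegerVector dw = Wt.attr("dim");
  int F = dw[3];
  const int HW = H * W;
  arma::mat dWm(9 * C, F, arma::fill::zeros);
  arma::rowvec db(F, arma::fill::zeros);
  arma::mat P(HW, 9 * C);
  const double* xp = REAL(X);
  const double* dyp = REAL(dY);
  for (int n = 0; n < N; ++n) {
    im2col3(xp + (std::size_t)n * HW * C, H, W, C, P);
    const arma::mat dYn(const_cast<double*>(dyp + (std::size_t)n * HW * F),
                        HW, F, false, true);
    dWm += P.t() * dYn;
    db += arma::sum(dYn, 0);
  }
  NumericVector dWt((R_xlen_t)9 * C * F);
  dWt.attr("dim") = IntegerVector::create(3, 3, C, F);
  for (int f = 0; f < F; ++f) {
    for (int c = 0; c < C; ++c) {
      for (int dj = 0; dj < 3; ++dj) {
        for (int di = 0; di < 3; ++di) {
          dWt[di + 3 * (dj + 3 * ((std::size_t)c + (std::size_t)C * f))] =
            dWm((std::size_t)(dj * 3 + di) * C + c, f);
        }
      }
    }
  }
  NumericVector dbv(F);
  for (int f = 0; f < F; ++f) dbv[f] = db[f];
  return List::create(Named("dW") = dWt, Named("db") = dbv);
}
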