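// Minimal CNN kernels for the modified U-net: same-padded 3x3 convolution
// (im2col + GEMM), 1x1 convolution, 2x2/stride-2 max pooling and transposed
// convolution. All tensors are R arrays in (H, W, C, N) layout (column-major,
// so each channel plane is contiguous).
//
// Weight layouts (fixed contract with the R side):
//   3x3 conv:        K  (9*Ci x Co), row index r = ci*9 + kj*3 + ki
//   1x1 conv:        K  (Ci   x Co)
//   2x2 up-conv:     U  (Ci   x 4*Co), col index = co*4 + kj*2 + ki
// Biases are length-Co vectors.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void get_dims4(const NumericVector& x, int& H, int& W, int& C, int& N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

static NumericVector make4(int H, int W, int C, int N) {
  NumericVector out(static_cast<R_xlen_t>(H) * W * C * N);
  out.attr("dim") = IntegerVector::create(H, W, C, N);
  return out;
}

// zero-padded 3x3 neighbourhoods: cols is (9*C) x (H*W), column q = i + H*j
static void im2col3(const double* x, int H, int W, int C, arma::mat& cols) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + static_cast<size_t>(c) * H * W;
    for (int kj = 0; kj < 3; ++kj) {
      for (int ki = 0; ki < 3; ++ki) {
        const int r = c * 9 + kj * 3 + ki;
        for (int j = 0; j < W; ++j) {
          const int jj = j + kj - 1;
          const bool jok = (jj >= 0 && jj < W);
          const double* src = xc + static_cast<size_t>(H) * (jok ? jj : 0);
          for (int i = 0; i < H; ++i) {
            const int ii = i + ki - 1;
            double v = 0.0;
            if (jok && ii >= 0 && ii < H) v = src[ii];
            cols(r, i + static_cast<size_t>(H) * j) = v;
          }
        }
      }
    }
  }
}

// scatter-add of dcols back onto the input grid (adjoint of im2col3)
static void col2im3(const arma::mat& dcols, int H, int W, int C, double* dx) {
  for (int c = 0; c < C; ++c) {
    double* xc = dx + static_cast<size_t>(c) * H * W;
    for (int kj = 0; kj < 3; ++kj) {
      for (int ki = 0; ki < 3; ++ki) {
        const int r = c * 9 + kj * 3 + ki;
        for (int j = 0; j < W; ++j) {
          const int jj = j + kj - 1;
          if (jj < 0 || jj >= W) continue;
          double* dst = xc + static_cast<size_t>(H) * jj;
          for (int i = 0; i < H; ++i) {
            const int ii = i + ki - 1;
            if (ii < 0 || ii >= H) continue;
            dst[ii] += dcols(r, i + static_cast<size_t>(H) * j);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv3x3_forward(NumericVector x, NumericMatrix K, NumericVector b) {
  int H, W, Ci, N;
  get_dims4(x, H, W, Ci, N);
  if (K.nrow() != 9 * Ci) stop("conv3x3: weight rows != 9*Ci");
  const int Co = K.ncol();
  if (b.size() != Co) stop("conv3x3: bias length != Co");
  const arma::mat Ka(const_cast<double*>(K.begin()), K.nrow(), Co, false, true);
  const arma::vec ba(const_cast<double*>(b.begin()), Co, false, true);
  NumericVector y = make4(H, W, Co, N);
  const size_t HW = static_cast<size_t>(H) * W;
  arma::mat cols(9 * Ci, HW);
  for (int n = 0; n < N; ++n) {
    im2col3(x.begin() + HW * Ci * n, H, W, Ci, cols);
    arma::mat Y(y.begin() + HW * Co * n, HW, Co, false, true);
    Y = cols.t() * Ka;          // single dgemm, no explicit transpose copy
    Y.each_row() += ba.t();
  }
  return y;
}

// [[Rcpp::export]]
List conv3x3_backward(NumericVector x, NumericMatrix K, NumericVector dy) {
  int H, W, Ci, N;
  get_dims4(x, H, W, Ci, N);
  int H2, W2, Co, N2;
  get_dims4(dy, H2, W2, Co, N2);
  if (H2 != H || W2 != W || N2 != N || K.nrow() != 9 * Ci || K.ncol() != Co)
    stop("conv3x3_backward: shape mismatch");
  const arma::mat Ka(const_cast<double*>(K.begin()), 9 * Ci, Co, false, true);
  NumericVector dx = make4(H, W, Ci, N);
  arma::mat dK(9 * Ci, Co, arma::fill::zeros);
  arma::vec db(Co, arma::fill::zeros);
  const size_t HW = static_cast<size_t>(H) * W;
  arma::mat cols(9 * Ci, HW);
  for (int n = 0; n < N; ++n) {
    im2col3(x.begin() + HW * Ci * n, H, W, Ci, cols);
    const arma::mat dY(const_cast<double*>(dy.begin()) + HW * Co * n, HW, Co, false, true);
    dK += cols * dY;
    db += arma::sum(dY, 0).t();
    arma::mat dcols = Ka * dY.t();
    col2im3(dcols, H, W, Ci, dx.begin() + HW * Ci * n);
  }
  return List::create(_["dx"] = dx, _["dK"] = wrap(dK), _["db"] = NumericVector(db.begin(), db.end()));
}

// [[Rcpp::export]]
NumericVector conv1x1_forward(NumericVector x, NumericMatrix K, NumericVector b) {
  int H, W, Ci, N;
  get_dims4(x, H, W, Ci, N);
  if (K.nrow() != Ci) stop("conv1x1: weight rows != Ci");
  const int Co = K.ncol();
  const arma::mat Ka(const_cast<double*>(K.begin()), Ci, Co, false, true);
  const arma::vec ba(const_cast<double*>(b.begin()), Co, false, true);
  NumericVector y = make4(H, W, Co, N);
  const size_t HW = static_cast<size_t>(H) * W;
  for (int n = 0; n < N; ++n) {
    const arma::mat X(const_cast<double*>(x.begin()) + HW * Ci * n, HW, Ci, false, true);
    arma::mat Y(y.begin() + HW * Co * n, HW, Co, false, true);
    Y = X * Ka;
    Y.each_row() += ba.t();
  }
  return y;
}

// [[Rcpp::export]]
List conv1x1_backward(NumericVector x, NumericMatrix K, NumericVector dy) {
  int H, W, Ci, N;
  get_dims4(x, H, W, Ci, N);
  int H2, W2, Co, N2;
  get_dims4(dy, H2, W2, Co, N2);
  if (H2 != H || W2 != W || N2 != N || K.nrow() != Ci || K.ncol() != Co)
    stop("conv1x1_backward: shape mismatch");
  const arma::mat Ka(const_cast<double*>(K.begin()), Ci, Co, false, true);
  NumericVector dx = make4(H, W, Ci, N);
  arma::mat dK(Ci, Co, arma::fill::zeros);
  arma::vec db(Co, arma::fill::zeros);
  const size_t HW = static_cast<size_t>(H) * W;
  for (int n = 0; n < N; ++n) {
    const arma::mat X(const_cast<double*>(x.begin()) + HW * Ci * n, HW, Ci, false, true);
    const arma::mat dY(const_cast<double*>(dy.begin()) + HW * Co * n, HW, Co, false, true);
    dK += X.t() * dY;
    db += arma::sum(dY, 0).t();
    arma::mat dX(dx.begin() + HW * Ci * n, HW, Ci, false, true);
    dX = dY * Ka.t();
  }
  return List::create(_["dx"] = dx, _["dK"] = wrap(dK), _["db"] = NumericVector(db.begin(), db.end()));
}

// [[Rcpp::export]]
List maxpool2_forward(NumericVector x) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  if (H % 2 || W % 2) stop("maxpool2: H and W must be even");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y = make4(Ho, Wo, C, N);
  IntegerVector idx(static_cast<R_xlen_t>(Ho) * Wo * C * N);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const size_t HW = static_cast<size_t>(H) * W;
  const size_t HWo = static_cast<size_t>(Ho) * Wo;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + HW * (c + static_cast<size_t>(C) * n);
      double* yp = y.begin() + HWo * (c + static_cast<size_t>(C) * n);
      int* ip = idx.begin() + HWo * (c + static_cast<size_t>(C) * n);
      for (int j = 0; j < Wo; ++j) {
        for (int i = 0; i < Ho; ++i) {
          const int i0 = 2 * i, j0 = 2 * j;
          int best = i0 + H * j0;
          double bv = xp[best];
          const int cand[3] = {i0 + 1 + H * j0, i0 + H * (j0 + 1), i0 + 1 + H * (j0 + 1)};
          for (int k = 0; k < 3; ++k)
            if (xp[cand[k]] > bv) { bv = xp[cand[k]]; best = cand[k]; }
          yp[i + Ho * j] = bv;
          ip[i + Ho * j] = best;  // 0-based offset within the (H, W) plane
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_backward(NumericVector dy, IntegerVector idx, int H, int W) {
  int Ho, Wo, C, N;
  get_dims4(dy, Ho, Wo, C, N);
  NumericVector dx = make4(H, W, C, N);
  const size_t HW = static_cast<size_t>(H) * W;
  const size_t HWo = static_cast<size_t>(Ho) * Wo;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* dp = dy.begin() + HWo * (c + static_cast<size_t>(C) * n);
      const int* ip = idx.begin() + HWo * (c + static_cast<size_t>(C) * n);
      double* xp = dx.begin() + HW * (c + static_cast<size_t>(C) * n);
      for (size_t q = 0; q < HWo; ++q) xp[ip[q]] += dp[q];
    }
  }
  return dx;
}

// [[Rcpp::export]]
NumericVector upconv2x2_forward(NumericVector x, NumericMatrix U, NumericVector b) {
  int H, W, Ci, N;
  get_dims4(x, H, W, Ci, N);
  if (U.nrow() != Ci || U.ncol() % 4) stop("upconv2x2: bad weight shape");
  const int Co = U.ncol() / 4;
  if (b.size() != Co) stop("upconv2x2: bias length != Co");
  const arma::mat Ua(const_cast<double*>(U.begin()), Ci, 4 * Co, false, true);
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y = make4(Ho, Wo, Co, N);
  const size_t HW = static_cast<size_t>(H) * W;
  const size_t HWo = static_cast<size_t>(Ho) * Wo;
  for (int n = 0; n < N; ++n) {
    const arma::mat X(const_cast<double*>(x.begin()) + HW * Ci * n, HW, Ci, false, true);
    arma::mat cols = X * Ua;  // HW x 4Co
    for (int co = 0; co < Co; ++co) {
      double* yp = y.begin() + HWo * (co + static_cast<size_t>(Co) * n);
      const double bc = b[co];
      for (int kj = 0; kj < 2; ++kj) {
        for (int ki = 0; ki < 2; ++ki) {
          const double* cp = cols.colptr(co * 4 + kj * 2 + ki);
          for (int j = 0; j < W; ++j)
            for (int i = 0; i < H; ++i)
              yp[(2 * i + ki) + static_cast<size_t>(Ho) * (2 * j + kj)] =
                  cp[i + static_cast<size_t>(H) * j] + bc;
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List upconv2x2_backward(NumericVector x, NumericMatrix U, NumericVector dy) {
  int H, W, Ci, N;
  get_dims4(x, H, W, Ci, N);
  int Ho, Wo, Co, N2;
  get_dims4(dy, Ho, Wo, Co, N2);
  if (Ho != 2 * H || Wo != 2 * W || N2 != N || U.nrow() != Ci || U.ncol() != 4 * Co)
    stop("upconv2x2_backward: shape mismatch");
  const arma::mat Ua(const_cast<double*>(U.begin()), Ci, 4 * Co, false, true);
  NumericVector dx = make4(H, W, Ci, N);
  arma::mat dU(Ci, 4 * Co, arma::fill::zeros);
  arma::vec db(Co, arma::fill::zeros);
  const size_t HW = static_cast<size_t>(H) * W;
  const size_t HWo = static_cast<size_t>(Ho) * Wo;
  arma::mat dcols(HW, 4 * Co);
  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Co; ++co) {
      const double* dp = dy.begin() + HWo * (co + static_cast<size_t>(Co) * n);
      double acc = 0.0;
      for (size_t q = 0; q < HWo; ++q) acc += dp[q];
      db[co] += acc;
      for (int kj = 0; kj < 2; ++kj) {
        for (int ki = 0; ki < 2; ++ki) {
          double* cp = dcols.colptr(co * 4 + kj * 2 + ki);
          for (int j = 0; j < W; ++j)
            for (int i = 0; i < H; ++i)
              cp[i + static_cast<size_t>(H) * j] =
                  dp[(2 * i + ki) + static_cast<size_t>(Ho) * (2 * j + kj)];
        }
      }
    }
    const arma::mat X(const_cast<double*>(x.begin()) + HW * Ci * n, HW, Ci, false, true);
    dU += X.t() * dcols;
    arma::mat dX(dx.begin() + HW * Ci * n, HW, Ci, false, true);
    dX = dcols * Ua.t();
  }
  return List::create(_["dx"] = dx, _["dU"] = wrap(dU), _["db"] = NumericVector(db.begin(), db.end()));
}
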