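// Batched convolution and max-pooling kernels for the multi-stream
// staging network. Layout convention throughout: a batch is an arma::cube
// (channels/features, positions, batch); 2D feature maps are stored with
// their H x W grid flattened column-major into the "positions" axis, so the
// same pooling/backprop machinery serves both streams.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// im2col for 1D convolution with zero padding. X: (C, L); out: (C*K, Lout)
static mat im2col1d(const mat& X, int K, int stride, int pad) {
  const int C = X.n_rows, L = X.n_cols;
  const int Lout = (L + 2 * pad - K) / stride + 1;
  mat col(C * K, Lout, fill::zeros);
  for (int j = 0; j < Lout; ++j) {
    int start = j * stride - pad;
    for (int k = 0; k < K; ++k) {
      int t = start + k;
      if (t >= 0 && t < L) col.submat(k * C, j, (k + 1) * C - 1, j) = X.col(t);
    }
  }
  return col;
}

// scatter-add transpose of im2col1d
static void col2im1d(const mat& col, mat& dX, int K, int stride, int pad) {
  const int C = dX.n_rows, L = dX.n_cols, Lout = col.n_cols;
  for (int j = 0; j < Lout; ++j) {
    int start = j * stride - pad;
    for (int k = 0; k < K; ++k) {
      int t = start + k;
      if (t >= 0 && t < L) dX.col(t) += col.submat(k * C, j, (k + 1) * C - 1, j);
    }
  }
}

// [[Rcpp::export(name = ".cpp_conv1d_fwd")]]
arma::cube cpp_conv1d_fwd(const arma::cube& X, const arma::mat& W,
                          const arma::vec& b, int stride) {
  const int K = W.n_cols / X.n_rows;
  const int pad = (K - 1) / 2;
  const int L = X.n_cols;
  const int Lout = (L + 2 * pad - K) / stride + 1;
  cube Y(W.n_rows, Lout, X.n_slices);
  for (uword n = 0; n < X.n_slices; ++n) {
    mat col = im2col1d(X.slice(n), K, stride, pad);
    Y.slice(n) = W * col;
    Y.slice(n).each_col() += b;
  }
  return Y;
}

// [[Rcpp::export(name = ".cpp_conv1d_bwd")]]
Rcpp::List cpp_conv1d_bwd(const arma::cube& X, const arma::mat& W,
                          const arma::cube& dY, int stride) {
  const int K = W.n_cols / X.n_rows;
  const int pad = (K - 1) / 2;
  cube dX(size(X), fill::zeros);
  mat dW(size(W), fill::zeros);
  vec db(W.n_rows, fill::zeros);
  for (uword n = 0; n < X.n_slices; ++n) {
    mat col = im2col1d(X.slice(n), K, stride, pad);
    const mat& g = dY.slice(n);
    dW += g * col.t();
    db += sum(g, 1);
    mat dcol = W.t() * g;
    col2im1d(dcol, dX.slice(n), K, stride, pad);
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX, Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// im2col for same-padded 3x3-style 2D convolution on a (C, H*W) map
static mat im2col2d(const mat& X, int H, int W_, int KH, int KW) {
  const int C = X.n_rows;
  const int ph = (KH - 1) / 2, pw = (KW - 1) / 2;
  mat col(C * KH * KW, H * W_, fill::zeros);
  for (int w = 0; w < W_; ++w) {
    for (int h = 0; h < H; ++h) {
      int out = h + H * w;
      for (int kj = 0; kj < KW; ++kj) {
        int ww = w - pw + kj;
        if (ww < 0 || ww >= W_) continue;
        for (int ki = 0; ki < KH; ++ki) {
          int hh = h - ph + ki;
          if (hh < 0 || hh >= H) continue;
          int r = C * (ki + KH * kj);
          col.submat(r, out, r + C - 1, out) = X.col(hh + H * ww);
        }
      }
    }
  }
  return col;
}

static void col2im2d(const mat& col, mat& dX, int H, int W_, int KH, int KW) {
  const int C = dX.n_rows;
  const int ph = (KH - 1) / 2, pw = (KW - 1) / 2;
  for (int w = 0; w < W_; ++w) {
    for (int h = 0; h < H; ++h) {
      int out = h + H * w;
      for (int kj = 0; kj < KW; ++kj) {
        int ww = w - pw + kj;
        if (ww < 0 || ww >= W_) continue;
        for (int ki = 0; ki < KH; ++ki) {
          int hh = h - ph + ki;
          if (hh < 0 || hh >= H) continue;
          int r = C * (ki + KH * kj);
          dX.col(hh + H * ww) += col.submat(r, out, r + C - 1, out);
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".cpp_conv2d_fwd")]]
arma::cube cpp_conv2d_fwd(const arma::cube& X, const arma::mat& W,
                          const arma::vec& b, int H, int Wd, int KH, int KW) {
  cube Y(W.n_rows, H * Wd, X.n_slices);
  for (uword n = 0; n < X.n_slices; ++n) {
    mat col = im2col2d(X.slice(n), H, Wd, KH, KW);
    Y.slice(n) = W * col;
    Y.slice(n).each_col() += b;
  }
  return Y;
}

// [[Rcpp::export(name = ".cpp_conv2d_bwd")]]
Rcpp::List cpp_conv2d_bwd(const arma::cube& X, const arma::mat& W,
                          const arma::cube& dY, int H, int Wd, int KH, int KW) {
  cube dX(size(X), fill::zeros);
  mat dW(size(W), fill::zeros);
  vec db(W.n_rows, fill::zeros);
  for (uword n = 0; n < X.n_slices; ++n) {
    mat col = im2col2d(X.slice(n), H, Wd, KH, KW);
    const mat& g = dY.slice(n);
    dW += g * col.t();
    db += sum(g, 1);
    mat dcol = W.t() * g;
    col2im2d(dcol, dX.slice(n), H, Wd, KH, KW);
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX, Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// batch normalization over (positions, batch) per feature row
// [[Rcpp::export(name = ".cpp_bn_fwd")]]
Rcpp::List cpp_bn_fwd(const arma::cube& X, const arma::vec& gamma,
                      const arma::vec& beta, const arma::vec& rmean,
                      const arma::vec& rvar, bool training,
                      double momentum, double eps) {
  const int F = X.n_rows;
  const double M = double(X.n_cols) * X.n_slices;
  vec m(F), v(F);
  if (training) {
    m.zeros(); v.zeros();
    for (uword n = 0; n < X.n_slices; ++n) {
      m += sum(X.slice(n), 1);
      v += sum(square(X.slice(n)), 1);
    }
    m /= M;
    v = v / M - square(m);
  } else { m = rmean; v = rvar; }
  vec inv = 1.0 / sqrt(v + eps);
  cube xhat(size(X)), y(size(X));
  for (uword n = 0; n < X.n_slices; ++n) {
    xhat.slice(n) = X.slice(n);
    xhat.slice(n).each_col() -= m;
    xhat.slice(n).each_col() %= inv;
    y.slice(n) = xhat.slice(n);
    y.slice(n).each_col() %= gamma;
    y.slice(n).each_col() += beta;
  }
  vec nmean = rmean, nvar = rvar;
  if (training) {
    nmean = (1 - momentum) * rmean + momentum * m;
    nvar = (1 - momentum) * rvar + momentum * v;
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("xhat") = xhat,
                            Rcpp::Named("inv") = inv,
                            Rcpp::Named("new_mean") = nmean,
                            Rcpp::Named("new_var") = nvar);
}

// [[Rcpp::export(name = ".cpp_bn_bwd")]]
Rcpp::List cpp_bn_bwd(const arma::cube& dY, const arma::cube& xhat,
                      const arma::vec& inv, const arma::vec& gamma,
                      bool batch_stats) {
  const int F = dY.n_rows;
  const double M = double(dY.n_cols) * dY.n_slices;
  vec dgamma(F, fill::zeros), dbeta(F, fill::zeros);
  for (uword n = 0; n < dY.n_slices; ++n) {
    dgamma += sum(dY.slice(n) % xhat.slice(n), 1);
    dbeta += sum(dY.slice(n), 1);
  }
  cube dX(size(dY));
  vec gi = gamma % inv;
  if (batch_stats) {
    vec a = dgamma / M, b = dbeta / M;
    for (uword n = 0; n < dY.n_slices; ++n) {
      dX.slice(n) = dY.slice(n);
      dX.slice(n).each_col() -= b;
      dX.slice(n) -= xhat.slice(n).each_col() % a;
      dX.slice(n).each_col() %= gi;
    }
  } else {
    for (uword n = 0; n < dY.n_slices; ++n) {
      dX.slice(n) = dY.slice(n);
      dX.slice(n).each_col() %= gi;
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dX,
                            Rcpp::Named("dgamma") = dgamma,
                            Rcpp::Named("dbeta") = dbeta);
}

// [[Rcpp::export(name = ".cpp_relu_fwd")]]
arma::cube cpp_relu_fwd(const arma::cube& X) {
  cube Y = X;
  Y.transform([](double x) { return x > 0 ? x : 0.0; });
  return Y;
}

// [[Rcpp::export(name = ".cpp_relu_bwd")]]
arma::cube cpp_relu_bwd(const arma::cube& dY, const arma::cube& Y) {
  cube dX = dY;
  for (uword i = 0; i < Y.n_elem; ++i) if (Y(i) <= 0) dX(i) = 0;
  return dX;
}

// non-overlapping 1D max pooling; trailing remainder positions dropped
// [[Rcpp::export(name = ".cpp_maxpool1d_fwd")]]
Rcpp::List cpp_maxpool1d_fwd(const arma::cube& X, int p) {
  const int F = X.n_rows, L = X.n_cols, N = X.n_slices;
  const int Lout = L / p;
  cube Y(F, Lout, N);
  icube idx(F, Lout, N);  // 0-based position of the max within the input axis
  for (int n = 0; n < N; ++n) {
    for (int j = 0; j < Lout; ++j) {
      for (int f = 0; f < F; ++f) {
        int best = j * p;
        double bv = X(f, best, n);
        for (int t = j * p + 1; t < (j + 1) * p; ++t)
          if (X(f, t, n) > bv) { bv = X(f, t, n); best = t; }
        Y(f, j, n) = bv;
        idx(f, j, n) = best;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("Y") = Y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export(name = ".cpp_maxpool1d_bwd")]]
arma::cube cpp_maxpool1d_bwd(const arma::icube& idx, const arma::cube& dY, int L) {
  const int F = dY.n_rows, Lout = dY.n_cols, N = dY.n_slices;
  cube dX(F, L, N, fill::zeros);
  for (int n = 0; n < N; ++n)
    for (int j = 0; j < Lout; ++j)
      for (int f = 0; f < F; ++f)
        dX(f, idx(f, j, n), n) += dY(f, j, n);
  return dX;
}

// p x p max pooling on a flattened H x W grid
// [[Rcpp::export(name = ".cpp_maxpool2d_fwd")]]
Rcpp::List cpp_maxpool2d_fwd(const arma::cube& X, int H, int Wd, int p) {
  const int F = X.n_rows, N = X.n_slices;
  const int Ho = H / p, Wo = Wd / p;
  cube Y(F, Ho * Wo, N);
  icube idx(F, Ho * Wo, N);
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        int out = ho + Ho * wo;
        for (int f = 0; f < F; ++f) {
          int best = -1; double bv = -datum::inf;
          for (int dw = 0; dw < p; ++dw) {
            for (int dh = 0; dh < p; ++dh) {
              int pos = (ho * p + dh) + H * (wo * p + dw);
              if (X(f, pos, n) > bv) { bv = X(f, pos, n); best = pos; }
            }
          }
          Y(f, out, n) = bv;
          idx(f, out, n) = best;
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("Y") = Y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export(name = ".cpp_maxpool2d_bwd")]]
arma::cube cpp_maxpool2d_bwd(const arma::icube& idx, const arma::cube& dY, int P) {
  const int F = dY.n_rows, Lout = dY.n_cols, N = dY.n_slices;
  cube dX(F, P, N, fill::zeros);
  for (int n = 0; n < N; ++n)
    for (int j = 0; j < Lout; ++j)
      for (int f = 0; f < F; ++f)
        dX(f, idx(f, j, n), n) += dY(f, j, n);
  return dX;
}
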