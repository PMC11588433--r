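// Compiled core of the portrait CNN: one full-batch forward/backward step
// (im2col convolutions via BLAS, max pooling with first-wins ties) and the
// inference pass. Layout conventions match the R wrappers: sample index
// varies fastest everywhere; patch columns are ordered (row offset, col
// offset, channel); conv outputs are (n * positions) x filters with
// positions column-major over the output grid.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

// A: n x (H*W*C) with column index i + j*H + c*H*W
mat im2col(const mat& A, int n, int H, int W, int C, int kh, int kw) {
  const int OH = H - kh + 1, OW = W - kw + 1, npos = OH * OW;
  mat P(static_cast<uword>(n) * npos, static_cast<uword>(kh) * kw * C);
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        const int k = di + dj * kh + c * kh * kw;
        double* dst = P.colptr(k);
        for (int j = 0; j < OW; ++j) {
          for (int i = 0; i < OH; ++i) {
            const int p = i + j * OH;
            const int src = (i + di) + (j + dj) * H + c * H * W;
            std::memcpy(dst + static_cast<size_t>(p) * n, A.colptr(src),
                        sizeof(double) * n);
          }
        }
      }
    }
  }
  return P;
}

mat col2im(const mat& dP, int n, int H, int W, int C, int kh, int kw) {
  const int OH = H - kh + 1, OW = W - kw + 1;
  mat dA(n, static_cast<uword>(H) * W * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        const int k = di + dj * kh + c * kh * kw;
        const double* srcp = dP.colptr(k);
        for (int j = 0; j < OW; ++j) {
          for (int i = 0; i < OH; ++i) {
            const int p = i + j * OH;
            double* dst = dA.colptr((i + di) + (j + dj) * H + c * H * W);
            const double* sp = srcp + static_cast<size_t>(p) * n;
            for (int s = 0; s < n; ++s) dst[s] += sp[s];
          }
        }
      }
    }
  }
  return dA;
}

inline mat relu(const mat& z) { return z % (z > zeros(size(z))); }

struct Cache {
  mat P1, Z1, P2, Z2, M, Z3, A3;
  umat pool_row;   // per pooled cell: source row in the (n*npos2) layout
  vec p;
};

Cache forward(const mat& W1, const vec& b1, const mat& W2, const vec& b2,
              const mat& W3, const vec& b3, const mat& W4, double b4,
              const mat& Xmat, int n, int H, int W,
              int kh1, int kw1, int kh2, int kw2, int ph_w, int pw_w) {
  Cache c;
  const int H1 = H - kh1 + 1, W1d = W - kw1 + 1;
  const int F1 = W1.n_cols;
  c.P1 = im2col(Xmat, n, H, W, 1, kh1, kw1);
  c.Z1 = c.P1 * W1;
  c.Z1.each_row() += b1.t();
  mat A1 = relu(c.Z1);                       // (n*npos1) x F1
  // reinterpret as n x (H1*W1d*F1): same memory order
  mat A1m(A1.memptr(), n, static_cast<uword>(H1) * W1d * F1, false, true);
  c.P2 = im2col(A1m, n, H1, W1d, F1, kh2, kw2);
  c.Z2 = c.P2 * W2;
  c.Z2.each_row() += b2.t();
  mat A2 = relu(c.Z2);                       // (n*npos2) x F2
  const int H2 = H1 - kh2 + 1, W2d = W1d - kw2 + 1;
  const int F2 = W2.n_cols;
  const int ph = (H2 >= ph_w) ? H2 / ph_w : 1;
  const int pw = (W2d >= pw_w) ? W2d / pw_w : 1;
  c.M.set_size(n, static_cast<uword>(ph) * pw * F2);
  c.pool_row.set_size(n, static_cast<uword>(ph) * pw * F2);
  for (int f = 0; f < F2; ++f) {
    for (int pj = 0; pj < pw; ++pj) {
      for (int pi = 0; pi < ph; ++pi) {
        const int out_col = pi + pj * ph + f * ph * pw;
        for (int s = 0; s < n; ++s) {
          double best = -datum::inf;
          uword best_row = 0;
          for (int b_ = 0; b_ < pw_w; ++b_) {        // ties: first offset wins,
            for (int a_ = 0; a_ < ph_w; ++a_) {      // row offset fastest
              const int i = pi * ph_w + a_;
              const int j = pj * pw_w + b_;
              if (i >= H2 || j >= W2d) continue;
              const uword row = s + static_cast<uword>(i + j * H2) * n;
              const double v = A2(row, f);
              if (v > best) { best = v; best_row = row; }
            }
          }
          c.M(s, out_col) = best;
          c.pool_row(s, out_col) = best_row;
        }
      }
    }
  }
  c.Z3 = c.M * W3;
  c.Z3.each_row() += b3.t();
  c.A3 = relu(c.Z3);
  vec z4 = c.A3 * W4 + b4;
  c.p = 1.0 / (1.0 + exp(-z4));
  return c;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List cnn_infer_cpp(const arma::mat& W1, const arma::vec& b1,
                         const arma::mat& W2, const arma::vec& b2,
                         const arma::mat& W3, const arma::vec& b3,
                         const arma::mat& W4, double b4,
                         const arma::mat& Xmat, int n, int H, int W,
                         int kh1, int kw1, int kh2, int kw2,
                         int ph_w, int pw_w) {
  Cache c = forward(W1, b1, W2, b2, W3, b3, W4, b4, Xmat, n, H, W,
                    kh1, kw1, kh2, kw2, ph_w, pw_w);
  return Rcpp::List::create(Rcpp::Named("p") = c.p);
}

// [[Rcpp::export]]
Rcpp::List cnn_step_cpp(const arma::mat& W1, const arma::vec& b1,
                        const arma::mat& W2, const arma::vec& b2,
                        const arma::mat& W3, const arma::vec& b3,
                        const arma::mat& W4, double b4,
                        const arma::mat& Xmat, const arma::vec& y,
                        int n, int H, int W,
                        int kh1, int kw1, int kh2, int kw2,
                        int ph_w, int pw_w) {
  Cache c = forward(W1, b1, W2, b2, W3, b3, W4, b4, Xmat, n, H, W,
                    kh1, kw1, kh2, kw2, ph_w, pw_w);
  const int H1 = H - kh1 + 1, W1d = W - kw1 + 1;
  const int H2 = H1 - kh2 + 1, W2d = W1d - kw2 + 1;
  const int F1 = W1.n_cols, F2 = W2.n_cols;

  vec dz4 = (c.p - y) / n;
  mat dW4 = c.A3.t() * dz4;
  double db4 = accu(dz4);
  mat dz3 = (dz4 * W4.t()) % (c.Z3 > zeros(size(c.Z3)));
  mat dW3 = c.M.t() * dz3;
  vec db3 = sum(dz3, 0).t();
  mat dM = dz3 * W3.t();

  mat dA2(static_cast<uword>(n) * H2 * W2d, F2, fill::zeros);
  for (uword col = 0; col < c.pool_row.n_cols; ++col) {
    const int f = col / (c.pool_row.n_cols / F2);
    for (int s = 0; s < n; ++s) {
      dA2(c.pool_row(s, col), f) += dM(s, col);
    }
  }
  mat dz2 = dA2 % (c.Z2 > zeros(size(c.Z2)));
  mat dW2 = c.P2.t() * dz2;
  vec db2 = sum(dz2, 0).t();
  mat dP2 = dz2 * W2.t();
  mat dA1m = col2im(dP2, n, H1, W1d, F1, kh2, kw2);    // n x (H1*W1d*F1)
  mat dz1(dA1m.memptr(), static_cast<uword>(n) * H1 * W1d, F1, false, true);
  mat dz1m = dz1 % (c.Z1 > zeros(size(c.Z1)));
  mat dW1 = c.P1.t() * dz1m;
  vec db1 = sum(dz1m, 0).t();

  return Rcpp::List::create(
    Rcpp::Named("p") = c.p,
    Rcpp::Named("W1") = dW1, Rcpp::Named("b1") = db1,
    Rcpp::Named("W2") = dW2, Rcpp::Named("b2") = db2,
    Rcpp::Named("W3") = dW3, Rcpp::Named("b3") = db3,
    Rcpp::Named("W4") = dW4, Rcpp::Named("b4") = db4);
}
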