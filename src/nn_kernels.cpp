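// Hot loops of the conv-GRU sleep stager: dilated 1-D convolution,
// non-overlapping max pooling and GRU recursion, forward and backward.
// Layouts: signals are (channels x time) matrices; conv kernels are
// (C_out x C_in x k) cubes with zero ("same") padding and centred taps;
// GRU gate weights are stacked (3H x I) / (3H x H) in z, r, n order.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
arma::mat cpp_conv1d_fwd(const arma::mat& X, const arma::cube& W,
                         const arma::vec& b, int dil) {
  const int L = X.n_cols, k = W.n_slices, c = (k - 1) / 2;
  arma::mat Y(W.n_rows, L);
  Y.each_col() = b;
  for (int j = 0; j < k; ++j) {
    int s = (j - c) * dil;                     // Y[, t] += W_j X[, t + s]
    int t0 = std::max(0, -s), t1 = std::min(L - 1, L - 1 - s);
    if (t0 > t1) continue;
    Y.cols(t0, t1) += W.slice(j) * X.cols(t0 + s, t1 + s);
  }
  return Y;
}

// [[Rcpp::export]]
List cpp_conv1d_bwd(const arma::mat& X, const arma::cube& W,
                    const arma::mat& dY, int dil) {
  const int L = X.n_cols, k = W.n_slices, c = (k - 1) / 2;
  arma::mat dX(X.n_rows, L, arma::fill::zeros);
  arma::cube dW(W.n_rows, W.n_cols, k, arma::fill::zeros);
  arma::vec db = arma::sum(dY, 1);
  for (int j = 0; j < k; ++j) {
    int s = (j - c) * dil;
    int t0 = std::max(0, -s), t1 = std::min(L - 1, L - 1 - s);
    if (t0 > t1) continue;
    dW.slice(j) = dY.cols(t0, t1) * X.cols(t0 + s, t1 + s).t();
    dX.cols(t0 + s, t1 + s) += W.slice(j).t() * dY.cols(t0, t1);
  }
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export]]
List cpp_maxpool_fwd(const arma::mat& X, int p) {
  const int C = X.n_rows, Lo = X.n_cols / p;
  arma::mat Y(C, Lo);
  arma::umat idx(C, Lo);
  for (int t = 0; t < Lo; ++t) {
    for (int ch = 0; ch < C; ++ch) {
      int best = t * p;
      double bv = X(ch, best);
      for (int j = 1; j < p; ++j)
        if (X(ch, t * p + j) > bv) { bv = X(ch, t * p + j); best = t * p + j; }
      Y(ch, t) = bv;
      idx(ch, t) = best;
    }
  }
  return List::create(_["Y"] = Y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::mat cpp_maxpool_bwd(const arma::mat& dY, const arma::umat& idx, int L) {
  arma::mat dX(dY.n_rows, L, arma::fill::zeros);
  for (unsigned t = 0; t < dY.n_cols; ++t)
    for (unsigned ch = 0; ch < dY.n_rows; ++ch)
      dX(ch, idx(ch, t)) += dY(ch, t);
  return dX;
}

static inline arma::vec sigm(const arma::vec& x) { return 1.0 / (1.0 + arma::exp(-x)); }

// [[Rcpp::export]]
List cpp_gru_fwd(const arma::mat& X, const arma::mat& W, const arma::mat& U,
                 const arma::vec& b, bool reverse) {
  const int T = X.n_cols, H = U.n_cols;
  arma::mat Hs(H, T), Z(H, T), R(H, T), N(H, T);
  arma::vec h(H, arma::fill::zeros);
  for (int step = 0; step < T; ++step) {
    int t = reverse ? T - 1 - step : step;
    arma::vec gx = W * X.col(t) + b;
    arma::vec gz = sigm(gx.rows(0, H - 1) + U.rows(0, H - 1) * h);
    arma::vec gr = sigm(gx.rows(H, 2 * H - 1) + U.rows(H, 2 * H - 1) * h);
    arma::vec gn = arma::tanh(gx.rows(2 * H, 3 * H - 1) +
                              U.rows(2 * H, 3 * H - 1) * (gr % h));
    h = (1.0 - gz) % gn + gz % h;
    Hs.col(t) = h; Z.col(t) = gz; R.col(t) = gr; N.col(t) = gn;
  }
  return List::create(_["H"] = Hs, _["Z"] = Z, _["R"] = R, _["N"] = N);
}

// [[Rcpp::export]]
List cpp_gru_bwd(const arma::mat& X, const arma::mat& W, const arma::mat& U,
                 const arma::mat& Hs, const arma::mat& Z, const arma::mat& R,
                 const arma::mat& N, const arma::mat& dH, bool reverse) {
  const int T = X.n_cols, H = U.n_cols;
  arma::mat Uz = U.rows(0, H - 1), Ur = U.rows(H, 2 * H - 1),
            Un = U.rows(2 * H, 3 * H - 1);
  arma::mat Wz = W.rows(0, H - 1), Wr = W.rows(H, 2 * H - 1),
            Wn = W.rows(2 * H, 3 * H - 1);
  arma::mat dX(X.n_rows, T, arma::fill::zeros), dW(3 * H, X.n_rows, arma::fill::zeros),
            dU(3 * H, H, arma::fill::zeros);
  arma::vec db(3 * H, arma::fill::zeros), carry(H, arma::fill::zeros);
  for (int step = T - 1; step >= 0; --step) {
    int t = reverse ? T - 1 - step : step;
    int tp = reverse ? t + 1 : t - 1;          // previous step in process order
    arma::vec h_prev = (step == 0) ? arma::vec(H, arma::fill::zeros)
                                   : arma::vec(Hs.col(tp));
    arma::vec z = Z.col(t), r = R.col(t), n = N.col(t);
    arma::vec dh = dH.col(t) + carry;
    arma::vec da_n = dh % (1.0 - z) % (1.0 - n % n);
    arma::vec da_z = dh % (h_prev - n) % z % (1.0 - z);
    arma::vec Unda = Un.t() * da_n;
    arma::vec da_r = Unda % h_prev % r % (1.0 - r);
    carry = dh % z + Uz.t() * da_z + Ur.t() * da_r + Unda % r;
    dW.rows(0, H - 1) += da_z * X.col(t).t();
    dW.rows(H, 2 * H - 1) += da_r * X.col(t).t();
    dW.rows(2 * H, 3 * H - 1) += da_n * X.col(t).t();
    dU.rows(0, H - 1) += da_z * h_prev.t();
    dU.rows(H, 2 * H - 1) += da_r * h_prev.t();
    dU.rows(2 * H, 3 * H - 1) += da_n * (r % h_prev).t();
    db.rows(0, H - 1) += da_z;
    db.rows(H, 2 * H - 1) += da_r;
    db.rows(2 * H, 3 * H - 1) += da_n;
    dX.col(t) = Wz.t() * da_z + Wr.t() * da_r + Wn.t() * da_n;
  }
  return List::create(_["dX"] = dX, _["dW"] = dW, _["dU"] = dU, _["db"] = db);
}

static const double SELU_L = 1.0507009873554805;
static const double SELU_A = 1.6732632423543772;

// [[Rcpp::export]]
arma::mat cpp_selu(const arma::mat& X) {
  arma::mat Y(X.n_rows, X.n_cols);
  const double* x = X.memptr(); double* y = Y.memptr();
  for (arma::uword i = 0; i < X.n_elem; ++i)
    y[i] = x[i] > 0 ? SELU_L * x[i] : SELU_L * SELU_A * (std::exp(x[i]) - 1.0);
  return Y;
}

// dY % selu'(pre), fused to avoid temporaries
// [[Rcpp::export]]
arma::mat cpp_selu_grad_mul(const arma::mat& Pre, const arma::mat& dY) {
  arma::mat Y(Pre.n_rows, Pre.n_cols);
  const double* p = Pre.memptr(); const double* d = dY.memptr();
  double* y = Y.memptr();
  for (arma::uword i = 0; i < Pre.n_elem; ++i)
    y[i] = d[i] * (p[i] > 0 ? SELU_L : SELU_L * SELU_A * std::exp(p[i]));
  return Y;
}
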