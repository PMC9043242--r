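// Batched LSTM sequence scan and backpropagation-through-time.
// Gate layout within the stacked weight matrix W (4h x (h+n)) and bias b:
// rows [f; i; c~; o]. The cell consumes [h_prev; x_t] in that order.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigm(const mat& z) { return 1.0 / (1.0 + exp(-z)); }

// [[Rcpp::export]]
Rcpp::List cpp_lstm_scan(const arma::mat& W, const arma::vec& b,
                         const arma::cube& X, bool reverse,
                         bool want_cache) {
  const uword h = W.n_rows / 4;
  const uword n = W.n_cols - h;
  const uword B = X.n_cols, T = X.n_slices;
  if (X.n_rows != n) Rcpp::stop("input row count does not match the cell");

  mat Wh = W.cols(0, h - 1);
  mat Wx = W.cols(h, h + n - 1);
  const mat Xm(const_cast<double*>(X.memptr()), n, B * T, false, true);
  mat Zx = Wx * Xm;
  Zx.each_col() += b;

  cube H(h, B, T, fill::zeros), C(h, B, T, fill::zeros);
  cube G;
  if (want_cache) G.set_size(4 * h, B, T);

  mat h_prev(h, B, fill::zeros), c_prev(h, B, fill::zeros);
  for (uword j = 0; j < T; ++j) {
    const uword t = reverse ? (T - 1 - j) : j;
    mat Z = Wh * h_prev + Zx.cols(t * B, t * B + B - 1);
    mat f = sigm(Z.rows(0, h - 1));
    mat i = sigm(Z.rows(h, 2 * h - 1));
    mat g = tanh(Z.rows(2 * h, 3 * h - 1));
    mat o = sigm(Z.rows(3 * h, 4 * h - 1));
    mat c_new = f % c_prev + i % g;
    mat h_new = o % tanh(c_new);
    H.slice(t) = h_new;
    C.slice(t) = c_new;
    if (want_cache) {
      G.slice(t).rows(0, h - 1) = f;
      G.slice(t).rows(h, 2 * h - 1) = i;
      G.slice(t).rows(2 * h, 3 * h - 1) = g;
      G.slice(t).rows(3 * h, 4 * h - 1) = o;
    }
    h_prev = std::move(h_new);
    c_prev = std::move(c_new);
  }
  return Rcpp::List::create(Rcpp::Named("H") = H, Rcpp::Named("C") = C,
                            Rcpp::Named("gates") = G,
                            Rcpp::Named("reverse") = reverse);
}

// [[Rcpp::export]]
Rcpp::List cpp_lstm_backprop(const arma::mat& W, const arma::cube& X,
                             const arma::cube& H, const arma::cube& C,
                             const arma::cube& G, const arma::cube& dHext,
                             bool reverse) {
  const uword h = W.n_rows / 4;
  const uword n = W.n_cols - h;
  const uword B = X.n_cols, T = X.n_slices;

  mat Wh = W.cols(0, h - 1);
  cube dZ_all(4 * h, B, T);
  mat dh(h, B, fill::zeros), dc(h, B, fill::zeros);

  for (uword jj = 0; jj < T; ++jj) {
    const uword j = T - 1 - jj;                    // reverse of scan order
    const uword t = reverse ? (T - 1 - j) : j;
    const mat f = G.slice(t).rows(0, h - 1);
    const mat i = G.slice(t).rows(h, 2 * h - 1);
    const mat g = G.slice(t).rows(2 * h, 3 * h - 1);
    const mat o = G.slice(t).rows(3 * h, 4 * h - 1);
    mat tc = tanh(C.slice(t));
    mat dht = dh + dHext.slice(t);
    mat do_ = dht % tc;
    mat dct = dc + dht % o % (1.0 - tc % tc);
    mat c_prev(h, B, fill::zeros);
    if (j > 0) {
      const uword t_prev = reverse ? (T - j) : (j - 1);
      c_prev = C.slice(t_prev);
    }
    mat dZ(4 * h, B);
    dZ.rows(0, h - 1)         = (dct % c_prev) % f % (1.0 - f);
    dZ.rows(h, 2 * h - 1)     = (dct % g) % i % (1.0 - i);
    dZ.rows(2 * h, 3 * h - 1) = (dct % i) % (1.0 - g % g);
    dZ.rows(3 * h, 4 * h - 1) = do_ % o % (1.0 - o);
    dc = dct % f;
    dZ_all.slice(t) = dZ;
    dh = Wh.t() * dZ;
  }

  // inputs aligned with each scan step: [h_prev ; x_t]
  cube Hprev(h, B, T, fill::zeros);
  for (uword j = 1; j < T; ++j) {
    if (reverse) Hprev.slice(T - 1 - j) = H.slice(T - j);
    else Hprev.slice(j) = H.slice(j - 1);
  }
  mat dZm(dZ_all.memptr(), 4 * h, B * T, false, true);
  mat M = join_cols(mat(Hprev.memptr(), h, B * T, false, true),
                    mat(const_cast<double*>(X.memptr()), n, B * T, false, true));
  mat dW = dZm * M.t();
  vec db = sum(dZm, 1);
  return Rcpp::List::create(Rcpp::Named("dW") = dW, Rcpp::Named("db") = db);
}
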