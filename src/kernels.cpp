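// Numeric kernels: causal IIR filtering with explicit initial state and the
// per-timestep recursions of the LSTM forward/backward passes. Everything
// else (layer stacking, dropout, dense layers, Adam) lives in R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Direct-form-II-transposed IIR filter. b, a are coefficient vectors with
// a[0] == 1; zi is the initial state (length max(len(a), len(b)) - 1),
// typically lfilter steady-state conditions scaled by the first sample.
// [[Rcpp::export(name = ".iir_filter_cpp")]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a,
                             NumericVector x, NumericVector zi) {
  int nb = b.size(), na = a.size();
  int n = std::max(nb, na);
  std::vector<double> bb(n, 0.0), aa(n, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  std::vector<double> z(n - 1, 0.0);
  for (int i = 0; i < (int)z.size() && i < zi.size(); ++i) z[i] = zi[i];
  int T = x.size();
  NumericVector y(T);
  for (int t = 0; t < T; ++t) {
    double xt = x[t];
    double yt = bb[0] * xt + z[0];
    for (int k = 0; k < n - 2; ++k) {
      z[k] = bb[k + 1] * xt + z[k + 1] - aa[k + 1] * yt;
    }
    z[n - 2] = bb[n - 1] * xt - aa[n - 1] * yt;
    y[t] = yt;
  }
  return y;
}

// LSTM forward pass over one sequence. `reverse` runs the recursion from the
// last timestep to the first (the backward direction of a bidirectional
// layer); caches are stored at their original time indices either way.
// Gate order in the 4U-wide weight blocks: input, forget, cell, output.
// X: T x D, W: D x 4U, R: U x 4U, b: 4U.
// [[Rcpp::export(name = ".lstm_forward_cpp")]]
List lstm_forward_cpp(const arma::mat& X, const arma::mat& W,
                      const arma::mat& R, const arma::rowvec& b,
                      bool reverse) {
  int T = X.n_rows;
  int U = R.n_rows;
  arma::mat H(T, U), I(T, U), F(T, U), G(T, U), O(T, U), C(T, U), TC(T, U);
  arma::rowvec h(U, arma::fill::zeros), c(U, arma::fill::zeros);
  arma::mat XW = X * W; // input contributions in one GEMM
  for (int k = 0; k < T; ++k) {
    int t = reverse ? (T - 1 - k) : k;
    arma::rowvec a = XW.row(t) + h * R + b;
    arma::rowvec gi = 1.0 / (1.0 + arma::exp(-a.cols(0, U - 1)));
    arma::rowvec gf = 1.0 / (1.0 + arma::exp(-a.cols(U, 2 * U - 1)));
    arma::rowvec gg = arma::tanh(a.cols(2 * U, 3 * U - 1));
    arma::rowvec go = 1.0 / (1.0 + arma::exp(-a.cols(3 * U, 4 * U - 1)));
    c = gf % c + gi % gg;
    arma::rowvec tc = arma::tanh(c);
    h = go % tc;
    I.row(t) = gi; F.row(t) = gf; G.row(t) = gg; O.row(t) = go;
    C.row(t) = c; TC.row(t) = tc; H.row(t) = h;
  }
  return List::create(_["H"] = H, _["I"] = I, _["F"] = F, _["G"] = G,
                      _["O"] = O, _["C"] = C, _["TC"] = TC);
}

// Backpropagation through time for one sequence (matching forward caches and
// direction). The recurrent part accumulates per-timestep gate deltas into
// dA; the weight gradients then come from three GEMMs.
// dH: T x U gradient of the loss w.r.t. the layer output.
// [[Rcpp::export(name = ".lstm_backward_cpp")]]
List lstm_backward_cpp(const arma::mat& X, const arma::mat& W,
                       const arma::mat& R, const arma::mat& I,
                       const arma::mat& F, const arma::mat& G,
                       const arma::mat& O, const arma::mat& C,
                       const arma::mat& TC, const arma::mat& dH,
                       bool reverse) {
  int T = X.n_rows;
  int U = R.n_rows;
  arma::mat dA(T, 4 * U);
  arma::mat Rt = R.t();
  arma::rowvec dh_next(U, arma::fill::zeros), dc_next(U, arma::fill::zeros);
  arma::rowvec cprev(U), da(4 * U);
  for (int k = T - 1; k >= 0; --k) {
    int t = reverse ? (T - 1 - k) : k;
    int tprev = -1;
    if (k > 0) tprev = reverse ? (T - k) : (k - 1);
    arma::rowvec dh = dH.row(t) + dh_next;
    arma::rowvec tc = TC.row(t);
    arma::rowvec go = O.row(t);
    arma::rowvec dov = dh % tc;
    arma::rowvec dc = dc_next + dh % go % (1.0 - tc % tc);
    arma::rowvec gi = I.row(t), gf = F.row(t), gg = G.row(t);
    if (tprev >= 0) cprev = C.row(tprev); else cprev.zeros();
    arma::rowvec di = dc % gg;
    arma::rowvec dg = dc % gi;
    arma::rowvec df = dc % cprev;
    dc_next = dc % gf;
    da.cols(0, U - 1)         = di % gi % (1.0 - gi);
    da.cols(U, 2 * U - 1)     = df % gf % (1.0 - gf);
    da.cols(2 * U, 3 * U - 1) = dg % (1.0 - gg % gg);
    da.cols(3 * U, 4 * U - 1) = dov % go % (1.0 - go);
    dA.row(t) = da;
    dh_next = da * Rt;
  }
  // h_{t-1} per original index, shifted along the recursion direction
  arma::mat Hprev(T, U, arma::fill::zeros);
  arma::mat H = O % TC;
  if (T > 1) {
    if (reverse) {
      Hprev.rows(0, T - 2) = H.rows(1, T - 1);
    } else {
      Hprev.rows(1, T - 1) = H.rows(0, T - 2);
    }
  }
  arma::mat dW = X.t() * dA;
  arma::mat dR = Hprev.t() * dA;
  arma::rowvec db = arma::sum(dA, 0);
  arma::mat dX = dA * W.t();
  return List::create(_["dX"] = dX, _["dW"] = dW, _["dR"] = dR,
                      _["db"] = db);
}
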