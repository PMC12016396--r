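// Batched LSTM forward / backward-through-time kernels.
//
// Layout: X is a B x In x L cube (batch, input, time); gate weights are
// packed as W ((H+In) x 4H) with column blocks [f | i | g | o] acting on
// z_t = [h_{t-1}, x_t]; states freeze once t exceeds a sequence's length,
// so padded timesteps can never influence an output. The semantics are
// defined by the per-timestep R reference (lstm_cell_step / run_lstm);
// these kernels only buy speed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// [[Rcpp::export(name = ".lstm_forward_cpp")]]
Rcpp::List lstm_forward_cpp(const arma::cube& X, const arma::ivec& lens,
                            const arma::mat& W, const arma::rowvec& b) {
  const uword B = X.n_rows, In = X.n_cols, L = X.n_slices;
  const uword H = W.n_cols / 4;
  if (W.n_rows != H + In) Rcpp::stop("weight/input shape mismatch");
  cube Hs(B, H, L + 1, fill::zeros), Cs(B, H, L + 1, fill::zeros);
  cube Fg(B, H, L), Ig(B, H, L), Gg(B, H, L), Og(B, H, L);
  mat h(B, H, fill::zeros), C(B, H, fill::zeros);
  for (uword t = 0; t < L; ++t) {
    mat z = join_rows(h, X.slice(t));
    mat a = z * W;
    a.each_row() += b;
    mat f = sigm(a.cols(0, H - 1));
    mat i = sigm(a.cols(H, 2 * H - 1));
    mat g = tanh(a.cols(2 * H, 3 * H - 1));
    mat o = sigm(a.cols(3 * H, 4 * H - 1));
    mat C_new = f % C + i % g;
    mat h_new = o % tanh(C_new);
    for (uword r = 0; r < B; ++r) {
      if ((sword)(t + 1) <= lens(r)) {      // active row: take the update
        C.row(r) = C_new.row(r);
        h.row(r) = h_new.row(r);
      }                                      // else freeze previous state
    }
    Hs.slice(t + 1) = h;
    Cs.slice(t + 1) = C;
    Fg.slice(t) = f; Ig.slice(t) = i; Gg.slice(t) = g; Og.slice(t) = o;
  }
  return Rcpp::List::create(
      Rcpp::Named("H") = Hs, Rcpp::Named("C") = Cs,
      Rcpp::Named("f") = Fg, Rcpp::Named("i") = Ig,
      Rcpp::Named("g") = Gg, Rcpp::Named("o") = Og);
}

// [[Rcpp::export(name = ".lstm_backward_cpp")]]
Rcpp::List lstm_backward_cpp(const arma::cube& X, const arma::ivec& lens,
                             const arma::mat& W,
                             const arma::cube& Hs, const arma::cube& Cs,
                             const arma::cube& Fg, const arma::cube& Ig,
                             const arma::cube& Gg, const arma::cube& Og,
                             const arma::cube& dHout) {
  const uword B = X.n_rows, In = X.n_cols, L = X.n_slices;
  const uword H = W.n_cols / 4;
  mat dW(H + In, 4 * H, fill::zeros);
  rowvec db(4 * H, fill::zeros);
  cube dX(B, In, L, fill::zeros);
  mat dh_next(B, H, fill::zeros), dC_next(B, H, fill::zeros);
  for (sword t = L - 1; t >= 0; --t) {
    mat dh = dh_next + dHout.slice(t);
    vec m(B);
    for (uword r = 0; r < B; ++r) m(r) = (sword)(t + 1) <= lens(r) ? 1.0 : 0.0;
    mat dh_new = dh.each_col() % m;
    mat dh_pass = dh - dh_new;
    mat dC_new = dC_next.each_col() % m;
    mat dC_pass = dC_next - dC_new;
    const mat& f = Fg.slice(t); const mat& i = Ig.slice(t);
    const mat& g = Gg.slice(t); const mat& o = Og.slice(t);
    mat tC = tanh(Cs.slice(t + 1));          // == tanh(C_new) on active rows
    mat d_o = dh_new % tC;
    dC_new += dh_new % o % (1.0 - tC % tC);
    mat df = dC_new % Cs.slice(t);
    mat di = dC_new % g;
    mat dg = dC_new % i;
    mat dC_prev = dC_new % f + dC_pass;
    mat dA(B, 4 * H);
    dA.cols(0, H - 1) = df % f % (1.0 - f);
    dA.cols(H, 2 * H - 1) = di % i % (1.0 - i);
    dA.cols(2 * H, 3 * H - 1) = dg % (1.0 - g % g);
    dA.cols(3 * H, 4 * H - 1) = d_o % o % (1.0 - o);
    mat z = join_rows(Hs.slice(t), X.slice(t));
    dW += z.t() * dA;
    db += sum(dA, 0);
    mat dz = dA * W.t();
    dX.slice(t) = dz.cols(H, H + In - 1);
    dh_next = dz.cols(0, H - 1) + dh_pass;
    dC_next = dC_prev;
  }
  return Rcpp::List::create(Rcpp::Named("dW") = dW, Rcpp::Named("db") = db,
                            Rcpp::Named("dX") = dX);
}
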