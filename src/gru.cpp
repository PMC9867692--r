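// Gated recurrent unit forward/backward kernels for variable-length,
// length-sorted batches. Gate order in all 3h-wide parameter blocks is
// (reset, update, candidate). The candidate gate follows the convention
// n_t = tanh(W_n x_t + b_n + r_t % (U_n h_{t-1} + b_hn)), i.e. the reset
// gate multiplies the hidden-side projection including its bias.
//
// Layout: sequence tensors are cubes of dimension (batch, width, time);
// rows must be sorted by non-increasing sequence length so that the
// active rows at step t are a leading block.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigm(const arma::mat& x) { return 1.0 / (1.0 + exp(-x)); }

static int n_active(const arma::ivec& lens, int t) {
  int na = 0;
  for (uword i = 0; i < lens.n_elem; ++i) {
    if (lens(i) > t) ++na; else break;
  }
  return na;
}

// [[Rcpp::export]]
Rcpp::List cpp_gru_forward(const arma::cube& X, const arma::ivec& lens,
                           const arma::mat& Wx, const arma::mat& Wh,
                           const arma::rowvec& b, const arma::rowvec& bh) {
  const int B = X.n_rows, T = X.n_slices;
  const int H = Wh.n_rows;
  for (uword i = 1; i < lens.n_elem; ++i) {
    if (lens(i) > lens(i - 1))
      Rcpp::stop("batch rows must be sorted by non-increasing length");
  }
  cube Hout(B, H, T, fill::zeros);
  cube Rg(B, H, T, fill::zeros), Zg(B, H, T, fill::zeros);
  cube Ng(B, H, T, fill::zeros), Ug(B, H, T, fill::zeros);
  mat h_prev(B, H, fill::zeros);
  mat hpre(B, 3 * H);

  for (int t = 0; t < T; ++t) {
    const int na = n_active(lens, t);
    if (na == 0) break;
    mat pre = X.slice(t).rows(0, na - 1) * Wx;
    pre.each_row() += b;
    hpre.rows(0, na - 1) = h_prev.rows(0, na - 1) * Wh;
    mat r = sigm(pre.cols(0, H - 1) + hpre.submat(0, 0, na - 1, H - 1));
    mat z = sigm(pre.cols(H, 2 * H - 1) +
                 hpre.submat(0, H, na - 1, 2 * H - 1));
    mat u = hpre.submat(0, 2 * H, na - 1, 3 * H - 1);
    u.each_row() += bh;
    mat n = tanh(pre.cols(2 * H, 3 * H - 1) + r % u);
    Rg.slice(t).rows(0, na - 1) = r;
    Zg.slice(t).rows(0, na - 1) = z;
    Ng.slice(t).rows(0, na - 1) = n;
    Ug.slice(t).rows(0, na - 1) = u;
    h_prev.rows(0, na - 1) = (1.0 - z) % n +
      z % h_prev.rows(0, na - 1);
    Hout.slice(t).rows(0, na - 1) = h_prev.rows(0, na - 1);
  }
  return Rcpp::List::create(Rcpp::Named("H") = Hout,
                            Rcpp::Named("r") = Rg, Rcpp::Named("z") = Zg,
                            Rcpp::Named("n") = Ng, Rcpp::Named("u") = Ug);
}

// [[Rcpp::export]]
Rcpp::List cpp_gru_backward(const arma::cube& X, const arma::ivec& lens,
                            const arma::mat& Wx, const arma::mat& Wh,
                            const arma::cube& Hout, const arma::cube& Rg, const arma::cube& Zg,
                            const arma::cube& Ng, const arma::cube& Ug, const arma::cube& dH,
                            const bool param_grads) {
  const int B = X.n_rows, D = X.n_cols, T = X.n_slices;
  const int H = Wh.n_rows;
  cube dX(B, D, T, fill::zeros);
  mat dWx(D, 3 * H, fill::zeros), dWh(H, 3 * H, fill::zeros);
  rowvec db(3 * H, fill::zeros), dbh(H, fill::zeros);
  mat carry(B, H, fill::zeros);

  const mat WhrT = Wh.cols(0, H - 1).t();
  const mat WhzT = Wh.cols(H, 2 * H - 1).t();
  const mat WhnT = Wh.cols(2 * H, 3 * H - 1).t();
  const mat WxT = Wx.t();

  for (int t = T - 1; t >= 0; --t) {
    const int na = n_active(lens, t);
    if (na == 0) continue;
    mat dh = dH.slice(t).rows(0, na - 1) + carry.rows(0, na - 1);
    mat hp = (t == 0) ? mat(na, H, fill::zeros)
                      : mat(Hout.slice(t - 1).rows(0, na - 1));
    mat r = Rg.slice(t).rows(0, na - 1);
    mat z = Zg.slice(t).rows(0, na - 1);
    mat n = Ng.slice(t).rows(0, na - 1);
    mat u = Ug.slice(t).rows(0, na - 1);

    mat dz_pre = dh % (hp - n) % z % (1.0 - z);
    mat dn_pre = dh % (1.0 - z) % (1.0 - n % n);
    mat dr_pre = dn_pre % u % r % (1.0 - r);
    mat du = dn_pre % r;

    mat dhp = dh % z + du * WhnT + dr_pre * WhrT + dz_pre * WhzT;
    mat G = join_rows(dr_pre, join_rows(dz_pre, dn_pre));
    dX.slice(t).rows(0, na - 1) = G * WxT;
    if (param_grads) {
      mat xt = X.slice(t).rows(0, na - 1);
      dWx += xt.t() * G;
      dWh += hp.t() * join_rows(dr_pre, join_rows(dz_pre, du));
      db += sum(G, 0);
      dbh += sum(du, 0);
    }
    carry.rows(0, na - 1) = dhp;
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dWx") = dWx, Rcpp::Named("dWh") = dWh,
                            Rcpp::Named("db") = db, Rcpp::Named("dbh") = dbh);
}

// Reverse each row's valid prefix in time; self-inverse for fixed lens.
// [[Rcpp::export]]
arma::cube cpp_reverse_sequences(const arma::cube& X, const arma::ivec& lens) {
  cube out(size(X), fill::zeros);
  const int T = X.n_slices;
  for (uword i = 0; i < lens.n_elem; ++i) {
    const int L = lens(i);
    for (int t = 0; t < L && t < T; ++t) {
      out.slice(t).row(i) = X.slice(L - 1 - t).row(i);
    }
  }
  return out;
}
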