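// Per-task additive attention over bidirectional GRU states, for
// variable-length, length-sorted batches. For task k and timestep t:
//   score s_kt = v_k' tanh(W_k m_t + b_k),  m_t = [hf_t, hb_t]
// softmax over the valid timesteps of each row, context c_k = sum_t
// alpha_kt m_t. Task parameter blocks are stacked column-wise: Wall is
// (2h x K*a), ball is length K*a, Vall is (a x K).
//
// The tanh activations are recomputed in the backward pass instead of
// being cached; at batch size B and length T the cache would be
// B*T*a*K doubles, which dwarfs the extra forward GEMM.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static int att_n_active(const ivec& lens, int t) {
  int na = 0;
  for (uword i = 0; i < lens.n_elem; ++i) {
    if (lens(i) > t) ++na; else break;
  }
  return na;
}

// [[Rcpp::export]]
Rcpp::List cpp_attention_forward(const arma::cube& Hf, const arma::cube& Hb,
                                 const arma::ivec& lens,
                                 const arma::mat& Wall,
                                 const arma::rowvec& ball,
                                 const arma::mat& Vall) {
  const int B = Hf.n_rows, H = Hf.n_cols, T = Hf.n_slices;
  const int A = Vall.n_rows, K = Vall.n_cols;
  cube S(B, T, K, fill::zeros);      // raw scores
  for (int t = 0; t < T; ++t) {
    const int na = att_n_active(lens, t);
    if (na == 0) break;
    mat M = join_rows(Hf.slice(t).rows(0, na - 1),
                      Hb.slice(t).rows(0, na - 1));
    mat Act = M * Wall;              // na x K*A
    Act.each_row() += ball;
    Act = tanh(Act);
    for (int k = 0; k < K; ++k) {
      S.slice(k).col(t).rows(0, na - 1) =
        Act.cols(k * A, (k + 1) * A - 1) * Vall.col(k);
    }
  }
  // masked softmax over time, per row and task
  cube alpha(B, T, K, fill::zeros);
  for (int k = 0; k < K; ++k) {
    for (int b = 0; b < B; ++b) {
      const int L = std::min<int>(lens(b), T);
      if (L <= 0) continue;
      rowvec s = S.slice(k).row(b).cols(0, L - 1);
      s -= s.max();
      rowvec e = exp(s);
      alpha.slice(k).row(b).cols(0, L - 1) = e / accu(e);
    }
  }
  // contexts c_k = sum_t alpha_kt [hf_t, hb_t]
  cube ctx(B, 2 * H, K, fill::zeros);
  for (int t = 0; t < T; ++t) {
    const int na = att_n_active(lens, t);
    if (na == 0) break;
    mat M = join_rows(Hf.slice(t).rows(0, na - 1),
                      Hb.slice(t).rows(0, na - 1));
    for (int k = 0; k < K; ++k) {
      const vec ak = alpha.slice(k).col(t).rows(0, na - 1);
      ctx.slice(k).rows(0, na - 1) += M.each_col() % ak;
    }
  }
  return Rcpp::List::create(Rcpp::Named("contexts") = ctx,
                            Rcpp::Named("alpha") = alpha);
}

// [[Rcpp::export]]
Rcpp::List cpp_attention_backward(const arma::cube& Hf, const arma::cube& Hb,
                                  const arma::ivec& lens,
                                  const arma::mat& Wall,
                                  const arma::rowvec& ball,
                                  const arma::mat& Vall,
                                  const arma::cube& alpha,
                                  const arma::cube& dctx,
                                  const bool param_grads) {
  const int B = Hf.n_rows, H = Hf.n_cols, T = Hf.n_slices;
  const int A = Vall.n_rows, K = Vall.n_cols;
  cube dHf(B, H, T, fill::zeros), dHb(B, H, T, fill::zeros);
  mat dWall(2 * H, K * A, fill::zeros), dVall(A, K, fill::zeros);
  rowvec dball(K * A, fill::zeros);

  // dalpha[b,t,k] = dot(dctx_k[b,], m_t[b,]); then softmax backward
  cube ds(B, T, K, fill::zeros);
  for (int t = 0; t < T; ++t) {
    const int na = att_n_active(lens, t);
    if (na == 0) break;
    mat M = join_rows(Hf.slice(t).rows(0, na - 1),
                      Hb.slice(t).rows(0, na - 1));
    for (int k = 0; k < K; ++k) {
      ds.slice(k).col(t).rows(0, na - 1) =
        sum(M % dctx.slice(k).rows(0, na - 1), 1);
    }
  }
  for (int k = 0; k < K; ++k) {
    mat al = alpha.slice(k);           // B x T
    mat da = ds.slice(k);              // currently holds dalpha
    vec inner = sum(al % da, 1);       // B
    ds.slice(k) = al % (da.each_col() - inner);
  }
  // dM_t = alpha_t .* dctx + dA_t W'; parameter grads; recompute tanh
  for (int t = 0; t < T; ++t) {
    const int na = att_n_active(lens, t);
    if (na == 0) break;
    mat M = join_rows(Hf.slice(t).rows(0, na - 1),
                      Hb.slice(t).rows(0, na - 1));
    mat Act = M * Wall;
    Act.each_row() += ball;
    Act = tanh(Act);
    mat dA(na, K * A, fill::zeros);
    mat dM(na, 2 * H, fill::zeros);
    for (int k = 0; k < K; ++k) {
      vec dsk = ds.slice(k).col(t).rows(0, na - 1);
      mat Ak = Act.cols(k * A, (k + 1) * A - 1);
      dA.cols(k * A, (k + 1) * A - 1) =
        (dsk * Vall.col(k).t()) % (1.0 - Ak % Ak);
      const vec ak = alpha.slice(k).col(t).rows(0, na - 1);
      mat dck = dctx.slice(k).rows(0, na - 1);
      dM += dck.each_col() % ak;
      if (param_grads) {
        dVall.col(k) += Ak.t() * dsk;
      }
    }
    dM += dA * Wall.t();
    if (param_grads) {
      dWall += M.t() * dA;
      dball += sum(dA, 0);
    }
    dHf.slice(t).rows(0, na - 1) = dM.cols(0, H - 1);
    dHb.slice(t).rows(0, na - 1) = dM.cols(H, 2 * H - 1);
  }
  return Rcpp::List::create(Rcpp::Named("dHf") = dHf,
                            Rcpp::Named("dHb") = dHb,
                            Rcpp::Named("dWall") = dWall,
                            Rcpp::Named("dball") = dball,
                            Rcpp::Named("dVall") = dVall);
}
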