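// One Transformer encoder layer (post-norm): multi-head self-attention
// with residual + layer norm, then a ReLU feed-forward block with residual
// + layer norm. Operates on the flat (S*B x D) layout with row
// (b-1)*S + s = position s of sample b. Forward returns every
// intermediate needed for the exact backward pass.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static const double LN_EPS = 1e-5;

static void layernorm_fwd(const mat& X, const rowvec& g, const rowvec& b,
                          mat& xhat, vec& inv, mat& Y) {
  vec mu = mean(X, 1);
  mat xc = X.each_col() - mu;
  vec v = mean(xc % xc, 1);
  inv = 1.0 / sqrt(v + LN_EPS);
  xhat = xc.each_col() % inv;
  Y = xhat.each_row() % g;
  Y.each_row() += b;
}

// returns dX; accumulates dg, db
static mat layernorm_bwd(const mat& dY, const mat& xhat, const vec& inv,
                         const rowvec& g, rowvec& dg, rowvec& db) {
  dg += sum(dY % xhat, 0);
  db += sum(dY, 0);
  mat dxhat = dY.each_row() % g;
  vec m1 = mean(dxhat, 1);
  vec m2 = mean(dxhat % xhat, 1);
  mat dX = dxhat;
  dX.each_col() -= m1;
  dX -= xhat.each_col() % m2;
  dX.each_col() %= inv;
  return dX;
}

// [[Rcpp::export]]
Rcpp::List tf_layer_forward(const arma::mat& X, int B, int n_heads,
                            const arma::mat& Wq, const arma::mat& Wk,
                            const arma::mat& Wv, const arma::mat& Wo,
                            const arma::rowvec& bo,
                            const arma::rowvec& g1, const arma::rowvec& c1,
                            const arma::mat& W1, const arma::rowvec& b1,
                            const arma::mat& W2, const arma::rowvec& b2,
                            const arma::rowvec& g2, const arma::rowvec& c2) {
  const uword SB = X.n_rows, D = X.n_cols;
  const uword S = SB / B;
  const uword dh = D / n_heads;
  const double scale = 1.0 / std::sqrt((double)dh);
  mat Q = X * Wq, K = X * Wk, V = X * Wv;
  mat O(SB, D);
  cube P(S, S, B * n_heads);
  mat Sc(S, S);
  for (int b = 0; b < B; ++b) {
    const uword r0 = b * S, r1 = (b + 1) * S - 1;
    for (int h = 0; h < n_heads; ++h) {
      const uword c0 = h * dh, c1h = (h + 1) * dh - 1;
      Sc = Q.submat(r0, c0, r1, c1h) * K.submat(r0, c0, r1, c1h).t();
      Sc *= scale;
      Sc.each_col() -= max(Sc, 1);
      mat& E = P.slice(b * n_heads + h);
      E = exp(Sc);
      E.each_col() /= sum(E, 1);
      O.submat(r0, c0, r1, c1h) = E * V.submat(r0, c0, r1, c1h);
    }
  }
  mat A = O * Wo;
  A.each_row() += bo;
  mat R1 = X + A;
  mat xhat1, Y1;
  vec inv1;
  layernorm_fwd(R1, g1, c1, xhat1, inv1, Y1);
  mat H1 = Y1 * W1;
  H1.each_row() += b1;
  mat HR = clamp(H1, 0.0, datum::inf);
  mat F2 = HR * W2;
  F2.each_row() += b2;
  mat R2 = Y1 + F2;
  mat xhat2, Y2;
  vec inv2;
  layernorm_fwd(R2, g2, c2, xhat2, inv2, Y2);
  return Rcpp::List::create(
      Rcpp::Named("Y") = Y2, Rcpp::Named("Q") = Q, Rcpp::Named("K") = K,
      Rcpp::Named("V") = V, Rcpp::Named("P") = P, Rcpp::Named("O") = O,
      Rcpp::Named("xhat1") = xhat1, Rcpp::Named("inv1") = inv1,
      Rcpp::Named("Y1") = Y1, Rcpp::Named("H1") = H1,
      Rcpp::Named("HR") = HR, Rcpp::Named("xhat2") = xhat2,
      Rcpp::Named("inv2") = inv2);
}

// [[Rcpp::export]]
Rcpp::List tf_layer_backward(const arma::mat& X, int B, int n_heads,
                             const arma::mat& dY,
                             const arma::mat& Wq, const arma::mat& Wk,
                             const arma::mat& Wv, const arma::mat& Wo,
                             const arma::rowvec& g1, const arma::rowvec& g2,
                             const arma::mat& W1, const arma::mat& W2,
                             const arma::mat& Q, const arma::mat& K,
                             const arma::mat& V, const arma::cube& P,
                             const arma::mat& O, const arma::mat& xhat1,
                             const arma::vec& inv1, const arma::mat& Y1,
                             const arma::mat& H1, const arma::mat& HR,
                             const arma::mat& xhat2, const arma::vec& inv2) {
  const uword SB = X.n_rows, D = X.n_cols;
  const uword S = SB / B;
  const uword dh = D / n_heads;
  const double scale = 1.0 / std::sqrt((double)dh);
  rowvec dg2(D, fill::zeros), dc2(D, fill::zeros);
  mat dR2 = layernorm_bwd(dY, xhat2, inv2, g2, dg2, dc2);
  // feed-forward branch
  mat dW2 = HR.t() * dR2;
  rowvec db2 = sum(dR2, 0);
  mat dHR = dR2 * W2.t();
  mat dH1 = dHR % (H1 > 0);
  mat dW1 = Y1.t() * dH1;
  rowvec db1 = sum(dH1, 0);
  mat dY1 = dR2 + dH1 * W1.t();
  rowvec dg1(D, fill::zeros), dc1(D, fill::zeros);
  mat dR1 = layernorm_bwd(dY1, xhat1, inv1, g1, dg1, dc1);
  // attention branch
  mat dA = dR1;
  mat dWo = O.t() * dA;
  rowvec dbo = sum(dA, 0);
  mat dO = dA * Wo.t();
  mat dQ(SB, D), dK(SB, D), dV(SB, D);
  mat dP(S, S), dS(S, S);
  vec rs(S);
  for (int b = 0; b < B; ++b) {
    const uword r0 = b * S, r1 = (b + 1) * S - 1;
    for (int h = 0; h < n_heads; ++h) {
      const uword c0 = h * dh, c1h = (h + 1) * dh - 1;
      const mat& Ph = P.slice(b * n_heads + h);
      dP = dO.submat(r0, c0, r1, c1h) * V.submat(r0, c0, r1, c1h).t();
      rs = sum(dP % Ph, 1);
      dP.each_col() -= rs;
      dS = Ph % dP;
      dS *= scale;
      dQ.submat(r0, c0, r1, c1h) = dS * K.submat(r0, c0, r1, c1h);
      dK.submat(r0, c0, r1, c1h) = dS.t() * Q.submat(r0, c0, r1, c1h);
      dV.submat(r0, c0, r1, c1h) = Ph.t() * dO.submat(r0, c0, r1, c1h);
    }
  }
  mat dX = dR1 + dQ * Wq.t() + dK * Wk.t() + dV * Wv.t();
  return Rcpp::List::create(
      Rcpp::Named("dX") = dX,
      Rcpp::Named("dWq") = X.t() * dQ, Rcpp::Named("dWk") = X.t() * dK,
      Rcpp::Named("dWv") = X.t() * dV, Rcpp::Named("dWo") = dWo,
      Rcpp::Named("dbo") = dbo,
      Rcpp::Named("dg1") = dg1, Rcpp::Named("dc1") = dc1,
      Rcpp::Named("dW1") = dW1, Rcpp::Named("db1") = db1,
      Rcpp::Named("dW2") = dW2, Rcpp::Named("db2") = db2,
      Rcpp::Named("dg2") = dg2, Rcpp::Named("dc2") = dc2);
}
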