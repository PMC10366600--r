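// GRU forward/backward kernels (gates ordered r, z, n), operating on the
// time-major stacked representation: a (T*B x nin) input whose t-th row
// block is the batch at step t. The input projection runs as one GEMM;
// the time loop only carries the hidden-to-hidden product.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// [[Rcpp::export]]
Rcpp::List gru_core_forward(const arma::mat& Xbig, int B,
                            const arma::mat& Wx, const arma::mat& Wh,
                            const arma::rowvec& bx, const arma::rowvec& bh,
                            const arma::mat& h0) {
  const uword TnB = Xbig.n_rows, H = Wh.n_rows;
  const uword Tn = TnB / B;
  mat GX = Xbig * Wx;
  GX.each_row() += bx;
  mat h = h0;
  mat Hbig(TnB, H), Hprev(TnB, H), R(TnB, H), Z(TnB, H), N(TnB, H),
      GHn(TnB, H);
  for (uword t = 0; t < Tn; ++t) {
    const uword r0 = t * B, r1 = (t + 1) * B - 1;
    mat gh = h * Wh;
    gh.each_row() += bh;
    mat r = 1.0 / (1.0 + exp(-(GX.submat(r0, 0, r1, H - 1) +
                               gh.cols(0, H - 1))));
    mat z = 1.0 / (1.0 + exp(-(GX.submat(r0, H, r1, 2 * H - 1) +
                               gh.cols(H, 2 * H - 1))));
    mat ghn = gh.cols(2 * H, 3 * H - 1);
    mat n = tanh(GX.submat(r0, 2 * H, r1, 3 * H - 1) + r % ghn);
    Hprev.rows(r0, r1) = h;
    h = (1.0 - z) % n + z % h;
    Hbig.rows(r0, r1) = h;
    R.rows(r0, r1) = r;
    Z.rows(r0, r1) = z;
    N.rows(r0, r1) = n;
    GHn.rows(r0, r1) = ghn;
  }
  return Rcpp::List::create(
      Rcpp::Named("Hbig") = Hbig, Rcpp::Named("h_last") = h,
      Rcpp::Named("Hprev") = Hprev, Rcpp::Named("r") = R,
      Rcpp::Named("z") = Z, Rcpp::Named("n") = N, Rcpp::Named("ghn") = GHn);
}

// [[Rcpp::export]]
Rcpp::List gru_core_backward(const arma::mat& Xbig, int B,
                             const arma::mat& Wx, const arma::mat& Wh,
                             const arma::mat& Hprev, const arma::mat& R,
                             const arma::mat& Z, const arma::mat& N,
                             const arma::mat& GHn, const arma::mat& dHbig,
                             const arma::mat& dh_last) {
  const uword TnB = Xbig.n_rows, H = Wh.n_rows;
  const uword Tn = TnB / B;
  mat dGX(TnB, 3 * H), dGH(TnB, 3 * H);
  mat carry = dh_last;
  mat WhT = Wh.t();
  for (uword tt = Tn; tt-- > 0;) {
    const uword r0 = tt * B, r1 = (tt + 1) * B - 1;
    mat dh = carry + dHbig.rows(r0, r1);
    mat r = R.rows(r0, r1), z = Z.rows(r0, r1), n = N.rows(r0, r1);
    mat hprev = Hprev.rows(r0, r1);
    mat dz = dh % (hprev - n);
    mat dn_pre = dh % (1.0 - z) % (1.0 - n % n);
    mat dr = dn_pre % GHn.rows(r0, r1);
    mat dz_pre = dz % z % (1.0 - z);
    mat dr_pre = dr % r % (1.0 - r);
    dGX.submat(r0, 0, r1, H - 1) = dr_pre;
    dGX.submat(r0, H, r1, 2 * H - 1) = dz_pre;
    dGX.submat(r0, 2 * H, r1, 3 * H - 1) = dn_pre;
    mat dgh = join_rows(dr_pre, dz_pre, dn_pre % r);
    dGH.rows(r0, r1) = dgh;
    carry = dh % z + dgh * WhT;
  }
  return Rcpp::List::create(
      Rcpp::Named("dWx") = Xbig.t() * dGX,
      Rcpp::Named("dWh") = Hprev.t() * dGH,
      Rcpp::Named("dbx") = sum(dGX, 0),
      Rcpp::Named("dbh") = sum(dGH, 0),
      Rcpp::Named("dX") = dGX * Wx.t(),
      Rcpp::Named("dh0") = carry);
}
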