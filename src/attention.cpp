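// Disentangled-attention kernels: per-sequence, per-head score
// computation (content-content, content-position, position-content over
// clipped relative-distance buckets), softmax, and the exact backward
// pass. Called from the R training loop; matrices arrive flattened as
// (B*L) x H with row (b-1)*L + i = sequence b, position i.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// bucket: L x L integer matrix (1-based bucket index per (i, j) pair)
// valid: B x L (0/1) — invalid key columns get no attention mass

// [[Rcpp::export]]
Rcpp::List attn_forward_cpp(const arma::mat& Q, const arma::mat& K, const arma::mat& V,
                            const arma::mat& Qr, const arma::mat& Kr,
                            const arma::imat& bucket, const arma::umat& valid,
                            const int n_heads, const double scale) {
  const int BL = Q.n_rows, H = Q.n_cols;
  const int B = valid.n_rows, L = valid.n_cols;
  const int dh = H / n_heads;
  mat O(BL, H, fill::zeros);
  cube P(L, L, B * n_heads);
  for (int b = 0; b < B; ++b) {
    const int r0 = b * L;
    for (int h = 0; h < n_heads; ++h) {
      const int c0 = h * dh;
      mat Qb = Q.submat(r0, c0, r0 + L - 1, c0 + dh - 1);
      mat Kb = K.submat(r0, c0, r0 + L - 1, c0 + dh - 1);
      mat Vb = V.submat(r0, c0, r0 + L - 1, c0 + dh - 1);
      mat c2p = Qb * Kr.cols(c0, c0 + dh - 1).t(); // L x n_buckets
      mat p2c = Kb * Qr.cols(c0, c0 + dh - 1).t();
      mat S = Qb * Kb.t();
      for (int i = 0; i < L; ++i) {
        for (int j = 0; j < L; ++j) {
          S(i, j) += c2p(i, bucket(i, j) - 1) + p2c(j, bucket(j, i) - 1);
        }
      }
      S *= scale;
      for (int j = 0; j < L; ++j) {
        if (!valid(b, j)) S.col(j).fill(-datum::inf);
      }
      // row-wise softmax (rows with some finite entry; -inf -> 0 mass)
      for (int i = 0; i < L; ++i) {
        double m = S.row(i).max();
        if (!std::isfinite(m)) m = 0.0;
        rowvec e = exp(S.row(i) - m);
        e.replace(datum::nan, 0.0);
        S.row(i) = e / accu(e);
      }
      P.slice(b * n_heads + h) = S;
      O.submat(r0, c0, r0 + L - 1, c0 + dh - 1) = S * Vb;
    }
  }
  return Rcpp::List::create(Rcpp::Named("O") = O, Rcpp::Named("P") = P);
}

// [[Rcpp::export]]
Rcpp::List attn_backward_cpp(const arma::mat& dO, const arma::mat& Q, const arma::mat& K,
                             const arma::mat& V, const arma::mat& Qr, const arma::mat& Kr,
                             const arma::cube& P, const arma::imat& bucket,
                             const arma::umat& valid, const int n_heads,
                             const double scale) {
  const int BL = Q.n_rows, H = Q.n_cols;
  const int B = valid.n_rows, L = valid.n_cols;
  const int dh = H / n_heads;
  const int nb = Qr.n_rows;
  mat dQ(BL, H, fill::zeros), dK(BL, H, fill::zeros),
      dV(BL, H, fill::zeros);
  mat dQr(nb, H, fill::zeros), dKr(nb, H, fill::zeros);
  for (int b = 0; b < B; ++b) {
    const int r0 = b * L;
    for (int h = 0; h < n_heads; ++h) {
      const int c0 = h * dh;
      mat Qb = Q.submat(r0, c0, r0 + L - 1, c0 + dh - 1);
      mat Kb = K.submat(r0, c0, r0 + L - 1, c0 + dh - 1);
      mat Vb = V.submat(r0, c0, r0 + L - 1, c0 + dh - 1);
      mat dOb = dO.submat(r0, c0, r0 + L - 1, c0 + dh - 1);
      const arma::mat& Pm = P.slice(b * n_heads + h);
      mat dP = dOb * Vb.t();
      dV.submat(r0, c0, r0 + L - 1, c0 + dh - 1) = Pm.t() * dOb;
      vec rs = sum(dP % Pm, 1);
      mat dS = (dP.each_col() - rs) % Pm * scale;
      dQ.submat(r0, c0, r0 + L - 1, c0 + dh - 1) += dS * Kb;
      dK.submat(r0, c0, r0 + L - 1, c0 + dh - 1) += dS.t() * Qb;
      mat dc2p(L, nb, fill::zeros), dp2c(L, nb, fill::zeros);
      for (int i = 0; i < L; ++i) {
        for (int j = 0; j < L; ++j) {
          dc2p(i, bucket(i, j) - 1) += dS(i, j);
          dp2c(j, bucket(j, i) - 1) += dS(i, j);
        }
      }
      dQ.submat(r0, c0, r0 + L - 1, c0 + dh - 1) +=
        dc2p * Kr.cols(c0, c0 + dh - 1);
      dKr.cols(c0, c0 + dh - 1) += dc2p.t() * Qb;
      dK.submat(r0, c0, r0 + L - 1, c0 + dh - 1) +=
        dp2c * Qr.cols(c0, c0 + dh - 1);
      dQr.cols(c0, c0 + dh - 1) += dp2c.t() * Kb;
    }
  }
  return Rcpp::List::create(
    Rcpp::Named("dQ") = dQ, Rcpp::Named("dK") = dK,
    Rcpp::Named("dV") = dV, Rcpp::Named("dQr") = dQr,
    Rcpp::Named("dKr") = dKr);
}
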