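#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Mean over prior draws of log det M(D, beta) for a paired-choice design,
// where D (n_sets x p) stacks the effects-coded profile differences and
// M(beta) = sum_s w_s d_s d_s^T with w_s = p_s (1 - p_s),
// p_s = logistic(d_s' beta). Returns -Inf when any draw's information
// matrix is singular beyond the condition threshold (diagonal ratio of the
// Cholesky factor), matching a condition number of about 1e10.
// [[Rcpp::export]]
double cpp_bayes_logdet(const arma::mat& D, const arma::mat& B) {
  const arma::uword p = D.n_cols;
  const arma::uword R = B.n_rows;
  if (B.n_cols != p) stop("draw matrix dimension does not match design");
  double acc = 0.0;
  arma::mat M(p, p);
  arma::mat L;
  for (arma::uword r = 0; r < R; ++r) {
    arma::vec eta = D * B.row(r).t();
    arma::vec pr = 1.0 / (1.0 + arma::exp(-eta));
    arma::vec w = pr % (1.0 - pr);
    M = D.t() * (D.each_col() % w);
    if (!arma::chol(L, M, "lower")) {
      return R_NegInf;
    }
    arma::vec dg = L.diag();
    double mx = dg.max(), mn = dg.min();
    if (!(mn > 0.0) || (mx / mn) * (mx / mn) > 1e10) {
      return R_NegInf;
    }
    acc += 2.0 * arma::accu(arma::log(dg));
  }
  return acc / static_cast<double>(R);
}

static inline double wlogis(double eta) {
  double pr = 1.0 / (1.0 + std::exp(-eta));
  return pr * (1.0 - pr);
}

// Initialize the coordinate-exchange state: per prior draw the inverse
// information matrix and its log determinant. ok = false when any draw is
// singular beyond the condition threshold.
// [[Rcpp::export]]
List cpp_exchange_init(const arma::mat& D, const arma::mat& B) {
  const arma::uword p = D.n_cols;
  const arma::uword R = B.n_rows;
  arma::cube Minv(p, p, R);
  arma::vec ld(R);
  arma::mat M(p, p), L;
  for (arma::uword r = 0; r < R; ++r) {
    arma::vec eta = D * B.row(r).t();
    arma::vec pr = 1.0 / (1.0 + arma::exp(-eta));
    arma::vec w = pr % (1.0 - pr);
    M = D.t() * (D.each_col() % w);
    if (!arma::chol(L, M, "lower")) {
      return List::create(Named("ok") = false);
    }
    arma::vec dg = L.diag();
    double mx = dg.max(), mn = dg.min();
    if (!(mn > 0.0) || (mx / mn) * (mx / mn) > 1e10) {
      return List::create(Named("ok") = false);
    }
    ld(r) = 2.0 * arma::accu(arma::log(dg));
    Minv.slice(r) = arma::inv_sympd(M);
  }
  return List::create(Named("ok") = true, Named("Minv") = Minv,
                      Named("logdet") = ld);
}

// Criterion value after replacing one design row d_old by d_new, computed
// from the stored per-draw inverses by two sequential rank-one
// (Sherman-Morrison) determinant updates; the state is not modified.
// Returns -Inf when any draw's updated matrix loses positive definiteness.
// [[Rcpp::export]]
double cpp_candidate_crit(NumericVector MinvR, NumericVector ldR,
                          IntegerVector dims, const arma::mat& B,
                          const arma::vec& dOld, const arma::vec& dNew) {
  const arma::uword p = dims[0];
  const arma::uword R = dims[2];
  const arma::cube Minv(MinvR.begin(), p, p, R, false);
  const arma::vec ld(ldR.begin(), R, false);
  double acc = 0.0;
  // The new row is added before the old one is removed, so the
  // intermediate matrix stays positive definite even when the design has
  // as many rows as columns; only the final removal can lose rank.
  for (arma::uword r = 0; r < R; ++r) {
    const double wOld = wlogis(arma::dot(dOld, B.row(r)));
    const double wNew = wlogis(arma::dot(dNew, B.row(r)));
    const arma::mat& Mi = Minv.slice(r);
    arma::vec Mu = Mi * dOld;
    const double a = arma::dot(dOld, Mu);
    const double b = arma::dot(dNew, Mu);
    const double c = arma::as_scalar(dNew.t() * Mi * dNew);
    const double denAdd = 1.0 + wNew * c;
    const double denRem = 1.0 - wOld * (a - wNew * b * b / denAdd);
    if (denRem < 1e-12) return R_NegInf;
    acc += ld(r) + std::log(denAdd) + std::log(denRem);
  }
  return acc / static_cast<double>(R);
}

// Apply an accepted exchange in place: two Sherman-Morrison updates of
// every per-draw inverse plus the log-determinant bookkeeping.
// [[Rcpp::export]]
void cpp_accept_update(NumericVector MinvR, NumericVector ldR,
                       IntegerVector dims, const arma::mat& B,
                       const arma::vec& dOld, const arma::vec& dNew) {
  const arma::uword p = dims[0];
  const arma::uword R = dims[2];
  arma::cube Minv(MinvR.begin(), p, p, R, false);
  arma::vec ld(ldR.begin(), R, false);
  // add-then-remove, mirroring cpp_candidate_crit
  for (arma::uword r = 0; r < R; ++r) {
    const double cAdd = wlogis(arma::dot(dNew, B.row(r)));
    const double cRem = -wlogis(arma::dot(dOld, B.row(r)));
    arma::mat& Mi = Minv.slice(r);
    {
      arma::vec Mv = Mi * dNew;
      const double den = 1.0 + cAdd * arma::dot(dNew, Mv);
      Mi -= (cAdd / den) * (Mv * Mv.t());
      ld(r) += std::log(den);
    }
    {
      arma::vec Mv = Mi * dOld;
      const double den = 1.0 + cRem * arma::dot(dOld, Mv);
      Mi -= (cRem / den) * (Mv * Mv.t());
      ld(r) += std::log(den);
    }
  }
}
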