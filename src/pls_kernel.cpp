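// Partial least squares (PLS1, NIPALS) kernel with leave-one-out prediction.
// Kept in compiled code because the genetic-algorithm variable selection
// evaluates this objective hundreds of thousands of times per analysis.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Coefficient path on autoscaled data: column a holds the regression vector
// of the a-component model. Components stop early when X or y is exhausted;
// trailing columns then repeat the last valid vector.
static mat pls1_coef_path(const mat& E0, const vec& f0, const int A) {
  const uword p = E0.n_cols;
  mat W(p, A, fill::zeros), P(p, A, fill::zeros);
  vec q(A, fill::zeros);
  mat B(p, A, fill::zeros);
  mat E = E0;
  vec f = f0;
  int a_used = 0;
  for (int a = 0; a < A; ++a) {
    vec w = E.t() * f;
    double nw = norm(w);
    if (nw < 1e-12) break;
    w /= nw;
    vec t = E * w;
    double tt = dot(t, t);
    if (tt < 1e-12) break;
    vec pa = E.t() * t / tt;
    double qa = dot(f, t) / tt;
    W.col(a) = w;
    P.col(a) = pa;
    q(a) = qa;
    E -= t * pa.t();
    f -= qa * t;
    a_used = a + 1;
    mat Wa = W.cols(0, a);
    mat PtW = P.cols(0, a).t() * Wa;
    vec qb;
    bool ok = solve(qb, PtW, q.subvec(0, a));
    if (!ok) { a_used = a; break; }
    B.col(a) = Wa * qb;
  }
  for (int a = a_used; a < A; ++a)
    B.col(a) = (a_used > 0) ? B.col(a_used - 1) : vec(p, fill::zeros);
  return B;
}

// Autoscale columns of X (training statistics); zero-variance columns get
// unit scale so they contribute nothing after centering.
static void scale_stats(const mat& X, rowvec& ctr, rowvec& scl) {
  ctr = mean(X, 0);
  scl = stddev(X, 0, 0);
  scl.elem(find(scl < 1e-12)).fill(1.0);
}

// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_pls_train_predict(const arma::mat& Xtr,
                                          const arma::vec& ytr,
                                          const arma::mat& Xte,
                                          const int lv_max) {
  rowvec ctr, scl;
  scale_stats(Xtr, ctr, scl);
  mat E = (Xtr.each_row() - ctr).each_row() / scl;
  double ybar = mean(ytr);
  mat B = pls1_coef_path(E, ytr - ybar, lv_max);
  mat Ete = (Xte.each_row() - ctr).each_row() / scl;
  mat pred = Ete * B;
  pred += ybar;
  return Rcpp::wrap(pred);
}

// Leave-one-out predictions: row i, column a is the prediction of sample i
// from an a-component model refit without sample i (autoscaling redone on
// each training fold).
// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_pls_loo(const arma::mat& X, const arma::vec& y,
                                const int lv_max) {
  const uword n = X.n_rows;
  mat out(n, lv_max, fill::zeros);
  for (uword i = 0; i < n; ++i) {
    uvec keep = find(regspace<uvec>(0, n - 1) != i);
    mat Xtr = X.rows(keep);
    vec ytr = y.elem(keep);
    rowvec ctr, scl;
    scale_stats(Xtr, ctr, scl);
    mat E = (Xtr.each_row() - ctr).each_row() / scl;
    double ybar = mean(ytr);
    mat B = pls1_coef_path(E, ytr - ybar, lv_max);
    rowvec xi = (X.row(i) - ctr) / scl;
    out.row(i) = xi * B + ybar;
  }
  return Rcpp::wrap(out);
}
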