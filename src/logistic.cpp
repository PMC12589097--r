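// Fast unpenalised logistic regression (IRLS Newton) for 1-2 features,
// with in-fold standardisation and coefficient capping, plus leave-one-out
// and leave-pair-out cross-validation drivers.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// fit on rows where keep != 0; returns (intercept, slopes on standardized
// scale) together with the standardisation (mu, sd)
static void logit_fit(const mat &X, const vec &y, const uvec &rows,
                      double cap, vec &beta, rowvec &mu, rowvec &sg) {
  mat Xt = X.rows(rows);
  vec yt = y.elem(rows);
  mu = mean(Xt, 0);
  sg = stddev(Xt, 0, 0);
  for (uword j = 0; j < sg.n_elem; ++j) if (sg(j) <= 0) sg(j) = 1.0;
  mat Z(Xt.n_rows, Xt.n_cols + 1);
  Z.col(0).ones();
  for (uword j = 0; j < Xt.n_cols; ++j)
    Z.col(j + 1) = (Xt.col(j) - mu(j)) / sg(j);
  beta.zeros(Z.n_cols);
  for (int it = 0; it < 30; ++it) {
    vec eta = Z * beta;
    eta = clamp(eta, -30.0, 30.0);
    vec p = 1.0 / (1.0 + exp(-eta));
    vec w = p % (1.0 - p) + 1e-10;
    vec g = Z.t() * (yt - p);
    mat H = Z.t() * (Z.each_col() % w);
    H.diag() += 1e-10;
    vec step = solve(H, g, solve_opts::fast);
    beta += step;
    bool capped = false;
    for (uword j = 1; j < beta.n_elem; ++j) {
      if (beta(j) > cap) { beta(j) = cap; capped = true; }
      if (beta(j) < -cap) { beta(j) = -cap; capped = true; }
    }
    if (capped || norm(step) < 1e-9) break;
  }
}

static double predict_one(const mat &X, uword i, const vec &beta,
                          const rowvec &mu, const rowvec &sg) {
  double eta = beta(0);
  for (uword j = 0; j < X.n_cols; ++j)
    eta += beta(j + 1) * (X(i, j) - mu(j)) / sg(j);
  if (eta > 30) eta = 30; if (eta < -30) eta = -30;
  return 1.0 / (1.0 + std::exp(-eta));
}

// [[Rcpp::export]]
arma::vec cpp_loocv_scores(const arma::mat &X, const arma::vec &y,
                           double cap) {
  uword n = X.n_rows;
  vec out(n);
  vec beta; rowvec mu, sg;
  for (uword i = 0; i < n; ++i) {
    uvec rows(n - 1);
    uword k = 0;
    for (uword r = 0; r < n; ++r) if (r != i) rows(k++) = r;
    logit_fit(X, y, rows, cap, beta, mu, sg);
    out(i) = predict_one(X, i, beta, mu, sg);
  }
  return out;
}

// Leave-pair-out CV AUROC: every (case, control) pair is held out, the
// model is refit on the remaining n-2, and the pair is scored by the
// held-out predicted probabilities (ties 1/2).
// [[Rcpp::export]]
double cpp_lpocv_auroc(const arma::mat &X, const arma::vec &y, double cap) {
  uvec cases = find(y == 1), ctrls = find(y == 0);
  uword n = X.n_rows;
  double wins = 0.0;
  vec beta; rowvec mu, sg;
  uvec rows(n - 2);
  for (uword a = 0; a < cases.n_elem; ++a) {
    for (uword b = 0; b < ctrls.n_elem; ++b) {
      uword i = cases(a), j = ctrls(b);
      uword k = 0;
      for (uword r = 0; r < n; ++r) if (r != i && r != j) rows(k++) = r;
      logit_fit(X, y, rows, cap, beta, mu, sg);
      double pi = predict_one(X, i, beta, mu, sg);
      double pj = predict_one(X, j, beta, mu, sg);
      if (pi > pj) wins += 1.0;
      else if (pi == pj) wins += 0.5;
    }
  }
  return wins / (double)(cases.n_elem * ctrls.n_elem);
}
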