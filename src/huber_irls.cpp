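#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// MAD about zero, scaled to be consistent for the Gaussian
static double mad0(const arma::vec &r) {
  return arma::median(arma::abs(r)) / 0.6745;
}

// Huber IRLS over the columns of Y (one regression per column, shared X).
// Scale is the MAD of current residuals, recomputed each iteration and
// floored so exact-fit (zero residual) columns stay at weights == 1.
// Standard errors follow Huber's small-sample-corrected formula on the
// unweighted (X'X)^-1, i.e. the classic M-estimation covariance.
// [[Rcpp::export(name = ".huberIrlsCpp")]]
List huberIrlsCpp(const arma::mat &X, const arma::mat &Y,
                  double k, double tol, int maxit,
                  double scaleFloorMult) {
  const arma::uword n = X.n_rows, p = X.n_cols, m = Y.n_cols;
  arma::mat XtX = X.t() * X;
  arma::mat XtXinv = arma::inv_sympd(XtX);
  arma::vec xtxDiag = XtXinv.diag();

  arma::mat beta(p, m), se(p, m), wts(n, m);
  arma::vec scaleOut(m);
  IntegerVector iters(m);
  LogicalVector conv(m);

  for (arma::uword j = 0; j < m; ++j) {
    arma::vec y = Y.col(j);
    double sFloor = scaleFloorMult * (1.0 + std::abs(arma::median(y)));
    arma::vec b = arma::solve(XtX, X.t() * y);   // OLS start
    arma::vec r = y - X * b;
    arma::vec w(n, arma::fill::ones);
    double s = std::max(mad0(r), sFloor);
    bool done = false;
    int it = 0;
    for (it = 1; it <= maxit; ++it) {
      s = std::max(mad0(r), sFloor);
      for (arma::uword i = 0; i < n; ++i) {
        double u = std::abs(r(i)) / s;
        w(i) = (u <= k) ? 1.0 : k / u;
      }
      arma::mat Xw = X.each_col() % w;
      arma::vec bNew = arma::solve(X.t() * Xw, Xw.t() * y);
      double d = arma::abs(bNew - b).max() / (1.0 + arma::abs(bNew).max());
      b = bNew;
      r = y - X * b;
      if (d < tol) { done = true; break; }
    }
    // SE at the final scale used for weighting (Huber 1981 / "XtX" form):
    //   S = sum(psi(r/s)^2 s^2)/(n-p), kappa = 1 + p var(psi')/(n mn^2)
    arma::vec u = r / s;
    arma::vec psiw(n), psip(n);
    for (arma::uword i = 0; i < n; ++i) {
      double au = std::abs(u(i));
      psiw(i) = (au <= k) ? 1.0 : k / au;  // weight psi(u)/u
      psip(i) = (au <= k) ? 1.0 : 0.0;     // psi'(u)
    }
    double S = arma::accu(arma::square(r % psiw)) / (double)(n - p);
    double mn = arma::mean(psip);
    double kap = 1.0 + (double)p * arma::var(psip) / ((double)n * mn * mn);
    double stddev = (mn > 0) ? std::sqrt(S) * kap / mn : NA_REAL;
    beta.col(j) = b;
    se.col(j) = stddev * arma::sqrt(xtxDiag);
    wts.col(j) = w;
    scaleOut(j) = s;
    iters[j] = it > maxit ? maxit : it;
    conv[j] = done;
  }

  return List::create(_["beta"] = beta, _["se"] = se,
                      _["weights"] = wts, _["scale"] = scaleOut,
                      _["iterations"] = iters, _["converged"] = conv);
}
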