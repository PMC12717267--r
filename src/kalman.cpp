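#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Univariate-observation Gaussian linear state-space machinery:
//   y_t = Z a_t + offset_t + eps_t,  eps ~ N(0, H)
//   a_{t+1} = T a_t + eta_t,         eta ~ N(0, Q)
// Missing y_t are skipped in the update step. R's RNG drives the backward
// sampler so draws are reproducible under set.seed().

// [[Rcpp::export]]
List kalman_filter_cpp(NumericVector y, NumericVector offset, arma::mat Tmat,
                       arma::rowvec Z, arma::mat Q, double H, arma::vec a1,
                       arma::mat P1) {
  const int n = y.size();
  const int m = a1.n_elem;

  arma::mat at(n, m), att(n, m);
  arma::cube Pt(m, m, n), Ptt(m, m, n);
  NumericVector pred_mean(n), pred_var(n);
  double loglik = 0.0;

  arma::vec a = a1;
  arma::mat P = P1;

  for (int t = 0; t < n; ++t) {
    at.row(t) = a.t();
    Pt.slice(t) = P;

    double mu = arma::as_scalar(Z * a) + offset[t];
    double Fv = arma::as_scalar(Z * P * Z.t()) + H;
    pred_mean[t] = mu;
    pred_var[t] = Fv;

    if (NumericVector::is_na(y[t])) {
      att.row(t) = a.t();
      Ptt.slice(t) = P;
    } else {
      double v = y[t] - mu;
      loglik += -0.5 * (std::log(2.0 * M_PI) + std::log(Fv) + v * v / Fv);
      arma::vec K = P * Z.t() / Fv;
      a = a + K * v;
      P = P - K * (Z * P);
      P = 0.5 * (P + P.t());
      att.row(t) = a.t();
      Ptt.slice(t) = P;
    }

    a = Tmat * a;
    P = Tmat * P * Tmat.t() + Q;
    P = 0.5 * (P + P.t());
  }

  return List::create(_["loglik"] = loglik, _["pred_mean"] = pred_mean,
                      _["pred_var"] = pred_var, _["at"] = at, _["att"] = att,
                      _["Pt"] = Pt, _["Ptt"] = Ptt);
}

static arma::vec draw_mvn(const arma::vec &mu, const arma::mat &Sigma) {
  int m = mu.n_elem;
  arma::vec z(m);
  for (int i = 0; i < m; ++i) z[i] = norm_rand();
  arma::mat S = 0.5 * (Sigma + Sigma.t());
  arma::mat L;
  bool ok = arma::chol(L, S + 1e-12 * arma::eye(m, m), "lower");
  if (!ok) {
    arma::vec eval;
    arma::mat evec;
    arma::eig_sym(eval, evec, S);
    eval.transform([](double v) { return v > 0 ? std::sqrt(v) : 0.0; });
    L = evec * arma::diagmat(eval);
  }
  return mu + L * z;
}

// Forward-filter backward-sample draw of the state sequence.
// [[Rcpp::export]]
arma::mat ffbs_cpp(NumericVector y, NumericVector offset, arma::mat Tmat,
                   arma::rowvec Z, arma::mat Q, double H, arma::vec a1,
                   arma::mat P1) {
  const int n = y.size();
  const int m = a1.n_elem;

  List kf = kalman_filter_cpp(y, offset, Tmat, Z, Q, H, a1, P1);
  arma::mat at = kf["at"], att = kf["att"];
  arma::cube Pt = kf["Pt"], Ptt = kf["Ptt"];

  arma::mat draws(n, m);
  arma::vec a = draw_mvn(att.row(n - 1).t(), Ptt.slice(n - 1));
  draws.row(n - 1) = a.t();

  for (int t = n - 2; t >= 0; --t) {
    // p(a_t | a_{t+1}, y_{1:t})
    arma::mat Ppred = Tmat * Ptt.slice(t) * Tmat.t() + Q; // P_{t+1|t}
    Ppred = 0.5 * (Ppred + Ppred.t());
    arma::vec apred = Tmat * att.row(t).t();
    arma::mat J = Ptt.slice(t) * Tmat.t() *
                  arma::pinv(Ppred + 1e-12 * arma::eye(m, m));
    arma::vec mu = att.row(t).t() + J * (a - apred);
    arma::mat V = Ptt.slice(t) - J * Ppred * J.t();
    a = draw_mvn(mu, V);
    draws.row(t) = a.t();
  }
  return draws;
}
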