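// Kalman filter / RTS smoother core for linear Gaussian state-space models
// with time-varying transition matrices and additive known inputs:
//   x_t = A_t x_{t-1} + a_t + q_t,  q_t ~ N(0, diag(qdiag))
//   y_t = H' x_t + g_t,             g_t ~ N(0, G)
// The t = 1 step uses the prior (mu1, P1) directly (no transition).
// Scalar observations only; that is all the pitch models need. Work
// matrices are preallocated outside the loops (the fits call this tens
// of thousands of times).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export]]
Rcpp::List kalman_core(const arma::vec& y,
                       const arma::cube& A,     // n x n x T (slice 1 unused)
                       const arma::mat& aoff,   // n x T
                       const arma::vec& qdiag,  // n
                       const arma::vec& H,      // n
                       const double G,
                       const arma::vec& mu1,
                       const arma::mat& P1,
                       const bool smooth) {
  const uword T = y.n_elem;
  const uword n = H.n_elem;
  const mat Q = diagmat(qdiag);
  const mat In = eye(n, n);

  mat x_pred(n, T), x_filt(n, T);
  cube P_pred(n, n, T), P_filt(n, n, T);
  vec innov(T), innov_var(T);
  double loglik = 0.0;
  const double log2pi = std::log(2.0 * M_PI);

  vec xp(n), K(n);
  mat Pp(n, n), IKH(n, n), Pf(n, n);

  for (uword t = 0; t < T; ++t) {
    if (t == 0) {
      xp = mu1;
      Pp = P1;
    } else {
      const mat& At = A.slice(t);
      xp = At * x_filt.col(t - 1) + aoff.col(t);
      Pp = At * P_filt.slice(t - 1) * At.t() + Q;
    }
    Pp = 0.5 * (Pp + Pp.t());
    const double S = as_scalar(H.t() * Pp * H) + G;
    if (!std::isfinite(S) || S <= 0.0)
      Rcpp::stop("non-positive innovation variance at t=%d", (int)(t + 1));
    const double v = y(t) - dot(H, xp);
    loglik += -0.5 * (log2pi + std::log(S) + v * v / S);
    K = Pp * H / S;
    x_pred.col(t) = xp;
    P_pred.slice(t) = Pp;
    x_filt.col(t) = xp + K * v;
    // Joseph form for numerical symmetry/PSD
    IKH = In - K * H.t();
    Pf = IKH * Pp * IKH.t() + (K * K.t()) * G;
    P_filt.slice(t) = 0.5 * (Pf + Pf.t());
    innov(t) = v;
    innov_var(t) = S;
  }

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("loglik") = loglik,
      Rcpp::Named("x_pred") = x_pred,
      Rcpp::Named("x_filt") = x_filt,
      Rcpp::Named("P_pred") = P_pred,
      Rcpp::Named("P_filt") = P_filt,
      Rcpp::Named("innov") = innov,
      Rcpp::Named("innov_var") = innov_var);

  if (!smooth) return out;

  // fixed-interval RTS smoother; lag-one covariance from the exact identity
  // Cov(x_t, x_{t-1} | y_{1:T}) = P_s[t] * J_{t-1}'
  mat x_s(n, T);
  cube P_s(n, n, T), V(n, n, T, fill::zeros);
  x_s.col(T - 1) = x_filt.col(T - 1);
  P_s.slice(T - 1) = P_filt.slice(T - 1);
  mat Ppi(n, n), J(n, n), Ps(n, n);
  for (uword t = T - 1; t >= 1; --t) {
    const mat& At = A.slice(t);
    const mat& Ppt = P_pred.slice(t);
    // jitter-regularized inverse for near-singular predicted covariances
    if (!inv_sympd(Ppi, Ppt)) {
      Ppi = inv_sympd(Ppt + 1e-10 * In);
    }
    J = P_filt.slice(t - 1) * At.t() * Ppi;
    x_s.col(t - 1) = x_filt.col(t - 1) + J * (x_s.col(t) - x_pred.col(t));
    Ps = P_filt.slice(t - 1) + J * (P_s.slice(t) - Ppt) * J.t();
    P_s.slice(t - 1) = 0.5 * (Ps + Ps.t());
    V.slice(t) = P_s.slice(t) * J.t();
  }

  out["x_smooth"] = x_s;
  out["P_smooth"] = P_s;
  out["V_lag1"] = V;
  return out;
}

// filter-only log-likelihood without storing per-step arrays; used by the
// direct-likelihood polish where only the scalar objective is needed
// [[Rcpp::export]]
double kalman_loglik(const arma::vec& y,
                     const arma::cube& A,
                     const arma::mat& aoff,
                     const arma::vec& qdiag,
                     const arma::vec& H,
                     const double G,
                     const arma::vec& mu1,
                     const arma::mat& P1) {
  const uword T = y.n_elem;
  const uword n = H.n_elem;
  const mat Q = diagmat(qdiag);
  const mat In = eye(n, n);
  double loglik = 0.0;
  const double log2pi = std::log(2.0 * M_PI);
  vec xf(n), xp(n), K(n), PH(n);
  mat Pf(n, n), Pp(n, n), IKH(n, n);
  for (uword t = 0; t < T; ++t) {
    if (t == 0) {
      xp = mu1;
      Pp = P1;
    } else {
      const mat& At = A.slice(t);
      xp = At * xf + aoff.col(t);
      Pp = At * Pf * At.t() + Q;
      Pp = 0.5 * (Pp + Pp.t());
    }
    PH = Pp * H;
    const double S = dot(H, PH) + G;
    if (!std::isfinite(S) || S <= 0.0)
      Rcpp::stop("non-positive innovation variance at t=%d", (int)(t + 1));
    const double v = y(t) - dot(H, xp);
    loglik += -0.5 * (log2pi + std::log(S) + v * v / S);
    K = PH / S;
    xf = xp + K * v;
    IKH = In - K * H.t();
    Pf = IKH * Pp * IKH.t() + (K * K.t()) * G;
    Pf = 0.5 * (Pf + Pf.t());
  }
  return loglik;
}
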