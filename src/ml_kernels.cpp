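// Compiled kernels for the normal-theory ML fit: discrepancy, analytic
// gradient and Fisher information.  The parameter vector layout is
// [free loadings in mask order, p unique variances]; maskij holds the
// zero-based (row, col) indices of the free loading entries.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static void build_model(const vec& par, const umat& maskij, int p, int m,
                        mat& Lambda, vec& theta, mat& Sigma) {
  Lambda.zeros(p, m);
  const uword q = maskij.n_rows;
  for (uword a = 0; a < q; ++a) Lambda(maskij(a, 0), maskij(a, 1)) = par[a];
  theta = par.subvec(q, q + p - 1);
  Sigma = Lambda * Lambda.t();
  Sigma.diag() += theta;
}

// penalty for a non-positive-definite implied covariance: finite, large,
// increasing in the violation so the line search backs off
static double pd_penalty(const mat& Sigma) {
  vec ev = eig_sym(Sigma);
  double viol = 0.0;
  for (uword i = 0; i < ev.n_elem; ++i) if (ev[i] < 0) viol -= ev[i];
  return 1e10 * (1.0 + viol);
}

// [[Rcpp::export(name = ".fml_obj_cpp")]]
double fml_obj_cpp(const arma::vec& par, const arma::mat& S, double ldS,
                   const arma::umat& maskij, int m) {
  const int p = S.n_rows;
  mat Lambda, Sigma;
  vec theta;
  build_model(par, maskij, p, m, Lambda, theta, Sigma);
  mat R;
  if (!chol(R, Sigma)) return pd_penalty(Sigma);
  double ldSigma = 2.0 * accu(log(R.diag()));
  mat SigInv = inv_sympd(Sigma);
  return ldSigma - ldS + accu(S % SigInv) - p;
}

// [[Rcpp::export(name = ".fml_grad_cpp")]]
arma::vec fml_grad_cpp(const arma::vec& par, const arma::mat& S, double ldS,
                       const arma::umat& maskij, int m) {
  const int p = S.n_rows;
  mat Lambda, Sigma;
  vec theta;
  build_model(par, maskij, p, m, Lambda, theta, Sigma);
  mat SigInv;
  if (!inv_sympd(SigInv, Sigma)) {
    // requested at a non-PD point (rare): ridge the matrix for a usable
    // descent-ish direction
    vec ev = eig_sym(Sigma);
    Sigma.diag() += std::abs(ev.min()) + 1e-4;
    SigInv = inv_sympd(Sigma);
  }
  mat A = SigInv - SigInv * S * SigInv;
  mat gL = 2.0 * (A * Lambda);
  const uword q = maskij.n_rows;
  vec g(q + p);
  for (uword a = 0; a < q; ++a) g[a] = gL(maskij(a, 0), maskij(a, 1));
  for (int i = 0; i < p; ++i) g[q + i] = A(i, i);
  return g;
}

// Fisher information of the ML discrepancy, 0.5 tr(SigInv dS_a SigInv dS_b),
// in closed form: with B = SigInv * Lambda and C = Lambda' * SigInv * Lambda,
//   loading x loading : B(j,k) B(i,l) + SigInv(i,j) C(k,l)
//   loading x theta_j : SigInv(i,j) B(j,k)
//   theta_i x theta_j : 0.5 SigInv(i,j)^2
// [[Rcpp::export(name = ".fisher_info_cpp")]]
arma::mat fisher_info_cpp(const arma::vec& par, const arma::umat& maskij,
                          int p, int m) {
  mat Lambda, Sigma;
  vec theta;
  build_model(par, maskij, p, m, Lambda, theta, Sigma);
  mat SigInv;
  if (!inv_sympd(SigInv, Sigma)) {
    vec ev = eig_sym(Sigma);
    Sigma.diag() += std::abs(ev.min()) + 1e-4;
    SigInv = inv_sympd(Sigma);
  }
  mat B = SigInv * Lambda;
  mat C = Lambda.t() * B;
  const uword q = maskij.n_rows;
  mat info(q + p, q + p);
  for (uword a = 0; a < q; ++a) {
    const uword i = maskij(a, 0), k = maskij(a, 1);
    for (uword b = a; b < q; ++b) {
      const uword j = maskij(b, 0), l = maskij(b, 1);
      double v = B(j, k) * B(i, l) + SigInv(i, j) * C(k, l);
      info(a, b) = v;
      info(b, a) = v;
    }
    for (int j = 0; j < p; ++j) {
      double v = SigInv(i, j) * B(j, k);
      info(a, q + j) = v;
      info(q + j, a) = v;
    }
  }
  for (int i = 0; i < p; ++i)
    for (int j = i; j < p; ++j) {
      double v = 0.5 * SigInv(i, j) * SigInv(i, j);
      info(q + i, q + j) = v;
      info(q + j, q + i) = v;
    }
  return info;
}
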