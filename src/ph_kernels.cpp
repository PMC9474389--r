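#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Density alpha e^{Qt} q and survival alpha e^{Qt} 1 of a phase-type
// distribution, evaluated at each t.  expmat() uses scaling-and-squaring
// with a Pade approximant, which stays stable when the sub-generator has
// repeated eigenvalues (common for Coxian chains), so no spectral shortcut
// is taken.
// [[Rcpp::export]]
List ph_phi_cpp(const arma::mat& Q, const arma::vec& q,
                const arma::rowvec& alpha, const arma::vec& t) {
  const arma::uword m = t.n_elem;
  arma::vec dens(m), surv(m);
  for (arma::uword i = 0; i < m; ++i) {
    arma::mat E = arma::expmat(Q * t(i));
    arma::rowvec v = alpha * E;
    dens(i) = arma::dot(v.t(), q);
    surv(i) = arma::accu(v);
  }
  return List::create(_["dens"] = dens, _["surv"] = surv);
}

// Pure-birth PH tree log-likelihood: density terms for internal branches,
// survival terms for pendant branches.  Returns -Inf when any term falls
// below the survival floor instead of propagating NaN.
// [[Rcpp::export]]
double ph_tree_loglik_cpp(const arma::mat& Q, const arma::vec& q,
                          const arma::rowvec& alpha,
                          const arma::vec& internal_b,
                          const arma::vec& pendant_b,
                          const double floor_val) {
  double ll = 0.0;
  for (arma::uword i = 0; i < internal_b.n_elem; ++i) {
    arma::rowvec v = alpha * arma::expmat(Q * internal_b(i));
    double d = arma::dot(v.t(), q);
    if (!(d > floor_val)) return R_NegInf;
    ll += std::log(d);
  }
  for (arma::uword j = 0; j < pendant_b.n_elem; ++j) {
    arma::rowvec v = alpha * arma::expmat(Q * pendant_b(j));
    double s = arma::accu(v);
    if (!(s > floor_val)) return R_NegInf;
    ll += std::log(s);
  }
  return ll;
}
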