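// Inner loop of the electronic-coefficient propagation: piecewise-exact
// unitary evolution under a linearly interpolated real-symmetric Hamiltonian.
// Each substep applies exp(-i H(s_m) dtau) built from the eigendecomposition
// of the midpoint Hamiltonian, so every substep is unitary to machine
// precision regardless of the substep count.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export]]
arma::cx_vec cpp_interp_propagate(const arma::cx_vec& c0,
                                  const arma::mat& H0,
                                  const arma::mat& H1,
                                  const double dt,
                                  const int n_substeps) {
  const double dtau = dt / n_substeps;
  arma::cx_vec c = c0;
  arma::vec eval;
  arma::mat evec;
  for (int m = 0; m < n_substeps; ++m) {
    const double s = (m + 0.5) / n_substeps;  // midpoint interpolation
    arma::mat H = (1.0 - s) * H0 + s * H1;
    arma::eig_sym(eval, evec, H);
    arma::cx_vec phases = arma::exp(arma::cx_vec(arma::zeros(eval.n_elem),
                                                 -eval * dtau));
    c = evec * (phases % (evec.t() * c));
  }
  return c;
}
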