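#include <Rcpp.h>
using namespace Rcpp;

// Mass-action derivative: dy = S * v, v_j = k_j * prod over reactant indices
// of y[idx]. Reactant indices are flattened (0-based) with an offsets vector
// of length n_reactions + 1. Zeroth-order reactions (no reactants) fire at
// constant rate k_j.
// [[Rcpp::export]]
NumericVector mass_action_deriv_cpp(NumericVector y, NumericVector k,
                                    IntegerVector reactant_idx,
                                    IntegerVector offsets,
                                    NumericMatrix S) {
  int n_sp = S.nrow();
  int n_rx = S.ncol();
  NumericVector dy(n_sp);
  for (int j = 0; j < n_rx; ++j) {
    double v = k[j];
    for (int p = offsets[j]; p < offsets[j + 1]; ++p) {
      v *= y[reactant_idx[p]];
    }
    if (v != 0.0) {
      for (int i = 0; i < n_sp; ++i) {
        double s = S(i, j);
        if (s != 0.0) dy[i] += s * v;
      }
    }
  }
  return dy;
}
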