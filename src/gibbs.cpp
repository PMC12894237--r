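#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double plogis_fast(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// Gibbs sampler for the {0,1} Ising model
//   P(x) propto exp( sum_i tau_i x_i + sum_{i<j} w_ij x_i x_j )
// with conditional P(x_i = 1 | x_{-i}) = plogis(tau_i + sum_j w_ij x_j).
//
// chains = "independent": one chain per row; each row starts from
// independent Bernoulli(plogis(tau_i)) draws, runs `burn_in` fixed-order
// sweeps and retains the final state (rows are i.i.d. persons).
// chains = "single": one long chain; `burn_in` sweeps, then one row
// retained every `thin` sweeps.
//
// The local field h = W x is maintained incrementally: a node update costs
// O(1) and a state flip O(p). Uses R's RNG, so set.seed() applies.
//
// [[Rcpp::export(name = ".gibbs_ising")]]
IntegerMatrix gibbs_ising(const arma::mat& W, const arma::vec& tau,
                          int n, int burn_in, int thin, bool independent) {
  const int p = tau.n_elem;
  IntegerMatrix out(n, p);
  RNGScope scope;

  arma::vec x(p), h(p);
  auto init_chain = [&]() {
    for (int i = 0; i < p; ++i) x[i] = (unif_rand() < plogis_fast(tau[i])) ? 1.0 : 0.0;
    h = W * x;
  };
  auto sweep = [&]() {
    for (int i = 0; i < p; ++i) {
      double pr = plogis_fast(tau[i] + h[i]);
      double xn = (unif_rand() < pr) ? 1.0 : 0.0;
      double d = xn - x[i];
      if (d != 0.0) {
        x[i] = xn;
        h += d * W.col(i);
      }
    }
  };

  if (independent) {
    for (int r = 0; r < n; ++r) {
      init_chain();
      for (int s = 0; s < burn_in; ++s) sweep();
      for (int i = 0; i < p; ++i) out(r, i) = (int)x[i];
    }
  } else {
    init_chain();
    for (int s = 0; s < burn_in; ++s) sweep();
    for (int r = 0; r < n; ++r) {
      for (int s = 0; s < thin; ++s) sweep();
      for (int i = 0; i < p; ++i) out(r, i) = (int)x[i];
    }
  }
  return out;
}
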