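#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Log-Euler forward simulation of the module-structured gLV system at
// taxon level. States are clamped below at lfloor and capped at lcap
// (cap hits flag the trajectory divergent instead of erroring).
// [[Rcpp::export]]
List cpp_glv_simulate(arma::vec logx0, arma::vec growth, arma::mat A,
                      arma::mat pert_taxa, arma::mat H, double dt,
                      double sigma_w2, double lfloor, double lcap,
                      IntegerVector out_idx) {
  int n = logx0.n_elem;
  int nsteps = H.n_cols;
  arma::mat out(n, out_idx.size());
  arma::vec logx = arma::clamp(logx0, lfloor, lcap);
  bool divergent = false;
  double sd = (sigma_w2 > 0) ? std::sqrt(dt * sigma_w2) : 0.0;

  std::vector< std::vector<int> > lookup(nsteps);
  for (int j = 0; j < out_idx.size(); j++) lookup[out_idx[j]].push_back(j);

  arma::vec x = arma::exp(logx);
  for (int k = 0; k < nsteps; k++) {
    for (size_t u = 0; u < lookup[k].size(); u++) out.col(lookup[k][u]) = x;
    if (k == nsteps - 1) break;
    arma::vec gmod = growth % (1.0 + pert_taxa.t() * H.col(k));
    arma::vec dl = dt * (gmod + A * x);
    if (sd > 0) for (int i = 0; i < n; i++) dl[i] += R::rnorm(0.0, sd);
    logx += dl;
    for (int i = 0; i < n; i++) {
      if (!std::isfinite(logx[i]) || logx[i] > lcap) {
        logx[i] = lcap; divergent = true;
      }
      if (logx[i] < lfloor) logx[i] = lfloor;
    }
    x = arma::exp(logx);
  }
  return List::create(_["x"] = out, _["divergent"] = divergent);
}
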