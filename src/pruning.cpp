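// Felsenstein pruning over a fixed tree for a 61-state codon process.
// One call evaluates per-site log-likelihoods for a single site class,
// i.e. a single assignment of transition matrices to edges.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// tipstate: ntip x nsite integer matrix, 0-based codon states, -1 = missing.
// edge:     nedge x 2 (parent, child), 1-based ape node ids, postorder.
// P:        61 x 61 x nedge cube of edge transition matrices (rows = from).
// pi:       stationary codon frequencies (length 61).
// nnode:    total number of nodes (tips + internals); root: 1-based root id.
// [[Rcpp::export]]
arma::vec prune_loglik_cpp(const arma::imat& tipstate,
                           const arma::imat& edge,
                           const arma::cube& P,
                           const arma::vec& pi,
                           const int nnode,
                           const int root) {
  const int ntip  = tipstate.n_rows;
  const int nsite = tipstate.n_cols;
  const int nedge = edge.n_rows;
  const int ns    = P.n_rows;

  cube L(ns, nsite, nnode, fill::none);
  vec logscale(nsite, fill::zeros);
  std::vector<bool> init(nnode, false);

  for (int e = 0; e < nedge; ++e) {
    const int par = edge(e, 0) - 1;
    const int chl = edge(e, 1) - 1;
    mat msg(ns, nsite);
    if (chl < ntip) {
      for (int s = 0; s < nsite; ++s) {
        const int st = tipstate(chl, s);
        if (st < 0) {
          msg.col(s).ones();
        } else {
          msg.col(s) = P.slice(e).col(st);
        }
      }
    } else {
      // rescale the child's partials before propagating
      mat& Lc = L.slice(chl);
      rowvec mx = max(Lc, 0);
      for (int s = 0; s < nsite; ++s) {
        double m = mx(s);
        if (m > 0 && (m < 1e-32 || m > 1e32)) {
          Lc.col(s) /= m;
          logscale(s) += std::log(m);
        }
      }
      msg = P.slice(e) * Lc;
    }
    if (!init[par]) {
      L.slice(par) = msg;
      init[par] = true;
    } else {
      L.slice(par) %= msg;
    }
  }

  vec out(nsite);
  const mat& Lr = L.slice(root - 1);
  for (int s = 0; s < nsite; ++s)
    out(s) = std::log(dot(pi, Lr.col(s))) + logscale(s);
  return out;
}
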