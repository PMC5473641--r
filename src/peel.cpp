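#include <Rcpp.h>
using namespace Rcpp;

// Felsenstein pruning over a set of site patterns.
//
// edge:   Nedge x 2 integer matrix (parent, child), 1-based ape node ids,
//         in postorder (every child edge appears before its parent's edge).
// pmat:   4 x (4*Nedge) matrix; columns 4*(e-1)+1 .. 4*e hold P_e, the
//         transition probability matrix for edge e (row = parent state,
//         col = child state).
// tips:   Ntip x Npat integer matrix of leaf states, codes 0..3 = A,C,G,T,
//         -1 = missing (gap or N, marginalised).
// pi:     equilibrium frequencies at the root (length 4).
// nnode:  total number of nodes (tips + internals).
// root:   1-based id of the root node.
//
// Returns log-likelihood per pattern (natural log); -Inf where the pattern
// has probability zero under the model.
// [[Rcpp::export]]
NumericVector peel_loglik_cpp(IntegerMatrix edge, NumericMatrix pmat,
                              IntegerMatrix tips, NumericVector pi,
                              int nnode, int root) {
  const int nedge = edge.nrow();
  const int ntip = tips.nrow();
  const int npat = tips.ncol();
  NumericVector out(npat);
  std::vector<double> L(4 * nnode);

  for (int p = 0; p < npat; ++p) {
    // initialise partials: internals to 1, leaves to indicator/missing
    for (int n = 0; n < nnode; ++n) {
      double v = (n < ntip) ? 0.0 : 1.0;
      L[4 * n] = v; L[4 * n + 1] = v; L[4 * n + 2] = v; L[4 * n + 3] = v;
    }
    for (int t = 0; t < ntip; ++t) {
      int s = tips(t, p);
      if (s < 0) {
        L[4 * t] = L[4 * t + 1] = L[4 * t + 2] = L[4 * t + 3] = 1.0;
      } else {
        L[4 * t + s] = 1.0;
      }
    }
    double logscale = 0.0;
    bool dead = false;
    for (int e = 0; e < nedge && !dead; ++e) {
      int par = edge(e, 0) - 1;
      int chl = edge(e, 1) - 1;
      double v[4];
      double m = 0.0;
      for (int i = 0; i < 4; ++i) {
        double s = 0.0;
        for (int j = 0; j < 4; ++j)
          s += pmat(i, 4 * e + j) * L[4 * chl + j];
        v[i] = s;
        if (s > m) m = s;
      }
      if (m <= 0.0) { dead = true; break; }
      logscale += std::log(m);
      for (int i = 0; i < 4; ++i)
        L[4 * par + i] *= v[i] / m;
    }
    if (dead) {
      out[p] = R_NegInf;
      continue;
    }
    double s = 0.0;
    for (int i = 0; i < 4; ++i)
      s += pi[i] * L[4 * (root - 1) + i];
    out[p] = (s > 0.0) ? std::log(s) + logscale : R_NegInf;
  }
  return out;
}

// Same peel, but builds the per-edge transition matrices internally from
// the model's cached eigendecomposition (P_e = V diag(exp(lambda*len_e))
// Vinv), avoiding per-evaluation matrix construction in R. `V` and `Vinv`
// are 4x4; `evals` length 4; `lens` length Nedge.
// [[Rcpp::export]]
NumericVector peel_loglik_eig_cpp(IntegerMatrix edge, NumericMatrix V,
                                  NumericMatrix Vinv, NumericVector evals,
                                  NumericVector lens, IntegerMatrix tips,
                                  NumericVector pi, int nnode, int root) {
  const int nedge = edge.nrow();
  NumericMatrix pmat(4, 4 * nedge);
  for (int e = 0; e < nedge; ++e) {
    if (lens[e] == 0.0) {  // exact identity at zero length
      for (int i = 0; i < 4; ++i)
        for (int j = 0; j < 4; ++j)
          pmat(i, 4 * e + j) = (i == j) ? 1.0 : 0.0;
      continue;
    }
    double ex[4];
    for (int k = 0; k < 4; ++k) ex[k] = std::exp(evals[k] * lens[e]);
    for (int i = 0; i < 4; ++i) {
      for (int j = 0; j < 4; ++j) {
        double s = 0.0;
        for (int k = 0; k < 4; ++k) s += V(i, k) * ex[k] * Vinv(k, j);
        pmat(i, 4 * e + j) = (s > 0.0) ? s : 0.0;
      }
    }
  }
  return peel_loglik_cpp(edge, pmat, tips, pi, nnode, root);
}
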