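// Generic Felsenstein pruning over precomputed transition matrices
// (any state count) and the RELL resampling inner loop.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// patt: ntip x npat (1-based states, 0 = missing)
// edge: ne x 2 (1-based node ids, postorder), P: list of k x k matrices
// [[Rcpp::export]]
NumericVector cpp_prune(IntegerMatrix patt, IntegerMatrix edge, List P,
                        int ntip, NumericVector pi_) {
  const int npat = patt.ncol(), ne = edge.nrow(), k = pi_.size();
  arma::vec pi(pi_.begin(), k);
  int nnode = 0;
  for (int e = 0; e < ne; ++e)
    nnode = std::max(nnode, std::max(edge(e, 0), edge(e, 1)));
  std::vector<arma::mat> Pm(ne);
  for (int e = 0; e < ne; ++e) {
    NumericMatrix M = P[e];
    Pm[e] = arma::mat(M.begin(), k, k);
  }
  std::vector<arma::mat> L(nnode + 1);
  std::vector<arma::rowvec> lsc(nnode + 1);
  for (int e = 0; e < ne; ++e) {
    int par = edge(e, 0), ch = edge(e, 1);
    arma::mat contrib(k, npat);
    if (ch <= ntip) {
      for (int p = 0; p < npat; ++p) {
        int st = patt(ch - 1, p);
        if (st > 0) contrib.col(p) = Pm[e].col(st - 1);
        else contrib.col(p).ones();
      }
    } else {
      contrib = Pm[e] * L[ch];
    }
    if (L[par].n_elem == 0) {
      L[par] = contrib;
      lsc[par] = arma::rowvec(npat, arma::fill::zeros);
    } else {
      L[par] %= contrib;
    }
    if (ch > ntip) lsc[par] += lsc[ch];
    arma::rowvec mx = arma::max(L[par], 0);
    mx(arma::find(mx <= 0)).ones();
    L[par].each_row() /= mx;
    lsc[par] += arma::log(mx);
  }
  int root = ntip + 1;
  arma::rowvec lik = pi.t() * L[root];
  lik.clamp(1e-300, arma::datum::inf);
  arma::rowvec res = arma::log(lik) + lsc[root];
  return NumericVector(res.begin(), res.end());
}

// RELL resampling: per scale, B resampled per-topology totals; returns
// win counts per (scale, topology) and the resampled totals at the
// reference scale (for KH/SH).  Uses R's RNG.
// [[Rcpp::export]]
List cpp_rell(NumericMatrix L, int B, NumericVector scales, int ref_scale) {
  const int n = L.nrow(), T = L.ncol(), S = scales.size();
  IntegerMatrix wins(S, T);
  NumericMatrix S1(B, T);
  std::vector<double> tot(T);
  RNGScope scope;
  for (int s = 0; s < S; ++s) {
    int np = std::max(2, (int)std::lround(scales[s] * n));
    for (int b = 0; b < B; ++b) {
      std::fill(tot.begin(), tot.end(), 0.0);
      for (int d = 0; d < np; ++d) {
        int idx = (int)(unif_rand() * n);
        if (idx >= n) idx = n - 1;
        for (int t = 0; t < T; ++t) tot[t] += L(idx, t);
      }
      int w = 0;
      double bestv = tot[0];
      int nties = 1;
      for (int t = 1; t < T; ++t) {
        if (tot[t] > bestv) { bestv = tot[t]; w = t; nties = 1; }
        else if (tot[t] == bestv) {
          ++nties;
          if (unif_rand() < 1.0 / nties) w = t;  // uniform tie-break
        }
      }
      wins(s, w) += 1;
      if (s == ref_scale - 1)
        for (int t = 0; t < T; ++t) S1(b, t) = tot[t];
    }
  }
  return List::create(_["wins"] = wins, _["S1"] = S1);
}
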