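// Codon-model likelihood kernel: GY94 rate-matrix construction, spectral
// transition probabilities and Felsenstein pruning over the 61 sense
// codons, for one or several omega categories in a single call.

#include <RcppArmadillo.h>
#include <map>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat gy94_Q(const IntegerMatrix& pairs, double kappa,
                        double omega, const arma::vec& pi) {
  arma::mat Q(61, 61, arma::fill::zeros);
  for (int r = 0; r < pairs.nrow(); ++r) {
    int i = pairs(r, 0) - 1, j = pairs(r, 1) - 1;
    double rate = (pairs(r, 2) ? kappa : 1.0) * (pairs(r, 3) ? 1.0 : omega);
    Q(i, j) = rate * pi(j);
    Q(j, i) = rate * pi(i);
  }
  Q.diag() = -arma::sum(Q, 1);
  double mu = -arma::dot(pi, Q.diag());
  if (mu > 0) Q /= mu;
  return Q;
}

struct Eig { arma::vec val; arma::mat A; arma::mat Bt; };

static Eig eig_rev(const arma::mat& Q, const arma::vec& sp) {
  arma::mat B = Q;
  B.each_col() %= sp;
  B.each_row() /= sp.t();
  B = (B + B.t()) / 2.0;
  Eig e;
  arma::mat vec;
  arma::eig_sym(e.val, vec, B);
  e.A = vec;  e.A.each_col() /= sp;    // D^-1/2 V
  e.Bt = vec; e.Bt.each_col() %= sp;   // D^1/2 V
  return e;
}

static arma::mat pmat_from(const Eig& e, const arma::vec& sp, double t) {
  arma::mat P = (e.A * arma::diagmat(arma::exp(e.val * t))) * e.Bt.t();
  P.clamp(0.0, arma::datum::inf);
  return P;
}

// [[Rcpp::export]]
NumericMatrix cpp_gy94_pmat(IntegerMatrix pairs, double kappa, double omega,
                            NumericVector pi_, double t) {
  arma::vec pi(pi_.begin(), 61);
  arma::vec sp = arma::sqrt(pi);
  Eig e = eig_rev(gy94_Q(pairs, kappa, omega, pi), sp);
  arma::mat P = pmat_from(e, sp, t);
  return wrap(P);
}

// Per-pattern log-likelihood for K omega categories.
// patt: ntip x npat (1-based codon states, 0 = missing)
// edge: ne x 2 (1-based node ids, rows in postorder: children first)
// edge_omega: ne x K
// cache: optional R environment memoizing eigendecompositions by omega
// (valid while kappa and pi are unchanged; numeric-gradient steps of an
// optimizer re-use most category omegas between evaluations)
// [[Rcpp::export]]
NumericMatrix cpp_codon_lnl(IntegerMatrix patt, IntegerMatrix edge,
                            NumericVector tlen, int ntip,
                            IntegerMatrix pairs, double kappa,
                            NumericVector pi_, NumericMatrix edge_omega,
                            Nullable<Environment> cache = R_NilValue) {
  const int npat = patt.ncol(), ne = edge.nrow(), K = edge_omega.ncol();
  arma::vec pi(pi_.begin(), 61);
  arma::vec sp = arma::sqrt(pi);
  int nnode = 0;
  for (int e = 0; e < ne; ++e)
    nnode = std::max(nnode, std::max(edge(e, 0), edge(e, 1)));
  bool use_cache = cache.isNotNull();
  Environment env = use_cache ? Environment(cache) : Environment::empty_env();
  // eigendecomposition per distinct omega
  std::map<double, int> omap;
  std::vector<Eig> eigs;
  char key[40];
  for (int k = 0; k < K; ++k)
    for (int e = 0; e < ne; ++e) {
      double w = edge_omega(e, k);
      if (omap.find(w) == omap.end()) {
        omap[w] = (int)eigs.size();
        bool hit = false;
        if (use_cache) {
          snprintf(key, sizeof(key), "w%.17g", w);
          if (env.exists(key)) {
            List l = env[key];
            Eig eg;
            NumericVector v = l[0];
            NumericMatrix A = l[1], Bt = l[2];
            eg.val = arma::vec(v.begin(), 61);
            eg.A = arma::mat(A.begin(), 61, 61);
            eg.Bt = arma::mat(Bt.begin(), 61, 61);
            eigs.push_back(eg);
            hit = true;
          }
        }
        if (!hit) {
          eigs.push_back(eig_rev(gy94_Q(pairs, kappa, w, pi), sp));
          if (use_cache) {
            const Eig& eg = eigs.back();
            env[key] = List::create(
              NumericVector(eg.val.begin(), eg.val.end()),
              NumericMatrix(61, 61, eg.A.begin()),
              NumericMatrix(61, 61, eg.Bt.begin()));
          }
        }
      }
    }
  NumericMatrix out(npat, K);
  for (int k = 0; k < K; ++k) {
    std::vector<arma::mat> P(ne);
    for (int e = 0; e < ne; ++e)
      P[e] = pmat_from(eigs[omap[edge_omega(e, k)]], sp, tlen[e]);
    std::vector<arma::mat> L(nnode + 1);
    std::vector<arma::rowvec> lsc(nnode + 1);
    for (int e = 0; e < ne; ++e) {
      int par = edge(e, 0), ch = edge(e, 1);
      arma::mat contrib(61, npat);
      if (ch <= ntip) {
        for (int p = 0; p < npat; ++p) {
          int st = patt(ch - 1, p);
          if (st > 0) contrib.col(p) = P[e].col(st - 1);
          else contrib.col(p).ones();
        }
      } else {
        contrib = P[e] * L[ch];
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
    for (int p = 0; p < npat; ++p) out(p, k) = res(p);
  }
  return out;
}
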