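#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Abundance-weighted beta mean nearest taxon distance (betaMNTD) between
// sample columns of a relative-abundance matrix P (taxa x samples), with
// patristic distances D (taxa x taxa).  A permutation `perm` relabels taxa
// onto tree positions (taxa-shuffle null); abundances stay with the taxa.
//
// For each sample s and taxon i we need m_s[i] = min_{j present in s}
// D(perm[i], perm[j]).  Precomputing m per sample makes the all-pairs pass
// O(S*T*n + pairs*T) per permutation instead of O(pairs * n_a * n_b).

static void nearest_taxon_mins(const NumericMatrix& D,
                               const std::vector< std::vector<int> >& pres,
                               const IntegerVector& perm,
                               NumericMatrix& M) {
  const int T = D.nrow();
  const int S = pres.size();
  for (int s = 0; s < S; ++s) {
    const std::vector<int>& idx = pres[s];
    for (int i = 0; i < T; ++i) {
      double m = R_PosInf;
      const int pi = perm[i];
      for (size_t v = 0; v < idx.size(); ++v) {
        const double d = D(pi, perm[idx[v]]);
        if (d < m) m = d;
      }
      M(i, s) = m;
    }
  }
}

static void presence_lists(const NumericMatrix& P,
                           std::vector< std::vector<int> >& pres) {
  const int T = P.nrow(), S = P.ncol();
  pres.assign(S, std::vector<int>());
  for (int s = 0; s < S; ++s)
    for (int i = 0; i < T; ++i)
      if (P(i, s) > 0.0) pres[s].push_back(i);
}

static double pair_bmntd(const NumericMatrix& P, const NumericMatrix& M,
                         const std::vector<int>& ia, const std::vector<int>& ib,
                         int a, int b) {
  double acc = 0.0;
  for (size_t u = 0; u < ia.size(); ++u)
    acc += 0.5 * P(ia[u], a) * M(ia[u], b);
  for (size_t v = 0; v < ib.size(); ++v)
    acc += 0.5 * P(ib[v], b) * M(ib[v], a);
  return acc;
}

// Observed betaMNTD for every sample pair; returns S x S symmetric matrix.
// [[Rcpp::export]]
NumericMatrix cpp_bmntd_all(NumericMatrix D, NumericMatrix P) {
  const int T = P.nrow(), S = P.ncol();
  if (D.nrow() != T || D.ncol() != T)
    stop("distance matrix dimension does not match taxon count");
  std::vector< std::vector<int> > pres;
  presence_lists(P, pres);
  IntegerVector id(T);
  for (int i = 0; i < T; ++i) id[i] = i;
  NumericMatrix M(T, S);
  nearest_taxon_mins(D, pres, id, M);
  NumericMatrix out(S, S);
  for (int b = 1; b < S; ++b)
    for (int a = 0; a < b; ++a) {
      const double v = pair_bmntd(P, M, pres[a], pres[b], a, b);
      out(a, b) = v;
      out(b, a) = v;
    }
  return out;
}

// Null betaMNTD under taxa-shuffle permutations.  `perms` is reps x T with
// 0-based indices.  Returns reps x npairs; pairs ordered column-wise over
// the upper triangle: (1,2), (1,3), (2,3), (1,4), ... matching
// which(upper.tri(x)) ordering in R.
// [[Rcpp::export]]
NumericMatrix cpp_bmntd_null(NumericMatrix D, NumericMatrix P, IntegerMatrix perms) {
  const int T = P.nrow(), S = P.ncol();
  const int reps = perms.nrow();
  if (perms.ncol() != T) stop("permutation width does not match taxon count");
  std::vector< std::vector<int> > pres;
  presence_lists(P, pres);
  const int npairs = S * (S - 1) / 2;
  NumericMatrix out(reps, npairs);
  NumericMatrix M(T, S);
  for (int r = 0; r < reps; ++r) {
    IntegerVector perm = perms(r, _);
    nearest_taxon_mins(D, pres, perm, M);
    int k = 0;
    for (int b = 1; b < S; ++b)
      for (int a = 0; a < b; ++a)
        out(r, k++) = pair_bmntd(P, M, pres[a], pres[b], a, b);
    Rcpp::checkUserInterrupt();
  }
  return out;
}
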