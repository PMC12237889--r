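#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// One probabilistically assembled null community: draw `richness` distinct
// taxa with probability proportional to occurrence weight (weighted sampling
// without replacement via smallest Exp(w) keys), seed each with one
// individual, then fill to `total` individuals with probability proportional
// to regional relative abundance of the drawn taxa (sequential binomials).
static void draw_null(const NumericVector& occ_w, const NumericVector& ab_w,
                      int richness, int total,
                      std::vector<double>& x, std::vector<int>& sel) {
  const int T = occ_w.size();
  std::vector< std::pair<double, int> > keys;
  keys.reserve(T);
  for (int i = 0; i < T; ++i)
    if (occ_w[i] > 0.0)
      keys.push_back(std::make_pair(R::exp_rand() / occ_w[i], i));
  int r = std::min<int>(richness, (int) keys.size());
  std::partial_sort(keys.begin(), keys.begin() + r, keys.end());
  sel.clear();
  double psum = 0.0;
  for (int k = 0; k < r; ++k) {
    sel.push_back(keys[k].second);
    psum += ab_w[keys[k].second];
  }
  for (size_t u = 0; u < sel.size(); ++u) x[sel[u]] = 1.0;
  int remaining = total - r;
  for (size_t u = 0; u + 1 < sel.size() && remaining > 0 && psum > 0; ++u) {
    double p = ab_w[sel[u]] / psum;
    if (p > 1.0) p = 1.0;
    int c = (int) R::rbinom((double) remaining, p);
    x[sel[u]] += c;
    remaining -= c;
    psum -= ab_w[sel[u]];
  }
  if (!sel.empty() && remaining > 0) x[sel.back()] += remaining;
}

// Null Bray-Curtis distribution for one sample pair: `reps` pairs of null
// communities with the pair's observed richnesses and totals, Bray-Curtis
// on relative abundances.  Uses R's RNG, so set.seed() upstream controls it.
// [[Rcpp::export]]
NumericVector cpp_rc_null_bc(NumericVector occ_w, NumericVector ab_w,
                             int rich1, int tot1, int rich2, int tot2,
                             int reps) {
  const int T = occ_w.size();
  NumericVector out(reps);
  std::vector<double> x1(T, 0.0), x2(T, 0.0);
  std::vector<int> sel1, sel2;
  for (int r = 0; r < reps; ++r) {
    draw_null(occ_w, ab_w, rich1, tot1, x1, sel1);
    draw_null(occ_w, ab_w, rich2, tot2, x2, sel2);
    double num = 0.0;
    for (size_t u = 0; u < sel1.size(); ++u) {
      const int i = sel1[u];
      num += std::fabs(x1[i] / tot1 - x2[i] / tot2);
      x1[i] = -x1[i];  // mark visited
    }
    for (size_t v = 0; v < sel2.size(); ++v) {
      const int i = sel2[v];
      if (x1[i] >= 0.0) num += x2[i] / tot2;
    }
    out[r] = num / 2.0;
    for (size_t u = 0; u < sel1.size(); ++u) x1[sel1[u]] = 0.0;
    for (size_t v = 0; v < sel2.size(); ++v) x2[sel2[v]] = 0.0;
    if (r % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
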