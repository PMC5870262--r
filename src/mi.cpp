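// Pairwise normalized mutual information over a list of candidate
// variable pairs (pairwise-complete observations).  Values are small
// non-negative integers; -1 marks missing.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector cpp_pairwise_nmi(const IntegerMatrix &X,
                               const IntegerVector &ii,
                               const IntegerVector &jj,
                               const IntegerVector &levels) {
  int m = ii.size();
  int n = X.nrow();
  NumericVector out(m);
  for (int p = 0; p < m; ++p) {
    int a = ii[p] - 1, b = jj[p] - 1;
    int la = levels[a], lb = levels[b];
    std::vector<double> joint(la * lb, 0.0);
    double tot = 0.0;
    for (int i = 0; i < n; ++i) {
      int va = X(i, a), vb = X(i, b);
      if (va < 0 || vb < 0) continue;
      joint[va * lb + vb] += 1.0;
      tot += 1.0;
    }
    if (tot == 0) { out[p] = NA_REAL; continue; }
    std::vector<double> pa(la, 0.0), pb(lb, 0.0);
    for (int va = 0; va < la; ++va)
      for (int vb = 0; vb < lb; ++vb) {
        pa[va] += joint[va * lb + vb];
        pb[vb] += joint[va * lb + vb];
      }
    double ha = 0.0, hb = 0.0, mi = 0.0;
    for (int va = 0; va < la; ++va)
      if (pa[va] > 0) ha -= pa[va] / tot * std::log2(pa[va] / tot);
    for (int vb = 0; vb < lb; ++vb)
      if (pb[vb] > 0) hb -= pb[vb] / tot * std::log2(pb[vb] / tot);
    if (ha == 0.0 || hb == 0.0) { out[p] = NA_REAL; continue; }
    for (int va = 0; va < la; ++va)
      for (int vb = 0; vb < lb; ++vb) {
        double pj = joint[va * lb + vb] / tot;
        if (pj > 0)
          mi += pj * std::log2(pj / ((pa[va] / tot) * (pb[vb] / tot)));
      }
    double v = mi / std::max(ha, hb);
    out[p] = v < 0 ? 0.0 : (v > 1 ? 1.0 : v);
  }
  return out;
}
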