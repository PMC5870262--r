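// EM for a latent class model: one discrete latent variable with
// conditionally independent discrete children; missing child values are
// marginalized out of the E-step.  Log-space throughout.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// One EM run from a random start (R RNG).  X: n x d integer matrix with
// values 0..levels[j]-1 and -1 for missing.
// [[Rcpp::export]]
List cpp_lcm_em_once(const IntegerMatrix &X, const IntegerVector &levels,
                     int card, double tol, int max_iter) {
  int n = X.nrow(), d = X.ncol();
  if (card < 2) stop("latent cardinality must be >= 2");
  if (n < 1) stop("no observations");

  // random initialization: Dirichlet(1) via exponential draws
  std::vector<double> prior(card);
  double s = 0.0;
  for (int c = 0; c < card; ++c) { prior[c] = -std::log(unif_rand()); s += prior[c]; }
  for (int c = 0; c < card; ++c) prior[c] /= s;
  std::vector<std::vector<double> > cpt(d);  // cpt[j][v * card + c]
  for (int j = 0; j < d; ++j) {
    cpt[j].assign(levels[j] * card, 0.0);
    for (int c = 0; c < card; ++c) {
      double t = 0.0;
      for (int v = 0; v < levels[j]; ++v) {
        double e = -std::log(unif_rand());
        cpt[j][v * card + c] = e;
        t += e;
      }
      for (int v = 0; v < levels[j]; ++v) cpt[j][v * card + c] /= t;
    }
  }

  std::vector<double> post(n * card);
  std::vector<double> trace;
  double ll_prev = R_NegInf, ll = R_NegInf;
  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    // E-step (+ log-likelihood under current parameters)
    ll = 0.0;
    for (int i = 0; i < n; ++i) {
      double mx = R_NegInf;
      std::vector<double> lw(card);
      for (int c = 0; c < card; ++c) {
        double w = std::log(prior[c]);
        for (int j = 0; j < d; ++j) {
          int v = X(i, j);
          if (v >= 0) w += std::log(cpt[j][v * card + c]);
        }
        lw[c] = w;
        if (w > mx) mx = w;
      }
      double z = 0.0;
      for (int c = 0; c < card; ++c) z += std::exp(lw[c] - mx);
      double lz = mx + std::log(z);
      ll += lz;
      for (int c = 0; c < card; ++c) post[i * card + c] = std::exp(lw[c] - lz);
    }
    trace.push_back(ll);
    if (it > 0 && ll - ll_prev < tol) break;
    ll_prev = ll;
    // M-step
    std::vector<double> nk(card, 0.0);
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < card; ++c) nk[c] += post[i * card + c];
    for (int c = 0; c < card; ++c) prior[c] = nk[c] / n;
    for (int j = 0; j < d; ++j) {
      std::vector<double> num(levels[j] * card, 0.0), den(card, 0.0);
      for (int i = 0; i < n; ++i) {
        int v = X(i, j);
        if (v < 0) continue;
        for (int c = 0; c < card; ++c) {
          num[v * card + c] += post[i * card + c];
          den[c] += post[i * card + c];
        }
      }
      for (int c = 0; c < card; ++c) {
        if (den[c] > 0) {
          for (int v = 0; v < levels[j]; ++v)
            cpt[j][v * card + c] = num[v * card + c] / den[c];
        } else {
          for (int v = 0; v < levels[j]; ++v)
            cpt[j][v * card + c] = 1.0 / levels[j];
        }
      }
    }
  }

  List cpts(d);
  for (int j = 0; j < d; ++j) {
    NumericMatrix m(levels[j], card);
    for (int v = 0; v < levels[j]; ++v)
      for (int c = 0; c < card; ++c) m(v, c) = cpt[j][v * card + c];
    cpts[j] = m;
  }
  return List::create(_["prior"] = NumericVector(prior.begin(), prior.end()),
                      _["cpts"] = cpts, _["loglik"] = ll,
                      _["trace"] = NumericVector(trace.begin(), trace.end()),
                      _["iterations"] = (int)trace.size());
}
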