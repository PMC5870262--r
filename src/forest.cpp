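// Embedded random forest core: Extra-trees grown inside meta-nodes,
// meta-variable cut-point search, and meta-tree recursion.  All
// randomness is drawn from R's RNG so results are reproducible with
// set.seed() from the R side.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static inline double h2(double a, double b) {
  // binary entropy in bits of counts (a, b)
  double n = a + b;
  if (n <= 0) return 0.0;
  double h = 0.0;
  if (a > 0) h -= (a / n) * std::log2(a / n);
  if (b > 0) h -= (b / n) * std::log2(b / n);
  return h;
}

static inline double disc_score(double pc, double pn, double lc, double ln,
                                double rc, double rn) {
  // information gain: parent (case, ctrl) split into left/right
  double n = pc + pn;
  double g = h2(pc, pn);
  if (lc + ln > 0) g -= (lc + ln) / n * h2(lc, ln);
  if (rc + rn > 0) g -= (rc + rn) / n * h2(rc, rn);
  return g;
}

// sample m distinct values from 0..(n-1), in random draw order
static std::vector<int> sample_wor(int n, int m) {
  std::vector<int> pool(n);
  for (int i = 0; i < n; ++i) pool[i] = i;
  std::vector<int> out;
  out.reserve(m);
  for (int i = 0; i < m; ++i) {
    int j = i + (int)(unif_rand() * (n - i));
    if (j >= n) j = n - 1;
    std::swap(pool[i], pool[j]);
    out.push_back(pool[i]);
  }
  return out;
}

struct ExtraTree {
  // parallel arrays; children index into the arrays, -1 for leaves
  std::vector<int> var;       // split variable (0-based column), -1 leaf
  std::vector<double> thr;    // threshold (go left iff value <= thr)
  std::vector<int> left, right;
  std::vector<double> prob;   // leaf case probability (leaves only)
  std::vector<int> n_node;    // observations reaching the node
  std::vector<int> n_case;
  std::vector<double> score;  // split gain (internal nodes only)
};

// Grows one Extra-tree on rows x vars, assigning each training row the
// case probability of the leaf it lands in (the meta-variable nu).
static int grow_extra_rec(const IntegerMatrix &geno, const IntegerVector &y,
                          std::vector<int> &rows, const std::vector<int> &vars,
                          int k, int s_n, int s_t, int &splits_used,
                          ExtraTree &tree, std::vector<double> &nu,
                          std::vector<int> &row_of) {
  int n = rows.size();
  int nc = 0;
  for (int r : rows) nc += y[r];
  int id = tree.var.size();
  tree.var.push_back(-1); tree.thr.push_back(NA_REAL);
  tree.left.push_back(-1); tree.right.push_back(-1);
  tree.prob.push_back(NA_REAL); tree.n_node.push_back(n);
  tree.n_case.push_back(nc); tree.score.push_back(NA_REAL);

  bool leaf = (n < s_n) || (nc == 0) || (nc == n) || (splits_used >= s_t);
  int best_var = -1; double best_thr = 0.0, best_score = -1.0;
  if (!leaf) {
    int m = std::min((int)vars.size(), k);
    std::vector<int> cand = sample_wor(vars.size(), m);
    for (int ci : cand) {
      int v = vars[ci];
      int vmin = geno(rows[0], v), vmax = vmin;
      for (int r : rows) {
        int g = geno(r, v);
        if (g < vmin) vmin = g;
        if (g > vmax) vmax = g;
      }
      if (vmin == vmax) continue;  // constant at this node
      double th = vmin + unif_rand() * (vmax - vmin);
      int lc = 0, ln = 0, rc = 0, rn = 0;
      for (int r : rows) {
        if (geno(r, v) <= th) { if (y[r]) ++lc; else ++ln; }
        else { if (y[r]) ++rc; else ++rn; }
      }
      double sc = disc_score(nc, n - nc, lc, ln, rc, rn);
      if (sc > best_score) { best_score = sc; best_var = v; best_thr = th; }
    }
    if (best_var < 0) leaf = true;  // every candidate constant
  }
  if (leaf) {
    double p = (double)nc / n;
    tree.prob[id] = p;
    for (int r : rows) nu[row_of[r]] = p;
    return id;
  }
  ++splits_used;
  tree.var[id] = best_var;
  tree.thr[id] = best_thr;
  tree.score[id] = best_score;
  std::vector<int> lrows, rrows;
  for (int r : rows)
    if (geno(r, best_var) <= best_thr) lrows.push_back(r); else rrows.push_back(r);
  tree.left[id] = grow_extra_rec(geno, y, lrows, vars, k, s_n, s_t,
                                 splits_used, tree, nu, row_of);
  tree.right[id] = grow_extra_rec(geno, y, rrows, vars, k, s_n, s_t,
                                  splits_used, tree, nu, row_of);
  return id;
}

static List tree_to_list(const ExtraTree &t) {
  int m = t.var.size();
  IntegerVector var(m), left(m), right(m), n_node(m), n_case(m);
  NumericVector thr(m), prob(m), score(m);
  for (int i = 0; i < m; ++i) {
    var[i] = t.var[i] >= 0 ? t.var[i] + 1 : NA_INTEGER;  // 1-based for R
    left[i] = t.left[i] >= 0 ? t.left[i] + 1 : NA_INTEGER;
    right[i] = t.right[i] >= 0 ? t.right[i] + 1 : NA_INTEGER;
    thr[i] = t.thr[i]; prob[i] = t.prob[i];
    n_node[i] = t.n_node[i]; n_case[i] = t.n_case[i]; score[i] = t.score[i];
  }
  return List::create(_["var"] = var, _["thr"] = thr, _["left"] = left,
                      _["right"] = right, _["prob"] = prob,
                      _["n_node"] = n_node, _["n_case"] = n_case,
                      _["score"] = score);
}

// [[Rcpp::export]]
List cpp_grow_extra_tree(const IntegerMatrix &geno, const IntegerVector &y,
                         const IntegerVector &rows1, const IntegerVector &vars1,
                         int k, int s_n, int s_t) {
  if (rows1.size() == 0) stop("empty learning set");
  std::vector<int> rows(rows1.begin(), rows1.end());
  for (int &r : rows) --r;
  std::vector<int> vars(vars1.begin(), vars1.end());
  for (int &v : vars) --v;
  if (k <= 0) k = vars.size();
  std::vector<double> nu(rows.size());
  std::vector<int> row_of(geno.nrow(), -1);
  for (size_t i = 0; i < rows.size(); ++i) row_of[rows[i]] = i;
  ExtraTree tree;
  int splits = 0;
  grow_extra_rec(geno, y, rows, vars, k, s_n, s_t, splits, tree, nu, row_of);
  return List::create(_["tree"] = tree_to_list(tree),
                      _["nu"] = NumericVector(nu.begin(), nu.end()));
}

// Best threshold on a meta-variable: candidates are the sorted distinct
// nu values except the largest; ties resolved to the smallest theta.
static bool optimal_meta_cut(const std::vector<double> &nu,
                             const IntegerVector &y,
                             const std::vector<int> &rows,
                             const std::vector<int> &row_of,
                             double &theta, double &score) {
  std::vector<double> dom;
  dom.reserve(rows.size());
  for (int r : rows) dom.push_back(nu[row_of[r]]);
  std::sort(dom.begin(), dom.end());
  dom.erase(std::unique(dom.begin(), dom.end()), dom.end());
  if (dom.size() < 2) return false;
  int n = rows.size(), nc = 0;
  for (int r : rows) nc += y[r];
  score = -1.0;
  for (size_t d = 0; d + 1 < dom.size(); ++d) {
    double th = dom[d];
    int lc = 0, ln = 0;
    for (int r : rows) {
      if (nu[row_of[r]] <= th) { if (y[r]) ++lc; else ++ln; }
    }
    double sc = disc_score(nc, n - nc, lc, ln, nc - lc, (n - nc) - ln);
    if (sc > score) { score = sc; theta = th; }
  }
  return true;
}

// [[Rcpp::export]]
List cpp_optimal_meta_cut(const NumericVector &nu, const IntegerVector &y) {
  if (nu.size() != y.size()) stop("nu and labels must have equal length");
  std::vector<double> nuv(nu.begin(), nu.end());
  std::vector<int> rows(nu.size()), row_of(nu.size());
  for (int i = 0; i < (int)nu.size(); ++i) { rows[i] = i; row_of[i] = i; }
  double theta = NA_REAL, score = NA_REAL;
  bool ok = optimal_meta_cut(nuv, y, rows, row_of, theta, score);
  return List::create(_["split"] = ok, _["theta"] = theta, _["score"] = score);
}

struct MetaGrower {
  const IntegerMatrix &geno;
  const IntegerVector &y;
  const std::vector<std::vector<int> > &clusters;
  int S_n, S_t, K, k, s_n, s_t;
  int nodes_used;
  std::vector<List> nodes;

  MetaGrower(const IntegerMatrix &g, const IntegerVector &yy,
             const std::vector<std::vector<int> > &cl,
             int Sn, int St, int KK, int kk, int sn, int st)
    : geno(g), y(yy), clusters(cl), S_n(Sn), S_t(St), K(KK), k(kk),
      s_n(sn), s_t(st), nodes_used(0) {}

  int grow(std::vector<int> &rows) {
    int n = rows.size();
    int nc = 0;
    for (int r : rows) nc += y[r];
    int id = nodes.size();
    nodes.push_back(List());  // placeholder
    bool leaf = (n < S_n) || (nodes_used >= S_t) || nc == 0 || nc == n;

    int best_cl = -1;
    double best_theta = 0.0, best_score = -1.0;
    ExtraTree best_tree;
    std::vector<double> best_nu;
    std::vector<int> row_of(geno.nrow(), -1);
    for (size_t i = 0; i < rows.size(); ++i) row_of[rows[i]] = i;

    if (!leaf) {
      int m = std::min((int)clusters.size(), K);
      std::vector<int> cand = sample_wor(clusters.size(), m);
      for (int ci : cand) {
        const std::vector<int> &vars = clusters[ci];
        int kk = k <= 0 ? (int)vars.size() : k;
        std::vector<double> nu(rows.size());
        ExtraTree tr;
        int splits = 0;
        std::vector<int> rcopy(rows);
        grow_extra_rec(geno, y, rcopy, vars, kk, s_n, s_t, splits, tr, nu, row_of);
        double theta, score;
        if (!optimal_meta_cut(nu, y, rows, row_of, theta, score)) continue;
        if (score > best_score) {
          best_score = score; best_theta = theta; best_cl = ci;
          best_tree = tr; best_nu = nu;
        }
      }
      if (best_cl < 0 || best_score <= 0.0) leaf = true;
    }
    if (leaf) {
      nodes[id] = List::create(_["type"] = "leaf", _["n"] = n,
                               _["prob"] = (double)nc / n);
      return id + 1;  // 1-based for R
    }
    ++nodes_used;
    std::vector<int> lrows, rrows;
    for (int r : rows) {
      if (best_nu[row_of[r]] <= best_theta) lrows.push_back(r);
      else rrows.push_back(r);
    }
    int lid = grow(lrows);
    int rid = grow(rrows);
    nodes[id] = List::create(_["type"] = "split", _["cluster"] = best_cl + 1,
                             _["theta"] = best_theta, _["score"] = best_score,
                             _["n"] = n, _["tree"] = tree_to_list(best_tree),
                             _["left"] = lid, _["right"] = rid);
    return id + 1;
  }
};

// [[Rcpp::export]]
List cpp_grow_meta_tree(const IntegerMatrix &geno, const IntegerVector &y,
                        const IntegerVector &rows1, const List &clusters1,
                        int S_n, double S_t, int K, int k, int s_n, int s_t) {
  if (rows1.size() == 0) stop("empty learning set");
  std::vector<std::vector<int> > clusters(clusters1.size());
  for (int i = 0; i < clusters1.size(); ++i) {
    IntegerVector cl = clusters1[i];
    clusters[i].assign(cl.begin(), cl.end());
    for (int &v : clusters[i]) --v;
  }
  std::vector<int> rows(rows1.begin(), rows1.end());
  for (int &r : rows) --r;
  int St = R_finite(S_t) ? (int)S_t : INT_MAX;
  MetaGrower mg(geno, y, clusters, S_n, St, K, k, s_n, s_t);
  mg.grow(rows);
  return List(mg.nodes.begin(), mg.nodes.end());
}
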