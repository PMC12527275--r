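// Histogram-based CART trees shared by the random-forest and
// gradient-boosting base learners.
//
// Features are pre-binned once per fit into at most `max_bins` quantile
// bins, so a node's split search costs O(n_node * mtry) regardless of n.
// Trees are grown on (gradient, hessian) summaries: a regression tree is
// the special case g = y, h = 1 (leaf = mean, gain = variance reduction);
// logistic boosting uses g = y - p, h = p(1 - p) with Newton leaf values.
// All randomness comes from a std::mt19937_64 seeded from R, so fits are
// reproducible independently of R's RNG state.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct BinnedData {
  int n = 0, p = 0;
  std::vector<uint16_t> bins;             // n x p, column-major
  std::vector<std::vector<double>> cuts;  // per-feature upper edges

  inline uint16_t bin(int row, int col) const {
    return bins[static_cast<size_t>(col) * n + row];
  }
};

// Quantile cut points; value v falls in bin b = #cuts(feature) < v.
// A split "bin <= s" is equivalent to "value <= cuts[s]" on raw data.
BinnedData bin_features(const NumericMatrix& x, int max_bins) {
  BinnedData bd;
  bd.n = x.nrow();
  bd.p = x.ncol();
  bd.bins.resize(static_cast<size_t>(bd.n) * bd.p);
  bd.cuts.resize(bd.p);
  std::vector<double> v(bd.n);
  for (int j = 0; j < bd.p; ++j) {
    for (int i = 0; i < bd.n; ++i) v[i] = x(i, j);
    std::vector<double> s(v);
    std::sort(s.begin(), s.end());
    s.erase(std::unique(s.begin(), s.end()), s.end());
    std::vector<double>& cuts = bd.cuts[j];
    int nu = static_cast<int>(s.size());
    if (nu <= 1) {
      // constant feature: no cuts, never splittable
    } else if (nu <= max_bins) {
      cuts.reserve(nu - 1);
      for (int u = 0; u + 1 < nu; ++u) cuts.push_back(s[u]);
    } else {
      cuts.reserve(max_bins - 1);
      for (int b = 1; b < max_bins; ++b) {
        size_t idx = static_cast<size_t>(
            std::floor(static_cast<double>(b) * nu / max_bins));
        if (idx >= s.size() - 1) idx = s.size() - 2;
        double c = s[idx];
        if (cuts.empty() || c > cuts.back()) cuts.push_back(c);
      }
    }
    for (int i = 0; i < bd.n; ++i) {
      const double val = v[i];
      // first index with cuts[idx] >= val  ->  bin index
      uint16_t b = static_cast<uint16_t>(
          std::lower_bound(cuts.begin(), cuts.end(), val) - cuts.begin());
      bd.bins[static_cast<size_t>(j) * bd.n + i] = b;
    }
  }
  return bd;
}

struct TreeBuf {
  std::vector<int> feature;   // -1 for leaf
  std::vector<double> thr;    // numeric threshold (raw scale)
  std::vector<int> sbin;      // split bin index (training scale)
  std::vector<int> left, right;
  std::vector<double> value;  // leaf value

  int add_node() {
    feature.push_back(-1);
    thr.push_back(0.0);
    sbin.push_back(0);
    left.push_back(-1);
    right.push_back(-1);
    value.push_back(0.0);
    return static_cast<int>(feature.size()) - 1;
  }
};

struct Grower {
  const BinnedData* bd;
  const double* g;
  const double* h;
  int mtry, min_leaf, max_depth;
  double lambda;  // L2 on leaf values; 0 for plain regression trees
  std::mt19937_64* rng;
  std::vector<int> feat_pool;
  std::vector<double> hg, hh;
  std::vector<int> hc;

  void init_scratch() {
    feat_pool.resize(bd->p);
    for (int j = 0; j < bd->p; ++j) feat_pool[j] = j;
    size_t mx = 2;
    for (int j = 0; j < bd->p; ++j)
      mx = std::max(mx, bd->cuts[j].size() + 1);
    hg.resize(mx);
    hh.resize(mx);
    hc.resize(mx);
  }

  void grow(TreeBuf& tree, int node, std::vector<int>& rows, int lo, int hi,
            int depth) {
    const int cnt = hi - lo;
    double sg = 0.0, sh = 0.0;
    for (int k = lo; k < hi; ++k) {
      sg += g[rows[k]];
      sh += h[rows[k]];
    }
    const double denom_all = sh + lambda;
    tree.value[node] = denom_all > 0.0 ? sg / denom_all : 0.0;
    if (cnt < 2 * min_leaf || depth >= max_depth) return;

    // sample mtry features without replacement (partial Fisher-Yates)
    const int m = std::min(mtry, bd->p);
    for (int k = 0; k < m; ++k) {
      std::uniform_int_distribution<int> u(k, bd->p - 1);
      std::swap(feat_pool[k], feat_pool[u(*rng)]);
    }

    const double base = denom_all > 0.0 ? sg * sg / denom_all : 0.0;
    double best_gain = 1e-12;
    int best_feat = -1, best_bin = -1;

    for (int k = 0; k < m; ++k) {
      const int j = feat_pool[k];
      const int nb = static_cast<int>(bd->cuts[j].size()) + 1;
      if (nb < 2) continue;
      std::fill(hg.begin(), hg.begin() + nb, 0.0);
      std::fill(hh.begin(), hh.begin() + nb, 0.0);
      std::fill(hc.begin(), hc.begin() + nb, 0);
      for (int t = lo; t < hi; ++t) {
        const int i = rows[t];
        const uint16_t b = bd->bin(i, j);
        hg[b] += g[i];
        hh[b] += h[i];
        hc[b] += 1;
      }
      double lg = 0.0, lh = 0.0;
      int lc = 0;
      for (int b = 0; b + 1 < nb; ++b) {
        lg += hg[b];
        lh += hh[b];
        lc += hc[b];
        if (lc < min_leaf) continue;
        if (cnt - lc < min_leaf) break;
        const double rg = sg - lg, rh = sh - lh;
        const double gain =
            lg * lg / (lh + lambda) + rg * rg / (rh + lambda) - base;
        if (gain > best_gain) {
          best_gain = gain;
          best_feat = j;
          best_bin = b;
        }
      }
    }
    if (best_feat < 0) return;

    // partition rows in place: bin <= best_bin goes left
    int mid = lo;
    for (int t = lo; t < hi; ++t) {
      if (bd->bin(rows[t], best_feat) <= best_bin) {
        std::swap(rows[t], rows[mid]);
        ++mid;
      }
    }
    if (mid == lo || mid == hi) return;  // degenerate (ties); keep leaf

    tree.feature[node] = best_feat;
    tree.sbin[node] = best_bin;
    tree.thr[node] = bd->cuts[best_feat][best_bin];
    const int L = tree.add_node();
    const int R = tree.add_node();
    tree.left[node] = L;
    tree.right[node] = R;
    grow(tree, L, rows, lo, mid, depth + 1);
    grow(tree, R, rows, mid, hi, depth + 1);
  }
};

// Forest/ensemble stored as flat arrays with per-tree offsets.
struct FlatTrees {
  std::vector<int> feature, left, right, offset;
  std::vector<double> thr, value;

  void append(const TreeBuf& t) {
    offset.push_back(static_cast<int>(feature.size()));
    feature.insert(feature.end(), t.feature.begin(), t.feature.end());
    left.insert(left.end(), t.left.begin(), t.left.end());
    right.insert(right.end(), t.right.begin(), t.right.end());
    thr.insert(thr.end(), t.thr.begin(), t.thr.end());
    value.insert(value.end(), t.value.begin(), t.value.end());
  }

  int n_trees() const { return static_cast<int>(offset.size()); }

  // prediction of tree t for a raw-feature row accessor
  template <typename GetX>
  double predict_tree(int t, GetX&& xval) const {
    const int off = offset[t];
    int node = off;
    while (feature[node] >= 0) {
      node = off + (xval(feature[node]) <= thr[node] ? left[node] : right[node]);
    }
    return value[node];
  }

  List to_list() const {
    return List::create(
        _["feature"] = IntegerVector(feature.begin(), feature.end()),
        _["thr"] = NumericVector(thr.begin(), thr.end()),
        _["left"] = IntegerVector(left.begin(), left.end()),
        _["right"] = IntegerVector(right.begin(), right.end()),
        _["value"] = NumericVector(value.begin(), value.end()),
        _["offset"] = IntegerVector(offset.begin(), offset.end()));
  }
};

struct TreesView {
  IntegerVector feature, left, right, offset;
  NumericVector thr, value;

  explicit TreesView(const List& fit) {
    List t = fit["trees"];
    feature = t["feature"];
    thr = t["thr"];
    left = t["left"];
    right = t["right"];
    value = t["value"];
    offset = t["offset"];
  }

  double predict_row(int t, const NumericMatrix& x, int row) const {
    const int off = offset[t];
    int node = off;
    while (feature[node] >= 0) {
      node = off + (x(row, feature[node]) <= thr[node] ? left[node] : right[node]);
    }
    return value[node];
  }
};

inline double sigmoid(double z) { return 1.0 / (1.0 + std::exp(-z)); }

}  // namespace

// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(NumericMatrix x, NumericVector y, int num_trees, int mtry,
                int min_leaf, int max_depth, double sample_fraction,
                bool bootstrap, int max_bins, int seed) {
  const int n = x.nrow();
  BinnedData bd = bin_features(x, max_bins);
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::vector<double> g(y.begin(), y.end());
  std::vector<double> h(n, 1.0);

  Grower gr;
  gr.bd = &bd;
  gr.g = g.data();
  gr.h = h.data();
  gr.mtry = std::max(1, mtry);
  gr.min_leaf = std::max(1, min_leaf);
  gr.max_depth = max_depth;
  gr.lambda = 0.0;
  gr.rng = &rng;
  gr.init_scratch();

  FlatTrees out;
  std::vector<int> rows;
  const int nsamp = std::max(
      2, static_cast<int>(std::round(sample_fraction * n)));
  std::uniform_int_distribution<int> ui(0, n - 1);
  for (int t = 0; t < num_trees; ++t) {
    rows.clear();
    if (bootstrap) {
      rows.reserve(n);
      for (int i = 0; i < n; ++i) rows.push_back(ui(rng));
    } else {
      std::vector<int> perm(n);
      for (int i = 0; i < n; ++i) perm[i] = i;
      for (int i = 0; i < nsamp; ++i) {
        std::uniform_int_distribution<int> u(i, n - 1);
        std::swap(perm[i], perm[u(rng)]);
      }
      rows.assign(perm.begin(), perm.begin() + nsamp);
    }
    TreeBuf tb;
    const int root = tb.add_node();
    gr.grow(tb, root, rows, 0, static_cast<int>(rows.size()), 0);
    out.append(tb);
  }
  return List::create(_["trees"] = out.to_list(),
                      _["num_trees"] = out.n_trees());
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
NumericVector rf_predict_cpp(List fit, NumericMatrix x) {
  TreesView tv(fit);
  const int ntree = tv.offset.size();
  const int n = x.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int t = 0; t < ntree; ++t) s += tv.predict_row(t, x, i);
    out[i] = s / ntree;
  }
  return out;
}

// Gradient boosting with optional early stopping on a held-out fraction.
// family: 0 = gaussian (squared error), 1 = binomial (log loss).
// [[Rcpp::export(name = ".gbm_fit_cpp")]]
List gbm_fit_cpp(NumericMatrix x, NumericVector y, int family, int n_rounds,
                 double shrinkage, int max_depth, int min_leaf,
                 double valid_fraction, int patience, int max_bins,
                 int seed) {
  const int n = x.nrow();
  BinnedData bd = bin_features(x, max_bins);
  std::mt19937_64 rng(static_cast<uint64_t>(seed));

  // held-out rows for early stopping
  std::vector<int> perm(n);
  for (int i = 0; i < n; ++i) perm[i] = i;
  int nvalid = 0;
  if (patience > 0) {
    nvalid = static_cast<int>(std::floor(valid_fraction * n));
    if (nvalid < 10 || n - nvalid < 2 * min_leaf) nvalid = 0;
  }
  for (int i = 0; i < nvalid; ++i) {
    std::uniform_int_distribution<int> u(i, n - 1);
    std::swap(perm[i], perm[u(rng)]);
  }
  std::vector<int> vrows(perm.begin(), perm.begin() + nvalid);
  std::vector<int> trows(perm.begin() + nvalid, perm.end());
  const int ntrain = static_cast<int>(trows.size());

  double ymean = 0.0;
  for (int k = 0; k < ntrain; ++k) ymean += y[trows[k]];
  ymean /= ntrain;
  double f0;
  if (family == 1) {
    const double pm = std::min(1.0 - 1e-6, std::max(1e-6, ymean));
    f0 = std::log(pm / (1.0 - pm));
  } else {
    f0 = ymean;
  }

  std::vector<double> F(n, f0), g(n, 0.0), h(n, 1.0);
  Grower gr;
  gr.bd = &bd;
  gr.g = g.data();
  gr.h = h.data();
  gr.mtry = bd.p;
  gr.min_leaf = std::max(1, min_leaf);
  gr.max_depth = max_depth;
  gr.lambda = family == 1 ? 1e-3 : 0.0;
  gr.rng = &rng;
  gr.init_scratch();

  FlatTrees out;
  double best_loss = R_PosInf;
  int best_round = 0, since_best = 0;
  std::vector<int> rows;

  for (int round = 0; round < n_rounds; ++round) {
    for (int k = 0; k < ntrain; ++k) {
      const int i = trows[k];
      if (family == 1) {
        const double p = sigmoid(F[i]);
        g[i] = y[i] - p;
        h[i] = std::max(1e-10, p * (1.0 - p));
      } else {
        g[i] = y[i] - F[i];
        h[i] = 1.0;
      }
    }
    rows = trows;
    TreeBuf tb;
    const int root = tb.add_node();
    gr.grow(tb, root, rows, 0, static_cast<int>(rows.size()), 0);
    out.append(tb);
    const int t = out.n_trees() - 1;
    // update F everywhere via binned traversal (thr is on the raw scale,
    // and all rows of x are binned consistently, so raw traversal is fine)
    for (int i = 0; i < n; ++i) {
      F[i] += shrinkage *
              out.predict_tree(t, [&](int j) { return x(i, j); });
    }
    if (nvalid > 0) {
      double loss = 0.0;
      for (int k = 0; k < nvalid; ++k) {
        const int i = vrows[k];
        if (family == 1) {
          const double p =
              std::min(1.0 - 1e-12, std::max(1e-12, sigmoid(F[i])));
          loss -= y[i] * std::log(p) + (1.0 - y[i]) * std::log(1.0 - p);
        } else {
          const double e = y[i] - F[i];
          loss += e * e;
        }
      }
      loss /= nvalid;
      if (loss < best_loss - 1e-10) {
        best_loss = loss;
        best_round = round + 1;
        since_best = 0;
      } else if (++since_best >= patience) {
        break;
      }
    } else {
      best_round = round + 1;
    }
  }

  return List::create(_["trees"] = out.to_list(), _["f0"] = f0,
                      _["shrinkage"] = shrinkage, _["family"] = family,
                      _["n_rounds_used"] = best_round);
}

// [[Rcpp::export(name = ".gbm_predict_cpp")]]
NumericVector gbm_predict_cpp(List fit, NumericMatrix x) {
  TreesView tv(fit);
  const int use = as<int>(fit["n_rounds_used"]);
  const double f0 = as<double>(fit["f0"]);
  const double shrink = as<double>(fit["shrinkage"]);
  const int family = as<int>(fit["family"]);
  const int n = x.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double s = f0;
    for (int t = 0; t < use; ++t) s += shrink * tv.predict_row(t, x, i);
    out[i] = family == 1 ? sigmoid(s) : s;
  }
  return out;
}
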