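// Compact CART learner shared by the tree-based classifiers.
//
// Supports weighted Gini classification splits and squared-error
// regression splits, per-node feature subsampling (mtry) for random
// forests, and deterministic growth under a caller-supplied seed.
// Thresholds are midpoints between distinct adjacent sorted values.

#include <Rcpp.h>
#include <algorithm>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct Builder {
  const NumericMatrix &X;
  const IntegerVector &ycls;   // classification targets (ignored if K == 0)
  const NumericVector &yreg;   // regression targets (ignored if K > 0)
  const NumericVector &w;
  int K, mtry, max_depth, min_split;
  std::mt19937 rng;

  std::vector<int> feat, left, right;
  std::vector<double> thr;
  std::vector<std::vector<double>> value;  // K probs, or {mean}

  Builder(const NumericMatrix &X_, const IntegerVector &yc,
          const NumericVector &yr, const NumericVector &w_, int K_,
          int mtry_, int maxd, int mins, unsigned seed)
      : X(X_), ycls(yc), yreg(yr), w(w_), K(K_), mtry(mtry_),
        max_depth(maxd), min_split(mins), rng(seed) {}

  int new_node() {
    feat.push_back(-1); thr.push_back(0.0);
    left.push_back(-1); right.push_back(-1);
    value.emplace_back();
    return (int)feat.size() - 1;
  }

  // weighted Gini impurity times total weight, from class weight sums
  static double gini_w(const std::vector<double> &cnt, double tot) {
    if (tot <= 0) return 0.0;
    double s = 0.0;
    for (double c : cnt) s += c * c;
    return tot - s / tot;  // tot * (1 - sum p^2)
  }

  int build(std::vector<int> &rows, int depth) {
    int id = new_node();
    double tot = 0.0;
    std::vector<double> cnt;
    double sum = 0.0, sumsq = 0.0;
    if (K > 0) {
      cnt.assign(K, 0.0);
      for (int r : rows) { cnt[ycls[r]] += w[r]; tot += w[r]; }
      value[id].assign(K, 0.0);
      for (int k = 0; k < K; ++k) value[id][k] = tot > 0 ? cnt[k] / tot : 0.0;
    } else {
      for (int r : rows) { sum += w[r] * yreg[r]; sumsq += w[r] * yreg[r] * yreg[r]; tot += w[r]; }
      value[id].assign(1, tot > 0 ? sum / tot : 0.0);
    }
    double imp = K > 0 ? gini_w(cnt, tot) : (sumsq - (tot > 0 ? sum * sum / tot : 0.0));
    if ((int)rows.size() < min_split || depth >= max_depth || imp <= 1e-12)
      return id;

    // candidate features: mtry distinct indices (partial Fisher-Yates)
    int d = X.ncol();
    int m = std::min(mtry, d);
    std::vector<int> fidx(d);
    for (int j = 0; j < d; ++j) fidx[j] = j;
    for (int j = 0; j < m; ++j) {
      std::uniform_int_distribution<int> u(j, d - 1);
      std::swap(fidx[j], fidx[u(rng)]);
    }

    double best_gain = 1e-12;
    int best_f = -1;
    double best_t = 0.0;
    std::vector<std::pair<double, int>> sv(rows.size());

    for (int jj = 0; jj < m; ++jj) {
      int f = fidx[jj];
      for (size_t i = 0; i < rows.size(); ++i)
        sv[i] = {X(rows[i], f), rows[i]};
      std::sort(sv.begin(), sv.end());
      if (sv.front().first == sv.back().first) continue;

      if (K > 0) {
        std::vector<double> lc(K, 0.0);
        double lw = 0.0;
        for (size_t i = 0; i + 1 < sv.size(); ++i) {
          int r = sv[i].second;
          lc[ycls[r]] += w[r]; lw += w[r];
          if (sv[i].first == sv[i + 1].first) continue;
          std::vector<double> rc(K);
          for (int k = 0; k < K; ++k) rc[k] = cnt[k] - lc[k];
          double gain = imp - gini_w(lc, lw) - gini_w(rc, tot - lw);
          if (gain > best_gain) {
            best_gain = gain; best_f = f;
            best_t = 0.5 * (sv[i].first + sv[i + 1].first);
          }
        }
      } else {
        double lsum = 0.0, lsq = 0.0, lw = 0.0;
        for (size_t i = 0; i + 1 < sv.size(); ++i) {
          int r = sv[i].second;
          lsum += w[r] * yreg[r]; lsq += w[r] * yreg[r] * yreg[r]; lw += w[r];
          if (sv[i].first == sv[i + 1].first) continue;
          double rw = tot - lw, rsum = sum - lsum, rsq = sumsq - lsq;
          double sse = (lsq - (lw > 0 ? lsum * lsum / lw : 0.0)) +
                       (rsq - (rw > 0 ? rsum * rsum / rw : 0.0));
          double gain = imp - sse;
          if (gain > best_gain) {
            best_gain = gain; best_f = f;
            best_t = 0.5 * (sv[i].first + sv[i + 1].first);
          }
        }
      }
    }
    if (best_f < 0) return id;

    std::vector<int> lrows, rrows;
    for (int r : rows)
      (X(r, best_f) <= best_t ? lrows : rrows).push_back(r);
    if (lrows.empty() || rrows.empty()) return id;

    feat[id] = best_f; thr[id] = best_t;
    left[id] = build(lrows, depth + 1);
    right[id] = build(rrows, depth + 1);
    return id;
  }
};

}  // namespace

// [[Rcpp::export]]
List cart_build(NumericMatrix X, IntegerVector ycls, NumericVector yreg,
                NumericVector w, int n_classes, int mtry, int max_depth,
                int min_split, int seed, IntegerVector rows0) {
  Builder b(X, ycls, yreg, w, n_classes, mtry, max_depth, min_split,
            (unsigned)seed);
  std::vector<int> rows(rows0.begin(), rows0.end());
  b.build(rows, 0);
  int n = (int)b.feat.size();
  int vk = n_classes > 0 ? n_classes : 1;
  NumericMatrix val(n, vk);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < vk; ++k) val(i, k) = b.value[i][k];
  return List::create(_["feature"] = wrap(b.feat), _["threshold"] = wrap(b.thr),
                      _["left"] = wrap(b.left), _["right"] = wrap(b.right),
                      _["value"] = val);
}

// leaf node index (0-based) for every row of X
// [[Rcpp::export]]
IntegerVector cart_leaf(List tree, NumericMatrix X) {
  IntegerVector feat = tree["feature"];
  NumericVector thr = tree["threshold"];
  IntegerVector left = tree["left"], right = tree["right"];
  int n = X.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feat[node] >= 0)
      node = X(i, feat[node]) <= thr[node] ? left[node] : right[node];
    out[i] = node;
  }
  return out;
}

// per-row leaf value vector (class distribution or regression mean)
// [[Rcpp::export]]
NumericMatrix cart_values(List tree, NumericMatrix X) {
  NumericMatrix val = tree["value"];
  IntegerVector lv = cart_leaf(tree, X);
  NumericMatrix out(X.nrow(), val.ncol());
  for (int i = 0; i < X.nrow(); ++i)
    out(i, _) = val(lv[i], _);
  return out;
}
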