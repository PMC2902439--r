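#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// BDeu log marginal likelihood from a 2 x q contingency table.
// cnt[2*j + c] = number of genes in parent configuration j with target class c;
// q = number of parent configurations; pseudocounts ESS/(2q) per cell.
static double bde_logml_from_counts(const std::vector<int>& cnt, int q, double ess) {
  const double aj = ess / q, ajc = ess / (2.0 * q);
  const double lg_aj = lgamma(aj), lg_ajc = lgamma(ajc);
  double s = 0.0;
  for (int j = 0; j < q; ++j) {
    const int n0 = cnt[2 * j], n1 = cnt[2 * j + 1];
    const int nj = n0 + n1;
    if (nj == 0) continue;
    s += lg_aj - lgamma(aj + nj)
       + lgamma(ajc + n0) - lg_ajc
       + lgamma(ajc + n1) - lg_ajc;
  }
  return s;
}

// parent configuration codes for a subset of feature columns (0/1 matrix)
static void subset_codes(const IntegerMatrix& feats, const std::vector<int>& idx,
                         std::vector<int>& code) {
  const int n = feats.nrow();
  const int k = (int) idx.size();
  std::fill(code.begin(), code.end(), 0);
  for (int b = 0; b < k; ++b) {
    const int col = idx[b];
    const int add = 1 << b;
    for (int g = 0; g < n; ++g)
      if (feats(g, col)) code[g] += add;
  }
}

static double subset_logml(const std::vector<int>& code, const IntegerVector& y,
                           int q, double ess) {
  const int n = (int) y.size();
  std::vector<int> cnt(2 * q, 0);
  for (int g = 0; g < n; ++g) cnt[2 * code[g] + y[g]]++;
  return bde_logml_from_counts(cnt, q, ess);
}

// Enumerate all parent subsets of the pool up to max_parents in a fixed
// deterministic order (by size, then lexicographic on column indices).
static void enumerate_subsets(int p, int max_parents,
                              std::vector< std::vector<int> >& out) {
  out.clear();
  for (int i = 0; i < p; ++i) out.push_back({i});
  if (max_parents >= 2)
    for (int i = 0; i < p; ++i)
      for (int j = i + 1; j < p; ++j) out.push_back({i, j});
  if (max_parents >= 3)
    for (int i = 0; i < p; ++i)
      for (int j = i + 1; j < p; ++j)
        for (int k = j + 1; k < p; ++k) out.push_back({i, j, k});
}

// [[Rcpp::export(name = ".bn_exhaustive_cpp")]]
List bn_exhaustive_cpp(IntegerMatrix feats, IntegerVector y, IntegerVector sizes,
                       double ess, double log_kappa, int max_parents) {
  const int n = feats.nrow(), p = feats.ncol();
  if ((int) y.size() != n) stop("y length must match feature rows");
  if ((int) sizes.size() != p) stop("sizes length must match feature columns");

  std::vector< std::vector<int> > subs;
  enumerate_subsets(p, max_parents, subs);

  // empty-set reference
  std::vector<int> code0(n, 0);
  const double logml_empty = subset_logml(code0, y, 1, ess);

  const int m = (int) subs.size();
  NumericVector score(m);
  List subsets(m);
  std::vector<int> code(n);
  for (int s = 0; s < m; ++s) {
    const std::vector<int>& idx = subs[s];
    const int k = (int) idx.size();
    const int q = 1 << k;
    subset_codes(feats, idx, code);
    double prior = 0.0;
    IntegerVector iv(k);
    for (int b = 0; b < k; ++b) { prior += sizes[idx[b]] * log_kappa; iv[b] = idx[b] + 1; }
    score[s] = subset_logml(code, y, q, ess) + prior - logml_empty;
    subsets[s] = iv;
  }
  return List::create(_["subsets"] = subsets, _["log_score"] = score,
                      _["logml_empty"] = logml_empty);
}

// Best nonempty log BN score of the full two-step search, for each column
// of a matrix of permuted labels.  Per permutation: every feature is
// scored as a singleton parent (step 1), the top pool_size features (ties
// broken by column order) plus the fixed columns form the candidate pool,
// and an exhaustive subset search up to max_parents (step 2) returns the
// optimal non-empty score.  Rerunning step 1 per permutation keeps the
// null exchangeable with the observed two-step statistic.
// [[Rcpp::export(name = ".bn_two_step_best_cpp")]]
NumericVector bn_two_step_best_cpp(IntegerMatrix feats, IntegerMatrix ymat,
                                   IntegerVector sizes, int pool_size,
                                   IntegerVector fixed_idx, double ess,
                                   double log_kappa, int max_parents) {
  const int n = feats.nrow(), p = feats.ncol(), nperm = ymat.ncol();
  if (ymat.nrow() != n) stop("ymat rows must match feature rows");
  if ((int) sizes.size() != p) stop("sizes length must match feature columns");

  std::vector<bool> is_fixed(p, false);
  for (int i = 0; i < fixed_idx.size(); ++i) {
    if (fixed_idx[i] < 0 || fixed_idx[i] >= p) stop("fixed_idx out of range");
    is_fixed[fixed_idx[i]] = true;
  }

  NumericVector best(nperm, R_NegInf);
  std::vector<int> code(n);
  std::vector<double> single(p);
  std::vector<int> ord(p);

  for (int w = 0; w < nperm; ++w) {
    IntegerVector y = ymat(_, w);
    std::vector<int> cnt0(2, 0);
    for (int g = 0; g < n; ++g) cnt0[y[g]]++;
    const double logml_empty = bde_logml_from_counts(cnt0, 1, ess);

    // step 1: singleton scores
    for (int j = 0; j < p; ++j) {
      std::vector<int> cnt(4, 0);
      for (int g = 0; g < n; ++g) cnt[2 * (feats(g, j) ? 1 : 0) + y[g]]++;
      single[j] = bde_logml_from_counts(cnt, 2, ess) +
        sizes[j] * log_kappa - logml_empty;
    }
    for (int j = 0; j < p; ++j) ord[j] = j;
    std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
      if (single[a] != single[b]) return single[a] > single[b];
      return a < b;
    });
    std::vector<int> pool;
    std::vector<bool> in_pool(p, false);
    const int npool = std::min(pool_size, p);
    for (int j = 0; j < npool; ++j) { pool.push_back(ord[j]); in_pool[ord[j]] = true; }
    for (int i = 0; i < fixed_idx.size(); ++i)
      if (!in_pool[fixed_idx[i]]) { pool.push_back(fixed_idx[i]); in_pool[fixed_idx[i]] = true; }
    std::sort(pool.begin(), pool.end());

    // step 2: exhaustive subsets of the pool
    const int m = (int) pool.size();
    double bw = R_NegInf;
    std::vector<int> idx;
    auto score_subset = [&](const std::vector<int>& ix) {
      const int k = (int) ix.size();
      const int q = 1 << k;
      std::vector<int> cnt(2 * q, 0);
      for (int g = 0; g < n; ++g) {
        int c = 0;
        for (int b = 0; b < k; ++b) if (feats(g, ix[b])) c += (1 << b);
        cnt[2 * c + y[g]]++;
      }
      double prior = 0.0;
      for (int b = 0; b < k; ++b) prior += sizes[ix[b]] * log_kappa;
      return bde_logml_from_counts(cnt, q, ess) + prior - logml_empty;
    };
    for (int i = 0; i < m; ++i) {
      double sc = single[pool[i]];
      if (sc > bw) bw = sc;
    }
    if (max_parents >= 2)
      for (int i = 0; i < m; ++i)
        for (int j = i + 1; j < m; ++j) {
          idx = {pool[i], pool[j]};
          double sc = score_subset(idx);
          if (sc > bw) bw = sc;
        }
    if (max_parents >= 3)
      for (int i = 0; i < m; ++i)
        for (int j = i + 1; j < m; ++j)
          for (int k2 = j + 1; k2 < m; ++k2) {
            idx = {pool[i], pool[j], pool[k2]};
            double sc = score_subset(idx);
            if (sc > bw) bw = sc;
          }
    best[w] = bw;
  }
  return best;
}
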