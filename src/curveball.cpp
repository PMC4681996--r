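#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Rows of the binary incidence matrix are kept as sorted-free vectors of
// 0-based column indices; a curveball trade picks two rows and redistributes
// their non-shared columns at random, which preserves both margins exactly.

typedef std::vector<std::vector<int>> RowSets;

static inline int runif_int(int n) {
  // integer in [0, n)
  int k = (int)(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

static void curveball_trade(RowSets &rows, std::vector<signed char> &mark) {
  int n = (int)rows.size();
  if (n < 2) return;
  int r1 = runif_int(n);
  int r2 = runif_int(n - 1);
  if (r2 >= r1) r2++;
  std::vector<int> &a = rows[r1];
  std::vector<int> &b = rows[r2];

  for (int c : a) mark[c] = 1;
  std::vector<int> shared, only_b;
  shared.reserve(b.size());
  for (int c : b) {
    if (mark[c]) { shared.push_back(c); mark[c] = 0; }
    else only_b.push_back(c);
  }
  std::vector<int> only_a;
  only_a.reserve(a.size());
  for (int c : a) {
    if (mark[c]) { only_a.push_back(c); mark[c] = 0; }
  }
  int na = (int)only_a.size(), nb = (int)only_b.size();
  if (na == 0 || nb == 0) return;

  std::vector<int> pool;
  pool.reserve(na + nb);
  pool.insert(pool.end(), only_a.begin(), only_a.end());
  pool.insert(pool.end(), only_b.begin(), only_b.end());
  int m = na + nb;
  for (int i = 0; i < na; ++i) {  // partial Fisher-Yates: new row-a extras
    int j = i + runif_int(m - i);
    std::swap(pool[i], pool[j]);
  }
  a.assign(shared.begin(), shared.end());
  a.insert(a.end(), pool.begin(), pool.begin() + na);
  b.assign(shared.begin(), shared.end());
  b.insert(b.end(), pool.begin() + na, pool.end());
}

static RowSets as_rowsets(List rowsets) {
  RowSets rows(rowsets.size());
  for (int i = 0; i < rowsets.size(); ++i) {
    IntegerVector v = rowsets[i];
    rows[i].assign(v.begin(), v.end());
  }
  return rows;
}

static List as_list(const RowSets &rows) {
  List out(rows.size());
  for (size_t i = 0; i < rows.size(); ++i) out[i] = wrap(rows[i]);
  return out;
}

// [[Rcpp::export]]
List cpp_curveball(List rowsets, int ncols, int nsteps) {
  RowSets rows = as_rowsets(rowsets);
  std::vector<signed char> mark(ncols, 0);
  GetRNGstate();
  for (int s = 0; s < nsteps; ++s) curveball_trade(rows, mark);
  PutRNGstate();
  return as_list(rows);
}

static inline int pair_index(int i, int j, int ncols) {
  // i < j, 0-based; lexicographic over the upper triangle
  return i * ncols - i * (i + 1) / 2 + (j - i - 1);
}

static void accumulate_cooccurrence(const RowSets &rows, int ncols,
                                    std::vector<int> &counts) {
  std::fill(counts.begin(), counts.end(), 0);
  std::vector<int> sorted;
  for (const std::vector<int> &r : rows) {
    sorted = r;
    std::sort(sorted.begin(), sorted.end());
    int k = (int)sorted.size();
    for (int u = 0; u < k; ++u)
      for (int v = u + 1; v < k; ++v)
        counts[pair_index(sorted[u], sorted[v], ncols)]++;
  }
}

// [[Rcpp::export]]
IntegerVector cpp_cooccurrence_counts(List rowsets, int ncols) {
  RowSets rows = as_rowsets(rowsets);
  int npairs = ncols * (ncols - 1) / 2;
  std::vector<int> counts(npairs);
  accumulate_cooccurrence(rows, ncols, counts);
  return wrap(counts);
}

// Per-pair histograms of co-occurrence over null replicates.
// mode 0: one long chain (burn-in, then `thin` trades between samples);
// mode 1: independent randomizations (`nsteps_indep` trades from the
// observed matrix for every replicate).
// Returns an integer matrix with npairs rows and (max_co + 1) columns;
// entry [p, c] counts replicates where pair p co-occurred c times.
// [[Rcpp::export]]
IntegerMatrix cpp_null_histograms(List rowsets, int ncols, int nreps,
                                  int burnin, int thin, int mode,
                                  int nsteps_indep) {
  RowSets rows0 = as_rowsets(rowsets);
  int npairs = ncols * (ncols - 1) / 2;

  // co-occurrence of a pair is bounded by the smaller column margin
  std::vector<int> colsum(ncols, 0);
  for (const std::vector<int> &r : rows0)
    for (int c : r) colsum[c]++;
  int max_co = 0;
  for (int c = 0; c < ncols; ++c) max_co = std::max(max_co, colsum[c]);

  IntegerMatrix hist(npairs, max_co + 1);
  std::vector<int> counts(npairs);
  std::vector<signed char> mark(ncols, 0);

  GetRNGstate();
  if (mode == 0) {
    RowSets rows = rows0;
    for (int s = 0; s < burnin; ++s) curveball_trade(rows, mark);
    for (int rep = 0; rep < nreps; ++rep) {
      for (int s = 0; s < thin; ++s) curveball_trade(rows, mark);
      accumulate_cooccurrence(rows, ncols, counts);
      for (int p = 0; p < npairs; ++p) hist(p, counts[p])++;
      if ((rep & 1023) == 0) Rcpp::checkUserInterrupt();
    }
  } else {
    for (int rep = 0; rep < nreps; ++rep) {
      RowSets rows = rows0;
      for (int s = 0; s < nsteps_indep; ++s) curveball_trade(rows, mark);
      accumulate_cooccurrence(rows, ncols, counts);
      for (int p = 0; p < npairs; ++p) hist(p, counts[p])++;
      if ((rep & 255) == 0) Rcpp::checkUserInterrupt();
    }
  }
  PutRNGstate();
  return hist;
}

// Draw held-out null replicates and count, per pair, how often the
// replicate's co-occurrence exceeds the supplied threshold. Used for
// type-I-error calibration of the percentile test.
// [[Rcpp::export]]
IntegerVector cpp_null_exceedances(List rowsets, int ncols, int ndraws,
                                   int burnin, int thin,
                                   NumericVector threshold) {
  RowSets rows = as_rowsets(rowsets);
  int npairs = ncols * (ncols - 1) / 2;
  if (threshold.size() != npairs) stop("threshold length must equal npairs");
  IntegerVector exceed(npairs);
  std::vector<int> counts(npairs);
  std::vector<signed char> mark(ncols, 0);
  GetRNGstate();
  for (int s = 0; s < burnin; ++s) curveball_trade(rows, mark);
  for (int d = 0; d < ndraws; ++d) {
    for (int s = 0; s < thin; ++s) curveball_trade(rows, mark);
    accumulate_cooccurrence(rows, ncols, counts);
    for (int p = 0; p < npairs; ++p)
      if (counts[p] > threshold[p]) exceed[p]++;
    if ((d & 255) == 0) Rcpp::checkUserInterrupt();
  }
  PutRNGstate();
  return exceed;
}
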