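// Core tree-growing primitives: pseudo-observations (within-node marginal
// ranks), empirical copula tabulation on a K^r lattice (histogram + cumulative
// sums, O(p + K^r) per node) or at arbitrary evaluation points (O(p*q)), the
// three node costs, and the exhaustive best-split search over candidate
// (feature, threshold) partitions.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// average ranks (ties averaged) divided by p, so values lie in (0, 1]
static void pseudo_col(const std::vector<double>& v, std::vector<double>& u) {
  const int p = (int)v.size();
  std::vector<int> ord(p);
  for (int i = 0; i < p; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return v[a] < v[b]; });
  u.resize(p);
  int i = 0;
  while (i < p) {
    int j = i;
    while (j + 1 < p && v[ord[j + 1]] == v[ord[i]]) ++j;
    const double avg = 0.5 * ((i + 1) + (j + 1));
    for (int k = i; k <= j; ++k) u[ord[k]] = avg / p;
    i = j + 1;
  }
}

// empirical copula on the lattice {(k1/K,...,kr/K)}: bin each pseudo-
// observation into the smallest lattice cell dominating it, then take
// cumulative sums along every axis; grid stored in column-major multi-index
// order (dimension 1 fastest), matching R's array(dim = rep(K, r)).
static void lattice_copula(const std::vector<std::vector<double> >& U,
                           int K, std::vector<double>& grid) {
  const int r = (int)U.size();
  const int p = (int)U[0].size();
  long G = 1;
  for (int j = 0; j < r; ++j) G *= K;
  grid.assign((size_t)G, 0.0);
  for (int i = 0; i < p; ++i) {
    long idx = 0, mult = 1;
    for (int j = 0; j < r; ++j) {
      int a = (int)std::ceil(U[j][i] * K - 1e-9);
      if (a < 1) a = 1;
      if (a > K) a = K;
      idx += (long)(a - 1) * mult;
      mult *= K;
    }
    grid[idx] += 1.0;
  }
  long stride = 1;
  for (int j = 0; j < r; ++j) {
    // one pass per axis: G/K pencils, each of K cells spaced by `stride`
    const long pencils = G / K;
    for (long o = 0; o < pencils; ++o) {
      const long base = (o / stride) * stride * K + (o % stride);
      for (int k = 1; k < K; ++k)
        grid[base + (long)k * stride] += grid[base + (long)(k - 1) * stride];
    }
    stride *= K;
  }
  for (long g = 0; g < G; ++g) grid[g] /= p;
}

// copula values at arbitrary evaluation points (rows of E)
static void copula_at_points(const std::vector<std::vector<double> >& U,
                             const NumericMatrix& E,
                             std::vector<double>& vals) {
  const int r = (int)U.size();
  const int p = (int)U[0].size();
  const int q = E.nrow();
  vals.assign(q, 0.0);
  for (int e = 0; e < q; ++e) {
    int cnt = 0;
    for (int i = 0; i < p; ++i) {
      bool in = true;
      for (int j = 0; j < r; ++j) {
        if (U[j][i] > E(e, j) + 1e-12) { in = false; break; }
      }
      if (in) ++cnt;
    }
    vals[e] = (double)cnt / p;
  }
}

// [[Rcpp::export(name = ".pseudo_obs_cpp")]]
NumericMatrix pseudo_obs_cpp(NumericMatrix Y) {
  const int p = Y.nrow(), r = Y.ncol();
  NumericMatrix out(p, r);
  std::vector<double> v(p), u;
  for (int j = 0; j < r; ++j) {
    for (int i = 0; i < p; ++i) v[i] = Y(i, j);
    pseudo_col(v, u);
    for (int i = 0; i < p; ++i) out(i, j) = u[i];
  }
  return out;
}

// [[Rcpp::export(name = ".lattice_copula_cpp")]]
NumericVector lattice_copula_cpp(NumericMatrix U, int K) {
  const int p = U.nrow(), r = U.ncol();
  std::vector<std::vector<double> > cols(r, std::vector<double>(p));
  for (int j = 0; j < r; ++j)
    for (int i = 0; i < p; ++i) cols[j][i] = U(i, j);
  std::vector<double> grid;
  lattice_copula(cols, K, grid);
  return NumericVector(grid.begin(), grid.end());
}

// [[Rcpp::export(name = ".copula_values_cpp")]]
NumericVector copula_values_cpp(NumericMatrix U, NumericMatrix E) {
  const int p = U.nrow(), r = U.ncol();
  std::vector<std::vector<double> > cols(r, std::vector<double>(p));
  for (int j = 0; j < r; ++j)
    for (int i = 0; i < p; ++i) cols[j][i] = U(i, j);
  std::vector<double> vals;
  copula_at_points(cols, E, vals);
  return NumericVector(vals.begin(), vals.end());
}

// ---------------------------------------------------------------------------

struct CostSpec {
  int kind;                       // 0 = sse, 1 = mahalanobis, 2 = copula
  double alpha;
  const NumericVector* rootC;     // root copula values (lattice or points)
  int K;
  const NumericVector* sigma2;
  const NumericMatrix* prec;      // precision matrix (Lambda^-1)
  const NumericMatrix* evalPts;   // eval points when !useLattice
  bool useLattice;
  const NumericMatrix* nodeU;     // root pseudo-obs of node rows (optional)
  bool useNodeU;                  // reuse root marginals instead of re-ranking
};

// node cost over the rows listed in idx; for the copula cost also reports
// its two components D1 (copula distortion) and D2 (normalised SSE)
static double node_cost(const NumericMatrix& Y, const std::vector<int>& idx,
                        const CostSpec& cs, double* d1out, double* d2out) {
  const int p = (int)idx.size();
  const int r = Y.ncol();
  if (d1out) *d1out = 0.0;
  if (d2out) *d2out = 0.0;
  if (p == 0) return 0.0;

  if (cs.kind == 0) {          // sum of squared deviations, all columns
    double tot = 0.0;
    for (int j = 0; j < r; ++j) {
      double mu = 0.0;
      for (int i = 0; i < p; ++i) mu += Y(idx[i], j);
      mu /= p;
      for (int i = 0; i < p; ++i) {
        const double d = Y(idx[i], j) - mu;
        tot += d * d;
      }
    }
    return tot;
  }

  if (cs.kind == 1) {          // sum of squared Mahalanobis distances
    std::vector<double> mu(r, 0.0);
    for (int j = 0; j < r; ++j) {
      for (int i = 0; i < p; ++i) mu[j] += Y(idx[i], j);
      mu[j] /= p;
    }
    const NumericMatrix& P = *cs.prec;
    double tot = 0.0;
    std::vector<double> dev(r);
    for (int i = 0; i < p; ++i) {
      for (int j = 0; j < r; ++j) dev[j] = Y(idx[i], j) - mu[j];
      for (int a = 0; a < r; ++a)
        for (int b = 0; b < r; ++b) tot += dev[a] * P(a, b) * dev[b];
    }
    return tot;
  }

  // copula cost D1 + alpha * D2
  double d2 = 0.0;
  for (int j = 0; j < r; ++j) {
    double mu = 0.0;
    for (int i = 0; i < p; ++i) mu += Y(idx[i], j);
    mu /= p;
    double ss = 0.0;
    for (int i = 0; i < p; ++i) {
      const double d = Y(idx[i], j) - mu;
      ss += d * d;
    }
    d2 += ss / (*cs.sigma2)[j];
  }
  double d1 = 0.0;
  // a 1-D copula carries no dependence information and a < 3 point node's
  // empirical copula is vacuous: D1 is defined as 0 in both cases
  if (r >= 2 && p >= 3) {
    std::vector<std::vector<double> > cols(r, std::vector<double>(p));
    if (cs.useNodeU) {
      for (int j = 0; j < r; ++j)
        for (int i = 0; i < p; ++i) cols[j][i] = (*cs.nodeU)(idx[i], j);
    } else {
      std::vector<double> v(p), u;
      for (int j = 0; j < r; ++j) {
        for (int i = 0; i < p; ++i) v[i] = Y(idx[i], j);
        pseudo_col(v, u);
        cols[j] = u;
      }
    }
    std::vector<double> cvals;
    if (cs.useLattice) lattice_copula(cols, cs.K, cvals);
    else copula_at_points(cols, *cs.evalPts, cvals);
    const NumericVector& rootC = *cs.rootC;
    double s = 0.0;
    const int G = (int)cvals.size();
    for (int g = 0; g < G; ++g) s += std::fabs(cvals[g] - rootC[g]);
    const double psi = s / G;
    d1 = 6.0 * p * psi;
  }
  if (d1out) *d1out = d1;
  if (d2out) *d2out = d2;
  return d1 + cs.alpha * d2;
}

// Exhaustive best-split search. X and Y hold only the node's rows (bootstrap
// multiplicities already expanded). `features` are 0-based columns of X in
// ascending order; thresholds are the observed in-node values of the feature
// ("<= z goes left"), the maximum excluded since its right child is empty.
// Ties in gain resolve to the smallest feature index, then smallest
// threshold, by strict-greater comparison in iteration order.
// [[Rcpp::export(name = ".split_search_cpp")]]
List split_search_cpp(NumericMatrix X, NumericMatrix Y, IntegerVector features,
                      int kind, double alpha, NumericVector rootC, int K,
                      NumericVector sigma2, NumericMatrix prec,
                      NumericMatrix evalPts, bool useLattice, bool returnAll,
                      int minChild, NumericMatrix nodeU, bool useNodeU) {
  const int p = X.nrow();
  CostSpec cs;
  cs.kind = kind;
  cs.alpha = alpha;
  cs.rootC = &rootC;
  cs.K = K;
  cs.sigma2 = &sigma2;
  cs.prec = &prec;
  cs.evalPts = &evalPts;
  cs.useLattice = useLattice;
  cs.nodeU = &nodeU;
  cs.useNodeU = useNodeU;

  std::vector<int> all(p);
  for (int i = 0; i < p; ++i) all[i] = i;
  double pd1, pd2;
  const double parent = node_cost(Y, all, cs, &pd1, &pd2);
  // gains equal up to floating-point noise (e.g. complementary partitions
  // of the same two subsets reached through different features) count as
  // ties and resolve to the earlier candidate: smallest feature index,
  // then smallest threshold
  const double tieTol = 1e-9 * (1.0 + std::fabs(parent));

  bool found = false;
  double bestGain = 0.0, bestThr = 0.0;
  int bestFeat = -1, bestNL = 0;

  std::vector<double> cf, ct, cg, cd1l, cd2l, cd1r, cd2r;
  std::vector<int> cnl;

  std::vector<double> xv(p);
  std::vector<int> left, right;
  for (int fi = 0; fi < features.size(); ++fi) {
    const int f = features[fi];
    for (int i = 0; i < p; ++i) xv[i] = X(i, f);
    std::vector<double> thr(xv);
    std::sort(thr.begin(), thr.end());
    thr.erase(std::unique(thr.begin(), thr.end()), thr.end());
    if (thr.size() < 2) continue;  // constant feature: no valid partition
    for (size_t t = 0; t + 1 < thr.size(); ++t) {
      const double z = thr[t];
      left.clear();
      right.clear();
      for (int i = 0; i < p; ++i) {
        if (xv[i] <= z) left.push_back(i);
        else right.push_back(i);
      }
      if ((int)left.size() < minChild || (int)right.size() < minChild)
        continue;
      double ld1, ld2, rd1, rd2;
      const double cl = node_cost(Y, left, cs, &ld1, &ld2);
      const double cr = node_cost(Y, right, cs, &rd1, &rd2);
      const double gain = parent - cl - cr;
      if (!found || gain > bestGain + tieTol) {
        found = true;
        bestGain = gain;
        bestFeat = f;
        bestThr = z;
        bestNL = (int)left.size();
      }
      if (returnAll) {
        cf.push_back(f + 1);
        ct.push_back(z);
        cg.push_back(gain);
        cd1l.push_back(ld1);
        cd2l.push_back(ld2);
        cd1r.push_back(rd1);
        cd2r.push_back(rd2);
        cnl.push_back((int)left.size());
      }
    }
  }

  List out = List::create(
      _["found"] = found,
      _["feature"] = bestFeat + 1,  // 1-based column of X
      _["threshold"] = bestThr,
      _["gain"] = bestGain,
      _["n_left"] = bestNL,
      _["parent_cost"] = parent,
      _["parent_d1"] = pd1,
      _["parent_d2"] = pd2);
  if (returnAll) {
    out["candidates"] = DataFrame::create(
        _["feature"] = cf, _["threshold"] = ct, _["gain"] = cg,
        _["n_left"] = cnl, _["d1_left"] = cd1l, _["d2_left"] = cd2l,
        _["d1_right"] = cd1r, _["d2_right"] = cd2r);
  }
  return out;
}
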