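#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Adaptive partitioning of 2-D / 3-D rank space.
//
// Inputs are strict rank vectors: each a permutation of 1..n, so marginals
// are exactly uniform and every axis-aligned interval [lo, hi) holds exactly
// hi - lo points in that dimension.  A cell is split at the per-dimension
// lower median of the points it contains into 2^d half-open subcells.  A
// cell holding at least max_cell points is always subdivided (the initial
// partitioning / resolution floor); between min_cell and max_cell the split
// is accepted only when a chi-square test rejects local uniformity of the
// 2^d child counts (expected count/2^d each, df = 2^d - 1).  Leaves are
// emitted in recursion order (children visited in binary order: bit k set =
// upper half of dimension k), which fixes the summation order of the
// plug-in estimates.

namespace {

struct APBuilder {
  int n, d, min_cell, max_cell;
  double crit;                 // chi-square critical value, df = 2^d - 1
  const int *r[3];             // rank vectors (values 1..n)
  std::vector<int> idx;        // point indices, reordered in place
  std::vector<int> vals;       // scratch for median selection
  // emitted leaves
  std::vector<int> lo[3], hi[3], cnt;

  void emit(const int *clo, const int *chi, int c) {
    for (int k = 0; k < d; ++k) { lo[k].push_back(clo[k]); hi[k].push_back(chi[k]); }
    cnt.push_back(c);
  }

  int lower_median(int dim, int b, int e) {
    vals.resize(e - b);
    for (int i = b; i < e; ++i) vals[i - b] = r[dim][idx[i]];
    int m = (e - b - 1) / 2;   // lower median for even counts
    std::nth_element(vals.begin(), vals.begin() + m, vals.end());
    return vals[m];
  }

  void recurse(int b, int e, const int *clo, const int *chi) {
    const int c = e - b;
    const int K = 1 << d;
    int med[3] = {0, 0, 0};
    int cc[8] = {0, 0, 0, 0, 0, 0, 0, 0};
    bool split = false;
    if (c >= min_cell) {
      for (int k = 0; k < d; ++k) med[k] = lower_median(k, b, e);
      for (int i = b; i < e; ++i) {
        int bit = 0;
        for (int k = 0; k < d; ++k)
          if (r[k][idx[i]] > med[k]) bit |= (1 << k);
        cc[bit]++;
      }
      if (c >= max_cell) {
        split = true;
      } else {
        const double ex = double(c) / K;
        double stat = 0.0;
        for (int j = 0; j < K; ++j) {
          const double dd = cc[j] - ex;
          stat += dd * dd / ex;
        }
        if (stat > crit) split = true;
      }
    }
    if (!split) { emit(clo, chi, c); return; }
    // stable counting sort of the segment into the K child buckets
    int off[9];
    off[0] = b;
    for (int j = 0; j < K; ++j) off[j + 1] = off[j] + cc[j];
    std::vector<int> tmp(idx.begin() + b, idx.begin() + e);
    int pos[8];
    for (int j = 0; j < K; ++j) pos[j] = off[j];
    for (int t = 0; t < c; ++t) {
      const int i = tmp[t];
      int bit = 0;
      for (int k = 0; k < d; ++k)
        if (r[k][i] > med[k]) bit |= (1 << k);
      idx[pos[bit]++] = i;
    }
    for (int j = 0; j < K; ++j) {
      int nlo[3], nhi[3];
      for (int k = 0; k < d; ++k) {
        if (j & (1 << k)) { nlo[k] = med[k] + 1; nhi[k] = chi[k]; }
        else              { nlo[k] = clo[k];     nhi[k] = med[k] + 1; }
      }
      recurse(off[j], off[j + 1], nlo, nhi);
    }
  }

  void run(int dim, const IntegerVector *rv, double crit_, int min_cell_,
           int max_cell_) {
    d = dim;
    n = rv[0].size();
    crit = crit_;
    min_cell = min_cell_;
    max_cell = max_cell_ < min_cell_ ? min_cell_ : max_cell_;
    for (int k = 0; k < d; ++k) r[k] = INTEGER(rv[k]);
    idx.resize(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    int clo[3], chi_[3];
    for (int k = 0; k < d; ++k) { clo[k] = 1; chi_[k] = n + 1; }
    recurse(0, n, clo, chi_);
  }
};

// MI plug-in with exact width marginals and Miller-Madow correction of the
// joint term (the marginals carry no estimation error under rank inputs,
// so the joint plug-in is the only biased one).
double mi_value(const APBuilder &ap) {
  const double n = ap.n;
  double v = 0.0;
  int occ = 0;
  for (size_t i = 0; i < ap.cnt.size(); ++i) {
    if (ap.cnt[i] == 0) continue;
    occ = occ + 1;
    const double p  = ap.cnt[i] / n;
    const double px = (ap.hi[0][i] - ap.lo[0][i]) / n;
    const double py = (ap.hi[1][i] - ap.lo[1][i]) / n;
    v = v + p * std::log(p / (px * py));
  }
  v = v - (occ - 1.0) / (2.0 * n);
  if (v < 0.0) v = 0.0;
  return v;
}

double cmi_value(const APBuilder &ap,
                 const int *rtf, const int *rtg, const int *rm) {
  const double n = ap.n;
  const int npt = ap.n;
  double v = 0.0;
  for (size_t i = 0; i < ap.cnt.size(); ++i) {
    if (ap.cnt[i] == 0) continue;
    const int l0 = ap.lo[0][i], h0 = ap.hi[0][i];
    const int l1 = ap.lo[1][i], h1 = ap.hi[1][i];
    const int l2 = ap.lo[2][i], h2 = ap.hi[2][i];
    int ctfm = 0, ctgm = 0;
    for (int j = 0; j < npt; ++j) {
      if (rm[j] < l2 || rm[j] >= h2) continue;
      if (rtf[j] >= l0 && rtf[j] < h0) ctfm++;
      if (rtg[j] >= l1 && rtg[j] < h1) ctgm++;
    }
    const double p3   = ap.cnt[i] / n;
    const double pm   = (h2 - l2) / n;
    const double ptfm = ctfm / n;
    const double ptgm = ctgm / n;
    v = v + p3 * std::log((pm * p3) / (ptfm * ptgm));
  }
  if (v < 0.0) v = 0.0;
  return v;
}

} // namespace

// [[Rcpp::export(name = ".ap_partition_cpp")]]
List ap_partition_cpp(List ranks, double crit, int min_cell, int max_cell) {
  const int d = ranks.size();
  if (d < 2 || d > 3) stop("ranks must hold 2 or 3 rank vectors");
  IntegerVector rv[3];
  for (int k = 0; k < d; ++k) rv[k] = ranks[k];
  for (int k = 1; k < d; ++k)
    if (rv[k].size() != rv[0].size()) stop("rank vectors differ in length");
  APBuilder ap;
  ap.run(d, rv, crit, min_cell, max_cell);
  const int nc = ap.cnt.size();
  IntegerMatrix lo(nc, d), hi(nc, d);
  for (int k = 0; k < d; ++k)
    for (int i = 0; i < nc; ++i) { lo(i, k) = ap.lo[k][i]; hi(i, k) = ap.hi[k][i]; }
  return List::create(_["lo"] = lo, _["hi"] = hi,
                      _["count"] = IntegerVector(ap.cnt.begin(), ap.cnt.end()),
                      _["n"] = ap.n);
}

// [[Rcpp::export(name = ".ap_mi_cpp")]]
double ap_mi_cpp(IntegerVector rx, IntegerVector ry, double crit,
                 int min_cell, int max_cell) {
  if (ry.size() != rx.size()) stop("rank vectors differ in length");
  IntegerVector rv[3] = {rx, ry, IntegerVector()};
  APBuilder ap;
  ap.run(2, rv, crit, min_cell, max_cell);
  return mi_value(ap);
}

// [[Rcpp::export(name = ".ap_cmi_cpp")]]
double ap_cmi_cpp(IntegerVector rtf, IntegerVector rtg, IntegerVector rm,
                  double crit, int min_cell, int max_cell) {
  if (rtg.size() != rtf.size() || rm.size() != rtf.size())
    stop("rank vectors differ in length");
  IntegerVector rv[3] = {rtf, rtg, rm};
  APBuilder ap;
  ap.run(3, rv, crit, min_cell, max_cell);
  return cmi_value(ap, INTEGER(rtf), INTEGER(rtg), INTEGER(rm));
}

// CMI of one (tf, tg) pair against many modulator rank vectors (columns of
// rms); the hot loop of the permutation null.
// [[Rcpp::export(name = ".ap_cmi_many_cpp")]]
NumericVector ap_cmi_many_cpp(IntegerVector rtf, IntegerVector rtg,
                              IntegerMatrix rms, double crit,
                              int min_cell, int max_cell) {
  const int n = rtf.size();
  if (rtg.size() != n || rms.nrow() != n)
    stop("rank vectors differ in length");
  const int m = rms.ncol();
  NumericVector out(m);
  IntegerVector col(n);
  for (int j = 0; j < m; ++j) {
    for (int i = 0; i < n; ++i) col[i] = rms(i, j);
    IntegerVector rv[3] = {rtf, rtg, col};
    APBuilder ap;
    ap.run(3, rv, crit, min_cell, max_cell);
    out[j] = cmi_value(ap, INTEGER(rtf), INTEGER(rtg), INTEGER(col));
  }
  return out;
}

// dense re-rank of distinct integers (1..k in value order)
static void rerank(const std::vector<int> &v, std::vector<int> &out) {
  const int k = v.size();
  std::vector<int> ord(k);
  for (int i = 0; i < k; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return v[a] < v[b]; });
  out.resize(k);
  for (int i = 0; i < k; ++i) out[ord[i]] = i + 1;
}

static double mi_of_ints(const std::vector<int> &x, const std::vector<int> &y,
                         double crit, int min_cell, int max_cell) {
  std::vector<int> rx, ry;
  rerank(x, rx);
  rerank(y, ry);
  IntegerVector vx(rx.begin(), rx.end()), vy(ry.begin(), ry.end());
  IntegerVector rv[3] = {vx, vy, IntegerVector()};
  APBuilder ap;
  ap.run(2, rv, crit, min_cell, max_cell);
  return mi_value(ap);
}

// Tail-restricted MI difference under tail-label permutations.
// rtf, rtg: global ranks of the 2t samples forming the pooled tails
// (first t entries = observed high tail, last t = observed low tail).
// perms: each column a permutation of 1..2t assigning pooled samples to
// tails (first t -> high).  Returns I_high - I_low per column.
// [[Rcpp::export(name = ".delta_i_perm_cpp")]]
NumericVector delta_i_perm_cpp(IntegerVector rtf, IntegerVector rtg,
                               IntegerMatrix perms, int t,
                               double crit, int min_cell, int max_cell) {
  const int n2 = rtf.size();
  if (rtg.size() != n2 || perms.nrow() != n2 || 2 * t != n2)
    stop("inconsistent tail sizes");
  const int m = perms.ncol();
  NumericVector out(m);
  std::vector<int> xh(t), yh(t), xl(t), yl(t);
  for (int j = 0; j < m; ++j) {
    for (int i = 0; i < t; ++i) {
      const int hi_i = perms(i, j) - 1, lo_i = perms(t + i, j) - 1;
      xh[i] = rtf[hi_i]; yh[i] = rtg[hi_i];
      xl[i] = rtf[lo_i]; yl[i] = rtg[lo_i];
    }
    out[j] = mi_of_ints(xh, yh, crit, min_cell, max_cell) -
             mi_of_ints(xl, yl, crit, min_cell, max_cell);
  }
  return out;
}

// CMI of one (tf, m) conditioning pair against many target rank vectors
// (columns of rtgs); the hot loop of genome-scale triplet scoring.  Each
// (tf, tg) pair is canonically ordered (lexicographically smaller vector
// first) exactly as estimate_cmi() does, so batch and scalar paths agree
// bit for bit.
// [[Rcpp::export(name = ".ap_cmi_batch_cpp")]]
NumericVector ap_cmi_batch_cpp(IntegerVector rtf, IntegerMatrix rtgs,
                               IntegerVector rm, double crit,
                               int min_cell, int max_cell) {
  const int n = rtf.size();
  if (rtgs.nrow() != n || rm.size() != n)
    stop("rank vectors differ in length");
  const int m = rtgs.ncol();
  NumericVector out(m);
  IntegerVector col(n);
  for (int j = 0; j < m; ++j) {
    for (int i = 0; i < n; ++i) col[i] = rtgs(i, j);
    bool swap = false;
    for (int i = 0; i < n; ++i) {
      if (rtf[i] != col[i]) { swap = rtf[i] > col[i]; break; }
    }
    IntegerVector a = swap ? col : rtf;
    IntegerVector b = swap ? rtf : col;
    IntegerVector rv[3] = {a, b, rm};
    APBuilder ap;
    ap.run(3, rv, crit, min_cell, max_cell);
    out[j] = cmi_value(ap, INTEGER(a), INTEGER(b), INTEGER(rm));
  }
  return out;
}
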