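// Exact dynamic programming kernels for PFM hit statistics.
//
// All scores live on an integer bin grid: each (column, letter) log-odds
// contribution is rounded once to round(score / bin_width) and every word
// score is the exact integer sum of those binned contributions. The hit
// threshold is a bin index, so the DP, the threshold search and the
// brute-force enumeration all share one discrete score definition and agree
// exactly (up to floating point summation order of probabilities).
//
// A contribution of NA_INTEGER marks log(0) = -Inf (only possible with
// pseudo = 0); any word using such a letter can never be a hit.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
#include <climits>
#include <string>

using namespace Rcpp;

static inline uint64_t pack_key(int su, int sv) {
  return (static_cast<uint64_t>(static_cast<uint32_t>(su + (1 << 29))) << 32) |
         static_cast<uint32_t>(sv + (1 << 29));
}
static inline int key_su(uint64_t k) {
  return static_cast<int>(static_cast<uint32_t>(k >> 32)) - (1 << 29);
}
static inline int key_sv(uint64_t k) {
  return static_cast<int>(static_cast<uint32_t>(k & 0xffffffffu)) - (1 << 29);
}

// Column-major accessor for a 4 x L contribution matrix.
struct BinnedMotif {
  int L;
  const int* c; // c[4*j + b]
  int t;        // threshold bin (hit iff sum >= t)
  inline int at(int b, int j) const { return c[4 * j + b]; }
};

// [[Rcpp::export]]
List cpp_score_dist(IntegerMatrix contrib, NumericMatrix weights) {
  const int L = contrib.ncol();
  if (contrib.nrow() != 4 || weights.nrow() != 4 || weights.ncol() != L)
    stop("contrib must be 4 x L and weights must match");
  std::vector<int> cmin(L), cmax(L);
  for (int j = 0; j < L; ++j) {
    int mn = INT_MAX, mx = INT_MIN;
    for (int b = 0; b < 4; ++b) {
      int v = contrib(b, j);
      if (v != NA_INTEGER) { if (v < mn) mn = v; if (v > mx) mx = v; }
    }
    if (mn == INT_MAX) { mn = 0; mx = 0; } // column fully -Inf: everything sinks
    cmin[j] = mn; cmax[j] = mx;
  }
  std::vector<double> cur(1, 1.0);
  long curlo = 0;
  double sink = 0.0;
  for (int j = 0; j < L; ++j) {
    double deadw = 0.0;
    bool anyfinite = false;
    for (int b = 0; b < 4; ++b) {
      if (contrib(b, j) == NA_INTEGER) deadw += weights(b, j);
      else anyfinite = true;
    }
    double mass = 0.0;
    for (double p : cur) mass += p;
    sink += mass * deadw;
    if (!anyfinite) { // all mass gone
      cur.assign(1, 0.0);
      continue;
    }
    long newlo = curlo + cmin[j];
    size_t newsize = cur.size() + static_cast<size_t>(cmax[j] - cmin[j]);
    std::vector<double> nxt(newsize, 0.0);
    for (size_t i = 0; i < cur.size(); ++i) {
      double p = cur[i];
      if (p == 0.0) continue;
      for (int b = 0; b < 4; ++b) {
        int v = contrib(b, j);
        if (v == NA_INTEGER) continue;
        nxt[i + static_cast<size_t>(v - cmin[j])] += p * weights(b, j);
      }
    }
    cur.swap(nxt);
    curlo = newlo;
  }
  return List::create(_["offset"] = static_cast<double>(curlo),
                      _["probs"] = NumericVector(cur.begin(), cur.end()),
                      _["sink"] = sink);
}

// Exact overlap-hit probability gamma_{X,Y}(k): probability under the iid
// background that one sequence covering the union window carries a hit of X
// (at position 0) and of Y (at position k) simultaneously.
//
// Phases: (1) joint DP over the overlap columns tracking the pair of partial
// score sums, pruning pairs that can no longer reach either threshold;
// (2) X-only rest columns, saturating states that are guaranteed to hit;
// (3) Y-only rest columns. Pruning/saturation use exact integer bounds, so
// the result is exact.
static double gamma_kernel(const BinnedMotif& X, const BinnedMotif& Y,
                           const double* bg, int k) {
  const int ov_lo = std::max(0, k), ov_hi = std::min(X.L, k + Y.L);
  const int nov = ov_hi - ov_lo;
  if (nov < 1) return NA_REAL;

  // Per-column finite max/min (max INT_MIN => column dead => gamma 0).
  auto colmax = [](const BinnedMotif& M, int j) {
    int mx = INT_MIN;
    for (int b = 0; b < 4; ++b) { int v = M.at(b, j); if (v != NA_INTEGER && v > mx) mx = v; }
    return mx;
  };
  auto colmin = [](const BinnedMotif& M, int j) {
    int mn = INT_MAX;
    for (int b = 0; b < 4; ++b) { int v = M.at(b, j); if (v != NA_INTEGER && v < mn) mn = v; }
    return mn;
  };
  for (int j = 0; j < X.L; ++j) if (colmax(X, j) == INT_MIN) return 0.0;
  for (int j = 0; j < Y.L; ++j) if (colmax(Y, j) == INT_MIN) return 0.0;

  // Rest (non-overlap) column lists.
  std::vector<int> xrest, yrest;
  for (int j = 0; j < ov_lo; ++j) xrest.push_back(j);
  for (int j = ov_hi; j < X.L; ++j) xrest.push_back(j);
  for (int j = 0; j < ov_lo - k; ++j) yrest.push_back(j);
  for (int j = ov_hi - k; j < Y.L; ++j) yrest.push_back(j);

  long xrest_max = 0, yrest_max = 0;
  for (int j : xrest) xrest_max += colmax(X, j);
  for (int j : yrest) yrest_max += colmax(Y, j);

  // Suffix max-sums over overlap columns (bound on remaining gain).
  std::vector<long> xov_sufmax(nov + 1, 0), yov_sufmax(nov + 1, 0);
  for (int c = nov - 1; c >= 0; --c) {
    xov_sufmax[c] = xov_sufmax[c + 1] + colmax(X, ov_lo + c);
    yov_sufmax[c] = yov_sufmax[c + 1] + colmax(Y, ov_lo + c - k);
  }

  typedef std::unordered_map<uint64_t, double> PairMap;
  PairMap cur, nxt;
  cur.reserve(64);
  cur[pack_key(0, 0)] = 1.0;
  for (int c = 0; c < nov; ++c) {
    nxt.clear();
    const int xj = ov_lo + c, yj = ov_lo + c - k;
    const long xbound = xov_sufmax[c + 1] + xrest_max; // max gain after col c
    const long ybound = yov_sufmax[c + 1] + yrest_max;
    for (PairMap::const_iterator it = cur.begin(); it != cur.end(); ++it) {
      const int su = key_su(it->first), sv = key_sv(it->first);
      const double p = it->second;
      for (int b = 0; b < 4; ++b) {
        const int cx = X.at(b, xj), cy = Y.at(b, yj);
        if (cx == NA_INTEGER || cy == NA_INTEGER) continue;
        const int su2 = su + cx, sv2 = sv + cy;
        if (su2 + xbound < X.t || sv2 + ybound < Y.t) continue;
        nxt[pack_key(su2, sv2)] += p * bg[b];
      }
    }
    cur.swap(nxt);
    if (cur.empty()) return 0.0;
  }

  // Phase 2: finish the side with FEWER rest columns first, over the pair
  // states, and collapse it into a "hit secured" 1D distribution over the
  // other side's partial sum; then finish the other side in 1D. Collapsing
  // early keeps the pair maps as small as the overlap DP left them.
  struct RestBounds {
    std::vector<long> sufmax, sufmin;
    std::vector<bool> clean; // no -Inf letters downstream
  };
  auto rest_bounds = [&](const BinnedMotif& M, const std::vector<int>& cols) {
    const size_t nc = cols.size();
    RestBounds rb;
    rb.sufmax.assign(nc + 1, 0);
    rb.sufmin.assign(nc + 1, 0);
    rb.clean.assign(nc + 1, true);
    for (int c = static_cast<int>(nc) - 1; c >= 0; --c) {
      const int j = cols[c];
      rb.sufmax[c] = rb.sufmax[c + 1] + colmax(M, j);
      rb.sufmin[c] = rb.sufmin[c + 1] + colmin(M, j);
      bool cl = true;
      for (int b = 0; b < 4; ++b) if (M.at(b, j) == NA_INTEGER) cl = false;
      rb.clean[c] = cl && rb.clean[c + 1];
    }
    return rb;
  };

  const bool x_first = xrest.size() <= yrest.size();
  const BinnedMotif& A = x_first ? X : Y; // finished first (moving side)
  const BinnedMotif& B = x_first ? Y : X; // finished second
  const std::vector<int>& arest = x_first ? xrest : yrest;
  const std::vector<int>& brest = x_first ? yrest : xrest;
  // reorder pair keys so the moving coordinate comes first
  auto get_move = x_first ? key_su : key_sv;
  auto get_keep = x_first ? key_sv : key_su;

  RestBounds ra = rest_bounds(A, arest);
  const size_t na = arest.size();
  std::unordered_map<int, double> keepacc; // kept sum -> prob, A hit secured
  for (size_t c = 0; c <= na; ++c) {
    nxt.clear();
    const bool last = (c == na);
    for (PairMap::const_iterator it = cur.begin(); it != cur.end(); ++it) {
      const int sa = get_move(it->first), sb = get_keep(it->first);
      const double p = it->second;
      if (ra.clean[c] && sa + ra.sufmin[c] >= A.t) { keepacc[sb] += p; continue; }
      if (last) continue; // sa < t at the end: A missed
      if (sa + ra.sufmax[c] < A.t) continue;
      const int j = arest[c];
      for (int b = 0; b < 4; ++b) {
        const int ca = A.at(b, j);
        if (ca == NA_INTEGER) continue;
        const int sa2 = sa + ca;
        nxt[x_first ? pack_key(sa2, sb) : pack_key(sb, sa2)] += p * bg[b];
      }
    }
    if (!last) cur.swap(nxt);
  }
  if (keepacc.empty()) return 0.0;

  // Phase 3: B's rest columns, 1D.
  RestBounds rb = rest_bounds(B, brest);
  const size_t nb = brest.size();
  std::unordered_map<int, double> vcur(keepacc), vnxt;
  double gamma = 0.0;
  for (size_t c = 0; c <= nb; ++c) {
    vnxt.clear();
    const bool last = (c == nb);
    for (std::unordered_map<int, double>::const_iterator it = vcur.begin();
         it != vcur.end(); ++it) {
      const int sb = it->first;
      const double p = it->second;
      if (rb.clean[c] && sb + rb.sufmin[c] >= B.t) { gamma += p; continue; }
      if (last) continue;
      if (sb + rb.sufmax[c] < B.t) continue;
      const int j = brest[c];
      for (int b = 0; b < 4; ++b) {
        const int cb = B.at(b, j);
        if (cb == NA_INTEGER) continue;
        vnxt[sb + cb] += p * bg[b];
      }
    }
    if (!last) vcur.swap(vnxt);
  }
  return gamma;
}

// [[Rcpp::export]]
double cpp_gamma(IntegerMatrix cX, int tX, IntegerMatrix cY, int tY,
                 NumericVector bg, int k) {
  if (cX.nrow() != 4 || cY.nrow() != 4) stop("contribution matrices must be 4 x L");
  BinnedMotif X = { static_cast<int>(cX.ncol()), INTEGER(cX), tX };
  BinnedMotif Y = { static_cast<int>(cY.ncol()), INTEGER(cY), tY };
  if (k < -(Y.L - 1) || k > X.L - 1) stop("offset k outside the overlap range");
  return gamma_kernel(X, Y, REAL(bg), k);
}

// Offsets ordered by (|k|, k): the documented tie order within an orientation.
static std::vector<int> ordered_offsets(int Lx, int Ly) {
  std::vector<int> ks;
  for (int k = -(Ly - 1); k <= Lx - 1; ++k) ks.push_back(k);
  std::stable_sort(ks.begin(), ks.end(), [](int a, int b) {
    int aa = a < 0 ? -a : a, bb = b < 0 ? -b : b;
    if (aa != bb) return aa < bb;
    return a < b;
  });
  return ks;
}

// [[Rcpp::export]]
List cpp_smax(IntegerMatrix cX, int tX, double alphaX,
              IntegerMatrix cYf, int tYf, double alphaYf,
              IntegerMatrix cYr, int tYr, double alphaYr,
              NumericVector bg) {
  BinnedMotif X = { static_cast<int>(cX.ncol()), INTEGER(cX), tX };
  BinnedMotif Yf = { static_cast<int>(cYf.ncol()), INTEGER(cYf), tYf };
  BinnedMotif Yr = { static_cast<int>(cYr.ncol()), INTEGER(cYr), tYr };
  const double* b = REAL(bg);
  double best = R_NegInf, best_gamma = 0.0;
  int best_k = 0, best_orient = 0;
  bool have = false;
  for (int orient = 0; orient < 2; ++orient) {
    const BinnedMotif& Y = orient == 0 ? Yf : Yr;
    const double aY = orient == 0 ? alphaYf : alphaYr;
    std::vector<int> ks = ordered_offsets(X.L, Y.L);
    for (size_t i = 0; i < ks.size(); ++i) {
      double g = gamma_kernel(X, Y, b, ks[i]);
      double s = (g > 0.0) ? std::log(g / (alphaX * aY)) : R_NegInf;
      if (!have || s > best) {
        best = s; best_gamma = g; best_k = ks[i]; best_orient = orient;
        have = true;
      }
    }
  }
  return List::create(_["s_max"] = best, _["gamma"] = best_gamma,
                      _["offset"] = best_k, _["orientation"] = best_orient);
}

// Brute-force oracle: enumerate every word over the union window at each
// offset, classify both hits directly, and accumulate background mass.
static double gamma_enum(const BinnedMotif& X, const BinnedMotif& Y,
                         const double* bg, int k) {
  const int ulo = std::min(0, k), uhi = std::max(X.L, k + Y.L);
  const int len = uhi - ulo;
  double total = 0.0;
  // iterative DFS with incremental sums
  std::vector<int> letter(len, -1);
  std::vector<double> prob(len + 1); prob[0] = 1.0;
  std::vector<long> sx(len + 1, 0), sy(len + 1, 0);
  std::vector<bool> alive(len + 1, true);
  int d = 0;
  while (d >= 0) {
    if (d == len) {
      if (alive[len] && sx[len] >= X.t && sy[len] >= Y.t) total += prob[len];
      --d;
      continue;
    }
    int b = ++letter[d];
    if (b > 3) { letter[d] = -1; --d; continue; }
    const int pos = ulo + d;
    long nsx = sx[d], nsy = sy[d];
    bool ok = alive[d];
    if (pos >= 0 && pos < X.L) {
      int v = X.at(b, pos);
      if (v == NA_INTEGER) ok = false; else nsx += v;
    }
    if (pos >= k && pos < k + Y.L) {
      int v = Y.at(b, pos - k);
      if (v == NA_INTEGER) ok = false; else nsy += v;
    }
    prob[d + 1] = prob[d] * bg[b];
    sx[d + 1] = nsx; sy[d + 1] = nsy; alive[d + 1] = ok;
    ++d;
  }
  return total;
}

// [[Rcpp::export]]
double cpp_gamma_brute(IntegerMatrix cX, int tX, IntegerMatrix cY, int tY,
                       NumericVector bg, int k) {
  BinnedMotif X = { static_cast<int>(cX.ncol()), INTEGER(cX), tX };
  BinnedMotif Y = { static_cast<int>(cY.ncol()), INTEGER(cY), tY };
  if (k < -(Y.L - 1) || k > X.L - 1) stop("offset k outside the overlap range");
  const int len = std::max(X.L, k + Y.L) - std::min(0, k);
  if (len > 12) stop("union window longer than 12 columns: enumeration refused");
  return gamma_enum(X, Y, REAL(bg), k);
}

// [[Rcpp::export]]
List cpp_smax_brute(IntegerMatrix cX, int tX, double alphaX,
                    IntegerMatrix cYf, int tYf, double alphaYf,
                    IntegerMatrix cYr, int tYr, double alphaYr,
                    NumericVector bg) {
  BinnedMotif X = { static_cast<int>(cX.ncol()), INTEGER(cX), tX };
  BinnedMotif Yf = { static_cast<int>(cYf.ncol()), INTEGER(cYf), tYf };
  BinnedMotif Yr = { static_cast<int>(cYr.ncol()), INTEGER(cYr), tYr };
  if (X.L + Yf.L - 1 > 12)
    stop("union window longer than 12 columns: enumeration refused");
  const double* b = REAL(bg);
  double best = R_NegInf, best_gamma = 0.0;
  int best_k = 0, best_orient = 0;
  bool have = false;
  for (int orient = 0; orient < 2; ++orient) {
    const BinnedMotif& Y = orient == 0 ? Yf : Yr;
    const double aY = orient == 0 ? alphaYf : alphaYr;
    std::vector<int> ks = ordered_offsets(X.L, Y.L);
    for (size_t i = 0; i < ks.size(); ++i) {
      double g = gamma_enum(X, Y, b, ks[i]);
      double s = (g > 0.0) ? std::log(g / (alphaX * aY)) : R_NegInf;
      if (!have || s > best) {
        best = s; best_gamma = g; best_k = ks[i]; best_orient = orient;
        have = true;
      }
    }
  }
  return List::create(_["s_max"] = best, _["gamma"] = best_gamma,
                      _["offset"] = best_k, _["orientation"] = best_orient);
}

// ---------------------------------------------------------------------------
// Fast S^max path: per offset, a DFS over the overlap columns only, with the
// non-overlap ("rest") score contributions of both motifs folded in as
// precomputed tail-probability tables. Exact: rest columns are independent of
// the overlap letters, so
//   gamma(k) = sum_{overlap words w} bg(w)
//              * P(A rest >= tA - sA(w)) * P(B rest >= tB - sB(w)).
// The tables are dense distributions over the integer score grid; building
// them once per motif pair (or once per candidate in batch scoring) removes
// all hashing from the hot loop. Offsets whose overlap exceeds MAX_DFS_OV
// columns fall back to the joint-DP kernel above.
// ---------------------------------------------------------------------------

static const int MAX_DFS_OV = 8;

struct HitM {
  int L;
  const int* c;
  int t;
  double alpha;
  inline int at(int b, int j) const { return c[4 * j + b]; }
};

struct Dense {
  long lo;                // score bin of tail[0]
  std::vector<double> tail; // tail[i] = P(sum >= lo + i); empty rest: lo=0,{1}
  long maxsum;            // largest attainable sum (pruning bound)
  inline double at(long theta) const {
    if (theta <= lo) return 1.0;
    long i = theta - lo;
    if (i >= static_cast<long>(tail.size())) return 0.0;
    return tail[i];
  }
};

// Distribution of the sum over columns [a0,a1) + [b0,b1) of M under bg,
// returned as a tail table. Dead (-Inf) letters drop their mass: words using
// them can never reach a finite threshold.
static Dense rest_dist(const HitM& M, int a0, int a1, int b0, int b1,
                       const double* bg) {
  std::vector<int> cols;
  for (int j = a0; j < a1; ++j) cols.push_back(j);
  for (int j = b0; j < b1; ++j) cols.push_back(j);
  long lo = 0, hi = 0;
  std::vector<double> cur(1, 1.0);
  for (size_t ci = 0; ci < cols.size(); ++ci) {
    const int j = cols[ci];
    int mn = INT_MAX, mx = INT_MIN;
    for (int b = 0; b < 4; ++b) {
      int v = M.at(b, j);
      if (v != NA_INTEGER) { if (v < mn) mn = v; if (v > mx) mx = v; }
    }
    if (mn == INT_MAX) { // column fully dead: no finite mass at all
      Dense d; d.lo = 0; d.tail.assign(1, 0.0); d.maxsum = LONG_MIN / 4;
      return d;
    }
    std::vector<double> nxt(cur.size() + static_cast<size_t>(mx - mn), 0.0);
    for (size_t i = 0; i < cur.size(); ++i) {
      const double p = cur[i];
      if (p == 0.0) continue;
      for (int b = 0; b < 4; ++b) {
        int v = M.at(b, j);
        if (v == NA_INTEGER) continue;
        nxt[i + static_cast<size_t>(v - mn)] += p * bg[b];
      }
    }
    cur.swap(nxt);
    lo += mn; hi += mx;
  }
  Dense d;
  d.lo = lo;
  d.maxsum = hi;
  d.tail.assign(cur.size(), 0.0);
  double acc = 0.0;
  for (long i = static_cast<long>(cur.size()) - 1; i >= 0; --i) {
    acc += cur[i];
    d.tail[i] = acc;
  }
  return d;
}

// gamma at one offset via overlap DFS + rest tail lookups.
// kB: offset of B relative to A (A is the shorter motif, so the overlap has
// at most L_A columns). tailA/tailB describe the rest of each motif for this
// offset.
// Columns are visited in order of decreasing joint score range so threshold
// pruning binds as close to the DFS root as possible (a permutation of
// independent columns leaves the result unchanged).
static void overlap_order(const HitM& A, const HitM& B, int kB, int ov_lo,
                          int nov, std::vector<int>& ord) {
  ord.resize(nov);
  std::vector<long> range(nov);
  for (int c = 0; c < nov; ++c) {
    ord[c] = c;
    int mxa = INT_MIN, mna = INT_MAX, mxb = INT_MIN, mnb = INT_MAX;
    for (int b = 0; b < 4; ++b) {
      int va = A.at(b, ov_lo + c), vb = B.at(b, ov_lo + c - kB);
      if (va != NA_INTEGER) { mxa = std::max(mxa, va); mna = std::min(mna, va); }
      if (vb != NA_INTEGER) { mxb = std::max(mxb, vb); mnb = std::min(mnb, vb); }
    }
    range[c] = (mxa == INT_MIN || mxb == INT_MIN)
      ? LONG_MAX // dead column: visit first, kills everything
      : static_cast<long>(mxa - mna) + (mxb - mnb);
  }
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return range[a] > range[b]; });
}

static double gamma_dfs(const HitM& A, const HitM& B, const double* bg,
                        int kB, const Dense& tailA, const Dense& tailB) {
  const int ov_lo = std::max(0, kB), ov_hi = std::min(A.L, kB + B.L);
  const int nov = ov_hi - ov_lo;
  std::vector<int> ord;
  overlap_order(A, B, kB, ov_lo, nov, ord);
  // permuted contributions, and per-level pruning bounds (max attainable
  // from remaining overlap + rest)
  std::vector<int> ca(4 * nov), cb(4 * nov);
  std::vector<long> remA(nov + 1), remB(nov + 1);
  remA[nov] = tailA.maxsum; remB[nov] = tailB.maxsum;
  for (int c = nov - 1; c >= 0; --c) {
    int mxa = INT_MIN, mxb = INT_MIN;
    for (int b = 0; b < 4; ++b) {
      int va = A.at(b, ov_lo + ord[c]), vb = B.at(b, ov_lo + ord[c] - kB);
      ca[4 * c + b] = va; cb[4 * c + b] = vb;
      if (va != NA_INTEGER && va > mxa) mxa = va;
      if (vb != NA_INTEGER && vb > mxb) mxb = vb;
    }
    if (mxa == INT_MIN || mxb == INT_MIN) return 0.0; // dead overlap column
    remA[c] = remA[c + 1] + mxa;
    remB[c] = remB[c + 1] + mxb;
  }
  double gamma = 0.0;
  std::vector<int> letter(nov, -1);
  std::vector<double> prob(nov + 1); prob[0] = 1.0;
  std::vector<long> sa(nov + 1, 0), sb(nov + 1, 0);
  int d = 0;
  while (d >= 0) {
    if (d == nov) {
      gamma += prob[nov] * tailA.at(A.t - sa[nov]) * tailB.at(B.t - sb[nov]);
      --d;
      continue;
    }
    int b = ++letter[d];
    if (b > 3) { letter[d] = -1; --d; continue; }
    const int va = ca[4 * d + b], vb = cb[4 * d + b];
    if (va == NA_INTEGER || vb == NA_INTEGER) continue;
    const long nsa = sa[d] + va, nsb = sb[d] + vb;
    if (nsa + remA[d + 1] < A.t || nsb + remB[d + 1] < B.t) continue;
    prob[d + 1] = prob[d] * bg[b];
    sa[d + 1] = nsa; sb[d + 1] = nsb;
    ++d;
  }
  return gamma;
}

// gamma at one offset for overlaps too long to enumerate: joint hash DP over
// the overlap columns (binned sums merge states), then the same rest tail
// lookups as the DFS path. Exact; pruning uses the rest maxima.
static double gamma_ov_hash(const HitM& A, const HitM& B, const double* bg,
                            int kB, const Dense& tailA, const Dense& tailB) {
  const int ov_lo = std::max(0, kB), ov_hi = std::min(A.L, kB + B.L);
  const int nov = ov_hi - ov_lo;
  std::vector<int> ord;
  overlap_order(A, B, kB, ov_lo, nov, ord);
  std::vector<long> remA(nov + 1), remB(nov + 1);
  remA[nov] = tailA.maxsum; remB[nov] = tailB.maxsum;
  for (int c = nov - 1; c >= 0; --c) {
    int mxa = INT_MIN, mxb = INT_MIN;
    for (int b = 0; b < 4; ++b) {
      int va = A.at(b, ov_lo + ord[c]), vb = B.at(b, ov_lo + ord[c] - kB);
      if (va != NA_INTEGER && va > mxa) mxa = va;
      if (vb != NA_INTEGER && vb > mxb) mxb = vb;
    }
    if (mxa == INT_MIN || mxb == INT_MIN) return 0.0;
    remA[c] = remA[c + 1] + mxa;
    remB[c] = remB[c + 1] + mxb;
  }
  std::unordered_map<uint64_t, double> cur, nxt;
  cur.reserve(64);
  cur[pack_key(0, 0)] = 1.0;
  for (int c = 0; c < nov; ++c) {
    nxt.clear();
    for (std::unordered_map<uint64_t, double>::const_iterator it = cur.begin();
         it != cur.end(); ++it) {
      const int sa = key_su(it->first), sb = key_sv(it->first);
      const double p = it->second;
      for (int b = 0; b < 4; ++b) {
        const int va = A.at(b, ov_lo + ord[c]), vb = B.at(b, ov_lo + ord[c] - kB);
        if (va == NA_INTEGER || vb == NA_INTEGER) continue;
        const long nsa = sa + va, nsb = sb + vb;
        if (nsa + remA[c + 1] < A.t || nsb + remB[c + 1] < B.t) continue;
        nxt[pack_key(static_cast<int>(nsa), static_cast<int>(nsb))] += p * bg[b];
      }
    }
    cur.swap(nxt);
    if (cur.empty()) return 0.0;
  }
  double gamma = 0.0;
  for (std::unordered_map<uint64_t, double>::const_iterator it = cur.begin();
       it != cur.end(); ++it) {
    gamma += it->second * tailA.at(A.t - key_su(it->first)) *
             tailB.at(B.t - key_sv(it->first));
  }
  return gamma;
}

// Rest-tail tables of the longer motif B against a shorter window of length
// La: entry a (a = 0 .. Lb - La) covers rest = [0,a) + [a+La, Lb).
struct RestTables {
  std::vector<Dense> two_piece; // indexed by a (valid when Lb >= La)
  std::vector<Dense> pref;      // pref[a]: rest = [0, a)
  std::vector<Dense> suf;       // suf[b]: rest = [b, Lb)
};

static RestTables build_rest_tables(const HitM& B, int La, const double* bg) {
  RestTables rt;
  rt.pref.resize(B.L + 1);
  rt.suf.resize(B.L + 1);
  for (int a = 0; a <= B.L; ++a) rt.pref[a] = rest_dist(B, 0, a, 0, 0, bg);
  for (int b = 0; b <= B.L; ++b) rt.suf[b] = rest_dist(B, b, B.L, 0, 0, bg);
  if (B.L >= La) {
    rt.two_piece.resize(B.L - La + 1);
    for (int a = 0; a <= B.L - La; ++a) {
      if (a == 0) rt.two_piece[a] = rt.suf[La];
      else if (a == B.L - La) rt.two_piece[a] = rt.pref[a];
      else rt.two_piece[a] = rest_dist(B, 0, a, a + La, B.L, bg);
    }
  }
  return rt;
}

// gamma between shorter A and longer B at offset kA of *A relative to B*
// ... kept in the caller's frame: here kB is B's offset relative to A.
// A's rest is a single prefix piece [0, kB) when kB > 0, else empty; B's rest
// is the two-piece table entry a = -kB for kB in [La-Lb, 0], else a suffix.
static double gamma_pair_fast(const HitM& A, const HitM& B, const double* bg,
                              int kB, const RestTables& rtB,
                              const std::vector<Dense>& prefA,
                              const std::vector<Dense>& sufA) {
  const int ov_lo = std::max(0, kB), ov_hi = std::min(A.L, kB + B.L);
  const int nov = ov_hi - ov_lo;
  if (nov < 1) return NA_REAL;
  // A's rest is one contiguous piece: a prefix [0, ov_lo) when B hangs off
  // the right end, or a suffix [ov_hi, La) when B hangs off the left end
  // (with Lb >= La at most one is non-empty).
  const Dense& tailA = (ov_lo > 0) ? prefA[ov_lo] : sufA[ov_hi];
  const Dense* tailB;
  if (kB > 0) {
    tailB = &rtB.suf[ov_hi - kB];        // B rest = [ov_hi - kB, Lb)
  } else if (kB + B.L <= A.L) {
    tailB = &rtB.pref[-kB];              // B hangs off the left: prefix rest
  } else {
    tailB = &rtB.two_piece[-kB];         // B covers A: two-piece rest
  }
  if (nov > MAX_DFS_OV) return gamma_ov_hash(A, B, bg, kB, tailA, *tailB);
  return gamma_dfs(A, B, bg, kB, tailA, *tailB);
}

// S^max of one candidate against a set of consensus models, sharing the
// candidate's rest tables across consensus motifs, orientations and offsets.
// models: list of hit models ordered f1, r1, f2, r2, ... (forward/revcomp
// pairs); returns one row per pair: s_max, offset (y relative to candidate),
// orientation (0 fwd / 1 rc), gamma.
// [[Rcpp::export]]
NumericMatrix cpp_smax_batch(IntegerMatrix candContrib, int candT,
                             double candAlpha, List models, NumericVector bg) {
  HitM cand = { static_cast<int>(candContrib.ncol()), INTEGER(candContrib),
                candT, candAlpha };
  const double* b = REAL(bg);
  const int nm = models.size();
  if (nm % 2 != 0) stop("models must come in forward/revcomp pairs");
  std::vector<HitM> ms(nm);
  std::vector<IntegerMatrix> keep(nm); // protect from gc
  for (int i = 0; i < nm; ++i) {
    List m = models[i];
    keep[i] = as<IntegerMatrix>(m["contrib"]);
    ms[i] = { static_cast<int>(keep[i].ncol()), INTEGER(keep[i]),
              as<int>(m["threshold"]), as<double>(m["alpha"]) };
  }
  // candidate rest tables per distinct consensus length (consensus shorter or
  // equal: candidate plays B). For consensus longer than the candidate the
  // roles swap and the consensus' own tables are built on the fly.
  std::map<int, RestTables> cand_tables;
  for (int i = 0; i < nm; ++i) {
    const int Lc = ms[i].L;
    if (Lc <= cand.L && cand_tables.find(Lc) == cand_tables.end())
      cand_tables[Lc] = build_rest_tables(cand, Lc, b);
  }
  // prefix rest tails of each consensus (role A) are cheap; build on demand
  NumericMatrix out(nm / 2, 4);
  for (int pair = 0; pair < nm / 2; ++pair) {
    double best = R_NegInf, best_g = 0.0;
    int best_k = 0, best_o = 0;
    bool have = false;
    for (int o = 0; o < 2; ++o) {
      const HitM& M = ms[2 * pair + o];
      std::vector<int> ks = ordered_offsets(cand.L, M.L); // y = consensus
      if (M.L <= cand.L) {
        const RestTables& rtB = cand_tables[M.L];
        std::vector<Dense> prefM(M.L + 1), sufM(M.L + 1);
        for (int a = 0; a <= M.L; ++a) prefM[a] = rest_dist(M, 0, a, 0, 0, b);
        for (int a = 0; a <= M.L; ++a) sufM[a] = rest_dist(M, a, M.L, 0, 0, b);
        for (size_t i = 0; i < ks.size(); ++i) {
          // y at offset ks[i] relative to candidate => candidate (B role) at
          // offset -ks[i] relative to the consensus (A role)
          double g = gamma_pair_fast(M, cand, b, -ks[i], rtB, prefM, sufM);
          double s = (g > 0.0) ? std::log(g / (cand.alpha * M.alpha))
                               : R_NegInf;
          if (!have || s > best) {
            best = s; best_g = g; best_k = ks[i]; best_o = o; have = true;
          }
        }
      } else { // consensus longer: candidate is the short side (A role)
        RestTables rtB = build_rest_tables(M, cand.L, b);
        std::vector<Dense> prefC(cand.L + 1), sufC(cand.L + 1);
        for (int a = 0; a <= cand.L; ++a)
          prefC[a] = rest_dist(cand, 0, a, 0, 0, b);
        for (int a = 0; a <= cand.L; ++a)
          sufC[a] = rest_dist(cand, a, cand.L, 0, 0, b);
        for (size_t i = 0; i < ks.size(); ++i) {
          double g = gamma_pair_fast(cand, M, b, ks[i], rtB, prefC, sufC);
          double s = (g > 0.0) ? std::log(g / (cand.alpha * M.alpha))
                               : R_NegInf;
          if (!have || s > best) {
            best = s; best_g = g; best_k = ks[i]; best_o = o; have = true;
          }
        }
      }
    }
    out(pair, 0) = best; out(pair, 1) = best_k; out(pair, 2) = best_o;
    out(pair, 3) = best_g;
  }
  colnames(out) = CharacterVector::create("s_max", "offset", "orientation",
                                          "gamma");
  return out;
}

// 64-bit FNV-1a over a string; used to fingerprint collections/nulls.
// [[Rcpp::export]]
std::string cpp_fnv1a(std::string s) {
  uint64_t h = 14695981039346656037ull;
  for (size_t i = 0; i < s.size(); ++i) {
    h ^= static_cast<unsigned char>(s[i]);
    h *= 1099511628211ull;
  }
  char buf[17];
  snprintf(buf, sizeof(buf), "%016llx", static_cast<unsigned long long>(h));
  return std::string(buf);
}
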