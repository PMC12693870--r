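#include <Rcpp.h>
using namespace Rcpp;

// Maximal runs of |x| > theta, split at internal sign changes, of length
// >= min_len. Returns a 3-column integer matrix (start, end, sign), 1-based.
// [[Rcpp::export(name = ".runs_cpp")]]
IntegerMatrix runs_cpp(NumericVector x, double theta, int min_len) {
  const int n = x.size();
  std::vector<int> st, en, sg;
  int i = 0;
  while (i < n) {
    if (std::fabs(x[i]) > theta) {
      int s = (x[i] > 0) ? 1 : -1;
      int j = i;
      while (j + 1 < n && std::fabs(x[j + 1]) > theta &&
             ((x[j + 1] > 0) ? 1 : -1) == s) ++j;
      if (j - i + 1 >= min_len) {
        st.push_back(i + 1); en.push_back(j + 1); sg.push_back(s);
      }
      i = j + 1;
    } else ++i;
  }
  IntegerMatrix out(st.size(), 3);
  for (size_t k = 0; k < st.size(); ++k) {
    out(k, 0) = st[k]; out(k, 1) = en[k]; out(k, 2) = sg[k];
  }
  colnames(out) = CharacterVector::create("start", "end", "sign");
  return out;
}

// zero crossing of v in (from, to] (1-based bounds, inclusive), direction
// down (+ -> -) or up (- -> +); among candidates pick the one with extremal
// raw value (max for down, min for up); nearest-integer localization after
// linear interpolation, ties toward the earlier sample. 0 when none.
static int find_zc(const NumericVector& v, const NumericVector& s,
                   int from, int to, bool down) {
  if (to <= from) return 0;
  int best = 0;
  double best_raw = down ? -1e300 : 1e300;
  for (int k = from; k < to; ++k) {      // 1-based k, pairs (k, k+1)
    double a = v[k - 1], b = v[k];
    bool cross = down ? (a >= 0 && b < 0) : (a <= 0 && b > 0);
    if (!cross) continue;
    double raw = s[k - 1];
    if (down ? (raw > best_raw) : (raw < best_raw)) { best_raw = raw; best = k; }
  }
  if (best == 0) return 0;
  double a = v[best - 1], b = v[best];
  double denom = a - b;
  double frac = (denom != 0.0) ? a / denom : 0.0;
  return (frac > 0.5) ? best + 1 : best;
}

// last index <= at with v <= 0, searching back at most max_back samples;
// 0 signals that the search ran past the trace start
static int bound_left(const NumericVector& v, int at, int max_back) {
  int lo = at - max_back; if (lo < 1) lo = 1;
  for (int k = at; k >= lo; --k) if (v[k - 1] <= 0) return k;
  return (lo == 1) ? 0 : lo;
}

static int bound_right(const NumericVector& v, int at, int max_fwd, int n) {
  int hi = at + max_fwd; if (hi > n) hi = n;
  for (int k = at; k <= hi; ++k) if (v[k - 1] <= 0) return k;
  return (hi == n) ? 0 : hi;
}

// Single-pass grouping of sign runs into bipolar events.
// Returns 4-column matrix (left, pos, neg, right) plus attribute
// "edge_dropped".
// [[Rcpp::export(name = ".group_bipolar_cpp")]]
IntegerMatrix group_bipolar_cpp(NumericVector v, NumericVector s,
                                IntegerMatrix runs, int gap_n) {
  const int nr = runs.nrow(), n = v.size();
  std::vector<int> L, P, Q, R;
  int edge_dropped = 0;
  int i = 0;
  while (i < nr) {
    if (runs(i, 2) > 0 && i + 1 < nr && runs(i + 1, 2) < 0 &&
        runs(i + 1, 0) - runs(i, 1) <= gap_n) {
      int j = i + 1;
      int consumed = j;
      bool has_trail = (j + 1 < nr) && runs(j + 1, 2) > 0 &&
        (runs(j + 1, 0) - runs(j, 1) <= gap_n);
      bool trail_needed = has_trail && (j + 2 < nr) && runs(j + 2, 2) < 0 &&
        (runs(j + 2, 0) - runs(j + 1, 1) <= gap_n);
      if (has_trail && !trail_needed) consumed = j + 1;

      int pos = find_zc(v, s, runs(i, 1), runs(j, 0), true);
      int neg_to = (consumed > j) ? runs(consumed, 0)
                                  : std::min(n, runs(j, 1) + gap_n);
      int neg = find_zc(v, s, runs(j, 1), neg_to, false);
      if (pos == 0) {  // fallback: raw extremum between the lobes
        double m = -1e300;
        for (int k = runs(i, 1); k <= runs(j, 0); ++k)
          if (s[k - 1] > m) { m = s[k - 1]; pos = k; }
      }
      if (neg == 0 && neg_to > runs(j, 1)) {
        double m = 1e300;
        for (int k = runs(j, 1); k <= neg_to; ++k)
          if (s[k - 1] < m) { m = s[k - 1]; neg = k; }
      }
      int left = bound_left(v, runs(i, 0), gap_n);
      int right_from = (consumed > j) ? runs(consumed, 1) : neg;
      int right = (right_from == 0) ? 0 : bound_right(v, right_from, gap_n, n);
      bool ok = (pos > 0) && (neg > 0) && (pos < neg);
      if (ok && (left == 0 || right == 0 ||
                 runs(i, 0) <= 2 || runs(consumed, 1) >= n - 1)) {
        ++edge_dropped;
        ok = false;
      }
      if (ok) {
        L.push_back(left); P.push_back(pos); Q.push_back(neg);
        R.push_back(right);
      }
      i = consumed + 1;
    } else ++i;
  }
  IntegerMatrix out(L.size(), 4);
  for (size_t k = 0; k < L.size(); ++k) {
    out(k, 0) = L[k]; out(k, 1) = P[k]; out(k, 2) = Q[k]; out(k, 3) = R[k];
  }
  out.attr("edge_dropped") = edge_dropped;
  return out;
}

// Pair each positive run with the nearest following negative run within
// gap_n, consuming the negative run. Returns (start, pos, neg, end) using
// the extremum sample of each run as the peak.
// [[Rcpp::export(name = ".pair_runs_cpp")]]
IntegerMatrix pair_runs_cpp(NumericVector x, IntegerMatrix runs, int gap_n) {
  const int nr = runs.nrow();
  std::vector<int> A, P, Q, B;
  int j = 0;
  for (int i = 0; i < nr; ++i) {
    if (runs(i, 2) <= 0) continue;
    if (j <= i) j = i + 1;
    while (j < nr && (runs(j, 2) > 0 || runs(j, 0) <= runs(i, 1))) ++j;
    if (j >= nr) break;
    if (runs(j, 0) - runs(i, 1) <= gap_n) {
      int p = runs(i, 0); double m = -1e300;
      for (int k = runs(i, 0); k <= runs(i, 1); ++k)
        if (x[k - 1] > m) { m = x[k - 1]; p = k; }
      int q = runs(j, 0); m = 1e300;
      for (int k = runs(j, 0); k <= runs(j, 1); ++k)
        if (x[k - 1] < m) { m = x[k - 1]; q = k; }
      A.push_back(runs(i, 0)); P.push_back(p); Q.push_back(q);
      B.push_back(runs(j, 1));
      ++j;
    }
  }
  IntegerMatrix out(A.size(), 4);
  for (size_t k = 0; k < A.size(); ++k) {
    out(k, 0) = A[k]; out(k, 1) = P[k]; out(k, 2) = Q[k]; out(k, 3) = B[k];
  }
  return out;
}
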