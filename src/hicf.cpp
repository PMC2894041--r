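#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Greedy one-to-one matching of two band lists sorted by (color, size).
// Bands match when colors are equal and |size difference| <= tol; each band
// is used at most once. For same-color sorted size lists this greedy rule
// attains the maximum matching (verified against an exhaustive oracle in the
// test suite).
static int match_count(const int* ca, const int* sa, int na,
                       const int* cb, const int* sb, int nb, int tol) {
  int i = 0, j = 0, m = 0;
  while (i < na && j < nb) {
    if (ca[i] != cb[j]) {
      if (ca[i] < cb[j]) ++i; else ++j;
      continue;
    }
    int d = sa[i] - sb[j];
    if (d < 0) d = -d;
    if (d <= tol) { ++m; ++i; ++j; }
    else if (sa[i] < sb[j]) ++i;
    else ++j;
  }
  return m;
}

// [[Rcpp::export]]
int count_shared_cpp(IntegerVector color_a, IntegerVector size_a,
                     IntegerVector color_b, IntegerVector size_b, int tol) {
  return match_count(color_a.begin(), size_a.begin(), color_a.size(),
                     color_b.begin(), size_b.begin(), color_b.size(), tol);
}

// Greedy tolerance matching of one color's sorted size list against another,
// returning for each element of a the 1-based index of the b element it
// matched, or 0. Used by the consensus-band builder.
// [[Rcpp::export]]
IntegerVector greedy_match_idx_cpp(IntegerVector size_a, IntegerVector size_b,
                                   int tol) {
  int na = size_a.size(), nb = size_b.size();
  IntegerVector out(na, 0);
  int i = 0, j = 0;
  while (i < na && j < nb) {
    int d = size_a[i] - size_b[j];
    if (d < 0) d = -d;
    if (d <= tol) { out[i] = j + 1; ++i; ++j; }
    else if (size_a[i] < size_b[j]) ++i;
    else ++j;
  }
  return out;
}

// log10 of the Sulston coincidence score: probability that two unrelated
// clones with n_low and n_high bands on a gel of `gellen` size units share at
// least M bands within `tol`, under the binomial approximation
//   p1 = 1 - (1 - 2*tol/gellen)^n_high
//   score = sum_{k=M}^{n_low} C(n_low, k) p1^k (1-p1)^(n_low-k)
static double sulston_log10_one(int M, int nlow, int nhigh, double tol,
                                double gellen) {
  if (M <= 0) return 0.0;           // full sum = 1
  if (M > nlow) return R_NegInf;
  double p1 = 1.0 - std::pow(1.0 - 2.0 * tol / gellen, (double) nhigh);
  if (p1 <= 0.0) return R_NegInf;
  if (p1 >= 1.0) return 0.0;
  double lp = std::log(p1), lq = std::log1p(-p1);
  double mx = R_NegInf;
  std::vector<double> terms;
  terms.reserve(nlow - M + 1);
  for (int k = M; k <= nlow; ++k) {
    double t = R::lchoose((double) nlow, (double) k) + k * lp + (nlow - k) * lq;
    terms.push_back(t);
    if (t > mx) mx = t;
  }
  if (!R_finite(mx)) return R_NegInf;
  double s = 0.0;
  for (size_t k = 0; k < terms.size(); ++k) s += std::exp(terms[k] - mx);
  return (mx + std::log(s)) / M_LN10;
}

// [[Rcpp::export]]
NumericVector sulston_log10_cpp(IntegerVector M, IntegerVector nlow,
                                IntegerVector nhigh, double tol,
                                double gellen) {
  int n = M.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = sulston_log10_one(M[i], nlow[i], nhigh[i], tol, gellen);
  return out;
}

// All-pairs band coincidence scoring over a fingerprint set. Bands arrive
// concatenated (sorted by color then size within each clone) with 0-based
// clone offsets (length n_clones + 1). Pairs whose shared-band count reaches
// m_min are scored; pairs with log10(score) <= keep_log10 are returned.
// [[Rcpp::export]]
DataFrame pair_scores_cpp(IntegerVector colors, IntegerVector sizes,
                          IntegerVector offsets, int tol, double gellen,
                          double keep_log10, int m_min) {
  int n = offsets.size() - 1;
  std::vector<int> oi, oj, om;
  std::vector<double> os;
  std::unordered_map<long long, double> memo;
  const int* cp = colors.begin();
  const int* sp = sizes.begin();
  for (int i = 0; i < n; ++i) {
    int ai = offsets[i], na = offsets[i + 1] - ai;
    if (na == 0) continue;
    for (int j = i + 1; j < n; ++j) {
      int aj = offsets[j], nb = offsets[j + 1] - aj;
      if (nb == 0) continue;
      int m = match_count(cp + ai, sp + ai, na, cp + aj, sp + aj, nb, tol);
      if (m < m_min) continue;
      int nl = na < nb ? na : nb, nh = na < nb ? nb : na;
      long long key = (long long) m + 1024LL * (nl + 1024LL * nh);
      double lg;
      std::unordered_map<long long, double>::iterator it = memo.find(key);
      if (it == memo.end()) {
        lg = sulston_log10_one(m, nl, nh, tol, gellen);
        memo[key] = lg;
      } else lg = it->second;
      if (lg <= keep_log10) {
        oi.push_back(i + 1); oj.push_back(j + 1);
        om.push_back(m); os.push_back(lg);
      }
    }
  }
  return DataFrame::create(_["i"] = oi, _["j"] = oj, _["m"] = om,
                           _["log10_score"] = os);
}

// Full shared-band count matrix for a (small) clone subset.
// [[Rcpp::export]]
IntegerMatrix shared_matrix_cpp(IntegerVector colors, IntegerVector sizes,
                                IntegerVector offsets, int tol) {
  int n = offsets.size() - 1;
  IntegerMatrix out(n, n);
  const int* cp = colors.begin();
  const int* sp = sizes.begin();
  for (int i = 0; i < n; ++i) {
    int ai = offsets[i], na = offsets[i + 1] - ai;
    out(i, i) = na;
    for (int j = i + 1; j < n; ++j) {
      int aj = offsets[j], nb = offsets[j + 1] - aj;
      int m = match_count(cp + ai, sp + ai, na, cp + aj, sp + aj, nb, tol);
      out(i, j) = m;
      out(j, i) = m;
    }
  }
  return out;
}

// Union-find connected components over an edge list (1-based vertex ids).
// [[Rcpp::export]]
IntegerVector components_cpp(IntegerVector from, IntegerVector to, int n) {
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  // find with path halving
  for (int e = 0; e < from.size(); ++e) {
    int a = from[e] - 1, b = to[e] - 1;
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    while (parent[b] != b) { parent[b] = parent[parent[b]]; b = parent[b]; }
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  }
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int a = i;
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    out[i] = a + 1;
  }
  return out;
}

// Monte-Carlo oracle for the band-coincidence tail: place n_low and n_high
// band sizes independently and uniformly on the continuous interval
// (0, gellen], and count how many of the n_low bands have at least one of
// the n_high bands within |diff| <= tol -- the per-band coincidence event
// whose binomial tail the Sulston formula describes. Returns counts of the
// match count 0..n_low over `reps` draws. Uses R's RNG so results are
// reproducible under set.seed().
// [[Rcpp::export]]
IntegerVector mc_coincidence_cpp(int n_low, int n_high, int reps, double tol,
                                 double gellen) {
  IntegerVector tally(n_low + 1, 0);
  std::vector<double> a(n_low), b(n_high);
  for (int r = 0; r < reps; ++r) {
    for (int i = 0; i < n_low; ++i) a[i] = unif_rand() * gellen;
    for (int j = 0; j < n_high; ++j) b[j] = unif_rand() * gellen;
    int m = 0;
    for (int i = 0; i < n_low; ++i) {
      for (int j = 0; j < n_high; ++j) {
        if (std::fabs(a[i] - b[j]) <= tol) { ++m; break; }
      }
    }
    tally[m] += 1;
  }
  return tally;
}
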