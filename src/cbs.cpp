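#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Maximal circular-arc statistic for a centered profile.
// Arcs are parameterized by boundary pairs (i, j), 0 <= i < j <= n, with the
// arc covering probes i+1..j (1-based). Enumerating all pairs with arc length
// k = j - i in [minLen, n - minLen] covers every circular arc/complement pair
// once, because an arc and its complement give the same statistic.
//
// The statistic maximized is |S_j - S_i| * sqrt(n / (k * (n - k))), the
// two-sample t numerator on mean-centered data; the pooled-variance term is
// constant over arcs and permutations, so it cancels from the permutation
// test and is dropped.
static void max_arc(const double* S, int n, int minLen,
                    double* out_stat, int* out_i, int* out_j) {
  double best = -1.0;
  int bi = 0, bj = 0;
  for (int k = minLen; k <= n - minLen; ++k) {
    double w = std::sqrt((double)n / ((double)k * (double)(n - k)));
    for (int i = 0; i + k <= n; ++i) {
      double d = std::fabs(S[i + k] - S[i]) * w;
      if (d > best) { best = d; bi = i; bj = i + k; }
    }
  }
  *out_stat = best;
  *out_i = bi;
  *out_j = bj;
}

// TRUE as soon as some arc statistic reaches `target` (early exit).
static bool arc_exceeds(const double* S, int n, int minLen, double target) {
  for (int k = minLen; k <= n - minLen; ++k) {
    double w = std::sqrt((double)n / ((double)k * (double)(n - k)));
    double need = target / w;  // |S_j - S_i| needed at this arc length
    for (int i = 0; i + k <= n; ++i) {
      if (std::fabs(S[i + k] - S[i]) >= need) return true;
    }
  }
  return false;
}

static void partial_sums(const std::vector<double>& x, std::vector<double>& S) {
  int n = (int)x.size();
  S[0] = 0.0;
  for (int i = 0; i < n; ++i) S[i + 1] = S[i] + x[i];
}

// [[Rcpp::export(name = ".cbs_split_test")]]
List cbs_split_test(NumericVector x, int nperm, double alpha, int min_seg) {
  int n = x.size();
  if (n < 2 * min_seg)
    return List::create(_["significant"] = false, _["p"] = 1.0,
                        _["i"] = 0, _["j"] = 0, _["stat"] = 0.0);

  // center once; permutation preserves the mean so S_n = 0 throughout
  std::vector<double> xc(n);
  double mu = 0.0;
  for (int i = 0; i < n; ++i) mu += x[i];
  mu /= n;
  for (int i = 0; i < n; ++i) xc[i] = x[i] - mu;

  std::vector<double> S(n + 1);
  partial_sums(xc, S);
  double obs; int oi, oj;
  max_arc(S.data(), n, min_seg, &obs, &oi, &oj);

  if (obs <= 0.0)  // constant profile: nothing to split
    return List::create(_["significant"] = false, _["p"] = 1.0,
                        _["i"] = oi, _["j"] = oj, _["stat"] = obs);

  const double eps = 1e-12;
  const double tol = obs * (1.0 - 1e-9) - eps;  // >= observed, tie-tolerant
  // the largest weight is attained at the shortest allowed arc
  double wmax = std::sqrt((double)n /
                          ((double)min_seg * (double)(n - min_seg)));
  // stop early once significance is impossible
  int cutoff = (int)std::floor(alpha * (nperm + 1) - 1e-9);

  RNGScope scope;
  std::vector<double> y(xc);
  int count = 0, done = 0;
  for (int p = 0; p < nperm; ++p) {
    // Fisher-Yates shuffle via R's RNG (seeded from R)
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(y[i], y[j]);
    }
    partial_sums(y, S);
    ++done;
    double smin = S[0], smax = S[0];
    for (int i = 1; i <= n; ++i) {
      if (S[i] < smin) smin = S[i];
      if (S[i] > smax) smax = S[i];
    }
    if ((smax - smin) * wmax < tol) continue;  // cannot reach observed
    if (arc_exceeds(S.data(), n, min_seg, tol)) {
      ++count;
      if (count > cutoff) break;  // p >= alpha guaranteed
    }
  }
  double pval = (1.0 + count) / (double)(done >= nperm ? nperm + 1 : done + 1);
  bool sig = (count <= cutoff) && (done >= nperm) && (pval < alpha);
  return List::create(_["significant"] = sig, _["p"] = pval,
                      _["i"] = oi, _["j"] = oj, _["stat"] = obs);
}

// [[Rcpp::export(name = ".cbs_max_arc")]]
List cbs_max_arc(NumericVector x, int min_seg) {
  int n = x.size();
  std::vector<double> xc(n);
  double mu = 0.0;
  for (int i = 0; i < n; ++i) mu += x[i];
  mu /= n;
  for (int i = 0; i < n; ++i) xc[i] = x[i] - mu;
  std::vector<double> S(n + 1);
  partial_sums(xc, S);
  double obs; int oi, oj;
  max_arc(S.data(), n, min_seg, &obs, &oi, &oj);
  return List::create(_["i"] = oi, _["j"] = oj, _["stat"] = obs);
}

// Permutation null for recurrent-aberration scores: each sample's per-probe
// contribution vector is cyclically shifted by an independent random offset,
// preserving within-sample segment structure and total aberration load.
// Returns an M x nperm matrix of null scores.
// [[Rcpp::export(name = ".gistic_null_G")]]
NumericMatrix gistic_null_G(NumericMatrix contrib, int nperm) {
  int M = contrib.nrow(), S = contrib.ncol();
  NumericMatrix out(M, nperm);
  // sparse per-sample representation: most probes contribute nothing
  std::vector< std::vector<int> > idx(S);
  std::vector< std::vector<double> > val(S);
  for (int s = 0; s < S; ++s) {
    for (int m = 0; m < M; ++m) {
      double v = contrib(m, s);
      if (v != 0.0) { idx[s].push_back(m); val[s].push_back(v); }
    }
  }
  RNGScope scope;
  for (int p = 0; p < nperm; ++p) {
    double* col = &out(0, p);
    for (int s = 0; s < S; ++s) {
      int off = (int)(unif_rand() * M);
      if (off >= M) off = M - 1;
      const std::vector<int>& ii = idx[s];
      const std::vector<double>& vv = val[s];
      for (size_t t = 0; t < ii.size(); ++t) {
        int m = ii[t] + off;
        if (m >= M) m -= M;
        col[m] += vv[t];
      }
    }
  }
  return out;
}
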