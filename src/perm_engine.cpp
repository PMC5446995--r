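#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Permutation engine for the cell-type label null.
//
// For each column b of `shuffles` (a full permutation of the observed type
// labels, 0-based integers in 0..C-1) the engine recomputes the per-type
// average standardized expression, re-derives the enriched sets (profile
// value strictly above tau) and the non-specific set (max absolute profile
// value strictly below tau), and scores every set against a fixed ranking
// encoded as per-gene reverse midranks (`revrank`, NA for genes absent from
// the homolog-restricted ranking).
//
// Returns a B x (C + 1) matrix of AUROCs; the last column is the
// non-specific set. Degenerate sets (empty, or covering the whole ranking)
// yield NA, not an error.
//
// [[Rcpp::export]]
NumericMatrix cpp_perm_auroc(NumericMatrix z, IntegerMatrix shuffles, int n_types,
                             NumericVector revrank, double tau) {
  const int G = z.nrow(), n = z.ncol(), B = shuffles.ncol(), C = n_types;
  if (shuffles.nrow() != n) stop("shuffles must have one row per cell");
  if (revrank.size() != G) stop("revrank must have one entry per gene");

  std::vector<char> inr(G);
  double Nrank = 0.0;
  std::vector<double> rr(G, 0.0);
  for (int g = 0; g < G; ++g) {
    inr[g] = !NumericVector::is_na(revrank[g]);
    if (inr[g]) { rr[g] = revrank[g]; Nrank += 1.0; }
  }

  NumericMatrix out(B, C + 1);
  std::vector<double> acc((size_t)G * C);
  std::vector<double> cnt(C), n1(C + 1), S(C + 1);

  for (int b = 0; b < B; ++b) {
    std::fill(acc.begin(), acc.end(), 0.0);
    std::fill(cnt.begin(), cnt.end(), 0.0);
    for (int j = 0; j < n; ++j) {
      int t = shuffles(j, b);
      if (t < 0 || t >= C) stop("shuffle label out of range");
      cnt[t] += 1.0;
      double* a = &acc[(size_t)t * G];
      const double* zc = &z(0, j);
      for (int g = 0; g < G; ++g) a[g] += zc[g];
    }
    std::fill(n1.begin(), n1.end(), 0.0);
    std::fill(S.begin(), S.end(), 0.0);
    for (int g = 0; g < G; ++g) {
      double maxabs = 0.0;
      for (int t = 0; t < C; ++t) {
        double m = cnt[t] > 0 ? acc[(size_t)t * G + g] / cnt[t] : 0.0;
        double am = std::fabs(m);
        if (am > maxabs) maxabs = am;
        if (m > tau && inr[g]) { n1[t] += 1.0; S[t] += rr[g]; }
      }
      if (maxabs < tau && inr[g]) { n1[C] += 1.0; S[C] += rr[g]; }
    }
    for (int c = 0; c <= C; ++c) {
      double n2 = Nrank - n1[c];
      if (n1[c] <= 0.0 || n2 <= 0.0) {
        out(b, c) = NA_REAL;
      } else {
        double U = S[c] - n1[c] * (n1[c] + 1.0) / 2.0;
        out(b, c) = U / (n1[c] * n2);
      }
    }
  }
  return out;
}
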