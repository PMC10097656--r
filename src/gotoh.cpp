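#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
#include <algorithm>
using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh three-state DP) with deterministic
// traceback.
//
// Scoring: a gap run of length L costs gap_open + (L-1)*gap_extend (the
// opening charge covers the first gapped position).  'X' never matches.
//
// mode 0: classic global alignment, path from (0,0) to (n,m).
// mode 1: overlap (semi-global, free end gaps) — a terminal gap run in ONE
//         sequence at each end is free (boundary cells cost 0, the optimum
//         is taken over the last row and column), so expression tags,
//         construct overhangs and reference truncations do not depress the
//         score, while unrelated sequences cannot cherry-pick a short
//         internal island.
// mode 2: local — the alignment may start and end at any matched pair
//         (match state floored at zero, optimum over all cells); used for
//         anchor search in constructs whose genuine region is a small
//         interior fraction of the chain.
//
// Traceback tie-break: diagonal, then gap in b (consume a), then gap in a;
// among equal-scoring terminal cells the (n, m) corner is preferred, then
// the last column bottom-up, then the last row right-to-left.

static inline double subst(char x, char y, double match, double mismatch) {
  if (x == 'X' || y == 'X') return mismatch;
  return (x == y) ? match : mismatch;
}

// [[Rcpp::export]]
List gotoh_align_cpp(std::string a, std::string b,
                     double match, double mismatch,
                     double gap_open, double gap_extend,
                     int mode) {
  const bool end_gaps_free = mode == 1, local = mode == 2;
  const int n = (int) a.size(), m = (int) b.size();
  const double NEG = -std::numeric_limits<double>::infinity();
  std::vector<double> M((n + 1) * (m + 1), NEG), X((n + 1) * (m + 1), NEG),
      Y((n + 1) * (m + 1), NEG);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i)
    X[at(i, 0)] = (end_gaps_free || local) ? 0.0
                                           : gap_open + (i - 1) * gap_extend;
  for (int j = 1; j <= m; ++j)
    Y[at(0, j)] = (end_gaps_free || local) ? 0.0
                                           : gap_open + (j - 1) * gap_extend;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double s = subst(a[i - 1], b[j - 1], match, mismatch);
      double diag = std::max(M[at(i - 1, j - 1)],
                    std::max(X[at(i - 1, j - 1)], Y[at(i - 1, j - 1)]));
      if (local && diag < 0.0) diag = 0.0; // free restart before a match
      M[at(i, j)] = s + diag;
      X[at(i, j)] = std::max(M[at(i - 1, j)] + gap_open,
                    std::max(X[at(i - 1, j)] + gap_extend,
                             Y[at(i - 1, j)] + gap_open));
      Y[at(i, j)] = std::max(M[at(i, j - 1)] + gap_open,
                    std::max(Y[at(i, j - 1)] + gap_extend,
                             X[at(i, j - 1)] + gap_open));
    }
  }

  auto cellbest = [&](int i, int j) {
    return std::max(M[at(i, j)], std::max(X[at(i, j)], Y[at(i, j)]));
  };

  int ei = n, ej = m;
  double best;
  int state;
  if (local) {
    best = 0.0;
    ei = 0; ej = 0;
    for (int i = n; i >= 1; --i)
      for (int j = m; j >= 1; --j)
        if (M[at(i, j)] > best) { best = M[at(i, j)]; ei = i; ej = j; }
    state = 0;
  } else {
    best = cellbest(n, m);
    if (end_gaps_free) {
      for (int i = n - 1; i >= 0; --i)
        if (cellbest(i, m) > best) { best = cellbest(i, m); ei = i; ej = m; }
      for (int j = m - 1; j >= 0; --j)
        if (cellbest(n, j) > best) { best = cellbest(n, j); ei = n; ej = j; }
    }
    const double c = cellbest(ei, ej);
    state = (M[at(ei, ej)] == c) ? 0 : (X[at(ei, ej)] == c) ? 1 : 2;
  }

  std::vector<int> pa, pb;
  int i = ei, j = ej, n_ident = 0;
  while (i > 0 && j > 0) {
    if (state == 0) {
      pa.push_back(i); pb.push_back(j);
      char ca = a[i - 1], cb = b[j - 1];
      if (ca == cb && ca != 'X') ++n_ident;
      const double prev = M[at(i, j)] - subst(ca, cb, match, mismatch);
      --i; --j;
      if (i == 0 && j == 0) break;
      if (M[at(i, j)] == prev) state = 0;
      else if (X[at(i, j)] == prev) state = 1;
      else if (Y[at(i, j)] == prev) state = 2;
      else break; // local mode: the restart floor was taken
    } else if (state == 1) { // gap in b, consume a
      const double cur = X[at(i, j)];
      --i;
      if (i == 0) break; // column 0: leading overhang of a
      if (M[at(i, j)] + gap_open == cur) state = 0;
      else if (X[at(i, j)] + gap_extend == cur) state = 1;
      else state = 2;
    } else { // gap in a, consume b
      const double cur = Y[at(i, j)];
      --j;
      if (j == 0) break;
      if (M[at(i, j)] + gap_open == cur) state = 0;
      else if (Y[at(i, j)] + gap_extend == cur) state = 2;
      else state = 1;
    }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());

  return List::create(_["score"] = best,
                      _["pos_a"] = IntegerVector(pa.begin(), pa.end()),
                      _["pos_b"] = IntegerVector(pb.begin(), pb.end()),
                      _["n_identical"] = n_ident,
                      _["n_aligned"] = (int) pa.size());
}
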