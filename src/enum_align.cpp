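#include <Rcpp.h>
#include <string>
#include <limits>
using namespace Rcpp;

// Exhaustive-enumeration reference for the affine-gap aligner: enumerates
// every monotone matching between the two sequences and scores it directly.
// For a fixed matching the optimal gap arrangement between consecutive
// matched pairs is one gap run per sequence; at the two ends, free end gaps
// waive the cost of the terminal run in one sequence (the cheaper one is
// charged when both sequences have terminal overhangs).  Exponential;
// intended for sequences of length <= ~10 as an independent oracle, never
// for production.

namespace {

struct EnumCtx {
  const char *a, *b;
  int n, m;
  double match, mismatch, open, ext, best;
  int mode; // 0 global, 1 overlap (free end gaps), 2 local
};

inline double run_cost(int len, double open, double ext) {
  return len > 0 ? open + (len - 1) * ext : 0.0;
}

inline double pair_score(char x, char y, double match, double mismatch) {
  if (x == 'X' || y == 'X') return mismatch;
  return (x == y) ? match : mismatch;
}

// cost of the unmatched residues (da in a, db in b) at a terminal region
inline double end_cost(int da, int db, const EnumCtx &c) {
  if (c.mode == 2) return 0.0; // local: ends are free in both sequences
  double ra = run_cost(da, c.open, c.ext), rb = run_cost(db, c.open, c.ext);
  if (c.mode == 0) return ra + rb;
  if (da > 0 && db > 0) return std::max(ra, rb); // cheaper run is charged
  return 0.0;
}

// prev matched pair at (pi, pj) (0 = none yet), acc = score so far
void recur(EnumCtx &c, int pi, int pj, double acc) {
  // close the matching here: trailing unmatched residues.  For the empty
  // matching with free ends, all of a is a leading run and all of b a
  // trailing run, so nothing is charged.
  {
    double tail = (pi == 0 && pj == 0 && c.mode != 0)
                      ? 0.0 : end_cost(c.n - pi, c.m - pj, c);
    if (acc + tail > c.best) c.best = acc + tail;
  }
  for (int p = pi + 1; p <= c.n; ++p) {
    for (int q = pj + 1; q <= c.m; ++q) {
      int da = p - pi - 1, db = q - pj - 1;
      double g = (pi == 0 && pj == 0)
                     ? end_cost(da, db, c)
                     : run_cost(da, c.open, c.ext) +
                           run_cost(db, c.open, c.ext);
      double s = pair_score(c.a[p - 1], c.b[q - 1], c.match, c.mismatch);
      recur(c, p, q, acc + g + s);
    }
  }
}

} // namespace

// [[Rcpp::export]]
double enum_align_score_cpp(std::string a, std::string b,
                            double match, double mismatch,
                            double gap_open, double gap_extend,
                            int mode) {
  EnumCtx c{a.c_str(), b.c_str(), (int) a.size(), (int) b.size(),
            match, mismatch, gap_open, gap_extend,
            -std::numeric_limits<double>::infinity(), mode};
  recur(c, 0, 0, 0.0);
  return c.best;
}
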