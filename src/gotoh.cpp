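#include <Rcpp.h>
#include <string>
#include <vector>
#include <limits>
using namespace Rcpp;

// Needleman-Wunsch global alignment with affine gaps (Gotoh three-state DP).
//
// Gap cost convention: a gap run of length k costs gap_open + (k-1) *
// gap_extend, i.e. gap_open is charged for the first gap column of a run and
// gap_extend for each subsequent column.
//
// States: M = a[i] aligned to b[j]; X = gap in b (consumes a); Y = gap in a
// (consumes b).  Ties are broken M > X > Y at every choice so the traceback
// is deterministic: diagonal preferred, then gap-in-b, then gap-in-a.
//
// free_end_gaps: leading and trailing gap runs in either sequence cost
// nothing (glocal/overlap mode), used when a short element is aligned
// against a longer genomic region.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double subst(char x, char y, double match, double mismatch) {
  if (x == 'N' || y == 'N') return mismatch;  // N never matches
  return (x == y) ? match : mismatch;
}

// pick max of (m, x, y) with preference M > X > Y; returns state index
static inline int argmax3(double m, double x, double y, double &best) {
  best = m; int s = 0;
  if (x > best) { best = x; s = 1; }
  if (y > best) { best = y; s = 2; }
  return s;
}

// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(std::string a, std::string b,
                 double match, double mismatch,
                 double gap_open, double gap_extend,
                 bool free_end_gaps) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty sequence");
  const size_t W = m + 1;
  auto at = [W](int i, int j) { return (size_t)i * W + (size_t)j; };

  std::vector<double> M((n + 1) * W, NEG_INF), X = M, Y = M;
  // predecessor state of the cell, per state matrix
  std::vector<signed char> pM((n + 1) * W, -1), pX = pM, pY = pM;

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[at(i, 0)] = free_end_gaps ? 0.0 : -(gap_open + (i - 1) * gap_extend);
    pX[at(i, 0)] = 1;  // continue X down to the origin
  }
  for (int j = 1; j <= m; ++j) {
    Y[at(0, j)] = free_end_gaps ? 0.0 : -(gap_open + (j - 1) * gap_extend);
    pY[at(0, j)] = 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double best;
      // M: diagonal move
      int s = argmax3(M[at(i - 1, j - 1)], X[at(i - 1, j - 1)],
                      Y[at(i - 1, j - 1)], best);
      M[at(i, j)] = best + subst(a[i - 1], b[j - 1], match, mismatch);
      pM[at(i, j)] = (signed char)s;
      // X: consume a[i], gap in b
      s = argmax3(M[at(i - 1, j)] - gap_open,
                  X[at(i - 1, j)] - gap_extend,
                  Y[at(i - 1, j)] - gap_open, best);
      X[at(i, j)] = best;
      pX[at(i, j)] = (signed char)s;
      // Y: consume b[j], gap in a
      s = argmax3(M[at(i, j - 1)] - gap_open,
                  X[at(i, j - 1)] - gap_open,
                  Y[at(i, j - 1)] - gap_extend, best);
      Y[at(i, j)] = best;
      pY[at(i, j)] = (signed char)s;
    }
  }

  // choose the terminal cell and state
  double score;
  int ti = n, tj = m;
  int ts = argmax3(M[at(n, m)], X[at(n, m)], Y[at(n, m)], score);
  if (free_end_gaps) {
    // free trailing gaps: best cell on the last row or last column wins;
    // (n, m) preferred, then larger i / j (shorter trailing gap)
    for (int i = n - 1; i >= 1; --i) {
      double v; int s = argmax3(M[at(i, m)], X[at(i, m)], Y[at(i, m)], v);
      if (v > score) { score = v; ti = i; tj = m; ts = s; }
    }
    for (int j = m - 1; j >= 1; --j) {
      double v; int s = argmax3(M[at(n, j)], X[at(n, j)], Y[at(n, j)], v);
      if (v > score) { score = v; ti = n; tj = j; ts = s; }
    }
  }

  std::string ga, gb;
  ga.reserve(n + m); gb.reserve(n + m);
  // trailing free gaps beyond the terminal cell
  for (int i = n; i > ti; --i) { ga.push_back(a[i - 1]); gb.push_back('-'); }
  for (int j = m; j > tj; --j) { ga.push_back('-'); gb.push_back(b[j - 1]); }

  int i = ti, j = tj, s = ts;
  while (i > 0 || j > 0) {
    if (s == 0) {
      int prev = pM[at(i, j)];
      ga.push_back(a[i - 1]); gb.push_back(b[j - 1]);
      --i; --j; s = prev;
    } else if (s == 1) {
      int prev = pX[at(i, j)];
      ga.push_back(a[i - 1]); gb.push_back('-');
      --i; s = prev;
    } else {
      int prev = pY[at(i, j)];
      ga.push_back('-'); gb.push_back(b[j - 1]);
      --j; s = prev;
    }
  }
  std::reverse(ga.begin(), ga.end());
  std::reverse(gb.begin(), gb.end());

  return List::create(_["gapped_a"] = ga, _["gapped_b"] = gb,
                      _["score"] = score);
}
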