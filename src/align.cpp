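#include <Rcpp.h>
#include <vector>
#include <string>
#include <climits>
using namespace Rcpp;

// Base coding: A/C/G/T (uppercase) -> 0..3, everything else -> -1.
// Any column involving a -1 code scores as a mismatch, including -1 vs -1
// (so N never matches N, and masked positions never match anything).
static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

static inline int col_score(int a, int b, int match, int mismatch) {
  return (a >= 0 && a == b) ? match : mismatch;
}

static const int NEG = INT_MIN / 4; // safe -infinity for affine DP

// Smith-Waterman with affine gaps (Gotoh). A gap of length k costs
// gap_open + k * gap_extend (BLAST convention: the first gapped base pays
// both the open and the extend cost).
//
// Two passes: a score-only O(m) memory sweep over the whole target locates
// the best-scoring end cell (ties: smallest target end, then smallest query
// end); alignments under this scoring scheme span at most ~1.6x the query
// on the target, so a full traceback DP is then run on a short target
// window ending at the best cell.
//
// Returns an empty vector when the best local score is <= 0, otherwise
// 9 integers: score, t_start, t_end, q_start, q_end (0-based, half-open),
// columns, matches, mismatches, gap_opens.
// [[Rcpp::export(name = ".sw_local_align")]]
IntegerVector sw_local_align(const std::string& target, const std::string& query,
                             int match, int mismatch, int gap_open, int gap_extend) {
  const int n = (int) target.size();
  const int m = (int) query.size();
  if (n == 0 || m == 0) stop("empty sequence passed to aligner");

  std::vector<int> t(n), q(m);
  for (int i = 0; i < n; ++i) t[i] = base_code(target[i]);
  for (int j = 0; j < m; ++j) q[j] = base_code(query[j]);

  const int open_total = gap_open + gap_extend; // cost of a gap's first base

  // ---- pass 1: score-only, rows = target ----
  // Combined H/E/F recurrence (H = best score of any alignment ending at the
  // cell; E = vertical gap state, F = horizontal). A gap-ended alignment can
  // never set a new maximum (its substitution core scores strictly higher
  // and is visited earlier), so `best` always marks a substitution-ended
  // alignment, which is what the traceback pass assumes.
  std::vector<int> H(m + 1, 0), E(m + 1, NEG);
  int best = 0, best_i = -1, best_j = -1;
  const int* qc = q.data();

  for (int i = 1; i <= n; ++i) {
    const int tc = t[i - 1];
    int Hdiag = 0, F = NEG, Hleft = 0;
    int* Hp = H.data();
    int* Ep = E.data();
    for (int j = 1; j <= m; ++j) {
      int e = Hp[j] - open_total;
      int e2 = Ep[j] - gap_extend;
      if (e2 > e) e = e2;
      int f = Hleft - open_total;
      int f2 = F - gap_extend;
      if (f2 > f) f = f2;
      int h = Hdiag + ((tc >= 0 && tc == qc[j - 1]) ? match : mismatch);
      if (e > h) h = e;
      if (f > h) h = f;
      if (h < 0) h = 0;
      Hdiag = Hp[j];
      Hp[j] = h;
      Ep[j] = e;
      F = f;
      Hleft = h;
      if (h > best) { best = h; best_i = i; best_j = j; }
    }
  }

  if (best <= 0) return IntegerVector(0);

  // ---- pass 2: traceback DP on a window ending at best_i ----
  // Read span of any positive-scoring alignment is < 2*m columns consuming
  // target (matches <= m, each mismatch costs 5x a match here and each
  // gapped base >= 3x), so 3*m + 16 is a safe window.
  int lo = best_i - (3 * m + 16);
  if (lo < 0) lo = 0;
  const int w = best_i - lo;

  std::vector<std::vector<int> > Mw(w + 1, std::vector<int>(m + 1, 0));
  std::vector<std::vector<int> > Ixw(w + 1, std::vector<int>(m + 1, NEG));
  std::vector<std::vector<int> > Iyw(w + 1, std::vector<int>(m + 1, NEG));

  for (int i = 1; i <= w; ++i) {
    for (int j = 1; j <= m; ++j) {
      int s = col_score(t[lo + i - 1], q[j - 1], match, mismatch);
      int from = Mw[i - 1][j - 1];
      if (Ixw[i - 1][j - 1] > from) from = Ixw[i - 1][j - 1];
      if (Iyw[i - 1][j - 1] > from) from = Iyw[i - 1][j - 1];
      if (from < 0) from = 0;
      Mw[i][j] = from + s;

      int ix = Mw[i - 1][j] - open_total;
      if (Ixw[i - 1][j] != NEG && Ixw[i - 1][j] - gap_extend > ix) ix = Ixw[i - 1][j] - gap_extend;
      Ixw[i][j] = ix;

      int iy = Mw[i][j - 1] - open_total;
      if (Iyw[i][j - 1] != NEG && Iyw[i][j - 1] - gap_extend > iy) iy = Iyw[i][j - 1] - gap_extend;
      Iyw[i][j] = iy;
    }
  }

  int ci = w, cj = best_j;
  if (Mw[ci][cj] != best)
    stop("internal error: traceback window does not reproduce the best score");

  int columns = 0, matches = 0, mismatches = 0, gap_opens = 0;
  int state = 0; // 0 = M, 1 = Ix (gap in query), 2 = Iy (gap in target)
  while (true) {
    if (state == 0) {
      int s = col_score(t[lo + ci - 1], q[cj - 1], match, mismatch);
      ++columns;
      if (t[lo + ci - 1] >= 0 && t[lo + ci - 1] == q[cj - 1]) ++matches; else ++mismatches;
      int vm = Mw[ci - 1][cj - 1], vx = Ixw[ci - 1][cj - 1], vy = Iyw[ci - 1][cj - 1];
      int from = Mw[ci][cj] - s;
      --ci; --cj;
      if (from <= 0) break;           // local alignment starts here
      if (vm == from) state = 0;      // prefer substitution columns on ties
      else if (vx == from) state = 1;
      else if (vy == from) state = 2;
      else stop("internal error: inconsistent traceback (M)");
    } else if (state == 1) {
      // gap in query: consumes target
      ++columns;
      int v = Ixw[ci][cj];
      int vm = Mw[ci - 1][cj], vx = Ixw[ci - 1][cj];
      --ci;
      if (vx != NEG && vx - gap_extend == v) state = 1; // extend run on tie
      else if (vm - open_total == v) { state = 0; ++gap_opens; }
      else stop("internal error: inconsistent traceback (Ix)");
    } else {
      // gap in target: consumes query
      ++columns;
      int v = Iyw[ci][cj];
      int vm = Mw[ci][cj - 1], vy = Iyw[ci][cj - 1];
      --cj;
      if (vy != NEG && vy - gap_extend == v) state = 2;
      else if (vm - open_total == v) { state = 0; ++gap_opens; }
      else stop("internal error: inconsistent traceback (Iy)");
    }
  }

  IntegerVector out(9);
  out[0] = best;
  out[1] = lo + ci;        // t_start, 0-based
  out[2] = best_i;         // t_end, exclusive
  out[3] = cj;             // q_start
  out[4] = best_j;         // q_end
  out[5] = columns;
  out[6] = matches;
  out[7] = mismatches;
  out[8] = gap_opens;
  return out;
}

// Exhaustive reference scorer: enumerates every local alignment path
// (every start cell and every sequence of substitution / gap columns)
// without memoization and returns the maximum score of a non-empty
// alignment. Exponential; intended for strings of length <= ~8 in tests.
static int bf_rec(const std::vector<int>& a, const std::vector<int>& b,
                  int i, int j, int last, // last: 0 start/M, 1 gap-in-b, 2 gap-in-a
                  int match, int mismatch, int open_total, int gap_extend) {
  const int n = (int) a.size(), m = (int) b.size();
  int best = NEG;
  if (i < n && j < m) {
    int s = col_score(a[i], b[j], match, mismatch);
    int cont = bf_rec(a, b, i + 1, j + 1, 0, match, mismatch, open_total, gap_extend);
    int v = s + (cont > 0 ? cont : 0);
    if (v > best) best = v;
  }
  if (i < n) { // gap column consuming a (gap in b)
    int cost = (last == 1) ? gap_extend : open_total;
    int cont = bf_rec(a, b, i + 1, j, 1, match, mismatch, open_total, gap_extend);
    int v = -cost + (cont > 0 ? cont : 0);
    if (v > best) best = v;
  }
  if (j < m) { // gap column consuming b (gap in a)
    int cost = (last == 2) ? gap_extend : open_total;
    int cont = bf_rec(a, b, i, j + 1, 2, match, mismatch, open_total, gap_extend);
    int v = -cost + (cont > 0 ? cont : 0);
    if (v > best) best = v;
  }
  return best;
}

// [[Rcpp::export(name = ".sw_brute_force_score")]]
int sw_brute_force_score(const std::string& sa, const std::string& sb,
                         int match, int mismatch, int gap_open, int gap_extend) {
  const int n = (int) sa.size(), m = (int) sb.size();
  if (n == 0 || m == 0) stop("empty sequence passed to brute-force scorer");
  std::vector<int> a(n), b(m);
  for (int i = 0; i < n; ++i) a[i] = base_code(sa[i]);
  for (int j = 0; j < m; ++j) b[j] = base_code(sb[j]);
  int best = NEG;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) {
      int v = bf_rec(a, b, i, j, 0, match, mismatch, gap_open + gap_extend, gap_extend);
      if (v > best) best = v;
    }
  return best;
}
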