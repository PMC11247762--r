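// Global (Needleman-Wunsch) pairwise alignment with affine gap costs,
// used by the greedy identity-threshold clustering. End gaps are
// penalized; identity is computed over alignment columns after trimming
// terminal gap runs, so identity and coverage stay decoupled. Among
// equal-score alignments the traceback prefers (1) more matches, then
// (2) more aligned (diagonal) columns, then the fixed state order
// M > X > Y; the enumeration oracle in the test suite replays the same
// rule.

#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double NEG = -std::numeric_limits<double>::infinity();

struct Cell {
  double score;
  int matches;  // wildcard-free identical diagonal columns
  int mcols;    // diagonal columns
};

static inline bool better(const Cell& a, const Cell& b) {
  if (a.score != b.score) return a.score > b.score;
  if (a.matches != b.matches) return a.matches > b.matches;
  return a.mcols > b.mcols;
}

// [[Rcpp::export(name = ".align_affine")]]
List align_affine(std::string a, std::string b, double match,
                  double mismatch, double gap_open, double gap_extend,
                  std::string wildcards) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty sequence");
  std::vector<bool> wc(256, false);
  for (char c : wildcards) wc[(unsigned char)c] = true;

  const int W = m + 1;
  // states: 0 = M (diagonal), 1 = X (gap in b, consumes a), 2 = Y
  std::vector<Cell> S[3];
  std::vector<signed char> from[3];  // predecessor state, -1 = none
  for (int s = 0; s < 3; ++s) {
    S[s].assign((n + 1) * W, {NEG, 0, 0});
    from[s].assign((n + 1) * W, -1);
  }
  S[0][0] = {0.0, 0, 0};
  for (int i = 1; i <= n; ++i) {
    S[1][i * W] = {gap_open + i * gap_extend, 0, 0};
    from[1][i * W] = (signed char)(i == 1 ? 0 : 1);
  }
  for (int j = 1; j <= m; ++j) {
    S[2][j] = {gap_open + j * gap_extend, 0, 0};
    from[2][j] = (signed char)(j == 1 ? 0 : 2);
  }

  for (int i = 1; i <= n; ++i) {
    const unsigned char ca = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const unsigned char cb = b[j - 1];
      const bool is_match = (ca == cb) && !wc[ca] && !wc[cb];
      const double sub = is_match ? match : mismatch;
      // M from any state at (i-1, j-1)
      {
        int idx = (i - 1) * W + (j - 1);
        Cell best = {NEG, 0, 0};
        signed char bs = -1;
        for (int s = 0; s < 3; ++s) {
          if (S[s][idx].score == NEG) continue;
          Cell cand = {S[s][idx].score + sub,
                       S[s][idx].matches + (is_match ? 1 : 0),
                       S[s][idx].mcols + 1};
          if (bs < 0 || better(cand, best)) { best = cand; bs = (signed char)s; }
        }
        S[0][i * W + j] = best;
        from[0][i * W + j] = bs;
      }
      // X from (i-1, j): open from M/Y, extend from X
      {
        int idx = (i - 1) * W + j;
        Cell best = {NEG, 0, 0};
        signed char bs = -1;
        for (int s = 0; s < 3; ++s) {
          if (S[s][idx].score == NEG) continue;
          double g = (s == 1) ? gap_extend : (gap_open + gap_extend);
          Cell cand = {S[s][idx].score + g, S[s][idx].matches, S[s][idx].mcols};
          if (bs < 0 || better(cand, best)) { best = cand; bs = (signed char)s; }
        }
        S[1][i * W + j] = best;
        from[1][i * W + j] = bs;
      }
      // Y from (i, j-1)
      {
        int idx = i * W + (j - 1);
        Cell best = {NEG, 0, 0};
        signed char bs = -1;
        for (int s = 0; s < 3; ++s) {
          if (S[s][idx].score == NEG) continue;
          double g = (s == 2) ? gap_extend : (gap_open + gap_extend);
          Cell cand = {S[s][idx].score + g, S[s][idx].matches, S[s][idx].mcols};
          if (bs < 0 || better(cand, best)) { best = cand; bs = (signed char)s; }
        }
        S[2][i * W + j] = best;
        from[2][i * W + j] = bs;
      }
    }
  }

  // Final-state preference Y > X > M on ties: an equal-score alignment
  // ending in a gap run keeps that run terminal, where it is excluded
  // from the identity denominator.
  int end = n * W + m;
  const int pref[3] = {2, 1, 0};
  int state = pref[0];
  for (int s = 1; s < 3; ++s)
    if (better(S[pref[s]][end], S[state][end])) state = pref[s];
  Cell fin = S[state][end];

  // traceback: record the move (0=M, 1=X, 2=Y) per column, end to start
  std::vector<signed char> moves;
  int i = n, j = m, s = state;
  while (i > 0 || j > 0) {
    moves.push_back((signed char)s);
    signed char prev = from[s][i * W + j];
    if (s == 0) { --i; --j; }
    else if (s == 1) { --i; }
    else { --j; }
    s = prev;
  }
  std::reverse(moves.begin(), moves.end());

  const int cols = moves.size();
  int lead = 0, trail = 0;
  while (lead < cols && moves[lead] != 0) ++lead;
  while (trail < cols - lead && moves[cols - 1 - trail] != 0) ++trail;
  const int core = cols - lead - trail;
  int a_core = 0, b_core = 0;
  for (int k = lead; k < cols - trail; ++k) {
    if (moves[k] == 0) { ++a_core; ++b_core; }
    else if (moves[k] == 1) ++a_core;
    else ++b_core;
  }
  double identity = core > 0 ? (double)fin.matches / core : 0.0;

  return List::create(
    _["score"] = fin.score,
    _["matches"] = fin.matches,
    _["aligned_columns"] = fin.mcols,
    _["columns"] = cols,
    _["core_columns"] = core,
    _["identity"] = identity,
    _["coverage_query"] = (double)a_core / n,
    _["coverage_target"] = (double)b_core / m);
}
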