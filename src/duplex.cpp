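#include <Rcpp.h>
#include <climits>
using namespace Rcpp;

// Intermolecular duplex minimum free energy by dynamic programming.
//
// mir: guide strand 5'->3' (miRNA with position 1 already trimmed), DNA letters.
// tar: target region 5'->3', DNA letters.
// A structure is a set of pairs (i, j), i on the guide, j on the target,
// strictly monotone (i increasing, j decreasing: antiparallel helix), no
// intramolecular pairs, no branching. Consecutive pairs are scored with a
// nearest-neighbour stacking table when contiguous, otherwise with affine
// bulge / interior-loop penalties; unpaired stretches between consecutive
// pairs are bounded by max_bulge on each side.
//
// `required` lists guide positions (1-based, trimmed coordinates) that must be
// paired; `anchor[i-1]` (1-based target index, 0 = free) additionally pins a
// required position to a specific target base (forced canonical seed helix).

static inline int pair_code(char a, char b) {
  if (a == 'A' && b == 'T') return 0;  // A:U
  if (a == 'T' && b == 'A') return 1;  // U:A
  if (a == 'C' && b == 'G') return 2;  // C:G
  if (a == 'G' && b == 'C') return 3;  // G:C
  if (a == 'G' && b == 'T') return 4;  // G:U
  if (a == 'T' && b == 'G') return 5;  // U:G
  return -1;
}

static inline double end_pen(int code, double term_au) {
  // closing A:U or G:U pairs are penalised at each duplex end
  return (code == 2 || code == 3) ? 0.0 : term_au;
}

// [[Rcpp::export]]
List duplex_dp_cpp(std::string mir, std::string tar, NumericMatrix stack,
                   double bulge_open, double bulge_ext, double interior_open,
                   double interior_ext, int max_bulge, double term_au,
                   double pair_bonus, IntegerVector required,
                   IntegerVector anchor) {
  const int m = mir.size(), n = tar.size();
  const double INF = 1e18;
  std::vector<int> pc((size_t)m * n);
  for (int i = 0; i < m; i++)
    for (int j = 0; j < n; j++) pc[(size_t)i * n + j] = pair_code(mir[i], tar[j]);

  std::vector<bool> is_req(m + 2, false);
  int minreq = INT_MAX, maxreq = 0;
  for (int k = 0; k < required.size(); k++) {
    int r = required[k];
    if (r >= 1 && r <= m) {
      is_req[r] = true;
      if (r < minreq) minreq = r;
      if (r > maxreq) maxreq = r;
    }
  }
  // nextreq[i]: smallest required position > i (1-based), INT_MAX if none
  std::vector<int> nextreq(m + 2, INT_MAX);
  for (int i = m - 1; i >= 0; i--)
    nextreq[i] = is_req[i + 1] ? i + 1 : nextreq[i + 1];

  std::vector<double> E((size_t)m * n, INF);
  std::vector<int> par((size_t)m * n, -1);

  for (int i2 = 1; i2 <= m; i2++) {
    for (int j2 = 1; j2 <= n; j2++) {
      int c2 = pc[(size_t)(i2 - 1) * n + (j2 - 1)];
      if (c2 < 0) continue;
      int a = anchor[i2 - 1];
      if (a > 0 && a != j2) continue;
      double best = INF;
      int bp = -1;
      if (minreq >= i2) {  // may open the duplex here
        best = end_pen(c2, term_au) + pair_bonus;
      }
      int i1lo = std::max(1, i2 - 1 - max_bulge);
      for (int i1 = i1lo; i1 < i2; i1++) {
        if (nextreq[i1] < i2) continue;  // would skip a required position
        int gi = i2 - i1 - 1;
        int j1hi = std::min(n, j2 + 1 + max_bulge);
        for (int j1 = j2 + 1; j1 <= j1hi; j1++) {
          double e1 = E[(size_t)(i1 - 1) * n + (j1 - 1)];
          if (e1 >= INF) continue;
          int gj = j1 - j2 - 1;
          double cost;
          if (gi == 0 && gj == 0) {
            cost = stack(pc[(size_t)(i1 - 1) * n + (j1 - 1)], c2);
          } else if (gi == 0 || gj == 0) {
            cost = bulge_open + bulge_ext * (gi + gj);
          } else {
            cost = interior_open + interior_ext * (gi + gj);
          }
          double v = e1 + cost + pair_bonus;
          if (v < best) { best = v; bp = (i1 - 1) * n + (j1 - 1); }
        }
      }
      E[(size_t)(i2 - 1) * n + (j2 - 1)] = best;
      par[(size_t)(i2 - 1) * n + (j2 - 1)] = bp;
    }
  }

  double bestTot = INF;
  int bestIdx = -1;
  for (int i = maxreq > 0 ? maxreq : 1; i <= m; i++) {
    for (int j = 1; j <= n; j++) {
      double e = E[(size_t)(i - 1) * n + (j - 1)];
      if (e >= INF) continue;
      double tot = e + end_pen(pc[(size_t)(i - 1) * n + (j - 1)], term_au);
      if (tot < bestTot) { bestTot = tot; bestIdx = (i - 1) * n + (j - 1); }
    }
  }

  IntegerVector pairing(m, 0);
  bool feasible = bestIdx >= 0;
  if (feasible) {
    int idx = bestIdx;
    while (idx >= 0) {
      int i = idx / n, j = idx % n;
      pairing[i] = j + 1;
      idx = par[idx];
    }
  }
  return List::create(_["mfe"] = feasible ? bestTot : 0.0,
                      _["pairing"] = pairing,
                      _["feasible"] = feasible);
}
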