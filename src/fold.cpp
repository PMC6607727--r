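#include <Rcpp.h>
#include <vector>
#include <string>

using namespace Rcpp;

// Pair weight for bases a, b (uppercase A/C/G/T; U already mapped to T).
// 0 means the two bases cannot pair.
static inline double pair_weight(char a, char b, double w_gc, double w_au,
                                 double w_gu) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return w_gc;
  if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A')) return w_au;
  if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) return w_gu;
  return 0.0;
}

// Lightweight stem-loop folding model. A structure is a set of nested
// stem-loops (no multiloops, no pseudoknots); its score is maximised:
//   + pair weight per base pair
//   + stack_bonus per pair stacked directly on the previous pair
//   - hairpin_penalty per hairpin loop
//   - interior loops / bulges cost interior_open plus interior_per_nt
//     per unpaired nt (total gap capped at max_interior nt)
// Tables:
//   C[i][j]  best score of the region [i, j] given (i, j) paired
//          = w(i,j) + max( -Ph,
//                          C[k][l] + (stacked ? +s : -Pi) )
//   E[j]    best score of the prefix [0, j]
//          = max( E[j-1], max_i E[i-1] + C[i][j] )
// Deterministic traceback: rightmost closing position first, smallest
// partner index on ties, stacked continuation preferred inside a helix,
// then interior loops by increasing total gap.
// [[Rcpp::export(name = ".fold_stemloop")]]
List fold_stemloop(std::string seq, double w_gc, double w_au, double w_gu,
                   int min_loop, double stack_bonus, double hairpin_penalty,
                   double interior_open, double interior_per_nt,
                   int max_interior) {
  const int n = (int)seq.size();
  IntegerVector pair_table(n, -1);
  if (n < 2) {
    return List::create(_["pair_table"] = pair_table, _["score"] = 0.0);
  }
  const double NEG = -1e18;
  std::vector<std::vector<double> > C(n, std::vector<double>(n, NEG));
  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      double w = pair_weight(seq[i], seq[j], w_gc, w_au, w_gu);
      if (w <= 0.0) continue;
      double best = -hairpin_penalty;  // hairpin closure
      int gmax = max_interior;
      for (int g5 = 0; g5 <= gmax; ++g5) {
        int k = i + 1 + g5;
        if (k >= j) break;
        for (int g3 = 0; g3 + g5 <= gmax; ++g3) {
          int l = j - 1 - g3;
          if (l <= k) break;
          if (C[k][l] <= NEG / 2) continue;
          double bonus = (g5 == 0 && g3 == 0)
                             ? stack_bonus
                             : -(interior_open + interior_per_nt * (g5 + g3));
          double cand = C[k][l] + bonus;
          if (cand > best) best = cand;
        }
      }
      C[i][j] = w + best;
    }
  }
  std::vector<double> E(n + 1, 0.0);  // E[j+1] = best for prefix [0, j]
  std::vector<int> Epair(n, -1);      // partner of j if j closes a pair
  for (int j = 0; j < n; ++j) {
    double paired_best = NEG;
    int partner = -1;
    for (int i = 0; i + min_loop + 1 <= j; ++i) {
      if (C[i][j] <= NEG / 2) continue;
      double cand = E[i] + C[i][j];
      if (cand > paired_best) {  // smallest i attaining the max wins
        paired_best = cand;
        partner = i;
      }
    }
    if (partner >= 0 && paired_best >= E[j]) {  // prefer pairing on ties
      E[j + 1] = paired_best;
      Epair[j] = partner;
    } else {
      E[j + 1] = E[j];
      Epair[j] = -1;
    }
  }
  // exterior traceback from the right
  std::vector<std::pair<int, int> > helices;
  {
    int j = n - 1;
    while (j >= 0) {
      if (Epair[j] < 0) {
        --j;
      } else {
        int i = Epair[j];
        helices.push_back(std::make_pair(i, j));
        j = i - 1;
      }
    }
  }
  // closed-region traceback
  std::vector<std::pair<int, int> > stack = helices;
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    pair_table[i] = j;
    pair_table[j] = i;
    double w = pair_weight(seq[i], seq[j], w_gc, w_au, w_gu);
    double inner = C[i][j] - w;
    // continuations are checked before the hairpin closure so that
    // helices stay maximal on ties
    bool done = false;
    // stacked continuation first
    if (i + 1 < j - 1 && C[i + 1][j - 1] > NEG / 2 &&
        C[i + 1][j - 1] + stack_bonus == inner) {
      stack.push_back(std::make_pair(i + 1, j - 1));
      done = true;
    }
    if (!done) {
      for (int g = 1; g <= max_interior && !done; ++g) {
        for (int g5 = 0; g5 <= g; ++g5) {
          int g3 = g - g5;
          int k = i + 1 + g5, l = j - 1 - g3;
          if (k >= l) continue;
          if (C[k][l] <= NEG / 2) continue;
          if (C[k][l] - (interior_open + interior_per_nt * g) == inner) {
            stack.push_back(std::make_pair(k, l));
            done = true;
            break;
          }
        }
      }
    }
    // otherwise: hairpin closure, interior left unpaired
  }
  return List::create(_["pair_table"] = pair_table,
                      _["score"] = E[n]);
}
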