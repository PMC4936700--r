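// Bundled secondary-structure folding backend.
//
// Energy model (integer kcal/mol, exact arithmetic):
//   * allowed pairs: AU, UA, GC, CG, GU, UG; hairpin loops >= 3 nt;
//   * a pair (i,j) whose inner neighbour (i+1,j-1) is also paired scores a
//     stacking bonus: -2 if (i,j) is GC/CG, -1 if AU/UA/GU/UG;
//   * a pair whose inner neighbour is NOT paired pays a +2 helix-opening
//     penalty (the loop-entropy cost of starting a new helix);
//   * each hairpin loop (a pair with no pairs strictly inside) costs +3;
//   * everything else (bulge/interior/multiloop size, dangles) is 0.
// The MFE is min over all pseudoknot-free structures, never above 0 (the
// open chain scores 0).

#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

static const int INF = 1000000000;
static const int MINLOOP = 3;
static const int HAIRPIN_PENALTY = 3;
static const int HELIX_OPEN = 2;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'U': case 'u': case 'T': case 't': return 3;
  default: return 4; // N or other
  }
}

static inline bool pairable(int a, int b) {
  // AU, UA, GC, CG, GU, UG
  return (a == 0 && b == 3) || (a == 3 && b == 0) ||
         (a == 2 && b == 1) || (a == 1 && b == 2) ||
         (a == 2 && b == 3) || (a == 3 && b == 2);
}

static inline int stack_energy(int a, int b) {
  // energy of the outer pair (a,b) stacked on a paired inner neighbour
  if ((a == 2 && b == 1) || (a == 1 && b == 2)) return -2; // GC/CG
  return -1; // AU/UA/GU/UG
}

struct FoldDP {
  int n;
  std::vector<int> code;
  // flattened n x n tables, index i*n+j (i < j)
  std::vector<int> V;   // min energy with (i,j) paired
  std::vector<int> Wp;  // min energy of i..j with >=1 pair, (i,j) not mutually paired
  std::vector<int> W;   // min energy of i..j, unconstrained (>= includes empty = 0)
  std::string db;

  explicit FoldDP(const std::string &seq) : n((int)seq.size()) {
    code.resize(n);
    for (int i = 0; i < n; ++i) code[i] = base_code(seq[i]);
    V.assign((size_t)n * n, INF);
    Wp.assign((size_t)n * n, INF);
    W.assign((size_t)n * n, 0);
    db.assign(n, '.');
  }

  inline int &v(int i, int j) { return V[(size_t)i * n + j]; }
  inline int &wp(int i, int j) { return Wp[(size_t)i * n + j]; }
  inline int &w(int i, int j) { return W[(size_t)i * n + j]; }

  void fill() {
    for (int span = MINLOOP + 2; span <= n; ++span) {
      for (int i = 0; i + span - 1 < n; ++i) {
        int j = i + span - 1;
        // V(i,j)
        if (pairable(code[i], code[j]) && j - i - 1 >= MINLOOP) {
          // hairpin closure: unstacked pair (+2) closing a loop (+3)
          int best = HAIRPIN_PENALTY + HELIX_OPEN;
          if (j - i - 1 >= MINLOOP + 2 && pairable(code[i + 1], code[j - 1]) &&
              v(i + 1, j - 1) < INF) {
            int e = stack_energy(code[i], code[j]) + v(i + 1, j - 1);
            if (e < best) best = e;
          }
          if (j - 1 > i + 1 && wp(i + 1, j - 1) < INF) {
            int e = HELIX_OPEN + wp(i + 1, j - 1);
            if (e < best) best = e;
          }
          v(i, j) = best;
        }
        // Wp(i,j): >=1 pair, i and j not paired to each other
        {
          int best = INF;
          if (i + 1 <= j && wp(i + 1, j) < INF) best = wp(i + 1, j);
          for (int k = i + MINLOOP + 1; k <= j - 1; ++k) {
            if (v(i, k) < INF) {
              int e = v(i, k) + w(k + 1, j);
              if (e < best) best = e;
            }
          }
          wp(i, j) = best;
        }
        // W(i,j)
        {
          int best = w(i + 1, j); // i unpaired (w defaults 0 for short spans)
          for (int k = i + MINLOOP + 1; k <= j; ++k) {
            if (v(i, k) < INF) {
              int e = v(i, k) + ((k + 1 <= j) ? w(k + 1, j) : 0);
              if (e < best) best = e;
            }
          }
          if (best > 0) best = 0; // open chain always available
          w(i, j) = best;
        }
      }
    }
  }

  void traceV(int i, int j);
  void traceWp(int i, int j);
  void traceW(int i, int j);
};

void FoldDP::traceW(int i, int j) {
  while (i < j) {
    if (j - i + 1 < MINLOOP + 2 || w(i, j) == 0) return;
    if (w(i, j) == w(i + 1, j)) { ++i; continue; }
    bool done = false;
    for (int k = i + MINLOOP + 1; k <= j && !done; ++k) {
      if (v(i, k) < INF &&
          v(i, k) + ((k + 1 <= j) ? w(k + 1, j) : 0) == w(i, j)) {
        traceV(i, k);
        i = k + 1;
        done = true;
      }
    }
    if (!done) return; // defensive; unreachable
  }
}

void FoldDP::traceWp(int i, int j) {
  while (i < j) {
    if (wp(i, j) >= INF) return;
    if (i + 1 <= j && wp(i + 1, j) == wp(i, j)) { ++i; continue; }
    for (int k = i + MINLOOP + 1; k <= j - 1; ++k) {
      if (v(i, k) < INF && v(i, k) + w(k + 1, j) == wp(i, j)) {
        traceV(i, k);
        traceW(k + 1, j);
        return;
      }
    }
    return;
  }
}

void FoldDP::traceV(int i, int j) {
  db[i] = '(';
  db[j] = ')';
  int e = v(i, j);
  if (j - i - 1 >= MINLOOP + 2 && pairable(code[i + 1], code[j - 1]) &&
      v(i + 1, j - 1) < INF &&
      e == stack_energy(code[i], code[j]) + v(i + 1, j - 1)) {
    traceV(i + 1, j - 1);
    return;
  }
  if (e == HAIRPIN_PENALTY + HELIX_OPEN && j - i - 1 >= MINLOOP)
    return; // hairpin loop
  if (j - 1 > i + 1 && wp(i + 1, j - 1) < INF &&
      e == HELIX_OPEN + wp(i + 1, j - 1)) {
    traceWp(i + 1, j - 1);
    return;
  }
}

// [[Rcpp::export(name = ".fold_bundled_cpp")]]
List fold_bundled_cpp(std::string seq) {
  int n = (int)seq.size();
  if (n == 0) return List::create(_["structure"] = "", _["mfe"] = 0.0);
  FoldDP dp(seq);
  if (n >= MINLOOP + 2) {
    dp.fill();
    int mfe = dp.w(0, n - 1);
    dp.traceW(0, n - 1);
    return List::create(_["structure"] = dp.db, _["mfe"] = (double)mfe);
  }
  return List::create(_["structure"] = std::string(n, '.'), _["mfe"] = 0.0);
}
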