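#include <Rcpp.h>
#include <map>
#include <string>
#include <vector>

// Reference secondary-structure folder: a deterministic "nearest-neighbor-lite"
// energy model over nested (pseudoknot-free) structures.
//
// Energies are integers in tenths of kcal/mol (minimized):
//   base pair:   G:C -30, A:U -20, G:U -10
//   stack bonus: adjacent pairs (i,j)/(i+1,j-1) add -10 if either pair is G:C,
//                else -5
//   hairpin:     a pair enclosing no other pair with loop length L >= 3 pays
//                +30 + (L - 3); other loop types are free
// Minimum hairpin loop is 3 nt. Ties between co-optimal structures are broken
// by the lexicographically smallest dot-bracket string ('(' < ')' < '.').
// The model is a consistent ordering device for tests, not an RNAfold clone.

static const int INF = 1000000000;
static const int MINLOOP = 3;

static inline int enc(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': case 'U': return 3;
  default:  return 4;
  }
}

// pair energy in tenths; INF if the two bases cannot pair
static inline int pairE(int a, int b) {
  if ((a == 2 && b == 1) || (a == 1 && b == 2)) return -30; // G:C
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return -20; // A:U
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return -10; // G:U
  return INF;
}

static inline bool isGC(int a, int b) {
  return (a == 2 && b == 1) || (a == 1 && b == 2);
}

static inline int hairpinPen(int L) { return 30 + (L - MINLOOP); }

struct FoldDP {
  int n;
  std::vector<int> s;
  // V is row-major (V[i*n+k] contiguous in k); W/W1 are column-major
  // (W[j*n+i] contiguous in i) so the decomposition loop over k touches
  // V(i,k) and W(k+1,j) as two contiguous streams.
  std::vector<int> V, W, W1;
  std::map<long long, std::string> mW, mW1, mV;

  int gW(int i, int j) const { return (i > j) ? 0 : W[(long long)j * n + i]; }
  int gW1(int i, int j) const { return (i > j) ? INF : W1[(long long)j * n + i]; }
  int gV(int i, int j) const { return (i > j) ? INF : V[(long long)i * n + j]; }

  explicit FoldDP(const std::string &seq) {
    n = (int)seq.size();
    s.resize(n);
    for (int i = 0; i < n; ++i) s[i] = enc(seq[i]);
    V.assign((long long)n * n, INF);
    W.assign((long long)n * n, 0);
    W1.assign((long long)n * n, INF);
    run();
  }

  int stackBonus(int i, int j) const {
    // bonus for stacking (i,j) on (i+1,j-1)
    bool gc = isGC(s[i], s[j]) || isGC(s[i + 1], s[j - 1]);
    return gc ? -10 : -5;
  }

  void run() {
    for (int j = 1; j < n; ++j) {
      int *Wj = &W[(long long)j * n];
      int *W1j = &W1[(long long)j * n];
      for (int i = j - 1; i >= 0; --i) {
        // V(i,j)
        int pe = pairE(s[i], s[j]);
        if (pe < INF && j - i - 1 >= MINLOOP) {
          int best = hairpinPen(j - i - 1);
          int vin = gV(i + 1, j - 1);
          if (vin < INF) {
            int cand = stackBonus(i, j) + vin;
            if (cand < best) best = cand;
          }
          int w1in = gW1(i + 1, j - 1);
          if (w1in < INF && w1in < best) best = w1in;
          V[(long long)i * n + j] = pe + best;
        }
        // W(i,j), W1(i,j): i unpaired, or i pairs k and the rest follows
        int bw = Wj[i + 1]; // W(i+1,j); i+1 <= j always holds here
        int bw1 = W1j[i + 1];
        const int *Vi = &V[(long long)i * n];
        for (int k = i + MINLOOP + 1; k < j; ++k) {
          int vik = Vi[k];
          if (vik >= INF) continue;
          int tot = vik + Wj[k + 1];
          if (tot < bw) bw = tot;
          if (tot < bw1) bw1 = tot;
        }
        int vij = Vi[j]; // k == j: empty remainder
        if (vij < INF) {
          if (vij < bw) bw = vij;
          if (vij < bw1) bw1 = vij;
        }
        Wj[i] = bw;
        W1j[i] = bw1;
      }
    }
  }

  std::string lexV(int i, int j);
  std::string lexW(int i, int j);
  std::string lexW1(int i, int j);
};

std::string FoldDP::lexV(int i, int j) {
  long long key = (long long)i * n + j;
  auto it = mV.find(key);
  if (it != mV.end()) return it->second;
  int pe = pairE(s[i], s[j]);
  int target = gV(i, j) - pe;
  int L = j - i - 1;
  std::string best;
  bool have = false;
  if (hairpinPen(L) == target) {
    best = std::string(L, '.');
    have = true;
  }
  int vin = gV(i + 1, j - 1);
  if (vin < INF && stackBonus(i, j) + vin == target) {
    std::string cand = lexV(i + 1, j - 1);
    if (!have || cand < best) { best = cand; have = true; }
  }
  int w1in = gW1(i + 1, j - 1);
  if (w1in < INF && w1in == target) {
    std::string cand = lexW1(i + 1, j - 1);
    if (!have || cand < best) { best = cand; have = true; }
  }
  std::string out = "(" + best + ")";
  mV[key] = out;
  return out;
}

std::string FoldDP::lexW(int i, int j) {
  if (i > j) return "";
  long long key = (long long)i * n + j;
  auto it = mW.find(key);
  if (it != mW.end()) return it->second;
  int w = gW(i, j);
  std::string best;
  bool have = false;
  for (int k = i + MINLOOP + 1; k <= j; ++k) {
    int vik = gV(i, k);
    if (vik >= INF) continue;
    if (vik + gW(k + 1, j) != w) continue;
    std::string cand = lexV(i, k) + lexW(k + 1, j);
    if (!have || cand < best) { best = cand; have = true; }
  }
  if (!have) {
    // '.' is larger than '(' so unpaired-i is only taken when no pairing works
    best = "." + lexW(i + 1, j);
  }
  mW[key] = best;
  return best;
}

std::string FoldDP::lexW1(int i, int j) {
  long long key = (long long)i * n + j;
  auto it = mW1.find(key);
  if (it != mW1.end()) return it->second;
  int w = gW1(i, j);
  std::string best;
  bool have = false;
  for (int k = i + MINLOOP + 1; k <= j; ++k) {
    int vik = gV(i, k);
    if (vik >= INF) continue;
    if (vik + gW(k + 1, j) != w) continue;
    std::string cand = lexV(i, k) + lexW(k + 1, j);
    if (!have || cand < best) { best = cand; have = true; }
  }
  if (!have) {
    best = "." + lexW1(i + 1, j);
  }
  mW1[key] = best;
  return best;
}

// [[Rcpp::export]]
Rcpp::List fold_reference_cpp(std::string seq, bool structure = true) {
  int n = (int)seq.size();
  if (n == 0) Rcpp::stop("empty sequence");
  FoldDP dp(seq);
  int e = dp.gW(0, n - 1);
  double mfe = e / 10.0;
  if (!structure) {
    return Rcpp::List::create(Rcpp::Named("structure") = R_NilValue,
                              Rcpp::Named("mfe") = mfe);
  }
  std::string db = dp.lexW(0, n - 1);
  return Rcpp::List::create(Rcpp::Named("structure") = db,
                            Rcpp::Named("mfe") = mfe);
}

// [[Rcpp::export]]
Rcpp::NumericVector fold_reference_mfe_many_cpp(std::vector<std::string> seqs) {
  Rcpp::NumericVector out(seqs.size());
  for (size_t i = 0; i < seqs.size(); ++i) {
    FoldDP dp(seqs[i]);
    out[i] = dp.gW(0, (int)seqs[i].size() - 1) / 10.0;
  }
  return out;
}
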