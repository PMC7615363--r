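#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Restricted (optimal string alignment) Damerau-Levenshtein distance:
// Wagner-Fischer dynamic program extended with one adjacent-transposition row.
// Unit cost for substitution, insertion, deletion and adjacent transposition;
// each substring may take part in at most one transposition.
static int osa_one(const std::string &a, const std::string &b) {
  const int la = a.size(), lb = b.size();
  if (la == 0) return lb;
  if (lb == 0) return la;
  std::vector<int> prev2(lb + 1), prev(lb + 1), cur(lb + 1);
  for (int j = 0; j <= lb; ++j) prev[j] = j;
  for (int i = 1; i <= la; ++i) {
    cur[0] = i;
    for (int j = 1; j <= lb; ++j) {
      int cost = (a[i - 1] == b[j - 1]) ? 0 : 1;
      int d = std::min(std::min(prev[j] + 1, cur[j - 1] + 1), prev[j - 1] + cost);
      if (i > 1 && j > 1 && a[i - 1] == b[j - 2] && a[i - 2] == b[j - 1])
        d = std::min(d, prev2[j - 2] + 1);
      cur[j] = d;
    }
    std::swap(prev2, prev);
    std::swap(prev, cur);
  }
  return prev[lb];
}

// [[Rcpp::export]]
IntegerVector osa_distance_cpp(CharacterVector a, CharacterVector b) {
  R_xlen_t n = std::max(a.size(), b.size());
  if (a.size() != n && a.size() != 1)
    stop("lengths of 'a' and 'b' must match or be 1");
  if (b.size() != n && b.size() != 1)
    stop("lengths of 'a' and 'b' must match or be 1");
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string sa = as<std::string>(a[a.size() == 1 ? 0 : i]);
    std::string sb = as<std::string>(b[b.size() == 1 ? 0 : i]);
    out[i] = osa_one(sa, sb);
  }
  return out;
}

static bool can_pair(char x, char y, bool wobble) {
  if ((x == 'A' && y == 'U') || (x == 'U' && y == 'A')) return true;
  if ((x == 'G' && y == 'C') || (x == 'C' && y == 'G')) return true;
  if (wobble && ((x == 'G' && y == 'U') || (x == 'U' && y == 'G'))) return true;
  return false;
}

// Maximum base-pair secondary structure (Nussinov-style dynamic program),
// hairpin loops of at least min_loop unpaired bases. Input must be uppercase
// RNA (A/C/G/U); any other character is treated as unpairable.
// [[Rcpp::export]]
List nussinov_cpp(std::string seq, int min_loop, bool wobble) {
  const int n = seq.size();
  std::string db(n, '.');
  if (n == 0) return List::create(_["structure"] = db, _["pairs"] = 0);
  std::vector<std::vector<int> > M(n, std::vector<int>(n, 0));
  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int best = M[i][j - 1];  // j unpaired
      for (int k = i; k <= j - min_loop - 1; ++k) {
        if (can_pair(seq[k], seq[j], wobble)) {
          int left = (k > i) ? M[i][k - 1] : 0;
          int inner = (k + 1 <= j - 1) ? M[k + 1][j - 1] : 0;
          best = std::max(best, left + inner + 1);
        }
      }
      M[i][j] = best;
    }
  }
  // traceback
  int pairs = 0;
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j) continue;
    if (M[i][j] == M[i][j - 1]) {
      stack.push_back(std::make_pair(i, j - 1));
      continue;
    }
    for (int k = i; k <= j - min_loop - 1; ++k) {
      if (!can_pair(seq[k], seq[j], wobble)) continue;
      int left = (k > i) ? M[i][k - 1] : 0;
      int inner = (k + 1 <= j - 1) ? M[k + 1][j - 1] : 0;
      if (left + inner + 1 == M[i][j]) {
        db[k] = '(';
        db[j] = ')';
        ++pairs;
        if (k > i) stack.push_back(std::make_pair(i, k - 1));
        if (k + 1 <= j - 1) stack.push_back(std::make_pair(k + 1, j - 1));
        break;
      }
    }
  }
  return List::create(_["structure"] = db, _["pairs"] = pairs);
}
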