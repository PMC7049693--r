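#include <Rcpp.h>
#include <vector>
#include <string>
#include <stack>
using namespace Rcpp;

// Watson-Crick plus wobble pairing on DNA alphabet (T stands for U).
static inline bool can_pair(char a, char b) {
  switch (a) {
  case 'A': return b == 'T';
  case 'T': return b == 'A' || b == 'G';
  case 'G': return b == 'C' || b == 'T';
  case 'C': return b == 'G';
  default: return false;
  }
}

// Base-pair maximization (Nussinov) with a minimum hairpin loop length.
// Returns the 1-based pairing partner for each position (0 = unpaired),
// from one maximal structure recovered by deterministic traceback.
// [[Rcpp::export(name = ".nussinov_pairs")]]
IntegerVector nussinov_pairs(std::string seq, int min_loop = 3) {
  int n = (int) seq.size();
  IntegerVector partner(n, 0);
  if (n < min_loop + 2) return partner;

  std::vector<std::vector<int>> F(n, std::vector<int>(n, 0));
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = F[i + 1][j];
      if (F[i][j - 1] > best) best = F[i][j - 1];
      if (can_pair(seq[i], seq[j]) && j - i - 1 >= min_loop) {
        int v = F[i + 1][j - 1] + 1;
        if (v > best) best = v;
      }
      for (int k = i + 1; k < j; ++k) {
        int v = F[i][k] + F[k + 1][j];
        if (v > best) best = v;
      }
      F[i][j] = best;
    }
  }

  std::stack<std::pair<int, int>> todo;
  todo.push(std::make_pair(0, n - 1));
  while (!todo.empty()) {
    int i = todo.top().first, j = todo.top().second;
    todo.pop();
    if (i >= j || j - i < min_loop + 1) continue;
    if (F[i][j] == 0) continue;
    // pair-first traceback: prefer closing (i,j), which reconstructs
    // designed stacked helices whenever they are co-optimal
    if (can_pair(seq[i], seq[j]) && j - i - 1 >= min_loop &&
        F[i][j] == F[i + 1][j - 1] + 1) {
      partner[i] = j + 1;
      partner[j] = i + 1;
      todo.push(std::make_pair(i + 1, j - 1));
      continue;
    }
    if (F[i][j] == F[i + 1][j]) {
      todo.push(std::make_pair(i + 1, j));
      continue;
    }
    if (F[i][j] == F[i][j - 1]) {
      todo.push(std::make_pair(i, j - 1));
      continue;
    }
    bool split = false;
    for (int k = i + 1; k < j && !split; ++k) {
      if (F[i][j] == F[i][k] + F[k + 1][j]) {
        todo.push(std::make_pair(i, k));
        todo.push(std::make_pair(k + 1, j));
        split = true;
      }
    }
  }
  return partner;
}
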