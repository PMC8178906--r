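#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>

// Longest common subsequence length by two-row dynamic programming.
// Equals the optimal score of a global alignment with match = 1,
// mismatch = 0 and gap = 0, which is the identity-scoring contract.
static int lcs_len(const std::string& a, const std::string& b) {
  const size_t n = a.size(), m = b.size();
  if (n == 0 || m == 0) return 0;
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  for (size_t i = 1; i <= n; ++i) {
    const char ai = a[i - 1];
    for (size_t j = 1; j <= m; ++j) {
      if (ai == b[j - 1]) {
        cur[j] = prev[j - 1] + 1;
      } else {
        cur[j] = std::max(prev[j], cur[j - 1]);
      }
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export]]
int lcs_length_cpp(std::string a, std::string b) {
  return lcs_len(a, b);
}

// Symmetric percent-identity matrix for one family: 100 * LCS / min length.
// [[Rcpp::export]]
Rcpp::NumericMatrix lcs_identity_matrix_cpp(std::vector<std::string> seqs) {
  const int n = seqs.size();
  Rcpp::NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    out(i, i) = 100.0;
    for (int j = i + 1; j < n; ++j) {
      const double mn = std::min(seqs[i].size(), seqs[j].size());
      const double pid = 100.0 * lcs_len(seqs[i], seqs[j]) / mn;
      out(i, j) = pid;
      out(j, i) = pid;
    }
  }
  return out;
}
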