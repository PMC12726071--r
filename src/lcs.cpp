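#include <Rcpp.h>
#include <string>
#include <vector>

// Length of the longest common subsequence of two strings: the number of
// matching positions in an optimal global alignment under match = 1,
// mismatch = 0, gap = 0 scoring (gaps and mismatches free).
static int lcs_len(const std::string &a, const std::string &b) {
  const size_t n = a.size(), m = b.size();
  if (n == 0 || m == 0) return 0;
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  for (size_t i = 1; i <= n; ++i) {
    for (size_t j = 1; j <= m; ++j) {
      if (a[i - 1] == b[j - 1]) cur[j] = prev[j - 1] + 1;
      else cur[j] = std::max(prev[j], cur[j - 1]);
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export(name = ".lcs_length")]]
Rcpp::IntegerVector lcs_length(Rcpp::CharacterVector a, Rcpp::CharacterVector b) {
  R_xlen_t n = std::max(a.size(), b.size());
  Rcpp::IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string sa = Rcpp::as<std::string>(a[i % a.size()]);
    std::string sb = Rcpp::as<std::string>(b[i % b.size()]);
    out[i] = lcs_len(sa, sb);
  }
  return out;
}
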