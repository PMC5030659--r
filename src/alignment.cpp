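#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Scoring: match/mismatch on single bases, linear gap penalty per gapped
// position. 'N' never matches anything (treated as mismatch even against 'N').
static inline bool base_match(char a, char b) {
  return a == b && a != 'N' && a != 'n';
}

static std::string compress_ops(const std::string &ops) {
  std::string out;
  size_t i = 0;
  while (i < ops.size()) {
    size_t j = i;
    while (j < ops.size() && ops[j] == ops[i]) ++j;
    out += std::to_string(j - i);
    out += ops[i];
    i = j;
  }
  return out;
}

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string a, std::string b,
                  double match, double mismatch, double gap) {
  const int n = a.size(), m = b.size();
  // DP over (n+1) x (m+1); store scores and traceback pointers.
  // ptr: 0 = stop (cell reset), 1 = diag, 2 = up (gap in b / consume a), 3 = left
  std::vector<double> H((size_t)(n + 1) * (m + 1), 0.0);
  std::vector<unsigned char> P((size_t)(n + 1) * (m + 1), 0);
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const size_t row = (size_t)i * (m + 1), prev = (size_t)(i - 1) * (m + 1);
    for (int j = 1; j <= m; ++j) {
      double diag = H[prev + j - 1] +
        (base_match(a[i - 1], b[j - 1]) ? match : mismatch);
      double up = H[prev + j] + gap;
      double left = H[row + j - 1] + gap;
      double s = diag; unsigned char p = 1;
      if (up > s)   { s = up;   p = 2; }
      if (left > s) { s = left; p = 3; }
      if (s <= 0.0) { s = 0.0;  p = 0; }
      H[row + j] = s; P[row + j] = p;
      if (s > best) { best = s; bi = i; bj = j; }
    }
  }
  // Traceback from the best cell.
  std::string ops;
  int i = bi, j = bj, n_match = 0;
  while (i > 0 && j > 0 && P[(size_t)i * (m + 1) + j] != 0) {
    unsigned char p = P[(size_t)i * (m + 1) + j];
    if (p == 1) {
      if (base_match(a[i - 1], b[j - 1])) { ops += '='; ++n_match; }
      else ops += 'X';
      --i; --j;
    } else if (p == 2) { ops += 'I'; --i; }
    else               { ops += 'D'; --j; }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(
    _["score"] = best,
    _["a_start"] = i, _["a_end"] = bi,     // 0-based half-open on a
    _["b_start"] = j, _["b_end"] = bj,     // 0-based half-open on b
    _["n_match"] = n_match,
    _["cigar"] = compress_ops(ops));
}

// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string a, std::string b,
                  double match, double mismatch, double gap) {
  const int n = a.size(), m = b.size();
  std::vector<double> H((size_t)(n + 1) * (m + 1), 0.0);
  std::vector<unsigned char> P((size_t)(n + 1) * (m + 1), 0);
  for (int i = 1; i <= n; ++i) { H[(size_t)i * (m + 1)] = i * gap; P[(size_t)i * (m + 1)] = 2; }
  for (int j = 1; j <= m; ++j) { H[j] = j * gap; P[j] = 3; }
  for (int i = 1; i <= n; ++i) {
    const size_t row = (size_t)i * (m + 1), prev = (size_t)(i - 1) * (m + 1);
    for (int j = 1; j <= m; ++j) {
      double diag = H[prev + j - 1] +
        (base_match(a[i - 1], b[j - 1]) ? match : mismatch);
      double up = H[prev + j] + gap;
      double left = H[row + j - 1] + gap;
      double s = diag; unsigned char p = 1;
      if (up > s)   { s = up;   p = 2; }
      if (left > s) { s = left; p = 3; }
      H[row + j] = s; P[row + j] = p;
    }
  }
  std::string ops;
  int i = n, j = m, n_match = 0;
  while (i > 0 || j > 0) {
    unsigned char p = P[(size_t)i * (m + 1) + j];
    if (p == 1) {
      if (base_match(a[i - 1], b[j - 1])) { ops += '='; ++n_match; }
      else ops += 'X';
      --i; --j;
    } else if (p == 2) { ops += 'I'; --i; }
    else               { ops += 'D'; --j; }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(
    _["score"] = H[(size_t)n * (m + 1) + m],
    _["n_match"] = n_match,
    _["cigar"] = compress_ops(ops));
}
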