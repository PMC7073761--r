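#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

static inline char revcomp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

// Constrained local (Smith-Waterman) alignment of a sequence against its
// own reverse complement, restricted to cells with i + j <= n so that the
// two aligned segments of the original sequence cannot overlap: this
// excludes the trivial self-diagonal and forces arm1 to lie strictly
// upstream of arm2. Linear gap penalty. Returns the best-scoring hit with
// full traceback (match count, alignment columns, segment coordinates).
// [[Rcpp::export]]
List sw_inverted_arm(std::string s, int match, int mismatch, int gap) {
  const int n = (int)s.size();
  std::string t(n, 'N');
  for (int k = 0; k < n; ++k) t[k] = revcomp_base(s[n - 1 - k]);

  std::vector<int> prev(n + 1, 0), cur(n + 1, 0);
  std::vector<unsigned char> ptr((size_t)(n + 1) * (n + 1), 0);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    std::fill(cur.begin(), cur.end(), 0);
    const int jmax = n - i;  // enforce i + j <= n (non-overlapping arms)
    for (int j = 1; j <= jmax; ++j) {
      const bool is_match = (s[i - 1] == t[j - 1] && s[i - 1] != 'N');
      const int sc = is_match ? match : mismatch;
      int h = prev[j - 1] + sc;
      unsigned char p = 1;
      if (prev[j] + gap > h) { h = prev[j] + gap; p = 2; }
      if (cur[j - 1] + gap > h) { h = cur[j - 1] + gap; p = 3; }
      if (h <= 0) { h = 0; p = 0; }
      cur[j] = h;
      ptr[(size_t)i * (n + 1) + j] = p;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(prev, cur);
  }
  if (best <= 0) return List::create(_["score"] = 0);

  int i = bi, j = bj, matches = 0, cols = 0;
  while (i > 0 && j > 0) {
    const unsigned char p = ptr[(size_t)i * (n + 1) + j];
    if (p == 0) break;
    if (p == 1) {
      if (s[i - 1] == t[j - 1] && s[i - 1] != 'N') ++matches;
      ++cols; --i; --j;
    } else if (p == 2) {
      ++cols; --i;
    } else {
      ++cols; --j;
    }
  }
  return List::create(_["score"] = best,
                      _["s_start"] = i + 1, _["s_end"] = bi,
                      _["t_start"] = j + 1, _["t_end"] = bj,
                      _["matches"] = matches, _["columns"] = cols);
}
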