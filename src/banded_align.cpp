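#include <Rcpp.h>
#include <vector>
#include <string>
#include <climits>
using namespace Rcpp;

// Banded global alignment with unit edit costs (Levenshtein). The DP is
// restricted to |i - j| <= band; cells outside the band are infinite, so the
// result equals the full-matrix edit distance whenever the optimal path stays
// inside the band. Traceback preference: diagonal (match/substitution), then
// up (deletion from a), then left (insertion into a), giving a deterministic
// decomposition of the distance into operation counts.
// [[Rcpp::export]]
List banded_edit_alignment(std::string a, std::string b, int band) {
  const int n = (int)a.size();
  const int m = (int)b.size();
  if (band < std::abs(n - m))
    stop("band too narrow to align (band < length difference)");
  const int W = 2 * band + 1;
  const int INF = INT_MAX / 4;

  // dp rows over offset k = j - i + band in [0, W)
  std::vector<int> prev(W, INF), cur(W, INF);
  std::vector<unsigned char> tb((size_t)(n + 1) * W, 255); // 0 diag, 1 up, 2 left

  for (int j = 0; j <= std::min(m, band); ++j) {
    prev[j + band] = j;                 // i = 0 row: j insertions
    if (j > 0) tb[(size_t)0 * W + (j + band)] = 2;
  }
  for (int i = 1; i <= n; ++i) {
    std::fill(cur.begin(), cur.end(), INF);
    int jlo = std::max(0, i - band);
    int jhi = std::min(m, i + band);
    for (int j = jlo; j <= jhi; ++j) {
      int k = j - i + band;
      int best = INF;
      unsigned char op = 255;
      if (j == 0) {
        best = i;                        // i deletions
        op = 1;
      } else {
        // diagonal: (i-1, j-1) -> same offset k
        if (prev[k] < INF) {
          int c = prev[k] + (a[i - 1] == b[j - 1] ? 0 : 1);
          if (c < best) { best = c; op = 0; }
        }
        // up: (i-1, j) -> offset k+1 (deletion of a[i])
        if (k + 1 < W && prev[k + 1] < INF) {
          int c = prev[k + 1] + 1;
          if (c < best) { best = c; op = 1; }
        }
        // left: (i, j-1) -> offset k-1 (insertion of b[j])
        if (k - 1 >= 0 && cur[k - 1] < INF) {
          int c = cur[k - 1] + 1;
          if (c < best) { best = c; op = 2; }
        }
      }
      cur[k] = best;
      tb[(size_t)i * W + k] = op;
    }
    std::swap(prev, cur);
  }
  int kfin = m - n + band;
  if (prev[kfin] >= INF)
    stop("band too narrow to align");
  int dist = prev[kfin];

  // traceback
  int i = n, j = m;
  long subs = 0, ins = 0, dels = 0, cols = 0;
  while (i > 0 || j > 0) {
    unsigned char op = tb[(size_t)i * W + (j - i + band)];
    if (op == 0) {
      if (a[i - 1] != b[j - 1]) ++subs;
      --i; --j;
    } else if (op == 1) {
      ++dels; --i;
    } else if (op == 2) {
      ++ins; --j;
    } else {
      stop("internal traceback error");
    }
    ++cols;
  }
  return List::create(
    _["distance"] = dist,
    _["substitutions"] = (double)subs,
    _["insertions"] = (double)ins,
    _["deletions"] = (double)dels,
    _["aligned_length"] = (double)cols
  );
}
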