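#include <Rcpp.h>
using namespace Rcpp;

// Windowed-identity dot-plot cells. For every window pair
// a[i, i+w) vs b[j, j+w) on a common diagonal, report (i, j, matches)
// when matches >= min_matches. 'N' never matches. Coordinates 0-based.
// [[Rcpp::export(name = ".dot_matches_cpp")]]
DataFrame dot_matches_cpp(std::string a, std::string b,
                          int window, int min_matches) {
  const int n = (int)a.size(), m = (int)b.size(), w = window;
  std::vector<int> vi, vj, vm;
  if (n >= w && m >= w && w >= 1) {
    for (int d = -(m - w); d <= n - w; ++d) {
      const int i0 = d > 0 ? d : 0;
      const int j0 = i0 - d;
      const int len = std::min(n - i0, m - j0);
      if (len < w) continue;
      int cnt = 0;
      for (int k = 0; k < len; ++k) {
        const char ca = a[i0 + k], cb = b[j0 + k];
        cnt += (ca == cb && ca != 'N');
        if (k >= w) {
          const char pa = a[i0 + k - w], pb = b[j0 + k - w];
          cnt -= (pa == pb && pa != 'N');
        }
        if (k >= w - 1 && cnt >= min_matches) {
          vi.push_back(i0 + k - w + 1);
          vj.push_back(j0 + k - w + 1);
          vm.push_back(cnt);
        }
      }
    }
  }
  return DataFrame::create(_["i"] = vi, _["j"] = vj, _["matches"] = vm);
}

// Ungapped identity (match count) of a[i0, i0+len) vs b[j0, j0+len),
// clipped to sequence bounds; 'N' never matches. Returns matches and the
// number of compared positions.
// [[Rcpp::export(name = ".diag_identity_cpp")]]
IntegerVector diag_identity_cpp(std::string a, std::string b,
                                int i0, int j0, int len) {
  const int n = (int)a.size(), m = (int)b.size();
  int matches = 0, compared = 0;
  for (int k = 0; k < len; ++k) {
    const int i = i0 + k, j = j0 + k;
    if (i < 0 || j < 0 || i >= n || j >= m) continue;
    ++compared;
    const char ca = a[i], cb = b[j];
    if (ca == cb && ca != 'N') ++matches;
  }
  return IntegerVector::create(matches, compared);
}
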