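// Connected-component labelling on binary 3D masks (6- or 26-connectivity),
// iterative BFS so deep stacks cannot overflow.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask, int connectivity) {
  IntegerVector dm = mask.attr("dim");
  const int d = dm[0], h = dm[1], w = dm[2];
  const size_t n = (size_t)d * h * w;
  IntegerVector lab(n, 0);
  lab.attr("dim") = dm;

  // neighbour offsets
  std::vector<int> da, db, dc;
  for (int c = -1; c <= 1; ++c)
    for (int b = -1; b <= 1; ++b)
      for (int a = -1; a <= 1; ++a) {
        if (a == 0 && b == 0 && c == 0) continue;
        int manh = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && manh != 1) continue;
        da.push_back(a); db.push_back(b); dc.push_back(c);
      }

  std::vector<size_t> stack;
  int next = 0;
  for (size_t i = 0; i < n; ++i) {
    if (mask[i] == 0 || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      size_t cur = stack.back(); stack.pop_back();
      int ia = cur % d, ib = (cur / d) % h, ic = cur / ((size_t)d * h);
      for (size_t t = 0; t < da.size(); ++t) {
        int ja = ia + da[t], jb = ib + db[t], jc = ic + dc[t];
        if (ja < 0 || ja >= d || jb < 0 || jb >= h || jc < 0 || jc >= w) continue;
        size_t j = ja + (size_t)d * (jb + (size_t)h * jc);
        if (mask[j] != 0 && lab[j] == 0) {
          lab[j] = next;
          stack.push_back(j);
        }
      }
    }
  }
  return lab;
}
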