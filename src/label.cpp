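// Connected-component labelling for binary images (4- or 8-connectivity),
// iterative flood fill.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerMatrix cpp_label_components(LogicalMatrix m, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = m.nrow(), nc = m.ncol();
  IntegerMatrix lab(nr, nc);
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nnb = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::vector<std::pair<int, int> > stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!m(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.clear();
      stack.push_back(std::make_pair(r, c));
      while (!stack.empty()) {
        std::pair<int, int> p = stack.back();
        stack.pop_back();
        for (int k = 0; k < nnb; ++k) {
          int rr = p.first + dr8[k], cc = p.second + dc8[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (m(rr, cc) && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            stack.push_back(std::make_pair(rr, cc));
          }
        }
      }
    }
  }
  return lab;
}
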