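#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labelling of a logical mask.
// connectivity: 4 or 8. Returns an integer matrix of component ids
// (0 = background), components numbered 1..k in scan order.
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(LogicalMatrix mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> qr, qc;
  qr.reserve(256); qc.reserve(256);
  int next = 0;
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  const int nn = (connectivity == 4) ? 4 : 8;
  const int *dr = (connectivity == 4) ? dr4 : dr8;
  const int *dc = (connectivity == 4) ? dc4 : dc8;
  for (int c0 = 0; c0 < nc; ++c0) {
    for (int r0 = 0; r0 < nr; ++r0) {
      if (!mask(r0, c0) || lab(r0, c0) != 0) continue;
      ++next;
      lab(r0, c0) = next;
      qr.clear(); qc.clear();
      qr.push_back(r0); qc.push_back(c0);
      size_t head = 0;
      while (head < qr.size()) {
        int r = qr[head], c = qc[head];
        ++head;
        for (int k = 0; k < nn; ++k) {
          int rr = r + dr[k], cc = c + dc[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            qr.push_back(rr); qc.push_back(cc);
          }
        }
      }
    }
  }
  return lab;
}
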