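#include <Rcpp.h>
using namespace Rcpp;

// Connected-component labeling of a binary mask by breadth-first search.
// Labels are assigned in column-major scan order starting at 1.
// The R wrapper guarantees mask has no NA.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> qr(nr * nc), qc(nr * nc);
  static const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  static const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  static const int dr4[4] = {-1, 1, 0, 0};
  static const int dc4[4] = {0, 0, -1, 1};
  const int ndir = (connectivity == 8) ? 8 : 4;
  const int *dr = (connectivity == 8) ? dr8 : dr4;
  const int *dc = (connectivity == 8) ? dc8 : dc4;
  int next = 0;
  for (int j = 0; j < nc; j++) {
    for (int i = 0; i < nr; i++) {
      if (mask(i, j) && lab(i, j) == 0) {
        next++;
        int head = 0, tail = 0;
        qr[tail] = i; qc[tail] = j; tail++;
        lab(i, j) = next;
        while (head < tail) {
          int r = qr[head], c = qc[head]; head++;
          for (int d = 0; d < ndir; d++) {
            int rr = r + dr[d], cc = c + dc[d];
            if (rr >= 0 && rr < nr && cc >= 0 && cc < nc &&
                mask(rr, cc) && lab(rr, cc) == 0) {
              lab(rr, cc) = next;
              qr[tail] = rr; qc[tail] = cc; tail++;
            }
          }
        }
      }
    }
  }
  return lab;
}
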