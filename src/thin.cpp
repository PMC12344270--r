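#include <Rcpp.h>
using namespace Rcpp;

// Guo-Hall two-subiteration thinning on a 0/1 integer matrix.
// Pixels outside the image are background. Iterates to a fixed point.

static inline int px(const IntegerMatrix &m, int r, int c) {
  if (r < 0 || r >= m.nrow() || c < 0 || c >= m.ncol()) return 0;
  return m(r, c);
}

// [[Rcpp::export]]
IntegerMatrix guo_hall_thin(IntegerMatrix mask) {
  IntegerMatrix m = clone(mask);
  int nr = m.nrow(), nc = m.ncol();
  std::vector<std::pair<int, int> > kill;
  kill.reserve(1024);
  bool changed = true;
  while (changed) {
    changed = false;
    for (int iter = 0; iter < 2; ++iter) {
      kill.clear();
      for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
          if (m(r, c) != 1) continue;
          int p2 = px(m, r - 1, c);      // N
          int p3 = px(m, r - 1, c + 1);  // NE
          int p4 = px(m, r, c + 1);      // E
          int p5 = px(m, r + 1, c + 1);  // SE
          int p6 = px(m, r + 1, c);      // S
          int p7 = px(m, r + 1, c - 1);  // SW
          int p8 = px(m, r, c - 1);      // W
          int p9 = px(m, r - 1, c - 1);  // NW
          int C = ((!p2) & (p3 | p4)) + ((!p4) & (p5 | p6)) +
                  ((!p6) & (p7 | p8)) + ((!p8) & (p9 | p2));
          int N1 = (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8);
          int N2 = (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9);
          int N = N1 < N2 ? N1 : N2;
          int mc = iter == 0 ? ((p6 | p7 | (!p9)) & p8)
                             : ((p2 | p3 | (!p5)) & p4);
          if (C == 1 && N >= 2 && N <= 3 && mc == 0) {
            kill.push_back(std::make_pair(r, c));
          }
        }
      }
      if (!kill.empty()) {
        changed = true;
        for (size_t i = 0; i < kill.size(); ++i) {
          m(kill[i].first, kill[i].second) = 0;
        }
      }
    }
  }
  return m;
}
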