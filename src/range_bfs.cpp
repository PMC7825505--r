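// Breadth-first clustering of the non-ground cells of a range image.
// Two 4-neighbouring cells merge when the angle beta subtended at the
// sensor between their returns exceeds the tolerance (near-continuous
// surface); columns wrap around the azimuth seam.
#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// [[Rcpp::export]]
IntegerMatrix cpp_range_bfs(NumericMatrix range, LogicalMatrix ground,
                            double alpha_v, double alpha_h,
                            double tol, int min_size) {
  int nb = range.nrow(), nc = range.ncol();
  IntegerMatrix lab(nb, nc);
  std::vector<int> queue(nb * nc);
  int cl = 0;
  std::vector<int> sizes;
  for (int c0 = 0; c0 < nc; ++c0) {
    for (int r0 = 0; r0 < nb; ++r0) {
      if (ISNA(range(r0, c0)) || ground(r0, c0) || lab(r0, c0) != 0) continue;
      ++cl;
      int head = 0, tail = 0;
      lab(r0, c0) = cl;
      queue[tail++] = r0 + c0 * nb;
      int count = 0;
      while (head < tail) {
        int cell = queue[head++];
        ++count;
        int r = cell % nb, c = cell / nb;
        double d1 = range(r, c);
        const int nr[4] = {r - 1, r + 1, r, r};
        const int ncl[4] = {c, c, (c + nc - 1) % nc, (c + 1) % nc};
        const double al[4] = {alpha_v, alpha_v, alpha_h, alpha_h};
        for (int j = 0; j < 4; ++j) {
          int rr = nr[j], cc = ncl[j];
          if (rr < 0 || rr >= nb) continue;
          if (ISNA(range(rr, cc)) || ground(rr, cc) || lab(rr, cc) != 0) continue;
          double d2 = range(rr, cc);
          double da = d1 > d2 ? d1 : d2;
          double db = d1 > d2 ? d2 : d1;
          double beta = std::atan2(db * std::sin(al[j]), da - db * std::cos(al[j]));
          if (beta > tol) {
            lab(rr, cc) = cl;
            queue[tail++] = rr + cc * nb;
          }
        }
      }
      sizes.push_back(count);
    }
  }
  // discard small clusters, compact the rest
  std::vector<int> remap(cl + 1, 0);
  int next = 0;
  for (int i = 1; i <= cl; ++i)
    remap[i] = (sizes[i - 1] >= min_size) ? ++next : -1;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nb; ++r)
      if (lab(r, c) > 0) lab(r, c) = remap[lab(r, c)];
  return lab;
}
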