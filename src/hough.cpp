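#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Circular Hough accumulator. Each edge pixel votes for all candidate
// centers lying on a circle of radius r around it; per radius, the cell
// with the most votes is kept. Strength is normalized by the number of
// distinct rasterized ring offsets, i.e. the ideal full-circle vote count.
//
// edge_row/edge_col are 0-based pixel coordinates.
// [[Rcpp::export]]
DataFrame hough_accumulate(IntegerVector edge_row, IntegerVector edge_col,
                           int nrow, int ncol, IntegerVector radii) {
  const int nr = radii.size();
  const int ne = edge_row.size();
  IntegerVector out_radius(nr), out_row(nr), out_col(nr), out_votes(nr),
      out_ring(nr);
  std::vector<int> acc((size_t)nrow * ncol);

  for (int ri = 0; ri < nr; ++ri) {
    const int r = radii[ri];
    // rasterize ring offsets by dense angular sampling + dedup
    const int nang = std::max(16, (int)std::ceil(2.0 * M_PI * r * 2.0));
    std::vector<long long> keys;
    keys.reserve(nang);
    for (int k = 0; k < nang; ++k) {
      const double th = 2.0 * M_PI * k / nang;
      const long long dr = (long long)std::lround(r * std::sin(th));
      const long long dc = (long long)std::lround(r * std::cos(th));
      keys.push_back((dr + 4096) * 8192 + (dc + 4096));
    }
    std::sort(keys.begin(), keys.end());
    keys.erase(std::unique(keys.begin(), keys.end()), keys.end());
    const int nk = (int)keys.size();
    std::vector<int> drs(nk), dcs(nk);
    for (int k = 0; k < nk; ++k) {
      drs[k] = (int)(keys[k] / 8192) - 4096;
      dcs[k] = (int)(keys[k] % 8192) - 4096;
    }

    std::fill(acc.begin(), acc.end(), 0);
    for (int e = 0; e < ne; ++e) {
      const int er = edge_row[e], ec = edge_col[e];
      for (int k = 0; k < nk; ++k) {
        const int rr = er + drs[k];
        const int cc = ec + dcs[k];
        if (rr >= 0 && rr < nrow && cc >= 0 && cc < ncol)
          ++acc[(size_t)cc * nrow + rr];
      }
    }
    int best = -1, brow = 0, bcol = 0;
    for (int cc = 0; cc < ncol; ++cc) {
      const size_t off = (size_t)cc * nrow;
      for (int rr2 = 0; rr2 < nrow; ++rr2) {
        const int v = acc[off + rr2];
        if (v > best) { best = v; brow = rr2; bcol = cc; }
      }
    }
    out_radius[ri] = r;
    out_row[ri] = brow;
    out_col[ri] = bcol;
    out_votes[ri] = best;
    out_ring[ri] = nk;
  }
  return DataFrame::create(_["radius"] = out_radius, _["row"] = out_row,
                           _["col"] = out_col, _["votes"] = out_votes,
                           _["ring_size"] = out_ring);
}
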