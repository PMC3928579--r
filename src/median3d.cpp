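#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Border handling: 0 = replicate (clamp), 1 = reflect (mirror without
// repeating the edge sample).
static inline int border_index(int idx, int n, int mode) {
  if (idx < 0) return mode == 0 ? 0 : -idx;
  if (idx >= n) return mode == 0 ? n - 1 : 2 * n - idx - 2;
  return idx;
}

//' @title 3-D moving-window median (internal kernel)
//' @description Median filtering of a 3-D numeric array with an odd-sized
//'   rectangular mask and replicate/reflect border handling. Called from
//'   [median_filter_3d()]; not exported.
//' @noRd
// [[Rcpp::export(name = ".median3d_cpp")]]
NumericVector median3d_cpp(NumericVector vol, IntegerVector dims,
                           IntegerVector mask, int border) {
  const int M = dims[0], N = dims[1], I = dims[2];
  const int hm = mask[0] / 2, hn = mask[1] / 2, hi = mask[2] / 2;
  const int w = mask[0] * mask[1] * mask[2];
  NumericVector out(no_init(vol.size()));
  std::vector<double> buf(w);

  for (int i = 0; i < I; ++i) {
    for (int n = 0; n < N; ++n) {
      for (int m = 0; m < M; ++m) {
        int k = 0;
        for (int di = -hi; di <= hi; ++di) {
          const int ii = border_index(i + di, I, border);
          for (int dn = -hn; dn <= hn; ++dn) {
            const int nn = border_index(n + dn, N, border);
            const R_xlen_t base = (R_xlen_t)M * (nn + (R_xlen_t)N * ii);
            for (int dm = -hm; dm <= hm; ++dm) {
              buf[k++] = vol[base + border_index(m + dm, M, border)];
            }
          }
        }
        std::nth_element(buf.begin(), buf.begin() + w / 2, buf.end());
        double med = buf[w / 2];
        if (w % 2 == 0) {
          // even mask volume never happens (odd dims enforced upstream) but
          // keep the kernel well-defined
          double lo = *std::max_element(buf.begin(), buf.begin() + w / 2);
          med = (med + lo) / 2.0;
        }
        out[(R_xlen_t)m + (R_xlen_t)M * (n + (R_xlen_t)N * i)] = med;
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}
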