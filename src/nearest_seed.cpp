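#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Exact Euclidean nearest-seed assignment on an H x W grid via the
// two-pass separable distance transform (column sweep for the nearest
// seed within each column, then a lower-envelope-of-parabolas sweep
// along each row). O(H * W) regardless of the number of seeds.
//
// seed_rows/seed_cols are 1-based; returns the seed *value* at each
// pixel's nearest seed. Ties resolve deterministically (by the envelope
// construction order).
// [[Rcpp::export]]
NumericMatrix nearest_seed_values(IntegerVector seed_rows,
                                  IntegerVector seed_cols,
                                  NumericVector seed_vals,
                                  int H, int W) {
  const double INF = std::numeric_limits<double>::infinity();
  int K = seed_rows.size();
  if (K == 0) stop("no seeds supplied");

  // Pass 1: per column, distance (in rows) and index of the nearest
  // seed within that column.
  std::vector<double> coldist((size_t)H * W, INF);
  std::vector<int> collab((size_t)H * W, -1);
  for (int k = 0; k < K; ++k) {
    int r = seed_rows[k] - 1, c = seed_cols[k] - 1;
    size_t idx = (size_t)c * H + r;
    if (coldist[idx] != 0.0) { coldist[idx] = 0.0; collab[idx] = k; }
  }
  for (int c = 0; c < W; ++c) {
    size_t base = (size_t)c * H;
    for (int r = 1; r < H; ++r) {         // downward sweep
      if (coldist[base + r - 1] + 1.0 < coldist[base + r]) {
        coldist[base + r] = coldist[base + r - 1] + 1.0;
        collab[base + r] = collab[base + r - 1];
      }
    }
    for (int r = H - 2; r >= 0; --r) {    // upward sweep
      if (coldist[base + r + 1] + 1.0 < coldist[base + r]) {
        coldist[base + r] = coldist[base + r + 1] + 1.0;
        collab[base + r] = collab[base + r + 1];
      }
    }
  }

  // Pass 2: per row, lower envelope of parabolas f(c') + (c - c')^2
  // where f(c') = coldist^2, carrying the seed label.
  NumericMatrix out(H, W);
  std::vector<int> v(W);        // columns of parabolas in the envelope
  std::vector<double> z(W + 1); // envelope breakpoints
  std::vector<double> f(W);
  for (int r = 0; r < H; ++r) {
    int nv = 0;
    for (int c = 0; c < W; ++c) {
      double d = coldist[(size_t)c * H + r];
      f[c] = (d == INF) ? INF : d * d;
      if (f[c] == INF) continue;
      double s;
      while (nv > 0) {
        int q = v[nv - 1];
        s = ((f[c] + (double)c * c) - (f[q] + (double)q * q)) /
            (2.0 * c - 2.0 * q);
        if (s <= z[nv - 1]) --nv; else break;
      }
      if (nv == 0) { v[0] = c; z[0] = -INF; z[1] = INF; nv = 1; }
      else { v[nv] = c; z[nv] = s; z[nv + 1] = INF; ++nv; }
    }
    if (nv == 0) stop("internal error: empty envelope row");
    int j = 0;
    for (int c = 0; c < W; ++c) {
      while (z[j + 1] < (double)c) ++j;
      int q = v[j];
      out(r, c) = seed_vals[collab[(size_t)q * H + r]];
    }
  }
  return out;
}
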