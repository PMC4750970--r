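#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Random-table entries are derived on the fly from the model seed with the
// splitmix64 mixer (keyed counter mode), so the "fixed matrix of random
// 64-bit numbers" never needs to be materialised or serialised: the seed
// fully determines it, on every platform.
static inline uint64_t mix64(uint64_t z) {
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline uint64_t table_value(uint64_t seed, uint64_t key) {
  return mix64(seed + (key + 1) * 0x9E3779B97F4A7C15ULL);
}

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Random-table entry for one (slot, level) pair, returned as two 32-bit
// halves so R can inspect the table without 64-bit integer support.
// [[Rcpp::export]]
IntegerVector cpp_table_entry(double seed, int slot, int level, int Q) {
  uint64_t v = table_value((uint64_t)(int64_t)seed,
                           (uint64_t)slot * (uint64_t)Q + (uint64_t)level);
  return IntegerVector::create((int)(uint32_t)(v >> 32), (int)(uint32_t)v);
}

// Hash explicit quantized-level rows (one grid example per row) into bins.
// Slot j of an example uses random-table key j*Q + level.  The 64-bit sum
// wraps modulo 2^64 before the final modulus by B.
// [[Rcpp::export]]
IntegerVector cpp_hash_levels(IntegerMatrix levels, double seed, int Q,
                              double B) {
  const int n = levels.nrow(), m = levels.ncol();
  const uint64_t useed = (uint64_t)(int64_t)seed;
  const uint64_t uB = (uint64_t)B;
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    uint64_t sum = 0;
    for (int j = 0; j < m; ++j) {
      int lev = levels(i, j);
      if (lev < 0 || lev >= Q)
        stop("quantized level %d outside table range [0, %d)", lev, Q);
      sum += table_value(useed, (uint64_t)j * (uint64_t)Q + (uint64_t)lev);
    }
    out[i] = (int)(sum % uB);
  }
  return out;
}

// Grid-example bins for selected pixel centers of one plane.
// plane: h*w*nch integer array (column-major, R layout), 0-based centers.
// [[Rcpp::export]]
IntegerVector cpp_pixel_bins(IntegerVector plane, int h, int w, int nch,
                             IntegerVector center_row, IntegerVector center_col,
                             int grid_size, int grid_spacing, double q,
                             int max_intensity, double B, double seed) {
  const int g = grid_size, s = grid_spacing;
  const int Q = (int)std::floor((double)max_intensity / q) + 1;
  const uint64_t useed = (uint64_t)(int64_t)seed;
  const uint64_t uB = (uint64_t)B;
  const int n = center_row.size();
  const int lo = -( (g - 1) / 2 ) * s;  // top-left-biased centering
  std::vector<int> offs(g);
  for (int j = 0; j < g; ++j) offs[j] = lo + j * s;
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const int cr = center_row[i], cc = center_col[i];
    if (cr < 0 || cr >= h || cc < 0 || cc >= w)
      stop("center (%d, %d) outside plane of %d x %d", cr, cc, h, w);
    uint64_t sum = 0;
    int cell = 0;
    for (int jr = 0; jr < g; ++jr) {
      const int rr = clampi(cr + offs[jr], 0, h - 1);
      for (int jc = 0; jc < g; ++jc, ++cell) {
        const int ccc = clampi(cc + offs[jc], 0, w - 1);
        for (int k = 0; k < nch; ++k) {
          const int val = plane[rr + (R_xlen_t)h * (ccc + (R_xlen_t)w * k)];
          const int lev = (int)std::floor((double)val / q);
          const uint64_t slot = (uint64_t)cell * nch + k;
          sum += table_value(useed, slot * (uint64_t)Q + (uint64_t)lev);
        }
      }
    }
    out[i] = (int)(sum % uB);
  }
  return out;
}

// Bins for every pixel of a plane, in column-major order (matches an
// h x w matrix filled the R way).
// [[Rcpp::export]]
IntegerVector cpp_plane_bins(IntegerVector plane, int h, int w, int nch,
                             int grid_size, int grid_spacing, double q,
                             int max_intensity, double B, double seed) {
  const int g = grid_size, s = grid_spacing;
  const int Q = (int)std::floor((double)max_intensity / q) + 1;
  const uint64_t useed = (uint64_t)(int64_t)seed;
  const uint64_t uB = (uint64_t)B;
  const int lo = -( (g - 1) / 2 ) * s;
  std::vector<int> offs(g);
  for (int j = 0; j < g; ++j) offs[j] = lo + j * s;
  IntegerVector out((R_xlen_t)h * w);
  for (int cc = 0; cc < w; ++cc) {
    for (int cr = 0; cr < h; ++cr) {
      uint64_t sum = 0;
      int cell = 0;
      for (int jr = 0; jr < g; ++jr) {
        const int rr = clampi(cr + offs[jr], 0, h - 1);
        for (int jc = 0; jc < g; ++jc, ++cell) {
          const int ccc = clampi(cc + offs[jc], 0, w - 1);
          for (int k = 0; k < nch; ++k) {
            const int val = plane[rr + (R_xlen_t)h * (ccc + (R_xlen_t)w * k)];
            const int lev = (int)std::floor((double)val / q);
            const uint64_t slot = (uint64_t)cell * nch + k;
            sum += table_value(useed, slot * (uint64_t)Q + (uint64_t)lev);
          }
        }
      }
      out[(R_xlen_t)h * cc + cr] = (int)(sum % uB);
    }
  }
  return out;
}
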