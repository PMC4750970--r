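#include <Rcpp.h>
using namespace Rcpp;

// Vertical pixel-line profiles: length-L runs within a single column whose
// pixels are all mask-positive and whose information content (mean absolute
// difference of adjacent intensities) reaches ic_min.  Scan order is
// column-major: columns left to right, start rows top to bottom.
// Returned rows/cols are 0-based origins of each profile.
// [[Rcpp::export]]
List cpp_extract_profiles(NumericMatrix plane, IntegerMatrix mask, int L,
                          double ic_min, int row_stride, int col_stride) {
  const int h = plane.nrow(), w = plane.ncol();
  std::vector<double> vals;
  std::vector<int> rows, cols;
  for (int c = 0; c < w; c += col_stride) {
    for (int r = 0; r + L <= h; r += row_stride) {
      bool ok = true;
      for (int i = 0; i < L; ++i) {
        if (mask(r + i, c) == 0) { ok = false; break; }
      }
      if (!ok) continue;
      double ic = 0.0;
      for (int i = 0; i + 1 < L; ++i)
        ic += std::abs(plane(r + i, c) - plane(r + i + 1, c));
      ic /= (double)(L - 1);
      if (ic < ic_min) continue;
      for (int i = 0; i < L; ++i) vals.push_back(plane(r + i, c));
      rows.push_back(r);
      cols.push_back(c);
    }
  }
  const int n = (int)rows.size();
  NumericMatrix prof(n, L);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < L; ++j) prof(i, j) = vals[(size_t)i * L + j];
  return List::create(_["profiles"] = prof,
                      _["row"] = IntegerVector(rows.begin(), rows.end()),
                      _["col"] = IntegerVector(cols.begin(), cols.end()));
}

// All-pairs Manhattan distances between profile rows of A and B.
// [[Rcpp::export]]
NumericMatrix cpp_manhattan_matrix(NumericMatrix A, NumericMatrix B) {
  const int na = A.nrow(), nb = B.nrow(), L = A.ncol();
  if (B.ncol() != L) stop("profile lengths differ: %d vs %d", L, B.ncol());
  NumericMatrix out(na, nb);
  for (int j = 0; j < nb; ++j) {
    for (int i = 0; i < na; ++i) {
      double d = 0.0;
      for (int k = 0; k < L; ++k) d += std::abs(A(i, k) - B(j, k));
      out(i, j) = d;
    }
  }
  return out;
}

// Separable Gaussian blur with edge replication; kernel radius 3 sigma.
// [[Rcpp::export]]
NumericMatrix cpp_gblur(NumericMatrix img, double sigma_row, double sigma_col) {
  const int h = img.nrow(), w = img.ncol();
  NumericMatrix tmp(h, w), out(h, w);
  auto make_kernel = [](double sigma) {
    int rad = std::max(1, (int)std::ceil(3.0 * sigma));
    std::vector<double> k(2 * rad + 1);
    double s = 0.0;
    for (int i = -rad; i <= rad; ++i) {
      k[i + rad] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
      s += k[i + rad];
    }
    for (auto &v : k) v /= s;
    return k;
  };
  if (sigma_row <= 0 && sigma_col <= 0) return clone(img);
  if (sigma_row > 0) {
    std::vector<double> k = make_kernel(sigma_row);
    const int rad = ((int)k.size() - 1) / 2;
    for (int c = 0; c < w; ++c)
      for (int r = 0; r < h; ++r) {
        double acc = 0.0;
        for (int i = -rad; i <= rad; ++i) {
          int rr = r + i;
          rr = rr < 0 ? 0 : (rr >= h ? h - 1 : rr);
          acc += k[i + rad] * img(rr, c);
        }
        tmp(r, c) = acc;
      }
  } else {
    tmp = clone(img);
  }
  if (sigma_col > 0) {
    std::vector<double> k = make_kernel(sigma_col);
    const int rad = ((int)k.size() - 1) / 2;
    for (int c = 0; c < w; ++c)
      for (int r = 0; r < h; ++r) {
        double acc = 0.0;
        for (int i = -rad; i <= rad; ++i) {
          int cc = c + i;
          cc = cc < 0 ? 0 : (cc >= w ? w - 1 : cc);
          acc += k[i + rad] * tmp(r, cc);
        }
        out(r, c) = acc;
      }
  } else {
    out = tmp;
  }
  return out;
}
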