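#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Squared distances are bounded by (grid extent)^2 << BIG; voxels still at
// ~BIG after all passes had no background voxel anywhere (mapped to Inf).
static const double BIG = 1e20;

// 1D squared distance transform of a sampled function (lower envelope of
// parabolas, Felzenszwalb & Huttenlocher), with sample positions i * s.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 double s) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; q++) {
    double xq = q * s;
    double sep;
    while (true) {
      double xv = v[k] * s;
      sep = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (k > 0 && sep <= z[k]) {
        k--;
      } else {
        break;
      }
    }
    k++;
    v[k] = q;
    z[k] = sep;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    double xq = q * s;
    while (z[k + 1] < xq) k++;
    double xv = v[k] * s;
    d[q] = (xq - xv) * (xq - xv) + f[v[k]];
  }
}

// Squared Euclidean distance from every voxel to the nearest zero voxel of
// `fg` (voxel-center to voxel-center), with per-axis physical spacing.
// Voxels where fg == 0 get 0. If fg is all-nonzero, returns all Inf.
// [[Rcpp::export]]
NumericVector cpp_sq_edt(LogicalVector fg, IntegerVector dim,
                         NumericVector spacing) {
  int d0 = dim[0], d1 = dim[1], d2 = dim.size() > 2 ? dim[2] : 1;
  R_xlen_t n = (R_xlen_t)d0 * d1 * d2;
  std::vector<double> D(n);
  for (R_xlen_t i = 0; i < n; i++) D[i] = fg[i] ? BIG : 0.0;

  int dims[3] = {d0, d1, d2};
  R_xlen_t strides[3] = {1, d0, (R_xlen_t)d0 * d1};
  int ndim = dim.size() > 2 ? 3 : 2;

  for (int ax = 0; ax < ndim; ax++) {
    int len = dims[ax];
    if (len <= 1) continue;
    double s = spacing[ax];
    std::vector<double> f(len), d(len);
    int oa = (ax + 1) % 3, ob = (ax + 2) % 3;
    for (int b = 0; b < dims[ob]; b++) {
      for (int a = 0; a < dims[oa]; a++) {
        R_xlen_t base = (R_xlen_t)a * strides[oa] + (R_xlen_t)b * strides[ob];
        bool allZero = true;
        for (int i = 0; i < len; i++) {
          f[i] = D[base + (R_xlen_t)i * strides[ax]];
          if (f[i] != 0.0) allZero = false;
        }
        if (allZero) continue;
        dt1d(f, d, len, s);
        for (int i = 0; i < len; i++)
          D[base + (R_xlen_t)i * strides[ax]] = d[i];
      }
    }
  }
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++)
    out[i] = (D[i] >= BIG / 2) ? R_PosInf : D[i];
  out.attr("dim") = dim;
  return out;
}

// Separable convolution of a 3D array with one 1D kernel per axis
// (odd-length, zero padding outside the grid).
// [[Rcpp::export]]
NumericVector cpp_sepconv3(NumericVector x, IntegerVector dim, List kernels) {
  int d0 = dim[0], d1 = dim[1], d2 = dim.size() > 2 ? dim[2] : 1;
  R_xlen_t n = (R_xlen_t)d0 * d1 * d2;
  std::vector<double> cur(x.begin(), x.end()), nxt(n);
  int dims[3] = {d0, d1, d2};
  R_xlen_t strides[3] = {1, d0, (R_xlen_t)d0 * d1};

  for (int ax = 0; ax < kernels.size(); ax++) {
    NumericVector k = kernels[ax];
    int klen = k.size();
    if (klen == 1 && k[0] == 1.0) continue;
    int half = (klen - 1) / 2;
    int len = dims[ax];
    int oa = (ax + 1) % 3, ob = (ax + 2) % 3;
    for (int b = 0; b < dims[ob]; b++) {
      for (int a = 0; a < dims[oa]; a++) {
        R_xlen_t base = (R_xlen_t)a * strides[oa] + (R_xlen_t)b * strides[ob];
        for (int i = 0; i < len; i++) {
          double acc = 0.0;
          int jlo = std::max(0, i - half), jhi = std::min(len - 1, i + half);
          for (int j = jlo; j <= jhi; j++)
            acc += cur[base + (R_xlen_t)j * strides[ax]] * k[half + i - j];
          nxt[base + (R_xlen_t)i * strides[ax]] = acc;
        }
      }
    }
    std::swap(cur, nxt);
  }
  NumericVector out(n);
  std::copy(cur.begin(), cur.end(), out.begin());
  out.attr("dim") = dim;
  return out;
}

// Local maxima over the 26-neighborhood (>= all neighbors). Ties on plateaus
// are all flagged; the caller deduplicates.
// [[Rcpp::export]]
LogicalVector cpp_local_max3(NumericVector x, IntegerVector dim) {
  int d0 = dim[0], d1 = dim[1], d2 = dim.size() > 2 ? dim[2] : 1;
  R_xlen_t n = (R_xlen_t)d0 * d1 * d2;
  LogicalVector out(n);
  for (int k = 0; k < d2; k++) {
    for (int j = 0; j < d1; j++) {
      for (int i = 0; i < d0; i++) {
        R_xlen_t idx = i + (R_xlen_t)d0 * (j + (R_xlen_t)d1 * k);
        double v = x[idx];
        bool ismax = true;
        for (int dk = -1; dk <= 1 && ismax; dk++) {
          int kk = k + dk;
          if (kk < 0 || kk >= d2) continue;
          for (int dj = -1; dj <= 1 && ismax; dj++) {
            int jj = j + dj;
            if (jj < 0 || jj >= d1) continue;
            for (int di = -1; di <= 1; di++) {
              int ii = i + di;
              if (ii < 0 || ii >= d0) continue;
              if (di == 0 && dj == 0 && dk == 0) continue;
              if (x[ii + (R_xlen_t)d0 * (jj + (R_xlen_t)d1 * kk)] > v) {
                ismax = false;
                break;
              }
            }
          }
        }
        out[idx] = ismax;
      }
    }
  }
  return out;
}
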