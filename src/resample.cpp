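#include <Rcpp.h>
using namespace Rcpp;

// Trilinear sampling of a 3D array at fractional 1-based voxel coordinates.
// Sample points outside [1, n] on any axis take `fill`.
// [[Rcpp::export]]
NumericVector cpp_sample_trilinear(NumericVector data, IntegerVector dims,
                                   NumericVector x, NumericVector y,
                                   NumericVector z, double fill) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = x.size();
  NumericVector out(n);
  const double *d = data.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    double xi = x[i], yi = y[i], zi = z[i];
    if (xi < 1 || xi > nx || yi < 1 || yi > ny || zi < 1 || zi > nz) {
      out[i] = fill;
      continue;
    }
    int x0 = (int)xi; if (x0 > nx - 1) x0 = nx - 1;
    int y0 = (int)yi; if (y0 > ny - 1) y0 = ny - 1;
    int z0 = (int)zi; if (z0 > nz - 1) z0 = nz - 1;
    double fx = xi - x0, fy = yi - y0, fz = zi - z0;
    // 0-based corner index
    R_xlen_t b = (x0 - 1) + (R_xlen_t)nx * (y0 - 1) + (R_xlen_t)nx * ny * (z0 - 1);
    R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
    double c00 = d[b] * (1 - fx) + d[b + sx] * fx;
    double c10 = d[b + sy] * (1 - fx) + d[b + sy + sx] * fx;
    double c01 = d[b + sz] * (1 - fx) + d[b + sz + sx] * fx;
    double c11 = d[b + sz + sy] * (1 - fx) + d[b + sz + sy + sx] * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[i] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// Nearest-neighbour sampling (round-half-up per axis, matching base::round
// semantics closely enough for voxel centres).
// [[Rcpp::export]]
NumericVector cpp_sample_nearest(NumericVector data, IntegerVector dims,
                                 NumericVector x, NumericVector y,
                                 NumericVector z, double fill) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = x.size();
  NumericVector out(n);
  const double *d = data.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    int xi = (int)std::lround(x[i]);
    int yi = (int)std::lround(y[i]);
    int zi = (int)std::lround(z[i]);
    if (xi < 1 || xi > nx || yi < 1 || yi > ny || zi < 1 || zi > nz) {
      out[i] = fill;
      continue;
    }
    out[i] = d[(xi - 1) + (R_xlen_t)nx * (yi - 1) + (R_xlen_t)nx * ny * (zi - 1)];
  }
  return out;
}
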