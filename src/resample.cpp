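#include <Rcpp.h>
using namespace Rcpp;

// Trilinear interpolation of a 3D array at arbitrary continuous voxel
// coordinates (0-based). Points with any coordinate outside [0, dim-1]
// yield NA so callers can exclude out-of-grid samples from histograms.
// [[Rcpp::export(name = ".trilinear_cpp")]]
NumericVector trilinear_cpp(NumericVector vol, IntegerVector dim,
                            NumericMatrix idx) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = idx.nrow();
  NumericVector out(n);
  const double *v = REAL(vol);
  for (R_xlen_t p = 0; p < n; ++p) {
    const double x = idx(p, 0), y = idx(p, 1), z = idx(p, 2);
    if (!(x >= 0.0 && x <= nx - 1.0 &&
          y >= 0.0 && y <= ny - 1.0 &&
          z >= 0.0 && z <= nz - 1.0)) {
      out[p] = NA_REAL;
      continue;
    }
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
        z0 = (int)std::floor(z);
    if (x0 == nx - 1) x0--;
    if (y0 == ny - 1) y0--;
    if (z0 == nz - 1) z0--;
    const double fx = x - x0, fy = y - y0, fz = z - z0;
    const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
    const R_xlen_t base = x0 * sx + (R_xlen_t)y0 * sy + (R_xlen_t)z0 * sz;
    const double c000 = v[base];
    const double c100 = v[base + sx];
    const double c010 = v[base + sy];
    const double c110 = v[base + sx + sy];
    const double c001 = v[base + sz];
    const double c101 = v[base + sx + sz];
    const double c011 = v[base + sy + sz];
    const double c111 = v[base + sx + sy + sz];
    const double c00 = c000 * (1 - fx) + c100 * fx;
    const double c10 = c010 * (1 - fx) + c110 * fx;
    const double c01 = c001 * (1 - fx) + c101 * fx;
    const double c11 = c011 * (1 - fx) + c111 * fx;
    const double c0 = c00 * (1 - fy) + c10 * fy;
    const double c1 = c01 * (1 - fy) + c11 * fy;
    out[p] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}
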