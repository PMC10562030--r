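#include <Rcpp.h>
using namespace Rcpp;

// 3x3x3 convolution lowering for 4D column-major arrays (nx, ny, nz, c).
// Fixed zero-padding of 1 voxel; output spatial dims are ((n-1)/stride)+1.
// Column order of the lowered matrix: dx fastest, then dy, dz, channel,
// matching matrix(W, 27*ci, co) for a weight array of dim (3,3,3,ci,co).

// [[Rcpp::export]]
NumericMatrix im2col3(NumericVector x, IntegerVector dims, int stride) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], ci = dims[3];
  const int ox = (nx - 1) / stride + 1;
  const int oy = (ny - 1) / stride + 1;
  const int oz = (nz - 1) / stride + 1;
  const R_xlen_t nout = (R_xlen_t)ox * oy * oz;
  NumericMatrix M(no_init(nout, 27 * ci));
  const double *X = x.begin();
  double *Mp = M.begin();
  for (int c = 0; c < ci; c++) {
    const R_xlen_t choff = (R_xlen_t)c * nx * ny * nz;
    for (int dz = 0; dz < 3; dz++) {
      for (int dy = 0; dy < 3; dy++) {
        for (int dx = 0; dx < 3; dx++) {
          const int col = dx + 3 * dy + 9 * dz + 27 * c;
          double *Mcol = Mp + (R_xlen_t)col * nout;
          for (int k = 0; k < oz; k++) {
            const int iz = k * stride + dz - 1;
            for (int j = 0; j < oy; j++) {
              const int iy = j * stride + dy - 1;
              const R_xlen_t mbase = ((R_xlen_t)k * oy + j) * ox;
              if (iz < 0 || iz >= nz || iy < 0 || iy >= ny) {
                std::fill(Mcol + mbase, Mcol + mbase + ox, 0.0);
                continue;
              }
              const R_xlen_t base = choff + ((R_xlen_t)iz * ny + iy) * nx;
              for (int i = 0; i < ox; i++) {
                const int ix = i * stride + dx - 1;
                Mcol[mbase + i] = (ix < 0 || ix >= nx) ? 0.0 : X[base + ix];
              }
            }
          }
        }
      }
    }
  }
  return M;
}

// Adjoint of im2col3: scatter-add a lowered gradient back onto the input grid.

// [[Rcpp::export]]
NumericVector col2im3(NumericMatrix M, IntegerVector dims, int stride) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], ci = dims[3];
  const int ox = (nx - 1) / stride + 1;
  const int oy = (ny - 1) / stride + 1;
  const int oz = (nz - 1) / stride + 1;
  const R_xlen_t nout = (R_xlen_t)ox * oy * oz;
  NumericVector out((R_xlen_t)nx * ny * nz * ci);
  double *X = out.begin();
  const double *Mp = M.begin();
  for (int c = 0; c < ci; c++) {
    const R_xlen_t choff = (R_xlen_t)c * nx * ny * nz;
    for (int dz = 0; dz < 3; dz++) {
      for (int dy = 0; dy < 3; dy++) {
        for (int dx = 0; dx < 3; dx++) {
          const int col = dx + 3 * dy + 9 * dz + 27 * c;
          const double *Mcol = Mp + (R_xlen_t)col * nout;
          for (int k = 0; k < oz; k++) {
            const int iz = k * stride + dz - 1;
            if (iz < 0 || iz >= nz) continue;
            for (int j = 0; j < oy; j++) {
              const int iy = j * stride + dy - 1;
              if (iy < 0 || iy >= ny) continue;
              const R_xlen_t base = choff + ((R_xlen_t)iz * ny + iy) * nx;
              const R_xlen_t mbase = ((R_xlen_t)k * oy + j) * ox;
              for (int i = 0; i < ox; i++) {
                const int ix = i * stride + dx - 1;
                if (ix < 0 || ix >= nx) continue;
                X[base + ix] += Mcol[mbase + i];
              }
            }
          }
        }
      }
    }
  }
  return out;
}
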