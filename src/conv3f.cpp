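// Single-precision fused conv path: im2col into a float buffer + SGEMM.
// Halves the memory traffic of the lowered-matrix convolution, which is the
// bottleneck of CPU training. Weights/activations enter and leave as R
// doubles; all heavy intermediates are float.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

extern "C" void sgemm_(const char *transa, const char *transb,
                       const int *m, const int *n, const int *k,
                       const float *alpha, const float *a, const int *lda,
                       const float *b, const int *ldb, const float *beta,
                       float *c, const int *ldc,
                       size_t, size_t);

static void sgemm(char ta, char tb, int m, int n, int k, const float *A,
                  int lda, const float *B, int ldb, float *C, int ldc) {
  const float one = 1.0f, zero = 0.0f;
  sgemm_(&ta, &tb, &m, &n, &k, &one, A, &lda, B, &ldb, &zero, C, &ldc, 1, 1);
}

static void im2col3f(const double *X, const int *d, int stride,
                     std::vector<float> &M, int ox, int oy, int oz) {
  const int nx = d[0], ny = d[1], nz = d[2], ci = d[3];
  const R_xlen_t nout = (R_xlen_t)ox * oy * oz;
  for (int c = 0; c < ci; c++) {
    const R_xlen_t choff = (R_xlen_t)c * nx * ny * nz;
    for (int dz = 0; dz < 3; dz++)
      for (int dy = 0; dy < 3; dy++)
        for (int dx = 0; dx < 3; dx++) {
          const int col = dx + 3 * dy + 9 * dz + 27 * c;
          float *Mcol = M.data() + (R_xlen_t)col * nout;
          for (int k = 0; k < oz; k++) {
            const int iz = k * stride + dz - 1;
            for (int j = 0; j < oy; j++) {
              const int iy = j * stride + dy - 1;
              const R_xlen_t mbase = ((R_xlen_t)k * oy + j) * ox;
              if (iz < 0 || iz >= nz || iy < 0 || iy >= ny) {
                std::fill(Mcol + mbase, Mcol + mbase + ox, 0.0f);
                continue;
              }
              const R_xlen_t base = choff + ((R_xlen_t)iz * ny + iy) * nx;
              for (int i = 0; i < ox; i++) {
                const int ix = i * stride + dx - 1;
                Mcol[mbase + i] = (ix < 0 || ix >= nx)
                  ? 0.0f : (float)X[base + ix];
              }
            }
          }
        }
  }
}

// y (ox,oy,oz,co) = conv3x3x3(x; W, b), zero padding 1
// [[Rcpp::export]]
NumericVector conv3f_forward(NumericVector x, IntegerVector dims,
                             NumericMatrix W, NumericVector b, int stride) {
  const int d[4] = {dims[0], dims[1], dims[2], dims[3]};
  const int ox = (d[0] - 1) / stride + 1, oy = (d[1] - 1) / stride + 1,
            oz = (d[2] - 1) / stride + 1;
  const int ci = d[3], co = W.ncol(), kk = 27 * ci;
  const R_xlen_t nout = (R_xlen_t)ox * oy * oz;
  std::vector<float> M((size_t)nout * kk);
  im2col3f(x.begin(), d, stride, M, ox, oy, oz);
  std::vector<float> Wf((size_t)kk * co), Y((size_t)nout * co);
  for (R_xlen_t i = 0; i < (R_xlen_t)kk * co; i++) Wf[i] = (float)W[i];
  sgemm('N', 'N', (int)nout, co, kk, M.data(), (int)nout, Wf.data(), kk,
        Y.data(), (int)nout);
  NumericVector y((R_xlen_t)nout * co);
  for (int c = 0; c < co; c++) {
    const double bc = b[c];
    const float *Yc = Y.data() + (R_xlen_t)c * nout;
    double *yc = y.begin() + (R_xlen_t)c * nout;
    for (R_xlen_t i = 0; i < nout; i++) yc[i] = (double)Yc[i] + bc;
  }
  y.attr("dim") = IntegerVector::create(ox, oy, oz, co);
  return y;
}

// gradients of the same convolution wrt weights, bias and input
// [[Rcpp::export]]
List conv3f_backward(NumericVector x, IntegerVector dims, NumericMatrix W,
                     NumericVector dy, int stride) {
  const int d[4] = {dims[0], dims[1], dims[2], dims[3]};
  const int ox = (d[0] - 1) / stride + 1, oy = (d[1] - 1) / stride + 1,
            oz = (d[2] - 1) / stride + 1;
  const int ci = d[3], co = W.ncol(), kk = 27 * ci;
  const R_xlen_t nout = (R_xlen_t)ox * oy * oz;

  std::vector<float> M((size_t)nout * kk);
  im2col3f(x.begin(), d, stride, M, ox, oy, oz);
  std::vector<float> dYf((size_t)nout * co);
  NumericVector db(co);
  for (int c = 0; c < co; c++) {
    const double *dc = dy.begin() + (R_xlen_t)c * nout;
    float *fc = dYf.data() + (R_xlen_t)c * nout;
    double s = 0;
    for (R_xlen_t i = 0; i < nout; i++) { fc[i] = (float)dc[i]; s += dc[i]; }
    db[c] = s;
  }

  std::vector<float> dWf((size_t)kk * co);
  sgemm('T', 'N', kk, co, (int)nout, M.data(), (int)nout, dYf.data(),
        (int)nout, dWf.data(), kk);
  NumericMatrix dW(kk, co);
  for (R_xlen_t i = 0; i < (R_xlen_t)kk * co; i++) dW[i] = (double)dWf[i];

  std::vector<float> Wf((size_t)kk * co);
  for (R_xlen_t i = 0; i < (R_xlen_t)kk * co; i++) Wf[i] = (float)W[i];
  std::vector<float> dM((size_t)nout * kk);
  sgemm('N', 'T', (int)nout, kk, co, dYf.data(), (int)nout, Wf.data(), kk,
        dM.data(), (int)nout);

  // col2im scatter-add (adjoint of im2col3f), accumulating in double
  NumericVector dx((R_xlen_t)d[0] * d[1] * d[2] * d[3]);
  double *DX = dx.begin();
  const int nx = d[0], ny = d[1], nz = d[2];
  for (int c = 0; c < ci; c++) {
    const R_xlen_t choff = (R_xlen_t)c * nx * ny * nz;
    for (int dz = 0; dz < 3; dz++)
      for (int dyy = 0; dyy < 3; dyy++)
        for (int dxx = 0; dxx < 3; dxx++) {
          const int col = dxx + 3 * dyy + 9 * dz + 27 * c;
          const float *Mcol = dM.data() + (R_xlen_t)col * nout;
          for (int k = 0; k < oz; k++) {
            const int iz = k * stride + dz - 1;
            if (iz < 0 || iz >= nz) continue;
            for (int j = 0; j < oy; j++) {
              const int iy = j * stride + dyy - 1;
              if (iy < 0 || iy >= ny) continue;
              const R_xlen_t base = choff + ((R_xlen_t)iz * ny + iy) * nx;
              const R_xlen_t mbase = ((R_xlen_t)k * oy + j) * ox;
              for (int i = 0; i < ox; i++) {
                const int ix = i * stride + dxx - 1;
                if (ix < 0 || ix >= nx) continue;
                DX[base + ix] += (double)Mcol[mbase + i];
              }
            }
          }
        }
  }
  dx.attr("dim") = IntegerVector::create(d[0], d[1], d[2], d[3]);
  return List::create(_["dW"] = dW, _["db"] = db, _["dx"] = dx);
}
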