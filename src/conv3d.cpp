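// 3D convolution forward/backward via slab-chunked im2col + BLAS GEMM.
// Arithmetic runs in single precision internally (standard for neural-net
// training); parameters and activations stay double at the R interface.
// Tensors are R arrays in column-major order:
//   x: (X, Y, Z, Cin), w: (k, k, k, Cin, Cout), y: (Xo, Yo, Zo, Cout).
// The im2col matrix is filled column by column in contiguous strips
// along the fastest (x) axis, so the pack/unpack cost stays far below
// the GEMM cost.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

extern "C" void sgemm_(const char *transa, const char *transb,
                       const int *m, const int *n, const int *k,
                       const float *alpha, const float *a, const int *lda,
                       const float *b, const int *ldb, const float *beta,
                       float *c, const int *ldc);

static void sgemm_nn(int m, int n, int k, const float *a, int lda,
                     const float *b, int ldb, float beta, float *c, int ldc) {
  const float one = 1.0f;
  sgemm_("N", "N", &m, &n, &k, &one, a, &lda, b, &ldb, &beta, c, &ldc);
}

static void sgemm_tn(int m, int n, int k, const float *a, int lda,
                     const float *b, int ldb, float beta, float *c, int ldc) {
  const float one = 1.0f;
  sgemm_("T", "N", &m, &n, &k, &one, a, &lda, b, &ldb, &beta, c, &ldc);
}

namespace {

struct ConvGeom {
  int nx, ny, nz, cin, k, cout, stride;
  int plo[3];
  int ox, oy, oz;
  long nout, kk;
};

ConvGeom geom(const IntegerVector &xdim, const IntegerVector &wdim,
              int stride, const IntegerVector &pad_lo, const IntegerVector &pad_hi) {
  ConvGeom g;
  g.nx = xdim[0]; g.ny = xdim[1]; g.nz = xdim[2]; g.cin = xdim[3];
  g.k = wdim[0]; g.cout = wdim[4]; g.stride = stride;
  for (int a = 0; a < 3; ++a) g.plo[a] = pad_lo[a];
  g.ox = (g.nx + pad_lo[0] + pad_hi[0] - g.k) / stride + 1;
  g.oy = (g.ny + pad_lo[1] + pad_hi[1] - g.k) / stride + 1;
  g.oz = (g.nz + pad_lo[2] + pad_hi[2] - g.k) / stride + 1;
  g.nout = (long)g.ox * g.oy * g.oz;
  g.kk = (long)g.k * g.k * g.k * g.cin;
  return g;
}

// admissible xo range for which x = xo*stride + dx0 lies in [0, nx)
inline void xo_range(int dx0, int stride, int nx, int ox, int &xs, int &xe) {
  xs = dx0 < 0 ? (-dx0 + stride - 1) / stride : 0;
  int num = nx - 1 - dx0;
  // C++ integer division truncates toward zero; a negative numerator
  // means the tap lies beyond the array for every output voxel
  int last = num < 0 ? -1 : num / stride;
  xe = last < ox - 1 ? last : ox - 1;
  if (xe < xs) { xs = 0; xe = -1; }
}

// Pack (mode 0) the chunk im2col matrix A from x, or scatter-add
// (mode 1) A back into x.
template <typename XT>
void im2col_slab(const ConvGeom &g, int z0, int z1, XT *x, float *A,
                 bool scatter) {
  long rows = (long)g.ox * g.oy * (z1 - z0);
  long planexy = (long)g.nx * g.ny;
  long planevol = planexy * g.nz;
  long col = 0;
  for (int ci = 0; ci < g.cin; ++ci)
    for (int kz = 0; kz < g.k; ++kz)
      for (int ky = 0; ky < g.k; ++ky)
        for (int kx = 0; kx < g.k; ++kx, ++col) {
          float *Acol = A + col * rows;
          int dx0 = kx - g.plo[0], dy0 = ky - g.plo[1], dz0 = kz - g.plo[2];
          int xs, xe;
          xo_range(dx0, g.stride, g.nx, g.ox, xs, xe);
          long r = 0;
          for (int zo = z0; zo < z1; ++zo) {
            int z = zo * g.stride + dz0;
            bool zin = z >= 0 && z < g.nz;
            for (int yo = 0; yo < g.oy; ++yo, r += g.ox) {
              int y = yo * g.stride + dy0;
              if (!zin || y < 0 || y >= g.ny) {
                if (!scatter) std::fill(Acol + r, Acol + r + g.ox, 0.0);
                continue;
              }
              XT *xrow = x + ci * planevol + z * planexy + (long)y * g.nx;
              if (!scatter) {
                for (int xo = 0; xo < xs; ++xo) Acol[r + xo] = 0.0;
                for (int xo = xs; xo <= xe; ++xo)
                  Acol[r + xo] = (float)xrow[xo * g.stride + dx0];
                for (int xo = xe + 1; xo < g.ox; ++xo) Acol[r + xo] = 0.0;
              } else {
                for (int xo = xs; xo <= xe; ++xo)
                  xrow[xo * g.stride + dx0] += (XT)Acol[r + xo];
              }
            }
          }
        }
}

arma::fmat weight_mat(const NumericVector &w, const ConvGeom &g) {
  arma::fmat W(g.kk, g.cout);
  long kkk = (long)g.k * g.k * g.k;
  for (int co = 0; co < g.cout; ++co)
    for (int ci = 0; ci < g.cin; ++ci)
      for (long p = 0; p < kkk; ++p)
        W((long)ci * kkk + p, co) = (float)w[p + kkk * (ci + (long)g.cin * co)];
  return W;
}

// pick a z-slab size so the chunk matrix stays around <= 32 MB
int slab_size(const ConvGeom &g) {
  long per_slab = (long)g.ox * g.oy * g.kk;
  long target = 4L * 1024 * 1024;
  int s = (int)(target / (per_slab > 0 ? per_slab : 1));
  if (s < 1) s = 1;
  if (s > g.oz) s = g.oz;
  return s;
}

// ---- stride-1 path: per-offset GEMMs on a shared padded layout --------
//
// For stride 1 the output voxel grid embeds into the padded input grid
// with a constant linear offset per kernel tap, so the whole
// convolution is k^3 rank-cin GEMM updates on flat buffers and no
// im2col matrix is ever materialized. Junk rows (padding positions)
// read zeros or write results that are never extracted.

struct PadGeom {
  int px, py, pz;
  long S, guard;
};

PadGeom pad_geom(const ConvGeom &g) {
  PadGeom p;
  // padded extents: p* = o* + k - 1 = n* + pad_lo + pad_hi
  p.px = g.ox + g.k - 1;
  p.py = g.oy + g.k - 1;
  p.pz = g.oz + g.k - 1;
  p.S = (long)p.px * p.py * p.pz;
  p.guard = (long)g.k * (1 + p.px + (long)p.px * p.py);
  return p;
}

// copy x (nx,ny,nz,cin) into the padded float buffer (channel stride S)
void fill_padded(const ConvGeom &g, const PadGeom &p, const double *x,
                 float *buf) {
  for (int c = 0; c < g.cin; ++c)
    for (int z = 0; z < g.nz; ++z)
      for (int y = 0; y < g.ny; ++y) {
        const double *src = x + ((long)c * g.nz + z) * g.nx * g.ny + (long)y * g.nx;
        float *dst = buf + (long)c * p.S +
          (g.plo[0]) + (long)p.px * ((y + g.plo[1]) + (long)p.py * (z + g.plo[2]));
        for (int xx = 0; xx < g.nx; ++xx) dst[xx] = (float)src[xx];
      }
}

NumericVector conv_s1_forward(const ConvGeom &g, NumericVector x,
                              NumericVector w, NumericVector b) {
  PadGeom p = pad_geom(g);
  std::vector<float> xbuf((long)g.cin * p.S + p.guard, 0.0f);
  std::vector<float> ybuf((long)g.cout * p.S + p.guard, 0.0f);
  fill_padded(g, p, REAL(x), xbuf.data());
  long kkk = (long)g.k * g.k * g.k;
  // all tap weights as (cin x cout) blocks, tap-major
  std::vector<float> Wt((size_t)kkk * g.cin * g.cout);
  for (long ptap = 0; ptap < kkk; ++ptap)
    for (int co = 0; co < g.cout; ++co)
      for (int ci = 0; ci < g.cin; ++ci)
        Wt[ptap * g.cin * g.cout + ci + (long)g.cin * co] =
          (float)w[ptap + kkk * (ci + (long)g.cin * co)];
  // z-slab blocking keeps the working set cache-resident across taps
  long planep = (long)p.px * p.py;
  int zs = (int)std::max(1L, (256L * 1024) / (planep * g.cin * 4));
  for (int z0 = 0; z0 < p.pz; z0 += zs) {
    long r0 = planep * z0;
    int rows = (int)(planep * std::min((long)zs, p.pz - (long)z0));
    for (long ptap = 0, kz = 0; kz < g.k; ++kz)
      for (long ky = 0; ky < g.k; ++ky)
        for (long kx = 0; kx < g.k; ++kx, ++ptap) {
          long off = kx + (long)p.px * ky + planep * kz;
          sgemm_nn(rows, g.cout, g.cin,
                   xbuf.data() + r0 + off, (int)p.S,
                   Wt.data() + ptap * g.cin * g.cout, g.cin,
                   1.0f, ybuf.data() + r0, (int)p.S);
        }
  }
  NumericVector y((long)g.nout * g.cout);
  for (int co = 0; co < g.cout; ++co)
    for (int z = 0; z < g.oz; ++z)
      for (int yy = 0; yy < g.oy; ++yy) {
        const float *src = ybuf.data() + (long)co * p.S +
          (long)p.px * (yy + (long)p.py * z);
        double *dst = REAL(y) + (long)co * g.nout +
          (long)g.ox * (yy + (long)g.oy * z);
        for (int xx = 0; xx < g.ox; ++xx) dst[xx] = (double)src[xx] + b[co];
      }
  y.attr("dim") = IntegerVector::create(g.ox, g.oy, g.oz, g.cout);
  return y;
}

List conv_s1_backward(const ConvGeom &g, NumericVector x, NumericVector w,
                      NumericVector dy) {
  PadGeom p = pad_geom(g);
  std::vector<float> xbuf((long)g.cin * p.S + p.guard, 0.0f);
  std::vector<float> dybuf((long)g.cout * p.S + p.guard, 0.0f);
  std::vector<float> dxbuf((long)g.cin * p.S + p.guard, 0.0f);
  fill_padded(g, p, REAL(x), xbuf.data());
  NumericVector db(g.cout);
  // place dy at padded coords [0, o*) and accumulate db
  for (int co = 0; co < g.cout; ++co) {
    double s = 0.0;
    for (int z = 0; z < g.oz; ++z)
      for (int yy = 0; yy < g.oy; ++yy) {
        const double *src = REAL(dy) + (long)co * g.nout +
          (long)g.ox * (yy + (long)g.oy * z);
        float *dst = dybuf.data() + (long)co * p.S +
          (long)p.px * (yy + (long)p.py * z);
        for (int xx = 0; xx < g.ox; ++xx) { dst[xx] = (float)src[xx]; s += src[xx]; }
      }
    db[co] = s;
  }
  long kkk = (long)g.k * g.k * g.k;
  NumericVector dw(w.size());
  std::vector<float> Wt((size_t)kkk * g.cin * g.cout);
  std::vector<float> dWt((size_t)kkk * g.cin * g.cout, 0.0f);
  for (long ptap = 0; ptap < kkk; ++ptap)
    for (int co = 0; co < g.cout; ++co)
      for (int ci = 0; ci < g.cin; ++ci)
        Wt[ptap * g.cin * g.cout + ci + (long)g.cin * co] =
          (float)w[ptap + kkk * (ci + (long)g.cin * co)];
  long planep = (long)p.px * p.py;
  int zs = (int)std::max(1L, (256L * 1024) / (planep * g.cin * 4));
  for (int z0 = 0; z0 < p.pz; z0 += zs) {
    long r0 = planep * z0;
    int rows = (int)(planep * std::min((long)zs, p.pz - (long)z0));
    for (long ptap = 0, kz = 0; kz < g.k; ++kz)
      for (long ky = 0; ky < g.k; ++ky)
        for (long kx = 0; kx < g.k; ++kx, ++ptap) {
          long off = kx + (long)p.px * ky + planep * kz;
          // dW_tap += X_slab^T dY_slab
          sgemm_tn(g.cin, g.cout, rows,
                   xbuf.data() + r0 + off, (int)p.S,
                   dybuf.data() + r0, (int)p.S,
                   1.0f, dWt.data() + ptap * g.cin * g.cout, g.cin);
          // dX_slab(+off) += dY_slab W_tap^T  (B = W^T given as T of cin x cout)
          const float one = 1.0f;
          int m = rows, n = g.cin, k2 = g.cout, lda = (int)p.S,
              ldb = g.cin, ldc = (int)p.S;
          sgemm_("N", "T", &m, &n, &k2, &one, dybuf.data() + r0, &lda,
                 Wt.data() + ptap * g.cin * g.cout, &ldb, &one,
                 dxbuf.data() + r0 + off, &ldc);
        }
  }
  for (long ptap = 0; ptap < kkk; ++ptap)
    for (int co = 0; co < g.cout; ++co)
      for (int ci = 0; ci < g.cin; ++ci)
        dw[ptap + kkk * (ci + (long)g.cin * co)] =
          dWt[ptap * g.cin * g.cout + ci + (long)g.cin * co];
  // extract interior of dxbuf back to (nx,ny,nz,cin)
  NumericVector dx((long)g.nx * g.ny * g.nz * g.cin);
  for (int c = 0; c < g.cin; ++c)
    for (int z = 0; z < g.nz; ++z)
      for (int yy = 0; yy < g.ny; ++yy) {
        const float *src = dxbuf.data() + (long)c * p.S +
          g.plo[0] + (long)p.px * ((yy + g.plo[1]) + (long)p.py * (z + g.plo[2]));
        double *dst = REAL(dx) + ((long)c * g.nz + z) * g.nx * g.ny +
          (long)yy * g.nx;
        for (int xx = 0; xx < g.nx; ++xx) dst[xx] = (double)src[xx];
      }
  dx.attr("dim") = IntegerVector::create(g.nx, g.ny, g.nz, g.cin);
  dw.attr("dim") = w.attr("dim");
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

} // namespace

// [[Rcpp::export(name = ".cpp_conv3d_forward")]]
NumericVector cpp_conv3d_forward(NumericVector x, NumericVector w, NumericVector b,
                                 int stride, IntegerVector pad_lo, IntegerVector pad_hi) {
  IntegerVector xdim = x.attr("dim"), wdim = w.attr("dim");
  ConvGeom g = geom(xdim, wdim, stride, pad_lo, pad_hi);
  if (stride == 1) return conv_s1_forward(g, x, w, b);
  NumericVector y((long)g.nout * g.cout);
  arma::fmat W = weight_mat(w, g);
  int slab = slab_size(g);
  long planeo = (long)g.ox * g.oy;
  arma::fmat A((long)planeo * slab, g.kk);
  for (int z0 = 0; z0 < g.oz; z0 += slab) {
    int z1 = std::min(z0 + slab, g.oz);
    long rows = planeo * (z1 - z0);
    if ((long)A.n_rows != rows) A.set_size(rows, g.kk);
    im2col_slab(g, z0, z1, REAL(x), A.memptr(), false);
    arma::fmat Y = A * W;
    for (int co = 0; co < g.cout; ++co) {
      double *yp = REAL(y) + (long)co * g.nout + (long)z0 * planeo;
      float *Yp = Y.colptr(co);
      for (long r = 0; r < rows; ++r) yp[r] = (double)Yp[r] + b[co];
    }
  }
  y.attr("dim") = IntegerVector::create(g.ox, g.oy, g.oz, g.cout);
  return y;
}

// [[Rcpp::export(name = ".cpp_conv3d_backward")]]
List cpp_conv3d_backward(NumericVector x, NumericVector w, NumericVector dy,
                         int stride, IntegerVector pad_lo, IntegerVector pad_hi) {
  IntegerVector xdim = x.attr("dim"), wdim = w.attr("dim");
  ConvGeom g = geom(xdim, wdim, stride, pad_lo, pad_hi);
  if (stride == 1) return conv_s1_backward(g, x, w, dy);
  arma::fmat W = weight_mat(w, g);
  arma::fmat dW(g.kk, g.cout, arma::fill::zeros);
  NumericVector dx((long)g.nx * g.ny * g.nz * g.cin);
  NumericVector db(g.cout);
  int slab = slab_size(g);
  long planeo = (long)g.ox * g.oy;
  arma::fmat A((long)planeo * slab, g.kk);
  for (int z0 = 0; z0 < g.oz; z0 += slab) {
    int z1 = std::min(z0 + slab, g.oz);
    long rows = planeo * (z1 - z0);
    if ((long)A.n_rows != rows) A.set_size(rows, g.kk);
    im2col_slab(g, z0, z1, REAL(x), A.memptr(), false);
    arma::fmat dY(rows, g.cout);
    for (int co = 0; co < g.cout; ++co) {
      double *dyp = REAL(dy) + (long)co * g.nout + (long)z0 * planeo;
      double s = 0.0;
      float *Dp = dY.colptr(co);
      for (long r = 0; r < rows; ++r) { Dp[r] = (float)dyp[r]; s += dyp[r]; }
      db[co] += s;
    }
    dW += A.t() * dY;
    arma::fmat dA = dY * W.t();
    im2col_slab(g, z0, z1, REAL(dx), dA.memptr(), true);
  }
  NumericVector dw(w.size());
  long kkk = (long)g.k * g.k * g.k;
  for (int co = 0; co < g.cout; ++co)
    for (int ci = 0; ci < g.cin; ++ci)
      for (long p = 0; p < kkk; ++p)
        dw[p + kkk * (ci + (long)g.cin * co)] = dW((long)ci * kkk + p, co);
  dx.attr("dim") = IntegerVector::create(g.nx, g.ny, g.nz, g.cin);
  dw.attr("dim") = wdim;
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
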