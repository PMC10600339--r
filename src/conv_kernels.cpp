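#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Feature maps are channel-first: dim(x) = c(C, nx, ny, nz).
// Convolutions are evaluated as GEMM on an im2col matrix whose rows are
// ordered (ci fastest, then kx, ky, kz) and whose columns enumerate output
// voxels in (x, y, z) order; zero padding (k-1)/2.

// [[Rcpp::export(name = ".im2col")]]
NumericMatrix im2col(NumericVector x, int ksize, int stride) {
  IntegerVector xd = x.attr("dim");
  const int ci = xd[0], nx = xd[1], ny = xd[2], nz = xd[3];
  const int pad = (ksize - 1) / 2;
  const int ox = (nx + 2 * pad - ksize) / stride + 1;
  const int oy = (ny + 2 * pad - ksize) / stride + 1;
  const int oz = (nz + 2 * pad - ksize) / stride + 1;
  const int rows = ci * ksize * ksize * ksize;
  NumericMatrix cols(rows, ox * oy * oz);
  const double *px = REAL(x);
  double *pc = REAL(cols);
  for (int z = 0; z < oz; ++z)
    for (int y = 0; y < oy; ++y)
      for (int xo = 0; xo < ox; ++xo) {
        double *col = pc + (size_t)rows * ((size_t)xo + (size_t)ox * (y + (size_t)oy * z));
        const int bx = xo * stride - pad, by = y * stride - pad, bz = z * stride - pad;
        for (int kz = 0; kz < ksize; ++kz) {
          const int zz = bz + kz;
          for (int ky = 0; ky < ksize; ++ky) {
            const int yy = by + ky;
            for (int kx = 0; kx < ksize; ++kx) {
              const int xx = bx + kx;
              double *dst = col + (size_t)ci * ((size_t)kx + (size_t)ksize * (ky + (size_t)ksize * kz));
              if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) {
                std::memset(dst, 0, sizeof(double) * ci);
              } else {
                const double *src = px + (size_t)ci * ((size_t)xx + (size_t)nx * (yy + (size_t)ny * zz));
                std::memcpy(dst, src, sizeof(double) * ci);
              }
            }
          }
        }
      }
  return cols;
}

// scatter-add the column gradients back onto the input feature map
// [[Rcpp::export(name = ".col2im")]]
NumericVector col2im(NumericMatrix gcols, IntegerVector xdim, int ksize, int stride) {
  const int ci = xdim[0], nx = xdim[1], ny = xdim[2], nz = xdim[3];
  const int pad = (ksize - 1) / 2;
  const int ox = (nx + 2 * pad - ksize) / stride + 1;
  const int oy = (ny + 2 * pad - ksize) / stride + 1;
  const int oz = (nz + 2 * pad - ksize) / stride + 1;
  const int rows = ci * ksize * ksize * ksize;
  NumericVector gx((R_xlen_t)ci * nx * ny * nz);
  gx.attr("dim") = xdim;
  double *pg = REAL(gx);
  const double *pc = REAL(gcols);
  for (int z = 0; z < oz; ++z)
    for (int y = 0; y < oy; ++y)
      for (int xo = 0; xo < ox; ++xo) {
        const double *col = pc + (size_t)rows * ((size_t)xo + (size_t)ox * (y + (size_t)oy * z));
        const int bx = xo * stride - pad, by = y * stride - pad, bz = z * stride - pad;
        for (int kz = 0; kz < ksize; ++kz) {
          const int zz = bz + kz; if (zz < 0 || zz >= nz) continue;
          for (int ky = 0; ky < ksize; ++ky) {
            const int yy = by + ky; if (yy < 0 || yy >= ny) continue;
            for (int kx = 0; kx < ksize; ++kx) {
              const int xx = bx + kx; if (xx < 0 || xx >= nx) continue;
              const double *src = col + (size_t)ci * ((size_t)kx + (size_t)ksize * (ky + (size_t)ksize * kz));
              double *dst = pg + (size_t)ci * ((size_t)xx + (size_t)nx * (yy + (size_t)ny * zz));
              for (int a = 0; a < ci; ++a) dst[a] += src[a];
            }
          }
        }
      }
  return gx;
}

// nearest-neighbour upsampling by 2 in each spatial dimension
// [[Rcpp::export(name = ".up2_fwd")]]
NumericVector up2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int c = xd[0], nx = xd[1], ny = xd[2], nz = xd[3];
  NumericVector out((R_xlen_t)c * 8 * nx * ny * nz);
  out.attr("dim") = IntegerVector::create(c, 2 * nx, 2 * ny, 2 * nz);
  const double *px = REAL(x);
  double *po = REAL(out);
  for (int z = 0; z < 2 * nz; ++z)
    for (int y = 0; y < 2 * ny; ++y)
      for (int xo = 0; xo < 2 * nx; ++xo) {
        const double *src = px + (size_t)c * ((size_t)(xo / 2) + (size_t)nx * ((y / 2) + (size_t)ny * (z / 2)));
        double *dst = po + (size_t)c * ((size_t)xo + (size_t)(2 * nx) * (y + (size_t)(2 * ny) * z));
        std::memcpy(dst, src, sizeof(double) * c);
      }
  return out;
}

// [[Rcpp::export(name = ".up2_bwd")]]
NumericVector up2_bwd(NumericVector g) {
  IntegerVector gd = g.attr("dim");
  const int c = gd[0], nx2 = gd[1], ny2 = gd[2], nz2 = gd[3];
  const int nx = nx2 / 2, ny = ny2 / 2, nz = nz2 / 2;
  NumericVector out((R_xlen_t)c * nx * ny * nz);
  out.attr("dim") = IntegerVector::create(c, nx, ny, nz);
  const double *pg = REAL(g);
  double *po = REAL(out);
  for (int z = 0; z < nz2; ++z)
    for (int y = 0; y < ny2; ++y)
      for (int xo = 0; xo < nx2; ++xo) {
        const double *src = pg + (size_t)c * ((size_t)xo + (size_t)nx2 * (y + (size_t)ny2 * z));
        double *dst = po + (size_t)c * ((size_t)(xo / 2) + (size_t)nx * ((y / 2) + (size_t)ny * (z / 2)));
        for (int a = 0; a < c; ++a) dst[a] += src[a];
      }
  return out;
}
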