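#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Flow fields are stored channel-first: dim(field) = c(3, gx, gy, gz),
// world position p maps to grid coordinate u = (p - origin) / spc, and queries
// outside the grid are clamped to the boundary before interpolation (so the
// spatial derivative is zero along a clamped axis).

struct FieldView {
  const double *f;
  int gx, gy, gz;
  double ox, oy, oz, sx, sy, sz;
};

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// value + (optionally) spatial Jacobian of the interpolated field at p
static inline void sample_point(const FieldView &fv, const double *p,
                                double *val, double *jac /* 3x3 row=dval,col=dpos or NULL */) {
  double u[3] = {(p[0] - fv.ox) / fv.sx, (p[1] - fv.oy) / fv.sy, (p[2] - fv.oz) / fv.sz};
  int g[3] = {fv.gx, fv.gy, fv.gz};
  double sp[3] = {fv.sx, fv.sy, fv.sz};
  int i0[3]; double t[3]; bool clamped[3];
  for (int a = 0; a < 3; ++a) {
    double uu = u[a];
    clamped[a] = (uu <= 0.0) || (uu >= g[a] - 1.0) || g[a] == 1;
    uu = clampd(uu, 0.0, (double)(g[a] - 1));
    int i = (int)std::floor(uu);
    if (i > g[a] - 2) i = g[a] - 2;
    if (i < 0) i = 0;
    i0[a] = i;
    t[a] = (g[a] == 1) ? 0.0 : uu - i;
  }
  for (int c = 0; c < 3; ++c) val[c] = 0;
  if (jac) for (int k = 0; k < 9; ++k) jac[k] = 0;
  for (int dz = 0; dz < 2; ++dz)
    for (int dy = 0; dy < 2; ++dy)
      for (int dx = 0; dx < 2; ++dx) {
        double wx = dx ? t[0] : 1 - t[0];
        double wy = dy ? t[1] : 1 - t[1];
        double wz = dz ? t[2] : 1 - t[2];
        double w = wx * wy * wz;
        int xi = std::min(i0[0] + dx, fv.gx - 1);
        int yi = std::min(i0[1] + dy, fv.gy - 1);
        int zi = std::min(i0[2] + dz, fv.gz - 1);
        size_t base = 3 * ((size_t)xi + (size_t)fv.gx * (yi + (size_t)fv.gy * zi));
        for (int c = 0; c < 3; ++c) {
          double fc = fv.f[base + c];
          val[c] += w * fc;
          if (jac) {
            double dwx = (dx ? 1.0 : -1.0) * wy * wz;
            double dwy = (dy ? 1.0 : -1.0) * wx * wz;
            double dwz = (dz ? 1.0 : -1.0) * wx * wy;
            if (!clamped[0]) jac[3 * c + 0] += dwx * fc / sp[0];
            if (!clamped[1]) jac[3 * c + 1] += dwy * fc / sp[1];
            if (!clamped[2]) jac[3 * c + 2] += dwz * fc / sp[2];
          }
        }
      }
}

static FieldView make_view(const NumericVector &field, const NumericVector &origin,
                           const NumericVector &spc) {
  IntegerVector d = field.attr("dim");
  FieldView fv;
  fv.f = REAL(field);
  fv.gx = d[1]; fv.gy = d[2]; fv.gz = d[3];
  fv.ox = origin[0]; fv.oy = origin[1]; fv.oz = origin[2];
  fv.sx = spc[0]; fv.sy = spc[1]; fv.sz = spc[2];
  return fv;
}

// [[Rcpp::export(name = ".sample_flow_cpp")]]
NumericMatrix sample_flow_cpp(NumericVector field, NumericVector origin,
                              NumericVector spc, NumericMatrix points) {
  FieldView fv = make_view(field, origin, spc);
  int n = points.nrow();
  NumericMatrix out(n, 3);
  double p[3], val[3];
  for (int i = 0; i < n; ++i) {
    p[0] = points(i, 0); p[1] = points(i, 1); p[2] = points(i, 2);
    sample_point(fv, p, val, nullptr);
    out(i, 0) = val[0]; out(i, 1) = val[1]; out(i, 2) = val[2];
  }
  return out;
}

// forward Euler over one stationary field; stores pre-step positions for the
// backward pass. traj has dim (n, 3, steps).
// [[Rcpp::export(name = ".euler_fwd_cpp")]]
List euler_fwd_cpp(NumericMatrix x0, NumericVector field, NumericVector origin,
                   NumericVector spc, double h, int steps) {
  FieldView fv = make_view(field, origin, spc);
  int n = x0.nrow();
  NumericMatrix x = clone(x0);
  NumericVector traj((R_xlen_t)n * 3 * steps);
  traj.attr("dim") = IntegerVector::create(n, 3, steps);
  double *tr = REAL(traj);
  double p[3], val[3];
  for (int s = 0; s < steps; ++s) {
    for (int i = 0; i < n; ++i) {
      p[0] = x(i, 0); p[1] = x(i, 1); p[2] = x(i, 2);
      for (int c = 0; c < 3; ++c) tr[(size_t)i + n * ((size_t)c + 3 * (size_t)s)] = p[c];
      sample_point(fv, p, val, nullptr);
      x(i, 0) = p[0] + h * val[0];
      x(i, 1) = p[1] + h * val[1];
      x(i, 2) = p[2] + h * val[2];
    }
  }
  return List::create(_["x"] = x, _["traj"] = traj);
}

// reverse-mode of euler_fwd_cpp: returns gradient w.r.t. x0 and the field grid
// [[Rcpp::export(name = ".euler_bwd_cpp")]]
List euler_bwd_cpp(NumericVector traj, NumericVector field, NumericVector origin,
                   NumericVector spc, double h, int steps, NumericMatrix g_out) {
  FieldView fv = make_view(field, origin, spc);
  IntegerVector td = traj.attr("dim");
  int n = td[0];
  const double *tr = REAL(traj);
  NumericMatrix gx = clone(g_out);
  NumericVector gf(field.size());
  gf.attr("dim") = field.attr("dim");
  double *pgf = REAL(gf);
  double p[3], val[3], jac[9];
  for (int s = steps - 1; s >= 0; --s) {
    for (int i = 0; i < n; ++i) {
      for (int c = 0; c < 3; ++c) p[c] = tr[(size_t)i + n * ((size_t)c + 3 * (size_t)s)];
      sample_point(fv, p, val, jac);
      double g[3] = {gx(i, 0), gx(i, 1), gx(i, 2)};
      // accumulate field-value gradient through the trilinear weights
      {
        double u[3] = {(p[0] - fv.ox) / fv.sx, (p[1] - fv.oy) / fv.sy, (p[2] - fv.oz) / fv.sz};
        int gsz[3] = {fv.gx, fv.gy, fv.gz};
        int i0[3]; double t[3];
        for (int a = 0; a < 3; ++a) {
          double uu = clampd(u[a], 0.0, (double)(gsz[a] - 1));
          int ii = (int)std::floor(uu);
          if (ii > gsz[a] - 2) ii = gsz[a] - 2;
          if (ii < 0) ii = 0;
          i0[a] = ii;
          t[a] = (gsz[a] == 1) ? 0.0 : uu - ii;
        }
        for (int dz = 0; dz < 2; ++dz)
          for (int dy = 0; dy < 2; ++dy)
            for (int dx = 0; dx < 2; ++dx) {
              double w = (dx ? t[0] : 1 - t[0]) * (dy ? t[1] : 1 - t[1]) * (dz ? t[2] : 1 - t[2]);
              int xi = std::min(i0[0] + dx, fv.gx - 1);
              int yi = std::min(i0[1] + dy, fv.gy - 1);
              int zi = std::min(i0[2] + dz, fv.gz - 1);
              size_t base = 3 * ((size_t)xi + (size_t)fv.gx * (yi + (size_t)fv.gy * zi));
              for (int c = 0; c < 3; ++c) pgf[base + c] += h * w * g[c];
            }
      }
      // position gradient: g_x = g_y + h * J^T g_y
      double gnew[3];
      for (int a = 0; a < 3; ++a) {
        gnew[a] = g[a];
        for (int c = 0; c < 3; ++c) gnew[a] += h * jac[3 * c + a] * g[c];
      }
      gx(i, 0) = gnew[0]; gx(i, 1) = gnew[1]; gx(i, 2) = gnew[2];
    }
  }
  return List::create(_["g_x"] = gx, _["g_field"] = gf);
}
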