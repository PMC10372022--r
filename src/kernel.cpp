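// Particle advection kernel: RK4 horizontal advection through gridded
// velocity snapshots, with behavioural vertical migration keyed to solar
// elevation and a (gradient-corrected) vertical random walk.
//
// Conventions: horizontal positions in km on the model grid, depth in m
// positive down, velocities in m s-1, time in hours since season start.
// Velocity arrays are (x, y, depth, time) with a uniform time axis.
// Status codes: 0 active, 1 beached, 2 exited.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct FieldView {
  const double *u, *v, *w;
  bool has_w;
  int nx, ny, nz, nt;
  double x0, y0, hx;       // km origin and spacing
  const double *zax;       // depth levels, m
  double t0, ht;           // time axis origin/spacing, hours
  inline double at(const double *a, int ix, int iy, int iz, int it) const {
    return a[ix + (size_t)nx * (iy + (size_t)ny * (iz + (size_t)nz * it))];
  }
  // trilinear in (x, y, depth), linear in time; depth and time clamped
  // outside the axis range (constant extrapolation)
  void interp(double x, double y, double z, double t,
              double &uo, double &vo, double &wo) const {
    double fx = (x - x0) / hx;
    double fy = (y - y0) / hx;
    if (fx < 0) fx = 0; if (fx > nx - 1) fx = nx - 1;
    if (fy < 0) fy = 0; if (fy > ny - 1) fy = ny - 1;
    int ix = (int)fx; if (ix > nx - 2) ix = nx - 2;
    int iy = (int)fy; if (iy > ny - 2) iy = ny - 2;
    double wx = fx - ix, wy = fy - iy;
    if (nx == 1) { ix = 0; wx = 0; }
    if (ny == 1) { iy = 0; wy = 0; }
    int iz = 0; double wz = 0;
    if (nz > 1) {
      if (z <= zax[0]) { iz = 0; wz = 0; }
      else if (z >= zax[nz - 1]) { iz = nz - 2; wz = 1; }
      else {
        while (iz < nz - 2 && zax[iz + 1] < z) ++iz;
        wz = (z - zax[iz]) / (zax[iz + 1] - zax[iz]);
      }
    }
    int it = 0; double wt = 0;
    if (nt > 1) {
      double ft = (t - t0) / ht;
      if (ft < 0) ft = 0; if (ft > nt - 1) ft = nt - 1;
      it = (int)ft; if (it > nt - 2) it = nt - 2;
      wt = ft - it;
    }
    double acc_u = 0, acc_v = 0, acc_w = 0;
    for (int dt_ = 0; dt_ <= (nt > 1 ? 1 : 0); ++dt_) {
      double tw = (nt > 1) ? (dt_ ? wt : 1 - wt) : 1.0;
      if (tw == 0) continue;
      for (int dz_ = 0; dz_ <= (nz > 1 ? 1 : 0); ++dz_) {
        double zw = (nz > 1) ? (dz_ ? wz : 1 - wz) : 1.0;
        if (zw == 0) continue;
        for (int dy_ = 0; dy_ <= 1; ++dy_) {
          double yw = dy_ ? wy : 1 - wy;
          if (yw == 0 && ny > 1) continue;
          for (int dx_ = 0; dx_ <= 1; ++dx_) {
            double xw = dx_ ? wx : 1 - wx;
            if (xw == 0 && nx > 1) continue;
            double wgt = tw * zw * yw * xw;
            int jx = ix + dx_, jy = iy + dy_, jz = iz + dz_,
                jt = it + dt_;
            if (jx > nx - 1) jx = nx - 1;
            if (jy > ny - 1) jy = ny - 1;
            acc_u += wgt * at(u, jx, jy, jz, jt);
            acc_v += wgt * at(v, jx, jy, jz, jt);
            if (has_w) acc_w += wgt * at(w, jx, jy, jz, jt);
          }
        }
      }
    }
    uo = acc_u; vo = acc_v; wo = acc_w;
  }
};

// piecewise-linear K(z), constant extrapolation
inline double eval_K(const double *zb, const double *Kv, int n, double z) {
  if (z <= zb[0]) return Kv[0];
  if (z >= zb[n - 1]) return Kv[n - 1];
  int i = 0;
  while (i < n - 2 && zb[i + 1] < z) ++i;
  double f = (z - zb[i]) / (zb[i + 1] - zb[i]);
  return Kv[i] + f * (Kv[i + 1] - Kv[i]);
}

inline double eval_dK(const double *zb, const double *Kv, int n, double z) {
  return (eval_K(zb, Kv, n, z + 0.1) - eval_K(zb, Kv, n, z - 0.1)) / 0.2;
}

inline double rw_step(const double *zb, const double *Kv, int n, double z,
                      double dt, bool corrected) {
  double R = norm_rand();
  if (!corrected) return R * std::sqrt(2.0 * eval_K(zb, Kv, n, z) * dt);
  double dK = eval_dK(zb, Kv, n, z);
  double Koff = eval_K(zb, Kv, n, z + 0.5 * dK * dt);
  return dK * dt + R * std::sqrt(2.0 * Koff * dt);
}

inline double reflect(double z, double zmin, double zmax) {
  // fold into [zmin, zmax] by reflection
  for (int it = 0; it < 64 && (z < zmin || z > zmax); ++it) {
    if (z < zmin) z = 2 * zmin - z;
    if (z > zmax) z = 2 * zmax - z;
  }
  if (z < zmin) z = zmin;
  if (z > zmax) z = zmax;
  return z;
}

// NOAA low-precision solar terms for one instant (shared by particles)
struct SolarStep {
  double sin_decl, cos_decl, eqtime, hour_frac;
  void set(int doy, double hour) {
    hour_frac = hour;
    double g = 2.0 * M_PI / 365.0 * (doy - 1 + (hour - 12.0) / 24.0);
    eqtime = 229.18 * (0.000075 + 0.001868 * std::cos(g) -
                       0.032077 * std::sin(g) -
                       0.014615 * std::cos(2 * g) -
                       0.040849 * std::sin(2 * g));
    double decl = 0.006918 - 0.399912 * std::cos(g) +
                  0.070257 * std::sin(g) - 0.006758 * std::cos(2 * g) +
                  0.000907 * std::sin(2 * g) - 0.002697 * std::cos(3 * g) +
                  0.00148 * std::sin(3 * g);
    sin_decl = std::sin(decl);
    cos_decl = std::cos(decl);
  }
  bool sun_up(double lat_deg, double lon_deg) const {
    double tst = hour_frac * 60.0 + 4.0 * lon_deg + eqtime;
    double ha = (tst / 4.0 - 180.0) * M_PI / 180.0;
    double lr = lat_deg * M_PI / 180.0;
    double s = std::sin(lr) * sin_decl +
               std::cos(lr) * cos_decl * std::cos(ha);
    return s > 0;
  }
};

} // namespace

// [[Rcpp::export]]
NumericMatrix kf_interp(NumericVector u, NumericVector v,
                        Nullable<NumericVector> w, NumericVector xax,
                        NumericVector yax, NumericVector zax,
                        NumericVector tax, NumericVector xq,
                        NumericVector yq, NumericVector zq,
                        NumericVector tq) {
  FieldView F;
  F.u = u.begin(); F.v = v.begin();
  F.has_w = w.isNotNull();
  NumericVector wv;
  if (F.has_w) { wv = w.get(); F.w = wv.begin(); } else F.w = nullptr;
  F.nx = xax.size(); F.ny = yax.size(); F.nz = zax.size();
  F.nt = tax.size();
  F.x0 = xax[0]; F.y0 = yax[0];
  F.hx = F.nx > 1 ? xax[1] - xax[0] : 1.0;
  F.zax = zax.begin();
  F.t0 = tax[0];
  F.ht = F.nt > 1 ? (tax[F.nt - 1] - tax[0]) / (F.nt - 1) : 1.0;
  int n = xq.size();
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    double uo, vo, wo;
    F.interp(xq[i], yq[i], zq[i], tq[i], uo, vo, wo);
    out(i, 0) = uo; out(i, 1) = vo; out(i, 2) = wo;
  }
  return out;
}

// [[Rcpp::export]]
List kf_advance(NumericVector u, NumericVector v, Nullable<NumericVector> w,
                NumericVector xax, NumericVector yax, NumericVector zax,
                NumericVector tax, LogicalMatrix land, double seabed,
                NumericVector px, NumericVector py, NumericVector pz,
                IntegerVector pstatus, double t_start_hours, double dt,
                int n_steps, int save_every, bool dvm_enabled,
                double dvm_min, double dvm_max, double dvm_speed,
                bool rw_on, NumericVector K_breaks, NumericVector K_vals,
                bool rw_corrected, bool use_fixed,
                NumericVector fixed_behavior_w,
                NumericVector fixed_random_w, double ref_lon,
                double ref_lat, int start_doy) {
  FieldView F;
  F.u = u.begin(); F.v = v.begin();
  F.has_w = w.isNotNull();
  NumericVector wv;
  if (F.has_w) { wv = w.get(); F.w = wv.begin(); } else F.w = nullptr;
  F.nx = xax.size(); F.ny = yax.size(); F.nz = zax.size();
  F.nt = tax.size();
  F.x0 = xax[0]; F.y0 = yax[0];
  F.hx = F.nx > 1 ? xax[1] - xax[0] : 1.0;
  F.zax = zax.begin();
  F.t0 = tax[0];
  F.ht = F.nt > 1 ? (tax[F.nt - 1] - tax[0]) / (F.nt - 1) : 1.0;
  const double xmin = xax[0], xmax = xax[F.nx - 1];
  const double ymin = yax[0], ymax = yax[F.ny - 1];
  const double zmin = 0.5, zmax = seabed - 0.5;
  const double coslat = std::cos(ref_lat * M_PI / 180.0);
  const int np = px.size();
  const int nsave = n_steps / save_every + 1;
  NumericMatrix X(np, nsave), Y(np, nsave), Z(np, nsave);
  IntegerMatrix S(np, nsave);
  std::vector<double> x(px.begin(), px.end());
  std::vector<double> y(py.begin(), py.end());
  std::vector<double> z(pz.begin(), pz.end());
  std::vector<int> st(pstatus.begin(), pstatus.end());

  auto on_land = [&](double xx, double yy) -> bool {
    int ix = (int)std::lround((xx - F.x0) / F.hx);
    int iy = (int)std::lround((yy - F.y0) / F.hx);
    if (ix < 0) ix = 0; if (ix > F.nx - 1) ix = F.nx - 1;
    if (iy < 0) iy = 0; if (iy > F.ny - 1) iy = F.ny - 1;
    return land(ix, iy);
  };

  // particles released on a land node beach immediately
  for (int i = 0; i < np; ++i) {
    if (st[i] == 0 && on_land(x[i], y[i])) st[i] = 1;
    z[i] = reflect(z[i], zmin, zmax);
    X(i, 0) = x[i]; Y(i, 0) = y[i]; Z(i, 0) = z[i]; S(i, 0) = st[i];
  }

  SolarStep sol;
  const int nK = K_breaks.size();
  const double *zb = K_breaks.begin(), *Kv = K_vals.begin();
  int isave = 1;
  for (int step = 0; step < n_steps; ++step) {
    double t = t_start_hours + step * dt / 3600.0;
    if (dvm_enabled) {
      double t_abs = t;  // hours since season start (00:00 UTC)
      int doy = start_doy + (int)std::floor(t_abs / 24.0);
      doy = ((doy - 1) % 365) + 1;
      double hour = t_abs - 24.0 * std::floor(t_abs / 24.0);
      sol.set(doy, hour);
    }
    for (int i = 0; i < np; ++i) {
      if (st[i] != 0) continue;
      // behavioural vertical velocity (positive down)
      double bw = 0.0, rw = 0.0;
      if (use_fixed) {
        bw = fixed_behavior_w[i];
        rw = fixed_random_w[i];
      } else {
        if (dvm_enabled) {
          double lat = ref_lat + y[i] / 110.574;
          double lon = ref_lon + x[i] / (111.320 * coslat);
          if (sol.sun_up(lat, lon)) {
            if (z[i] < dvm_max) bw = dvm_speed;
          } else {
            if (z[i] > dvm_min) bw = -dvm_speed;
          }
        }
        if (rw_on) rw = rw_step(zb, Kv, nK, z[i], dt, rw_corrected);
      }
      // RK4 horizontal advection at the current depth
      double u1, v1, w1, u2, v2, w2, u3, v3, w3, u4, v4, w4;
      double km = dt / 1000.0;  // m s-1 * s -> km
      F.interp(x[i], y[i], z[i], t, u1, v1, w1);
      F.interp(x[i] + 0.5 * km * u1, y[i] + 0.5 * km * v1, z[i],
               t + dt / 7200.0, u2, v2, w2);
      F.interp(x[i] + 0.5 * km * u2, y[i] + 0.5 * km * v2, z[i],
               t + dt / 7200.0, u3, v3, w3);
      F.interp(x[i] + km * u3, y[i] + km * v3, z[i], t + dt / 3600.0,
               u4, v4, w4);
      double xn = x[i] + km * (u1 + 2 * u2 + 2 * u3 + u4) / 6.0;
      double yn = y[i] + km * (v1 + 2 * v2 + 2 * v3 + v4) / 6.0;
      double wadv = F.has_w ? (w1 + 2 * w2 + 2 * w3 + w4) / 6.0 : 0.0;
      double zn = z[i] + (wadv + bw) * dt + rw;
      zn = reflect(zn, zmin, zmax);
      if (xn < xmin || xn > xmax || yn < ymin || yn > ymax) {
        // left the domain: freeze at the (clamped) exit point
        st[i] = 2;
        x[i] = std::min(std::max(xn, xmin), xmax);
        y[i] = std::min(std::max(yn, ymin), ymax);
        z[i] = zn;
      } else if (on_land(xn, yn)) {
        st[i] = 1;  // beached: stay at last water position
      } else {
        x[i] = xn; y[i] = yn; z[i] = zn;
      }
    }
    if ((step + 1) % save_every == 0) {
      for (int i = 0; i < np; ++i) {
        X(i, isave) = x[i]; Y(i, isave) = y[i]; Z(i, isave) = z[i];
        S(i, isave) = st[i];
      }
      ++isave;
    }
  }
  return List::create(_["x"] = X, _["y"] = Y, _["depth"] = Z,
                      _["status"] = S);
}

// [[Rcpp::export]]
NumericVector kf_rw_ensemble(NumericVector z0, NumericVector K_breaks,
                             NumericVector K_vals, double dt, int n_steps,
                             double zmin, double zmax, bool corrected) {
  int n = z0.size();
  const int nK = K_breaks.size();
  const double *zb = K_breaks.begin(), *Kv = K_vals.begin();
  NumericVector z = clone(z0);
  for (int s = 0; s < n_steps; ++s)
    for (int i = 0; i < n; ++i)
      z[i] = reflect(z[i] + rw_step(zb, Kv, nK, z[i], dt, corrected),
                     zmin, zmax);
  return z;
}
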