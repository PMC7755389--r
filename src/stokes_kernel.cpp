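// Steady Stokes solver on a staggered Cartesian (MAC) grid.
//
// Quasi-steady creeping flow at one beat phase: artificial-compressibility
// pseudo-time iteration with implicit drag (volume penalization for solids,
// Brinkman resistance for porous collar shells) and direct forcing of the
// moving flagellar sheets. Boundary conditions: x periodic, z symmetry
// planes, y = 0 uniform-pressure inlet over open (non-solid) faces,
// y = Ly uniform-pressure outlet.
//
// Index convention (0-based, i fastest):
//   p, cell centres:   nx * ny * nz
//   u, x-faces:        nx * ny * nz   (u[i] sits between cells i-1 and i, periodic)
//   v, y-faces:        nx * (ny+1) * nz
//   w, z-faces:        nx * ny * (nz+1)  (w at k=0 and k=nz are symmetry planes)

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline int wrap(int i, int n) { return (i + n) % n; }

// [[Rcpp::export]]
List stokes_phase_kernel(int nx, int ny, int nz, double h, double mu,
                         NumericVector solid_frac, NumericVector brinkman,
                         IntegerVector mem_u_idx, NumericVector mem_u_coef,
                         IntegerVector mem_w_idx, NumericVector mem_w_coef,
                         double alpha_pen, double alpha_sheet, double p_in,
                         IntegerVector fidx_u, NumericVector fval_u,
                         NumericVector fwgt_u,
                         IntegerVector fidx_v, NumericVector fwgt_v,
                         IntegerVector fidx_w, NumericVector fval_w,
                         NumericVector fwgt_w,
                         NumericVector u0, NumericVector v0, NumericVector w0,
                         NumericVector p0,
                         double tol, int max_iter, int check_every,
                         double safety) {
  const int ncell = nx * ny * nz;
  const int nu = nx * ny * nz;
  const int nv = nx * (ny + 1) * nz;
  const int nw = nx * ny * (nz + 1);

  auto ip = [&](int i, int j, int k) { return i + nx * (j + ny * k); };
  auto iu = [&](int i, int j, int k) { return wrap(i, nx) + nx * (j + ny * k); };
  auto iv = [&](int i, int j, int k) { return wrap(i, nx) + nx * (j + (ny + 1) * k); };
  auto iw = [&](int i, int j, int k) { return wrap(i, nx) + nx * (j + ny * k); };

  std::vector<double> u(u0.begin(), u0.end());
  std::vector<double> v(v0.begin(), v0.end());
  std::vector<double> w(w0.begin(), w0.end());
  std::vector<double> p(p0.begin(), p0.end());
  if ((int)u.size() != nu || (int)v.size() != nv || (int)w.size() != nw ||
      (int)p.size() != ncell)
    stop("field size mismatch");

  // drag coefficient per cell
  std::vector<double> acell(ncell);
  for (int c = 0; c < ncell; ++c)
    acell[c] = alpha_pen * solid_frac[c] + brinkman[c];

  // porous collar walls: membrane drag on the faces cut by the collar
  // cylinder (full wall resistance over one-cell depth)
  std::vector<double> bu(nu, 0.0), bw(nw, 0.0);
  for (int q = 0; q < mem_u_idx.size(); ++q) {
    int a = mem_u_idx[q];
    if (a >= 0 && a < nu) bu[a] += mem_u_coef[q];
  }
  for (int q = 0; q < mem_w_idx.size(); ++q) {
    int a = mem_w_idx[q];
    if (a >= 0 && a < nw) bw[a] += mem_w_coef[q];
  }

  // penalized moving sheets, face-based: each velocity face the sheet
  // surface cuts is dragged toward the sheet's no-slip velocity (beat-plane
  // motion on u/w faces, zero vertical velocity on v faces; the small axial
  // rescaling velocity is dropped) with coefficient alpha_sheet scaled by
  // the face's vane-coverage weight, so a vane narrower than the grid
  // spacing exerts a proportionately weaker constraint. Penalized faces
  // still feel the pressure gradient, so the prescribed motion cannot act
  // as a volume source; the residual slip scales as 1/alpha_sheet.
  std::vector<double> asu(nu, 0.0), asv(nv, 0.0), asw(nw, 0.0);
  std::vector<double> fuv(nu, 0.0), fwv(nw, 0.0);
  for (int q = 0; q < fidx_u.size(); ++q) {
    int a = fidx_u[q];
    if (a >= 0 && a < nu && bu[a] == 0.0) {
      asu[a] = alpha_sheet * fwgt_u[q]; fuv[a] = fval_u[q];
    }
  }
  for (int q = 0; q < fidx_v.size(); ++q) {
    int a = fidx_v[q];
    if (a >= 0 && a < nv) asv[a] = alpha_sheet * fwgt_v[q];
  }
  for (int q = 0; q < fidx_w.size(); ++q) {
    int a = fidx_w[q];
    if (a >= 0 && a < nw && bw[a] == 0.0) {
      asw[a] = alpha_sheet * fwgt_w[q]; fwv[a] = fval_w[q];
    }
  }

  // open (non-solid) bottom faces: pressure inlet where the ostium mouth is
  std::vector<char> open_bot(nx * nz, 0);
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i)
      open_bot[i + nx * k] = solid_frac[ip(i, 0, k)] < 0.5 ? 1 : 0;

  const double dtau = safety * h * h / (6.0 * mu);
  const double beta = safety * h * h / (3.0 * dtau);
  const double c1 = mu / (h * h);

  double u_scale = 1e-30;
  for (int q = 0; q < fidx_u.size(); ++q)
    if (std::fabs(fval_u[q]) > u_scale) u_scale = std::fabs(fval_u[q]);
  for (int q = 0; q < fidx_w.size(); ++q)
    if (std::fabs(fval_w[q]) > u_scale) u_scale = std::fabs(fval_w[q]);
  if (p_in != 0.0) {
    double u_p = std::fabs(p_in) * h / mu * 0.1;  // crude pressure-driven scale
    if (u_p > u_scale) u_scale = u_p;
  }

  std::vector<double> un(nu), vn(nv), wn(nw);
  double res = NA_REAL;
  int iter = 0;
  for (iter = 0; iter < max_iter; ++iter) {
    double dmax = 0.0;
    bool record = ((iter + 1) % check_every == 0) || (iter == max_iter - 1);

    // u update
    for (int k = 0; k < nz; ++k) {
      for (int j = 0; j < ny; ++j) {
        for (int i = 0; i < nx; ++i) {
          int a = iu(i, j, k);
          double uc = u[a];
          double lap = u[iu(i - 1, j, k)] + u[iu(i + 1, j, k)] - 2.0 * uc;
          // y neighbours: zero-gradient ghosts at open boundaries
          double uym = (j > 0) ? u[iu(i, j - 1, k)] : uc;
          double uyp = (j < ny - 1) ? u[iu(i, j + 1, k)] : uc;
          lap += uym + uyp - 2.0 * uc;
          // z neighbours: symmetry (zero-gradient)
          double uzm = (k > 0) ? u[iu(i, j, k - 1)] : uc;
          double uzp = (k < nz - 1) ? u[iu(i, j, k + 1)] : uc;
          lap += uzm + uzp - 2.0 * uc;
          double dpdx = (p[ip(i, j, k)] - p[ip(wrap(i - 1, nx), j, k)]) / h;
          double af = 0.5 * (acell[ip(i, j, k)] + acell[ip(wrap(i - 1, nx), j, k)])
                      + bu[a] + asu[a];
          double rhs_s = asu[a] * fuv[a];
          double unew = (uc + dtau * (c1 * lap - dpdx + rhs_s)) /
                        (1.0 + dtau * af);
          un[a] = unew;
          if (record) { double d = std::fabs(unew - uc); if (d > dmax) dmax = d; }
        }
      }
    }

    // v update (j = 0..ny faces)
    for (int k = 0; k < nz; ++k) {
      for (int j = 0; j <= ny; ++j) {
        for (int i = 0; i < nx; ++i) {
          int a = iv(i, j, k);
          double vc = v[a];
          double lap = v[iv(i - 1, j, k)] + v[iv(i + 1, j, k)] - 2.0 * vc;
          double vym = (j > 0) ? v[iv(i, j - 1, k)] : vc;
          double vyp = (j < ny) ? v[iv(i, j + 1, k)] : vc;
          lap += vym + vyp - 2.0 * vc;
          double vzm = (k > 0) ? v[iv(i, j, k - 1)] : vc;
          double vzp = (k < nz - 1) ? v[iv(i, j, k + 1)] : vc;
          lap += vzm + vzp - 2.0 * vc;
          double dpdy, af;
          if (j == 0) {
            int c = ip(i, 0, k);
            if (!open_bot[i + nx * k]) { vn[a] = 0.0; continue; }
            dpdy = (p[c] - p_in) / (0.5 * h);
            af = acell[c];
          } else if (j == ny) {
            int c = ip(i, ny - 1, k);
            dpdy = (0.0 - p[c]) / (0.5 * h);
            af = acell[c];
          } else {
            dpdy = (p[ip(i, j, k)] - p[ip(i, j - 1, k)]) / h;
            af = 0.5 * (acell[ip(i, j, k)] + acell[ip(i, j - 1, k)]);
          }
          af += asv[a];  // sheet no-slip: zero vertical target
          double vnew = (vc + dtau * (c1 * lap - dpdy)) / (1.0 + dtau * af);
          vn[a] = vnew;
          if (record) { double d = std::fabs(vnew - vc); if (d > dmax) dmax = d; }
        }
      }
    }

    // w update (k = 0..nz faces; k=0 and k=nz symmetry -> w = 0)
    for (int k = 0; k <= nz; ++k) {
      for (int j = 0; j < ny; ++j) {
        for (int i = 0; i < nx; ++i) {
          int a = iw(i, j, k);
          if (k == 0 || k == nz) { wn[a] = 0.0; continue; }
          double wc = w[a];
          double lap = w[iw(i - 1, j, k)] + w[iw(i + 1, j, k)] - 2.0 * wc;
          double wym = (j > 0) ? w[iw(i, j - 1, k)] : wc;
          double wyp = (j < ny - 1) ? w[iw(i, j + 1, k)] : wc;
          lap += wym + wyp - 2.0 * wc;
          lap += w[iw(i, j, k - 1)] + w[iw(i, j, k + 1)] - 2.0 * wc;
          double dpdz = (p[ip(i, j, k)] - p[ip(i, j, k - 1)]) / h;
          double af = 0.5 * (acell[ip(i, j, k)] + acell[ip(i, j, k - 1)])
                      + bw[a] + asw[a];
          double rhs_s = asw[a] * fwv[a];
          double wnew = (wc + dtau * (c1 * lap - dpdz + rhs_s)) /
                        (1.0 + dtau * af);
          wn[a] = wnew;
          if (record) { double d = std::fabs(wnew - wc); if (d > dmax) dmax = d; }
        }
      }
    }

    u.swap(un); v.swap(vn); w.swap(wn);

    // pressure update from divergence
    for (int k = 0; k < nz; ++k) {
      for (int j = 0; j < ny; ++j) {
        for (int i = 0; i < nx; ++i) {
          int c = ip(i, j, k);
          double div = (u[iu(i + 1, j, k)] - u[iu(i, j, k)] +
                        v[iv(i, j + 1, k)] - v[iv(i, j, k)] +
                        w[iw(i, j, k + 1)] - w[iw(i, j, k)]) / h;
          p[c] -= beta * div;
        }
      }
    }

    if (record) {
      res = dmax / (dtau * c1 * u_scale);  // momentum residual, viscous scale
      if (!std::isfinite(res)) { ++iter; break; }
      if (res < tol) { ++iter; break; }
    }
  }

  // diagnostics -----------------------------------------------------------
  // bottom (ostium mouth) influx and top outflux
  double q_in = 0.0, q_top = 0.0;
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      if (open_bot[i + nx * k]) q_in += v[iv(i, 0, k)] * h * h;
      q_top += v[iv(i, ny, k)] * h * h;
    }

  // max divergence in clearly-fluid cells
  double div_max = 0.0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int c = ip(i, j, k);
        if (solid_frac[c] > 0.01) continue;
        double div = (u[iu(i + 1, j, k)] - u[iu(i, j, k)] +
                      v[iv(i, j + 1, k)] - v[iv(i, j, k)] +
                      w[iw(i, j, k + 1)] - w[iw(i, j, k)]) / h;
        if (std::fabs(div) > div_max) div_max = std::fabs(div);
      }

  // energy: viscous dissipation ~ mu * |grad u|^2 (all cells; solid interiors
  // contribute ~0), Brinkman/penalization dissipation, and direct-forcing
  // sheet power (momentum-residual force at forced faces times face velocity)
  double phi_visc = 0.0, phi_brink = 0.0, phi_pen = 0.0, power_sheets = 0.0;
  const double vol = h * h * h;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        // gradients of u at u-face (i,j,k)
        int a = iu(i, j, k);
        double uc = u[a];
        double gx = (u[iu(i + 1, j, k)] - u[iu(i - 1, j, k)]) / (2 * h);
        double gy = ((j < ny - 1 ? u[iu(i, j + 1, k)] : uc) -
                     (j > 0 ? u[iu(i, j - 1, k)] : uc)) / (2 * h);
        double gz = ((k < nz - 1 ? u[iu(i, j, k + 1)] : uc) -
                     (k > 0 ? u[iu(i, j, k - 1)] : uc)) / (2 * h);
        phi_visc += (gx * gx + gy * gy + gz * gz) * vol;
        int av = iv(i, j, k);
        double vc = v[av];
        gx = (v[iv(i + 1, j, k)] - v[iv(i - 1, j, k)]) / (2 * h);
        gy = (v[iv(i, j + 1, k)] - (j > 0 ? v[iv(i, j - 1, k)] : v[av])) /
             ((j > 0 ? 2 : 1) * h);
        gz = ((k < nz - 1 ? v[iv(i, j, k + 1)] : vc) -
              (k > 0 ? v[iv(i, j, k - 1)] : vc)) / (2 * h);
        phi_visc += (gx * gx + gy * gy + gz * gz) * vol;
        int aw = iw(i, j, k);
        double wc = w[aw];
        gx = (w[iw(i + 1, j, k)] - w[iw(i - 1, j, k)]) / (2 * h);
        gy = ((j < ny - 1 ? w[iw(i, j + 1, k)] : wc) -
              (j > 0 ? w[iw(i, j - 1, k)] : wc)) / (2 * h);
        gz = (w[iw(i, j, k + 1)] - w[iw(i, j, k)]) / h;
        phi_visc += (gx * gx + gy * gy + gz * gz) * vol;

        int c = ip(i, j, k);
        double uavg = 0.5 * (u[iu(i, j, k)] + u[iu(i + 1, j, k)]);
        double vavg = 0.5 * (v[iv(i, j, k)] + v[iv(i, j + 1, k)]);
        double wavg = 0.5 * (w[iw(i, j, k)] + w[iw(i, j, k + 1)]);
        double q2 = uavg * uavg + vavg * vavg + wavg * wavg;
        phi_brink += brinkman[c] * q2 * vol;
        phi_pen += alpha_pen * solid_frac[c] * q2 * vol;
      }
  for (int a = 0; a < nu; ++a)
    if (bu[a] > 0) phi_brink += bu[a] * u[a] * u[a] * vol;
  for (int a = 0; a < nw; ++a)
    if (bw[a] > 0) phi_brink += bw[a] * w[a] * w[a] * vol;
  phi_visc *= mu;

  // sheet power: work done by the penalization force on the fluid, and the
  // residual slip of fully covered sheet faces (no-slip quality diagnostic)
  double slip_max = 0.0;
  for (int a = 0; a < nu; ++a)
    if (asu[a] > 0) {
      power_sheets += asu[a] * (fuv[a] - u[a]) * u[a] * vol;
      if (asu[a] >= 0.99 * alpha_sheet) {
        double s = std::fabs(fuv[a] - u[a]);
        if (s > slip_max) slip_max = s;
      }
    }
  for (int a = 0; a < nv; ++a)
    if (asv[a] > 0) power_sheets += asv[a] * (0.0 - v[a]) * v[a] * vol;
  for (int a = 0; a < nw; ++a)
    if (asw[a] > 0) power_sheets += asw[a] * (fwv[a] - w[a]) * w[a] * vol;

  return List::create(
    _["u"] = NumericVector(u.begin(), u.end()),
    _["v"] = NumericVector(v.begin(), v.end()),
    _["w"] = NumericVector(w.begin(), w.end()),
    _["p"] = NumericVector(p.begin(), p.end()),
    _["iterations"] = iter,
    _["residual"] = res,
    _["div_max"] = div_max,
    _["q_in"] = q_in,
    _["q_top"] = q_top,
    _["phi_visc"] = phi_visc,
    _["phi_brink"] = phi_brink,
    _["phi_pen"] = phi_pen,
    _["power_sheets"] = power_sheets,
    _["slip_max"] = slip_max,
    _["u_scale"] = u_scale,
    _["converged"] = std::isfinite(res) && res < tol
  );
}

// Trilinear interpolation of one staggered component onto arbitrary points,
// used by the tracer advection. Grid origin of each component differs.
static double interp_comp(const std::vector<double> &f, int nx, int nyf, int nzf,
                          double ox, double oy, double oz, double h,
                          double x, double y, double z, int ny_dom, int nz_dom,
                          bool periodic_x) {
  double gx = (x - ox) / h, gy = (y - oy) / h, gz = (z - oz) / h;
  int i0 = (int)std::floor(gx), j0 = (int)std::floor(gy), k0 = (int)std::floor(gz);
  double fx = gx - i0, fy = gy - j0, fz = gz - k0;
  double val = 0.0;
  for (int dk = 0; dk <= 1; ++dk)
    for (int dj = 0; dj <= 1; ++dj)
      for (int di = 0; di <= 1; ++di) {
        int i = i0 + di, j = j0 + dj, k = k0 + dk;
        if (periodic_x) i = wrap(i, nx); else i = std::min(std::max(i, 0), nx - 1);
        j = std::min(std::max(j, 0), nyf - 1);
        k = std::min(std::max(k, 0), nzf - 1);
        double wgt = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) * (dk ? fz : 1 - fz);
        val += wgt * f[(size_t)i + nx * ((size_t)j + (size_t)nyf * k)];
      }
  return val;
}

// [[Rcpp::export]]
List advect_tracers_kernel(NumericMatrix pos0, List u_phases, List v_phases,
                           List w_phases, int nx, int ny, int nz, double h,
                           double period, double dt, double t_max,
                           NumericVector capture_centres_x,
                           NumericVector capture_centres_z,
                           double capture_r, double capture_y0,
                           double capture_y1, double top_y,
                           double floor_y) {
  const int np = pos0.nrow();
  const int nph = u_phases.size();
  std::vector<std::vector<double>> U(nph), V(nph), W(nph);
  for (int q = 0; q < nph; ++q) {
    NumericVector uu = u_phases[q], vv = v_phases[q], ww = w_phases[q];
    U[q].assign(uu.begin(), uu.end());
    V[q].assign(vv.begin(), vv.end());
    W[q].assign(ww.begin(), ww.end());
  }
  const double Lx = nx * h, Lz = nz * h;
  const int nc = capture_centres_x.size();

  std::vector<double> px(np), py(np), pz(np);
  std::vector<int> fate(np, 0);  // 0 active, 1 captured, 2 exited, 3 lost
  std::vector<double> t_fate(np, NA_REAL);
  for (int q = 0; q < np; ++q) {
    px[q] = pos0(q, 0); py[q] = pos0(q, 1); pz[q] = pos0(q, 2);
  }

  auto velocity = [&](double x, double y, double z, double t,
                      double &vx, double &vy, double &vz) {
    double tp = t / period;
    double ph = (tp - std::floor(tp)) * nph;  // avoid fmod: glibc-version portability
    int q0 = (int)std::floor(ph) % nph;
    int q1 = (q0 + 1) % nph;
    double fq = ph - std::floor(ph);
    // staggered origins: u at (0, h/2, h/2); v at (h/2, 0, h/2); w at (h/2, h/2, 0)
    double vx0 = interp_comp(U[q0], nx, ny, nz, 0.0, h / 2, h / 2, h, x, y, z, ny, nz, true);
    double vx1 = interp_comp(U[q1], nx, ny, nz, 0.0, h / 2, h / 2, h, x, y, z, ny, nz, true);
    double vy0 = interp_comp(V[q0], nx, ny + 1, nz, h / 2, 0.0, h / 2, h, x, y, z, ny, nz, true);
    double vy1 = interp_comp(V[q1], nx, ny + 1, nz, h / 2, 0.0, h / 2, h, x, y, z, ny, nz, true);
    double vz0 = interp_comp(W[q0], nx, ny, nz + 1, h / 2, h / 2, 0.0, h, x, y, z, ny, nz, true);
    double vz1 = interp_comp(W[q1], nx, ny, nz + 1, h / 2, h / 2, 0.0, h, x, y, z, ny, nz, true);
    vx = (1 - fq) * vx0 + fq * vx1;
    vy = (1 - fq) * vy0 + fq * vy1;
    vz = (1 - fq) * vz0 + fq * vz1;
  };

  const int nstep = (int)std::ceil(t_max / dt);
  for (int s = 0; s < nstep; ++s) {
    double t = s * dt;
    bool any_active = false;
    for (int q = 0; q < np; ++q) {
      if (fate[q] != 0) continue;
      any_active = true;
      double x = px[q], y = py[q], z = pz[q];
      double k1x, k1y, k1z, k2x, k2y, k2z, k3x, k3y, k3z, k4x, k4y, k4z;
      velocity(x, y, z, t, k1x, k1y, k1z);
      velocity(x + 0.5 * dt * k1x, y + 0.5 * dt * k1y, z + 0.5 * dt * k1z,
               t + 0.5 * dt, k2x, k2y, k2z);
      velocity(x + 0.5 * dt * k2x, y + 0.5 * dt * k2y, z + 0.5 * dt * k2z,
               t + 0.5 * dt, k3x, k3y, k3z);
      velocity(x + dt * k3x, y + dt * k3y, z + dt * k3z, t + dt, k4x, k4y, k4z);
      x += dt / 6.0 * (k1x + 2 * k2x + 2 * k3x + k4x);
      y += dt / 6.0 * (k1y + 2 * k2y + 2 * k3y + k4y);
      z += dt / 6.0 * (k1z + 2 * k2z + 2 * k3z + k4z);
      // periodic x, reflective z (symmetry planes)
      x -= Lx * std::floor(x / Lx);  // periodic wrap
      if (z < 0) z = -z;
      if (z > Lz) z = 2 * Lz - z;
      px[q] = x; py[q] = y; pz[q] = z;
      if (y >= top_y) { fate[q] = 2; t_fate[q] = t + dt; continue; }
      if (y < floor_y - 0.5 * h) { fate[q] = 3; t_fate[q] = t + dt; continue; }
      // capture: within capture_r of a collar axis at collar heights
      if (y >= capture_y0 && y <= capture_y1) {
        for (int c = 0; c < nc; ++c) {
          double dx = x - capture_centres_x[c], dz = z - capture_centres_z[c];
          if (dx * dx + dz * dz <= capture_r * capture_r) {
            fate[q] = 1; t_fate[q] = t + dt; break;
          }
        }
      }
    }
    if (!any_active) break;
  }

  return List::create(
    _["x"] = NumericVector(px.begin(), px.end()),
    _["y"] = NumericVector(py.begin(), py.end()),
    _["z"] = NumericVector(pz.begin(), pz.end()),
    _["fate"] = IntegerVector(fate.begin(), fate.end()),
    _["t_fate"] = NumericVector(t_fate.begin(), t_fate.end())
  );
}
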