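#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Staggered (MAC) grid layout, 0-based:
//   u: (nx+1) x ny x nz   face-normal x velocity
//   v: nx x (ny+1) x nz   face-normal y velocity
//   w: nx x ny x (nz+1)   face-normal z velocity
//   cell arrays: nx x ny x nz
// Boundary conditions live on the x-min / x-max walls only (type per (j,k):
// 0 = no-slip wall, 1 = open / fixed pressure, 2 = prescribed normal
// velocity); y and z extremes are always no-slip walls. In 2D mode (nz = 1)
// the z walls are free-slip and w is identically zero.

static inline int IU(int i, int j, int k, int nx, int ny) {
  return i + (nx + 1) * (j + ny * k);
}
static inline int IV(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + (ny + 1) * k);
}
static inline int IW(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}
static inline int IC(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// ghost value for a tangential velocity beyond a wall: no-slip -> -val,
// free-slip -> +val
static inline double ghost(double val, bool noslip) {
  return noslip ? -val : val;
}

// [[Rcpp::export(name = ".mac_momentum_rhs")]]
List mac_momentum_rhs(NumericVector u, NumericVector v, NumericVector w,
                      int nx, int ny, int nz,
                      double dx, double dy, double dz, double dt,
                      double nu, NumericVector cdrag,
                      NumericVector Xu, NumericVector Yv,
                      double omega2, double theta, double gz,
                      bool upwind, bool two_d,
                      IntegerVector bct_xmin, NumericVector bcu_xmin,
                      IntegerVector bct_xmax, NumericVector bcu_xmax) {
  NumericVector us(clone(u)), vs(clone(v)), ws(clone(w));
  const double idx2 = 1.0 / (dx * dx), idy2 = 1.0 / (dy * dy),
               idz2 = (nz > 1) ? 1.0 / (dz * dz) : 0.0;

  // ---- u faces (interior i = 1..nx-1) ----
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 1; i < nx; ++i) {
        const double ue = u[IU(i, j, k, nx, ny)];
        const double um = u[IU(i - 1, j, k, nx, ny)];
        const double up = u[IU(i + 1, j, k, nx, ny)];
        const double ujm = (j > 0) ? u[IU(i, j - 1, k, nx, ny)] : ghost(ue, true);
        const double ujp = (j < ny - 1) ? u[IU(i, j + 1, k, nx, ny)] : ghost(ue, true);
        const double ukm = (nz == 1) ? ue
          : ((k > 0) ? u[IU(i, j, k - 1, nx, ny)] : ghost(ue, !two_d));
        const double ukp = (nz == 1) ? ue
          : ((k < nz - 1) ? u[IU(i, j, k + 1, nx, ny)] : ghost(ue, !two_d));
        const double vbar = 0.25 * (v[IV(i - 1, j, k, nx, ny)] + v[IV(i, j, k, nx, ny)] +
                                    v[IV(i - 1, j + 1, k, nx, ny)] + v[IV(i, j + 1, k, nx, ny)]);
        const double wbar = (nz == 1) ? 0.0
          : 0.25 * (w[IW(i - 1, j, k, nx, ny)] + w[IW(i, j, k, nx, ny)] +
                    w[IW(i - 1, j, k + 1, nx, ny)] + w[IW(i, j, k + 1, nx, ny)]);
        double adv;
        if (upwind) {
          const double dudx = (ue > 0) ? (ue - um) / dx : (up - ue) / dx;
          const double dudy = (vbar > 0) ? (ue - ujm) / dy : (ujp - ue) / dy;
          const double dudz = (nz == 1) ? 0.0
            : ((wbar > 0) ? (ue - ukm) / dz : (ukp - ue) / dz);
          adv = -(ue * dudx + vbar * dudy + wbar * dudz);
        } else {
          adv = -(ue * (up - um) / (2 * dx) + vbar * (ujp - ujm) / (2 * dy) +
                  ((nz == 1) ? 0.0 : wbar * (ukp - ukm) / (2 * dz)));
        }
        const double lap = (up - 2 * ue + um) * idx2 + (ujp - 2 * ue + ujm) * idy2 +
                           ((nz == 1) ? 0.0 : (ukp - 2 * ue + ukm) * idz2);
        const double fx = omega2 * Xu[i];
        const double cf = 0.5 * (cdrag[IC(i - 1, j, k, nx, ny)] + cdrag[IC(i, j, k, nx, ny)]);
        us[IU(i, j, k, nx, ny)] = (ue + dt * (adv + nu * lap + fx)) / (1.0 + dt * cf);
      }

  // boundary u faces: walls -> 0, prescribed -> value, open -> momentum
  // update with a zero-gradient ghost outside the domain
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      const int jk = j + ny * k;
      for (int side = 0; side < 2; ++side) {
        const int bt = (side == 0) ? bct_xmin[jk] : bct_xmax[jk];
        const int i = (side == 0) ? 0 : nx;
        const int id = IU(i, j, k, nx, ny);
        if (bt == 0) { us[id] = 0.0; continue; }
        if (bt == 2) { us[id] = (side == 0) ? bcu_xmin[jk] : bcu_xmax[jk]; continue; }
        const int ic = (side == 0) ? 0 : nx - 1;   // adjacent interior cell
        const double ue = u[id];
        const double um = (side == 0) ? ue : u[IU(nx - 1, j, k, nx, ny)];
        const double up = (side == 0) ? u[IU(1, j, k, nx, ny)] : ue;
        const double ujm = (j > 0) ? u[IU(i, j - 1, k, nx, ny)] : ghost(ue, true);
        const double ujp = (j < ny - 1) ? u[IU(i, j + 1, k, nx, ny)] : ghost(ue, true);
        const double ukm = (nz == 1) ? ue
          : ((k > 0) ? u[IU(i, j, k - 1, nx, ny)] : ghost(ue, !two_d));
        const double ukp = (nz == 1) ? ue
          : ((k < nz - 1) ? u[IU(i, j, k + 1, nx, ny)] : ghost(ue, !two_d));
        const double vbar = 0.5 * (v[IV(ic, j, k, nx, ny)] + v[IV(ic, j + 1, k, nx, ny)]);
        const double wbar = (nz == 1) ? 0.0
          : 0.5 * (w[IW(ic, j, k, nx, ny)] + w[IW(ic, j, k + 1, nx, ny)]);
        double adv;
        if (upwind) {
          const double dudx = (ue > 0) ? (ue - um) / dx : (up - ue) / dx;
          const double dudy = (vbar > 0) ? (ue - ujm) / dy : (ujp - ue) / dy;
          const double dudz = (nz == 1) ? 0.0
            : ((wbar > 0) ? (ue - ukm) / dz : (ukp - ue) / dz);
          adv = -(ue * dudx + vbar * dudy + wbar * dudz);
        } else {
          adv = -(ue * (up - um) / (2 * dx) + vbar * (ujp - ujm) / (2 * dy) +
                  ((nz == 1) ? 0.0 : wbar * (ukp - ukm) / (2 * dz)));
        }
        const double lap = (up - 2 * ue + um) * idx2 + (ujp - 2 * ue + ujm) * idy2 +
                           ((nz == 1) ? 0.0 : (ukp - 2 * ue + ukm) * idz2);
        const double fx = omega2 * Xu[i];
        const double cf = cdrag[IC(ic, j, k, nx, ny)];
        us[id] = (ue + dt * (adv + nu * lap + fx)) / (1.0 + dt * cf);
      }
    }

  // ---- v faces (interior j = 1..ny-1) ----
  for (int k = 0; k < nz; ++k)
    for (int j = 1; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const double ve = v[IV(i, j, k, nx, ny)];
        const int jk_m = j - 1 + ny * k, jk_c = j + ny * k; // bc rows for adjacent cells
        const double vim = (i > 0) ? v[IV(i - 1, j, k, nx, ny)]
          : ((bct_xmin[jk_m] == 0 || bct_xmin[jk_c] == 0) ? ghost(ve, true) : ve);
        const double vip = (i < nx - 1) ? v[IV(i + 1, j, k, nx, ny)]
          : ((bct_xmax[jk_m] == 0 || bct_xmax[jk_c] == 0) ? ghost(ve, true) : ve);
        const double vjm = v[IV(i, j - 1, k, nx, ny)];
        const double vjp = v[IV(i, j + 1, k, nx, ny)];
        const double vkm = (nz == 1) ? ve
          : ((k > 0) ? v[IV(i, j, k - 1, nx, ny)] : ghost(ve, !two_d));
        const double vkp = (nz == 1) ? ve
          : ((k < nz - 1) ? v[IV(i, j, k + 1, nx, ny)] : ghost(ve, !two_d));
        const double ubar = 0.25 * (u[IU(i, j - 1, k, nx, ny)] + u[IU(i + 1, j - 1, k, nx, ny)] +
                                    u[IU(i, j, k, nx, ny)] + u[IU(i + 1, j, k, nx, ny)]);
        const double wbar = (nz == 1) ? 0.0
          : 0.25 * (w[IW(i, j - 1, k, nx, ny)] + w[IW(i, j - 1, k + 1, nx, ny)] +
                    w[IW(i, j, k, nx, ny)] + w[IW(i, j, k + 1, nx, ny)]);
        double adv;
        if (upwind) {
          const double dvdx = (ubar > 0) ? (ve - vim) / dx : (vip - ve) / dx;
          const double dvdy = (ve > 0) ? (ve - vjm) / dy : (vjp - ve) / dy;
          const double dvdz = (nz == 1) ? 0.0
            : ((wbar > 0) ? (ve - vkm) / dz : (vkp - ve) / dz);
          adv = -(ubar * dvdx + ve * dvdy + wbar * dvdz);
        } else {
          adv = -(ubar * (vip - vim) / (2 * dx) + ve * (vjp - vjm) / (2 * dy) +
                  ((nz == 1) ? 0.0 : wbar * (vkp - vkm) / (2 * dz)));
        }
        const double lap = (vip - 2 * ve + vim) * idx2 + (vjp - 2 * ve + vjm) * idy2 +
                           ((nz == 1) ? 0.0 : (vkp - 2 * ve + vkm) * idz2);
        const double fy = omega2 * Yv[j];
        const double cf = 0.5 * (cdrag[IC(i, j - 1, k, nx, ny)] + cdrag[IC(i, j, k, nx, ny)]);
        vs[IV(i, j, k, nx, ny)] = (ve + dt * (adv + nu * lap + fy)) / (1.0 + dt * cf);
      }
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      vs[IV(i, 0, k, nx, ny)] = 0.0;
      vs[IV(i, ny, k, nx, ny)] = 0.0;
    }

  // ---- w faces (interior k = 1..nz-1; absent in 2D) ----
  if (nz > 1) {
    for (int k = 1; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          const double we = w[IW(i, j, k, nx, ny)];
          const int jk_c = j + ny * k, jk_m = j + ny * (k - 1);
          const double wim = (i > 0) ? w[IW(i - 1, j, k, nx, ny)]
            : ((bct_xmin[jk_c] == 0 || bct_xmin[jk_m] == 0) ? ghost(we, true) : we);
          const double wip = (i < nx - 1) ? w[IW(i + 1, j, k, nx, ny)]
            : ((bct_xmax[jk_c] == 0 || bct_xmax[jk_m] == 0) ? ghost(we, true) : we);
          const double wjm = (j > 0) ? w[IW(i, j - 1, k, nx, ny)] : ghost(we, true);
          const double wjp = (j < ny - 1) ? w[IW(i, j + 1, k, nx, ny)] : ghost(we, true);
          const double wkm = w[IW(i, j, k - 1, nx, ny)];
          const double wkp = w[IW(i, j, k + 1, nx, ny)];
          const double ubar = 0.25 * (u[IU(i, j, k - 1, nx, ny)] + u[IU(i + 1, j, k - 1, nx, ny)] +
                                      u[IU(i, j, k, nx, ny)] + u[IU(i + 1, j, k, nx, ny)]);
          const double vbar = 0.25 * (v[IV(i, j, k - 1, nx, ny)] + v[IV(i, j + 1, k - 1, nx, ny)] +
                                      v[IV(i, j, k, nx, ny)] + v[IV(i, j + 1, k, nx, ny)]);
          double adv;
          if (upwind) {
            const double dwdx = (ubar > 0) ? (we - wim) / dx : (wip - we) / dx;
            const double dwdy = (vbar > 0) ? (we - wjm) / dy : (wjp - we) / dy;
            const double dwdz = (we > 0) ? (we - wkm) / dz : (wkp - we) / dz;
            adv = -(ubar * dwdx + vbar * dwdy + we * dwdz);
          } else {
            adv = -(ubar * (wip - wim) / (2 * dx) + vbar * (wjp - wjm) / (2 * dy) +
                    we * (wkp - wkm) / (2 * dz));
          }
          const double lap = (wip - 2 * we + wim) * idx2 + (wjp - 2 * we + wjm) * idy2 +
                             (wkp - 2 * we + wkm) * idz2;
          const double cf = 0.5 * (cdrag[IC(i, j, k - 1, nx, ny)] + cdrag[IC(i, j, k, nx, ny)]);
          ws[IW(i, j, k, nx, ny)] = (we + dt * (adv + nu * lap + gz)) / (1.0 + dt * cf);
        }
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        ws[IW(i, j, 0, nx, ny)] = 0.0;
        ws[IW(i, j, nz, nx, ny)] = 0.0;
      }
  }

  // ---- Coriolis: exact split-step rotation of the horizontal components ----
  // du/dt = a v, dv/dt = -a u (a = 2 Omega_z) integrated exactly over dt,
  // using interpolated opposite components; |G| <= 1 for any dt.
  if (theta != 0.0) {
    const double ct = std::cos(theta), stn = std::sin(theta);
    NumericVector ur(clone(us)), vr(clone(vs));
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 1; i < nx; ++i) {
          const double vbar = 0.25 * (vr[IV(i - 1, j, k, nx, ny)] + vr[IV(i, j, k, nx, ny)] +
                                      vr[IV(i - 1, j + 1, k, nx, ny)] + vr[IV(i, j + 1, k, nx, ny)]);
          us[IU(i, j, k, nx, ny)] = ct * ur[IU(i, j, k, nx, ny)] + stn * vbar;
        }
    for (int k = 0; k < nz; ++k)
      for (int j = 1; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          const double ubar = 0.25 * (ur[IU(i, j - 1, k, nx, ny)] + ur[IU(i + 1, j - 1, k, nx, ny)] +
                                      ur[IU(i, j, k, nx, ny)] + ur[IU(i + 1, j, k, nx, ny)]);
          vs[IV(i, j, k, nx, ny)] = ct * vr[IV(i, j, k, nx, ny)] - stn * ubar;
        }
  }

  // ---- divergence of the provisional field ----
  NumericVector div(nx * ny * nz);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double d = (us[IU(i + 1, j, k, nx, ny)] - us[IU(i, j, k, nx, ny)]) / dx +
                   (vs[IV(i, j + 1, k, nx, ny)] - vs[IV(i, j, k, nx, ny)]) / dy;
        if (nz > 1)
          d += (ws[IW(i, j, k + 1, nx, ny)] - ws[IW(i, j, k, nx, ny)]) / dz;
        div[IC(i, j, k, nx, ny)] = d;
      }

  return List::create(_["us"] = us, _["vs"] = vs, _["ws"] = ws, _["div"] = div);
}

// Applies the pressure correction u = u* - T * grad(phi) (phi = p*dt/rho,
// T = 1/(1 + dt*c_face)) and reports convergence statistics against the
// previous field.
// [[Rcpp::export(name = ".mac_project")]]
NumericVector mac_project(NumericVector us, NumericVector vs, NumericVector ws,
                          NumericVector uo, NumericVector vo, NumericVector wo,
                          NumericVector phi,
                          int nx, int ny, int nz,
                          double dx, double dy, double dz, double dt,
                          NumericVector cdrag,
                          IntegerVector bct_xmin, NumericVector bcp_xmin,
                          IntegerVector bct_xmax, NumericVector bcp_xmax) {
  double maxdiff = 0.0, maxu = 0.0, maxdiv = 0.0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 1; i < nx; ++i) {
        const double cf = 0.5 * (cdrag[IC(i - 1, j, k, nx, ny)] + cdrag[IC(i, j, k, nx, ny)]);
        const double T = 1.0 / (1.0 + dt * cf);
        const int id = IU(i, j, k, nx, ny);
        us[id] -= T * (phi[IC(i, j, k, nx, ny)] - phi[IC(i - 1, j, k, nx, ny)]) / dx;
      }
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      const int jk = j + ny * k;
      if (bct_xmin[jk] == 1) {
        const int id = IU(0, j, k, nx, ny);
        const double T = 1.0 / (1.0 + dt * cdrag[IC(0, j, k, nx, ny)]);
        us[id] -= T * 2.0 * (phi[IC(0, j, k, nx, ny)] - bcp_xmin[jk]) / dx;
      }
      if (bct_xmax[jk] == 1) {
        const int id = IU(nx, j, k, nx, ny);
        const double T = 1.0 / (1.0 + dt * cdrag[IC(nx - 1, j, k, nx, ny)]);
        us[id] -= T * 2.0 * (bcp_xmax[jk] - phi[IC(nx - 1, j, k, nx, ny)]) / dx;
      }
    }
  for (int k = 0; k < nz; ++k)
    for (int j = 1; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const double cf = 0.5 * (cdrag[IC(i, j - 1, k, nx, ny)] + cdrag[IC(i, j, k, nx, ny)]);
        const double T = 1.0 / (1.0 + dt * cf);
        vs[IV(i, j, k, nx, ny)] -=
          T * (phi[IC(i, j, k, nx, ny)] - phi[IC(i, j - 1, k, nx, ny)]) / dy;
      }
  if (nz > 1)
    for (int k = 1; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          const double cf = 0.5 * (cdrag[IC(i, j, k - 1, nx, ny)] + cdrag[IC(i, j, k, nx, ny)]);
          const double T = 1.0 / (1.0 + dt * cf);
          ws[IW(i, j, k, nx, ny)] -=
            T * (phi[IC(i, j, k, nx, ny)] - phi[IC(i, j, k - 1, nx, ny)]) / dz;
        }

  for (int n = 0; n < us.size(); ++n) {
    const double d = std::fabs(us[n] - uo[n]);
    if (d > maxdiff) maxdiff = d;
    if (std::fabs(us[n]) > maxu) maxu = std::fabs(us[n]);
  }
  for (int n = 0; n < vs.size(); ++n) {
    const double d = std::fabs(vs[n] - vo[n]);
    if (d > maxdiff) maxdiff = d;
    if (std::fabs(vs[n]) > maxu) maxu = std::fabs(vs[n]);
  }
  if (nz > 1)
    for (int n = 0; n < ws.size(); ++n) {
      const double d = std::fabs(ws[n] - wo[n]);
      if (d > maxdiff) maxdiff = d;
      if (std::fabs(ws[n]) > maxu) maxu = std::fabs(ws[n]);
    }
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double d = (us[IU(i + 1, j, k, nx, ny)] - us[IU(i, j, k, nx, ny)]) / dx +
                   (vs[IV(i, j + 1, k, nx, ny)] - vs[IV(i, j, k, nx, ny)]) / dy;
        if (nz > 1)
          d += (ws[IW(i, j, k + 1, nx, ny)] - ws[IW(i, j, k, nx, ny)]) / dz;
        if (std::fabs(d) > maxdiv) maxdiv = std::fabs(d);
      }
  return NumericVector::create(maxdiff, maxu, maxdiv);
}

static double interp_comp(const NumericVector &f, double x, double y, double z,
                          int n0, int n1, int n2,
                          double ox, double oy, double oz,
                          double dx, double dy, double dz) {
  // component grid with n0 x n1 x n2 nodes at offsets (ox,oy,oz) in units of
  // cell spacing; clamped trilinear interpolation
  double gx = x / dx - ox, gy = y / dy - oy, gz = z / dz - oz;
  if (gx < 0) gx = 0; if (gx > n0 - 1) gx = n0 - 1;
  if (gy < 0) gy = 0; if (gy > n1 - 1) gy = n1 - 1;
  if (gz < 0) gz = 0; if (gz > n2 - 1) gz = n2 - 1;
  int i0 = (int)gx, j0 = (int)gy, k0 = (int)gz;
  if (i0 > n0 - 2) i0 = n0 - 2; if (i0 < 0) i0 = 0;
  if (j0 > n1 - 2) j0 = n1 - 2; if (j0 < 0) j0 = 0;
  if (k0 > n2 - 2) k0 = n2 - 2; if (k0 < 0) k0 = 0;
  if (n0 == 1) i0 = 0; if (n1 == 1) j0 = 0; if (n2 == 1) k0 = 0;
  const double fx = (n0 == 1) ? 0 : gx - i0, fy = (n1 == 1) ? 0 : gy - j0,
               fz = (n2 == 1) ? 0 : gz - k0;
  const int i1 = (n0 == 1) ? 0 : i0 + 1, j1 = (n1 == 1) ? 0 : j0 + 1,
            k1 = (n2 == 1) ? 0 : k0 + 1;
  auto at = [&](int a, int b, int c) { return f[a + n0 * (b + n1 * c)]; };
  const double c00 = at(i0, j0, k0) * (1 - fx) + at(i1, j0, k0) * fx;
  const double c10 = at(i0, j1, k0) * (1 - fx) + at(i1, j1, k0) * fx;
  const double c01 = at(i0, j0, k1) * (1 - fx) + at(i1, j0, k1) * fx;
  const double c11 = at(i0, j1, k1) * (1 - fx) + at(i1, j1, k1) * fx;
  return (c00 * (1 - fy) + c10 * fy) * (1 - fz) + (c01 * (1 - fy) + c11 * fy) * fz;
}

// Massless tracer advection with fixed-arclength midpoint steps. Tracers are
// released at given seed positions; integration stops when a tracer crosses
// the x-min wall inside the outlet window (status 1), inside the inlet
// window (status 2), or when the step cap is reached / velocity vanishes
// (status 0). 'far' records whether the tracer ever entered x > x_far.
// [[Rcpp::export(name = ".advect_tracers")]]
List advect_tracers(NumericVector u, NumericVector v, NumericVector w,
                    int nx, int ny, int nz,
                    double dx, double dy, double dz,
                    NumericMatrix seeds, double x_far,
                    NumericVector outlet_box, NumericVector inlet_box,
                    bool outlet_on_xmax,
                    double ds, int max_steps, double vmin) {
  const double Lx = nx * dx, Ly = ny * dy, Lz = nz * dz;
  const int nt = seeds.nrow();
  IntegerVector status(nt);
  LogicalVector far(nt);
  auto vel = [&](double x, double y, double z, double *out) {
    out[0] = interp_comp(u, x, y, z, nx + 1, ny, nz, 0.0, 0.5, 0.5, dx, dy, dz);
    out[1] = interp_comp(v, x, y, z, nx, ny + 1, nz, 0.5, 0.0, 0.5, dx, dy, dz);
    out[2] = (nz == 1) ? 0.0
      : interp_comp(w, x, y, z, nx, ny, nz + 1, 0.5, 0.5, 0.0, dx, dy, dz);
  };
  for (int t = 0; t < nt; ++t) {
    double x = seeds(t, 0), y = seeds(t, 1), z = seeds(t, 2);
    int st = 0; bool wentfar = false;
    for (int s = 0; s < max_steps; ++s) {
      double v1[3];
      vel(x, y, z, v1);
      double sp = std::sqrt(v1[0] * v1[0] + v1[1] * v1[1] + v1[2] * v1[2]);
      if (sp < vmin) break;
      double dtt = ds / sp;
      double v2[3];
      vel(x + 0.5 * dtt * v1[0], y + 0.5 * dtt * v1[1], z + 0.5 * dtt * v1[2], v2);
      x += dtt * v2[0]; y += dtt * v2[1]; z += dtt * v2[2];
      if (x > x_far) wentfar = true;
      if (x <= 0.0) {
        if (!outlet_on_xmax &&
            y >= outlet_box[0] && y <= outlet_box[1] &&
            z >= outlet_box[2] && z <= outlet_box[3]) { st = 1; break; }
        if (y >= inlet_box[0] && y <= inlet_box[1] &&
            z >= inlet_box[2] && z <= inlet_box[3]) { st = 2; break; }
        x = 1e-6 * dx; // wall: push back inside
      }
      if (x >= Lx) {
        if (outlet_on_xmax &&
            y >= outlet_box[0] && y <= outlet_box[1] &&
            z >= outlet_box[2] && z <= outlet_box[3]) { st = 1; break; }
        x = Lx - 1e-6 * dx;
      }
      if (y <= 0.0) y = 1e-6 * dy;
      if (y >= Ly) y = Ly - 1e-6 * dy;
      if (z <= 0.0) z = 1e-6 * dz;
      if (z >= Lz) z = Lz - 1e-6 * dz;
    }
    status[t] = st;
    far[t] = wentfar;
  }
  return List::create(_["status"] = status, _["far"] = far);
}
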