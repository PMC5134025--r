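#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Staggered (MAC) layout, 0-based in this file:
//   cell (i,j), i = 0..nx-1, j = 0..ny-1; mask(i,j) = 1 fluid, 0 solid
//   u(i,j): x-velocity on vertical face i = 0..nx (west face of cell i)
//   v(i,j): y-velocity on horizontal face j = 0..ny (south face of cell j)
// Domain boundary faces are walls unless tagged inlet (left, u Dirichlet)
// or outlet (right, zero-gradient velocity, zero face pressure).

struct GridCtx {
  int nx, ny;
  const IntegerMatrix &mask;
  std::vector<char> inlet, outlet; // per row j
  GridCtx(const IntegerMatrix &m, const IntegerVector &inlet_j,
          const IntegerVector &outlet_j)
      : nx(m.nrow()), ny(m.ncol()), mask(m), inlet(m.ncol(), 0),
        outlet(m.ncol(), 0) {
    for (int k = 0; k < inlet_j.size(); ++k) inlet[inlet_j[k] - 1] = 1;
    for (int k = 0; k < outlet_j.size(); ++k) outlet[outlet_j[k] - 1] = 1;
  }
  bool fluid(int i, int j) const {
    return i >= 0 && i < nx && j >= 0 && j < ny && mask(i, j) == 1;
  }
  // u-face classification
  bool u_interior(int i, int j) const {
    return i >= 1 && i <= nx - 1 && fluid(i - 1, j) && fluid(i, j);
  }
  bool u_inlet(int i, int j) const {
    return i == 0 && j >= 0 && j < ny && inlet[j] && fluid(0, j);
  }
  bool u_outlet(int i, int j) const {
    return i == nx && j >= 0 && j < ny && outlet[j] && fluid(nx - 1, j);
  }
  bool u_live(int i, int j) const {
    return j >= 0 && j < ny &&
           (u_interior(i, j) || u_inlet(i, j) || u_outlet(i, j));
  }
  bool v_interior(int i, int j) const {
    return j >= 1 && j <= ny - 1 && fluid(i, j - 1) && fluid(i, j);
  }
  bool v_live(int i, int j) const { return v_interior(i, j); }
};

// value of u at face (i,j) for stencil use; ghosts get no-slip reflection
// about the wall plane next to the live face (ic,jc).
static inline double u_nb_y(const GridCtx &g, const NumericMatrix &u, int i,
                            int j, int ic, int jc) {
  if (g.u_live(i, j)) return u(i, j);
  return -u(ic, jc); // wall plane between rows jc and j
}
static inline double u_nb_x(const GridCtx &g, const NumericMatrix &u, int i,
                            int j) {
  if (g.u_live(i, j)) return u(i, j);
  return 0.0; // wall-normal face or embedded in solid
}
static inline double v_nb_x(const GridCtx &g, const NumericMatrix &v, int i,
                            int j, int ic, int jc) {
  if (g.v_live(i, j)) return v(i, j);
  if (i < 0 || i >= g.nx) {
    // domain left/right: inlet plug (v = 0) or outlet zero-gradient
    if (i < 0 && jc >= 1 && jc <= g.ny - 1 && g.inlet[jc] && g.inlet[jc - 1])
      return -v(ic, jc);
    if (i >= g.nx && jc >= 1 && jc <= g.ny - 1 && g.outlet[jc] &&
        g.outlet[jc - 1])
      return v(ic, jc);
  }
  return -v(ic, jc); // solid wall beside: reflect
}
static inline double v_nb_y(const GridCtx &g, const NumericMatrix &v, int i,
                            int j) {
  if (g.v_live(i, j)) return v(i, j);
  return 0.0;
}

static inline double face_avg(const NumericMatrix &c, const GridCtx &g, int i1,
                              int j1, int i2, int j2) {
  bool f1 = g.fluid(i1, j1), f2 = g.fluid(i2, j2);
  if (f1 && f2) return 0.5 * (c(i1, j1) + c(i2, j2));
  if (f1) return c(i1, j1);
  if (f2) return c(i2, j2);
  return 0.0;
}

// Preconditioned CG for the variable-coefficient pressure Poisson system.
// beta_e/w/n/s: face coefficients dt*eps_f/rho stored per cell; coefficient
// 0 closes the face (wall/inlet); outlet faces use a one-sided Dirichlet
// p = 0 at the face.
struct Poisson {
  const GridCtx &g;
  double dx2, dy2;
  std::vector<double> be, bw, bn, bs, bo; // bo: outlet one-sided coef
  std::vector<int> cells;                 // linear fluid cell ids i + nx*j
  std::vector<int> id;                    // cell -> slot (-1 solid)
  Poisson(const GridCtx &gg, double dx, double dy)
      : g(gg), dx2(dx * dx), dy2(dy * dy), id(gg.nx * gg.ny, -1) {
    for (int j = 0; j < g.ny; ++j)
      for (int i = 0; i < g.nx; ++i)
        if (g.fluid(i, j)) {
          id[i + g.nx * j] = cells.size();
          cells.push_back(i + g.nx * j);
        }
    size_t n = cells.size();
    be.assign(n, 0); bw.assign(n, 0); bn.assign(n, 0); bs.assign(n, 0);
    bo.assign(n, 0);
  }
  // flattened neighbor slots and matrix entries, built by finalize()
  std::vector<int> iE, iW, iN, iS;       // neighbor slot or -1
  std::vector<double> aE, aW, aN, aS, ad; // off-diagonals (negative), diag
  // neighbor slots point at a sentinel slot n (value forced to 0) when the
  // face is closed, so the inner loops are branch-free
  void finalize() {
    size_t n = cells.size();
    iE.assign(n, (int)n); iW.assign(n, (int)n);
    iN.assign(n, (int)n); iS.assign(n, (int)n);
    aE.assign(n, 0); aW.assign(n, 0); aN.assign(n, 0); aS.assign(n, 0);
    ad.assign(n, 0);
    for (size_t k = 0; k < n; ++k) {
      int c = cells[k];
      if (be[k] > 0) { iE[k] = id[c + 1]; aE[k] = -be[k] / dx2; }
      if (bw[k] > 0) { iW[k] = id[c - 1]; aW[k] = -bw[k] / dx2; }
      if (bn[k] > 0) { iN[k] = id[c + g.nx]; aN[k] = -bn[k] / dy2; }
      if (bs[k] > 0) { iS[k] = id[c - g.nx]; aS[k] = -bs[k] / dy2; }
      ad[k] = -(aE[k] + aW[k] + aN[k] + aS[k]) + 2.0 * bo[k] / dx2;
    }
  }
  void apply(const std::vector<double> &p, std::vector<double> &ap) const {
    size_t n = cells.size();
    for (size_t k = 0; k < n; ++k) {
      ap[k] = ad[k] * p[k] + aE[k] * p[iE[k]] + aW[k] * p[iW[k]] +
              aN[k] * p[iN[k]] + aS[k] * p[iS[k]];
    }
  }
  int solve(std::vector<double> &pout, const std::vector<double> &b,
            double tol, int maxit, bool pure_neumann, struct SolverCtx &S,
            double dt, const NumericMatrix &eps, double rho);
};

// Cached banded Cholesky factorization of the dt-independent Poisson
// operator (coefficients eps_face/rho), used as the CG preconditioner.
// Cells are ordered minor-dimension-first so the half bandwidth is
// min(nx, ny); solid cells carry identity rows to keep the band regular.
struct SolverCtx {
  int nx = -1, ny = -1, m = 0, N = 0;
  bool yminor = true, neumann = false;
  std::vector<double> Lb;   // band factor, row i holds L(i, i-m..i)
  std::vector<double> epsc; // eps snapshot at factorization
  std::vector<int> lin;     // fluid slot -> band index
  bool valid = false;

  int bidx(int i, int j) const { return yminor ? i * ny + j : j * nx + i; }

  bool stale(const GridCtx &g, const NumericMatrix &eps,
             bool pure_neumann) const {
    if (!valid || nx != g.nx || ny != g.ny || neumann != pure_neumann)
      return true;
    double drift = 0;
    for (int k = 0; k < N; ++k) {
      double d = std::fabs(eps[k] - epsc[k]);
      if (d > drift) drift = d;
    }
    return drift > 3e-3;
  }

  void factor(const GridCtx &g, const Poisson &P, const NumericMatrix &eps,
              double rho, double dx, double dy, bool pure_neumann) {
    nx = g.nx; ny = g.ny; N = nx * ny;
    yminor = (ny <= nx);
    m = yminor ? ny : nx;
    neumann = pure_neumann;
    epsc.assign(eps.begin(), eps.end());
    double dx2 = dx * dx, dy2 = dy * dy;
    std::vector<double> aD(N, 1.0), a1(N, 0.0), am(N, 0.0);
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        if (!g.fluid(i, j)) continue;
        int k = bidx(i, j);
        double d = 0;
        if (g.u_interior(i, j)) {
          double c = 0.5 * (eps(i - 1, j) + eps(i, j)) / (rho * dx2);
          d += c;
          (yminor ? am[k] : a1[k]) = -c; // coupling to (i-1, j)
        }
        if (g.u_interior(i + 1, j)) {
          d += 0.5 * (eps(i, j) + eps(i + 1, j)) / (rho * dx2);
        }
        if (g.v_interior(i, j)) {
          double c = 0.5 * (eps(i, j - 1) + eps(i, j)) / (rho * dy2);
          d += c;
          (yminor ? a1[k] : am[k]) = -c; // coupling to (i, j-1)
        }
        if (g.v_interior(i, j + 1)) {
          d += 0.5 * (eps(i, j) + eps(i, j + 1)) / (rho * dy2);
        }
        if (i == nx - 1 && g.u_outlet(nx, j)) {
          d += 2.0 * eps(i, j) / (rho * dx2);
        }
        aD[k] = d > 0 ? d : 1.0;
        if (pure_neumann) aD[k] *= 1.0 + 1e-8;
      }
    }
    // band Cholesky (full fill inside the band)
    int w = m + 1;
    Lb.assign((size_t)N * w, 0.0);
    std::vector<double> row(w);
    for (int i = 0; i < N; ++i) {
      for (int k = 0; k < w; ++k) row[k] = 0.0;
      row[m] = aD[i];
      if (m >= 1) row[m - 1] = a1[i];
      row[0] = am[i];
      int j0 = i - m < 0 ? 0 : i - m;
      for (int j = j0; j <= i; ++j) {
        int k = j - (i - m);
        double s = row[k];
        int l0 = j - m < j0 ? j0 : j - m;
        const double *Li = &Lb[(size_t)i * w];
        const double *Lj = &Lb[(size_t)j * w];
        for (int l = l0; l < j; ++l) {
          s -= Li[l - (i - m)] * Lj[l - (j - m)];
        }
        if (j < i) {
          Lb[(size_t)i * w + k] = s / Lj[m];
        } else {
          Lb[(size_t)i * w + m] = std::sqrt(s > 1e-300 ? s : 1e-300);
        }
      }
    }
    // map fluid slots to band indices
    lin.resize(P.cells.size());
    for (size_t k = 0; k < P.cells.size(); ++k) {
      int c = P.cells[k];
      lin[k] = bidx(c % nx, c / nx);
    }
    valid = true;
  }

  // solve (L L^T) z = r over the full band vector
  void bandsolve(std::vector<double> &x) const {
    int w = m + 1;
    for (int i = 0; i < N; ++i) {
      double s = x[i];
      const double *Li = &Lb[(size_t)i * w];
      int l0 = i - m < 0 ? 0 : i - m;
      for (int l = l0; l < i; ++l) s -= Li[l - (i - m)] * x[l];
      x[i] = s / Li[m];
    }
    for (int i = N; i-- > 0;) {
      double s = x[i];
      int j1 = i + m < N - 1 ? i + m : N - 1;
      for (int j = i + 1; j <= j1; ++j) {
        s -= Lb[(size_t)j * (m + 1) + (i - (j - m))] * x[j];
      }
      x[i] = s / Lb[(size_t)i * (m + 1) + m];
    }
  }
};

int Poisson::solve(std::vector<double> &pout, const std::vector<double> &b,
                   double tol, int maxit, bool pure_neumann, SolverCtx &S,
                   double dt, const NumericMatrix &eps, double rho) {
    finalize();
    size_t n = cells.size();
    if (S.stale(g, eps, pure_neumann)) {
      S.factor(g, *this, eps, rho, std::sqrt(dx2), std::sqrt(dy2),
               pure_neumann);
    }
    // n+1 sized work vectors: slot n is a zero sentinel for closed faces
    std::vector<double> p(n + 1, 0.0), r(n), z(n + 1, 0.0), d(n + 1, 0.0),
        ap(n), full((size_t)S.N, 0.0);
    for (size_t k = 0; k < n; ++k) p[k] = pout[k];
    // preconditioner: scatter to the band ordering, solve with the cached
    // factor of the dt-independent operator, rescale by 1/dt
    auto precond = [&](const std::vector<double> &rr, std::vector<double> &zz) {
      std::fill(full.begin(), full.end(), 0.0);
      for (size_t k = 0; k < n; ++k) full[S.lin[k]] = rr[k];
      S.bandsolve(full);
      for (size_t k = 0; k < n; ++k) zz[k] = full[S.lin[k]] / dt;
    };
    std::vector<double> bb(b);
    if (pure_neumann) {
      double m = 0;
      for (size_t k = 0; k < n; ++k) m += bb[k];
      m /= n;
      for (size_t k = 0; k < n; ++k) bb[k] -= m;
    }
    apply(p, ap);
    double bnorm = 0;
    for (size_t k = 0; k < n; ++k) {
      r[k] = bb[k] - ap[k];
      bnorm += bb[k] * bb[k];
    }
    bnorm = std::sqrt(bnorm);
    double atol = tol * (bnorm > 1e-300 ? bnorm : 1.0);
    precond(r, z);
    double rz = 0;
    for (size_t k = 0; k < n; ++k) {
      d[k] = z[k];
      rz += r[k] * z[k];
    }
    int it = 0;
    for (; it < maxit; ++it) {
      double rn = 0;
      for (size_t k = 0; k < n; ++k) rn += r[k] * r[k];
      if (std::sqrt(rn) <= atol) break;
      apply(d, ap);
      double dad = 0;
      for (size_t k = 0; k < n; ++k) dad += d[k] * ap[k];
      if (dad <= 0) break;
      double alpha = rz / dad;
      for (size_t k = 0; k < n; ++k) {
        p[k] += alpha * d[k];
        r[k] -= alpha * ap[k];
      }
      precond(r, z);
      double rz2 = 0;
      for (size_t k = 0; k < n; ++k) rz2 += r[k] * z[k];
      double betacg = rz2 / rz;
      rz = rz2;
      for (size_t k = 0; k < n; ++k) d[k] = z[k] + betacg * d[k];
    }
    if (pure_neumann) {
      double m = 0;
      for (size_t k = 0; k < n; ++k) m += p[k];
      m /= n;
      for (size_t k = 0; k < n; ++k) p[k] -= m;
    }
    for (size_t k = 0; k < n; ++k) pout[k] = p[k];
    return it;
}

// One fractional-step update of the momentum equations:
// explicit upwind-biased convection and variable-viscosity diffusion,
// pointwise-implicit Brinkman sink, pressure projection.
// [[Rcpp::export(name = ".step_flow_cpp")]]
List step_flow_cpp(NumericMatrix u0, NumericMatrix v0, NumericMatrix p0,
                   IntegerMatrix mask, NumericMatrix mu, NumericMatrix eps,
                   NumericMatrix sinkc, double dx, double dy, double dt,
                   double rho, IntegerVector inlet_j, IntegerVector outlet_j,
                   NumericVector u_inlet, double tol, int maxit,
                   Nullable<Environment> cache = R_NilValue) {
  // persistent preconditioner cache (per-grid environment)
  SolverCtx *S;
  SolverCtx local_ctx;
  if (cache.isNotNull()) {
    Environment e(cache.get());
    S = nullptr;
    if (e.exists(".solver_ptr")) {
      SEXP sp = e[".solver_ptr"];
      if (TYPEOF(sp) == EXTPTRSXP && R_ExternalPtrAddr(sp) != nullptr) {
        S = (SolverCtx *)R_ExternalPtrAddr(sp);
      }
    }
    if (S == nullptr) {
      XPtr<SolverCtx> xp(new SolverCtx(), true);
      e[".solver_ptr"] = xp;
      S = xp.get();
    }
  } else {
    S = &local_ctx;
  }
  GridCtx g(mask, inlet_j, outlet_j);
  int nx = g.nx, ny = g.ny;
  NumericMatrix u(clone(u0)), v(clone(v0)), p(clone(p0));

  // enforce boundary values on the working copies
  for (int j = 0; j < ny; ++j) {
    if (g.u_inlet(0, j)) u(0, j) = u_inlet[j];
    else u(0, j) = 0;
  }

  NumericMatrix us(nx + 1, ny), vs(nx, ny + 1);

  // u* : interior u faces
  for (int j = 0; j < ny; ++j) {
    for (int i = 1; i <= nx - 1; ++i) {
      if (!g.u_interior(i, j)) { us(i, j) = 0; continue; }
      double uc = u(i, j);
      double uE = u_nb_x(g, u, i + 1, j), uW = u_nb_x(g, u, i - 1, j);
      if (i - 1 == 0 && g.u_inlet(0, j)) uW = u(0, j);
      double uN = u_nb_y(g, u, i, j + 1, i, j);
      double uS = u_nb_y(g, u, i, j - 1, i, j);
      // cross velocity at the u face
      double vbar = 0.25 * (v_nb_y(g, v, i - 1, j) + v_nb_y(g, v, i - 1, j + 1) +
                            v_nb_y(g, v, i, j) + v_nb_y(g, v, i, j + 1));
      // convection, 2nd-order upwind with 1st-order fallback at boundaries
      double dudx;
      if (uc > 0) {
        bool ho = g.u_live(i - 1, j) && g.u_live(i - 2, j);
        dudx = ho ? (3 * uc - 4 * uW + u(i - 2, j)) / (2 * dx)
                  : (uc - uW) / dx;
      } else {
        bool ho = g.u_live(i + 1, j) && g.u_live(i + 2, j);
        dudx = ho ? (-3 * uc + 4 * uE - u(i + 2, j)) / (2 * dx)
                  : (uE - uc) / dx;
      }
      double dudy;
      if (vbar > 0) {
        bool ho = g.u_live(i, j - 1) && g.u_live(i, j - 2);
        dudy = ho ? (3 * uc - 4 * uS + u(i, j - 2)) / (2 * dy)
                  : (uc - uS) / dy;
      } else {
        bool ho = g.u_live(i, j + 1) && g.u_live(i, j + 2);
        dudy = ho ? (-3 * uc + 4 * uN - u(i, j + 2)) / (2 * dy)
                  : (uN - uc) / dy;
      }
      double conv = uc * dudx + vbar * dudy;
      // diffusion div(mu grad u); mu at cells for x, at corners for y
      double muE = g.fluid(i, j) ? mu(i, j) : 0;
      double muW = g.fluid(i - 1, j) ? mu(i - 1, j) : 0;
      double muN = 0.5 * (face_avg(mu, g, i - 1, j, i - 1, j + 1) +
                          face_avg(mu, g, i, j, i, j + 1));
      double muS = 0.5 * (face_avg(mu, g, i - 1, j, i - 1, j - 1) +
                          face_avg(mu, g, i, j, i, j - 1));
      double visc = (muE * (uE - uc) - muW * (uc - uW)) / (dx * dx) +
                    (muN * (uN - uc) - muS * (uc - uS)) / (dy * dy);
      double ef = 0.5 * (eps(i - 1, j) + eps(i, j));
      double sf = 0.5 * (sinkc(i - 1, j) + sinkc(i, j));
      double ustar = uc + dt * (ef / rho) * (-rho * conv + visc);
      us(i, j) = ustar / (1.0 + dt * ef * sf / rho);
    }
  }
  // v* : interior v faces
  for (int j = 1; j <= ny - 1; ++j) {
    for (int i = 0; i < nx; ++i) {
      if (!g.v_interior(i, j)) { vs(i, j) = 0; continue; }
      double vc = v(i, j);
      double vE = v_nb_x(g, v, i + 1, j, i, j);
      double vW = v_nb_x(g, v, i - 1, j, i, j);
      double vN = v_nb_y(g, v, i, j + 1), vS = v_nb_y(g, v, i, j - 1);
      double ubar = 0.25 * (u_nb_x(g, u, i, j - 1) + u_nb_x(g, u, i + 1, j - 1) +
                            u_nb_x(g, u, i, j) + u_nb_x(g, u, i + 1, j));
      double dvdx;
      if (ubar > 0) {
        bool ho = g.v_live(i - 1, j) && g.v_live(i - 2, j);
        dvdx = ho ? (3 * vc - 4 * vW + v(i - 2, j)) / (2 * dx)
                  : (vc - vW) / dx;
      } else {
        bool ho = g.v_live(i + 1, j) && g.v_live(i + 2, j);
        dvdx = ho ? (-3 * vc + 4 * vE - v(i + 2, j)) / (2 * dx)
                  : (vE - vc) / dx;
      }
      double dvdy;
      if (vc > 0) {
        bool ho = g.v_live(i, j - 1) && g.v_live(i, j - 2);
        dvdy = ho ? (3 * vc - 4 * vS + v(i, j - 2)) / (2 * dy)
                  : (vc - vS) / dy;
      } else {
        bool ho = g.v_live(i, j + 1) && g.v_live(i, j + 2);
        dvdy = ho ? (-3 * vc + 4 * vN - v(i, j + 2)) / (2 * dy)
                  : (vN - vc) / dy;
      }
      double conv = ubar * dvdx + vc * dvdy;
      double muN = g.fluid(i, j) ? mu(i, j) : 0;
      double muS = g.fluid(i, j - 1) ? mu(i, j - 1) : 0;
      double muE = 0.5 * (face_avg(mu, g, i, j - 1, i + 1, j - 1) +
                          face_avg(mu, g, i, j, i + 1, j));
      double muW = 0.5 * (face_avg(mu, g, i, j - 1, i - 1, j - 1) +
                          face_avg(mu, g, i, j, i - 1, j));
      double visc = (muE * (vE - vc) - muW * (vc - vW)) / (dx * dx) +
                    (muN * (vN - vc) - muS * (vc - vS)) / (dy * dy);
      double ef = 0.5 * (eps(i, j - 1) + eps(i, j));
      double sf = 0.5 * (sinkc(i, j - 1) + sinkc(i, j));
      double vstar = vc + dt * (ef / rho) * (-rho * conv + visc);
      vs(i, j) = vstar / (1.0 + dt * ef * sf / rho);
    }
  }
  // boundary faces of u*
  for (int j = 0; j < ny; ++j) {
    us(0, j) = g.u_inlet(0, j) ? u_inlet[j] : 0.0;
    us(nx, j) = g.u_outlet(nx, j) ? us(nx - 1, j) : 0.0;
  }
  for (int i = 0; i < nx; ++i) { vs(i, 0) = 0; vs(i, ny) = 0; }

  // assemble Poisson coefficients
  Poisson P(g, dx, dy);
  bool has_outlet = false;
  for (size_t k = 0; k < P.cells.size(); ++k) {
    int c = P.cells[k], i = c % nx, j = c / nx;
    if (g.u_interior(i + 1, j))
      P.be[k] = dt * 0.5 * (eps(i, j) + eps(i + 1, j)) / rho;
    if (g.u_interior(i, j))
      P.bw[k] = dt * 0.5 * (eps(i - 1, j) + eps(i, j)) / rho;
    if (g.v_interior(i, j + 1))
      P.bn[k] = dt * 0.5 * (eps(i, j) + eps(i, j + 1)) / rho;
    if (g.v_interior(i, j))
      P.bs[k] = dt * 0.5 * (eps(i, j - 1) + eps(i, j)) / rho;
    if (g.u_outlet(nx, j) && i == nx - 1) {
      P.bo[k] = dt * eps(i, j) / rho;
      has_outlet = true;
    }
  }
  std::vector<double> b(P.cells.size()), pv(P.cells.size());
  for (size_t k = 0; k < P.cells.size(); ++k) {
    int c = P.cells[k], i = c % nx, j = c / nx;
    double div = (us(i + 1, j) - us(i, j)) / dx + (vs(i, j + 1) - vs(i, j)) / dy;
    b[k] = -div;
    pv[k] = p(i, j);
  }
  int iters = P.solve(pv, b, tol, maxit, !has_outlet, *S, dt, eps, rho);

  // velocity correction
  NumericMatrix pn(nx, ny);
  for (size_t k = 0; k < P.cells.size(); ++k) {
    int c = P.cells[k];
    pn(c % nx, c / nx) = pv[k];
  }
  for (int j = 0; j < ny; ++j)
    for (int i = 1; i <= nx - 1; ++i)
      if (g.u_interior(i, j)) {
        double bf = dt * 0.5 * (eps(i - 1, j) + eps(i, j)) / rho;
        us(i, j) -= bf * (pn(i, j) - pn(i - 1, j)) / dx;
      }
  for (int j = 1; j <= ny - 1; ++j)
    for (int i = 0; i < nx; ++i)
      if (g.v_interior(i, j)) {
        double bf = dt * 0.5 * (eps(i, j - 1) + eps(i, j)) / rho;
        vs(i, j) -= bf * (pn(i, j) - pn(i, j - 1)) / dy;
      }
  for (int j = 0; j < ny; ++j)
    if (g.u_outlet(nx, j)) {
      double bf = dt * eps(nx - 1, j) / rho;
      us(nx, j) += 2.0 * bf * pn(nx - 1, j) / dx;
    }

  // post-projection divergence diagnostic
  double divmax = 0, uscale = 0;
  for (size_t k = 0; k < P.cells.size(); ++k) {
    int c = P.cells[k], i = c % nx, j = c / nx;
    double div = (us(i + 1, j) - us(i, j)) / dx + (vs(i, j + 1) - vs(i, j)) / dy;
    if (std::fabs(div) > divmax) divmax = std::fabs(div);
    double um = std::fabs(us(i, j)) + std::fabs(vs(i, j));
    if (um > uscale) uscale = um;
  }
  return List::create(_["u"] = us, _["v"] = vs, _["p"] = pn,
                      _["div_max"] = divmax, _["u_scale"] = uscale,
                      _["cg_iters"] = iters);
}

// van Leer limiter
static inline double vl(double r) {
  double ar = std::fabs(r);
  return (r + ar) / (1.0 + ar);
}

// MUSCL face value for advection; up2 is the second upstream value (valid2
// tells whether it exists), up the upstream, dn the downstream cell value.
static inline double muscl_face(double up2, double up, double dn, bool valid2) {
  double d = dn - up;
  if (!valid2 || d == 0) return up;
  double r = (up - up2) / d;
  return up + 0.5 * vl(r) * d;
}

// Conservative convection-diffusion update of a cell scalar:
// d(eps*phi)/dt + s_conv * div(u phi) = div(D grad phi) + src
// Inlet: Dirichlet phi_in; outlet: upwinded advective outflow, zero
// diffusive flux; walls: zero flux.
// [[Rcpp::export(name = ".scalar_step_cpp")]]
NumericMatrix scalar_step_cpp(NumericMatrix phi, NumericMatrix u,
                              NumericMatrix v, IntegerMatrix mask,
                              NumericMatrix eps_old, NumericMatrix eps_new,
                              double D, double dx, double dy, double dt,
                              IntegerVector inlet_j, IntegerVector outlet_j,
                              double phi_in, NumericMatrix src,
                              NumericMatrix conv_scale) {
  GridCtx g(mask, inlet_j, outlet_j);
  int nx = g.nx, ny = g.ny;
  NumericMatrix out(nx, ny);
  // advective fluxes on faces
  NumericMatrix Fx(nx + 1, ny), Fy(nx, ny + 1);
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i <= nx; ++i) {
      double uf = u(i, j);
      if (g.u_inlet(i, j)) { Fx(i, j) = uf * (uf > 0 ? phi_in : phi(0, j)); continue; }
      if (g.u_outlet(i, j)) { Fx(i, j) = uf * phi(nx - 1, j); continue; }
      if (!g.u_interior(i, j)) { Fx(i, j) = 0; continue; }
      if (uf >= 0) {
        bool v2 = g.fluid(i - 2, j);
        Fx(i, j) = uf * muscl_face(v2 ? phi(i - 2, j) : 0.0, phi(i - 1, j),
                                   phi(i, j), v2);
      } else {
        bool v2 = g.fluid(i + 1, j);
        Fx(i, j) = uf * muscl_face(v2 ? phi(i + 1, j) : 0.0, phi(i, j),
                                   phi(i - 1, j), v2);
      }
    }
  }
  for (int j = 0; j <= ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      if (!g.v_interior(i, j)) { Fy(i, j) = 0; continue; }
      double vf = v(i, j);
      if (vf >= 0) {
        bool v2 = g.fluid(i, j - 2);
        Fy(i, j) = vf * muscl_face(v2 ? phi(i, j - 2) : 0.0, phi(i, j - 1),
                                   phi(i, j), v2);
      } else {
        bool v2 = g.fluid(i, j + 1);
        Fy(i, j) = vf * muscl_face(v2 ? phi(i, j + 1) : 0.0, phi(i, j),
                                   phi(i, j - 1), v2);
      }
    }
  }
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      if (!g.fluid(i, j)) { out(i, j) = phi(i, j); continue; }
      double conv = (Fx(i + 1, j) - Fx(i, j)) / dx + (Fy(i, j + 1) - Fy(i, j)) / dy;
      double diff = 0;
      if (g.fluid(i + 1, j)) diff += D * (phi(i + 1, j) - phi(i, j)) / (dx * dx);
      if (g.fluid(i - 1, j)) diff += D * (phi(i - 1, j) - phi(i, j)) / (dx * dx);
      else if (g.u_inlet(0, j) && i == 0)
        diff += 2.0 * D * (phi_in - phi(i, j)) / (dx * dx);
      if (g.fluid(i, j + 1)) diff += D * (phi(i, j + 1) - phi(i, j)) / (dy * dy);
      if (g.fluid(i, j - 1)) diff += D * (phi(i, j - 1) - phi(i, j)) / (dy * dy);
      double rhs = -conv_scale(i, j) * conv + diff + src(i, j);
      out(i, j) = (eps_old(i, j) * phi(i, j) + dt * rhs) / eps_new(i, j);
    }
  }
  return out;
}

// Shear-rate magnitude sqrt(2 D:D) at cell centers and WSS magnitude at
// wall faces (one-sided gradient of the tangential velocity).
// wall face table columns are 1-based (i, j, side); side 1 W, 2 E, 3 S, 4 N.
// [[Rcpp::export(name = ".shear_fields_cpp")]]
List shear_fields_cpp(NumericMatrix u, NumericMatrix v, IntegerMatrix mask,
                      NumericMatrix mu, double dx, double dy,
                      IntegerVector inlet_j, IntegerVector outlet_j,
                      IntegerVector wf_i, IntegerVector wf_j,
                      IntegerVector wf_side) {
  GridCtx g(mask, inlet_j, outlet_j);
  int nx = g.nx, ny = g.ny;
  NumericMatrix gam(nx, ny);
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      if (!g.fluid(i, j)) { gam(i, j) = 0; continue; }
      double ux = (u(i + 1, j) - u(i, j)) / dx;
      double vy = (v(i, j + 1) - v(i, j)) / dy;
      // corner-averaged cross gradients with no-slip ghosts
      double dudy = 0, dvdx = 0;
      for (int sj = 0; sj <= 1; ++sj) {
        int jj = j + sj; // corner row: between j-1+sj and j+sj
        double ua = u_nb_y(g, u, i, jj, i, j);
        double ub = u_nb_y(g, u, i, jj - 1, i, j);
        double uc = u_nb_y(g, u, i + 1, jj, i + 1, j);
        double ud = u_nb_y(g, u, i + 1, jj - 1, i + 1, j);
        if (!g.u_live(i, j)) { ua = 0; ub = 0; }
        if (!g.u_live(i + 1, j)) { uc = 0; ud = 0; }
        dudy += 0.5 * ((ua - ub) / dy + (uc - ud) / dy);
      }
      dudy *= 0.5;
      for (int si = 0; si <= 1; ++si) {
        int ii = i + si;
        double va = v_nb_x(g, v, ii, j, i, j);
        double vb = v_nb_x(g, v, ii - 1, j, i, j);
        double vc = v_nb_x(g, v, ii, j + 1, i, j + 1);
        double vd = v_nb_x(g, v, ii - 1, j + 1, i, j + 1);
        if (!g.v_live(i, j)) { va = 0; vb = 0; }
        if (!g.v_live(i, j + 1)) { vc = 0; vd = 0; }
        dvdx += 0.5 * ((va - vb) / dx + (vc - vd) / dx);
      }
      dvdx *= 0.5;
      gam(i, j) = std::sqrt(2 * ux * ux + 2 * vy * vy +
                            (dudy + dvdx) * (dudy + dvdx));
    }
  }
  int nf = wf_i.size();
  NumericVector wss(nf);
  for (int k = 0; k < nf; ++k) {
    int i = wf_i[k] - 1, j = wf_j[k] - 1, side = wf_side[k];
    double ut;
    if (side <= 2) { // vertical wall: tangential is v at cell center
      ut = 0.5 * (v_nb_y(g, v, i, j) + v_nb_y(g, v, i, j + 1));
      wss[k] = mu(i, j) * std::fabs(ut) / (dx / 2);
    } else { // horizontal wall: tangential is u
      ut = 0.5 * (u_nb_x(g, u, i, j) + u_nb_x(g, u, i + 1, j));
      wss[k] = mu(i, j) * std::fabs(ut) / (dy / 2);
    }
  }
  return List::create(_["gamma"] = gam, _["wss"] = wss);
}
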