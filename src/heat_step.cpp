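// Backward-Euler finite-volume step of the conjugate bioheat system on a
// labeled Cartesian voxel grid.
//
// Tissue cells: Pennes equation with effective (apparent) heat capacity and
// conductivity; perfusion + metabolic sources switch off for T <= Tu.
// Lumen cells: advection-diffusion with constant blood properties and a
// precomputed steady face-velocity field (first-order implicit upwind, with
// an optional deferred-correction second-order upwind).
// Coupling: single linear system over TISSUE+LUMEN cells, harmonic-mean face
// conductivity across the artery surface.
//
// The latent-heat nonlinearity is resolved by a Newton-type enthalpy
// linearization: the apparent capacity at the current iterate is the Jacobian
// of the enthalpy residual, so the converged step satisfies the enthalpy
// balance exactly. Linear solves: matrix-free ILU(0)-preconditioned BiCGSTAB
// on the 7-point stencil.
//
// The grid topology (active-cell numbering, neighbor tables, face velocities
// per cell) never changes during a run, so it is built once by cpp_heat_plan
// and reused by every step.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

const int TISSUE = 1, LUMEN = 2, PROBE_TIP = 3;
// EXTERIOR = 0 and PROBE_SHAFT = 4 are both adiabatic.

// neighbor classification per direction
const int NB_ADIABATIC = 0, NB_ACTIVE = 1, NB_PROBE = 2, NB_BOUNDARY = 3;

struct Props {
  double Ct, Cf, Cb, Qf, kf, kt, kb, omega, Qm, Tu, Tl, Tcb;
  double khat(double T) const {
    if (T < Tl) return kf;
    if (T > Tu) return kt;
    return kf + (kt - kf) * (T - Tl) / (Tu - Tl);
  }
  double chat(double T) const {
    if (T < Tl) return Cf;
    if (T > Tu) return Ct;
    double dT = Tu - Tl;
    return Qf / dT + Cf + (Ct - Cf) * (T - Tl) / dT;
  }
  double enthalpy(double T) const {  // integral of chat from Tl
    double dT = Tu - Tl, x = T - Tl;
    if (x < 0) return Cf * x;
    double xb = x < dT ? x : dT;
    double H = (Qf / dT + Cf) * xb + (Ct - Cf) * xb * xb / (2 * dT);
    if (x > dT) H += Ct * (x - dT);
    return H;
  }
};

inline Props read_props(List props_in) {
  Props P;
  P.Ct = props_in["Ct"];   P.Cf = props_in["Cf"];   P.Cb = props_in["Cb"];
  P.Qf = props_in["Qf"];   P.kf = props_in["kappa_f"];
  P.kt = props_in["kappa_t"]; P.kb = props_in["kappa_b"];
  P.omega = props_in["omega_cb"]; P.Qm = props_in["Qm"];
  P.Tu = props_in["Tu"];   P.Tl = props_in["Tl"];   P.Tcb = props_in["Tcb"];
  return P;
}

// y = A x on the 7-point stencil: diag * x - sum_dir a[dir] * x[nbr]
inline void matvec(const std::vector<double>& diag,
                   const std::vector<std::vector<double>>& a,
                   const std::vector<const int*>& nbr,
                   const std::vector<double>& x, std::vector<double>& y) {
  const int n = (int)diag.size();
  for (int c = 0; c < n; ++c) {
    double s = diag[c] * x[c];
    for (int d = 0; d < 6; ++d) {
      int nb = nbr[d][c];
      if (nb >= 0) s -= a[d][c] * x[nb];
    }
    y[c] = s;
  }
}

// ILU(0) of the 7-point matrix in natural ordering: only the pivot diagonal
// changes (no fill within the stencil). Lower dirs (0, 2, 4) point to
// smaller eq indices by construction.
inline void ilu0_factor(const std::vector<double>& diag,
                        const std::vector<std::vector<double>>& a,
                        const std::vector<const int*>& nbr,
                        std::vector<double>& d) {
  const int n = (int)diag.size();
  for (int i = 0; i < n; ++i) {
    double di = diag[i];
    for (int q = 0; q < 6; q += 2) {
      int j = nbr[q][i];
      if (j >= 0) di -= a[q][i] * a[q + 1][j] / d[j];
    }
    d[i] = di > 1e-300 ? di : 1e-300;
  }
}

// solve M z = r with M = (D~ + L) D~^{-1} (D~ + U); a holds -offdiag values
inline void ilu0_solve(const std::vector<double>& d,
                       const std::vector<std::vector<double>>& a,
                       const std::vector<const int*>& nbr,
                       const std::vector<double>& r, std::vector<double>& z,
                       std::vector<double>& work) {
  const int n = (int)d.size();
  for (int i = 0; i < n; ++i) {
    double t = r[i];
    for (int q = 0; q < 6; q += 2) {
      int j = nbr[q][i];
      if (j >= 0) t += a[q][i] * work[j];
    }
    work[i] = t / d[i];
  }
  for (int i = n - 1; i >= 0; --i) {
    double t = 0;
    for (int q = 1; q < 6; q += 2) {
      int j = nbr[q][i];
      if (j >= 0) t += a[q][i] * z[j];
    }
    z[i] = work[i] + t / d[i];
  }
}

// ILU(0)-preconditioned BiCGSTAB; returns iterations used, -1 on failure.
int bicgstab(const std::vector<double>& diag,
             const std::vector<std::vector<double>>& a,
             const std::vector<const int*>& nbr,
             const std::vector<double>& b, std::vector<double>& x,
             double tol, int maxit) {
  const int n = (int)b.size();
  std::vector<double> r(n), r0(n), p(n), v(n), s(n), t(n), y(n), z(n);
  std::vector<double> dilu(n), work(n);
  ilu0_factor(diag, a, nbr, dilu);
  matvec(diag, a, nbr, x, r);
  double bnorm = 0;
  for (int i = 0; i < n; ++i) { r[i] = b[i] - r[i]; bnorm += b[i] * b[i]; }
  bnorm = std::sqrt(bnorm);
  if (bnorm == 0) bnorm = 1;
  double rnorm = 0;
  for (int i = 0; i < n; ++i) rnorm += r[i] * r[i];
  rnorm = std::sqrt(rnorm);
  if (rnorm <= tol * bnorm) return 0;
  r0 = r;
  double rho = 1, alpha = 1, omega = 1;
  std::fill(p.begin(), p.end(), 0.0);
  std::fill(v.begin(), v.end(), 0.0);
  for (int it = 1; it <= maxit; ++it) {
    double rho1 = 0;
    for (int i = 0; i < n; ++i) rho1 += r0[i] * r[i];
    if (std::fabs(rho1) < 1e-300) return -1;
    double beta = (rho1 / rho) * (alpha / omega);
    rho = rho1;
    for (int i = 0; i < n; ++i) p[i] = r[i] + beta * (p[i] - omega * v[i]);
    ilu0_solve(dilu, a, nbr, p, y, work);
    matvec(diag, a, nbr, y, v);
    double r0v = 0;
    for (int i = 0; i < n; ++i) r0v += r0[i] * v[i];
    if (std::fabs(r0v) < 1e-300) return -1;
    alpha = rho / r0v;
    double snorm = 0;
    for (int i = 0; i < n; ++i) { s[i] = r[i] - alpha * v[i]; snorm += s[i] * s[i]; }
    if (std::sqrt(snorm) <= tol * bnorm) {
      for (int i = 0; i < n; ++i) x[i] += alpha * y[i];
      return it;
    }
    ilu0_solve(dilu, a, nbr, s, z, work);
    matvec(diag, a, nbr, z, t);
    double tt = 0, ts = 0;
    for (int i = 0; i < n; ++i) { tt += t[i] * t[i]; ts += t[i] * s[i]; }
    if (tt < 1e-300) return -1;
    omega = ts / tt;
    rnorm = 0;
    for (int i = 0; i < n; ++i) {
      x[i] += alpha * y[i] + omega * z[i];
      r[i] = s[i] - omega * t[i];
      rnorm += r[i] * r[i];
    }
    if (std::sqrt(rnorm) <= tol * bnorm) return it;
  }
  return -1;
}

} // namespace

// Build the static per-run topology: active-cell list, per-direction neighbor
// eq indices and types, outward face velocities, and second-upwind indices.
// [[Rcpp::export]]
List cpp_heat_plan(IntegerVector labels, IntegerVector dims,
                   NumericVector u, NumericVector v, NumericVector w) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int N = nx * ny * nz;
  if (labels.size() != N) stop("label size mismatch");
  const int sx = 1, sy = nx, sz = nx * ny;

  std::vector<int> eq(N, -1);
  std::vector<int> cells;
  cells.reserve(N);
  for (int c = 0; c < N; ++c)
    if (labels[c] == TISSUE || labels[c] == LUMEN) {
      eq[c] = (int)cells.size();
      cells.push_back(c);
    }
  const int n = (int)cells.size();
  if (n == 0) stop("no active cells");

  auto face_u = [&](int i, int j, int k) { return u[i + (nx + 1) * (j + (R_xlen_t)ny * k)]; };
  auto face_v = [&](int i, int j, int k) { return v[i + nx * (j + (R_xlen_t)(ny + 1) * k)]; };
  auto face_w = [&](int i, int j, int k) { return w[i + nx * (j + (R_xlen_t)ny * k)]; };

  IntegerVector cell_out(n), isl(n);
  List nbr_eq(6), nbr_type(6), qout(6), upup(6);
  std::vector<IntegerVector> ne(6), nt(6), uu(6);
  std::vector<NumericVector> qo(6);
  for (int d = 0; d < 6; ++d) {
    ne[d] = IntegerVector(n); nt[d] = IntegerVector(n);
    qo[d] = NumericVector(n); uu[d] = IntegerVector(n);
  }
  auto raw_nbr = [&](int c, int d) -> int {
    int k = c / sz, j = (c - k * sz) / nx, i = c - k * sz - j * nx;
    switch (d) {
      case 0: return i > 0 ? c - sx : -1;
      case 1: return i < nx - 1 ? c + sx : -1;
      case 2: return j > 0 ? c - sy : -1;
      case 3: return j < ny - 1 ? c + sy : -1;
      case 4: return k > 0 ? c - sz : -1;
      default: return k < nz - 1 ? c + sz : -1;
    }
  };

  for (int e = 0; e < n; ++e) {
    int c = cells[e];
    int k = c / sz, j = (c - k * sz) / nx, i = c - k * sz - j * nx;
    cell_out[e] = c + 1;  // back to R's 1-based indexing
    isl[e] = labels[c];
    double q6[6] = {0, 0, 0, 0, 0, 0};
    if (labels[c] == LUMEN) {
      q6[0] = -face_u(i, j, k);     q6[1] = face_u(i + 1, j, k);
      q6[2] = -face_v(i, j, k);     q6[3] = face_v(i, j + 1, k);
      q6[4] = -face_w(i, j, k);     q6[5] = face_w(i, j, k + 1);
    }
    for (int d = 0; d < 6; ++d) {
      qo[d][e] = q6[d];
      int nc = raw_nbr(c, d);
      if (nc < 0) {
        nt[d][e] = NB_BOUNDARY; ne[d][e] = -1; uu[d][e] = -1;
        continue;
      }
      int nl = labels[nc];
      if (nl == TISSUE || nl == LUMEN) {
        nt[d][e] = NB_ACTIVE;
        ne[d][e] = eq[nc];
        // up-upwind eq index for the deferred second-order correction:
        // outflow (q > 0) extrapolates from the opposite neighbor of c,
        // inflow from the far neighbor of nc
        int far = q6[d] > 0 ? raw_nbr(c, d ^ 1) : raw_nbr(nc, d);
        uu[d][e] = (far >= 0 && labels[far] == LUMEN) ? eq[far] : -1;
      } else if (nl == PROBE_TIP) {
        nt[d][e] = NB_PROBE; ne[d][e] = -1; uu[d][e] = -1;
      } else {
        nt[d][e] = NB_ADIABATIC; ne[d][e] = -1; uu[d][e] = -1;
      }
    }
  }
  for (int d = 0; d < 6; ++d) {
    nbr_eq[d] = ne[d]; nbr_type[d] = nt[d]; qout[d] = qo[d]; upup[d] = uu[d];
  }
  return List::create(_["cell"] = cell_out, _["label"] = isl,
                      _["nbr_eq"] = nbr_eq, _["nbr_type"] = nbr_type,
                      _["qout"] = qout, _["upup"] = upup, _["n"] = n);
}

// [[Rcpp::export]]
List cpp_heat_step(List plan, NumericVector Tfield, double h, double dt,
                   List props_in, List bounds, List opts) {
  const Props P = read_props(props_in);
  const double T0 = bounds["T_inlet"], Tp = bounds["T_probe"];
  const double picard_tol = opts["picard_tol"];
  const int picard_max = opts["picard_max"];
  const double relax = opts["relax"];
  const double lin_tol = opts["lin_tol"];
  const int lin_max = opts["lin_max"];
  const int adv_order = opts["advection_order"];
  const double A = h * h, V = h * h * h;

  const int n = plan["n"];
  IntegerVector cell = plan["cell"], isl = plan["label"];
  List nbr_eq_l = plan["nbr_eq"], nbr_type_l = plan["nbr_type"],
    qout_l = plan["qout"], upup_l = plan["upup"];
  std::vector<const int*> nbr(6), ntyp(6), uup(6);
  std::vector<const double*> qo(6);
  std::vector<IntegerVector> nbr_keep(6), ntyp_keep(6), uup_keep(6);
  std::vector<NumericVector> qo_keep(6);
  for (int d = 0; d < 6; ++d) {
    nbr_keep[d] = nbr_eq_l[d];   nbr[d] = INTEGER(nbr_keep[d]);
    ntyp_keep[d] = nbr_type_l[d]; ntyp[d] = INTEGER(ntyp_keep[d]);
    uup_keep[d] = upup_l[d];     uup[d] = INTEGER(uup_keep[d]);
    qo_keep[d] = qout_l[d];      qo[d] = REAL(qo_keep[d]);
  }

  std::vector<double> Told(n), Tk(n), Kprev(n), kap(n), cap(n), Hold(n);
  for (int e = 0; e < n; ++e) {
    Told[e] = Tfield[cell[e] - 1];
    Tk[e] = Told[e];
    bool lum = isl[e] == LUMEN;
    Kprev[e] = lum ? P.kb : P.khat(Told[e]);
    Hold[e] = lum ? 0.0 : P.enthalpy(Told[e]);
  }

  std::vector<double> diag(n), rhs(n), Tsol(n);
  std::vector<std::vector<double>> a(6, std::vector<double>(n));

  int picard = 0, lin_total = 0;
  double maxch = R_PosInf;
  bool converged = false;

  for (picard = 1; picard <= picard_max; ++picard) {
    for (int e = 0; e < n; ++e) {
      if (isl[e] == LUMEN) { kap[e] = P.kb; cap[e] = P.Cb; continue; }
      kap[e] = relax * P.khat(Tk[e]) + (1 - relax) * Kprev[e];
      Kprev[e] = kap[e];
      cap[e] = P.chat(Tk[e]);  // Newton Jacobian of the enthalpy residual
    }

    for (int e = 0; e < n; ++e) {
      bool lum = isl[e] == LUMEN;
      double dg = cap[e] * V / dt;
      double b = lum ? dg * Told[e]
                     : dg * Tk[e] - (P.enthalpy(Tk[e]) - Hold[e]) * V / dt;
      for (int d = 0; d < 6; ++d) {
        a[d][e] = 0.0;
        int typ = ntyp[d][e];
        double F = P.Cb * qo[d][e] * A;  // outward mass-capacity flux, W/K
        if (typ == NB_ACTIVE) {
          int ne_ = nbr[d][e];
          double kface = 2.0 * kap[e] * kap[ne_] / (kap[e] + kap[ne_]);
          dg += kface * h;
          a[d][e] += kface * h;
          if (F != 0.0 && lum && isl[ne_] == LUMEN) {
            if (F > 0) dg += F; else a[d][e] += -F;
            if (adv_order == 2) {
              int far = uup[d][e];
              if (far >= 0) {
                double Tup = F > 0 ? Tk[e] : Tk[ne_];
                b -= F * 0.5 * (Tup - Tk[far]);
              }
            }
          }
        } else if (typ == NB_PROBE) {
          double coefP = 2.0 * kap[e] * h;  // Dirichlet at the shared face
          dg += coefP;
          b += coefP * Tp;
        } else if (typ == NB_BOUNDARY && lum && F != 0.0) {
          if (F < 0) {            // inflow: Dirichlet T0 + advected enthalpy
            b += (-F) * T0;
            dg += 2.0 * P.kb * h;
            b += 2.0 * P.kb * h * T0;
          } else {                // outflow: upwind out, zero gradient
            dg += F;
          }
        }
        // NB_ADIABATIC (shaft, exterior) and no-flow boundaries: nothing
      }
      if (!lum && Tk[e] > P.Tu) {
        dg += P.omega * P.Cb * V;
        b += P.omega * P.Cb * P.Tcb * V + P.Qm * V;
      }
      diag[e] = dg;
      rhs[e] = b;
    }

    Tsol = Tk;
    int its = bicgstab(diag, a, nbr, rhs, Tsol, lin_tol, lin_max);
    if (its < 0)
      stop("step failure: linear solver did not converge; reduce dt");
    lin_total += its;
    // mild damping once the Newton updates oscillate across the band kinks
    double theta = picard <= 12 ? 1.0 : 0.5;
    maxch = 0;
    for (int e = 0; e < n; ++e) {
      if (!std::isfinite(Tsol[e])) stop("step failure: NaN in temperature field");
      double d = std::fabs(Tsol[e] - Tk[e]);
      if (d > maxch) maxch = d;
      Tk[e] += theta * (Tsol[e] - Tk[e]);
    }
    if (maxch < picard_tol) { converged = true; break; }
  }
  if (!converged && maxch >= 10 * picard_tol)
    stop("step failure: Picard iteration did not converge; reduce dt");

  // energy bookkeeping at the converged state (W)
  double Q_probe = 0, Q_bnd = 0, Q_perf = 0, Q_met = 0;
  for (int e = 0; e < n; ++e) {
    bool lum = isl[e] == LUMEN;
    for (int d = 0; d < 6; ++d) {
      int typ = ntyp[d][e];
      double F = P.Cb * qo[d][e] * A;
      if (typ == NB_PROBE)
        Q_probe += 2.0 * kap[e] * h * (Tp - Tk[e]);
      else if (typ == NB_BOUNDARY && lum && F != 0.0) {
        if (F < 0) Q_bnd += (-F) * T0 + 2.0 * P.kb * h * (T0 - Tk[e]);
        else       Q_bnd -= F * Tk[e];
      }
    }
    if (!lum && Tk[e] > P.Tu) {
      Q_perf += P.omega * P.Cb * (P.Tcb - Tk[e]) * V;
      Q_met += P.Qm * V;
    }
  }

  NumericVector Tout = clone(Tfield);
  for (int e = 0; e < n; ++e) Tout[cell[e] - 1] = Tk[e];
  return List::create(
    _["T"] = Tout, _["picard"] = picard, _["max_change"] = maxch,
    _["converged"] = converged, _["lin_iters"] = lin_total,
    _["Q_probe"] = Q_probe, _["Q_boundary"] = Q_bnd,
    _["Q_perfusion"] = Q_perf, _["Q_metabolic"] = Q_met);
}
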