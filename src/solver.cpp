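#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Explicit two-step (Richtmyer) Lax-Wendroff solver for the 1-D
// cross-sectional-area / flow system on a bifurcating network, in CGS units:
//   A_t + q_x = 0
//   q_t + (q^2/A + B)_x = -(2 pi nu R / delta) q/A + S_geom
// with wall law p - p0 = f(x) (1 - sqrt(A0/A)), f = (4/3) Eh/r0. The
// pressure-gradient term is written in the well-balanced form
//   (A/rho) p_x = Bt_x - St_geom,  Bt = (f/rho)(sqrt(A0 A) - A0),
//   St_geom = (1/rho)[ f'(x)(2 sqrt(A0 A) - A - A0)
//                      + f(x) A0'(x)(sqrt(A/A0) - 1) ],
// which vanishes identically at the unstressed state, so a tapered vessel
// at rest is an exact discrete equilibrium of the scheme.
// Inlet: prescribed flow + outgoing characteristic; junctions: pressure
// continuity + mass conservation + characteristics (Newton); terminals:
// periodic convolution of the structured-tree kernel with the outlet flow.

struct Vessel {
  int nx;
  double dx;
  std::vector<double> A0, f, dA0, df;       // nodal geometry
  std::vector<double> A0h, fh, dA0h, dfh;   // half-grid geometry
  std::vector<double> A, q;                 // state
  std::vector<double> Ah, qh;               // half-step state
  std::vector<double> An, qn;               // next state
  std::vector<double> F, S, Fh, Sh;         // per-step scratch
  int kernel_id; // index into kernels, -1 if not terminal
};

struct Junction { int parent; int child[2]; int nchild; };

static inline double wave_c(double f, double rho, double A0, double A) {
  return std::sqrt(f / (2.0 * rho)) * std::sqrt(std::sqrt(A0 / A));
}

// dense solve by Gaussian elimination with partial pivoting (n <= 6)
static bool solve_dense(int n, double J[6][6], double r[6], double d[6]) {
  int piv[6];
  for (int i = 0; i < n; ++i) piv[i] = i;
  for (int c = 0; c < n; ++c) {
    int best = c;
    for (int i = c + 1; i < n; ++i)
      if (std::fabs(J[i][c]) > std::fabs(J[best][c])) best = i;
    if (std::fabs(J[best][c]) < 1e-300) return false;
    if (best != c) {
      for (int k = 0; k < n; ++k) std::swap(J[c][k], J[best][k]);
      std::swap(r[c], r[best]);
    }
    for (int i = c + 1; i < n; ++i) {
      double m = J[i][c] / J[c][c];
      for (int k = c; k < n; ++k) J[i][k] -= m * J[c][k];
      r[i] -= m * r[c];
    }
  }
  for (int i = n - 1; i >= 0; --i) {
    double s = r[i];
    for (int k = i + 1; k < n; ++k) s -= J[i][k] * d[k];
    d[i] = s / J[i][i];
  }
  return true;
}

class NetSolver {
public:
  std::vector<Vessel> ves;
  std::vector<Junction> jns;
  int root;
  std::vector<std::vector<double> > kernels;  // per terminal, length n_t
  std::vector<std::vector<double> > qhist;    // outlet flow ring buffers
  std::vector<double> inflow;                 // length n_t
  double rho, nu, delta, dt, p0;
  double visc; // artificial-dissipation coefficient (0 = off)
  int n_t;
  long gstep;

  double pres(const Vessel &v, int i, double A) const {
    return v.f[i] * (1.0 - std::sqrt(v.A0[i] / A));
  }

  // Boundary nodes are treated as conservative half-cells: the area update
  // uses the interior half-step mass flux and the trapezoidal boundary flow
  //   A_b^{n+1} = A_b^n -/+ (2 dt/dx) ( q_b^{n+1} - qh_adjacent ),
  // so in the periodic regime the cycle-averaged flow telescopes exactly
  // from the inlet through every junction to the terminals. The remaining
  // flow unknowns are closed by the boundary conditions themselves
  // (prescribed inflow; junction pressure continuity + mass conservation;
  // terminal impedance convolution).

  double friction(double A, double q) const {
    double R = std::sqrt(A / M_PI);
    return -2.0 * M_PI * nu * R * q / (delta * A);
  }

  void interior_step(Vessel &v) {
    int nx = v.nx;
    double lam = dt / v.dx;
    std::vector<double> &F = v.F, &S = v.S;
    for (int i = 0; i < nx; ++i) {
      double A = v.A[i], q = v.q[i];
      if (!(A > 0.0)) stop("solver instability: non-positive area");
      double B = v.f[i] * (std::sqrt(v.A0[i] * A) - v.A0[i]) / rho;
      F[i] = q * q / A + B;
      double sg = (v.df[i] * (2.0 * std::sqrt(v.A0[i] * A) - A - v.A0[i]) +
                   v.f[i] * (std::sqrt(A / v.A0[i]) - 1.0) * v.dA0[i]) / rho;
      S[i] = friction(A, q) + sg;
    }
    for (int i = 0; i < nx - 1; ++i) {
      v.Ah[i] = 0.5 * (v.A[i] + v.A[i + 1]) -
                0.5 * lam * (v.q[i + 1] - v.q[i]);
      v.qh[i] = 0.5 * (v.q[i] + v.q[i + 1]) -
                0.5 * lam * (F[i + 1] - F[i]) +
                0.25 * dt * (S[i] + S[i + 1]);
      if (!(v.Ah[i] > 0.0)) stop("solver instability: non-positive area");
    }
    std::vector<double> &Fh = v.Fh, &Sh = v.Sh;
    for (int i = 0; i < nx - 1; ++i) {
      double A = v.Ah[i], q = v.qh[i];
      double B = v.fh[i] * (std::sqrt(v.A0h[i] * A) - v.A0h[i]) / rho;
      Fh[i] = q * q / A + B;
      double sg = (v.dfh[i] *
                     (2.0 * std::sqrt(v.A0h[i] * A) - A - v.A0h[i]) +
                   v.fh[i] * (std::sqrt(A / v.A0h[i]) - 1.0) * v.dA0h[i]) /
                  rho;
      Sh[i] = friction(A, q) + sg;
    }
    for (int i = 1; i < nx - 1; ++i) {
      v.An[i] = v.A[i] - lam * (v.qh[i] - v.qh[i - 1]);
      v.qn[i] = v.q[i] - lam * (Fh[i] - Fh[i - 1]) +
                0.5 * dt * (Sh[i] + Sh[i - 1]);
    }
    if (visc > 0.0) {
      // conservative second-difference dissipation on the deviation from
      // the unstressed state; regularises near-sonic steepening in
      // extreme geometries, off by default
      for (int i = 1; i < nx - 1; ++i) {
        double dA = (v.A[i - 1] - v.A0[i - 1]) - 2.0 * (v.A[i] - v.A0[i]) +
                    (v.A[i + 1] - v.A0[i + 1]);
        double dq = v.q[i - 1] - 2.0 * v.q[i] + v.q[i + 1];
        v.An[i] += visc * dA;
        v.qn[i] += visc * dq;
      }
    }
  }

  void cfl_check(const Vessel &v, int vi) const {
    for (int i = 0; i < v.nx; ++i) {
      double c = wave_c(v.f[i], rho, v.A0[i], v.A[i]);
      double lam = std::fabs(v.q[i] / v.A[i]) + c;
      if (lam * dt / v.dx > 1.0)
        stop("CFL condition violated at step %ld (vessel %d, node %d: "
             "A/A0 = %.3f, u = %.1f cm/s, c = %.1f cm/s)",
             gstep, vi + 1, i + 1, v.A[i] / v.A0[i], v.q[i] / v.A[i], c);
    }
  }

  void inlet_update(double qin) {
    Vessel &v = ves[root];
    double A = v.A[0] -
               (2.0 * dt / v.dx) * (v.qh[0] - qin);
    if (!(A > 0.0)) stop("solver instability: non-positive inlet area");
    v.An[0] = A;
    v.qn[0] = qin;
  }

  void junction_update(const Junction &jn) {
    Vessel &p = ves[jn.parent];
    int Np = p.nx - 1;
    int nc = jn.nchild;
    int n = 2 + 2 * nc;
    // unknowns x = (Ap, qp, A1, q1[, A2, q2]) at the new time level
    double x[6];
    x[0] = p.A[Np]; x[1] = p.q[Np];
    for (int d = 0; d < nc; ++d) {
      Vessel &cv = ves[jn.child[d]];
      x[2 + 2 * d] = cv.A[0];
      x[3 + 2 * d] = cv.q[0];
    }
    double fscale = p.f[Np];
    bool ok = false;
    for (int it = 0; it < 30; ++it) {
      double J[6][6] = {{0}}, r[6] = {0}, d[6];
      double Ap = x[0], qp = x[1];
      // parent outlet half-cell mass balance
      r[0] = Ap - p.A[Np] +
             (2.0 * dt / p.dx) * (qp - p.qh[Np - 1]);
      J[0][0] = 1.0;
      J[0][1] = 2.0 * dt / p.dx;
      double pp = pres(p, Np, Ap);
      double dpp = p.f[Np] * std::sqrt(p.A0[Np]) / (2.0 * std::pow(Ap, 1.5));
      // mass conservation row
      int mrow = 1 + nc;
      r[mrow] = qp;
      J[mrow][1] = 1.0;
      for (int dgt = 0; dgt < nc; ++dgt) {
        Vessel &cv = ves[jn.child[dgt]];
        double Ad = x[2 + 2 * dgt], qd = x[3 + 2 * dgt];
        // daughter inlet half-cell mass balance
        r[1 + dgt] = Ad - cv.A[0] +
                     (2.0 * dt / cv.dx) *
                         (cv.qh[0] - qd);
        J[1 + dgt][2 + 2 * dgt] = 1.0;
        J[1 + dgt][3 + 2 * dgt] = -2.0 * dt / cv.dx;
        r[mrow] -= qd;
        J[mrow][3 + 2 * dgt] = -1.0;
        // pressure continuity rows
        int prow = mrow + 1 + dgt;
        double pd = pres(cv, 0, Ad);
        double dpd = cv.f[0] * std::sqrt(cv.A0[0]) /
                     (2.0 * std::pow(Ad, 1.5));
        r[prow] = pp - pd;
        J[prow][0] = dpp;
        J[prow][2 + 2 * dgt] = -dpd;
      }
      double ra = 0.0, rm = 0.0, rp = 0.0;
      for (int i = 0; i <= nc; ++i) ra = std::max(ra, std::fabs(r[i]));
      rm = std::fabs(r[mrow]);
      for (int i = mrow + 1; i < n; ++i) rp = std::max(rp, std::fabs(r[i]));
      if (ra < 1e-11 * p.A0[Np] && rm < 1e-9 && rp < 1e-11 * fscale) {
        ok = true;
        break;
      }
      if (!solve_dense(n, J, r, d)) stop("singular junction system");
      for (int i = 0; i < n; ++i) x[i] -= d[i];
      if (x[0] <= 0.0) x[0] = 0.5 * p.A[Np];
      for (int dgt = 0; dgt < nc; ++dgt)
        if (x[2 + 2 * dgt] <= 0.0)
          x[2 + 2 * dgt] = 0.5 * ves[jn.child[dgt]].A[0];
    }
    if (!ok) stop("junction Newton iteration failed to converge");
    p.An[Np] = x[0]; p.qn[Np] = x[1];
    for (int dgt = 0; dgt < nc; ++dgt) {
      Vessel &cv = ves[jn.child[dgt]];
      cv.An[0] = x[2 + 2 * dgt];
      cv.qn[0] = x[3 + 2 * dgt];
    }
  }

  void terminal_update(Vessel &v) {
    int N = v.nx - 1;
    std::vector<double> &K = kernels[v.kernel_id];
    std::vector<double> &h = qhist[v.kernel_id];
    // convolution of past outlet flows with kernel lags >= 1; the cyclic
    // index splits into two contiguous runs, so no modulo in the hot loop
    long m = gstep + 1; // index of the new time level
    long mm = m % n_t;  // ring position of the new sample
    double conv = 0.0;
    {
      const double *Kp = &K[0];
      const double *hp = &h[0];
      long j = 1;
      for (long idx = mm - 1; idx >= 0; --idx, ++j) conv += Kp[j] * hp[idx];
      for (long idx = n_t - 1; j < n_t; --idx, ++j) conv += Kp[j] * hp[idx];
    }
    double A = v.A[N], q = v.q[N];
    bool ok = false;
    for (int it = 0; it < 50; ++it) {
      // half-cell mass balance + impedance convolution
      double R1 = A - v.A[N] +
                  (2.0 * dt / v.dx) * (q - v.qh[N - 1]);
      double R2 = pres(v, N, A) - K[0] * q - conv;
      double J11 = 1.0, J12 = 2.0 * dt / v.dx;
      double J21 = v.f[N] * std::sqrt(v.A0[N]) / (2.0 * std::pow(A, 1.5));
      double J22 = -K[0];
      double det = J11 * J22 - J12 * J21;
      if (std::fabs(det) < 1e-300) stop("singular terminal system");
      double dA = (R1 * J22 - R2 * J12) / det;
      double dq = (J11 * R2 - J21 * R1) / det;
      A -= dA; q -= dq;
      if (A <= 0.0) A = 0.5 * v.A[N];
      if (std::fabs(R1) < 1e-11 * v.A0[N] &&
          std::fabs(R2) < 1e-11 * v.f[N]) {
        ok = true;
        break;
      }
    }
    if (!ok) stop("terminal Newton iteration failed to converge");
    v.An[N] = A; v.qn[N] = q;
    long idx = (gstep + 1) % n_t;
    h[idx] = q;
  }

  void step() {
    for (size_t vi = 0; vi < ves.size(); ++vi) {
      cfl_check(ves[vi], (int)vi);
      interior_step(ves[vi]);
    }
    inlet_update(inflow[(gstep + 1) % n_t]);
    for (size_t j = 0; j < jns.size(); ++j) junction_update(jns[j]);
    for (size_t vi = 0; vi < ves.size(); ++vi)
      if (ves[vi].kernel_id >= 0) terminal_update(ves[vi]);
    for (size_t vi = 0; vi < ves.size(); ++vi) {
      ves[vi].A.swap(ves[vi].An);
      ves[vi].q.swap(ves[vi].qn);
      // carry over boundary values not touched by any handler
    }
    ++gstep;
  }
};

static std::vector<double> as_vec(NumericVector x) {
  return std::vector<double>(x.begin(), x.end());
}

// [[Rcpp::export(name = ".solve_lw_cpp")]]
List solve_lw_cpp(List vessels, List junctions, int root,
                  NumericVector inflow, List kernels, double rho,
                  double nu, double delta, double dt, int n_t,
                  int max_cycles, double tol, int fixed_cycles,
                  double visc) {
  NetSolver S;
  S.rho = rho; S.nu = nu; S.delta = delta; S.dt = dt; S.n_t = n_t;
  S.visc = visc;
  S.gstep = 0; S.root = root;
  S.inflow = as_vec(inflow);
  int nv = vessels.size();
  S.ves.resize(nv);
  for (int i = 0; i < nv; ++i) {
    List vl = vessels[i];
    Vessel &v = S.ves[i];
    v.nx = as<int>(vl["nx"]);
    v.dx = as<double>(vl["dx"]);
    v.A0 = as_vec(vl["A0"]);   v.f = as_vec(vl["f"]);
    v.dA0 = as_vec(vl["dA0"]); v.df = as_vec(vl["df"]);
    v.A0h = as_vec(vl["A0h"]); v.fh = as_vec(vl["fh"]);
    v.dA0h = as_vec(vl["dA0h"]); v.dfh = as_vec(vl["dfh"]);
    v.kernel_id = as<int>(vl["kernel_id"]);
    v.A = v.A0; v.q.assign(v.nx, 0.0);
    v.An = v.A; v.qn = v.q;
    v.Ah.assign(v.nx - 1, 0.0); v.qh.assign(v.nx - 1, 0.0);
    v.F.assign(v.nx, 0.0); v.S.assign(v.nx, 0.0);
    v.Fh.assign(v.nx - 1, 0.0); v.Sh.assign(v.nx - 1, 0.0);
  }
  int nk = kernels.size();
  S.kernels.resize(nk);
  S.qhist.assign(nk, std::vector<double>(n_t, 0.0));
  for (int i = 0; i < nk; ++i) S.kernels[i] = as_vec(kernels[i]);
  int nj = junctions.size();
  S.jns.resize(nj);
  for (int j = 0; j < nj; ++j) {
    IntegerVector je = junctions[j];
    S.jns[j].parent = je[0];
    S.jns[j].nchild = je.size() - 1;
    for (int d = 0; d < S.jns[j].nchild; ++d) S.jns[j].child[d] = je[d + 1];
  }

  // per-cycle storage of the full state + mid-vessel pressure monitor
  std::vector<NumericMatrix> Asave(nv), qsave(nv);
  for (int i = 0; i < nv; ++i) {
    Asave[i] = NumericMatrix(S.ves[i].nx, n_t);
    qsave[i] = NumericMatrix(S.ves[i].nx, n_t);
  }
  std::vector<std::vector<double> > pm_prev(nv), pm_cur(nv);
  for (int i = 0; i < nv; ++i) {
    pm_prev[i].assign(n_t, 0.0);
    pm_cur[i].assign(n_t, 0.0);
  }

  int cycles_run = 0;
  bool converged = false;
  double perr = NA_REAL;
  int target = (fixed_cycles > 0) ? fixed_cycles : max_cycles;
  for (int cyc = 0; cyc < target; ++cyc) {
    for (int s = 0; s < n_t; ++s) {
      S.step();
      for (int i = 0; i < nv; ++i) {
        Vessel &v = S.ves[i];
        for (int k = 0; k < v.nx; ++k) {
          Asave[i](k, s) = v.A[k];
          qsave[i](k, s) = v.q[k];
        }
        int mid = v.nx / 2;
        pm_cur[i][s] = S.pres(v, mid, v.A[mid]);
      }
    }
    ++cycles_run;
    if (cyc > 0) {
      double worst = 0.0;
      for (int i = 0; i < nv; ++i) {
        double num = 0.0, den = 0.0;
        for (int s = 0; s < n_t; ++s) {
          double dd = pm_cur[i][s] - pm_prev[i][s];
          num += dd * dd;
          den += pm_cur[i][s] * pm_cur[i][s];
        }
        double e = std::sqrt(num / (den + 1e-300));
        if (e > worst) worst = e;
      }
      perr = worst;
      if (fixed_cycles <= 0 && worst < tol) {
        converged = true;
        break;
      }
    }
    pm_prev = pm_cur;
  }
  if (fixed_cycles > 0) converged = true;

  List out(nv);
  for (int i = 0; i < nv; ++i)
    out[i] = List::create(_["A"] = Asave[i], _["q"] = qsave[i]);
  return List::create(_["vessels"] = out, _["cycles"] = cycles_run,
                      _["converged"] = converged, _["periodicity"] = perr);
}

// Single uniform vessel, interior scheme only, ends pinned at their initial
// values: used for convergence and conservation studies on compact pulses.
// [[Rcpp::export(name = ".lw_single_cpp")]]
List lw_single_cpp(NumericVector A_init, NumericVector q_init, double A0,
                   double f, double rho, double nu, double delta,
                   double dx, double dt, int n_steps, bool friction_on) {
  int nx = A_init.size();
  NetSolver S;
  S.rho = rho; S.nu = friction_on ? nu : 0.0; S.delta = delta;
  S.dt = dt; S.n_t = 1; S.gstep = 0; S.root = 0; S.visc = 0.0;
  S.ves.resize(1);
  Vessel &v = S.ves[0];
  v.nx = nx; v.dx = dx; v.kernel_id = -1;
  v.A0.assign(nx, A0); v.f.assign(nx, f);
  v.dA0.assign(nx, 0.0); v.df.assign(nx, 0.0);
  v.A0h.assign(nx - 1, A0); v.fh.assign(nx - 1, f);
  v.dA0h.assign(nx - 1, 0.0); v.dfh.assign(nx - 1, 0.0);
  v.A = as_vec(A_init); v.q = as_vec(q_init);
  v.An = v.A; v.qn = v.q;
  v.Ah.assign(nx - 1, 0.0); v.qh.assign(nx - 1, 0.0);
  v.F.assign(nx, 0.0); v.S.assign(nx, 0.0);
  v.Fh.assign(nx - 1, 0.0); v.Sh.assign(nx - 1, 0.0);
  NumericVector mass(n_steps);
  for (int s = 0; s < n_steps; ++s) {
    S.cfl_check(v, 0);
    S.interior_step(v);
    // ends held fixed
    v.An[0] = v.A[0]; v.qn[0] = v.q[0];
    v.An[nx - 1] = v.A[nx - 1]; v.qn[nx - 1] = v.q[nx - 1];
    v.A.swap(v.An); v.q.swap(v.qn);
    double m = 0.0;
    for (int i = 0; i < nx; ++i) m += v.A[i];
    mass[s] = m * dx;
  }
  return List::create(_["A"] = NumericVector(v.A.begin(), v.A.end()),
                      _["q"] = NumericVector(v.q.begin(), v.q.end()),
                      _["mass"] = mass);
}
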