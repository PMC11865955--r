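#include <Rcpp.h>
#include <complex>
#include <vector>
#include <cmath>

using namespace Rcpp;
typedef std::complex<double> cd;

// Ratio J1(z)/J0(z) for complex z.
// Moderate |z|: continued fraction from the three-term recurrence
// (modified Lentz); large |z| with Im(z) > 0: asymptotic ratio from the
// Hankel-type P/Q expansions, where the e^{-iz} branch dominates.
static cd besselj_ratio(cd z) {
  double az = std::abs(z);
  if (az < 1e-8) return z / 2.0;
  if (az <= 15.0) {
    const double tiny = 1e-290;
    cd f(tiny, 0.0), C = f, D(0.0, 0.0);
    for (int k = 1; k <= 2000; ++k) {
      cd b = 2.0 * (double)k / z;
      cd a = (k == 1) ? cd(1.0, 0.0) : cd(-1.0, 0.0);
      D = b + a * D;
      if (std::abs(D) < tiny) D = tiny;
      C = b + a / C;
      if (std::abs(C) < tiny) C = tiny;
      D = 1.0 / D;
      cd delta = C * D;
      f *= delta;
      if (std::abs(delta - 1.0) < 1e-15) break;
    }
    return f;
  }
  // asymptotic (valid here: arg(z) = 3*pi/4, Im z >> 0); relative error
  // ~1e-6 at |z| = 15, falling as |z|^-4
  cd iz2 = 1.0 / (z * z);
  cd P0 = 1.0 - 9.0 / 128.0 * iz2;
  cd Q0 = -1.0 / (8.0 * z) + 75.0 / (1024.0 * z * z * z);
  cd P1 = 1.0 + 15.0 / 128.0 * iz2;
  cd Q1 = 3.0 / (8.0 * z) - 105.0 / (1024.0 * z * z * z);
  cd i(0.0, 1.0);
  return i * (P1 - i * Q1) / (P0 - i * Q0);
}

// Womersley viscous factor F_J = 2 J1(w)/(w J0(w)), w^2 = i^3 r^2 omega / nu
static cd womersley_fj(double r, double omega, double nu) {
  double x = r * std::sqrt(omega / nu);
  cd w = x * std::polar(1.0, 3.0 * M_PI / 4.0); // i^{3/2} x
  return 2.0 * besselj_ratio(w) / w;
}

// [[Rcpp::export(name = ".womersley_fj_cpp")]]
ComplexVector womersley_fj_cpp(NumericVector r, NumericVector omega,
                               double nu) {
  int n = std::max(r.size(), omega.size());
  ComplexVector out(n);
  for (int k = 0; k < n; ++k) {
    double rr = r[k % r.size()], om = omega[k % omega.size()];
    cd v = womersley_fj(rr, om, nu);
    out[k] = Rcomplex{v.real(), v.imag()};
  }
  return out;
}

// Input impedance of one small vessel given its distal impedance ZL.
// omega = 0 uses the analytic Poiseuille limit Z0 = 8 mu L /(pi r^4) + ZL.
static cd vessel_z0(cd ZL, double omega, double r, double L, double Ehr,
                    double rho, double mu) {
  if (omega <= 0.0) {
    return ZL + 8.0 * mu * L / (M_PI * r * r * r * r);
  }
  double A0 = M_PI * r * r;
  double Ccomp = 3.0 * A0 / (2.0 * Ehr); // dA/dp at A0
  cd FJ = womersley_fj(r, omega, mu / rho);
  cd sm = std::sqrt(1.0 - FJ);
  // g = sqrt(C A0 (1-FJ)/rho), c = sqrt(A0 (1-FJ)/(rho C)) share sqrt(1-FJ)
  cd g = std::sqrt(Ccomp * A0 / rho) * sm;
  cd c = std::sqrt(A0 / (rho * Ccomp)) * sm;
  cd kL = omega * L / c;
  cd i(0.0, 1.0);
  cd e = std::exp(i * kL), einv = 1.0 / e;
  cd s = (e - einv) / (2.0 * i), co = (e + einv) / 2.0;
  return (i / g * s + ZL * co) / (co + i * g * ZL * s);
}

// Termination with a smooth pinch ramp, so the root impedance is a
// continuous (C1) function of alpha, beta, lrr and r_min:
//   r >= r_min              : full vessel, recurse into both daughters
//   PINCH*r_min <= r < r_min: terminal stub with zero distal impedance and
//                             length L = smoothstep(t) * lrr * r,
//                             t = (r - PINCH r_min)/((1-PINCH) r_min)
//   r < PINCH*r_min         : zero-impedance short (the arteriolar
//                             termination assumption applied at the
//                             junction; it shorts the sibling branch)
// At r = r_min the stub equals the smallest full leaf and at the lower edge
// its length (hence impedance) vanishes, so no topology jump remains.
static const double PINCH = 0.9;

struct TreeMemo {
  double r_root, alpha, beta, lrr, rmin, ks1, ks2, ks3, rho, mu;
  const std::vector<double> *omega;
  std::vector<std::vector<std::vector<cd> > > memo;
  std::vector<std::vector<char> > done;

  double ehr(double r) const { return ks1 * std::exp(ks2 * r) + ks3; }

  // daughter input impedance including pinch handling; short -> all zeros
  std::vector<cd> daughter(int a, int b) {
    double r = r_root * std::pow(alpha, a) * std::pow(beta, b);
    int K = (int)omega->size();
    if (r >= rmin) return compute(a, b);
    std::vector<cd> Z(K, cd(0.0, 0.0));
    if (r > PINCH * rmin) {
      double t = (r - PINCH * rmin) / ((1.0 - PINCH) * rmin);
      double w = t * t * (3.0 - 2.0 * t);
      double L = w * lrr * r;
      for (int k = 0; k < K; ++k)
        Z[k] = vessel_z0(cd(0.0, 0.0), (*omega)[k], r, L, ehr(r), rho, mu);
    }
    return Z;
  }

  std::vector<cd> &compute(int a, int b) {
    if (done[a][b]) return memo[a][b];
    double r = r_root * std::pow(alpha, a) * std::pow(beta, b);
    double L = lrr * r;
    int K = (int)omega->size();
    std::vector<cd> ZL(K, cd(0.0, 0.0));
    std::vector<cd> Za = daughter(a + 1, b);
    std::vector<cd> Zb = daughter(a, b + 1);
    for (int k = 0; k < K; ++k) {
      if (std::abs(Za[k]) == 0.0 || std::abs(Zb[k]) == 0.0) {
        ZL[k] = cd(0.0, 0.0); // a shorted daughter grounds the junction
      } else {
        ZL[k] = Za[k] * Zb[k] / (Za[k] + Zb[k]);
      }
    }
    std::vector<cd> Z0(K);
    for (int k = 0; k < K; ++k)
      Z0[k] = vessel_z0(ZL[k], (*omega)[k], r, L, ehr(r), rho, mu);
    memo[a][b] = Z0;
    done[a][b] = 1;
    return memo[a][b];
  }
};

// Root input impedance spectrum of an asymmetric structured tree.
// [[Rcpp::export(name = ".root_impedance_cpp")]]
ComplexVector root_impedance_cpp(double r_root, double alpha, double beta,
                                 double lrr, double r_min, double ks1,
                                 double ks2, double ks3, double rho,
                                 double mu, NumericVector omega) {
  if (r_root <= r_min)
    stop("empty structured tree: r_root must exceed r_min");
  if (!(beta <= alpha && alpha < 1.0 && beta > 0.0))
    stop("require 0 < beta <= alpha < 1");
  int amax = 0, bmax = 0;
  while (r_root * std::pow(alpha, amax + 1) >= r_min && amax < 5000) ++amax;
  while (r_root * std::pow(beta, bmax + 1) >= r_min && bmax < 5000) ++bmax;
  std::vector<double> om(omega.begin(), omega.end());
  TreeMemo tm;
  tm.r_root = r_root; tm.alpha = alpha; tm.beta = beta; tm.lrr = lrr;
  tm.rmin = r_min; tm.ks1 = ks1; tm.ks2 = ks2; tm.ks3 = ks3;
  tm.rho = rho; tm.mu = mu; tm.omega = &om;
  tm.memo.assign(amax + 2, std::vector<std::vector<cd> >(bmax + 2));
  tm.done.assign(amax + 2, std::vector<char>(bmax + 2, 0));
  std::vector<cd> &Z = tm.compute(0, 0);
  ComplexVector out(om.size());
  for (size_t k = 0; k < om.size(); ++k)
    out[k] = Rcomplex{Z[k].real(), Z[k].imag()};
  return out;
}
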