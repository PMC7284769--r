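// Core numerical kernels: force field evaluation, equilibrium Monte Carlo
// sampler, NVT integrators, and the single-chain structure factor.
// Reduced units throughout: epsilon = sigma = m = k_B T-scale = 1 by default.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct FF {
  double eps, sigma, kappa, rmax, b;   // b = bending stiffness in k_BT units
  double rc2;                          // WCA cutoff squared: (2^(1/6) sigma)^2
  double rmax2;
};

FF make_ff(double eps, double sigma, double kappa, double rmax, double b) {
  FF p;
  p.eps = eps; p.sigma = sigma; p.kappa = kappa; p.rmax = rmax; p.b = b;
  p.rc2 = std::pow(2.0, 1.0 / 3.0) * sigma * sigma;
  p.rmax2 = rmax * rmax;
  return p;
}

// WCA pair energy from squared distance; 0 beyond cutoff.
inline double wca_e2(double r2, const FF& p) {
  if (r2 >= p.rc2) return 0.0;
  double s2 = p.sigma * p.sigma / r2;
  double s6 = s2 * s2 * s2;
  return 4.0 * p.eps * (s6 * s6 - s6) + p.eps;
}

// dU/dr * (1/r) for the WCA pair term (used as force prefactor).
inline double wca_dudr_over_r(double r2, const FF& p) {
  if (r2 >= p.rc2) return 0.0;
  double s2 = p.sigma * p.sigma / r2;
  double s6 = s2 * s2 * s2;
  // dU/dr = -24 eps (2 s12 - s6)/r ; divide by r again for vector use
  return -24.0 * p.eps * (2.0 * s6 * s6 - s6) / r2;
}

inline double fene_e(double l, const FF& p) {
  double x = l / p.rmax;
  return -0.5 * p.kappa * p.rmax2 * std::log(1.0 - x * x);
}

// dU/dl / l for FENE
inline double fene_dudr_over_r(double l2, const FF& p) {
  return p.kappa / (1.0 - l2 / p.rmax2);
}

struct Array2D {
  bool use;
  double Sp, Dp;
  double reach;  // Dp/2 + 2^(1/6) sigma: beyond this axis distance, no force
};

// Shifted WCA energy of a bead against one post at axis distance r.
// Negative s (bead inside effective core) signalled by caller.
inline double post_e(double raxis, const Array2D& a, const FF& p) {
  double s = raxis - 0.5 * a.Dp;
  if (s * s >= p.rc2 || s <= 0.0) return (s <= 0.0) ? R_PosInf : 0.0;
  return wca_e2(s * s, p);
}

// Sum of shifted-WCA energies of bead (y,z) over all lattice posts within
// reach.  Posts sit at (m Sp, n Sp); the window is computed from the reach so
// the lattice is effectively infinite.  Returns +Inf on core overlap.
inline double post_energy_yz(double y, double z, const Array2D& a, const FF& p) {
  double e = 0.0;
  int m0 = (int)std::ceil((y - a.reach) / a.Sp);
  int m1 = (int)std::floor((y + a.reach) / a.Sp);
  int n0 = (int)std::ceil((z - a.reach) / a.Sp);
  int n1 = (int)std::floor((z + a.reach) / a.Sp);
  for (int m = m0; m <= m1; ++m) {
    for (int n = n0; n <= n1; ++n) {
      double dy = y - m * a.Sp, dz = z - n * a.Sp;
      double r = std::sqrt(dy * dy + dz * dz);
      double s = r - 0.5 * a.Dp;
      if (s <= 0.0) return R_PosInf;
      if (s * s < p.rc2) e += wca_e2(s * s, p);
    }
  }
  return e;
}

// Accumulate post force on bead (y,z) into (fy,fz); returns false on overlap.
inline bool post_force_yz(double y, double z, const Array2D& a, const FF& p,
                          double& fy, double& fz) {
  int m0 = (int)std::ceil((y - a.reach) / a.Sp);
  int m1 = (int)std::floor((y + a.reach) / a.Sp);
  int n0 = (int)std::ceil((z - a.reach) / a.Sp);
  int n1 = (int)std::floor((z + a.reach) / a.Sp);
  for (int m = m0; m <= m1; ++m) {
    for (int n = n0; n <= n1; ++n) {
      double dy = y - m * a.Sp, dz = z - n * a.Sp;
      double r = std::sqrt(dy * dy + dz * dz);
      double s = r - 0.5 * a.Dp;
      if (s <= 0.0) return false;
      if (s * s < p.rc2) {
        double s2 = p.sigma * p.sigma / (s * s);
        double s6 = s2 * s2 * s2;
        double dUds = -24.0 * p.eps * (2.0 * s6 * s6 - s6) / s;
        // force = -dU/ds * (rho_hat)
        fy += -dUds * dy / r;
        fz += -dUds * dz / r;
      }
    }
  }
  return true;
}

inline double dist2(const std::vector<double>& x, const std::vector<double>& y,
                    const std::vector<double>& z, int i, int j) {
  double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
  return dx * dx + dy * dy + dz * dz;
}

// Bending energy of the angle centred on bead i (bonds i-1->i, i->i+1):
// U = b (1 - u1.u2), zero for a straight chain.
inline double bend_e(const std::vector<double>& x, const std::vector<double>& y,
                     const std::vector<double>& z, int i, const FF& p) {
  double ax = x[i] - x[i - 1], ay = y[i] - y[i - 1], az = z[i] - z[i - 1];
  double bx = x[i + 1] - x[i], by = y[i + 1] - y[i], bz = z[i + 1] - z[i];
  double la = std::sqrt(ax * ax + ay * ay + az * az);
  double lb = std::sqrt(bx * bx + by * by + bz * bz);
  double c = (ax * bx + ay * by + az * bz) / (la * lb);
  if (c > 1.0) c = 1.0; else if (c < -1.0) c = -1.0;
  return p.b * (1.0 - c);
}

struct EnergyBreak {
  double wca, fene, bend, post;
  bool overstretch, overlap;
  double total() const { return wca + fene + bend + post; }
};

EnergyBreak total_energy(const std::vector<double>& x,
                         const std::vector<double>& y,
                         const std::vector<double>& z,
                         const FF& p, const Array2D& a) {
  int n = (int)x.size();
  EnergyBreak e{0, 0, 0, 0, false, false};
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      e.wca += wca_e2(dist2(x, y, z, i, j), p);
  for (int i = 0; i + 1 < n; ++i) {
    double l2 = dist2(x, y, z, i, i + 1);
    if (l2 >= p.rmax2) { e.overstretch = true; return e; }
    e.fene += fene_e(std::sqrt(l2), p);
  }
  if (p.b > 0.0)
    for (int i = 1; i + 1 < n; ++i) e.bend += bend_e(x, y, z, i, p);
  if (a.use) {
    for (int i = 0; i < n; ++i) {
      double pe = post_energy_yz(y[i], z[i], a, p);
      if (!R_FINITE(pe)) { e.overlap = true; return e; }
      e.post += pe;
    }
  }
  return e;
}

void total_forces(const std::vector<double>& x, const std::vector<double>& y,
                  const std::vector<double>& z, const FF& p, const Array2D& a,
                  std::vector<double>& fx, std::vector<double>& fy,
                  std::vector<double>& fz, bool& bad) {
  int n = (int)x.size();
  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);
  std::fill(fz.begin(), fz.end(), 0.0);
  bad = false;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
      double r2 = dx * dx + dy * dy + dz * dz;
      double g = wca_dudr_over_r(r2, p);  // dU/dr / r
      if (g != 0.0) {
        fx[i] -= g * dx; fy[i] -= g * dy; fz[i] -= g * dz;
        fx[j] += g * dx; fy[j] += g * dy; fz[j] += g * dz;
      }
    }
  }
  for (int i = 0; i + 1 < n; ++i) {
    double dx = x[i] - x[i + 1], dy = y[i] - y[i + 1], dz = z[i] - z[i + 1];
    double l2 = dx * dx + dy * dy + dz * dz;
    if (l2 >= p.rmax2) { bad = true; return; }
    double g = fene_dudr_over_r(l2, p);  // dU/dl / l
    fx[i] -= g * dx; fy[i] -= g * dy; fz[i] -= g * dz;
    fx[i + 1] += g * dx; fy[i + 1] += g * dy; fz[i + 1] += g * dz;
  }
  if (p.b > 0.0) {
    for (int i = 1; i + 1 < n; ++i) {
      double ax = x[i] - x[i - 1], ay = y[i] - y[i - 1], az = z[i] - z[i - 1];
      double bx = x[i + 1] - x[i], by = y[i + 1] - y[i], bz = z[i + 1] - z[i];
      double la = std::sqrt(ax * ax + ay * ay + az * az);
      double lb = std::sqrt(bx * bx + by * by + bz * bz);
      double iab = 1.0 / (la * lb);
      double c = (ax * bx + ay * by + az * bz) * iab;
      if (c > 1.0) c = 1.0; else if (c < -1.0) c = -1.0;
      // E = b(1 - c); dc/dr1 = (u2 - c u1)/l1, dc/dr2 = (u1 - c u2)/l2
      double u1x = ax / la, u1y = ay / la, u1z = az / la;
      double u2x = bx / lb, u2y = by / lb, u2z = bz / lb;
      double d1x = (u2x - c * u1x) / la, d1y = (u2y - c * u1y) / la,
             d1z = (u2z - c * u1z) / la;
      double d2x = (u1x - c * u2x) / lb, d2y = (u1y - c * u2y) / lb,
             d2z = (u1z - c * u2z) / lb;
      // dE/dA = b d1 ; dE/dC = -b d2 ; dE/dB = -(dE/dA + dE/dC); F = -dE/dr
      double gAx = p.b * d1x, gAy = p.b * d1y, gAz = p.b * d1z;
      double gCx = -p.b * d2x, gCy = -p.b * d2y, gCz = -p.b * d2z;
      fx[i - 1] -= gAx; fy[i - 1] -= gAy; fz[i - 1] -= gAz;
      fx[i + 1] -= gCx; fy[i + 1] -= gCy; fz[i + 1] -= gCz;
      fx[i] += gAx + gCx; fy[i] += gAy + gCy; fz[i] += gAz + gCz;
    }
  }
  if (a.use) {
    for (int i = 0; i < n; ++i) {
      if (!post_force_yz(y[i], z[i], a, p, fy[i], fz[i])) { bad = true; return; }
    }
  }
}

void rodrigues(double ux, double uy, double uz, double ang, double R[3][3]) {
  double c = std::cos(ang), s = std::sin(ang), t = 1.0 - c;
  R[0][0] = c + ux * ux * t; R[0][1] = ux * uy * t - uz * s; R[0][2] = ux * uz * t + uy * s;
  R[1][0] = uy * ux * t + uz * s; R[1][1] = c + uy * uy * t; R[1][2] = uy * uz * t - ux * s;
  R[2][0] = uz * ux * t - uy * s; R[2][1] = uz * uy * t + ux * s; R[2][2] = c + uz * uz * t;
}

NumericMatrix snapshot(const std::vector<double>& x, const std::vector<double>& y,
                       const std::vector<double>& z) {
  int n = (int)x.size();
  NumericMatrix m(n, 3);
  for (int i = 0; i < n; ++i) { m(i, 0) = x[i]; m(i, 1) = y[i]; m(i, 2) = z[i]; }
  return m;
}

}  // namespace

// [[Rcpp::export(name = ".chain_energy_cpp")]]
List chain_energy_cpp(NumericMatrix pos, double eps, double sigma, double kappa,
                      double rmax, double b, bool use_array, double Sp, double Dp) {
  int n = pos.nrow();
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) { x[i] = pos(i, 0); y[i] = pos(i, 1); z[i] = pos(i, 2); }
  FF p = make_ff(eps, sigma, kappa, rmax, b);
  Array2D a{use_array, Sp, Dp, 0.5 * Dp + std::pow(2.0, 1.0 / 6.0) * sigma};
  EnergyBreak e = total_energy(x, y, z, p, a);
  if (e.overstretch) stop("bond overstretch: a bond length reached r_max");
  if (e.overlap) stop("bead inside post core (divergent overlap)");
  return List::create(_["wca"] = e.wca, _["fene"] = e.fene, _["bend"] = e.bend,
                      _["post"] = e.post, _["total"] = e.total());
}

// [[Rcpp::export(name = ".chain_forces_cpp")]]
NumericMatrix chain_forces_cpp(NumericMatrix pos, double eps, double sigma,
                               double kappa, double rmax, double b,
                               bool use_array, double Sp, double Dp) {
  int n = pos.nrow();
  std::vector<double> x(n), y(n), z(n), fx(n), fy(n), fz(n);
  for (int i = 0; i < n; ++i) { x[i] = pos(i, 0); y[i] = pos(i, 1); z[i] = pos(i, 2); }
  FF p = make_ff(eps, sigma, kappa, rmax, b);
  Array2D a{use_array, Sp, Dp, 0.5 * Dp + std::pow(2.0, 1.0 / 6.0) * sigma};
  bool bad = false;
  total_forces(x, y, z, p, a, fx, fy, fz, bad);
  if (bad) stop("force evaluation failed: overstretched bond or post overlap");
  NumericMatrix f(n, 3);
  for (int i = 0; i < n; ++i) { f(i, 0) = fx[i]; f(i, 1) = fy[i]; f(i, 2) = fz[i]; }
  return f;
}

// Equilibrium Metropolis sampler for a FREE chain (no posts): mixture of
// single-bead displacement, crankshaft and pivot moves.  Uses R's RNG so
// set.seed() on the R side makes runs reproducible.
// [[Rcpp::export(name = ".mc_run_cpp")]]
List mc_run_cpp(NumericMatrix pos0, double eps, double sigma, double kappa,
                double rmax, double b, double temp, double n_moves_d,
                double p_pivot, double p_crank, double disp_delta,
                double rot_amp, double pivot_amp, double sample_every_d) {
  long long n_moves = (long long)n_moves_d;
  long long sample_every = (long long)sample_every_d;
  int n = pos0.nrow();
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) { x[i] = pos0(i, 0); y[i] = pos0(i, 1); z[i] = pos0(i, 2); }
  FF p = make_ff(eps, sigma, kappa, rmax, b);
  double beta = 1.0 / temp;
  const double HARD2 = 0.36 * sigma * sigma;  // r < 0.6 sigma: auto-reject

  // local energy of bead i: WCA vs all, FENE bonds, adjacent bending angles
  auto local_e = [&](int i) -> double {
    double e = 0.0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      e += wca_e2(dist2(x, y, z, i, j), p);
    }
    if (i > 0) {
      double l2 = dist2(x, y, z, i - 1, i);
      if (l2 >= p.rmax2) return R_PosInf;
      e += fene_e(std::sqrt(l2), p);
    }
    if (i + 1 < n) {
      double l2 = dist2(x, y, z, i, i + 1);
      if (l2 >= p.rmax2) return R_PosInf;
      e += fene_e(std::sqrt(l2), p);
    }
    if (p.b > 0.0)
      for (int c = i - 1; c <= i + 1; ++c)
        if (c >= 1 && c + 1 < n) e += bend_e(x, y, z, c, p);
    return e;
  };

  long long acc[3] = {0, 0, 0}, att[3] = {0, 0, 0};
  std::vector<NumericMatrix> frames;
  std::vector<double> ox(n), oy(n), oz(n);

  for (long long mv = 1; mv <= n_moves; ++mv) {
    double u = unif_rand();
    if (u < p_pivot && n >= 3) {
      // ---- pivot ----
      att[0]++;
      int k = 1 + (int)(unif_rand() * (n - 2));  // pivot bead, interior
      bool tail = (n - 1 - k) <= k;              // rotate the shorter side
      int lo = tail ? k + 1 : 0, hi = tail ? n - 1 : k - 1;
      // random axis (uniform on sphere), limited angle
      double a1 = norm_rand(), a2 = norm_rand(), a3 = norm_rand();
      double an = std::sqrt(a1 * a1 + a2 * a2 + a3 * a3);
      if (an < 1e-12) continue;
      double ang = pivot_amp * (2.0 * unif_rand() - 1.0);
      double R[3][3];
      rodrigues(a1 / an, a2 / an, a3 / an, ang, R);
      double e_old = (p.b > 0.0) ? bend_e(x, y, z, k, p) : 0.0;
      for (int i = lo; i <= hi; ++i) { ox[i] = x[i]; oy[i] = y[i]; oz[i] = z[i]; }
      // apply rotation about bead k
      for (int i = lo; i <= hi; ++i) {
        double dx = x[i] - x[k], dy = y[i] - y[k], dz = z[i] - z[k];
        x[i] = x[k] + R[0][0] * dx + R[0][1] * dy + R[0][2] * dz;
        y[i] = y[k] + R[1][0] * dx + R[1][1] * dy + R[1][2] * dz;
        z[i] = z[k] + R[2][0] * dx + R[2][1] * dy + R[2][2] * dz;
      }
      // cross-segment WCA difference in one pass (new minus old), with a
      // cheap axis cull: a pair beyond the cutoff in any one coordinate
      // contributes nothing.
      const double rc = std::sqrt(p.rc2);
      double dcross = 0.0;
      bool reject = false;
      const int jlo = tail ? 0 : k, jhi = tail ? k : n - 1;
      for (int i = lo; i <= hi && !reject; ++i) {
        const double xi = x[i], yi = y[i], zi = z[i];
        const double oxi = ox[i], oyi = oy[i], ozi = oz[i];
        for (int j = jlo; j <= jhi; ++j) {
          double dx = xi - x[j];
          if (dx < rc && dx > -rc) {
            double dy = yi - y[j], dz = zi - z[j];
            double r2 = dx * dx + dy * dy + dz * dz;
            if (r2 < p.rc2) {
              if (r2 < HARD2 && !(j == k && (i == k + 1 || i == k - 1))) {
                reject = true; break;
              }
              dcross += wca_e2(r2, p);
            }
          }
          double odx = oxi - x[j];
          if (odx < rc && odx > -rc) {
            double ody = oyi - y[j], odz = ozi - z[j];
            double or2 = odx * odx + ody * ody + odz * odz;
            if (or2 < p.rc2) dcross -= wca_e2(or2, p);
          }
        }
      }
      double e_new = (p.b > 0.0) ? bend_e(x, y, z, k, p) : 0.0;
      double dE = dcross + (e_new - e_old);
      if (!reject && (dE <= 0.0 || unif_rand() < std::exp(-beta * dE))) {
        acc[0]++;
      } else {
        for (int i = lo; i <= hi; ++i) { x[i] = ox[i]; y[i] = oy[i]; z[i] = oz[i]; }
      }
    } else if (u < p_pivot + p_crank && n >= 3) {
      // ---- crankshaft: rotate bead i about the (i-1, i+1) axis ----
      att[1]++;
      int i = 1 + (int)(unif_rand() * (n - 2));
      double axx = x[i + 1] - x[i - 1], axy = y[i + 1] - y[i - 1],
             axz = z[i + 1] - z[i - 1];
      double an = std::sqrt(axx * axx + axy * axy + axz * axz);
      if (an < 1e-9) continue;
      double ang = rot_amp * (2.0 * unif_rand() - 1.0);
      double R[3][3];
      rodrigues(axx / an, axy / an, axz / an, ang, R);
      double e_old = local_e(i);
      double px = x[i], py = y[i], pz = z[i];
      double dx = x[i] - x[i - 1], dy = y[i] - y[i - 1], dz = z[i] - z[i - 1];
      x[i] = x[i - 1] + R[0][0] * dx + R[0][1] * dy + R[0][2] * dz;
      y[i] = y[i - 1] + R[1][0] * dx + R[1][1] * dy + R[1][2] * dz;
      z[i] = z[i - 1] + R[2][0] * dx + R[2][1] * dy + R[2][2] * dz;
      double e_new = local_e(i);
      double dE = e_new - e_old;
      if (R_FINITE(dE) && (dE <= 0.0 || unif_rand() < std::exp(-beta * dE))) {
        acc[1]++;
      } else {
        x[i] = px; y[i] = py; z[i] = pz;
      }
    } else {
      // ---- single-bead displacement ----
      att[2]++;
      int i = (int)(unif_rand() * n);
      if (i >= n) i = n - 1;
      double e_old = local_e(i);
      double px = x[i], py = y[i], pz = z[i];
      x[i] += disp_delta * (2.0 * unif_rand() - 1.0);
      y[i] += disp_delta * (2.0 * unif_rand() - 1.0);
      z[i] += disp_delta * (2.0 * unif_rand() - 1.0);
      double e_new = local_e(i);
      double dE = e_new - e_old;
      if (R_FINITE(dE) && (dE <= 0.0 || unif_rand() < std::exp(-beta * dE))) {
        acc[2]++;
      } else {
        x[i] = px; y[i] = py; z[i] = pz;
      }
    }
    if (sample_every > 0 && mv % sample_every == 0)
      frames.push_back(snapshot(x, y, z));
    if (mv % 100000 == 0) Rcpp::checkUserInterrupt();
  }

  List fl(frames.size());
  for (size_t i = 0; i < frames.size(); ++i) fl[i] = frames[i];
  return List::create(
      _["frames"] = fl, _["final"] = snapshot(x, y, z),
      _["attempted"] = NumericVector::create(_["pivot"] = (double)att[0],
                                             _["crank"] = (double)att[1],
                                             _["disp"] = (double)att[2]),
      _["accepted"] = NumericVector::create(_["pivot"] = (double)acc[0],
                                            _["crank"] = (double)acc[1],
                                            _["disp"] = (double)acc[2]));
}

// NVT / NVE integrator (velocity-Verlet core).  thermostat: 0 = none (NVE),
// 1 = Nose-Hoover (single variable, Q = dof * T * tau^2), 2 = Langevin
// (BAOAB, friction 1/tau).  Uses R's RNG (Langevin noise only).
// [[Rcpp::export(name = ".md_run_cpp")]]
List md_run_cpp(NumericMatrix pos0, NumericMatrix vel0, double eps, double sigma,
                double kappa, double rmax, double b, bool use_array, double Sp,
                double Dp, double dt, double n_steps_d, double sample_every_d,
                int thermostat, double temp, double tau_t, int dof_mode) {
  long long n_steps = (long long)n_steps_d;
  long long sample_every = (long long)sample_every_d;
  int n = pos0.nrow();
  std::vector<double> x(n), y(n), z(n), vx(n), vy(n), vz(n);
  for (int i = 0; i < n; ++i) {
    x[i] = pos0(i, 0); y[i] = pos0(i, 1); z[i] = pos0(i, 2);
    vx[i] = vel0(i, 0); vy[i] = vel0(i, 1); vz[i] = vel0(i, 2);
  }
  FF p = make_ff(eps, sigma, kappa, rmax, b);
  Array2D a{use_array, Sp, Dp, 0.5 * Dp + std::pow(2.0, 1.0 / 6.0) * sigma};
  double dof = (dof_mode == 0) ? (3.0 * n - 3.0) : (3.0 * n);
  double Q = dof * temp * tau_t * tau_t;  // Nose-Hoover mass
  double xi = 0.0;
  double gamma = 1.0 / tau_t;
  double c1 = std::exp(-gamma * dt), c2 = std::sqrt(temp * (1.0 - c1 * c1));

  std::vector<double> fx(n), fy(n), fz(n);
  bool bad = false;
  total_forces(x, y, z, p, a, fx, fy, fz, bad);
  if (bad) stop("invalid initial configuration");

  std::vector<NumericMatrix> frames;
  std::vector<double> t_samp, ekin_samp, epot_samp;
  long long fail_step = -1;

  auto kinetic = [&]() {
    double k = 0.0;
    for (int i = 0; i < n; ++i) k += vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i];
    return 0.5 * k;
  };

  for (long long st = 1; st <= n_steps; ++st) {
    if (thermostat == 2) {
      // BAOAB
      for (int i = 0; i < n; ++i) {
        vx[i] += 0.5 * dt * fx[i]; vy[i] += 0.5 * dt * fy[i]; vz[i] += 0.5 * dt * fz[i];
        x[i] += 0.5 * dt * vx[i]; y[i] += 0.5 * dt * vy[i]; z[i] += 0.5 * dt * vz[i];
      }
      for (int i = 0; i < n; ++i) {
        vx[i] = c1 * vx[i] + c2 * norm_rand();
        vy[i] = c1 * vy[i] + c2 * norm_rand();
        vz[i] = c1 * vz[i] + c2 * norm_rand();
      }
      for (int i = 0; i < n; ++i) {
        x[i] += 0.5 * dt * vx[i]; y[i] += 0.5 * dt * vy[i]; z[i] += 0.5 * dt * vz[i];
      }
      total_forces(x, y, z, p, a, fx, fy, fz, bad);
      if (bad) { fail_step = st; break; }
      for (int i = 0; i < n; ++i) {
        vx[i] += 0.5 * dt * fx[i]; vy[i] += 0.5 * dt * fy[i]; vz[i] += 0.5 * dt * fz[i];
      }
    } else {
      // velocity Verlet, optional Nose-Hoover friction
      for (int i = 0; i < n; ++i) {
        vx[i] += 0.5 * dt * (fx[i] - xi * vx[i]);
        vy[i] += 0.5 * dt * (fy[i] - xi * vy[i]);
        vz[i] += 0.5 * dt * (fz[i] - xi * vz[i]);
        x[i] += dt * vx[i]; y[i] += dt * vy[i]; z[i] += dt * vz[i];
      }
      total_forces(x, y, z, p, a, fx, fy, fz, bad);
      if (bad) { fail_step = st; break; }
      if (thermostat == 1) {
        double ke = kinetic();
        xi += dt * (2.0 * ke - dof * temp) / Q;
        double denom = 1.0 + 0.5 * dt * xi;
        for (int i = 0; i < n; ++i) {
          vx[i] = (vx[i] + 0.5 * dt * fx[i]) / denom;
          vy[i] = (vy[i] + 0.5 * dt * fy[i]) / denom;
          vz[i] = (vz[i] + 0.5 * dt * fz[i]) / denom;
        }
      } else {
        for (int i = 0; i < n; ++i) {
          vx[i] += 0.5 * dt * fx[i]; vy[i] += 0.5 * dt * fy[i]; vz[i] += 0.5 * dt * fz[i];
        }
      }
    }
    if (sample_every > 0 && st % sample_every == 0) {
      EnergyBreak e = total_energy(x, y, z, p, a);
      if (e.overstretch || e.overlap) { fail_step = st; break; }
      frames.push_back(snapshot(x, y, z));
      t_samp.push_back(st * dt);
      ekin_samp.push_back(kinetic());
      epot_samp.push_back(e.total());
    }
    if (st % 20000 == 0) Rcpp::checkUserInterrupt();
  }

  List fl(frames.size());
  for (size_t i = 0; i < frames.size(); ++i) fl[i] = frames[i];
  NumericMatrix vfin(n, 3);
  for (int i = 0; i < n; ++i) { vfin(i, 0) = vx[i]; vfin(i, 1) = vy[i]; vfin(i, 2) = vz[i]; }
  return List::create(
      _["frames"] = fl, _["time"] = wrap(t_samp), _["ekin"] = wrap(ekin_samp),
      _["epot"] = wrap(epot_samp), _["final"] = snapshot(x, y, z),
      _["vel_final"] = vfin, _["dof"] = dof,
      _["fail_step"] = (double)fail_step);
}

// Orientationally averaged single-chain structure factor:
// S(q) = (1/N^2) < sum_ij sin(q r_ij) / (q r_ij) >, i = j terms contribute 1.
// [[Rcpp::export(name = ".sq_cpp")]]
NumericVector sq_cpp(List frames, NumericVector q) {
  int nf = frames.size(), nq = q.size();
  NumericVector S(nq);
  if (nf == 0) return S;
  for (int f = 0; f < nf; ++f) {
    NumericMatrix m = frames[f];
    int n = m.nrow();
    std::vector<double> d;
    d.reserve((size_t)n * (n - 1) / 2);
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double dx = m(i, 0) - m(j, 0), dy = m(i, 1) - m(j, 1), dz = m(i, 2) - m(j, 2);
        d.push_back(std::sqrt(dx * dx + dy * dy + dz * dz));
      }
    for (int k = 0; k < nq; ++k) {
      double qq = q[k], s = 0.0;
      for (size_t t = 0; t < d.size(); ++t) {
        double qr = qq * d[t];
        s += (qr < 1e-8) ? 1.0 : std::sin(qr) / qr;
      }
      S[k] += (n + 2.0 * s) / ((double)n * n);
    }
    Rcpp::checkUserInterrupt();
  }
  for (int k = 0; k < nq; ++k) S[k] /= nf;
  return S;
}
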