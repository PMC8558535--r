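#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Rigid three-site water Metropolis Monte Carlo in a cubic periodic box.
// Energy: Lennard-Jones on O-O plus Coulomb over all site pairs, with a
// spherical cutoff applied to the O-O distance; the O-O minimum-image
// shift is applied to the partner molecule as a whole so molecules are
// never split across the boundary. Uses R's RNG, so set.seed() in R
// makes runs reproducible.

static const double COULOMB = 332.0637; // kcal A / (mol e^2)

static inline double wrap(double d, double box) {
  return d - box * std::round(d / box);
}

// interaction energy of molecules i and j (site rows 3i..3i+2)
static double pair_energy(const double *x, const double *y, const double *z,
                          int i, int j, double box, double eps, double sigma,
                          double cut2, const double *q) {
  int oi = 3 * i, oj = 3 * j;
  double dx = wrap(x[oi] - x[oj], box);
  double dy = wrap(y[oi] - y[oj], box);
  double dz = wrap(z[oi] - z[oj], box);
  double r2 = dx * dx + dy * dy + dz * dz;
  if (r2 > cut2) return 0.0;
  // image shift to apply to molecule j's sites
  double sx = dx - (x[oi] - x[oj]);
  double sy = dy - (y[oi] - y[oj]);
  double sz = dz - (z[oi] - z[oj]);
  double s6 = sigma * sigma / r2;
  s6 = s6 * s6 * s6;
  double e = 4.0 * eps * (s6 * s6 - s6);
  for (int a = 0; a < 3; ++a) {
    for (int b = 0; b < 3; ++b) {
      double ddx = x[oi + a] - (x[oj + b] + sx);
      double ddy = y[oi + a] - (y[oj + b] + sy);
      double ddz = z[oi + a] - (z[oj + b] + sz);
      double r = std::sqrt(ddx * ddx + ddy * ddy + ddz * ddz);
      e += COULOMB * q[a] * q[b] / r;
    }
  }
  return e;
}

static double mol_energy(const double *x, const double *y, const double *z,
                         int i, int n, double box, double eps, double sigma,
                         double cut2, const double *q) {
  double e = 0.0;
  for (int j = 0; j < n; ++j) {
    if (j == i) continue;
    e += pair_energy(x, y, z, i, j, box, eps, sigma, cut2, q);
  }
  return e;
}

// [[Rcpp::export]]
double mc_total_energy(NumericMatrix coords, int n_waters, double box,
                       double eps, double sigma, double q_o, double q_h,
                       double cutoff) {
  std::vector<double> x(coords.nrow()), y(coords.nrow()), z(coords.nrow());
  for (int k = 0; k < coords.nrow(); ++k) {
    x[k] = coords(k, 0); y[k] = coords(k, 1); z[k] = coords(k, 2);
  }
  double q[3] = {q_o, q_h, q_h};
  double cut2 = cutoff * cutoff;
  double e = 0.0;
  for (int i = 0; i < n_waters; ++i)
    for (int j = i + 1; j < n_waters; ++j)
      e += pair_energy(x.data(), y.data(), z.data(), i, j, box, eps, sigma,
                       cut2, q);
  return e;
}

// [[Rcpp::export]]
List mc_water_run(NumericMatrix coords, int n_waters, double box,
                  double eps, double sigma, double q_o, double q_h,
                  double cutoff, double kT,
                  int equil_sweeps, int prod_sweeps, int sample_interval,
                  double dt, double rot, bool tune) {
  int nsite = 3 * n_waters;
  std::vector<double> x(nsite), y(nsite), z(nsite);
  for (int k = 0; k < nsite; ++k) {
    x[k] = coords(k, 0); y[k] = coords(k, 1); z[k] = coords(k, 2);
  }
  double q[3] = {q_o, q_h, q_h};
  double cut2 = cutoff * cutoff;

  double etot = 0.0;
  for (int i = 0; i < n_waters; ++i)
    for (int j = i + 1; j < n_waters; ++j)
      etot += pair_energy(x.data(), y.data(), z.data(), i, j, box, eps,
                          sigma, cut2, q);

  int total_sweeps = equil_sweeps + prod_sweeps;
  NumericVector energy(total_sweeps);
  long accepted = 0, attempted = 0;
  long tune_acc = 0, tune_att = 0;
  List frames;

  for (int sweep = 0; sweep < total_sweeps; ++sweep) {
    for (int m = 0; m < n_waters; ++m) {
      int i = (int)(R::unif_rand() * n_waters);
      if (i >= n_waters) i = n_waters - 1;
      int oi = 3 * i;
      double e_old = mol_energy(x.data(), y.data(), z.data(), i, n_waters,
                                box, eps, sigma, cut2, q);
      double ox[3], oy[3], oz[3];
      for (int a = 0; a < 3; ++a) {
        ox[a] = x[oi + a]; oy[a] = y[oi + a]; oz[a] = z[oi + a];
      }
      // random translation
      double tx = (R::unif_rand() - 0.5) * 2.0 * dt;
      double ty = (R::unif_rand() - 0.5) * 2.0 * dt;
      double tz = (R::unif_rand() - 0.5) * 2.0 * dt;
      // random rotation about the oxygen
      double ax = R::norm_rand(), ay = R::norm_rand(), az = R::norm_rand();
      double an = std::sqrt(ax * ax + ay * ay + az * az);
      if (an < 1e-12) { ax = 1; ay = 0; az = 0; an = 1; }
      ax /= an; ay /= an; az /= an;
      double ang = (R::unif_rand() - 0.5) * 2.0 * rot;
      double c = std::cos(ang), s = std::sin(ang), t1 = 1.0 - c;
      double Rm[3][3] = {
        {c + ax * ax * t1, ax * ay * t1 - az * s, ax * az * t1 + ay * s},
        {ay * ax * t1 + az * s, c + ay * ay * t1, ay * az * t1 - ax * s},
        {az * ax * t1 - ay * s, az * ay * t1 + ax * s, c + az * az * t1}};
      for (int a = 0; a < 3; ++a) {
        double rx = ox[a] - ox[0], ry = oy[a] - oy[0], rz = oz[a] - oz[0];
        double nx = Rm[0][0] * rx + Rm[0][1] * ry + Rm[0][2] * rz;
        double ny = Rm[1][0] * rx + Rm[1][1] * ry + Rm[1][2] * rz;
        double nz = Rm[2][0] * rx + Rm[2][1] * ry + Rm[2][2] * rz;
        x[oi + a] = ox[0] + nx + tx;
        y[oi + a] = oy[0] + ny + ty;
        z[oi + a] = oz[0] + nz + tz;
      }
      double e_new = mol_energy(x.data(), y.data(), z.data(), i, n_waters,
                                box, eps, sigma, cut2, q);
      double de = e_new - e_old;
      attempted++; tune_att++;
      bool accept = de <= 0.0 || R::unif_rand() < std::exp(-de / kT);
      if (accept) {
        etot += de;
        accepted++; tune_acc++;
      } else {
        for (int a = 0; a < 3; ++a) {
          x[oi + a] = ox[a]; y[oi + a] = oy[a]; z[oi + a] = oz[a];
        }
      }
    }
    energy[sweep] = etot;
    // move-size auto-tuning during the first half of equilibration only
    if (tune && sweep < equil_sweeps / 2 && (sweep + 1) % 25 == 0) {
      double rate = tune_att > 0 ? (double)tune_acc / tune_att : 0.0;
      double f = rate > 0.45 ? 1.1 : (rate < 0.35 ? 0.9 : 1.0);
      dt = std::min(std::max(dt * f, 0.01), box / 4.0);
      rot = std::min(std::max(rot * f, 0.01), M_PI);
      tune_acc = 0; tune_att = 0;
    }
    if (sweep >= equil_sweeps &&
        (sweep - equil_sweeps + 1) % sample_interval == 0) {
      NumericMatrix fr(nsite, 3);
      for (int i = 0; i < n_waters; ++i) {
        int oi = 3 * i;
        // wrap each molecule by its oxygen for tidy output
        double wx = std::floor(x[oi] / box) * box;
        double wy = std::floor(y[oi] / box) * box;
        double wz = std::floor(z[oi] / box) * box;
        for (int a = 0; a < 3; ++a) {
          fr(oi + a, 0) = x[oi + a] - wx;
          fr(oi + a, 1) = y[oi + a] - wy;
          fr(oi + a, 2) = z[oi + a] - wz;
        }
      }
      frames.push_back(fr);
    }
    if (sweep % 200 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix final_xyz(nsite, 3);
  for (int k = 0; k < nsite; ++k) {
    final_xyz(k, 0) = x[k]; final_xyz(k, 1) = y[k]; final_xyz(k, 2) = z[k];
  }
  return List::create(
    _["frames"] = frames,
    _["energy"] = energy,
    _["coords"] = final_xyz,
    _["acceptance"] = attempted > 0 ? (double)accepted / attempted : 0.0,
    _["dt"] = dt, _["rot"] = rot);
}
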