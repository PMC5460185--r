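#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Energy model shared with the R reference implementation (total_energy):
//   bonds:      0.5 * kb * (d - deq)^2 on consecutive beads
//   restraints: w * (d - dbar)^2                   for d >= dbar
//               w * (d - dbar*log(d/dbar) - dbar)  for d <  dbar
// The lower branch has value 0 and slope 0 at d = dbar and diverges as
// d -> 0, acting as a soft excluded-volume wall. Distances below
// DFRAC * dbar are clamped for the gradient so forces stay finite.
static const double DFRAC = 0.01;
static const double DMIN = 1e-12;

static inline void pair_dist(const double* x, const double* y, const double* z,
                             int i, int j, double& dx, double& dy, double& dz,
                             double& d) {
  dx = x[i] - x[j];
  dy = y[i] - y[j];
  dz = z[i] - z[j];
  d = std::sqrt(dx * dx + dy * dy + dz * dz);
}

// accumulate gradient of E into (gx, gy, gz); returns nothing
static void accumulate_gradient(const double* x, const double* y, const double* z,
                                int n, const int* ri, const int* rj,
                                const double* dbar, const double* w, int nr,
                                const double* deq, const double* kb,
                                double* gx, double* gy, double* gz) {
  for (int i = 0; i < n; ++i) { gx[i] = 0.0; gy[i] = 0.0; gz[i] = 0.0; }
  for (int k = 0; k < n - 1; ++k) {  // bonds on consecutive beads
    double dx, dy, dz, d;
    pair_dist(x, y, z, k, k + 1, dx, dy, dz, d);
    double dd = d < DMIN ? DMIN : d;
    double coef = kb[k] * (d - deq[k]) / dd;  // dE/dd / d
    double fx = coef * dx, fy = coef * dy, fz = coef * dz;
    gx[k] += fx; gy[k] += fy; gz[k] += fz;
    gx[k + 1] -= fx; gy[k + 1] -= fy; gz[k + 1] -= fz;
  }
  for (int k = 0; k < nr; ++k) {
    int i = ri[k], j = rj[k];
    double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
    double d2 = dx * dx + dy * dy + dz * dz;
    double d = std::sqrt(d2);
    double db = dbar[k];
    double invd = 1.0 / (d < DMIN ? DMIN : d);
    double coef;  // (dE/dd) / d
    if (d >= db) {
      coef = 2.0 * w[k] * (1.0 - db * invd);
    } else if (d >= DFRAC * db) {
      coef = w[k] * (invd - db * invd * invd);
    } else {
      coef = w[k] * (1.0 - 1.0 / DFRAC) * invd;  // clamped wall gradient
    }
    double fx = coef * dx, fy = coef * dy, fz = coef * dz;
    gx[i] += fx; gy[i] += fy; gz[i] += fz;
    gx[j] -= fx; gy[j] -= fy; gz[j] -= fz;
  }
}

static double total_energy_c(const double* x, const double* y, const double* z,
                             int n, const int* ri, const int* rj,
                             const double* dbar, const double* w, int nr,
                             const double* deq, const double* kb) {
  double e = 0.0;
  for (int k = 0; k < n - 1; ++k) {
    double dx, dy, dz, d;
    pair_dist(x, y, z, k, k + 1, dx, dy, dz, d);
    double v = d - deq[k];
    e += 0.5 * kb[k] * v * v;
  }
  for (int k = 0; k < nr; ++k) {
    double dx, dy, dz, d;
    pair_dist(x, y, z, ri[k], rj[k], dx, dy, dz, d);
    double db = dbar[k];
    if (d >= db) {
      double v = d - db;
      e += w[k] * v * v;
    } else {
      double dcl = d < DFRAC * db ? DFRAC * db : d;
      e += w[k] * (dcl - db * std::log(dcl / db) - db);
    }
  }
  return e;
}

static double satisfaction_c(const double* x, const double* y, const double* z,
                             const int* ri, const int* rj, const double* dbar,
                             int nr, double lo, double hi) {
  long ok = 0;
  for (int k = 0; k < nr; ++k) {
    double dx, dy, dz, d;
    pair_dist(x, y, z, ri[k], rj[k], dx, dy, dz, d);
    if (d >= lo * dbar[k] && d <= hi * dbar[k]) ++ok;
  }
  return nr > 0 ? (double)ok / nr : NA_REAL;
}

// [[Rcpp::export(name = ".energy_gradient_cpp")]]
List energy_gradient_cpp(NumericMatrix coords, IntegerVector ri, IntegerVector rj,
                         NumericVector dbar, NumericVector w,
                         NumericVector deq, NumericVector kb) {
  int n = coords.nrow();
  std::vector<double> x(n), y(n), z(n), gx(n), gy(n), gz(n);
  for (int i = 0; i < n; ++i) { x[i] = coords(i, 0); y[i] = coords(i, 1); z[i] = coords(i, 2); }
  accumulate_gradient(x.data(), y.data(), z.data(), n, ri.begin(), rj.begin(),
                      dbar.begin(), w.begin(), ri.size(), deq.begin(), kb.begin(),
                      gx.data(), gy.data(), gz.data());
  NumericMatrix g(n, 3);
  for (int i = 0; i < n; ++i) { g(i, 0) = gx[i]; g(i, 1) = gy[i]; g(i, 2) = gz[i]; }
  double e = total_energy_c(x.data(), y.data(), z.data(), n, ri.begin(), rj.begin(),
                            dbar.begin(), w.begin(), ri.size(), deq.begin(), kb.begin());
  return List::create(_["energy"] = e, _["gradient"] = g);
}

// Velocity-assisted adaptive gradient descent. Uses R's RNG so a single
// set.seed() call in R makes the whole trajectory reproducible.
// [[Rcpp::export(name = ".optimize_cpp")]]
List optimize_cpp(NumericMatrix coords, IntegerVector ri, IntegerVector rj,
                  NumericVector dbar, NumericVector w,
                  NumericVector deq, NumericVector kb,
                  int n_steps, int resample_every, double step_scale,
                  double dt_max, double max_disp, double kick_um,
                  bool anneal, int checkpoint_every, double lo, double hi) {
  int n = coords.nrow();
  int nr = ri.size();
  std::vector<double> x(n), y(n), z(n), gx(n), gy(n), gz(n),
      vx(n, 0.0), vy(n, 0.0), vz(n, 0.0);
  for (int i = 0; i < n; ++i) { x[i] = coords(i, 0); y[i] = coords(i, 1); z[i] = coords(i, 2); }

  std::vector<int> cp_step;
  std::vector<double> cp_energy, cp_sat;
  double e0 = total_energy_c(x.data(), y.data(), z.data(), n, ri.begin(), rj.begin(),
                             dbar.begin(), w.begin(), nr, deq.begin(), kb.begin());
  cp_step.push_back(0);
  cp_energy.push_back(e0);
  cp_sat.push_back(satisfaction_c(x.data(), y.data(), z.data(), ri.begin(), rj.begin(),
                                  dbar.begin(), nr, lo, hi));
  int high_energy_run = 0;
  bool diverged = false;
  int snap_step = (int)(0.95 * n_steps);
  NumericMatrix snap(n, 3);  // coordinates after 95% of the steps

  for (int step = 1; step <= n_steps; ++step) {
    accumulate_gradient(x.data(), y.data(), z.data(), n, ri.begin(), rj.begin(),
                        dbar.begin(), w.begin(), nr, deq.begin(), kb.begin(),
                        gx.data(), gy.data(), gz.data());
    double fmax2 = 0.0, fsum2 = 0.0;
    for (int i = 0; i < n; ++i) {
      double f2 = gx[i] * gx[i] + gy[i] * gy[i] + gz[i] * gz[i];
      fsum2 += f2;
      if (f2 > fmax2) fmax2 = f2;
    }
    double fmax = std::sqrt(fmax2);
    // dt inversely proportional to the max force, capped by the curvature
    // bound dt_max so displacements become force-proportional near a minimum
    double dt = fmax > 0.0 ? step_scale / fmax : dt_max;
    if (dt > dt_max) dt = dt_max;
    if ((step - 1) % resample_every == 0) {
      // velocities sized so one resample epoch drifts each bead by at most
      // about kick_um (annealed quadratically to zero) and never beyond the
      // rms force scale: bounded exploration, no force/noise feedback loop,
      // and an exactly-satisfied conformation stays put
      double frms = std::sqrt(fsum2 / n);
      double fac = anneal ? 1.0 - (double)step / n_steps : 1.0;
      double cap = dt > 0.0 ? kick_um / (resample_every * dt) : 0.0;
      double sigma = fac * fac * (frms < cap ? frms : cap);
      for (int i = 0; i < n; ++i) {
        vx[i] = sigma * norm_rand();
        vy[i] = sigma * norm_rand();
        vz[i] = sigma * norm_rand();
      }
    }
    for (int i = 0; i < n; ++i) {
      double mx = dt * (-gx[i] + vx[i]);
      double my = dt * (-gy[i] + vy[i]);
      double mz = dt * (-gz[i] + vz[i]);
      double m2 = mx * mx + my * my + mz * mz;
      if (m2 > max_disp * max_disp) {
        double s = max_disp / std::sqrt(m2);
        mx *= s; my *= s; mz *= s;
      }
      x[i] += mx; y[i] += my; z[i] += mz;
    }
    if (step == snap_step) {
      for (int i = 0; i < n; ++i) { snap(i, 0) = x[i]; snap(i, 1) = y[i]; snap(i, 2) = z[i]; }
    }
    if (step % checkpoint_every == 0 || step == n_steps) {
      double e = total_energy_c(x.data(), y.data(), z.data(), n, ri.begin(), rj.begin(),
                                dbar.begin(), w.begin(), nr, deq.begin(), kb.begin());
      cp_step.push_back(step);
      cp_energy.push_back(e);
      cp_sat.push_back(satisfaction_c(x.data(), y.data(), z.data(), ri.begin(), rj.begin(),
                                      dbar.begin(), nr, lo, hi));
      if (!std::isfinite(e) || e > 10.0 * e0) ++high_energy_run; else high_energy_run = 0;
      if (high_energy_run >= 3) { diverged = true; break; }
    }
  }

  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) { out(i, 0) = x[i]; out(i, 1) = y[i]; out(i, 2) = z[i]; }
  return List::create(_["coords"] = out,
                      _["coords_95"] = snap,
                      _["checkpoint_step"] = wrap(cp_step),
                      _["checkpoint_energy"] = wrap(cp_energy),
                      _["checkpoint_satisfaction"] = wrap(cp_sat),
                      _["diverged"] = diverged);
}
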