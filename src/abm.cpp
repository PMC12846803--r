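#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Inverse-CDF lookup by binary search + linear interpolation; F is the
// cumulative integral of the inlet orientation density on grid th.
static inline double inv_cdf(const NumericVector &F, const NumericVector &th,
                             double u) {
  int lo = 0, hi = F.size() - 1;
  if (u <= F[0]) return th[0];
  if (u >= F[hi]) return th[hi];
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (F[mid] <= u) lo = mid; else hi = mid;
  }
  double span = F[hi] - F[lo];
  double w = span > 0 ? (u - F[lo]) / span : 0.0;
  return th[lo] + w * (th[hi] - th[lo]);
}

// Euler--Maruyama simulation of swimmers in unit shear over an absorbing
// wall at y = 0. Per timestep: inject (y draws, then theta draws), then step
// every live agent in storage order drawing one standard normal each; this
// draw order matches the pure-R reference engine exactly so both engines
// produce identical trajectories from the same RNG seed.
// [[Rcpp::export]]
List abm_run_cpp(double vs, double per, double beta, double dt,
                 double H, double l, int n_inject,
                 double t_end, double t_burnin,
                 NumericVector cdf_F, NumericVector cdf_theta,
                 bool uniform_inlet, int top_policy,
                 bool record, double record_start, int record_every,
                 int nx, int ny) {
  RNGScope scope;
  const int n_steps = (int)std::lround(t_end / dt);
  const double two_pi = 2.0 * M_PI;
  const double noise = std::sqrt(2.0 * dt / per);

  std::vector<double> x, y, th;
  std::vector<double> ev_t, ev_x;
  double injected = 0, adhered = 0, exited = 0;

  NumericMatrix counts(nx, ny);
  const double bw_x = l / nx, bw_y = H / ny;
  double n_snapshots = 0;

  std::vector<double> ynew(n_inject), tnew(n_inject);

  for (int step = 0; step < n_steps; ++step) {
    const double t0 = step * dt;

    // injection: flux-weighted heights, then inlet orientations
    for (int i = 0; i < n_inject; ++i) ynew[i] = H * std::sqrt(unif_rand());
    for (int i = 0; i < n_inject; ++i) {
      double u = unif_rand();
      tnew[i] = uniform_inlet ? two_pi * u : inv_cdf(cdf_F, cdf_theta, u);
    }
    for (int i = 0; i < n_inject; ++i) {
      x.push_back(0.0);
      y.push_back(ynew[i]);
      th.push_back(tnew[i]);
      injected += 1;
    }

    // one EM step for every live agent, compacting in place
    size_t keep = 0;
    for (size_t a = 0; a < x.size(); ++a) {
      const double xo = x[a], yo = y[a], to = th[a];
      const double xn = xo + (yo + vs * std::cos(to)) * dt;
      double yn = yo + vs * std::sin(to) * dt;
      double tn = to + 0.5 * (beta * std::cos(2.0 * to) - 1.0) * dt +
                  noise * norm_rand();

      if (yn <= 0.0) {  // absorbed: interpolate the crossing
        const double frac = yo / (yo - yn);
        const double et = t0 + frac * dt;
        adhered += 1;
        if (et >= t_burnin) {
          double ex = xo + frac * (xn - xo);
          if (ex < 0.0) ex = 0.0;
          if (ex > l) ex = l;
          ev_t.push_back(et);
          ev_x.push_back(ex);
        }
        continue;
      }
      if (xn > l) { exited += 1; continue; }
      if (yn > H) {
        if (top_policy == 0) {          // specular reflection
          yn = 2.0 * H - yn;
          tn = -tn;
        } else {                        // periodic wrap
          yn -= H * std::floor(yn / H);
        }
      }
      tn -= two_pi * std::floor(tn / two_pi);
      x[keep] = xn; y[keep] = yn; th[keep] = tn;
      ++keep;
    }
    x.resize(keep); y.resize(keep); th.resize(keep);

    const double t1 = t0 + dt;
    if (record && t1 >= record_start && (step % record_every) == 0) {
      for (size_t a = 0; a < x.size(); ++a) {
        int ix = (int)(x[a] / bw_x);
        int iy = (int)(y[a] / bw_y);
        if (ix < 0) ix = 0; if (ix >= nx) ix = nx - 1;
        if (iy < 0) iy = 0; if (iy >= ny) iy = ny - 1;
        counts(ix, iy) += 1.0;
      }
      n_snapshots += 1;
    }
  }

  return List::create(
    _["event_time"] = NumericVector(ev_t.begin(), ev_t.end()),
    _["event_x"] = NumericVector(ev_x.begin(), ev_x.end()),
    _["counts"] = counts,
    _["n_snapshots"] = n_snapshots,
    _["injected"] = injected,
    _["adhered"] = adhered,
    _["exited"] = exited,
    _["live"] = (double)x.size());
}

// Orientation-only ensemble: evolves a vector of angles under the Jeffery
// drift + rotational diffusion SDE (no walls), one normal draw per agent per
// step in input order.
// [[Rcpp::export]]
NumericVector theta_ensemble_cpp(NumericVector theta0, double per,
                                 double beta, double dt, int n_steps) {
  RNGScope scope;
  const double two_pi = 2.0 * M_PI;
  const double noise = std::sqrt(2.0 * dt / per);
  NumericVector th = clone(theta0);
  const int n = th.size();
  for (int step = 0; step < n_steps; ++step) {
    for (int a = 0; a < n; ++a) {
      double tn = th[a] + 0.5 * (beta * std::cos(2.0 * th[a]) - 1.0) * dt +
                  noise * norm_rand();
      tn -= two_pi * std::floor(tn / two_pi);
      th[a] = tn;
    }
  }
  return th;
}
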