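// Discrete-time engine for the neurite-outgrowth network.
//
// One Euler step (interval length = 1 simulated time step):
//   1. draw one uniform threshold per neuron; non-refractory neurons with
//      v >= threshold spike,
//   2. v <- v + (v_rest - v)/tau_v + sum_j eps_j * Omega_ij * spike_j,
//      clipped to [v_floor, 1],
//   3. ca <- ca - ca/tau_ca + beta_ca * spike,
//   4. spiking neurons become refractory for `refractory_steps` steps,
//   5. d <- d - rho_d*(ca - ca_target), a <- a + rho_a*(ca - ca_target),
//      both clipped at 0; Omega recomputed from the fields,
//   6. optional one-time inhibitory conversion when mean calcium first
//      reaches the target (or at a fixed step).
//
// RNG: Rcpp::runif draws from R's stream, so a run is bit-identical to the
// pure-R reference engine under the same seed.

#include <Rcpp.h>
using namespace Rcpp;

static inline double disk_overlap_1(double R, double r, double dist) {
  if (R <= 0.0 || r <= 0.0) return 0.0;
  if (dist >= R + r) return 0.0;
  double lo = std::fabs(R - r);
  if (dist <= lo) { double m = (R < r) ? R : r; return M_PI * m * m; }
  double d2 = dist * dist, R2 = R * R, r2 = r * r;
  double t1 = R2 * std::acos((d2 + R2 - r2) / (2.0 * dist * R));
  double t2 = r2 * std::acos((d2 + r2 - R2) / (2.0 * dist * r));
  double k = (-dist + R + r) * (dist + R - r) * (dist - R + r) * (dist + R + r);
  if (k < 0.0) k = 0.0;
  return t1 + t2 - 0.5 * std::sqrt(k);
}

static inline double gauss_overlap_1(double R, double r, double dist) {
  if (R <= 0.0 || r <= 0.0) return 0.0;
  double s2 = R * R + r * r;
  return 2.0 * M_PI * R * R * r * r / s2 * std::exp(-dist * dist / (2.0 * s2));
}

static void fill_omega(NumericMatrix omega, const NumericVector& a,
                       const NumericVector& d, const NumericMatrix& dist,
                       int kernel) {
  int n = a.size();
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      if (i == j) { omega(i, j) = 0.0; continue; }
      omega(i, j) = (kernel == 0)
        ? disk_overlap_1(d[i], a[j], dist(i, j))
        : gauss_overlap_1(d[i], a[j], dist(i, j));
    }
}

// [[Rcpp::export(name = ".sim_core_cpp")]]
List sim_core_cpp(int n_steps,
                  NumericVector v, NumericVector ca,
                  NumericVector a, NumericVector d,
                  NumericVector eps, IntegerVector refrac,
                  NumericMatrix dist,
                  double tau_v, double tau_ca, double v_rest, double beta_ca,
                  double ca_target, double rho_d, double rho_a,
                  int refractory_steps, double v_floor, int kernel,
                  IntegerVector inhib_idx, double w_inh_val,
                  int switch_mode, int switch_step, bool gaba_switched,
                  int record_every, bool record_raster, int t0) {
  int n = v.size();
  NumericMatrix omega(n, n);
  fill_omega(omega, a, d, dist, kernel);

  std::vector<int> sp_t, sp_u;
  if (record_raster) { sp_t.reserve(1024); sp_u.reserve(1024); }

  int n_rec = n_steps / record_every;
  NumericMatrix traj(n_rec, 7);
  int rec_i = 0;
  long win_spikes = 0;
  int switched_at = -1;
  std::vector<int> spk(n);

  for (int step = 0; step < n_steps; ++step) {
    int t = t0 + step;
    NumericVector xi = runif(n);
    for (int j = 0; j < n; ++j)
      spk[j] = (refrac[j] == 0 && v[j] >= xi[j]) ? 1 : 0;
    if (record_raster) {
      for (int j = 0; j < n; ++j)
        if (spk[j]) { sp_t.push_back(t); sp_u.push_back(j + 1); }
    }
    for (int j = 0; j < n; ++j) win_spikes += spk[j];

    for (int i = 0; i < n; ++i) {
      double inp = 0.0;
      for (int j = 0; j < n; ++j)
        if (spk[j]) inp += eps[j] * omega(i, j);
      double vn = v[i] + (v_rest - v[i]) / tau_v + inp;
      if (vn > 1.0) vn = 1.0;
      if (vn < v_floor) vn = v_floor;
      v[i] = vn;
    }
    for (int i = 0; i < n; ++i)
      ca[i] = ca[i] - ca[i] / tau_ca + beta_ca * spk[i];
    for (int i = 0; i < n; ++i) {
      if (spk[i]) refrac[i] = refractory_steps;
      else if (refrac[i] > 0) refrac[i]--;
    }
    for (int i = 0; i < n; ++i) {
      double dev = ca[i] - ca_target;
      double dn = d[i] - rho_d * dev;
      double an = a[i] + rho_a * dev;
      d[i] = (dn < 0.0) ? 0.0 : dn;
      a[i] = (an < 0.0) ? 0.0 : an;
    }
    fill_omega(omega, a, d, dist, kernel);

    if (!gaba_switched && switch_mode != 0) {
      bool trig = false;
      if (switch_mode == 1) {
        double cam = 0.0;
        for (int i = 0; i < n; ++i) cam += ca[i];
        trig = (cam / n >= ca_target);
      } else if (switch_mode == 2) {
        trig = (t >= switch_step);
      }
      if (trig) {
        for (int k = 0; k < inhib_idx.size(); ++k)
          eps[inhib_idx[k] - 1] = -w_inh_val;
        gaba_switched = true;
        switched_at = t;
      }
    }

    if ((step + 1) % record_every == 0 && rec_i < n_rec) {
      double vm = 0, cm = 0, am = 0, dm = 0, om = 0;
      for (int i = 0; i < n; ++i) { vm += v[i]; cm += ca[i]; am += a[i]; dm += d[i]; }
      for (int i = 0; i < n; ++i)
        for (int j = 0; j < n; ++j) om += omega(i, j);
      traj(rec_i, 0) = t;
      traj(rec_i, 1) = vm / n;
      traj(rec_i, 2) = cm / n;
      traj(rec_i, 3) = am / n;
      traj(rec_i, 4) = dm / n;
      traj(rec_i, 5) = om / (double(n) * (n - 1));
      traj(rec_i, 6) = double(win_spikes) / (double(n) * record_every);
      win_spikes = 0;
      rec_i++;
    }
  }
  return List::create(_["spike_t"] = wrap(sp_t), _["spike_u"] = wrap(sp_u),
                      _["traj"] = traj, _["v"] = v, _["ca"] = ca,
                      _["a"] = a, _["d"] = d, _["eps"] = eps,
                      _["refrac"] = refrac, _["omega"] = omega,
                      _["switched_at"] = switched_at,
                      _["gaba_switched"] = gaba_switched);
}

// [[Rcpp::export(name = ".connectivity_cpp")]]
NumericMatrix connectivity_cpp(NumericVector a, NumericVector d,
                               NumericMatrix dist, int kernel) {
  int n = a.size();
  NumericMatrix omega(n, n);
  fill_omega(omega, a, d, dist, kernel);
  return omega;
}
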