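#include <Rcpp.h>
using namespace Rcpp;

// Sigmoidal population transfer function H(x) = (a x - b) / (1 - exp(-d (a x - b))),
// evaluated stably through the removable singularity at a x = b.
static inline double transfer_H(double x, double a, double b, double d) {
  double u = a * x - b;
  double du = d * u;
  if (std::fabs(du) < 1e-8) return 1.0 / d;  // L'Hopital limit
  return u / (1.0 - std::exp(-du));
}

// Euler-Maruyama integration of the coupled mean-field equations
//   dS_i = [-S_i/tau_s + r (1 - S_i) H(x_i)] dt + sigma_i sqrt(dt) dW_i
//   x_i  = w_i J S_i + G J sum_j C_ij S_j + I_i
// with S clamped to [0,1] after every step. Noise uses R's RNG stream so a
// set.seed() call on the R side makes runs reproducible.
//
// An optional amplitude perturbation (the causal state-switching experiment)
// is applied after the Euler update on steps [pert_start, pert_start + pert_n)
// (1-based): for each target region, S is pushed towards S_max when below the
// (S_max + S_min)/2 midpoint and towards S_min when above.
// [[Rcpp::export]]
NumericMatrix integrate_mfm_cpp(NumericVector w, NumericVector I,
                                NumericVector sigma, double G,
                                NumericMatrix C, double J, double a, double b,
                                double d, double r_kin, double tau_s,
                                double dt, int n_steps, NumericVector S0,
                                double noise_scale,
                                int pert_start, int pert_n,
                                IntegerVector pert_regions, double pert_factor,
                                double pert_smax, double pert_smin) {
  const int N = C.nrow();
  NumericMatrix S_out(N, n_steps);
  std::vector<double> S(S0.begin(), S0.end());
  std::vector<double> coupling(N);
  // noise_scale multiplies sigma_i per step: 1 for per-step additive noise,
  // sqrt(dt) for the SDE-consistent Euler-Maruyama convention
  const double sqdt = noise_scale;
  const double pert_mid = 0.5 * (pert_smax + pert_smin);
  const double *Cp = C.begin();  // column-major; C symmetric, so columns = rows

  GetRNGstate();
  for (int t = 0; t < n_steps; ++t) {
    // inter-regional input G J (C S); symmetry lets us walk columns
    for (int i = 0; i < N; ++i) coupling[i] = 0.0;
    for (int j = 0; j < N; ++j) {
      const double sj = S[j];
      const double *col = Cp + (size_t)j * N;
      for (int i = 0; i < N; ++i) coupling[i] += col[i] * sj;
    }
    for (int i = 0; i < N; ++i) {
      double x = w[i] * J * S[i] + G * J * coupling[i] + I[i];
      double drift = -S[i] / tau_s + r_kin * (1.0 - S[i]) * transfer_H(x, a, b, d);
      double s_new = S[i] + dt * drift + sigma[i] * sqdt * norm_rand();
      if (!std::isfinite(s_new)) {
        PutRNGstate();
        stop("mean-field integration diverged at step %d (region %d)", t + 1, i + 1);
      }
      if (s_new < 0.0) s_new = 0.0;
      if (s_new > 1.0) s_new = 1.0;
      S[i] = s_new;
    }
    if (pert_start > 0 && (t + 1) >= pert_start && (t + 1) < pert_start + pert_n) {
      for (int k = 0; k < pert_regions.size(); ++k) {
        int i = pert_regions[k];
        if (S[i] < pert_mid)
          S[i] = S[i] + pert_factor * (pert_smax - S[i]);
        else
          S[i] = S[i] - pert_factor * (S[i] - pert_smin);
      }
    }
    for (int i = 0; i < N; ++i) S_out(i, t) = S[i];
  }
  PutRNGstate();
  return S_out;
}

// Balloon-Windkessel haemodynamic model driven by the synaptic gating
// variable z = S_i(t), Euler-integrated at the same resolution dt:
//   ds/dt = z - kappa s - gamma (f - 1)
//   df/dt = s
//   tau dv/dt = f - v^{1/alpha}
//   tau dq/dt = f E(f)/rho - v^{1/alpha} q / v,   E(f) = 1 - (1 - rho)^{1/f}
// BOLD(t) = 100 (V0/rho) [k1 (1 - q) + k2 (1 - q/v) + k3 (1 - v)].
// Initial resting state s = 0, f = v = q = 1 gives BOLD = 0 at baseline.
// [[Rcpp::export]]
NumericMatrix balloon_windkessel_cpp(NumericMatrix S, double dt, double kappa,
                                     double gamma, double tau, double alpha,
                                     double rho, double V0, double k1,
                                     double k2, double k3) {
  const int N = S.nrow(), T = S.ncol();
  NumericMatrix bold(N, T);
  const double ialpha = 1.0 / alpha;
  const double scale = 100.0 * V0 / rho;
  for (int i = 0; i < N; ++i) {
    double s = 0.0, f = 1.0, v = 1.0, q = 1.0;
    for (int t = 0; t < T; ++t) {
      double z = S(i, t);
      double vfl = std::pow(v, ialpha);
      double Ef = 1.0 - std::pow(1.0 - rho, 1.0 / f);
      double ds = z - kappa * s - gamma * (f - 1.0);
      double df = s;
      double dv = (f - vfl) / tau;
      double dq = (f * Ef / rho - vfl * q / v) / tau;
      s += dt * ds;
      f += dt * df;
      v += dt * dv;
      q += dt * dq;
      if (!(v > 0.0) || !(q > 0.0) || !std::isfinite(v) || !std::isfinite(q))
        stop("haemodynamic integration diverged at step %d (region %d)", t + 1, i + 1);
      bold(i, t) = scale * (k1 * (1.0 - q) + k2 * (1.0 - q / v) + k3 * (1.0 - v));
    }
  }
  return bold;
}
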