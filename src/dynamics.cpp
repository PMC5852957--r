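#include <Rcpp.h>
using namespace Rcpp;

// Step a discrete-state Markov chain. cum_tpm holds row-wise cumulative
// transition probabilities; u are pre-drawn uniforms (one per transition) so
// that R's RNG/seed semantics apply unchanged. States are 0-based.
// [[Rcpp::export]]
IntegerVector chain_steps_cpp(NumericMatrix cum_tpm, int start,
                              NumericVector u) {
  const int n = u.size();
  const int k = cum_tpm.ncol();
  IntegerVector out(n + 1);
  out[0] = start;
  int s = start;
  for (int t = 0; t < n; ++t) {
    const double uu = u[t];
    int j = 0;
    while (j < k - 1 && uu > cum_tpm(s, j)) ++j;
    s = j;
    out[t + 1] = s;
  }
  return out;
}

// Euler-Maruyama integration of overdamped Langevin dynamics
//   x_{t+1} = x_t + F(x_t)/gamma * dt + sqrt(2 kT dt / gamma) * xi_t
// with pre-drawn standard normals in `noise` ((n_steps-1) x d).
// pot_type 0: isotropic harmonic, par = (k, c_1..c_d)
// pot_type 1: quartic double well along dim 1, harmonic in the rest,
//             par = (height, half_separation, k_perp)
// [[Rcpp::export]]
NumericMatrix em_langevin_cpp(NumericVector x0, NumericMatrix noise,
                              double dt, double gamma, double kT,
                              int pot_type, NumericVector par) {
  const int d = x0.size();
  const int nsteps = noise.nrow() + 1;
  NumericMatrix out(nsteps, d);
  std::vector<double> x(d);
  for (int j = 0; j < d; ++j) { x[j] = x0[j]; out(0, j) = x0[j]; }
  const double amp = std::sqrt(2.0 * kT * dt / gamma);
  for (int t = 1; t < nsteps; ++t) {
    for (int j = 0; j < d; ++j) {
      double force;
      if (pot_type == 0) {
        force = -par[0] * (x[j] - par[1 + j]);
      } else {
        if (j == 0) {
          const double a2 = par[1] * par[1];
          force = -4.0 * par[0] * x[0] * (x[0] * x[0] - a2) / (a2 * a2);
        } else {
          force = -par[2] * x[j];
        }
      }
      x[j] += force / gamma * dt + amp * noise(t - 1, j);
      out(t, j) = x[j];
    }
  }
  return out;
}

// Sliding-window transition counts at integer lag; dtraj is 0-based.
// [[Rcpp::export]]
NumericMatrix count_transitions_cpp(IntegerVector dtraj, int lag, int nstates,
                                    NumericMatrix counts) {
  const int n = dtraj.size();
  for (int t = 0; t + lag < n; ++t)
    counts(dtraj[t], dtraj[t + lag]) += 1.0;
  return counts;
}
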