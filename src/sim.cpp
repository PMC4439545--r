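#include <Rcpp.h>
using namespace Rcpp;

// Surrogate network of noisy subthreshold oscillators with
// spike-and-reset.  Each neuron carries a damped harmonic pair (x, u)
// around a baseline b_n set by the excitatory and inhibitory input
// conductances, plus an independent fast OU fluctuation z modelling
// synaptic bombardment.  Lattice neighbours are coupled diffusively
// through the slow membrane component with strength g_c; a shared slow
// noise term models common afferent drive.  Euler-Maruyama integration;
// all noise comes from R's RNG so set.seed() in the caller fixes a run.
//
// v_n = b_n + x_n + z_n, spike when v_n >= 1 outside the refractory
// period; x resets after a spike.
// [[Rcpp::export]]
List sim_network_cpp(int n_neurons, int n_steps, double dt,
                     NumericVector baseline, NumericVector omega,
                     double damp, double gc_eff, double kick,
                     IntegerVector edge_from, IntegerVector edge_to,
                     NumericVector edge_weight,
                     double sd_x, double sd_shared, double sd_u,
                     double sd_z, double tau_z,
                     double x_reset, double refrac_s) {
  const double thr = 1.0;
  const int n_edges = edge_from.size();
  const double sq = std::sqrt(dt);
  std::vector<double> x(n_neurons, 0.0), u(n_neurons, 0.0),
    z(n_neurons, 0.0);
  std::vector<double> dx(n_neurons), last_spike(n_neurons, -1e9);
  std::vector< std::vector<double> > spikes(n_neurons);

  for (int k = 0; k < n_steps; ++k) {
    const double t = k * dt;
    for (int n = 0; n < n_neurons; ++n)
      dx[n] = (omega[n] * u[n] - damp * x[n]) * dt;
    // diffusive gap-junction coupling on the slow membrane component
    if (gc_eff > 0.0) {
      for (int e = 0; e < n_edges; ++e) {
        const int a = edge_from[e], b = edge_to[e];
        const double d = gc_eff * edge_weight[e] * (x[b] - x[a]) * dt;
        dx[a] += d;
        dx[b] -= d;
      }
    }
    const double shared = sd_shared * sq * R::norm_rand();
    std::vector<int> fired;
    for (int n = 0; n < n_neurons; ++n) {
      const double du = (-omega[n] * x[n] - damp * u[n]) * dt +
        sd_u * sq * R::norm_rand();
      const double dz = -z[n] / tau_z * dt + sd_z * sq * R::norm_rand();
      x[n] += dx[n] + sd_x * sq * R::norm_rand() + shared;
      u[n] += du;
      z[n] += dz;
      if (baseline[n] + x[n] + z[n] >= thr &&
          (t - last_spike[n]) >= refrac_s) {
        spikes[n].push_back(t);
        last_spike[n] = t;
        x[n] = x_reset;
        z[n] = 0.0;
        fired.push_back(n);
      }
    }
    // gap junctions also transmit spikelets: a spike depolarizes the
    // lattice neighbours in proportion to the junctional strength
    if (kick > 0.0 && !fired.empty()) {
      for (size_t f = 0; f < fired.size(); ++f) {
        const int n = fired[f];
        for (int e = 0; e < n_edges; ++e) {
          if (edge_from[e] == n) x[edge_to[e]] += kick * edge_weight[e];
          else if (edge_to[e] == n) x[edge_from[e]] += kick * edge_weight[e];
        }
      }
    }
  }
  List out(n_neurons);
  for (int n = 0; n < n_neurons; ++n) out[n] = wrap(spikes[n]);
  return out;
}
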