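// Current-based leaky integrate-and-fire winner-take-all network.
//
// Two excitatory populations (A, B) with selective recurrent excitation and
// a shared inhibitory population; exponential current-based synapses with a
// fixed transmission delay; instantaneous external Poisson synapses; common
// stimulus currents injected into all neurons of each excitatory population.
// Euler integration at a fixed step (0.1 ms by default from R).
//
// Uses R's RNG (set up via GetRNGstate) so trials are reproducible under the
// package's substream seeding.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List lif_trial_cpp(List net, NumericVector stimA, NumericVector stimB,
                   double dt_ms, int n_steps, int stim_on_step,
                   double rate_bin_ms, double kick_pA, int kick_on_step,
                   int kick_off_step, bool record_raster) {
  const int n_e = as<int>(net["n_e"]);
  const int n_i = as<int>(net["n_i"]);
  const int N = 2 * n_e + n_i;           // [0,n_e) = A, [n_e,2n_e) = B, rest I
  const double tau_m_e = as<double>(net["tau_m_e_ms"]);
  const double tau_m_i = as<double>(net["tau_m_i_ms"]);
  const double E_l = as<double>(net["E_l_mV"]);
  const double theta = as<double>(net["theta_mV"]);
  const double E_r = as<double>(net["E_r_mV"]);
  const double tau_ref = as<double>(net["tau_ref_ms"]);
  const double tau_s_e = as<double>(net["tau_s_e_ms"]);
  const double tau_s_i = as<double>(net["tau_s_i_ms"]);
  const double delay_ms = as<double>(net["delay_ms"]);
  const double nu_ext_e = as<double>(net["nu_ext_e_hz"]);
  const double nu_ext_i = as<double>(net["nu_ext_i_hz"]);
  const double J_ext_e = as<double>(net["J_ext_e_mV"]);
  const double J_ext_i = as<double>(net["J_ext_i_mV"]);
  const double g_L = as<double>(net["g_L_nS"]);

  // adjacency in CSR form: for presynaptic neuron j (global index), targets
  // in adj[ptr[j] .. ptr[j+1]) with signed weight w[.] (mV); positive ->
  // excitatory trace, negative -> inhibitory trace of the target.
  const IntegerVector ptr = net["adj_ptr"];
  const IntegerVector adj = net["adj_idx"];
  const NumericVector wgt = net["adj_w"];

  const double decE = std::exp(-dt_ms / tau_s_e);
  const double decI = std::exp(-dt_ms / tau_s_i);
  const int delay_steps = std::max(1, (int)std::lround(delay_ms / dt_ms));
  const int ref_steps = (int)std::lround(tau_ref / dt_ms);
  const double lamE = nu_ext_e * dt_ms / 1000.0;   // per E neuron per step
  const double lamI = nu_ext_i * dt_ms / 1000.0;

  std::vector<double> V(N), sE(N, 0.0), sI(N, 0.0);
  std::vector<int> refr(N, 0);
  for (int i = 0; i < N; ++i) V[i] = E_l + unif_rand() * (theta - E_l);

  // ring buffer of spike lists for delayed delivery
  std::vector< std::vector<int> > ring(delay_steps);

  const int bin_steps = (int)std::lround(rate_bin_ms / dt_ms);
  const int n_bins = n_steps / bin_steps + 1;
  IntegerVector cntA(n_bins, 0), cntB(n_bins, 0), cntI(n_bins, 0);
  std::vector<double> rast_t;
  std::vector<int> rast_id;

  const int last100_from = n_steps - (int)std::lround(100.0 / dt_ms);
  int lastA = 0, lastB = 0;

  for (int s = 0; s < n_steps; ++s) {
    const int bin = s / bin_steps;
    const int slot = s % delay_steps;

    // deliver spikes that occurred delay_steps ago
    for (size_t q = 0; q < ring[slot].size(); ++q) {
      const int j = ring[slot][q];
      for (int e = ptr[j]; e < ptr[j + 1]; ++e) {
        const double w = wgt[e];
        if (w >= 0) sE[adj[e]] += w; else sI[adj[e]] -= w;
      }
    }
    ring[slot].clear();

    // external Poisson input: one pooled draw per population, assigned
    // uniformly (exact thinning of independent per-neuron processes)
    int kE = (int)R::rpois(lamE * 2 * n_e);
    for (int q = 0; q < kE; ++q) {
      int i = (int)(unif_rand() * (2 * n_e));
      if (i >= 2 * n_e) i = 2 * n_e - 1;
      V[i] += J_ext_e;
    }
    int kI = (int)R::rpois(lamI * n_i);
    for (int q = 0; q < kI; ++q) {
      int i = 2 * n_e + (int)(unif_rand() * n_i);
      if (i >= N) i = N - 1;
      V[i] += J_ext_i;
    }

    const bool stim_on = s >= stim_on_step;
    const double iA = stim_on ? stimA[s - stim_on_step] / g_L : 0.0;
    const double iB = stim_on ? stimB[s - stim_on_step] / g_L : 0.0;
    const double kick = (s >= kick_on_step && s < kick_off_step) ? kick_pA / g_L : 0.0;

    for (int i = 0; i < N; ++i) {
      const bool is_e = i < 2 * n_e;
      if (refr[i] > 0) { refr[i]--; sE[i] *= decE; sI[i] *= decI; continue; }
      double inj = 0.0;
      if (is_e) inj = (i < n_e) ? (iA + kick) : iB;
      const double tau_m = is_e ? tau_m_e : tau_m_i;
      V[i] += dt_ms / tau_m * (-(V[i] - E_l) + sE[i] - sI[i] + inj);
      sE[i] *= decE; sI[i] *= decI;
      if (V[i] >= theta) {
        V[i] = E_r;
        refr[i] = ref_steps;
        ring[slot].push_back(i);  // delivered when this slot comes around again
        if (i < n_e) { cntA[bin]++; if (s >= last100_from) lastA++; }
        else if (i < 2 * n_e) { cntB[bin]++; if (s >= last100_from) lastB++; }
        else cntI[bin]++;
        if (record_raster) { rast_t.push_back(s * dt_ms); rast_id.push_back(i); }
      }
    }
  }

  return List::create(
    _["count_A"] = cntA, _["count_B"] = cntB, _["count_I"] = cntI,
    _["bin_ms"] = rate_bin_ms,
    _["last100_A"] = lastA, _["last100_B"] = lastB,
    _["raster_t_ms"] = wrap(rast_t), _["raster_id"] = wrap(rast_id));
}
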