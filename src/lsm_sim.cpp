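#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Fixed-step simulation of a recurrent network of leaky integrate-and-fire
// neurons with exponential postsynaptic currents, optional Tsodyks-Markram
// short-term plasticity on recurrent synapses, per-neuron Poisson noise
// injections and externally supplied input current events.
//
// Units: mV, pA, pF, ms are used via the identity pA/pF = mV/ms; arguments
// are passed in SI-flavored units (s for times) and converted here.
//
// ev_step/ev_post/ev_w: pre-expanded input events (arrival step, target
// neuron 0-based, weight pA), sorted by arrival step. Recurrent spikes are
// delivered through ring buffers indexed by delay steps.
// [[Rcpp::export]]
List lsm_simulate_cpp(IntegerVector is_exc,
                      NumericVector Cm, NumericVector tau_m,
                      NumericVector theta, NumericVector Vreset,
                      NumericVector Vrest, NumericVector tref,
                      NumericVector Iconst,
                      double tau_synE, double tau_synI,
                      IntegerVector syn_pre, IntegerVector syn_post,
                      NumericVector syn_w, IntegerVector syn_delay_steps,
                      IntegerVector syn_stp, NumericVector syn_U,
                      NumericVector syn_taurec, NumericVector syn_taufac,
                      IntegerVector ev_step, IntegerVector ev_post,
                      NumericVector ev_w,
                      NumericVector noise_w, double noise_rate,
                      NumericVector V_init,
                      double t_start, double t_end, double dt,
                      bool record_all) {
  const int n = is_exc.size();
  const int n_syn = syn_pre.size();
  const int n_steps = (int)std::lround((t_end - t_start) / dt);
  const double dt_ms = dt * 1000.0;

  // CSR adjacency over presynaptic neuron
  std::vector<int> deg(n, 0);
  for (int s = 0; s < n_syn; ++s) deg[syn_pre[s]]++;
  std::vector<int> ptr(n + 1, 0);
  for (int i = 0; i < n; ++i) ptr[i + 1] = ptr[i] + deg[i];
  std::vector<int> adj(n_syn);
  {
    std::vector<int> fill(ptr.begin(), ptr.end() - 1);
    for (int s = 0; s < n_syn; ++s) adj[fill[syn_pre[s]]++] = s;
  }

  int max_delay = 1;
  for (int s = 0; s < n_syn; ++s)
    max_delay = std::max(max_delay, (int)syn_delay_steps[s]);
  const int L = max_delay + 2;
  std::vector<double> bufE((size_t)L * n, 0.0), bufI((size_t)L * n, 0.0);

  std::vector<double> V(V_init.begin(), V_init.end());
  std::vector<double> IE(n, 0.0), II(n, 0.0);
  std::vector<double> refr_until(n, -1e300);
  std::vector<double> decE(n), decI(n);
  for (int i = 0; i < n; ++i) {
    decE[i] = std::exp(-dt_ms / tau_synE);
    decI[i] = std::exp(-dt_ms / tau_synI);
  }

  // STP state per synapse
  std::vector<double> stp_u(n_syn, 0.0), stp_R(n_syn, 1.0);
  std::vector<double> last_sp(n_syn, -1e300);
  std::vector<char> stp_seen(n_syn, 0);
  double u_min = 1.0, u_max = 0.0, R_min = 1.0, R_max = 0.0;
  bool any_stp_event = false;

  std::vector<int> out_nrn;
  std::vector<double> out_t;

  int ev_i = 0;
  const int n_ev = ev_step.size();
  const double p_noise = noise_rate * dt;

  for (int s = 0; s < n_steps; ++s) {
    const double t = t_start + s * dt;
    const int row = s % L;
    double *bE = &bufE[(size_t)row * n];
    double *bI = &bufI[(size_t)row * n];
    // decay currents, collect deliveries scheduled for this step
    for (int i = 0; i < n; ++i) {
      IE[i] = IE[i] * decE[i] + bE[i];
      II[i] = II[i] * decI[i] + bI[i];
      bE[i] = 0.0; bI[i] = 0.0;
    }
    // external input events arriving now
    while (ev_i < n_ev && ev_step[ev_i] == s) {
      const double w = ev_w[ev_i];
      if (w >= 0) IE[ev_post[ev_i]] += w; else II[ev_post[ev_i]] += w;
      ++ev_i;
    }
    while (ev_i < n_ev && ev_step[ev_i] < s) ++ev_i; // skip stale (pre-start)
    // noise
    if (noise_rate > 0) {
      for (int i = 0; i < n; ++i) {
        if (unif_rand() < p_noise) {
          const double w = noise_w[i];
          if (w >= 0) IE[i] += w; else II[i] += w;
        }
      }
    }
    // integrate + threshold
    for (int i = 0; i < n; ++i) {
      if (t < refr_until[i]) continue;
      const double dV = dt_ms * ((Vrest[i] - V[i]) / tau_m[i] +
                                 (IE[i] + II[i] + Iconst[i]) / Cm[i]);
      V[i] += dV;
      if (!R_FINITE(V[i]))
        stop("membrane potential diverged (neuron %d, t = %g s)", i + 1, t);
      if (V[i] >= theta[i]) {
        if (record_all || is_exc[i]) {
          out_nrn.push_back(i + 1);
          out_t.push_back(t);
        }
        V[i] = Vreset[i];
        refr_until[i] = t + tref[i] / 1000.0;  // tref given in ms, t in s
        // propagate through outgoing synapses
        for (int k = ptr[i]; k < ptr[i + 1]; ++k) {
          const int sy = adj[k];
          double eff = syn_w[sy];
          if (syn_stp[sy]) {
            any_stp_event = true;
            double u, R;
            if (!stp_seen[sy]) {
              u = syn_U[sy]; R = 1.0; stp_seen[sy] = 1;
            } else {
              const double dms = (t - last_sp[sy]) * 1000.0;
              const double eF = std::exp(-dms / syn_taufac[sy]);
              const double eD = std::exp(-dms / syn_taurec[sy]);
              u = syn_U[sy] + stp_u[sy] * (1.0 - syn_U[sy]) * eF;
              R = 1.0 + (stp_R[sy] - stp_u[sy] * stp_R[sy] - 1.0) * eD;
            }
            stp_u[sy] = u; stp_R[sy] = R; last_sp[sy] = t;
            if (u < u_min) u_min = u; if (u > u_max) u_max = u;
            if (R < R_min) R_min = R; if (R > R_max) R_max = R;
            eff *= u * R;
          }
          const int arr = (s + std::max(1, (int)syn_delay_steps[sy])) % L;
          double *tgt = (syn_w[sy] >= 0 ? &bufE[(size_t)arr * n]
                                        : &bufI[(size_t)arr * n]);
          tgt[syn_post[sy]] += eff;
        }
      }
    }
  }

  return List::create(
    _["neuron"] = wrap(out_nrn),
    _["time"] = wrap(out_t),
    _["stp_u_range"] = any_stp_event ?
      NumericVector::create(u_min, u_max) : NumericVector::create(NA_REAL, NA_REAL),
    _["stp_R_range"] = any_stp_event ?
      NumericVector::create(R_min, R_max) : NumericVector::create(NA_REAL, NA_REAL),
    _["V_final"] = wrap(V));
}
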