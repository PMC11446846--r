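#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Forward-Euler leaky integrate-and-fire trial.
//
// Update order per step n (1-based; step n covers [(n-1)*dt, n*dt)):
//   1. membrane: refractory neurons sit clamped at v_reset and count down;
//      others leak, v += (dt/tau_mem) * (v_rest - v)  (+ dt * g for the
//      exponential kernel, whose trace g decays by exp(-dt/tau_syn) first).
//   2. synaptic delivery: recurrent events scheduled for this step and
//      external input events at this step are applied after the membrane
//      update. Delta kernel: v += w (discarded while refractory).
//      Exponential kernel: g += w / tau_syn (accumulates regardless).
//   3. threshold: non-refractory neurons with v >= v_thresh spike; spike time
//      is n*dt, v -> v_reset, refractory counter set, and their outgoing
//      weights are queued for step n + delay_steps.
//
// This ordering is part of the contract: the scalar reference integrator in
// the test suite reproduces it operation for operation.
// [[Rcpp::export]]
List lif_run_trial(int n_neurons,
                   IntegerVector edge_pre, IntegerVector edge_post,
                   NumericVector edge_w,
                   IntegerVector ext_step, IntegerVector ext_target,
                   NumericVector ext_w,
                   int n_steps, double dt_ms,
                   double v_rest, double v_thresh, double v_reset,
                   double tau_mem, int refract_steps, int delay_steps,
                   double tau_syn, int kernel) {
  const int n_edges = edge_pre.size();
  const int n_ext = ext_step.size();
  const double dt_over_tau = dt_ms / tau_mem;
  const double syn_decay = std::exp(-dt_ms / tau_syn);
  const bool exp_kernel = (kernel == 1);

  // outgoing adjacency (CSR)
  std::vector<int> deg(n_neurons + 1, 0);
  for (int e = 0; e < n_edges; ++e) deg[edge_pre[e] + 1]++;
  for (int i = 0; i < n_neurons; ++i) deg[i + 1] += deg[i];
  std::vector<int> adj_post(n_edges);
  std::vector<double> adj_w(n_edges);
  {
    std::vector<int> fill(deg.begin(), deg.end() - 1);
    for (int e = 0; e < n_edges; ++e) {
      int p = edge_pre[e];
      adj_post[fill[p]] = edge_post[e];
      adj_w[fill[p]] = edge_w[e];
      fill[p]++;
    }
  }

  std::vector<double> v(n_neurons, v_rest), g(n_neurons, 0.0);
  std::vector<int> refr(n_neurons, 0);
  const int n_slots = delay_steps + 1;
  std::vector<double> buf((size_t)n_slots * n_neurons, 0.0);

  std::vector<int> spike_neuron, spike_step;
  int ext_ptr = 0;  // ext events sorted by step (checked in R)

  for (int n = 1; n <= n_steps; ++n) {
    // 1. membrane update
    if (exp_kernel) {
      for (int i = 0; i < n_neurons; ++i) {
        g[i] *= syn_decay;
        if (refr[i] > 0) {
          refr[i]--;
          v[i] = v_reset;
        } else {
          v[i] += dt_over_tau * (v_rest - v[i]) + dt_ms * g[i];
        }
      }
    } else {
      for (int i = 0; i < n_neurons; ++i) {
        if (refr[i] > 0) {
          refr[i]--;
          v[i] = v_reset;
        } else {
          v[i] += dt_over_tau * (v_rest - v[i]);
        }
      }
    }
    // 2. synaptic delivery (recurrent buffer slot for this step, then
    //    external input events stamped with this step)
    double *slot = &buf[(size_t)(n % n_slots) * n_neurons];
    if (exp_kernel) {
      for (int i = 0; i < n_neurons; ++i) {
        if (slot[i] != 0.0) { g[i] += slot[i] / tau_syn; slot[i] = 0.0; }
      }
      while (ext_ptr < n_ext && ext_step[ext_ptr] == n) {
        g[ext_target[ext_ptr]] += ext_w[ext_ptr] / tau_syn;
        ext_ptr++;
      }
    } else {
      for (int i = 0; i < n_neurons; ++i) {
        if (slot[i] != 0.0) {
          if (refr[i] == 0) v[i] += slot[i];
          slot[i] = 0.0;
        }
      }
      while (ext_ptr < n_ext && ext_step[ext_ptr] == n) {
        int tgt = ext_target[ext_ptr];
        if (refr[tgt] == 0) v[tgt] += ext_w[ext_ptr];
        ext_ptr++;
      }
    }
    // 3. threshold, reset, queue outgoing deliveries
    for (int i = 0; i < n_neurons; ++i) {
      if (refr[i] == 0 && v[i] >= v_thresh) {
        spike_neuron.push_back(i);
        spike_step.push_back(n);
        v[i] = v_reset;
        refr[i] = refract_steps;
        int due = n + delay_steps;
        if (due <= n_steps) {
          double *dst = &buf[(size_t)(due % n_slots) * n_neurons];
          for (int k = deg[i]; k < deg[i + 1]; ++k) dst[adj_post[k]] += adj_w[k];
        }
      }
    }
  }

  return List::create(_["neuron"] = wrap(spike_neuron),
                      _["step"] = wrap(spike_step));
}
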