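// Clock-driven simulation core for the heterogeneous recurrent spiking
// network. One call simulates one stimulus presentation: input spike
// delivery, exponential-Euler LIF integration of the recurrent layer,
// non-spiking (by default) integration of the output layer, and
// optional trace-based STDP on the input and recurrent synapse sets.
//
// Conventions (mirrored by the R reference implementation in R/lif.R
// and R/plasticity.R):
//  - spikes detected at step end with strict v > v_threshold;
//  - recurrent spikes are delivered as current w/dt at the *next* step
//    (one-step transmission latency); input events are delivered at
//    the step containing their timestamp;
//  - refractory neurons are clamped at v_reset and ignore input;
//  - per step: trace decay, then trace increments, then potentiation
//    before depression, acting on |w| clipped to [0, w_max] with the
//    sign fixed by the pre-neuron type (Dale's law).
#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct SynGroup {
  // flat per-synapse arrays plus a CSR index from pre-neuron id to
  // synapse rows, for O(spikes) current delivery
  IntegerVector pre, post;
  NumericVector w, sign;
  NumericVector Ap, Am, ap, am;
  NumericVector dec_p, dec_m;  // exp(-dt/tau_plus), exp(-dt/tau_minus)
  NumericVector Tpre, Tpost;
  bool plastic;
  std::vector<int> csr_ptr, csr_idx;      // by pre neuron
  std::vector<int> csr_ptr_p, csr_idx_p;  // by post neuron
  std::vector<int> last_t;  // step of the last trace update per synapse
  int n;

  void load(const List& syn, int n_pre_neurons, double dt, bool has_stdp) {
    pre = syn["pre"];
    post = syn["post"];
    w = clone(as<NumericVector>(syn["weight"]));
    n = w.size();
    if (syn.containsElementNamed("dale_sign")) {
      sign = syn["dale_sign"];
    } else {
      sign = NumericVector(n);
      for (int s = 0; s < n; ++s) sign[s] = (w[s] < 0.0) ? -1.0 : 1.0;
    }
    plastic = has_stdp;
    if (has_stdp) {
      Ap = syn["A_plus"];
      Am = syn["A_minus"];
      ap = syn["a_plus"];
      am = syn["a_minus"];
      NumericVector tp = syn["tau_plus"], tm = syn["tau_minus"];
      dec_p = NumericVector(n);
      dec_m = NumericVector(n);
      for (int s = 0; s < n; ++s) {
        dec_p[s] = std::exp(-dt / tp[s]);
        dec_m[s] = std::exp(-dt / tm[s]);
      }
      Tpre = clone(as<NumericVector>(syn["T_pre"]));
      Tpost = clone(as<NumericVector>(syn["T_post"]));
      last_t.assign(n, 0);
    }
    // CSR by pre id (1-based in R)
    csr_ptr.assign(n_pre_neurons + 1, 0);
    for (int s = 0; s < n; ++s) csr_ptr[pre[s]]++;
    for (int i = 0; i < n_pre_neurons; ++i) csr_ptr[i + 1] += csr_ptr[i];
    csr_idx.assign(n, 0);
    std::vector<int> cursor(csr_ptr.begin(), csr_ptr.end() - 1);
    for (int s = 0; s < n; ++s) csr_idx[cursor[pre[s] - 1]++] = s;
    if (has_stdp) {
      // CSR by post id (post is always a recurrent neuron)
      int n_post = 0;
      for (int s = 0; s < n; ++s) n_post = std::max(n_post, (int)post[s]);
      csr_ptr_p.assign(n_post + 1, 0);
      for (int s = 0; s < n; ++s) csr_ptr_p[post[s]]++;
      for (int i = 0; i < n_post; ++i) csr_ptr_p[i + 1] += csr_ptr_p[i];
      csr_idx_p.assign(n, 0);
      std::vector<int> cur(csr_ptr_p.begin(), csr_ptr_p.end() - 1);
      for (int s = 0; s < n; ++s) csr_idx_p[cur[post[s] - 1]++] = s;
    }
  }

  // Lazily decay both traces of synapse s up to step t (traces decay
  // exponentially, so the update can be deferred until a spike needs
  // the value; exact, not an approximation).
  inline void catch_up(int s, int t) {
    const int el = t - last_t[s];
    if (el > 0) {
      Tpre[s] *= std::pow(dec_p[s], el);
      Tpost[s] *= std::pow(dec_m[s], el);
      last_t[s] = t;
    }
  }

  // One synapse touched by a pre and/or post spike at step t: decay,
  // then both trace increments, then potentiation before depression.
  inline void touch(int s, int t, bool ps, bool qs, double w_max) {
    catch_up(s, t);
    if (ps) Tpre[s] += ap[s];
    if (qs) Tpost[s] += am[s];
    double mag = std::fabs(w[s]);
    if (qs) mag += Ap[s] * Tpre[s];  // potentiation first
    if (ps) mag -= Am[s] * Tpost[s];
    if (mag < 0.0) mag = 0.0;
    if (mag > w_max) mag = w_max;
    w[s] = sign[s] * mag;
  }

  // plasticity for one step: only synapses whose pre or post neuron
  // spiked this step are visited (others only decay, handled lazily)
  void step_plasticity(const std::vector<int>& pre_ids,
                       const std::vector<int>& post_ids,
                       const std::vector<char>& pre_spk,
                       const std::vector<char>& post_spk,
                       int t, double w_max) {
    for (int i : pre_ids) {
      if (i >= (int)csr_ptr.size() - 1) continue;
      for (int k = csr_ptr[i]; k < csr_ptr[i + 1]; ++k) {
        const int s = csr_idx[k];
        touch(s, t, true, post_spk[post[s] - 1] != 0, w_max);
      }
    }
    for (int j : post_ids) {
      if (j >= (int)csr_ptr_p.size() - 1) continue;
      for (int k = csr_ptr_p[j]; k < csr_ptr_p[j + 1]; ++k) {
        const int s = csr_idx_p[k];
        // pre+post pairs were already handled in the pre pass
        if (pre_spk.size() > (size_t)(pre[s] - 1) && pre_spk[pre[s] - 1])
          continue;
        touch(s, t, false, true, w_max);
      }
    }
  }

  // bring every trace up to the final step before returning state
  void finalize(int n_steps) {
    if (!plastic) return;
    for (int s = 0; s < n; ++s) catch_up(s, n_steps);
  }
};

}  // namespace

// [[Rcpp::export(name = ".cpp_run_network")]]
List cpp_run_network(List rec_pop, List out_pop, List syn_input,
                     List syn_recurrent, List syn_output,
                     IntegerVector input_step, IntegerVector input_source,
                     int n_input, List sim) {
  const double dt = as<double>(sim["dt"]);
  const int n_steps = as<int>(sim["n_steps"]);
  const bool plastic_on = as<bool>(sim["plasticity_on"]);
  const double w_max = as<double>(sim["w_max"]);
  const bool rec_mem = as<bool>(sim["record_membrane"]);
  const bool spiking_output = as<bool>(sim["spiking_output"]);
  const double t0 = as<double>(sim["t0"]);

  // recurrent population
  NumericVector tau = rec_pop["tau_m"], Rm = rec_pop["R_m"],
                ar = rec_pop["a"], vth = rec_pop["v_threshold"],
                vre = rec_pop["v_reset"], refr = rec_pop["refractory"];
  NumericVector v = clone(as<NumericVector>(rec_pop["membrane"]));
  NumericVector runtil = clone(as<NumericVector>(rec_pop["refractory_until"]));
  const int n_rec = v.size();
  std::vector<double> dec(n_rec);
  for (int i = 0; i < n_rec; ++i) dec[i] = std::exp(-dt / tau[i]);

  // output population (non-spiking integrators unless spiking_output)
  NumericVector tau_o = out_pop["tau_m"], Rm_o = out_pop["R_m"],
                a_o = out_pop["a"], vth_o = out_pop["v_threshold"],
                vre_o = out_pop["v_reset"], refr_o = out_pop["refractory"];
  NumericVector v_o = clone(as<NumericVector>(out_pop["membrane"]));
  NumericVector runtil_o =
      clone(as<NumericVector>(out_pop["refractory_until"]));
  const int n_out = v_o.size();
  std::vector<double> dec_o(n_out);
  for (int i = 0; i < n_out; ++i) dec_o[i] = std::exp(-dt / tau_o[i]);

  SynGroup g_in, g_rec, g_out;
  g_in.load(syn_input, n_input, dt, true);
  g_rec.load(syn_recurrent, n_rec, dt, true);
  g_out.load(syn_output, n_rec, dt, false);

  std::vector<char> prev_rec_spk(n_rec, 0), rec_spk(n_rec, 0),
      in_spk(n_input, 0);
  std::vector<int> in_spk_ids, rec_spk_ids;
  std::vector<double> I_rec(n_rec), I_out(n_out);
  std::vector<int> ev_step, ev_neuron;      // recurrent spikes
  std::vector<int> ev_step_o, ev_neuron_o;  // output spikes (if spiking)

  NumericMatrix mem_hist =
      rec_mem ? NumericMatrix(n_steps, n_rec + n_out) : NumericMatrix(0, 0);

  int cursor = 0;  // into input_step/input_source (sorted by step)
  const int n_events = input_step.size();

  for (int t = 0; t < n_steps; ++t) {
    const double t_start = t0 + t * dt, t_end = t0 + (t + 1) * dt;
    std::fill(I_rec.begin(), I_rec.end(), 0.0);
    std::fill(I_out.begin(), I_out.end(), 0.0);
    for (int i : in_spk_ids) in_spk[i] = 0;
    in_spk_ids.clear();
    rec_spk_ids.clear();

    // recurrent + output-tap delivery of last step's spikes
    for (int i = 0; i < n_rec; ++i) {
      if (!prev_rec_spk[i]) continue;
      for (int k = g_rec.csr_ptr[i]; k < g_rec.csr_ptr[i + 1]; ++k) {
        const int s = g_rec.csr_idx[k];
        I_rec[g_rec.post[s] - 1] += g_rec.w[s] / dt;
      }
      for (int k = g_out.csr_ptr[i]; k < g_out.csr_ptr[i + 1]; ++k) {
        const int s = g_out.csr_idx[k];
        I_out[g_out.post[s] - 1] += g_out.w[s] / dt;
      }
    }
    // input events scheduled in [t_start, t_end)
    while (cursor < n_events && input_step[cursor] == t) {
      const int src = input_source[cursor] - 1;
      if (!in_spk[src]) in_spk_ids.push_back(src);
      in_spk[src] = 1;
      for (int k = g_in.csr_ptr[src]; k < g_in.csr_ptr[src + 1]; ++k) {
        const int s = g_in.csr_idx[k];
        I_rec[g_in.post[s] - 1] += g_in.w[s] / dt;
      }
      ++cursor;
    }

    // integrate recurrent layer
    for (int i = 0; i < n_rec; ++i) {
      if (t_start < runtil[i]) {
        v[i] = vre[i];
        rec_spk[i] = 0;
        continue;
      }
      const double vinf = ar[i] + Rm[i] * I_rec[i];
      double vi = vinf + (v[i] - vinf) * dec[i];
      if (vi > vth[i]) {
        rec_spk[i] = 1;
        rec_spk_ids.push_back(i);
        vi = vre[i];
        runtil[i] = t_end + refr[i];
        ev_step.push_back(t);
        ev_neuron.push_back(i + 1);
      } else {
        rec_spk[i] = 0;
      }
      v[i] = vi;
    }

    // integrate output layer
    for (int i = 0; i < n_out; ++i) {
      if (spiking_output && t_start < runtil_o[i]) {
        v_o[i] = vre_o[i];
        continue;
      }
      const double vinf = a_o[i] + Rm_o[i] * I_out[i];
      double vi = vinf + (v_o[i] - vinf) * dec_o[i];
      if (spiking_output && vi > vth_o[i]) {
        vi = vre_o[i];
        runtil_o[i] = t_end + refr_o[i];
        ev_step_o.push_back(t);
        ev_neuron_o.push_back(i + 1);
      }
      v_o[i] = vi;
    }

    if (plastic_on) {
      g_in.step_plasticity(in_spk_ids, rec_spk_ids, in_spk, rec_spk,
                           t, w_max);
      g_rec.step_plasticity(rec_spk_ids, rec_spk_ids, rec_spk, rec_spk,
                            t, w_max);
    }

    if (rec_mem) {
      for (int i = 0; i < n_rec; ++i) mem_hist(t, i) = v[i];
      for (int i = 0; i < n_out; ++i) mem_hist(t, n_rec + i) = v_o[i];
    }
    std::swap(prev_rec_spk, rec_spk);
  }
  if (plastic_on) {
    g_in.finalize(n_steps);
    g_rec.finalize(n_steps);
  }

  List res = List::create(
      _["spike_step"] = wrap(ev_step), _["spike_neuron"] = wrap(ev_neuron),
      _["out_spike_step"] = wrap(ev_step_o),
      _["out_spike_neuron"] = wrap(ev_neuron_o),
      _["membrane"] = v, _["refractory_until"] = runtil,
      _["out_membrane"] = v_o, _["out_refractory_until"] = runtil_o,
      _["w_input"] = g_in.w, _["w_recurrent"] = g_rec.w,
      _["T_pre_input"] = g_in.Tpre, _["T_post_input"] = g_in.Tpost,
      _["T_pre_recurrent"] = g_rec.Tpre,
      _["T_post_recurrent"] = g_rec.Tpost);
  if (rec_mem) res["membrane_history"] = mem_hist;
  return res;
}
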