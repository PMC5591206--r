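#include <Rcpp.h>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Compact network view for the simulation core. Synapses are kept in their
// original (R-side) order for weights / n_act / kernel factors; a CSR index
// by presynaptic neuron gives fast fan-out during propagation.
struct NetView {
  int n;                  // total neuron count
  int out;                // output neuron, 0-based
  int n_syn;
  std::vector<int> off;   // CSR offsets, size n + 1
  std::vector<int> post;  // CSR-ordered postsynaptic neuron per slot
  std::vector<int> sid;   // original synapse index per CSR slot
  std::vector<double> sgn; // +1 excitatory / -1 inhibitory presynaptic neuron,
                           // indexed by original synapse index
};

static NetView build_view(int n_neurons, const IntegerVector& syn_pre,
                          const IntegerVector& syn_post,
                          const NumericVector& sign, int output_id) {
  NetView nv;
  nv.n = n_neurons;
  nv.out = output_id - 1;
  nv.n_syn = syn_pre.size();
  nv.off.assign(nv.n + 1, 0);
  for (int s = 0; s < nv.n_syn; ++s) nv.off[syn_pre[s]] += 1; // pre is 1-based
  for (int i = 0; i < nv.n; ++i) nv.off[i + 1] += nv.off[i];
  nv.post.resize(nv.n_syn);
  nv.sid.resize(nv.n_syn);
  std::vector<int> cur(nv.off.begin(), nv.off.end() - 1);
  for (int s = 0; s < nv.n_syn; ++s) {
    int slot = cur[syn_pre[s] - 1]++;
    nv.post[slot] = syn_post[s] - 1;
    nv.sid[slot] = s;
  }
  nv.sgn.assign(sign.begin(), sign.end());
  return nv;
}

// Synchronous integrate-and-fire engine. One instance is reused across the
// many trials of an initialization or training run.
struct Simulator {
  const NetView& nv;
  double v_max, delta_eta;
  int t_refr;
  bool linear;          // activation proportional to firing potential
  bool same_step_block; // a neuron firing this step rejects same-step input
  int step_cap;

  std::vector<double> v, eta, amp;
  std::vector<int> refr, fired;
  std::vector<char> fired_now, in_next;
  std::vector<int> n_act;          // per original synapse index
  bool out_fired, v_changed;
  int duration;
  bool log_firings;
  std::vector<int> fire_t, fire_id;
  std::vector<int> cand, next_cand, refr_list, refr_keep;

  Simulator(const NetView& nv_, double v_max_, double delta_eta_, int t_refr_,
            bool linear_, bool same_step_block_, int step_cap_)
      : nv(nv_), v_max(v_max_), delta_eta(delta_eta_), t_refr(t_refr_),
        linear(linear_), same_step_block(same_step_block_),
        step_cap(step_cap_), v(nv_.n), eta(nv_.n), amp(nv_.n),
        refr(nv_.n), fired_now(nv_.n, 0), in_next(nv_.n, 0),
        n_act(nv_.n_syn), log_firings(false) {}

  // Run a full presentation: start_ids fire at the first step; iterate until
  // quiescence (no eligible firer and no refractory neuron still holding a
  // supra-threshold potential). Weights are read-only here. Only neurons
  // touched since the last step are candidates, so cost scales with actual
  // activity, not network size.
  void trial(const std::vector<double>& w, const std::vector<int>& start_ids) {
    std::fill(v.begin(), v.end(), 0.0);
    std::fill(eta.begin(), eta.end(), 1.0);
    std::fill(refr.begin(), refr.end(), 0);
    std::fill(n_act.begin(), n_act.end(), 0);
    out_fired = false;
    v_changed = false;
    duration = 0;
    fire_t.clear();
    fire_id.clear();
    cand.assign(start_ids.begin(), start_ids.end());
    refr_list.clear();
    for (size_t k = 0; k < start_ids.size(); ++k) v[start_ids[k]] = v_max;

    int t = 0;
    const bool block_same = same_step_block && t_refr > 0;
    while (true) {
      fired.clear();
      for (size_t k = 0; k < cand.size(); ++k) {
        int i = cand[k];
        if (refr[i] == 0 && v[i] >= v_max && !fired_now[i]) {
          fired_now[i] = 1;
          fired.push_back(i);
        }
      }
      std::sort(fired.begin(), fired.end()); // stable id order for logs
      if (fired.empty()) {
        // a neuron can sit refractory with v >= v_max (open same-step
        // dialect); time must pass until its window expires
        bool pending = false;
        for (size_t k = 0; k < refr_list.size(); ++k)
          if (v[refr_list[k]] >= v_max) { pending = true; break; }
        if (!pending) break;
        ++t;
        if (t > step_cap)
          stop("simulation exceeded step cap (%d): divergence indicates a bug",
               step_cap);
        cand.clear();
        refr_keep.clear();
        for (size_t k = 0; k < refr_list.size(); ++k) {
          int i = refr_list[k];
          refr[i] -= 1;
          if (refr[i] == 0) { if (v[i] >= v_max) cand.push_back(i); }
          else refr_keep.push_back(i);
        }
        refr_list.swap(refr_keep);
        continue;
      }
      ++t;
      if (t > step_cap)
        stop("simulation exceeded step cap (%d): divergence indicates a bug",
             step_cap);
      duration = t;

      // capture firing amplitudes before any reset (linear mode needs the
      // supra-threshold potential at firing time)
      for (size_t k = 0; k < fired.size(); ++k) {
        int i = fired[k];
        amp[i] = linear ? eta[i] * v[i] : eta[i];
        if (log_firings) { fire_t.push_back(t); fire_id.push_back(i); }
      }
      for (size_t k = 0; k < fired.size(); ++k) v[fired[k]] = 0.0;

      // deliveries: lost when the target is refractory (or, under the default
      // dialect, firing at this very step); accepted targets become next
      // step's candidates
      next_cand.clear();
      for (size_t k = 0; k < fired.size(); ++k) {
        int i = fired[k];
        double a = amp[i];
        for (int slot = nv.off[i]; slot < nv.off[i + 1]; ++slot) {
          int j = nv.post[slot];
          if (refr[j] > 0 || (block_same && fired_now[j])) continue;
          int s = nv.sid[slot];
          v[j] += nv.sgn[s] * w[s] * a;
          n_act[s] += 1;
          if (j == nv.out) v_changed = true;
          if (!in_next[j]) { in_next[j] = 1; next_cand.push_back(j); }
        }
      }

      for (size_t k = 0; k < fired.size(); ++k) {
        int i = fired[k];
        eta[i] = std::max(0.0, eta[i] - delta_eta);
        if (i == nv.out) out_fired = true;
      }
      // countdown for neurons already refractory (none of them fired);
      // those whose window expires while supra-threshold become candidates
      refr_keep.clear();
      for (size_t k = 0; k < refr_list.size(); ++k) {
        int i = refr_list[k];
        refr[i] -= 1;
        if (refr[i] == 0) {
          if (v[i] >= v_max && !in_next[i]) {
            in_next[i] = 1;
            next_cand.push_back(i);
          }
        } else refr_keep.push_back(i);
      }
      refr_list.swap(refr_keep);
      // firing neurons enter the refractory state
      if (t_refr > 0) {
        for (size_t k = 0; k < fired.size(); ++k) {
          refr[fired[k]] = t_refr;
          refr_list.push_back(fired[k]);
        }
      }
      for (size_t k = 0; k < fired.size(); ++k) fired_now[fired[k]] = 0;
      for (size_t k = 0; k < next_cand.size(); ++k) in_next[next_cand[k]] = 0;
      cand.swap(next_cand);
    }
  }
};

static std::vector<std::vector<int> > pattern_starts(
    const IntegerMatrix& patterns, const IntegerVector& input_ids) {
  std::vector<std::vector<int> > starts(patterns.nrow());
  for (int p = 0; p < patterns.nrow(); ++p)
    for (int k = 0; k < patterns.ncol(); ++k)
      if (patterns(p, k) == 1) starts[p].push_back(input_ids[k] - 1);
  return starts;
}

// [[Rcpp::export]]
List cpp_run_trial(int n_neurons, IntegerVector syn_pre, IntegerVector syn_post,
                   NumericVector weight, NumericVector sign, int output_id,
                   IntegerVector fire_ids, double v_max, double delta_eta,
                   int t_refr, bool linear, bool same_step_block, int step_cap,
                   bool record_firings) {
  NetView nv = build_view(n_neurons, syn_pre, syn_post, sign, output_id);
  Simulator sim(nv, v_max, delta_eta, t_refr, linear, same_step_block,
                step_cap);
  sim.log_firings = record_firings;
  std::vector<double> w(weight.begin(), weight.end());
  std::vector<int> start;
  for (int k = 0; k < fire_ids.size(); ++k) start.push_back(fire_ids[k] - 1);
  sim.trial(w, start);

  List out = List::create(
      Named("output_fired") = sim.out_fired,
      Named("output_voltage_changed") = sim.v_changed,
      Named("n_act") = IntegerVector(sim.n_act.begin(), sim.n_act.end()),
      Named("duration") = sim.duration);
  if (record_firings) {
    IntegerVector ft(sim.fire_t.begin(), sim.fire_t.end());
    IntegerVector fi(sim.fire_id.begin(), sim.fire_id.end());
    for (int k = 0; k < fi.size(); ++k) fi[k] += 1;
    out["firings_time"] = ft;
    out["firings_neuron"] = fi;
  } else {
    out["firings_time"] = R_NilValue;
    out["firings_neuron"] = R_NilValue;
  }
  return out;
}

static void boost_weights(std::vector<double>& w, double factor,
                          double omega_max) {
  for (size_t s = 0; s < w.size(); ++s)
    w[s] = std::min(w[s] * (1.0 + factor), omega_max);
}

// [[Rcpp::export]]
List cpp_critical_init(int n_neurons, IntegerVector syn_pre,
                       IntegerVector syn_post, NumericVector weight,
                       NumericVector sign, int output_id,
                       IntegerMatrix patterns, IntegerVector input_ids,
                       double factor, double omega_max, int max_boosts,
                       double v_max, double delta_eta, int t_refr, bool linear,
                       bool same_step_block, int step_cap) {
  NetView nv = build_view(n_neurons, syn_pre, syn_post, sign, output_id);
  Simulator sim(nv, v_max, delta_eta, t_refr, linear, same_step_block,
                step_cap);
  std::vector<double> w(weight.begin(), weight.end());
  std::vector<std::vector<int> > starts = pattern_starts(patterns, input_ids);

  int boosts = 0;
  while (true) {
    for (size_t p = 0; p < starts.size(); ++p) {
      sim.trial(w, starts[p]);
      if (sim.out_fired)
        return List::create(Named("weight") = NumericVector(w.begin(), w.end()),
                            Named("boosts") = boosts);
    }
    if (boosts >= max_boosts)
      stop("critical initialization failed: output never fired within %d "
           "global boosts", max_boosts);
    boost_weights(w, factor, omega_max);
    ++boosts;
  }
}

static void adapt_weights(std::vector<double>& w, const std::vector<int>& n_act,
                          const NumericVector& kern, const NetView& nv,
                          double alpha, double omega_max, int dir) {
  for (size_t s = 0; s < w.size(); ++s) {
    if (n_act[s] == 0) continue;
    double d = alpha * w[s] * n_act[s] * kern[s];
    double nw = w[s] + dir * nv.sgn[s] * d;
    if (nw < 0.0) nw = 0.0;
    if (nw > omega_max) nw = omega_max;
    w[s] = nw;
  }
}

// Supervised loop: present patterns cyclically; a wrong answer triggers one
// adaptation event (or, if no signal ever reached the output, a global
// boost). Success = a full cycle of consecutive correct answers.
// [[Rcpp::export]]
List cpp_train(int n_neurons, IntegerVector syn_pre, IntegerVector syn_post,
               NumericVector weight, NumericVector sign, int output_id,
               IntegerMatrix patterns, IntegerVector targets,
               IntegerVector input_ids, NumericVector kern, double alpha,
               double omega_max, double boost_factor, int t_max,
               double v_max, double delta_eta, int t_refr, bool linear,
               bool same_step_block, int step_cap, bool record_history) {
  NetView nv = build_view(n_neurons, syn_pre, syn_post, sign, output_id);
  Simulator sim(nv, v_max, delta_eta, t_refr, linear, same_step_block,
                step_cap);
  std::vector<double> w(weight.begin(), weight.end());
  std::vector<std::vector<int> > starts = pattern_starts(patterns, input_ids);
  const int P = patterns.nrow();

  int steps = 0, boosts = 0, streak = 0, p = 0;
  bool learned = false;
  std::vector<int> h_pat, h_prod, h_tgt, h_evt; // event log, optional

  while (true) {
    sim.trial(w, starts[p]);
    int produced = sim.out_fired ? 1 : 0;
    if (produced == targets[p]) {
      streak += 1;
      if (streak >= P) { learned = true; break; }
    } else {
      streak = 0;
      if (steps >= t_max) break;
      int evt;
      if (!sim.v_changed && targets[p] == 1) {
        boost_weights(w, boost_factor, omega_max);
        boosts += 1;
        evt = 2;
      } else if (targets[p] == 1) {
        adapt_weights(w, sim.n_act, kern, nv, alpha, omega_max, +1);
        evt = 0;
      } else {
        adapt_weights(w, sim.n_act, kern, nv, alpha, omega_max, -1);
        evt = 1;
      }
      steps += 1;
      if (record_history) {
        h_pat.push_back(p + 1);
        h_prod.push_back(produced);
        h_tgt.push_back(targets[p]);
        h_evt.push_back(evt);
      }
    }
    p = (p + 1) % P;
  }

  List out = List::create(
      Named("learned") = learned,
      Named("learning_steps") = steps,
      Named("boosts") = boosts,
      Named("weight") = NumericVector(w.begin(), w.end()));
  if (record_history) {
    out["history_pattern"] = IntegerVector(h_pat.begin(), h_pat.end());
    out["history_produced"] = IntegerVector(h_prod.begin(), h_prod.end());
    out["history_target"] = IntegerVector(h_tgt.begin(), h_tgt.end());
    out["history_event"] = IntegerVector(h_evt.begin(), h_evt.end());
  } else {
    out["history_pattern"] = R_NilValue;
  }
  return out;
}
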