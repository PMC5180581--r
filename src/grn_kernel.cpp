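#include <Rcpp.h>
using namespace Rcpp;

// Controller update for a single organism, mirroring the R composition
// activate_signalling -> transduce -> actuator_outputs ->
// update_concentrations (see R/grn.R). Kept in C++ because it runs once per
// robot per timestep and dominates the cost of a simulation.
//
// Agent bookkeeping: at most one agent per locus; re-expression adds to the
// living agent's concentration, capped at c_max. New agents are appended in
// ascending locus order, matching the R path, so states stay comparable.

struct GrnParams {
  int n_actuators;
  double decay, gain, fscale, c_min, c_max, c_init;
};

static void grn_step_core(
    const int* in_loc, const double* in_conc, const int* in_age, int n_in,
    const double* chan_mag, int n_chan,
    const int* chan_ptr, const int* chan_tgt, const double* chan_q,
    const int* adj_ptr, const int* adj_tgt, const double* adj_q,
    const int* locus_kind, const int* locus_mode,
    const int* locus_act, const double* locus_val, int n_loci,
    double feedback, const GrnParams& p,
    std::vector<int>& out_loc, std::vector<double>& out_conc,
    std::vector<int>& out_age, std::vector<double>& outputs) {
  std::vector<int> loc(in_loc, in_loc + n_in);
  std::vector<double> conc(in_conc, in_conc + n_in);
  std::vector<int> age(in_age, in_age + n_in);
  std::vector<int> slot(n_loci, -1);  // locus -> agent index (or -1)
  for (int i = 0; i < n_in; ++i) slot[loc[i] - 1] = i;

  // --- signalling activation from active channels ---------------------------
  std::vector<double> expr(n_loci, 0.0);
  for (int c = 0; c < n_chan; ++c) {
    double m = chan_mag[c];
    if (m <= 0) continue;
    for (int j = chan_ptr[c]; j < chan_ptr[c + 1]; ++j) {
      double e = m * chan_q[j];
      if (e < p.c_init) e = p.c_init;
      expr[chan_tgt[j] - 1] += e;
    }
  }
  for (int t = 0; t < n_loci; ++t) {
    if (expr[t] <= 0) continue;
    if (slot[t] >= 0) {
      conc[slot[t]] = std::min(conc[slot[t]] + expr[t], p.c_max);
    } else {
      slot[t] = (int)loc.size();
      loc.push_back(t + 1);
      conc.push_back(std::min(expr[t], p.c_max));
      age.push_back(0);
    }
  }

  // --- transduction: living binders express unblocked target loci -----------
  std::vector<double> act(n_loci, 0.0);
  std::vector<bool> blocked(n_loci, false);
  const int n_binder = (int)loc.size();
  for (int i = 0; i < n_binder; ++i) {
    int g = loc[i] - 1;
    if (locus_kind[g] == 2) continue;  // structural products do not bind
    bool repress = (locus_kind[g] == 1 && locus_mode[g] == 1);
    for (int j = adj_ptr[g]; j < adj_ptr[g + 1]; ++j) {
      int t = adj_tgt[j] - 1;
      if (repress) blocked[t] = true;
      else act[t] += conc[i] * adj_q[j];
    }
  }
  for (int t = 0; t < n_loci; ++t) {
    if (locus_kind[t] == 0 || blocked[t] || act[t] <= 0) continue;
    if (slot[t] >= 0) {
      conc[slot[t]] = std::min(conc[slot[t]] + act[t], p.c_max);
    } else {
      slot[t] = (int)loc.size();
      loc.push_back(t + 1);
      conc.push_back(std::min(act[t], p.c_max));
      age.push_back(0);
    }
  }

  // --- actuator read-out: concentration-weighted mean of structural values --
  outputs.assign(p.n_actuators, 0.0);
  std::vector<double> den(p.n_actuators, 0.0);
  for (size_t i = 0; i < loc.size(); ++i) {
    int g = loc[i] - 1;
    if (locus_kind[g] != 2) continue;
    int a = locus_act[g] - 1;
    outputs[a] += conc[i] * locus_val[g];
    den[a] += conc[i];
  }
  for (int a = 0; a < p.n_actuators; ++a)
    outputs[a] = den[a] > 0 ? outputs[a] / den[a] : 0.0;

  // --- decay, feedback, deletion below the floor ----------------------------
  // Per-agent credit: the feedback term is weighted by how strongly a
  // structural agent's output value aligns with the robot's current actuator
  // output (its contribution to the behaviour whose payoff is being felt);
  // signalling and regulatory agents feel pure decay.
  double f = std::min(std::abs(feedback) / p.fscale, 1.0);
  double sgn = (feedback > 0) - (feedback < 0);
  out_loc.clear(); out_conc.clear(); out_age.clear();
  for (size_t i = 0; i < loc.size(); ++i) {
    int g = loc[i] - 1;
    double align = 0.0;
    if (locus_kind[g] == 2) {
      double o = outputs[locus_act[g] - 1];
      align = 2.0 * (1.0 - std::abs(locus_val[g] - o)) - 1.0;
    }
    double c2 = conc[i] * (1.0 - p.decay) * (1.0 + p.gain * sgn * f * align);
    if (c2 >= p.c_min) {
      out_loc.push_back(loc[i]);
      out_conc.push_back(c2);
      out_age.push_back(age[i] + 1);
    }
  }
}

// [[Rcpp::export(name = ".grn_step_cpp")]]
List grn_step_cpp(IntegerVector agent_loc, NumericVector agent_conc,
                  IntegerVector agent_age, NumericVector chan_mag,
                  IntegerVector chan_ptr, IntegerVector chan_tgt,
                  NumericVector chan_q, IntegerVector adj_ptr,
                  IntegerVector adj_tgt, NumericVector adj_q,
                  IntegerVector locus_kind, IntegerVector locus_mode,
                  IntegerVector locus_act, NumericVector locus_val,
                  int n_actuators, double feedback, double decay, double gain,
                  double fscale, double c_min, double c_max, double c_init) {
  GrnParams p{n_actuators, decay, gain, fscale, c_min, c_max, c_init};
  std::vector<int> oloc, oage;
  std::vector<double> oconc, oout;
  grn_step_core(agent_loc.begin(), agent_conc.begin(), agent_age.begin(),
                agent_loc.size(), chan_mag.begin(), chan_mag.size(),
                chan_ptr.begin(), chan_tgt.begin(), chan_q.begin(),
                adj_ptr.begin(), adj_tgt.begin(), adj_q.begin(),
                locus_kind.begin(), locus_mode.begin(), locus_act.begin(),
                locus_val.begin(), locus_kind.size(), feedback, p,
                oloc, oconc, oage, oout);
  return List::create(_["loc"] = wrap(oloc), _["conc"] = wrap(oconc),
                      _["age"] = wrap(oage), _["outputs"] = wrap(oout));
}

// Whole-population variant: one call per timestep. `agents` holds one
// list(loc, conc, age) per robot and `tabs` the per-genome wiring tables
// (as produced by genome_tables()); robots sharing nothing, the update is
// independent per robot and identical to .grn_step_cpp.
// [[Rcpp::export(name = ".grn_step_all_cpp")]]
List grn_step_all_cpp(List agents, List tabs, NumericMatrix mags,
                      NumericVector feedback, int n_actuators, double decay,
                      double gain, double fscale, double c_min, double c_max,
                      double c_init) {
  const int n = agents.size();
  GrnParams p{n_actuators, decay, gain, fscale, c_min, c_max, c_init};
  List out_agents(n);
  NumericMatrix outputs(n, n_actuators);
  std::vector<int> oloc, oage;
  std::vector<double> oconc, oout;
  std::vector<double> mag(mags.ncol());
  for (int i = 0; i < n; ++i) {
    List ag = agents[i];
    List tab = tabs[i];
    IntegerVector loc = ag["loc"];
    NumericVector conc = ag["conc"];
    IntegerVector age = ag["age"];
    IntegerVector chan_ptr = tab["chan_ptr"], chan_tgt = tab["chan_tgt"];
    NumericVector chan_q = tab["chan_q"];
    IntegerVector adj_ptr = tab["adj_ptr"], adj_tgt = tab["adj_tgt"];
    NumericVector adj_q = tab["adj_q"];
    IntegerVector kind = tab["kind"], mode = tab["mode"], actu = tab["actuator"];
    NumericVector val = tab["value"];
    for (int c = 0; c < mags.ncol(); ++c) mag[c] = mags(i, c);
    grn_step_core(loc.begin(), conc.begin(), age.begin(), loc.size(),
                  mag.data(), (int)mag.size(),
                  chan_ptr.begin(), chan_tgt.begin(), chan_q.begin(),
                  adj_ptr.begin(), adj_tgt.begin(), adj_q.begin(),
                  kind.begin(), mode.begin(), actu.begin(), val.begin(),
                  kind.size(), feedback[i], p, oloc, oconc, oage, oout);
    out_agents[i] = List::create(_["loc"] = wrap(oloc),
                                 _["conc"] = wrap(oconc),
                                 _["age"] = wrap(oage));
    for (int a = 0; a < n_actuators; ++a) outputs(i, a) = oout[a];
  }
  return List::create(_["agents"] = out_agents, _["outputs"] = outputs);
}
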