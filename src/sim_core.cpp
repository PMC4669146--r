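// Conductance-based LIF trial simulator for the four-population
// visible/hidden + per-layer inhibitory-pool architecture.
//
// Units: membrane potentials in mV, times in ms, conductances dimensionless
// (relative to the leak conductance).  Integration is exponential Euler with
// synaptic conductances held constant across each step, which is exact for
// constant drive.  No RNG is used here: given the input spike trains the
// trial is fully deterministic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct Pop {
  int n = 0;
  bool adapt = false;
  arma::vec V, ge, gi, ga, ref_until;
  std::vector<double> sp_t;
  std::vector<int> sp_id;  // 1-based neuron ids

  void init(int n_, double v_rest, bool adapt_) {
    n = n_;
    adapt = adapt_;
    V = arma::vec(n, arma::fill::value(v_rest));
    ge = arma::vec(n, arma::fill::zeros);
    gi = arma::vec(n, arma::fill::zeros);
    ga = arma::vec(n, arma::fill::zeros);
    ref_until = arma::vec(n, arma::fill::value(-1e9));
  }
};

struct Params {
  double tau_m, v_rest, v_thresh, v_reset, t_ref;
  double tau_e, tau_i, e_e, e_i, adapt_b, tau_adapt;
  double de, di, da;  // per-step conductance decay factors

  void load(const NumericVector& p, double dt) {
    tau_m = p[0]; v_rest = p[1]; v_thresh = p[2]; v_reset = p[3];
    t_ref = p[4]; tau_e = p[5]; tau_i = p[6]; e_e = p[7]; e_i = p[8];
    adapt_b = p[9]; tau_adapt = p[10];
    de = std::exp(-dt / tau_e);
    di = std::exp(-dt / tau_i);
    da = std::exp(-dt / tau_adapt);
  }
};

inline void step_pop(Pop& pop, const Params& pr, double t_now, double t_spk,
                     double dt, const arma::vec* drive) {
  for (int i = 0; i < pop.n; ++i) {
    if (t_now < pop.ref_until(i)) {
      pop.V(i) = pr.v_reset;
      continue;
    }
    double ge = pop.ge(i) + (drive ? (*drive)(i) : 0.0);
    double gi = pop.gi(i);
    double ga = pop.ga(i);
    double gtot = 1.0 + ge + gi + ga;
    double vinf = (pr.v_rest + ge * pr.e_e + gi * pr.e_i + ga * pr.e_i) / gtot;
    double v = vinf + (pop.V(i) - vinf) * std::exp(-dt * gtot / pr.tau_m);
    if (v >= pr.v_thresh) {
      pop.sp_t.push_back(t_spk);
      pop.sp_id.push_back(i + 1);
      pop.V(i) = pr.v_reset;
      pop.ref_until(i) = t_spk + pr.t_ref;
      if (pop.adapt) pop.ga(i) += pr.adapt_b;
    } else {
      pop.V(i) = v;
    }
  }
}

}  // namespace

// [[Rcpp::export]]
List lif_trial_cpp(double dt, double duration, double delay,
                   NumericVector np_exc, NumericVector np_hid_in,
                   NumericVector np_inh,
                   arma::mat Wexc, arma::mat Winh,
                   arma::mat Qexc, arma::mat Qinh,
                   double w_vis_to_inh, double w_inh_to_vis,
                   double w_hid_to_inh, double w_inh_to_hid,
                   int n_inh_vis, int n_inh_hid,
                   NumericVector ext_t, IntegerVector ext_id, double w_ext,
                   arma::vec const_drive) {
  const int n_vis = Wexc.n_rows;
  const int n_hid = Wexc.n_cols;
  const int n_steps = (int)std::ceil(duration / dt);
  int delay_steps = (int)std::lround(delay / dt);
  if (delay_steps < 1) delay_steps = 1;
  const int n_slots = n_steps + delay_steps + 2;

  Params pe, ph, pi;
  pe.load(np_exc, dt);
  ph.load(np_hid_in, dt);
  pi.load(np_inh, dt);

  Pop vis, hid, iv, ih;
  vis.init(n_vis, pe.v_rest, pe.adapt_b > 0);
  hid.init(n_hid, ph.v_rest, ph.adapt_b > 0);
  iv.init(n_inh_vis, pi.v_rest, false);
  ih.init(n_inh_hid, pi.v_rest, false);

  // scheduled conductance increments, one row per step
  arma::mat b_ge_vis(n_slots, n_vis, arma::fill::zeros);
  arma::mat b_gi_vis(n_slots, n_vis, arma::fill::zeros);
  arma::mat b_ge_hid(n_slots, n_hid, arma::fill::zeros);
  arma::mat b_gi_hid(n_slots, n_hid, arma::fill::zeros);
  arma::vec b_ge_iv(n_slots, arma::fill::zeros);  // uniform within pool
  arma::vec b_ge_ih(n_slots, arma::fill::zeros);

  // external input spikes: delivered at the step containing their timestamp
  for (int k = 0; k < ext_t.size(); ++k) {
    int s = (int)std::floor(ext_t[k] / dt);
    if (s < 0) s = 0;
    if (s >= n_slots) continue;
    b_ge_vis(s, ext_id[k] - 1) += w_ext;
  }

  const bool has_drive = const_drive.n_elem == (arma::uword)n_vis &&
                         arma::any(const_drive != 0.0);

  for (int s = 0; s < n_steps; ++s) {
    const double t_now = s * dt;
    const double t_spk = (s + 1) * dt;
    const int s_del = s + delay_steps;

    vis.ge = vis.ge * pe.de + b_ge_vis.row(s).t();
    vis.gi = vis.gi * pe.di + b_gi_vis.row(s).t();
    vis.ga *= pe.da;
    hid.ge = hid.ge * ph.de + b_ge_hid.row(s).t();
    hid.gi = hid.gi * ph.di + b_gi_hid.row(s).t();
    hid.ga *= ph.da;
    if (iv.n) { iv.ge = iv.ge * pi.de + b_ge_iv(s); iv.gi *= pi.di; }
    if (ih.n) { ih.ge = ih.ge * pi.de + b_ge_ih(s); ih.gi *= pi.di; }

    size_t vis0 = vis.sp_t.size(), hid0 = hid.sp_t.size();
    size_t iv0 = iv.sp_t.size(), ih0 = ih.sp_t.size();

    step_pop(vis, pe, t_now, t_spk, dt, has_drive ? &const_drive : nullptr);
    step_pop(hid, ph, t_now, t_spk, dt, nullptr);
    if (iv.n) step_pop(iv, pi, t_now, t_spk, dt, nullptr);
    if (ih.n) step_pop(ih, pi, t_now, t_spk, dt, nullptr);

    // deliver this step's spikes after the synaptic delay
    for (size_t k = vis0; k < vis.sp_t.size(); ++k) {
      int i = vis.sp_id[k] - 1;
      b_ge_hid.row(s_del) += Wexc.row(i);
      b_gi_hid.row(s_del) += Winh.row(i);
      if (iv.n) b_ge_iv(s_del) += w_vis_to_inh;
    }
    for (size_t k = hid0; k < hid.sp_t.size(); ++k) {
      int j = hid.sp_id[k] - 1;
      b_ge_vis.row(s_del) += Qexc.row(j);
      b_gi_vis.row(s_del) += Qinh.row(j);
      if (ih.n) b_ge_ih(s_del) += w_hid_to_inh;
    }
    for (size_t k = iv0; k < iv.sp_t.size(); ++k)
      b_gi_vis.row(s_del) += w_inh_to_vis;
    for (size_t k = ih0; k < ih.sp_t.size(); ++k)
      b_gi_hid.row(s_del) += w_inh_to_hid;
  }

  auto pack = [](const Pop& p) {
    return List::create(_["time_ms"] = wrap(p.sp_t),
                        _["neuron"] = wrap(p.sp_id));
  };
  return List::create(_["visible"] = pack(vis), _["hidden"] = pack(hid),
                      _["inh_visible"] = pack(iv), _["inh_hidden"] = pack(ih));
}
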