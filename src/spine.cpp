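#include <Rcpp.h>
using namespace Rcpp;

// Reduced spine model: closed-form voltage kernels (BAP + EPSP difference of
// exponentials), saturating NMDA glutamate-binding state, extracellular-Mg
// voltage gate, exponentially decaying calcium, OU membrane noise.
// All times in ms. One call = one spine group over one simulation window.

namespace {

// peak of exp(-t/td) - exp(-t/tr) for tr < td, used to normalise kernels to
// unit peak so amplitude parameters are literal mV
double diffexp_peak(double tr, double td) {
  double tp = std::log(td / tr) * tr * td / (td - tr);
  return std::exp(-tp / td) - std::exp(-tp / tr);
}

struct SpineSim {
  // decay multipliers per step
  double f_br, f_bd, f_er, f_ed, f_xr, f_xd, f_ca, f_n;
  double bap_gain, epsp_gain, nmda_norm;
  double rest, mg_fac, mg_slope, noise_amp, dt;
  bool noisy;

  SpineSim(const List& p, double dt_) {
    dt = dt_;
    double bap_rise = p["bap_rise"], bap_decay = p["bap_decay"];
    double epsp_rise = p["epsp_rise"], epsp_decay = p["epsp_decay"];
    double nmda_rise = p["nmda_rise"], nmda_decay = p["nmda_decay"];
    double ca_decay = p["ca_decay"], noise_corr = p["noise_corr_time"];
    double noise_sd = p["noise_sd"];
    double n_syn = p["synapses_per_axon"];
    f_br = std::exp(-dt / bap_rise);  f_bd = std::exp(-dt / bap_decay);
    f_er = std::exp(-dt / epsp_rise); f_ed = std::exp(-dt / epsp_decay);
    f_xr = std::exp(-dt / nmda_rise); f_xd = std::exp(-dt / nmda_decay);
    f_ca = std::exp(-dt / ca_decay);
    f_n  = std::exp(-dt / noise_corr);
    bap_gain  = as<double>(p["bap_amplitude"]) / diffexp_peak(bap_rise, bap_decay);
    epsp_gain = as<double>(p["epsp_amplitude"]) * n_syn /
                diffexp_peak(epsp_rise, epsp_decay);
    nmda_norm = 1.0 / diffexp_peak(nmda_rise, nmda_decay);
    rest = p["resting_potential"];
    mg_fac = as<double>(p["mg_conc"]) / as<double>(p["mg_k"]);
    mg_slope = p["mg_slope"];
    noisy = noise_sd > 0;
    noise_amp = noise_sd * std::sqrt(1.0 - f_n * f_n);
  }

  // pre/bap spike times in ms, already >= 0; impulse lands in bin floor(t/dt)
  double run(const NumericVector& pre, const NumericVector& bap, int n_steps,
             double epsp_mult, NumericVector* v_out, NumericVector* ca_out) const {
    std::vector<int> pre_bin(pre.size()), bap_bin(bap.size());
    for (int i = 0; i < pre.size(); ++i) pre_bin[i] = (int)std::floor(pre[i] / dt);
    for (int i = 0; i < bap.size(); ++i) bap_bin[i] = (int)std::floor(bap[i] / dt);
    std::sort(pre_bin.begin(), pre_bin.end());
    std::sort(bap_bin.begin(), bap_bin.end());

    double br = 0, bd = 0, er = 0, ed = 0, xr = 0, xd = 0, ca = 0, nz = 0;
    double score = 0;
    size_t ip = 0, ib = 0;
    for (int t = 0; t < n_steps; ++t) {
      br *= f_br; bd *= f_bd; er *= f_er; ed *= f_ed;
      xr *= f_xr; xd *= f_xd;
      while (ip < pre_bin.size() && pre_bin[ip] == t) { er += 1; ed += 1; xr += 1; xd += 1; ++ip; }
      while (ib < bap_bin.size() && bap_bin[ib] == t) { br += 1; bd += 1; ++ib; }
      if (noisy) nz = f_n * nz + noise_amp * norm_rand();
      double v = rest + bap_gain * (bd - br) + epsp_mult * epsp_gain * (ed - er) + nz;
      double s = nmda_norm * (xd - xr);
      if (s > 1.0) s = 1.0;
      double mg = 1.0 / (1.0 + mg_fac * std::exp(-mg_slope * v));
      ca = f_ca * ca + s * mg * dt;
      double ca2 = ca * ca;
      score += ca2 * ca2 * dt;
      if (v_out) (*v_out)[t] = v;
      if (ca_out) (*ca_out)[t] = ca;
    }
    return score;
  }
};

} // namespace

// [[Rcpp::export]]
List sim_spine_cpp(NumericVector pre_ms, NumericVector bap_ms, int n_steps,
                   double dt, List params, double epsp_mult = 1.0) {
  SpineSim sim(params, dt);
  NumericVector v(n_steps), ca(n_steps);
  double score = sim.run(pre_ms, bap_ms, n_steps, epsp_mult, &v, &ca);
  return List::create(_["voltage"] = v, _["calcium"] = ca, _["score"] = score);
}

// [[Rcpp::export]]
double spine_score_cpp(NumericVector pre_ms, NumericVector bap_ms, int n_steps,
                       double dt, List params, double epsp_mult = 1.0) {
  SpineSim sim(params, dt);
  return sim.run(pre_ms, bap_ms, n_steps, epsp_mult, nullptr, nullptr);
}

// One score per axon; each axon has its own presynaptic train and its own
// spine-group BAP arrival train (latency already applied), independent noise.
// [[Rcpp::export]]
NumericVector score_axons_cpp(List pre_list, List bap_list, int n_steps,
                              double dt, List params, NumericVector epsp_mult) {
  SpineSim sim(params, dt);
  int n = pre_list.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    NumericVector pre = pre_list[i], bap = bap_list[i];
    double m = epsp_mult.size() == 1 ? epsp_mult[0] : epsp_mult[i];
    out[i] = sim.run(pre, bap, n_steps, m, nullptr, nullptr);
  }
  return out;
}
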