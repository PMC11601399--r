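// Fast trial/episode engine. Mirrors the R reference path (runTrial /
// runEpisode) operation for operation, including the order in which random
// numbers are consumed: per-stripe gating noise (only when noise_sd > 0),
// then one uniform draw per non-response recall. Equivalence between the
// two paths is asserted in the test suite.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double TWOPI = 2.0 * M_PI;

static inline double posmod(double x, double m) {
  double r = x - std::floor(x / m) * m;
  if (r >= m) r -= m;
  if (r < 0) r += m;
  return r;
}

// signed degrees in [-180, 180)
static inline double wrapDeg(double d) {
  return posmod(d + 180.0, 360.0) - 180.0;
}

struct Engine {
  int R, K, n, chunk_stripe, n_cycles;
  double tuning_width, ge_gain, scale_input, scale_pfc, chunk_gamma;
  double noise_sd, decode_floor, occupy_floor;
  double lr_v, lr_w, lr_rep, tag_decay, nogo_tag_scale, nogo_burst_credit, w_max, burst_gain, dip_gain;
  double maintain_leak;
  bool occ_drive_in, occ_drive_out;
  // neuron params
  double E_e, E_i, E_l, gbar_e, gbar_i, gbar_l, theta, g_l;
  // fffb params
  double Gi, ff_gain, ff_floor, fb_gain, fb_tau;

  NumericMatrix kernel;
  NumericMatrix U_ori;
  NumericMatrix Wgo_in, Wnogo_in, Wgo_out, Wnogo_out;
  NumericVector Wocc_go_in, Wocc_nogo_in, Wocc_go_out, Wocc_nogo_out;
  NumericMatrix Wrep_in, Wrep_pfc;
  NumericMatrix tag_in, tag_nogo_in, tag_out, tag_nogo_out;
  NumericVector tag_occ_in, tag_occ_nogo_in, tag_occ_out, tag_occ_nogo_out;
  NumericMatrix deep;
  LogicalVector occupied;
  double v;

  std::vector<double> pref_sin, pref_cos;

  explicit Engine(List net) {
    List cfg = net["config"];
    R = as<int>(cfg["ring_size"]);
    K = as<int>(cfg["n_orientations"]);
    n = as<int>(cfg["n_stripes"]);
    chunk_stripe = as<int>(cfg["chunk_stripe"]); // 1-based, 0 = none
    n_cycles = as<int>(cfg["n_cycles"]);
    tuning_width = as<double>(cfg["tuning_width"]);
    ge_gain = as<double>(cfg["ge_gain"]);
    scale_input = as<double>(cfg["scale_input"]);
    scale_pfc = as<double>(cfg["scale_pfc"]);
    chunk_gamma = as<double>(cfg["chunk_gamma"]);
    noise_sd = as<double>(cfg["noise_sd"]);
    decode_floor = as<double>(cfg["decode_floor"]);
    occupy_floor = as<double>(cfg["occupy_floor"]);
    lr_v = as<double>(cfg["lr_v"]);
    lr_w = as<double>(cfg["lr_w"]);
    lr_rep = as<double>(cfg["lr_rep"]);
    tag_decay = as<double>(cfg["tag_decay"]);
    nogo_tag_scale = as<double>(cfg["nogo_tag_scale"]);
    nogo_burst_credit = as<double>(cfg["nogo_burst_credit"]);
    w_max = as<double>(cfg["w_max"]);
    burst_gain = as<double>(cfg["burst_gain"]);
    dip_gain = as<double>(cfg["dip_gain"]);
    maintain_leak = as<double>(cfg["maintain_leak"]);
    occ_drive_in = as<bool>(cfg["occ_drive_in"]);
    occ_drive_out = as<bool>(cfg["occ_drive_out"]);
    List nrn = cfg["neuron"];
    E_e = as<double>(nrn["E_e"]); E_i = as<double>(nrn["E_i"]);
    E_l = as<double>(nrn["E_l"]);
    gbar_e = as<double>(nrn["gbar_e"]); gbar_i = as<double>(nrn["gbar_i"]);
    gbar_l = as<double>(nrn["gbar_l"]);
    theta = as<double>(nrn["theta"]); g_l = as<double>(nrn["g_l"]);
    List fffb = cfg["fffb"];
    Gi = as<double>(fffb["Gi"]); ff_gain = as<double>(fffb["ff_gain"]);
    ff_floor = as<double>(fffb["ff_floor"]);
    fb_gain = as<double>(fffb["fb_gain"]); fb_tau = as<double>(fffb["fb_tau"]);

    kernel = clone(as<NumericMatrix>(net["kernel"]));
    U_ori = clone(as<NumericMatrix>(net["U_ori"]));
    Wgo_in = clone(as<NumericMatrix>(net["Wgo_in"]));
    Wnogo_in = clone(as<NumericMatrix>(net["Wnogo_in"]));
    Wgo_out = clone(as<NumericMatrix>(net["Wgo_out"]));
    Wnogo_out = clone(as<NumericMatrix>(net["Wnogo_out"]));
    Wocc_go_in = clone(as<NumericVector>(net["Wocc_go_in"]));
    Wocc_nogo_in = clone(as<NumericVector>(net["Wocc_nogo_in"]));
    Wocc_go_out = clone(as<NumericVector>(net["Wocc_go_out"]));
    Wocc_nogo_out = clone(as<NumericVector>(net["Wocc_nogo_out"]));
    Wrep_in = clone(as<NumericMatrix>(net["Wrep_in"]));
    Wrep_pfc = clone(as<NumericMatrix>(net["Wrep_pfc"]));
    tag_in = clone(as<NumericMatrix>(net["tag_in"]));
    tag_nogo_in = clone(as<NumericMatrix>(net["tag_nogo_in"]));
    tag_out = clone(as<NumericMatrix>(net["tag_out"]));
    tag_nogo_out = clone(as<NumericMatrix>(net["tag_nogo_out"]));
    tag_occ_in = clone(as<NumericVector>(net["tag_occ_in"]));
    tag_occ_nogo_in = clone(as<NumericVector>(net["tag_occ_nogo_in"]));
    tag_occ_out = clone(as<NumericVector>(net["tag_occ_out"]));
    tag_occ_nogo_out = clone(as<NumericVector>(net["tag_occ_nogo_out"]));
    deep = clone(as<NumericMatrix>(net["deep"]));
    occupied = clone(as<LogicalVector>(net["occupied"]));
    v = as<double>(net["v"]);

    pref_sin.resize(R); pref_cos.resize(R);
    for (int i = 0; i < R; ++i) {
      double a = TWOPI * i / R;
      pref_sin[i] = std::sin(a);
      pref_cos[i] = std::cos(a);
    }
  }

  void encode(double angle, std::vector<double> &bump) const {
    double a = posmod(angle, TWOPI);
    for (int i = 0; i < R; ++i) {
      double d = posmod(TWOPI * i / R - a + M_PI, TWOPI) - M_PI;
      bump[i] = std::exp(-d * d / (2.0 * tuning_width * tuning_width));
    }
  }

  // decoded angle in [0, 2pi), or NA when nothing clears the floor
  double decode(const std::vector<double> &act) const {
    double mx = 0.0, ss = 0.0, sc = 0.0;
    for (int i = 0; i < R; ++i) {
      double a = act[i] > 0 ? act[i] : 0.0;
      if (a > mx) mx = a;
      ss += a * pref_sin[i];
      sc += a * pref_cos[i];
    }
    if (!(mx > decode_floor)) return NA_REAL;
    return posmod(std::atan2(ss, sc), TWOPI);
  }

  void chunkSettle(const std::vector<double> &x,
                   std::vector<double> &y) const {
    std::vector<double> ge(R, 0.0);
    for (int j = 0; j < R; ++j) {
      double acc = 0.0;
      for (int i = 0; i < R; ++i) acc += x[i] * kernel(i, j);
      ge[j] = scale_input * acc / R;
    }
    int n_occ = 0;
    for (int s = 0; s < n; ++s) if (occupied[s]) ++n_occ;
    for (int s = 0; s < n; ++s) {
      if (!occupied[s]) continue;
      for (int j = 0; j < R; ++j) {
        double acc = 0.0;
        for (int i = 0; i < R; ++i) acc += deep(i, s) * kernel(i, j);
        ge[j] += (scale_pfc / n_occ) * acc / R;
      }
    }
    double mean_ge = 0.0;
    for (int j = 0; j < R; ++j) { ge[j] *= ge_gain; mean_ge += ge[j]; }
    mean_ge /= R;
    double ff = ff_gain * std::max(0.0, mean_ge - ff_floor);
    double fb = 0.0;
    std::fill(y.begin(), y.end(), 0.0);
    for (int cyc = 0; cyc < n_cycles; ++cyc) {
      double mean_y = 0.0;
      for (int j = 0; j < R; ++j) mean_y += y[j];
      mean_y /= R;
      fb += (1.0 / fb_tau) * (fb_gain * mean_y - fb);
      double gi = Gi * (ff + fb);
      double ge_theta = (gi * gbar_i * (E_i - theta) +
                         g_l * gbar_l * (E_l - theta)) /
                        ((theta - E_e) * gbar_e);
      for (int j = 0; j < R; ++j) {
        double d = ge[j] - ge_theta;
        y[j] = d > 0 ? 1.0 / (1.0 + 1.0 / (chunk_gamma * d)) : 0.0;
      }
    }
  }

  void decayTags() {
    for (int i = 0; i < K * n; ++i) {
      tag_in[i] *= tag_decay;
      tag_nogo_in[i] *= tag_decay;
      tag_out[i] *= tag_decay;
      tag_nogo_out[i] *= tag_decay;
    }
    for (int s = 0; s < n; ++s) {
      tag_occ_in[s] *= tag_decay;
      tag_occ_nogo_in[s] *= tag_decay;
      tag_occ_out[s] *= tag_decay;
      tag_occ_nogo_out[s] *= tag_decay;
    }
  }

  void resetTags() {
    std::fill(tag_in.begin(), tag_in.end(), 0.0);
    std::fill(tag_nogo_in.begin(), tag_nogo_in.end(), 0.0);
    std::fill(tag_out.begin(), tag_out.end(), 0.0);
    std::fill(tag_nogo_out.begin(), tag_nogo_out.end(), 0.0);
    std::fill(tag_occ_in.begin(), tag_occ_in.end(), 0.0);
    std::fill(tag_occ_nogo_in.begin(), tag_occ_nogo_in.end(), 0.0);
    std::fill(tag_occ_out.begin(), tag_occ_out.end(), 0.0);
    std::fill(tag_occ_nogo_out.begin(), tag_occ_nogo_out.end(), 0.0);
  }

  void threeFactor(NumericMatrix &go, NumericMatrix &nogo,
                   const NumericMatrix &tags_go,
                   const NumericMatrix &tags_nogo, double da) {
    int len = go.size();
    for (int i = 0; i < len; ++i) {
      double d = lr_w * da *
        (tags_go[i] - (da < 0 ? 1.0 : nogo_burst_credit) * tags_nogo[i]);
      go[i] = std::min(std::max(go[i] + d, 0.0), w_max);
      nogo[i] = std::min(std::max(nogo[i] - d, 0.0), w_max);
    }
  }
  void threeFactorVec(NumericVector &go, NumericVector &nogo,
                      const NumericVector &tags_go,
                      const NumericVector &tags_nogo, double da) {
    for (int i = 0; i < go.size(); ++i) {
      double d = lr_w * da *
        (tags_go[i] - (da < 0 ? 1.0 : nogo_burst_credit) * tags_nogo[i]);
      go[i] = std::min(std::max(go[i] + d, 0.0), w_max);
      nogo[i] = std::min(std::max(nogo[i] - d, 0.0), w_max);
    }
  }

  void gateCompetition(int ori, const std::vector<double> &occ,
                       const NumericMatrix &go_w, const NumericMatrix &nogo_w,
                       const NumericVector &occ_go, const NumericVector &occ_nogo,
                       std::vector<int> &open) {
    for (int s = 0; s < n; ++s) {
      double go = occ[s] * occ_go[s];
      double nogo = occ[s] * occ_nogo[s];
      for (int k = 0; k < K; ++k) {
        double u = U_ori(ori, k);
        if (u == 0.0) continue;
        go += u * go_w(k, s);
        nogo += u * nogo_w(k, s);
      }
      double noise = noise_sd > 0 ? R::rnorm(0.0, noise_sd) : 0.0;
      open[s] = (go - nogo + noise) > 0 ? 1 : 0;
    }
  }

  void storeTrial(int ori, double color, bool learn) {
    std::vector<double> x(R), chunk(R);
    encode(color, x);
    bool use_chunk = chunk_stripe > 0;
    if (use_chunk) chunkSettle(x, chunk);
    std::vector<double> occ_pre(n);
    for (int s = 0; s < n; ++s)
      occ_pre[s] = (occ_drive_in && occupied[s]) ? 1.0 : 0.0;
    std::vector<int> open(n);
    gateCompetition(ori, occ_pre, Wgo_in, Wnogo_in, Wocc_go_in,
                    Wocc_nogo_in, open);
    if (learn) {
      decayTags();
      for (int s = 0; s < n; ++s) {
        if (open[s]) {
          for (int k = 0; k < K; ++k) tag_in(k, s) += U_ori(ori, k);
          tag_occ_in[s] += occ_pre[s];
        } else {
          for (int k = 0; k < K; ++k)
            tag_nogo_in(k, s) += nogo_tag_scale * U_ori(ori, k);
          tag_occ_nogo_in[s] += nogo_tag_scale * occ_pre[s];
        }
      }
    }
    // input gating: latch source bump, peak-normalized
    for (int s = 0; s < n; ++s) {
      if (open[s]) {
        const std::vector<double> &src = (s + 1 == chunk_stripe) ? chunk : x;
        double pk = 0.0;
        for (int i = 0; i < R; ++i) if (src[i] > pk) pk = src[i];
        if (pk > occupy_floor) {
          for (int i = 0; i < R; ++i) deep(i, s) = src[i] / pk;
          occupied[s] = true;
        } else {
          for (int i = 0; i < R; ++i) deep(i, s) = 0.0;
          occupied[s] = false;
        }
      } else if (maintain_leak > 0 && occupied[s]) {
        double pk = 0.0;
        for (int i = 0; i < R; ++i) {
          deep(i, s) *= (1.0 - maintain_leak);
          if (deep(i, s) > pk) pk = deep(i, s);
        }
        if (!(pk > occupy_floor)) {
          for (int i = 0; i < R; ++i) deep(i, s) = 0.0;
          occupied[s] = false;
        }
      }
    }
    // supervised report mapping from input
    std::vector<double> produced(R, 0.0);
    for (int j = 0; j < R; ++j) {
      double acc = 0.0;
      for (int i = 0; i < R; ++i) acc += Wrep_in(j, i) * x[i];
      produced[j] = acc;
    }
    if (learn) {
      for (int j = 0; j < R; ++j) {
        double err = lr_rep * (x[j] - produced[j]);
        if (err == 0.0) continue;
        for (int i = 0; i < R; ++i) Wrep_in(j, i) += err * x[i];
      }
    }
  }

  // returns recall metrics through the out-parameters
  void recallTrial(int ori, double target, bool learn,
                   double &error_deg, int &responded, int &gated_flag,
                   int &n_output_gated, double &response_deg,
                   double &reward_out, double &delta_out, double &da_out) {
    std::vector<double> occ_pre(n);
    for (int s = 0; s < n; ++s)
      occ_pre[s] = (occ_drive_out && occupied[s]) ? 1.0 : 0.0;
    std::vector<int> open(n);
    gateCompetition(ori, occ_pre, Wgo_out, Wnogo_out, Wocc_go_out,
                    Wocc_nogo_out, open);
    if (learn) {
      decayTags();
      for (int s = 0; s < n; ++s) {
        if (open[s]) {
          for (int k = 0; k < K; ++k) tag_out(k, s) += U_ori(ori, k);
          tag_occ_out[s] += occ_pre[s];
        } else {
          for (int k = 0; k < K; ++k)
            tag_nogo_out(k, s) += nogo_tag_scale * U_ori(ori, k);
          tag_occ_nogo_out[s] += nogo_tag_scale * occ_pre[s];
        }
      }
    }
    int n_eff = 0;
    n_output_gated = 0;
    std::vector<double> drive(R, 0.0);
    for (int s = 0; s < n; ++s) {
      if (open[s]) ++n_output_gated;
      if (open[s] && occupied[s]) {
        ++n_eff;
        for (int i = 0; i < R; ++i) drive[i] += deep(i, s);
      }
    }
    bool gated = n_eff > 0;
    gated_flag = gated ? 1 : 0;
    if (gated) for (int i = 0; i < R; ++i) drive[i] /= n_eff;

    double response = NA_REAL;
    std::vector<double> produced_raw(R, 0.0);
    if (gated) {
      std::vector<double> rect(R);
      for (int j = 0; j < R; ++j) {
        double acc = 0.0;
        for (int i = 0; i < R; ++i) acc += Wrep_pfc(j, i) * drive[i];
        produced_raw[j] = acc;
        rect[j] = acc > 0 ? acc : 0.0;
      }
      response = decode(rect);
    }
    responded = (gated && !ISNA(response)) ? 1 : 0;
    if (responded) {
      error_deg = wrapDeg(response * 180.0 / M_PI - target * 180.0 / M_PI);
      response_deg = wrapDeg(response * 180.0 / M_PI);
    } else {
      error_deg = R::runif(-180.0, 180.0);
      response_deg = NA_REAL;
    }
    double reward = 1.0 - std::fabs(error_deg) / 90.0;
    reward = std::min(1.0, std::max(-1.0, reward));
    reward_out = reward;
    delta_out = NA_REAL;
    da_out = NA_REAL;
    if (learn) {
      double delta = reward - v;
      v += lr_v * delta;
      double da = delta > 0 ? burst_gain * delta : dip_gain * delta;
      delta_out = delta;
      da_out = da;
      threeFactor(Wgo_in, Wnogo_in, tag_in, tag_nogo_in, da);
      threeFactorVec(Wocc_go_in, Wocc_nogo_in, tag_occ_in,
                     tag_occ_nogo_in, da);
      threeFactor(Wgo_out, Wnogo_out, tag_out, tag_nogo_out, da);
      threeFactorVec(Wocc_go_out, Wocc_nogo_out, tag_occ_out,
                     tag_occ_nogo_out, da);
      if (gated) {
        std::vector<double> tgt(R);
        encode(target, tgt);
        for (int j = 0; j < R; ++j) {
          double err = lr_rep * (tgt[j] - produced_raw[j]);
          if (err == 0.0) continue;
          for (int i = 0; i < R; ++i) Wrep_pfc(j, i) += err * drive[i];
        }
      }
      resetTags();
    }
  }

  List exportNet(List net_in) const {
    List net = clone(net_in);
    net["Wgo_in"] = Wgo_in; net["Wnogo_in"] = Wnogo_in;
    net["Wgo_out"] = Wgo_out; net["Wnogo_out"] = Wnogo_out;
    net["Wocc_go_in"] = Wocc_go_in; net["Wocc_nogo_in"] = Wocc_nogo_in;
    net["Wocc_go_out"] = Wocc_go_out; net["Wocc_nogo_out"] = Wocc_nogo_out;
    net["Wrep_in"] = Wrep_in; net["Wrep_pfc"] = Wrep_pfc;
    net["tag_in"] = tag_in; net["tag_nogo_in"] = tag_nogo_in;
    net["tag_out"] = tag_out; net["tag_nogo_out"] = tag_nogo_out;
    net["tag_occ_in"] = tag_occ_in; net["tag_occ_nogo_in"] = tag_occ_nogo_in;
    net["tag_occ_out"] = tag_occ_out;
    net["tag_occ_nogo_out"] = tag_occ_nogo_out;
    net["deep"] = deep; net["occupied"] = occupied;
    net["v"] = v;
    return net;
  }
};

// Run a batch of episodes through the network.
//
// epi_oris: n_epi x max_N matrix of 0-based orientation ids
// epi_colors: n_epi x max_N matrix of color angles (radians)
// epi_N: per-episode set size; epi_probe: 1-based probed store index
// [[Rcpp::export]]
List cpp_run_episodes(List net, IntegerMatrix epi_oris,
                      NumericMatrix epi_colors, IntegerVector epi_N,
                      IntegerVector epi_probe, bool learn) {
  Engine eng(net);
  int n_epi = epi_N.size();
  NumericVector error_deg(n_epi), response_deg(n_epi), target_deg(n_epi);
  NumericVector reward(n_epi), delta(n_epi), da(n_epi);
  IntegerVector responded(n_epi), gated(n_epi), n_out(n_epi), lag(n_epi);
  IntegerVector probe_ori(n_epi);
  LogicalMatrix occ_final(n_epi, eng.n);

  for (int e = 0; e < n_epi; ++e) {
    int N = epi_N[e];
    for (int i = 0; i < N; ++i)
      eng.storeTrial(epi_oris(e, i), epi_colors(e, i), learn);
    for (int s = 0; s < eng.n; ++s) occ_final(e, s) = eng.occupied[s];
    int pi = epi_probe[e] - 1;
    double ed, rd, rw, dl, dav;
    int resp, gt, nog;
    eng.recallTrial(epi_oris(e, pi), epi_colors(e, pi), learn,
                    ed, resp, gt, nog, rd, rw, dl, dav);
    error_deg[e] = ed; response_deg[e] = rd;
    target_deg[e] = wrapDeg(posmod(epi_colors(e, pi), TWOPI) * 180.0 / M_PI);
    responded[e] = resp; gated[e] = gt; n_out[e] = nog;
    lag[e] = N - epi_probe[e];
    probe_ori[e] = epi_oris(e, pi);
    reward[e] = rw; delta[e] = dl; da[e] = dav;
  }
  DataFrame recall = DataFrame::create(
    _["episode"] = seq_len(n_epi),
    _["probe_orientation"] = probe_ori,
    _["target_deg"] = target_deg,
    _["response_deg"] = response_deg,
    _["error_deg"] = error_deg,
    _["responded"] = responded,
    _["gated"] = gated,
    _["n_output_gated"] = n_out,
    _["lag"] = lag,
    _["reward"] = reward,
    _["delta"] = delta,
    _["da"] = da);
  return List::create(_["net"] = eng.exportNet(net),
                      _["recall"] = recall,
                      _["occupancy_final_store"] = occ_final);
}

// Settle the chunk layer once against the given deep-layer state.
// [[Rcpp::export]]
NumericVector cpp_chunk_settle(List net, NumericVector input_bump) {
  Engine eng(net);
  std::vector<double> x(input_bump.begin(), input_bump.end());
  std::vector<double> y(eng.R, 0.0);
  eng.chunkSettle(x, y);
  return wrap(y);
}
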