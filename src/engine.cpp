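// Fixed-timestep integration core for small feedforward LIF networks with
// alpha-function synapses, weight-dependent STDP, correlated Poisson
// background drive, and closed-loop spike-triggered stimulation (STS).
//
// Design notes:
//  * Per-neuron synaptic drive is aggregated: A = sum_k w_k * g_k and
//    B = sum_k w_k * z_k evolve under the same linear alpha kinetics as the
//    individual (g, z) pairs, with each presynaptic arrival adding
//    w * g_norm to B (weight taken at transmission time). This is exact by
//    linearity and keeps the per-step cost independent of the background
//    fan-in.
//  * The stimulation channel (A_stim, B_stim) is a separate alpha
//    conductance, exempt from plasticity, and cleared when its target
//    spikes so that one trigger evokes at most one action potential.
//  * Event order within a step at time t: (1) deliver due arrivals
//    (background, network, stimulation) and apply arrival-side depression;
//    (2) advance alpha states; (3) integrate membranes and detect spikes at
//    time t; (4) apply spike-side potentiation, schedule transmissions and
//    stimulation. A suprathreshold stimulus arriving at t therefore evokes
//    a spike stamped t.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>
#include <random>

using namespace Rcpp;

namespace {

// Portable 64-bit Mersenne Twister wrapper: we avoid std::*_distribution so
// that streams are bit-reproducible across standard library versions.
struct Rng {
  std::mt19937_64 eng;
  explicit Rng(uint64_t seed) : eng(seed) {}
  double unif() {
    // 53-bit mantissa uniform in [0, 1)
    return (eng() >> 11) * (1.0 / 9007199254740992.0);
  }
};

// splitmix64 finalizer: decorrelates per-stream seeds derived from one seed
uint64_t mix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

// Inverse-CDF binomial sampler driven by a single uniform. n is small
// (<= a few hundred) and p tiny, so the expected number of pmf steps is ~1.
int rbinom_inv(Rng& rng, int n, double p, double log1mp) {
  if (p <= 0.0 || n == 0) return 0;
  if (p >= 1.0) return n;
  double u = rng.unif();
  double pmf = std::exp(n * log1mp);  // P(X = 0)
  double cdf = pmf;
  int k = 0;
  const double odds = p / (1.0 - p);
  while (u > cdf && k < n) {
    ++k;
    pmf *= odds * (double)(n - k + 1) / (double)k;
    cdf += pmf;
    if (pmf < 1e-300 && cdf < u) return k;  // numeric guard, p astronomically small
  }
  return k;
}

struct SpikeRec {
  std::vector<double> t;
  std::vector<int> id;
};

}  // namespace

// Run `n_steps` steps of the network, mutating a copy of `state` and
// returning the new state plus logs. All times in ms, weights in pS.
// [[Rcpp::export(name = ".engine_run")]]
List engine_run(List state, List params, int n_steps, double seed,
                bool record_spikes, double w_every_ms, double r_every_ms) {
  // ---- unpack parameters ----
  const double dt        = as<double>(params["dt"]);
  const double Cm        = as<double>(params["C_memb"]);
  const double Rm        = as<double>(params["R_memb"]);
  const double E_rest    = as<double>(params["E_rest"]);
  const double V_thr     = as<double>(params["V_thr"]);
  const double tau_ref   = as<double>(params["tau_refrac"]);
  const double t_del     = as<double>(params["t_delay_syn"]);
  const double tau       = as<double>(params["tau_rise"]);
  const double g_norm    = as<double>(params["g_norm"]);
  const double gain      = as<double>(params["current_gain"]);
  const int    cond_mode = as<int>(params["drive_mode"]);  // 0 current, 1 conductance
  const double E_ex      = as<double>(params["E_ex"]);
  const double A_p       = as<double>(params["A_p"]);
  const double tau_p     = as<double>(params["tau_p"]);
  const double A_d       = as<double>(params["A_d"]);
  const double tau_d     = as<double>(params["tau_d"]);
  const double g_max     = as<double>(params["g_max"]);
  const double c_back    = as<double>(params["c_back"]);
  const double q_hot     = as<double>(params["q_hot"]);
  const bool   sts_on    = as<int>(params["sts_on"]) != 0;
  const int    sts_src   = as<int>(params["sts_source"]) - 1;  // 0-based
  const int    sts_tgt   = as<int>(params["sts_target"]) - 1;
  const double sts_delay = as<double>(params["sts_delay_ms"]);
  const double stim_B    = as<double>(params["stim_impulse"]);  // added to B_stim per arrival

  const double tau_m  = Rm * Cm;          // GOhm * pF = ms
  const double a_dec  = 1.0 - dt / tau;   // alpha decay factor per step
  const double dtp_cut = 46.0 * std::max(tau_p, tau_d);  // exp() underflow cutoff

  // ---- unpack state (copied; R semantics preserved) ----
  NumericVector V      = clone(as<NumericVector>(state["V"]));
  NumericVector refrac = clone(as<NumericVector>(state["refrac"]));
  NumericVector lastEm = clone(as<NumericVector>(state["last_emit"]));
  NumericVector A      = clone(as<NumericVector>(state["A"]));
  NumericVector B      = clone(as<NumericVector>(state["B"]));
  NumericVector As     = clone(as<NumericVector>(state["A_stim"]));
  NumericVector Bs     = clone(as<NumericVector>(state["B_stim"]));
  IntegerVector bgPtr  = as<IntegerVector>(state["bg_ptr"]);     // length N+1, 0-based
  NumericVector bgW    = clone(as<NumericVector>(state["bg_w"]));
  NumericVector bgArr  = clone(as<NumericVector>(state["bg_last_arr"]));
  NumericVector bgRate = as<NumericVector>(state["bg_rate_hz"]); // per neuron
  IntegerVector sPre   = as<IntegerVector>(state["syn_pre"]);    // 1-based
  IntegerVector sPost  = as<IntegerVector>(state["syn_post"]);
  NumericVector sW     = clone(as<NumericVector>(state["syn_w"]));
  NumericVector sArr   = clone(as<NumericVector>(state["syn_last_arr"]));
  IntegerVector sPlast = as<IntegerVector>(state["syn_plastic"]);
  const int bgPlast    = as<int>(state["bg_plastic"]);
  double t_now         = as<double>(state["t_ms"]);

  const int N = V.size();
  const int S = sPre.size();

  // per-neuron background mixture probabilities (two-point global mixture)
  std::vector<double> p1(N), p0(N), l1(N), l0(N);
  std::vector<int> nbg(N);
  for (int i = 0; i < N; ++i) {
    nbg[i] = bgPtr[i + 1] - bgPtr[i];
    double pbar = bgRate[i] * dt / 1000.0;
    double s = (c_back > 0.0) ? std::sqrt(c_back * pbar * (1.0 - pbar)) : 0.0;
    p1[i] = pbar + s;
    p0[i] = pbar - s;
    if (p0[i] < 0.0) stop("infeasible background mixture: c_back too large for rate*dt");
    if (p1[i] >= 1.0) stop("infeasible background mixture: p1 >= 1");
    l1[i] = std::log1p(-p1[i]);
    l0[i] = (p0[i] > 0.0) ? std::log1p(-p0[i]) : 0.0;
  }

  // adjacency: afferent / efferent network synapses per neuron
  std::vector<std::vector<int>> aff(N), eff(N);
  for (int s = 0; s < S; ++s) {
    eff[sPre[s] - 1].push_back(s);
    aff[sPost[s] - 1].push_back(s);
  }

  // delay rings (synaptic transmission + stimulation)
  const int delay_steps = (int)std::lround(t_del / dt);
  const int sts_steps   = (int)std::lround(sts_delay / dt);
  const int ring_len    = std::max(std::max(delay_steps, sts_steps), 1) + 1;
  std::vector<std::vector<int>> synRing(ring_len);  // synapse indices
  std::vector<int> stimRing(ring_len, 0);           // count of stimuli due

  // Pending cross-chunk events are stored as absolute due times and pulled
  // into the ring as their step comes up; events still due after this chunk
  // are re-emitted in the result.
  std::vector<std::pair<double,int>> pendSyn;   // (due time, synapse)
  std::vector<double> pendStim;                 // due times
  {
    NumericVector pt = as<NumericVector>(state["pend_syn_t"]);
    IntegerVector ps = as<IntegerVector>(state["pend_syn_id"]);
    for (int k = 0; k < pt.size(); ++k) pendSyn.push_back({pt[k], ps[k] - 1});
    NumericVector st = as<NumericVector>(state["pend_stim_t"]);
    for (int k = 0; k < st.size(); ++k) pendStim.push_back(st[k]);
  }

  // one independent stream per neuron (background sampling is then local:
  // re-parameterizing one neuron's ensemble leaves the others' untouched)
  // plus a shared stream for the global hot/cold draw
  std::vector<Rng> rngs;
  rngs.reserve(N + 1);
  for (int i = 0; i <= N; ++i) {
    rngs.emplace_back(mix64((uint64_t)seed * 1000003ULL + (uint64_t)i));
  }
  Rng& rng_global = rngs[N];

  // ---- recorders ----
  SpikeRec spikes;
  std::vector<double> wSampT;
  std::vector<std::vector<double>> wSamp;  // rows: time sample; cols: N bg means + S syn weights
  std::vector<double> rSampT;
  std::vector<std::vector<double>> rCountRows;
  std::vector<double> rCount(N, 0.0);
  double next_w = 0.0, next_r = 0.0;
  if (w_every_ms > 0) next_w = (std::floor(t_now / w_every_ms) + 1.0) * w_every_ms;
  if (r_every_ms > 0) next_r = (std::floor(t_now / r_every_ms) + 1.0) * r_every_ms;

  std::vector<int> spiked;  // scratch
  spiked.reserve(8);
  std::vector<int> chosen;  // scratch for background train indices
  chosen.reserve(8);

  const double t_end = t_now + n_steps * dt + 1e-9;

  for (int step = 0; step < n_steps; ++step) {
    const double t = t_now + (step + 1) * dt;
    const int slot = (int)((int64_t)std::llround(t / dt) % ring_len);

    // (0) pull any pending cross-chunk events due now
    if (!pendSyn.empty()) {
      for (size_t k = 0; k < pendSyn.size();) {
        if (std::abs(pendSyn[k].first - t) < dt * 1e-6) {
          synRing[slot].push_back(pendSyn[k].second);
          pendSyn[k] = pendSyn.back(); pendSyn.pop_back();
        } else ++k;
      }
    }
    if (!pendStim.empty()) {
      for (size_t k = 0; k < pendStim.size();) {
        if (std::abs(pendStim[k] - t) < dt * 1e-6) {
          stimRing[slot] += 1;
          pendStim[k] = pendStim.back(); pendStim.pop_back();
        } else ++k;
      }
    }

    // (1a) background arrivals: one global hot/cold draw shared by all trains
    const bool hot = (c_back > 0.0) && (rng_global.unif() < q_hot);
    for (int i = 0; i < N; ++i) {
      Rng& rng = rngs[i];
      if (nbg[i] == 0 || bgRate[i] <= 0.0) continue;
      const double p = (c_back > 0.0) ? (hot ? p1[i] : p0[i])
                                      : p1[i];  // c=0: p1==p0==pbar
      const double lg = (c_back > 0.0) ? (hot ? l1[i] : l0[i]) : l1[i];
      if (p <= 0.0) continue;
      int k = rbinom_inv(rng, nbg[i], p, lg);
      if (k == 0) continue;
      // choose k distinct trains
      chosen.clear();
      for (int j = 0; j < k; ++j) {
        int idx;
        bool dup;
        do {
          idx = (int)(rng.unif() * nbg[i]);
          if (idx >= nbg[i]) idx = nbg[i] - 1;
          dup = false;
          for (int c : chosen) if (c == idx) { dup = true; break; }
        } while (dup);
        chosen.push_back(idx);
      }
      for (int c : chosen) {
        const int m = bgPtr[i] + c;
        B[i] += bgW[m] * g_norm;  // transmission with pre-update weight
        if (bgPlast && A_d > 0.0 && !ISNA(lastEm[i])) {
          const double d = t - lastEm[i];  // |post - pre_arrival|, pre after post
          if (d > 0.0 && d < dtp_cut) {
            bgW[m] -= A_d * bgW[m] * std::exp(-d / tau_d);
            if (bgW[m] < 0.0) bgW[m] = 0.0;
          }
        }
        bgArr[m] = t;
      }
    }

    // (1b) network synapse arrivals
    {
      std::vector<int>& due = synRing[slot];
      for (int s : due) {
        const int j = sPost[s] - 1;
        B[j] += sW[s] * g_norm;
        if (sPlast[s] && A_d > 0.0 && !ISNA(lastEm[j])) {
          const double d = t - lastEm[j];
          if (d > 0.0 && d < dtp_cut) {
            sW[s] -= A_d * sW[s] * std::exp(-d / tau_d);
            if (sW[s] < 0.0) sW[s] = 0.0;
          }
        }
        sArr[s] = t;
      }
      due.clear();
    }

    // (1c) stimulation arrivals (swallowed during absolute refractoriness)
    if (stimRing[slot] > 0) {
      if (refrac[sts_tgt] <= 0.0) Bs[sts_tgt] += stimRing[slot] * stim_B;
      stimRing[slot] = 0;
    }

    // (2) alpha kinetics (forward Euler; impulses landed in B above)
    for (int i = 0; i < N; ++i) {
      A[i]  = a_dec * A[i] + dt * B[i];
      B[i] *= a_dec;
      if (As[i] != 0.0 || Bs[i] != 0.0) {
        As[i] = a_dec * As[i] + dt * Bs[i];
        Bs[i] *= a_dec;
        if (As[i] < 1e-300) As[i] = 0.0;
        if (Bs[i] < 1e-300) Bs[i] = 0.0;
      }
    }

    // (3) membrane integration + spike detection at time t
    spiked.clear();
    for (int i = 0; i < N; ++i) {
      if (refrac[i] > 0.0) {
        V[i] = E_rest;
        refrac[i] -= dt;
        continue;
      }
      const double G = A[i] + As[i];
      const double I = cond_mode ? gain * G * (E_ex - V[i]) : gain * G;
      V[i] += dt * ((E_rest - V[i]) / tau_m + I / Cm);
      if (!std::isfinite(V[i])) stop("membrane voltage diverged (non-finite) at t=%f ms", t);
      if (V[i] > V_thr) {
        V[i] = E_rest;
        refrac[i] = tau_ref;
        spiked.push_back(i);
      }
    }

    // (4) spike-side bookkeeping: potentiation, scheduling, stimulation
    for (int i : spiked) {
      if (record_spikes) { spikes.t.push_back(t); spikes.id.push_back(i + 1); }
      rCount[i] += 1.0;
      // potentiation of afferents against their latest pre-arrival
      if (A_p > 0.0) {
        for (int m = bgPtr[i]; m < bgPtr[i + 1]; ++m) {
          if (bgPlast && !ISNA(bgArr[m])) {
            const double d = t - bgArr[m];
            if (d > 0.0 && d < dtp_cut) {
              bgW[m] += A_p * (g_max - bgW[m]) * std::exp(-d / tau_p);
              if (bgW[m] > g_max) bgW[m] = g_max;
            }
          }
        }
        for (int s : aff[i]) {
          if (sPlast[s] && !ISNA(sArr[s])) {
            const double d = t - sArr[s];
            if (d > 0.0 && d < dtp_cut) {
              sW[s] += A_p * (g_max - sW[s]) * std::exp(-d / tau_p);
              if (sW[s] > g_max) sW[s] = g_max;
            }
          }
        }
      }
      lastEm[i] = t;
      // synaptic transmission
      for (int s : eff[i]) {
        const double due = t + delay_steps * dt;
        if (due < t_end) synRing[(int)((int64_t)std::llround(due / dt) % ring_len)].push_back(s);
        else pendSyn.push_back({due, s});
      }
      // closed-loop stimulation trigger
      if (sts_on && i == sts_src) {
        const double due = t + sts_steps * dt;
        if (due < t_end) stimRing[(int)((int64_t)std::llround(due / dt) % ring_len)] += 1;
        else pendStim.push_back(due);
      }
      // one trigger, at most one evoked spike: drop the stimulation tail
      if (i == sts_tgt) { As[i] = 0.0; Bs[i] = 0.0; }
    }

    // (5) recorders
    if (w_every_ms > 0 && t >= next_w - dt * 1e-6) {
      std::vector<double> row;
      row.reserve(N + S);
      for (int i = 0; i < N; ++i) {
        double m = 0.0;
        if (nbg[i] > 0) {
          for (int k = bgPtr[i]; k < bgPtr[i + 1]; ++k) m += bgW[k];
          m /= nbg[i];
        }
        row.push_back(m);
      }
      for (int s = 0; s < S; ++s) row.push_back(sW[s]);
      wSampT.push_back(t);
      wSamp.push_back(std::move(row));
      next_w += w_every_ms;
    }
    if (r_every_ms > 0 && t >= next_r - dt * 1e-6) {
      rSampT.push_back(t);
      rCountRows.push_back(rCount);
      std::fill(rCount.begin(), rCount.end(), 0.0);
      next_r += r_every_ms;
    }
  }

  t_now += n_steps * dt;

  // flush ring into pending lists for the next chunk
  for (int off = 0; off < ring_len; ++off) {
    // slot holding events due at t_now + off*dt (off=0 impossible: already delivered)
    double due = t_now + off * dt;
    int slot = (int)((int64_t)std::llround(due / dt) % ring_len);
    if (off >= 1) {
      for (int s : synRing[slot]) pendSyn.push_back({due, s});
      for (int k = 0; k < stimRing[slot]; ++k) pendStim.push_back(due);
      synRing[slot].clear();
      stimRing[slot] = 0;
    }
  }

  // ---- assemble result ----
  int nP = pendSyn.size();
  NumericVector pT(nP); IntegerVector pS(nP);
  for (int k = 0; k < nP; ++k) { pT[k] = pendSyn[k].first; pS[k] = pendSyn[k].second + 1; }
  NumericVector pStim(pendStim.size());
  for (size_t k = 0; k < pendStim.size(); ++k) pStim[k] = pendStim[k];

  List newState = List::create(
    _["t_ms"] = t_now, _["V"] = V, _["refrac"] = refrac, _["last_emit"] = lastEm,
    _["A"] = A, _["B"] = B, _["A_stim"] = As, _["B_stim"] = Bs,
    _["bg_ptr"] = bgPtr, _["bg_w"] = bgW, _["bg_last_arr"] = bgArr,
    _["bg_rate_hz"] = bgRate, _["bg_plastic"] = bgPlast,
    _["syn_pre"] = sPre, _["syn_post"] = sPost, _["syn_w"] = sW,
    _["syn_last_arr"] = sArr, _["syn_plastic"] = sPlast,
    _["pend_syn_t"] = pT, _["pend_syn_id"] = pS, _["pend_stim_t"] = pStim);

  NumericMatrix wM(wSampT.size(), N + S + 1);
  for (size_t r = 0; r < wSampT.size(); ++r) {
    wM(r, 0) = wSampT[r];
    for (int c = 0; c < N + S; ++c) wM(r, c + 1) = wSamp[r][c];
  }
  NumericMatrix rM(rSampT.size(), N + 1);
  for (size_t r = 0; r < rSampT.size(); ++r) {
    rM(r, 0) = rSampT[r];
    for (int c = 0; c < N; ++c) rM(r, c + 1) = rCountRows[r][c];
  }

  return List::create(
    _["state"] = newState,
    _["spike_t"] = NumericVector(spikes.t.begin(), spikes.t.end()),
    _["spike_id"] = IntegerVector(spikes.id.begin(), spikes.id.end()),
    _["w_samples"] = wM,
    _["r_counts"] = rM);
}

// Monte-Carlo summary for the correlated background generator: simulates
// `n_steps` steps of an ensemble of `n` trains under the two-point global
// mixture and returns per-step total counts' first two moments plus the
// exact per-train spike total for two tracked trains (for cross-step and
// marginal checks).
// [[Rcpp::export(name = ".mixture_moments")]]
List mixture_moments(int n, double p_bar, double c, double q_hot,
                     double n_steps, double seed) {
  Rng rng((uint64_t)seed);
  double s = (c > 0.0) ? std::sqrt(c * p_bar * (1.0 - p_bar)) : 0.0;
  double p1 = p_bar + s, p0 = p_bar - s;
  if (p0 < 0.0 || p1 >= 1.0) stop("infeasible mixture");
  double l1 = std::log1p(-p1), l0 = (p0 > 0.0) ? std::log1p(-p0) : 0.0;
  double sum = 0.0, sumsq = 0.0, sumcu = 0.0, sumqu = 0.0;
  double tA = 0.0, tB = 0.0, tAB = 0.0, tA_lag = 0.0;
  int prevA = 0;
  long long T = (long long)n_steps;
  for (long long step = 0; step < T; ++step) {
    bool hot = rng.unif() < q_hot;
    double p = hot ? p1 : p0;
    double lg = hot ? l1 : l0;
    int k = (p > 0.0) ? rbinom_inv(rng, n, p, lg) : 0;
    double kd = (double)k;
    sum += kd; sumsq += kd * kd; sumcu += kd * kd * kd;
    sumqu += kd * kd * kd * kd;
    // two tracked trains, sampled independently given the global draw
    int a = (p > 0.0 && rng.unif() < p) ? 1 : 0;
    int b = (p > 0.0 && rng.unif() < p) ? 1 : 0;
    tA += a; tB += b; tAB += a * b; tA_lag += a * prevA;
    prevA = a;
  }
  return List::create(_["sum"] = sum, _["sumsq"] = sumsq,
                      _["sumcu"] = sumcu, _["sumqu"] = sumqu,
                      _["n_steps"] = (double)T,
                      _["trainA"] = tA, _["trainB"] = tB, _["coinc"] = tAB,
                      _["lag1"] = tA_lag);
}
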