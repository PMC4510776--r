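// Discrete-time (1 ms grid) spiking-network engine.
//
// Semantics mirror the R-level reference operations:
//  per step: dopamine decay -> DA-STDP weight integration -> conductance
//  decay -> delivery of due arrivals (pre-event plasticity) -> background
//  noise -> scheduled input spikes -> membrane half-steps -> spike
//  detect/reset (post-event plasticity, enqueue deliveries).
//
// Pairings are nearest-neighbour: lastArr per synapse (arrival time,
// delay included), lastPost per neuron.  Neurons at the common resting
// point with zero conductance are skipped until an input wakes them.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <random>
#include <cstdint>

using namespace Rcpp;

static const double SPIKE_V = 30.0;
static const double TAU_AMPA = 5.0, TAU_NMDA = 100.0;
static const double TAU_GABAA = 6.0, TAU_GABAB = 150.0;
static const double NEVER = -1e18;

struct ProjPar {
  double Aplus, Aminus, taup, taum;       // E-STDP kernel
  double Bplus, Bminus, lam, gam;         // I-STDP windows
  double wmin, wmax;
  double c_decay;                          // exp(-dt/tau_c)
  int plasticity;                          // 0 none 1 estdp 2 istdp 3 da
  int pool;                                // dopamine pool index or -1
  bool inhibitory;
  double frac;                             // AMPA (or GABA_A) share
};

struct Pool {
  double d, tau_decay, da_syn, baseline, peak;
  int source_group;
};

// [[Rcpp::export]]
List run_engine(List net, IntegerVector in_t, IntegerVector in_id,
                int duration_ms, int seed, List opts) {
  List groups = net["groups"];
  List projections = net["projections"];
  List poolspec = net["pools"];
  const int ngroups = groups.size();

  // ---- groups / neurons -------------------------------------------------
  std::vector<int> g_off(ngroups), g_n(ngroups);
  std::vector<bool> g_record(ngroups), g_da_source(ngroups);
  std::vector<double> g_bg_rate(ngroups), g_bg_w(ngroups);
  std::vector<int> g_d1(ngroups);
  int N = 0;
  for (int g = 0; g < ngroups; ++g) {
    List gr = groups[g];
    g_off[g] = N;
    g_n[g] = as<int>(gr["n"]);
    g_record[g] = as<bool>(gr["record"]);
    g_da_source[g] = as<bool>(gr["da_source"]);
    g_bg_rate[g] = as<double>(gr["bg_rate"]);
    g_bg_w[g] = as<double>(gr["bg_weight"]);
    g_d1[g] = as<int>(gr["d1_pool"]);
    N += g_n[g];
  }
  std::vector<double> pa(N), pb(N), pc(N), pd(N);
  std::vector<int16_t> n_group(N);
  for (int g = 0; g < ngroups; ++g) {
    List gr = groups[g];
    double a = as<double>(gr["a"]), b = as<double>(gr["b"]);
    double c = as<double>(gr["c"]), d = as<double>(gr["d"]);
    for (int i = g_off[g]; i < g_off[g] + g_n[g]; ++i) {
      pa[i] = a; pb[i] = b; pc[i] = c; pd[i] = d;
      n_group[i] = (int16_t)g;
    }
  }

  // ---- pools ------------------------------------------------------------
  std::vector<Pool> pools;
  for (int p = 0; p < poolspec.size(); ++p) {
    List ps = poolspec[p];
    Pool pl;
    pl.baseline = as<double>(ps["baseline"]);
    pl.d = pl.baseline;
    pl.tau_decay = std::exp(-1.0 / as<double>(ps["tau_d"]));
    pl.da_syn = as<double>(ps["da_syn"]);
    pl.peak = as<double>(ps["peak"]);
    pl.source_group = as<int>(ps["source_group"]);
    pools.push_back(pl);
  }
  const int npools = (int)pools.size();

  // ---- synapses (CSR by pre) -------------------------------------------
  const int nproj = projections.size();
  std::vector<ProjPar> pp(nproj);
  long nsyn = 0;
  std::vector<IntegerVector> proj_pre(nproj), proj_post(nproj),
      proj_delay(nproj);
  std::vector<NumericVector> proj_w(nproj);
  int max_delay = 1;
  for (int p = 0; p < nproj; ++p) {
    List pr = projections[p];
    proj_pre[p] = as<IntegerVector>(pr["pre"]);
    proj_post[p] = as<IntegerVector>(pr["post"]);
    proj_w[p] = as<NumericVector>(pr["w"]);
    proj_delay[p] = as<IntegerVector>(pr["delay"]);
    nsyn += proj_pre[p].size();
    for (int k = 0; k < proj_delay[p].size(); ++k)
      if (proj_delay[p][k] > max_delay) max_delay = proj_delay[p][k];
    ProjPar q;
    q.Aplus = as<double>(pr["A_plus"]); q.Aminus = as<double>(pr["A_minus"]);
    q.taup = as<double>(pr["tau_plus"]); q.taum = as<double>(pr["tau_minus"]);
    q.Bplus = as<double>(pr["B_plus"]); q.Bminus = as<double>(pr["B_minus"]);
    q.lam = as<double>(pr["lambda_win"]); q.gam = as<double>(pr["gamma_win"]);
    q.wmin = as<double>(pr["w_min"]); q.wmax = as<double>(pr["w_max"]);
    q.c_decay = std::exp(-1.0 / as<double>(pr["tau_c"]));
    q.plasticity = as<int>(pr["plasticity_code"]);
    q.pool = as<int>(pr["pool_index"]);
    q.inhibitory = as<bool>(pr["inhibitory"]);
    q.frac = as<double>(pr["receptor_frac"]);
    pp[p] = q;
  }

  std::vector<int32_t> syn_post(nsyn), syn_delay(nsyn), syn_orig(nsyn);
  std::vector<int16_t> syn_proj(nsyn);
  std::vector<double> syn_w(nsyn);
  std::vector<int32_t> pre_start(N + 1, 0);
  {
    std::vector<int32_t> cnt(N, 0);
    for (int p = 0; p < nproj; ++p)
      for (int k = 0; k < proj_pre[p].size(); ++k) cnt[proj_pre[p][k]]++;
    for (int i = 0; i < N; ++i) pre_start[i + 1] = pre_start[i] + cnt[i];
    std::vector<int32_t> fill(pre_start.begin(), pre_start.end() - 1);
    for (int p = 0; p < nproj; ++p) {
      for (int k = 0; k < proj_pre[p].size(); ++k) {
        int s = fill[proj_pre[p][k]]++;
        syn_post[s] = proj_post[p][k];
        syn_w[s] = proj_w[p][k];
        syn_delay[s] = std::max(1, (int)proj_delay[p][k]);
        syn_proj[s] = (int16_t)p;
        syn_orig[s] = k;
      }
    }
  }

  // plastic in-synapse lists (CSC restricted to plastic synapses)
  std::vector<int32_t> in_start(N + 1, 0), in_list;
  {
    std::vector<int32_t> cnt(N, 0);
    for (long s = 0; s < nsyn; ++s)
      if (pp[syn_proj[s]].plasticity > 0) cnt[syn_post[s]]++;
    for (int i = 0; i < N; ++i) in_start[i + 1] = in_start[i] + cnt[i];
    in_list.resize(in_start[N]);
    std::vector<int32_t> fill(in_start.begin(), in_start.end() - 1);
    for (long s = 0; s < nsyn; ++s)
      if (pp[syn_proj[s]].plasticity > 0)
        in_list[fill[syn_post[s]]++] = (int32_t)s;
  }

  // ---- state ------------------------------------------------------------
  std::vector<double> v(N, -70.0), u(N, -14.0);
  std::vector<double> gA(N, 0), gN(N, 0), gGa(N, 0), gGb(N, 0);
  std::vector<double> lastPost(N, NEVER), lastArr(nsyn, NEVER);
  std::vector<double> ctr(nsyn, 0.0);           // eligibility traces
  std::vector<uint8_t> c_active(nsyn, 0);
  std::vector<int32_t> active_list;
  std::vector<uint8_t> awake(N, 0);
  const double dA = std::exp(-1.0 / TAU_AMPA), dN = std::exp(-1.0 / TAU_NMDA);
  const double dGa = std::exp(-1.0 / TAU_GABAA),
               dGb = std::exp(-1.0 / TAU_GABAB);

  const bool estdp_on = as<bool>(opts["estdp_on"]);
  const bool dastdp_on = as<bool>(opts["dastdp_on"]);
  const bool da_trace_on = as<bool>(opts["da_trace"]);

  // delay ring
  const int ring_n = max_delay + 1;
  std::vector<std::vector<int32_t> > ring(ring_n);

  std::mt19937_64 rng((uint64_t)seed * 2654435761u + 12345u);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  // background noise: per-group aggregate exponential skipping
  std::vector<double> next_noise(ngroups, 1e18);
  for (int g = 0; g < ngroups; ++g) {
    double lam = g_bg_rate[g] * g_n[g] / 1000.0;   // events per step
    if (lam > 0)
      next_noise[g] = -std::log(1.0 - unif(rng)) / lam;
  }

  std::vector<int32_t> rec_t, rec_id;
  std::vector<long> group_spikes(ngroups, 0);
  NumericMatrix pool_trace(da_trace_on ? duration_ms : 0,
                           da_trace_on ? npools : 0);

  // scratch for per-step fired neurons
  std::vector<int32_t> fired;
  fired.reserve(1024);

  long in_ptr = 0;
  const long n_in = in_t.size();

  for (int t = 0; t < duration_ms; ++t) {
    // 1. dopamine pools: decay toward 0 with reflecting baseline floor
    for (int p = 0; p < npools; ++p) {
      pools[p].d *= pools[p].tau_decay;
      if (pools[p].d < pools[p].baseline) pools[p].d = pools[p].baseline;
    }

    // 2. DA-STDP: integrate w by c*d, decay traces
    if (dastdp_on && !active_list.empty()) {
      size_t keep = 0;
      for (size_t i = 0; i < active_list.size(); ++i) {
        int32_t s = active_list[i];
        const ProjPar &q = pp[syn_proj[s]];
        double d = pools[q.pool].d;
        double w = syn_w[s] + ctr[s] * d;
        if (w < q.wmin) w = q.wmin;
        if (w > q.wmax) w = q.wmax;
        syn_w[s] = w;
        ctr[s] *= q.c_decay;
        if (std::fabs(ctr[s]) > 1e-9) {
          active_list[keep++] = s;
        } else {
          ctr[s] = 0.0;
          c_active[s] = 0;
        }
      }
      active_list.resize(keep);
    }

    // 3. conductance decay (awake neurons only)
    for (int i = 0; i < N; ++i) {
      if (!awake[i]) continue;
      gA[i] *= dA; gN[i] *= dN; gGa[i] *= dGa; gGb[i] *= dGb;
    }

    // 4. deliver arrivals due now
    {
      std::vector<int32_t> &slot = ring[t % ring_n];
      for (size_t k = 0; k < slot.size(); ++k) {
        int32_t s = slot[k];
        const ProjPar &q = pp[syn_proj[s]];
        int post = syn_post[s];
        // pre-event plasticity (uses last post spike)
        if (q.plasticity == 1 && estdp_on) {
          if (lastPost[post] > NEVER) {
            double dlt = lastPost[post] - (double)t;   // <= 0
            double w = syn_w[s] - q.Aminus * std::exp(dlt / q.taum);
            syn_w[s] = (w < q.wmin) ? q.wmin : (w > q.wmax ? q.wmax : w);
          }
        } else if (q.plasticity == 2 && estdp_on) {
          if (lastPost[post] > NEVER) {
            double x = (double)t - lastPost[post];
            double w = syn_w[s];
            if (x > 0 && x <= q.lam) w += q.Bplus;
            else if (x > q.lam && x <= q.gam) w -= q.Bminus;
            syn_w[s] = (w < q.wmin) ? q.wmin : (w > q.wmax ? q.wmax : w);
          }
        } else if (q.plasticity == 3 && dastdp_on) {
          if (lastPost[post] > NEVER) {
            double dlt = lastPost[post] - (double)t;
            ctr[s] -= q.Aminus * std::exp(dlt / q.taum);
            if (!c_active[s]) { c_active[s] = 1; active_list.push_back(s); }
          }
        }
        lastArr[s] = (double)t;
        double w = syn_w[s];
        if (q.inhibitory) {
          gGa[post] += w * q.frac;
          gGb[post] += w * (1.0 - q.frac);
        } else {
          gA[post] += w * q.frac;
          gN[post] += w * (1.0 - q.frac);
        }
        awake[post] = 1;
      }
      slot.clear();
    }

    // 5. background noise (AMPA kicks)
    for (int g = 0; g < ngroups; ++g) {
      while (next_noise[g] <= (double)t) {
        int i = g_off[g] + (int)(unif(rng) * g_n[g]);
        if (i >= g_off[g] + g_n[g]) i = g_off[g] + g_n[g] - 1;
        gA[i] += g_bg_w[g];
        awake[i] = 1;
        double lam = g_bg_rate[g] * g_n[g] / 1000.0;
        next_noise[g] += -std::log(1.0 - unif(rng)) / lam;
      }
    }

    fired.clear();

    // 6. scheduled input spikes (forced firings of source neurons)
    while (in_ptr < n_in && in_t[in_ptr] == t) {
      fired.push_back(in_id[in_ptr]);
      ++in_ptr;
    }

    // 7. membrane integration and threshold detection
    for (int i = 0; i < N; ++i) {
      if (!awake[i]) continue;
      double gtot = gA[i] + gN[i] + gGa[i] + gGb[i];
      if (gtot < 1e-7 && std::fabs(v[i] + 70.0) < 1e-4 &&
          std::fabs(u[i] + 14.0) < 1e-4) {
        v[i] = -70.0; u[i] = -14.0;
        gA[i] = gN[i] = gGa[i] = gGb[i] = 0.0;
        awake[i] = 0;
        continue;
      }
      double vm = v[i];
      double ga = gA[i], gn = gN[i];
      int d1 = g_d1[n_group[i]];
      if (d1 >= 0) {
        double gain = 0.9 + 0.1 * pools[d1].d;
        ga *= gain; gn *= gain;
      }
      // two half-steps on v, one step on u.  The conductance currents are
      // linear in v and can be stiff (total g of order 1 gives an
      // effective time constant below the grid step), so their -v*G part
      // is taken implicitly; the quadratic intrinsic term stays explicit
      // and is capped at 90 mV so it cannot overflow past threshold.
      for (int half = 0; half < 2; ++half) {
        double mg = (-80.0 - vm) / 60.0;
        double mg2 = mg * mg;
        double gneff = gn * (mg2 / (1.0 + mg2));
        double G = ga + gneff + gGa[i] + gGb[i];
        double drive = gGa[i] * (-70.0) + gGb[i] * (-90.0);
        vm = (vm + 0.5 * (0.04 * vm * vm + 5.0 * vm + 140.0 - u[i] +
                          drive)) / (1.0 + 0.5 * G);
        if (vm > 90.0) { vm = 90.0; break; }
      }
      u[i] += pa[i] * (pb[i] * vm - u[i]);
      if (!std::isfinite(vm) || !std::isfinite(u[i]))
        stop("integration divergence: non-finite state for neuron index %d",
             i + 1);
      if (vm >= SPIKE_V) {
        v[i] = pc[i];
        u[i] += pd[i];
        fired.push_back(i);
      } else {
        v[i] = vm;
      }
    }

    // 8. spike bookkeeping: record, plasticity post-events, enqueue, DA
    for (size_t fi = 0; fi < fired.size(); ++fi) {
      int i = fired[fi];
      int g = n_group[i];
      group_spikes[g]++;
      if (g_record[g]) {
        rec_t.push_back(t);
        rec_id.push_back(i);
      }
      // post-event plasticity over incoming plastic synapses
      for (int32_t k = in_start[i]; k < in_start[i + 1]; ++k) {
        int32_t s = in_list[k];
        if (lastArr[s] <= NEVER) continue;
        const ProjPar &q = pp[syn_proj[s]];
        double dlt = (double)t - lastArr[s];   // >= 0
        if (q.plasticity == 1 && estdp_on) {
          if (dlt > 0) {
            double w = syn_w[s] + q.Aplus * std::exp(-dlt / q.taup);
            syn_w[s] = (w < q.wmin) ? q.wmin : (w > q.wmax ? q.wmax : w);
          }
        } else if (q.plasticity == 2 && estdp_on) {
          double w = syn_w[s];
          if (dlt > 0 && dlt <= q.lam) w += q.Bplus;
          else if (dlt > q.lam && dlt <= q.gam) w -= q.Bminus;
          syn_w[s] = (w < q.wmin) ? q.wmin : (w > q.wmax ? q.wmax : w);
        } else if (q.plasticity == 3 && dastdp_on) {
          if (dlt > 0) {
            ctr[s] += q.Aplus * std::exp(-dlt / q.taup);
            if (!c_active[s]) { c_active[s] = 1; active_list.push_back(s); }
          }
        }
      }
      lastPost[i] = (double)t;
      // enqueue outgoing deliveries
      for (int32_t s = pre_start[i]; s < pre_start[i + 1]; ++s) {
        ring[(t + syn_delay[s]) % ring_n].push_back(s);
      }
      // dopaminergic source: bump every pool fed by this group
      if (g_da_source[g]) {
        for (int p = 0; p < npools; ++p) {
          if (pools[p].source_group == g) {
            pools[p].d += pools[p].da_syn;
            if (pools[p].d > pools[p].peak) pools[p].d = pools[p].peak;
          }
        }
      }
    }

    if (da_trace_on) {
      for (int p = 0; p < npools; ++p) pool_trace(t, p) = pools[p].d;
    }
  }

  // write weights back per projection
  List w_out(nproj);
  {
    std::vector<NumericVector> wv(nproj);
    for (int p = 0; p < nproj; ++p)
      wv[p] = NumericVector(proj_w[p].size());
    for (long s = 0; s < nsyn; ++s)
      wv[syn_proj[s]][syn_orig[s]] = syn_w[s];
    for (int p = 0; p < nproj; ++p) w_out[p] = wv[p];
  }

  IntegerVector out_t(rec_t.begin(), rec_t.end());
  IntegerVector out_id(rec_id.begin(), rec_id.end());
  NumericVector counts(ngroups);
  for (int g = 0; g < ngroups; ++g) counts[g] = (double)group_spikes[g];
  NumericVector pool_final(npools);
  for (int p = 0; p < npools; ++p) pool_final[p] = pools[p].d;

  return List::create(_["spike_t"] = out_t, _["spike_id"] = out_id,
                      _["weights"] = w_out, _["group_spike_counts"] = counts,
                      _["pool_trace"] = pool_trace,
                      _["pool_final"] = pool_final);
}
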