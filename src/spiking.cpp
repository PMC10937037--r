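#include <Rcpp.h>
using namespace Rcpp;

// Conductance-based LIF / AdEx network with alpha-function synapses.
//
// Units: ms, mV, pA, pF, nS. Membrane equations (leak reversal at V_reset):
//   LIF : Cm dV/dt = I_dc - gL (V - Vreset) + I_syn
//   AdEx: Cm dV/dt = I_dc - gL (V - Vreset) - w
//                    + gL DeltaT exp((V - VT)/DeltaT) + I_syn
//         tau_w dw/dt = a (V - Vreset) - w ; on spike w += b
// Synaptic current is applied so that input with a reversal potential above
// the membrane potential depolarizes: I_syn = -g_e (V - E_e) - g_i (V - E_i).
// Each afferent spike, after its transmission delay, launches an alpha
// conductance transient g(t) = J (t/tau) exp(-(t - tau)/tau) whose peak is J.
// The alpha kernel is realized by the exact two-state update
//   h <- h * exp(-dt/tau);  g <- exp(-dt/tau) * (g + h_prev * dt/tau)
// with h jumping by J*e on arrival. Membrane equations use classical RK4
// with conductances held at their start-of-step values; threshold crossing
// and reset are resolved at step boundaries.
//
// External drive per population: an independent homogeneous Poisson spike
// train per neuron (rate_ext, Hz) onto the excitatory channel with peak
// conductance J_ext, plus a DC bias current I_dc (pA).
// [[Rcpp::export]]
List spiking_sim_cpp(IntegerVector pop_size, IntegerVector kind,
                     NumericVector Cm, NumericVector gL,
                     NumericVector Vreset, NumericVector Vth,
                     NumericVector tref,
                     NumericVector DeltaT, NumericVector VT,
                     NumericVector a_w, NumericVector b_w,
                     NumericVector tau_w,
                     NumericVector tau_exc, NumericVector tau_inh,
                     NumericVector E_exc, NumericVector E_inh,
                     NumericVector rate_ext, NumericVector J_ext,
                     NumericVector I_dc,
                     IntegerVector con_src, IntegerVector con_tgt,
                     NumericVector con_J, NumericVector con_delay,
                     NumericVector con_p, LogicalVector con_inh,
                     double T, double dt) {
  const int npop = pop_size.size();
  std::vector<int> off(npop + 1, 0);
  for (int p = 0; p < npop; ++p) off[p + 1] = off[p] + pop_size[p];
  const int N = off[npop];
  const int nsteps = (int)std::round(T / dt);
  const double E = std::exp(1.0);

  // realize random connectivity: per connection, per source neuron, targets
  const int ncon = con_src.size();
  std::vector< std::vector< std::vector<int> > > targets(ncon);
  std::vector<int> dstep(ncon);
  int maxd = 1;
  for (int c = 0; c < ncon; ++c) {
    dstep[c] = std::max(1, (int)std::round(con_delay[c] / dt));
    if (dstep[c] + 1 > maxd) maxd = dstep[c] + 1;
    const int sp = con_src[c], tp = con_tgt[c];
    targets[c].resize(pop_size[sp]);
    for (int i = 0; i < pop_size[sp]; ++i) {
      std::vector<int> &tl = targets[c][i];
      for (int j = 0; j < pop_size[tp]; ++j) {
        if (sp == tp && i == j) continue;      // no autapses
        if (R::unif_rand() < con_p[c]) tl.push_back(off[tp] + j);
      }
    }
  }

  // ring buffers of future conductance-kernel launches
  std::vector<double> ebuf((size_t)maxd * N, 0.0), ibuf((size_t)maxd * N, 0.0);

  // state
  std::vector<double> V(N), w(N, 0.0), ge(N, 0.0), he(N, 0.0),
                      gi(N, 0.0), hi(N, 0.0);
  std::vector<int> refr(N, 0), popof(N);
  for (int p = 0; p < npop; ++p)
    for (int i = off[p]; i < off[p + 1]; ++i) {
      popof[i] = p;
      V[i] = Vreset[p] + R::unif_rand() * (Vth[p] - Vreset[p]);
    }

  std::vector<int> spk_id;
  std::vector<double> spk_t;
  spk_id.reserve(100000); spk_t.reserve(100000);

  // precompute synaptic decay factors per population
  std::vector<double> de(npop), di(npop);
  for (int p = 0; p < npop; ++p) {
    de[p] = std::exp(-dt / tau_exc[p]);
    di[p] = std::exp(-dt / tau_inh[p]);
  }

  for (int s = 0; s < nsteps; ++s) {
    const double t = s * dt;
    const int slot = s % maxd;
    // deliver scheduled arrivals and Poisson drive, then update synapses
    for (int i = 0; i < N; ++i) {
      const int p = popof[i];
      double arr_e = ebuf[(size_t)slot * N + i];
      ebuf[(size_t)slot * N + i] = 0.0;
      double arr_i = ibuf[(size_t)slot * N + i];
      ibuf[(size_t)slot * N + i] = 0.0;
      if (rate_ext[p] > 0.0) {
        int k = (int)R::rpois(rate_ext[p] * dt * 1e-3);
        if (k > 0) arr_e += k * J_ext[p] * E;
      }
      const double he0 = he[i] + arr_e, hi0 = hi[i] + arr_i;
      ge[i] = de[p] * (ge[i] + he0 * dt / tau_exc[p]);
      he[i] = de[p] * he0;
      gi[i] = di[p] * (gi[i] + hi0 * dt / tau_inh[p]);
      hi[i] = di[p] * hi0;
    }
    // membrane update
    for (int i = 0; i < N; ++i) {
      const int p = popof[i];
      if (refr[i] > 0) { --refr[i]; V[i] = Vreset[p]; continue; }
      const double gei = ge[i], gii = gi[i];
      bool spiked = false;
      if (kind[p] == 0) {                              // LIF, RK4
        auto f = [&](double v) {
          return (I_dc[p] - gL[p] * (v - Vreset[p])
                  - gei * (v - E_exc[p]) - gii * (v - E_inh[p])) / Cm[p];
        };
        double k1 = f(V[i]);
        double k2 = f(V[i] + 0.5 * dt * k1);
        double k3 = f(V[i] + 0.5 * dt * k2);
        double k4 = f(V[i] + dt * k3);
        V[i] += dt / 6.0 * (k1 + 2 * k2 + 2 * k3 + k4);
        if (V[i] >= Vth[p]) spiked = true;
      } else {                                         // AdEx, RK4 on (V,w)
        auto fV = [&](double v, double ww) {
          double ex = (v - VT[p]) / DeltaT[p];
          if (ex > 20.0) ex = 20.0;                    // overflow guard
          return (I_dc[p] - gL[p] * (v - Vreset[p]) - ww
                  + gL[p] * DeltaT[p] * std::exp(ex)
                  - gei * (v - E_exc[p]) - gii * (v - E_inh[p])) / Cm[p];
        };
        auto fw = [&](double v, double ww) {
          return (a_w[p] * (v - Vreset[p]) - ww) / tau_w[p];
        };
        double v0 = V[i], w0 = w[i];
        double k1v = fV(v0, w0),               k1w = fw(v0, w0);
        double k2v = fV(v0 + 0.5 * dt * k1v, w0 + 0.5 * dt * k1w);
        double k2w = fw(v0 + 0.5 * dt * k1v, w0 + 0.5 * dt * k1w);
        double k3v = fV(v0 + 0.5 * dt * k2v, w0 + 0.5 * dt * k2w);
        double k3w = fw(v0 + 0.5 * dt * k2v, w0 + 0.5 * dt * k2w);
        double k4v = fV(v0 + dt * k3v,       w0 + dt * k3w);
        double k4w = fw(v0 + dt * k3v,       w0 + dt * k3w);
        V[i] += dt / 6.0 * (k1v + 2 * k2v + 2 * k3v + k4v);
        w[i] += dt / 6.0 * (k1w + 2 * k2w + 2 * k3w + k4w);
        if (V[i] >= Vth[p]) { spiked = true; w[i] += b_w[p]; }
      }
      if (spiked) {
        V[i] = Vreset[p];
        refr[i] = (int)std::round(tref[p] / dt);
        spk_id.push_back(i + 1);
        spk_t.push_back(t + dt);
        // schedule deliveries
        for (int c = 0; c < ncon; ++c) {
          if (con_src[c] != p) continue;
          const std::vector<int> &tl = targets[c][i - off[p]];
          const int dslot = (s + dstep[c]) % maxd;
          const double inc = con_J[c] * E;
          if (con_inh[c])
            for (size_t q = 0; q < tl.size(); ++q)
              ibuf[(size_t)dslot * N + tl[q]] += inc;
          else
            for (size_t q = 0; q < tl.size(); ++q)
              ebuf[(size_t)dslot * N + tl[q]] += inc;
        }
      }
    }
  }
  return List::create(_["id"] = wrap(spk_id), _["time"] = wrap(spk_t),
                      _["n_neurons"] = N);
}
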