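#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Voltage-dependent opening/closing rates for one gate.
// Activation gates (m, n, a):
//   alpha = k1 (theta - V) / (exp((theta - V)/sigma1) - 1),  beta = k2 exp(V/sigma2)
// Inactivation gate (h) uses the original Hodgkin-Huxley h-forms with the same
// constants: alpha = k1 exp(V/sigma1) (recovery, fast at hyperpolarized V),
//   beta = k2 (theta - V) / (exp((theta - V)/sigma2) - 1) (closing, grows with V).
static inline double rate_f1(double V, double th, double s, double k) {
  double u = th - V;
  double z = u / s;
  if (std::fabs(z) < 1e-9) return k * s;          // removable singularity at V = theta
  return k * u / std::expm1(z);
}

struct GateKin {
  double th, s1, s2, k1, k2;
  int role;  // 0 activation, 1 inactivation
  inline void rates(double V, double &a, double &b) const {
    if (role == 0) {
      a = rate_f1(V, th, s1, k1);
      b = k2 * std::exp(V / s2);
    } else {
      a = k1 * std::exp(V / s1);
      b = rate_f1(V, th, s2, k2);
    }
  }
  inline double xinf(double V) const {
    double a, b; rates(V, a, b); return a / (a + b);
  }
};

struct NeuronPar {
  double CM, gL, EL, gNa, gKv1, gKv3;
};

static const double E_NA = 50.0, E_K = -90.0, E_CHR = 0.0;

// dstate/dt for one neuron; I_extra is the summed non-intrinsic current (pA)
// already in the convention "positive depolarizes".
static inline void derivs(const double *s, const NeuronPar &p, const GateKin *kin,
                          double I_extra, double *ds) {
  double V = s[0], m = s[1], h = s[2], n = s[3], a = s[4];
  double I = p.gNa * m * m * m * h * (E_NA - V)
           + p.gKv1 * a * a * a * a * (E_K - V)
           + p.gKv3 * n * n * n * n * (E_K - V)
           + p.gL * (p.EL - V)
           + I_extra;
  ds[0] = I / p.CM;
  double al, be;
  kin[0].rates(V, al, be); ds[1] = al * (1.0 - m) - be * m;
  kin[1].rates(V, al, be); ds[2] = al * (1.0 - h) - be * h;
  kin[2].rates(V, al, be); ds[3] = al * (1.0 - n) - be * n;
  kin[3].rates(V, al, be); ds[4] = al * (1.0 - a) - be * a;
}

static void fill_kin(const NumericMatrix &kin, const IntegerVector &role, GateKin *out) {
  for (int g = 0; g < 4; g++) {
    out[g].th = kin(g, 0); out[g].s1 = kin(g, 1); out[g].s2 = kin(g, 2);
    out[g].k1 = kin(g, 3); out[g].k2 = kin(g, 4); out[g].role = role[g];
  }
}

// Raised-cosine theta drive conductance, 0 at t = 0, g_max at the half-cycle.
static inline double theta_g(double t, double gmax, double freq) {
  return 0.5 * gmax * (1.0 - std::cos(2.0 * M_PI * freq * t / 1000.0));
}

// Biexponential conductance waveform (peak-normalized by F, supplied as g_peak*F).
static inline double biexp_g(double t, double t_on, double gF, double tau1, double tau2) {
  if (t < t_on) return 0.0;
  double u = t - t_on;
  return gF * (std::exp(-u / tau1) - std::exp(-u / tau2));
}

// [[Rcpp::export]]
List cpp_simulate_neuron(NumericVector par, NumericMatrix kin, IntegerVector role,
                         double dur, double dt, int method,
                         double I_app, double g_const,
                         double theta_gmax, double theta_freq,
                         NumericVector pert, NumericVector init,
                         bool record_v, bool record_state,
                         double v_thresh, double lockout, bool error_on_blowup) {
  NeuronPar p{par[0], par[1], par[2], par[3], par[4], par[5]};
  GateKin K[4];
  fill_kin(kin, role, K);
  int n_steps = (int) std::lround(dur / dt);
  bool has_pert = pert.size() >= 5;
  double pt_on = 0, pgF = 0, ptau1 = 1, ptau2 = 1, pE = 0;
  if (has_pert) {
    pt_on = pert[0]; ptau1 = pert[2]; ptau2 = pert[3]; pE = pert[4];
    double tpk = ptau1 * ptau2 / (ptau1 - ptau2) * std::log(ptau1 / ptau2);
    double F = 1.0 / (std::exp(-tpk / ptau1) - std::exp(-tpk / ptau2));
    pgF = pert[1] * F;
  }
  double s[5];
  if (init.size() == 5) {
    for (int i = 0; i < 5; i++) s[i] = init[i];
  } else {
    s[0] = p.EL;
    for (int g = 0; g < 4; g++) s[g + 1] = K[g].xinf(p.EL);
  }
  NumericVector Vtr(record_v ? n_steps : 0);
  NumericMatrix Str(record_state ? n_steps : 0, 5);
  std::vector<double> spikes;
  double last_sp = -1e9;
  bool blown = false;
  int blow_step = -1;

  auto extra = [&](double t, double V) {
    double g = g_const;
    if (theta_gmax > 0) g += theta_g(t, theta_gmax, theta_freq);
    double I = I_app + g * (E_CHR - V);
    if (has_pert) I += biexp_g(t, pt_on, pgF, ptau1, ptau2) * (pE - V);
    return I;
  };

  double ds[5], s2[5], k1v[5], k2v[5], k3v[5], k4v[5];
  for (int i = 0; i < n_steps; i++) {
    double t = i * dt;
    double Vold = s[0];
    if (method == 0) {
      derivs(s, p, K, extra(t, s[0]), ds);
      for (int j = 0; j < 5; j++) s[j] += dt * ds[j];
    } else {
      derivs(s, p, K, extra(t, s[0]), k1v);
      for (int j = 0; j < 5; j++) s2[j] = s[j] + 0.5 * dt * k1v[j];
      derivs(s2, p, K, extra(t + 0.5 * dt, s2[0]), k2v);
      for (int j = 0; j < 5; j++) s2[j] = s[j] + 0.5 * dt * k2v[j];
      derivs(s2, p, K, extra(t + 0.5 * dt, s2[0]), k3v);
      for (int j = 0; j < 5; j++) s2[j] = s[j] + dt * k3v[j];
      derivs(s2, p, K, extra(t + dt, s2[0]), k4v);
      for (int j = 0; j < 5; j++)
        s[j] += dt / 6.0 * (k1v[j] + 2.0 * k2v[j] + 2.0 * k3v[j] + k4v[j]);
    }
    if (s[0] >= v_thresh && Vold < v_thresh && (t - last_sp) > lockout) {
      double tc = t + dt * (v_thresh - Vold) / (s[0] - Vold);
      spikes.push_back(tc);
      last_sp = tc;
    }
    if (record_v) Vtr[i] = s[0];
    if (record_state) for (int j = 0; j < 5; j++) Str(i, j) = s[j];
    if (std::fabs(s[0]) > 200.0 || !std::isfinite(s[0])) {
      blown = true; blow_step = i + 1;
      if (error_on_blowup)
        stop("membrane potential diverged (|V| > 200 mV) at step %d (t = %.4f ms)",
             blow_step, t);
      break;
    }
  }
  NumericVector fin(5);
  for (int j = 0; j < 5; j++) fin[j] = s[j];
  return List::create(_["spikes"] = wrap(spikes), _["V"] = Vtr, _["states"] = Str,
                      _["final_state"] = fin, _["blown"] = blown,
                      _["blow_step"] = blow_step);
}

// [[Rcpp::export]]
List cpp_simulate_network(NumericMatrix par, NumericMatrix thetas, NumericMatrix kin,
                          IntegerVector role,
                          IntegerVector syn_pre, IntegerVector syn_post,
                          NumericVector syn_w, NumericVector syn_delay,
                          double E_syn, double tau1, double tau2,
                          IntegerVector gap_i, IntegerVector gap_j, NumericVector gap_g,
                          double g_const, double theta_gmax, double theta_freq,
                          NumericVector I_app,
                          bool std_on, double tau_r, double U_SE,
                          double dur, double dt, NumericMatrix init,
                          IntegerVector record_idx, double v_thresh, double lockout) {
  int N = par.nrow();
  int n_steps = (int) std::lround(dur / dt);
  int n_syn = syn_pre.size(), n_gap = gap_i.size(), n_rec = record_idx.size();

  std::vector<NeuronPar> P(N);
  for (int i = 0; i < N; i++)
    P[i] = NeuronPar{par(i, 0), par(i, 1), par(i, 2), par(i, 3), par(i, 4), par(i, 5)};
  // per-neuron kinetics: shared constants, per-neuron theta
  std::vector<GateKin> K(N * 4);
  for (int i = 0; i < N; i++)
    for (int g = 0; g < 4; g++) {
      K[i * 4 + g].th = thetas(i, g);
      K[i * 4 + g].s1 = kin(g, 1); K[i * 4 + g].s2 = kin(g, 2);
      K[i * 4 + g].k1 = kin(g, 3); K[i * 4 + g].k2 = kin(g, 4);
      K[i * 4 + g].role = role[g];
    }
  // outgoing synapse adjacency
  std::vector<int> out_start(N + 1, 0);
  for (int k = 0; k < n_syn; k++) out_start[syn_pre[k] + 1]++;
  for (int i = 0; i < N; i++) out_start[i + 1] += out_start[i];
  std::vector<int> out_syn(n_syn);
  {
    std::vector<int> pos(out_start.begin(), out_start.end() - 1);
    for (int k = 0; k < n_syn; k++) out_syn[pos[syn_pre[k]]++] = k;
  }
  double tpk = tau1 * tau2 / (tau1 - tau2) * std::log(tau1 / tau2);
  double Fnorm = 1.0 / (std::exp(-tpk / tau1) - std::exp(-tpk / tau2));
  double e1 = std::exp(-dt / tau1), e2 = std::exp(-dt / tau2);

  // ring buffer of pending conductance-onset events
  double max_delay = 0;
  for (int k = 0; k < n_syn; k++) if (syn_delay[k] > max_delay) max_delay = syn_delay[k];
  int ring_n = (int) std::ceil(max_delay / dt) + 8;
  std::vector<std::vector<std::pair<int, double> > > ring(ring_n);

  std::vector<double> V(N), m(N), h(N), nn(N), aa(N);
  for (int i = 0; i < N; i++) {
    V[i] = init(i, 0); m[i] = init(i, 1); h[i] = init(i, 2);
    nn[i] = init(i, 3); aa[i] = init(i, 4);
  }
  std::vector<double> A(N, 0.0), B(N, 0.0), Igap(N, 0.0);
  std::vector<double> x(N, 1.0), x_time(N, 0.0);
  std::vector<double> last_sp(N, -1e9), Vn(N);
  std::vector<std::vector<double> > spikes(N);
  NumericMatrix traces(n_rec > 0 ? n_steps : 0, n_rec);

  for (int step = 0; step < n_steps; step++) {
    double t = step * dt;
    // deliver scheduled conductance onsets
    std::vector<std::pair<int, double> > &slot = ring[step % ring_n];
    for (size_t e = 0; e < slot.size(); e++) {
      A[slot[e].first] += slot[e].second;
      B[slot[e].first] += slot[e].second;
    }
    slot.clear();
    // gap currents from same-step voltages
    if (n_gap > 0) {
      std::fill(Igap.begin(), Igap.end(), 0.0);
      for (int k = 0; k < n_gap; k++) {
        double c = gap_g[k] * (V[gap_i[k]] - V[gap_j[k]]);
        Igap[gap_i[k]] -= c;
        Igap[gap_j[k]] += c;
      }
    }
    double gdrive = g_const + (theta_gmax > 0 ? theta_g(t, theta_gmax, theta_freq) : 0.0);
    for (int i = 0; i < N; i++) {
      double Vi = V[i];
      const NeuronPar &p = P[i];
      const GateKin *Ki = &K[i * 4];
      double I = (I_app.size() == N ? I_app[i] : 0.0)
               + p.gNa * m[i] * m[i] * m[i] * h[i] * (E_NA - Vi)
               + p.gKv1 * aa[i] * aa[i] * aa[i] * aa[i] * (E_K - Vi)
               + p.gKv3 * nn[i] * nn[i] * nn[i] * nn[i] * (E_K - Vi)
               + p.gL * (p.EL - Vi)
               + gdrive * (E_CHR - Vi)
               + (A[i] - B[i]) * (E_syn - Vi)
               + (n_gap > 0 ? Igap[i] : 0.0);
      Vn[i] = Vi + dt * I / p.CM;
      double al, be;
      Ki[0].rates(Vi, al, be); m[i]  += dt * (al * (1.0 - m[i])  - be * m[i]);
      Ki[1].rates(Vi, al, be); h[i]  += dt * (al * (1.0 - h[i])  - be * h[i]);
      Ki[2].rates(Vi, al, be); nn[i] += dt * (al * (1.0 - nn[i]) - be * nn[i]);
      Ki[3].rates(Vi, al, be); aa[i] += dt * (al * (1.0 - aa[i]) - be * aa[i]);
    }
    for (int i = 0; i < N; i++) { A[i] *= e1; B[i] *= e2; }
    for (int i = 0; i < N; i++) {
      if (Vn[i] >= v_thresh && V[i] < v_thresh && (t - last_sp[i]) > lockout) {
        double tc = t + dt * (v_thresh - V[i]) / (Vn[i] - V[i]);
        spikes[i].push_back(tc);
        last_sp[i] = tc;
        double amp_scale = 1.0;
        if (std_on) {
          // analytic recovery since last spike, read x, then deplete
          x[i] = 1.0 - (1.0 - x[i]) * std::exp(-(tc - x_time[i]) / tau_r);
          amp_scale = x[i];
          x[i] *= (1.0 - U_SE);
          x_time[i] = tc;
        }
        for (int q = out_start[i]; q < out_start[i + 1]; q++) {
          int k = out_syn[q];
          int dstep = (int) std::ceil((tc + syn_delay[k]) / dt - 1e-9);
          if (dstep <= step) dstep = step + 1;
          if (dstep < n_steps + ring_n)
            ring[dstep % ring_n].push_back(
                std::make_pair(syn_post[k], syn_w[k] * Fnorm * amp_scale));
        }
      }
      V[i] = Vn[i];
      if (std::fabs(V[i]) > 200.0 || !std::isfinite(V[i]))
        stop("membrane potential of neuron %d diverged at step %d (t = %.4f ms)",
             i + 1, step + 1, t);
    }
    for (int r = 0; r < n_rec; r++) traces(step, r) = V[record_idx[r]];
  }
  List sp(N);
  for (int i = 0; i < N; i++) sp[i] = wrap(spikes[i]);
  return List::create(_["spikes"] = sp, _["traces"] = traces);
}
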