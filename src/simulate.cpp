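// Time-steppers for the plasticity models.
//
// Events arrive as (synapse, onset-step) pairs sorted by onset; each event
// holds its synapse active for ev_dur steps and overlapping events merge
// into a single ON interval (the indicator stays binary).  Explicit Euler
// everywhere except the stiff P/B pair, which is advanced by the exact
// exponential solution of its linear ODE with M and Y frozen over the step
// (plain Euler is unstable there once (1+M)*dt/tau_P > 2).

#include <Rcpp.h>
#include <random>
#include <vector>
using namespace Rcpp;

namespace {

// binary event indicator bookkeeping with merged overlaps
struct EventFeed {
  const int *syn, *step;
  int n, dur, ptr;
  std::vector<int> cnt;
  std::vector<std::vector<int>> offsets;  // circular buffer of size dur+1
  EventFeed(const IntegerVector &s, const IntegerVector &t, int n_syn, int d)
      : syn(s.begin()), step(t.begin()), n(s.size()), dur(d), ptr(0),
        cnt(n_syn, 0), offsets(d + 1) {}
  // advance to step t, update counts
  void tick(int t) {
    std::vector<int> &off = offsets[t % (dur + 1)];
    for (int k : off) cnt[k]--;
    off.clear();
    while (ptr < n && step[ptr] <= t) {
      int k = syn[ptr];
      cnt[k]++;
      offsets[(t + dur) % (dur + 1)].push_back(k);
      ptr++;
    }
  }
  bool active(int k) const { return cnt[k] > 0; }
};

inline double clip01(double x) { return x < 0 ? 0 : (x > 1 ? 1 : x); }

} // namespace

// [[Rcpp::export]]
List cpp_sim_generalized(
    int n_steps, double dt,
    IntegerVector ev_syn, IntegerVector ev_step, int ev_dur,
    NumericMatrix S, NumericVector sk,
    NumericVector v0, NumericVector u0, NumericVector w0,
    double tau_v, double tau_u, double tau_w,
    double phi_eff, double rho,
    double gamma, double c1, double c2, double c3,
    bool coop_on, IntegerVector nbr_ptr, IntegerVector nbr_idx,
    double coop_timing, int coop_min,
    bool freeze_w,
    bool bap_on, double A_th, double bap_prob, double B_amp,
    int bap_dur_steps, double refractory_ms,
    IntegerVector forced_bap_steps,
    double drive_scale,
    int record_every, int seed, bool record_A = false) {
  const int N = v0.size();
  std::vector<double> v(v0.begin(), v0.end()), u(u0.begin(), u0.end()),
      w(w0.begin(), w0.end()), usyn(u0.begin(), u0.end()),
      drive(N), mean_dw(N, 0.0), last_act(N, -1e18);
  EventFeed ev(ev_syn, ev_step, N, ev_dur);

  std::mt19937_64 rng(seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  const double av = dt / tau_v, au = dt / tau_u, aw = 1.0 / tau_w;
  int n_rec = record_every > 0 ? n_steps / record_every + 1 : 0;
  NumericMatrix w_hist(record_every > 0 ? N : 0, n_rec);
  NumericVector A_hist(record_every > 0 && bap_on ? n_rec : 0);
  NumericVector A_full(record_A && bap_on ? n_steps : 0);
  int rec_i = 0;

  int bap_left = 0, fb_ptr = 0, n_bap = 0, n_cross = 0;
  double prev_A = 0.0, refrac_until = -1.0;
  std::vector<double> bap_times;

  std::vector<int> act;
  act.reserve(N);

  for (int t = 0; t < n_steps; ++t) {
    ev.tick(t);
    act.clear();
    for (int k = 0; k < N; ++k)
      if (ev.active(k)) { act.push_back(k); last_act[k] = t * dt; }

    // postsynaptic drive from active synapses
    std::fill(drive.begin(), drive.end(), 0.0);
    for (int l : act) {
      const double wl = w[l] * drive_scale;
      const double *col = &S(0, l);
      for (int k = 0; k < N; ++k) drive[k] += col[k] * wl;
    }
    if (gamma > 0) {
      for (int k = 0; k < N; ++k)
        drive[k] = gamma * c1 / (1.0 + std::exp(-c2 * (drive[k] - c3))) +
                   (1.0 - gamma) * drive[k];
    }

    // soma: accumulator excludes the bAP feedback (usyn has no bAP term)
    double bap_ind = 0.0;
    if (bap_on || forced_bap_steps.size() > 0) {
      if (bap_on) {
        double A = 0.0;
        for (int k = 0; k < N; ++k) A += w[k] * usyn[k];
        double tms = t * dt;
        if (prev_A < A_th && A >= A_th && tms >= refrac_until) {
          n_cross++;
          refrac_until = tms + refractory_ms;
          if (unif(rng) < bap_prob) {
            bap_left = bap_dur_steps;
            n_bap++;
            if (bap_times.size() < 100000) bap_times.push_back(tms);
          }
        }
        prev_A = A;
        if (record_A) A_full[t] = A;
        if (record_every > 0 && t % record_every == 0) A_hist[rec_i] = A;
      }
      while (fb_ptr < forced_bap_steps.size() && forced_bap_steps[fb_ptr] == t) {
        bap_left = bap_dur_steps;
        fb_ptr++;
      }
      if (bap_left > 0) { bap_ind = 1.0; bap_left--; }
    }

    if (record_every > 0 && t % record_every == 0) {
      for (int k = 0; k < N; ++k) w_hist(k, rec_i) = w[k];
      rec_i++;
    }

    for (int k = 0; k < N; ++k) {
      const double x = ev.active(k) ? 1.0 : 0.0;
      v[k] += av * (-v[k] + phi_eff * x);
      const double inj = sk[k] * B_amp * bap_ind;
      u[k] += au * (-u[k] + drive[k] + inj);
      if (bap_on) usyn[k] += au * (-usyn[k] + drive[k]);
      double dw = u[k] * (v[k] + rho) * aw;
      if (coop_on) {
        int cnt = 0;
        const double tms = t * dt;
        for (int p = nbr_ptr[k]; p < nbr_ptr[k + 1]; ++p)
          if (tms - last_act[nbr_idx[p]] <= coop_timing) cnt++;
        if (cnt <= coop_min) dw = 0.0;
      }
      mean_dw[k] += dw;
      if (!freeze_w) w[k] = clip01(w[k] + dt * dw);
    }
  }
  if (record_every > 0 && rec_i < n_rec) {
    for (int k = 0; k < N; ++k) w_hist(k, rec_i) = w[k];
    if (bap_on) A_hist[rec_i] = prev_A;
    rec_i++;
  }
  for (int k = 0; k < N; ++k) mean_dw[k] /= n_steps;

  return List::create(
      _["v"] = NumericVector(v.begin(), v.end()),
      _["u"] = NumericVector(u.begin(), u.end()),
      _["w"] = NumericVector(w.begin(), w.end()),
      _["mean_dw"] = NumericVector(mean_dw.begin(), mean_dw.end()),
      _["w_hist"] = w_hist, _["A_hist"] = A_hist, _["A_full"] = A_full,
      _["n_bap"] = n_bap, _["n_crossings"] = n_cross,
      _["bap_times"] = NumericVector(bap_times.begin(), bap_times.end()));
}

// [[Rcpp::export]]
List cpp_sim_neurotrophin(
    int n_steps, double dt,
    IntegerVector ev_syn, IntegerVector ev_step, int ev_dur,
    IntegerVector gev_syn, IntegerVector gev_step,
    NumericMatrix S_ee, NumericMatrix S_ei, NumericVector sk,
    NumericVector M0, NumericVector Y0, NumericVector P0, NumericVector B0,
    NumericVector W0, NumericVector Wg0,
    double tau_M, double tau_Y, double tau_P, double tau_B, double tau_W,
    double phi_eff, double eta, double alpha, double beta,
    int gaba_sign0, int gaba_switch_step,
    bool y_floor, bool freeze_W,
    IntegerVector forced_bap_steps, double B_amp, int bap_dur_steps,
    double drive_scale,
    int record_every) {
  const int N = M0.size(), NI = Wg0.size();
  std::vector<double> M(M0.begin(), M0.end()), Y(Y0.begin(), Y0.end()),
      P(P0.begin(), P0.end()), B(B0.begin(), B0.end()),
      W(W0.begin(), W0.end()), Wg(Wg0.begin(), Wg0.end()),
      drive(N), mean_BP(N, 0.0);
  EventFeed ev(ev_syn, ev_step, N, ev_dur);
  EventFeed gev(gev_syn, gev_step, NI > 0 ? NI : 1, ev_dur);

  const double aM = dt / tau_M, aY = dt / tau_Y, aW = dt / tau_W;
  const double eB = std::exp(-dt / tau_B);
  int n_rec = record_every > 0 ? n_steps / record_every + 1 : 0;
  NumericMatrix W_hist(record_every > 0 ? N : 0, n_rec);
  NumericMatrix Tr(record_every > 0 ? 4 * (N >= 1 ? 1 : 0) : 0, n_rec);
  int rec_i = 0;
  int bap_left = 0, fb_ptr = 0;

  std::vector<int> act, gact;

  for (int t = 0; t < n_steps; ++t) {
    ev.tick(t);
    act.clear();
    for (int k = 0; k < N; ++k) if (ev.active(k)) act.push_back(k);
    int gsign = 0;
    if (NI > 0) {
      gev.tick(t);
      gact.clear();
      for (int k = 0; k < NI; ++k) if (gev.active(k)) gact.push_back(k);
      gsign = (t >= gaba_switch_step) ? -1 : gaba_sign0;
    }

    std::fill(drive.begin(), drive.end(), 0.0);
    for (int l : act) {
      const double wl = W[l] * drive_scale;
      const double *col = &S_ee(0, l);
      for (int k = 0; k < N; ++k) drive[k] += col[k] * wl;
    }
    for (int l : gact) {
      const double wl = gsign * Wg[l];
      const double *col = &S_ei(0, l);
      for (int k = 0; k < N; ++k) drive[k] += col[k] * wl;
    }

    while (fb_ptr < forced_bap_steps.size() && forced_bap_steps[fb_ptr] == t) {
      bap_left = bap_dur_steps;
      fb_ptr++;
    }
    double bap_ind = 0.0;
    if (bap_left > 0) { bap_ind = 1.0; bap_left--; }

    if (record_every > 0 && t % record_every == 0) {
      for (int k = 0; k < N; ++k) W_hist(k, rec_i) = W[k];
      if (Tr.nrow() == 4) {
        Tr(0, rec_i) = M[0]; Tr(1, rec_i) = Y[0];
        Tr(2, rec_i) = P[0]; Tr(3, rec_i) = B[0];
      }
      rec_i++;
    }

    for (int k = 0; k < N; ++k) {
      const double x = ev.active(k) ? 1.0 : 0.0;
      M[k] += aM * (-M[k] + phi_eff * x);
      Y[k] += aY * (-Y[k] + drive[k] + sk[k] * B_amp * bap_ind);
      if (y_floor && Y[k] < 0) Y[k] = 0;
      // exact exponential update of P given frozen M, Y
      const double m = M[k];
      const double Pss = (1.0 - eta) * Y[k] / (1.0 + m);
      const double eP = std::exp(-(1.0 + m) * dt / tau_P);
      const double Pnew = Pss + (P[k] - Pss) * eP;
      const double Pbar = 0.5 * (P[k] + Pnew);
      P[k] = Pnew;
      const double Bss = eta * Y[k] + m * Pbar;
      B[k] = Bss + (B[k] - Bss) * eB;
      mean_BP[k] += B[k] - P[k];
      if (!freeze_W) W[k] = clip01(W[k] + aW * (alpha * B[k] - beta * P[k]));
    }
    if (NI > 0) {
      for (int g = 0; g < NI; ++g) {
        double d = 0.0;
        for (int k = 0; k < N; ++k) d += S_ei(k, g) * (B[k] - P[k]);
        Wg[g] = clip01(Wg[g] + aW * d);
      }
    }
  }
  if (record_every > 0 && rec_i < n_rec) {
    for (int k = 0; k < N; ++k) W_hist(k, rec_i) = W[k];
    if (Tr.nrow() == 4) {
      Tr(0, rec_i) = M[0]; Tr(1, rec_i) = Y[0];
      Tr(2, rec_i) = P[0]; Tr(3, rec_i) = B[0];
    }
    rec_i++;
  }
  for (int k = 0; k < N; ++k) mean_BP[k] /= n_steps;

  return List::create(
      _["M"] = NumericVector(M.begin(), M.end()),
      _["Y"] = NumericVector(Y.begin(), Y.end()),
      _["P"] = NumericVector(P.begin(), P.end()),
      _["B"] = NumericVector(B.begin(), B.end()),
      _["W"] = NumericVector(W.begin(), W.end()),
      _["W_gaba"] = NumericVector(Wg.begin(), Wg.end()),
      _["mean_BP"] = NumericVector(mean_BP.begin(), mean_BP.end()),
      _["W_hist"] = W_hist, _["trace1"] = Tr);
}
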