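// Single-cell drivers for the ventricular myocyte model: published initial
// state, plain right-hand side, beat pacing, and limit-cycle search with the
// inter-beat calcium RMSE convergence criterion.
#include "ord_shared.h"
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector ord_initial_state_cpp() {
  NumericVector s(ORD_N_STATE);
  s[iV] = -87.0;
  s[iNai] = 7.0; s[iNass] = 7.0; s[iKi] = 145.0; s[iKss] = 145.0;
  s[iCai] = 1.0e-4; s[iCass] = 1.0e-4; s[iCansr] = 1.2; s[iCajsr] = 1.2;
  s[iM] = 0.0; s[iHf] = 1.0; s[iHs] = 1.0; s[iJ] = 1.0; s[iHsp] = 1.0;
  s[iJp] = 1.0;
  s[iML] = 0.0; s[iHL] = 1.0; s[iHLp] = 1.0;
  s[iA] = 0.0; s[iIF] = 1.0; s[iIS] = 1.0; s[iAp] = 0.0; s[iIFp] = 1.0;
  s[iISp] = 1.0;
  s[iD] = 0.0; s[iFF] = 1.0; s[iFS] = 1.0; s[iFcaf] = 1.0; s[iFcas] = 1.0;
  s[iJca] = 1.0; s[iNca] = 0.0; s[iFFp] = 1.0; s[iFcafp] = 1.0;
  s[iXrf] = 0.0; s[iXrs] = 0.0; s[iXs1] = 0.0; s[iXs2] = 0.0; s[iXk1] = 1.0;
  s[iJrelnp] = 0.0; s[iJrelp] = 0.0; s[iCaMKt] = 0.0;
  return s;
}

// full right-hand side, direct (non-LUT) evaluation
// [[Rcpp::export]]
NumericVector ord_rhs_cpp(NumericVector state, NumericVector params,
                          double Istim) {
  OrdParamsS P = ord_unpack(params);
  const double* S = REAL(state);
  OrdVDep X;
  ord_vdep(S[iV], X);
  OrdCurrents C;
  ord_compute_currents(S, P, X, C);
  NumericVector d(ORD_N_STATE);
  ord_conc_derivs(S, P, C, Istim, REAL(d));
  double inf[ORD_N_GATE], tau[ORD_N_GATE];
  ord_gate_inf_tau(S[iV], P.epi, inf, tau);
  for (int g = 0; g < ORD_N_GATE; ++g)
    d[ORD_GATE_IDX[g]] = (inf[g] - S[ORD_GATE_IDX[g]]) / tau[g];
  const double Kmn = 0.002, k2n = 1000.0;
  double km2n = S[iJca];
  double q = 1.0 + Kmn / S[iCass];
  double anca = 1.0 / (k2n / km2n + q * q * q * q);
  d[iNca] = anca * k2n - S[iNca] * km2n;
  d[iJrelnp] = (C.Jrel_inf - S[iJrelnp]) / C.tau_rel;
  d[iJrelp] = (C.Jrel_infp - S[iJrelp]) / C.tau_relp;
  d[iCaMKt] = C.dCaMKt;
  return d;
}

// ionic current sum (diagnostic; µA/µF)
// [[Rcpp::export]]
double ord_itot_cpp(NumericVector state, NumericVector params) {
  OrdParamsS P = ord_unpack(params);
  const double* S = REAL(state);
  OrdVDep X;
  ord_vdep(S[iV], X);
  OrdCurrents C;
  ord_compute_currents(S, P, X, C);
  return C.Itot;
}

// pace a single cell for n_beats; returns the final state and the last
// beat's trace sampled every sample_dt ms
// [[Rcpp::export]]
List ord_pace_cpp(NumericVector state, NumericVector params, double cl,
                  int n_beats, double dt, double stim_amp, double stim_dur,
                  double sample_dt) {
  OrdParamsS P = ord_unpack(params);
  GateLutS T;
  ord_build_lut(T, P.epi, dt);
  std::vector<double> S(state.begin(), state.end());
  long steps_per_beat = (long)(cl / dt + 0.5);
  std::vector<double> tr_t, tr_v, tr_ca;
  for (int b = 0; b < n_beats; ++b) {
    bool last = (b == n_beats - 1);
    long next_samp = 0;
    for (long s = 0; s < steps_per_beat; ++s) {
      double t = s * dt;
      if (last && t >= next_samp * sample_dt - 1e-9) {
        tr_t.push_back(t); tr_v.push_back(S[iV]); tr_ca.push_back(S[iCai]);
        ++next_samp;
      }
      double Istim = (t < stim_dur) ? stim_amp : 0.0;
      ord_rl_step(S.data(), P, T, dt, Istim);
      if (!std::isfinite(S[iV]) || fabs(S[iV]) > 300.0)
        stop("membrane potential diverged during pacing (beat %d, t = %f ms)",
             b + 1, t);
    }
    if (b % 50 == 49) Rcpp::checkUserInterrupt();
  }
  return List::create(_["state"] = NumericVector(S.begin(), S.end()),
                      _["t"] = NumericVector(tr_t.begin(), tr_t.end()),
                      _["v"] = NumericVector(tr_v.begin(), tr_v.end()),
                      _["cai"] = NumericVector(tr_ca.begin(), tr_ca.end()));
}

// free-running (unstimulated) integration, used for resting-state checks
// [[Rcpp::export]]
List ord_run_cpp(NumericVector state, NumericVector params, double duration,
                 double dt, double sample_dt) {
  OrdParamsS P = ord_unpack(params);
  GateLutS T;
  ord_build_lut(T, P.epi, dt);
  std::vector<double> S(state.begin(), state.end());
  long nsteps = (long)(duration / dt + 0.5);
  std::vector<double> tr_t, tr_v;
  long next_samp = 0;
  for (long s = 0; s < nsteps; ++s) {
    double t = s * dt;
    if (t >= next_samp * sample_dt - 1e-9) {
      tr_t.push_back(t); tr_v.push_back(S[iV]);
      ++next_samp;
    }
    ord_rl_step(S.data(), P, T, dt, 0.0);
    if (!std::isfinite(S[iV]))
      stop("membrane potential became non-finite at t = %f ms", t);
    if (s % 100000 == 99999) Rcpp::checkUserInterrupt();
  }
  return List::create(_["state"] = NumericVector(S.begin(), S.end()),
                      _["t"] = NumericVector(tr_t.begin(), tr_t.end()),
                      _["v"] = NumericVector(tr_v.begin(), tr_v.end()));
}

// pace until the inter-beat RMSE of the 1-ms-resampled [Ca]i trace drops
// below tol
// [[Rcpp::export]]
List ord_limit_cycle_cpp(NumericVector state, NumericVector params, double cl,
                         double dt, double tol, int max_beats,
                         double stim_amp, double stim_dur) {
  OrdParamsS P = ord_unpack(params);
  GateLutS T;
  ord_build_lut(T, P.epi, dt);
  std::vector<double> S(state.begin(), state.end());
  long steps_per_beat = (long)(cl / dt + 0.5);
  int ngrid = (int)cl; // 1-ms resampling grid for the convergence criterion
  std::vector<double> prev(ngrid, 0.0), cur(ngrid, 0.0);
  std::vector<double> rmse_hist;
  int nb = 0;
  bool converged = false;
  for (int b = 0; b < max_beats; ++b) {
    int gi = 0;
    for (long s = 0; s < steps_per_beat; ++s) {
      double t = s * dt;
      if (gi < ngrid && t >= gi * 1.0 - 1e-9) { cur[gi] = S[iCai]; ++gi; }
      double Istim = (t < stim_dur) ? stim_amp : 0.0;
      ord_rl_step(S.data(), P, T, dt, Istim);
      if (!std::isfinite(S[iV]) || fabs(S[iV]) > 300.0)
        stop("membrane potential diverged during limit-cycle pacing (beat %d)",
             b + 1);
    }
    nb = b + 1;
    if (!std::isfinite(tol)) { converged = true; break; } // vacuous criterion
    if (b > 0) {
      double ss = 0.0;
      for (int k = 0; k < ngrid; ++k) {
        double e = cur[k] - prev[k];
        ss += e * e;
      }
      double rmse = sqrt(ss / ngrid);
      rmse_hist.push_back(rmse);
      if (rmse < tol) { converged = true; break; }
    }
    prev.swap(cur);
    if (b % 20 == 19) Rcpp::checkUserInterrupt();
  }
  return List::create(
      _["state"] = NumericVector(S.begin(), S.end()),
      _["n_beats"] = nb,
      _["rmse_history"] = NumericVector(rmse_hist.begin(), rmse_hist.end()),
      _["converged"] = converged);
}
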