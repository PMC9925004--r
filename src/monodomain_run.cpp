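// Monodomain time loop on a tetrahedral mesh.
//
// Operator splitting per global step dt (default 0.01 ms):
//   1. reaction: Rush-Larsen/forward-Euler update of the ionic model at
//      every excitable node (non-excitable regions skip reaction);
//   2. diffusion: explicit lumped-mass FEM update V -= dt * M^-1 K V,
//      sub-stepped automatically to satisfy the Gershgorin stability bound.
//
// The stiffness matrix K (region-wise anisotropic diffusion tensors,
// zero-flux boundaries) and the lumped mass vector are assembled in R and
// passed in CSR form (0-based indices).
#include "ord_shared.h"
using namespace Rcpp;

// [[Rcpp::export]]
List monodomain_run_cpp(IntegerVector ia, IntegerVector ja, NumericVector ka,
                        NumericVector mass, IntegerVector group,
                        NumericMatrix pmat, NumericVector gks_scale,
                        NumericMatrix states,
                        IntegerVector stim_ptr, IntegerVector stim_node,
                        NumericVector stim_onset, NumericVector stim_dur,
                        NumericVector stim_amp,
                        double dt, double duration, double snapshot_dt,
                        bool quiesce_stop, double last_stim_end) {
  const int n = mass.size();
  const int nst = ORD_N_STATE;
  if (states.nrow() != n || states.ncol() != nst)
    stop("state matrix must be n_nodes x 41");

  const int ng = pmat.nrow();
  std::vector<OrdParamsS> gp(ng);
  bool need_epi = false, need_nonepi = false;
  for (int g = 0; g < ng; ++g) {
    NumericVector row = pmat(g, _);
    gp[g] = ord_unpack(row);
    if (gp[g].epi) need_epi = true; else need_nonepi = true;
  }
  GateLutS lut_epi, lut_non;
  if (need_epi) ord_build_lut(lut_epi, 1, dt);
  if (need_nonepi) ord_build_lut(lut_non, 0, dt);

  // explicit diffusion sub-steps from the Gershgorin bound on M^-1 K
  double lam = 0.0;
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int k = ia[i]; k < ia[i + 1]; ++k) s += fabs(ka[k]);
    double l = s / mass[i];
    if (l > lam) lam = l;
  }
  int nsub = (int)ceil(dt * lam / 1.8);
  if (nsub < 1) nsub = 1;
  double dts = dt / nsub;

  long nsteps = (long)(duration / dt + 0.5);
  int nsnap = snapshot_dt > 0 ? (int)(duration / snapshot_dt) + 1 : 0;
  NumericMatrix snaps(nsnap > 0 ? n : 1, nsnap > 0 ? nsnap : 1);
  std::vector<double> snap_times;
  int snap_i = 0;

  std::vector<double> S(states.begin(), states.end()); // column-major n x 41
  std::vector<double> V(n), Vnew(n), Vprev(n), istim(n, 0.0);
  for (int i = 0; i < n; ++i) V[i] = S[i];
  std::vector<double> last_ev(n, -1e9);
  std::vector<int> ev_node;
  std::vector<double> ev_time;
  const int nstim = stim_onset.size();
  bool stopped_early = false;
  double t_end = duration;

  // reversal potentials change slowly with the concentrations; refresh the
  // per-node cache every 20 reaction steps (0.2 ms at the default dt)
  std::vector<double> nernst(3 * (size_t)n, 0.0);
  const double rtf = ord_R * ord_T / ord_F;
  const int nernst_every = 20;

  std::vector<double> st(nst);
  std::vector<int> touched;
  for (long s = 0; s < nsteps; ++s) {
    double t = s * dt;
    for (int i = 0; i < n; ++i) Vprev[i] = V[i];

    if (s % nernst_every == 0) {
      for (int i = 0; i < n; ++i) {
        if (group[i] < 0) continue;
        double nai = S[(size_t)iNai * n + i];
        double ki = S[(size_t)iKi * n + i];
        nernst[3 * (size_t)i] = rtf * log(ord_nao / nai);
        nernst[3 * (size_t)i + 1] = rtf * log(ord_ko / ki);
        nernst[3 * (size_t)i + 2] = rtf * log((ord_ko + ord_PKNa * ord_nao) /
                                              (ki + ord_PKNa * nai));
      }
    }

    touched.clear();
    for (int q = 0; q < nstim; ++q) {
      if (t >= stim_onset[q] - 1e-9 && t < stim_onset[q] + stim_dur[q] - 1e-9) {
        for (int k = stim_ptr[q]; k < stim_ptr[q + 1]; ++k) {
          istim[stim_node[k]] += stim_amp[q];
          touched.push_back(stim_node[k]);
        }
      }
    }

    // reaction
    for (int i = 0; i < n; ++i) {
      int g = group[i];
      if (g < 0) continue; // passive (dense scar)
      for (int c = 0; c < nst; ++c) st[c] = S[(size_t)c * n + i];
      OrdParamsS P = gp[g];
      P.GKs *= gks_scale[i];
      const GateLutS& T = P.epi ? lut_epi : lut_non;
      ord_rl_step(st.data(), P, T, dt, istim[i], &nernst[3 * (size_t)i]);
      if (!std::isfinite(st[0]) || fabs(st[0]) > 300.0)
        stop("membrane potential diverged at node %d, t = %.2f ms", i + 1, t);
      for (int c = 1; c < nst; ++c) S[(size_t)c * n + i] = st[c];
      V[i] = st[0];
    }
    for (size_t k = 0; k < touched.size(); ++k) istim[touched[k]] = 0.0;

    // diffusion
    for (int sub = 0; sub < nsub; ++sub) {
      for (int i = 0; i < n; ++i) {
        double acc = 0.0;
        for (int k = ia[i]; k < ia[i + 1]; ++k) acc += ka[k] * V[ja[k]];
        Vnew[i] = V[i] - dts * acc / mass[i];
      }
      V.swap(Vnew);
    }
    double tn = t + dt;

    // local activation: first upward crossing of 0 mV (per-node refractory
    // guard suppresses numerical double counting)
    for (int i = 0; i < n; ++i) {
      if (Vprev[i] < 0.0 && V[i] >= 0.0 && tn - last_ev[i] > 30.0) {
        ev_node.push_back(i + 1);
        ev_time.push_back(tn);
        last_ev[i] = tn;
      }
      S[i] = V[i];
    }

    if (nsnap > 0 && snap_i < nsnap && tn >= snap_i * snapshot_dt - 1e-9) {
      for (int i = 0; i < n; ++i) snaps(i, snap_i) = V[i];
      snap_times.push_back(tn);
      ++snap_i;
    }

    // quiescence early stop (tachycardia trials): fully repolarized tissue
    // well after the last stimulus cannot produce further activity
    if (quiesce_stop && (s % 1000 == 999) && tn > last_stim_end + 120.0) {
      double vmax = -1e9;
      for (int i = 0; i < n; ++i) if (V[i] > vmax) vmax = V[i];
      if (vmax < -65.0) { stopped_early = true; t_end = tn; break; }
    }
    if (s % 5000 == 4999) Rcpp::checkUserInterrupt();
  }

  NumericMatrix out_states(n, nst);
  std::copy(S.begin(), S.end(), out_states.begin());
  List res = List::create(
      _["states"] = out_states,
      _["event_node"] = IntegerVector(ev_node.begin(), ev_node.end()),
      _["event_time"] = NumericVector(ev_time.begin(), ev_time.end()),
      _["stopped_early"] = stopped_early,
      _["t_end"] = t_end,
      _["n_substeps"] = nsub);
  if (nsnap > 0) {
    res["snapshots"] = snaps;
    res["snapshot_times"] = NumericVector(snap_times.begin(), snap_times.end());
  }
  return res;
}
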