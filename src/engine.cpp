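#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Synchronous discrete-time update of the whole network, n_steps at a time.
//
// Per step (identical to the R reference step_network()):
//   1. outputs from the previous step's potentials:
//        phi_e = 1{V_e - alpha*omega > thresh},  phi_i = max(V_i, 0)
//   2. net inputs: W_ee * phi_e - g_ie*phi_i - kG*omega_G[area] + ext  (E)
//                  W_ei * phi_e                                        (I)
//   3. Euler membrane update with per-excitatory-cell uniform noise
//      (R's RNG stream, one draw per excitatory cell per step, cell order)
//   4. low-pass updates of omega (tau_adapt), omega_E (tau_favg) and the
//      per-area omega_G (tau_glob, fed with the area's total spike count)
//   5. optional Hebbian update of every E->E weight, clipped to [0, w_max]
//
// Weight matrices come in as dgCMatrix slots (0-based CSC). All state
// vectors and the weight vector are cloned, never modified in place.
// [[Rcpp::export]]
List engine_run(NumericVector V_e_, NumericVector V_i_,
                NumericVector omega_, NumericVector omega_E_,
                NumericVector omega_G_,
                NumericVector phi_e_, NumericVector phi_i_,
                IntegerVector area_of, int n_areas,
                IntegerVector ee_i, IntegerVector ee_p, NumericVector ee_x_,
                IntegerVector ei_i, IntegerVector ei_p, NumericVector ei_x,
                double g_ie, NumericVector ext, int n_steps,
                List params, bool learn, double w_max, bool record,
                int t0) {
  NumericVector V_e = clone(V_e_), V_i = clone(V_i_);
  NumericVector omega = clone(omega_), omega_E = clone(omega_E_);
  NumericVector omega_G = clone(omega_G_);
  NumericVector phi_e = clone(phi_e_), phi_i = clone(phi_i_);
  NumericVector ee_x = clone(ee_x_);

  const int Ne = V_e.size();
  const double tau_exc = params["tau_exc"], tau_inh = params["tau_inh"];
  const double k1 = params["k1"], k2 = params["k2"], kG = params["kG"];
  const double thresh = params["thresh"], alpha = params["alpha"];
  const double tau_adapt = params["tau_adapt"], tau_favg = params["tau_favg"];
  const double tau_glob = params["tau_glob"];
  const double th_plus = params["theta_plus"], th_minus = params["theta_minus"];
  const double th_pre = params["theta_pre"], delta = params["delta"];
  const double inv_te = 1.0 / tau_exc, inv_ti = 1.0 / tau_inh;
  const double inv_ta = 1.0 / tau_adapt, inv_tf = 1.0 / tau_favg;
  const double inv_tg = 1.0 / tau_glob;

  NumericMatrix serp, spikes;
  if (record) {
    serp = NumericMatrix(n_areas, n_steps);
    spikes = NumericMatrix(n_areas, n_steps);
  }
  NumericVector vin_e(Ne), vin_i(Ne), oE_sum(Ne);
  std::vector<double> area_spk(n_areas), area_serp(n_areas);

  // row-major (CSR) view of the E->E matrix so the plasticity pass can
  // visit only synapses of cells that spiked this step
  std::vector<int> row_ptr, row_entry, ee_pre;
  if (learn) {
    const int nnz = ee_x.size();
    ee_pre.resize(nnz);
    for (int j = 0; j < Ne; ++j)
      for (int k = ee_p[j]; k < ee_p[j + 1]; ++k) ee_pre[k] = j;
    row_ptr.assign(Ne + 1, 0);
    for (int k = 0; k < nnz; ++k) row_ptr[ee_i[k] + 1]++;
    for (int r = 0; r < Ne; ++r) row_ptr[r + 1] += row_ptr[r];
    row_entry.resize(nnz);
    std::vector<int> cursor(row_ptr.begin(), row_ptr.end() - 1);
    for (int k = 0; k < nnz; ++k) row_entry[cursor[ee_i[k]]++] = k;
  }

  for (int step = 0; step < n_steps; ++step) {
    // 1. outputs from current potentials
    for (int c = 0; c < Ne; ++c) {
      phi_e[c] = (V_e[c] - alpha * omega[c] > thresh) ? 1.0 : 0.0;
      phi_i[c] = (V_i[c] > 0.0) ? V_i[c] : 0.0;
    }
    // 2. net inputs (column-major accumulation, as Matrix::%*% does)
    std::fill(vin_e.begin(), vin_e.end(), 0.0);
    std::fill(vin_i.begin(), vin_i.end(), 0.0);
    for (int j = 0; j < Ne; ++j) {
      if (phi_e[j] != 0.0) {
        for (int k = ee_p[j]; k < ee_p[j + 1]; ++k)
          vin_e[ee_i[k]] += ee_x[k] * phi_e[j];
        for (int k = ei_p[j]; k < ei_p[j + 1]; ++k)
          vin_i[ei_i[k]] += ei_x[k] * phi_e[j];
      }
    }
    for (int c = 0; c < Ne; ++c) {
      vin_e[c] = ((vin_e[c] - g_ie * phi_i[c]) -
                  kG * omega_G[area_of[c] - 1]) + ext[c];
    }
    // 3. membrane updates (noise drawn per excitatory cell, cell order)
    for (int c = 0; c < Ne; ++c) {
      double eta = unif_rand() - 0.5;
      V_e[c] = V_e[c] + inv_te * (-V_e[c] + k1 * (vin_e[c] + k2 * eta));
    }
    for (int c = 0; c < Ne; ++c) {
      V_i[c] = V_i[c] + inv_ti * (-V_i[c] + k1 * vin_i[c]);
    }
    // 4. low-pass updates
    std::fill(area_spk.begin(), area_spk.end(), 0.0);
    std::fill(area_serp.begin(), area_serp.end(), 0.0);
    bool finite = true;
    for (int c = 0; c < Ne; ++c) {
      omega[c] = omega[c] + inv_ta * (-omega[c] + phi_e[c]);
      omega_E[c] = omega_E[c] + inv_tf * (-omega_E[c] + phi_e[c]);
      oE_sum[c] += omega_E[c];
      int a = area_of[c] - 1;
      area_spk[a] += phi_e[c];
      area_serp[a] += V_e[c];
      if (!std::isfinite(V_e[c])) finite = false;
    }
    if (!finite) {
      stop("non-finite membrane potential at step %d", t0 + step + 1);
    }
    for (int a = 0; a < n_areas; ++a) {
      omega_G[a] = omega_G[a] + inv_tg * (-omega_G[a] + area_spk[a]);
      if (record) {
        serp(a, step) = area_serp[a];
        spikes(a, step) = area_spk[a];
      }
    }
    // 5. Hebbian update on every gated E->E synapse (pre or post spiked);
    //    updates are independent per synapse, so visiting spiking pres'
    //    columns plus spiking posts' rows (skipping spiking pres there)
    //    touches each gated synapse exactly once
    if (learn) {
      auto apply_rule = [&](int k, int pre, int post) {
        const double v = V_e[post];
        double dw = 0.0;
        if (omega_E[pre] >= th_pre) {
          if (v >= th_plus) dw = delta;            // LTP
          else if (v >= th_minus) dw = -delta;     // homosynaptic LTD
        } else if (v >= th_plus) {
          dw = -delta;                             // heterosynaptic LTD
        }
        if (dw != 0.0) {
          double w = ee_x[k] + dw;
          if (w < 0.0) w = 0.0; else if (w > w_max) w = w_max;
          ee_x[k] = w;
        }
      };
      for (int j = 0; j < Ne; ++j) {
        if (phi_e[j] != 1.0) continue;
        for (int k = ee_p[j]; k < ee_p[j + 1]; ++k) apply_rule(k, j, ee_i[k]);
      }
      for (int r = 0; r < Ne; ++r) {
        if (phi_e[r] != 1.0) continue;
        for (int q = row_ptr[r]; q < row_ptr[r + 1]; ++q) {
          const int k = row_entry[q];
          if (phi_e[ee_pre[k]] == 1.0) continue;   // handled in the pre pass
          apply_rule(k, ee_pre[k], r);
        }
      }
    }
  }
  for (int c = 0; c < Ne; ++c) oE_sum[c] /= n_steps;

  List out = List::create(
    _["V_e"] = V_e, _["V_i"] = V_i, _["omega"] = omega,
    _["omega_E"] = omega_E, _["omega_G"] = omega_G,
    _["phi_e"] = phi_e, _["phi_i"] = phi_i,
    _["ee_x"] = ee_x, _["omega_E_mean"] = oE_sum);
  if (record) {
    out["serp"] = serp;
    out["spikes"] = spikes;
  }
  return out;
}
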