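#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Forward-Euler integration of the two-cluster network: Morris-Lecar membranes
// driven by per-step Gaussian noise plus synaptic current I_syn = sum_i A_i y_i,
// with modified Tsodyks-Markram resource kinetics per presynaptic neuron.
// All efferent synapses of a neuron share identical kinetics in this model
// (only the strength A differs by target type), so one resource state per
// presynaptic neuron is exact.
//
// Adjacency is passed in CSR-by-presyn form: targets of neuron i are
// tgt_idx[tgt_ptr[i] .. tgt_ptr[i+1]-1] (0-based), with strengths tgt_w.
//
// nparams columns: gCa gK gL VCa VK VL V1 V2 V3 V4 Cm phi
// sparams columns: tau_rec tau_d tau_facil U0 u_dynamic
// [[Rcpp::export]]
List sim_core(IntegerVector tgt_ptr, IntegerVector tgt_idx, NumericVector tgt_w,
              NumericMatrix nparams, NumericMatrix sparams,
              double mu, double sigma,
              double dt, double duration_ms,
              double v_thresh, double refractory_ms,
              double v0_min, double v0_max,
              IntegerVector trace_ids, int trace_every,
              double v_bound) {
  const int n = nparams.nrow();
  const long nsteps = (long)std::floor(duration_ms / dt + 0.5);

  std::vector<double> V(n), W(n), x(n, 1.0), y(n, 0.0), z(n, 0.0), u(n);
  std::vector<double> last_spike(n, -1e18);
  std::vector<double> Isyn(n, 0.0);

  std::vector<double> gCa(n), gK(n), gL(n), VCa(n), VK(n), VL(n),
      V1(n), V2(n), V3(n), V4(n), Cm(n), phi(n);
  std::vector<double> tau_rec(n), tau_d(n), tau_facil(n), U0(n);
  std::vector<int> u_dyn(n);
  for (int i = 0; i < n; ++i) {
    gCa[i] = nparams(i, 0); gK[i] = nparams(i, 1); gL[i] = nparams(i, 2);
    VCa[i] = nparams(i, 3); VK[i] = nparams(i, 4); VL[i] = nparams(i, 5);
    V1[i] = nparams(i, 6);  V2[i] = nparams(i, 7); V3[i] = nparams(i, 8);
    V4[i] = nparams(i, 9);  Cm[i] = nparams(i, 10); phi[i] = nparams(i, 11);
    tau_rec[i] = sparams(i, 0); tau_d[i] = sparams(i, 1);
    tau_facil[i] = sparams(i, 2); U0[i] = sparams(i, 3);
    u_dyn[i] = sparams(i, 4) != 0.0;
    u[i] = U0[i];
  }

  RNGScope scope;
  for (int i = 0; i < n; ++i) {
    V[i] = R::runif(v0_min, v0_max);
    W[i] = 0.5 * (1.0 + std::tanh((V[i] - V3[i]) / V4[i]));
  }

  std::vector<int> sp_id;
  std::vector<double> sp_t;
  sp_id.reserve(1 << 16);
  sp_t.reserve(1 << 16);

  const int ntr = trace_ids.size();
  long ntr_rows = 0;
  if (ntr > 0 && trace_every > 0) ntr_rows = nsteps / trace_every + 1;
  NumericMatrix traces(ntr_rows, ntr);
  NumericVector trace_t(ntr_rows);
  long trow = 0;

  double cons_err = 0.0;
  const double y_eps = 1e-10;

  for (long k = 1; k <= nsteps; ++k) {
    const double t = k * dt;

    // synaptic currents from current active resources
    std::fill(Isyn.begin(), Isyn.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      const double yi = y[i];
      if (yi <= y_eps) continue;
      for (int p = tgt_ptr[i]; p < tgt_ptr[i + 1]; ++p)
        Isyn[tgt_idx[p]] += tgt_w[p] * yi;
    }

    for (int i = 0; i < n; ++i) {
      const double In = R::rnorm(mu, sigma);
      const double Vi = V[i], Wi = W[i];
      const double mss = 0.5 * (1.0 + std::tanh((Vi - V1[i]) / V2[i]));
      const double wss = 0.5 * (1.0 + std::tanh((Vi - V3[i]) / V4[i]));
      const double dV = (In + Isyn[i]
                         - gCa[i] * mss * (Vi - VCa[i])
                         - gK[i] * Wi * (Vi - VK[i])
                         - gL[i] * (Vi - VL[i])) / Cm[i];
      const double dW = phi[i] * (wss - Wi) * std::cosh((Vi - V3[i]) / (2.0 * V4[i]));
      const double Vn = Vi + dt * dV;
      W[i] = Wi + dt * dW;

      // synapse continuous kinetics (per presynaptic neuron)
      if (y[i] > y_eps || z[i] > y_eps || (u_dyn[i] && u[i] > y_eps)) {
        const double zc = std::min(std::max(z[i], 0.0), 1.0);
        const double rec = zc * (-std::tan(1.2 * zc - 1.2)) / tau_rec[i];
        const double dec = y[i] / tau_d[i];
        x[i] += dt * rec;
        y[i] += dt * (-dec);
        z[i] += dt * (dec - rec);
        if (u_dyn[i]) u[i] += dt * (-u[i] / tau_facil[i]);
        double s = x[i] + y[i] + z[i];
        double err = std::fabs(s - 1.0);
        if (err > cons_err) cons_err = err;
        x[i] = std::min(std::max(x[i], 0.0), 1.0);
        y[i] = std::min(std::max(y[i], 0.0), 1.0);
        z[i] = std::min(std::max(z[i], 0.0), 1.0);
        s = x[i] + y[i] + z[i];
        if (s > 0.0) { x[i] /= s; y[i] /= s; z[i] /= s; }
      }

      // spike: upward threshold crossing outside the refractory lockout
      if (Vn >= v_thresh && Vi < v_thresh && (t - last_spike[i]) > refractory_ms) {
        last_spike[i] = t;
        sp_id.push_back(i + 1);
        sp_t.push_back(t);
        if (u_dyn[i]) u[i] += U0[i] * (1.0 - u[i]);
        const double dx = u[i] * x[i];
        x[i] -= dx;
        y[i] += dx;
      }
      V[i] = Vn;
      if (!(std::fabs(Vn) < v_bound))
        stop("simulation diverged: |V| exceeded %.0f mV at t = %.1f ms", v_bound, t);
    }

    if (ntr_rows > 0 && (k % trace_every) == 0 && trow < ntr_rows) {
      for (int c = 0; c < ntr; ++c) traces(trow, c) = V[trace_ids[c]];
      trace_t[trow] = t;
      ++trow;
    }
  }

  List out = List::create(
      _["spike_id"] = wrap(sp_id),
      _["spike_t"] = wrap(sp_t),
      _["conservation_error"] = cons_err);
  if (ntr_rows > 0) {
    out["traces"] = traces(Range(0, std::max(trow - 1, 0L)), _);
    out["trace_t"] = trace_t[Range(0, std::max(trow - 1, 0L))];
  }
  return out;
}
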