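#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double clip01(double p) {
  if (p < 0.0) return 0.0;
  if (p > 1.0) return 1.0;
  return p;
}

// Discrete-time stochastic network: per-bin spike probability is
//   linear link : clip(r0 + alpha * sum_j M(i,j) S_j(t-1), 0, 1)
//   logistic    : sigmoid(r0 + alpha * sum_j M(i,j) S_j(t-1))
// M(i,j) is the drive from presynaptic j onto i (zero diagonal). The first
// bin uses the baseline only. Uses the R RNG so set.seed() governs runs.
// [[Rcpp::export]]
List cpp_simulate_net(NumericMatrix M, double r0, double alpha, int T,
                      bool logistic) {
  const int N = M.nrow();
  if (M.ncol() != N) stop("drive matrix must be square");
  std::vector<int> si, st;
  std::vector<int> prev, cur;
  std::vector<double> drive(N, 0.0);
  const double p_base = logistic ? 1.0 / (1.0 + std::exp(-r0)) : clip01(r0);

  for (int t = 0; t < T; ++t) {
    cur.clear();
    if (prev.empty()) {
      for (int i = 0; i < N; ++i)
        if (unif_rand() < p_base) cur.push_back(i);
    } else {
      std::fill(drive.begin(), drive.end(), 0.0);
      for (size_t s = 0; s < prev.size(); ++s) {
        const double* col = &M(0, prev[s]);
        for (int i = 0; i < N; ++i) drive[i] += col[i];
      }
      for (int i = 0; i < N; ++i) {
        double h = r0 + alpha * drive[i];
        double p = logistic ? 1.0 / (1.0 + std::exp(-h)) : clip01(h);
        if (unif_rand() < p) cur.push_back(i);
      }
    }
    for (size_t s = 0; s < cur.size(); ++s) {
      si.push_back(cur[s] + 1);  // 1-based neuron index
      st.push_back(t + 1);       // 1-based bin index
    }
    prev.swap(cur);
  }
  return List::create(_["i"] = wrap(si), _["t"] = wrap(st));
}

// Izhikevich network, forward Euler with the membrane potential advanced in
// two half-steps of dt/2 and the recovery variable in one step of dt.
// Synaptic input at each step is the weighted sum of the previous step's
// spikes. External input is a Gaussian noise process with a 1-ms
// correlation time: a fresh draw per neuron per millisecond, held constant
// across the integration steps inside that millisecond. Tying the noise
// path to the (fixed) output bin rather than to dt means refining dt only
// refines the ODE solve instead of changing the driving process.
// Adjacency is passed column-compressed by presynaptic source: targets of
// source j are tgt[src_ptr[j] .. src_ptr[j+1]-1] (0-based) with weights w.
// [[Rcpp::export]]
List cpp_simulate_izhikevich(int N, int steps, double dt,
                             double a, double b, double c_reset, double d_jump,
                             double v_thresh, double mu_ext, double sigma_ext,
                             IntegerVector src_ptr, IntegerVector tgt,
                             NumericVector w, int steps_per_ms) {
  std::vector<double> v(N, c_reset), u(N), syn(N, 0.0), syn_next(N, 0.0);
  std::vector<double> noise(N, 0.0);
  for (int i = 0; i < N; ++i) u[i] = b * v[i];
  std::vector<int> si, sstep;
  const double hdt = dt / 2.0;

  for (int tstep = 0; tstep < steps; ++tstep) {
    if (tstep % steps_per_ms == 0) {
      for (int i = 0; i < N; ++i) noise[i] = sigma_ext * norm_rand();
    }
    std::fill(syn_next.begin(), syn_next.end(), 0.0);
    for (int i = 0; i < N; ++i) {
      double I = mu_ext + noise[i] + syn[i];
      // two half-steps for v, one step for u
      v[i] += hdt * (0.04 * v[i] * v[i] + 5.0 * v[i] + 140.0 - u[i] + I);
      v[i] += hdt * (0.04 * v[i] * v[i] + 5.0 * v[i] + 140.0 - u[i] + I);
      u[i] += dt * a * (b * v[i] - u[i]);
      if (!std::isfinite(v[i]) || v[i] < -1e3) {
        stop("membrane potential diverged; use a smaller dt");
      }
      if (v[i] >= v_thresh) {
        v[i] = c_reset;
        u[i] += d_jump;
        si.push_back(i + 1);
        sstep.push_back(tstep + 1);
        for (int k = src_ptr[i]; k < src_ptr[i + 1]; ++k)
          syn_next[tgt[k]] += w[k];
      }
    }
    syn.swap(syn_next);
  }
  return List::create(_["i"] = wrap(si), _["step"] = wrap(sstep));
}
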