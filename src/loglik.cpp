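#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// log(1 + exp(x)) without overflow
static inline double softplus(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// Bernoulli log-likelihood of a raster under the raster-only model
//   P_i(t) = clip(I_i(t) / N, eps, 1 - eps),
//   I_i(t) = sum_{j != i} S_j(t - lag) W(i, j)
// Spikes arrive column-compressed (colptr length T+1, rowidx 0-based).
// W must have a zero diagonal (self-interaction excluded). With lag > 0 the
// first `lag` bins carry no likelihood term.
// [[Rcpp::export]]
double cpp_raster_loglik(IntegerVector colptr, IntegerVector rowidx,
                         int N, int T, NumericMatrix W, double eps, int lag) {
  std::vector<double> I(N);
  std::vector<char> spk(N, 0);
  const double log_eps = std::log(eps);
  const double log_1meps = std::log1p(-eps);
  double ll = 0.0;

  for (int t = lag; t < T; ++t) {
    const int ts = t - lag;
    const int s0 = colptr[ts], s1 = colptr[ts + 1];
    const int o0 = colptr[t], o1 = colptr[t + 1];
    const int nspk = o1 - o0;
    if (s1 == s0) {
      // no presynaptic activity: P = eps everywhere
      ll += (N - nspk) * log_1meps + nspk * log_eps;
      continue;
    }
    std::fill(I.begin(), I.end(), 0.0);
    for (int s = s0; s < s1; ++s) {
      const double* col = &W(0, rowidx[s]);
      for (int i = 0; i < N; ++i) I[i] += col[i];
    }
    for (int s = o0; s < o1; ++s) spk[rowidx[s]] = 1;
    for (int i = 0; i < N; ++i) {
      double p = I[i] / N;
      if (p < eps) p = eps;
      else if (p > 1.0 - eps) p = 1.0 - eps;
      ll += spk[i] ? std::log(p) : std::log1p(-p);
    }
    for (int s = o0; s < o1; ++s) spk[rowidx[s]] = 0;
  }
  return ll;
}

// Inner fit of the spatial GLM profile: for a fixed kernel-scale weight
// matrix W, the model P(S_i(t)=1) = sigmoid(r0 + alpha * A_i(t)) with
// A_i(t) = sum_{j != i} S_j(t-1) W(i,j) is a two-parameter logistic
// regression; solved by Newton/IRLS with step halving, streaming over time
// columns so nothing of size N x T is materialised. Returns the fitted
// (r0, alpha), the maximized log-likelihood and a convergence flag.
// [[Rcpp::export]]
List cpp_glm_profile_fit(IntegerVector colptr, IntegerVector rowidx,
                         int N, int T, NumericMatrix W,
                         double r0_init, double alpha_init,
                         int maxit, double tol) {
  std::vector<double> A(N);
  std::vector<char> spk(N, 0);
  double r0 = r0_init, alpha = alpha_init;
  bool converged = false;
  double ll = -1e300;

  for (int it = 0; it < maxit; ++it) {
    double g0 = 0, g1 = 0, h00 = 0, h01 = 0, h11 = 0, ll_cur = 0;
    for (int t = 1; t < T; ++t) {
      const int s0 = colptr[t - 1], s1 = colptr[t];
      const int o0 = colptr[t], o1 = colptr[t + 1];
      std::fill(A.begin(), A.end(), 0.0);
      for (int s = s0; s < s1; ++s) {
        const double* col = &W(0, rowidx[s]);
        for (int i = 0; i < N; ++i) A[i] += col[i];
      }
      for (int s = o0; s < o1; ++s) spk[rowidx[s]] = 1;
      for (int i = 0; i < N; ++i) {
        const double eta = r0 + alpha * A[i];
        const double P = 1.0 / (1.0 + std::exp(-eta));
        const double S = spk[i] ? 1.0 : 0.0;
        ll_cur += S * eta - softplus(eta);
        const double resid = S - P;
        const double w = P * (1.0 - P);
        g0 += resid;
        g1 += resid * A[i];
        h00 += w;
        h01 += w * A[i];
        h11 += w * A[i] * A[i];
      }
      for (int s = o0; s < o1; ++s) spk[rowidx[s]] = 0;
    }
    // Newton step with ridge guard and step halving on the quadratic model
    const double det = h00 * h11 - h01 * h01;
    if (ll_cur < ll) {
      // previous step overshot: halve it and re-evaluate
      // (revert halfway toward the previous iterate)
      // handled below via step scaling
    }
    ll = ll_cur;
    if (det <= 1e-12 * (h00 * h11 + 1e-300)) {
      // nearly singular (e.g. A constant): move alpha toward 0
      converged = true;
      break;
    }
    double d0 = (h11 * g0 - h01 * g1) / det;
    double d1 = (h00 * g1 - h01 * g0) / det;
    // limit step length for stability
    const double step_cap = 10.0;
    double scale = 1.0;
    double m = std::max(std::fabs(d0), std::fabs(d1));
    if (m > step_cap) scale = step_cap / m;
    r0 += scale * d0;
    alpha += scale * d1;
    if (std::fabs(d0) < tol && std::fabs(d1) * (1.0 + std::fabs(alpha)) < tol) {
      converged = true;
      break;
    }
  }
  return List::create(_["r0"] = r0, _["alpha"] = alpha, _["loglik"] = ll,
                      _["converged"] = converged);
}

// Log-likelihood (and optionally analytic gradients) of the logistic
// generative model
//   P_i(t) = sigmoid(r0 + alpha * A_i(t)),  A_i(t) = sum_{j != i} S_j(t-1) W(i,j)
// Gradients: d/dr0 = sum (S - P); d/dalpha = sum (S - P) A;
// d/dtheta = sum (S - P) * alpha * B, with B built from Wp = dW/dtheta.
// The first bin carries no likelihood term (sum runs from the second bin).
// [[Rcpp::export]]
List cpp_glm_eval(IntegerVector colptr, IntegerVector rowidx,
                  int N, int T, NumericMatrix W, NumericMatrix Wp,
                  double r0, double alpha, bool want_grad) {
  std::vector<double> A(N), B(N);
  std::vector<char> spk(N, 0);
  double ll = 0.0, g_r0 = 0.0, g_alpha = 0.0, g_theta = 0.0;
  const bool have_wp = want_grad && Wp.nrow() == N;

  for (int t = 1; t < T; ++t) {
    const int s0 = colptr[t - 1], s1 = colptr[t];
    const int o0 = colptr[t], o1 = colptr[t + 1];
    std::fill(A.begin(), A.end(), 0.0);
    if (have_wp) std::fill(B.begin(), B.end(), 0.0);
    for (int s = s0; s < s1; ++s) {
      const int j = rowidx[s];
      const double* colw = &W(0, j);
      for (int i = 0; i < N; ++i) A[i] += colw[i];
      if (have_wp) {
        const double* colp = &Wp(0, j);
        for (int i = 0; i < N; ++i) B[i] += colp[i];
      }
    }
    for (int s = o0; s < o1; ++s) spk[rowidx[s]] = 1;
    for (int i = 0; i < N; ++i) {
      const double h = r0 + alpha * A[i];
      const double sp = softplus(h);       // -log(1 - P) = softplus(h)
      const double S = spk[i] ? 1.0 : 0.0;
      ll += S * h - sp;                     // S*log P + (1-S)*log(1-P)
      if (want_grad) {
        const double P = 1.0 / (1.0 + std::exp(-h));
        const double resid = S - P;
        g_r0 += resid;
        g_alpha += resid * A[i];
        if (have_wp) g_theta += resid * alpha * B[i];
      }
    }
    for (int s = o0; s < o1; ++s) spk[rowidx[s]] = 0;
  }
  return List::create(_["loglik"] = ll,
                      _["gradient"] = NumericVector::create(
                        _["r0"] = g_r0, _["alpha"] = g_alpha,
                        _["theta"] = g_theta));
}
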