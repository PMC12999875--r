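#ifndef HUEFORAGE_MODEL_H
#define HUEFORAGE_MODEL_H

#include <cmath>
#include <cstring>
#include <vector>
#include <emmintrin.h>

// glibc vector math: 2-wide SSE exp (same image provides libmvec)
extern "C" __m128d _ZGVbN2v_exp(__m128d);

// Sequential-choice likelihood internals shared by the exported kernels and
// the sampler. The design matrix is candidate-major (K x N column-major), so
// one candidate's K predictor values are contiguous and an event's block
// stays in cache between the weight and gradient passes.

template <int KF>
static inline double event_ll_t(const double* xt, int a, int n,
                                const double* tl, int chosen,
                                double* eta, double* gacc /* K or nullptr */) {
  const double* xe = xt + (size_t)a * KF;
  for (int i = 0; i < n; ++i) {
    const double* xi = xe + (size_t)i * KF;
    double s = 0.0;
    for (int k = 0; k < KF; ++k) s -= xi[k] * tl[k];
    eta[i] = s;
  }
  double m = eta[0];
  for (int i = 1; i < n; ++i) if (eta[i] > m) m = eta[i];
  const double lsel = eta[chosen] - m;
  const __m128d mm = _mm_set1_pd(m);
  int i = 0;
  for (; i + 1 < n; i += 2) {
    __m128d v = _mm_sub_pd(_mm_loadu_pd(eta + i), mm);
    _mm_storeu_pd(eta + i, _ZGVbN2v_exp(v));
  }
  for (; i < n; ++i) eta[i] = std::exp(eta[i] - m);
  double Z = 0.0;
  for (int j = 0; j < n; ++j) Z += eta[j];
  if (gacc) {
    const double invZ = 1.0 / Z;
    for (int j = 0; j < n; ++j) {
      const double wi = eta[j] * invZ;
      const double* xi = xe + (size_t)j * KF;
      for (int k = 0; k < KF; ++k) gacc[k] += wi * xi[k];
    }
    const double* xc = xe + (size_t)chosen * KF;
    for (int k = 0; k < KF; ++k) gacc[k] -= xc[k];
  }
  return lsel - std::log(Z);
}

static inline double event_ll(const double* xt, int K, int a, int n,
                              const double* tl, int chosen,
                              double* eta, double* gacc) {
  switch (K) {
  case 4: return event_ll_t<4>(xt, a, n, tl, chosen, eta, gacc);
  case 3: return event_ll_t<3>(xt, a, n, tl, chosen, eta, gacc);
  case 2: return event_ll_t<2>(xt, a, n, tl, chosen, eta, gacc);
  default: return event_ll_t<1>(xt, a, n, tl, chosen, eta, gacc);
  }
}

// lower Cholesky factor of a correlation matrix from tanh-transformed
// canonical partial correlations (row-filling order); L is K x K col-major
static inline void chol_from_w(const double* w, int K, double* L) {
  std::memset(L, 0, sizeof(double) * K * K);
  L[0] = 1.0;
  int idx = 0;
  for (int i = 1; i < K; ++i) {
    double s = 1.0;
    for (int j = 0; j < i; ++j) {
      const double lij = w[idx++] * std::sqrt(s);
      L[j * K + i] = lij;
      s -= lij * lij;
    }
    L[i * K + i] = std::sqrt(s);
  }
}

// LKJ(eta) log kernel on L plus the log Jacobian of y -> L
static inline double corr_log_prior_w(const double* y, int K, double eta) {
  if (K < 2) return 0.0;
  double lp = 0.0;
  int idx = 0;
  for (int i = 1; i < K; ++i) {
    double s = 1.0;
    for (int j = 0; j < i; ++j) {
      const double w = std::tanh(y[idx++]);
      lp += std::log1p(-w * w) + 0.5 * std::log(s);
      s -= w * w * s;
    }
    lp += (K - (i + 1) + 2.0 * eta - 2.0) * 0.5 * std::log(s);
  }
  return lp;
}

// Hierarchical log posterior for the choice model.
// q = (beta[K], log_sigma[K], y[m], z[K*P]); priors: beta_k ~ N(loc, scale),
// sigma ~ Exponential(rate) (with log-Jacobian), corr ~ LKJ(lkj_eta),
// z ~ N(0, 1). The non-centered branch sets theta_p = beta + sigma L z_p.
// The correlation-transform block is differentiated by central differences
// (dimension at most 6); everything else is analytic.
struct HierModel {
  const double* X;
  const int* ptr;
  const int* chosen;
  const int* part;
  int nev;
  int K, P, m, dim;
  const double* loc;
  const double* scale;
  double rate, lkj_eta;
  bool use_lik;
  bool centered;  // random effects: theta_p directly (centered) or z_p
  double const_ll;
  std::vector<double> eta;  // candidate workspace

  void init_workspace() { eta.resize(256); }

  double lp_grad(const double* q, double* grad) {
    if (centered) return lp_grad_centered(q, grad);
    const double* beta = q;
    const double* ls = beta + K;
    const double* y = ls + K;
    const double* z = y + m;
    std::vector<double> sigma(K), w(m), L(K * K), theta(K * P), Lz(K * P);
    for (int k = 0; k < K; ++k) sigma[k] = std::exp(ls[k]);
    for (int u = 0; u < m; ++u) w[u] = std::tanh(y[u]);
    chol_from_w(w.data(), K, L.data());
    for (int p = 0; p < P; ++p)
      for (int i = 0; i < K; ++i) {
        double acc = 0.0;
        for (int j = 0; j <= i; ++j) acc += L[j * K + i] * z[p * K + j];
        Lz[p * K + i] = acc;
        theta[p * K + i] = beta[i] + sigma[i] * acc;
      }

    double ll = 0.0;
    std::vector<double> G(K * P, 0.0);
    if (use_lik) {
      for (int e = 0; e < nev; ++e) {
        const int a = ptr[e], n = ptr[e + 1] - a, p = part[e];
        if ((size_t)n > eta.size()) eta.resize(n);
        ll += event_ll(X, K, a, n, theta.data() + (size_t)p * K, chosen[e],
                       eta.data(), G.data() + (size_t)p * K);
      }
      ll += const_ll;
    }

    double lp = ll;
    const double half_l2pi = 0.9189385332046727;  // log(2*pi)/2
    for (int k = 0; k < K; ++k) {
      const double d = (beta[k] - loc[k]) / scale[k];
      lp += -half_l2pi - std::log(scale[k]) - 0.5 * d * d;
      lp += std::log(rate) - rate * sigma[k] + ls[k];
    }
    for (int i = 0; i < K * P; ++i) lp += -half_l2pi - 0.5 * z[i] * z[i];
    lp += corr_log_prior_w(y, K, lkj_eta);

    double* gb = grad;
    double* gls = gb + K;
    double* gy = gls + K;
    double* gz = gy + m;
    for (int k = 0; k < K; ++k) {
      double sb = 0.0, ss = 0.0;
      for (int p = 0; p < P; ++p) {
        sb += G[p * K + k];
        ss += G[p * K + k] * Lz[p * K + k];
      }
      gb[k] = sb - (beta[k] - loc[k]) / (scale[k] * scale[k]);
      gls[k] = ss * sigma[k] + 1.0 - rate * sigma[k];
    }
    for (int p = 0; p < P; ++p)
      for (int j = 0; j < K; ++j) {
        double acc = 0.0;
        for (int i = j; i < K; ++i) acc += L[j * K + i] * sigma[i] * G[p * K + i];
        gz[p * K + j] = acc - z[p * K + j];
      }
    if (m > 0) {
      std::vector<double> M(K * K, 0.0);
      for (int p = 0; p < P; ++p)
        for (int i = 0; i < K; ++i) {
          const double gi = sigma[i] * G[p * K + i];
          for (int j = 0; j <= i; ++j) M[j * K + i] += gi * z[p * K + j];
        }
      const double h = 1e-6;
      std::vector<double> yp(m), wp(m), Lp(K * K), Lm(K * K);
      for (int u = 0; u < m; ++u) {
        std::copy(y, y + m, yp.begin());
        yp[u] = y[u] + h;
        for (int v = 0; v < m; ++v) wp[v] = std::tanh(yp[v]);
        chol_from_w(wp.data(), K, Lp.data());
        const double cp = corr_log_prior_w(yp.data(), K, lkj_eta);
        yp[u] = y[u] - h;
        for (int v = 0; v < m; ++v) wp[v] = std::tanh(yp[v]);
        chol_from_w(wp.data(), K, Lm.data());
        const double cm = corr_log_prior_w(yp.data(), K, lkj_eta);
        double acc = 0.0;
        for (int i = 0; i < K * K; ++i) acc += M[i] * (Lp[i] - Lm[i]);
        gy[u] = acc / (2.0 * h) + (cp - cm) / (2.0 * h);
      }
    }
    return lp;
  }

  // theta_p - beta = sigma * (L u_p): forward/back solves for the MVN prior
  // of the centered parameterization, scalar prior term as a function of y
  double mvn_prior_term(const double* y_in, const double* beta,
                        const double* sigma, const double* theta) const {
    std::vector<double> w(m), L(K * K), v(K), u(K);
    for (int t = 0; t < m; ++t) w[t] = std::tanh(y_in[t]);
    chol_from_w(w.data(), K, L.data());
    double ldet = 0.0;
    for (int k = 0; k < K; ++k) ldet += std::log(L[k * K + k]);
    double quad = 0.0;
    for (int p = 0; p < P; ++p) {
      for (int k = 0; k < K; ++k) v[k] = (theta[p * K + k] - beta[k]) / sigma[k];
      for (int i = 0; i < K; ++i) {           // forward solve L u = v
        double acc = v[i];
        for (int j = 0; j < i; ++j) acc -= L[j * K + i] * u[j];
        u[i] = acc / L[i * K + i];
      }
      for (int k = 0; k < K; ++k) quad += u[k] * u[k];
    }
    return -0.5 * quad - P * ldet + corr_log_prior_w(y_in, K, lkj_eta);
  }

  double lp_grad_centered(const double* q, double* grad) {
    const double* beta = q;
    const double* ls = beta + K;
    const double* y = ls + K;
    const double* theta = y + m;  // K x P participant coefficients
    std::vector<double> sigma(K), w(m), L(K * K);
    for (int k = 0; k < K; ++k) sigma[k] = std::exp(ls[k]);
    for (int u = 0; u < m; ++u) w[u] = std::tanh(y[u]);
    chol_from_w(w.data(), K, L.data());

    double ll = 0.0;
    std::vector<double> G(K * P, 0.0);
    if (use_lik) {
      for (int e = 0; e < nev; ++e) {
        const int a = ptr[e], n = ptr[e + 1] - a, p = part[e];
        if ((size_t)n > eta.size()) eta.resize(n);
        ll += event_ll(X, K, a, n, theta + (size_t)p * K, chosen[e],
                       eta.data(), G.data() + (size_t)p * K);
      }
      ll += const_ll;
    }

    double lp = ll;
    const double half_l2pi = 0.9189385332046727;
    for (int k = 0; k < K; ++k) {
      const double dv = (beta[k] - loc[k]) / scale[k];
      lp += -half_l2pi - std::log(scale[k]) - 0.5 * dv * dv;
      lp += std::log(rate) - rate * sigma[k] + ls[k];
    }
    // MVN(beta, D L L' D) prior on theta_p
    double ldet = 0.0;
    for (int k = 0; k < K; ++k)
      ldet += std::log(sigma[k]) + std::log(L[k * K + k]);
    lp += -(double)(K * P) * half_l2pi - P * ldet;
    lp += corr_log_prior_w(y, K, lkj_eta);

    double* gb = grad;
    double* gls = gb + K;
    double* gy = gls + K;
    double* gt = gy + m;
    for (int k = 0; k < K; ++k) {
      gb[k] = -(beta[k] - loc[k]) / (scale[k] * scale[k]);
      gls[k] = 1.0 - rate * sigma[k] - P;
    }
    std::vector<double> v(K), u(K), wv(K);
    double quad = 0.0;
    for (int p = 0; p < P; ++p) {
      for (int k = 0; k < K; ++k) v[k] = (theta[p * K + k] - beta[k]) / sigma[k];
      for (int i = 0; i < K; ++i) {           // forward solve L u = v
        double acc = v[i];
        for (int j = 0; j < i; ++j) acc -= L[j * K + i] * u[j];
        u[i] = acc / L[i * K + i];
      }
      for (int k = 0; k < K; ++k) quad += u[k] * u[k];
      for (int i = K - 1; i >= 0; --i) {      // back solve L' wv = u
        double acc = u[i];
        for (int j = i + 1; j < K; ++j) acc -= L[i * K + j] * wv[j];
        wv[i] = acc / L[i * K + i];
      }
      for (int k = 0; k < K; ++k) {
        gt[p * K + k] = G[p * K + k] - wv[k] / sigma[k];
        gb[k] += wv[k] / sigma[k];
        gls[k] += wv[k] * v[k];
      }
    }
    lp += -0.5 * quad;
    if (m > 0) {
      const double h = 1e-6;
      std::vector<double> yp(m);
      for (int t = 0; t < m; ++t) {
        std::copy(y, y + m, yp.begin());
        yp[t] = y[t] + h;
        const double fp = mvn_prior_term(yp.data(), beta, sigma.data(), theta);
        yp[t] = y[t] - h;
        const double fm = mvn_prior_term(yp.data(), beta, sigma.data(), theta);
        gy[t] = (fp - fm) / (2.0 * h);
      }
    }
    return lp;
  }
};

#endif
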