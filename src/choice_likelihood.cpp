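#include <Rcpp.h>
#include "model.h"
using namespace Rcpp;

// Exported wrappers around the shared kernels in model.h.
//
// Events are the click-2+ selection opportunities of a dataset, flattened:
// X holds one predictor column per candidate item (K x N), grouped by event;
// ptr gives 0-based offsets (length n_events + 1); chosen is the 0-based
// offset of the selected item within its event; part is the 0-based
// participant index per event. Weights are w_i = exp(-x_i . theta_p);
// per-event log-probabilities use the max-shifted log-sum-exp.

// [[Rcpp::export]]
List cf_event_ll_grad(const NumericMatrix& X, const IntegerVector& ptr,
                      const IntegerVector& chosen, const IntegerVector& part,
                      const NumericMatrix& Theta) {
  const int nev = ptr.size() - 1;
  const int K = Theta.nrow();
  const int P = Theta.ncol();
  NumericMatrix G(K, P);
  double* g = REAL(G);
  const double* x = REAL(X);
  const double* th = REAL(Theta);
  const int* pp = INTEGER(ptr);
  const int* pc = INTEGER(chosen);
  const int* pt = INTEGER(part);
  double ll = 0.0;
  std::vector<double> eta(256);
  for (int e = 0; e < nev; ++e) {
    const int a = pp[e], n = pp[e + 1] - a, p = pt[e];
    if ((size_t)n > eta.size()) eta.resize(n);
    ll += event_ll(x, K, a, n, th + (size_t)p * K, pc[e],
                   eta.data(), g + (size_t)p * K);
  }
  return List::create(_["ll"] = ll, _["G"] = G);
}

// Per-event log-probabilities at a single Theta (K x P).
// [[Rcpp::export]]
NumericVector cf_event_ll(const NumericMatrix& X, const IntegerVector& ptr,
                          const IntegerVector& chosen, const IntegerVector& part,
                          const NumericMatrix& Theta) {
  const int nev = ptr.size() - 1;
  const int K = Theta.nrow();
  NumericVector out(nev);
  double* o = REAL(out);
  const double* x = REAL(X);
  const double* th = REAL(Theta);
  const int* pp = INTEGER(ptr);
  const int* pc = INTEGER(chosen);
  const int* pt = INTEGER(part);
  std::vector<double> eta(256);
  for (int e = 0; e < nev; ++e) {
    const int a = pp[e], n = pp[e + 1] - a;
    if ((size_t)n > eta.size()) eta.resize(n);
    o[e] = event_ll(x, K, a, n, th + (size_t)pt[e] * K, pc[e],
                    eta.data(), nullptr);
  }
  return out;
}

// Per-event log-probabilities for S posterior draws of Theta.
// theta_draws has dimensions (K, P, S) flattened column-major; returns an
// S x n_events matrix.
// [[Rcpp::export]]
NumericMatrix cf_event_ll_draws(const NumericMatrix& X, const IntegerVector& ptr,
                                const IntegerVector& chosen, const IntegerVector& part,
                                const NumericVector& theta_draws,
                                const int K, const int P, const int S) {
  const int nev = ptr.size() - 1;
  NumericMatrix out(S, nev);
  double* o = REAL(out);
  const double* x = REAL(X);
  const double* td = REAL(theta_draws);
  const int* pp = INTEGER(ptr);
  const int* pc = INTEGER(chosen);
  const int* pt = INTEGER(part);
  std::vector<double> eta(256);
  for (int s = 0; s < S; ++s) {
    const double* th = td + (size_t)s * K * P;
    for (int e = 0; e < nev; ++e) {
      const int a = pp[e], n = pp[e + 1] - a;
      if ((size_t)n > eta.size()) eta.resize(n);
      o[(size_t)e * S + s] = event_ll(x, K, a, n, th + (size_t)pt[e] * K,
                                      pc[e], eta.data(), nullptr);
    }
  }
  return out;
}

static HierModel make_model(const NumericMatrix& X, const IntegerVector& ptr,
                            const IntegerVector& chosen, const IntegerVector& part,
                            int K, int P, const NumericVector& loc,
                            const NumericVector& scale, double rate,
                            double lkj_eta, bool use_lik, double const_ll,
                            bool centered) {
  HierModel M;
  M.X = REAL(X);
  M.ptr = INTEGER(ptr);
  M.chosen = INTEGER(chosen);
  M.part = INTEGER(part);
  M.nev = ptr.size() - 1;
  M.K = K;
  M.P = P;
  M.m = K * (K - 1) / 2;
  M.dim = 2 * K + M.m + K * P;
  M.loc = REAL(loc);
  M.scale = REAL(scale);
  M.rate = rate;
  M.lkj_eta = lkj_eta;
  M.use_lik = use_lik;
  M.centered = centered;
  M.const_ll = const_ll;
  M.init_workspace();
  return M;
}

// Full non-centered hierarchical log posterior and gradient (see model.h).
// [[Rcpp::export]]
List hier_lp_grad(const NumericVector& q, const NumericMatrix& X,
                  const IntegerVector& ptr, const IntegerVector& chosen,
                  const IntegerVector& part, const int K, const int P,
                  const NumericVector& loc, const NumericVector& scale,
                  const double rate, const double lkj_eta,
                  const bool use_lik, const double const_ll,
                  const bool centered) {
  HierModel M = make_model(X, ptr, chosen, part, K, P, loc, scale, rate,
                           lkj_eta, use_lik, const_ll, centered);
  NumericVector grad(M.dim);
  const double lp = M.lp_grad(REAL(q), REAL(grad));
  return List::create(_["lp"] = lp, _["grad"] = grad);
}

// ---- No-U-Turn sampler -----------------------------------------------------
//
// Mirrors the reference R implementation in R/nuts.R step for step,
// including the order of RNG calls, so the two samplers produce identical
// chains from the same R random seed.

namespace {

// in-place lower Cholesky of a symmetric positive-definite matrix
// (col-major); returns false if a non-positive pivot is hit
bool cholesky_lower(const std::vector<double>& A, int d, std::vector<double>& L) {
  L.assign((size_t)d * d, 0.0);
  for (int c = 0; c < d; ++c) {
    double sdiag = A[(size_t)c * d + c];
    for (int k = 0; k < c; ++k) sdiag -= L[(size_t)k * d + c] * L[(size_t)k * d + c];
    if (!(sdiag > 0.0)) return false;
    const double lcc = std::sqrt(sdiag);
    L[(size_t)c * d + c] = lcc;
    for (int r = c + 1; r < d; ++r) {
      double acc = A[(size_t)c * d + r];
      for (int k = 0; k < c; ++k) acc -= L[(size_t)k * d + c] * L[(size_t)k * d + r];
      L[(size_t)c * d + r] = acc / lcc;
    }
  }
  return true;
}

struct Sampler {
  HierModel* M;
  int d;
  std::vector<double> inv_mass;   // diagonal metric (inverse mass)
  bool dense = false;             // dense metric active?
  std::vector<double> Minv;       // dense inverse mass (d x d, col-major)
  std::vector<double> Lch;        // lower Cholesky factor of Minv
  double dmax;

  // out = Minv * r
  void apply_minv(const double* r, double* out) const {
    for (int i = 0; i < d; ++i) out[i] = 0.0;
    for (int c = 0; c < d; ++c) {
      const double rc = r[c];
      const double* col = Minv.data() + (size_t)c * d;
      for (int i = 0; i < d; ++i) out[i] += col[i] * rc;
    }
  }

  double kinetic(const double* r) const {
    if (dense) {
      // 0.5 * || L' r ||^2 with Minv = L L'
      double k = 0.0;
      for (int c = 0; c < d; ++c) {
        double t = 0.0;
        const double* col = Lch.data() + (size_t)c * d;
        for (int j = c; j < d; ++j) t += col[j] * r[j];
        k += t * t;
      }
      return 0.5 * k;
    }
    // long-double accumulation and operation order match base R's sum()
    long double k = 0.0;
    for (int i = 0; i < d; ++i) k += inv_mass[i] * r[i] * r[i];
    return 0.5 * (double)k;
  }

  // momentum ~ N(0, Minv^{-1})
  void draw_momentum(double* r) const {
    if (!dense) {
      for (int i = 0; i < d; ++i) r[i] = R::norm_rand() / std::sqrt(inv_mass[i]);
      return;
    }
    // solve L' r = z by back substitution
    std::vector<double> z(d);
    for (int i = 0; i < d; ++i) z[i] = R::norm_rand();
    for (int i = d - 1; i >= 0; --i) {
      double acc = z[i];
      const double* col = Lch.data() + (size_t)i * d;
      for (int j = i + 1; j < d; ++j) acc -= col[j] * r[j];
      r[i] = acc / col[i];
    }
  }

  // one leapfrog step in place; returns lp
  double leapfrog(double* q, double* r, double* grad, double eps) {
    for (int i = 0; i < d; ++i) r[i] += (eps / 2) * grad[i];
    if (dense) {
      std::vector<double> v(d);
      apply_minv(r, v.data());
      for (int i = 0; i < d; ++i) q[i] += eps * v[i];
    } else {
      for (int i = 0; i < d; ++i) q[i] += eps * (inv_mass[i] * r[i]);
    }
    double lp = M->lp_grad(q, grad);
    bool ok = std::isfinite(lp);
    if (ok) for (int i = 0; i < d; ++i) if (!std::isfinite(grad[i])) { ok = false; break; }
    if (!ok) {
      lp = -std::numeric_limits<double>::infinity();
      std::fill(grad, grad + d, 0.0);
    }
    for (int i = 0; i < d; ++i) r[i] += (eps / 2) * grad[i];
    return lp;
  }

  bool no_uturn(const double* qm, const double* qp,
                const double* rm, const double* rp) const {
    if (dense) {
      std::vector<double> vm(d), vp(d);
      apply_minv(rm, vm.data());
      apply_minv(rp, vp.data());
      double a = 0.0, b = 0.0;
      for (int i = 0; i < d; ++i) {
        const double dq = qp[i] - qm[i];
        a += dq * vm[i];
        b += dq * vp[i];
      }
      return a >= 0.0 && b >= 0.0;
    }
    long double a = 0.0, b = 0.0;
    for (int i = 0; i < d; ++i) {
      const double dq = qp[i] - qm[i];
      a += dq * (inv_mass[i] * rm[i]);
      b += dq * (inv_mass[i] * rp[i]);
    }
    return (double)a >= 0.0 && (double)b >= 0.0;
  }

  double find_epsilon(const double* q0, double lp0, const double* grad0) {
    double eps = 0.1;
    std::vector<double> r0(d), q(d), r(d), g(d);
    draw_momentum(r0.data());
    const double j0 = lp0 - kinetic(r0.data());
    std::copy(q0, q0 + d, q.begin());
    std::copy(r0.begin(), r0.end(), r.begin());
    std::copy(grad0, grad0 + d, g.begin());
    double lp = leapfrog(q.data(), r.data(), g.data(), eps);
    double la = lp - kinetic(r.data()) - j0;
    if (!std::isfinite(la)) la = -std::numeric_limits<double>::infinity();
    const double a = (la > std::log(0.5)) ? 1.0 : -1.0;
    for (int it = 0; it < 50; ++it) {
      if (!(a * la > -a * std::log(2.0))) break;
      eps *= std::pow(2.0, a);
      std::copy(q0, q0 + d, q.begin());
      std::copy(r0.begin(), r0.end(), r.begin());
      std::copy(grad0, grad0 + d, g.begin());
      lp = leapfrog(q.data(), r.data(), g.data(), eps);
      la = lp - kinetic(r.data()) - j0;
      if (!std::isfinite(la)) la = -std::numeric_limits<double>::infinity();
    }
    return eps;
  }

  struct Tree {
    std::vector<double> qm, rm, gm, qp, rp, gp, qprop, gprop;
    double lpm, lpp, lpprop;
    long n;
    bool s, div;
    double alpha;
    long nalpha;
  };

  Tree build_tree(const double* q, const double* r, const double* g, double lp,
                  double log_u, int v, int j, double eps, double joint0) {
    if (j == 0) {
      Tree t;
      t.qm.assign(q, q + d);
      t.rm.assign(r, r + d);
      t.gm.assign(g, g + d);
      const double lp1 = leapfrog(t.qm.data(), t.rm.data(), t.gm.data(), v * eps);
      double joint = lp1 - kinetic(t.rm.data());
      if (!std::isfinite(joint)) joint = -std::numeric_limits<double>::infinity();
      t.qp = t.qm; t.rp = t.rm; t.gp = t.gm;
      t.qprop = t.qm; t.gprop = t.gm;
      t.lpm = t.lpp = t.lpprop = lp1;
      t.n = (log_u <= joint) ? 1 : 0;
      t.div = (joint - log_u) < -dmax;
      t.s = !t.div;
      t.alpha = std::min(1.0, std::exp(joint - joint0));
      if (!std::isfinite(t.alpha)) t.alpha = 0.0;
      t.nalpha = 1;
      return t;
    }
    Tree t1 = build_tree(q, r, g, lp, log_u, v, j - 1, eps, joint0);
    if (!t1.s) return t1;
    Tree t2 = (v == -1)
      ? build_tree(t1.qm.data(), t1.rm.data(), t1.gm.data(), t1.lpm,
                   log_u, v, j - 1, eps, joint0)
      : build_tree(t1.qp.data(), t1.rp.data(), t1.gp.data(), t1.lpp,
                   log_u, v, j - 1, eps, joint0);
    if (v == -1) {
      t1.qm = t2.qm; t1.rm = t2.rm; t1.gm = t2.gm; t1.lpm = t2.lpm;
    } else {
      t1.qp = t2.qp; t1.rp = t2.rp; t1.gp = t2.gp; t1.lpp = t2.lpp;
    }
    const long ntot = t1.n + t2.n;
    if (t2.n > 0 && unif_rand() < (double)t2.n / (double)ntot) {
      t1.qprop = t2.qprop; t1.gprop = t2.gprop; t1.lpprop = t2.lpprop;
    }
    t1.n = ntot;
    t1.alpha += t2.alpha;
    t1.nalpha += t2.nalpha;
    t1.div = t1.div || t2.div;
    t1.s = t2.s && no_uturn(t1.qm.data(), t1.qp.data(), t1.rm.data(), t1.rp.data());
    return t1;
  }
};

}  // namespace

// [[Rcpp::export]]
List nuts_chain_cpp(const NumericVector& q0_, const NumericMatrix& X,
                    const IntegerVector& ptr, const IntegerVector& chosen,
                    const IntegerVector& part, const int K, const int P,
                    const NumericVector& loc, const NumericVector& scale,
                    const double rate, const double lkj_eta,
                    const bool use_lik, const double const_ll,
                    const int n_warmup, const int n_draws,
                    const int max_treedepth, const int warmup_treedepth,
                    const double adapt_delta,
                    int init_buffer, int term_buffer, int base_window,
                    const double max_delta_energy, const bool dense_metric,
                    const bool centered) {
  HierModel M = make_model(X, ptr, chosen, part, K, P, loc, scale, rate,
                           lkj_eta, use_lik, const_ll, centered);
  Sampler S;
  S.M = &M;
  S.d = M.dim;
  S.inv_mass.assign(M.dim, 1.0);
  S.dmax = max_delta_energy;
  const int d = M.dim;

  std::vector<double> q(REAL(q0_), REAL(q0_) + d), grad(d);
  double lp = M.lp_grad(q.data(), grad.data());
  if (!std::isfinite(lp))
    stop("initial point has non-finite log density");

  // dual averaging
  double eps = S.find_epsilon(q.data(), lp, grad.data());
  double da_mu = std::log(10.0 * eps);
  double da_h = 0.0, da_leps_bar = 0.0;
  long da_count = 0;
  const double gamma = 0.05, t0 = 10.0, kappa = 0.75;
  const double delta = adapt_delta;

  // mass adaptation windows
  if (n_warmup > 0 && init_buffer + term_buffer + base_window > n_warmup) {
    init_buffer = std::max(1, (int)std::floor(0.15 * n_warmup));
    term_buffer = std::max(1, (int)std::floor(0.10 * n_warmup));
    base_window = std::max(1, n_warmup - init_buffer - term_buffer);
  }
  std::vector<int> window_ends;
  if (n_warmup > init_buffer + term_buffer) {
    int pos = init_buffer, w = base_window;
    while (pos + w <= n_warmup - term_buffer) {
      int e = pos + w;
      if (pos + 3 * w > n_warmup - term_buffer) e = n_warmup - term_buffer;
      window_ends.push_back(e);
      pos = e;
      w *= 2;
    }
  }
  long welford_n = 0;
  std::vector<double> welford_m(d, 0.0), welford_s(d, 0.0);
  std::vector<double> welford_c;
  if (dense_metric) welford_c.assign((size_t)d * d, 0.0);

  NumericMatrix draws(n_draws, d);
  NumericVector lp_out(n_draws);
  IntegerVector td_out(n_draws);
  long n_div = 0;
  double accept_sum = 0.0;

  std::vector<double> r0(d), qm(d), qp(d), rm(d), rp(d), gm(d), gp(d);
  std::vector<double> qprop(d), gprop(d);

  const int n_total = n_warmup + n_draws;
  for (int it = 1; it <= n_total; ++it) {
    S.draw_momentum(r0.data());
    const double joint0 = lp - S.kinetic(r0.data());
    const double log_u = joint0 - exp_rand();
    qm = q; qp = q; rm = r0; rp = r0; gm = grad; gp = grad;
    double lpm = lp, lpp = lp;
    qprop = q; gprop = grad;
    double lpprop = lp;
    long n = 1;
    bool s = true;
    int j = 0;
    double alpha = 0.0;
    long nalpha = 0;
    bool diverged = false;
    const int cap = (it <= n_warmup) ? warmup_treedepth : max_treedepth;
    while (s && j < cap) {
      const int v = (unif_rand() < 0.5) ? -1 : 1;
      Sampler::Tree tt = (v == -1)
        ? S.build_tree(qm.data(), rm.data(), gm.data(), lpm, log_u, v, j, eps, joint0)
        : S.build_tree(qp.data(), rp.data(), gp.data(), lpp, log_u, v, j, eps, joint0);
      if (v == -1) {
        qm = tt.qm; rm = tt.rm; gm = tt.gm; lpm = tt.lpm;
      } else {
        qp = tt.qp; rp = tt.rp; gp = tt.gp; lpp = tt.lpp;
      }
      if (tt.s && tt.n > 0 &&
          unif_rand() < std::min(1.0, (double)tt.n / (double)n)) {
        qprop = tt.qprop; gprop = tt.gprop; lpprop = tt.lpprop;
      }
      n += tt.n;
      alpha += tt.alpha;
      nalpha += tt.nalpha;
      diverged = diverged || tt.div;
      s = tt.s && S.no_uturn(qm.data(), qp.data(), rm.data(), rp.data());
      ++j;
    }
    q = qprop;
    grad = gprop;
    lp = lpprop;
    const double astat = (nalpha > 0) ? alpha / (double)nalpha : 0.0;

    if (it <= n_warmup) {
      da_count += 1;
      da_h = (1.0 - 1.0 / (da_count + t0)) * da_h + (delta - astat) / (da_count + t0);
      const double leps = da_mu - std::sqrt((double)da_count) / gamma * da_h;
      const double wda = std::pow((double)da_count, -kappa);
      da_leps_bar = wda * leps + (1.0 - wda) * da_leps_bar;
      eps = std::exp(leps);
      if (it > init_buffer && it <= n_warmup - term_buffer) {
        welford_n += 1;
        std::vector<double> dlt(d);
        for (int i = 0; i < d; ++i) {
          dlt[i] = q[i] - welford_m[i];
          welford_m[i] += dlt[i] / welford_n;
          welford_s[i] += dlt[i] * (q[i] - welford_m[i]);
        }
        if (dense_metric)
          for (int cj = 0; cj < d; ++cj) {
            const double dj = q[cj] - welford_m[cj];
            double* col = welford_c.data() + (size_t)cj * d;
            for (int i = 0; i < d; ++i) col[i] += dlt[i] * dj;
          }
      }
      bool at_window_end = false;
      for (int e : window_ends) if (e == it) { at_window_end = true; break; }
      if (at_window_end && welford_n > 2) {
        const double shrink = (double)welford_n / (welford_n + 5);
        const double ridge = 1e-3 * (5.0 / (welford_n + 5));
        for (int i = 0; i < d; ++i) {
          const double v_est = welford_s[i] / (welford_n - 1);
          S.inv_mass[i] = v_est * shrink + ridge;
        }
        if (dense_metric && welford_n >= 2 * d) {
          std::vector<double> Sig((size_t)d * d);
          for (size_t i = 0; i < Sig.size(); ++i)
            Sig[i] = welford_c[i] / (welford_n - 1) * shrink;
          for (int i = 0; i < d; ++i) Sig[(size_t)i * d + i] += ridge;
          std::vector<double> L;
          bool ok = cholesky_lower(Sig, d, L);
          for (int tries = 0; !ok && tries < 3; ++tries) {
            for (int i = 0; i < d; ++i) Sig[(size_t)i * d + i] += 1e-6 * (tries + 1);
            ok = cholesky_lower(Sig, d, L);
          }
          if (ok) {
            S.Minv = Sig;
            S.Lch = L;
            S.dense = true;
          } else {
            // fall back to the diagonal estimate for this window
            S.dense = false;
          }
          std::fill(welford_c.begin(), welford_c.end(), 0.0);
        }
        welford_n = 0;
        std::fill(welford_m.begin(), welford_m.end(), 0.0);
        std::fill(welford_s.begin(), welford_s.end(), 0.0);
        eps = S.find_epsilon(q.data(), lp, grad.data());
        da_mu = std::log(10.0 * eps);
        da_h = 0.0; da_leps_bar = 0.0; da_count = 0;
      }
      if (it == n_warmup) eps = std::exp(da_leps_bar);
    } else {
      const int k = it - n_warmup - 1;
      for (int i = 0; i < d; ++i) draws(k, i) = q[i];
      lp_out[k] = lp;
      td_out[k] = j;
      if (diverged) ++n_div;
      accept_sum += astat;
    }
  }

  return List::create(
    _["draws"] = draws, _["lp"] = lp_out, _["divergences"] = (int)n_div,
    _["treedepth"] = td_out, _["stepsize"] = eps,
    _["inv_mass"] = NumericVector(S.inv_mass.begin(), S.inv_mass.end()),
    _["accept_rate"] = accept_sum / std::max(1, n_draws));
}
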