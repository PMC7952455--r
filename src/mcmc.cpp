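// Hamiltonian Monte Carlo for cumulative probability (proportional-odds) models.
//
// Two posteriors are implemented on unconstrained scales:
//   * single-level ordinal logit: cutpoints (first free, positive gaps) + slope,
//     Normal(0, prior_sd) priors on cutpoint values and slope;
//   * hierarchical ordinal logit: population cutpoints/slope, per-cutpoint and
//     slope scales with Exponential priors, an LKJ(eta)-priored correlation over
//     the joint per-taxon effect vector (K-1 cutpoint offsets + slope offset),
//     and non-centered standard-normal taxon effects.
//
// Gradients are analytic except for the 6 canonical-partial-correlation
// coordinates of the correlation Cholesky, which enter the posterior only
// through a cheap m x m construction; that block is differentiated centrally
// at negligible cost. Randomness flows through R's RNG (RNGScope), so draws
// are reproducible under set.seed().

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <functional>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// log standard logistic CDF, stable in both tails
static inline double log_plogis(double z) {
  if (z > 0.0) return -log1p(std::exp(-z));
  return z - log1p(std::exp(z));
}

static inline double plogis_(double z) {
  if (z > 0.0) return 1.0 / (1.0 + std::exp(-z));
  double e = std::exp(z);
  return e / (1.0 + e);
}

// one ordinal observation: log density and its derivatives w.r.t. the linear
// terms eta_k = alpha_k - b*x at the (at most two) cutpoints involved.
// Returns the log density; d_lo is d/d eta_{y-1}, d_hi is d/d eta_y.
static inline double ordinal_ll_grad(const double* eta, int K, int y,
                                     double& d_lo, double& d_hi) {
  d_lo = d_hi = 0.0;
  if (y == 1) {
    double F = plogis_(eta[0]);
    d_hi = 1.0 - F;                 // d log F / d eta
    return log_plogis(eta[0]);
  }
  if (y == K) {
    double F = plogis_(eta[K - 2]);
    d_lo = -F;                      // d log(1-F) / d eta
    return log_plogis(-eta[K - 2]);
  }
  double Fu = plogis_(eta[y - 1]), Fl = plogis_(eta[y - 2]);
  double p = Fu - Fl;
  if (p <= 0.0 || !std::isfinite(p)) return NEG_INF;
  d_hi = Fu * (1.0 - Fu) / p;
  d_lo = -Fl * (1.0 - Fl) / p;
  return std::log(p);
}

// ---------------------------------------------------------------------------
// single-level model
// ---------------------------------------------------------------------------

struct CpmData {
  std::vector<double> x;
  std::vector<int> y;  // 1..K
  int K;
  double cut_sd, slope_sd;
};

// theta: [a1, log-gap_2..log-gap_{K-1}, beta], length K.
// Fills grad (length K) when non-null; returns the joint log density.
static double cpm_logpost_grad(const double* theta, const CpmData& d,
                               double* grad) {
  const int K = d.K;
  std::vector<double> alpha(K - 1), galpha(K - 1, 0.0);
  alpha[0] = theta[0];
  double lp = 0.0;
  for (int k = 1; k < K - 1; ++k) {
    alpha[k] = alpha[k - 1] + std::exp(theta[k]);
    lp += theta[k];  // Jacobian of the log-gap transform
  }
  for (int k = 0; k < K - 1; ++k) {
    lp += R::dnorm(alpha[k], 0.0, d.cut_sd, 1);
    galpha[k] = -alpha[k] / (d.cut_sd * d.cut_sd);
  }
  double beta = theta[K - 1];
  lp += R::dnorm(beta, 0.0, d.slope_sd, 1);
  double gbeta = -beta / (d.slope_sd * d.slope_sd);

  const int n = (int)d.x.size();
  std::vector<double> eta(K - 1);
  for (int i = 0; i < n; ++i) {
    double bx = beta * d.x[i];
    for (int k = 0; k < K - 1; ++k) eta[k] = alpha[k] - bx;
    double dlo, dhi;
    double ll = ordinal_ll_grad(eta.data(), K, d.y[i], dlo, dhi);
    if (ll == NEG_INF) return NEG_INF;
    lp += ll;
    int y = d.y[i];
    if (y < K) galpha[y - 1] += dhi;
    if (y > 1) galpha[y - 2] += dlo;
    gbeta -= d.x[i] * (dlo + dhi);
  }
  if (grad) {
    // a1 feeds every alpha; gap g_k feeds alpha_{k..K-2} scaled by exp(g_k)
    double tail = 0.0;
    for (int k = K - 2; k >= 1; --k) {
      tail += galpha[k];
      grad[k] = std::exp(theta[k]) * tail + 1.0;
    }
    grad[0] = tail + galpha[0];
    grad[K - 1] = gbeta;
  }
  return lp;
}

// ---------------------------------------------------------------------------
// hierarchical model
// ---------------------------------------------------------------------------

struct HierData {
  std::vector<double> x;
  std::vector<int> y;    // 1..K
  std::vector<int> tax;  // 0..J-1
  int K, J;
  double pop_sd, scale_rate, lkj_eta;
};

// effect dimension m = (K-1) cutpoint offsets + 1 slope offset
static int hier_dim(int K, int J) {
  int m = K;
  return (K - 1) + 1 + m + m * (m - 1) / 2 + J * m;
}

// Cholesky factor of the correlation matrix from canonical partial
// correlations z = tanh(y); returns false on numerical failure. When `extra`
// is non-null it receives the tanh + scaling Jacobians plus the LKJ-Cholesky
// log prior (the y-dependent prior mass).
static bool cpc_to_cholesky(const double* ycpc, int m, double eta,
                            std::vector<double>& L, double* extra) {
  std::fill(L.begin(), L.end(), 0.0);
  L[0] = 1.0;
  double lp = 0.0;
  int idx = 0;
  for (int i = 1; i < m; ++i) {
    double sumsq = 0.0;
    for (int j = 0; j < i; ++j) {
      double z = std::tanh(ycpc[idx]);
      lp += std::log1p(-z * z);
      double rem = 1.0 - sumsq;
      if (rem <= 0.0) return false;
      if (j > 0) lp += 0.5 * std::log(rem);
      L[i * m + j] = z * std::sqrt(rem);
      sumsq += L[i * m + j] * L[i * m + j];
      ++idx;
    }
    double rem = 1.0 - sumsq;
    if (rem <= 0.0) return false;
    L[i * m + i] = std::sqrt(rem);
    lp += (m - (i + 1) + 2.0 * eta - 2.0) * std::log(L[i * m + i]);
  }
  if (extra) *extra = lp;
  return true;
}

// theta layout: [a1, lg_2..lg_{K-1}] (K-1) | beta | log sigma (m) |
//               cpc y (m(m-1)/2) | z (J*m, taxon-major)
static double hier_logpost_grad(const double* theta, const HierData& d,
                                double* grad) {
  const int K = d.K, J = d.J, m = K;
  const int ncpc = m * (m - 1) / 2;
  double lp = 0.0;
  // population cutpoints
  std::vector<double> alpha(K - 1), galpha(K - 1, 0.0);
  alpha[0] = theta[0];
  for (int k = 1; k < K - 1; ++k) {
    alpha[k] = alpha[k - 1] + std::exp(theta[k]);
    lp += theta[k];
  }
  for (int k = 0; k < K - 1; ++k) {
    lp += R::dnorm(alpha[k], 0.0, d.pop_sd, 1);
    galpha[k] = -alpha[k] / (d.pop_sd * d.pop_sd);
  }
  double beta = theta[K - 1];
  lp += R::dnorm(beta, 0.0, d.pop_sd, 1);
  double gbeta = -beta / (d.pop_sd * d.pop_sd);
  // scales
  const double* ls = theta + K;
  std::vector<double> sigma(m), gls(m);
  for (int i = 0; i < m; ++i) {
    sigma[i] = std::exp(ls[i]);
    if (!std::isfinite(sigma[i])) return NEG_INF;
    lp += std::log(d.scale_rate) - d.scale_rate * sigma[i] + ls[i];
    gls[i] = 1.0 - d.scale_rate * sigma[i];
  }
  // correlation Cholesky and its prior mass
  const double* ycpc = theta + K + m;
  std::vector<double> L(m * m);
  double cpc_lp = 0.0;
  if (!cpc_to_cholesky(ycpc, m, d.lkj_eta, L, &cpc_lp)) return NEG_INF;
  lp += cpc_lp;
  // non-centered taxon effects
  const double* z = theta + K + m + ncpc;
  std::vector<double> w((size_t)J * m);          // (L z_j)_i
  std::vector<double> ta((size_t)J * (K - 1)), tb(J);
  for (int j = 0; j < J; ++j) {
    const double* zj = z + (size_t)j * m;
    for (int i = 0; i < m; ++i) lp += R::dnorm(zj[i], 0.0, 1.0, 1);
    for (int i = 0; i < m; ++i) {
      double wv = 0.0;
      for (int k = 0; k <= i; ++k) wv += L[i * m + k] * zj[k];
      w[(size_t)j * m + i] = wv;
      double u = sigma[i] * wv;
      if (i < K - 1) ta[(size_t)j * (K - 1) + i] = alpha[i] + u;
      else tb[j] = beta + u;
    }
    for (int k = 1; k < K - 1; ++k)
      if (ta[(size_t)j * (K - 1) + k] < ta[(size_t)j * (K - 1) + k - 1])
        return NEG_INF;  // taxon cutpoints must stay ordered
  }
  // likelihood pass, accumulating G[j][i] = d LL / d u_{j,i}
  std::vector<double> G((size_t)J * m, 0.0);
  std::vector<double> eta(K - 1);
  const int n = (int)d.x.size();
  for (int i = 0; i < n; ++i) {
    int j = d.tax[i];
    double bx = tb[j] * d.x[i];
    const double* taj = &ta[(size_t)j * (K - 1)];
    for (int k = 0; k < K - 1; ++k) eta[k] = taj[k] - bx;
    double dlo, dhi;
    double ll = ordinal_ll_grad(eta.data(), K, d.y[i], dlo, dhi);
    if (ll == NEG_INF) return NEG_INF;
    lp += ll;
    int y = d.y[i];
    if (y < K) G[(size_t)j * m + (y - 1)] += dhi;
    if (y > 1) G[(size_t)j * m + (y - 2)] += dlo;
    G[(size_t)j * m + (m - 1)] -= d.x[i] * (dlo + dhi);
  }
  if (!grad) return lp;

  // chain rule back to the unconstrained parameters
  for (int k = 0; k < K - 1; ++k)
    for (int j = 0; j < J; ++j) galpha[k] += G[(size_t)j * m + k];
  for (int j = 0; j < J; ++j) gbeta += G[(size_t)j * m + (m - 1)];
  double tail = 0.0;
  for (int k = K - 2; k >= 1; --k) {
    tail += galpha[k];
    grad[k] = std::exp(theta[k]) * tail + 1.0;
  }
  grad[0] = tail + galpha[0];
  grad[K - 1] = gbeta;
  for (int i = 0; i < m; ++i) {
    double s = 0.0;
    for (int j = 0; j < J; ++j) s += G[(size_t)j * m + i] * w[(size_t)j * m + i];
    grad[K + i] = s * sigma[i] + gls[i];
  }
  // z gradients and d LL / d L
  std::vector<double> Gl(m * m, 0.0);
  for (int j = 0; j < J; ++j) {
    const double* zj = z + (size_t)j * m;
    for (int k = 0; k < m; ++k) {
      double s = 0.0;
      for (int i = k; i < m; ++i)
        s += G[(size_t)j * m + i] * sigma[i] * L[i * m + k];
      grad[K + m + ncpc + (size_t)j * m + k] = s - zj[k];
    }
    for (int i = 0; i < m; ++i) {
      double gs = G[(size_t)j * m + i] * sigma[i];
      for (int k = 0; k <= i; ++k) Gl[i * m + k] += gs * zj[k];
    }
  }
  // cpc coordinates: prior mass + <Gl, L> differentiated through the cheap
  // Cholesky construction (no data pass involved)
  std::vector<double> Lh(m * m);
  std::vector<double> yv(ycpc, ycpc + ncpc);
  for (int q = 0; q < ncpc; ++q) {
    double h = 1e-6 * (1.0 + std::fabs(yv[q]));
    double orig = yv[q];
    double fp = NEG_INF, fm = NEG_INF, ex = 0.0;
    yv[q] = orig + h;
    if (cpc_to_cholesky(yv.data(), m, d.lkj_eta, Lh, &ex)) {
      fp = ex;
      for (int i = 0; i < m; ++i)
        for (int k = 0; k <= i; ++k) fp += Gl[i * m + k] * Lh[i * m + k];
    }
    yv[q] = orig - h;
    if (cpc_to_cholesky(yv.data(), m, d.lkj_eta, Lh, &ex)) {
      fm = ex;
      for (int i = 0; i < m; ++i)
        for (int k = 0; k <= i; ++k) fm += Gl[i * m + k] * Lh[i * m + k];
    }
    yv[q] = orig;
    grad[K + m + q] =
        (std::isfinite(fp) && std::isfinite(fm)) ? (fp - fm) / (2.0 * h) : 0.0;
  }
  return lp;
}

// ---------------------------------------------------------------------------
// HMC with dual-averaging step size and diagonal mass adaptation
// ---------------------------------------------------------------------------

// returns lp, fills grad
typedef std::function<double(const double*, double*)> LogPostGrad;

struct HmcResult {
  NumericMatrix draws;  // kept x D (unconstrained)
  double accept_rate;
  double step_size;
  int divergences;
};

static HmcResult hmc_sample(const LogPostGrad& lpg, std::vector<double> theta,
                            int warmup, int keep, int max_leapfrog,
                            double target_accept) {
  const int D = (int)theta.size();
  std::vector<double> inv_mass(D, 1.0), grad(D), g_new(D), p(D), th_new(D);
  NumericMatrix draws(keep, D);
  double cur_lp = lpg(theta.data(), grad.data());
  if (!std::isfinite(cur_lp)) stop("initial point has zero posterior density");

  // crude initial step size: scale until the one-step acceptance crosses 0.5
  double eps = 0.1;
  {
    for (int i = 0; i < D; ++i) p[i] = norm_rand();
    double ke0 = 0.0;
    for (int i = 0; i < D; ++i) ke0 += 0.5 * p[i] * p[i];
    double dir = 0.0;
    for (int it = 0; it < 60; ++it) {
      std::vector<double> th1 = theta, p1 = p, g1 = grad;
      for (int i = 0; i < D; ++i) p1[i] += 0.5 * eps * g1[i];
      for (int i = 0; i < D; ++i) th1[i] += eps * p1[i];
      double lp1 = lpg(th1.data(), g1.data());
      for (int i = 0; i < D; ++i) p1[i] += 0.5 * eps * g1[i];
      double ke1 = 0.0;
      for (int i = 0; i < D; ++i) ke1 += 0.5 * p1[i] * p1[i];
      double dH = (std::isfinite(lp1) ? lp1 - ke1 : NEG_INF) - (cur_lp - ke0);
      double want = (dH > std::log(0.5)) ? 1.0 : -1.0;
      if (dir == 0.0) dir = want;
      else if (want != dir) break;
      eps *= (dir > 0) ? 2.0 : 0.5;
      if (eps < 1e-10 || eps > 1e6) break;
    }
  }

  // dual averaging (Hoffman & Gelman defaults)
  double mu = std::log(10.0 * eps), log_eps = std::log(eps), log_eps_bar = 0.0;
  double H_bar = 0.0;
  const double da_gamma = 0.05, da_t0 = 10.0, da_kappa = 0.75;
  int da_count = 0;

  // two variance-accumulation windows for the diagonal mass matrix: a first
  // rough estimate, then a refit on better-mixed draws; final 10% of warmup
  // adapts the step size only
  int w1_lo = (int)(0.15 * warmup), w1_hi = (int)(0.50 * warmup);
  int w2_hi = (int)(0.90 * warmup);
  std::vector<double> acc_m(D, 0.0), acc_s(D, 0.0);
  int acc_n = 0;

  int total = warmup + keep;
  long n_acc = 0, n_prop = 0;
  int divergences = 0;

  for (int iter = 0; iter < total; ++iter) {
    bool adapting = iter < warmup;
    double step = adapting ? std::exp(log_eps) : std::exp(log_eps_bar);
    int L = 1 + (int)std::floor(unif_rand() * max_leapfrog);
    for (int i = 0; i < D; ++i) p[i] = norm_rand() / std::sqrt(inv_mass[i]);
    double ke0 = 0.0;
    for (int i = 0; i < D; ++i) ke0 += 0.5 * inv_mass[i] * p[i] * p[i];
    double H0 = cur_lp - ke0;

    th_new = theta;
    std::vector<double> p_new = p;
    g_new = grad;
    bool bad = false;
    double new_lp = NEG_INF;
    for (int l = 0; l < L; ++l) {
      for (int i = 0; i < D; ++i) p_new[i] += 0.5 * step * g_new[i];
      for (int i = 0; i < D; ++i) th_new[i] += step * inv_mass[i] * p_new[i];
      new_lp = lpg(th_new.data(), g_new.data());
      if (!std::isfinite(new_lp)) { bad = true; break; }
      for (int i = 0; i < D; ++i) p_new[i] += 0.5 * step * g_new[i];
    }
    double alpha_acc = 0.0;
    if (!bad && std::isfinite(new_lp)) {
      double ke1 = 0.0;
      for (int i = 0; i < D; ++i) ke1 += 0.5 * inv_mass[i] * p_new[i] * p_new[i];
      double dH = (new_lp - ke1) - H0;
      if (dH < -1000.0) { ++divergences; }
      else alpha_acc = std::min(1.0, std::exp(dH));
      if (unif_rand() < alpha_acc) {
        theta = th_new;
        cur_lp = new_lp;
        grad = g_new;
        ++n_acc;
      }
    } else {
      ++divergences;
    }
    ++n_prop;

    if (adapting) {
      ++da_count;
      double eta = 1.0 / (da_count + da_t0);
      H_bar = (1.0 - eta) * H_bar + eta * (target_accept - alpha_acc);
      log_eps = mu - std::sqrt((double)da_count) / da_gamma * H_bar;
      double wpow = std::pow((double)da_count, -da_kappa);
      log_eps_bar = wpow * log_eps + (1.0 - wpow) * log_eps_bar;
      if (iter >= w1_lo && iter < w2_hi) {
        ++acc_n;
        for (int i = 0; i < D; ++i) {
          double dlt = theta[i] - acc_m[i];
          acc_m[i] += dlt / acc_n;
          acc_s[i] += dlt * (theta[i] - acc_m[i]);
        }
      }
      if ((iter == w1_hi - 1 || iter == w2_hi - 1) && acc_n > 10) {
        for (int i = 0; i < D; ++i) {
          double v = acc_s[i] / (acc_n - 1);
          // regularize toward unit variance as Stan does
          v = v * acc_n / (acc_n + 5.0) + 1e-3 * (5.0 / (acc_n + 5.0));
          if (v > 1e-10 && std::isfinite(v)) inv_mass[i] = v;
        }
        std::fill(acc_m.begin(), acc_m.end(), 0.0);
        std::fill(acc_s.begin(), acc_s.end(), 0.0);
        acc_n = 0;
        mu = std::log(10.0 * std::exp(log_eps));
        H_bar = 0.0;
        da_count = 0;
        log_eps_bar = log_eps;
      }
    } else {
      draws(iter - warmup, _) = NumericVector(theta.begin(), theta.end());
    }
    if (iter % 256 == 0) checkUserInterrupt();
  }

  HmcResult res{draws, (double)n_acc / n_prop, std::exp(log_eps_bar),
                divergences};
  return res;
}

// ---------------------------------------------------------------------------
// exported entry points: one chain each, constrained draws returned
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_cpm_chain(NumericVector x, IntegerVector y, int K,
                   double cut_sd, double slope_sd,
                   int warmup, int keep, int max_leapfrog,
                   NumericVector init, double target_accept = 0.8) {
  CpmData d;
  d.x = as<std::vector<double>>(x);
  d.y = as<std::vector<int>>(y);
  d.K = K;
  d.cut_sd = cut_sd;
  d.slope_sd = slope_sd;
  LogPostGrad lpg = [&d](const double* th, double* g) {
    return cpm_logpost_grad(th, d, g);
  };
  RNGScope scope;
  HmcResult r = hmc_sample(lpg, as<std::vector<double>>(init), warmup, keep,
                           max_leapfrog, target_accept);
  NumericMatrix out(keep, K);
  for (int i = 0; i < keep; ++i) {
    double a = r.draws(i, 0);
    out(i, 0) = a;
    for (int k = 1; k < K - 1; ++k) {
      a += std::exp(r.draws(i, k));
      out(i, k) = a;
    }
    out(i, K - 1) = r.draws(i, K - 1);
  }
  return List::create(_["draws"] = out, _["accept_rate"] = r.accept_rate,
                      _["step_size"] = r.step_size,
                      _["divergences"] = r.divergences);
}

// [[Rcpp::export]]
List cpp_hier_chain(NumericVector x, IntegerVector y, IntegerVector taxon,
                    int K, int J, double pop_sd, double scale_rate,
                    double lkj_eta, int warmup, int keep, int max_leapfrog,
                    NumericVector init, double target_accept = 0.8) {
  HierData d;
  d.x = as<std::vector<double>>(x);
  d.y = as<std::vector<int>>(y);
  d.tax = as<std::vector<int>>(taxon);
  d.K = K;
  d.J = J;
  d.pop_sd = pop_sd;
  d.scale_rate = scale_rate;
  d.lkj_eta = lkj_eta;
  const int m = K;
  const int ncpc = m * (m - 1) / 2;
  const int D = hier_dim(K, J);
  if (init.size() != D) stop("init has wrong length");
  LogPostGrad lpg = [&d](const double* th, double* g) {
    return hier_logpost_grad(th, d, g);
  };
  RNGScope scope;
  HmcResult r = hmc_sample(lpg, as<std::vector<double>>(init), warmup, keep,
                           max_leapfrog, target_accept);
  // constrained layout:
  //   alpha (K-1) | beta | sigma (m) | R upper triangle (ncpc) |
  //   per-taxon: alpha_j (K-1), beta_j  -> J*m
  int nc = (K - 1) + 1 + m + ncpc + J * m;
  NumericMatrix out(keep, nc);
  std::vector<double> L(m * m);
  for (int i = 0; i < keep; ++i) {
    int c = 0;
    std::vector<double> alpha(K - 1);
    alpha[0] = r.draws(i, 0);
    out(i, c++) = alpha[0];
    for (int k = 1; k < K - 1; ++k) {
      alpha[k] = alpha[k - 1] + std::exp(r.draws(i, k));
      out(i, c++) = alpha[k];
    }
    double beta = r.draws(i, K - 1);
    out(i, c++) = beta;
    std::vector<double> sigma(m);
    for (int q = 0; q < m; ++q) {
      sigma[q] = std::exp(r.draws(i, K + q));
      out(i, c++) = sigma[q];
    }
    std::vector<double> ycpc(ncpc);
    for (int q = 0; q < ncpc; ++q) ycpc[q] = r.draws(i, K + m + q);
    cpc_to_cholesky(ycpc.data(), m, d.lkj_eta, L, nullptr);
    for (int a = 0; a < m; ++a)
      for (int b = a + 1; b < m; ++b) {
        double rr = 0.0;
        for (int k = 0; k <= a; ++k) rr += L[a * m + k] * L[b * m + k];
        out(i, c++) = rr;
      }
    int zoff = K + m + ncpc;
    for (int j = 0; j < J; ++j) {
      for (int q = 0; q < m; ++q) {
        double u = 0.0;
        for (int k = 0; k <= q; ++k)
          u += L[q * m + k] * r.draws(i, zoff + j * m + k);
        u *= sigma[q];
        out(i, c++) = (q < K - 1) ? alpha[q] + u : beta + u;
      }
    }
  }
  return List::create(_["draws"] = out, _["accept_rate"] = r.accept_rate,
                      _["step_size"] = r.step_size,
                      _["divergences"] = r.divergences);
}

// direct access to the joint log densities and gradients; the tests verify
// the analytic gradients against central finite differences through these
// [[Rcpp::export]]
List cpp_cpm_logpost(NumericVector theta, NumericVector x, IntegerVector y,
                     int K, double cut_sd, double slope_sd) {
  CpmData d;
  d.x = as<std::vector<double>>(x);
  d.y = as<std::vector<int>>(y);
  d.K = K;
  d.cut_sd = cut_sd;
  d.slope_sd = slope_sd;
  NumericVector g(theta.size());
  double lp = cpm_logpost_grad(REAL(theta), d, REAL(g));
  return List::create(_["logpost"] = lp, _["grad"] = g);
}

// [[Rcpp::export]]
List cpp_hier_logpost(NumericVector theta, NumericVector x, IntegerVector y,
                      IntegerVector taxon, int K, int J, double pop_sd,
                      double scale_rate, double lkj_eta,
                      bool with_grad = true) {
  HierData d;
  d.x = as<std::vector<double>>(x);
  d.y = as<std::vector<int>>(y);
  d.tax = as<std::vector<int>>(taxon);
  d.K = K;
  d.J = J;
  d.pop_sd = pop_sd;
  d.scale_rate = scale_rate;
  d.lkj_eta = lkj_eta;
  if (theta.size() != hier_dim(K, J)) stop("theta has wrong length");
  if (!with_grad) {
    double lp = hier_logpost_grad(REAL(theta), d, nullptr);
    return List::create(_["logpost"] = lp);
  }
  NumericVector g(theta.size());
  double lp = hier_logpost_grad(REAL(theta), d, REAL(g));
  return List::create(_["logpost"] = lp, _["grad"] = g);
}
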