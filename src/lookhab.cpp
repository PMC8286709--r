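// Core samplers for looking-time habituation models.
//
// Families (parameter z on the real line, sigma > 0, support (0, Inf)):
//   0 = N  truncated normal:            y ~ Normal(z, sigma) | y > 0
//   1 = E  trunc. normal, exp mean:     y ~ Normal(exp(z), sigma) | y > 0
//   2 = L  lognormal:                   log y ~ Normal(z, sigma)
//   3 = W  Weibull:                     shape sigma, scale exp(z)
//   4 = G  gamma:                       shape sigma, scale exp(z)
// Structures: 0 = trend, 1 = quadratic, 2 = autoregressive.
//
// The hierarchical model samples the redundant population-mean blocks in a
// rotated orthonormal basis supplied by the R wrapper: the iid normal prior
// is rotation-invariant, and the rotation isolates the prior-only flat
// directions of the additive group-mean decomposition into single
// coordinates, which keeps NUTS trajectories short.

#include <Rcpp.h>
#include <vector>
#include <random>
#include <cmath>
#include <algorithm>

using Rcpp::NumericVector;
using Rcpp::IntegerVector;
using Rcpp::NumericMatrix;
using Rcpp::List;

typedef std::vector<double> dvec;

static const double LN_SQRT_2PI = 0.91893853320467274178;

// ---------------------------------------------------------------------------
// family log-density and gradient wrt (z, sigma)
// ---------------------------------------------------------------------------

// per-(infant, sigma) constants hoisted out of the trial loop
struct FamCst {
  double lgam, dig, logs, inv;
};

static inline FamCst fam_constants(int fam, double s) {
  FamCst c;
  c.inv = 1.0 / s;
  c.logs = std::log(s);
  c.lgam = c.dig = 0.0;
  if (fam == 4) {
    c.lgam = R::lgammafn(s);
    c.dig = R::digamma(s);
  }
  return c;
}

// ly = log(y), precomputed once per dataset
static inline double trial_lp(int fam, double y, double ly, double z, double s,
                              const FamCst &cst, double &gz, double &gs) {
  double lp;
  switch (fam) {
  case 0: { // truncated normal
    double u = (y - z) * cst.inv;
    double a = z * cst.inv;
    double lF = R::pnorm(a, 0.0, 1.0, 1, 1); // log Phi(z/s)
    double ratio = std::exp(-0.5 * a * a - LN_SQRT_2PI - lF);
    lp = -0.5 * u * u - LN_SQRT_2PI - cst.logs - lF;
    gz = (u - ratio) * cst.inv;
    gs = (-1.0 + u * u + a * ratio) * cst.inv;
    break;
  }
  case 1: { // truncated normal with exponential mean
    double m = std::exp(z);
    double u = (y - m) * cst.inv;
    double a = m * cst.inv;
    double lF = R::pnorm(a, 0.0, 1.0, 1, 1);
    double ratio = std::exp(-0.5 * a * a - LN_SQRT_2PI - lF);
    lp = -0.5 * u * u - LN_SQRT_2PI - cst.logs - lF;
    gz = (u - ratio) * cst.inv * m;
    gs = (-1.0 + u * u + a * ratio) * cst.inv;
    break;
  }
  case 2: { // lognormal
    double u = (ly - z) * cst.inv;
    lp = -0.5 * u * u - LN_SQRT_2PI - cst.logs - ly;
    gz = u * cst.inv;
    gs = (-1.0 + u * u) * cst.inv;
    break;
  }
  case 3: { // Weibull, shape s, scale exp(z)
    double u = ly - z;
    double w = std::exp(s * u);
    lp = cst.logs - z + (s - 1.0) * u - w;
    gz = s * (w - 1.0);
    gs = cst.inv + u * (1.0 - w);
    break;
  }
  default: { // gamma, shape s, scale exp(z)
    double u = ly - z;
    double ye = std::exp(u);
    lp = -cst.lgam - s * z + (s - 1.0) * ly - ye;
    gz = -s + ye;
    gs = -cst.dig + u;
    break;
  }
  }
  return lp;
}

// ---------------------------------------------------------------------------
// posterior models
// ---------------------------------------------------------------------------

class PosteriorModel {
public:
  virtual ~PosteriorModel() {}
  virtual int dim() const = 0;
  // log posterior density and gradient; grad has length dim()
  virtual double logp_grad(const dvec &q, dvec &grad) const = 0;
};

// habituation state and its derivatives wrt (alpha, beta, gamma, delta)
static inline double state_and_partials(int structure, double a, double b,
                                        double g, double delta, int t, int d,
                                        double prev_r, double &da, double &db,
                                        double &dg, double &dd) {
  da = db = dg = dd = 0.0;
  if (structure == 0) { // trend
    double ind = (t > d) ? 1.0 : 0.0;
    da = 1.0; db = (double)t; dg = ind;
    return a + b * t + g * ind;
  } else if (structure == 1) { // quadratic
    double ind = (t > d) ? 1.0 : 0.0;
    double tc = (double)t - delta;
    da = 1.0; db = tc * tc; dg = ind; dd = -2.0 * b * tc;
    return a + b * tc * tc + g * ind;
  } else { // autoregressive
    if (t == 1) { da = 1.0; return a; }
    double ind = (t - 1 == d) ? 1.0 : 0.0;
    db = 1.0; dg = ind;
    return prev_r + b + g * ind;
  }
}

// --- no-pooling model: one infant -----------------------------------------
// parameters: alpha, beta, gamma, log(sigma) [, delta for quadratic]
class NoPoolModel : public PosteriorModel {
public:
  dvec y, logy, prev_r;
  std::vector<int> t;
  int d, fam, structure;
  double mu_sd, scale_sd, delta_mean, delta_sd;

  void prepare() {
    logy.resize(y.size());
    for (size_t k = 0; k < y.size(); ++k) logy[k] = std::log(y[k]);
  }

  int dim() const { return structure == 1 ? 5 : 4; }

  double logp_grad(const dvec &q, dvec &grad) const {
    std::fill(grad.begin(), grad.end(), 0.0);
    double a = q[0], b = q[1], g = q[2], ls = q[3];
    double delta = (structure == 1) ? q[4] : 0.0;
    if (ls > 40.0 || ls < -40.0) return -INFINITY;
    double s = std::exp(ls);

    // priors: N(0, mu_sd) on a, b, g; half-N(0, scale_sd) on sigma (+Jacobian)
    double lp = R::dnorm(a, 0.0, mu_sd, 1) + R::dnorm(b, 0.0, mu_sd, 1) +
                R::dnorm(g, 0.0, mu_sd, 1) + M_LN2 +
                R::dnorm(s, 0.0, scale_sd, 1) + ls;
    grad[0] -= a / (mu_sd * mu_sd);
    grad[1] -= b / (mu_sd * mu_sd);
    grad[2] -= g / (mu_sd * mu_sd);
    double gs_sigma = -s / (scale_sd * scale_sd); // d/ds of half-normal kernel
    if (structure == 1) {
      lp += R::dnorm(delta, delta_mean, delta_sd, 1);
      grad[4] -= (delta - delta_mean) / (delta_sd * delta_sd);
    }

    FamCst cst = fam_constants(fam, s);
    for (size_t k = 0; k < y.size(); ++k) {
      double da, db, dg, dd, gz, gsig;
      double z = state_and_partials(structure, a, b, g, delta, t[k], d,
                                    prev_r[k], da, db, dg, dd);
      double l = trial_lp(fam, y[k], logy[k], z, s, cst, gz, gsig);
      if (!std::isfinite(l)) return -INFINITY;
      lp += l;
      grad[0] += gz * da;
      grad[1] += gz * db;
      grad[2] += gz * dg;
      gs_sigma += gsig;
      if (structure == 1) grad[4] += gz * dd;
    }
    grad[3] += gs_sigma * s + 1.0; // chain rule to log sigma + Jacobian
    return lp;
  }
};

// --- hierarchical (partial-pooling) model ----------------------------------
// packing (see R/inference.R, must stay in sync):
//   u_alpha[6] (rotated mu_alpha_b[3], mu_alpha_c[3]),
//   u_beta[6]  (rotated mu_beta_b[3], mu_beta_c[3]),
//   u_gamma[gl] (rotated gamma block; gl = 10 main, 12 interaction)
//   [log sigma_alpha, log sigma_beta, log sigma_gamma]   (if scales free)
//   [mu_logsigma, log tau_logsigma]                      (if pool_sigma)
//   [delta]                                              (if quadratic)
//   alpha_raw[n], beta_raw[n], gamma_raw[n], sigma_raw[n]
class HierModel : public PosteriorModel {
public:
  dvec y, logy, prev_r;
  std::vector<int> t, inf;               // per-trial
  std::vector<int> b, c, dlev, dval;     // per-infant
  std::vector<int> start, len;           // per-infant trial ranges
  int n_inf, fam, structure, layout;
  bool pool_sigma, scales_free;
  double fs_a, fs_b, fs_g;               // fixed scales when !scales_free
  double mu_sd, scale_sd, delta_mean, delta_sd;
  dvec Qa, Qg;                           // column-major 6x6 and gl x gl
  mutable dvec A, B, G, S, gA, gB, gG, gS, mu_a, mu_b2, mu_g, gmu_a, gmu_b,
      gmu_g;

  int gamma_len() const { return layout == 0 ? 10 : 12; }
  int o_scales() const { return 12 + gamma_len(); }
  int o_sighyp() const { return o_scales() + (scales_free ? 3 : 0); }
  int o_delta() const { return o_sighyp() + (pool_sigma ? 2 : 0); }
  int o_raw() const { return o_delta() + (structure == 1 ? 1 : 0); }
  int dim() const { return o_raw() + 4 * n_inf; }

  void prepare() {
    logy.resize(y.size());
    for (size_t k = 0; k < y.size(); ++k) logy[k] = std::log(y[k]);
    start.assign(n_inf, 0);
    len.assign(n_inf, 0);
    for (size_t k = 0; k < y.size(); ++k) {
      if (len[inf[k]] == 0) start[inf[k]] = (int)k;
      len[inf[k]]++;
    }
    int gl = gamma_len();
    A.resize(n_inf); B.resize(n_inf); G.resize(n_inf); S.resize(n_inf);
    gA.resize(n_inf); gB.resize(n_inf); gG.resize(n_inf); gS.resize(n_inf);
    mu_a.resize(6); mu_b2.resize(6); mu_g.resize(gl);
    gmu_a.resize(6); gmu_b.resize(6); gmu_g.resize(gl);
  }

  double logp_grad(const dvec &q, dvec &grad) const {
    std::fill(grad.begin(), grad.end(), 0.0);
    const int gl = gamma_len(), os = o_scales(), oh = o_sighyp(),
              od = o_delta(), orw = o_raw();
    double lp = 0.0;

    // rotated population means, iid N(0, mu_sd) prior on the u coordinates
    for (int j = 0; j < 12 + gl; ++j) {
      lp += -0.5 * q[j] * q[j] / (mu_sd * mu_sd) - LN_SQRT_2PI -
            std::log(mu_sd);
      grad[j] -= q[j] / (mu_sd * mu_sd);
    }
    for (int j = 0; j < 6; ++j) {
      double sa = 0.0, sb = 0.0;
      for (int k = 0; k < 6; ++k) {
        sa += Qa[j + 6 * k] * q[k];
        sb += Qa[j + 6 * k] * q[6 + k];
      }
      mu_a[j] = sa;
      mu_b2[j] = sb;
    }
    for (int j = 0; j < gl; ++j) {
      double sg = 0.0;
      for (int k = 0; k < gl; ++k) sg += Qg[j + gl * k] * q[12 + k];
      mu_g[j] = sg;
    }

    // population scales, half-N(0, scale_sd), sampled on log scale
    double sa = fs_a, sb = fs_b, sg = fs_g;
    if (scales_free) {
      for (int j = 0; j < 3; ++j) {
        double lsx = q[os + j];
        if (lsx > 40.0 || lsx < -40.0) return -INFINITY;
        double sx = std::exp(lsx);
        lp += M_LN2 + R::dnorm(sx, 0.0, scale_sd, 1) + lsx;
        grad[os + j] += 1.0 - sx * sx / (scale_sd * scale_sd);
        if (j == 0) sa = sx; else if (j == 1) sb = sx; else sg = sx;
      }
    }
    double mu_ls = 0.0, tau = 0.0;
    if (pool_sigma) {
      mu_ls = q[oh];
      double lt = q[oh + 1];
      if (lt > 40.0 || lt < -40.0) return -INFINITY;
      tau = std::exp(lt);
      lp += R::dnorm(mu_ls, 0.0, mu_sd, 1);
      grad[oh] -= mu_ls / (mu_sd * mu_sd);
      lp += M_LN2 + R::dnorm(tau, 0.0, scale_sd, 1) + lt;
      grad[oh + 1] += 1.0 - tau * tau / (scale_sd * scale_sd);
    }
    double delta = 0.0;
    if (structure == 1) {
      delta = q[od];
      lp += R::dnorm(delta, delta_mean, delta_sd, 1);
      grad[od] -= (delta - delta_mean) / (delta_sd * delta_sd);
    }

    // infant-level parameters (non-centered)
    for (int i = 0; i < n_inf; ++i) {
      double ar = q[orw + i], br = q[orw + n_inf + i],
             gr = q[orw + 2 * n_inf + i], sr = q[orw + 3 * n_inf + i];
      lp += -0.5 * (ar * ar + br * br + gr * gr) - 3.0 * LN_SQRT_2PI;
      grad[orw + i] -= ar;
      grad[orw + n_inf + i] -= br;
      grad[orw + 2 * n_inf + i] -= gr;
      A[i] = mu_a[b[i]] + mu_a[3 + c[i]] + sa * ar;
      B[i] = mu_b2[b[i]] + mu_b2[3 + c[i]] + sb * br;
      if (layout == 0)
        G[i] = mu_g[b[i]] + mu_g[3 + c[i]] + mu_g[6 + dlev[i]] + sg * gr;
      else
        G[i] = mu_g[4 * b[i] + dlev[i]] + sg * gr;
      double ls_i;
      if (pool_sigma) {
        lp += -0.5 * sr * sr - LN_SQRT_2PI;
        grad[orw + 3 * n_inf + i] -= sr;
        ls_i = mu_ls + tau * sr;
      } else {
        // sr is log(sigma_i), half-N(0, scale_sd) prior + Jacobian
        ls_i = sr;
        if (sr > 40.0 || sr < -40.0) return -INFINITY;
        double si0 = std::exp(sr);
        lp += M_LN2 + R::dnorm(si0, 0.0, scale_sd, 1) + sr;
        grad[orw + 3 * n_inf + i] += 1.0 - si0 * si0 / (scale_sd * scale_sd);
      }
      if (ls_i > 40.0 || ls_i < -40.0) return -INFINITY;
      S[i] = std::exp(ls_i);
    }

    // likelihood, grouped by infant so family constants are hoisted
    std::fill(gmu_a.begin(), gmu_a.end(), 0.0);
    std::fill(gmu_b.begin(), gmu_b.end(), 0.0);
    std::fill(gmu_g.begin(), gmu_g.end(), 0.0);
    double gdelta = 0.0;
    for (int i = 0; i < n_inf; ++i) {
      double ga = 0.0, gb = 0.0, gg = 0.0, gs = 0.0;
      FamCst cst = fam_constants(fam, S[i]);
      const int k0 = start[i], k1 = start[i] + len[i];
      for (int k = k0; k < k1; ++k) {
        double da, db, dg, dd, gz, gsig;
        double z = state_and_partials(structure, A[i], B[i], G[i], delta,
                                      t[k], dval[i], prev_r[k], da, db, dg,
                                      dd);
        double l = trial_lp(fam, y[k], logy[k], z, S[i], cst, gz, gsig);
        if (!std::isfinite(l)) return -INFINITY;
        lp += l;
        ga += gz * da;
        gb += gz * db;
        gg += gz * dg;
        gs += gsig;
        gdelta += gz * dd;
      }
      // map infant-level gradients to population and raw coordinates
      double ar = q[orw + i], br = q[orw + n_inf + i],
             gr = q[orw + 2 * n_inf + i], sr = q[orw + 3 * n_inf + i];
      gmu_a[b[i]] += ga;
      gmu_a[3 + c[i]] += ga;
      grad[orw + i] += ga * sa;
      gmu_b[b[i]] += gb;
      gmu_b[3 + c[i]] += gb;
      grad[orw + n_inf + i] += gb * sb;
      if (layout == 0) {
        gmu_g[b[i]] += gg;
        gmu_g[3 + c[i]] += gg;
        gmu_g[6 + dlev[i]] += gg;
      } else {
        gmu_g[4 * b[i] + dlev[i]] += gg;
      }
      grad[orw + 2 * n_inf + i] += gg * sg;
      double dls = gs * S[i]; // d logp / d log(sigma_i)
      if (pool_sigma) {
        grad[oh] += dls;
        grad[orw + 3 * n_inf + i] += dls * tau;
        grad[oh + 1] += dls * tau * sr;
      } else {
        grad[orw + 3 * n_inf + i] += dls;
      }
      if (scales_free) {
        grad[os] += ga * ar * sa;
        grad[os + 1] += gb * br * sb;
        grad[os + 2] += gg * gr * sg;
      }
    }
    if (structure == 1) grad[od] += gdelta;

    // rotate population-mean gradients back to the u coordinates
    for (int k = 0; k < 6; ++k) {
      double ta = 0.0, tb = 0.0;
      for (int j = 0; j < 6; ++j) {
        ta += Qa[j + 6 * k] * gmu_a[j];
        tb += Qa[j + 6 * k] * gmu_b[j];
      }
      grad[k] += ta;
      grad[6 + k] += tb;
    }
    for (int k = 0; k < gl; ++k) {
      double tg = 0.0;
      for (int j = 0; j < gl; ++j) tg += Qg[j + gl * k] * gmu_g[j];
      grad[12 + k] += tg;
    }
    return lp;
  }
};

// ---------------------------------------------------------------------------
// No-U-Turn sampler (Hoffman & Gelman 2014, Algorithm 6) with dual-averaging
// step-size adaptation and diagonal mass-matrix estimation during warm-up.
// ---------------------------------------------------------------------------

struct Rng {
  std::mt19937_64 gen;
  std::normal_distribution<double> norm;
  std::uniform_real_distribution<double> unif;
  explicit Rng(uint64_t seed) : gen(seed), norm(0.0, 1.0), unif(0.0, 1.0) {}
  double rnorm() { return norm(gen); }
  double runif() { return unif(gen); }
};

struct Phase {
  const PosteriorModel *model;
  dvec inv_mass;   // diagonal of M^{-1}
  double eps;
  int n_div;

  double hamiltonian(const dvec &q, const dvec &p, double lp) const {
    double k = 0.0;
    for (size_t j = 0; j < p.size(); ++j) k += 0.5 * p[j] * p[j] * inv_mass[j];
    return lp - k;
  }

  // one leapfrog step; returns log posterior at new q (grad updated)
  double leapfrog(dvec &q, dvec &p, dvec &grad, double dir) const {
    double h = dir * eps;
    for (size_t j = 0; j < q.size(); ++j) {
      p[j] += 0.5 * h * grad[j];
      q[j] += h * p[j] * inv_mass[j];
    }
    double lp = model->logp_grad(q, grad);
    if (!std::isfinite(lp)) {
      std::fill(grad.begin(), grad.end(), 0.0);
      return -INFINITY;
    }
    for (size_t j = 0; j < q.size(); ++j) p[j] += 0.5 * h * grad[j];
    return lp;
  }
};

struct Tree {
  dvec qm, pm, gm, qp, pp, gp, qs; // minus/plus ends and proposal
  double lpm, lpp;
  int n;
  bool s;
  double alpha;
  int n_alpha;
};

static bool no_uturn(const dvec &qm, const dvec &qp, const dvec &pm,
                     const dvec &pp, const dvec &inv_mass) {
  double a = 0.0, bb = 0.0;
  for (size_t j = 0; j < qm.size(); ++j) {
    double dq = qp[j] - qm[j];
    a += dq * pm[j] * inv_mass[j];
    bb += dq * pp[j] * inv_mass[j];
  }
  return a >= 0.0 && bb >= 0.0;
}

static void build_tree(Phase &ph, Rng &rng, const dvec &q, const dvec &p,
                       const dvec &grad, double lp, double log_u, double dir,
                       int depth, double h0, Tree &out) {
  if (depth == 0) {
    out.qm = q; out.pm = p; out.gm = grad;
    double lp1 = ph.leapfrog(out.qm, out.pm, out.gm, dir);
    double h1 = ph.hamiltonian(out.qm, out.pm, lp1);
    out.qp = out.qm; out.pp = out.pm; out.gp = out.gm;
    out.lpm = out.lpp = lp1;
    out.qs = out.qm;
    out.n = (log_u <= h1) ? 1 : 0;
    out.s = std::isfinite(h1) && (log_u < h1 + 1000.0);
    if (!out.s) ph.n_div++;
    double da = h1 - h0;
    out.alpha = std::isfinite(da) ? std::min(1.0, std::exp(da)) : 0.0;
    out.n_alpha = 1;
    return;
  }
  build_tree(ph, rng, q, p, grad, lp, log_u, dir, depth - 1, h0, out);
  if (!out.s) return;
  Tree t2;
  if (dir < 0) {
    build_tree(ph, rng, out.qm, out.pm, out.gm, out.lpm, log_u, dir, depth - 1,
               h0, t2);
    out.qm = t2.qm; out.pm = t2.pm; out.gm = t2.gm; out.lpm = t2.lpm;
  } else {
    build_tree(ph, rng, out.qp, out.pp, out.gp, out.lpp, log_u, dir, depth - 1,
               h0, t2);
    out.qp = t2.qp; out.pp = t2.pp; out.gp = t2.gp; out.lpp = t2.lpp;
  }
  if (t2.n > 0 &&
      rng.runif() < (double)t2.n / std::max(1, out.n + t2.n))
    out.qs = t2.qs;
  out.n += t2.n;
  out.alpha += t2.alpha;
  out.n_alpha += t2.n_alpha;
  out.s = out.s && t2.s && no_uturn(out.qm, out.qp, out.pm, out.pp, ph.inv_mass);
}

static double find_epsilon(Phase &ph, Rng &rng, const dvec &q0) {
  int n = (int)q0.size();
  dvec q(q0), p(n), grad(n);
  double lp = ph.model->logp_grad(q, grad);
  for (int j = 0; j < n; ++j) p[j] = rng.rnorm() / std::sqrt(ph.inv_mass[j]);
  double h0 = ph.hamiltonian(q, p, lp);
  ph.eps = 1.0;
  dvec q1(q), p1(p), g1(grad);
  double lp1 = ph.leapfrog(q1, p1, g1, 1.0);
  double h1 = ph.hamiltonian(q1, p1, lp1);
  double da = std::isfinite(h1) ? h1 - h0 : -INFINITY;
  double dir = (da > std::log(0.5)) ? 1.0 : -1.0;
  for (int it = 0; it < 50; ++it) {
    ph.eps *= std::pow(2.0, dir);
    q1 = q; p1 = p; g1 = grad;
    lp1 = ph.leapfrog(q1, p1, g1, 1.0);
    h1 = ph.hamiltonian(q1, p1, lp1);
    da = std::isfinite(h1) ? h1 - h0 : -INFINITY;
    if (dir > 0 ? (da <= std::log(0.5)) : (da >= std::log(0.5))) break;
  }
  return ph.eps;
}

// one NUTS transition; q and grad updated in place, returns logp
static double nuts_transition(Phase &ph, Rng &rng, dvec &q, dvec &grad,
                              double lp, int max_depth, double &alpha_out) {
  int n = (int)q.size();
  dvec p(n);
  for (int j = 0; j < n; ++j) p[j] = rng.rnorm() / std::sqrt(ph.inv_mass[j]);
  double h0 = ph.hamiltonian(q, p, lp);
  // exp(log_u) ~ U(0, exp(h0))
  double log_u = h0 + std::log(rng.runif());
  dvec qm(q), pm(p), gm(grad), qp(q), pp(p), gp(grad);
  double lpm = lp, lpp = lp;
  dvec qs(q);
  int ntot = 1;
  bool s = true;
  alpha_out = 1.0;
  for (int depth = 0; depth < max_depth && s; ++depth) {
    Tree t;
    double dir = (rng.runif() < 0.5) ? -1.0 : 1.0;
    if (dir < 0) {
      build_tree(ph, rng, qm, pm, gm, lpm, log_u, dir, depth, h0, t);
      qm = t.qm; pm = t.pm; gm = t.gm; lpm = t.lpm;
    } else {
      build_tree(ph, rng, qp, pp, gp, lpp, log_u, dir, depth, h0, t);
      qp = t.qp; pp = t.pp; gp = t.gp; lpp = t.lpp;
    }
    if (t.s && t.n > 0 && rng.runif() < (double)t.n / ntot) qs = t.qs;
    ntot += t.n;
    s = t.s && no_uturn(qm, qp, pm, pp, ph.inv_mass);
    alpha_out = t.alpha / t.n_alpha;
  }
  q = qs;
  lp = ph.model->logp_grad(q, grad);
  return lp;
}

// run one chain; returns matrix of retained draws
static NumericMatrix run_chain(const PosteriorModel &model, const dvec &init,
                               int iter, int warmup, int thin, uint64_t seed,
                               int max_depth, int &n_div_out, double &eps_out) {
  int n = model.dim();
  Rng rng(seed);
  Phase ph;
  ph.model = &model;
  ph.inv_mass.assign(n, 1.0);
  ph.n_div = 0;

  dvec q(init), grad(n);
  double lp = model.logp_grad(q, grad);
  if (!std::isfinite(lp)) Rcpp::stop("initial point has non-finite density");

  // dual averaging state
  const double target = 0.8, gamma_da = 0.05, t0 = 10.0, kappa = 0.75;
  double mu_da, log_eps_bar = 0.0, h_bar = 0.0;
  int m_da = 0;
  ph.eps = find_epsilon(ph, rng, q);
  mu_da = std::log(10.0 * ph.eps);

  // mass-matrix estimation window: (0.25, 0.75) of warm-up, Welford
  int w_lo = warmup / 4, w_hi = (3 * warmup) / 4;
  dvec wm(n, 0.0), ws(n, 0.0);
  long wcount = 0;

  int n_keep = (iter - warmup + thin - 1) / thin;
  NumericMatrix draws(n_keep, n);
  int kept = 0;

  for (int it = 0; it < iter; ++it) {
    double alpha;
    lp = nuts_transition(ph, rng, q, grad, lp, max_depth, alpha);
    if (it < warmup) {
      // step-size adaptation
      m_da++;
      double eta = 1.0 / (m_da + t0);
      h_bar = (1.0 - eta) * h_bar + eta * (target - alpha);
      double log_eps = mu_da - std::sqrt((double)m_da) / gamma_da * h_bar;
      double w = std::pow((double)m_da, -kappa);
      log_eps_bar = w * log_eps + (1.0 - w) * log_eps_bar;
      ph.eps = std::exp(log_eps);
      if (it >= w_lo && it < w_hi) {
        wcount++;
        for (int j = 0; j < n; ++j) {
          double dlt = q[j] - wm[j];
          wm[j] += dlt / wcount;
          ws[j] += dlt * (q[j] - wm[j]);
        }
      }
      if (it == w_hi - 1 && wcount > 10) {
        for (int j = 0; j < n; ++j) {
          double v = ws[j] / (wcount - 1);
          ph.inv_mass[j] =
              v * ((double)wcount / (wcount + 5.0)) + 1e-3 * (5.0 / (wcount + 5.0));
        }
        // restart step-size search under the new metric
        ph.eps = find_epsilon(ph, rng, q);
        mu_da = std::log(10.0 * ph.eps);
        m_da = 0; h_bar = 0.0; log_eps_bar = std::log(ph.eps);
      }
      if (it == warmup - 1) ph.eps = std::exp(log_eps_bar);
    } else {
      if ((it - warmup) % thin == 0 && kept < n_keep) {
        for (int j = 0; j < n; ++j) draws(kept, j) = q[j];
        kept++;
      }
    }
  }
  n_div_out = ph.n_div;
  eps_out = ph.eps;
  return draws;
}

static List run_chains(const PosteriorModel &model, const dvec &center,
                       double jitter, int chains, int iter, int warmup,
                       int thin, int seed, int max_depth) {
  int n = model.dim();
  int n_keep = (iter - warmup + thin - 1) / thin;
  NumericMatrix all(n_keep * chains, n);
  IntegerVector chain_id(n_keep * chains);
  IntegerVector divs(chains);
  NumericVector eps(chains);
  for (int ch = 0; ch < chains; ++ch) {
    uint64_t s = (uint64_t)seed * 1000003ULL + 7919ULL * (ch + 1);
    Rng jr(s ^ 0x9e3779b97f4a7c15ULL);
    dvec init(center);
    for (int j = 0; j < n; ++j) init[j] += jitter * jr.rnorm();
    int nd = 0;
    double ep = 0.0;
    NumericMatrix d = run_chain(model, init, iter, warmup, thin, s, max_depth,
                                nd, ep);
    for (int r = 0; r < n_keep; ++r) {
      for (int j = 0; j < n; ++j) all(ch * n_keep + r, j) = d(r, j);
      chain_id[ch * n_keep + r] = ch + 1;
    }
    divs[ch] = nd;
    eps[ch] = ep;
    Rcpp::checkUserInterrupt();
  }
  return List::create(Rcpp::Named("draws") = all,
                      Rcpp::Named("chain") = chain_id,
                      Rcpp::Named("divergent") = divs,
                      Rcpp::Named("stepsize") = eps);
}

// ---------------------------------------------------------------------------
// exported entry points
// ---------------------------------------------------------------------------

static void fill_hier_model(HierModel &m, NumericVector y, IntegerVector t,
                            NumericVector prev_r, IntegerVector inf,
                            IntegerVector b, IntegerVector c,
                            IntegerVector dlev, IntegerVector dval, int family,
                            int structure, int layout, bool pool_sigma,
                            NumericVector fixed_scales, NumericMatrix Qa,
                            NumericMatrix Qg, List prior) {
  m.y = dvec(y.begin(), y.end());
  m.prev_r = dvec(prev_r.begin(), prev_r.end());
  m.t = std::vector<int>(t.begin(), t.end());
  m.inf = std::vector<int>(inf.begin(), inf.end());
  m.b = std::vector<int>(b.begin(), b.end());
  m.c = std::vector<int>(c.begin(), c.end());
  m.dlev = std::vector<int>(dlev.begin(), dlev.end());
  m.dval = std::vector<int>(dval.begin(), dval.end());
  m.n_inf = (int)m.b.size();
  m.fam = family;
  m.structure = structure;
  m.layout = layout;
  m.pool_sigma = pool_sigma;
  m.scales_free = fixed_scales.size() == 0;
  if (!m.scales_free) {
    m.fs_a = fixed_scales[0];
    m.fs_b = fixed_scales[1];
    m.fs_g = fixed_scales[2];
  } else {
    m.fs_a = m.fs_b = m.fs_g = NA_REAL;
  }
  m.Qa = dvec(Qa.begin(), Qa.end());
  m.Qg = dvec(Qg.begin(), Qg.end());
  if ((int)m.Qa.size() != 36 || (int)m.Qg.size() != m.gamma_len() * m.gamma_len())
    Rcpp::stop("rotation matrices have the wrong size");
  m.mu_sd = Rcpp::as<double>(prior["mu_sd"]);
  m.scale_sd = Rcpp::as<double>(prior["scale_sd"]);
  m.delta_mean = Rcpp::as<double>(prior["delta_mean"]);
  m.delta_sd = Rcpp::as<double>(prior["delta_sd"]);
  m.prepare();
}

// [[Rcpp::export(name = ".nuts_nopool")]]
List nuts_nopool(NumericVector y, IntegerVector t, NumericVector prev_r, int d,
                 int family, int structure, List prior, NumericVector center,
                 double jitter, int chains, int iter, int warmup, int thin,
                 int seed, int max_depth) {
  NoPoolModel m;
  m.y = dvec(y.begin(), y.end());
  m.prev_r = dvec(prev_r.begin(), prev_r.end());
  m.t = std::vector<int>(t.begin(), t.end());
  m.d = d;
  m.fam = family;
  m.structure = structure;
  m.mu_sd = Rcpp::as<double>(prior["mu_sd"]);
  m.scale_sd = Rcpp::as<double>(prior["scale_sd"]);
  m.delta_mean = Rcpp::as<double>(prior["delta_mean"]);
  m.delta_sd = Rcpp::as<double>(prior["delta_sd"]);
  m.prepare();
  dvec c0(center.begin(), center.end());
  return run_chains(m, c0, jitter, chains, iter, warmup, thin, seed, max_depth);
}

// [[Rcpp::export(name = ".nuts_hier")]]
List nuts_hier(NumericVector y, IntegerVector t, NumericVector prev_r,
               IntegerVector inf, IntegerVector b, IntegerVector c,
               IntegerVector dlev, IntegerVector dval, int family,
               int structure, int layout, bool pool_sigma,
               NumericVector fixed_scales, NumericMatrix Qa, NumericMatrix Qg,
               List prior, NumericVector center, double jitter, int chains,
               int iter, int warmup, int thin, int seed, int max_depth) {
  HierModel m;
  fill_hier_model(m, y, t, prev_r, inf, b, c, dlev, dval, family, structure,
                  layout, pool_sigma, fixed_scales, Qa, Qg, prior);
  dvec c0(center.begin(), center.end());
  return run_chains(m, c0, jitter, chains, iter, warmup, thin, seed, max_depth);
}

// log posterior of the hierarchical model at a point (used in tests)
// [[Rcpp::export(name = ".hier_logp")]]
Rcpp::List hier_logp(NumericVector q, NumericVector y, IntegerVector t,
                     NumericVector prev_r, IntegerVector inf, IntegerVector b,
                     IntegerVector c, IntegerVector dlev, IntegerVector dval,
                     int family, int structure, int layout, bool pool_sigma,
                     NumericVector fixed_scales, NumericMatrix Qa,
                     NumericMatrix Qg, List prior) {
  HierModel m;
  fill_hier_model(m, y, t, prev_r, inf, b, c, dlev, dval, family, structure,
                  layout, pool_sigma, fixed_scales, Qa, Qg, prior);
  dvec q0(q.begin(), q.end()), g(m.dim());
  double lp = m.logp_grad(q0, g);
  return List::create(Rcpp::Named("logp") = lp,
                      Rcpp::Named("grad") = NumericVector(g.begin(), g.end()));
}

// log posterior of the no-pooling model at a point (used in tests)
// [[Rcpp::export(name = ".nopool_logp")]]
double nopool_logp(NumericVector q, NumericVector y, IntegerVector t,
                   NumericVector prev_r, int d, int family, int structure,
                   List prior) {
  NoPoolModel m;
  m.y = dvec(y.begin(), y.end());
  m.prev_r = dvec(prev_r.begin(), prev_r.end());
  m.t = std::vector<int>(t.begin(), t.end());
  m.d = d;
  m.fam = family;
  m.structure = structure;
  m.mu_sd = Rcpp::as<double>(prior["mu_sd"]);
  m.scale_sd = Rcpp::as<double>(prior["scale_sd"]);
  m.delta_mean = Rcpp::as<double>(prior["delta_mean"]);
  m.delta_sd = Rcpp::as<double>(prior["delta_sd"]);
  m.prepare();
  dvec q0(q.begin(), q.end()), g(m.dim());
  return m.logp_grad(q0, g);
}
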