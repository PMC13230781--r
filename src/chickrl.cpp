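#include <Rcpp.h>
#include <functional>
#include <cmath>
using namespace Rcpp;

// Model bank encoding shared with R (see model_spec()):
//   family: 0 = reward (delta rule on own action values),
//           1 = belief (fictitious play on opponent swerve probability),
//           2 = belief2 (belief + second-order influence term)
//   n_alphas: 0 (no learning), 1 (shared alpha), 2 (alpha_h / alpha_l)
//   has_theta / has_kappa: extra parameters present
//   frozen: preference-only baselines; EV pinned at its initial value
// Parameter vector order (natural scale):
//   [alpha | alpha_h, alpha_l] [kappa] beta [theta]
// Choice coding: swerve = 1, go straight = 0. Opponent: HCO = 0, LCO = 1.

static const double BELIEF_EPS = 1e-6;

struct ModelCode {
  int family, n_alphas;
  bool has_theta, has_kappa, frozen;
};

static ModelCode read_spec(const IntegerVector& spec) {
  ModelCode mc;
  mc.family = spec[0];
  mc.n_alphas = spec[1];
  mc.has_theta = spec[2] != 0;
  mc.has_kappa = spec[3] != 0;
  mc.frozen = spec[4] != 0;
  return mc;
}

struct Params {
  double a[2];  // learning rate by opponent index
  double kappa, beta, theta;
};

static Params unpack(const ModelCode& mc, const double* th) {
  Params p;
  p.a[0] = p.a[1] = 0.0;
  p.kappa = 0.0;
  p.theta = 0.0;
  int i = 0;
  if (mc.n_alphas == 1) {
    p.a[0] = p.a[1] = th[i++];
  } else if (mc.n_alphas == 2) {
    p.a[0] = th[i++];
    p.a[1] = th[i++];
  }
  if (mc.has_kappa) p.kappa = th[i++];
  p.beta = th[i++];
  if (mc.has_theta) p.theta = th[i++];
  return p;
}

static inline double clip01(double x) {
  if (x < BELIEF_EPS) return BELIEF_EPS;
  if (x > 1.0 - BELIEF_EPS) return 1.0 - BELIEF_EPS;
  return x;
}

// Replay one session under one parameter set; returns total log-likelihood of
// the observed choices and (optionally) the per-trial values.
// A, B: belief-family EV coefficients, EV(p) = A + B * p with
//   A = sg - gg, B = (ss - gs) - (sg - gg) from the payoff matrix.
// rscale: divisor applied to rewards before the delta-rule update (reward
//   family only; belief families work in matrix units).
static double replay_ll(const ModelCode& mc, const Params& pp,
                        const int* opp, const int* cho, const int* och,
                        const double* rew, int n,
                        double A, double B, double rscale,
                        double* pointwise) {
  double V[2][2] = {{0.0, 0.0}, {0.0, 0.0}};  // [opponent][action]
  double pbel[2] = {0.5, 0.5};
  const double ev_frozen = (mc.family == 0) ? 0.0 : (A + 0.5 * B);
  double ll = 0.0;
  for (int t = 0; t < n; ++t) {
    const int o = opp[t];
    double ev;
    if (mc.frozen) {
      ev = ev_frozen;
    } else if (mc.family == 0) {
      ev = V[o][1] - V[o][0];
    } else {
      ev = A + B * pbel[o];
    }
    const double x = pp.beta * ev + pp.theta;
    // log P(choice) computed stably: log sigmoid(+-x)
    const double s = (cho[t] == 1) ? x : -x;
    const double l = (s >= 0) ? -std::log1p(std::exp(-s))
                              : s - std::log1p(std::exp(s));
    ll += l;
    if (pointwise) pointwise[t] = l;
    if (mc.frozen || mc.n_alphas == 0) continue;
    const double a = pp.a[o];
    if (mc.family == 0) {
      const double r = rew[t] / rscale;
      V[o][cho[t]] += a * (r - V[o][cho[t]]);
    } else {
      const double O = (och[t] == 1) ? 1.0 : 0.0;
      if (mc.family == 2) {
        const double p0 = clip01(pbel[o]);
        const double beta = (pp.beta > 1e-12) ? pp.beta : 1e-12;
        const double q = (std::log(p0 / (1.0 - p0)) / beta - A) / B;
        const double Q = (cho[t] == 1) ? 1.0 : 0.0;
        pbel[o] = clip01(pbel[o] + a * (O - pbel[o]) + pp.kappa * (Q - q));
      } else {
        pbel[o] += a * (O - pbel[o]);
      }
    }
  }
  return ll;
}

// [[Rcpp::export]]
NumericVector cpp_session_loglik(IntegerVector spec, NumericVector params,
                                 IntegerVector opp, IntegerVector choice,
                                 IntegerVector opp_choice, NumericVector reward,
                                 double A, double B, double rscale,
                                 bool pointwise) {
  const ModelCode mc = read_spec(spec);
  const Params pp = unpack(mc, params.begin());
  const int n = opp.size();
  if (pointwise) {
    NumericVector out(n);
    replay_ll(mc, pp, opp.begin(), choice.begin(), opp_choice.begin(),
              reward.begin(), n, A, B, rscale, out.begin());
    return out;
  }
  NumericVector out(1);
  out[0] = replay_ll(mc, pp, opp.begin(), choice.begin(), opp_choice.begin(),
                     reward.begin(), n, A, B, rscale, (double*)0);
  return out;
}

// Per-draw, per-trial log-likelihoods given subject-level natural parameters.
// nat: draws x (S*K) matrix, subject-major (columns s*K + k).
// [[Rcpp::export]]
NumericMatrix cpp_pointwise_ll(IntegerVector spec, NumericMatrix nat,
                               IntegerVector offsets, IntegerVector opp,
                               IntegerVector choice, IntegerVector opp_choice,
                               NumericVector reward, int K,
                               double A, double B, double rscale) {
  const ModelCode mc = read_spec(spec);
  const int S = offsets.size() - 1;
  const int D = nat.nrow();
  const int N = opp.size();
  NumericMatrix out(D, N);
  std::vector<double> th(K);
  for (int d = 0; d < D; ++d) {
    for (int s = 0; s < S; ++s) {
      for (int k = 0; k < K; ++k) th[k] = nat(d, s * K + k);
      const Params pp = unpack(mc, th.data());
      const int t0 = offsets[s], t1 = offsets[s + 1];
      std::vector<double> pw(t1 - t0);
      replay_ll(mc, pp, opp.begin() + t0, choice.begin() + t0,
                opp_choice.begin() + t0, reward.begin() + t0, t1 - t0,
                A, B, rscale, pw.data());
      for (int t = t0; t < t1; ++t) out(d, t) = pw[t - t0];
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Hierarchical sampler: non-centered parameterization
//   subject raw  phi_raw[s,k] = mu[k] + exp(eta[k]) * z[s,k]
//   natural      phi[s,k]     = lower + (upper - lower) * Phi(phi_raw)  (bounded)
//                               phi_raw                                  (unbounded)
//   priors       mu[k] ~ N(0, mu_scale), sigma[k] = exp(eta[k]) ~ HC(0, sigma_scale),
//                z ~ N(0,1)
// Updates: univariate slice sampling (stepping out + shrinkage) in a fixed
// Gibbs sweep over mu, eta, then all z. Uses R's RNG (seed set from R).
// ---------------------------------------------------------------------------

static double slice_update(const std::function<double(double)>& logf,
                           double x0, double f0, double w, int max_steps,
                           double* f_out) {
  const double logy = f0 - R::exp_rand();
  double u = R::unif_rand() * w;
  double L = x0 - u;
  double Rr = L + w;
  int j = (int)std::floor(R::unif_rand() * max_steps);
  int k = max_steps - 1 - j;
  while (j-- > 0 && logf(L) > logy) L -= w;
  while (k-- > 0 && logf(Rr) > logy) Rr += w;
  for (int it = 0; it < 1000; ++it) {
    const double x1 = L + R::unif_rand() * (Rr - L);
    const double f1 = logf(x1);
    if (f1 > logy) { *f_out = f1; return x1; }
    if (x1 < x0) L = x1; else Rr = x1;
  }
  *f_out = f0;
  return x0;
}

struct HierData {
  ModelCode mc;
  int S, K;
  const int *offsets, *opp, *cho, *och;
  const double *rew;
  double A, B, rscale;
  const double *lower, *upper;
  const int *bounded;
  const double *mu_scale, *sigma_scale;
};

class HierModel {
public:
  HierData d;
  std::vector<double> mu, eta, z;  // z is subject-major: z[s*K + k]
  std::vector<double> subj_ll;     // cached per-subject log-likelihood

  double natural(int k, double raw) const {
    if (!d.bounded[k]) return raw;
    return d.lower[k] + (d.upper[k] - d.lower[k]) * R::pnorm(raw, 0.0, 1.0, 1, 0);
  }

  double loglik_subject(int s, const double* mu_v, const double* eta_v,
                        const double* z_v) const {
    std::vector<double> th(d.K);
    for (int k = 0; k < d.K; ++k)
      th[k] = natural(k, mu_v[k] + std::exp(eta_v[k]) * z_v[s * d.K + k]);
    const Params pp = unpack(d.mc, th.data());
    const int t0 = d.offsets[s], t1 = d.offsets[s + 1];
    return replay_ll(d.mc, pp, d.opp + t0, d.cho + t0, d.och + t0, d.rew + t0,
                     t1 - t0, d.A, d.B, d.rscale, (double*)0);
  }

  void refresh_cache() {
    subj_ll.resize(d.S);
    for (int s = 0; s < d.S; ++s)
      subj_ll[s] = loglik_subject(s, mu.data(), eta.data(), z.data());
  }

  double prior_mu(int k, double v) const {
    return R::dnorm(v, 0.0, d.mu_scale[k], 1);
  }

  // half-Cauchy prior on sigma plus log-Jacobian of sigma = exp(eta)
  double prior_eta(int k, double v) const {
    const double sigma = std::exp(v);
    const double sc = d.sigma_scale[k];
    return std::log(2.0 / (M_PI * sc * (1.0 + (sigma / sc) * (sigma / sc)))) + v;
  }

  // Gibbs sweep. Subject-level z moves are always non-centered (likelihood
  // informed). Hyperparameters move through an ancillarity-sufficiency
  // interweaving step every sweep -- conditioning on the subject raw
  // parameters phi = mu + sigma * z, whose conditional is likelihood-free,
  // which decouples the hierarchical funnel -- plus a periodic non-centered
  // slice pass so small-sigma regimes still mix.
  void sweep(bool nc_hyper) {
    const double w = 1.0;
    const int max_steps = 50;
    if (nc_hyper) nc_hyper_sweep(w, max_steps);
    z_sweep(w, max_steps);
    z_direction_sweep(w, max_steps);
    interweave_sweep(w, max_steps);
    z_sweep(w, max_steps);
    z_direction_sweep(w, max_steps);
    interweave_sweep(w, max_steps);
  }

  // One slice move per subject along a random direction of its own z block;
  // mixes along the within-subject posterior correlations (e.g. learning
  // rate vs temperature ridges) that coordinate-wise moves crawl across.
  void z_direction_sweep(double w, int max_steps) {
    const int K = d.K;
    std::vector<double> dir(K), base(K);
    for (int s = 0; s < d.S; ++s) {
      double norm = 0.0;
      for (int k = 0; k < K; ++k) {
        dir[k] = R::norm_rand();
        norm += dir[k] * dir[k];
      }
      norm = std::sqrt(norm);
      for (int k = 0; k < K; ++k) {
        dir[k] /= norm;
        base[k] = z[s * K + k];
      }
      auto logf = [&](double t) {
        double lp = 0.0;
        for (int k = 0; k < K; ++k) {
          const double zv = base[k] + t * dir[k];
          z[s * K + k] = zv;
          lp -= 0.5 * zv * zv;
        }
        lp += loglik_subject(s, mu.data(), eta.data(), z.data());
        for (int k = 0; k < K; ++k) z[s * K + k] = base[k];
        return lp;
      };
      double f0 = subj_ll[s];
      for (int k = 0; k < K; ++k) f0 -= 0.5 * base[k] * base[k];
      double f1;
      const double t1 = slice_update(logf, 0.0, f0, w, max_steps, &f1);
      if (t1 != 0.0) {
        double zsq = 0.0;
        for (int k = 0; k < K; ++k) {
          z[s * K + k] = base[k] + t1 * dir[k];
          zsq += 0.5 * z[s * K + k] * z[s * K + k];
        }
        subj_ll[s] = f1 + zsq;
      }
    }
  }

  void nc_hyper_sweep(double w, int max_steps) {
    for (int k = 0; k < d.K; ++k) {
      // mu[k]: conditional touches every subject's likelihood
      {
        auto logf = [&](double v) {
          double lp = prior_mu(k, v);
          const double old = mu[k];
          mu[k] = v;
          for (int s = 0; s < d.S; ++s)
            lp += loglik_subject(s, mu.data(), eta.data(), z.data());
          mu[k] = old;
          return lp;
        };
        double f0 = prior_mu(k, mu[k]);
        for (int s = 0; s < d.S; ++s) f0 += subj_ll[s];
        double f1;
        mu[k] = slice_update(logf, mu[k], f0, w, max_steps, &f1);
      }
      // eta[k]
      {
        auto logf = [&](double v) {
          double lp = prior_eta(k, v);
          const double old = eta[k];
          eta[k] = v;
          for (int s = 0; s < d.S; ++s)
            lp += loglik_subject(s, mu.data(), eta.data(), z.data());
          eta[k] = old;
          return lp;
        };
        double f0 = prior_eta(k, eta[k]);
        refresh_cache();
        for (int s = 0; s < d.S; ++s) f0 += subj_ll[s];
        double f1;
        eta[k] = slice_update(logf, eta[k], f0, w, max_steps, &f1);
      }
      refresh_cache();
    }
  }

  void z_sweep(double w, int max_steps) {
    // subject-level z: conditional touches one subject
    for (int s = 0; s < d.S; ++s) {
      for (int k = 0; k < d.K; ++k) {
        const int idx = s * d.K + k;
        auto logf = [&](double v) {
          const double old = z[idx];
          z[idx] = v;
          const double lp = -0.5 * v * v +
            loglik_subject(s, mu.data(), eta.data(), z.data());
          z[idx] = old;
          return lp;
        };
        const double f0 = -0.5 * z[idx] * z[idx] + subj_ll[s];
        double f1;
        z[idx] = slice_update(logf, z[idx], f0, w, max_steps, &f1);
        subj_ll[s] = f1 + 0.5 * z[idx] * z[idx];
      }
    }
  }

  // Centered hyper-update given phi = mu + sigma * z held fixed: mu is
  // conjugate normal, log-sigma gets a slice step; z is then back-solved so
  // the subject parameters (and the likelihood cache) are untouched.
  void interweave_sweep(double w, int max_steps) {
    std::vector<double> phi(d.S);
    for (int k = 0; k < d.K; ++k) {
      double sigma = std::exp(eta[k]);
      double sum_phi = 0.0;
      for (int s = 0; s < d.S; ++s) {
        phi[s] = mu[k] + sigma * z[s * d.K + k];
        sum_phi += phi[s];
      }
      const double prec = d.S / (sigma * sigma) +
        1.0 / (d.mu_scale[k] * d.mu_scale[k]);
      const double mean = (sum_phi / (sigma * sigma)) / prec;
      mu[k] = mean + R::norm_rand() / std::sqrt(prec);
      auto logf = [&](double v) {
        const double sg = std::exp(v);
        double lp = prior_eta(k, v) - d.S * v;
        double ss = 0.0;
        for (int s = 0; s < d.S; ++s) {
          const double r = phi[s] - mu[k];
          ss += r * r;
        }
        return lp - 0.5 * ss / (sg * sg);
      };
      double f1;
      eta[k] = slice_update(logf, eta[k], logf(eta[k]), w, max_steps, &f1);
      sigma = std::exp(eta[k]);
      for (int s = 0; s < d.S; ++s) z[s * d.K + k] = (phi[s] - mu[k]) / sigma;
    }
  }
};

// Returns a list with draws of mu (raw), sigma, and subject natural parameters.
// [[Rcpp::export]]
List cpp_fit_hier(IntegerVector spec, IntegerVector offsets, IntegerVector opp,
                  IntegerVector choice, IntegerVector opp_choice,
                  NumericVector reward, NumericVector lower,
                  NumericVector upper, IntegerVector bounded,
                  NumericVector mu_scale, NumericVector sigma_scale,
                  double A, double B, double rscale,
                  int chains, int warmup, int iter) {
  HierModel h;
  h.d.mc = read_spec(spec);
  h.d.S = offsets.size() - 1;
  h.d.K = lower.size();
  h.d.offsets = offsets.begin();
  h.d.opp = opp.begin();
  h.d.cho = choice.begin();
  h.d.och = opp_choice.begin();
  h.d.rew = reward.begin();
  h.d.A = A; h.d.B = B; h.d.rscale = rscale;
  h.d.lower = lower.begin();
  h.d.upper = upper.begin();
  h.d.bounded = bounded.begin();
  h.d.mu_scale = mu_scale.begin();
  h.d.sigma_scale = sigma_scale.begin();

  const int S = h.d.S, K = h.d.K;
  const int n_keep = chains * iter;
  NumericMatrix mu_draws(n_keep, K), sigma_draws(n_keep, K);
  NumericMatrix nat_draws(n_keep, S * K);
  IntegerVector chain_id(n_keep);

  int row = 0;
  for (int c = 0; c < chains; ++c) {
    // overdispersed-but-modest chain initialization
    h.mu.assign(K, 0.0);
    h.eta.assign(K, 0.0);
    h.z.assign(S * K, 0.0);
    for (int k = 0; k < K; ++k) {
      h.mu[k] = 0.5 * R::norm_rand();
      h.eta[k] = std::log(0.5) + 0.3 * R::norm_rand();
    }
    for (int i = 0; i < S * K; ++i) h.z[i] = 0.2 * R::norm_rand();
    h.refresh_cache();
    for (int it = 0; it < warmup + iter; ++it) {
      // two full passes per recorded iteration keep the retained draws
      // close to independent even at reduced chain lengths
      h.sweep(it % 3 == 0);
      h.sweep(false);
      if (it >= warmup) {
        for (int k = 0; k < K; ++k) {
          mu_draws(row, k) = h.mu[k];
          sigma_draws(row, k) = std::exp(h.eta[k]);
        }
        for (int s = 0; s < S; ++s)
          for (int k = 0; k < K; ++k)
            nat_draws(row, s * K + k) =
              h.natural(k, h.mu[k] + std::exp(h.eta[k]) * h.z[s * K + k]);
        chain_id[row] = c + 1;
        ++row;
      }
      if ((it & 63) == 0) Rcpp::checkUserInterrupt();
    }
  }
  return List::create(_["mu"] = mu_draws, _["sigma"] = sigma_draws,
                      _["nat"] = nat_draws, _["chain"] = chain_id);
}
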