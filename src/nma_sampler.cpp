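#include <Rcpp.h>
using namespace Rcpp;

// Adaptive random-walk Metropolis-within-Gibbs sampler for the arm-based
// negative binomial network meta-analysis.
//
// Model (arms a = 0..A-1 grouped by study, baseline arm first within study):
//   y_a ~ NB(mean = E_a * exp(mu_{s(a)} + delta_a), dispersion = kappa)
//   delta = 0 for baseline arms.
// Random effects: study contrasts delta_i (non-baseline arms of study i) are
// multivariate normal with mean md_ik = d[t_ik] - d[t_i,base], unit-variance
// sigma^2 and between-arm correlation 1/2:
//   Sigma = sigma^2 (I + J) / 2,  Sigma^{-1} = (2/sigma^2)(I - J/(m+1)),
//   det(Sigma) = (sigma^2/2)^m (m+1).
// Fixed effects: delta_ik == md_ik, sigma == 0.
// Priors: d, mu ~ N(0, prior_sd^2); sigma ~ U(0, sigma_upper);
// kappa ~ Gamma(kappa_shape, kappa_rate), sampled on the log scale.
//
// Uses R's RNG throughout, so chains are exactly reproducible from set.seed.

namespace {

struct NmaData {
  IntegerVector y;
  NumericVector E;
  IntegerVector study;   // 0-based study index per arm
  IntegerVector treat;   // 0-based treatment index per arm (0 = reference)
  int S, T, A;
  std::vector<int> s_start, s_end;      // arm ranges per study
  std::vector<int> base_treat;          // baseline treatment per study
  std::vector<std::vector<int>> studies_with_treat;  // per treatment
};

struct NmaState {
  std::vector<double> d;      // length T, d[0] fixed at 0
  std::vector<double> mu;     // length S
  std::vector<double> delta;  // length A, baseline arms 0
  double sigma;
  std::vector<double> kappa;  // length 1 (shared) or S (per-study)
  bool random_effects;
  bool per_study_kappa;
  bool kappa_is_fixed;
};

inline double kappa_of(const NmaData &dat, const NmaState &st, int arm) {
  return st.per_study_kappa ? st.kappa[dat.study[arm]] : st.kappa[0];
}

inline double delta_eff(const NmaData &dat, const NmaState &st, int arm) {
  if (st.random_effects) return st.delta[arm];
  int s = dat.study[arm];
  return st.d[dat.treat[arm]] - st.d[dat.base_treat[s]];
}

inline double ll_arm(const NmaData &dat, const NmaState &st, int arm) {
  double m = dat.E[arm] * std::exp(st.mu[dat.study[arm]] +
                                   delta_eff(dat, st, arm));
  return R::dnbinom_mu(dat.y[arm], kappa_of(dat, st, arm), m, 1);
}

// log prior of the random study contrasts of study s
double delta_prior_study(const NmaData &dat, const NmaState &st, int s) {
  if (!st.random_effects) return 0.0;
  int lo = dat.s_start[s], hi = dat.s_end[s];
  int m = hi - lo;  // non-baseline arms (baseline is arm lo - 1)
  if (m <= 0) return 0.0;
  double se = 0.0, sse = 0.0;
  for (int a = lo; a < hi; ++a) {
    double md = st.d[dat.treat[a]] - st.d[dat.base_treat[s]];
    double e = st.delta[a] - md;
    se += e;
    sse += e * e;
  }
  double s2 = st.sigma * st.sigma;
  double quad = (2.0 / s2) * (sse - se * se / (m + 1.0));
  return -0.5 * (m * std::log(2.0 * M_PI) + m * std::log(s2 / 2.0) +
                 std::log(m + 1.0) + quad);
}

double ll_study(const NmaData &dat, const NmaState &st, int s) {
  double out = 0.0;
  for (int a = dat.s_start[s] - 1; a < dat.s_end[s]; ++a)
    out += ll_arm(dat, st, a);
  return out;
}

double ll_all(const NmaData &dat, const NmaState &st) {
  double out = 0.0;
  for (int a = 0; a < dat.A; ++a) out += ll_arm(dat, st, a);
  return out;
}

struct Adapt {
  std::vector<double> lsd;    // log proposal sd per parameter
  std::vector<int> n, acc;
  void init(int k, double start) {
    lsd.assign(k, start);
    n.assign(k, 0);
    acc.assign(k, 0);
  }
  void tally(int i, bool accepted, bool adapting) {
    if (!adapting) return;
    n[i]++;
    if (accepted) acc[i]++;
    if (n[i] == 50) {
      double rate = acc[i] / 50.0;
      lsd[i] += (rate > 0.44 ? 0.1 : -0.1);
      if (lsd[i] > 4.0) lsd[i] = 4.0;
      if (lsd[i] < -8.0) lsd[i] = -8.0;
      n[i] = 0;
      acc[i] = 0;
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".nma_mcmc_chain")]]
List nma_mcmc_chain(IntegerVector y, NumericVector E, IntegerVector study,
                    IntegerVector treat, int S, int T,
                    bool random_effects, double sigma_upper, double prior_sd,
                    double kappa_shape, double kappa_rate,
                    bool per_study_kappa, double kappa_fixed,
                    int n_burn, int n_draw,
                    NumericVector init_mu, double init_sigma,
                    double init_kappa) {
  NmaData dat;
  dat.y = y;
  dat.E = E;
  dat.study = study;
  dat.treat = treat;
  dat.S = S;
  dat.T = T;
  dat.A = y.size();
  dat.s_start.assign(S, -1);
  dat.s_end.assign(S, -1);
  dat.base_treat.assign(S, -1);
  for (int a = 0; a < dat.A; ++a) {
    int s = study[a];
    if (dat.base_treat[s] < 0) {       // first (baseline) arm of the study
      dat.base_treat[s] = treat[a];
      dat.s_start[s] = a + 1;           // non-baseline arms start after it
    }
    dat.s_end[s] = a + 1;
  }
  dat.studies_with_treat.assign(T, std::vector<int>());
  for (int s = 0; s < S; ++s) {
    std::vector<bool> seen(T, false);
    for (int a = dat.s_start[s] - 1; a < dat.s_end[s]; ++a)
      seen[treat[a]] = true;
    for (int t = 0; t < T; ++t)
      if (seen[t]) dat.studies_with_treat[t].push_back(s);
  }

  NmaState st;
  st.random_effects = random_effects;
  st.per_study_kappa = per_study_kappa;
  st.kappa_is_fixed = kappa_fixed > 0;
  st.d.assign(T, 0.0);
  st.mu.assign(S, 0.0);
  for (int s = 0; s < S; ++s) st.mu[s] = init_mu[s];
  st.delta.assign(dat.A, 0.0);
  st.sigma = random_effects ? init_sigma : 0.0;
  int nk = per_study_kappa ? S : 1;
  st.kappa.assign(nk, st.kappa_is_fixed ? kappa_fixed : init_kappa);

  RNGScope scope;
  // small deterministic jitter so over-dispersed chains differ
  for (int t = 1; t < T; ++t) st.d[t] = R::rnorm(0.0, 0.2);
  for (int s = 0; s < S; ++s) st.mu[s] += R::rnorm(0.0, 0.2);
  if (random_effects) {
    for (int s = 0; s < S; ++s)
      for (int a = dat.s_start[s]; a < dat.s_end[s]; ++a)
        st.delta[a] = st.d[treat[a]] - st.d[dat.base_treat[s]] +
                      R::rnorm(0.0, 0.1);
    st.sigma = std::min(sigma_upper * 0.999,
                        std::max(1e-3, init_sigma * std::exp(R::rnorm(0, 0.2))));
  }

  // parameter bookkeeping: d (T-1), mu (S), delta (#non-baseline arms, RE),
  // sigma (RE), kappa (nk unless fixed)
  int n_delta = 0;
  std::vector<int> delta_arms;
  if (random_effects) {
    for (int s = 0; s < S; ++s)
      for (int a = dat.s_start[s]; a < dat.s_end[s]; ++a)
        delta_arms.push_back(a);
    n_delta = delta_arms.size();
  }
  int off_d = 0, off_mu = T - 1, off_delta = off_mu + S,
      off_sigma = off_delta + n_delta, off_kappa = off_sigma + 1,
      off_joint = off_kappa + nk;
  int off_joint2 = off_joint + (T - 1);
  int n_par = off_joint2 + 1;
  Adapt ad;
  ad.init(n_par, std::log(0.2));

  int n_out = (T - 1) + S + 1 + nk + n_delta;
  NumericMatrix draws(n_draw, n_out);

  int total = n_burn + n_draw;
  for (int iter = 0; iter < total; ++iter) {
    bool adapting = iter < n_burn;

    // --- d updates ---
    for (int t = 1; t < T; ++t) {
      int pi = off_d + (t - 1);
      double prop = st.d[t] + R::rnorm(0.0, std::exp(ad.lsd[pi]));
      double cur_lp = R::dnorm(st.d[t], 0.0, prior_sd, 1);
      double new_lp = R::dnorm(prop, 0.0, prior_sd, 1);
      double old_d = st.d[t];
      double delta_ll = 0.0;
      const std::vector<int> &ss = dat.studies_with_treat[t];
      if (random_effects) {
        for (size_t j = 0; j < ss.size(); ++j)
          delta_ll -= delta_prior_study(dat, st, ss[j]);
        st.d[t] = prop;
        for (size_t j = 0; j < ss.size(); ++j)
          delta_ll += delta_prior_study(dat, st, ss[j]);
      } else {
        for (size_t j = 0; j < ss.size(); ++j)
          delta_ll -= ll_study(dat, st, ss[j]);
        st.d[t] = prop;
        for (size_t j = 0; j < ss.size(); ++j)
          delta_ll += ll_study(dat, st, ss[j]);
      }
      double lacc = delta_ll + new_lp - cur_lp;
      bool accepted = std::log(R::runif(0.0, 1.0)) < lacc;
      if (!accepted) st.d[t] = old_d;
      ad.tally(pi, accepted, adapting);
    }

    // --- joint d translation moves (random effects only) ---
    // shifting d[t] by eps while shifting the coupled study contrasts the
    // same way keeps delta - md invariant (delta prior unchanged), so the
    // move is judged by the likelihood: this decouples d from the tight
    // random-effects prior and fixes the slow mixing of plain d updates.
    if (random_effects) {
      for (int t = 1; t < T; ++t) {
        int pi = off_joint + (t - 1);
        double eps = R::rnorm(0.0, std::exp(ad.lsd[pi]));
        const std::vector<int> &ss = dat.studies_with_treat[t];
        double delta_ll = 0.0;
        for (size_t j = 0; j < ss.size(); ++j)
          delta_ll -= ll_study(dat, st, ss[j]);
        double old_d = st.d[t];
        std::vector<std::pair<int, double>> saved;
        for (size_t j = 0; j < ss.size(); ++j) {
          int s = ss[j];
          for (int a = dat.s_start[s]; a < dat.s_end[s]; ++a) {
            double shift = 0.0;
            if (dat.base_treat[s] == t) shift = -eps;
            else if (dat.treat[a] == t) shift = eps;
            if (shift != 0.0) {
              saved.push_back(std::make_pair(a, st.delta[a]));
              st.delta[a] += shift;
            }
          }
        }
        st.d[t] = old_d + eps;
        for (size_t j = 0; j < ss.size(); ++j)
          delta_ll += ll_study(dat, st, ss[j]);
        delta_ll += R::dnorm(st.d[t], 0.0, prior_sd, 1) -
                    R::dnorm(old_d, 0.0, prior_sd, 1);
        bool accepted = std::log(R::runif(0.0, 1.0)) < delta_ll;
        if (!accepted) {
          st.d[t] = old_d;
          for (size_t j = 0; j < saved.size(); ++j)
            st.delta[saved[j].first] = saved[j].second;
        }
        ad.tally(pi, accepted, adapting);
      }
    }

    // --- mu updates ---
    for (int s = 0; s < S; ++s) {
      int pi = off_mu + s;
      double old_mu = st.mu[s];
      double prop = old_mu + R::rnorm(0.0, std::exp(ad.lsd[pi]));
      double delta_ll = -ll_study(dat, st, s);
      st.mu[s] = prop;
      delta_ll += ll_study(dat, st, s);
      delta_ll += R::dnorm(prop, 0.0, prior_sd, 1) -
                  R::dnorm(old_mu, 0.0, prior_sd, 1);
      bool accepted = std::log(R::runif(0.0, 1.0)) < delta_ll;
      if (!accepted) st.mu[s] = old_mu;
      ad.tally(pi, accepted, adapting);
    }

    // --- delta updates (random effects) ---
    if (random_effects) {
      for (int j = 0; j < n_delta; ++j) {
        int a = delta_arms[j];
        int s = dat.study[a];
        int pi = off_delta + j;
        double old_delta = st.delta[a];
        double prop = old_delta + R::rnorm(0.0, std::exp(ad.lsd[pi]));
        double delta_ll = -ll_arm(dat, st, a) - delta_prior_study(dat, st, s);
        st.delta[a] = prop;
        delta_ll += ll_arm(dat, st, a) + delta_prior_study(dat, st, s);
        bool accepted = std::log(R::runif(0.0, 1.0)) < delta_ll;
        if (!accepted) st.delta[a] = old_delta;
        ad.tally(pi, accepted, adapting);
      }

      // --- sigma update: log-scale walk (uniform prior, so Jacobian only) ---
      {
        int pi = off_sigma;
        double old_sigma = st.sigma;
        double prop = old_sigma * std::exp(R::rnorm(0.0, std::exp(ad.lsd[pi])));
        bool accepted = false;
        if (prop > 0.0 && prop < sigma_upper) {
          double delta_ll = 0.0;
          for (int s = 0; s < S; ++s)
            delta_ll -= delta_prior_study(dat, st, s);
          st.sigma = prop;
          for (int s = 0; s < S; ++s)
            delta_ll += delta_prior_study(dat, st, s);
          delta_ll += std::log(prop) - std::log(old_sigma);
          accepted = std::log(R::runif(0.0, 1.0)) < delta_ll;
          if (!accepted) st.sigma = old_sigma;
        }
        ad.tally(pi, accepted, adapting);
      }
    }

    // --- joint sigma rescaling move ---
    // (sigma, delta) -> (c sigma, md + c (delta - md)): the delta-prior
    // change cancels the transform Jacobian exactly, so the move is judged
    // by the likelihood plus the log-walk Jacobian on sigma. Avoids the
    // funnel between sigma and the contrast residuals.
    if (random_effects) {
      int pi = off_joint2;
      double c = std::exp(R::rnorm(0.0, std::exp(ad.lsd[pi])));
      double prop = st.sigma * c;
      bool accepted = false;
      if (prop > 0.0 && prop < sigma_upper) {
        double delta_ll = 0.0;
        for (int j = 0; j < n_delta; ++j)
          delta_ll -= ll_arm(dat, st, delta_arms[j]);
        std::vector<double> saved(n_delta);
        for (int j = 0; j < n_delta; ++j) {
          int a = delta_arms[j];
          int s = dat.study[a];
          double md = st.d[dat.treat[a]] - st.d[dat.base_treat[s]];
          saved[j] = st.delta[a];
          st.delta[a] = md + c * (st.delta[a] - md);
        }
        double old_sigma = st.sigma;
        st.sigma = prop;
        for (int j = 0; j < n_delta; ++j)
          delta_ll += ll_arm(dat, st, delta_arms[j]);
        delta_ll += std::log(c);
        accepted = std::log(R::runif(0.0, 1.0)) < delta_ll;
        if (!accepted) {
          st.sigma = old_sigma;
          for (int j = 0; j < n_delta; ++j)
            st.delta[delta_arms[j]] = saved[j];
        }
      }
      ad.tally(pi, accepted, adapting);
    }

    // --- kappa updates (log scale) ---
    if (!st.kappa_is_fixed) {
      for (int k = 0; k < nk; ++k) {
        int pi = off_kappa + k;
        double old_kappa = st.kappa[k];
        double prop = old_kappa * std::exp(R::rnorm(0.0, std::exp(ad.lsd[pi])));
        double delta_ll;
        if (per_study_kappa) {
          delta_ll = -ll_study(dat, st, k);
          st.kappa[k] = prop;
          delta_ll += ll_study(dat, st, k);
        } else {
          delta_ll = -ll_all(dat, st);
          st.kappa[k] = prop;
          delta_ll += ll_all(dat, st);
        }
        // Gamma(shape, rate) prior + log-scale Jacobian
        delta_ll += kappa_shape * (std::log(prop) - std::log(old_kappa)) -
                    kappa_rate * (prop - old_kappa);
        bool accepted = std::log(R::runif(0.0, 1.0)) < delta_ll;
        if (!accepted) st.kappa[k] = old_kappa;
        ad.tally(pi, accepted, adapting);
      }
    }

    if (iter >= n_burn) {
      int r = iter - n_burn;
      int c = 0;
      for (int t = 1; t < T; ++t) draws(r, c++) = st.d[t];
      for (int s = 0; s < S; ++s) draws(r, c++) = st.mu[s];
      draws(r, c++) = st.sigma;
      for (int k = 0; k < nk; ++k) draws(r, c++) = st.kappa[k];
      for (int j = 0; j < n_delta; ++j) draws(r, c++) = st.delta[delta_arms[j]];
    }
  }

  return List::create(_["draws"] = draws,
                      _["n_delta"] = n_delta,
                      _["delta_arms"] = IntegerVector(delta_arms.begin(),
                                                      delta_arms.end()));
}
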