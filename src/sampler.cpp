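// Adaptive Metropolis-within-Gibbs sampler for the hierarchical
// ordered-probit maturation-timing model. Single-site random-walk updates
// with per-parameter step-size adaptation during burn-in only (target
// acceptance 0.44); random-effect and imputed-covariate updates touch only
// the observations they enter, so one sweep is linear in the data.
//
// The parameter vector layout is built on the R side (model_layout()) and
// passed here as 0-based block offsets; an offset of -1 marks an absent
// block. All R RNG draws go through the R generator, so set.seed() on the
// R side makes chains bit-reproducible.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct Model {
  NumericVector t, mass, dt;
  IntegerVector bat, treat, cls;
  std::vector<std::vector<int>> obs_by_bat;
  int n_obs, n_bats, K, nf, npar;
  double fixed_day, su_fix, se_fix;
  bool est_delay, est_cov, est_su, est_se, impute;
  double p_tau, p_del, p_eff, p_sig, h_mu_sd, h_sd_scale, prob_floor;
  int link;
  // offsets
  int off_e, off_d, off_gm0, off_gm1, off_gd0, off_gd1, off_u;
  int off_lsu, off_lse, off_hyper, off_im, off_id;
  IntegerVector miss_m, miss_d;
  // working covariate values (imputed entries overwritten in place)
  std::vector<double> mass_cur, dt_cur;
  long clip_count = 0;

  double sigma_u(const std::vector<double>& th) const {
    return est_su ? std::exp(th[off_lsu]) : su_fix;
  }
  double sigma_e(const std::vector<double>& th) const {
    return est_se ? std::exp(th[off_lse]) : se_fix;
  }
  double cdf(double z) const {
    return link == 0 ? R::pnorm(z, 0.0, 1.0, 1, 0)
                     : 1.0 / (1.0 + std::exp(-z));
  }

  // log P(cls_j | theta), covariates taken from mass_cur/dt_cur
  double obs_loglik(int j, const std::vector<double>& th) {
    double se = sigma_e(th);
    double lat = t[j] + th[off_u + bat[j]];
    int y = cls[j];
    // S_c = P(class >= c); need S_y and S_{y+1}
    double Sy = 1.0, Sy1 = 0.0;
    double cum = fixed_day;
    int g = treat[j];
    for (int k = 1; k <= K; ++k) {
      double thr;
      if (k == 1) {
        thr = fixed_day;
      } else {
        cum += th[off_e + (k - 2)];
        thr = cum;
        if (est_delay && g == 1) thr += th[off_d + (k - 2)];
        if (est_cov) {
          int gm = (g == 0) ? off_gm0 : off_gm1;
          int gd = (g == 0) ? off_gd0 : off_gd1;
          thr += th[gm + (k - 2)] * mass_cur[j] + th[gd + (k - 2)] * dt_cur[j];
        }
      }
      if (k == y || k == y + 1) {
        double S = cdf((lat - thr) / se);
        if (k == y) Sy = S; else Sy1 = S;
      }
      if (k > y + 1) break;  // later thresholds don't enter this cell
    }
    double p = Sy - Sy1;
    if (p < prob_floor) { p = prob_floor; ++clip_count; }
    return std::log(p);
  }

  double full_loglik(std::vector<double>& th) {
    double s = 0;
    for (int j = 0; j < n_obs; ++j) s += obs_loglik(j, th);
    return s;
  }
  double bat_loglik(int i, std::vector<double>& th) {
    double s = 0;
    for (int j : obs_by_bat[i]) s += obs_loglik(j, th);
    return s;
  }

  double half_normal_lp(double x, double scale) const {
    if (x <= 0) return R_NegInf;
    return R::dnorm(x, 0.0, scale, 1);
  }

  // log conditional posterior terms that involve parameter p
  double cond_lp(int p, std::vector<double>& th) {
    // threshold increments: positivity + half-normal prior + full lik
    if (p >= off_e && p < off_e + nf) {
      double lp = half_normal_lp(th[p], p_tau);
      if (!std::isfinite(lp)) return lp;
      return lp + full_loglik(th);
    }
    if (est_delay && p >= off_d && p < off_d + nf) {
      return R::dnorm(th[p], 0.0, p_del, 1) + full_loglik(th);
    }
    if (est_cov && p >= off_gm0 && p < off_gd1 + nf && off_gm0 >= 0 &&
        p < off_u) {
      return R::dnorm(th[p], 0.0, p_eff, 1) + full_loglik(th);
    }
    if (p >= off_u && p < off_u + n_bats) {
      int i = p - off_u;
      return R::dnorm(th[p], 0.0, sigma_u(th), 1) + bat_loglik(i, th);
    }
    if (est_su && p == off_lsu) {
      double su = std::exp(th[p]);
      double lp = half_normal_lp(su, p_sig) + th[p];  // + log-Jacobian
      for (int i = 0; i < n_bats; ++i) {
        lp += R::dnorm(th[off_u + i], 0.0, su, 1);
      }
      return lp;
    }
    if (est_se && p == off_lse) {
      double se = std::exp(th[p]);
      return half_normal_lp(se, p_sig) + th[p] + full_loglik(th);
    }
    if (impute && p >= off_hyper && p < off_hyper + 4) {
      bool is_mass = (p - off_hyper) < 2;
      double mu = th[off_hyper + (is_mass ? 0 : 2)];
      double sd = std::exp(th[off_hyper + (is_mass ? 1 : 3)]);
      double lp;
      if (p == off_hyper || p == off_hyper + 2) {
        lp = R::dnorm(mu, 0.0, h_mu_sd, 1);
      } else {
        lp = half_normal_lp(sd, h_sd_scale) + th[p];
      }
      // observed values inform the hyper-parameters; imputed values too
      const std::vector<double>& x = is_mass ? mass_cur : dt_cur;
      for (int j = 0; j < n_obs; ++j) lp += R::dnorm(x[j], mu, sd, 1);
      return lp;
    }
    if (impute && off_im >= 0 && p >= off_im && p < off_im + miss_m.size()) {
      int j = miss_m[p - off_im];
      mass_cur[j] = th[p];
      double mu = th[off_hyper + 0], sd = std::exp(th[off_hyper + 1]);
      return R::dnorm(th[p], mu, sd, 1) + obs_loglik(j, th);
    }
    if (impute && off_id >= 0 && p >= off_id && p < off_id + miss_d.size()) {
      int j = miss_d[p - off_id];
      dt_cur[j] = th[p];
      double mu = th[off_hyper + 2], sd = std::exp(th[off_hyper + 3]);
      return R::dnorm(th[p], mu, sd, 1) + obs_loglik(j, th);
    }
    stop("internal: parameter index out of range");
    return 0;
  }

  // full joint log posterior (for cross-checks from R)
  double log_posterior(std::vector<double>& th) {
    double lp = 0;
    for (int k = 0; k < nf; ++k) {
      double v = half_normal_lp(th[off_e + k], p_tau);
      if (!std::isfinite(v)) return R_NegInf;
      lp += v;
    }
    if (est_delay) {
      for (int k = 0; k < nf; ++k) lp += R::dnorm(th[off_d + k], 0, p_del, 1);
    }
    if (est_cov) {
      for (int o : {off_gm0, off_gm1, off_gd0, off_gd1}) {
        for (int k = 0; k < nf; ++k) lp += R::dnorm(th[o + k], 0, p_eff, 1);
      }
    }
    double su = sigma_u(th);
    for (int i = 0; i < n_bats; ++i) {
      lp += R::dnorm(th[off_u + i], 0.0, su, 1);
    }
    if (est_su) lp += half_normal_lp(su, p_sig) + th[off_lsu];
    if (est_se) {
      lp += half_normal_lp(sigma_e(th), p_sig) + th[off_lse];
    }
    if (impute) {
      double mu_m = th[off_hyper], sd_m = std::exp(th[off_hyper + 1]);
      double mu_d = th[off_hyper + 2], sd_d = std::exp(th[off_hyper + 3]);
      lp += R::dnorm(mu_m, 0, h_mu_sd, 1) +
            half_normal_lp(sd_m, h_sd_scale) + th[off_hyper + 1] +
            R::dnorm(mu_d, 0, h_mu_sd, 1) +
            half_normal_lp(sd_d, h_sd_scale) + th[off_hyper + 3];
      for (int j = 0; j < n_obs; ++j) {
        lp += R::dnorm(mass_cur[j], mu_m, sd_m, 1) +
              R::dnorm(dt_cur[j], mu_d, sd_d, 1);
      }
    }
    return lp + full_loglik(th);
  }
};

Model build_model(const List& pay, const std::vector<double>& init) {
  Model m;
  m.t = pay["t"]; m.bat = pay["bat"]; m.treat = pay["treat"];
  m.cls = pay["cls"]; m.mass = pay["mass"]; m.dt = pay["dt"];
  m.miss_m = pay["miss_m"]; m.miss_d = pay["miss_d"];
  m.n_obs = m.t.size();
  m.n_bats = as<int>(pay["n_bats"]);
  m.K = as<int>(pay["K"]);
  m.nf = m.K - 1;
  m.npar = as<int>(pay["npar"]);
  m.fixed_day = as<double>(pay["fixed_day"]);
  m.est_delay = as<int>(pay["est_delay"]) != 0;
  m.est_cov = as<int>(pay["est_cov"]) != 0;
  m.est_su = as<int>(pay["est_su"]) != 0;
  m.est_se = as<int>(pay["est_se"]) != 0;
  m.impute = as<int>(pay["impute"]) != 0;
  m.su_fix = as<double>(pay["su_fix"]);
  m.se_fix = as<double>(pay["se_fix"]);
  m.p_tau = as<double>(pay["p_tau"]);
  m.p_del = as<double>(pay["p_del"]);
  m.p_eff = as<double>(pay["p_eff"]);
  m.p_sig = as<double>(pay["p_sig"]);
  m.h_mu_sd = as<double>(pay["h_mu_sd"]);
  m.h_sd_scale = as<double>(pay["h_sd_scale"]);
  m.prob_floor = as<double>(pay["prob_floor"]);
  m.link = as<int>(pay["link"]);
  List off = pay["off"];
  m.off_e = as<int>(off["e"]); m.off_d = as<int>(off["d"]);
  m.off_gm0 = as<int>(off["gm0"]); m.off_gm1 = as<int>(off["gm1"]);
  m.off_gd0 = as<int>(off["gd0"]); m.off_gd1 = as<int>(off["gd1"]);
  m.off_u = as<int>(off["u"]); m.off_lsu = as<int>(off["lsu"]);
  m.off_lse = as<int>(off["lse"]); m.off_hyper = as<int>(off["hyper"]);
  m.off_im = as<int>(off["im"]); m.off_id = as<int>(off["id"]);
  List obb = pay["obs_by_bat"];
  m.obs_by_bat.resize(m.n_bats);
  for (int i = 0; i < m.n_bats; ++i) {
    IntegerVector v = obb[i];
    m.obs_by_bat[i] = std::vector<int>(v.begin(), v.end());
  }
  m.mass_cur = std::vector<double>(m.mass.begin(), m.mass.end());
  m.dt_cur = std::vector<double>(m.dt.begin(), m.dt.end());
  // seed working covariates from initial imputed values
  if (m.impute && m.off_im >= 0) {
    for (int q = 0; q < m.miss_m.size(); ++q) {
      m.mass_cur[m.miss_m[q]] = init[m.off_im + q];
    }
  }
  if (m.impute && m.off_id >= 0) {
    for (int q = 0; q < m.miss_d.size(); ++q) {
      m.dt_cur[m.miss_d[q]] = init[m.off_id + q];
    }
  }
  return m;
}

}  // namespace

// [[Rcpp::export]]
List run_mcmc_chain(List pay, NumericVector init, NumericVector step,
                    int n_iter, int burnin, int thin) {
  std::vector<double> th(init.begin(), init.end());
  Model m = build_model(pay, th);
  int npar = m.npar;
  if ((int)th.size() != npar || step.size() != npar) {
    stop("init/step length does not match parameter count");
  }
  std::vector<double> ls(npar);
  for (int p = 0; p < npar; ++p) ls[p] = std::log(step[p]);
  std::vector<long> acc(npar, 0), tot(npar, 0);
  std::vector<int> acc_win(npar, 0);
  double ls_scale = std::log(0.5);
  int acc_scale_win = 0;
  int n_keep = (n_iter - burnin) / thin;
  NumericMatrix draws(n_keep, npar);
  int kept = 0, batch = 0;
  const int adapt_every = 50;

  for (int it = 0; it < n_iter; ++it) {
    for (int p = 0; p < npar; ++p) {
      double old = th[p];
      double cur_lp = m.cond_lp(p, th);  // also syncs covariate caches
      th[p] = old + std::exp(ls[p]) * norm_rand();
      double new_lp = m.cond_lp(p, th);
      bool accept = std::isfinite(new_lp) &&
                    std::log(unif_rand()) < new_lp - cur_lp;
      if (!accept) {
        th[p] = old;
        // restore covariate cache if this was an imputed value
        if (m.impute && m.off_im >= 0 && p >= m.off_im &&
            p < m.off_im + m.miss_m.size()) {
          m.mass_cur[m.miss_m[p - m.off_im]] = old;
        }
        if (m.impute && m.off_id >= 0 && p >= m.off_id &&
            p < m.off_id + m.miss_d.size()) {
          m.dt_cur[m.miss_d[p - m.off_id]] = old;
        }
      } else {
        ++acc[p]; ++acc_win[p];
      }
      ++tot[p];
    }
    // joint rescaling of (sigma_u, u): the per-site sweep mixes the scale
    // of a hierarchy slowly, so propose u' = c*u, log sigma_u' += log c.
    // The u-prior terms cancel exactly against the transform Jacobian,
    // leaving the likelihood and the sigma_u prior (incl. its log-scale
    // Jacobian term) in the ratio.
    if (m.est_su) {
      double delta = std::exp(ls_scale) * norm_rand();
      double c = std::exp(delta);
      double su = std::exp(th[m.off_lsu]);
      double cur = m.full_loglik(th) +
                   m.half_normal_lp(su, m.p_sig) + th[m.off_lsu];
      std::vector<double> th2 = th;
      th2[m.off_lsu] += delta;
      for (int i = 0; i < m.n_bats; ++i) th2[m.off_u + i] *= c;
      double prop = m.full_loglik(th2) +
                    m.half_normal_lp(su * c, m.p_sig) + th2[m.off_lsu];
      if (std::isfinite(prop) && std::log(unif_rand()) < prop - cur) {
        th = th2;
        ++acc_scale_win;
      }
    }
    if (it < burnin && (it + 1) % adapt_every == 0) {
      ++batch;
      double delta = std::min(0.1, 1.0 / std::sqrt((double)batch));
      for (int p = 0; p < npar; ++p) {
        double rate = acc_win[p] / (double)adapt_every;
        ls[p] += (rate > 0.44) ? delta : -delta;
        acc_win[p] = 0;
      }
      if (m.est_su) {
        ls_scale += (acc_scale_win / (double)adapt_every > 0.3)
                        ? delta : -delta;
        acc_scale_win = 0;
      }
    }
    if (it >= burnin && (it - burnin) % thin == 0 && kept < n_keep) {
      for (int p = 0; p < npar; ++p) draws(kept, p) = th[p];
      ++kept;
    }
  }
  NumericVector arate(npar);
  for (int p = 0; p < npar; ++p) arate[p] = acc[p] / (double)tot[p];
  return List::create(_["draws"] = draws, _["accept"] = arate,
                      _["n_clipped"] = (double)m.clip_count);
}

// [[Rcpp::export]]
double cpp_log_posterior(List pay, NumericVector theta) {
  std::vector<double> th(theta.begin(), theta.end());
  Model m = build_model(pay, th);
  return m.log_posterior(th);
}
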