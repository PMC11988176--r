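#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Inverse-Gaussian draw (Michael-Schucany-Haas); uses R's RNG stream.
static double rinvgauss(double mu, double lambda) {
  double v = norm_rand();
  double y = v * v;
  double x = mu + (mu * mu * y) / (2.0 * lambda) -
             (mu / (2.0 * lambda)) *
                 std::sqrt(4.0 * mu * lambda * y + mu * mu * y * y);
  if (x <= 0) x = 1e-12;
  if (unif_rand() <= mu / (mu + x)) return x;
  return mu * mu / x;
}

static double dot(const double* a, const double* b, int n) {
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += a[i] * b[i];
  return s;
}

// Single-site Gibbs engine for the marker-effect models
//   y = mu + W g + e
// with W column-centered genotypes. model: 0 = BayesA, 1 = BayesB,
// 2 = BayesC, 3 = Bayesian LASSO, 4 = BayesR. Residuals are maintained
// incrementally on every effect update. pi is the prior probability of a
// ZERO effect (spike mass). S_* are sum-of-squares scales: the prior
// scaled-inverse-chi-square draw is (SS + S) / chisq(df + df_data).
// [[Rcpp::export]]
List gibbs_engine(NumericMatrix W, NumericVector y, int model, int n_iter,
                  int burn_in, int thin, double df_e, double S_e, double df_g,
                  double S_g, double pi0, bool update_pi, double bl_shape,
                  double bl_rate, double lambda2_init, double varg_init,
                  NumericVector comp_var_frac, double df_r, double S_r,
                  double sigma_g2_init) {
  const int n = W.nrow();
  const int m = W.ncol();
  if (y.size() != n) stop("y length does not match genotype rows");
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter");

  std::vector<double> xtx(m);
  for (int j = 0; j < m; ++j) xtx[j] = dot(&W(0, j), &W(0, j), n);

  std::vector<double> g(m, 0.0), sig2(m, varg_init), tau2(m, 1.0);
  std::vector<int> comp(m, 0), d_incl(m, 1);
  double mu = mean(y);
  std::vector<double> r(n);
  for (int i = 0; i < n; ++i) r[i] = y[i] - mu;

  double sigma_e2 = dot(r.data(), r.data(), n) / n * 0.5 + 1e-8;
  double pi = pi0;                 // P(effect == 0) for BayesB/C
  double lambda2 = lambda2_init;   // Bayesian LASSO
  double sigma_g2 = sigma_g2_init; // BayesR scale
  const int K = comp_var_frac.size();
  std::vector<double> pk(K, 1.0 / K); // BayesR mixture proportions

  const int n_keep = (n_iter - burn_in) / thin;
  NumericVector g_sum(m), pip_sum(m);
  NumericMatrix trace(n_keep, 5); // mu, sigma_e2, varg, pi, m_nonzero
  NumericVector comp_occ(K);
  double mu_sum = 0.0;
  int kept = 0;

  for (int it = 1; it <= n_iter; ++it) {
    // overall mean
    double rbar = 0.0;
    for (int i = 0; i < n; ++i) rbar += r[i];
    rbar /= n;
    double mu_new = R::rnorm(mu + rbar, std::sqrt(sigma_e2 / n));
    double dmu = mu_new - mu;
    for (int i = 0; i < n; ++i) r[i] -= dmu;
    mu = mu_new;

    int m_nz = 0;
    double ss_r = 0.0; // BayesR: sum g^2 / c_k over nonzero components
    std::vector<int> counts(K, 0);

    for (int j = 0; j < m; ++j) {
      const double* wj = &W(0, j);
      if (xtx[j] <= 0) { g[j] = 0.0; d_incl[j] = 0; if (model == 4) comp[j] = 0; continue; }
      double g_old = g[j];
      double rhs = dot(wj, r.data(), n) + xtx[j] * g_old;
      double g_new = 0.0;

      if (model == 0 || model == 3) { // BayesA / BL: always-in normal prior
        double vj = (model == 0) ? sig2[j] : tau2[j] * sigma_e2;
        if (vj < 1e-12) vj = 1e-12;
        double C = xtx[j] + sigma_e2 / vj;
        g_new = R::rnorm(rhs / C, std::sqrt(sigma_e2 / C));
        d_incl[j] = 1;
        ++m_nz;
      } else if (model == 1 || model == 2) { // BayesB / BayesC spike-slab
        double vj = (model == 1) ? sig2[j] : sig2[0];
        if (vj < 1e-12) vj = 1e-12;
        double v0 = xtx[j] * sigma_e2;
        double v1 = xtx[j] * xtx[j] * vj + v0;
        double logBF = 0.5 * (std::log(v0 / v1) + rhs * rhs * (1.0 / v0 - 1.0 / v1));
        bool incl;
        if (pi <= 0.0) incl = true;
        else if (pi >= 1.0) incl = false;
        else {
          double logodds = std::log((1.0 - pi) / pi) + logBF;
          double p_in = 1.0 / (1.0 + std::exp(-logodds));
          incl = unif_rand() < p_in;
        }
        if (incl) {
          double C = xtx[j] + sigma_e2 / vj;
          g_new = R::rnorm(rhs / C, std::sqrt(sigma_e2 / C));
          ++m_nz;
        }
        d_incl[j] = incl ? 1 : 0;
      } else { // BayesR four-component mixture
        double v0 = xtx[j] * sigma_e2;
        double maxlp = -INFINITY;
        std::vector<double> lp(K);
        for (int k = 0; k < K; ++k) {
          double ck = comp_var_frac[k];
          double vk = (ck > 0) ? xtx[j] * xtx[j] * ck * sigma_g2 + v0 : v0;
          lp[k] = std::log(pk[k] > 1e-300 ? pk[k] : 1e-300) -
                  0.5 * std::log(vk) - 0.5 * rhs * rhs / vk;
          if (lp[k] > maxlp) maxlp = lp[k];
        }
        double tot = 0.0;
        for (int k = 0; k < K; ++k) { lp[k] = std::exp(lp[k] - maxlp); tot += lp[k]; }
        double u = unif_rand() * tot, acc = 0.0;
        int k_sel = K - 1;
        for (int k = 0; k < K; ++k) { acc += lp[k]; if (u <= acc) { k_sel = k; break; } }
        comp[j] = k_sel;
        ++counts[k_sel];
        if (comp_var_frac[k_sel] > 0) {
          double vj = comp_var_frac[k_sel] * sigma_g2;
          double C = xtx[j] + sigma_e2 / vj;
          g_new = R::rnorm(rhs / C, std::sqrt(sigma_e2 / C));
          ss_r += g_new * g_new / comp_var_frac[k_sel];
          ++m_nz;
          d_incl[j] = 1;
        } else {
          d_incl[j] = 0;
        }
      }

      if (g_new != g_old) {
        double dg = g_old - g_new;
        for (int i = 0; i < n; ++i) r[i] += wj[i] * dg;
        g[j] = g_new;
      } else {
        g[j] = g_new;
      }
    }

    // variance updates
    if (model == 0) {
      for (int j = 0; j < m; ++j)
        sig2[j] = (g[j] * g[j] + S_g) / R::rchisq(df_g + 1.0);
    } else if (model == 1) {
      for (int j = 0; j < m; ++j) {
        if (d_incl[j]) sig2[j] = (g[j] * g[j] + S_g) / R::rchisq(df_g + 1.0);
        else sig2[j] = S_g / R::rchisq(df_g); // prior draw
      }
    } else if (model == 2) {
      double ssg = 0.0; int m_in = 0;
      for (int j = 0; j < m; ++j) if (d_incl[j]) { ssg += g[j] * g[j]; ++m_in; }
      sig2[0] = (ssg + S_g) / R::rchisq(df_g + m_in);
      if (update_pi) pi = R::rbeta(m - m_in + 1.0, m_in + 1.0);
    } else if (model == 3) {
      double sum_tau2 = 0.0;
      for (int j = 0; j < m; ++j) {
        double g2 = g[j] * g[j];
        if (g2 < 1e-12) {
          tau2[j] = exp_rand() * 2.0 / lambda2; // prior Exp(lambda2/2)
        } else {
          double mu_ig = std::sqrt(lambda2 * sigma_e2 / g2);
          double inv_t2 = rinvgauss(mu_ig, lambda2);
          tau2[j] = 1.0 / inv_t2;
        }
        sum_tau2 += tau2[j];
      }
      lambda2 = R::rgamma(bl_shape + m, 1.0 / (bl_rate + sum_tau2 / 2.0));
    } else if (model == 4) {
      int m_nz_r = 0;
      for (int k = 1; k < K; ++k) m_nz_r += counts[k];
      sigma_g2 = (ss_r + S_r) / R::rchisq(df_r + m_nz_r);
      // Dirichlet(1 + counts)
      double tot = 0.0;
      for (int k = 0; k < K; ++k) { pk[k] = R::rgamma(1.0 + counts[k], 1.0); tot += pk[k]; }
      for (int k = 0; k < K; ++k) pk[k] /= tot;
    }

    double sse = dot(r.data(), r.data(), n);
    sigma_e2 = (sse + S_e) / R::rchisq(df_e + n);
    if (sigma_e2 < 1e-12) sigma_e2 = 1e-12;

    if (it > burn_in && (it - burn_in) % thin == 0) {
      for (int j = 0; j < m; ++j) {
        g_sum[j] += g[j];
        pip_sum[j] += d_incl[j];
      }
      mu_sum += mu;
      double varg_snap;
      if (model == 0 || model == 1) {
        double s = 0.0;
        for (int j = 0; j < m; ++j) s += sig2[j];
        varg_snap = s / m;
      } else if (model == 2) varg_snap = sig2[0];
      else if (model == 3) {
        double s = 0.0;
        for (int j = 0; j < m; ++j) s += tau2[j];
        varg_snap = sigma_e2 * s / m;
      } else varg_snap = sigma_g2;
      trace(kept, 0) = mu;
      trace(kept, 1) = sigma_e2;
      trace(kept, 2) = varg_snap;
      trace(kept, 3) = pi;
      trace(kept, 4) = m_nz;
      if (model == 4)
        for (int k = 0; k < K; ++k) comp_occ[k] += counts[k];
      ++kept;
    }
  }

  for (int j = 0; j < m; ++j) {
    g_sum[j] /= kept;
    pip_sum[j] /= kept;
  }
  if (model == 4)
    for (int k = 0; k < K; ++k) comp_occ[k] /= kept;

  return List::create(
      _["effect_mean"] = g_sum, _["inclusion_prob"] = pip_sum,
      _["mu"] = mu_sum / kept, _["trace"] = trace, _["n_kept"] = kept,
      _["comp_occupancy"] = comp_occ);
}
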