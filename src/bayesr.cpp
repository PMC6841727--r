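#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Individual-level BayesR Gibbs sampler. Same hierarchical model as the
// summary-statistics sampler, but the state is maintained on individuals:
// the residual vector e = y - X beta is updated after every effect draw and
// r_j = x_j'e + x_j'x_j beta_j is computed by a dense dot product. Coded
// separately from the summary core so it can serve as an independent
// reference; the RNG call pattern (one uniform per label, one normal per
// nonzero effect, then rchisq/rgamma in fixed order) is the same, so seeded
// runs are comparable draw for draw.

static inline int categorical_draw_b(const std::vector<double>& logL, int C) {
  double m = logL[0];
  for (int c = 1; c < C; ++c) if (logL[c] > m) m = logL[c];
  double sum = 0.0;
  std::vector<double> pr(C);
  for (int c = 0; c < C; ++c) { pr[c] = std::exp(logL[c] - m); sum += pr[c]; }
  double u = unif_rand() * sum;
  double cum = 0.0;
  for (int c = 0; c < C; ++c) {
    cum += pr[c];
    if (u <= cum) return c;
  }
  return C - 1;
}

// [[Rcpp::export]]
List bayesr_mcmc_cpp(NumericMatrix X, NumericVector y,
                     NumericVector gamma, NumericVector pi_init,
                     NumericVector dirichlet_alpha,
                     double nu_beta, double S2_beta,
                     double nu_eps, double S2_eps,
                     int n_iter, int burn_in, int thin,
                     bool permute, int resid_check_every) {
  const int n = X.nrow();
  const int p = X.ncol();
  const int C = gamma.size();
  if (n == 0 || p == 0) stop("empty genotype matrix");

  std::vector<double> d(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    d[j] = s;
  }

  std::vector<double> beta(p, 0.0), e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i];
  std::vector<int> comp(p, 0);
  std::vector<double> pi(C), logpi(C);
  for (int c = 0; c < C; ++c) pi[c] = pi_init[c];
  double s2b = S2_beta, s2e = S2_eps;

  const int n_keep = (n_iter - burn_in) / thin;
  NumericMatrix beta_samples(p, n_keep);
  IntegerMatrix comp_samples(p, n_keep);
  NumericMatrix pi_samples(C, n_keep);
  NumericMatrix sigma2_samples(2, n_keep);
  NumericVector h2_samples(n_keep);
  double resid_max_rel_err = 0.0;

  std::vector<int> order(p);
  for (int j = 0; j < p; ++j) order[j] = j;
  std::vector<double> logL(C);

  for (int iter = 1; iter <= n_iter; ++iter) {
    if (permute) {
      for (int j = p - 1; j > 0; --j) {
        int k = (int)(unif_rand() * (j + 1));
        if (k > j) k = j;
        std::swap(order[j], order[k]);
      }
    }
    for (int c = 0; c < C; ++c) logpi[c] = std::log(pi[c]);

    for (int jj = 0; jj < p; ++jj) {
      const int j = order[jj];
      const double d_j = d[j];
      const double* xj = &X(0, j);
      double xe = 0.0;
      for (int i = 0; i < n; ++i) xe += xj[i] * e[i];
      const double r_j = xe + d_j * beta[j];
      logL[0] = logpi[0];
      for (int c = 1; c < C; ++c) {
        const double gs = gamma[c] * s2b;
        logL[c] = logpi[c] + 0.5 * (std::log(s2e / (s2e + gs * d_j)) +
                                    r_j * r_j * gs /
                                        (s2e * (s2e + gs * d_j)));
      }
      const int new_comp = categorical_draw_b(logL, C);
      double beta_new = 0.0;
      if (new_comp > 0) {
        const double l_jc = d_j + s2e / (gamma[new_comp] * s2b);
        beta_new = r_j / l_jc + std::sqrt(s2e / l_jc) * norm_rand();
      }
      const double delta = beta_new - beta[j];
      comp[j] = new_comp;
      beta[j] = beta_new;
      if (delta != 0.0) {
        for (int i = 0; i < n; ++i) e[i] -= xj[i] * delta;
      }
    }

    int q = 0;
    double ssq = 0.0;
    for (int j = 0; j < p; ++j) {
      if (comp[j] > 0) { ++q; ssq += beta[j] * beta[j] / gamma[comp[j]]; }
    }
    {
      const double df = nu_beta + q;
      const double scale = (ssq + nu_beta * S2_beta) / df;
      s2b = df * scale / Rf_rchisq(df);
    }

    {
      std::vector<int> counts(C, 0);
      for (int j = 0; j < p; ++j) counts[comp[j]]++;
      double tot = 0.0;
      for (int c = 0; c < C; ++c) {
        pi[c] = Rf_rgamma(dirichlet_alpha[c] + counts[c], 1.0);
        tot += pi[c];
      }
      for (int c = 0; c < C; ++c) pi[c] /= tot;
    }

    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    {
      const double df = nu_eps + n;
      const double scale = (sse + nu_eps * S2_eps) / df;
      s2e = df * scale / Rf_rchisq(df);
    }

    double gg = 0.0;
    for (int i = 0; i < n; ++i) {
      const double gi = y[i] - e[i];
      gg += gi * gi;
    }
    const double sigma_g2 = gg / n;
    const double h2 = sigma_g2 / (sigma_g2 + s2e);

    if (resid_check_every > 0 && iter % resid_check_every == 0) {
      std::vector<double> e_exact(n);
      for (int i = 0; i < n; ++i) e_exact[i] = y[i];
      for (int j = 0; j < p; ++j) {
        if (beta[j] != 0.0) {
          const double* xj = &X(0, j);
          for (int i = 0; i < n; ++i) e_exact[i] -= xj[i] * beta[j];
        }
      }
      double scale = 0.0, maxdiff = 0.0;
      for (int i = 0; i < n; ++i) {
        const double a = std::fabs(e_exact[i]);
        if (a > scale) scale = a;
        const double dd = std::fabs(e_exact[i] - e[i]);
        if (dd > maxdiff) maxdiff = dd;
      }
      const double rel = maxdiff / (scale > 0.0 ? scale : 1.0);
      if (rel > resid_max_rel_err) resid_max_rel_err = rel;
    }

    if (iter > burn_in && (iter - burn_in) % thin == 0) {
      const int s = (iter - burn_in) / thin - 1;
      if (s < n_keep) {
        for (int j = 0; j < p; ++j) {
          beta_samples(j, s) = beta[j];
          comp_samples(j, s) = comp[j] + 1;
        }
        for (int c = 0; c < C; ++c) pi_samples(c, s) = pi[c];
        sigma2_samples(0, s) = s2b;
        sigma2_samples(1, s) = s2e;
        h2_samples[s] = h2;
      }
    }
  }

  return List::create(_["beta_samples"] = beta_samples,
                      _["comp_samples"] = comp_samples,
                      _["pi_samples"] = pi_samples,
                      _["sigma2_samples"] = sigma2_samples,
                      _["h2_samples"] = h2_samples,
                      _["rhs_max_rel_err"] = resid_max_rel_err);
}
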