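#include <Rcpp.h>
using namespace Rcpp;

// Gibbs samplers for the Bayesian-alphabet marker-effect models A/B/C on
// y = mu + X w + e, e ~ N(0, se2 I), se2 ~ scaled-inv-chi2(df_e, Se).
//
// variant 1 (A): w_j ~ N(0, s2_j), s2_j ~ scaled-inv-chi2(df_w, Sw)
//                (marginally a scaled-t prior on w_j)
// variant 2 (B): spike at 0 with probability pi, scaled-t slab otherwise
//                (per-marker slab variance as in A)
// variant 3 (C): spike at 0 with probability pi, common-variance normal slab
//
// pi is the spike (exclusion) probability; it gets a Beta(1,1) prior and is
// sampled unless pi_sample is false (then it stays at pi_init; pi_init = 0
// puts every marker in the slab). Uses R's RNG, so results are reproducible
// under set.seed() from the calling R code.

static inline double rinvchisq(double df, double scale) {
  // scaled-inverse-chi-squared draw: df * scale / chi2_df
  return df * scale / R::rchisq(df);
}

// [[Rcpp::export]]
List bayes_gibbs_cpp(NumericMatrix X, NumericVector y, int variant,
                     int n_iter, int burn_in, int thin,
                     double df_w, double Sw, double df_e, double Se,
                     double pi_init, bool pi_sample, bool keep_traces) {
  const int n = X.nrow(), m = X.ncol();
  std::vector<double> xx(m);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xx[j] = s;
  }

  double mu = mean(y);
  std::vector<double> w(m, 0.0), s2(m, Sw * df_w / std::max(df_w - 2.0, 1.0));
  std::vector<int> incl(m, 1);
  double s2c = Sw * df_w / std::max(df_w - 2.0, 1.0); // common slab var (C)
  double se2 = Se * df_e / std::max(df_e - 2.0, 1.0);
  double pi = pi_init;
  bool spike = (variant != 1);
  if (!spike) pi = 0.0;

  std::vector<double> e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;

  std::vector<double> w_sum(m, 0.0);
  double mu_sum = 0.0, pi_sum = 0.0, se2_sum = 0.0;
  std::vector<double> incl_sum(m, 0.0);
  int n_kept = 0;
  std::vector<double> tr_se2, tr_pi, tr_mu;

  for (int it = 0; it < n_iter; ++it) {
    // intercept
    double ebar = 0.0;
    for (int i = 0; i < n; ++i) ebar += e[i];
    ebar /= n;
    double mu_new = mu + ebar + R::norm_rand() * std::sqrt(se2 / n);
    double dmu = mu_new - mu;
    for (int i = 0; i < n; ++i) e[i] -= dmu;
    mu = mu_new;

    int n_in = 0;
    double ssq_in = 0.0; // sum w_j^2 over included (for C)
    for (int j = 0; j < m; ++j) {
      if (xx[j] <= 0.0) { w[j] = 0.0; incl[j] = 0; continue; }
      double wj_old = w[j];
      // rhs = x_j' (e + x_j w_j)
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += X(i, j) * e[i];
      rhs += xx[j] * wj_old;

      double slab_var = (variant == 3) ? s2c : s2[j];
      bool in = true;
      if (spike && pi > 0.0) {
        // marginal likelihood ratio slab vs spike for this marker
        double v = se2 + slab_var * xx[j];
        double log_odds = std::log((1.0 - pi) / pi) +
          0.5 * (std::log(se2) - std::log(v)) +
          0.5 * slab_var * rhs * rhs / (se2 * v);
        double p_in = 1.0 / (1.0 + std::exp(-log_odds));
        in = (unif_rand() < p_in);
      }
      double wj_new = 0.0;
      if (in) {
        double Cjj = xx[j] + se2 / slab_var;
        wj_new = rhs / Cjj + R::norm_rand() * std::sqrt(se2 / Cjj);
        ++n_in;
        ssq_in += wj_new * wj_new;
      }
      incl[j] = in ? 1 : 0;
      double dw = wj_new - wj_old;
      if (dw != 0.0)
        for (int i = 0; i < n; ++i) e[i] -= X(i, j) * dw;
      w[j] = wj_new;

      // per-marker slab variance (A and B)
      if (variant != 3) {
        if (in)
          s2[j] = rinvchisq(df_w + 1.0, (df_w * Sw + wj_new * wj_new) / (df_w + 1.0));
        else
          s2[j] = rinvchisq(df_w, Sw); // refresh from the prior when excluded
      }
    }

    // common slab variance (C)
    if (variant == 3)
      s2c = rinvchisq(df_w + n_in, (df_w * Sw + ssq_in) / (df_w + n_in));

    // spike probability
    if (spike && pi_sample)
      pi = R::rbeta(1.0 + (m - n_in), 1.0 + n_in);

    // residual variance
    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    se2 = rinvchisq(df_e + n, (df_e * Se + sse) / (df_e + n));
    if (!R_finite(se2) || se2 <= 0.0)
      stop("divergent residual-variance draw at iteration %d", it + 1);

    if (it >= burn_in && ((it - burn_in) % thin == 0)) {
      ++n_kept;
      mu_sum += mu; pi_sum += pi; se2_sum += se2;
      for (int j = 0; j < m; ++j) {
        w_sum[j] += w[j];
        incl_sum[j] += incl[j];
      }
      if (keep_traces) {
        tr_se2.push_back(se2);
        tr_pi.push_back(pi);
        tr_mu.push_back(mu);
      }
    }
  }

  NumericVector w_post(m), incl_post(m);
  for (int j = 0; j < m; ++j) {
    w_post[j] = w_sum[j] / n_kept;
    incl_post[j] = incl_sum[j] / n_kept;
  }
  List out = List::create(
    _["posterior_mean_w"] = w_post,
    _["posterior_mean_mu"] = mu_sum / n_kept,
    _["posterior_mean_pi"] = pi_sum / n_kept,
    _["posterior_mean_se2"] = se2_sum / n_kept,
    _["posterior_inclusion"] = incl_post,
    _["n_kept"] = n_kept);
  if (keep_traces) {
    out["trace_se2"] = wrap(tr_se2);
    out["trace_pi"] = wrap(tr_pi);
    out["trace_mu"] = wrap(tr_mu);
  }
  return out;
}
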