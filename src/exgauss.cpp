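#include <Rcpp.h>
using namespace Rcpp;

// Log-density of the exponentially modified Gaussian (Normal(mu, sigma) +
// Exponential(mean tau)), evaluated fully in log space:
//   log f = -log(tau) + v^2/2 - u*v + log Phi(u - v),  u = (x-mu)/sigma, v = sigma/tau
// For z = u - v << 0 the pieces are each O(z^2) and cancel to O(u^2); doing
// that cancellation in doubles destroys all precision once v is large, so the
// z < -20 branch performs it analytically with the asymptotic expansion of
// log Phi (mirrors exg_tail_term on the R side; keep both in sync).
static inline double exg_tail_term(double u, double v) {
  const double z = u - v;
  if (z < -20.0) {
    const double z2 = z * z;
    return -0.5 * u * u - std::log(-z) - 0.5 * std::log(2.0 * M_PI) +
           std::log1p(-1.0 / z2 + 3.0 / (z2 * z2) - 15.0 / (z2 * z2 * z2));
  }
  return 0.5 * v * v - u * v + R::pnorm(z, 0.0, 1.0, 1, 1);
}

static inline double exg_logpdf1(double x, double mu, double sigma, double tau) {
  const double u = (x - mu) / sigma;
  const double v = sigma / tau;
  return -std::log(tau) + exg_tail_term(u, v);
}

// [[Rcpp::export(name = ".exg_logpdf_cpp")]]
NumericVector exg_logpdf_cpp(NumericVector x, double mu, double sigma, double tau) {
  const int n = x.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = exg_logpdf1(x[i], mu, sigma, tau);
  return out;
}

// [[Rcpp::export(name = ".exg_nll_cpp")]]
double exg_nll_cpp(NumericVector x, double mu, double sigma, double tau) {
  double s = 0.0;
  const int n = x.size();
  for (int i = 0; i < n; ++i) s -= exg_logpdf1(x[i], mu, sigma, tau);
  return s;
}

// Negative log-likelihood on a cartesian (mu, sigma, tau) grid; flattened with
// mu fastest.  Used by the brute-force posterior oracle in the tests.
// [[Rcpp::export(name = ".exg_nll_grid_cpp")]]
NumericVector exg_nll_grid_cpp(NumericVector x, NumericVector mu_grid,
                               NumericVector sigma_grid, NumericVector tau_grid) {
  const int nm = mu_grid.size(), ns = sigma_grid.size(), nt = tau_grid.size();
  NumericVector out((R_xlen_t)nm * ns * nt);
  R_xlen_t idx = 0;
  for (int it = 0; it < nt; ++it)
    for (int is = 0; is < ns; ++is)
      for (int im = 0; im < nm; ++im)
        out[idx++] = exg_nll_cpp(x, mu_grid[im], sigma_grid[is], tau_grid[it]);
  return out;
}

// Random-walk Metropolis over (mu, log sigma, log tau) with a flat prior on the
// natural scale inside the box [lower, upper]; the Jacobian log(sigma)+log(tau)
// is folded into the target so the prior stays uniform on (mu, sigma, tau).
// Proposal scales adapt during burn-in only (frozen afterwards, preserving
// detailed balance in the retained samples).  Uses R's RNG so set.seed()
// controls reproducibility.
// [[Rcpp::export(name = ".exg_metropolis_cpp")]]
List exg_metropolis_cpp(NumericVector x, NumericVector start,
                        NumericVector lower, NumericVector upper,
                        int n_samples, int n_burn, int thin,
                        NumericVector prop_init, int tune_interval) {
  auto log_target = [&](double mu, double lsig, double ltau) -> double {
    const double sigma = std::exp(lsig), tau = std::exp(ltau);
    if (mu < lower[0] || mu > upper[0] || sigma < lower[1] || sigma > upper[1] ||
        tau < lower[2] || tau > upper[2])
      return R_NegInf;
    return -exg_nll_cpp(x, mu, sigma, tau) + lsig + ltau;
  };

  double cur[3] = {start[0], std::log(start[1]), std::log(start[2])};
  double lp = log_target(cur[0], cur[1], cur[2]);
  if (!R_finite(lp)) stop("start point has zero posterior density");

  double scale[3] = {prop_init[0], prop_init[1], prop_init[2]};
  const int n_keep = (n_samples - n_burn) / thin;
  NumericMatrix kept(n_keep, 3);
  int kept_i = 0;
  int win_acc = 0, win_n = 0;   // tuning window (burn-in)
  int post_acc = 0, post_n = 0; // acceptance bookkeeping after burn-in

  for (int iter = 1; iter <= n_samples; ++iter) {
    double prop[3];
    for (int j = 0; j < 3; ++j) prop[j] = cur[j] + R::norm_rand() * scale[j];
    const double lp_new = log_target(prop[0], prop[1], prop[2]);
    bool accept = false;
    if (R_finite(lp_new)) {
      if (lp_new >= lp) accept = true;
      else accept = (std::log(R::unif_rand()) < lp_new - lp);
    }
    if (accept) {
      for (int j = 0; j < 3; ++j) cur[j] = prop[j];
      lp = lp_new;
    }

    if (iter <= n_burn) {
      win_acc += accept; ++win_n;
      if (win_n == tune_interval) {
        const double rate = (double)win_acc / win_n;
        for (int j = 0; j < 3; ++j) {
          if (rate < 0.2) scale[j] *= 0.8;
          else if (rate > 0.5) scale[j] *= 1.25;
        }
        win_acc = 0; win_n = 0;
      }
    } else {
      post_acc += accept; ++post_n;
      if ((iter - n_burn) % thin == 0 && kept_i < n_keep) {
        kept(kept_i, 0) = cur[0];
        kept(kept_i, 1) = std::exp(cur[1]);
        kept(kept_i, 2) = std::exp(cur[2]);
        ++kept_i;
      }
    }
  }

  return List::create(_["samples"] = kept,
                      _["acceptance_rate"] = post_n > 0 ? (double)post_acc / post_n : NA_REAL,
                      _["prop_scales"] = NumericVector::create(scale[0], scale[1], scale[2]));
}

// Metropolis over (mu, log sigma) for the Gaussian fallback used on
// low-multiplicity reflections; same conventions as above.
// [[Rcpp::export(name = ".gauss_metropolis_cpp")]]
List gauss_metropolis_cpp(NumericVector x, NumericVector start,
                          NumericVector lower, NumericVector upper,
                          int n_samples, int n_burn, int thin,
                          NumericVector prop_init, int tune_interval) {
  auto log_target = [&](double mu, double lsig) -> double {
    const double sigma = std::exp(lsig);
    if (mu < lower[0] || mu > upper[0] || sigma < lower[1] || sigma > upper[1])
      return R_NegInf;
    double s = 0.0;
    for (int i = 0; i < x.size(); ++i) s += R::dnorm(x[i], mu, sigma, 1);
    return s + lsig;
  };

  double cur[2] = {start[0], std::log(start[1])};
  double lp = log_target(cur[0], cur[1]);
  if (!R_finite(lp)) stop("start point has zero posterior density");

  double scale[2] = {prop_init[0], prop_init[1]};
  const int n_keep = (n_samples - n_burn) / thin;
  NumericMatrix kept(n_keep, 2);
  int kept_i = 0, win_acc = 0, win_n = 0, post_acc = 0, post_n = 0;

  for (int iter = 1; iter <= n_samples; ++iter) {
    double prop[2];
    for (int j = 0; j < 2; ++j) prop[j] = cur[j] + R::norm_rand() * scale[j];
    const double lp_new = log_target(prop[0], prop[1]);
    bool accept = false;
    if (R_finite(lp_new)) {
      if (lp_new >= lp) accept = true;
      else accept = (std::log(R::unif_rand()) < lp_new - lp);
    }
    if (accept) { cur[0] = prop[0]; cur[1] = prop[1]; lp = lp_new; }

    if (iter <= n_burn) {
      win_acc += accept; ++win_n;
      if (win_n == tune_interval) {
        const double rate = (double)win_acc / win_n;
        for (int j = 0; j < 2; ++j) {
          if (rate < 0.2) scale[j] *= 0.8;
          else if (rate > 0.5) scale[j] *= 1.25;
        }
        win_acc = 0; win_n = 0;
      }
    } else {
      post_acc += accept; ++post_n;
      if ((iter - n_burn) % thin == 0 && kept_i < n_keep) {
        kept(kept_i, 0) = cur[0];
        kept(kept_i, 1) = std::exp(cur[1]);
        ++kept_i;
      }
    }
  }

  return List::create(_["samples"] = kept,
                      _["acceptance_rate"] = post_n > 0 ? (double)post_acc / post_n : NA_REAL);
}
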