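#' MCMC settings for Ideal Crystal merging
#'
#' Defaults follow the published procedure: 50 000 Metropolis samples, the
#' first 40 000 discarded as burn-in, thinning by 10 (1000 retained samples),
#' and the idealized intensity read off where each sampled ex-Gaussian CDF
#' reaches 0.95.
#'
#' @param n_samples total Metropolis iterations.
#' @param n_burn burn-in iterations discarded (< \code{n_samples}).
#' @param thin thinning stride (>= 1).
#' @param critical_cdf CDF level defining I_ideal, in (0, 1).
#' @param seed integer seed controlling the whole merge.
#' @param prior optional list with elements \code{mu}, \code{sigma},
#'   \code{tau}, each a length-2 numeric interval; when \code{NULL} the
#'   data-adaptive flat boxes of \code{\link{default_prior_bounds}} are used
#'   per reflection.
#' @return list of class \code{exg_mcmc_settings}.
#' @export
mcmc_settings <- function(n_samples = 50000L, n_burn = 40000L, thin = 10L,
                          critical_cdf = 0.95, seed = 1L, prior = NULL) {
  if (n_burn >= n_samples) stop("n_burn must be < n_samples")
  if (thin < 1L) stop("thin must be >= 1")
  if (critical_cdf <= 0 || critical_cdf >= 1) stop("critical_cdf must lie in (0,1)")
  if (!is.null(prior)) {
    stopifnot(all(c("mu", "sigma", "tau") %in% names(prior)))
    if (prior$sigma[1] <= 0 || prior$tau[1] <= 0) stop("sigma/tau prior lower bounds must be > 0")
  }
  structure(list(n_samples = as.integer(n_samples), n_burn = as.integer(n_burn),
                 thin = as.integer(thin), critical_cdf = critical_cdf,
                 seed = as.integer(seed), prior = prior),
            class = "exg_mcmc_settings")
}

#' Data-adaptive uniform prior box
#'
#' Minimally informative flat intervals wide enough to keep the posterior
#' proper: mu in [min(x) - 5 range, max(x) + range], sigma in
#' [1e-3 sd, 10 sd], tau in [1e-3 sd, 20 sd].
#'
#' @param values the reflection's intensity observations.
#' @return list with elements \code{mu}, \code{sigma}, \code{tau}.
#' @export
default_prior_bounds <- function(values) {
  r <- diff(range(values))
  s <- sd(values)
  if (!is.finite(s) || s <= 0) stop("degenerate group: zero variance")
  list(mu = c(min(values) - 5 * r, max(values) + r),
       sigma = c(1e-3 * s, 10 * s),
       tau = c(1e-3 * s, 20 * s))
}

#' Sample the ex-Gaussian posterior for one reflection
#'
#' Random-walk Metropolis in \eqn{(\mu, \log\sigma, \log\tau)}; the Jacobian
#' is folded into the target so the prior remains uniform on the natural
#' scale.  The chain starts at the maximum a posteriori point (the MLE under
#' a uniform prior, clipped into the prior box; bounds are auto-widened with
#' a warning if the MLE falls outside).  Proposal scales are tuned during
#' burn-in toward an acceptance rate in [0.2, 0.5] and frozen afterwards.
#'
#' @param values intensities of one reflection group (multiplicity >= 5).
#' @param settings an \code{\link{mcmc_settings}}.
#' @param start optional \code{\link{exgauss_params}} overriding the MLE start.
#' @return list of class \code{exg_chain}: \code{samples} (matrix with
#'   columns mu, sigma, tau), \code{acceptance_rate}, \code{map_start},
#'   \code{flagged} (TRUE when acceptance < 0.01 after tuning),
#'   \code{prior}.
#' @export
sample_posterior <- function(values, settings, start = NULL) {
  stopifnot(inherits(settings, "exg_mcmc_settings"))
  if (length(values) < 5L) stop("insufficient multiplicity: need at least 5 observations")

  if (is.null(start)) start <- fit_exgauss_mle(values)$params
  prior <- if (is.null(settings$prior)) default_prior_bounds(values) else settings$prior

  widen <- function(bounds, val, name) {
    if (val < bounds[1] || val > bounds[2]) {
      warning(sprintf("MAP %s outside prior bounds; widening", name))
      c(min(bounds[1], val / 2, val * 2), max(bounds[2], val * 2, val / 2))
    } else bounds
  }
  prior$mu <- if (start$mu < prior$mu[1] || start$mu > prior$mu[2]) {
    warning("MAP mu outside prior bounds; widening")
    range(c(prior$mu, start$mu - abs(start$mu), start$mu + abs(start$mu) + 1))
  } else prior$mu
  prior$sigma <- widen(prior$sigma, start$sigma, "sigma")
  prior$tau <- widen(prior$tau, start$tau, "tau")

  s <- sd(values)
  prop0 <- c(0.5 * s / sqrt(length(values)), 0.15, 0.15)

  set.seed(settings$seed)
  res <- .exg_metropolis_cpp(values,
                             c(start$mu, start$sigma, start$tau),
                             c(prior$mu[1], prior$sigma[1], prior$tau[1]),
                             c(prior$mu[2], prior$sigma[2], prior$tau[2]),
                             settings$n_samples, settings$n_burn, settings$thin,
                             prop0, 250L)
  samples <- res$samples
  colnames(samples) <- c("mu", "sigma", "tau")
  structure(list(samples = samples,
                 acceptance_rate = res$acceptance_rate,
                 map_start = start,
                 flagged = is.na(res$acceptance_rate) || res$acceptance_rate < 0.01,
                 prior = prior),
            class = "exg_chain")
}

#' Idealized intensity from a posterior chain
#'
#' For every retained posterior sample the idealized intensity I_ideal is the
#' intensity at which that sample's ex-Gaussian CDF reaches
#' \code{critical_cdf}; the reported intensity is the mean of I_ideal over
#' the chain and its uncertainty the standard deviation.
#'
#' @param chain an \code{exg_chain} from \code{\link{sample_posterior}}.
#' @param critical_cdf CDF level in (0, 1), default 0.95.
#' @return list of class \code{exg_merged_intensity}: \code{i_ideal_mean},
#'   \code{i_ideal_sd}, \code{i_ideal_samples}, \code{multiplicity} (NA here;
#'   filled by \code{\link{merge_dataset}}), \code{flagged}.
#' @export
ideal_intensity <- function(chain, critical_cdf = 0.95) {
  stopifnot(inherits(chain, "exg_chain"))
  m <- chain$samples
  if (nrow(m) == 0L) stop("empty chain")
  iid <- exg_quantile_core(critical_cdf, m[, 1], m[, 2], m[, 3])
  structure(list(i_ideal_mean = mean(iid),
                 i_ideal_sd = if (length(iid) > 1L) sd(iid) else 0,
                 i_ideal_samples = iid,
                 multiplicity = NA_integer_,
                 flagged = chain$flagged),
            class = "exg_merged_intensity")
}

# per-reflection RNG stream derived from the dataset seed; kept < 2^31
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(i) * 9973) %% 2147483629 + 1)
}

# Gaussian-posterior fallback for low-multiplicity reflections: Metropolis
# over (mu, log sigma) with flat priors, I_ideal = qnorm(critical_cdf) per
# retained sample.
gauss_fallback <- function(values, settings, rng_seed) {
  n <- length(values)
  mu0 <- mean(values)
  s0 <- sqrt(sum((values - mu0)^2) / n)
  if (s0 <= 0) s0 <- max(abs(mu0) * 1e-3, 1)
  lower <- c(mu0 - 20 * s0 - 1, 1e-3 * s0)
  upper <- c(mu0 + 20 * s0 + 1, 20 * s0)
  set.seed(rng_seed)
  res <- .gauss_metropolis_cpp(values, c(mu0, s0), lower, upper,
                               settings$n_samples, settings$n_burn, settings$thin,
                               c(s0 / sqrt(n), 0.3), 250L)
  iid <- qnorm(settings$critical_cdf, res$samples[, 1], res$samples[, 2])
  structure(list(i_ideal_mean = mean(iid),
                 i_ideal_sd = if (length(iid) > 1L) sd(iid) else 0,
                 i_ideal_samples = iid,
                 multiplicity = n,
                 flagged = is.na(res$acceptance_rate) || res$acceptance_rate < 0.01),
            class = "exg_merged_intensity")
}

#' Ideal Crystal merging of a whole dataset
#'
#' Runs \code{\link{sample_posterior}} + \code{\link{ideal_intensity}} for
#' every non-absent reflection group.  Groups below the multiplicity floor
#' of 5 fall back to a Gaussian-posterior quantile at the same critical CDF
#' level and are flagged \code{"fallback"}; groups with fewer than 3
#' observations or zero variance are flagged \code{"degenerate"} and report
#' the sample mean/SD.  Systematic absences are excluded from the merged
#' output and returned separately.  Fully deterministic given
#' \code{settings$seed} (each reflection gets a derived seed, so the result
#' does not depend on evaluation order).
#'
#' @param groups an \code{exg_group_list}.
#' @param settings an \code{\link{mcmc_settings}}.
#' @param keep_samples keep per-reflection I_ideal chains in the
#'   \code{"i_ideal_samples"} attribute (default TRUE).
#' @return data.frame of class \code{exg_merged} with one row per non-absent
#'   group: \code{h,k,l,d,q,intensity,sigma,multiplicity,flag,
#'   acceptance_rate}.  Attributes: \code{absent} (data.frame of excluded
#'   absent groups), \code{i_ideal_samples} (list), \code{settings}.
#' @export
merge_dataset <- function(groups, settings = mcmc_settings(), keep_samples = TRUE) {
  stopifnot(inherits(groups, "exg_group_list"), inherits(settings, "exg_mcmc_settings"))
  absent <- Filter(function(g) g$is_absent, groups)
  present <- Filter(function(g) !g$is_absent, groups)
  if (length(present) == 0L) stop("empty dataset: no non-absent reflection groups")

  rows <- vector("list", length(present))
  chains <- if (keep_samples) vector("list", length(present)) else NULL
  n_fallback <- 0L; n_flagged <- 0L

  for (i in seq_along(present)) {
    g <- present[[i]]
    rs <- derive_seed(settings$seed, i)
    x <- g$intensities
    ar <- NA_real_
    if (g$multiplicity >= 5L && sd(x) > 0) {
      st <- settings; st$seed <- rs
      chain <- suppressWarnings(sample_posterior(x, st))
      ar <- chain$acceptance_rate
      mi <- ideal_intensity(chain, settings$critical_cdf)
      flag <- if (mi$flagged) "flagged" else "ok"
    } else if (g$multiplicity >= 3L && sd(x) > 0) {
      mi <- gauss_fallback(x, settings, rs)
      flag <- "fallback"
      n_fallback <- n_fallback + 1L
    } else {
      mi <- structure(list(i_ideal_mean = mean(x),
                           i_ideal_sd = if (length(x) > 1L) sd(x) else 0,
                           i_ideal_samples = numeric(0),
                           multiplicity = g$multiplicity, flagged = TRUE),
                      class = "exg_merged_intensity")
      flag <- "degenerate"
    }
    if (flag == "flagged") n_flagged <- n_flagged + 1L
    rows[[i]] <- data.frame(h = g$h, k = g$k, l = g$l,
                            d = g$d_spacing, q = g$q,
                            intensity = mi$i_ideal_mean,
                            sigma = mi$i_ideal_sd,
                            multiplicity = g$multiplicity,
                            flag = flag,
                            acceptance_rate = ar,
                            stringsAsFactors = FALSE)
    if (keep_samples) chains[[i]] <- mi$i_ideal_samples
  }

  out <- do.call(rbind, rows)
  message(sprintf("merge_dataset: %d reflections merged (%d fallback, %d flagged), %d absences excluded",
                  nrow(out), n_fallback, n_flagged, length(absent)))
  attr(out, "absent") <- if (length(absent)) {
    data.frame(h = vapply(absent, `[[`, integer(1), "h"),
               k = vapply(absent, `[[`, integer(1), "k"),
               l = vapply(absent, `[[`, integer(1), "l"),
               d = vapply(absent, `[[`, numeric(1), "d_spacing"),
               multiplicity = vapply(absent, `[[`, integer(1), "multiplicity"))
  } else {
    data.frame(h = integer(0), k = integer(0), l = integer(0),
               d = numeric(0), multiplicity = integer(0))
  }
  if (keep_samples) attr(out, "i_ideal_samples") <- chains
  attr(out, "settings") <- settings
  class(out) <- c("exg_merged", "data.frame")
  out
}
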