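#' Upper-tail chi-squared critical value
#'
#' At \code{alpha = 0.05}, \code{dof = 1} this is 3.84, the cutoff used to
#' decide between the nested Gaussian and ex-Gaussian fits.
#'
#' @param alpha significance level in (0, 1).
#' @param dof degrees of freedom, >= 1.
#' @return critical value.
#' @export
chi2_cutoff <- function(alpha, dof = 1L) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) stop("alpha must lie in (0,1)")
  if (dof < 1) stop("dof must be >= 1")
  qchisq(1 - alpha, df = dof)
}

#' Nested likelihood-ratio test: Gaussian vs ex-Gaussian
#'
#' The Gaussian is the tau -> 0 boundary of the ex-Gaussian family, so twice
#' the drop in negative log-likelihood is referred to a chi-squared
#' distribution with one extra degree of freedom.  Optimizer noise can make
#' the nested difference slightly negative; the statistic is clamped at 0.
#' (Because tau > 0 sits on the parameter boundary, the chi-squared(1)
#' reference is conservative; the 5% criterion is an upper bound.)
#'
#' @param fit_g Gaussian \code{exg_fit}; @param fit_exg ex-Gaussian
#'   \code{exg_fit} on the same data.
#' @param alpha significance level (default 0.05).
#' @return list of class \code{exg_lrt}: \code{chi2}, \code{dof},
#'   \code{cutoff}, \code{prefers_exgauss}.
#' @export
likelihood_ratio_test <- function(fit_g, fit_exg, alpha = 0.05) {
  stopifnot(inherits(fit_g, "exg_fit"), inherits(fit_exg, "exg_fit"))
  if (fit_g$n_obs != fit_exg$n_obs) stop("fits are not on the same data (n_obs differ)")
  chi2 <- max(0, 2 * (fit_g$neg_log_likelihood - fit_exg$neg_log_likelihood))
  cutoff <- chi2_cutoff(alpha, 1L)
  structure(list(chi2 = chi2, dof = 1L, cutoff = cutoff,
                 prefers_exgauss = chi2 > cutoff),
            class = "exg_lrt")
}

#' Fit both models and run the LRT for every reflection group
#'
#' Produces the per-reflection diagnostics table (one row per unique
#' reflection): Miller indices, resolution, multiplicity, chi-squared, both
#' parameter sets, model preference and the absence flag.  Groups that are
#' degenerate (multiplicity < 5 or zero variance) get \code{fit_ok = FALSE}
#' and NA parameters; they are excluded from model-selection statistics.
#'
#' @param groups an \code{exg_group_list} from \code{\link{group_observations}}.
#' @param alpha LRT significance level.
#' @return data.frame with columns \code{h,k,l,d,q,M,is_absent,fit_ok,chi2,
#'   prefers_exgauss,mu_g,sigma_g,mu_exg,sigma_exg,tau_exg}.
#' @export
fit_reflections <- function(groups, alpha = 0.05) {
  stopifnot(inherits(groups, "exg_group_list"))
  rows <- lapply(groups, function(g) {
    out <- list(h = g$h, k = g$k, l = g$l, d = g$d_spacing, q = g$q,
                M = g$multiplicity, is_absent = g$is_absent, fit_ok = FALSE,
                chi2 = NA_real_, prefers_exgauss = NA,
                mu_g = NA_real_, sigma_g = NA_real_,
                mu_exg = NA_real_, sigma_exg = NA_real_, tau_exg = NA_real_)
    fg <- tryCatch(fit_gaussian_mle(g$intensities), error = function(e) NULL)
    fe <- tryCatch(fit_exgauss_mle(g$intensities), error = function(e) NULL)
    if (!is.null(fg)) {
      out$mu_g <- fg$params$mu; out$sigma_g <- fg$params$sigma
    }
    if (!is.null(fg) && !is.null(fe)) {
      lrt <- likelihood_ratio_test(fg, fe, alpha)
      out$fit_ok <- TRUE
      out$chi2 <- lrt$chi2
      out$prefers_exgauss <- lrt$prefers_exgauss
      out$mu_exg <- fe$params$mu; out$sigma_exg <- fe$params$sigma
      out$tau_exg <- fe$params$tau
    }
    out
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Resolution-shell summary of model preference and fitted parameters
#'
#' Partitions the fitted, non-absent reflections into \code{n_shells}
#' equal-count shells ordered from low resolution (high d) to high resolution
#' (low d), and reports per shell the ex-Gaussian preference fraction and the
#' mean fitted parameters.
#'
#' @param diagnostics data.frame from \code{\link{fit_reflections}}.
#' @param n_shells number of shells (>= 2; default 20).
#' @return data.frame with one row per shell: \code{shell, d_max, d_min,
#'   q_min, q_max, n_reflections, fraction_exgauss_preferred, mean_mu_g,
#'   mean_mu_exg, mean_sigma_exg, mean_tau_exg}.
#' @export
shell_summary <- function(diagnostics, n_shells = 20L) {
  if (n_shells < 2L) stop("n_shells must be >= 2")
  dd <- diagnostics[!diagnostics$is_absent & diagnostics$fit_ok, , drop = FALSE]
  if (nrow(dd) < n_shells) stop("fewer fitted reflections than shells")
  dd <- dd[order(-dd$d), , drop = FALSE]
  # equal-count assignment (+-1)
  shell <- floor((seq_len(nrow(dd)) - 1) * n_shells / nrow(dd)) + 1L
  res <- lapply(split(seq_len(nrow(dd)), shell), function(i) {
    s <- dd[i, , drop = FALSE]
    data.frame(
      d_max = max(s$d), d_min = min(s$d),
      q_min = min(s$q), q_max = max(s$q),
      n_reflections = nrow(s),
      fraction_exgauss_preferred = mean(s$prefers_exgauss),
      mean_mu_g = mean(s$mu_g), mean_mu_exg = mean(s$mu_exg),
      mean_sigma_exg = mean(s$sigma_exg), mean_tau_exg = mean(s$tau_exg)
    )
  })
  out <- do.call(rbind, res)
  out <- cbind(shell = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}
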