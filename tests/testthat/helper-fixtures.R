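# Shared fixture builders; everything is generated in code at test time.

paper_cell <- function() unit_cell(57.9, 84.8, 384.3)

# flat-dialect lines for a hand-specified observation table
flat_lines <- function(df) {
  sprintf("%s %d %d %d %.10g%s", df$frame_id, df$h, df$k, df$l, df$intensity,
          ifelse(is.na(df$sigma), "", sprintf(" %.10g", df$sigma)))
}

# stream-lite lines: one BEGIN/END block per frame
stream_lines <- function(df) {
  unlist(lapply(split(df, df$frame_id), function(blk) {
    c(sprintf("BEGIN_CHUNK %s", blk$frame_id[1]),
      sprintf("%d %d %d %.10g %.10g", blk$h, blk$k, blk$l, blk$intensity, blk$sigma),
      "END_CHUNK")
  }), use.names = FALSE)
}

# draws from ExGauss(mu, sigma, tau) by construction (Normal + Exponential)
rexgauss <- function(n, mu, sigma, tau) rnorm(n, mu, sigma) + rexp(n, rate = 1 / tau)

# quadrature oracle for the ex-Gaussian density: numerical convolution of the
# Normal density with the Exponential density (independent of the package's
# closed form)
exg_pdf_quadrature <- function(x, mu, sigma, tau) {
  # finite bracket covering the Gaussian factor's support; an infinite lower
  # limit lets integrate() miss the narrow bump when |x - mu| >> sigma
  vapply(x, function(xx) {
    integrate(function(u) dnorm(u, mu, sigma) * dexp(xx - u, rate = 1 / tau),
              lower = mu - 13 * sigma, upper = xx, rel.tol = 1e-10)$value
  }, numeric(1))
}

# quadrature oracle for the CDF: P(N + E <= x) = E_u[P(E <= x - u)]
exg_cdf_quadrature <- function(x, mu, sigma, tau) {
  vapply(x, function(xx) {
    integrate(function(u) dnorm(u, mu, sigma) * pexp(xx - u, rate = 1 / tau),
              lower = mu - 13 * sigma, upper = xx, rel.tol = 1e-10)$value
  }, numeric(1))
}

# brute-force grid posterior for one reflection: uniform prior over the given
# box, likelihood evaluated on an n^3 cartesian grid, posterior means/SDs by
# direct summation.  Likelihood evaluation is the compiled kernel already
# validated against quadrature; the *integration route* is independent of the
# Metropolis sampler this oracle checks.
grid_posterior <- function(values, prior, n_grid = 81L) {
  mu_g <- seq(prior$mu[1], prior$mu[2], length.out = n_grid)
  sg_g <- seq(prior$sigma[1], prior$sigma[2], length.out = n_grid)
  ta_g <- seq(prior$tau[1], prior$tau[2], length.out = n_grid)
  nll <- exgmerge:::.exg_nll_grid_cpp(values, mu_g, sg_g, ta_g)
  w <- exp(-(nll - min(nll)))
  w <- w / sum(w)
  grid <- expand.grid(mu = mu_g, sigma = sg_g, tau = ta_g)
  means <- colSums(grid * w)
  sds <- sqrt(colSums(sweep(grid, 2, means)^2 * w))
  list(mean = means, sd = sds)
}
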