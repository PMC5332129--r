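test_that("mcmc_settings validates its invariants", {
  s <- mcmc_settings()
  expect_equal((s$n_samples - s$n_burn) / s$thin, 1000)
  expect_error(mcmc_settings(n_samples = 100, n_burn = 100), "n_burn")
  expect_error(mcmc_settings(thin = 0), "thin")
  expect_error(mcmc_settings(critical_cdf = 1), "critical_cdf")
  expect_error(mcmc_settings(prior = list(mu = c(-1, 1), sigma = c(0, 1), tau = c(1, 2))),
               "lower bounds")
})

test_that("sample_posterior is seed-deterministic with the contracted chain length", {
  set.seed(41)
  x <- rexgauss(60, 0, 600, 2500)
  st <- mcmc_settings(n_samples = 6000, n_burn = 4000, thin = 10, seed = 99)
  ch1 <- sample_posterior(x, st)
  ch2 <- sample_posterior(x, st)
  expect_identical(ch1$samples, ch2$samples)
  expect_equal(nrow(ch1$samples), 200)
  expect_true(all(ch1$samples[, "sigma"] > 0 & ch1$samples[, "tau"] > 0))
  expect_gt(ch1$acceptance_rate, 0.01)
  # samples respect the prior box
  pr <- ch1$prior
  expect_true(all(ch1$samples[, "mu"] >= pr$mu[1] & ch1$samples[, "mu"] <= pr$mu[2]))
  expect_error(sample_posterior(x[1:4], st), "insufficient multiplicity")
})

test_that("prior bounds auto-widen with a warning when the MAP falls outside", {
  set.seed(42)
  x <- rexgauss(60, 0, 1, 4)
  st <- mcmc_settings(n_samples = 2000, n_burn = 1000, thin = 10, seed = 5,
                      prior = list(mu = c(-1, 1), sigma = c(0.5, 2), tau = c(0.01, 0.02)))
  expect_warning(ch <- sample_posterior(x, st), "widening")
  expect_gt(max(ch$samples[, "tau"]), 0.02)
})

test_that("Metropolis posterior matches the brute-force grid posterior at n = 30", {
  set.seed(43)
  x <- rexgauss(30, 0, 1, 4)
  # explicit in-box start keeps the prior box identical for both routes
  prior <- list(mu = c(-6, 6), sigma = c(0.05, 6), tau = c(0.3, 20))
  oracle <- grid_posterior(x, prior, n_grid = 81L)
  # long chain so the Monte Carlo error sits well below the 5%-of-SD tolerance
  st <- mcmc_settings(n_samples = 200000, n_burn = 20000, thin = 20,
                      seed = 17, prior = prior)
  ch <- sample_posterior(x, st, start = exgauss_params(0, 1, 4))
  mcmc_mean <- colMeans(ch$samples)
  for (j in 1:3) {
    expect_lt(abs(mcmc_mean[j] - oracle$mean[j]), 0.05 * oracle$sd[j])
  }
  # posterior means within 3 posterior SDs of truth
  truth <- c(0, 1, 4)
  expect_true(all(abs(mcmc_mean - truth) < 3 * oracle$sd))
})

test_that("ideal_intensity satisfies the quantile identity and degenerate contracts", {
  set.seed(44)
  x <- rexgauss(80, 0, 600, 3000)
  st <- mcmc_settings(n_samples = 6000, n_burn = 5000, thin = 10, seed = 3)
  ch <- sample_posterior(x, st)
  mi <- ideal_intensity(ch, 0.95)
  for (j in seq_along(mi$i_ideal_samples)) {
    p <- exgauss_params(ch$samples[j, 1], ch$samples[j, 2], ch$samples[j, 3])
    expect_lt(abs(exgauss_cdf(mi$i_ideal_samples[j], p) - 0.95), 1e-9)
  }
  # single-sample chain: sd = 0
  ch1 <- ch; ch1$samples <- ch$samples[1, , drop = FALSE]
  mi1 <- ideal_intensity(ch1, 0.95)
  expect_equal(mi1$i_ideal_sd, 0)
  # degenerate chain of identical samples reduces to the plain quantile
  chd <- ch
  chd$samples <- matrix(rep(c(0, 1, 2), each = 5), 5, 3,
                        dimnames = list(NULL, c("mu", "sigma", "tau")))
  mid <- ideal_intensity(chd, 0.95)
  expect_equal(mid$i_ideal_mean, exgauss_quantile(0.95, exgauss_params(0, 1, 2)))
  expect_equal(mid$i_ideal_sd, 0)
})

test_that("raising critical_cdf never decreases I_ideal on a fixed chain", {
  set.seed(45)
  x <- rexgauss(60, 0, 600, 2000)
  ch <- suppressWarnings(
    sample_posterior(x, mcmc_settings(n_samples = 4000, n_burn = 3000, seed = 6)))
  i90 <- ideal_intensity(ch, 0.90)$i_ideal_samples
  i99 <- ideal_intensity(ch, 0.99)$i_ideal_samples
  expect_true(all(i99 >= i90))
})

test_that("merge_dataset routes absences, fallbacks and conserves records", {
  cell <- paper_cell()
  set.seed(46)
  mk_obs <- function(h, k, l, x) data.frame(frame_id = "f", h = h, k = k, l = l,
                                            intensity = x, sigma = NA_real_)
  obs <- rbind(mk_obs(1, 2, 3, rexgauss(40, 0, 600, 2000)),
               mk_obs(2, 3, 4, rexgauss(12, 0, 600, 4000)),
               mk_obs(4, 1, 7, rnorm(4, 0, 600)),     # below multiplicity floor
               mk_obs(3, 0, 0, rnorm(25, 0, 600)))    # systematic absence
  class(obs) <- c("exg_observations", "data.frame")
  groups <- group_observations(obs, cell)
  st <- mcmc_settings(n_samples = 4000, n_burn = 3000, thin = 10, seed = 11)
  merged <- suppressMessages(merge_dataset(groups, st))
  expect_equal(nrow(merged), 3L)                     # non-absent groups only
  expect_equal(nrow(attr(merged, "absent")), 1L)
  expect_equal(attr(merged, "absent")$h, 3L)
  expect_equal(merged$flag[merged$h == 4], "fallback")
  expect_true(all(merged$flag[merged$h != 4] == "ok"))
  expect_true(all(merged$sigma >= 0))
  expect_equal(sort(merged$multiplicity), c(4L, 12L, 40L))

  # seeded determinism end to end
  merged2 <- suppressMessages(merge_dataset(groups, st))
  expect_identical(merged$intensity, merged2$intensity)
  expect_identical(merged$sigma, merged2$sigma)
})
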