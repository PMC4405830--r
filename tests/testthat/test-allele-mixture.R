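test_that("beta-binomial pmf: closed form, normalization, edge cases", {
  # Beta(1,1) mixing gives the uniform distribution on 0..N
  expect_equal(exp(betabin_logpmf(0:7, 7, 1, 1)), rep(1 / 8, 8))
  expect_equal(betabin_logpmf(0, 0, 2, 5), 0)

  # normalization property over random parameters
  set.seed(4)
  for (i in 1:20) {
    N <- sample(1:60, 1)
    a <- stats::rexp(1) + 0.05
    b <- stats::rexp(1) + 0.05
    expect_equal(sum(exp(betabin_logpmf(0:N, N, a, b))), 1,
                 tolerance = 1e-10)
  }

  # numerical-integration oracle: average the binomial pmf over a fine
  # grid of Beta(a, b)-weighted p values
  p_grid <- seq(1e-6, 1 - 1e-6, length.out = 2e4)
  w <- stats::dbeta(p_grid, 2, 3)
  oracle <- sum(stats::dbinom(2, 5, p_grid) * w) / sum(w)
  expect_equal(exp(betabin_logpmf(2, 5, 2, 3)), oracle, tolerance = 1e-6)

  expect_error(betabin_logpmf(3, 2, 1, 1), "m <= N")
  expect_error(betabin_logpmf(1, 2, -1, 1), "positive")
})

test_that("(a,b) <-> (r,s) reparameterization is an exact bijection", {
  set.seed(8)
  for (i in 1:25) {
    a <- stats::rexp(1) + 0.01
    b <- stats::rexp(1) + 0.01
    rs <- ab_to_rs(a, b)
    back <- rs_to_ab(rs$r, rs$s)
    expect_equal(back$a, a, tolerance = 1e-12)
    expect_equal(back$b, b, tolerance = 1e-12)
    expect_equal(rs$mu, a / (a + b), tolerance = 1e-12)
  }
})

test_that("joint log posterior matches a direct transcription of the density", {
  data <- data.frame(m = c(2, 9, 5), N = c(10, 10, 10))
  prior <- mixture_prior()
  params <- list(rbar = -0.4, d = 1.2, z = 1, s1 = 12, s2 = 30,
                 assign = c(1L, 2L, 1L))
  got <- joint_log_posterior(params, data, prior)

  # independent transcription: explicit lgamma beta-binomial, explicit priors
  bb <- function(m, N, a, b) {
    lgamma(N + 1) - lgamma(m + 1) - lgamma(N - m + 1) +
      lgamma(m + a) + lgamma(N - m + b) - lgamma(N + a + b) +
      lgamma(a + b) - lgamma(a) - lgamma(b)
  }
  r <- c(params$rbar - params$d / 2, params$rbar + params$d / 2)
  s <- c(params$s1, params$s2)
  mu <- 1 / (1 + exp(-r))
  want <- -0.5 * (params$rbar / 2)^2 - log(2) - 0.5 * log(2 * pi) +  # N(0,2)
    log(0.5) + log(0.5) - 0.5 * params$d +                            # slab
    log(0.025) - 0.025 * params$s1 + log(0.025) - 0.025 * params$s2 +
    3 * log(0.5)
  for (j in 1:3) {
    i <- params$assign[j]
    want <- want + bb(data$m[j], data$N[j], s[i] * mu[i], s[i] * (1 - mu[i]))
  }
  expect_equal(got, want, tolerance = 1e-10)

  # label symmetry at d = 0 with equal s: assignments do not matter
  p0 <- list(rbar = 0.3, d = 0, z = 0, s1 = 20, s2 = 20, assign = c(1L, 1L, 2L))
  p1 <- p0; p1$assign <- c(2L, 2L, 1L)
  expect_equal(joint_log_posterior(p0, data, prior),
               joint_log_posterior(p1, data, prior))

  expect_error(joint_log_posterior(list(rbar = 0, d = -1, z = 1, s1 = 1,
                                        s2 = 1, assign = 1L),
                                   data.frame(m = 1, N = 2), prior),
               "invalid")
})

test_that("Gelman-Rubin PSRF: identical, disjoint and well-mixed chains", {
  x <- stats::rnorm(500)
  expect_equal(gelman_rubin(cbind(x, x, x)), 1)
  expect_gt(gelman_rubin(cbind(rep(0, 100), rep(1, 100))), 10)
  set.seed(12)
  iid <- matrix(stats::rnorm(3e4 * 3), ncol = 3)
  expect_lt(gelman_rubin(iid), 1.01)
  expect_error(gelman_rubin(matrix(1, 5, 1)), "2 chains")
})

test_that("Q1 score conventions", {
  same <- data.frame(m = rep(4, 6), N = rep(10, 6))
  expect_equal(q1_score(same), 40)
  five <- data.frame(m = c(0, 2, 4, 6, 8), N = rep(10, 5))
  expect_equal(q1_score(five), 20)  # type-7 interpolated quartile
  # bimodal sample: Q1 sits near the lower allele, far below the mean
  set.seed(31)
  d <- simulate_counts(n_clones = 60, mu = c(0.05, 0.8), s = c(25, 25),
                       assay_n = 56, missing_rate = 0, seed = 31)
  q1 <- q1_score(d)
  expect_lt(q1, 15)
  expect_lt(q1, mean(100 * d$m / d$N) - 15)
})

test_that("overdispersion ratio: binomial null, 4x beta-binomial, edge cases", {
  N <- 56
  # binomial data (huge s): ratio near 1
  d_bin <- simulate_counts(n_clones = 600, mu = c(0.3, 0.3), s = c(1e7, 1e7),
                           assay_n = N, missing_rate = 0, seed = 41)
  expect_equal(overdispersion_ratio(d_bin), 1, tolerance = 0.15)

  # s chosen so the theoretical inflation 1 + (N-1)/(s+1) = 4
  s4 <- (N - 1) / 3 - 1
  d_bb <- simulate_counts(n_clones = 800, mu = c(0.3, 0.3), s = c(s4, s4),
                          assay_n = N, missing_rate = 0, seed = 42)
  expect_equal(overdispersion_ratio(d_bb), 4, tolerance = 0.15)

  expect_equal(overdispersion_ratio(data.frame(m = c(5, 5, 5), N = rep(10, 3))), 0)
  expect_error(overdispersion_ratio(data.frame(m = 1, N = 10)), "insufficient")
  # clones with missing sites are excluded from the diagnostic
  d_mix <- data.frame(m = c(2, 3, 4, 1), N = c(10, 10, 10, 8))
  d_full <- data.frame(m = c(2, 3, 4), N = c(10, 10, 10))
  expect_equal(overdispersion_ratio(d_mix), overdispersion_ratio(d_full))
})

test_that("mono-allelic fit: degenerate and simulated data", {
  cfg <- mcmc_config(n_iter = 6000, seed = 5)
  all_meth <- data.frame(m = rep(10, 10), N = rep(10, 10))
  expect_gt(fit_monoallelic(all_meth, config = cfg)$percent, 90)
  none <- data.frame(m = rep(0, 10), N = rep(10, 10))
  expect_lt(fit_monoallelic(none, config = cfg)$percent, 10)
  d <- simulate_counts(n_clones = 20, mu = c(0.3, 0.3), s = c(20, 20),
                       assay_n = 56, seed = 6)
  expect_equal(fit_monoallelic(d, config = cfg)$percent, 30, tolerance = 5)
})

test_that("posterior summaries are reproducible and respect the label order", {
  d <- simulate_counts(n_clones = 30, mu = c(0.15, 0.6), s = c(15, 15),
                       assay_n = 56, seed = 51)
  cfg <- mcmc_config(n_iter = 4000, seed = 99)
  f1 <- sample_posterior(d, config = cfg)
  f2 <- sample_posterior(d, config = cfg)
  expect_identical(f1$allele1_percent, f2$allele1_percent)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$assign_p1, f2$assign_p1)
  expect_lte(f1$allele1_percent, f1$allele2_percent)
  expect_true(all(f1$assign_p1 >= 0 & f1$assign_p1 <= 1))
  expect_true(all(f1$psrf >= 1 - 1e-8))
})

test_that("spike at full mass reduces the mixture to the mono-allelic model", {
  d <- simulate_counts(n_clones = 40, mu = c(0.4, 0.4), s = c(20, 20),
                       assay_n = 56, seed = 61)
  spike_only <- sample_posterior(d, prior = mixture_prior(zero_mass = 1),
                                 config = mcmc_config(seed = 62))
  mono <- fit_monoallelic(d, config = mcmc_config(seed = 63))
  expect_equal(spike_only$p_d_gt_0, 0)
  expect_equal(spike_only$allele1_percent, spike_only$allele2_percent,
               tolerance = 1e-9)
  expect_equal(spike_only$allele1_percent, mono$percent, tolerance = 1)
})

test_that("oracle: symmetric data give 0.5 assignments; full spike drops d", {
  sym <- data.frame(m = rep(4, 4), N = rep(10, 4))
  or <- grid_oracle_posterior(sym)
  # identical clones get identical assignment posteriors, 0.5 up to the
  # residual of the label-ordering constraint on the d > 0 branch
  expect_equal(max(or$assign_p1) - min(or$assign_p1), 0, tolerance = 1e-12)
  expect_equal(or$assign_p1, rep(0.5, 4), tolerance = 0.01)

  or_spike <- grid_oracle_posterior(sym, prior = mixture_prior(zero_mass = 1))
  expect_equal(or_spike$p_d_gt_0, 0)
  expect_equal(or_spike$d_mean, 0)
  expect_equal(or_spike$allele1_percent, or_spike$allele2_percent)

  expect_error(grid_oracle_posterior(data.frame(m = rep(1, 13), N = rep(2, 13))),
               "infeasible")
})

test_that("degenerate inputs: low-confidence flag and errors", {
  tiny <- data.frame(m = c(1, 9, 2), N = rep(10, 3))
  f <- sample_posterior(tiny, config = mcmc_config(n_iter = 3000, seed = 1))
  expect_true(f$low_confidence)
  expect_error(sample_posterior(data.frame(m = numeric(0), N = numeric(0))),
               "at least one")
  expect_error(sample_posterior(data.frame(m = 5, N = 3)), "invalid")
})
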