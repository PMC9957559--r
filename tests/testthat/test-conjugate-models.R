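test_that("DIP beta prior matches its closed form and end-of-trial limit", {
  p <- dip_beta(0.1, N = 50, n = 10)
  expect_equal(p$a, 5)
  expect_equal(p$b, 37)
  expect_equal(ess(p), 2 + 40)

  # non-informative once the unobserved sample size hits zero
  for (p0 in c(0, 0.17, 0.5, 1)) {
    p <- dip_beta(p0, N = 20, n = 20)
    expect_equal(p$a, 1)
    expect_equal(p$b, 1)
  }

  # symmetric case: mode at p0
  p <- dip_beta(0.5, N = 20, n = 0)
  expect_equal(p$a, 11)
  expect_equal(p$b, 11)
  expect_equal((p$a - 1) / (p$a + p$b - 2), 0.5)

  # prior mode equals p0 whenever n < N
  for (p0 in c(0.1, 0.3, 0.7)) {
    p <- dip_beta(p0, N = 40, n = 13)
    expect_equal((p$a - 1) / (p$a + p$b - 2), p0)
  }

  expect_error(dip_beta(1.2, 10, 0), "p0")
  expect_error(dip_beta(0.5, 10, 11), "n must")
})

test_that("mode-centred DIP beta variant differs by two pseudo-counts", {
  p <- dip_beta(0.3, N = 30, n = 5, centering = "mode")
  expect_equal(p$a, 1 + 0.3 * 23)
  expect_equal(p$b, 1 + 0.7 * 23)
  # floored to proper Beta(1,1) near completion
  p_end <- dip_beta(0.3, N = 30, n = 29, centering = "mode")
  expect_equal(c(p_end$a, p_end$b), c(1, 1))
})

test_that("Thall-Simon prior has mean p0 + delta0/2 and ESS c_e", {
  p <- thall_simon_beta(0.2, 0.2, c_e = 10)
  expect_equal(p$a, 3)
  expect_equal(p$b, 7)
  p <- thall_simon_beta(0.5, 0, c_e = 2)
  expect_equal(c(p$a, p$b), c(1, 1))
  for (p0 in c(0.1, 0.4)) for (d in c(0, 0.1, 0.3)) for (ce in c(2, 6, 10)) {
    p <- thall_simon_beta(p0, d, ce)
    expect_equal(p$a / (p$a + p$b), p0 + d / 2)
    expect_equal(ess(p), ce)
  }
  expect_error(thall_simon_beta(0.95, 0.2, 10), "mean")
})

test_that("DIP gamma prior matches its closed form and Jeffreys limit", {
  p <- dip_gamma(0.5, N = 100, n = 50)
  expect_equal(p$shape, 25.5)
  expect_equal(p$rate, 50.001)
  p <- dip_gamma(5, N = 10, n = 0)
  expect_equal(p$shape, 50.5)
  expect_equal(p$rate, 10.001)
  for (l0 in c(0.5, 5, 12)) {
    p <- dip_gamma(l0, N = 30, n = 30)
    expect_equal(p$shape, 0.5)
    expect_equal(p$rate, 0.001)
  }
  expect_error(dip_gamma(0.5, 10, 11), "n must")
})

test_that("effective sample size follows each family's formula", {
  expect_equal(ess(beta_params(1, 1)), 2)
  expect_equal(ess(gamma_params(0.5, 0.001)), 0.001)
  expect_equal(ess(normal_params(100, 15^2 / 8), sampling_sd = 15), 8)
  expect_error(ess(normal_params(0, 1)), "sampling_sd")

  # telescoping: prior ESS at look n plus n is constant over the trial
  N <- 37
  sb <- prior_spec("beta", "dip", null_center = 0.2, planned_N = N)
  sg <- prior_spec("gamma", "dip", null_center = 2, planned_N = N)
  sn <- prior_spec("normal", "dip", null_center = 100, planned_N = N)
  for (n in 0:N) {
    expect_equal(ess(sb, n = n) + n, 2 + N)
    expect_equal(ess(sg, n = n) + n, 0.001 + N)
    expect_equal(ess(sn, n = n, sampling_sd = 15) + n, N)
  }
})

test_that("conjugate posterior updates are correct for fixed priors", {
  post <- posterior(prior_spec("beta", "noninformative"), suff_stat(10, 4))
  expect_equal(c(post$a, post$b), c(5, 7))

  post <- posterior(prior_spec("gamma", "jeffreys_gamma"), suff_stat(12, 30))
  expect_equal(c(post$shape, post$rate), c(30.5, 12.001))

  sp <- prior_spec("normal", "normal_fixed_ess", null_center = 100, n0 = 4)
  post <- posterior(sp, suff_stat(8, 95), sampling_sd = 15)
  expect_equal(post$mean, (4 * 100 + 8 * 95) / 12)
  expect_equal(post$variance, 225 / 12)

  # batch update equals chaining one observation at a time (fixed prior)
  y <- c(1, 0, 1, 1, 0, 1)
  batch <- posterior(prior_spec("beta", "noninformative"),
                     suff_stat(length(y), sum(y)))
  a <- 1; b <- 1
  for (yi in y) { a <- a + yi; b <- b + (1 - yi) }
  expect_equal(c(batch$a, batch$b), c(a, b))

  expect_error(posterior(prior_spec("beta", "noninformative"),
                         suff_stat(3, 5)), "0 <= y <= n")
})

test_that("DIP posteriors at completion equal the non-informative posteriors", {
  N <- 22
  y <- 6
  dip <- posterior(prior_spec("beta", "dip", null_center = 0.1, planned_N = N),
                   suff_stat(N, y))
  flat <- posterior(prior_spec("beta", "noninformative"), suff_stat(N, y))
  expect_equal(c(dip$a, dip$b), c(flat$a, flat$b))

  tot <- 11
  dipg <- posterior(prior_spec("gamma", "dip", null_center = 5, planned_N = N),
                    suff_stat(N, tot))
  jeff <- posterior(prior_spec("gamma", "jeffreys_gamma"), suff_stat(N, tot))
  expect_equal(c(dipg$shape, dipg$rate), c(jeff$shape, jeff$rate))

  dn <- posterior(prior_spec("normal", "dip", null_center = 100, planned_N = 61),
                  suff_stat(61, 95), sampling_sd = 15)
  expect_equal(dn$mean, 95)
  expect_equal(dn$variance, 225 / 61)
})

test_that("DIP posterior forms hold at every look", {
  N <- 40
  sp <- prior_spec("gamma", "dip", null_center = 0.5, planned_N = N)
  for (n in c(1, 7, 20, 39, 40)) {
    post <- posterior(sp, suff_stat(n, 3))
    expect_equal(post$rate, 0.001 + N)   # independent of n
    expect_equal(post$shape, 0.5 + 0.5 * (N - n) + 3)
  }
  sn <- prior_spec("normal", "dip", null_center = 100, planned_N = N)
  for (n in c(1, 13, 40)) {
    post <- posterior(sn, suff_stat(n, 96), sampling_sd = 15)
    expect_equal(post$variance, 225 / N)  # constant over the trial
    expect_equal(post$mean, (N - n) / N * 100 + n / N * 96)
  }
  # n = 0: the prior itself, with a defined value for the DIP posterior form
  p0 <- posterior(sn, suff_stat(0, NA), sampling_sd = 15)
  expect_equal(p0$mean, 100)
})

test_that("efficacy_probability has the right tails, symmetry and monotonicity", {
  expect_equal(efficacy_probability(beta_params(1, 1), 0.5), 0.5)
  expect_equal(
    efficacy_probability(normal_params(100, 4), 100,
                         direction = "lower_better"), 0.5)

  # quadrature oracle for the gamma tail
  post <- gamma_params(50.5, 10.001)
  q <- integrate(dgamma, 0, 5, shape = 50.5, rate = 10.001,
                 rel.tol = 1e-10)$value
  expect_equal(
    efficacy_probability(post, 5, direction = "lower_better"), q,
    tolerance = 1e-6)

  # strictly monotone in the sufficient statistic
  pr_beta <- sapply(0:10, function(y)
    efficacy_probability(beta_params(1 + y, 1 + 10 - y), 0.3))
  expect_true(all(diff(pr_beta) > 0))
  pr_gam <- sapply(0:15, function(y)
    efficacy_probability(gamma_params(0.5 + y, 10.001), 1,
                         direction = "lower_better"))
  expect_true(all(diff(pr_gam) < 0))
  pr_norm <- sapply(seq(90, 110, 2), function(m)
    efficacy_probability(normal_params(m, 4), 100,
                         direction = "lower_better"))
  expect_true(all(diff(pr_norm) < 0))

  # bounds
  for (y in 0:10) expect_true(pr_beta[y + 1] >= 0 && pr_beta[y + 1] <= 1)
})

test_that("prior_spec validates family/flavor combinations", {
  expect_error(prior_spec("gamma", "informative_ts", null_center = 1),
               "not valid")
  expect_error(prior_spec("beta", "normal_fixed_ess", null_center = 0.1),
               "not valid")
  expect_error(prior_spec("beta", "dip", null_center = 0.1), "planned_N")
  expect_error(prior_spec("beta", "informative_ts", null_center = 0.1),
               "c_e")
  expect_error(prior_spec("beta", "dip", null_center = 1.4, planned_N = 10),
               "null_center")
  # gamma "noninformative" aliases to the Jeffreys limit
  sp <- prior_spec("gamma", "noninformative")
  expect_equal(sp$flavor, "jeffreys_gamma")
})
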