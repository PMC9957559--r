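test_that("exact recursion matches exhaustive enumeration on small designs", {
  des6 <- trial_design("bernoulli", theta0 = 0.3,
                       prior = prior_spec("beta", "noninformative"),
                       N = 6, p_s = 0.90, p_f = 0.10)
  for (th in c(0.3, 0.5)) {
    ex <- exact_oc_bernoulli(des6, th)
    en <- enumerate_bernoulli_oc(des6, th)
    expect_equal(ex$reject_rate, en$reject_rate, tolerance = 1e-12)
    expect_equal(ex$expected_n, en$expected_n, tolerance = 1e-12)
  }
  des10 <- bernoulli_dip_design(0.2, N = 10, p_s = 0.90, p_f = 0.10)
  for (th in c(0.2, 0.45)) {
    ex <- exact_oc_bernoulli(des10, th)
    en <- enumerate_bernoulli_oc(des10, th)
    expect_equal(ex$reject_rate, en$reject_rate, tolerance = 1e-12)
    expect_equal(ex$expected_n, en$expected_n, tolerance = 1e-12)
  }
})

test_that("exact recursion degenerates correctly at theta 0 and 1", {
  des <- bernoulli_dip_design(0.1, N = 22, p_s = 0.98, p_f = 0.02)
  ex0 <- exact_oc_bernoulli(des, 0)
  expect_equal(ex0$reject_rate, 0)
  # the single all-failure path stops where the scan oracle says
  oracle <- scan_first_crossing(0.1, 22, 0.98, 0.02, success = FALSE)
  expect_equal(unname(which(ex0$stop_dist > 0)), oracle$n)

  ex1 <- exact_oc_bernoulli(des, 1)
  oracle1 <- scan_first_crossing(0.1, 22, 0.98, 0.02, success = TRUE)
  expect_equal(ex1$reject_rate, as.numeric(oracle1$decision == "efficacy"))
  expect_equal(unname(which(ex1$stop_dist > 0)), oracle1$n)
})

test_that("Monte Carlo estimates agree with the exact oracle within 3 SE", {
  des <- bernoulli_dip_design(0.1, N = 22, p_s = 0.98, p_f = 0.02)
  for (th in c(0.1, 0.3)) {
    mc <- estimate_oc(des, th, R = 1000, seed = 11)
    ex <- exact_oc_bernoulli(des, th)
    tol <- 3 * max(mc$mc_se, sqrt(ex$reject_rate * (1 - ex$reject_rate) / 1000))
    expect_lt(abs(mc$reject_rate - ex$reject_rate), tol)
    expect_lt(abs(mc$expected_n - ex$expected_n),
              3 * sd(rep(seq_len(22), mc$stop_dist)) / sqrt(1000) + 1e-9)
  }
})

test_that("Monte Carlo runs are seed-reproducible and well-formed", {
  des <- poisson_dip_design(5, N = 10, p_s = 0.95, p_f = 0.03)
  a <- estimate_oc(des, 3, R = 300, seed = 5)
  b <- estimate_oc(des, 3, R = 300, seed = 5)
  expect_identical(a, b)
  c_ <- estimate_oc(des, 3, R = 300, seed = 6)
  expect_false(identical(a$reject_rate, c_$reject_rate) &&
                 identical(a$stop_dist, c_$stop_dist))
  expect_equal(sum(a$stop_dist), 300)
  expect_equal(a$expected_n,
               sum(seq_len(des$N) * a$stop_dist) / 300)
  expect_equal(a$reject_rate + a$futility_rate + a$inconclusive_rate, 1)
  expect_error(estimate_oc(des, 3, R = 0), "positive integer")
})

test_that("exact stopping distribution conserves mass and expected n", {
  des <- bernoulli_dip_design(0.1, N = 42, p_s = 0.98, p_f = 0.06)
  ex <- exact_oc_bernoulli(des, 0.25)
  expect_equal(sum(ex$stop_dist), 1, tolerance = 1e-9)
  expect_equal(ex$expected_n, sum(seq_len(42) * ex$stop_dist))
  expect_equal(ex$reject_rate + ex$futility_rate + ex$inconclusive_rate, 1,
               tolerance = 1e-12)
})

test_that("exact power is non-decreasing in the true response rate", {
  des <- bernoulli_dip_design(0.1, N = 22, p_s = 0.98, p_f = 0.02)
  pw <- sapply(seq(0.05, 0.6, by = 0.05),
               function(th) exact_oc_bernoulli(des, th)$reject_rate)
  expect_true(all(diff(pw) >= -1e-12))
})

test_that("boundary_table agrees with the sequential engine", {
  des <- bernoulli_dip_design(0.1, N = 22, p_s = 0.98, p_f = 0.02)
  bt <- boundary_table(des)

  # the success-count cutoff is non-decreasing once reachable: later looks
  # need at least as many successes (regression check; for this design the
  # sequence is 4,4,...,5,...,6)
  reach <- bt$eff_cutoff[!is.na(bt$eff_cutoff)]
  expect_true(length(reach) > 0 && all(diff(reach) >= 0))
  expect_equal(reach[1], 4L)

  # cross-validation: the engine stops exactly when the success count
  # crosses the tabulated cutoffs
  set.seed(99)
  for (i in 1:200) {
    outcomes <- rbinom(22, 1, runif(1, 0.05, 0.6))
    res <- simulate_trial(des, outcomes = outcomes, keep_path = TRUE)
    y <- cumsum(outcomes)
    hit <- rep(FALSE, 22)
    for (n in 1:22) {
      hit[n] <- (!is.na(bt$eff_cutoff[n]) && y[n] >= bt$eff_cutoff[n]) ||
        (!is.na(bt$fut_cutoff[n]) && y[n] <= bt$fut_cutoff[n])
    }
    first <- if (any(hit)) which(hit)[1] else 22L
    expect_equal(res$n_stop, first)
    expect_equal(res$decision == "efficacy",
                 !is.na(bt$eff_cutoff[first]) &&
                   y[first] >= bt$eff_cutoff[first])
  }

  # poisson: cutoffs on the cumulative event count, lower counts favourable
  pdes <- poisson_dip_design(5, N = 10, p_s = 0.95, p_f = 0.03)
  pbt <- boundary_table(pdes)
  set.seed(100)
  for (i in 1:100) {
    outcomes <- rpois(10, runif(1, 2, 7))
    res <- simulate_trial(pdes, outcomes = outcomes)
    y <- cumsum(outcomes)
    hit <- rep(FALSE, 10)
    for (n in 1:10) {
      hit[n] <- (!is.na(pbt$eff_cutoff[n]) && y[n] <= pbt$eff_cutoff[n]) ||
        (!is.na(pbt$fut_cutoff[n]) && y[n] >= pbt$fut_cutoff[n])
    }
    first <- if (any(hit)) which(hit)[1] else 10L
    expect_equal(res$n_stop, first)
  }

  expect_error(boundary_table(normal_dip_design(100, 15, 10, 0.9, 0.1)),
               "discrete")
})
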