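# Builders for the designs exercised repeatedly in the tests, plus small
# independent oracles. Everything here is built in code; no fixtures on disk.

bernoulli_dip_design <- function(p0, N, p_s, p_f) {
  trial_design("bernoulli", theta0 = p0,
               prior = prior_spec("beta", "dip", null_center = p0,
                                  planned_N = N),
               N = N, p_s = p_s, p_f = p_f)
}

bernoulli_flat_design <- function(p0, N, p_s, p_f) {
  trial_design("bernoulli", theta0 = p0,
               prior = prior_spec("beta", "noninformative"),
               N = N, p_s = p_s, p_f = p_f)
}

poisson_dip_design <- function(lambda0, N, p_s, p_f) {
  trial_design("poisson", theta0 = lambda0,
               prior = prior_spec("gamma", "dip", null_center = lambda0,
                                  planned_N = N),
               N = N, p_s = p_s, p_f = p_f)
}

normal_dip_design <- function(mu0, s, N, p_s, p_f) {
  trial_design("normal", theta0 = mu0,
               prior = prior_spec("normal", "dip", null_center = mu0,
                                  planned_N = N),
               N = N, p_s = p_s, p_f = p_f, sampling_sd = s)
}

# Exhaustive enumeration oracle for Bernoulli rejection probability: run the
# engine over every outcome sequence of length N and sum binomial path
# probabilities of the sequences that stop for efficacy. Exact, O(2^N).
enumerate_bernoulli_oc <- function(design, theta) {
  N <- design$N
  reject <- 0
  expected_n <- 0
  for (code in 0:(2^N - 1)) {
    bits <- as.integer(intToBits(code))[seq_len(N)]
    s <- sum(bits)
    w <- theta^s * (1 - theta)^(N - s)
    res <- simulate_trial(design, outcomes = bits)
    if (res$reject_null) reject <- reject + w
    expected_n <- expected_n + w * res$n_stop
  }
  list(reject_rate = reject, expected_n = expected_n)
}

# Independent scan oracle: smallest look at which a forced outcome stream
# (e.g. all successes) crosses a boundary, using pbeta directly.
scan_first_crossing <- function(p0, N, p_s, p_f, success = TRUE) {
  for (n in 1:N) {
    y <- if (success) n else 0
    pr <- pbeta(p0, 1 + p0 * (N - n) + y, 1 + (1 - p0) * (N - n) + (n - y),
                lower.tail = FALSE)
    if (pr >= p_s) return(list(n = n, decision = "efficacy"))
    if (pr <= p_f) return(list(n = n, decision = "futility"))
  }
  list(n = N, decision = "inconclusive_at_N")
}
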