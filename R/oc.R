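#' Monte Carlo operating characteristics
#'
#' Estimates the rejection probability (power when `theta_true` is the
#' alternative, type I error when it equals the null), the expected sample
#' size, and the stopping-time distribution of a sequentially monitored
#' design by independent replicate trials.
#'
#' Reproducibility: each replicate runs on its own deterministically derived
#' seed (`(seed * 1009 + replicate) mod (2^31 - 1)`), so the result is
#' invariant to how replicates are batched or parallelised.
#'
#' @param design A [trial_design()].
#' @param theta_true True parameter value generating the data.
#' @param R Number of replicate trials (default 1000).
#' @param seed Integer seed for the whole run.
#' @return An object of class `oc_result` with fields `reject_rate`,
#'   `mc_se`, `expected_n`, `stop_dist` (counts over `n_stop`, summing to
#'   `R`), `futility_rate`, `inconclusive_rate`, `n_replicates` and
#'   `method = "monte_carlo"`.
#' @seealso [exact_oc_bernoulli()] for the exact counterpart in the
#'   Bernoulli family.
#' @examples
#' des <- trial_design("bernoulli", theta0 = 0.1,
#'                     prior = prior_spec("beta", "dip", null_center = 0.1,
#'                                        planned_N = 22),
#'                     N = 22, p_s = 0.98, p_f = 0.02)
#' estimate_oc(des, theta_true = 0.3, R = 200, seed = 1)
#' @export
estimate_oc <- function(design, theta_true, R = 1000L, seed = 1L) {
  stopifnot(inherits(design, "trial_design"))
  if (!(R >= 1 && R == round(R))) stop("R must be a positive integer")
  R <- as.integer(R)
  n_stop <- integer(R)
  decision <- character(R)
  for (r in seq_len(R)) {
    set.seed(replicate_seed(seed, r))
    res <- simulate_trial(design, theta_true = theta_true)
    n_stop[r] <- res$n_stop
    decision[r] <- res$decision
  }
  rate <- mean(decision == "efficacy")
  sd_tab <- table(factor(n_stop, levels = seq_len(design$N)))
  stop_dist <- as.numeric(sd_tab)
  names(stop_dist) <- seq_len(design$N)
  structure(list(
    reject_rate = rate,
    mc_se = sqrt(rate * (1 - rate) / R),
    expected_n = mean(n_stop),
    stop_dist = stop_dist,
    futility_rate = mean(decision == "futility"),
    inconclusive_rate = mean(decision == "inconclusive_at_N"),
    n_replicates = R,
    method = "monte_carlo"
  ), class = "oc_result")
}

replicate_seed <- function(seed, r) {
  (as.double(seed) * 1009 + r) %% 2147483647
}

#' Exact operating characteristics for Bernoulli designs
#'
#' Computes the rejection probability and stopping distribution exactly by
#' forward recursion over the reachable states `(n, y)`: the stopping
#' decision at each look depends on the data only through the success count
#' `y`, so continuation probability mass can be propagated with transition
#' probabilities `theta_true` and `1 - theta_true` in `O(N^2)` time. Serves
#' as the deterministic oracle for the Monte Carlo engine.
#'
#' @inheritParams estimate_oc
#' @return An `oc_result` with `mc_se = 0`, `stop_dist` a probability
#'   distribution over `n_stop` (summing to 1), and `method = "exact_dp"`.
#' @examples
#' des <- trial_design("bernoulli", theta0 = 0.1,
#'                     prior = prior_spec("beta", "dip", null_center = 0.1,
#'                                        planned_N = 22),
#'                     N = 22, p_s = 0.98, p_f = 0.02)
#' exact_oc_bernoulli(des, theta_true = 0.3)$reject_rate
#' @export
exact_oc_bernoulli <- function(design, theta_true) {
  stopifnot(inherits(design, "trial_design"))
  if (design$family != "bernoulli") {
    stop("exact_oc_bernoulli requires a Bernoulli design")
  }
  if (!(theta_true >= 0 && theta_true <= 1)) {
    stop("theta_true must lie in [0, 1]")
  }
  N <- design$N
  stop_dist <- numeric(N)
  reject <- 0
  futility <- 0
  w <- 1  # mass of continuing states, indexed by y = 0..n
  for (n in seq_len(N)) {
    w2 <- numeric(n + 1L)
    w2[1:n] <- w * (1 - theta_true)
    w2[2:(n + 1L)] <- w2[2:(n + 1L)] + w * theta_true
    pr <- posterior_prob_bernoulli(design, n, 0:n)
    eff <- pr >= design$p_s
    fut <- pr <= design$p_f & !eff
    reject <- reject + sum(w2[eff])
    futility <- futility + sum(w2[fut])
    stop_dist[n] <- sum(w2[eff | fut])
    w <- w2
    w[eff | fut] <- 0
  }
  inconclusive <- sum(w)
  stop_dist[N] <- stop_dist[N] + inconclusive
  names(stop_dist) <- seq_len(N)
  structure(list(
    reject_rate = reject,
    mc_se = 0,
    expected_n = sum(seq_len(N) * stop_dist),
    stop_dist = stop_dist,
    futility_rate = futility,
    inconclusive_rate = inconclusive,
    n_replicates = NULL,
    method = "exact_dp"
  ), class = "oc_result")
}

# Posterior probability of benefit at look n for all supplied success
# counts y, vectorised through pbeta. Shared by the exact recursion and the
# boundary tabulation so both use exactly the decision rule of the engine.
posterior_prob_bernoulli <- function(design, n, y) {
  pp <- prior_params(design$prior, n = n)
  higher <- design$direction == "higher_better"
  thr <- if (higher) design$theta0 + design$delta0 else design$theta0 - design$delta0
  stats::pbeta(thr, pp$a + y, pp$b + (n - y), lower.tail = !higher)
}

posterior_prob_poisson <- function(design, n, y) {
  pp <- prior_params(design$prior, n = n)
  higher <- design$direction == "higher_better"
  thr <- if (higher) design$theta0 + design$delta0 else design$theta0 - design$delta0
  stats::pgamma(thr, shape = pp$shape + y, rate = pp$rate + n,
                lower.tail = !higher)
}

#' Stopping boundaries on the sufficient-statistic scale
#'
#' Translates the posterior-probability stopping rule into per-look cutoffs
#' on the discrete sufficient statistic, by monotone search. For a Bernoulli
#' design with higher-is-better, `eff_cutoff` is the smallest success count
#' triggering efficacy at look `n` and `fut_cutoff` the largest count
#' triggering futility. For a Poisson design with lower-is-better,
#' `eff_cutoff` is the *largest* cumulative event count still triggering
#' efficacy and `fut_cutoff` the smallest count triggering futility. `NA`
#' marks looks where no statistic value can trigger the rule.
#'
#' @param design A Bernoulli or Poisson [trial_design()] using the default
#'   direction of benefit for its family.
#' @return A data frame with columns `n`, `eff_cutoff`, `fut_cutoff`.
#' @export
boundary_table <- function(design) {
  stopifnot(inherits(design, "trial_design"))
  if (design$family == "normal") {
    stop("boundary_table supports discrete families only (bernoulli, poisson)")
  }
  N <- design$N
  eff <- rep(NA_integer_, N)
  fut <- rep(NA_integer_, N)
  if (design$family == "bernoulli") {
    if (design$direction != "higher_better") {
      stop("bernoulli boundary_table assumes direction = 'higher_better'")
    }
    for (n in seq_len(N)) {
      pr <- posterior_prob_bernoulli(design, n, 0:n)  # increasing in y
      hit_e <- which(pr >= design$p_s)
      hit_f <- which(pr <= design$p_f)
      if (length(hit_e)) eff[n] <- hit_e[1L] - 1L
      if (length(hit_f)) fut[n] <- hit_f[length(hit_f)] - 1L
    }
  } else {
    if (design$direction != "lower_better") {
      stop("poisson boundary_table assumes direction = 'lower_better'")
    }
    # probability of benefit decreases in the cumulative count y; cap the
    # scan where the futility rule is guaranteed hit
    for (n in seq_len(N)) {
      y_max <- 0L
      repeat {
        y_max <- y_max + max(20L, 4L * ceiling(design$theta0 * n))
        if (posterior_prob_poisson(design, n, y_max) <= design$p_f ||
            y_max > 1e6) break
      }
      y <- 0:y_max
      pr <- posterior_prob_poisson(design, n, y)
      hit_e <- which(pr >= design$p_s)
      hit_f <- which(pr <= design$p_f)
      if (length(hit_e)) eff[n] <- y[hit_e[length(hit_e)]]
      if (length(hit_f)) fut[n] <- y[hit_f[1L]]
    }
  }
  data.frame(n = seq_len(N), eff_cutoff = eff, fut_cutoff = fut)
}

#' @export
print.oc_result <- function(x, ...) {
  cat(sprintf(
    "oc_result (%s): reject rate = %.4f (SE %.4f), E[n] = %.2f, futility = %.4f, inconclusive = %.4f\n",
    x$method, x$reject_rate, x$mc_se, x$expected_n, x$futility_rate,
    x$inconclusive_rate))
  invisible(x)
}
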