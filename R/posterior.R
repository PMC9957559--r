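#' Conjugate posterior update
#'
#' Combines a prior specification with the sufficient statistic of the data
#' observed so far. For fixed priors this is the textbook conjugate update;
#' for DIP priors the prior is first re-evaluated at the *current* observed
#' sample size `n`, so that (for example) the gamma DIP posterior rate is
#' `0.001 + (N - n) + n = 0.001 + N` at every look, and the normal DIP
#' posterior is `N((N-n)/N * mu0 + n/N * ybar, s^2/N)` directly from its
#' closed form (well defined at both `n = 0` and `n = N`).
#'
#' @param prior A [prior_spec()].
#' @param data A [suff_stat()] consistent with the prior's family:
#'   success count (beta), total event count (gamma), or sample mean
#'   (normal).
#' @param sampling_sd Known sampling SD `s` (normal family only; required).
#' @return A `conjugate_params` object of the matching family.
#' @examples
#' # Non-informative beta prior, 4 successes out of 10:
#' posterior(prior_spec("beta", "noninformative"), suff_stat(10, 4))
#' # DIP beta at the final look equals the Beta(1,1) posterior:
#' posterior(prior_spec("beta", "dip", null_center = 0.1, planned_N = 22),
#'           suff_stat(22, 5))
#' @export
posterior <- function(prior, data, sampling_sd = NULL) {
  stopifnot(inherits(prior, "prior_spec"), inherits(data, "suff_stat"))
  n <- data$n
  y <- data$stat
  if (prior$family == "beta") {
    if (n > 0 && !(y >= 0 && y <= n)) {
      stop("Bernoulli sufficient statistic must satisfy 0 <= y <= n")
    }
    pp <- prior_params(prior, n = n)
    if (n == 0L) return(pp)
    return(beta_params(pp$a + y, pp$b + (n - y)))
  }
  if (prior$family == "gamma") {
    if (n > 0 && !(y >= 0)) stop("Poisson total event count must be >= 0")
    pp <- prior_params(prior, n = n)
    if (n == 0L) return(pp)
    return(gamma_params(pp$shape + y, pp$rate + n))
  }
  # normal, known variance
  if (is.null(sampling_sd) || !(sampling_sd > 0)) {
    stop("sampling_sd > 0 is required for the normal family")
  }
  s2 <- sampling_sd^2
  if (prior$flavor == "dip") {
    N <- prior$planned_N
    if (!(n >= 0 && n <= N)) stop("n must satisfy 0 <= n <= N")
    ybar <- if (n == 0L) prior$null_center else y
    m <- ((N - n) / N) * prior$null_center + (n / N) * ybar
    return(normal_params(m, s2 / N))
  }
  # fixed prior ESS n0
  n0 <- prior$n0
  if (n == 0L) return(normal_params(prior$null_center, s2 / n0))
  m <- (n0 * prior$null_center + n * y) / (n0 + n)
  normal_params(m, s2 / (n0 + n))
}

#' Posterior probability of treatment benefit
#'
#' The posterior probability that the parameter clears the efficacy
#' threshold: `P(theta > theta0 + delta0)` when larger values mean benefit,
#' or `P(theta < theta0 - delta0)` when smaller values do. Tail
#' probabilities are computed with `lower.tail` chosen to avoid
#' catastrophic cancellation near 1.
#'
#' @param post Posterior parameters (`beta_params`, `gamma_params` or
#'   `normal_params`).
#' @param theta0 Null parameter value.
#' @param delta0 Targeted improvement margin (>= 0; the testing margin, kept
#'   independent of any prior-centring margin).
#' @param direction `"higher_better"` or `"lower_better"`.
#' @return A probability in \[0, 1\].
#' @examples
#' efficacy_probability(beta_params(1, 1), 0.5)  # 0.5 by symmetry
#' @export
efficacy_probability <- function(post, theta0, delta0 = 0,
                                 direction = c("higher_better", "lower_better")) {
  direction <- match.arg(direction)
  stopifnot(inherits(post, "conjugate_params"), delta0 >= 0)
  higher <- direction == "higher_better"
  thr <- if (higher) theta0 + delta0 else theta0 - delta0
  if (inherits(post, "beta_params")) {
    return(stats::pbeta(thr, post$a, post$b, lower.tail = !higher))
  }
  if (inherits(post, "gamma_params")) {
    return(stats::pgamma(thr, shape = post$shape, rate = post$rate,
                         lower.tail = !higher))
  }
  stats::pnorm(thr, mean = post$mean, sd = sqrt(post$variance),
               lower.tail = !higher)
}
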