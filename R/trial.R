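#' Sequential single-arm trial design
#'
#' A complete specification of a continuously monitored single-arm trial:
#' outcome family, null value and testing margin, direction of benefit,
#' prior, planned maximum sample size `N`, and the posterior-probability
#' stopping boundaries. After every enrolled subject the posterior
#' probability of benefit is compared with the efficacy boundary `p_s`
#' (stop and reject the null when `>= p_s`) and the futility boundary `p_f`
#' (stop without rejecting when `<= p_f`).
#'
#' Default directions of benefit follow the usual conventions: higher
#' response rates are better (Bernoulli), lower event rates are better
#' (Poisson), and lower means are better (normal).
#'
#' @param family Outcome family: `"bernoulli"`, `"poisson"` or `"normal"`.
#' @param theta0 Null parameter value (`p0`, `lambda0` or `mu0`).
#' @param prior A [prior_spec()] of the matching conjugate family.
#' @param N Planned maximum sample size (integer >= 1).
#' @param p_s Efficacy (superiority) boundary, in (0, 1).
#' @param p_f Futility boundary, in (0, 1); must satisfy `p_f < p_s`.
#' @param delta0 Testing margin (>= 0, default 0).
#' @param direction `"higher_better"` or `"lower_better"`; default depends
#'   on `family` as described above.
#' @param sampling_sd Known sampling SD (normal family only, > 0).
#' @return An object of class `trial_design`.
#' @examples
#' trial_design("bernoulli", theta0 = 0.1,
#'              prior = prior_spec("beta", "dip", null_center = 0.1,
#'                                 planned_N = 22),
#'              N = 22, p_s = 0.98, p_f = 0.02)
#' @export
trial_design <- function(family = c("bernoulli", "poisson", "normal"),
                         theta0, prior, N, p_s, p_f, delta0 = 0,
                         direction = NULL, sampling_sd = NULL) {
  family <- match.arg(family)
  stopifnot(inherits(prior, "prior_spec"))
  want <- c(bernoulli = "beta", poisson = "gamma", normal = "normal")[[family]]
  if (prior$family != want) {
    stop(sprintf("a %s trial requires a %s-family prior", family, want))
  }
  if (!(N >= 1 && N == round(N))) stop("N must be a positive integer")
  if (!is.null(prior$planned_N) && prior$planned_N != N) {
    stop("the prior's planned_N must equal the design's N")
  }
  if (!(p_s > 0 && p_s < 1 && p_f > 0 && p_f < 1)) {
    stop("p_s and p_f must lie in (0, 1)")
  }
  if (!(p_f < p_s)) stop("p_f < p_s required")
  if (!(delta0 >= 0)) stop("delta0 must be >= 0")
  if (is.null(direction)) {
    direction <- switch(family, bernoulli = "higher_better",
                        poisson = "lower_better", normal = "lower_better")
  }
  direction <- match.arg(direction, c("higher_better", "lower_better"))
  if (family == "normal") {
    if (is.null(sampling_sd) || !(sampling_sd > 0)) {
      stop("the normal family requires a known sampling_sd > 0")
    }
  }
  structure(list(family = family, theta0 = theta0, delta0 = delta0,
                 direction = direction, prior = prior, N = as.integer(N),
                 p_s = p_s, p_f = p_f, sampling_sd = sampling_sd),
            class = "trial_design")
}

#' @export
print.trial_design <- function(x, ...) {
  cat(sprintf(
    "Sequential %s trial: theta0 = %g, delta0 = %g, %s\n  N = %d, p_s = %g, p_f = %g, prior = %s\n",
    x$family, x$theta0, x$delta0, x$direction, x$N, x$p_s, x$p_f,
    x$prior$flavor))
  invisible(x)
}

#' Boundary decision for one monitoring look
#'
#' Applies the stopping rule to a posterior probability of benefit:
#' `"efficacy"` when `prob >= p_s`, `"futility"` when `prob <= p_f`,
#' `"continue"` inside the open band. Both boundaries are inclusive.
#'
#' @param prob Posterior probability of benefit.
#' @param p_s,p_f Efficacy and futility boundaries, `0 < p_f < p_s < 1`.
#' @return One of `"efficacy"`, `"futility"`, `"continue"`.
#' @examples
#' decide(0.98, p_s = 0.98, p_f = 0.02)  # "efficacy" (boundary inclusive)
#' @export
decide <- function(prob, p_s, p_f) {
  if (!(p_f < p_s)) stop("p_f < p_s required")
  if (prob >= p_s) "efficacy" else if (prob <= p_f) "futility" else "continue"
}

#' Draw subject outcomes from the assumed sampling model
#'
#' @param family Outcome family.
#' @param theta_true True parameter value generating the data.
#' @param n Number of outcomes to draw.
#' @param sampling_sd Known SD (normal family only).
#' @return Numeric vector of length `n`; uses (and advances) the current
#'   R random number stream.
#' @export
sample_outcome <- function(family = c("bernoulli", "poisson", "normal"),
                           theta_true, n = 1L, sampling_sd = NULL) {
  family <- match.arg(family)
  switch(family,
    bernoulli = {
      if (!(theta_true >= 0 && theta_true <= 1)) {
        stop("a Bernoulli probability must lie in [0, 1]")
      }
      stats::rbinom(n, 1L, theta_true)
    },
    poisson = {
      if (!(theta_true >= 0)) stop("a Poisson rate must be >= 0")
      stats::rpois(n, theta_true)
    },
    normal = {
      if (is.null(sampling_sd) || !(sampling_sd > 0)) {
        stop("the normal family requires sampling_sd > 0")
      }
      stats::rnorm(n, theta_true, sampling_sd)
    })
}

update_stat <- function(family, cum, n, outcome) {
  # cum holds the running sum for all families; the normal suff stat is the
  # mean, derived at use sites as cum / n
  cum + outcome
}

stat_value <- function(family, cum, n) {
  if (family == "normal") cum / n else cum
}

#' Simulate one sequentially monitored trial
#'
#' Enrols subjects one at a time up to the planned maximum `N`. After each
#' subject the conjugate posterior is formed (DIP priors re-evaluated at the
#' current `n`), the posterior probability of benefit is computed, and the
#' stopping rule is applied. The boundary test at `n = N` is applied like
#' any other look; a remaining `"continue"` verdict at `N` is recorded as
#' `"inconclusive_at_N"` and does not reject the null.
#'
#' @param design A [trial_design()].
#' @param theta_true True parameter value generating the outcomes; if
#'   omitted, outcomes must be supplied.
#' @param outcomes Optional fixed outcome vector of length `N` (for replay
#'   or forced-stream analysis); bypasses random generation.
#' @param keep_path If `TRUE`, record the posterior probability at every
#'   look and the outcome stream in the result.
#' @return An object of class `trial_result` with fields `n_stop`,
#'   `decision` (`"efficacy"`, `"futility"` or `"inconclusive_at_N"`),
#'   `reject_null`, `final_stat` (a [suff_stat()]), and, when requested,
#'   `prob_path` and `outcomes`.
#' @examples
#' des <- trial_design("bernoulli", theta0 = 0.1,
#'                     prior = prior_spec("beta", "dip", null_center = 0.1,
#'                                        planned_N = 22),
#'                     N = 22, p_s = 0.98, p_f = 0.02)
#' set.seed(1)
#' simulate_trial(des, theta_true = 0.3)
#' @export
simulate_trial <- function(design, theta_true = NULL, outcomes = NULL,
                           keep_path = FALSE) {
  stopifnot(inherits(design, "trial_design"))
  N <- design$N
  if (is.null(outcomes)) {
    if (is.null(theta_true)) stop("either theta_true or outcomes is required")
    outcomes <- sample_outcome(design$family, theta_true, n = N,
                               sampling_sd = design$sampling_sd)
  } else {
    stopifnot(length(outcomes) >= N)
  }
  cum <- 0
  probs <- if (keep_path) numeric(N) else NULL
  decision <- "continue"
  n_stop <- N
  for (n in seq_len(N)) {
    cum <- cum + outcomes[n]
    st <- suff_stat(n, stat_value(design$family, cum, n))
    post <- posterior(design$prior, st, sampling_sd = design$sampling_sd)
    pr <- efficacy_probability(post, design$theta0, design$delta0,
                               design$direction)
    if (keep_path) probs[n] <- pr
    verdict <- decide(pr, design$p_s, design$p_f)
    if (verdict != "continue") {
      decision <- verdict
      n_stop <- n
      break
    }
  }
  if (decision == "continue") decision <- "inconclusive_at_N"
  structure(list(
    n_stop = n_stop,
    decision = decision,
    reject_null = decision == "efficacy",
    final_stat = suff_stat(n_stop, stat_value(design$family, cum, n_stop)),
    prob_path = if (keep_path) probs[seq_len(n_stop)] else NULL,
    outcomes = if (keep_path) outcomes[seq_len(n_stop)] else NULL
  ), class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  cat(sprintf("trial_result: %s at n = %d (stat = %g)%s\n",
              x$decision, x$n_stop, x$final_stat$stat,
              if (x$reject_null) ", null rejected" else ""))
  invisible(x)
}
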