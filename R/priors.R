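#' Decreasingly informative beta prior for a response rate
#'
#' Constructs the DIP beta prior for a Bernoulli response rate: a skeptical
#' prior centred at the null rate `p0` whose effective sample size is tied to
#' the *unobserved* sample size `N - n`. With `a = 1 + p0 (N - n)` and
#' `b = 1 + (1 - p0) (N - n)` the prior mode is `p0` while accrual is
#' incomplete, the ESS is `2 + (N - n)`, and at `n = N` the prior collapses
#' to the non-informative Beta(1, 1).
#'
#' @param p0 Null response rate, in \[0, 1\].
#' @param N Planned maximum sample size (integer >= 1).
#' @param n Observed sample size so far (integer, `0 <= n <= N`).
#' @param centering `"canonical"` uses the pseudo-count `N - n` (the working
#'   form used everywhere in this package); `"mode"` uses the strict
#'   mode-centred solution with pseudo-count `N - n - 2` (floored at 0 so the
#'   prior stays proper near completion). The two differ only by 2 in ESS.
#' @return A [beta_params()] object.
#' @examples
#' dip_beta(0.1, N = 50, n = 10)   # Beta(5, 37)
#' dip_beta(0.3, N = 20, n = 20)   # Beta(1, 1): non-informative at completion
#' @export
dip_beta <- function(p0, N, n, centering = c("canonical", "mode")) {
  centering <- match.arg(centering)
  stopifnot(length(p0) == 1L, length(N) == 1L, length(n) == 1L)
  if (!(p0 >= 0 && p0 <= 1)) stop("p0 must lie in [0, 1]")
  if (!(N >= 1 && N == round(N))) stop("N must be a positive integer")
  if (!(n >= 0 && n <= N && n == round(n))) stop("n must satisfy 0 <= n <= N")
  m <- switch(centering, canonical = N - n, mode = max(N - n - 2, 0))
  beta_params(1 + p0 * m, 1 + (1 - p0) * m)
}

#' Thall-Simon informative beta prior
#'
#' A beta prior with mean `p0 + delta0/2` (half way between the null rate and
#' the targeted rate) and total concentration `c_e = a + b` controlling how
#' informative it is: `c_e = 2` is sparse, `c_e = 10` is tightly localised
#' around its mean.
#'
#' @param p0 Null response rate.
#' @param delta0 Targeted improvement over `p0` (>= 0).
#' @param c_e Concentration (prior ESS), strictly positive.
#' @return A [beta_params()] object with `a + b = c_e`.
#' @examples
#' thall_simon_beta(0.2, 0.2, c_e = 10)  # Beta(3, 7)
#' @export
thall_simon_beta <- function(p0, delta0, c_e) {
  stopifnot(length(p0) == 1L, length(delta0) == 1L, length(c_e) == 1L)
  mu <- p0 + delta0 / 2
  if (!(mu >= 0 && mu <= 1)) stop("prior mean p0 + delta0/2 must lie in [0, 1]")
  if (!(c_e > 0)) stop("c_e must be > 0")
  beta_params(c_e * mu, c_e * (1 - mu))
}

#' Decreasingly informative gamma prior for a Poisson event rate
#'
#' The DIP for a Poisson rate: Gamma(`0.5 + lambda0 (N - n)`,
#' `0.001 + (N - n)`) in shape/rate form, so the ESS (the rate) equals
#' `0.001 + (N - n)` and the prior degrades to the limiting Jeffreys prior
#' Gamma(0.5, 0.001) when accrual completes.
#'
#' @param lambda0 Null event rate (>= 0).
#' @inheritParams dip_beta
#' @return A [gamma_params()] object.
#' @examples
#' dip_gamma(0.5, N = 100, n = 50)  # Gamma(25.5, 50.001)
#' dip_gamma(5, N = 10, n = 10)     # Gamma(0.5, 0.001)
#' @export
dip_gamma <- function(lambda0, N, n) {
  stopifnot(length(lambda0) == 1L, length(N) == 1L, length(n) == 1L)
  if (!(lambda0 >= 0)) stop("lambda0 must be >= 0")
  if (!(N >= 1 && N == round(N))) stop("N must be a positive integer")
  if (!(n >= 0 && n <= N && n == round(n))) stop("n must satisfy 0 <= n <= N")
  gamma_params(0.5 + lambda0 * (N - n), 0.001 + (N - n))
}

#' Limiting Jeffreys gamma prior
#'
#' Gamma(0.5, 0.001): the near-non-informative limiting prior for a Poisson
#' rate under the shape/rate convention (prior ESS 0.001).
#'
#' @return A [gamma_params()] object.
#' @export
jeffreys_gamma <- function() gamma_params(0.5, 0.001)

#' Prior specification for a sequential trial design
#'
#' Bundles a conjugate family with a prior *flavor* and the scalars that
#' flavor needs, so the monitoring engine can materialise the prior at any
#' observed sample size `n`. DIP flavors are dynamic (re-evaluated at the
#' current `n`); all other flavors are fixed.
#'
#' Supported flavors by family:
#' \describe{
#'   \item{beta}{`"dip"` (canonical DIP), `"dip_mode"` (strict mode-centred
#'     variant), `"noninformative"` (Beta(1, 1)), `"informative_ts"`
#'     (Thall-Simon, needs `c_e` and uses `delta0`).}
#'   \item{gamma}{`"dip"`, `"jeffreys_gamma"` (alias `"noninformative"`).}
#'   \item{normal}{`"dip"`, `"normal_fixed_ess"` (needs `n0`).}
#' }
#'
#' @param family One of `"beta"`, `"gamma"`, `"normal"`.
#' @param flavor Prior flavor; see Details.
#' @param null_center Null parameter value the skeptical prior is centred at
#'   (`p0`, `lambda0` or `mu0`). Required for all flavors except the
#'   non-informative ones.
#' @param planned_N Planned maximum sample size; required for DIP flavors.
#' @param c_e Thall-Simon concentration (beta `"informative_ts"` only).
#' @param n0 Fixed prior ESS (normal `"normal_fixed_ess"` only).
#' @param delta0 Targeted improvement used for prior centring by
#'   `"informative_ts"` (defaults to 0). Independent of the testing margin.
#' @return An object of class `prior_spec`.
#' @seealso [prior_params()] to materialise the prior at an observed `n`,
#'   [posterior()] for the conjugate update.
#' @examples
#' prior_spec("beta", "dip", null_center = 0.1, planned_N = 22)
#' prior_spec("beta", "informative_ts", null_center = 0.2, c_e = 10,
#'            delta0 = 0.2)
#' @export
prior_spec <- function(family = c("beta", "gamma", "normal"),
                       flavor = c("dip", "dip_mode", "noninformative",
                                  "informative_ts", "jeffreys_gamma",
                                  "normal_fixed_ess"),
                       null_center = NULL, planned_N = NULL,
                       c_e = NULL, n0 = NULL, delta0 = 0) {
  family <- match.arg(family)
  flavor <- match.arg(flavor)
  if (family == "gamma" && flavor == "noninformative") flavor <- "jeffreys_gamma"
  ok <- switch(family,
    beta   = c("dip", "dip_mode", "noninformative", "informative_ts"),
    gamma  = c("dip", "jeffreys_gamma"),
    normal = c("dip", "normal_fixed_ess"))
  if (!flavor %in% ok) {
    stop(sprintf("flavor '%s' is not valid for family '%s'", flavor, family))
  }
  dynamic <- flavor %in% c("dip", "dip_mode")
  if (dynamic) {
    if (is.null(planned_N) || !(planned_N >= 1 && planned_N == round(planned_N))) {
      stop("DIP flavors require planned_N >= 1")
    }
    if (is.null(null_center)) stop("DIP flavors require a null_center")
  }
  if (flavor == "informative_ts") {
    if (is.null(c_e)) stop("informative_ts requires c_e")
    if (is.null(null_center)) stop("informative_ts requires a null_center")
  }
  if (flavor == "normal_fixed_ess") {
    if (is.null(n0) || !(n0 > 0)) stop("normal_fixed_ess requires n0 > 0")
    if (is.null(null_center)) stop("normal_fixed_ess requires a null_center")
  }
  if (family == "beta" && !is.null(null_center) &&
      !(null_center >= 0 && null_center <= 1)) {
    stop("null_center must lie in [0, 1] for the beta family")
  }
  structure(list(family = family, flavor = flavor, null_center = null_center,
                 planned_N = if (is.null(planned_N)) NULL else as.integer(planned_N),
                 c_e = c_e, n0 = n0, delta0 = delta0),
            class = "prior_spec")
}

#' Materialise a prior specification at an observed sample size
#'
#' Evaluates a [prior_spec()] at observed sample size `n`. Fixed flavors
#' ignore `n`; DIP flavors return the prior with pseudo-data `N - n`. For the
#' normal DIP at `n = N` the prior variance `s^2/(N - n)` is no longer
#' defined, so the fully diffuse prior (infinite variance, ESS 0) is
#' returned; the posterior is computed directly from its closed form in
#' [posterior()] and does not go through this degenerate prior.
#'
#' @param spec A [prior_spec()].
#' @param n Observed sample size (`0 <= n <= planned_N` for DIP flavors).
#' @param sampling_sd Known sampling SD (normal family only).
#' @return A `conjugate_params` object.
#' @export
prior_params <- function(spec, n = 0L, sampling_sd = NULL) {
  stopifnot(inherits(spec, "prior_spec"))
  switch(spec$flavor,
    dip = switch(spec$family,
      beta  = dip_beta(spec$null_center, spec$planned_N, n),
      gamma = dip_gamma(spec$null_center, spec$planned_N, n),
      normal = {
        if (is.null(sampling_sd)) stop("sampling_sd required for the normal family")
        if (!(n >= 0 && n <= spec$planned_N)) stop("n must satisfy 0 <= n <= N")
        v <- if (n < spec$planned_N) sampling_sd^2 / (spec$planned_N - n) else Inf
        normal_params(spec$null_center, v)
      }),
    dip_mode = dip_beta(spec$null_center, spec$planned_N, n, centering = "mode"),
    noninformative = beta_params(1, 1),
    informative_ts = thall_simon_beta(spec$null_center, spec$delta0, spec$c_e),
    jeffreys_gamma = jeffreys_gamma(),
    normal_fixed_ess = {
      if (is.null(sampling_sd)) stop("sampling_sd required for the normal family")
      normal_params(spec$null_center, sampling_sd^2 / spec$n0)
    })
}

#' @rdname ess
#' @param n Observed sample size at which a dynamic (DIP) prior is evaluated.
#' @export
ess.prior_spec <- function(params, n = 0L, sampling_sd = NULL, ...) {
  ess(prior_params(params, n = n, sampling_sd = sampling_sd),
      sampling_sd = sampling_sd)
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(sprintf("prior_spec: family = %s, flavor = %s", x$family, x$flavor))
  if (!is.null(x$null_center)) cat(sprintf(", null_center = %g", x$null_center))
  if (!is.null(x$planned_N)) cat(sprintf(", planned_N = %d", x$planned_N))
  if (!is.null(x$c_e)) cat(sprintf(", c_e = %g", x$c_e))
  if (!is.null(x$n0)) cat(sprintf(", n0 = %g", x$n0))
  cat("\n")
  invisible(x)
}
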