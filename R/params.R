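#' Conjugate-family parameter containers
#'
#' Lightweight S3 containers for the three conjugate families used throughout
#' the package: beta (Bernoulli response rate), gamma in shape/rate form
#' (Poisson event rate), and normal with known sampling variance (Gaussian
#' mean). The gamma rate convention is deliberate: under it the rate
#' parameter *is* the effective prior sample size, which is what makes
#' Gamma(0.5, 0.001) near-non-informative.
#'
#' @param a,b Beta shape parameters (pseudo-counts of successes/failures),
#'   both strictly positive.
#' @return An object of class `beta_params`, `gamma_params` or
#'   `normal_params` (all inheriting from `conjugate_params`).
#' @seealso [ess()] for the effective prior sample size of each family.
#' @examples
#' beta_params(1, 1)
#' gamma_params(0.5, 0.001)
#' normal_params(100, 15^2 / 10)
#' @export
beta_params <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) == 1L, length(b) == 1L)
  if (!(a > 0 && b > 0)) stop("beta parameters must satisfy a > 0 and b > 0")
  structure(list(a = a, b = b),
            class = c("beta_params", "conjugate_params"))
}

#' @rdname beta_params
#' @param shape,rate Gamma shape and rate, both strictly positive.
#' @export
gamma_params <- function(shape, rate) {
  stopifnot(is.numeric(shape), is.numeric(rate),
            length(shape) == 1L, length(rate) == 1L)
  if (!(shape > 0 && rate > 0)) {
    stop("gamma parameters must satisfy shape > 0 and rate > 0")
  }
  structure(list(shape = shape, rate = rate),
            class = c("gamma_params", "conjugate_params"))
}

#' @rdname beta_params
#' @param mean Normal mean, in outcome units.
#' @param variance Normal variance, in squared outcome units; strictly
#'   positive (`Inf` is allowed and denotes a fully diffuse prior).
#' @export
normal_params <- function(mean, variance) {
  stopifnot(is.numeric(mean), is.numeric(variance),
            length(mean) == 1L, length(variance) == 1L)
  if (!(variance > 0)) stop("normal variance must be > 0")
  structure(list(mean = mean, variance = variance),
            class = c("normal_params", "conjugate_params"))
}

#' Effective prior sample size
#'
#' The number of hypothetical observations a prior (or posterior) is worth:
#' `a + b` for a beta, the rate parameter for a gamma in shape/rate form, and
#' `s^2 / variance` for a normal prior on a mean observed with known sampling
#' standard deviation `s`.
#'
#' @param params A `beta_params`, `gamma_params` or `normal_params` object,
#'   or a [prior_spec()] (evaluated at a given observed sample size).
#' @param ... Passed to methods.
#' @return A non-negative scalar.
#' @examples
#' ess(beta_params(1, 1))                    # 2
#' ess(gamma_params(0.5, 0.001))             # 0.001
#' ess(normal_params(100, 15^2 / 8), sampling_sd = 15)  # 8
#' @export
ess <- function(params, ...) UseMethod("ess")

#' @export
ess.beta_params <- function(params, ...) params$a + params$b

#' @export
ess.gamma_params <- function(params, ...) params$rate

#' @rdname ess
#' @param sampling_sd Known sampling standard deviation `s` (normal family
#'   only; required there).
#' @export
ess.normal_params <- function(params, sampling_sd = NULL, ...) {
  if (is.null(sampling_sd)) {
    stop("sampling_sd is required to compute the ESS of a normal prior")
  }
  stopifnot(sampling_sd > 0)
  sampling_sd^2 / params$variance
}

#' @export
print.beta_params <- function(x, ...) {
  cat(sprintf("Beta(a = %g, b = %g), ESS = %g, mean = %g\n",
              x$a, x$b, x$a + x$b, x$a / (x$a + x$b)))
  invisible(x)
}

#' @export
print.gamma_params <- function(x, ...) {
  cat(sprintf("Gamma(shape = %g, rate = %g), ESS = %g, mean = %g\n",
              x$shape, x$rate, x$rate, x$shape / x$rate))
  invisible(x)
}

#' @export
print.normal_params <- function(x, ...) {
  cat(sprintf("Normal(mean = %g, variance = %g)\n", x$mean, x$variance))
  invisible(x)
}

#' Sufficient statistic for a partially observed trial
#'
#' @param n Number of subjects observed so far (integer, >= 0).
#' @param stat Family-specific aggregate: number of successes (Bernoulli,
#'   `0 <= stat <= n`), total event count (Poisson, `stat >= 0`), or the
#'   sample mean (normal; undefined and ignored when `n = 0`).
#' @return An object of class `suff_stat`.
#' @examples
#' suff_stat(10, 4)
#' @export
suff_stat <- function(n, stat) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 0, n == round(n))
  if (n > 0) stopifnot(is.numeric(stat), length(stat) == 1L)
  structure(list(n = as.integer(n), stat = stat), class = "suff_stat")
}
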