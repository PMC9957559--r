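#' Design-search grid
#'
#' The grid of candidate `(N, p_s, p_f)` configurations searched for the
#' smallest admissible design. Defaults follow the usual simulation
#' template: `p_s` from 0.80 to 0.99 and `p_f` from 0.01 to 0.10 in steps
#' of 0.01, `N` from 10 to 100 in steps of 1, with admissibility defined as
#' power >= 0.80 and type I error <= 0.05.
#'
#' @param N_range,ps_range,pf_range Length-2 inclusive ranges.
#' @param N_step,ps_step,pf_step Grid steps.
#' @param power_min Minimum admissible power (default 0.80).
#' @param alpha_max Maximum admissible type I error (default 0.05).
#' @return An object of class `search_grid`.
#' @export
search_grid <- function(N_range = c(10L, 100L), ps_range = c(0.80, 0.99),
                        pf_range = c(0.01, 0.10), N_step = 1L,
                        ps_step = 0.01, pf_step = 0.01,
                        power_min = 0.80, alpha_max = 0.05) {
  N_vals <- seq(N_range[1], N_range[2], by = N_step)
  ps_vals <- round(seq(ps_range[1], ps_range[2], by = ps_step), 10)
  pf_vals <- round(seq(pf_range[1], pf_range[2], by = pf_step), 10)
  if (any(pf_vals >= min(ps_vals))) {
    bad <- outer(pf_vals, ps_vals, ">=")
    if (all(bad)) stop("grid contains no point with p_f < p_s")
  }
  if (!length(N_vals) || !length(ps_vals) || !length(pf_vals)) {
    stop("empty search grid")
  }
  structure(list(N_vals = as.integer(N_vals), ps_vals = ps_vals,
                 pf_vals = pf_vals, power_min = power_min,
                 alpha_max = alpha_max),
            class = "search_grid")
}

#' Model setting for a design search
#'
#' The scientific scenario a search is run for: outcome family, prior
#' flavor, null and alternative parameter values, and any flavor- or
#' family-specific scalars. The planned `N` and boundaries are supplied by
#' the search grid, not here.
#'
#' @param family `"bernoulli"`, `"poisson"` or `"normal"`.
#' @param flavor Prior flavor (see [prior_spec()]); families map to their
#'   conjugate prior family automatically.
#' @param theta0,theta1 Null and alternative parameter values.
#' @param delta0 Testing margin (default 0).
#' @param c_e,n0 Flavor-specific scalars (Thall-Simon concentration; fixed
#'   normal prior ESS).
#' @param sampling_sd Known SD (normal family).
#' @param direction Direction of benefit; defaults to the family convention.
#' @return An object of class `model_setting`.
#' @export
model_setting <- function(family = c("bernoulli", "poisson", "normal"),
                          flavor = "dip", theta0, theta1, delta0 = 0,
                          c_e = NULL, n0 = NULL, sampling_sd = NULL,
                          direction = NULL) {
  family <- match.arg(family)
  structure(list(family = family, flavor = flavor, theta0 = theta0,
                 theta1 = theta1, delta0 = delta0, c_e = c_e, n0 = n0,
                 sampling_sd = sampling_sd, direction = direction),
            class = "model_setting")
}

#' Build the concrete trial design for a grid point
#'
#' @param setting A [model_setting()].
#' @param N,p_s,p_f The grid point.
#' @return A [trial_design()].
#' @export
setting_design <- function(setting, N, p_s, p_f) {
  stopifnot(inherits(setting, "model_setting"))
  prior_family <- c(bernoulli = "beta", poisson = "gamma",
                    normal = "normal")[[setting$family]]
  dynamic <- setting$flavor %in% c("dip", "dip_mode")
  prior <- prior_spec(prior_family, setting$flavor,
                      null_center = setting$theta0,
                      planned_N = if (dynamic) N else NULL,
                      c_e = setting$c_e, n0 = setting$n0,
                      delta0 = setting$delta0)
  trial_design(setting$family, theta0 = setting$theta0, prior = prior,
               N = N, p_s = p_s, p_f = p_f, delta0 = setting$delta0,
               direction = setting$direction,
               sampling_sd = setting$sampling_sd)
}

oc_backend_fun <- function(backend, R, seed) {
  if (backend == "exact_dp") {
    function(design, theta) exact_oc_bernoulli(design, theta)
  } else {
    function(design, theta) {
      estimate_oc(design, theta, R = R,
                  seed = replicate_seed(seed, design$N * 100003 +
                                          round(design$p_s * 1e4) * 11 +
                                          round(design$p_f * 1e4)))
    }
  }
}

#' Smallest-N admissible design search
#'
#' Scans the grid in order of increasing planned sample size `N`, computing
#' power at `theta1` for every `(p_s, p_f)` and type I error at `theta0` for
#' the points that reach the power floor. The first `N` carrying an
#' admissible point (power >= `power_min`, type I <= `alpha_max`) wins;
#' among its admissible points ties are broken deterministically by highest
#' power, then lowest type I error, then highest `p_s`, then lowest `p_f`.
#'
#' If no grid point is admissible, one of two fallback rules fires: when
#' some points reach the power floor, the one with the lowest type I error
#' (`rule_applied = "fallback_min_type1"`); otherwise the point with the
#' highest power and, among powers within one Monte Carlo SE of the
#' maximum, the lowest type I error (`"fallback_max_power"`).
#'
#' @param setting A [model_setting()].
#' @param grid A [search_grid()].
#' @param R Replicates per grid point (Monte Carlo backend).
#' @param seed Seed for the Monte Carlo backend.
#' @param backend `"exact_dp"` (Bernoulli only; deterministic) or
#'   `"monte_carlo"`.
#' @return An object of class `search_result` with the selected
#'   [trial_design()], its power and type I estimates, the admissibility
#'   flag, `rule_applied`, and `evaluated` (number of grid points whose
#'   power was computed).
#' @examples
#' st <- model_setting("bernoulli", "dip", theta0 = 0.1, theta1 = 0.3)
#' g <- search_grid(N_range = c(20, 30))
#' search_smallest_admissible(st, g, backend = "exact_dp")
#' @export
search_smallest_admissible <- function(setting, grid, R = 1000L, seed = 1L,
                                       backend = c("exact_dp", "monte_carlo")) {
  backend <- match.arg(backend)
  stopifnot(inherits(setting, "model_setting"), inherits(grid, "search_grid"))
  if (backend == "exact_dp" && setting$family != "bernoulli") {
    stop("the exact_dp backend is available for the Bernoulli family only")
  }
  oc <- oc_backend_fun(backend, R, seed)
  pts <- expand.grid(p_f = grid$pf_vals, p_s = grid$ps_vals,
                     KEEP.OUT.ATTRS = FALSE)
  pts <- pts[pts$p_f < pts$p_s, , drop = FALSE]
  if (!nrow(pts)) stop("empty search grid")

  rows <- vector("list", length(grid$N_vals))
  evaluated <- 0L
  pick <- NULL
  for (i in seq_along(grid$N_vals)) {
    N <- grid$N_vals[i]
    power <- numeric(nrow(pts))
    type1 <- rep(NA_real_, nrow(pts))
    pse <- numeric(nrow(pts))
    for (j in seq_len(nrow(pts))) {
      des <- setting_design(setting, N, pts$p_s[j], pts$p_f[j])
      r <- oc(des, setting$theta1)
      power[j] <- r$reject_rate
      pse[j] <- r$mc_se
      evaluated <- evaluated + 1L
      if (power[j] >= grid$power_min) {
        type1[j] <- oc(des, setting$theta0)$reject_rate
      }
    }
    rows[[i]] <- data.frame(N = N, p_s = pts$p_s, p_f = pts$p_f,
                            power = power, type1 = type1, power_se = pse)
    adm <- which(power >= grid$power_min & !is.na(type1) &
                   type1 <= grid$alpha_max)
    if (length(adm)) {
      cand <- rows[[i]][adm, , drop = FALSE]
      o <- order(-cand$power, cand$type1, -cand$p_s, cand$p_f)
      pick <- cand[o[1L], , drop = FALSE]
      rule <- "admissible_min_N"
      break
    }
  }

  tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(pick)) {
    floor_ok <- tab[!is.na(tab$type1), , drop = FALSE]
    if (nrow(floor_ok)) {
      # power floor reachable but type I never controlled
      o <- order(floor_ok$type1, -floor_ok$power, floor_ok$N,
                 -floor_ok$p_s, floor_ok$p_f)
      pick <- floor_ok[o[1L], , drop = FALSE]
      rule <- "fallback_min_type1"
    } else {
      # power floor unreachable: highest power, then best-controlled type I
      pmax_ <- max(tab$power)
      near <- tab[tab$power >= pmax_ - tab$power_se, , drop = FALSE]
      for (k in seq_len(nrow(near))) {
        if (is.na(near$type1[k])) {
          des <- setting_design(setting, near$N[k], near$p_s[k], near$p_f[k])
          near$type1[k] <- oc(des, setting$theta0)$reject_rate
        }
      }
      o <- order(-near$power, near$type1, near$N, -near$p_s, near$p_f)
      pick <- near[o[1L], , drop = FALSE]
      rule <- "fallback_max_power"
    }
  }

  design <- setting_design(setting, pick$N, pick$p_s, pick$p_f)
  structure(list(
    design = design,
    N = pick$N, p_s = pick$p_s, p_f = pick$p_f,
    power = pick$power, type1 = pick$type1,
    admissible = rule == "admissible_min_N",
    rule_applied = rule,
    evaluated = evaluated,
    backend = backend,
    grid_table = tab
  ), class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf(
    "search_result [%s, %s]: N = %d, p_f = %.2f, p_s = %.2f, power = %.3f, type I = %.3f (%d points evaluated)\n",
    x$rule_applied, x$backend, x$N, x$p_f, x$p_s, x$power, x$type1,
    x$evaluated))
  invisible(x)
}

#' Sweep a list of model settings through the design search
#'
#' Runs [search_smallest_admissible()] for each setting and assembles the
#' selected designs into one table in the usual reporting layout (model,
#' prior flavor, null and true parameter, selected N and boundaries, power,
#' type I error, selection rule).
#'
#' @param settings A list of [model_setting()] objects.
#' @inheritParams search_smallest_admissible
#' @return A data frame with one row per setting.
#' @export
sweep_report <- function(settings, grid = search_grid(), R = 1000L,
                         seed = 1L, backend = c("exact_dp", "monte_carlo")) {
  backend <- match.arg(backend)
  if (!length(settings)) {
    return(data.frame(model = character(), prior_flavor = character(),
                      theta0 = numeric(), theta1 = numeric(), N = integer(),
                      p_f = numeric(), p_s = numeric(), power = numeric(),
                      type1 = numeric(), rule_applied = character()))
  }
  out <- lapply(settings, function(st) {
    sr <- search_smallest_admissible(st, grid, R = R, seed = seed,
                                     backend = backend)
    data.frame(model = st$family, prior_flavor = st$flavor,
               theta0 = st$theta0, theta1 = st$theta1, N = sr$N,
               p_f = sr$p_f, p_s = sr$p_s, power = sr$power,
               type1 = sr$type1, rule_applied = sr$rule_applied)
  })
  do.call(rbind, out)
}
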