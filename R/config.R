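#' Parse and validate a run configuration
#'
#' Reads a JSON configuration file (and/or a list of overrides, e.g. parsed
#' command-line flags; overrides win) and validates it into a `run_config`.
#' Unknown keys are rejected; defaults (`R = 1000`, `delta0 = 0`, the
#' standard search grid) are applied and echoed in the resolved object.
#'
#' Recognised keys: `mode` (`"oc"`, `"search"`, `"sweep"`, `"trace"`),
#' `family`, `prior` (flavor), `theta0`, `theta1` (scalar, or a vector for
#' `sweep`), `delta0`, `sampling_sd`, `c_e`, `n0`, `N`, `p_s`, `p_f`
#' (fixed-design modes), `N_range`, `ps_range`, `pf_range`, `power_min`,
#' `alpha_max` (search modes), `R`, `seed`, `backend`, `out`.
#'
#' @param path Path to a JSON config file, or `NULL`.
#' @param overrides Named list of values overriding the file.
#' @return An object of class `run_config`.
#' @examples
#' cfg <- parse_config(overrides = list(mode = "oc", family = "bernoulli",
#'   prior = "dip", theta0 = 0.1, theta1 = 0.3, N = 22,
#'   p_s = 0.98, p_f = 0.02))
#' cfg$R  # default 1000
#' @export
parse_config <- function(path = NULL, overrides = list()) {
  known <- c("mode", "family", "prior", "theta0", "theta1", "delta0",
             "sampling_sd", "c_e", "n0", "N", "p_s", "p_f", "N_range",
             "ps_range", "pf_range", "power_min", "alpha_max", "R", "seed",
             "backend", "out")
  cfg <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  overrides <- overrides[!vapply(overrides, is.null, logical(1))]
  cfg[names(overrides)] <- overrides
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  need <- function(key) {
    if (is.null(cfg[[key]])) stop("config field '", key, "' is required")
    cfg[[key]]
  }
  mode <- match.arg(need("mode"), c("oc", "search", "sweep", "trace"))
  family <- match.arg(need("family"), c("bernoulli", "poisson", "normal"))
  flavor <- if (is.null(cfg$prior)) "dip" else cfg$prior
  if (is.null(cfg$R)) cfg$R <- 1000L
  if (is.null(cfg$delta0)) cfg$delta0 <- 0
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$backend)) {
    cfg$backend <- if (mode %in% c("search", "sweep") &&
                       family == "bernoulli") "exact_dp" else "monte_carlo"
  }
  cfg$backend <- match.arg(cfg$backend, c("exact_dp", "monte_carlo"))
  if (!(cfg$R >= 1 && cfg$R == round(cfg$R))) stop("R must be a positive integer")
  theta0 <- need("theta0")
  setting_for <- function(theta1) {
    model_setting(family, flavor, theta0 = theta0, theta1 = theta1,
                  delta0 = cfg$delta0, c_e = cfg$c_e, n0 = cfg$n0,
                  sampling_sd = cfg$sampling_sd)
  }
  if (mode %in% c("oc", "trace")) {
    for (key in c("N", "p_s", "p_f")) need(key)
    if (!(cfg$p_f < cfg$p_s)) stop("p_f < p_s required")
    theta1 <- if (is.null(cfg$theta1)) theta0 else cfg$theta1
    design <- setting_design(setting_for(theta1), cfg$N, cfg$p_s, cfg$p_f)
  } else {
    design <- NULL
  }
  grid <- NULL
  if (mode %in% c("search", "sweep")) {
    ga <- function(key, default) if (is.null(cfg[[key]])) default else cfg[[key]]
    grid <- search_grid(N_range = ga("N_range", c(10L, 100L)),
                        ps_range = ga("ps_range", c(0.80, 0.99)),
                        pf_range = ga("pf_range", c(0.01, 0.10)),
                        power_min = ga("power_min", 0.80),
                        alpha_max = ga("alpha_max", 0.05))
  }
  theta1 <- if (is.null(cfg$theta1)) theta0 else cfg$theta1
  structure(list(mode = mode, family = family, flavor = flavor,
                 theta0 = theta0, theta1 = theta1, delta0 = cfg$delta0,
                 sampling_sd = cfg$sampling_sd, c_e = cfg$c_e, n0 = cfg$n0,
                 design = design, grid = grid, R = as.integer(cfg$R),
                 seed = cfg$seed, backend = cfg$backend,
                 out = cfg$out, settings = lapply(theta1, setting_for)),
            class = "run_config")
}

#' Serialise a run configuration
#'
#' Writes the resolved scalar fields of a `run_config` as JSON that
#' [parse_config()] reads back to an identical configuration (round-trip
#' identity).
#'
#' @param config A `run_config`.
#' @param path Output path; when `NULL` the JSON string is returned.
#' @export
write_config <- function(config, path = NULL) {
  stopifnot(inherits(config, "run_config"))
  fields <- list(mode = config$mode, family = config$family,
                 prior = config$flavor, theta0 = config$theta0,
                 theta1 = config$theta1, delta0 = config$delta0,
                 sampling_sd = config$sampling_sd, c_e = config$c_e,
                 n0 = config$n0, R = config$R, seed = config$seed,
                 backend = config$backend, out = config$out)
  if (!is.null(config$design)) {
    fields$N <- config$design$N
    fields$p_s <- config$design$p_s
    fields$p_f <- config$design$p_f
  }
  if (!is.null(config$grid)) {
    fields$N_range <- range(config$grid$N_vals)
    fields$ps_range <- range(config$grid$ps_vals)
    fields$pf_range <- range(config$grid$pf_vals)
    fields$power_min <- config$grid$power_min
    fields$alpha_max <- config$grid$alpha_max
  }
  fields <- fields[!vapply(fields, is.null, logical(1))]
  json <- jsonlite::toJSON(fields, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(json))
  writeLines(as.character(json), path)
  invisible(path)
}

#' Execute a run configuration
#'
#' Dispatches on `config$mode`:
#' \describe{
#'   \item{oc}{Operating characteristics of the fixed design: power at
#'     `theta1`, type I error at `theta0`, expected sample size.}
#'   \item{search}{Smallest-N admissible design search over the grid.}
#'   \item{sweep}{One search per `theta1` value; table layout of the usual
#'     simulation reports.}
#'   \item{trace}{A single simulated trial with its full per-look record.}
#' }
#' When `config$out` is set, results are written there as CSV
#' (probabilities to 3 decimals), a provenance JSON (`<out>.provenance.json`
#' holding the resolved config and package version) alongside; `trace`
#' writes JSON lines. The computed object is returned invisibly.
#'
#' @param config A `run_config` from [parse_config()].
#' @return The result object, invisibly.
#' @export
run_mode <- function(config) {
  stopifnot(inherits(config, "run_config"))
  result <- switch(config$mode,
    oc = {
      pw <- estimate_oc(config$design, config$theta1, R = config$R,
                        seed = config$seed)
      t1 <- estimate_oc(config$design, config$theta0, R = config$R,
                        seed = config$seed)
      data.frame(model = config$family, prior_flavor = config$flavor,
                 theta0 = config$theta0, theta1 = config$theta1,
                 N = config$design$N, p_f = config$design$p_f,
                 p_s = config$design$p_s, power = pw$reject_rate,
                 type1 = t1$reject_rate, expected_n = pw$expected_n,
                 mc_se = pw$mc_se)
    },
    search = {
      sr <- search_smallest_admissible(config$settings[[1L]], config$grid,
                                       R = config$R, seed = config$seed,
                                       backend = config$backend)
      data.frame(model = config$family, prior_flavor = config$flavor,
                 theta0 = config$theta0, theta1 = config$settings[[1L]]$theta1,
                 N = sr$N, p_f = sr$p_f, p_s = sr$p_s, power = sr$power,
                 type1 = sr$type1, rule_applied = sr$rule_applied)
    },
    sweep = sweep_report(config$settings, config$grid, R = config$R,
                         seed = config$seed, backend = config$backend),
    trace = {
      set.seed(replicate_seed(config$seed, 1L))
      simulate_trial(config$design, theta_true = config$theta1,
                     keep_path = TRUE)
    })
  if (!is.null(config$out)) {
    if (config$mode == "trace") {
      write_trace(result, config$design, config$out)
    } else {
      tab <- result
      num <- vapply(tab, is.numeric, logical(1)) &
        !names(tab) %in% c("N", "theta0", "theta1", "expected_n")
      tab[num] <- lapply(tab[num], round, 3)
      utils::write.csv(tab, config$out, row.names = FALSE)
    }
    write_config(config, paste0(config$out, ".provenance.json"))
  }
  invisible(result)
}

# one JSON line per monitoring look
write_trace <- function(result, design, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cum <- 0
  for (n in seq_len(result$n_stop)) {
    cum <- cum + result$outcomes[n]
    st <- suff_stat(n, stat_value(design$family, cum, n))
    post <- posterior(design$prior, st, sampling_sd = design$sampling_sd)
    rec <- list(n = n, stat = st$stat, posterior = unclass(post),
                prob = result$prob_path[n],
                decision = if (n < result$n_stop) "continue" else result$decision)
    writeLines(as.character(jsonlite::toJSON(rec, auto_unbox = TRUE,
                                             digits = NA)), con)
  }
  invisible(path)
}
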