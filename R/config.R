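# YAML/JSON configuration for simulations.
#
# The reproduction hazard in this model is the unit of the treatment
# intensity: sigma is defined per 4-day cell cycle, while doses are often
# quoted as daily arrest (sigma / 4). Config files therefore take either
# `sigma_cycle` or `sigma_day` (never both), and rates given as strings
# with a "%" suffix are parsed as percentages. A bare numeric sigma of
# 0.5 or more is rejected as ambiguous (it could only be a percentage).

.param_defaults <- list(T = 4, s = 0.004, c = 0.001, u = 3.4e-5, v = 1e-6,
                        M = 1e9, kappa = 1e-4, days_per_year = 365)

.scenario_defaults <- list(kind = "prevention_fixed", M0 = 1e6,
                           discovery_threshold = 1e9, residual_size = 1e6,
                           metronomic = FALSE, horizon_years = NULL,
                           replicates = 1L, base_seed = 1L, max_years = 150)

# internal: parse a rate that may carry a "%" suffix
parse_rate <- function(x, field, ambiguous_above = Inf) {
  if (is.character(x)) {
    x <- trimws(x)
    if (grepl("%$", x)) {
      val <- suppressWarnings(as.numeric(sub("%$", "", x)))
      if (is.na(val)) stop("config field '", field, "': cannot parse '", x, "'")
      return(val / 100)
    }
    val <- suppressWarnings(as.numeric(x))
    if (is.na(val)) stop("config field '", field, "': cannot parse '", x, "'")
    x <- val
  }
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    stop("config field '", field, "' must be a single finite number")
  }
  if (x >= ambiguous_above) {
    stop("config field '", field, "': bare value ", x,
         " is ambiguous; use a '%' suffix for percentages")
  }
  x
}

# internal: plain number that may arrive as a YAML string ("1.0e9")
parse_number <- function(x, field) {
  if (is.null(x)) return(NULL)
  if (is.character(x)) {
    val <- suppressWarnings(as.numeric(x))
    if (is.na(val)) stop("config field '", field, "': cannot parse '", x, "'")
    return(val)
  }
  if (is.logical(x) || !is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    stop("config field '", field, "' must be a single finite number")
  }
  as.numeric(x)
}

#' Load a simulation configuration file
#'
#' Reads a YAML (or JSON) file with two sections, `params` and
#' `scenario`, filling unspecified model parameters with the baseline
#' defaults (4-day cycle, s = 0.4%, c = 0.1%, u = 3.4e-5, v = 1e-6,
#' M = 1e9 cells, kappa = 0.01%, M0 = 1e6). The maximum driver count `N`
#' has no default and must be given (5 or 9 depending on the scenario
#' family). The treatment intensity is given as `sigma_cycle` (per
#' 4-day cycle) or `sigma_day` (daily arrest, multiplied by the cycle
#' length); giving both is an error. Percentages may be written as
#' strings with a `%` suffix (`"1.5%"`).
#'
#' @param path Path to the YAML/JSON config file.
#' @return A list with elements `params` (a [model_params()]) and
#'   `scenario` (a [scenario_config()]).
#' @examples
#' tf <- tempfile(fileext = ".yaml")
#' writeLines(c("params:", "  N: 5", "scenario:",
#'              "  kind: prevention_fixed", "  sigma_day: '0.15%'"), tf)
#' cfg <- load_config(tf)
#' cfg$scenario$sigma  # 0.006 per cycle
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  bad <- setdiff(names(raw), c("params", "scenario"))
  if (length(bad)) stop("unknown top-level config keys: ",
                        paste(bad, collapse = ", "))
  praw <- raw$params %||% list()
  sraw <- raw$scenario %||% list()
  # YAML 1.1 resolves a bare `N` key to the boolean FALSE; map it back
  names(praw)[names(praw) == "FALSE"] <- "N"

  known_p <- c(names(.param_defaults), "N")
  bad <- setdiff(names(praw), known_p)
  if (length(bad)) stop("unknown keys in params: ", paste(bad, collapse = ", "))
  if (is.null(praw$N)) {
    stop("params.N (maximum additional drivers) must be set explicitly ",
         "(5 for fixed-composition prevention analyses, 9 otherwise)")
  }
  pv <- modifyList(.param_defaults, praw)
  for (fld in c("s", "c", "u", "v", "kappa")) {
    pv[[fld]] <- parse_rate(pv[[fld]], paste0("params.", fld),
                            ambiguous_above = 1)
  }
  for (fld in c("N", "T", "M", "days_per_year")) {
    pv[[fld]] <- parse_number(pv[[fld]], paste0("params.", fld))
  }
  params <- model_params(N = pv$N, s = pv$s, c = pv$c, u = pv$u, v = pv$v,
                         T = pv$T, M = pv$M, kappa = pv$kappa,
                         days_per_year = pv$days_per_year)

  known_s <- c(names(.scenario_defaults), "sigma_cycle", "sigma_day",
               "kappa", "R0")
  bad <- setdiff(names(sraw), known_s)
  if (length(bad)) stop("unknown keys in scenario: ", paste(bad, collapse = ", "))
  if (!is.null(sraw$sigma_cycle) && !is.null(sraw$sigma_day)) {
    stop("scenario: give sigma_cycle or sigma_day, not both")
  }
  sigma <- if (!is.null(sraw$sigma_day)) {
    params$T * parse_rate(sraw$sigma_day, "scenario.sigma_day",
                          ambiguous_above = 0.5)
  } else if (!is.null(sraw$sigma_cycle)) {
    parse_rate(sraw$sigma_cycle, "scenario.sigma_cycle", ambiguous_above = 0.5)
  } else {
    0
  }
  sv <- modifyList(.scenario_defaults,
                   sraw[setdiff(names(sraw), c("sigma_cycle", "sigma_day"))],
                   keep.null = TRUE)
  if (!is.null(sv$kappa)) sv$kappa <- parse_rate(sv$kappa, "scenario.kappa",
                                                 ambiguous_above = 1)
  for (fld in c("M0", "discovery_threshold", "residual_size", "R0",
                "horizon_years", "replicates", "base_seed", "max_years")) {
    sv[[fld]] <- parse_number(sv[[fld]], paste0("scenario.", fld))
  }
  scenario <- scenario_config(
    kind = sv$kind, M0 = sv$M0, sigma = sigma, kappa = sv$kappa, R0 = sv$R0,
    discovery_threshold = sv$discovery_threshold,
    residual_size = sv$residual_size, metronomic = isTRUE(sv$metronomic),
    horizon_years = sv$horizon_years, replicates = sv$replicates,
    base_seed = sv$base_seed, max_years = sv$max_years
  )
  list(params = params, scenario = scenario)
}

#' Write a configuration to YAML
#'
#' Inverse of [load_config()]: `load_config(write_config(cfg, path))`
#' resolves to the same parameters and scenario.
#'
#' @param cfg A list with `params` and `scenario`, as returned by
#'   [load_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg$params, "model_params"),
            inherits(cfg$scenario, "scenario_config"))
  p <- unclass(cfg$params)
  s <- unclass(cfg$scenario)
  s$sigma_cycle <- s$sigma
  s$sigma <- NULL
  s <- s[!vapply(s, is.null, logical(1))]
  yaml::write_yaml(list(params = p, scenario = s), path)
  invisible(path)
}

#' Write per-replicate outcomes to CSV
#'
#' Flat RFC-4180 CSV with columns `replicate_id`, `scenario`,
#' `sigma_cycle`, `status`, `t_detect_years`, `t_relapse_years`,
#' `t_discovery_years`, `resistant_fraction`, `mean_drivers`,
#' `resistant_count_4y`, `below_M_20y`, `seed` (snapshot list-columns
#' are dropped).
#'
#' @param outcomes A tibble from [run_scenario()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_outcomes <- function(outcomes, path) {
  df <- data.frame(
    replicate_id = outcomes$replicate,
    scenario = outcomes$scenario,
    sigma_cycle = outcomes$sigma_cycle,
    status = outcomes$status,
    t_detect_years = outcomes$t_detect_years,
    t_relapse_years = outcomes$t_relapse_years,
    t_discovery_years = outcomes$t_discovery_years,
    resistant_fraction = outcomes$resistant_fraction,
    mean_drivers = outcomes$mean_drivers,
    resistant_count_4y = outcomes$resistant_count_4y,
    below_M_20y = outcomes$below_M_20y,
    seed = outcomes$seed
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Run manifest
#'
#' Records everything needed to reproduce a run bit-exactly: the fully
#' resolved configuration, the package version, the base seed and the
#' per-replicate seed rule, a timestamp and the output file inventory.
#'
#' @param cfg A list with `params` and `scenario`.
#' @param files Character vector of output files produced.
#' @return A list suitable for JSON serialisation.
#' @export
run_manifest <- function(cfg, files = character()) {
  list(
    package = "oncoprev",
    version = as.character(packageVersion("oncoprev")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    params = unclass(cfg$params),
    scenario = unclass(cfg$scenario),
    base_seed = cfg$scenario$base_seed,
    seed_rule = "replicate k is seeded with base_seed + k",
    files = files
  )
}
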