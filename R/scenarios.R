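`%||%` <- function(a, b) if (is.null(a)) b else a

#' Scenario configuration
#'
#' Describes one intervention protocol:
#' * `prevention_fixed` — the lesion starts as `M0` identical (i = 0)
#'   cells of which `R0` (or `round(kappa * M0)`) are resistant, and a
#'   constant measure of intensity `sigma` is applied until detection.
#' * `prevention_grown` — the tumour grows untreated from one sensitive
#'   cell to `M0` cells (accumulating drivers and possibly resistance on
#'   the way), then treatment at `sigma` begins; the treatment clock
#'   starts at the `M0` event.
#' * `post_diagnostic` — the tumour grows untreated from one cell to
#'   `discovery_threshold` cells, is resected to `residual_size` cells,
#'   and the residual population is treated at `sigma` until relapse
#'   (regrowth to the detection threshold).
#' * `second_chance` — prevention from the `M0` event at `sigma`; should
#'   the tumour still reach 10^9 cells, it is resected back to `M0`
#'   cells and treatment continues at the same `sigma`; the protocol
#'   fails if 10^9 cells are reached a second time within
#'   `horizon_years` (default 50) of the `M0` event.
#'
#' Growth phases condition on non-extinction: attempts that die out are
#' discarded and redrawn, and the number of attempts is reported.
#'
#' @param kind One of `"prevention_fixed"`, `"prevention_grown"`,
#'   `"post_diagnostic"`, `"second_chance"`.
#' @param M0 Initial (or resection-residual, for `second_chance`) cell
#'   count at which the measure starts.
#' @param sigma Per-cycle treatment intensity.
#' @param kappa Initial resistant fraction (`prevention_fixed` only);
#'   defaults to the model parameter `kappa`.
#' @param R0 Absolute initial resistant cell count; overrides `kappa`.
#' @param discovery_threshold Cell count triggering resection
#'   (`post_diagnostic`), typically 1e9 or 1e11.
#' @param residual_size Cells left after resection (`post_diagnostic`).
#' @param metronomic If `TRUE`, treatment is applied on a step only when
#'   sensitive cells outnumber resistant cells.
#' @param horizon_years Horizon for the treatment phase in years, or
#'   `NULL` for uncapped (a hard safety cap of `max_years` applies).
#' @param replicates Number of replicate simulations.
#' @param base_seed Base RNG seed; replicate k uses `base_seed + k`.
#' @param max_years Hard safety cap on any single phase.
#' @return An object of class `scenario_config`.
#' @examples
#' scenario_config("prevention_fixed", M0 = 1e6, sigma = 0.006,
#'                 replicates = 10, base_seed = 1)
#' @export
scenario_config <- function(kind = c("prevention_fixed", "prevention_grown",
                                     "post_diagnostic", "second_chance"),
                            M0 = 1e6, sigma = 0, kappa = NULL, R0 = NULL,
                            discovery_threshold = 1e9, residual_size = 1e6,
                            metronomic = FALSE, horizon_years = NULL,
                            replicates = 1L, base_seed = 1L,
                            max_years = 150) {
  kind <- match.arg(kind)
  stopifnot(M0 >= 1, sigma >= 0, replicates >= 1,
            residual_size <= discovery_threshold,
            is.null(horizon_years) || horizon_years > 0,
            max_years > 0)
  if (!is.null(R0) && R0 > M0) stop("R0 exceeds M0")
  if (!is.null(kappa) && (kappa < 0 || kappa > 1)) stop("kappa must be in [0, 1]")
  structure(
    list(kind = kind, M0 = M0, sigma = sigma, kappa = kappa, R0 = R0,
         discovery_threshold = discovery_threshold,
         residual_size = residual_size, metronomic = metronomic,
         horizon_years = horizon_years, replicates = as.integer(replicates),
         base_seed = as.integer(base_seed), max_years = max_years),
    class = "scenario_config"
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("Scenario %s: M0 = %g, sigma = %g/cycle, %d replicate(s), seed %d\n",
              x$kind, x$M0, x$sigma, x$replicates, x$base_seed))
  invisible(x)
}

# internal: value of a recorded trajectory at step k, frozen at episode end
traj_at <- function(traj, k, init_value) {
  if (length(traj) == 0) return(init_value)
  if (k <= length(traj)) traj[k] else traj[length(traj)]
}

# internal: grow a single sensitive cell to `target`, redrawing attempts
# that go extinct ("excluding extinctions" conditioning).
grow_from_one_cell <- function(target, params, max_years, max_attempts = 1e6) {
  counts <- matrix(0, params$N + 1, 2)
  max_steps <- years_to_steps(max_years, params)
  for (attempt in seq_len(max_attempts)) {
    counts[] <- 0
    counts[1, 1] <- 1
    res <- cpp_run(counts, 0, FALSE, params$s, params$c, params$u, params$v,
                   target, max_steps, FALSE)
    if (res$status == 0) {
      return(list(counts = res$counts, steps = res$steps, attempts = attempt))
    }
  }
  stop("growth phase failed to reach target in ", max_attempts, " attempts")
}

# internal: one treated episode from `counts`, returning outcome metrics.
# The 4-year and 20-year marks are measured on the supplied trajectory,
# whose clock starts when this episode starts.
treated_episode <- function(counts, config, params, target, horizon_steps) {
  res <- cpp_run(counts, config$sigma, isTRUE(config$metronomic),
                 params$s, params$c, params$u, params$v,
                 target, horizon_steps, TRUE)
  status <- c("reached", "extinct", "horizon")[res$status + 1L]
  res$status_label <- status
  res
}

outcome_row <- function(config, params, status, t_detect = NA_real_,
                        t_relapse = NA_real_, t_discovery = NA_real_,
                        drivers_discovery = NA_real_, final_counts = NULL,
                        total_traj = numeric(), resist_traj = numeric(),
                        init_total = NA_real_, init_resist = NA_real_,
                        growth_attempts = NA_integer_, snapshots = list()) {
  step4 <- years_to_steps(4, params)
  step20 <- years_to_steps(20, params)
  tot <- if (is.null(final_counts)) 0 else sum(final_counts)
  resi <- if (is.null(final_counts)) 0 else sum(final_counts[, 2])
  t_event <- if (config$kind %in% c("post_diagnostic", "second_chance")) {
    t_relapse
  } else {
    t_detect
  }
  tibble::tibble(
    scenario = config$kind,
    sigma_cycle = config$sigma,
    status = status,
    t_event_years = t_event,
    t_detect_years = t_detect,
    t_relapse_years = t_relapse,
    t_discovery_years = t_discovery,
    mean_drivers_at_discovery = drivers_discovery,
    resistant_fraction = if (tot > 0) resi / tot else NA_real_,
    resistant_count = resi,
    mean_drivers = if (!is.null(final_counts)) state_mean_drivers(final_counts) else NA_real_,
    resistant_count_4y = traj_at(resist_traj, step4, init_resist),
    below_M_20y = traj_at(total_traj, step20, init_total) < params$M,
    growth_attempts = growth_attempts,
    snapshots = list(snapshots)
  )
}

#' Run one replicate of a scenario
#'
#' Dispatches on `config$kind`. The caller is responsible for seeding the
#' RNG; [run_scenario()] does this per replicate.
#'
#' @param config A [scenario_config()].
#' @param params A [model_params()].
#' @return A one-row [tibble::tibble] (see [run_scenario()] for the
#'   column descriptions).
#' @export
run_replicate <- function(config, params) {
  stopifnot(inherits(config, "scenario_config"),
            inherits(params, "model_params"))
  switch(config$kind,
    prevention_fixed = run_prevention_fixed(config, params),
    prevention_grown = run_prevention_grown(config, params),
    post_diagnostic = run_post_diagnostic(config, params),
    second_chance = run_second_chance(config, params)
  )
}

#' @rdname run_replicate
#' @export
run_prevention_fixed <- function(config, params) {
  kappa <- config$kappa %||% params$kappa
  R0 <- config$R0 %||% round(kappa * config$M0)
  if (R0 > config$M0) stop("initial resistant count exceeds M0")
  if (config$M0 > params$M) stop("M0 exceeds the detection threshold")
  counts <- matrix(0, params$N + 1, 2)
  counts[1, 1] <- config$M0 - R0
  counts[1, 2] <- R0
  horizon <- years_to_steps(config$horizon_years %||% config$max_years, params)
  ep <- treated_episode(counts, config, params, params$M, horizon)
  status <- switch(ep$status_label, reached = "detected", extinct = "extinct",
                   horizon = "undetected_at_horizon")
  outcome_row(
    config, params, status,
    t_detect = if (status == "detected") steps_to_years(ep$steps, params) else NA_real_,
    final_counts = ep$counts,
    total_traj = ep$total_traj, resist_traj = ep$resist_traj,
    init_total = config$M0, init_resist = R0,
    snapshots = list(at_end = ep$counts)
  )
}

#' @rdname run_replicate
#' @export
run_prevention_grown <- function(config, params) {
  g <- grow_from_one_cell(config$M0, params, config$max_years)
  horizon <- years_to_steps(config$horizon_years %||% config$max_years, params)
  ep <- treated_episode(g$counts, config, params, params$M, horizon)
  status <- switch(ep$status_label, reached = "detected", extinct = "extinct",
                   horizon = "undetected_at_horizon")
  outcome_row(
    config, params, status,
    t_detect = if (status == "detected") steps_to_years(ep$steps, params) else NA_real_,
    t_discovery = steps_to_years(g$steps, params),
    drivers_discovery = state_mean_drivers(g$counts),
    final_counts = ep$counts,
    total_traj = ep$total_traj, resist_traj = ep$resist_traj,
    init_total = sum(g$counts), init_resist = sum(g$counts[, 2]),
    growth_attempts = g$attempts,
    snapshots = list(at_start = g$counts, at_end = ep$counts)
  )
}

#' @rdname run_replicate
#' @export
run_post_diagnostic <- function(config, params) {
  g <- grow_from_one_cell(config$discovery_threshold, params, config$max_years)
  pre <- population_state(g$counts)
  resected <- resect(pre, config$residual_size)
  horizon <- years_to_steps(config$horizon_years %||% config$max_years, params)
  ep <- treated_episode(resected$counts, config, params, params$M, horizon)
  status <- switch(ep$status_label, reached = "relapsed", extinct = "extinct",
                   horizon = "undetected_at_horizon")
  outcome_row(
    config, params, status,
    t_relapse = if (status == "relapsed") steps_to_years(ep$steps, params) else NA_real_,
    t_discovery = steps_to_years(g$steps, params),
    drivers_discovery = state_mean_drivers(g$counts),
    final_counts = ep$counts,
    total_traj = ep$total_traj, resist_traj = ep$resist_traj,
    init_total = config$residual_size, init_resist = sum(resected$counts[, 2]),
    growth_attempts = g$attempts,
    snapshots = list(at_discovery = g$counts,
                     post_resection = resected$counts,
                     at_end = ep$counts)
  )
}

#' @rdname run_replicate
#' @export
run_second_chance <- function(config, params) {
  g <- grow_from_one_cell(config$M0, params, config$max_years)
  horizon <- years_to_steps(config$horizon_years %||% 50, params)
  ep1 <- treated_episode(g$counts, config, params, params$M, horizon)
  snaps <- list(at_start = g$counts)
  if (ep1$status_label != "reached") {
    # prevention never failed: identical to prevention_grown
    status <- switch(ep1$status_label, extinct = "extinct",
                     horizon = "undetected_at_horizon")
    return(outcome_row(
      config, params, status,
      t_discovery = steps_to_years(g$steps, params),
      drivers_discovery = state_mean_drivers(g$counts),
      final_counts = ep1$counts,
      total_traj = ep1$total_traj, resist_traj = ep1$resist_traj,
      init_total = sum(g$counts), init_resist = sum(g$counts[, 2]),
      growth_attempts = g$attempts,
      snapshots = c(snaps, list(at_end = ep1$counts))
    ))
  }
  # first failure: resect back to M0 cells and continue at the same sigma
  t_detect <- steps_to_years(ep1$steps, params)
  detected <- population_state(ep1$counts)
  resected <- resect(detected, config$M0)
  remaining <- horizon - ep1$steps
  snaps <- c(snaps, list(at_detection = ep1$counts,
                         post_resection = resected$counts))
  if (remaining <= 0) {
    # failed at the horizon edge; no time left for a second chance
    return(outcome_row(
      config, params, "relapsed", t_detect = t_detect, t_relapse = 0,
      t_discovery = steps_to_years(g$steps, params),
      drivers_discovery = state_mean_drivers(g$counts),
      final_counts = ep1$counts,
      total_traj = ep1$total_traj, resist_traj = ep1$resist_traj,
      init_total = sum(g$counts), init_resist = sum(g$counts[, 2]),
      growth_attempts = g$attempts, snapshots = snaps
    ))
  }
  ep2 <- treated_episode(resected$counts, config, params, params$M, remaining)
  status <- switch(ep2$status_label, reached = "relapsed", extinct = "extinct",
                   horizon = "undetected_at_horizon")
  full_total <- c(ep1$total_traj, ep2$total_traj)
  full_resist <- c(ep1$resist_traj, ep2$resist_traj)
  outcome_row(
    config, params, status,
    t_detect = t_detect,
    t_relapse = if (status == "relapsed") steps_to_years(ep2$steps, params) else NA_real_,
    t_discovery = steps_to_years(g$steps, params),
    drivers_discovery = state_mean_drivers(g$counts),
    final_counts = ep2$counts,
    total_traj = full_total, resist_traj = full_resist,
    init_total = sum(g$counts), init_resist = sum(g$counts[, 2]),
    growth_attempts = g$attempts,
    snapshots = c(snaps, list(at_end = ep2$counts))
  )
}

#' Run all replicates of a scenario
#'
#' Replicate k is seeded with `base_seed + k` before it starts, so an
#' outcome set is a deterministic function of the configuration.
#'
#' @param config A [scenario_config()].
#' @param params A [model_params()].
#' @return A [tibble::tibble] with one row per replicate. Columns:
#'   `replicate`, `seed`, `scenario`, `sigma_cycle`, `status` (one of
#'   `detected`, `relapsed`, `extinct`, `undetected_at_horizon`),
#'   `t_event_years` (the protocol's primary endpoint: detection or
#'   relapse), `t_detect_years`, `t_relapse_years` (clock starts at
#'   resection), `t_discovery_years` (untreated growth phase),
#'   `mean_drivers_at_discovery`, `resistant_fraction`,
#'   `resistant_count`, `mean_drivers` (at episode end),
#'   `resistant_count_4y` (resistant cells 4 years into treatment),
#'   `below_M_20y` (below the detection threshold 20 years into
#'   treatment), `growth_attempts` (including discarded extinct
#'   attempts), and a `snapshots` list-column of count matrices at the
#'   protocol's defining events.
#' @examples
#' p <- model_params(N = 5)
#' cfg <- scenario_config("prevention_fixed", M0 = 1e6, sigma = 0,
#'                        replicates = 3, base_seed = 1)
#' run_scenario(cfg, p)
#' @export
run_scenario <- function(config, params) {
  stopifnot(inherits(config, "scenario_config"))
  rows <- vector("list", config$replicates)
  for (k in seq_len(config$replicates)) {
    seed <- config$base_seed + k
    set.seed(seed)
    row <- run_replicate(config, params)
    row <- tibble::add_column(row, replicate = k, seed = seed,
                              .before = "scenario")
    rows[[k]] <- row
  }
  do.call(rbind, rows)
}

#' Parameter sweep over scenario and model settings
#'
#' Runs [run_scenario()] at every row of `grid`, a data.frame whose
#' columns are a subset of `sigma`, `s`, `c`, `u`, `v`, `N`, `M0`,
#' `kappa`, `R0`, `residual_size`, `discovery_threshold`. Grid point p
#' uses base seed `config$base_seed + (p - 1) * seed_stride`, so every
#' grid point and replicate maps deterministically to a seed.
#'
#' @param config Base [scenario_config()].
#' @param params Base [model_params()].
#' @param grid Data.frame of parameter overrides (one row per point).
#' @param seed_stride Seed spacing between grid points; must exceed the
#'   replicate count.
#' @return A tibble of outcomes with the grid columns and a `point`
#'   index prepended.
#' @export
run_sweep <- function(config, params, grid, seed_stride = 100000L) {
  stopifnot(inherits(config, "scenario_config"), is.data.frame(grid))
  if (nrow(grid) == 0) stop("sweep grid is empty")
  scen_keys <- c("sigma", "M0", "kappa", "R0", "residual_size",
                 "discovery_threshold")
  par_keys <- c("s", "c", "u", "v", "N")
  bad <- setdiff(names(grid), c(scen_keys, par_keys))
  if (length(bad)) stop("unknown sweep columns: ", paste(bad, collapse = ", "))
  if (seed_stride <= config$replicates) stop("seed_stride must exceed replicates")
  out <- vector("list", nrow(grid))
  for (p in seq_len(nrow(grid))) {
    cfg <- config
    par <- params
    for (key in names(grid)) {
      val <- grid[[key]][p]
      if (key %in% scen_keys) cfg[[key]] <- val else par[[key]] <- val
    }
    if ("N" %in% names(grid)) par <- model_params(
      N = par$N, s = par$s, c = par$c, u = par$u, v = par$v, T = par$T,
      M = par$M, kappa = par$kappa, days_per_year = par$days_per_year)
    cfg$base_seed <- as.integer(config$base_seed + (p - 1) * seed_stride)
    res <- run_scenario(cfg, par)
    for (key in rev(names(grid))) {
      res <- do.call(tibble::add_column,
                     c(list(res), stats::setNames(list(grid[[key]][p]), key),
                       list(.before = 1)))
    }
    res <- tibble::add_column(res, point = p, .before = 1)
    out[[p]] <- res
  }
  do.call(rbind, out)
}
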