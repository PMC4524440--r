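# Distributional statistics over replicate outcomes.
#
# "90% confidence interval" follows the figure convention of the study
# design: the 5th-95th percentile band of the replicate distribution,
# with linear interpolation between order statistics (quantile type 7).

#' Detection/relapse-time statistics over an outcome set
#'
#' Central statistics are computed over replicates whose endpoint event
#' occurred (`status` `detected` or `relapsed`); undetected and extinct
#' replicates contribute to the success metrics only, unless
#' `assign_undetected_years` is set, in which case undetected replicates
#' enter the time distribution at that value (the convention used when
#' summarising all cases against a horizon, e.g. 50 years).
#'
#' @param outcomes A tibble from [run_scenario()] (or a subset).
#' @param assign_undetected_years If non-`NULL`, undetected-at-horizon
#'   replicates are assigned this event time instead of being excluded.
#' @param bin_years Histogram bin width in years; the default 0.25 is
#'   the 3-month binning used for detection-time distributions.
#' @return An object of class `scenario_summary`: a list with
#'   `n_replicates`, `n_events`, `median`, `p5`, `p95`, `mean`,
#'   `success_20y` (fraction below the detection threshold 20 years into
#'   treatment), `success_horizon` (fraction whose episode ended without
#'   the endpoint event), `frac_lt100_resistant_4y`,
#'   `mean_resistant_fraction` and `mean_drivers` (both over event
#'   cases), and `histogram` (a data.frame of 3-month bins with
#'   relative frequencies summing to 1 over event cases).
#' @examples
#' p <- model_params(N = 5)
#' out <- run_scenario(scenario_config("prevention_fixed", M0 = 1e6,
#'                     sigma = 0, replicates = 5, base_seed = 1), p)
#' detection_time_stats(out)
#' @export
detection_time_stats <- function(outcomes, assign_undetected_years = NULL,
                                 bin_years = 0.25) {
  stopifnot(is.data.frame(outcomes), nrow(outcomes) >= 1)
  times <- outcomes$t_event_years[outcomes$status %in% c("detected", "relapsed")]
  if (!is.null(assign_undetected_years)) {
    n_und <- sum(outcomes$status == "undetected_at_horizon")
    times <- c(times, rep(assign_undetected_years, n_und))
  }
  n_events <- length(times)
  have <- n_events > 0
  qs <- if (have) quantile(times, c(0.05, 0.5, 0.95), names = FALSE, type = 7)
        else rep(NA_real_, 3)
  hist_df <- NULL
  if (have) {
    breaks <- seq(0, (max(times) %/% bin_years + 1) * bin_years, by = bin_years)
    cnt <- table(cut(times, breaks, right = FALSE))
    hist_df <- data.frame(
      bin_start = breaks[-length(breaks)],
      bin_end = breaks[-1],
      frequency = as.vector(cnt) / n_events
    )
  }
  ev <- outcomes[outcomes$status %in% c("detected", "relapsed"), ]
  structure(list(
    n_replicates = nrow(outcomes),
    n_events = n_events,
    median = qs[2], p5 = qs[1], p95 = qs[3],
    mean = if (have) mean(times) else NA_real_,
    success_20y = mean(outcomes$below_M_20y),
    success_horizon = mean(outcomes$status %in%
                             c("extinct", "undetected_at_horizon")),
    frac_lt100_resistant_4y = mean(outcomes$resistant_count_4y < 100),
    mean_resistant_fraction = if (nrow(ev) > 0)
      mean(ev$resistant_fraction, na.rm = TRUE) else NA_real_,
    mean_drivers = if (nrow(ev) > 0)
      mean(ev$mean_drivers, na.rm = TRUE) else NA_real_,
    histogram = hist_df
  ), class = "scenario_summary")
}

#' @export
print.scenario_summary <- function(x, ...) {
  cat(sprintf("Scenario summary over %d replicate(s), %d event(s)\n",
              x$n_replicates, x$n_events))
  if (x$n_events > 0) {
    cat(sprintf("  event time: median %.2f y, 90%% band [%.2f, %.2f] y, mean %.2f y\n",
                x$median, x$p5, x$p95, x$mean))
  }
  cat(sprintf("  below threshold at 20 y: %.1f%% | event-free at horizon: %.1f%%\n",
              100 * x$success_20y, 100 * x$success_horizon))
  cat(sprintf("  <100 resistant cells at 4 y: %.1f%%\n",
              100 * x$frac_lt100_resistant_4y))
  invisible(x)
}

#' Resistance metrics over an outcome set
#'
#' @param outcomes A tibble from [run_scenario()].
#' @return A list with `mean_resistant_fraction` (over replicates whose
#'   endpoint event occurred) and `frac_lt100_resistant_4y` (over all
#'   replicates; an extinct tumour trivially has fewer than 100
#'   resistant cells).
#' @export
resistance_metrics <- function(outcomes) {
  stopifnot(is.data.frame(outcomes), nrow(outcomes) >= 1)
  if (any(is.na(outcomes$resistant_count_4y))) {
    stop("outcomes lack 4-year snapshots")
  }
  ev <- outcomes[outcomes$status %in% c("detected", "relapsed"), ]
  list(
    mean_resistant_fraction = if (nrow(ev) > 0)
      mean(ev$resistant_fraction, na.rm = TRUE) else NA_real_,
    frac_lt100_resistant_4y = mean(outcomes$resistant_count_4y < 100)
  )
}

#' Subclone-size distribution over drivers at a protocol event
#'
#' Averages the composition snapshots recorded at a named event across
#' replicates, giving the mean subclone size per driver count i (split
#' by resistance status) and the cell-weighted mean number of drivers.
#'
#' @param outcomes A tibble from [run_scenario()].
#' @param event Snapshot name, e.g. `"at_discovery"`, `"post_resection"`,
#'   `"at_end"` (availability depends on the scenario kind).
#' @return A list with `mean_sizes` (data.frame: `i`, `sensitive`,
#'   `resistant`, `total` mean cells per replicate) and
#'   `mean_drivers_per_replicate` (vector of cell-weighted means, `NA`
#'   for empty snapshots) plus its average `mean_drivers`.
#' @export
driver_distribution <- function(outcomes, event) {
  stopifnot(is.data.frame(outcomes), nrow(outcomes) >= 1)
  snaps <- lapply(outcomes$snapshots, function(s) s[[event]])
  if (any(vapply(snaps, is.null, logical(1)))) {
    stop("snapshot '", event, "' absent from some outcomes")
  }
  acc <- Reduce(`+`, snaps) / length(snaps)
  per_rep <- vapply(snaps, state_mean_drivers, numeric(1))
  list(
    mean_sizes = data.frame(
      i = 0:(nrow(acc) - 1),
      sensitive = acc[, 1],
      resistant = acc[, 2],
      total = rowSums(acc)
    ),
    mean_drivers_per_replicate = per_rep,
    mean_drivers = mean(per_rep, na.rm = TRUE)
  )
}

# internal: R-squared of a fitted model against observed y
r_squared <- function(y, fitted) {
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum((y - fitted)^2) / ss_tot
}

#' Predictors of relapse time after resection
#'
#' Fits two regressions of the relapse time (years from resection):
#' a simple linear regression on the discovery time (years from tumour
#' initiation to reaching the discovery threshold), and a negative
#' exponential `y = a * exp(-b * x)` on the cell-weighted mean driver
#' count of the resected tumour. The driver-count model is typically the
#' far better predictor.
#'
#' @param outcomes A tibble of `post_diagnostic` outcomes containing at
#'   least 10 relapsed replicates.
#' @return A list with `discovery` (list `intercept`, `slope`,
#'   `r_squared`) and `drivers` (list `a`, `b`, `r_squared`); an element
#'   is `NULL` when its predictor or response is degenerate.
#' @export
relapse_regressions <- function(outcomes) {
  rel <- outcomes[outcomes$status == "relapsed" &
                    !is.na(outcomes$t_relapse_years), ]
  if (nrow(rel) < 10) stop("need at least 10 relapsed replicates")
  y <- rel$t_relapse_years
  out <- list(discovery = NULL, drivers = NULL)
  x1 <- rel$t_discovery_years
  if (sd(x1) > 0 && sd(y) > 0) {
    fit <- lm(y ~ x1)
    out$discovery <- list(
      intercept = unname(coef(fit)[1]),
      slope = unname(coef(fit)[2]),
      r_squared = r_squared(y, fitted(fit))
    )
  }
  x2 <- rel$mean_drivers_at_discovery
  if (sd(x2) > 0 && sd(y) > 0 && all(y > 0)) {
    # log-linear start values, then the exponential fit itself; nls cannot
    # iterate on zero-residual data, so fall back to the log-linear solution
    lf <- lm(log(y) ~ x2)
    ab <- c(a = unname(exp(coef(lf)[1])), b = unname(-coef(lf)[2]))
    fit2 <- tryCatch(
      nls(y ~ a * exp(-b * x2), start = as.list(ab)),
      error = function(e) NULL
    )
    if (!is.null(fit2)) ab <- coef(fit2)[c("a", "b")]
    out$drivers <- list(
      a = unname(ab["a"]),
      b = unname(ab["b"]),
      r_squared = r_squared(y, ab["a"] * exp(-ab["b"] * x2))
    )
  }
  out
}

#' Plot median detection time and 90% band against treatment intensity
#'
#' Convenience figure for sweep results: the median event time (line)
#' and the 5th-95th percentile band (ribbon) per sigma.
#'
#' @param sweep_outcomes Output of [run_sweep()] over a `sigma` grid.
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_detection_times <- function(sweep_outcomes) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  stopifnot("sigma" %in% names(sweep_outcomes))
  stats <- lapply(split(sweep_outcomes, sweep_outcomes$sigma), function(d) {
    s <- detection_time_stats(d)
    data.frame(sigma = d$sigma[1], median = s$median, p5 = s$p5, p95 = s$p95)
  })
  df <- do.call(rbind, stats)
  ggplot2::ggplot(df, ggplot2::aes(x = sigma)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = p5, ymax = p95), alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = median)) +
    ggplot2::labs(x = "treatment intensity (per cycle)",
                  y = "event time (years)")
}

utils::globalVariables(c("sigma", "p5", "p95"))
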