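#' Model parameters for the branching-process tumour model
#'
#' Bundles the biological and therapeutic constants of the model. The
#' defaults are the baseline empirical estimates used throughout the
#' package: a 4-day cell cycle, a selective advantage of 0.4% per driver,
#' a 0.1% cost of resistance, driver and resistance mutation rates of
#' 3.4e-5 and 1e-6 per division, a detection threshold of 1e9 cells and a
#' pre-resistance level of 0.01%. The maximum number of additional drivers
#' `N` has no default because it is a scenario-level choice (5 for the
#' prevention analyses on an initially homogeneous lesion, 9 for tumours
#' grown from a single cell).
#'
#' @param N Maximum number of additional driver mutations per cell
#'   (non-negative integer). Must be given explicitly.
#' @param s Selective advantage per driver, per cell cycle (dimensionless).
#' @param c Fitness cost of resistance per cell cycle.
#' @param u Probability per division that one daughter gains a driver.
#' @param v Probability per division that one daughter gains resistance.
#' @param T Cell-cycle length in days (one simulation step).
#' @param M Detection threshold in cells.
#' @param kappa Initial resistant fraction used by fixed-composition
#'   prevention scenarios.
#' @param days_per_year Calendar conversion constant; 365 gives 91.25
#'   steps per year at `T = 4`.
#'
#' @return An object of class `model_params` (a named list).
#' @examples
#' p <- model_params(N = 5)
#' fitness(0, 0, sigma = 0, p)
#' @export
model_params <- function(N, s = 0.004, c = 0.001, u = 3.4e-5, v = 1e-6,
                         T = 4, M = 1e9, kappa = 1e-4,
                         days_per_year = 365) {
  if (missing(N)) stop("`N` (maximum additional drivers) must be given explicitly")
  stopifnot(
    is.numeric(N), length(N) == 1, N >= 0, N == round(N),
    is.numeric(T), T > 0,
    is.numeric(s), s >= 0,
    is.numeric(c), c >= 0,
    is.numeric(u), u >= 0,
    is.numeric(v), v >= 0,
    is.numeric(M), M >= 1,
    is.numeric(kappa), kappa >= 0, kappa <= 1,
    days_per_year > 0
  )
  if (u + v > 1) stop("u + v must not exceed 1")
  structure(
    list(N = as.integer(N), s = s, c = c, u = u, v = v, T = T, M = M,
         kappa = kappa, days_per_year = days_per_year),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat("Branching-process model parameters\n")
  cat(sprintf("  cycle T = %g d | s = %g | c = %g | u = %g | v = %g\n",
              x$T, x$s, x$c, x$u, x$v))
  cat(sprintf("  N = %d extra drivers | detection M = %g cells | kappa = %g\n",
              x$N, x$M, x$kappa))
  invisible(x)
}

#' Treatment policy
#'
#' A policy maps the current population state to the per-cycle treatment
#' intensity applied on that step. `"constant"` always applies `sigma`;
#' `"metronomic"` applies `sigma` only on steps where sensitive cells
#' outnumber resistant cells (and 0 otherwise); `"none"` is shorthand for
#' a constant intensity of 0.
#'
#' @param kind One of `"constant"`, `"metronomic"`, `"none"`.
#' @param sigma Per-cycle fitness reduction applied to sensitive
#'   (j = 0) cells; resistant cells are never affected.
#' @return An object of class `treatment_policy`.
#' @examples
#' treatment_policy("constant", sigma = 0.015)
#' @export
treatment_policy <- function(kind = c("constant", "metronomic", "none"),
                             sigma = 0) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(sigma), length(sigma) == 1, is.finite(sigma))
  if (sigma < 0) stop("sigma must be non-negative")
  if (kind == "none") {
    kind <- "constant"
    sigma <- 0
  }
  structure(list(kind = kind, sigma = sigma), class = "treatment_policy")
}

#' @export
print.treatment_policy <- function(x, ...) {
  cat(sprintf("Treatment policy: %s, sigma = %g per cycle (%g%% daily arrest)\n",
              x$kind, x$sigma, 100 * x$sigma / 4))
  invisible(x)
}

#' Critical treatment intensity
#'
#' The per-cycle intensity above which every sensitive subclone is
#' subcritical: with additive fitness `s * (i + 1) - sigma`, the fastest
#' sensitive subclone (i = N) has negative fitness whenever
#' `sigma > s * (N + 1)`. When resistance is impossible (v = 0, no initial
#' resistant cells), median detection times diverge as sigma approaches
#' this value from below.
#'
#' @param params A [model_params()] object.
#' @return The critical per-cycle intensity `s * (N + 1)`.
#' @examples
#' critical_intensity(model_params(N = 5))  # 0.024
#' @export
critical_intensity <- function(params) {
  stopifnot(inherits(params, "model_params"))
  params$s * (params$N + 1)
}

# internal: calendar helpers
years_to_steps <- function(years, params) {
  as.integer(round(years * params$days_per_year / params$T))
}

steps_to_years <- function(steps, params) {
  steps * params$T / params$days_per_year
}
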