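#' Expectation transition matrix of the branching process
#'
#' The expected counts evolve linearly: `E[n(t+1)] = A %*% E[n(t)]`. For
#' a source subclone (i, j) with birth probability b and effective
#' mutation rates u' (0 at i = N) and v' (0 at j = 1), the expected
#' contributions are `b * (2 - u' - v')` to (i, j), `b * u'` to
#' (i + 1, j) and `b * v'` to (i, 1). Each column therefore sums to
#' `2b = 1 + f`, the expected offspring per cell. This recursion is the
#' exact expectation of the stochastic engine and serves as its analytic
#' (mean-field) oracle.
#'
#' States are ordered sensitive first: (0,0)..(N,0), (0,1)..(N,1).
#'
#' @param sigma Per-cycle treatment intensity.
#' @param params A [model_params()] object.
#' @return A dense `2(N+1) x 2(N+1)` matrix `A`.
#' @examples
#' A <- transition_matrix(0, model_params(N = 0, v = 0))
#' A  # 1 + s for the single sensitive type (resistant type unreachable)
#' @export
transition_matrix <- function(sigma, params) {
  stopifnot(inherits(params, "model_params"), sigma >= 0)
  N <- params$N
  K <- 2 * (N + 1)
  idx <- function(i, j) i + 1 + j * (N + 1)
  A <- matrix(0, K, K)
  for (j in 0:1) {
    for (i in 0:N) {
      f <- fitness(i, j, sigma, params)
      b <- (1 + min(max(f, -1), 1)) / 2
      u_eff <- if (i < N) params$u else 0
      v_eff <- if (j == 0) params$v else 0
      from <- idx(i, j)
      A[idx(i, j), from] <- A[idx(i, j), from] + b * (2 - u_eff - v_eff)
      if (u_eff > 0) A[idx(i + 1, j), from] <- A[idx(i + 1, j), from] + b * u_eff
      if (v_eff > 0) A[idx(i, 1), from] <- A[idx(i, 1), from] + b * v_eff
    }
  }
  nm <- c(paste0("i", 0:N, "_j0"), paste0("i", 0:N, "_j1"))
  dimnames(A) <- list(to = nm, from = nm)
  A
}

# internal: population_state or matrix -> expectation vector in A's ordering
as_expectation_vector <- function(e0, params) {
  counts <- if (inherits(e0, "population_state")) e0$counts else as.matrix(e0)
  if (nrow(counts) != params$N + 1 || ncol(counts) != 2) {
    stop("expectation state must be (N + 1) x 2")
  }
  as.vector(counts)
}

#' Expected trajectory of the population
#'
#' Applies the expectation recursion `e(t+1) = A e(t)` for `t` steps.
#' To remain finite beyond ~1e308 cells, the vector is renormalised
#' whenever its sum grows large and the accumulated factor is kept on a
#' log scale.
#'
#' @param e0 Initial expected counts: a [population_state()] or an
#'   `(N + 1) x 2` matrix of non-negative reals.
#' @param sigma Per-cycle treatment intensity.
#' @param params A [model_params()] object.
#' @param t Number of steps (non-negative integer).
#' @return A list with `counts` (an `(N + 1) x 2` matrix of expected
#'   counts on the original scale, `Inf` if not representable),
#'   `log_total` (log of the total expectation) and `log_scale` (the
#'   accumulated log renormalisation factor).
#' @examples
#' p <- model_params(N = 0, v = 0)
#' e <- expected_trajectory(initial_state(p, 1e6), 0, p, 10)
#' sum(e$counts)  # 1e6 * (1 + s)^10
#' @export
expected_trajectory <- function(e0, sigma, params, t) {
  stopifnot(t >= 0, t == round(t))
  A <- transition_matrix(sigma, params)
  v <- as_expectation_vector(e0, params)
  if (any(v < 0) || any(!is.finite(v))) stop("expected counts must be finite and non-negative")
  log_scale <- 0
  for (k in seq_len(t)) {
    v <- as.vector(A %*% v)
    s <- sum(v)
    if (s > 1e250) {
      v <- v / s
      log_scale <- log_scale + log(s)
    } else if (s == 0) {
      break
    }
  }
  counts <- matrix(v * exp(log_scale), nrow = params$N + 1, ncol = 2)
  dimnames(counts) <- list(i = 0:params$N, j = 0:1)
  tot <- sum(v)
  list(
    counts = counts,
    log_total = if (tot > 0) log(tot) + log_scale else -Inf,
    log_scale = log_scale
  )
}

#' Deterministic (expectation-based) detection time
#'
#' The smallest number of steps at which the total expected population
#' reaches the detection threshold, converted to years. Returns `NA` if
#' the expectation is bounded, i.e. no subclone reachable from the
#' initial state is supercritical (expected growth factor above 1).
#'
#' @inheritParams expected_trajectory
#' @param M Detection threshold (defaults to `params$M`).
#' @param max_years Safety horizon for the iteration.
#' @return Years until the expected total first reaches `M`, or `NA`.
#' @examples
#' p <- model_params(N = 0, v = 0)
#' deterministic_detection_time(initial_state(p, 1e6), 0, p)  # ~19 y
#' @export
deterministic_detection_time <- function(e0, sigma, params, M = params$M,
                                         max_years = 1000) {
  A <- transition_matrix(sigma, params)
  v <- as_expectation_vector(e0, params)
  if (sum(v) >= M) return(0)
  # reachability on the (i, j) lattice: i only increases, j only 0 -> 1
  N <- params$N
  occ <- matrix(v, N + 1, 2) > 0
  reach <- matrix(FALSE, N + 1, 2)
  for (i in 0:N) for (j in 0:1) {
    if (occ[i + 1, j + 1]) {
      reach[(i + 1):(N + 1), (j + 1):2] <- TRUE
      reach[(i + 1):(N + 1), 2] <- TRUE
    }
  }
  growth <- outer(0:N, 0:1, function(i, j)
    1 + fitness(i, j, sigma, params))
  if (!any(reach & growth > 1)) return(NA_real_)
  max_steps <- years_to_steps(max_years, params)
  log_scale <- 0
  for (k in seq_len(max_steps)) {
    v <- as.vector(A %*% v)
    s <- sum(v)
    if (s > 1e250) {
      v <- v / s
      log_scale <- log_scale + log(s)
      s <- 1
    }
    if (s == 0) return(NA_real_)
    if (log(s) + log_scale >= log(M)) return(steps_to_years(k, params))
  }
  NA_real_
}

#' Write an expectation trajectory to CSV
#'
#' Long format with columns `step`, `i`, `j`, `expected_count`.
#'
#' @inheritParams expected_trajectory
#' @param steps Number of steps to record (every step is written).
#' @param path Output CSV path.
#' @return The data.frame written, invisibly.
#' @export
write_expected_trajectory <- function(e0, sigma, params, steps, path) {
  A <- transition_matrix(sigma, params)
  v <- as_expectation_vector(e0, params)
  N <- params$N
  rows <- vector("list", steps + 1)
  grid <- expand.grid(i = 0:N, j = 0:1)
  rows[[1]] <- cbind(step = 0, grid, expected_count = v)
  for (k in seq_len(steps)) {
    v <- as.vector(A %*% v)
    rows[[k + 1]] <- cbind(step = k, grid, expected_count = v)
  }
  df <- do.call(rbind, rows)
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}
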