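#' Per-cycle fitness of a subclone
#'
#' Fitness is the difference between the per-cycle birth and death
#' probabilities of a cell. It is additive in drivers: a sensitive cell
#' with i additional drivers has fitness `s * (i + 1) - sigma`, while a
#' resistant cell pays the constant cost c and ignores treatment
#' entirely: `s * (i + 1) - c`.
#'
#' @param i Driver index (0..N); vectorised.
#' @param j Resistance status, 0 (sensitive) or 1 (resistant); vectorised.
#' @param sigma Per-cycle treatment intensity (non-negative).
#' @param params A [model_params()] object.
#' @return Per-cycle fitness `s*(i+1) - sigma*(1-j) - c*j`.
#' @examples
#' p <- model_params(N = 5)
#' fitness(0, 0, 0, p)        # s
#' fitness(0, 1, 0.02, p)     # s - c, independent of sigma
#' @export
fitness <- function(i, j, sigma, params) {
  stopifnot(inherits(params, "model_params"))
  if (any(i < 0) || any(i > params$N)) stop("driver index i out of range 0..N")
  if (any(!j %in% c(0, 1))) stop("resistance status j must be 0 or 1")
  if (any(sigma < 0)) stop("sigma must be non-negative")
  params$s * (i + 1) - sigma * (1 - j) - params$c * j
}

#' Birth and death probabilities from fitness
#'
#' One cell per step either divides (probability b) or dies (probability
#' d), with `b + d = 1` and `b - d = f`, i.e. `b = (1 + f) / 2`. The
#' expected number of offspring per cell per step is `2b = 1 + f`.
#' Fitness outside `[-1, 1]` is clipped with a warning; baseline
#' parameters never approach the bound.
#'
#' @param f Per-cycle fitness (vectorised).
#' @return A list with components `b` and `d`.
#' @examples
#' birth_death_probs(0.004)
#' @export
birth_death_probs <- function(f) {
  if (any(!is.finite(f))) stop("fitness must be finite")
  if (any(f < -1) || any(f > 1)) {
    warning("fitness clipped to [-1, 1]")
    f <- pmin(pmax(f, -1), 1)
  }
  list(b = (1 + f) / 2, d = (1 - f) / 2)
}

#' Per-cell fate probabilities for one step
#'
#' A cell dies with probability d, or divides with probability b; a
#' division passes, to exactly one daughter, a driver mutation with
#' probability u or a resistance mutation with probability v (mutually
#' exclusive). At the lattice boundaries the mutation is impossible
#' (wasted): driver mutations at i = N, resistance mutations at j = 1.
#'
#' @inheritParams fitness
#' @return An object of class `step_outcome_probs`: a list with
#'   `p_death`, `p_div_plain`, `p_div_driver`, `p_div_resist`, summing
#'   to 1. A plain division yields two (i, j) cells; a driver division
#'   one (i, j) and one (i+1, j) cell; a resistance division one (i, j)
#'   and one (i, 1) cell.
#' @examples
#' outcome_probs(0, 0, 0, model_params(N = 5))
#' @export
outcome_probs <- function(i, j, sigma, params) {
  stopifnot(length(i) == 1, length(j) == 1, length(sigma) == 1)
  f <- fitness(i, j, sigma, params)
  bd <- birth_death_probs(f)
  u_eff <- if (i < params$N) params$u else 0
  v_eff <- if (j == 0) params$v else 0
  structure(
    list(
      p_death = bd$d,
      p_div_plain = bd$b * (1 - u_eff - v_eff),
      p_div_driver = bd$b * u_eff,
      p_div_resist = bd$b * v_eff
    ),
    class = "step_outcome_probs"
  )
}

# internal: policy -> effective sigma for the current counts
effective_sigma <- function(policy, counts) {
  if (policy$kind == "metronomic") {
    sens <- sum(counts[, 1])
    resi <- sum(counts[, 2])
    if (sens > resi) policy$sigma else 0
  } else {
    policy$sigma
  }
}

#' Advance the population by one step
#'
#' For every occupied subclone, the counts of the four per-cell fates are
#' drawn from a multinomial distribution and the next state assembled
#' from the offspring rules. Cells do not interact: there is no
#' competition for space or resources. Uses R's global RNG stream, so
#' `set.seed()` makes steps bit-reproducible.
#'
#' @param state A [population_state()].
#' @param policy A [treatment_policy()].
#' @param params A [model_params()].
#' @return A new `population_state` with `step_index` incremented; the
#'   input is not modified.
#' @examples
#' p <- model_params(N = 5)
#' set.seed(1)
#' step(initial_state(p, 1000), treatment_policy("none"), p)
#' @export
step <- function(state, policy, params) {
  stopifnot(inherits(state, "population_state"),
            inherits(policy, "treatment_policy"),
            inherits(params, "model_params"))
  if (nrow(state$counts) != params$N + 1) {
    stop("state lattice height does not match params$N")
  }
  sig <- effective_sigma(policy, state$counts)
  res <- cpp_step(state$counts, sig, params$s, params$c, params$u, params$v)
  if (res$clips > 0) warning("fitness clipped to [-1, 1] for ", res$clips,
                             " subclone(s)")
  population_state(res$counts, state$step_index + 1L)
}

#' Run until a target size, extinction, or a step horizon
#'
#' Iterates [step()] until the total population is at least `target`
#' (checked after each completed step), the population goes extinct, or
#' `max_steps` steps have elapsed.
#'
#' @inheritParams step
#' @param target Cell count to reach (at least the current total).
#' @param max_steps Step horizon.
#' @param record If `TRUE`, per-step total and resistant-cell
#'   trajectories are returned.
#' @return A list with `state` (final `population_state`), `steps`
#'   (elapsed), `status` (`"reached"`, `"extinct"` or `"horizon"`), and,
#'   when recorded, `total_traj` and `resist_traj` (numeric vectors, one
#'   entry per completed step).
#' @examples
#' p <- model_params(N = 0, v = 0)
#' set.seed(1)
#' grow_to_size(initial_state(p, 1000), 2000, treatment_policy("none"), p)
#' @export
grow_to_size <- function(state, target, policy, params,
                         max_steps = 100000L, record = FALSE) {
  stopifnot(inherits(state, "population_state"),
            inherits(policy, "treatment_policy"),
            inherits(params, "model_params"))
  if (target < state_total(state) && state_total(state) > 0) {
    stop("target must be at least the current total")
  }
  res <- cpp_run(state$counts, policy$sigma,
                 policy$kind == "metronomic",
                 params$s, params$c, params$u, params$v,
                 target, as.integer(max_steps), record)
  if (res$clips > 0) warning("fitness clipped to [-1, 1] on ", res$clips,
                             " subclone-step(s)")
  out <- list(
    state = population_state(res$counts, state$step_index + res$steps),
    steps = res$steps,
    status = c("reached", "extinct", "horizon")[res$status + 1L]
  )
  if (record) {
    out$total_traj <- res$total_traj
    out$resist_traj <- res$resist_traj
  }
  out
}

#' Resect a tumour to a residual cell count
#'
#' Residual cells are drawn by proportional multinomial sampling across
#' subclones, so the expected post-resection composition equals the
#' pre-resection composition and the total equals `residual` exactly.
#' Sampling is with replacement, indistinguishable from hypergeometric
#' sampling when `residual` is much smaller than the tumour.
#'
#' @param state A [population_state()].
#' @param residual Number of cells left behind (at most the current
#'   total, and below 2^31 so the exact multinomial sampler applies).
#' @return A new `population_state` with total exactly `residual`.
#' @examples
#' p <- model_params(N = 5)
#' set.seed(1)
#' resect(initial_state(p, 1e6, resistant = 100), 1e4)
#' @export
resect <- function(state, residual) {
  stopifnot(inherits(state, "population_state"))
  total <- state_total(state)
  if (residual > total) stop("residual exceeds current total")
  if (residual >= 2^31) stop("residual must be below 2^31")
  if (residual == total) return(state)
  probs <- as.vector(state$counts) / total
  drawn <- as.vector(rmultinom(1, size = residual, prob = probs))
  counts <- matrix(drawn, nrow = nrow(state$counts), ncol = 2)
  population_state(counts, state$step_index)
}
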