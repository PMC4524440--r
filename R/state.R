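#' Population state on the (driver, resistance) lattice
#'
#' A population state is an integer-valued count matrix with `N + 1` rows
#' (driver index i = 0..N) and 2 columns (resistance status j = 0
#' sensitive, j = 1 resistant), plus the number of elapsed steps. Counts
#' are stored as doubles, exact up to 2^53 cells.
#'
#' @param counts Numeric matrix of non-negative whole cell counts,
#'   dimensions `(N + 1) x 2`.
#' @param step_index Number of elapsed steps (non-negative integer).
#' @return An object of class `population_state`.
#' @examples
#' st <- initial_state(model_params(N = 5), size = 1e6, resistant = 100)
#' state_total(st)
#' @export
population_state <- function(counts, step_index = 0L) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 2) stop("counts must have 2 columns (j = 0, 1)")
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("counts must be non-negative finite whole numbers")
  }
  storage.mode(counts) <- "double"
  dimnames(counts) <- list(i = 0:(nrow(counts) - 1), j = 0:1)
  structure(list(counts = counts, step_index = as.integer(step_index)),
            class = "population_state")
}

#' Construct an initial state
#'
#' @param params A [model_params()] object (fixes the lattice height N).
#' @param size Total initial cell count.
#' @param resistant Number of initially resistant cells (i = 0, j = 1);
#'   the remaining `size - resistant` cells are sensitive (i = 0, j = 0).
#' @param i Driver index at which the cells are placed (default 0).
#' @return A `population_state`.
#' @export
initial_state <- function(params, size, resistant = 0, i = 0) {
  stopifnot(inherits(params, "model_params"),
            size >= 0, resistant >= 0, resistant <= size,
            i >= 0, i <= params$N)
  counts <- matrix(0, nrow = params$N + 1, ncol = 2)
  counts[i + 1, 1] <- size - resistant
  counts[i + 1, 2] <- resistant
  population_state(counts)
}

#' @rdname population_state
#' @param state A `population_state`.
#' @export
state_total <- function(state) sum(state$counts)

#' @rdname population_state
#' @export
state_resistant <- function(state) sum(state$counts[, 2])

#' Cell-weighted mean number of additional drivers
#'
#' @param state A `population_state` (or a bare count matrix).
#' @return Mean of the driver index i weighted by cell counts; `NA` for an
#'   empty population.
#' @export
state_mean_drivers <- function(state) {
  counts <- if (inherits(state, "population_state")) state$counts else state
  tot <- sum(counts)
  if (tot <= 0) return(NA_real_)
  i <- seq_len(nrow(counts)) - 1
  sum(i * rowSums(counts)) / tot
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("Population state at step %d: %g cells (%g resistant)\n",
              x$step_index, state_total(x), state_resistant(x)))
  occ <- which(x$counts > 0, arr.ind = TRUE)
  if (nrow(occ) > 0) {
    for (k in seq_len(nrow(occ))) {
      cat(sprintf("  i=%d j=%d : %g\n", occ[k, 1] - 1L, occ[k, 2] - 1L,
                  x$counts[occ[k, 1], occ[k, 2]]))
    }
  }
  invisible(x)
}

#' Long-format view of a population state
#'
#' @param x A `population_state`.
#' @param ... Unused.
#' @return A data.frame with columns `step`, `i`, `j`, `count`.
#' @export
as.data.frame.population_state <- function(x, ...) {
  n <- nrow(x$counts)
  data.frame(
    step = x$step_index,
    i = rep(0:(n - 1), times = 2),
    j = rep(0:1, each = n),
    count = as.vector(x$counts)
  )
}

#' Write / read a population state snapshot as CSV
#'
#' The on-disk format is the long format of
#' [as.data.frame.population_state()]: columns `step`, `i`, `j`, `count`.
#'
#' @param state A `population_state`.
#' @param path File path.
#' @return `write_state` returns `path` invisibly; `read_state` returns a
#'   `population_state`.
#' @export
write_state <- function(state, path) {
  write.csv(as.data.frame(state), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_state
#' @export
read_state <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("step", "i", "j", "count") %in% names(df)))
  N <- max(df$i)
  counts <- matrix(0, nrow = N + 1, ncol = 2)
  counts[cbind(df$i + 1, df$j + 1)] <- df$count
  population_state(counts, step_index = df$step[1])
}
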