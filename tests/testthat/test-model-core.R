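test_that("fitness is additive in drivers, treatment only hits sensitive cells", {
  p <- baseline_params(N = 5)
  expect_equal(fitness(0, 0, sigma = 0, p), 0.004)
  # sigma term vanishes for resistant cells: s - c
  expect_equal(fitness(0, 1, sigma = 0.02, p), 0.003)
  # balance point 2s - sigma = 0 for the one-driver subclone
  expect_equal(fitness(1, 0, sigma = 0.008, p), 0)
  # resistant fitness is independent of sigma
  for (sig in c(0, 0.005, 0.02, 0.1)) {
    expect_equal(fitness(3, 1, sig, p), fitness(3, 1, 0, p))
  }
  expect_error(fitness(6, 0, 0, p), "out of range")
  expect_error(fitness(-1, 0, 0, p), "out of range")
  expect_error(fitness(0, 0, -0.01, p), "non-negative")
})

test_that("birth/death split keeps one fate per cell and mean offspring 1 + f", {
  expect_equal(birth_death_probs(0), list(b = 0.5, d = 0.5))
  expect_equal(birth_death_probs(0.004), list(b = 0.502, d = 0.498))
  expect_equal(birth_death_probs(-1), list(b = 0, d = 1))
  bd <- birth_death_probs(0.37)
  expect_equal(bd$b + bd$d, 1)
  expect_equal(2 * bd$b, 1 + 0.37)
  expect_warning(out <- birth_death_probs(1.5), "clipped")
  expect_equal(out$b, 1)
  expect_error(birth_death_probs(NaN), "finite")
})

test_that("fate probabilities fold boundary mutations into plain division", {
  p <- baseline_params(N = 5)
  # absorbing corner: no driver space left, no back mutation
  corner <- outcome_probs(p$N, 1, 0, p)
  expect_equal(corner$p_div_driver, 0)
  expect_equal(corner$p_div_resist, 0)
  probs <- outcome_probs(0, 0, 0, p)
  expect_equal(probs$p_div_driver, 0.502 * 3.4e-5)
  expect_equal(probs$p_death + probs$p_div_plain + probs$p_div_driver +
                 probs$p_div_resist, 1)
  # mutation-free reduction
  p0 <- model_params(N = 2, u = 0, v = 0)
  probs0 <- outcome_probs(1, 0, 0.001, p0)
  bd <- birth_death_probs(fitness(1, 0, 0.001, p0))
  expect_equal(probs0$p_div_plain, bd$b)
  expect_equal(probs0$p_death, bd$d)
  expect_error(model_params(N = 2, u = 0.6, v = 0.5), "u \\+ v")
})

test_that("one step multiplies an isolated subclone by 1 + f on average", {
  p <- baseline_params(N = 5)
  set.seed(42)
  st <- initial_state(p, 1e6)
  totals <- replicate(300, state_total(step(st, untreated, p)))
  se <- sd(totals) / sqrt(length(totals))
  expect_lt(abs(mean(totals) - 1e6 * 1.004), 3 * se)
  # treated, resistant compartment: f = s - c regardless of sigma
  st_r <- initial_state(p, 1e5, resistant = 1e5)
  pol <- treatment_policy("constant", 0.02)
  totals_r <- replicate(300, state_total(step(st_r, pol, p)))
  se_r <- sd(totals_r) / sqrt(length(totals_r))
  expect_lt(abs(mean(totals_r) - 1e5 * 1.003), 3 * se_r)
})

test_that("single-cell fate frequencies match the four outcome probabilities", {
  # inflate mutation rates so all four fates are well represented
  p <- model_params(N = 5, u = 0.05, v = 0.02)
  pr <- outcome_probs(0, 0, 0, p)
  expected <- c(pr$p_death, pr$p_div_plain, pr$p_div_driver, pr$p_div_resist)
  one <- matrix(0, p$N + 1, 2)
  one[1, 1] <- 1
  set.seed(7)
  n <- 1e5
  fates <- integer(4)
  for (k in seq_len(n)) {
    nxt <- oncoprev:::cpp_step(one, 0, p$s, p$c, p$u, p$v)$counts
    if (sum(nxt) == 0) fates[1] <- fates[1] + 1
    else if (nxt[1, 1] == 2) fates[2] <- fates[2] + 1
    else if (nxt[2, 1] == 1) fates[3] <- fates[3] + 1
    else if (nxt[1, 2] == 1) fates[4] <- fates[4] + 1
    else stop("impossible fate")
  }
  gof <- chisq.test(fates, p = expected)
  expect_gt(gof$p.value, 0.001)
})

test_that("mutation-free dynamics stay in one subclone; v = 0 never creates resistance", {
  p0 <- model_params(N = 3, u = 0, v = 0)
  set.seed(1)
  st <- initial_state(p0, 1000, i = 1)
  nxt <- step(st, untreated, p0)
  expect_equal(sum(nxt$counts[-2, ]), 0)
  # no back mutation: with v = 0 and no initial resistant cells,
  # the resistant column stays empty for all time
  p <- model_params(N = 5, v = 0)
  set.seed(2)
  st <- initial_state(p, 1e5)
  for (k in 1:50) {
    st <- step(st, treatment_policy("constant", 0.002), p)
    expect_equal(state_resistant(st), 0)
  }
})

test_that("counts remain non-negative integers on the lattice", {
  p <- model_params(N = 2, u = 0.01, v = 0.01)
  set.seed(3)
  st <- initial_state(p, 500)
  for (k in 1:100) {
    st <- step(st, treatment_policy("constant", 0.01), p)
    expect_true(all(st$counts >= 0))
    expect_true(all(st$counts == round(st$counts)))
    expect_equal(nrow(st$counts), 3)
    if (state_total(st) == 0) break
  }
})

test_that("a fixed seed makes steps bit-reproducible", {
  p <- baseline_params(N = 5)
  st <- initial_state(p, 12345, resistant = 12)
  pol <- treatment_policy("constant", 0.006)
  run <- function() {
    set.seed(99)
    s <- st
    for (k in 1:25) s <- step(s, pol, p)
    s$counts
  }
  expect_identical(run(), run())
})

test_that("metronomic policy treats only while sensitive cells dominate", {
  pol <- treatment_policy("metronomic", 0.01)
  counts_s <- matrix(c(10, 0, 0, 0), 2, 2)  # all sensitive
  counts_r <- matrix(c(1, 0, 5, 0), 2, 2)   # resistant majority
  expect_equal(oncoprev:::effective_sigma(pol, counts_s), 0.01)
  expect_equal(oncoprev:::effective_sigma(pol, counts_r), 0)
  # "none" is constant zero
  expect_equal(treatment_policy("none")$sigma, 0)
  expect_equal(treatment_policy("none")$kind, "constant")
})

test_that("critical intensity is the fitness of the fastest sensitive subclone", {
  expect_equal(critical_intensity(model_params(N = 5)), 0.024)
  expect_equal(critical_intensity(model_params(N = 0)), 0.004)
  expect_equal(critical_intensity(model_params(N = 9)), 0.04)
})

test_that("state snapshots round-trip through CSV", {
  p <- baseline_params(N = 3)
  st <- initial_state(p, 1e4, resistant = 7, i = 1)
  st$step_index <- 12L
  path <- tempfile(fileext = ".csv")
  write_state(st, path)
  back <- read_state(path)
  expect_equal(back$counts, st$counts)
  expect_equal(back$step_index, 12L)
})
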