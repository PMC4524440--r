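test_that("prevention from a lesion already at the detection threshold detects at once", {
  p <- baseline_params(N = 5, M = 1e6)
  cfg <- scenario_config("prevention_fixed", M0 = 1e6, sigma = 0.01,
                         replicates = 2, base_seed = 1)
  out <- run_scenario(cfg, p)
  expect_true(all(out$status == "detected"))
  expect_true(all(out$t_detect_years == 0))
})

test_that("fully subcritical prevention goes extinct in every replicate", {
  # sigma > s with a single type and no resistance: f = s - sigma < 0
  p <- model_params(N = 0, v = 0)
  cfg <- scenario_config("prevention_fixed", M0 = 1e5, sigma = 0.02, R0 = 0,
                         replicates = 30, base_seed = 2)
  out <- run_scenario(cfg, p)
  expect_true(all(out$status == "extinct"))
  expect_true(all(out$below_M_20y))
  expect_true(all(out$resistant_count_4y == 0))
})

test_that("initial resistant cells follow kappa, or an explicit count", {
  p <- baseline_params(N = 5)
  set.seed(1)
  out <- run_prevention_fixed(
    scenario_config("prevention_fixed", M0 = 1e6, sigma = 0, replicates = 1), p)
  # kappa = 0.01% of 1e6 = 100 resistant cells at the start
  snap <- out$snapshots[[1]]$at_end
  expect_true(out$status == "detected")
  set.seed(1)
  out_r <- run_prevention_fixed(
    scenario_config("prevention_fixed", M0 = 1e6, sigma = 0, R0 = 100,
                    replicates = 1), p)
  expect_identical(out_r$t_detect_years, out$t_detect_years)
  expect_identical(out_r$snapshots[[1]]$at_end, snap)
  expect_error(run_prevention_fixed(
    scenario_config("prevention_fixed", M0 = 100, R0 = 0, kappa = 1,
                    replicates = 1), p), NA)
})

test_that("outcome sets are a deterministic function of config and base seed", {
  p <- baseline_params(N = 5)
  cfg <- scenario_config("prevention_fixed", M0 = 1e5, sigma = 0.006,
                         replicates = 5, base_seed = 123, horizon_years = 30)
  a <- run_scenario(cfg, p)
  b <- run_scenario(cfg, p)
  expect_identical(a$t_detect_years, b$t_detect_years)
  expect_identical(a$status, b$status)
  expect_identical(a$snapshots, b$snapshots)
  expect_identical(a$seed, 123L + 1:5)
})

test_that("growth-phase conditioning discards extinct attempts", {
  p <- baseline_params(N = 9)
  cfg <- scenario_config("post_diagnostic", discovery_threshold = 1e6,
                         residual_size = 1e4, sigma = 0.01,
                         replicates = 8, base_seed = 3, horizon_years = 30)
  out <- run_scenario(cfg, p)
  # every reported replicate survived its growth phase
  expect_true(all(out$t_discovery_years > 0))
  expect_true(all(out$growth_attempts >= 1))
  # with survival odds near 2s/(1+s), most replicates need many attempts
  expect_gt(mean(out$growth_attempts), 10)
  expect_false(any(out$status == "detected"))  # post-diagnostic relapses
})

test_that("degenerate resection at the detection threshold relapses at time zero", {
  p <- model_params(N = 5, M = 1e4)
  cfg <- scenario_config("post_diagnostic", discovery_threshold = 1e4,
                         residual_size = 1e4, sigma = 0.01,
                         replicates = 2, base_seed = 4)
  out <- run_scenario(cfg, p)
  expect_true(all(out$status == "relapsed"))
  expect_true(all(out$t_relapse_years == 0))
})

test_that("untreated second chance fails within the horizon at M0 = 1e6", {
  # untreated regrowth 1e6 -> 1e9 takes ~16-19 y; two phases fit inside 50 y
  p <- baseline_params(N = 9)
  cfg <- scenario_config("second_chance", M0 = 1e6, sigma = 0,
                         replicates = 8, base_seed = 5)
  out <- run_scenario(cfg, p)
  expect_true(all(out$status == "relapsed"))
  expect_true(all(out$t_detect_years + out$t_relapse_years <= 50))
})

test_that("a second chance that never triggers reduces to grown prevention", {
  p <- baseline_params(N = 5)
  # strong treatment from a tiny lesion: detection never happens
  cfg_sc <- scenario_config("second_chance", M0 = 1e3, sigma = 0.03,
                            replicates = 4, base_seed = 6, horizon_years = 5)
  cfg_pg <- scenario_config("prevention_grown", M0 = 1e3, sigma = 0.03,
                            replicates = 4, base_seed = 6, horizon_years = 5)
  out_sc <- run_scenario(cfg_sc, p)
  out_pg <- run_scenario(cfg_pg, p)
  expect_identical(out_sc$status, out_pg$status)
  expect_equal(out_sc$t_discovery_years, out_pg$t_discovery_years)
  expect_false(any(out_sc$status %in% c("detected", "relapsed")))
})

test_that("sweeps tag outcomes by grid point with deterministic seeds", {
  p <- baseline_params(N = 5)
  cfg <- scenario_config("prevention_fixed", M0 = 1e4, sigma = 0,
                         replicates = 3, base_seed = 7, horizon_years = 20)
  expect_error(run_sweep(cfg, p, data.frame()), "empty")
  expect_error(run_sweep(cfg, p, data.frame(bogus = 1)), "unknown")
  grid <- data.frame(sigma = c(0, 0.01), v = c(0, 0))
  out <- run_sweep(cfg, p, grid)
  expect_equal(nrow(out), 6)
  expect_equal(unique(out$point), 1:2)
  # v = 0 knockout: no resistant cells anywhere
  expect_true(all(out$resistant_count == 0))
  expect_true(all(out$resistant_count_4y == 0))
  # the sigma = 0 point reproduces a plain prevention run at the same seeds
  solo <- run_scenario(cfg, p)
  expect_equal(out$t_detect_years[out$point == 1], solo$t_detect_years)
})

test_that("undetected at a 50-year horizon implies below threshold at 20 years", {
  p <- baseline_params(N = 5)
  cfg <- scenario_config("prevention_fixed", M0 = 1e6, sigma = 0.01,
                         replicates = 25, base_seed = 8, horizon_years = 50)
  out <- run_scenario(cfg, p)
  und <- out[out$status == "undetected_at_horizon", ]
  if (nrow(und) > 0) expect_true(all(und$below_M_20y))
  # times only exist for replicates whose endpoint event happened
  expect_true(all(is.na(out$t_detect_years[out$status != "detected"])))
})

test_that("prevention delays failure at least as long as post-diagnostic care", {
  p <- baseline_params(N = 9)
  sg <- 0.01
  cfg_prev <- scenario_config("prevention_grown", M0 = 1e6, sigma = sg,
                              replicates = 60, base_seed = 9,
                              horizon_years = 50)
  cfg_post <- scenario_config("post_diagnostic", discovery_threshold = 1e9,
                              residual_size = 1e6, sigma = sg,
                              replicates = 60, base_seed = 10)
  med_prev <- detection_time_stats(run_scenario(cfg_prev, p))$median
  med_post <- detection_time_stats(run_scenario(cfg_post, p))$median
  # allow a small Monte-Carlo margin on the ordering
  expect_gt(med_prev, med_post - 1)
})
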