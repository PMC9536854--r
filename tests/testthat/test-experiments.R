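# experiment orchestration is exercised on a hand-constructed response
# library so the tests check bookkeeping, determinism and filters without
# rebuilding axon simulations

small_cfg <- function(...) {
  experiment_config(amplitudes_pct_mt = c(40, 80), n_maps = 2,
                    targeting = "surround", duration_s = 4, stim_onset_s = 2,
                    seed = 1, ...)
}

test_that("amplitude sweeps produce one row per seed x targeting x amplitude", {
  grid <- dc_fiber_grid()
  lib <- fake_library(grid, train = function(amp) {
    if (amp >= 80) seq(5, 1495, by = 1000 / 90) else numeric(0)
  })
  cfg <- small_cfg()
  sw <- run_amplitude_sweep(cfg, library = lib, grid = grid)
  expect_equal(nrow(sw), 2 * 1 * 2)
  expect_setequal(sw$amplitude_pct_mt, c(40, 80))
  expect_true(all(sw$amplitude_ua == sw$amplitude_pct_mt))  # MT = 100 uA
  # empty dorsal column drive (all-silent library at 40): near-baseline change
  expect_true(all(abs(sw$norm_delta[sw$amplitude_pct_mt == 40]) < 0.5))
  # uniform 90-Hz drive on every slot of every zone: direct excitation of the
  # zone-1 WDR dominates the recruited inhibition
  expect_true(all(sw$raw_delta_hz[sw$amplitude_pct_mt == 80] > 0))
  # determinism given the same seeds and library
  sw2 <- run_amplitude_sweep(cfg, library = lib, grid = grid)
  expect_identical(sw$raw_delta_hz, sw2$raw_delta_hz)
})

test_that("a no-op pain state reproduces the default state bit-exact", {
  grid <- dc_fiber_grid()
  lib <- fake_library(grid, train = function(amp) {
    if (amp >= 80) seq(5, 1495, by = 1000 / 90) else numeric(0)
  })
  cfg <- small_cfg()
  sw0 <- run_amplitude_sweep(cfg, library = lib, grid = grid)
  swn <- run_amplitude_sweep(cfg, library = lib, grid = grid,
                             pain = pain_state())  # all axes at no-op values
  expect_identical(sw0$raw_delta_hz, swn$raw_delta_hz)
  expect_identical(sw0$baseline_hz, swn$baseline_hz)
})

test_that("parameter grids tally one optimal setting per seed", {
  grid <- dc_fiber_grid()
  lib <- fake_library(grid, freq = 90, pw = 225, train = function(amp) {
    if (amp >= 80) seq(5, 1495, by = 1000 / 90) else numeric(0)
  })
  # add a second setting to the same library object
  for (i in grid$index) for (d in dc_diameter_grid()) for (a in c(40, 80)) {
    assign(scsdh:::lib_key(i, d, 50, 300, a),
           if (a >= 80) seq(5, 1495, by = 20) else numeric(0),
           envir = lib$entries)
  }
  lib$grids$freqs <- c(50, 90); lib$grids$pws <- c(225, 300)
  cfg <- small_cfg(frequencies_hz = c(50, 90), pulse_widths_us = c(300, 225))
  pg <- run_parameter_grid(cfg, therapeutic_pct_mt = c(30, 90),
                           library = lib, grid = grid)
  expect_equal(sum(pg$tally$fraction), 1)
  expect_equal(sum(pg$tally$n_best), 2)        # one winner per map seed
  expect_true(all(pg$tally$setting %in% c("50/300", "90/225")))
  expect_equal(nrow(pg$curves), 2 * 2 * 2)     # settings x seeds x amplitudes
})

test_that("onset timecourse filters the rate and finds half-suppression", {
  # constructed simulation: 40 Hz before onset, 5 Hz after
  spk <- c(seq(10, 3000, by = 25), seq(3050, 6000, by = 200))
  sim <- list(spikes = list(NULL, NULL, spk), duration_s = 6, stim_onset_s = 3)
  tc <- run_onset_timecourse(sim, tau_s = 0.5)
  expect_equal(tc$pre_rate_hz, 40, tolerance = 0.2)
  expect_lt(tc$time_to_half_suppression_s, 3)
  expect_gt(tc$time_to_half_suppression_s, 0)
  # no stimulation: flat trace, no half-suppression point
  spk_flat <- seq(10, 6000, by = 25)
  sim_flat <- list(spikes = list(NULL, NULL, spk_flat),
                   duration_s = 6, stim_onset_s = 3)
  tc_flat <- run_onset_timecourse(sim_flat, tau_s = 0.5)
  post <- tc_flat$rate_hz[tc_flat$time_s > 1]
  expect_lt(diff(range(post)) / mean(post), 0.3)
  expect_true(is.na(tc_flat$time_to_half_suppression_s))
  # a fast filter converges to the binned rate (fine sampling avoids aliasing)
  tc_fast <- run_onset_timecourse(sim_flat, tau_s = 0.05, dt_s = 0.001)
  mid <- tc_fast$time_s > 1 & tc_fast$time_s < 5
  expect_equal(mean(tc_fast$rate_hz[mid]), 40, tolerance = 0.08)
})
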