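test_that("axon geometry matches the published table and its monotonicity", {
  g <- mrg_geometry(5.7)
  expect_equal(g$deltax, 500)          # published internode length at 5.7 um
  expect_equal(g$flut_len, 35)
  expect_equal(g$axon_d, 3.4)
  # internode length strictly increases with diameter
  ds <- c(2.2, 3, 4.4, 5.7, 6.5, 8)
  dl <- vapply(ds, function(d) mrg_geometry(d)$deltax, numeric(1))
  expect_true(all(diff(dl) > 0))
  expect_error(mrg_geometry(1.5), "within")
  expect_error(mrg_geometry(9), "within")
  # physical floors below the published range
  g22 <- mrg_geometry(2.2)
  expect_gte(g22$axon_d, 1)
  expect_gt(g22$deltax, 0)
})

test_that("built axons have a contiguous chain, >= 21 nodes, and need a long enough trajectory", {
  ax <- fx_axon()
  expect_s3_class(ax, "axon_model")
  expect_gte(ax$n_nodes, 21)
  expect_equal(sum(ax$type == 1), ax$n_nodes)
  # compartments contiguous: coordinates move monotonically along z
  expect_true(all(diff(ax$coords_mm[, 3]) > 0))
  expect_error(build_axon(4.4, rbind(c(0, 0, 0), c(0, 0, 0.5))), "shorter")
  expect_error(build_axon(4.4, rbind(c(0, 0, 0)), n_nodes = 21))
})

test_that("zero amplitude is silent and a single pulse at 2x threshold spikes exactly once", {
  fm <- std_field(); el <- std_electrode()
  ax <- fx_axon()
  r0 <- simulate_axon(ax, fm, el, pulse_train_spec(90, 225, 0, 0.2))
  expect_length(r0$spike_times_ms, 0)
  at <- fx_at()
  expect_true(is.finite(at))
  phi <- scsdh:::axon_phi_unit(ax, fm, el)
  spk <- scsdh:::single_pulse_response(ax, phi, 2 * at, 225, 0.0125)
  expect_length(spk, 1)
  # subthreshold: no spike just below threshold
  expect_length(scsdh:::single_pulse_response(ax, phi, 0.95 * at, 225, 0.0125), 0)
})

test_that("conduction is faster in larger axons", {
  fm <- std_field(); el <- std_electrode()
  latency <- function(d) {
    # long axon so the rostral stretch is clear of both contacts (initiation
    # can occur at the anode during the second phase)
    ax <- axon_at_position(0.05, 0.05, d, n_nodes = 41)
    at <- find_activation_threshold(ax, fm, el, 225)
    phi <- scsdh:::axon_phi_unit(ax, fm, el)
    cur <- scsdh:::single_pulse_series(2 * at, 225, 0.0125, post_ms = 10)
    out <- scsdh:::axon_simulate_cpp(ax, phi, cur, 0.0125, 10)
    spk <- out$spikes_by_node
    n <- length(spk)
    (spk[[n]][1] - spk[[n - 8]][1]) / 8  # ms per internode
  }
  t3 <- latency(3); t8 <- latency(8)
  expect_true(t3 > 0 && t8 > 0)
  # larger diameter: more distance per node in less time per node
  v3 <- mrg_geometry(3)$deltax / t3
  v8 <- mrg_geometry(8)$deltax / t8
  expect_gt(v8, v3)
})

test_that("threshold search brackets correctly and scales with the field", {
  fm <- std_field(); el <- std_electrode()
  at <- fx_at()
  # halving conductivities doubles potentials and halves the threshold
  fm2 <- field_model(sigma_long_s_m = 0.3, sigma_trans_s_m = 0.0415)
  at2 <- find_activation_threshold(fx_axon(), fm2, el, 225)
  expect_equal(at2, at / 2, tolerance = 0.03)
  # deep lateral fiber: threshold far above the simulated amplitude range,
  # and "inexcitable" when the search bracket cannot reach it
  ax_deep <- axon_at_position(0.7, 0.45, 2.2)
  at_deep <- find_activation_threshold(ax_deep, fm, el, 225)
  expect_gt(at_deep, 150)
  expect_identical(find_activation_threshold(ax_deep, fm, el, 225,
                                             upper_ua = 150), Inf)
})

test_that("response library covers the grid, is deterministic and respects thresholds", {
  fm <- std_field(); el <- std_electrode()
  pos <- data.frame(index = c(1, 2), x_mm = c(0.05, 0.10),
                    y_mm = c(0.05, 0.05))
  at <- fx_at()
  amps <- c(round(0.5 * at), round(1.3 * at))
  lib <- build_response_library(pos, c(4.4, 5.8), 90, 225, amps,
                                stim_duration_s = 0.25, field = fm,
                                electrode = el)
  expect_equal(length(ls(lib$entries)), 2 * 2 * 2)  # pos x diam x amp
  expect_equal(nrow(lib$thresholds), 4)
  # below threshold -> empty spike list
  expect_length(lib_lookup(lib, 1, 4.4, 90, 225, amps[1]), 0)
  expect_gt(length(lib_lookup(lib, 1, 4.4, 90, 225, amps[2])), 0)
  # determinism: identical libraries from the same configuration
  lib2 <- build_response_library(pos, c(4.4, 5.8), 90, 225, amps,
                                 stim_duration_s = 0.25, field = fm,
                                 electrode = el)
  for (k in ls(lib$entries)) {
    expect_identical(get(k, envir = lib$entries), get(k, envir = lib2$entries))
  }
  # nearest-diameter lookup
  expect_identical(lib_lookup(lib, 1, 4.45, 90, 225, amps[2]),
                   lib_lookup(lib, 1, 4.4, 90, 225, amps[2]))
})

test_that("entrainment metrics follow the per-pulse response rule", {
  pulses <- seq(0, 11 * 89, by = 11)  # 90 pulses
  em1 <- entrainment_metrics(pulses + 1, pulses)
  expect_equal(em1$per_pulse_fire_fraction, 1)
  em0 <- entrainment_metrics(numeric(0), pulses)
  expect_equal(em0$per_pulse_fire_fraction, 0)
  em5 <- entrainment_metrics(pulses[seq(1, 89, by = 2)] + 1, pulses)
  expect_equal(em5$per_pulse_fire_fraction, 0.5)
  expect_error(entrainment_metrics(c(1, 2), numeric(0)), "nonempty")
  # spike 4 ms after a pulse is outside the (0, 3] ms response window
  em_late <- entrainment_metrics(pulses + 4, pulses)
  expect_equal(em_late$per_pulse_fire_fraction, 0)
})

test_that("driven firing rate falls off with distance from the electrode", {
  fm <- std_field(); el <- std_electrode()
  tr <- pulse_train_spec(90, 225, 40, 0.5)
  rates <- vapply(c(0.05, 0.13, 0.21), function(y) {
    r <- simulate_axon(axon_at_position(0.05, y, 4.4), fm, el, tr)
    length(r$spike_times_ms) / 0.5
  }, numeric(1))
  expect_true(all(diff(rates) <= 0))
  expect_gt(rates[1], rates[3])
})

test_that("periodic extension preserves the pulse-aligned pattern", {
  period <- 1000 / 90
  spk <- c(3, 14.4, 25.5, 100.3, 111.4)
  ext <- scsdh:::extend_periodic(spk, sim_ms = 200, target_ms = 600,
                                 period_ms = period)
  expect_true(all(diff(ext) > 0))
  expect_true(max(ext) <= 600)
  expect_true(all(spk %in% ext))
})
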