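test_that("the built network reproduces the published geometry and synapse tables", {
  geo <- dh_neuron_geometry()
  expect_equal(geo$soma_diam[geo$class == "EX"], 25)
  expect_equal(geo$soma_diam[geo$class == "IN"], 10)
  expect_equal(geo$soma_diam[geo$class == "WDR"], 20)
  expect_equal(geo$dend_len, c(300, 400, 350))

  net <- build_network()
  aud <- network_synapse_audit(net)
  # within-node conductances, checked per node against the published table
  expected <- list(
    c("Abeta", "IN", "AMPA", 14.6), c("Abeta", "WDR", "AMPA", 24),
    c("Abeta", "WDR", "NMDA", 0.1), c("Adelta", "WDR", "AMPA", 24),
    c("Adelta", "WDR", "NMDA", 0.1), c("C", "EX", "AMPA", 8),
    c("C", "EX", "NMDA", 4), c("C", "EX", "NK1", 0.02),
    c("C", "WDR", "NK1", 0.014), c("IN", "EX", "GABAA", 5.3),
    c("IN", "WDR", "GABAA", 5.3), c("IN", "WDR", "Glycine", 5.3),
    c("EX", "WDR", "NMDA", 0.21), c("EX", "WDR", "AMPA", 0.29))
  for (node in 1:3) {
    for (e in expected) {
      rows <- aud[!aud$inter_node & aud$src_node == node &
                  aud$source == e[1] & aud$target == e[2] &
                  aud$receptor == e[3], ]
      expect_true(all(rows$gmax_ns == as.numeric(e[4])),
                  info = paste(node, e[1], e[2], e[3]))
      expect_gt(nrow(rows), 0)
    }
  }
  # inter-node rows: reciprocal for every ordered pair
  inter <- aud[aud$inter_node, ]
  expect_equal(nrow(inter), 30)  # 6 ordered pairs x 5 receptor instances
  for (e in list(c("IN", "EX", "GABAA", 3.66), c("IN", "WDR", "GABAA", 4.5),
                 c("IN", "WDR", "Glycine", 4.5), c("EX", "WDR", "NMDA", 0.014),
                 c("EX", "WDR", "AMPA", 0.14))) {
    rows <- inter[inter$source == e[1] & inter$target == e[2] &
                  inter$receptor == e[3], ]
    expect_equal(nrow(rows), 6)
    expect_true(all(rows$gmax_ns == as.numeric(e[4])))
    expect_true(all(rows$src_node != rows$tgt_node))
  }
  # kinetics and reversals per receptor
  kin <- dh_receptor_table()
  expect_equal(kin$tau1_ms, c(0.1, 20, 100, 0.1, 0.1))
  expect_equal(kin$tau2_ms, c(5, 100, 3000, 20, 10))
  expect_equal(kin$e_syn_mv, c(0, 0, 0, -70, -70))
  for (r in kin$receptor) {
    rows <- aud[aud$receptor == r, ]
    expect_true(all(rows$tau1_ms == kin$tau1_ms[kin$receptor == r]))
    expect_true(all(rows$tau2_ms == kin$tau2_ms[kin$receptor == r]))
    expect_true(all(rows$e_syn_mv == kin$e_syn_mv[kin$receptor == r]))
  }
  # afferent slots per node
  expect_equal(unname(net$n_slots), c(15L, 15L, 3L))
  for (node in 1:3) {
    ab <- aud[!aud$inter_node & aud$src_node == node & aud$source == "Abeta" &
              aud$target == "IN", ]
    expect_equal(nrow(ab), 15)
  }
})

test_that("pain-state scalars act on the right parameters and bad states are rejected", {
  ps <- pain_state(gaba_scale = 0.5, e_inh_shift_mv = 16,
                   extra_nociceptor_fraction = 0.25, abeta_to_in_scale = 0.75)
  net <- build_network(ps)
  aud <- network_synapse_audit(net)
  gab <- aud[aud$receptor == "GABAA", ]
  expect_true(all(gab$gmax_ns == 0.5 * gab$gmax_table_ns))
  expect_true(all(aud$e_syn_mv[aud$receptor %in% c("GABAA", "Glycine")] == -54))
  gly <- aud[aud$receptor == "Glycine", ]
  expect_true(all(gly$gmax_ns == gly$gmax_table_ns))  # glycine conductance unscaled
  abin <- aud[aud$source == "Abeta" & aud$target == "IN", ]
  expect_true(all(abin$gmax_ns == 0.75 * 14.6))
  expect_error(pain_state(gaba_scale = 0.2))
  expect_error(pain_state(e_inh_shift_mv = 5))
  expect_error(pain_state(extra_nociceptor_fraction = 0.8))
  expect_error(build_network(pain_state = "disinhibited"))
})

test_that("double-exponential synapse peaks at gmax at the closed-form peak time", {
  tau1 <- 0.1; tau2 <- 5; gmax <- 24
  tp <- tau1 * tau2 / (tau2 - tau1) * log(tau2 / tau1)
  tt <- seq(0, 40, by = 0.001)
  g <- synaptic_conductance(tt, 0, tau1, tau2, gmax)
  expect_equal(max(g), gmax, tolerance = 1e-5)
  expect_equal(tt[which.max(g)], tp, tolerance = 1e-2)
  # two well-separated spikes superpose to the single-event peak twice
  g2 <- synaptic_conductance(tt, c(0, 1000), tau1, tau2, gmax)
  expect_equal(max(g2[tt < 100]), gmax, tolerance = 1e-5)
  expect_error(synaptic_conductance(1, 0, 5, 5, 1))
})

test_that("rate-change bookkeeping matches hand-computed values", {
  spk <- c(seq(50, 4950, by = 100), seq(5050, 9950, by = 200))  # 10 Hz -> 5 Hz
  ch <- wdr_change(spk, c(0, 5), c(5, 10))
  expect_equal(ch$raw_delta_hz, -5)
  expect_equal(ch$norm_delta, -0.5)
  ch0 <- wdr_change(seq(50, 9950, by = 100), c(0, 5), c(5, 10))
  expect_equal(ch0$raw_delta_hz, 0)
  expect_equal(ch0$norm_delta, 0)
  ch_empty <- wdr_change(seq(50, 4950, by = 100), c(0, 5), c(5, 10))
  expect_equal(ch_empty$raw_delta_hz, -10)
  expect_equal(ch_empty$norm_delta, -1)
  chz <- wdr_change(numeric(0), c(0, 5), c(5, 10))
  expect_true(is.na(chz$norm_delta))
  expect_error(wdr_change(spk, c(5, 10), c(0, 5)), "precede")
})

test_that("network dynamics: quiescent without input, driven by pain input, disinhibited by knockout", {
  net <- build_network()
  sim0 <- simulate_network(net, empty_afferents(2), NULL, 2, 1)
  expect_lt(length(sim0$spikes[[3]]) / 2, 1)   # WDR < 1 Hz without input
  expect_false(any(sim0$diverged))

  aff <- fx_afferents(4)
  sim <- simulate_network(net, aff, NULL, 4, 2)
  wdr_rate <- length(sim$spikes[[3]]) / 4
  expect_gt(wdr_rate, 5)                        # sustained firing under pain input
  # firing persists through the window (spikes in every second)
  expect_true(all(table(cut(sim$spikes[[3]], seq(0, 4000, 1000))) > 0))

  netko <- build_network()
  netko$synapses$gmax_ns[netko$synapses$receptor %in% c("GABAA", "Glycine")] <- 0
  simko <- simulate_network(netko, aff, NULL, 4, 2)
  expect_gt(length(simko$spikes[[3]]), length(sim$spikes[[3]]))
})

test_that("peripheral recruitment: center stimulation excites, far surround inhibits", {
  aff <- fx_afferents(4)
  net <- build_network()
  rec <- data.frame(amplitude = c(0, 1), fraction = c(0, 1))
  r1 <- peripheral_recruitment_experiment(rec, stim_zone = 1, aff, net,
                                          duration_s = 4, stim_onset_s = 2)
  r3 <- peripheral_recruitment_experiment(rec, stim_zone = 3, aff, net,
                                          duration_s = 4, stim_onset_s = 2)
  # zero recruitment: response equals baseline statistics (small change)
  expect_lt(abs(r1$norm_delta[1]), 0.35)
  # full recruitment: zone-1 stimulation excites the zone-1 WDR ...
  expect_gt(r1$raw_delta_hz[2], 0)
  # ... and zone-3 stimulation inhibits it
  expect_lt(r3$raw_delta_hz[2], 0)
  # zone-1 response exceeds the zone-3 response everywhere (ordering)
  expect_true(all(r1$raw_delta_hz[2] > r3$raw_delta_hz[2]))
  expect_error(peripheral_recruitment_experiment(
    data.frame(amplitude = 1:2, fraction = c(0.5, 0.1)), 1, aff, net))
  expect_error(peripheral_recruitment_experiment(
    data.frame(amplitude = 1, fraction = 2), 1, aff, net))
})
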