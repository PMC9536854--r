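test_that("afferent generation is seed-deterministic and respects duration", {
  a1 <- gen_pain_afferents(3, 5, seed = 7)
  a2 <- gen_pain_afferents(3, 5, seed = 7)
  expect_identical(a1$nodes, a2$nodes)
  expect_identical(a1$bursts, a2$bursts)
  a3 <- gen_pain_afferents(3, 5, seed = 8)
  expect_false(identical(a1$nodes, a3$nodes))
  # zero duration -> empty trains
  a0 <- gen_pain_afferents(3, 0, seed = 1)
  expect_true(all(vapply(unlist(a0$nodes, recursive = FALSE),
                         function(cl) all(lengths(cl) == 0), logical(1))))
  # structure: 15 + 15 + 3 trains per node, one third of A fibers bursting
  expect_length(a1$nodes, 3)
  expect_equal(lengths(a1$nodes[[1]])[c("Abeta", "Adelta", "C")],
               c(Abeta = 15L, Adelta = 15L, C = 3L))
  per_node <- table(a1$fibers$node[a1$fibers$bursting])
  expect_true(all(per_node == 10))
  # spike times sorted and within range
  for (tr in a1$nodes[[1]]$Abeta) {
    expect_true(!is.unsorted(tr))
    expect_true(all(tr >= 0 & tr <= 5000))
  }
})

test_that("afferent rates and burst statistics match the stated means", {
  a <- gen_pain_afferents(20, 60, seed = 3)   # 600 A fibers x 60 s
  pooled_a <- sum(vapply(a$nodes, function(n) {
    sum(lengths(n$Abeta)) + sum(lengths(n$Adelta))
  }, numeric(1))) / (600 * 60)
  expect_equal(pooled_a, 2.2, tolerance = 0.1)   # Monte-Carlo at this n
  pooled_c <- sum(vapply(a$nodes, function(n) sum(lengths(n$C)),
                         numeric(1))) / (60 * 60)
  expect_equal(pooled_c, 1.5, tolerance = 0.15)
  cb <- a$bursts[a$bursts$complete, ]
  expect_gt(nrow(cb), 500)
  expect_equal(mean(cb$n_spikes), 6, tolerance = 0.25)
  expect_equal(mean(a$interburst_ms), 551, tolerance = 30 / 551)
  # bimodal ISI structure in bursting trains: intra-burst vs quiescent modes
  bf <- a$fibers[a$fibers$bursting & a$fibers$node == 1, ][1, ]
  tr <- a$nodes[[1]][[bf$class]][[bf$slot]]
  isi <- diff(tr)
  expect_gt(sum(isi > 5 * 30) / length(isi), 0.02)  # long gaps present
  expect_gt(sum(isi <= 90) / length(isi), 0.5)      # dominated by intra-burst
  expect_gt(median(isi[isi > 150]) / median(isi[isi <= 150]), 5)
})

test_that("Latin hypercube pain states stratify every axis and quantize the reversal shift", {
  st <- sample_pain_states(30, seed = 5)
  expect_length(st, 30)
  u <- attr(st, "lhs")
  # LHS definition: exactly one sample in each of the 30 strata per axis
  for (j in 1:4) {
    expect_equal(sort(findInterval(u[, j], seq(0, 1, by = 1 / 30),
                                   rightmost.closed = TRUE)), 1:30)
  }
  gs <- vapply(st, `[[`, numeric(1), "gaba_scale")
  expect_true(all(gs >= 0.5 & gs <= 1))
  ei <- vapply(st, `[[`, numeric(1), "e_inh_shift_mv")
  expect_true(all(ei %in% c(0, 4, 8, 12, 16)))
  ex <- vapply(st, `[[`, numeric(1), "extra_nociceptor_fraction")
  expect_true(all(ex >= 0 & ex <= 0.5))
  ab <- vapply(st, `[[`, numeric(1), "abeta_to_in_scale")
  expect_true(all(ab >= 0.5 & ab <= 1))
  # deterministic under the seed
  expect_identical(attr(sample_pain_states(30, seed = 5), "lhs"), u)
  # marginal uniformity of the continuous axes (KS at alpha = 0.01)
  for (j in c(1, 3, 4)) {
    expect_gt(suppressWarnings(stats::ks.test(u[, j], "punif")$p.value), 0.01)
  }
})

test_that("waveform generation reproduces the two-Gaussian model exactly at zero noise", {
  w <- gen_unit_waveform("pEX", noise_sd = 0, seed = 2)
  expect_equal(w$v, waveform_model(w$t_ms, w$params))
  expect_equal(length(w$t_ms), 49)  # 1.2 ms at 40 kHz
  # class invariants of generated parameters
  expect_lt(abs(w$params$a2 / w$params$a1), 0.25)
  wi <- gen_unit_waveform("pIN", noise_sd = 0, seed = 2)
  expect_lt(wi$params$a2 / wi$params$a1, 0)   # opposite-sign lobes
  expect_gt(abs(wi$params$a2 / wi$params$a1), 0.25)
  # degenerate amplitudes -> flat zero waveform
  w0 <- gen_unit_waveform("pEX", params = list(a1 = 0, b1 = 0.4, c1 = 0.1,
                                               a2 = 0, b2 = 0.6, c2 = 0.2),
                          noise_sd = 0)
  expect_true(all(w0$v == 0))
})

test_that("recorded sessions honor the modulation truth", {
  u <- list(
    synthetic_unit("pEX", baseline_hz = 10,
                   modulation = c("20" = 1, "40" = 0, "60" = 3)),
    synthetic_unit("pIN", baseline_hz = 5,
                   modulation = c("20" = 1, "40" = 1, "60" = 1))
  )
  s <- gen_recorded_session(u, c(20, 40, 60), seed = 4)
  expect_length(s, 2)
  # factor 0 -> empty stimulation window
  expect_length(s[[1]]$conditions[["40"]]$spikes_ms, 0)
  # factor 3 at 10 Hz over 30 s: ~900 spikes
  expect_equal(length(s[[1]]$conditions[["60"]]$spikes_ms), 900,
               tolerance = 0.2)
  # pulse bookkeeping at 90 Hz
  expect_equal(length(s[[1]]$conditions[["20"]]$pulse_times_ms), 2700)
  # determinism
  s2 <- gen_recorded_session(u, c(20, 40, 60), seed = 4)
  expect_identical(s[[1]]$baseline_spikes_ms, s2[[1]]$baseline_spikes_ms)
  # session export writes the CSV dialect plus sidecar
  dir <- tempfile()
  write_session(s, dir)
  expect_true(file.exists(file.path(dir, "baseline.csv")))
  expect_true(file.exists(file.path(dir, "stim_40.csv")))
  expect_true(file.exists(file.path(dir, "session.json")))
  base <- utils::read.csv(file.path(dir, "baseline.csv"))
  expect_equal(sort(unique(base$unit_id)), 1:2)
})
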