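test_that("bin-width selection matches an independent evaluation of the cost and scales", {
  set.seed(31)
  spk <- sort(runif(1200, 0, 60000))  # stationary 20 Hz, 60 s
  w <- optimal_binwidth(spk, window_ms = c(0, 60000))
  expect_true(is.finite(w) && w >= 10 && w <= 2000)
  # independent single-offset evaluation of the same cost functional
  cost1 <- function(D, st, win) {
    edges <- seq(win[1], win[2] + D, by = D)
    k <- tabulate(findInterval(st, edges), nbins = length(edges) - 1)
    (2 * mean(k) - mean((k - mean(k))^2)) / D^2
  }
  cands <- exp(seq(log(10), log(2000), length.out = 30))
  oracle <- cands[which.min(vapply(cands, cost1, numeric(1),
                                   st = spk, win = c(0, 60000)))]
  expect_lt(abs(log(w / oracle)), log(4))  # same region of the cost curve
  # scaling: stretching time by 2 scales the optimal width by 2
  w2 <- optimal_binwidth(spk * 2, window_ms = c(0, 120000),
                         candidates_ms = 2 * cands)
  expect_equal(as.numeric(w2) / as.numeric(w), 2, tolerance = 0.75)
  expect_warning(wf <- optimal_binwidth(numeric(0)), "fallback")
  expect_equal(unclass(wf), 500)
})

make_recording <- function(baseline_ms, stim_ms, pulses_ms = numeric(0),
                           baseline_s = 30, stim_s = 30) {
  structure(list(unit_id = 1L, waveform = NULL,
                 baseline_spikes_ms = baseline_ms,
                 baseline_s = baseline_s, stim_s = stim_s,
                 conditions = list("40" = list(amplitude = 40,
                                               spikes_ms = stim_ms,
                                               pulse_times_ms = pulses_ms)),
                 truth = NULL),
            class = "unit_recording")
}

test_that("responder rule: identical statistics fail, strong modulation passes, 2 bins are not enough", {
  set.seed(41)
  base <- sort(runif(300, 0, 30000))
  # same construction for baseline and stimulation: non-responder
  r <- responder_test(make_recording(base, base), "40", bin_width_ms = 1000)
  expect_false(r$responder)
  # 3x rate: excited responder (z per bin ~ (30-10)/sqrt(10) >> 1.96)
  stim <- sort(runif(900, 0, 30000))
  r3 <- responder_test(make_recording(base, stim), "40", bin_width_ms = 1000)
  expect_true(r3$responder)
  expect_equal(r3$direction, "excited")
  expect_equal(r3$raw_delta_hz, 20, tolerance = 0.2)
  # exactly 2 consecutive elevated bins then a gap: non-responder
  base_reg <- seq(50, 29950, by = 100)               # regular 10 Hz
  burst <- c(seq(1000, 1999, by = 10), seq(2000, 2999, by = 10))
  stim2 <- sort(c(base_reg, burst))
  r2 <- responder_test(make_recording(base_reg, stim2), "40",
                       bin_width_ms = 1000)
  sig <- abs(r2$z) >= 1.96
  expect_equal(max(rle(sig)$lengths[rle(sig)$values]), 2)
  expect_false(r2$responder)
  # three elevated bins: responder
  stim3 <- sort(c(base_reg, burst, seq(3000, 3999, by = 10)))
  expect_true(responder_test(make_recording(base_reg, stim3), "40",
                             bin_width_ms = 1000)$responder)
  # zero baseline variance falls back to Poisson, flagged
  expect_true(responder_test(make_recording(base_reg, stim3), "40",
                             bin_width_ms = 1000)$poisson_fallback)
})

test_that("artifact bins are dropped pairwise from stimulation and baseline", {
  base <- seq(50, 29950, by = 100)
  stim <- seq(50, 29950, by = 100)
  # dense pulses in the 5th bin only: 500 x 1 ms blanking = 50% of the bin
  pulses <- seq(4000, 4998, by = 2)
  r <- responder_test(make_recording(base, stim, pulses), "40",
                      bin_width_ms = 1000)
  expect_equal(r$dropped_bins, 5L)
  expect_true(is.na(r$z[5]))
  expect_false(r$responder)
})

test_that("normalization and the inclusion filter follow the stated rules exactly", {
  expect_equal(normalize_responses(c(2, -4, 1)), c(0.5, -1, 0.25))
  expect_equal(normalize_responses(c(0, 0)), c(0, 0))
  expect_equal(normalize_responses(-3), -1)
  tab <- data.frame(
    unit_id = rep(1:3, each = 2),
    responder = c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE),
    baseline_hz = c(1.4, 1.4, 5, 5, 5, 5))
  keep <- inclusion_filter(tab)
  expect_equal(keep, 3L)      # 1.4 Hz responder excluded; 5 Hz non-responder excluded
  tab$baseline_hz[1:2] <- 1.5 # boundary: exactly 1.5 Hz is included
  expect_equal(inclusion_filter(tab), c(1L, 3L))
})

test_that("fuzzy c-means recovers separated blobs and matches an independent implementation", {
  set.seed(17)
  blobs <- rbind(matrix(rnorm(60, 0), ncol = 2),
                 matrix(rnorm(60, 10), ncol = 2))
  truth <- rep(1:2, each = 30)
  cr <- cluster_responses(cbind(blobs, blobs), k_range = 2:4, seed = 2)
  lab <- cr$labels[["2"]]
  expect_equal(cr$k_silhouette, 2)
  expect_true(adjusted_rand(lab, truth) == 1)  # perfect up to permutation
  # membership rows sum to 1
  for (m in cr$membership) {
    expect_true(all(abs(rowSums(m) - 1) < 1e-9))
  }
  # independent implementation agrees on the objective's optimum (e1071)
  skip_if_not_installed("e1071")
  fit_mine <- scsdh:::fcm(blobs, 2, seed = 3)
  set.seed(3)
  fit_ref <- e1071::cmeans(blobs, 2, m = 2, iter.max = 500)
  perm <- if (sum((fit_mine$centers[1, ] - fit_ref$centers[1, ])^2) <
              sum((fit_mine$centers[1, ] - fit_ref$centers[2, ])^2)) 1:2 else 2:1
  expect_equal(unname(fit_mine$centers), unname(fit_ref$centers[perm, ]),
               tolerance = 0.02)
  # duplication stability: duplicating every point leaves the solution intact
  fit_dup <- scsdh:::fcm(rbind(blobs, blobs), 2, seed = 3)
  perm2 <- if (sum((fit_dup$centers[1, ] - fit_mine$centers[1, ])^2) <
               sum((fit_dup$centers[1, ] - fit_mine$centers[2, ])^2)) 1:2 else 2:1
  expect_equal(unname(fit_dup$centers[perm2, ]), unname(fit_mine$centers),
               tolerance = 0.02)
})

test_that("waveform fits recover generator parameters and flag degenerate inputs", {
  w <- gen_unit_waveform("pIN", noise_sd = 0, seed = 12)
  f <- fit_waveform(w$t_ms, w$v)
  expect_false(f$unclassifiable)
  p0 <- unlist(w$params)
  expect_equal(unname(f$params[names(p0)]), unname(p0), tolerance = 0.01)
  # flat zero waveform: unclassifiable with near-zero amplitudes
  fz <- fit_waveform(seq(0, 1.2, length.out = 49), rep(0, 49))
  expect_true(fz$unclassifiable)
  # single-Gaussian input: one fitted amplitude is ~0
  t_ms <- seq(0, 1.2, length.out = 49)
  v1 <- 1.0 * exp(-((t_ms - 0.5) / 0.12)^2)
  f1 <- fit_waveform(t_ms, v1)
  expect_lt(min(abs(f1$params[c("a1", "a2")])), 0.02)
  expect_error(fit_waveform(1:10, 1:10), "20 samples")
})

test_that("unit classification follows the confidence rule and recovers class truth", {
  clf <- train_waveform_classifier(n_per_class = 60, seed = 77)
  w_mono <- gen_unit_waveform("pEX",
                              params = list(a1 = 1, b1 = 0.4, c1 = 0.1,
                                            a2 = -0.05, b2 = 0.65, c2 = 0.25),
                              noise_sd = 0.01, seed = 5)
  f <- fit_waveform(w_mono$t_ms, w_mono$v)
  cl <- classify_unit(f, clf)
  expect_equal(cl$class, "pEX")
  expect_gt(cl$confidence, 0.9)
  w_bi <- gen_unit_waveform("pIN",
                            params = list(a1 = 1, b1 = 0.4, c1 = 0.12,
                                          a2 = -1, b2 = 0.6, c2 = 0.12),
                            noise_sd = 0.01, seed = 6)
  cl2 <- classify_unit(fit_waveform(w_bi$t_ms, w_bi$v), clf)
  expect_equal(cl2$class, "pIN")
  # posterior below the confidence threshold -> unclassified
  cl3 <- classify_unit(f, clf, confidence = 1)
  expect_equal(cl3$class, "unclassified")
  # unclassifiable fit propagates
  fz <- fit_waveform(seq(0, 1.2, length.out = 49), rep(0, 49))
  expect_equal(classify_unit(fz, clf)$class, "unclassified")
})
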