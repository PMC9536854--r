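#' Generate neuropathic pain afferent input spike trains
#'
#' Per node: 15 Abeta, 15 Adelta and 3 C spike trains over `[0, duration_s]`.
#' Per-fiber mean rates are drawn from gamma distributions (shape 2) with
#' population means 2.2 Hz (A fibers) and 1.5 Hz (C fibers). One third of the
#' A fibers in each node fire in bursting episodes instead of Poisson trains:
#' within an episode, bursts of 2 + Poisson(4) spikes (intra-burst intervals
#' exponential, mean 30 ms) are separated by exponential inter-burst intervals
#' (mean 551 ms), and the quiescent gap between episodes is set so each train
#' realizes its drawn mean rate. Burst structure is annotated so burst
#' statistics are measurable directly from the output.
#'
#' @param node_count Number of nodes (default 3).
#' @param duration_s Train duration (s).
#' @param seed Integer seed (generation is deterministic given the seed).
#' @param extra_nociceptor_fraction_surround Fraction of additional active
#'   Adelta/C inputs merged into the surround nodes' slots (pain-state axis;
#'   default 0).
#' @param a_rate_hz,c_rate_hz Population mean rates (defaults 2.2 and 1.5).
#' @param rate_shape Gamma shape of the per-fiber rate distribution
#'   (default 2).
#' @param burst_isi_ms,burst_interburst_ms,burst_spikes_mean Burst statistics
#'   (defaults 30 ms, 551 ms, 6 spikes/burst).
#' @return Object of class `afferent_bundle`: `nodes` (per node, lists
#'   `Abeta`, `Adelta`, `C` of spike-time vectors in ms), `fibers`
#'   (annotation data.frame), `bursts` (data.frame: node, slot, start_ms,
#'   n_spikes), `interburst_ms` (within-episode intervals).
#' @export
gen_pain_afferents <- function(node_count = 3, duration_s, seed = 1L,
                               extra_nociceptor_fraction_surround = 0,
                               a_rate_hz = 2.2, c_rate_hz = 1.5,
                               rate_shape = 2,
                               burst_isi_ms = 30, burst_interburst_ms = 551,
                               burst_spikes_mean = 6) {
  stopifnot(duration_s >= 0)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  dur_ms <- duration_s * 1000
  n_ab <- 15L; n_ad <- 15L; n_c <- 3L
  # annotation accumulators (parallel vectors; data.frames built once at end)
  bu_node <- integer(0); bu_slot <- character(0); bu_start <- numeric(0)
  bu_n <- integer(0); bu_complete <- logical(0)
  fi_node <- integer(0); fi_class <- character(0); fi_slot <- integer(0)
  fi_burst <- logical(0); fi_rate <- numeric(0)
  interburst <- numeric(0)

  poisson_train <- function(rate_hz) {
    n <- stats::rpois(1, rate_hz * duration_s)
    sort(stats::runif(n, 0, dur_ms))
  }
  burst_train <- function(rate_hz, node, slot_label) {
    # expected spikes/episode and episode length under the burst parameters
    k_mean <- 2                       # bursts per episode: 1 + Poisson(1)
    sp_mean <- burst_spikes_mean      # spikes per burst: 2 + Poisson(sp-2)
    ep_spikes <- k_mean * sp_mean
    ep_len <- (k_mean - 1) * burst_interburst_ms +
      k_mean * (sp_mean - 1) * burst_isi_ms
    gap_mean <- max(200, 1000 * ep_spikes / rate_hz - ep_len)
    t <- stats::rexp(1, 1 / gap_mean)
    spikes <- list(); b_start <- list(); b_n <- list(); b_ok <- list()
    ib_all <- list()
    while (t < dur_ms) {
      k <- 1 + stats::rpois(1, k_mean - 1)
      for (b in seq_len(k)) {
        nsp <- 2 + stats::rpois(1, sp_mean - 2)
        isis <- stats::rexp(nsp - 1, 1 / burst_isi_ms)
        st <- t + c(0, cumsum(isis))
        st <- st[st < dur_ms]
        if (length(st)) {
          i <- length(spikes) + 1L
          spikes[[i]] <- st
          b_start[[i]] <- st[1]; b_n[[i]] <- length(st)
          b_ok[[i]] <- length(st) == nsp
        }
        t <- t + sum(isis)
        if (b < k) {
          ib <- stats::rexp(1, 1 / burst_interburst_ms)
          if (t < dur_ms) ib_all[[length(ib_all) + 1L]] <- ib
          t <- t + ib
        }
        if (t >= dur_ms) break
      }
      t <- t + stats::rexp(1, 1 / gap_mean)
    }
    nb <- length(spikes)
    if (nb) {
      bu_node <<- c(bu_node, rep.int(node, nb))
      bu_slot <<- c(bu_slot, rep.int(slot_label, nb))
      bu_start <<- c(bu_start, unlist(b_start))
      bu_n <<- c(bu_n, unlist(b_n))
      bu_complete <<- c(bu_complete, unlist(b_ok))
    }
    if (length(ib_all)) interburst <<- c(interburst, unlist(ib_all))
    sort(unlist(spikes))
  }

  nodes <- lapply(seq_len(node_count), function(node) {
    # one third of the 30 A fibers burst; choose slots at random
    burst_slots <- sample.int(n_ab + n_ad, (n_ab + n_ad) / 3)
    a_rates <- stats::rgamma(n_ab + n_ad, shape = rate_shape,
                             scale = a_rate_hz / rate_shape)
    c_rates <- stats::rgamma(n_c, shape = rate_shape,
                             scale = c_rate_hz / rate_shape)
    mk_a <- function(j, label, slot) {
      burst <- j %in% burst_slots
      fi_node <<- c(fi_node, node); fi_class <<- c(fi_class, label)
      fi_slot <<- c(fi_slot, slot); fi_burst <<- c(fi_burst, burst)
      fi_rate <<- c(fi_rate, a_rates[j])
      if (burst) burst_train(a_rates[j], node, paste0(label, slot))
      else poisson_train(a_rates[j])
    }
    ab <- lapply(seq_len(n_ab), function(s) mk_a(s, "Abeta", s))
    ad <- lapply(seq_len(n_ad), function(s) mk_a(n_ab + s, "Adelta", s))
    cc <- lapply(seq_len(n_c), function(s) {
      fi_node <<- c(fi_node, node); fi_class <<- c(fi_class, "C")
      fi_slot <<- c(fi_slot, s); fi_burst <<- c(fi_burst, FALSE)
      fi_rate <<- c(fi_rate, c_rates[s])
      poisson_train(c_rates[s])
    })
    list(Abeta = ab, Adelta = ad, C = cc)
  })

  f <- extra_nociceptor_fraction_surround
  if (f > 0 && node_count >= 2) {
    for (node in 2:node_count) {
      for (s in seq_len(ceiling(f * n_ad))) {
        r <- stats::rgamma(1, shape = rate_shape, scale = a_rate_hz / rate_shape)
        nodes[[node]]$Adelta[[s]] <-
          sort(c(nodes[[node]]$Adelta[[s]], poisson_train(r)))
      }
      for (s in seq_len(ceiling(f * n_c))) {
        r <- stats::rgamma(1, shape = rate_shape, scale = c_rate_hz / rate_shape)
        nodes[[node]]$C[[s]] <- sort(c(nodes[[node]]$C[[s]], poisson_train(r)))
      }
    }
  }

  structure(list(
    nodes = nodes,
    fibers = if (length(fi_node)) data.frame(node = fi_node, class = fi_class,
                                             slot = fi_slot,
                                             bursting = fi_burst,
                                             rate_hz = fi_rate) else NULL,
    bursts = if (length(bu_node)) data.frame(node = bu_node, slot = bu_slot,
                                             start_ms = bu_start,
                                             n_spikes = bu_n,
                                             complete = bu_complete) else NULL,
    interburst_ms = interburst,
    duration_s = duration_s, seed = seed),
    class = "afferent_bundle")
}

#' Latin hypercube sample of pain states
#'
#' Four-dimensional Latin hypercube over the disinhibition axes: each axis is
#' partitioned into `n` strata with exactly one sample per stratum. The
#' inhibitory-reversal shift is snapped to the nearest 4-mV step in [0, 16].
#'
#' @param n Number of states (default 30).
#' @param seed Integer seed.
#' @return List of [pain_state()] objects; the raw unit-cube sample is in
#'   attribute `"lhs"`.
#' @export
sample_pain_states <- function(n = 30, seed = 1L) {
  stopifnot(n >= 1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  u <- lhs::randomLHS(n, 4)
  states <- lapply(seq_len(n), function(i) {
    pain_state(gaba_scale = 1 - 0.5 * u[i, 1],
               e_inh_shift_mv = 4 * round(4 * u[i, 2]),
               extra_nociceptor_fraction = 0.5 * u[i, 3],
               abeta_to_in_scale = 1 - 0.5 * u[i, 4])
  })
  attr(states, "lhs") <- u
  states
}

#' Evaluate the two-Gaussian mean-waveform model
#'
#' V(x) = a1 exp(-((x - b1)/c1)^2) + a2 exp(-((x - b2)/c2)^2), with x in ms.
#'
#' @param t_ms Time grid (ms).
#' @param params Named list/vector with a1, b1, c1, a2, b2, c2.
#' @return Numeric vector.
#' @export
waveform_model <- function(t_ms, params) {
  p <- as.list(params)
  p$a1 * exp(-((t_ms - p$b1) / p$c1)^2) + p$a2 * exp(-((t_ms - p$b2) / p$c2)^2)
}

#' Draw waveform-shape parameters for a synthetic unit class
#'
#' Monophasic (putatively excitatory, pEX) units have one dominant lobe
#' (|a2/a1| < 0.25); biphasic (putatively inhibitory, pIN) units have
#' opposite-sign lobes of comparable size.
#'
#' @param class `"pEX"` or `"pIN"`.
#' @return Named list a1, b1, c1, a2, b2, c2 (uses the current RNG stream).
#' @export
synth_unit_params <- function(class = c("pEX", "pIN")) {
  class <- match.arg(class)
  a1 <- stats::runif(1, 0.8, 1.2)
  b1 <- stats::runif(1, 0.35, 0.5)
  c1 <- stats::runif(1, 0.08, 0.16)
  if (class == "pEX") {
    a2 <- -a1 * stats::runif(1, 0.02, 0.2)
    b2 <- b1 + stats::runif(1, 0.2, 0.35)
    c2 <- stats::runif(1, 0.2, 0.35)
  } else {
    a2 <- -a1 * stats::runif(1, 0.6, 1.0)
    b2 <- b1 + stats::runif(1, 0.12, 0.3)
    c2 <- stats::runif(1, 0.1, 0.2)
  }
  list(a1 = a1, b1 = b1, c1 = c1, a2 = a2, b2 = b2, c2 = c2)
}

#' Generate a sampled extracellular unit waveform
#'
#' The two-Gaussian model evaluated on a regular grid plus white Gaussian
#' noise.
#'
#' @param class `"pEX"` or `"pIN"` (used when `params` is NULL).
#' @param params Waveform parameters (see [waveform_model()]); drawn from
#'   [synth_unit_params()] when NULL.
#' @param noise_sd Noise standard deviation.
#' @param seed Integer seed.
#' @param sample_rate_hz Sampling rate (default 40 kHz).
#' @param duration_ms Window length (default 1.2 ms).
#' @return List with `t_ms`, `v`, `params`, `class`.
#' @export
gen_unit_waveform <- function(class = c("pEX", "pIN"), params = NULL,
                              noise_sd = 0, seed = 1L,
                              sample_rate_hz = 40000, duration_ms = 1.2) {
  class <- match.arg(class)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (is.null(params)) params <- synth_unit_params(class)
  t_ms <- seq(0, duration_ms, by = 1000 / sample_rate_hz)
  v <- waveform_model(t_ms, params) + stats::rnorm(length(t_ms), 0, noise_sd)
  list(t_ms = t_ms, v = v, params = params, class = class)
}

#' Define a synthetic unit for emulated recordings
#'
#' @param class `"pEX"` or `"pIN"`.
#' @param baseline_hz Baseline firing rate.
#' @param modulation Named numeric vector of multiplicative rate factors per
#'   stimulation amplitude label (e.g. `c("20" = 1, "40" = 0.5, ...)`).
#' @param noise_sd Waveform noise SD.
#' @param params Optional explicit waveform parameters.
#' @return Object of class `synthetic_unit`.
#' @export
synthetic_unit <- function(class, baseline_hz, modulation, noise_sd = 0.02,
                           params = NULL) {
  stopifnot(class %in% c("pEX", "pIN"), baseline_hz >= 0,
            all(modulation >= 0))
  structure(list(class = class, baseline_hz = baseline_hz,
                 modulation = modulation, noise_sd = noise_sd,
                 params = params),
            class = "synthetic_unit")
}

#' Generate an emulated recording session
#'
#' For each synthetic unit: a baseline window of Poisson spiking at the
#' unit's rate, then one stimulation window per amplitude at rate x
#' modulation factor, with stimulation pulse times recorded for artifact-bin
#' bookkeeping. All windows are generated independently per unit with a
#' deterministic per-unit substream.
#'
#' @param units List of [synthetic_unit()] objects.
#' @param amplitudes Amplitude labels matching the units' modulation names.
#' @param seed Integer seed.
#' @param baseline_s,stim_s Window durations (defaults: 600 s of
#'   spontaneous activity, mirroring the ten-minute spontaneous recordings
#'   such sessions are based on, and 30 s of stimulation).
#' @param stim_freq_hz Stimulation rate for pulse bookkeeping (default 90).
#' @return List of `unit_recording` objects: `unit_id`, `waveform`
#'   (mean waveform list), `baseline_spikes_ms`, `conditions` (per amplitude:
#'   `spikes_ms`, `pulse_times_ms`), `truth` (class and modulation).
#' @export
gen_recorded_session <- function(units, amplitudes, seed = 1L,
                                 baseline_s = 600, stim_s = 30,
                                 stim_freq_hz = 90) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  lapply(seq_along(units), function(i) {
    u <- units[[i]]
    set.seed(seed + 1000L * i)
    params <- if (is.null(u$params)) synth_unit_params(u$class) else u$params
    wf_t <- seq(0, 1.2, by = 1000 / 40000)
    wf_v <- waveform_model(wf_t, params) +
      stats::rnorm(length(wf_t), 0, u$noise_sd)
    pois <- function(rate_hz, dur_s) {
      n <- stats::rpois(1, rate_hz * dur_s)
      sort(stats::runif(n, 0, dur_s * 1000))
    }
    conds <- lapply(amplitudes, function(a) {
      fac <- u$modulation[[as.character(a)]]
      if (is.null(fac)) stop("unit has no modulation factor for amplitude ", a)
      list(amplitude = a,
           spikes_ms = pois(u$baseline_hz * fac, stim_s),
           pulse_times_ms = (seq_len(floor(stim_s * stim_freq_hz)) - 1) *
             (1000 / stim_freq_hz))
    })
    names(conds) <- as.character(amplitudes)
    structure(list(unit_id = i,
                   waveform = list(t_ms = wf_t, v = wf_v, params = params),
                   baseline_spikes_ms = pois(u$baseline_hz, baseline_s),
                   baseline_s = baseline_s, stim_s = stim_s,
                   conditions = conds,
                   truth = list(class = u$class, modulation = u$modulation,
                                baseline_hz = u$baseline_hz)),
              class = "unit_recording")
  })
}

#' Write a recorded session as spike-time CSVs plus a JSON sidecar
#'
#' Emits `baseline.csv` and one `stim_<amplitude>.csv` (columns
#' `unit_id,t_ms`), and `session.json` holding waveforms, pulse times and
#' ground truth for closed-loop tests.
#'
#' @param session List of `unit_recording` objects.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- do.call(rbind, lapply(session, function(u) {
    if (!length(u$baseline_spikes_ms)) return(NULL)
    data.frame(unit_id = u$unit_id, t_ms = u$baseline_spikes_ms)
  }))
  utils::write.csv(base, file.path(dir, "baseline.csv"), row.names = FALSE)
  amps <- names(session[[1]]$conditions)
  for (a in amps) {
    df <- do.call(rbind, lapply(session, function(u) {
      s <- u$conditions[[a]]$spikes_ms
      if (!length(s)) return(NULL)
      data.frame(unit_id = u$unit_id, t_ms = s)
    }))
    utils::write.csv(df, file.path(dir, paste0("stim_", a, ".csv")),
                     row.names = FALSE)
  }
  side <- lapply(session, function(u) {
    list(unit_id = u$unit_id, class = u$truth$class,
         baseline_hz = u$truth$baseline_hz,
         modulation = as.list(u$truth$modulation),
         waveform_t_ms = u$waveform$t_ms, waveform_v = u$waveform$v,
         pulse_times_ms = lapply(u$conditions, function(cc) cc$pulse_times_ms))
  })
  jsonlite::write_json(side, file.path(dir, "session.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
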