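#' Experiment configuration
#'
#' Bundles the stimulation grid and simulation scales for the in-silico
#' experiments. Amplitudes are expressed as percent of the model motor
#' threshold (MT, default 100 uA; perception threshold is `pt_fraction` x MT).
#' The default durations are acceptance scale (6 s with stimulation over the
#' last 3 s); `paper_scale = TRUE` restores the 18 s / 10 s protocol.
#'
#' @param frequencies_hz,pulse_widths_us Setting grids (paired per setting via
#'   `settings`; defaults to the seven approximately charge-matched
#'   frequency/pulse-width combinations).
#' @param amplitudes_pct_mt Amplitude grid in percent MT.
#' @param mt_ua Model motor threshold (uA, default 100).
#' @param pt_fraction Perception threshold as a fraction of MT (default 0.5).
#' @param targeting Targeting conditions to run.
#' @param n_maps Number of dorsal column map seeds (default 25).
#' @param n_pain_states Number of pain states (default 30).
#' @param duration_s,stim_onset_s Simulation windows.
#' @param paper_scale Use the full 18 s / 10 s protocol.
#' @param lib_max_sim_s Longest explicitly simulated library train (s).
#' @param seed Base seed.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(frequencies_hz = c(30, 50, 90, 90, 130, 150, 200),
                              pulse_widths_us = c(450, 300, 225, 275, 210, 200, 200),
                              amplitudes_pct_mt = c(20, 40, 60, 80),
                              mt_ua = 100, pt_fraction = 0.5,
                              targeting = c("center", "mix", "surround"),
                              n_maps = 25, n_pain_states = 30,
                              duration_s = 6, stim_onset_s = 3,
                              paper_scale = FALSE,
                              lib_max_sim_s = 1.0, seed = 1L) {
  stopifnot(length(frequencies_hz) == length(pulse_widths_us),
            pt_fraction > 0, pt_fraction < 1, mt_ua > 0)
  if (paper_scale) { duration_s <- 18; stim_onset_s <- 8 }
  structure(list(settings = data.frame(freq = frequencies_hz,
                                       pw = pulse_widths_us),
                 amplitudes_pct_mt = amplitudes_pct_mt,
                 mt_ua = mt_ua, pt_fraction = pt_fraction,
                 targeting = targeting, n_maps = n_maps,
                 n_pain_states = n_pain_states,
                 duration_s = duration_s, stim_onset_s = stim_onset_s,
                 lib_max_sim_s = lib_max_sim_s, seed = seed),
            class = "experiment_config")
}

#' Build the response library needed by a set of maps
#'
#' Enumerates the unique (position, snapped diameter) pairs over the maps and
#' simulates only those, for the requested settings and amplitudes.
#'
#' @param maps List of `dc_map` objects (sharing one position grid).
#' @param grid The position grid used to sample the maps.
#' @param settings data.frame with columns `freq`, `pw`.
#' @param amplitudes_ua Amplitudes in uA.
#' @param stim_duration_s Stimulation duration each entry must cover.
#' @param field,electrode Volume conductor and electrode.
#' @param ... Passed to [build_response_library()] (e.g. `max_sim_s`).
#' @return A `response_library`.
#' @export
build_map_library <- function(maps, grid, settings, amplitudes_ua,
                              stim_duration_s, field = field_model(),
                              electrode = electrode_pair(), ...) {
  fibers <- do.call(rbind, lapply(maps, function(m) {
    m$fibers[, c("index", "x_mm", "y_mm", "diameter_um")]
  }))
  fibers$diameter_um <- snap_diameter(fibers$diameter_um)
  libs <- list()
  for (s in seq_len(nrow(settings))) {
    for (idx in unique(fibers$index)) {
      sub <- fibers[fibers$index == idx, ]
      pos <- grid[grid$index == idx, c("index", "x_mm", "y_mm")]
      diams <- unique(sub$diameter_um)
      libs[[length(libs) + 1L]] <- build_response_library(
        pos, diams, settings$freq[s], settings$pw[s], amplitudes_ua,
        stim_duration_s, field, electrode, ...)
    }
  }
  merge_libraries(libs)
}

# combine libraries built over disjoint grid chunks
merge_libraries <- function(libs) {
  out <- libs[[1]]
  if (length(libs) > 1) {
    for (l in libs[-1]) {
      for (k in ls(l$entries)) assign(k, get(k, envir = l$entries),
                                      envir = out$entries)
      out$thresholds <- rbind(out$thresholds, l$thresholds)
      out$grids$positions <- unique(rbind(out$grids$positions,
                                          l$grids$positions))
      out$grids$diameters <- sort(unique(c(out$grids$diameters,
                                           l$grids$diameters)))
      out$grids$freqs <- sort(unique(c(out$grids$freqs, l$grids$freqs)))
      out$grids$pws <- sort(unique(c(out$grids$pws, l$grids$pws)))
      out$grids$amplitudes <- sort(unique(c(out$grids$amplitudes,
                                            l$grids$amplitudes)))
      out$failures <- c(out$failures, l$failures)
    }
    out$thresholds <- unique(out$thresholds)
  }
  out
}

# one network run: returns the zone-1 WDR rate change. `baseline_state`
# (a checkpoint at the stimulation onset) avoids re-integrating the
# pre-stimulation epoch, which is identical across amplitudes for one seed.
run_wdr_trial <- function(map, library, freq, pw, amp_ua, afferents,
                          net, duration_s, stim_onset_s,
                          baseline_start_s = 0.5, baseline_state = NULL) {
  dc <- map_to_network_inputs(map, library, freq, pw, amp_ua)
  sim <- simulate_network(net, afferents, dc, duration_s, stim_onset_s,
                          resume_state = baseline_state)
  ch <- wdr_change(sim$spikes[[3]], c(baseline_start_s, stim_onset_s),
                   c(stim_onset_s, duration_s))
  c(baseline_hz = ch$baseline_hz, stim_hz = ch$stim_hz,
    raw_delta_hz = ch$raw_delta_hz, norm_delta = ch$norm_delta)
}

# checkpoint of the unstimulated network at the stimulation onset
baseline_checkpoint <- function(net, afferents, stim_onset_s, dt_ms = 0.0125) {
  simulate_network(net, afferents, NULL, stim_onset_s, stim_onset_s,
                   dt_ms = dt_ms, return_state = TRUE)$state
}

#' Amplitude sweep across map seeds and targeting conditions
#'
#' For each map seed and targeting condition, simulates the baseline and
#' stimulation epochs at every amplitude and records the raw and normalized
#' change in the zone-1 WDR firing rate. Deterministic given the seeds.
#'
#' @param config An [experiment_config()].
#' @param setting Row index into `config$settings` (default the 90 Hz/225 us
#'   setting if present, else 1).
#' @param library Optional prebuilt `response_library`; built on demand
#'   otherwise.
#' @param pain A [pain_state()] or NULL.
#' @param field,electrode Volume conductor and electrode.
#' @param grid Position grid (default [dc_fiber_grid()]).
#' @param progress Print progress lines.
#' @return data.frame: map_seed, targeting, amplitude_pct_mt, amplitude_ua,
#'   baseline_hz, stim_hz, raw_delta_hz, norm_delta. The library used is in
#'   attribute `"library"`.
#' @export
run_amplitude_sweep <- function(config = experiment_config(), setting = NULL,
                                library = NULL, pain = NULL,
                                field = field_model(),
                                electrode = electrode_pair(),
                                grid = dc_fiber_grid(), progress = FALSE) {
  st <- config$settings
  if (is.null(setting)) {
    setting <- which(st$freq == 90 & st$pw == 225)[1]
    if (is.na(setting)) setting <- 1L
  }
  freq <- st$freq[setting]; pw <- st$pw[setting]
  amps_ua <- config$amplitudes_pct_mt / 100 * config$mt_ua
  tiers <- rank_positions(grid)$tiers
  rows <- list()
  net <- build_network(pain)
  maps_by_tg <- lapply(config$targeting, function(tg) {
    sample_maps(tiers, tg, n_maps = config$n_maps,
                seed_base = config$seed * 1000L)
  })
  names(maps_by_tg) <- config$targeting
  if (is.null(library)) {
    library <- build_map_library(do.call(c, maps_by_tg), grid,
                                 data.frame(freq = freq, pw = pw),
                                 amps_ua,
                                 config$duration_s - config$stim_onset_s,
                                 field, electrode,
                                 max_sim_s = config$lib_max_sim_s)
  }
  aff_cache <- list(); ckpt_cache <- list()
  for (tg in config$targeting) {
    maps <- maps_by_tg[[tg]]
    for (mi in seq_along(maps)) {
      key <- as.character(mi)
      if (is.null(aff_cache[[key]])) {
        aff_cache[[key]] <- gen_pain_afferents(
          3, config$duration_s, seed = config$seed * 1000L + mi,
          extra_nociceptor_fraction_surround =
            if (is.null(pain)) 0 else pain$extra_nociceptor_fraction)
        ckpt_cache[[key]] <- baseline_checkpoint(net, aff_cache[[key]],
                                                 config$stim_onset_s)
      }
      aff <- aff_cache[[key]]; ckpt <- ckpt_cache[[key]]
      for (ai in seq_along(amps_ua)) {
        r <- run_wdr_trial(maps[[mi]], library, freq, pw, amps_ua[ai], aff,
                           net, config$duration_s, config$stim_onset_s,
                           baseline_state = ckpt)
        rows[[length(rows) + 1L]] <- data.frame(
          map_seed = maps[[mi]]$seed, targeting = tg,
          amplitude_pct_mt = config$amplitudes_pct_mt[ai],
          amplitude_ua = amps_ua[ai], t(r))
        if (progress) message(sprintf("%s seed %d amp %g%%: d=%.2f Hz",
                                      tg, maps[[mi]]$seed,
                                      config$amplitudes_pct_mt[ai],
                                      r[["raw_delta_hz"]]))
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "library") <- library
  attr(out, "manifest") <- run_manifest(config, pain = pain,
                                        setting = c(freq = freq, pw = pw))
  out
}

# provenance manifest: configuration, seeds, package version and a checksum
# of the configuration object; re-running a manifest reproduces outputs
# bit-exactly (all randomness is seed-derived)
run_manifest <- function(config, ...) {
  payload <- list(config = config, ...)
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(payload, tf)
  list(package = "scsdh",
       version = as.character(utils::packageVersion("scsdh")),
       seed = config$seed,
       config = payload,
       config_md5 = unname(tools::md5sum(tf)),
       created = format(Sys.time(), tz = "UTC"))
}

#' Frequency/pulse-width parameter grid with per-seed optimal setting
#'
#' Runs the amplitude sweep for every setting in the grid and tallies, per map
#' seed, the setting producing the greatest WDR suppression at any amplitude
#' within the therapeutic range (30-60% MT by default).
#'
#' @param config An [experiment_config()].
#' @param therapeutic_pct_mt Range of amplitudes eligible for the tally.
#' @param targeting Targeting condition (default "surround").
#' @param ... Passed to [run_amplitude_sweep()].
#' @return List with `curves` (all rows) and `tally` (data.frame setting,
#'   n_best, fraction).
#' @export
run_parameter_grid <- function(config = experiment_config(),
                               therapeutic_pct_mt = c(30, 60),
                               targeting = "surround", ...) {
  cfg <- config
  cfg$targeting <- targeting
  rows <- list()
  for (s in seq_len(nrow(config$settings))) {
    sw <- run_amplitude_sweep(cfg, setting = s, ...)
    sw$freq <- config$settings$freq[s]; sw$pw <- config$settings$pw[s]
    rows[[s]] <- sw
  }
  curves <- do.call(rbind, rows)
  inr <- curves[curves$amplitude_pct_mt >= therapeutic_pct_mt[1] &
                curves$amplitude_pct_mt <= therapeutic_pct_mt[2], ]
  tal <- lapply(split(inr, inr$map_seed), function(d) {
    best <- d[which.min(d$raw_delta_hz), ]
    sprintf("%g/%g", best$freq, best$pw)
  })
  tt <- table(unlist(tal))
  tally <- data.frame(setting = names(tt), n_best = as.integer(tt),
                      fraction = as.numeric(tt) / length(tal))
  list(curves = curves, tally = tally)
}

#' Suppression curves across sampled pain states
#'
#' Re-runs the amplitude sweep for each Latin-hypercube pain state and reports
#' the across-state dispersion.
#'
#' @param config An [experiment_config()].
#' @param states Optional list of [pain_state()]; sampled via
#'   [sample_pain_states()] otherwise.
#' @param ... Passed to [run_amplitude_sweep()].
#' @return List with `curves` (rows carrying `state_id`) and
#'   `state_variance` (per amplitude, variance of the per-state median raw
#'   change).
#' @export
run_pain_state_sweep <- function(config = experiment_config(), states = NULL,
                                 ...) {
  if (is.null(states)) {
    states <- sample_pain_states(config$n_pain_states, seed = config$seed)
  }
  rows <- list()
  for (i in seq_along(states)) {
    sw <- tryCatch(run_amplitude_sweep(config, pain = states[[i]], ...),
                   error = function(e) {
                     warning("pain state ", i, " failed: ",
                             conditionMessage(e))
                     NULL
                   })
    if (is.null(sw)) next
    sw$state_id <- i
    rows[[length(rows) + 1L]] <- sw
  }
  curves <- do.call(rbind, rows)
  med <- stats::aggregate(raw_delta_hz ~ amplitude_pct_mt + state_id,
                          curves, stats::median)
  sv <- stats::aggregate(raw_delta_hz ~ amplitude_pct_mt, med, stats::var)
  names(sv)[2] <- "var_across_states"
  list(curves = curves, state_variance = sv)
}

#' Filtered WDR firing rate around stimulation onset
#'
#' Causal exponential filter of the zone-1 WDR spike train and the time to
#' half-maximal suppression relative to the pre-stimulation rate.
#'
#' @param sim A [simulate_network()] result.
#' @param tau_s Filter time constant (default 1 s).
#' @param dt_s Output sampling (default 0.05 s).
#' @return List with `time_s`, `rate_hz`, `time_to_half_suppression_s`
#'   (NA when stimulation does not halve the rate).
#' @export
run_onset_timecourse <- function(sim, tau_s = 1, dt_s = 0.05) {
  spk_s <- sim$spikes[[3]] / 1000
  tt <- seq(0, sim$duration_s, by = dt_s)
  lam <- 1 / tau_s
  rate <- numeric(length(tt))
  r <- 0; tprev <- 0; si <- 1
  spk_s <- sort(spk_s)
  for (i in seq_along(tt)) {
    t1 <- tt[i]
    while (si <= length(spk_s) && spk_s[si] <= t1) {
      r <- r * exp(-lam * (spk_s[si] - tprev)) + lam
      tprev <- spk_s[si]; si <- si + 1
    }
    rate[i] <- r * exp(-lam * (t1 - tprev))
  }
  pre <- mean(rate[tt >= max(0.5, sim$stim_onset_s - 2) & tt < sim$stim_onset_s])
  post <- rate[tt >= sim$stim_onset_s]
  tpost <- tt[tt >= sim$stim_onset_s]
  hit <- which(post <= pre / 2)
  list(time_s = tt, rate_hz = rate,
       pre_rate_hz = pre,
       time_to_half_suppression_s =
         if (length(hit)) tpost[hit[1]] - sim$stim_onset_s else NA_real_)
}
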