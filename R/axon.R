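#' Simulated dorsal column fiber diameter grid
#'
#' The diameter grid over which axon responses are simulated: 2.2 to 6 um in
#' 0.2-um increments and 6 to 8 um in 0.5-um increments.
#' @return Numeric vector of diameters (um).
#' @export
dc_diameter_grid <- function() {
  c(seq(2.2, 6, by = 0.2), seq(6.5, 8, by = 0.5))
}

# snap a diameter to the nearest simulated grid value
snap_diameter <- function(d, grid = dc_diameter_grid()) {
  grid[max.col(-abs(outer(d, grid, "-")), ties.method = "first")]
}

#' Build an axon at a dorsal column position
#'
#' Straight rostrocaudal axon centered over the cathodic contact.
#'
#' @param x_mm,y_mm Position within the dorsal columns (mm).
#' @param fiber_d_um Fiber diameter (um).
#' @param n_nodes Nodes of Ranvier (default 21).
#' @param z_center_mm Rostrocaudal center (default -1 mm, over the cathode).
#' @param membrane Membrane overrides, see [build_axon()].
#' @return An `axon_model`.
#' @export
axon_at_position <- function(x_mm, y_mm, fiber_d_um, n_nodes = 21,
                             z_center_mm = -1, membrane = list()) {
  geo <- mrg_geometry(fiber_d_um)
  total_um <- (n_nodes - 1) * geo$deltax + geo$node_len
  traj <- rbind(c(x_mm, y_mm, z_center_mm - total_um / 2000),
                c(x_mm, y_mm, z_center_mm + total_um / 2000 + 0.01))
  build_axon(fiber_d_um, traj, n_nodes = n_nodes, membrane = membrane)
}

# unit-current extracellular potential at each compartment center
axon_phi_unit <- function(axon, field, electrode) {
  as.numeric(potential_at(field, electrode, axon$coords_mm, current_ua = 1))
}

#' Simulate an axon's response to a stimulation pulse train
#'
#' Extracellular potentials from the volume conductor are applied to every
#' compartment and the double-cable membrane equations are integrated with a
#' second-order implicit (Crank-Nicolson) scheme. A spike is an upward
#' crossing of -20 mV with a 1-ms lockout; the recording node is the most
#' rostral node of Ranvier.
#'
#' @param axon An `axon_model`.
#' @param field A [field_model()].
#' @param electrode An [electrode_pair()].
#' @param train A [pulse_train_spec()].
#' @param dt_ms Integration step (default 0.0125 ms).
#' @param settle_ms Unstimulated settling time prepended before the train
#'   (default 10 ms); spike times are reported relative to the train series.
#' @return List with `spike_times_ms` (recording node), `spikes_by_node`,
#'   `pulse_times_ms`, and `diverged`.
#' @export
simulate_axon <- function(axon, field, electrode, train, dt_ms = 0.0125,
                          settle_ms = 10) {
  stopifnot(inherits(axon, "axon_model"))
  phi <- axon_phi_unit(axon, field, electrode)
  tr <- make_pulse_train(train, dt_ms)
  out <- axon_simulate_cpp(axon, phi, tr$current_ua, dt_ms, settle_ms)
  if (out$diverged) warning("axon simulation diverged (|V| > 200 mV)")
  rec <- length(out$spikes_by_node)  # most rostral node
  list(spike_times_ms = out$spikes_by_node[[rec]],
       spikes_by_node = out$spikes_by_node,
       pulse_times_ms = tr$pulse_times_ms,
       diverged = out$diverged)
}

# single biphasic pulse current series with a post-pulse observation window
single_pulse_series <- function(amplitude_ua, pulse_width_us, dt_ms,
                                post_ms = 6) {
  n_phase <- max(1L, round(pulse_width_us / 1000 / dt_ms))
  c(rep(-amplitude_ua, n_phase), rep(amplitude_ua, n_phase),
    numeric(round(post_ms / dt_ms)))
}

# spike at the recording node for a single pulse at the given amplitude?
single_pulse_response <- function(axon, phi, amplitude_ua, pulse_width_us,
                                  dt_ms, settle_ms = 10) {
  cur <- single_pulse_series(amplitude_ua, pulse_width_us, dt_ms)
  out <- axon_simulate_cpp(axon, phi, cur, dt_ms, settle_ms)
  out$spikes_by_node[[length(out$spikes_by_node)]]
}

#' Find the single-pulse activation threshold of an axon
#'
#' Bisection on the amplitude of a single symmetric biphasic pulse until the
#' bracketing amplitudes agree to the stated relative tolerance. The threshold
#' is the lowest amplitude producing a propagated spike at the recording node.
#'
#' @param axon An `axon_model`.
#' @param field,electrode Volume conductor and electrode.
#' @param pulse_width_us Phase width of the test pulse (us).
#' @param lower_ua,upper_ua Bracketing amplitudes (default 1 and 1000 uA).
#' @param rel_tol Relative tolerance (default 0.01).
#' @param dt_ms Integration step.
#' @return Threshold in uA, or `Inf` if no spike at `upper_ua` (inexcitable).
#' @export
find_activation_threshold <- function(axon, field, electrode, pulse_width_us,
                                      lower_ua = 1, upper_ua = 1000,
                                      rel_tol = 0.01, dt_ms = 0.0125) {
  phi <- axon_phi_unit(axon, field, electrode)
  fire <- function(a) length(single_pulse_response(axon, phi, a,
                                                   pulse_width_us, dt_ms)) > 0
  if (!fire(upper_ua)) return(Inf)
  if (fire(lower_ua)) return(lower_ua)
  lo <- lower_ua; hi <- upper_ua
  while ((hi - lo) / hi > rel_tol) {
    mid <- 0.5 * (lo + hi)
    if (fire(mid)) hi <- mid else lo <- mid
  }
  hi
}

# deterministic periodic extension of a stationary train response:
# repeat the pulse-aligned terminal block of the simulated window
extend_periodic <- function(spikes_ms, sim_ms, target_ms, period_ms) {
  if (sim_ms >= target_ms) return(spikes_ms[spikes_ms <= target_ms])
  n_per <- floor((sim_ms / 2) / period_ms)
  if (n_per < 1) return(spikes_ms)
  block <- n_per * period_ms
  base <- spikes_ms[spikes_ms > sim_ms - block & spikes_ms <= sim_ms]
  out <- spikes_ms
  k <- 1
  repeat {
    nxt <- base + k * block
    nxt <- nxt[nxt <= target_ms]
    if (!length(nxt)) break
    out <- c(out, nxt)
    k <- k + 1
    if (max(base) + k * block > target_ms + block) break
  }
  sort(out)
}

#' Build a library of axon responses over a stimulation grid
#'
#' For every combination of position, diameter, frequency, pulse width and
#' amplitude, simulates the axon's spike-time response and stores the
#' single-pulse activation threshold (AT). Entries are deterministic for a
#' fixed configuration. Amplitudes below AT yield empty trains (an axon silent
#' for a single pulse is silent for the train). Amplitudes above
#' `strong_drive_ratio` x AT are represented as 1:1 pulse-locked firing at the
#' single-pulse spike latency (the fully entrained regime); between AT and
#' that ratio the full train is simulated. Train simulations run for
#' `min(stim_duration_s, max_sim_s)` and are extended periodically
#' (pulse-aligned) when shorter than `stim_duration_s`.
#'
#' @param positions data.frame with columns `index`, `x_mm`, `y_mm`.
#' @param diameters Diameters to simulate (um); snapped to the simulated grid.
#' @param freqs,pws,amplitudes Stimulation grids (Hz, us, uA).
#' @param stim_duration_s Train duration represented in each entry.
#' @param field,electrode Volume conductor and electrode.
#' @param dt_ms Integration step.
#' @param n_nodes Nodes of Ranvier per axon.
#' @param max_sim_s Longest explicitly simulated train window (default Inf).
#' @param strong_drive_ratio Amplitude/AT ratio above which the entrained
#'   regime is used (default 1.6; the cable model entrains 1:1 from about
#'   1.2-1.4 x AT, so 1.6 is conservative; only applied when the pulse
#'   period is at least 3 ms).
#' @param progress Print progress lines (default FALSE).
#' @return Object of class `response_library` with `thresholds` (data.frame:
#'   `position`, `diameter_um`, `pulse_width_us`, `at_ua`) and spike-time
#'   `entries`.
#' @export
build_response_library <- function(positions, diameters, freqs, pws,
                                   amplitudes, stim_duration_s,
                                   field, electrode, dt_ms = 0.0125,
                                   n_nodes = 21, max_sim_s = Inf,
                                   strong_drive_ratio = 1.6,
                                   progress = FALSE) {
  stopifnot(nrow(positions) > 0, length(diameters) > 0, length(freqs) > 0,
            length(pws) > 0, length(amplitudes) > 0)
  diameters <- sort(unique(snap_diameter(diameters)))
  entries <- new.env(parent = emptyenv())
  thr <- list()
  failures <- list()
  for (pi in seq_len(nrow(positions))) {
    px <- positions$x_mm[pi]; py <- positions$y_mm[pi]
    pid <- positions$index[pi]
    for (d in diameters) {
      axon <- axon_at_position(px, py, d, n_nodes = n_nodes)
      phi <- axon_phi_unit(axon, field, electrode)
      for (pw in pws) {
        at <- find_activation_threshold(axon, field, electrode, pw,
                                        dt_ms = dt_ms)
        thr[[length(thr) + 1L]] <- data.frame(position = pid,
                                              diameter_um = d,
                                              pulse_width_us = pw,
                                              at_ua = at)
        for (f in freqs) {
          period_ms <- 1000 / f
          lat <- NULL
          for (a in amplitudes) {
            key <- lib_key(pid, d, f, pw, a)
            if (a < at) { assign(key, numeric(0), envir = entries); next }
            if (is.finite(at) && a > strong_drive_ratio * at &&
                period_ms >= 3) {
              spk <- single_pulse_response(axon, phi, a, pw, dt_ms)
              if (length(spk)) {
                lat <- spk[1]
                n_pulses <- floor(f * stim_duration_s)
                train <- (seq_len(n_pulses) - 1) * period_ms + lat
                assign(key, train, envir = entries)
                next
              }
            }
            sim_s <- min(stim_duration_s, max_sim_s)
            tr <- pulse_train_spec(f, pw, a, sim_s)
            res <- tryCatch(simulate_axon(axon, field, electrode, tr,
                                          dt_ms = dt_ms),
                            error = function(e) NULL)
            if (is.null(res) || isTRUE(res$diverged)) {
              failures[[length(failures) + 1L]] <- key
              assign(key, numeric(0), envir = entries)
            } else {
              spk <- extend_periodic(res$spike_times_ms, sim_s * 1000,
                                     stim_duration_s * 1000, period_ms)
              assign(key, spk, envir = entries)
            }
          }
        }
      }
      if (progress) {
        message(sprintf("library: position %s diameter %.1f done", pid, d))
      }
    }
  }
  structure(list(thresholds = do.call(rbind, thr), entries = entries,
                 grids = list(positions = positions, diameters = diameters,
                              freqs = freqs, pws = pws,
                              amplitudes = amplitudes),
                 stim_duration_s = stim_duration_s,
                 failures = unlist(failures)),
            class = "response_library")
}

lib_key <- function(position, diameter, freq, pw, amp) {
  sprintf("p%s|d%.1f|f%g|pw%g|a%g", position, diameter, freq, pw, amp)
}

#' Look up a spike train in a response library
#'
#' @param library A `response_library`.
#' @param position Position index.
#' @param diameter_um Fiber diameter (snapped to the nearest simulated value).
#' @param freq,pw,amp Stimulation setting.
#' @return Numeric vector of spike times (ms from stimulation onset).
#' @export
lib_lookup <- function(library, position, diameter_um, freq, pw, amp) {
  stopifnot(inherits(library, "response_library"))
  d <- snap_diameter(diameter_um, library$grids$diameters)
  key <- lib_key(position, d, freq, pw, amp)
  if (!exists(key, envir = library$entries, inherits = FALSE)) {
    stop("library has no entry for ", key)
  }
  get(key, envir = library$entries, inherits = FALSE)
}

#' Entrainment metrics of a stimulated spike train
#'
#' A pulse is "responded to" if at least one spike falls within
#' `(0, window_ms]` after it. Frequency prevalence is the interspike-interval
#' probability per frequency bin normalized to the stimulation frequency, and
#' bursts are runs of interspike intervals no longer than 1.5 pulse periods.
#'
#' @param spike_times_ms Spike times (ms).
#' @param pulse_times_ms Stimulation pulse times (ms), nonempty.
#' @param window_ms Response window after each pulse (default 3 ms).
#' @param freq_breaks_hz Histogram breaks for frequency prevalence.
#' @return List: `per_pulse_fire_fraction`, `mean_rate_hz`, `isi_ms`,
#'   `frequency_prevalence` (data.frame), `burst` (mean spikes/burst, counts).
#' @export
entrainment_metrics <- function(spike_times_ms, pulse_times_ms,
                                window_ms = 3,
                                freq_breaks_hz = c(0, 2^(0:9) * 2)) {
  if (!length(pulse_times_ms)) stop("pulse_times_ms must be nonempty")
  resp <- vapply(pulse_times_ms, function(p) {
    any(spike_times_ms > p & spike_times_ms <= p + window_ms)
  }, logical(1))
  period_ms <- if (length(pulse_times_ms) > 1) {
    stats::median(diff(pulse_times_ms))
  } else window_ms * 2
  f_stim <- 1000 / period_ms
  dur_ms <- max(pulse_times_ms) + period_ms - min(pulse_times_ms)
  isi <- diff(sort(spike_times_ms))
  prevalence <- NULL
  if (length(isi)) {
    f_inst <- 1000 / isi
    cut_id <- findInterval(f_inst, freq_breaks_hz)
    prob <- tabulate(cut_id, nbins = length(freq_breaks_hz)) / length(isi)
    centers <- c((freq_breaks_hz[-length(freq_breaks_hz)] +
                  freq_breaks_hz[-1]) / 2, freq_breaks_hz[length(freq_breaks_hz)])
    prevalence <- data.frame(freq_hz = centers,
                             prevalence = prob * f_stim / pmax(centers, 1e-9))
  }
  burst_len <- integer(0)
  if (length(isi)) {
    in_burst <- isi <= 1.5 * period_ms
    r <- rle(in_burst)
    burst_len <- r$lengths[r$values] + 1L  # spikes per burst
  }
  list(per_pulse_fire_fraction = mean(resp),
       mean_rate_hz = 1000 * length(spike_times_ms) / dur_ms,
       isi_ms = isi,
       frequency_prevalence = prevalence,
       burst = list(mean_spikes_per_burst =
                      if (length(burst_len)) mean(burst_len) else NA_real_,
                    n_bursts = length(burst_len)))
}

#' Serialize / read a response library as JSON
#'
#' Stores the threshold table, grid axes and every spike-time entry in a
#' plain-text JSON file.
#'
#' @param library A `response_library`.
#' @param path Output path.
#' @return `path` (write) or a `response_library` (read).
#' @export
write_response_library <- function(library, path) {
  stopifnot(inherits(library, "response_library"))
  keys <- ls(library$entries)
  entries <- stats::setNames(lapply(keys, function(k) {
    get(k, envir = library$entries)
  }), keys)
  jsonlite::write_json(list(thresholds = library$thresholds,
                            grids = library$grids,
                            stim_duration_s = library$stim_duration_s,
                            entries = entries),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_response_library
#' @export
read_response_library <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  entries <- new.env(parent = emptyenv())
  for (k in names(obj$entries)) {
    v <- obj$entries[[k]]
    assign(k, if (length(v)) as.numeric(v) else numeric(0), envir = entries)
  }
  structure(list(thresholds = as.data.frame(obj$thresholds),
                 entries = entries,
                 grids = list(positions = as.data.frame(obj$grids$positions),
                              diameters = obj$grids$diameters,
                              freqs = obj$grids$freqs, pws = obj$grids$pws,
                              amplitudes = obj$grids$amplitudes),
                 stim_duration_s = obj$stim_duration_s,
                 failures = NULL),
            class = "response_library")
}
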