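#' Neuron compartment geometries of the dorsal horn circuit
#'
#' Four-compartment neurons (dendrite cylinder, soma sphere, axon hillock
#' cone, axon cylinder) for the three cell classes: excitatory interneuron
#' (EX), inhibitory interneuron (IN) and wide-dynamic-range projection neuron
#' (WDR). Dimensions in um.
#'
#' @return data.frame with one row per class.
#' @export
dh_neuron_geometry <- function() {
  data.frame(
    class = c("EX", "IN", "WDR"),
    dend_diam = c(3, 3, 2.5), dend_len = c(300, 400, 350),
    soma_diam = c(25, 10, 20),
    hillock_d0 = c(2, 1, 2), hillock_d1 = c(1, 0.5, 1),
    hillock_len = c(9, 30, 9),
    axon_diam = c(1, 1, 1), axon_len = c(1000, 1000, 1000)
  )
}

#' Synaptic connection table of the dorsal horn circuit
#'
#' Within-node rows connect afferent inputs and neurons of one node;
#' `inter_node = TRUE` rows are the reciprocal connections from a node's
#' interneurons (and excitatory interneuron) to the other nodes' neurons,
#' instantiated for every ordered node pair. Conductances in nS.
#'
#' @return data.frame with columns `source`, `target`, `receptor`, `gmax_ns`,
#'   `inter_node`.
#' @export
dh_synapse_table <- function() {
  data.frame(
    source = c("Abeta", "Abeta", "Abeta", "Adelta", "Adelta",
               "C", "C", "C", "C",
               "IN", "IN", "IN", "EX", "EX",
               "IN", "IN", "IN", "EX", "EX"),
    target = c("IN", "WDR", "WDR", "WDR", "WDR",
               "EX", "EX", "EX", "WDR",
               "EX", "WDR", "WDR", "WDR", "WDR",
               "EX", "WDR", "WDR", "WDR", "WDR"),
    receptor = c("AMPA", "AMPA", "NMDA", "AMPA", "NMDA",
                 "AMPA", "NMDA", "NK1", "NK1",
                 "GABAA", "GABAA", "Glycine", "NMDA", "AMPA",
                 "GABAA", "GABAA", "Glycine", "NMDA", "AMPA"),
    gmax_ns = c(14.6, 24, 0.1, 24, 0.1,
                8, 4, 0.02, 0.014,
                5.3, 5.3, 5.3, 0.21, 0.29,
                3.66, 4.5, 4.5, 0.014, 0.14),
    inter_node = c(rep(FALSE, 14), rep(TRUE, 5))
  )
}

#' Synaptic kinetics and reversal potentials
#'
#' Double-exponential conductance time constants (rise tau1, fall tau2, ms)
#' and reversal potentials (mV) per receptor.
#'
#' @return data.frame keyed by `receptor`.
#' @export
dh_receptor_table <- function() {
  data.frame(
    receptor = c("AMPA", "NMDA", "NK1", "GABAA", "Glycine"),
    tau1_ms = c(0.1, 20, 100, 0.1, 0.1),
    tau2_ms = c(5, 100, 3000, 20, 10),
    e_syn_mv = c(0, 0, 0, -70, -70)
  )
}

#' Pain-state perturbation of the dorsal horn circuit
#'
#' Disinhibition axes representing neuropathic-pain changes: scaling of the
#' GABAergic conductance, depolarizing shift of the inhibitory reversal
#' potential (4-mV steps up to 16 mV), extra active nociceptive (Adelta/C)
#' afferents in the surround nodes, and reduced Abeta drive to the inhibitory
#' interneuron.
#'
#' @param gaba_scale GABA_A conductance multiplier, in [0.5, 1].
#' @param e_inh_shift_mv Depolarizing shift of GABA_A and glycine reversal
#'   potentials (mV); must be one of 0, 4, 8, 12, 16.
#' @param extra_nociceptor_fraction Fractional increase of active Adelta/C
#'   afferents in surround nodes, in [0, 0.5].
#' @param abeta_to_in_scale Multiplier on Abeta -> IN conductance, in [0.5, 1].
#' @return Object of class `pain_state`.
#' @export
pain_state <- function(gaba_scale = 1, e_inh_shift_mv = 0,
                       extra_nociceptor_fraction = 0, abeta_to_in_scale = 1) {
  if (gaba_scale < 0.5 || gaba_scale > 1) stop("gaba_scale must be in [0.5, 1]")
  if (!e_inh_shift_mv %in% c(0, 4, 8, 12, 16)) {
    stop("e_inh_shift_mv must be one of 0, 4, 8, 12, 16")
  }
  if (extra_nociceptor_fraction < 0 || extra_nociceptor_fraction > 0.5) {
    stop("extra_nociceptor_fraction must be in [0, 0.5]")
  }
  if (abeta_to_in_scale < 0.5 || abeta_to_in_scale > 1) {
    stop("abeta_to_in_scale must be in [0.5, 1]")
  }
  structure(list(gaba_scale = gaba_scale, e_inh_shift_mv = e_inh_shift_mv,
                 extra_nociceptor_fraction = extra_nociceptor_fraction,
                 abeta_to_in_scale = abeta_to_in_scale),
            class = "pain_state")
}

#' Membrane configuration of the dorsal horn neurons
#'
#' Channel densities (S/cm2) per compartment and passive constants. The
#' circuit's ionic inventory: Hodgkin-Huxley-type Na and delayed-rectifier K
#' on soma, hillock and axon of every neuron; an A-type K current on the IN
#' soma; and a slow Ca current plus Ca-dependent nonspecific cation (CAN)
#' current on the WDR soma supporting wind-up under repetitive C-fiber drive.
#'
#' @return Nested list of densities and constants; override entries via the
#'   `config` argument of [build_network()].
#' @export
dh_membrane_defaults <- function() {
  list(
    rho_axial = 100, cm_uf_cm2 = 1, g_leak = 4e-4, e_leak = -65,
    g_leak_in = 1e-3,  # IN: low input resistance -> summation-driven firing
    e_na = 50, e_k = -80, v_init = -65,
    gna = c(dend = 0, soma = 0.06, hillock = 0.30, axon = 0.10),
    gk = c(dend = 0, soma = 0.02, hillock = 0.06, axon = 0.03),
    in_ga_soma = 0.03,
    in_gca_soma = 3e-4, in_gkca_soma = 2e-3,  # IN adaptation (Ca-gated K)
    wdr_gca_soma = 3e-4, wdr_gcan_soma = 2.5e-4,
    ca_gain = 0.01, ca_tau_ms = 600, ca_half = 0.5,
    e_can = -20, e_kca = -90, e_ca = 80,
    nmda_vhalf = -20, nmda_slope = 8,
    synaptic_delay_ms = 0.5, internode_delay_ms = 1,
    spike_thresh_mv = -20, spike_lockout_ms = 2
  )
}

# compartment areas (um2) for one neuron class row
neuron_areas <- function(row) {
  c(dend = pi * row$dend_diam * row$dend_len,
    soma = pi * row$soma_diam^2,
    hillock = pi * (row$hillock_d0 + row$hillock_d1) / 2 * row$hillock_len,
    axon = pi * row$axon_diam * row$axon_len)
}

# axial conductances (uS) between the 4 compartments of one neuron
neuron_axial <- function(row, rho) {
  half <- function(len, diam) (rho / 100) * (len / 2) / (pi * diam^2 / 4)
  hd <- (row$hillock_d0 + row$hillock_d1) / 2
  h <- c(dend = half(row$dend_len, row$dend_diam),
         soma = half(row$soma_diam, row$soma_diam),
         hillock = half(row$hillock_len, hd),
         axon = half(row$axon_len, row$axon_diam))
  c(1 / (h["dend"] + h["soma"]),
    1 / (h["soma"] + h["hillock"]),
    1 / (h["hillock"] + h["axon"]))
}

#' Build the three-node center/surround dorsal horn network
#'
#' Instantiates three nodes (zones), each with one EX, one IN and one WDR
#' neuron, 15 Abeta, 15 Adelta and 3 C afferent input slots, all within-node
#' synaptic connections, and the reciprocal inter-node connections from each
#' node's interneurons to the other nodes' neurons. Pain-state scalars are
#' applied to the synapse table (GABA_A conductance scaling, inhibitory
#' reversal shift, Abeta -> IN scaling); the extra-nociceptor axis acts on
#' afferent generation (see [gen_pain_afferents()]).
#'
#' @param pain_state A [pain_state()] or NULL for the naive circuit.
#' @param config Named list overriding [dh_membrane_defaults()] entries.
#' @return Object of class `dh_network`.
#' @export
build_network <- function(pain_state = NULL, config = list()) {
  if (!is.null(pain_state) && !inherits(pain_state, "pain_state")) {
    stop("pain_state must be a pain_state object or NULL")
  }
  cfg <- utils::modifyList(dh_membrane_defaults(), config)
  geo <- dh_neuron_geometry()
  rec <- dh_receptor_table()

  # neurons: index (node-1)*3 + class (1 EX, 2 IN, 3 WDR)
  classes <- c("EX", "IN", "WDR")
  n_neuron <- 9L
  cm <- matrix(0, n_neuron, 4); gax <- matrix(0, n_neuron, 3)
  gna <- matrix(0, n_neuron, 4); gk <- matrix(0, n_neuron, 4)
  gleak <- matrix(0, n_neuron, 4)
  ga_a <- matrix(0, n_neuron, 4); gca <- matrix(0, n_neuron, 4)
  gcan <- matrix(0, n_neuron, 4); e_can_mv <- rep(-20, n_neuron)
  neuron_class <- character(n_neuron); neuron_node <- integer(n_neuron)
  for (node in 1:3) for (ci in 1:3) {
    idx <- (node - 1L) * 3L + ci
    row <- geo[geo$class == classes[ci], ]
    area <- neuron_areas(row)
    cm[idx, ] <- cfg$cm_uf_cm2 * 1e-5 * area  # uF/cm2 * um2 -> nF
    gax[idx, ] <- neuron_axial(row, cfg$rho_axial)
    gna[idx, ] <- cfg$gna * 1e-2 * area
    gk[idx, ] <- cfg$gk * 1e-2 * area
    gl_cls <- if (classes[ci] == "IN") cfg$g_leak_in else cfg$g_leak
    gleak[idx, ] <- gl_cls * 1e-2 * area
    if (classes[ci] == "IN") {
      ga_a[idx, 2] <- cfg$in_ga_soma * 1e-2 * area[2]
      gca[idx, 2] <- cfg$in_gca_soma * 1e-2 * area[2]
      gcan[idx, 2] <- cfg$in_gkca_soma * 1e-2 * area[2]  # Ca-gated K (AHP)
      e_can_mv[idx] <- cfg$e_kca
    }
    if (classes[ci] == "WDR") {
      gca[idx, 2] <- cfg$wdr_gca_soma * 1e-2 * area[2]
      gcan[idx, 2] <- cfg$wdr_gcan_soma * 1e-2 * area[2]
      e_can_mv[idx] <- cfg$e_can
    }
    neuron_class[idx] <- classes[ci]; neuron_node[idx] <- node
  }

  ps <- if (is.null(pain_state)) pain_state() else pain_state
  syn_rows <- dh_synapse_table()
  n_slots <- c(Abeta = 15L, Adelta = 15L, C = 3L)
  neuron_id <- function(node, cls) (node - 1L) * 3L + match(cls, classes)

  syn <- list()
  add_syn <- function(src_kind, src_id, src_node, src_label, tgt_node, tgt_cls,
                      receptor, gmax_ns, delay_ms, inter) {
    k <- rec[rec$receptor == receptor, ]
    e_syn <- k$e_syn_mv
    if (receptor %in% c("GABAA", "Glycine")) e_syn <- e_syn + ps$e_inh_shift_mv
    g <- gmax_ns
    if (receptor == "GABAA") g <- g * ps$gaba_scale
    if (src_label == "Abeta" && tgt_cls == "IN") g <- g * ps$abeta_to_in_scale
    syn[[length(syn) + 1L]] <<- data.frame(
      src_kind = src_kind, src_id = src_id, src_node = src_node,
      source = src_label, tgt_neuron = neuron_id(tgt_node, tgt_cls),
      tgt_node = tgt_node, target = tgt_cls, receptor = receptor,
      gmax_ns = g, gmax_table_ns = gmax_ns,
      tau1_ms = k$tau1_ms, tau2_ms = k$tau2_ms, e_syn_mv = e_syn,
      delay_ms = delay_ms, inter_node = inter)
  }

  for (node in 1:3) {
    for (r in seq_len(nrow(syn_rows))) {
      rw <- syn_rows[r, ]
      if (rw$inter_node) next
      if (rw$source %in% names(n_slots)) {
        # afferent slot stream ids: global stream index
        for (s in seq_len(n_slots[[rw$source]])) {
          sid <- afferent_stream_id(node, rw$source, s)
          add_syn(0L, sid, node, rw$source, node, rw$target, rw$receptor,
                  rw$gmax_ns, 0, FALSE)
        }
      } else {
        add_syn(1L, neuron_id(node, rw$source), node, rw$source, node,
                rw$target, rw$receptor, rw$gmax_ns, cfg$synaptic_delay_ms,
                FALSE)
      }
    }
  }
  for (src_node in 1:3) for (tgt_node in setdiff(1:3, src_node)) {
    for (r in which(syn_rows$inter_node)) {
      rw <- syn_rows[r, ]
      add_syn(1L, neuron_id(src_node, rw$source), src_node, rw$source,
              tgt_node, rw$target, rw$receptor, rw$gmax_ns,
              cfg$internode_delay_ms, TRUE)
    }
  }
  syn <- do.call(rbind, syn)
  # excitatory receptors on the dendrite, inhibitory on the soma
  syn$tgt_comp <- ifelse(syn$receptor %in% c("GABAA", "Glycine"), 2L, 1L)

  structure(list(
    cm_nf = cm, g_axial_us = gax, gna_us = gna, gk_us = gk,
    gleak_us = gleak, ga_a_us = ga_a, gca_us = gca, gcan_us = gcan,
    e_can_mv = e_can_mv,
    neuron_class = neuron_class, neuron_node = neuron_node,
    synapses = syn, n_slots = n_slots, config = cfg, pain_state = ps
  ), class = "dh_network")
}

# global afferent stream index: node-major, Abeta(1-15), Adelta(16-30), C(31-33)
afferent_stream_id <- function(node, class, slot) {
  base <- (node - 1L) * 33L
  off <- switch(class, Abeta = 0L, Adelta = 15L, C = 30L)
  base + off + slot
}

#' Audit table of the built network's synaptic parameters
#'
#' One row per synapse instance with conductance (as built and as tabulated),
#' kinetics and reversal potential, for programmatic comparison against the
#' published parameter tables.
#'
#' @param net A `dh_network`.
#' @return data.frame.
#' @export
network_synapse_audit <- function(net) {
  stopifnot(inherits(net, "dh_network"))
  net$synapses[, c("source", "target", "src_node", "tgt_node", "receptor",
                   "gmax_ns", "gmax_table_ns", "tau1_ms", "tau2_ms",
                   "e_syn_mv", "inter_node")]
}

#' Normalized double-exponential synaptic conductance
#'
#' g(t) = gmax * N * (exp(-(t-ts)/tau2) - exp(-(t-ts)/tau1)) summed over
#' spikes, with N chosen so a single event peaks at gmax. The synaptic
#' current is g * (V - E_syn).
#'
#' @param t_ms Evaluation times (ms).
#' @param spike_times_ms Presynaptic spike times (ms).
#' @param tau1_ms,tau2_ms Rise and fall time constants (tau2 > tau1 > 0).
#' @param gmax_ns Peak conductance per event (nS).
#' @return Conductance (nS) at `t_ms`.
#' @export
synaptic_conductance <- function(t_ms, spike_times_ms, tau1_ms, tau2_ms,
                                 gmax_ns) {
  stopifnot(tau2_ms > tau1_ms, tau1_ms > 0)
  tp <- tau1_ms * tau2_ms / (tau2_ms - tau1_ms) * log(tau2_ms / tau1_ms)
  nrm <- 1 / (exp(-tp / tau2_ms) - exp(-tp / tau1_ms))
  vapply(t_ms, function(tt) {
    dt <- tt - spike_times_ms
    dt <- dt[dt > 0]
    gmax_ns * nrm * sum(exp(-dt / tau2_ms) - exp(-dt / tau1_ms))
  }, numeric(1))
}

#' Simulate the dorsal horn network
#'
#' Integrates all nine neurons with a second-order implicit scheme at the
#' network time step, driven by afferent pain input and (optionally) dorsal
#' column spike trains merged into the Abeta slots of each zone during the
#' stimulation window. Spikes are soma upward crossings of -20 mV with a 2-ms
#' lockout.
#'
#' @param net A `dh_network`.
#' @param afferents An `afferent_bundle` from [gen_pain_afferents()] covering
#'   the full duration.
#' @param dc_inputs NULL, or a list of 3 zones, each a list of 15 spike-time
#'   vectors (ms relative to stimulation onset) as returned by
#'   [map_to_network_inputs()].
#' @param duration_s Total simulated time (default 18 s).
#' @param stim_onset_s Stimulation onset (default 8 s; stimulation stays on
#'   to the end of the simulation).
#' @param dt_ms Integration step (default 0.0125 ms).
#' @param resume_state Optional checkpoint from a previous call with
#'   `return_state = TRUE` (integration resumes bit-exactly at the
#'   checkpoint time; inputs before the checkpoint must be unchanged).
#' @param return_state Also return the full dynamic state at `duration_s`
#'   (for checkpoint/resume across the common pre-stimulation epoch).
#' @return List with `spikes` (list of 9 spike-time vectors, ms),
#'   `neuron_class`, `neuron_node`, `diverged` (logical per neuron), and
#'   `state` when requested.
#' @export
simulate_network <- function(net, afferents, dc_inputs = NULL,
                             duration_s = 18, stim_onset_s = 8,
                             dt_ms = 0.0125, resume_state = NULL,
                             return_state = FALSE) {
  stopifnot(inherits(net, "dh_network"))
  streams <- flatten_afferents(afferents)
  if (!is.null(dc_inputs)) {
    stopifnot(length(dc_inputs) == 3)
    for (z in 1:3) {
      trains <- dc_inputs[[z]]
      stopifnot(length(trains) == net$n_slots[["Abeta"]])
      for (s in seq_along(trains)) {
        if (!length(trains[[s]])) next
        if (!is.null(resume_state) &&
            any(trains[[s]] + stim_onset_s * 1000 < resume_state$t_ms)) {
          stop("dorsal column input precedes the checkpoint time")
        }
        sid <- afferent_stream_id(z, "Abeta", s)
        streams[[sid]] <- sort(c(streams[[sid]],
                                 trains[[s]] + stim_onset_s * 1000))
      }
    }
  }
  out <- dh_network_simulate_cpp(net, streams, duration_s * 1000, dt_ms,
                                 resume_state, return_state)
  res <- list(spikes = out$spikes, neuron_class = net$neuron_class,
              neuron_node = net$neuron_node, diverged = out$diverged,
              duration_s = duration_s, stim_onset_s = stim_onset_s)
  if (return_state) res$state <- out$state
  res
}

# afferent bundle (nested by node/class) -> flat list of 99 streams
flatten_afferents <- function(afferents) {
  stopifnot(inherits(afferents, "afferent_bundle"))
  streams <- vector("list", 3L * 33L)
  for (node in seq_along(afferents$nodes)) {
    nd <- afferents$nodes[[node]]
    for (cls in c("Abeta", "Adelta", "C")) {
      trains <- nd[[cls]]
      for (s in seq_along(trains)) {
        streams[[afferent_stream_id(node, cls, s)]] <- trains[[s]]
      }
    }
  }
  for (i in seq_along(streams)) if (is.null(streams[[i]])) streams[[i]] <- numeric(0)
  streams
}

#' Firing-rate change of the WDR neuron between two windows
#'
#' @param spikes_ms Spike times of one neuron (ms).
#' @param baseline_window_s,stim_window_s Two-element windows in seconds;
#'   baseline must precede the stimulation window.
#' @return List with `baseline_hz`, `stim_hz`, `raw_delta_hz` and
#'   `norm_delta` (raw / baseline; NA when the baseline rate is zero).
#' @export
wdr_change <- function(spikes_ms, baseline_window_s, stim_window_s) {
  stopifnot(length(baseline_window_s) == 2, length(stim_window_s) == 2)
  if (baseline_window_s[2] > stim_window_s[1] + 1e-9) {
    stop("baseline window must precede the stimulation window")
  }
  rate <- function(w) {
    sum(spikes_ms >= w[1] * 1000 & spikes_ms < w[2] * 1000) / diff(w)
  }
  b <- rate(baseline_window_s); s <- rate(stim_window_s)
  list(baseline_hz = b, stim_hz = s, raw_delta_hz = s - b,
       norm_delta = if (b > 0) (s - b) / b else NA_real_)
}

#' Peripheral recruitment experiment
#'
#' Models graded peripheral electrical stimulation of one receptive-field zone
#' as increasing recruitment of that zone's Abeta/Adelta afferents: at each
#' amplitude the stated fraction of the zone's afferents fires phase-locked to
#' the peripheral stimulus, and the change in the zone-1 WDR rate is reported.
#'
#' @param recruitment data.frame with columns `amplitude` and `fraction`
#'   (monotone nondecreasing, within [0, 1]).
#' @param stim_zone Zone receiving the peripheral stimulus (1-3).
#' @param afferents Background pain afferents ([gen_pain_afferents()]).
#' @param net A `dh_network` (default naive network).
#' @param stim_freq_hz Peripheral stimulus rate (default 10 Hz).
#' @param duration_s,stim_onset_s Simulation windows (defaults 6 and 3 s).
#' @param dt_ms Integration step.
#' @return data.frame: `amplitude`, `fraction`, `baseline_hz`, `stim_hz`,
#'   `raw_delta_hz`, `norm_delta` for the zone-1 WDR neuron.
#' @export
peripheral_recruitment_experiment <- function(recruitment, stim_zone,
                                              afferents, net = build_network(),
                                              stim_freq_hz = 10,
                                              duration_s = 6, stim_onset_s = 3,
                                              dt_ms = 0.0125) {
  stopifnot(all(c("amplitude", "fraction") %in% names(recruitment)))
  fr <- recruitment$fraction
  if (any(fr < 0 | fr > 1)) stop("recruitment fractions must be in [0, 1]")
  if (is.unsorted(fr)) stop("recruitment curve must be monotone nondecreasing")
  stim_ms <- seq(stim_onset_s * 1000, duration_s * 1000, by = 1000 / stim_freq_hz)
  out <- lapply(seq_len(nrow(recruitment)), function(i) {
    f <- recruitment$fraction[i]
    n_ab <- floor(f * net$n_slots[["Abeta"]])
    n_ad <- floor(f * net$n_slots[["Adelta"]])
    aff2 <- afferents
    if (n_ab > 0) {
      for (s in seq_len(n_ab)) {
        aff2$nodes[[stim_zone]]$Abeta[[s]] <-
          sort(c(aff2$nodes[[stim_zone]]$Abeta[[s]], stim_ms))
      }
    }
    if (n_ad > 0) {
      for (s in seq_len(n_ad)) {
        aff2$nodes[[stim_zone]]$Adelta[[s]] <-
          sort(c(aff2$nodes[[stim_zone]]$Adelta[[s]], stim_ms))
      }
    }
    sim <- simulate_network(net, aff2, NULL, duration_s, stim_onset_s, dt_ms)
    wdr1 <- sim$spikes[[3]]
    ch <- wdr_change(wdr1, c(0.5, stim_onset_s), c(stim_onset_s, duration_s))
    data.frame(amplitude = recruitment$amplitude[i], fraction = f,
               baseline_hz = ch$baseline_hz, stim_hz = ch$stim_hz,
               raw_delta_hz = ch$raw_delta_hz, norm_delta = ch$norm_delta)
  })
  do.call(rbind, out)
}

#' Attach dorsal column spike trains to network zone inputs
#'
#' Resolves each fiber of a dorsal column map in a response library (nearest
#' simulated diameter) and bundles the spike trains by zone, ready to merge
#' into the network's Abeta slots. Silent (subthreshold) fibers yield empty
#' trains.
#'
#' @param map A `dc_map` from [sample_map()].
#' @param library A `response_library`.
#' @param freq,pw,amp Stimulation setting (Hz, us, uA).
#' @return List of 3 zones, each a list of 15 spike-time vectors (ms from
#'   stimulation onset).
#' @export
map_to_network_inputs <- function(map, library, freq, pw, amp) {
  stopifnot(inherits(map, "dc_map"), inherits(library, "response_library"))
  if (!length(ls(library$entries))) stop("response library is empty")
  zones <- lapply(1:3, function(z) {
    fz <- map$fibers[map$fibers$zone == z, ]
    lapply(seq_len(nrow(fz)), function(i) {
      lib_lookup(library, fz$index[i], fz$diameter_um[i], freq, pw, amp)
    })
  })
  zones
}

#' Write network simulation output as spike-time CSV plus a JSON manifest
#'
#' The CSV has columns `neuron_id`, `node`, `class`, `t_ms`; the manifest
#' records the simulation windows and (when provided) seeds and stimulus
#' description.
#'
#' @param sim A [simulate_network()] result.
#' @param path Output CSV path; the manifest is written next to it with a
#'   `.json` extension.
#' @param manifest Optional named list merged into the manifest.
#' @return `path`, invisibly.
#' @export
write_network_spikes <- function(sim, path, manifest = list()) {
  rows <- do.call(rbind, lapply(seq_along(sim$spikes), function(i) {
    s <- sim$spikes[[i]]
    if (!length(s)) return(NULL)
    data.frame(neuron_id = i, node = sim$neuron_node[i],
               class = sim$neuron_class[i], t_ms = s)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  mf <- utils::modifyList(list(duration_s = sim$duration_s,
                               stim_onset_s = sim$stim_onset_s,
                               package = "scsdh",
                               version = as.character(
                                 utils::packageVersion("scsdh"))),
                          manifest)
  jsonlite::write_json(mf, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
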