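# shared fixtures; everything is generated in code

std_field <- function() field_model()
std_electrode <- function() electrode_pair()

# small axon at a fixed dorsomedial position, cached across tests
.fx <- new.env(parent = emptyenv())

fx_axon <- function(d = 4.4, x = 0.05, y = 0.05) {
  key <- sprintf("ax_%g_%g_%g", d, x, y)
  if (is.null(.fx[[key]])) .fx[[key]] <- axon_at_position(x, y, d)
  .fx[[key]]
}

fx_at <- function(d = 4.4, x = 0.05, y = 0.05, pw = 225) {
  key <- sprintf("at_%g_%g_%g_%g", d, x, y, pw)
  if (is.null(.fx[[key]])) {
    .fx[[key]] <- find_activation_threshold(fx_axon(d, x, y), std_field(),
                                            std_electrode(), pw)
  }
  .fx[[key]]
}

# a hand-constructed response library for wiring tests (no simulation)
fake_library <- function(grid, freq = 90, pw = 225, amps = c(40, 80),
                         train = function(amp) if (amp >= 80) c(5, 16) else numeric(0)) {
  entries <- new.env(parent = emptyenv())
  diams <- dc_diameter_grid()
  thr <- list()
  for (i in grid$index) for (d in diams) for (a in amps) {
    assign(scsdh:::lib_key(i, d, freq, pw, a), train(a), envir = entries)
  }
  structure(list(
    thresholds = data.frame(position = grid$index, diameter_um = 4.4,
                            pulse_width_us = pw, at_ua = 60),
    entries = entries,
    grids = list(positions = grid, diameters = diams, freqs = freq,
                 pws = pw, amplitudes = amps),
    stim_duration_s = 3, failures = NULL), class = "response_library")
}

# short afferent bundle shared by network tests
fx_afferents <- function(duration_s = 4, seed = 11) {
  key <- sprintf("aff_%g_%g", duration_s, seed)
  if (is.null(.fx[[key]])) {
    .fx[[key]] <- gen_pain_afferents(3, duration_s, seed = seed)
  }
  .fx[[key]]
}

empty_afferents <- function(duration_s = 2) {
  aff <- gen_pain_afferents(3, duration_s, seed = 1)
  aff$nodes <- lapply(aff$nodes, function(n) {
    lapply(n, function(cl) lapply(cl, function(x) numeric(0)))
  })
  aff
}

# adjusted Rand index (for planted-structure recovery)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_idx <- si * sj / n2
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}
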