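#' Optimal peristimulus histogram bin width
#'
#' Shift-averaged bin-width selection from the spike-count statistics: for
#' each candidate width the cost C(D) = (2*mean(k) - var(k)) / D^2 is computed
#' from the per-bin counts k (biased variance), averaged over several bin-grid
#' offsets, and the width minimizing the cost is returned.
#'
#' @param spike_times_ms Spike times (ms).
#' @param window_ms Two-element observation window; defaults to the spike
#'   range.
#' @param candidates_ms Candidate widths (default 30 log-spaced values in
#'   [10, 2000] ms).
#' @param n_shifts Number of bin-grid offsets to average (default 10).
#' @param fallback_ms Width returned (with a warning) for fewer than 2 spikes.
#' @return Width in ms; the cost curve is attached as attribute `"cost"`.
#' @export
optimal_binwidth <- function(spike_times_ms, window_ms = NULL,
                             candidates_ms = NULL, n_shifts = 10,
                             fallback_ms = 500) {
  if (length(spike_times_ms) < 2) {
    warning("fewer than 2 spikes; using fallback bin width")
    return(fallback_ms)
  }
  if (is.null(window_ms)) window_ms <- range(spike_times_ms)
  if (is.null(candidates_ms)) {
    candidates_ms <- exp(seq(log(10), log(2000), length.out = 30))
  }
  span <- diff(window_ms)
  cost <- vapply(candidates_ms, function(D) {
    if (span < 2 * D) return(Inf)
    shifts <- seq(0, D, length.out = n_shifts + 1)[-(n_shifts + 1)]
    mean(vapply(shifts, function(s0) {
      edges <- seq(window_ms[1] - s0, window_ms[2] + D, by = D)
      k <- tabulate(findInterval(spike_times_ms, edges),
                    nbins = length(edges) - 1)
      kb <- mean(k)
      vb <- mean((k - kb)^2)
      (2 * kb - vb) / D^2
    }, numeric(1)))
  }, numeric(1))
  out <- candidates_ms[which.min(cost)]
  attr(out, "cost") <- data.frame(width_ms = candidates_ms, cost = cost)
  out
}

# bins overlapped by stimulation blanking windows beyond a fraction threshold
artifact_bins <- function(edges, pulse_times_ms, blank_ms, max_fraction) {
  if (!length(pulse_times_ms) || blank_ms <= 0) {
    return(logical(length(edges) - 1))
  }
  nb <- length(edges) - 1
  blanked <- numeric(nb)
  D <- diff(edges)[1]
  for (p in pulse_times_ms) {
    lo <- p; hi <- p + blank_ms
    i0 <- max(1, findInterval(lo, edges)); i1 <- min(nb, findInterval(hi, edges))
    if (i0 > nb || i1 < 1) next
    for (i in i0:i1) {
      blanked[i] <- blanked[i] + max(0, min(hi, edges[i + 1]) - max(lo, edges[i]))
    }
  }
  blanked / D > max_fraction
}

#' Responder test for one unit and one stimulation condition
#'
#' Bins the stimulation window at the (optimal or supplied) bin width,
#' z-scores each stimulation bin against the mean and SD of baseline bin
#' counts at the same width, and classifies the unit as a responder when three
#' or more consecutive bins reach |z| >= 1.96. Bins contaminated by
#' stimulation artifacts (blanking-window overlap above `artifact_fraction`)
#' are omitted together with the corresponding baseline bins for a direct
#' bin-to-bin comparison. Zero baseline variance falls back to the Poisson
#' approximation (sigma = sqrt(mean)), flagged in the result.
#'
#' @param recording A `unit_recording` (see [gen_recorded_session()]).
#' @param condition Amplitude label of the condition to test.
#' @param bin_width_ms Bin width; when NULL, selected by [optimal_binwidth()]
#'   on the baseline train.
#' @param analysis_window_s Length of the stimulation window analysed
#'   (default 30 s).
#' @param z_crit Significance threshold (default 1.96).
#' @param n_consecutive Required run of significant bins (default 3).
#' @param blank_ms Artifact blanking window per pulse (default 1 ms).
#' @param artifact_fraction Blanked-time fraction above which a bin is
#'   dropped (default 0.25).
#' @return Object of class `responder_result`: bin width, z series, responder
#'   flag, direction, raw and normalized rate change.
#' @export
responder_test <- function(recording, condition, bin_width_ms = NULL,
                           analysis_window_s = 30, z_crit = 1.96,
                           n_consecutive = 3, blank_ms = 1,
                           artifact_fraction = 0.25) {
  stopifnot(inherits(recording, "unit_recording"))
  cond <- recording$conditions[[as.character(condition)]]
  if (is.null(cond)) stop("no such condition: ", condition)
  stim_dur <- min(analysis_window_s, recording$stim_s) * 1000
  base_dur <- recording$baseline_s * 1000
  if (base_dur < stim_dur) {
    stop("baseline must be at least as long as the analysed window")
  }
  if (is.null(bin_width_ms)) {
    bin_width_ms <- suppressWarnings(
      optimal_binwidth(recording$baseline_spikes_ms, c(0, base_dur)))
  }
  D <- as.numeric(bin_width_ms)
  nb <- floor(stim_dur / D)
  if (nb < n_consecutive) stop("analysis window shorter than 3 bins")
  edges <- seq(0, nb * D, by = D)
  k_stim <- tabulate(findInterval(cond$spikes_ms, edges), nbins = nb)
  # baseline statistics from every complete baseline bin at the same width
  nb_base <- max(nb, floor(base_dur / D))
  edges_base <- seq(0, nb_base * D, by = D)
  k_base <- tabulate(findInterval(recording$baseline_spikes_ms, edges_base),
                     nbins = nb_base)
  drop <- artifact_bins(edges, cond$pulse_times_ms, blank_ms,
                        artifact_fraction)
  keep <- !drop
  if (!any(keep)) stop("all bins contaminated by stimulation artifacts")
  # drop the phase-matched baseline bins for a direct bin-to-bin comparison
  keep_base <- !(((seq_len(nb_base) - 1) %% nb) + 1) %in% which(drop)
  mu <- mean(k_base[keep_base]); sg <- stats::sd(k_base[keep_base])
  poisson_fallback <- FALSE
  if (!is.finite(sg) || sg == 0) {
    sg <- sqrt(max(mu, .Machine$double.eps))
    poisson_fallback <- TRUE
  }
  z <- rep(NA_real_, nb)
  z[keep] <- (k_stim[keep] - mu) / sg
  sig <- !is.na(z) & abs(z) >= z_crit
  r <- rle(sig)
  responder <- any(r$lengths[r$values] >= n_consecutive)
  direction <- if (!responder) NA_character_ else {
    if (sum(z[sig]) > 0) "excited" else "inhibited"
  }
  base_rate <- sum(k_base[keep_base]) / (sum(keep_base) * D / 1000)
  stim_rate <- sum(k_stim[keep]) / (sum(keep) * D / 1000)
  structure(list(unit_id = recording$unit_id, condition = condition,
                 bin_width_ms = D, z = z, responder = responder,
                 direction = direction,
                 raw_delta_hz = stim_rate - base_rate,
                 norm_delta = if (base_rate > 0)
                   (stim_rate - base_rate) / base_rate else NA_real_,
                 baseline_hz = base_rate, stim_hz = stim_rate,
                 poisson_fallback = poisson_fallback,
                 dropped_bins = which(drop)),
            class = "responder_result")
}

#' Responder table over a session
#'
#' Runs [responder_test()] for every unit and amplitude.
#'
#' @param session List of `unit_recording` objects.
#' @param amplitudes Amplitude labels (default: all conditions of the first
#'   unit).
#' @param ... Passed to [responder_test()].
#' @return data.frame, one row per unit x amplitude.
#' @export
responder_table <- function(session, amplitudes = NULL, ...) {
  if (is.null(amplitudes)) amplitudes <- names(session[[1]]$conditions)
  do.call(rbind, lapply(session, function(u) {
    do.call(rbind, lapply(amplitudes, function(a) {
      r <- responder_test(u, a, ...)
      data.frame(unit_id = u$unit_id, condition = a,
                 bin_width_ms = r$bin_width_ms, responder = r$responder,
                 direction = ifelse(is.na(r$direction), "", r$direction),
                 raw_delta_hz = r$raw_delta_hz, norm_delta = r$norm_delta,
                 baseline_hz = r$baseline_hz)
    }))
  }))
}

#' Normalize per-amplitude rate changes to [-1, 1]
#'
#' Divides by the largest absolute change so the largest change maps to +1
#' (excitatory) or -1 (inhibitory); an all-zero vector is returned unchanged.
#'
#' @param deltas Numeric vector of rate changes.
#' @return Normalized vector.
#' @export
normalize_responses <- function(deltas) {
  m <- max(abs(deltas))
  if (m == 0) return(deltas)
  deltas / m
}

#' Inclusion filter for clustering analyses
#'
#' Retains units with baseline firing rate of at least `min_rate_hz` that are
#' responders at one or more amplitudes.
#'
#' @param responders data.frame from [responder_table()].
#' @param min_rate_hz Minimum baseline rate (default 1.5 Hz).
#' @return Integer vector of retained unit ids.
#' @export
inclusion_filter <- function(responders, min_rate_hz = 1.5) {
  by_unit <- split(responders, responders$unit_id)
  keep <- vapply(by_unit, function(d) {
    mean(d$baseline_hz) >= min_rate_hz && any(d$responder)
  }, logical(1))
  as.integer(names(by_unit))[keep]
}

# fuzzy c-means with fixed fuzzifier, tolerance and seeded restarts
fcm <- function(x, k, m = 2, iter_max = 500, tol = 1e-5, nstart = 10,
                seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  best <- NULL
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  for (st in seq_len(nstart)) {
    set.seed(seed + st)
    u <- matrix(stats::runif(n * k), n, k)
    u <- u / rowSums(u)
    j_old <- Inf
    for (it in seq_len(iter_max)) {
      um <- u^m
      centers <- t(um) %*% x / colSums(um)
      d2 <- outer(rowSums(x^2), rep(1, k)) - 2 * x %*% t(centers) +
        outer(rep(1, n), rowSums(centers^2))
      d2[d2 < 1e-12] <- 1e-12
      u <- 1 / (d2^(1 / (m - 1)) * rowSums((1 / d2)^(1 / (m - 1))))
      j_new <- sum(u^m * d2)
      if (abs(j_old - j_new) < tol) break
      j_old <- j_new
    }
    if (is.null(best) || j_new < best$objective) {
      best <- list(membership = u, centers = centers, objective = j_new,
                   iterations = it)
    }
  }
  best$cluster <- max.col(best$membership)
  best
}

# Davies-Bouldin index on hard labels (euclidean)
davies_bouldin <- function(x, labels) {
  x <- as.matrix(x)
  ks <- sort(unique(labels))
  cent <- t(vapply(ks, function(k) colMeans(x[labels == k, , drop = FALSE]),
                   numeric(ncol(x))))
  s <- vapply(seq_along(ks), function(i) {
    xi <- x[labels == ks[i], , drop = FALSE]
    mean(sqrt(rowSums((xi - matrix(cent[i, ], nrow(xi), ncol(x),
                                   byrow = TRUE))^2)))
  }, numeric(1))
  mean(vapply(seq_along(ks), function(i) {
    max(vapply(setdiff(seq_along(ks), i), function(j) {
      (s[i] + s[j]) / sqrt(sum((cent[i, ] - cent[j, ])^2))
    }, numeric(1)))
  }, numeric(1)))
}

#' Cluster normalized response profiles
#'
#' Centers the unit x amplitude matrix, projects onto the first two principal
#' components (covariance PCA; responses are already on a common [-1, 1]
#' scale), and runs fuzzy c-means (fuzzifier 2.0, at most 500 iterations,
#' objective-improvement tolerance 1e-5, 10 seeded restarts) for each
#' candidate cluster count. Cluster-count quality is reported as the mean
#' silhouette and the Davies-Bouldin index of the hard labels.
#'
#' @param responses Numeric matrix (units x amplitudes) of normalized
#'   responses.
#' @param k_range Candidate cluster counts (default 2:6).
#' @param m Fuzzifier (default 2).
#' @param seed Seed for the fuzzy c-means restarts.
#' @return Object of class `cluster_result`: `scores` (n x 2), per-k
#'   `membership` and `labels`, `quality` (data.frame k, silhouette,
#'   davies_bouldin), `k_silhouette`, `k_davies_bouldin`.
#' @export
cluster_responses <- function(responses, k_range = 2:6, m = 2, seed = 1L) {
  responses <- as.matrix(responses)
  if (nrow(responses) < 2 * min(k_range)) {
    stop("need at least 2*k units to cluster")
  }
  pc <- stats::prcomp(responses, center = TRUE, scale. = FALSE)
  ncomp <- min(2L, ncol(pc$x))
  rank_deficient <- ncomp < 2L
  if (rank_deficient) warning("rank-deficient response matrix; using ",
                              ncomp, " component")
  scores <- pc$x[, seq_len(ncomp), drop = FALSE]
  k_range <- k_range[k_range <= nrow(responses) / 2]
  fits <- lapply(k_range, function(k) fcm(scores, k, m = m, seed = seed))
  names(fits) <- as.character(k_range)
  quality <- do.call(rbind, lapply(seq_along(k_range), function(i) {
    lab <- fits[[i]]$cluster
    sil <- if (length(unique(lab)) > 1) {
      mean(cluster::silhouette(lab, stats::dist(scores))[, 3])
    } else NA_real_
    db <- if (length(unique(lab)) > 1) davies_bouldin(scores, lab) else NA_real_
    data.frame(k = k_range[i], silhouette = sil, davies_bouldin = db)
  }))
  structure(list(
    scores = scores,
    membership = lapply(fits, `[[`, "membership"),
    labels = lapply(fits, `[[`, "cluster"),
    quality = quality,
    k_silhouette = quality$k[which.max(quality$silhouette)],
    k_davies_bouldin = quality$k[which.min(quality$davies_bouldin)],
    rank_deficient = rank_deficient
  ), class = "cluster_result")
}

#' Fit the two-Gaussian model to a mean waveform
#'
#' Nonlinear least squares of V(x) = a1 exp(-((x-b1)/c1)^2) +
#' a2 exp(-((x-b2)/c2)^2) with multiple starts from peak/trough heuristics.
#' Returns the fitted parameters with lobes ordered by time, the residual
#' norm, and shape features used for classification (signed lobe amplitude
#' ratio, lobe widths, inter-lobe interval).
#'
#' @param t_ms Sample times (ms), >= 20 samples.
#' @param v Waveform samples.
#' @param n_starts Number of starting points (default 5).
#' @return Object of class `waveform_fit`; `unclassifiable` is TRUE when no
#'   start converges or the waveform is flat.
#' @export
fit_waveform <- function(t_ms, v, n_starts = 5) {
  stopifnot(length(t_ms) == length(v))
  if (length(v) < 20) stop("waveform must have at least 20 samples")
  flat <- structure(list(params = c(a1 = 0, b1 = NA, c1 = NA,
                                    a2 = 0, b2 = NA, c2 = NA),
                         rss = sum(v^2), features = NULL,
                         unclassifiable = TRUE),
                    class = "waveform_fit")
  if (max(abs(v)) < 10 * .Machine$double.eps || stats::sd(v) == 0) {
    return(flat)
  }
  ipk <- which.max(v); itr <- which.min(v)
  span <- diff(range(t_ms))
  starts <- list(
    c(a1 = v[ipk], b1 = t_ms[ipk], c1 = span / 10,
      a2 = v[itr], b2 = t_ms[itr], c2 = span / 8),
    c(a1 = v[ipk], b1 = t_ms[ipk], c1 = span / 20,
      a2 = v[itr], b2 = t_ms[itr], c2 = span / 20),
    c(a1 = v[ipk], b1 = t_ms[ipk], c1 = span / 6,
      a2 = v[itr], b2 = t_ms[itr], c2 = span / 4),
    c(a1 = v[ipk], b1 = t_ms[ipk], c1 = span / 10,
      a2 = -0.1 * v[ipk], b2 = t_ms[ipk] + span / 5, c2 = span / 6),
    c(a1 = max(v), b1 = t_ms[ipk], c1 = span / 12,
      a2 = min(v), b2 = t_ms[itr], c2 = span / 12)
  )[seq_len(n_starts)]
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        v ~ a1 * exp(-((t_ms - b1) / c1)^2) + a2 * exp(-((t_ms - b2) / c2)^2),
        start = as.list(s),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(coef = stats::coef(fit), rss = rss)
    }
  }
  if (is.null(best)) return(flat)
  p <- best$coef
  p["c1"] <- abs(p["c1"]); p["c2"] <- abs(p["c2"])
  if (p["b2"] < p["b1"]) {  # order lobes by time
    p <- c(a1 = unname(p["a2"]), b1 = unname(p["b2"]), c1 = unname(p["c2"]),
           a2 = unname(p["a1"]), b2 = unname(p["b1"]), c2 = unname(p["c1"]))
  }
  dom <- if (abs(p["a1"]) >= abs(p["a2"])) 1 else 2
  ratio <- if (dom == 1) p["a2"] / p["a1"] else p["a1"] / p["a2"]
  width_other <- unname(if (dom == 1) p["c2"] else p["c1"])
  # a lobe narrower than ~1.5 samples is a fit artifact, not a real phase
  dt_samp <- stats::median(diff(sort(t_ms)))
  if (width_other < 1.5 * dt_samp) ratio <- 0
  feats <- c(amp_ratio = unname(ratio),
             width_dom = unname(if (dom == 1) p["c1"] else p["c2"]),
             width_other = width_other,
             interlobe_ms = unname(abs(p["b2"] - p["b1"])))
  structure(list(params = p, rss = best$rss, features = feats,
                 unclassifiable = FALSE),
            class = "waveform_fit")
}

#' Train the waveform class discriminant
#'
#' Fits a quadratic Gaussian discriminant on shape features of synthetic
#' units generated from both classes (monophasic pEX, biphasic pIN), closing
#' the loop between the generator and the classifier. The returned object is
#' a plain list and can be serialized with [saveRDS()] or JSON.
#'
#' @param n_per_class Training units per class (default 150).
#' @param noise_sd Waveform noise during training (default 0.1, a
#'   signal-to-noise ratio near 10 for unit-amplitude lobes).
#' @param seed Integer seed.
#' @return Object of class `waveform_classifier`.
#' @export
train_waveform_classifier <- function(n_per_class = 150, noise_sd = 0.1,
                                      seed = 42L) {
  rows <- list()
  for (cls in c("pEX", "pIN")) {
    for (i in seq_len(n_per_class)) {
      w <- gen_unit_waveform(cls, noise_sd = noise_sd,
                             seed = seed + i + (cls == "pIN") * 10 * n_per_class)
      f <- fit_waveform(w$t_ms, w$v)
      if (f$unclassifiable) next
      rows[[length(rows) + 1L]] <- data.frame(class = cls,
                                              t(f$features))
    }
  }
  df <- do.call(rbind, rows)
  fit <- MASS::qda(class ~ amp_ratio + width_dom + width_other + interlobe_ms,
                   data = df)
  structure(list(qda = fit, features = df), class = "waveform_classifier")
}

#' Classify a unit as putatively excitatory or inhibitory
#'
#' Applies the trained discriminant to the fitted waveform features; the unit
#' is assigned pEX or pIN only when the class posterior exceeds
#' `confidence` (default 0.60), otherwise "unclassified".
#'
#' @param fit A `waveform_fit` from [fit_waveform()].
#' @param classifier A `waveform_classifier`; a package-default classifier is
#'   trained (and memoized) when NULL.
#' @param confidence Posterior threshold (default 0.6).
#' @return List with `class` ("pEX", "pIN" or "unclassified") and
#'   `confidence`.
#' @export
classify_unit <- function(fit, classifier = NULL, confidence = 0.6) {
  stopifnot(inherits(fit, "waveform_fit"))
  if (fit$unclassifiable) {
    return(list(class = "unclassified", confidence = NA_real_))
  }
  if (is.null(classifier)) classifier <- default_classifier()
  nd <- as.data.frame(t(fit$features))
  pr <- stats::predict(classifier$qda, nd)
  post <- max(pr$posterior)
  cls <- as.character(pr$class)
  list(class = if (post > confidence) cls else "unclassified",
       confidence = post)
}

.classifier_cache <- new.env(parent = emptyenv())
default_classifier <- function() {
  if (is.null(.classifier_cache$clf)) {
    .classifier_cache$clf <- train_waveform_classifier()
  }
  .classifier_cache$clf
}
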