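#' Default dorsal column fiber position lattice
#'
#' A mediolateral x dorsoventral lattice of candidate fiber positions within
#' the dorsal columns. Positions carry both physical coordinates (mm; `x_mm`
#' mediolateral from the midline, `y_mm` depth below the dorsal surface) and
#' normalized ranks `X`, `Y` in [0, 1] (0 = most medial / most dorsal) used for
#' somatotopic tier ranking.
#'
#' @param n_ml Number of mediolateral columns (default 10).
#' @param n_dv Number of dorsoventral rows (default 6).
#' @param ml_extent_mm Mediolateral extent of the lattice (default 0.05 to
#'   0.95 mm from the midline).
#' @param dv_extent_mm Dorsoventral extent (default 0.05 to 0.55 mm below the
#'   surface).
#' @return A data.frame with columns `index`, `x_mm`, `y_mm`, `X`, `Y`.
#' @export
dc_fiber_grid <- function(n_ml = 10, n_dv = 6,
                          ml_extent_mm = c(0.05, 0.70),
                          dv_extent_mm = c(0.05, 0.45)) {
  stopifnot(n_ml >= 2, n_dv >= 2)
  xs <- seq(ml_extent_mm[1], ml_extent_mm[2], length.out = n_ml)
  ys <- seq(dv_extent_mm[1], dv_extent_mm[2], length.out = n_dv)
  g <- expand.grid(x_mm = xs, y_mm = ys)
  g$X <- (match(g$x_mm, xs) - 1) / (n_ml - 1)
  g$Y <- (match(g$y_mm, ys) - 1) / (n_dv - 1)
  g$index <- seq_len(nrow(g))
  g[, c("index", "x_mm", "y_mm", "X", "Y")]
}

#' Rank fiber positions into somatotopic tiers
#'
#' Orders candidate positions by the somatotopic score Z = X^0.15 + Y^0.45
#' (X mediolateral rank, Y dorsoventral rank, both normalized to [0, 1]);
#' the 20 smallest-Z (most medial and dorsal) positions form tier 1, the next
#' 20 tier 2, the next 20 tier 3. Ties are broken by (X, then Y) ascending.
#'
#' @param grid A data.frame from [dc_fiber_grid()] (>= 60 unique positions).
#' @param tier_size Positions per tier (default 20).
#' @return A list with `tiers` (list of 3 data.frames of `tier_size` rows,
#'   ordered by Z) and the scored grid (`ranked`).
#' @export
rank_positions <- function(grid, tier_size = 20) {
  stopifnot(is.data.frame(grid), all(c("X", "Y") %in% names(grid)))
  if (anyDuplicated(grid[, c("X", "Y")])) stop("duplicate fiber positions")
  if (nrow(grid) < 3 * tier_size) {
    stop("grid must contain at least ", 3 * tier_size, " positions")
  }
  g <- grid
  g$Z <- g$X^0.15 + g$Y^0.45
  ord <- order(g$Z, g$X, g$Y)
  g <- g[ord, ]
  tiers <- lapply(0:2, function(k) g[(k * tier_size + 1):((k + 1) * tier_size), ])
  list(tiers = tiers, ranked = g)
}

# truncated-normal sampler by inverse CDF (exact, vectorized)
rtruncnorm <- function(n, mean, sd, lower, upper) {
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  stats::qnorm(pl + stats::runif(n) * (pu - pl), mean, sd)
}

# post-truncation mean/SD of Normal(mu, sigma) truncated to [lo, hi]
truncnorm_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma; b <- (hi - mu) / sigma
  z <- stats::pnorm(b) - stats::pnorm(a)
  m1 <- mu + sigma * (stats::dnorm(a) - stats::dnorm(b)) / z
  v <- sigma^2 * (1 + (a * stats::dnorm(a) - b * stats::dnorm(b)) / z -
                    ((stats::dnorm(a) - stats::dnorm(b)) / z)^2)
  c(mean = m1, sd = sqrt(v))
}

# solve pre-truncation (mu0, sigma0) so the truncated distribution has the
# requested mean and SD (moment matching; cached per parameter set)
.truncnorm_cache <- new.env(parent = emptyenv())
truncnorm_matched <- function(mean, sd, lower, upper) {
  key <- paste(mean, sd, lower, upper, sep = "|")
  if (!is.null(.truncnorm_cache[[key]])) return(.truncnorm_cache[[key]])
  obj <- function(p) {
    mm <- truncnorm_moments(p[1], exp(p[2]), lower, upper)
    (mm[1] - mean)^2 + (mm[2] - sd)^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  res <- c(mu = fit$par[1], sigma = exp(fit$par[2]))
  .truncnorm_cache[[key]] <- res
  res
}

#' Draw fiber diameters with the dorsal column diameter distribution
#'
#' Truncated normal on the simulated diameter range whose post-truncation
#' mean and SD equal the requested values (the published values describe the
#' drawn diameters, so the pre-truncation parameters are moment-matched).
#'
#' @param n Number of draws.
#' @param mean_um,sd_um Target mean and SD of the drawn diameters.
#' @param range_um Truncation range (default c(2.2, 8)).
#' @return Numeric vector of diameters (um).
#' @export
draw_fiber_diameters <- function(n, mean_um = 4.4, sd_um = 1.0,
                                 range_um = c(2.2, 8)) {
  p <- truncnorm_matched(mean_um, sd_um, range_um[1], range_um[2])
  rtruncnorm(n, p[["mu"]], p[["sigma"]], range_um[1], range_um[2])
}

#' Sample a randomized dorsal column map
#'
#' Draws 15 of the 20 positions in each somatotopic tier (without replacement),
#' wires tiers to the three dorsal horn zones according to the targeting
#' condition, and assigns each fiber a diameter from a truncated normal
#' distribution.
#'
#' Targeting conditions (tier -> zone): `center`: 1->1, 2->2, 3->3;
#' `surround`: 1->2, 2->1, 3->3; `mix`: tier 1 split 8 -> zone 1 and
#' 7 -> zone 2, tier 2 fills the complements (7 -> zone 1, 8 -> zone 2),
#' tier 3 -> zone 3.
#'
#' @param tiers The `tiers` element of [rank_positions()].
#' @param targeting `"center"`, `"mix"` or `"surround"`.
#' @param seed Integer seed; the map is reproducible given the seed.
#' @param n_per_tier Fibers sampled per tier (default 15).
#' @param diameter_mean_um,diameter_sd_um Diameter distribution (default
#'   4.4 and 1.0 um), truncated to `diameter_range_um`.
#' @param diameter_range_um Truncation bounds (default c(2.2, 8), the
#'   simulated diameter grid).
#' @return An object of class `dc_map`: data.frame `fibers` with columns
#'   `index`, `x_mm`, `y_mm`, `X`, `Y`, `tier`, `zone`, `diameter_um`, plus
#'   `targeting` and `seed`.
#' @export
sample_map <- function(tiers, targeting = c("center", "mix", "surround"),
                       seed = 1L, n_per_tier = 15,
                       diameter_mean_um = 4.4, diameter_sd_um = 1.0,
                       diameter_range_um = c(2.2, 8)) {
  targeting <- match.arg(targeting)
  stopifnot(is.list(tiers), length(tiers) == 3)
  if (any(vapply(tiers, nrow, 1L) < n_per_tier)) {
    stop("each tier must contain at least ", n_per_tier, " positions")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  picks <- lapply(tiers, function(tt) {
    tt[sort(sample.int(nrow(tt), n_per_tier)), , drop = FALSE]
  })
  zone_of <- switch(targeting,
    center   = list(`1` = 1L, `2` = 2L, `3` = 3L),
    surround = list(`1` = 2L, `2` = 1L, `3` = 3L),
    mix      = NULL)
  fibers <- do.call(rbind, lapply(1:3, function(k) {
    p <- picks[[k]]
    p$tier <- k
    if (targeting == "mix") {
      if (k == 1) {
        sel <- sample.int(n_per_tier, 8)
        p$zone <- ifelse(seq_len(n_per_tier) %in% sel, 1L, 2L)
      } else if (k == 2) {
        sel <- sample.int(n_per_tier, 7)  # complement of tier 1's 8
        p$zone <- ifelse(seq_len(n_per_tier) %in% sel, 1L, 2L)
      } else {
        p$zone <- 3L
      }
    } else {
      p$zone <- zone_of[[as.character(k)]]
    }
    p
  }))
  fibers$diameter_um <- draw_fiber_diameters(nrow(fibers), diameter_mean_um,
                                             diameter_sd_um, diameter_range_um)
  rownames(fibers) <- NULL
  structure(list(fibers = fibers, targeting = targeting, seed = seed),
            class = "dc_map")
}

# save/restore global RNG state so seeded helpers do not perturb user RNG
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Serialize / read a dorsal column map as JSON
#' @param map A `dc_map`.
#' @param path Output path.
#' @return `path` (write) or a `dc_map` (read).
#' @export
write_dc_map <- function(map, path) {
  stopifnot(inherits(map, "dc_map"))
  jsonlite::write_json(list(fibers = map$fibers, targeting = map$targeting,
                            seed = map$seed),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dc_map
#' @export
read_dc_map <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(fibers = as.data.frame(obj$fibers),
                 targeting = obj$targeting, seed = obj$seed),
            class = "dc_map")
}

#' Generate the default collection of dorsal column maps
#'
#' @param tiers Tier list from [rank_positions()].
#' @param targeting Targeting condition for all maps.
#' @param n_maps Number of maps (default 25).
#' @param seeds Optional explicit seeds (default `seq_len(n_maps)` offset by
#'   `seed_base`).
#' @param seed_base Added to 1..n_maps to form seeds (default 0).
#' @param ... Passed to [sample_map()].
#' @return List of `dc_map` objects.
#' @export
sample_maps <- function(tiers, targeting = "center", n_maps = 25,
                        seeds = NULL, seed_base = 0L, ...) {
  if (is.null(seeds)) seeds <- seed_base + seq_len(n_maps)
  lapply(seeds, function(s) sample_map(tiers, targeting, seed = s, ...))
}
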