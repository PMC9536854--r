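#' Bipolar epidural electrode pair
#'
#' Two platinum contacts on the dorsal midline, collapsed to their center
#' points (point-source approximation). Coordinates are in mm: `x` is
#' mediolateral (0 = midline), `y` is dorsoventral depth below the cord dorsal
#' surface (positive = ventral, so the epidural contacts sit at negative `y`),
#' and `z` is rostrocaudal (positive = rostral). The contacts are spaced along
#' `z` and centered on z = 0.
#'
#' @param contact_length_mm Contact length along the cord (default 2).
#' @param contact_width_mm Contact width (default 1).
#' @param center_spacing_mm Center-to-center contact spacing (default 2).
#' @param offset_mm Dorsoventral gap between contact and cord surface
#'   (default 0.15; rat dorsal epidural gap plus dura, set so sampled-fiber
#'   recruitment reproduces the modeled cord's operating points: activation
#'   onset at ~20-30% of the 100-uA motor threshold, near-surround (tier 2)
#'   recruitment beginning just above the 50%-MT perception threshold, and
#'   deep fibers inexcitable below 150 uA).
#' @param cathode Which contact is the cathode: `"caudal"` (default) or
#'   `"rostral"`. The other contact carries the equal-magnitude anodic return.
#'
#' @return An object of class `electrode_pair` with `cathode_mm` and
#'   `anode_mm` 3-vectors.
#' @export
electrode_pair <- function(contact_length_mm = 2, contact_width_mm = 1,
                           center_spacing_mm = 2, offset_mm = 0.15,
                           cathode = c("caudal", "rostral")) {
  cathode <- match.arg(cathode)
  stopifnot(center_spacing_mm > 0, contact_length_mm > 0, contact_width_mm > 0)
  half <- center_spacing_mm / 2
  caudal  <- c(0, -offset_mm, -half)
  rostral <- c(0, -offset_mm,  half)
  structure(list(contact_length_mm = contact_length_mm,
                 contact_width_mm = contact_width_mm,
                 center_spacing_mm = center_spacing_mm,
                 offset_mm = offset_mm,
                 cathode = cathode,
                 cathode_mm = if (cathode == "caudal") caudal else rostral,
                 anode_mm   = if (cathode == "caudal") rostral else caudal),
            class = "electrode_pair")
}

#' Volume conductor model for extracellular potentials
#'
#' Either an analytic infinite homogeneous anisotropic medium (white-matter
#' conductivities, longitudinal along `z`) or a rectilinear lookup table of
#' potentials per unit current (e.g., exported from a finite element model).
#' Potentials are always linear in the injected current.
#'
#' In analytic mode an insulating dorsal boundary in the electrode plane
#' (silicone backing and vertebral bone above an epidural paddle) is
#' represented by image sources; with the point sources lying in the boundary
#' plane this doubles the potential everywhere in the tissue.
#'
#' @param mode `"analytic"` or `"table"`.
#' @param sigma_long_s_m Longitudinal conductivity (S/m, default 0.6).
#' @param sigma_trans_s_m Transverse conductivity (S/m, default 0.083).
#' @param dorsal_boundary Include the insulating dorsal boundary
#'   (default TRUE).
#' @param table For table mode: list with sorted grid axes `x_mm`, `y_mm`,
#'   `z_mm` and 3-D array `phi_mv_per_ua` of dimension
#'   `c(length(x), length(y), length(z))`.
#' @return An object of class `field_model`.
#' @export
field_model <- function(mode = c("analytic", "table"),
                        sigma_long_s_m = 0.6, sigma_trans_s_m = 0.083,
                        dorsal_boundary = TRUE, table = NULL) {
  mode <- match.arg(mode)
  if (mode == "analytic") {
    stopifnot(sigma_long_s_m > 0, sigma_trans_s_m > 0)
  } else {
    stopifnot(is.list(table),
              all(c("x_mm", "y_mm", "z_mm", "phi_mv_per_ua") %in% names(table)))
    for (ax in c("x_mm", "y_mm", "z_mm")) {
      v <- table[[ax]]
      if (length(v) < 2 || any(diff(v) <= 0)) {
        stop("table grid axis ", ax, " must be strictly increasing")
      }
    }
    dm <- dim(table$phi_mv_per_ua)
    stopifnot(length(dm) == 3,
              dm[1] == length(table$x_mm),
              dm[2] == length(table$y_mm),
              dm[3] == length(table$z_mm))
  }
  structure(list(mode = mode,
                 sigma_long_s_m = sigma_long_s_m,
                 sigma_trans_s_m = sigma_trans_s_m,
                 dorsal_boundary = isTRUE(dorsal_boundary),
                 table = table),
            class = "field_model")
}

# potential of a single point source in an infinite anisotropic medium.
# I in uA, coordinates in mm, sigma in S/m -> potential in mV:
# phi = I / (4*pi*sqrt(st*sl*(x^2+y^2) + st^2*z^2))
point_source_phi <- function(dx, dy, dz, current_ua, sl, st) {
  denom <- 4 * pi * sqrt(st * sl * (dx^2 + dy^2) + st^2 * dz^2)
  if (any(denom == 0)) stop("query point coincides with a point source")
  current_ua / denom
}

#' Extracellular potential at arbitrary points
#'
#' Superposition of the cathodic (-I) and anodic (+I) point sources for the
#' analytic medium, or trilinear interpolation of a unit-current table scaled
#' by the current. `current_ua` is the pulse amplitude; the cathode injects
#' `-current_ua` and the anode `+current_ua`.
#'
#' @param field A [field_model()].
#' @param electrode An [electrode_pair()] (ignored in table mode, where the
#'   table already encodes the electrode geometry).
#' @param points Numeric matrix (n x 3) of x, y, z in mm.
#' @param current_ua Injected current (uA) of the cathodic phase.
#' @return Numeric vector of potentials (mV), one per point.
#' @export
potential_at <- function(field, electrode, points, current_ua = 1) {
  stopifnot(inherits(field, "field_model"))
  points <- rbind(points)
  stopifnot(ncol(points) == 3)
  if (field$mode == "analytic") {
    stopifnot(inherits(electrode, "electrode_pair"))
    sl <- field$sigma_long_s_m; st <- field$sigma_trans_s_m
    ca <- electrode$cathode_mm; an <- electrode$anode_mm
    phi_c <- point_source_phi(points[, 1] - ca[1], points[, 2] - ca[2],
                              points[, 3] - ca[3], -current_ua, sl, st)
    phi_a <- point_source_phi(points[, 1] - an[1], points[, 2] - an[2],
                              points[, 3] - an[3], current_ua, sl, st)
    gain <- if (field$dorsal_boundary) 2 else 1  # image sources in the plane
    unname(gain * (phi_c + phi_a))
  } else {
    unname(interp_trilinear(field$table, points) * current_ua)
  }
}

# trilinear interpolation on a rectilinear grid; errors outside the grid
interp_trilinear <- function(tab, points) {
  x <- tab$x_mm; y <- tab$y_mm; z <- tab$z_mm; phi <- tab$phi_mv_per_ua
  out <- numeric(nrow(points))
  for (i in seq_len(nrow(points))) {
    p <- points[i, ]
    if (p[1] < x[1] || p[1] > x[length(x)] ||
        p[2] < y[1] || p[2] > y[length(y)] ||
        p[3] < z[1] || p[3] > z[length(z)]) {
      stop("query point outside the field table grid")
    }
    ix <- max(1L, min(length(x) - 1L, findInterval(p[1], x)))
    iy <- max(1L, min(length(y) - 1L, findInterval(p[2], y)))
    iz <- max(1L, min(length(z) - 1L, findInterval(p[3], z)))
    fx <- (p[1] - x[ix]) / (x[ix + 1L] - x[ix])
    fy <- (p[2] - y[iy]) / (y[iy + 1L] - y[iy])
    fz <- (p[3] - z[iz]) / (z[iz + 1L] - z[iz])
    acc <- 0
    for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
      w <- (if (a) fx else 1 - fx) * (if (b) fy else 1 - fy) *
           (if (cc) fz else 1 - fz)
      acc <- acc + w * phi[ix + a, iy + b, iz + cc]
    }
    out[i] <- acc
  }
  out
}

#' Read a unit-current field table from CSV
#'
#' The CSV has columns `x_mm`, `y_mm`, `z_mm`, `phi_mv_per_ua` and must contain
#' every node of a rectilinear grid (the outer product of the unique axis
#' values). This is the import path for users with genuine finite element
#' exports.
#'
#' @param path Path to the CSV file.
#' @return A [field_model()] in table mode.
#' @export
load_field_table <- function(path) {
  df <- utils::read.csv(path)
  need <- c("x_mm", "y_mm", "z_mm", "phi_mv_per_ua")
  if (!all(need %in% names(df))) {
    stop("field table must have columns ", paste(need, collapse = ", "))
  }
  x <- sort(unique(df$x_mm)); y <- sort(unique(df$y_mm)); z <- sort(unique(df$z_mm))
  if (nrow(df) != length(x) * length(y) * length(z)) {
    stop("field table rows do not form a complete rectilinear grid")
  }
  phi <- array(NA_real_, dim = c(length(x), length(y), length(z)))
  ix <- match(df$x_mm, x); iy <- match(df$y_mm, y); iz <- match(df$z_mm, z)
  phi[cbind(ix, iy, iz)] <- df$phi_mv_per_ua
  if (anyNA(phi)) stop("field table has duplicated or missing grid nodes")
  field_model(mode = "table",
              table = list(x_mm = x, y_mm = y, z_mm = z, phi_mv_per_ua = phi))
}

#' Write a unit-current field table sampled from a field model
#'
#' Convenience exporter: evaluates `field` at the outer product of the axis
#' vectors (unit current) and writes the CSV dialect read by
#' [load_field_table()].
#'
#' @param field A [field_model()].
#' @param electrode An [electrode_pair()].
#' @param x_mm,y_mm,z_mm Strictly increasing axis vectors.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_field_table <- function(field, electrode, x_mm, y_mm, z_mm, path) {
  grid <- expand.grid(x_mm = x_mm, y_mm = y_mm, z_mm = z_mm)
  phi <- potential_at(field, electrode, as.matrix(grid), current_ua = 1)
  utils::write.csv(cbind(grid, phi_mv_per_ua = phi), path, row.names = FALSE)
  invisible(path)
}
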