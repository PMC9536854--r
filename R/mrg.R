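#' Published double-cable myelinated axon geometry table
#'
#' Diameter-dependent geometric parameters of the standard double-cable
#' mammalian myelinated axon model (node / myelin attachment (MYSA) /
#' paranode main segment (FLUT) / internode (STIN) architecture): fiber
#' diameter, internodal axon diameter, node diameter, internode spacing,
#' FLUT length and number of myelin lamellae. Node length is 1 um and MYSA
#' length 3 um for all diameters.
#'
#' @return data.frame with one row per published fiber diameter.
#' @export
mrg_parameter_table <- function() {
  data.frame(
    fiber_d  = c(5.7, 7.3, 8.7, 10.0, 11.5, 12.8, 14.0, 15.0, 16.0),
    axon_d   = c(3.4, 4.6, 5.8, 6.9, 8.1, 8.8, 9.2, 10.4, 12.7),
    node_d   = c(1.9, 2.4, 2.8, 3.3, 3.7, 4.2, 4.7, 5.0, 5.5),
    deltax   = c(500, 750, 1000, 1150, 1250, 1350, 1400, 1450, 1500),
    flut_len = c(35, 38, 40, 46, 50, 54, 56, 58, 60),
    n_lamella = c(80, 100, 110, 120, 130, 135, 140, 145, 150)
  )
}

# Interpolate a geometric parameter at fiber diameter d.
# Inside the published range: piecewise-linear between table rows.
# Below the smallest published diameter (5.7 um): linear extrapolation anchored
# at the 5.7-um row with the least-squares slope over the whole table, floored
# at a physical minimum.
mrg_interp <- function(d, values, floor_val) {
  tab <- mrg_parameter_table()
  fd <- tab$fiber_d
  out <- numeric(length(d))
  inside <- d >= fd[1]
  if (any(inside)) {
    out[inside] <- stats::approx(fd, values, xout = d[inside], rule = 2)$y
  }
  if (any(!inside)) {
    slope <- stats::cov(fd, values) / stats::var(fd)
    out[!inside] <- values[1] - slope * (fd[1] - d[!inside])
  }
  pmax(out, floor_val)
}

#' Diameter-dependent axon geometry
#'
#' @param fiber_d_um Fiber diameter in um, within [2.2, 8].
#' @return List of geometric parameters (um): `axon_d`, `node_d`, `deltax`,
#'   `flut_len`, `n_lamella`, `node_len` (1), `mysa_len` (3).
#' @export
mrg_geometry <- function(fiber_d_um) {
  stopifnot(length(fiber_d_um) == 1, is.finite(fiber_d_um))
  if (fiber_d_um < 2.2 || fiber_d_um > 8) {
    stop("fiber diameter must be within [2.2, 8] um")
  }
  tab <- mrg_parameter_table()
  list(fiber_d = fiber_d_um,
       axon_d  = mrg_interp(fiber_d_um, tab$axon_d, 1.0),
       node_d  = mrg_interp(fiber_d_um, tab$node_d, 0.5),
       deltax  = mrg_interp(fiber_d_um, tab$deltax, 50),
       flut_len = mrg_interp(fiber_d_um, tab$flut_len, 10),
       n_lamella = mrg_interp(fiber_d_um, tab$n_lamella, 20),
       node_len = 1, mysa_len = 3)
}

#' Default membrane parameters of the dorsal column axon model
#'
#' Nodal fast Na+, persistent Na+, slow K+ and linear leak channels with
#' double-cable passive internodes. Conductances in S/cm2, capacitances in
#' uF/cm2, resistivities in ohm cm, potentials in mV.
#'
#' @return Named list of membrane constants; override entries via the
#'   `membrane` argument of [build_axon()].
#' @export
axon_membrane_defaults <- function() {
  list(rho_axial = 70,      # axoplasmic resistivity
       rho_peri  = 70,      # periaxonal resistivity
       cm_node = 2, cm_axolemma = 2,
       g_mysa = 0.001, g_flut = 0.0001, g_stin = 0.0001,
       cm_myelin_lamella = 0.1, g_myelin_lamella = 0.001,
       space_node = 0.002, space_mysa = 0.002,
       space_flut = 0.004, space_stin = 0.004,  # periaxonal widths, um
       g_naf = 3.0, g_nap = 0.01, g_ks = 0.08, g_leak = 0.007,
       e_na = 50, e_k = -90, e_leak = -90, v_rest = -80)
}

# place points at arc lengths s (um) along a polyline (n x 3 matrix, mm)
polyline_points <- function(traj, s_um) {
  traj <- rbind(traj)
  if (nrow(traj) < 2) stop("trajectory needs at least two points")
  seg <- sqrt(rowSums((traj[-1, , drop = FALSE] -
                       traj[-nrow(traj), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg)) * 1000  # mm -> um
  if (max(cum) < max(s_um)) stop("trajectory shorter than the axon")
  out <- matrix(0, length(s_um), 3)
  for (j in 1:3) out[, j] <- stats::approx(cum, traj[, j], xout = s_um)$y
  out
}

#' Build a double-cable myelinated dorsal column axon model
#'
#' Constructs the compartment chain (node, MYSA, FLUT, 3 STIN, FLUT, MYSA,
#' node, ...) along a rostrocaudal trajectory, with geometry interpolated from
#' the published diameter table and membrane parameters from
#' [axon_membrane_defaults()]. The recording node is the most rostral node
#' (the last along the trajectory).
#'
#' @param fiber_d_um Fiber diameter in um, within [2.2, 8].
#' @param trajectory n x 3 matrix of polyline vertices in mm (x mediolateral,
#'   y dorsoventral, z rostrocaudal, increasing z = rostral). The axon is laid
#'   out from the first vertex.
#' @param n_nodes Number of nodes of Ranvier (default 21, minimum 21).
#' @param membrane Named list overriding [axon_membrane_defaults()] entries.
#' @return Object of class `axon_model`: compartment tables (type, length,
#'   diameter, 3-D center coordinates) plus electrical constants used by the
#'   integrator.
#' @export
build_axon <- function(fiber_d_um, trajectory, n_nodes = 21, membrane = list()) {
  if (n_nodes < 21) stop("n_nodes must be at least 21")
  geo <- mrg_geometry(fiber_d_um)
  mb <- utils::modifyList(axon_membrane_defaults(), membrane)
  stin_len <- (geo$deltax - geo$node_len - 2 * geo$mysa_len -
               2 * geo$flut_len) / 3
  if (stin_len <= 0) stop("internode too short for the paranode lengths")

  # per-internode section pattern (types: 1 node, 2 MYSA, 3 FLUT, 4 STIN)
  pat_type <- c(2L, 3L, 4L, 4L, 4L, 3L, 2L)
  pat_len <- c(geo$mysa_len, geo$flut_len, stin_len, stin_len, stin_len,
               geo$flut_len, geo$mysa_len)
  type <- c(1L, rep(c(pat_type, 1L), n_nodes - 1))
  len <- c(geo$node_len, rep(c(pat_len, geo$node_len), n_nodes - 1))
  ncomp <- length(type)
  # internal axon diameter per type: node/MYSA use node_d, FLUT/STIN axon_d
  diam <- ifelse(type <= 2, geo$node_d, geo$axon_d)
  space <- c(mb$space_node, mb$space_mysa, mb$space_flut,
             mb$space_stin)[type]

  ends <- cumsum(len)
  centers_um <- ends - len / 2
  coords <- polyline_points(trajectory, centers_um)

  area <- pi * diam * len                       # axolemma area, um2
  two_nl <- 2 * geo$n_lamella
  cm <- ifelse(type == 1, mb$cm_node, mb$cm_axolemma) * 2e-5 * area  # nF
  gpas <- c(NA, mb$g_mysa, mb$g_flut, mb$g_stin)[type] * 1e-2 * area # uS
  gpas[type == 1] <- 0                           # node leak handled ionically
  myel_area <- pi * geo$fiber_d * len
  cmy <- (mb$cm_myelin_lamella / two_nl) * 2e-5 * myel_area
  gmy <- (mb$g_myelin_lamella / two_nl) * 1e-2 * myel_area
  # nodes: periaxonal layer effectively shorted to the bath
  cmy[type == 1] <- 1e-6
  gmy[type == 1] <- 1e4

  # axial conductances between consecutive compartment centers (uS)
  r_half <- 0.7 * mb$rho_axial / 70 * (len / 2) / (pi * diam^2 / 4) # MOhm
  g_axial <- 1 / (r_half[-ncomp] + r_half[-1])
  peri_area <- pi * diam * space                  # annulus cross-section, um2
  rp_half <- 0.7 * mb$rho_peri / 70 * (len / 2) / peri_area
  g_peri <- 1 / (rp_half[-ncomp] + rp_half[-1])

  node_idx <- which(type == 1L)
  node_area <- area[node_idx]
  structure(list(
    fiber_d_um = fiber_d_um, n_nodes = n_nodes, geometry = geo,
    membrane = mb, type = type, length_um = len, diameter_um = diam,
    coords_mm = coords, cm_nf = cm, cmy_nf = cmy, gmy_us = gmy,
    gpas_us = gpas, g_axial_us = g_axial, g_peri_us = g_peri,
    node_idx = node_idx,
    g_naf_us = mb$g_naf * 1e-2 * node_area,
    g_nap_us = mb$g_nap * 1e-2 * node_area,
    g_ks_us  = mb$g_ks * 1e-2 * node_area,
    g_l_us   = mb$g_leak * 1e-2 * node_area,
    internode_length_um = geo$deltax
  ), class = "axon_model")
}

#' Straight rostrocaudal trajectory through a dorsal column position
#'
#' @param x_mm,y_mm Mediolateral and dorsoventral position (mm).
#' @param z_center_mm Rostrocaudal center of the axon (mm); default -1 places
#'   the axon midpoint over the caudal (cathodic) contact.
#' @param span_mm Total rostrocaudal extent (mm).
#' @return 2 x 3 matrix usable as `trajectory` in [build_axon()].
#' @export
straight_trajectory <- function(x_mm, y_mm, z_center_mm = -1, span_mm = 20) {
  rbind(c(x_mm, y_mm, z_center_mm - span_mm / 2),
        c(x_mm, y_mm, z_center_mm + span_mm / 2))
}
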