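#' @importFrom Matrix sparseMatrix Diagonal Cholesky solve t crossprod
#' @importFrom stats approx rexp runif setNames sd uniroot integrate
#' @importFrom utils modifyList write.csv
NULL

# Package-wide units: lengths in micrometres, time in seconds, concentrations
# in micromolar, currents in picoamperes.

#' Describe one incisure
#'
#' An incisure is a radial slit in a disk, extending inward from the rim. It
#' reflects membrane proteins diffusing on the disk surface and, being filled
#' with cytosol, provides an axial conduit for cGMP and Ca2+ between
#' interdiskal layers.
#'
#' @param angle angular position in radians, in [0, 2*pi)
#' @param depth_um radial penetration from the disk rim, um; must be positive
#'   and strictly less than the disk radius
#' @param width_um slit width, um; 0 (the default) means an idealized
#'   zero-width slit: a perfect reflecting barrier on the disk surface whose
#'   axial conductance is controlled by the geometry's effective width
#' @return a list of class `rod_incisure`
#' @export
incisure <- function(angle, depth_um, width_um = 0) {
  stopifnot(is.numeric(angle), length(angle) == 1L, is.finite(angle))
  if (!is.numeric(depth_um) || depth_um <= 0)
    stop("incisure depth must be a positive length (um)")
  if (width_um < 0) stop("incisure width must be >= 0")
  structure(list(angle = angle %% (2 * pi), depth_um = depth_um,
                 width_um = width_um), class = "rod_incisure")
}

#' Build a rod outer-segment geometry
#'
#' Presets encode the published morphologies: the mouse rod disk has radius
#' 0.685 um and a single incisure penetrating 0.31 um; the salamander disk
#' has radius 5.5 um and 23 evenly spaced incisures of depth 4.64 um, aligned
#' across the disk stack. Interdiskal layers are 14.5 nm thick.
#'
#' @param preset one of "mouse", "salamander", "custom"
#' @param ... named overrides of geometry fields (see Details)
#' @details Fields: `disk_radius_um`, `shell_um` (outer-shell thickness,
#'   i.e. the cytosolic gap between disk rims and the plasma membrane),
#'   `interdisk_um`, `disk_thickness_um`, `n_disks`, `special_disk_index`
#'   (1-based; the disk bearing the photoisomerization, central by default),
#'   `incisures` (list of [incisure()]), `incisures_aligned`,
#'   `incisure_eff_width_um` (effective slit cross-section width used for the
#'   axial cytosolic conductance of zero-width incisures).
#' @return a validated list of class `rod_geometry`
#' @export
build_geometry <- function(preset = c("mouse", "salamander", "custom"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    mouse = list(
      disk_radius_um = 0.685,
      shell_um = 0.015,
      interdisk_um = 0.0145,
      disk_thickness_um = 0.016,
      n_disks = 800L,
      special_disk_index = 400L,
      incisures = list(incisure(0, 0.31)),
      incisures_aligned = TRUE,
      incisure_eff_width_um = 0.2),
    salamander = list(
      disk_radius_um = 5.5,
      shell_um = 0.015,
      interdisk_um = 0.0145,
      disk_thickness_um = 0.016,
      n_disks = 720L,
      special_disk_index = 360L,
      incisures = evenly_spaced_incisures(23, 4.64),
      incisures_aligned = TRUE,
      incisure_eff_width_um = 0.2),
    custom = list(
      disk_radius_um = NA_real_,
      shell_um = 0.015,
      interdisk_um = 0.0145,
      disk_thickness_um = 0.016,
      n_disks = 720L,
      special_disk_index = 360L,
      incisures = list(),
      incisures_aligned = TRUE,
      incisure_eff_width_um = 0.2))
  ov <- list(...)
  unknown <- setdiff(names(ov), names(base))
  if (length(unknown))
    stop("unknown geometry fields: ", paste(unknown, collapse = ", "))
  base[names(ov)] <- ov    # plain replacement (no recursive list merge)
  g <- base
  g$preset <- preset
  class(g) <- "rod_geometry"
  validate_geometry(g)
}

#' Evenly spaced identical incisures
#'
#' @param n number of incisures
#' @param depth_um common depth, um
#' @param width_um common width, um
#' @return list of [incisure()], the first at angle 0
#' @export
evenly_spaced_incisures <- function(n, depth_um, width_um = 0) {
  lapply(seq_len(n) - 1L, function(i) incisure(2 * pi * i / n, depth_um, width_um))
}

validate_geometry <- function(g) {
  lens <- c(g$disk_radius_um, g$shell_um, g$interdisk_um, g$disk_thickness_um)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("all geometry lengths must be positive and finite")
  if (g$n_disks < 1) stop("n_disks must be >= 1")
  if (g$special_disk_index < 1 || g$special_disk_index > g$n_disks)
    stop("special_disk_index must lie within [1, n_disks]")
  if (length(g$incisures)) {
    ang <- vapply(g$incisures, `[[`, numeric(1), "angle")
    dep <- vapply(g$incisures, `[[`, numeric(1), "depth_um")
    if (any(dep >= g$disk_radius_um))
      stop("incisure depth must be strictly less than the disk radius")
    if (anyDuplicated(round(ang, 10)))
      stop("incisure angular positions must be distinct")
  }
  g
}

#' Outer-segment derived dimensions
#'
#' @param geom a [build_geometry()] object
#' @return list with `os_radius_um` (= disk radius + shell thickness),
#'   `length_um`, `shell_area_um2`, `cytosol_fraction` (interdiskal volume
#'   fraction of the disk-stack interior) and `z_repeat_um`
#' @export
os_dimensions <- function(geom) {
  zr <- geom$interdisk_um + geom$disk_thickness_um
  L <- geom$n_disks * zr
  R <- geom$disk_radius_um + geom$shell_um
  list(os_radius_um = R,
       length_um = L,
       shell_area_um2 = 2 * pi * R * L,
       cytosol_fraction = geom$interdisk_um / zr,
       z_repeat_um = zr)
}

#' Build cascade kinetic and transport parameters
#'
#' Mouse and salamander presets carry the published per-state mean durations
#' of the stepwise rhodopsin shutoff and cGMP diffusivities (mouse
#' D_cG = 120 um^2/s, salamander 160 um^2/s). Remaining constants (dark
#' levels, channel/exchanger/cyclase kinetics, surface diffusivity and decay
#' of activated PDE, hydrolytic coefficient) are package defaults drawn from
#' the rod phototransduction modeling literature; see the methods vignette.
#'
#' @param preset "mouse" or "salamander"
#' @param ... named overrides of any parameter field
#' @return a validated list of class `cascade_params`
#' @export
build_params <- function(preset = c("mouse", "salamander"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    mouse = list(
      D_cG = 120, D_Ca = 60, D_E = 0.8,
      tau_states = c(0.0159, 0.0190, 0.0238, 0.0109, 0.0123, 0.0142, 0.0167),
      nu_states = 400 * 0.85^(0:6),
      k_E = 5, beta_dark = 4.1, k_star = 0.6,
      alpha_max = 40, alpha_min = 40 / 30, K_cyc = 0.132, m_cyc = 2,
      j_dark = 14, m_cG = 3, K_cG = 20,
      K_ex = 1.5, f_Ca = 0.12, B_Ca = 20, B_cG = 2.5,
      g_dark = 3.0, Ca_dark = 0.25,
      two_transducin_mode = FALSE, second_binding_rate = 60),
    salamander = list(
      D_cG = 160, D_Ca = 60, D_E = 0.2,
      tau_states = c(0.0833, 0.1000, 0.1250, 0.0625, 0.0714, 0.0833, 0.1000),
      nu_states = 600 * 0.85^(0:6),
      k_E = 2, beta_dark = 1.0, k_star = 0.15,
      alpha_max = 25, alpha_min = 25 / 30, K_cyc = 0.160, m_cyc = 2,
      j_dark = 66, m_cG = 3, K_cG = 20,
      K_ex = 1.5, f_Ca = 0.12, B_Ca = 20, B_cG = 2.5,
      g_dark = 3.0, Ca_dark = 0.40,
      two_transducin_mode = FALSE, second_binding_rate = 25))
  ov <- list(...)
  unknown <- setdiff(names(ov), names(base))
  if (length(unknown))
    stop("unknown parameter fields: ", paste(unknown, collapse = ", "))
  base[names(ov)] <- ov
  p <- base
  p$preset <- preset
  class(p) <- "cascade_params"
  validate_params(p)
}

validate_params <- function(p) {
  rates <- c(p$D_cG, p$D_Ca, p$D_E, p$k_E, p$beta_dark, p$k_star,
             p$alpha_max, p$alpha_min, p$K_cyc, p$j_dark, p$K_cG, p$K_ex,
             p$f_Ca, p$B_Ca, p$B_cG, p$g_dark, p$Ca_dark)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all rates and constants must be finite and non-negative")
  if (length(p$tau_states) != 7L || any(p$tau_states <= 0))
    stop("tau_states must be 7 positive mean dwell times (s)")
  if (length(p$nu_states) != 7L || any(p$nu_states < 0))
    stop("nu_states must be 7 non-negative catalytic rates")
  if (any(diff(p$nu_states) > 1e-12))
    stop("nu_states must be non-increasing with phosphorylation")
  if (p$f_Ca > 1) stop("f_Ca is a fraction and must be <= 1")
  if (p$second_binding_rate <= 0) stop("second_binding_rate must be > 0")
  p
}

#' Dark current partition between channels and exchanger
#'
#' In darkness the exchanger extrudes exactly the Ca2+ entering through the
#' CNG channels (one net charge moved inward per Ca2+ extruded, two charges
#' per Ca2+ carried inward), so j_ex_dark = (f_Ca/2) * j_cng_dark and
#' j_dark = j_cng_dark + j_ex_dark.
#'
#' @param params a [build_params()] object
#' @return list with `j_cng_dark`, `j_ex_dark`, `j_ex_sat` (pA)
#' @export
dark_current_split <- function(params) {
  j_cng <- params$j_dark / (1 + params$f_Ca / 2)
  j_ex <- params$j_dark - j_cng
  j_ex_sat <- j_ex * (params$Ca_dark + params$K_ex) / params$Ca_dark
  list(j_cng_dark = j_cng, j_ex_dark = j_ex, j_ex_sat = j_ex_sat)
}

#' Idealized radius-sweep variants
#'
#' Builds a family of hypothetical rods with salamander kinetics, no
#' incisures, and disk radii given by `radii_um`, keeping the ionic channel
#' density on the outer shell constant so that the dark current scales with
#' shell area.
#'
#' @param radii_um vector of disk radii, um
#' @return a list of `list(geometry =, params =)` pairs, one per radius
#' @export
radius_sweep_presets <- function(radii_um) {
  if (length(radii_um) == 0) stop("radii_um must be a non-empty vector")
  if (any(!is.finite(radii_um)) || any(radii_um <= 0))
    stop("all radii must be positive")
  g0 <- build_geometry("salamander", incisures = list())
  p0 <- build_params("salamander")
  a0 <- os_dimensions(g0)$shell_area_um2
  lapply(radii_um, function(r) {
    g <- build_geometry("salamander", disk_radius_um = r, incisures = list())
    a <- os_dimensions(g)$shell_area_um2
    p <- build_params("salamander", j_dark = p0$j_dark * a / a0)
    list(geometry = g, params = p)
  })
}

#' @export
print.rod_geometry <- function(x, ...) {
  d <- os_dimensions(x)
  cat(sprintf("<rod_geometry> preset=%s r=%.3f um, shell=%.3f um, %d disks (L=%.1f um), %d incisure(s)\n",
              x$preset, x$disk_radius_um, x$shell_um, x$n_disks,
              d$length_um, length(x$incisures)))
  invisible(x)
}

#' @export
print.cascade_params <- function(x, ...) {
  cat(sprintf("<cascade_params> preset=%s D_cG=%g um^2/s, j_dark=%g pA, tau1=%g s\n",
              x$preset, x$D_cG, x$j_dark, x$tau_states[1]))
  invisible(x)
}

geometry_as_list <- function(g) {
  out <- unclass(g)
  out$incisures <- lapply(g$incisures, unclass)
  out
}

geometry_from_list <- function(lst) {
  lst$incisures <- lapply(lst$incisures, function(i)
    incisure(i$angle, i$depth_um, i$width_um))
  # rebuild through the constructor so invariants are revalidated
  preset <- lst$preset %||% "custom"
  lst$preset <- NULL
  do.call(build_geometry, c(list(preset = preset), lst))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
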