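# Configuration files (YAML) and run manifests.
#
# A config names a preset plus overrides; key names carry units (suffixes
# _um, _s, _uM, _pA) to prevent unit bugs. Unknown keys are rejected.

config_schema <- c("preset", "set", "n_trials", "seed", "t_end_s",
                   "geometry", "params", "position", "mesh")
geom_keys <- c("disk_radius_um", "shell_um", "interdisk_um",
               "disk_thickness_um", "n_disks", "special_disk_index",
               "incisures", "incisures_aligned", "incisure_eff_width_um")
param_keys <- c("D_cG", "D_Ca", "D_E", "tau_states", "nu_states", "k_E",
                "beta_dark", "k_star", "alpha_max", "alpha_min", "K_cyc",
                "m_cyc", "j_dark", "m_cG", "K_cG", "K_ex", "f_Ca", "B_Ca",
                "B_cG", "g_dark", "Ca_dark", "two_transducin_mode",
                "second_binding_rate")
pos_keys <- c("mode", "rho_um", "theta_rad", "tag")
mesh_keys <- c("n_rho", "n_theta", "dt", "dz0", "dz_grow", "dz_max",
               "dt_report")

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop(sprintf("config schema violation in %s: unknown key(s) %s",
                 where, paste(bad, collapse = ", ")))
}

#' Load an experiment condition from a YAML config
#'
#' @param path config file path
#' @return an [experiment_condition()] with all defaults materialized
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  check_keys(cfg, config_schema, "top level")
  preset <- cfg$preset %||% "mouse"
  gov <- cfg$geometry %||% list()
  check_keys(gov, geom_keys, "geometry")
  if (!is.null(gov$incisures)) {
    gov$incisures <- lapply(gov$incisures, function(i) {
      check_keys(i, c("angle", "depth_um", "width_um"), "incisure")
      incisure(i$angle, i$depth_um, i$width_um %||% 0)
    })
  }
  geom <- do.call(build_geometry, c(list(preset = preset), gov))
  pov <- cfg$params %||% list()
  check_keys(pov, param_keys, "params")
  params <- do.call(build_params, c(list(preset = preset), pov))
  position <- NULL
  if (!is.null(cfg$position)) {
    check_keys(cfg$position, pos_keys, "position")
    position <- place_rstar(geom, cfg$position$mode %||% "center",
                            rho = cfg$position$rho_um,
                            theta = cfg$position$theta_rad %||% 0,
                            tag = cfg$position$tag %||% "midway")
  }
  mesh <- cfg$mesh %||% list()
  check_keys(mesh, mesh_keys, "mesh")
  experiment_condition(geom, params,
                       set = cfg$set %||% "deterministic",
                       position = position,
                       n_trials = cfg$n_trials %||% 1000L,
                       seed = cfg$seed %||% 1L,
                       t_end = cfg$t_end_s %||% 1,
                       mesh = mesh)
}

#' Write a fully resolved condition back to YAML
#'
#' Emitting and reloading the file reproduces the condition exactly
#' (lossless round-trip).
#' @param cond an [experiment_condition()]
#' @param path output file
#' @export
write_config <- function(cond, path) {
  g <- cond$geometry; p <- cond$params
  cfg <- list(
    # every field is written explicitly, so the preset only names the base
    preset = cond$params$preset %||% "mouse",
    set = cond$set,
    n_trials = cond$n_trials,
    seed = cond$seed,
    t_end_s = cond$t_end,
    geometry = c(geometry_as_list(g)[geom_keys]),
    params = unclass(p)[param_keys],
    mesh = cond$mesh[mesh_keys])
  cfg$geometry$incisures <- lapply(g$incisures, unclass)
  if (!is.null(cond$position))
    cfg$position <- list(mode = "explicit",
                         rho_um = cond$position$rho,
                         theta_rad = cond$position$theta,
                         tag = cond$position$tag)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# FNV-1a hash of a serialized object (stable fingerprint without external
# dependencies)
fnv1a <- function(obj) {
  bytes <- as.integer(serialize(obj, NULL, version = 2))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", h)
}

#' Build a run manifest
#'
#' A manifest records everything needed to reproduce a run exactly: the
#' fully resolved condition, seeds, solver settings and package version,
#' plus a stable hash embedded in result files.
#'
#' @param cond an [experiment_condition()]
#' @param extra optional named list of additional entries (e.g. timings)
#' @return a `run_manifest` list with a `hash` field
#' @export
run_manifest <- function(cond, extra = list()) {
  core <- list(package = "rodspr",
               version = as.character(utils::packageVersion("rodspr")),
               set = cond$set, seed = cond$seed, n_trials = cond$n_trials,
               t_end_s = cond$t_end, mesh = cond$mesh,
               geometry = geometry_as_list(cond$geometry),
               params = unclass(cond$params))
  m <- c(core, extra)
  m$hash <- fnv1a(core)
  class(m) <- "run_manifest"
  m
}

#' Export ensemble summary curves as CSV
#' @param ens an [run_ensemble()] result
#' @param path output file
#' @export
write_ensemble_csv <- function(ens, path) {
  df <- data.frame(time_s = ens$time, mean_j = ens$mean_j, sd_j = ens$sd_j,
                   cv_j = ens$cv_j, mean_I = ens$mean_I, sd_I = ens$sd_I,
                   cv_I = ens$cv_I)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
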