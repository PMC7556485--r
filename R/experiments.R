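# Monte-Carlo experiment drivers.
#
# Randomization sets follow the study design:
#   set1: R* position random (uniform by area), deterministic shutoff
#   set2: R* position fixed (centre by default), stochastic shutoff
#   set3: both randomized
#   deterministic: fixed position, mean dwell times (a single run)
#
# For set 1 the photocurrent is a deterministic function of the R* position,
# so ensembles are generated by sampling positions per trial and evaluating
# a response surface interpolated from a small set of full PDE solves at
# position-quadrature nodes (exploiting rotational/mirror symmetry of the
# incisure pattern). Sets 2 and 3 run the full pipeline per trial.

derive_seed <- function(master, k) {
  ((master %% 2147480000) * 2903 + k * 7919 + 13) %% 2147483629 + 1
}

default_mesh <- function(geom) {
  if (geom$disk_radius_um <= 1.5) {
    list(n_rho = 8, n_theta = 12, dt = 5e-4, dz0 = 0.03,
         dz_grow = 1.7, dz_max = 1.5, dt_report = 1e-3)
  } else {
    n_inc <- length(geom$incisures)
    nt <- if (n_inc > 1) 2L * n_inc else 24L
    list(n_rho = 10, n_theta = nt, dt = 5e-3, dz0 = 0.03,
         dz_grow = 1.7, dz_max = 2, dt_report = 1e-2)
  }
}

symmetric_incisures <- function(geom) {
  n <- length(geom$incisures)
  if (n < 2 || !isTRUE(geom$incisures_aligned)) return(FALSE)
  ang <- sort(vapply(geom$incisures, `[[`, numeric(1), "angle"))
  dep <- vapply(geom$incisures, `[[`, numeric(1), "depth_um")
  gaps <- diff(c(ang, ang[1] + 2 * pi))
  max(abs(gaps - 2 * pi / n)) < 1e-9 && max(abs(dep - dep[1])) < 1e-9
}

# symmetry-reduced engine for a centred source, if available
engine_for <- function(geom, params, mesh, centred) {
  n_inc <- length(geom$incisures)
  if (centred && n_inc == 0) {
    build_engine(geom, params, n_rho = mesh$n_rho, n_theta = 1L,
                 theta_span = 2 * pi, dt = mesh$dt, dz0 = mesh$dz0,
                 dz_grow = mesh$dz_grow, dz_max = mesh$dz_max)
  } else if (centred && symmetric_incisures(geom)) {
    build_engine(geom, params, n_rho = mesh$n_rho,
                 n_theta = max(2L, round(mesh$n_theta / n_inc)),
                 theta_span = 2 * pi / n_inc, dt = mesh$dt, dz0 = mesh$dz0,
                 dz_grow = mesh$dz_grow, dz_max = mesh$dz_max)
  } else {
    build_engine(geom, params, n_rho = mesh$n_rho, n_theta = mesh$n_theta,
                 theta_span = 2 * pi, dt = mesh$dt, dz0 = mesh$dz0,
                 dz_grow = mesh$dz_grow, dz_max = mesh$dz_max)
  }
}

#' Define an experiment condition
#'
#' @param geometry,params a [build_geometry()] / [build_params()] pair
#' @param set randomization set: "set1" (location only), "set2" (shutoff
#'   only), "set3" (both), or "deterministic"
#' @param position an [place_rstar()] position; required for set2 and
#'   deterministic (defaults to the disk centre)
#' @param n_trials trials per ensemble
#' @param seed master seed; per-trial seeds are derived from it
#' @param t_end simulated duration, s
#' @param mesh optional list overriding the preset mesh/step defaults
#'   (`n_rho`, `n_theta`, `dt`, `dz0`, `dz_grow`, `dz_max`, `dt_report`)
#' @return an `experiment_condition`
#' @export
experiment_condition <- function(geometry, params,
                                 set = c("set1", "set2", "set3", "deterministic"),
                                 position = NULL, n_trials = 1000L, seed = 1L,
                                 t_end = 1, mesh = list()) {
  set <- match.arg(set)
  if (n_trials < 1) stop("n_trials must be >= 1")
  if (set %in% c("set2", "deterministic") && is.null(position))
    position <- place_rstar(geometry, "center")
  m <- modifyList(default_mesh(geometry), mesh)
  structure(list(geometry = geometry, params = params, set = set,
                 position = position, n_trials = as.integer(n_trials),
                 seed = as.integer(seed), t_end = t_end, mesh = m),
            class = "experiment_condition")
}

#' Run a single deterministic simulation
#'
#' End-to-end pipeline at mean dwell times for a fixed position:
#' place R* -> deterministic shutoff -> E* spread -> cytosol -> currents.
#'
#' @param cond an [experiment_condition()] with `set = "deterministic"`,
#'   or geometry/params/position supplied directly
#' @param record passed to [engine_run()]
#' @return a `current_trace`
#' @export
run_single <- function(cond, record = "currents") {
  stopifnot(inherits(cond, "experiment_condition"))
  if (is.null(cond$position)) stop("a fixed position is required")
  traj <- sample_shutoff(cond$params, "deterministic")
  centred <- cond$position$rho == 0
  eng <- engine_for(cond$geometry, cond$params, cond$mesh, centred)
  engine_run(eng, traj, cond$position, cond$t_end, record = record)
}

ensemble_stats <- function(time, J, j_dark) {
  mean_j <- rowMeans(J)
  sd_j <- apply(J, 1, sd)
  I <- 1 - J / j_dark
  mean_I <- rowMeans(I)
  sd_I <- apply(I, 1, sd)
  list(time = time,
       mean_j = mean_j, sd_j = sd_j,
       cv_j = ifelse(mean_j > 0, sd_j / mean_j, NA_real_),
       mean_I = mean_I, sd_I = sd_I,
       # the ratio is meaningless while the mean response is at round-off
       cv_I = ifelse(abs(mean_I) > 1e-12, sd_I / mean_I, NA_real_))
}

# fold an angle into [0, half] exploiting the mirror + rotation symmetry of
# an evenly spaced incisure pattern whose first slit sits at `a0`
fold_angle <- function(theta, a0, sector) {
  phi <- (theta - a0) %% sector
  pmin(phi, sector - phi)
}

# --- response surface for set 1 -------------------------------------------
set1_surface <- function(cond, n_u = 9, n_phi = 4) {
  geom <- cond$geometry; params <- cond$params; mesh <- cond$mesh
  n_inc <- length(geom$incisures)
  eng <- engine_for(geom, params, mesh, centred = FALSE)
  u_nodes <- seq(0, 1, length.out = n_u)
  r <- geom$disk_radius_um
  if (n_inc == 0) {
    traces <- lapply(u_nodes, function(u) {
      pos <- place_rstar(geom, "explicit", rho = min(r * sqrt(u), r * 0.999),
                         theta = 0)
      engine_run(eng, sample_shutoff(params, "deterministic"), pos, cond$t_end)
    })
    J <- vapply(traces, function(tr) tr$j_tot, numeric(nrow(traces[[1]])))
    list(kind = "radial", u = u_nodes, J = J, time = traces[[1]]$time_s,
         j_dark = params$j_dark)
  } else {
    sector <- if (n_inc > 1) 2 * pi / n_inc else 2 * pi
    a0 <- geom$incisures[[1]]$angle
    phi_nodes <- seq(0, sector / 2, length.out = n_phi)
    Jlist <- vector("list", n_u)
    time <- NULL
    for (iu in seq_len(n_u)) {
      u <- u_nodes[iu]
      if (u == 0) {
        tr <- engine_run(eng, sample_shutoff(params, "deterministic"),
                         place_rstar(geom, "center"), cond$t_end)
        time <- tr$time_s
        Jlist[[iu]] <- matrix(tr$j_tot, nrow = length(tr$j_tot),
                              ncol = n_phi)
      } else {
        cols <- lapply(phi_nodes, function(phi) {
          pos <- place_rstar(geom, "explicit",
                             rho = min(r * sqrt(u), r * 0.999),
                             theta = a0 + max(phi, 1e-4))
          engine_run(eng, sample_shutoff(params, "deterministic"),
                     pos, cond$t_end)$j_tot
        })
        Jlist[[iu]] <- do.call(cbind, cols)
      }
    }
    list(kind = "polar", u = u_nodes, phi = phi_nodes, J = Jlist,
         time = time, j_dark = params$j_dark,
         sector = sector, a0 = a0)
  }
}

surface_eval <- function(surf, rho_r2, theta) {
  u <- rho_r2
  uu <- surf$u
  ku <- findInterval(u, uu, rightmost.closed = TRUE)
  ku <- min(max(ku, 1L), length(uu) - 1L)
  wu <- (u - uu[ku]) / (uu[ku + 1L] - uu[ku])
  if (surf$kind == "radial") {
    (1 - wu) * surf$J[, ku] + wu * surf$J[, ku + 1L]
  } else {
    phi <- fold_angle(theta, surf$a0, surf$sector)
    pp <- surf$phi
    kp <- findInterval(phi, pp, rightmost.closed = TRUE)
    kp <- min(max(kp, 1L), length(pp) - 1L)
    wp <- (phi - pp[kp]) / (pp[kp + 1L] - pp[kp])
    j00 <- surf$J[[ku]][, kp];     j01 <- surf$J[[ku]][, kp + 1L]
    j10 <- surf$J[[ku + 1L]][, kp]; j11 <- surf$J[[ku + 1L]][, kp + 1L]
    (1 - wu) * ((1 - wp) * j00 + wp * j01) + wu * ((1 - wp) * j10 + wp * j11)
  }
}

#' Run a Monte-Carlo ensemble
#'
#' @param cond an [experiment_condition()]
#' @param surface_nodes for set 1: `c(n_radial, n_angular)` response-surface
#'   quadrature nodes
#' @return an `ensemble_result`: per-trial `J` (times x trials) matrix of
#'   j_tot, summary curves (mean/SD/CV for j_tot and for I), metadata
#' @export
run_ensemble <- function(cond, surface_nodes = c(9, 4)) {
  stopifnot(inherits(cond, "experiment_condition"))
  geom <- cond$geometry; params <- cond$params
  n <- cond$n_trials
  seeds <- vapply(seq_len(n), function(k) derive_seed(cond$seed, k), numeric(1))
  failures <- integer(0)

  if (cond$set == "deterministic") {
    tr <- run_single(cond)
    J <- matrix(tr$j_tot, ncol = 1)
    time <- tr$time_s
  } else if (cond$set == "set1") {
    surf <- set1_surface(cond, surface_nodes[1], surface_nodes[2])
    time <- surf$time
    J <- matrix(0, length(time), n)
    r <- geom$disk_radius_um
    for (k in seq_len(n)) {
      uv <- with_seed(seeds[k], runif(2))
      J[, k] <- surface_eval(surf, uv[1], 2 * pi * uv[2])
    }
  } else {
    centred <- cond$set == "set2" && !is.null(cond$position) &&
      cond$position$rho == 0
    eng <- engine_for(geom, params, cond$mesh, centred)
    cols <- vector("list", n)
    time <- NULL
    for (k in seq_len(n)) {
      res <- tryCatch({
        traj <- sample_shutoff(params, "stochastic", rng_seed = seeds[k])
        pos <- if (cond$set == "set2") cond$position else
          place_rstar(geom, "random", rng_seed = derive_seed(seeds[k], 7L))
        tr <- engine_run(eng, traj, pos, cond$t_end)
        if (is.null(time)) time <- tr$time_s
        tr$j_tot
      }, error = function(err) err)
      if (inherits(res, "error")) failures <- c(failures, k) else cols[[k]] <- res
    }
    if (length(failures) > 0.01 * n)
      stop(sprintf("%d of %d trials failed", length(failures), n))
    if (length(failures))
      warning(sprintf("excluded %d failed trial(s)", length(failures)))
    cols <- cols[!vapply(cols, is.null, logical(1))]
    J <- do.call(cbind, cols)
  }

  stats <- ensemble_stats(time, J, params$j_dark)
  structure(c(stats,
              list(J = J, j_dark = params$j_dark, set = cond$set,
                   n_trials = ncol(J), seed = cond$seed,
                   failed_trials = failures,
                   condition = cond)),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("<ensemble_result> %s, %d trials, %d time points, j_dark=%.3g pA\n",
              x$set, x$n_trials, length(x$time), x$j_dark))
  invisible(x)
}

#' Gate time for CV analysis
#'
#' Default start gate: the first time at which the ensemble mean of I(t)
#' exceeds `frac` of its maximum (the early divide-by-small-mean transient
#' is excluded from crossover detection).
#' @param mean_I ensemble mean of I(t)
#' @param time time grid, s
#' @param frac threshold fraction of the peak (default 0.01)
#' @return gate time, s
#' @export
default_gate <- function(mean_I, time, frac = 0.01) {
  pk <- max(mean_I)
  if (pk <= 0) return(time[1])
  i <- which(mean_I > frac * pk)[1]
  if (is.na(i)) time[length(time)] else time[i]
}

#' Crossover time between two CV curves
#'
#' First time after `start_gate` at which `cv_shutoff` is at least
#' `cv_location`, linearly interpolated between grid points. If the curves
#' already satisfy the condition at the gate, the gate time itself is
#' returned (documented convention). Returns `NA` when no crossing occurs
#' within the grid.
#'
#' @param cv_location,cv_shutoff CV curves on a common time grid
#' @param time the common grid, s
#' @param start_gate gate time, s
#' @return crossover time, s (or `NA`)
#' @export
crossover_time <- function(cv_location, cv_shutoff, time, start_gate = 0) {
  stopifnot(length(cv_location) == length(cv_shutoff),
            length(time) == length(cv_location))
  d <- cv_shutoff - cv_location
  ok <- time >= start_gate & is.finite(d)
  idx <- which(ok)
  if (!length(idx)) return(NA_real_)
  if (d[idx[1]] >= 0) return(max(start_gate, time[idx[1]]))
  for (k in idx[-1]) {
    if (is.finite(d[k]) && d[k] >= 0) {
      k0 <- k - 1L
      w <- d[k0] / (d[k0] - d[k])
      return(time[k0] + w * (time[k] - time[k0]))
    }
  }
  NA_real_
}

#' Radius sweep of location-driven variability
#'
#' Runs set-1 ensembles (random location, deterministic shutoff) for
#' idealized no-incisure rods with salamander kinetics at each radius,
#' keeping the shell channel density constant, and reports the three
#' statistic families that expose the contrast between SD of the total
#' current (increasing with radius) and CV of the relative drop
#' (decreasing with radius).
#'
#' @param radii_um disk radii, um
#' @param n_trials trials per radius
#' @param seed master seed
#' @param t_end duration, s
#' @param mesh mesh override list
#' @return list of per-radius entries: `radius`, `ensemble`, and summary
#'   scalars `peak_sd_j`, `cv_I_at` (CV of I at the post-gate probe time)
#' @export
radius_sweep <- function(radii_um, n_trials = 200, seed = 1, t_end = 0.8,
                         mesh = list()) {
  variants <- radius_sweep_presets(radii_um)
  lapply(seq_along(variants), function(i) {
    v <- variants[[i]]
    cond <- experiment_condition(v$geometry, v$params, set = "set1",
                                 n_trials = n_trials,
                                 seed = derive_seed(seed, i),
                                 t_end = t_end, mesh = mesh)
    ens <- run_ensemble(cond)
    gate <- default_gate(ens$mean_I, ens$time)
    probe <- min(gate + 0.25 * (max(ens$time) - gate), max(ens$time))
    k <- which.min(abs(ens$time - probe))
    list(radius = v$geometry$disk_radius_um,
         ensemble = ens,
         gate = gate,
         peak_sd_j = max(ens$sd_j),
         cv_I_probe_time = ens$time[k],
         cv_I_at = ens$cv_I[k])
  })
}
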