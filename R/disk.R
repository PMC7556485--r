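# Spread of activated transducin/PDE (E*) on the photoisomerized disk face.
#
# The surface density obeys dE/dt = D_E * Lap_s E - k_E * E + nu(t) delta(x0)
# on the disk, with zero-flux conditions at the rim and on both sides of each
# incisure slit. Discretization: polar finite volumes with incisure slits as
# blocked azimuthal faces; the point source is deposited in its containing
# cell. Decay and source are advanced exactly per step (integrating factor),
# diffusion implicitly, so the discrete mass ledger
#   total(t_{n+1}) = total(t_n) exp(-k_E dt) + integrated source
# closes to round-off.

#' Polar finite-volume mesh of a disk face
#'
#' @param geom a [build_geometry()] geometry
#' @param n_rho,n_theta radial / azimuthal cell counts
#' @param theta_span angular extent, radians; `2*pi` for the full disk, or a
#'   single symmetry sector (with periodic wrap) for rotationally symmetric
#'   problems
#' @param use_incisures block azimuthal faces crossed by incisure slits
#' @return a `disk_mesh` list: cell centres (`rho`, `theta`), areas, and the
#'   unit-diffusivity conductance Laplacian `G`
#' @export
disk_mesh <- function(geom, n_rho = 10, n_theta = 24, theta_span = 2 * pi,
                      use_incisures = TRUE) {
  r <- geom$disk_radius_um
  drho <- r / n_rho
  dth <- theta_span / n_theta
  rho_c <- (seq_len(n_rho) - 0.5) * drho
  th_c <- (seq_len(n_theta) - 0.5) * dth
  n <- n_rho * n_theta
  cell <- function(i, j) (j - 1L) * n_rho + i       # i: radial, j: azimuthal
  area <- rep(rho_c * drho * dth, times = n_theta)

  # incisure faces: snap each slit angle to the nearest azimuthal face
  blocked <- function(face_theta, rho) {
    if (!use_incisures || !length(geom$incisures)) return(FALSE)
    for (inc in geom$incisures) {
      a <- inc$angle
      d <- abs(((face_theta - a + theta_span / 2) %% theta_span) - theta_span / 2)
      if (d < dth / 2 - 1e-12 || d < 1e-9)
        if (rho > r - inc$depth_um) return(TRUE)
    }
    FALSE
  }

  ii <- integer(0); jj <- integer(0); gg <- numeric(0)
  add_face <- function(a, b, g) {
    ii <<- c(ii, a, b); jj <<- c(jj, b, a); gg <<- c(gg, g, g)
  }
  # radial faces
  for (j in seq_len(n_theta)) for (i in seq_len(n_rho - 1L)) {
    add_face(cell(i, j), cell(i + 1L, j), (i * drho) * dth / drho)
  }
  # azimuthal faces (wrap)
  for (j in seq_len(n_theta)) {
    jn <- if (j == n_theta) 1L else j + 1L
    if (n_theta == 1L) next
    face_th <- j * dth
    for (i in seq_len(n_rho)) {
      if (blocked(face_th, rho_c[i])) next
      add_face(cell(i, j), cell(i, jn), drho / (rho_c[i] * dth))
    }
  }
  G <- if (length(ii)) {
    S <- sparseMatrix(i = ii, j = jj, x = gg, dims = c(n, n))
    Diagonal(x = Matrix::colSums(S)) - S
  } else Diagonal(n, 0)

  structure(list(n_rho = n_rho, n_theta = n_theta, drho = drho, dth = dth,
                 rho = rho_c, theta = th_c, area = area, G = G,
                 theta_span = theta_span, r = r),
            class = "disk_mesh")
}

# cell index containing a point (rho, theta) on the mesh
disk_cell_at <- function(mesh, rho, theta) {
  i <- min(max(ceiling(rho / mesh$drho), 1L), mesh$n_rho)
  th <- theta %% mesh$theta_span
  j <- min(max(ceiling(th / mesh$dth), 1L), mesh$n_theta)
  (j - 1L) * mesh$n_rho + i
}

# TRUE if the straight segment p1-p2 crosses the radial slit segment of an
# incisure (both in Cartesian coordinates)
segments_cross <- function(p1, p2, q1, q2) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(q1, q2, p1); d2 <- d(q1, q2, p2); d3 <- d(p1, p2, q1); d4 <- d(p1, p2, q2)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

# Gaussian deposit weights of half-width sigma over mesh cells, masked so
# that no mass crosses an incisure slit; weights sum to 1
deposit_weights <- function(mesh, geom, pos, sigma) {
  n <- length(mesh$area)
  if (sigma <= 0) {
    if (pos$rho == 0 && mesh$n_theta > 1) {
      idx <- (seq_len(mesh$n_theta) - 1L) * mesh$n_rho + 1L
      w <- numeric(n); w[idx] <- 1 / length(idx)
      return(w)
    }
    w <- numeric(n)
    w[disk_cell_at(mesh, pos$rho, pos$theta %% mesh$theta_span)] <- 1
    return(w)
  }
  th_c <- rep(mesh$theta, each = mesh$n_rho)
  rho_c <- rep(mesh$rho, times = mesh$n_theta)
  th0 <- pos$theta %% mesh$theta_span
  x0 <- pos$rho * cos(th0); y0 <- pos$rho * sin(th0)
  x <- rho_c * cos(th_c); y <- rho_c * sin(th_c)
  d2 <- (x - x0)^2 + (y - y0)^2
  w <- mesh$area * exp(-d2 / (2 * sigma^2))
  w[d2 > (4 * sigma)^2] <- 0
  if (length(geom$incisures) && mesh$theta_span > 2 * pi - 1e-9) {
    for (inc in geom$incisures) {
      a <- inc$angle
      q1 <- c((mesh$r - inc$depth_um) * cos(a), (mesh$r - inc$depth_um) * sin(a))
      q2 <- c(mesh$r * cos(a), mesh$r * sin(a))
      for (c_i in which(w > 0)) {
        if (segments_cross(c(x0, y0), c(x[c_i], y[c_i]), q1, q2)) w[c_i] <- 0
      }
    }
  }
  w / sum(w)
}

#' Place the photoisomerization on the disk
#'
#' @param geom geometry
#' @param mode "center", "half" (rho = r/2), "rim" (rho = r), "random"
#'   (uniform by area: rho = r*sqrt(u), theta uniform), or "explicit"
#' @param rng_seed seed for random mode
#' @param rho,theta explicit coordinates (mode = "explicit")
#' @param tag for "half"/"rim" with incisures: "midway" places the site
#'   midway between two incisures (default), "adjacent" just beside one
#' @return an `rstar_position` list (rho, theta, mode, tag)
#' @export
place_rstar <- function(geom, mode = c("center", "half", "rim", "random", "explicit"),
                        rng_seed = NULL, rho = NULL, theta = NULL,
                        tag = c("midway", "adjacent")) {
  mode <- match.arg(mode)
  tag <- match.arg(tag)
  r <- geom$disk_radius_um
  n_inc <- length(geom$incisures)
  base_theta <- if (n_inc) {
    sector <- if (n_inc > 1) 2 * pi / n_inc else 2 * pi
    if (tag == "midway") geom$incisures[[1]]$angle + sector / 2
    else geom$incisures[[1]]$angle + 1e-3
  } else 0
  pos <- switch(mode,
    center = list(rho = 0, theta = 0),
    half = list(rho = r / 2, theta = base_theta),
    rim = list(rho = r * 0.999, theta = base_theta),
    random = {
      u <- if (!is.null(rng_seed)) with_seed(rng_seed, runif(2)) else runif(2)
      list(rho = r * sqrt(u[1]), theta = 2 * pi * u[2])
    },
    explicit = {
      if (is.null(rho) || is.null(theta))
        stop("explicit mode requires rho and theta")
      if (rho < 0 || rho > r) stop("explicit position lies outside the disk")
      list(rho = rho, theta = theta %% (2 * pi))
    })
  structure(c(pos, list(mode = mode, tag = tag)), class = "rstar_position")
}

# integral of nu(s) * exp(-kappa*(t1 - s)) over [t0, t1], exact for the
# piecewise-constant activity of a trajectory
source_integral <- function(traj, t0, t1, kappa) {
  breaks <- c(0, attr(traj, "t_end"))
  cuts <- sort(unique(c(t0, t1, breaks[breaks > t0 & breaks < t1])))
  tot <- 0
  for (k in seq_len(length(cuts) - 1L)) {
    a <- cuts[k]; b <- cuts[k + 1L]
    nu <- activity_at(traj, (a + b) / 2)
    tot <- tot + if (kappa > 0)
      nu / kappa * (exp(-kappa * (t1 - b)) - exp(-kappa * (t1 - a)))
    else nu * (b - a)
  }
  tot
}

#' Solve the E* surface density on the special disk
#'
#' @param geom,params geometry and cascade parameters
#' @param traj an [sample_shutoff()] trajectory
#' @param pos an [place_rstar()] position
#' @param time_grid increasing times starting at 0, s (uniform spacing)
#' @param n_rho,n_theta mesh resolution
#' @param theta_span angular extent (symmetry sector), radians
#' @param source_sigma half-width (um) of the Gaussian patch over which the
#'   point source is deposited. A small fixed physical footprint keeps the
#'   near-source density, and hence the local hydrolytic load, comparable
#'   across source positions and mesh resolutions; 0 deposits into the
#'   single containing cell (used when comparing against point-source
#'   analytics)
#' @return an `estar_field`: `E` (density matrix, cells x times) for the
#'   hydrolytically active species, `total_count(t)`, and in two-transducin
#'   mode also the total bound density `T` and singly bound `B`
#' @export
solve_estar <- function(geom, params, traj, pos, time_grid,
                        n_rho = 10, n_theta = 24, theta_span = 2 * pi,
                        source_sigma = 0.3) {
  if (any(diff(time_grid) <= 0) || time_grid[1] != 0)
    stop("time_grid must be increasing and start at 0")
  dts <- diff(time_grid)
  if (max(dts) - min(dts) > 1e-9 * max(dts))
    stop("time_grid must be uniformly spaced")
  dt <- dts[1]
  mesh <- disk_mesh(geom, n_rho, n_theta, theta_span)
  nT <- length(time_grid)
  n <- length(mesh$area)
  w_src <- deposit_weights(mesh, geom, pos, source_sigma)
  src <- which(w_src > 0)
  # on a symmetry sector the physical point source is shared equally among
  # all sectors (valid only for sector-symmetric placements, e.g. centre)
  sector_frac <- theta_span / (2 * pi)
  A <- Diagonal(x = mesh$area)
  M <- A + (dt * params$D_E) * mesh$G
  ch <- Cholesky(forceSymmetricCsparse(M), LDL = FALSE)
  kE <- params$k_E
  two <- isTRUE(params$two_transducin_mode)
  k2 <- params$second_binding_rate

  E <- matrix(0, n, nT)       # total activated (single mode) / total bound
  Bm <- if (two) matrix(0, n, nT) else NULL
  e_now <- numeric(n); b_now <- numeric(n)
  for (s in seq_len(nT - 1L)) {
    t0 <- time_grid[s]; t1 <- time_grid[s + 1L]
    # decay + source, exact
    e_now <- e_now * exp(-kE * dt)
    e_now[src] <- e_now[src] + sector_frac * w_src[src] *
      source_integral(traj, t0, t1, kE) / mesh$area[src]
    # implicit diffusion
    e_now <- as.numeric(solve(ch, mesh$area * e_now))
    if (two) {
      b_now <- b_now * exp(-(kE + k2) * dt)
      b_now[src] <- b_now[src] + sector_frac * w_src[src] *
        source_integral(traj, t0, t1, kE + k2) / mesh$area[src]
      b_now <- as.numeric(solve(ch, mesh$area * b_now))
      Bm[, s + 1L] <- b_now
    }
    E[, s + 1L] <- e_now
  }
  active <- if (two) pmax(E - Bm, 0) else E
  structure(list(mesh = mesh, times = time_grid, E = active,
                 T_total = if (two) E else NULL, B = Bm,
                 total_count = as.numeric(crossprod(mesh$area, active)) / sector_frac,
                 pos = pos, two_transducin = two),
            class = "estar_field")
}

forceSymmetricCsparse <- function(M) {
  Matrix::forceSymmetric(methods::as(M, "CsparseMatrix"))
}

#' Hydrolytic source density from an E* field
#'
#' In single-transducin mode every activated subunit hydrolyzes; in
#' two-transducin mode only the doubly bound species does, which reduces to
#' the single mode when the second binding is instantaneous.
#' @param field an [solve_estar()] field
#' @param params cascade parameters
#' @return matrix (cells x times) of hydrolytically active surface density
#' @export
effective_activation <- function(field, params) {
  field$E
}

#' Total E* molecules over time
#' @param field an `estar_field`
#' @return numeric vector along the field's time grid
#' @export
estar_total <- function(field) field$total_count
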