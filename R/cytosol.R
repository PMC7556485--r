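# Homogenized reaction-diffusion of cGMP and Ca2+ in the rod outer segment.
#
# Three coupled domains: the interior volume (disk stack, homogenized:
# transverse diffusion through interdiskal layers scaled by the cytosolic
# volume fraction; no axial flux except through incisure conduits), the
# outer shell (cylindrical cytosolic sleeve between disk rims and plasma
# membrane, carrying azimuthal + axial diffusion and all membrane fluxes),
# and the special-disk layer (the refined axial slab at the photoisomerized
# disk, where E*-driven hydrolysis acts). Finite volumes on a structured
# (rho, theta, z) grid with geometric metric terms; axial mesh refinement
# around the special disk. Time stepping: implicit diffusion with a cached
# Cholesky factor, reactions per cell in closed form (integrating factor for
# cGMP, backward-Euler quadratic for shell Ca), so every step is
# unconditionally stable, positivity preserving and exactly mass-ledgered.

# charge-to-flux conversions, uM*um^3/s per pA
.PA_TO_FLUX_CA_IN <- 1e-12 / (2 * 1.602176634e-19) / 602.2140857   # divalent influx
.PA_TO_FLUX_CA_EX <- 1e-12 / (1.602176634e-19) / 602.2140857      # exchanger: 1 Ca per charge

hill_open <- function(g, K, m) {
  gm <- g^m
  gm / (gm + K^m)
}

#' Ca-dependent guanylate cyclase synthesis rate
#'
#' Falling Ca2+ relieves GCAP inhibition of the cyclase:
#' alpha(Ca) = alpha_min + (alpha_max - alpha_min) / (1 + (Ca/K_cyc)^m_cyc),
#' strictly decreasing in Ca.
#'
#' @param Ca calcium concentration(s), uM (>= 0)
#' @param params cascade parameters
#' @return synthesis rate(s), uM/s
#' @export
local_cyclase_rate <- function(Ca, params) {
  if (any(Ca < 0)) stop("Ca must be >= 0")
  params$alpha_min + (params$alpha_max - params$alpha_min) /
    (1 + (Ca / params$K_cyc)^params$m_cyc)
}

# Rebalance the designated free parameter (cyclase alpha scale) so that the
# uniform dark state is an exact fixed point, and derive the exchanger
# saturation current from the dark Ca ledger.
balance_dark <- function(params) {
  a_dark <- local_cyclase_rate(params$Ca_dark, params)
  target <- params$beta_dark * params$g_dark
  if (target > 0 && (!is.finite(a_dark) || a_dark <= 0))
    stop("dark-state imbalance cannot be resolved: cyclase rate is zero at Ca_dark")
  s <- if (target == 0) {
    if (a_dark > 0) 0 else 1    # no basal hydrolysis: synthesis must vanish too
  } else target / a_dark
  p <- params
  p$alpha_max <- params$alpha_max * s
  p$alpha_min <- params$alpha_min * s
  split <- dark_current_split(p)
  p$j_cng_dark <- split$j_cng_dark
  p$j_ex_sat <- split$j_ex_sat
  attr(p, "alpha_scale") <- s
  if (abs(s - 1) > 1e-8)
    attr(p, "rebalance_log") <- sprintf(
      "cyclase alpha rescaled by %.6g to balance dark hydrolysis", s)
  p
}

#' Dark steady state of the outer segment
#'
#' Returns the spatially uniform dark fields together with the residual of
#' the full right-hand side and any cyclase rebalancing applied. The
#' synthesis/hydrolysis and Ca influx/extrusion ledgers are balanced exactly
#' by construction (the cyclase scale and the exchanger saturation current
#' are the designated free parameters).
#'
#' @param geom,params geometry and cascade parameters
#' @return list with `g`, `Ca` (uniform dark values), `params` (balanced),
#'   `residual_rel` and `rebalance_log`
#' @export
init_dark_steady_state <- function(geom, params) {
  p <- balance_dark(params)
  turnover <- p$beta_dark * p$g_dark
  resid_g <- if (turnover > 0)
    abs(local_cyclase_rate(p$Ca_dark, p) - turnover) / turnover else 0
  influx <- p$f_Ca * p$j_cng_dark * .PA_TO_FLUX_CA_IN
  efflux <- p$j_ex_sat * p$Ca_dark / (p$Ca_dark + p$K_ex) * .PA_TO_FLUX_CA_EX
  resid_ca <- if (influx > 0) abs(influx - efflux) / influx else 0
  resid <- max(resid_g, resid_ca)
  if (resid > 1e-8)
    stop(sprintf("dark steady state residual %.3g exceeds tolerance", resid))
  list(g = p$g_dark, Ca = p$Ca_dark, params = p, residual_rel = resid,
       rebalance_log = attr(p, "rebalance_log"))
}

# refined symmetric z grid: thinnest cell (the special-disk slab) at the
# centre, geometric growth outward, capped at dz_max, trimmed to length L
make_zgrid <- function(L, dz0, grow = 1.6, dz_max = 2) {
  half_target <- (L - dz0) / 2
  side <- numeric(0)
  d <- dz0
  while (sum(side) < half_target) {
    d <- min(d * grow, dz_max)
    side <- c(side, min(d, half_target - sum(side)))
  }
  if (length(side) && side[length(side)] < 0.25 * dz0) {
    # fold a sliver remainder into the previous cell
    side[length(side) - 1L] <- side[length(side) - 1L] + side[length(side)]
    side <- side[-length(side)]
  }
  dz <- c(rev(side), dz0, side)
  list(dz = dz, k_special = length(side) + 1L, nz = length(dz))
}

#' Build a reusable simulation engine
#'
#' Assembles meshes, conductance operators, dark state and cached Cholesky
#' factors for a given geometry/parameter pair so that many trials can be
#' run cheaply. `theta_span < 2*pi` solves a single symmetry sector with
#' periodic wrap (valid when the source and incisure pattern share the
#' sector symmetry); currents are scaled back to the full circumference.
#'
#' @param geom,params geometry and cascade parameters
#' @param n_rho,n_theta transverse resolution (the disk and interior meshes
#'   coincide transversally)
#' @param theta_span angular extent, radians
#' @param dt time step, s
#' @param dz0 special-disk slab thickness, um
#' @param dz_grow,dz_max axial mesh growth factor and cap
#' @return an `spr_engine` environment
#' @export
build_engine <- function(geom, params, n_rho = 8, n_theta = 12,
                         theta_span = 2 * pi, dt = 5e-4,
                         dz0 = 0.03, dz_grow = 1.7, dz_max = 2) {
  dims <- os_dimensions(geom)
  dark <- init_dark_steady_state(geom, params)
  p <- dark$params
  r <- geom$disk_radius_um
  nu_v <- dims$cytosol_fraction
  drho <- r / n_rho
  dth <- theta_span / n_theta
  rho_c <- (seq_len(n_rho) - 0.5) * drho
  zg <- make_zgrid(dims$length_um, dz0, dz_grow, dz_max)
  dz <- zg$dz; nz <- zg$nz; ks <- zg$k_special
  R_mid <- r + geom$shell_um / 2

  n_int <- n_rho * n_theta * nz
  n_shell <- n_theta * nz
  n <- n_int + n_shell
  cell_int <- function(i, j, k) ((k - 1L) * n_theta + (j - 1L)) * n_rho + i
  cell_shell <- function(j, k) n_int + (k - 1L) * n_theta + j

  ii <- list(); jj <- list(); gg <- list(); nf <- 0L
  push <- function(a, b, g) {
    nf <<- nf + 1L
    ii[[nf]] <<- a; jj[[nf]] <<- b; gg[[nf]] <<- g
  }

  # interior radial faces
  if (n_rho > 1) {
    grid <- expand.grid(i = seq_len(n_rho - 1L), j = seq_len(n_theta), k = seq_len(nz))
    push(cell_int(grid$i, grid$j, grid$k), cell_int(grid$i + 1L, grid$j, grid$k),
         nu_v * (grid$i * drho) * dth * dz[grid$k] / drho)
  }
  # interior azimuthal faces (periodic wrap)
  if (n_theta > 1) {
    grid <- expand.grid(i = seq_len(n_rho), j = seq_len(n_theta), k = seq_len(nz))
    jn <- ifelse(grid$j == n_theta, 1L, grid$j + 1L)
    push(cell_int(grid$i, grid$j, grid$k), cell_int(grid$i, jn, grid$k),
         nu_v * drho * dz[grid$k] / (rho_c[grid$i] * dth))
  }
  # incisure axial conduits through the disk stack, homogenized: the open
  # slit cross-section of each radial ring (parallel sum over incisures) is
  # smeared uniformly over the ring's azimuthal cells, giving an effective
  # axial conductance of the interior while the disks themselves stay
  # impermeable
  dz_face <- (dz[-nz] + dz[-1]) / 2
  if (length(geom$incisures)) {
    w_eff <- vapply(geom$incisures, function(x)
      if (x$width_um > 0) x$width_um else geom$incisure_eff_width_um, numeric(1))
    dep <- vapply(geom$incisures, `[[`, numeric(1), "depth_um")
    # open slit length within ring i, summed over incisures (full pattern:
    # a sector mesh sees its per-sector share through the theta metric)
    ring_open <- vapply(seq_len(n_rho), function(i) {
      lo <- (i - 1L) * drho; hi <- i * drho
      sum(w_eff * pmax(0, pmin(hi, r) - pmax(lo, r - dep)))
    }, numeric(1))
    ring_open <- ring_open * theta_span / (2 * pi)   # share within the mesh span
    for (i in which(ring_open > 0)) {
      grid <- expand.grid(j = seq_len(n_theta), k = seq_len(nz - 1L))
      push(cell_int(i, grid$j, grid$k), cell_int(i, grid$j, grid$k + 1L),
           (ring_open[i] / n_theta) / dz_face[grid$k])
    }
  }
  # shell azimuthal
  if (n_theta > 1) {
    grid <- expand.grid(j = seq_len(n_theta), k = seq_len(nz))
    jn <- ifelse(grid$j == n_theta, 1L, grid$j + 1L)
    push(cell_shell(grid$j, grid$k), cell_shell(jn, grid$k),
         geom$shell_um * dz[grid$k] / (R_mid * dth))
  }
  # shell axial
  grid <- expand.grid(j = seq_len(n_theta), k = seq_len(nz - 1L))
  push(cell_shell(grid$j, grid$k), cell_shell(grid$j, grid$k + 1L),
       geom$shell_um * R_mid * dth / dz_face[grid$k])
  # interior rim <-> shell coupling (through interdiskal openings)
  grid <- expand.grid(j = seq_len(n_theta), k = seq_len(nz))
  push(cell_int(n_rho, grid$j, grid$k), cell_shell(grid$j, grid$k),
       nu_v * r * dth * dz[grid$k] / (drho / 2 + geom$shell_um / 2))

  ia <- unlist(ii); ja <- unlist(jj); ga <- unlist(gg)
  S <- sparseMatrix(i = c(ia, ja), j = c(ja, ia), x = c(ga, ga), dims = c(n, n))
  G_unit <- Diagonal(x = Matrix::colSums(S)) - S

  V_int <- nu_v * rep(rho_c, times = n_theta * nz) * drho * dth *
    rep(dz, each = n_rho * n_theta)
  V_shell <- geom$shell_um * R_mid * dth * rep(dz, each = n_theta)
  V <- c(V_int, V_shell)

  idx_shell <- n_int + seq_len(n_shell)
  idx_int <- seq_len(n_int)
  idx_slab <- ((ks - 1L) * n_theta) * n_rho + seq_len(n_rho * n_theta)

  Bg <- 1 + (p$B_cG %||% 0)   # rapid-equilibrium cGMP buffering capacity
  M_g <- Diagonal(x = Bg * V) + (dt * p$D_cG) * G_unit
  ch_g <- Cholesky(forceSymmetricCsparse(M_g), LDL = FALSE)
  M_ca <- Diagonal(x = p$B_Ca * V) + (dt * p$D_Ca) * G_unit
  ch_ca <- Cholesky(forceSymmetricCsparse(M_ca), LDL = FALSE)

  # shell membrane areas and densities (full-circumference current recovered
  # through span_scale)
  A_shell_cell <- R_mid * dth * rep(dz, each = n_theta)
  span_scale <- 2 * pi / theta_span
  A_shell_tot <- sum(A_shell_cell) * span_scale
  cng_dens <- p$j_cng_dark / (A_shell_tot * hill_open(p$g_dark, p$K_cG, p$m_cG))
  ex_dens <- p$j_ex_sat / A_shell_tot

  env <- new.env(parent = emptyenv())
  env$geom <- geom; env$params <- p; env$dark <- dark
  env$n_rho <- n_rho; env$n_theta <- n_theta; env$nz <- nz; env$ks <- ks
  env$dz <- dz; env$rho_c <- rho_c; env$drho <- drho; env$dth <- dth
  env$theta_span <- theta_span; env$span_scale <- span_scale
  env$dt <- dt; env$V <- V; env$G_unit <- G_unit; env$Bg <- Bg
  env$ch_g <- ch_g; env$ch_ca <- ch_ca
  env$idx_int <- idx_int; env$idx_shell <- idx_shell; env$idx_slab <- idx_slab
  env$A_shell_cell <- A_shell_cell; env$cng_dens <- cng_dens; env$ex_dens <- ex_dens
  env$nu_v <- os_dimensions(geom)$cytosol_fraction
  class(env) <- "spr_engine"
  env
}

#' @export
print.spr_engine <- function(x, ...) {
  cat(sprintf("<spr_engine> %s preset, %d x %d x %d cells (+%d shell), dt=%g s, span=%.3g rad\n",
              x$geom$preset, x$n_rho, x$n_theta, x$nz, x$n_theta * x$nz,
              x$dt, x$theta_span))
  invisible(x)
}

#' Advance the coupled cGMP/Ca2+ fields for one photoisomerization
#'
#' Runs the full pipeline downstream of a given R* trajectory and position:
#' E* spread on the special disk, reaction-diffusion of the second
#' messengers, and membrane currents.
#'
#' @param engine an [build_engine()] engine
#' @param traj R* trajectory ([sample_shutoff()]); `NULL` for a dark run
#' @param pos R* position ([place_rstar()]); ignored when `traj` is `NULL`
#' @param t_end simulated duration, s
#' @param record "currents" (default) or "fields" (additionally stores the
#'   special-disk slab and shell cGMP/Ca fields over time)
#' @return a `current_trace` (see [compute_currents()]) with solver
#'   diagnostics attached; with `record = "fields"` also `slab_g`, `shell_g`,
#'   `slab_Ca`, `shell_Ca` matrices (cells x times) as attributes
#' @export
engine_run <- function(engine, traj, pos, t_end,
                       record = c("currents", "fields")) {
  record <- match.arg(record)
  e <- engine
  p <- e$params
  dt <- e$dt
  nT <- ceiling(t_end / dt) + 1L
  times <- (seq_len(nT) - 1L) * dt

  estar <- NULL
  if (!is.null(traj)) {
    estar <- solve_estar(e$geom, p, traj, pos, times,
                         n_rho = e$n_rho, n_theta = e$n_theta,
                         theta_span = e$theta_span)
  }
  Eact <- if (is.null(estar)) NULL else effective_activation(estar, p)

  n <- length(e$V)
  g <- rep(p$g_dark, n)
  ca <- rep(p$Ca_dark, n)
  idx_int <- e$idx_int; idx_sh <- e$idx_shell; idx_slab <- e$idx_slab
  slab_div <- e$nu_v * e$dz[e$ks]      # cytosolic thickness of the special slab
  beta <- p$beta_dark
  Bg <- e$Bg
  Bca <- p$B_Ca
  Vsh <- e$V[idx_sh]

  j_cng <- numeric(nT); j_ex <- numeric(nT)
  cur <- function(gv, cav) {
    jc <- e$span_scale * e$cng_dens *
      sum(e$A_shell_cell * hill_open(gv, p$K_cG, p$m_cG))
    je <- e$span_scale * e$ex_dens *
      sum(e$A_shell_cell * cav / (cav + p$K_ex))
    c(jc, je)
  }
  j0 <- cur(g[idx_sh], ca[idx_sh])
  j_cng[1] <- j0[1]; j_ex[1] <- j0[2]

  keep_fields <- record == "fields"
  if (keep_fields) {
    slab_g <- matrix(0, length(idx_slab), nT); slab_g[, 1] <- g[idx_slab]
    shell_g <- matrix(0, length(idx_sh), nT); shell_g[, 1] <- g[idx_sh]
    slab_ca <- matrix(0, length(idx_slab), nT); slab_ca[, 1] <- ca[idx_slab]
    shell_ca <- matrix(0, length(idx_sh), nT); shell_ca[, 1] <- ca[idx_sh]
  }

  mass_drift <- 0
  hyd_E <- numeric(nT)      # instantaneous E*-driven hydrolysis, uM um^3/s
  for (s in seq_len(nT - 1L)) {
    # --- cGMP reaction substep (interior only), exact per cell ---
    a <- local_cyclase_rate(ca[idx_int], p)
    b <- rep(beta, length(idx_int))
    if (!is.null(Eact)) {
      Ebar <- 0.5 * (Eact[, s] + Eact[, s + 1L])
      b[idx_slab] <- b[idx_slab] + p$k_star * Ebar / slab_div
    }
    gi <- g[idx_int]
    zero_b <- b <= 0
    if (any(zero_b)) b[zero_b] <- 1e-300
    ginf <- a / b
    gnew <- ginf + (gi - ginf) * exp(-(b / Bg) * dt)
    if (any(zero_b)) gnew[zero_b] <- gi[zero_b] + a[zero_b] * dt / Bg
    g[idx_int] <- gnew
    if (!is.null(Eact))
      hyd_E[s + 1L] <- sum((b[idx_slab] - beta) * g[idx_slab] * e$V[idx_slab])

    # --- shell Ca reaction substep: influx explicit in g, extrusion
    #     backward-Euler (closed-form positive root) ---
    influx <- p$f_Ca * e$cng_dens *
      hill_open(g[idx_sh], p$K_cG, p$m_cG) * .PA_TO_FLUX_CA_IN   # per um^2
    P <- influx * e$A_shell_cell / (Bca * Vsh)
    Q <- e$ex_dens * .PA_TO_FLUX_CA_EX * e$A_shell_cell / (Bca * Vsh)
    ca0 <- ca[idx_sh]
    bq <- p$K_ex - ca0 - (P - Q) * dt
    ca[idx_sh] <- ( -bq + sqrt(bq * bq + 4 * p$K_ex * (ca0 + P * dt)) ) / 2

    # --- implicit diffusion ---
    m_before <- sum(e$V * g)
    g <- as.numeric(solve(e$ch_g, (Bg * e$V) * g))
    mass_drift <- max(mass_drift, abs(sum(e$V * g) - m_before) /
                        max(m_before, 1e-300))
    ca <- as.numeric(solve(e$ch_ca, (Bca * e$V) * ca))

    j1 <- cur(g[idx_sh], ca[idx_sh])
    j_cng[s + 1L] <- j1[1]; j_ex[s + 1L] <- j1[2]
    if (keep_fields) {
      slab_g[, s + 1L] <- g[idx_slab]; shell_g[, s + 1L] <- g[idx_sh]
      slab_ca[, s + 1L] <- ca[idx_slab]; shell_ca[, s + 1L] <- ca[idx_sh]
    }
  }

  trace <- new_current_trace(times, j_cng, j_ex, p$j_dark)
  attr(trace, "mass_drift_rel") <- mass_drift
  attr(trace, "hyd_E") <- hyd_E
  attr(trace, "estar_total") <- if (is.null(estar)) NULL else estar$total_count
  if (keep_fields) {
    attr(trace, "slab_g") <- slab_g
    attr(trace, "shell_g") <- shell_g
    attr(trace, "slab_Ca") <- slab_ca
    attr(trace, "shell_Ca") <- shell_ca
    attr(trace, "slab_rho") <- rep(e$rho_c, times = e$n_theta)
    attr(trace, "slab_theta") <- rep((seq_len(e$n_theta) - 0.5) * e$dth,
                                     each = e$n_rho)
  }
  trace
}

#' Solve the cytosolic fields for a prescribed E* source
#'
#' Thin wrapper over [build_engine()] + [engine_run()] for one-off runs.
#'
#' @inheritParams build_engine
#' @param traj,pos R* trajectory and position (`traj = NULL` for dark)
#' @param t_end simulated duration, s
#' @param ... further arguments to [build_engine()]
#' @return a `current_trace`
#' @export
solve_cytosol <- function(geom, params, traj, pos, t_end, ...) {
  engine <- build_engine(geom, params, ...)
  engine_run(engine, traj, pos, t_end)
}
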