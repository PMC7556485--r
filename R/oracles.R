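# Independent analytic references used by the test suite.

# first n positive zeros of d/dx J_m(x)
besselJprime_zeros <- function(m, n) {
  f <- if (m == 0) function(x) -besselJ(x, 1) else
    function(x) 0.5 * (besselJ(x, m - 1) - besselJ(x, m + 1))
  zeros <- numeric(0)
  x0 <- if (m == 0) 2.0 else m + 0.25
  x <- x0
  step <- 0.05
  while (length(zeros) < n) {
    x1 <- x + step
    if (f(x) == 0) zeros <- c(zeros, x)
    else if (sign(f(x)) != sign(f(x1)))
      zeros <- c(zeros, uniroot(f, c(x, x1), tol = 1e-13)$root)
    x <- x1
    if (x > x0 + 20 * (n + m + 5)) stop("Bessel zero search failed")
  }
  zeros[seq_len(n)]
}

#' Eigenfunction-series solution of the disk heat problem
#'
#' Truncated Neumann-Laplacian eigenfunction expansion (Bessel modes) for
#' du/dt = D Lap u - k_E u + source at a point, on a disk of radius `r` with
#' a reflecting rim and no incisures. Serves as the independent oracle for
#' the finite-volume disk solver.
#'
#' @param r disk radius, um
#' @param D surface diffusivity, um^2/s
#' @param k_E first-order decay rate, 1/s
#' @param source_pos c(rho0, theta0) of the point source
#' @param t evaluation time, s (single value)
#' @param eval_rho,eval_theta coordinates of evaluation points (equal length)
#' @param n_m number of angular orders (m = 0..n_m)
#' @param n_r number of radial modes per order
#' @param source "constant" (rate molecules/s from t = 0) or "impulse"
#'   (mass deposited at t = 0)
#' @param rate,mass source strength for the respective mode
#' @return list with `u` (density at the evaluation points),
#'   `total` (exact total mass at `t`), and `tail` (magnitude of the last
#'   retained radial mode's contribution, a truncation indicator)
#' @export
bessel_heat_oracle <- function(r, D, k_E, source_pos, t, eval_rho, eval_theta,
                               n_m = 12, n_r = 20,
                               source = c("constant", "impulse"),
                               rate = 1, mass = 1) {
  source <- match.arg(source)
  rho0 <- source_pos[1]; th0 <- source_pos[2]
  stopifnot(length(eval_rho) == length(eval_theta))
  u <- numeric(length(eval_rho))
  tail_mag <- 0

  time_factor <- function(mu) {
    if (source == "constant") {
      if (mu == 0) rate * t else rate * (1 - exp(-mu * t)) / mu
    } else mass * exp(-mu * t)
  }

  # m = 0, lambda = 0 (uniform mode)
  u <- u + time_factor(k_E) / (pi * r^2)
  for (m in 0:n_m) {
    lam <- besselJprime_zeros(m, n_r)
    for (s in seq_along(lam)) {
      l <- lam[s]
      mu <- D * (l / r)^2 + k_E
      Jm_l <- besselJ(l, m)
      if (m == 0) {
        norm2 <- pi * r^2 * Jm_l^2
        contrib <- besselJ(l * eval_rho / r, 0) * besselJ(l * rho0 / r, 0) /
          norm2 * time_factor(mu)
      } else {
        norm2 <- pi * r^2 / 2 * (1 - m^2 / l^2) * Jm_l^2
        ang <- cos(m * (eval_theta - th0))
        contrib <- besselJ(l * eval_rho / r, m) * besselJ(l * rho0 / r, m) *
          ang / norm2 * time_factor(mu)
      }
      u <- u + contrib
      if (s == length(lam)) tail_mag <- max(tail_mag, max(abs(contrib)))
    }
  }
  total <- if (source == "constant") {
    if (k_E > 0) rate * (1 - exp(-k_E * t)) / k_E else rate * t
  } else mass * exp(-k_E * t)
  list(u = u, total = total, tail = tail_mag)
}

#' Transversally well-stirred reference model
#'
#' Spatially lumped ODE version of the cascade (single cGMP and Ca2+ pools,
#' total E* from the trajectory): the large-diffusivity limit of the
#' space-resolved solver, used as an independent cross-check. By
#' construction the R* location has no effect here.
#'
#' @param geom,params geometry and cascade parameters
#' @param traj R* trajectory (`NULL` for a dark run)
#' @param t_end duration, s
#' @param dt step, s
#' @return a `current_trace`
#' @export
wellstirred_oracle <- function(geom, params, traj, t_end, dt = 1e-4) {
  dims <- os_dimensions(geom)
  p <- balance_dark(params)
  V_cyt <- dims$cytosol_fraction * pi * geom$disk_radius_um^2 * dims$length_um +
    dims$shell_area_um2 * geom$shell_um
  n <- ceiling(t_end / dt) + 1L
  times <- (seq_len(n) - 1L) * dt
  Bg <- 1 + (p$B_cG %||% 0)
  g <- p$g_dark; ca <- p$Ca_dark; Etot <- 0
  gs <- numeric(n); cas <- numeric(n)
  gs[1] <- g; cas[1] <- ca
  h_dark <- hill_open(p$g_dark, p$K_cG, p$m_cG)
  for (s in seq_len(n - 1L)) {
    if (!is.null(traj)) {
      Etot <- Etot * exp(-p$k_E * dt) +
        source_integral(traj, times[s], times[s + 1L], p$k_E)
    }
    # cGMP: exact linear update given Ca
    a <- local_cyclase_rate(ca, p)
    b <- p$beta_dark + p$k_star * Etot / V_cyt
    g <- a / b + (g - a / b) * exp(-(b / Bg) * dt)
    # Ca: influx explicit in g, extrusion backward Euler (positive root)
    jc <- p$j_cng_dark * hill_open(g, p$K_cG, p$m_cG) / h_dark
    P <- p$f_Ca * jc * .PA_TO_FLUX_CA_IN / (p$B_Ca * V_cyt)
    Q <- p$j_ex_sat * .PA_TO_FLUX_CA_EX / (p$B_Ca * V_cyt)
    bq <- p$K_ex - ca - (P - Q) * dt
    ca <- (-bq + sqrt(bq * bq + 4 * p$K_ex * (ca + P * dt))) / 2
    gs[s + 1L] <- g; cas[s + 1L] <- ca
  }
  j_cng <- p$j_cng_dark * hill_open(gs, p$K_cG, p$m_cG) / h_dark
  j_ex <- p$j_ex_sat * cas / (cas + p$K_ex)
  new_current_trace(times, j_cng, j_ex, p$j_dark)
}
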