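# Membrane currents and the normalized response.
#
# The circulating current enters through CNG channels (local density
# proportional to a Hill function of shell cGMP) and through the
# Na+/K+,Ca2+ exchanger (Michaelis in shell Ca2+); currents are reported as
# positive inward magnitudes. The relative response is
# I(t) = 1 - j_tot(t)/j_dark.

new_current_trace <- function(time, j_cng, j_ex, j_dark) {
  j_tot <- j_cng + j_ex
  structure(data.frame(time_s = time, j_cng = j_cng, j_ex = j_ex,
                       j_tot = j_tot, I = 1 - j_tot / j_dark),
            j_dark = j_dark,
            class = c("current_trace", "data.frame"))
}

#' Dark current of a trace
#' @param trace a `current_trace`
#' @return j_dark, pA
#' @export
j_dark_of <- function(trace) attr(trace, "j_dark")

#' Compute membrane currents from shell fields
#'
#' Integrates the local CNG current density (Hill in cGMP) and exchanger
#' density (Michaelis in Ca2+) over the shell area, given matrices of shell
#' cGMP and Ca2+ (cells x times).
#'
#' @param shell_g,shell_Ca matrices (shell cells x time points), uM
#' @param shell_areas per-cell membrane areas, um^2
#' @param time time grid, s
#' @param params balanced cascade parameters (with `j_cng_dark`, `j_ex_sat`)
#' @return a `current_trace` data frame
#' @export
compute_currents <- function(shell_g, shell_Ca, shell_areas, time, params) {
  if (is.null(shell_g) || is.null(shell_Ca)) stop("missing shell field data")
  p <- if (is.null(params$j_cng_dark)) balance_dark(params) else params
  A_tot <- sum(shell_areas)
  cng_dens <- p$j_cng_dark / (A_tot * hill_open(p$g_dark, p$K_cG, p$m_cG))
  ex_dens <- p$j_ex_sat / A_tot
  j_cng <- cng_dens * as.numeric(crossprod(shell_areas,
                                           hill_open(shell_g, p$K_cG, p$m_cG)))
  j_ex <- ex_dens * as.numeric(crossprod(shell_areas,
                                         shell_Ca / (shell_Ca + p$K_ex)))
  new_current_trace(time, j_cng, j_ex, p$j_dark)
}

#' Peak amplitude and time-to-peak of the relative response
#'
#' @param trace a `current_trace`
#' @return list with `peak` (max of I) and `t_peak` (s; earliest argmax).
#'   An all-zero trace yields peak 0 at t = 0 (documented convention).
#' @export
peak_metrics <- function(trace) {
  if (!nrow(trace)) stop("empty trace")
  i <- which.max(trace$I)
  if (max(trace$I) <= 0) return(list(peak = 0, t_peak = 0))
  list(peak = trace$I[i], t_peak = trace$time_s[i])
}

#' Detect a damped oscillation in the recovery phase
#'
#' Counts sign reversals of dI/dt after the peak, ignoring ripples smaller
#' than `thresh_frac` of the peak amplitude. A damped oscillation (secondary
#' trough/peak in the recovery) is reported when at least one
#' above-threshold reversal to a rising-then-falling excursion occurs.
#'
#' @param trace a `current_trace`
#' @param thresh_frac amplitude threshold as a fraction of peak (default
#'   0.005, i.e. 0.5 percent, to reject numerical ripple)
#' @return list with `oscillating` (logical) and `n_reversals`
#' @export
detect_oscillation <- function(trace, thresh_frac = 0.005) {
  pm <- peak_metrics(trace)
  if (pm$peak <= 0) return(list(oscillating = FALSE, n_reversals = 0L))
  post <- trace$I[trace$time_s >= pm$t_peak]
  # local minima followed by a rebound exceeding the threshold
  n_rev <- 0L
  i <- 1L
  while (i < length(post)) {
    # next local minimum
    j <- i
    while (j < length(post) && post[j + 1L] <= post[j]) j <- j + 1L
    if (j >= length(post)) break
    k <- j
    while (k < length(post) && post[k + 1L] >= post[k]) k <- k + 1L
    if (post[k] - post[j] > thresh_frac * pm$peak) n_rev <- n_rev + 1L
    if (k == i) break
    i <- k
  }
  list(oscillating = n_rev > 0L, n_reversals = n_rev)
}

#' Resample a trace to a uniform reporting grid
#' @param trace a `current_trace`
#' @param dt_report reporting interval, s
#' @return a `current_trace` on the new grid (linear interpolation)
#' @export
resample_trace <- function(trace, dt_report) {
  tmax <- max(trace$time_s)
  tt <- seq(0, tmax, by = dt_report)
  new_current_trace(tt,
                    approx(trace$time_s, trace$j_cng, tt)$y,
                    approx(trace$time_s, trace$j_ex, tt)$y,
                    attr(trace, "j_dark"))
}
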