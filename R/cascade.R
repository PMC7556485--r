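# Stepwise shutoff of photoexcited rhodopsin (R*).
#
# R* passes through 7 activity states (0..6 phosphates); each state has its
# own mean duration and catalytic rate (activated PDE produced per second),
# the rate non-increasing with phosphorylation. In stochastic mode each dwell
# is exponential with the state's mean; the end of the 7th state is complete
# quench (arrestin capture folded into the final exit).

#' Sample or construct an R* shutoff trajectory
#'
#' @param params a [build_params()] object
#' @param mode "deterministic" (each dwell equals its mean) or "stochastic"
#'   (independent exponential dwells)
#' @param rng_seed integer seed; ignored in deterministic mode. Each
#'   trajectory is drawn from its own RNG stream so trials are reproducible
#'   and order-independent.
#' @return an `rstar_trajectory`: data.frame of (state, dwell_s, nu) plus
#'   `quench_time` attribute
#' @export
sample_shutoff <- function(params, mode = c("deterministic", "stochastic"),
                           rng_seed = NULL) {
  mode <- match.arg(mode)
  tau <- params$tau_states
  dwell <- if (mode == "deterministic") {
    tau
  } else if (!is.null(rng_seed)) {
    with_seed(rng_seed, rexp(length(tau), rate = 1 / tau))
  } else {
    rexp(length(tau), rate = 1 / tau)
  }
  traj <- data.frame(state = 0:6, dwell_s = dwell, nu = params$nu_states)
  structure(traj,
            quench_time = sum(dwell),
            t_end = cumsum(dwell),
            class = c("rstar_trajectory", "data.frame"))
}

# Evaluate code under a private RNG state, restoring the caller's stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Quench time of a trajectory
#' @param traj an `rstar_trajectory`
#' @return time (s) after which R* activity is exactly zero
#' @export
quench_time <- function(traj) attr(traj, "quench_time")

#' R* catalytic activity at a time point
#'
#' Piecewise-constant, right-continuous at transitions (the value at a jump
#' instant is that of the newly entered state), and exactly zero at and
#' after the quench time.
#'
#' @param traj an `rstar_trajectory`
#' @param t time(s) since photoisomerization, s; must be >= 0
#' @return catalytic rate(s) (activated PDE per second)
#' @export
activity_at <- function(traj, t) {
  if (any(t < 0)) stop("time must be >= 0")
  t_end <- attr(traj, "t_end")
  idx <- findInterval(t, c(0, t_end), left.open = FALSE, rightmost.closed = FALSE)
  # findInterval with breaks c(0, t_end): t in [t_end[j-1], t_end[j]) -> j
  out <- numeric(length(t))
  inside <- idx >= 1 & idx <= nrow(traj) & t < attr(traj, "quench_time")
  out[inside] <- traj$nu[idx[inside]]
  out
}

#' Mean activity of a trajectory over a time step
#'
#' Exact time average of the piecewise-constant activity over
#' [t0, t0 + dt]; used by the disk solver to integrate the source exactly
#' across state transitions.
#' @param traj an `rstar_trajectory`
#' @param t0 interval start, s
#' @param dt interval length, s
#' @return average catalytic rate over the interval
#' @export
mean_activity <- function(traj, t0, dt) {
  if (dt <= 0) stop("dt must be > 0")
  breaks <- c(0, attr(traj, "t_end"))
  v <- vapply(seq_along(t0), function(i) {
    a <- t0[i]; b <- t0[i] + dt
    cuts <- sort(unique(c(a, b, breaks[breaks > a & breaks < b])))
    mids <- (cuts[-1] + cuts[-length(cuts)]) / 2
    sum(activity_at(traj, mids) * diff(cuts)) / dt
  }, numeric(1))
  v
}

#' Activity-weighted mean R* lifetime
#'
#' Integral of the activity over time divided by the initial activity; a
#' diagnostic summary of how long R* remains effectively active, shorter
#' than the plain sum of dwell times because later states are less active.
#' @param traj an `rstar_trajectory`
#' @return effective lifetime, s
#' @export
effective_lifetime <- function(traj) {
  sum(traj$dwell_s * traj$nu) / traj$nu[1]
}

#' @export
print.rstar_trajectory <- function(x, ...) {
  cat(sprintf("<rstar_trajectory> %d states, quench at %.4f s\n",
              nrow(x), attr(x, "quench_time")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Write a trajectory as tabular text
#' @param traj an `rstar_trajectory`
#' @param path output file (CSV: state, dwell_s, nu)
#' @export
write_trajectory <- function(traj, path) {
  write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
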