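# Shared coarse fixtures for fast unit tests. Meshes here are deliberately
# small; quantitative reproduction runs live in test-acceptance.R.

coarse_mouse <- function(...) {
  list(geometry = build_geometry("mouse", ...),
       params = build_params("mouse"),
       mesh = list(n_rho = 6, n_theta = 8, dt = 1e-3, dz_max = 2))
}

coarse_salamander <- function(...) {
  list(geometry = build_geometry("salamander", ...),
       params = build_params("salamander"),
       mesh = list(n_rho = 8, n_theta = 46, dt = 1e-2, dz_max = 3))
}

# deterministic trajectory with a single never-ending unit-rate state, handy
# for constant-source tests
constant_source_traj <- function(params, rate = 1, dur = 1e3) {
  sample_shutoff(build_params(params$preset,
                              nu_states = rate * rep(1, 7) / 1,
                              tau_states = rep(dur, 7)),
                 "deterministic")
}

# near-impulse trajectory: all mass released in the first 0.1 ms
impulse_traj <- function(params, mass = 1) {
  tau0 <- 1e-4
  sample_shutoff(build_params(params$preset,
                              nu_states = c(mass / tau0, rep(0, 6)),
                              tau_states = c(tau0, rep(1, 6))),
                 "deterministic")
}
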