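test_that("dark steady state balances synthesis, hydrolysis and Ca fluxes", {
  for (preset in c("mouse", "salamander")) {
    d <- init_dark_steady_state(build_geometry(preset), build_params(preset))
    expect_lt(d$residual_rel, 1e-8)
    expect_equal(d$g, build_params(preset)$g_dark)
  }
})

test_that("doubling the cyclase maximum triggers a logged rebalance", {
  p <- build_params("mouse")
  d <- init_dark_steady_state(build_geometry("mouse"),
                              build_params("mouse", alpha_max = 2 * p$alpha_max))
  expect_false(is.null(d$rebalance_log))
  expect_lt(d$residual_rel, 1e-8)
})

test_that("cyclase rate has the Hill form with the documented landmarks", {
  p <- rodspr:::balance_dark(build_params("salamander"))
  expect_equal(local_cyclase_rate(p$K_cyc, p), (p$alpha_min + p$alpha_max) / 2)
  expect_equal(local_cyclase_rate(1e6, p), p$alpha_min, tolerance = 1e-6)
  # dark balance: synthesis at Ca_dark equals basal hydrolysis of g_dark
  expect_equal(local_cyclase_rate(p$Ca_dark, p), p$beta_dark * p$g_dark,
               tolerance = 1e-12)
  # strictly decreasing in Ca
  ca <- seq(0.01, 2, length.out = 50)
  expect_true(all(diff(local_cyclase_rate(ca, p)) < 0))
  expect_error(local_cyclase_rate(-1, p), ">= 0")
})

test_that("a dark run is a fixed point of the space-resolved solver", {
  fx <- coarse_mouse()
  eng <- do.call(build_engine, c(list(fx$geometry, fx$params), fx$mesh))
  tr <- engine_run(eng, NULL, NULL, t_end = 0.5)
  expect_lt(max(abs(tr$I)), 1e-8)
  expect_lt(attr(tr, "mass_drift_rel"), 1e-10)
  expect_equal(tr$j_tot[1], fx$params$j_dark, tolerance = 1e-10)
})

test_that("with all reactions off, transport conserves total cGMP", {
  g <- build_geometry("mouse", incisures = list())
  p <- build_params("mouse", beta_dark = 0, alpha_max = 0, alpha_min = 0,
                    f_Ca = 0)   # no Ca influx so channels stay passive
  eng <- build_engine(g, p, n_rho = 6, n_theta = 8, dt = 1e-3)
  tr <- engine_run(eng, NULL, NULL, t_end = 0.2)
  expect_lt(attr(tr, "mass_drift_rel"), 1e-8)
})

test_that("no E* source leaves the fields at dark values", {
  fx <- coarse_mouse()
  p0 <- build_params("mouse", nu_states = rep(0, 7))
  eng <- do.call(build_engine, c(list(fx$geometry, p0), fx$mesh))
  tr <- engine_run(eng, sample_shutoff(p0, "deterministic"),
                   place_rstar(fx$geometry, "center"), t_end = 0.3)
  expect_lt(max(abs(tr$I)), 1e-8)
})

test_that("centred activation depletes the active layer far more than the rim", {
  g <- build_geometry("salamander", incisures = list())
  p <- build_params("salamander")
  eng <- build_engine(g, p, n_rho = 8, n_theta = 1, dt = 1e-2)
  tr <- engine_run(eng, sample_shutoff(p, "deterministic"),
                   place_rstar(g, "center"), t_end = 1.5, record = "fields")
  sg <- attr(tr, "slab_g")
  k <- ncol(sg)
  drop_centre <- 1 - sg[1, k] / p$g_dark
  drop_rim <- 1 - sg[8, k] / p$g_dark
  expect_gt(drop_centre, 3 * drop_rim)
  expect_gt(drop_centre, 0.05)
})

test_that("incisures reduce the peak cGMP drop at the active layer", {
  p <- build_params("salamander")
  traj <- sample_shutoff(p, "deterministic")
  g0 <- build_geometry("salamander", incisures = list())
  e0 <- build_engine(g0, p, n_rho = 8, n_theta = 1, dt = 1e-2)
  tr0 <- engine_run(e0, traj, place_rstar(g0, "center"), t_end = 1.5,
                    record = "fields")
  g1 <- build_geometry("salamander")
  e1 <- build_engine(g1, p, n_rho = 8, n_theta = 2, theta_span = 2 * pi / 23,
                     dt = 1e-2)
  tr1 <- engine_run(e1, traj, place_rstar(g1, "center"), t_end = 1.5,
                    record = "fields")
  drop0 <- 1 - min(attr(tr0, "slab_g")) / p$g_dark
  drop1 <- 1 - min(attr(tr1, "slab_g")) / p$g_dark
  expect_lt(drop1, drop0)
})

test_that("sector and axisymmetric reductions match the full mesh for a centred R*", {
  g <- build_geometry("salamander", incisures = list())
  p <- build_params("salamander")
  traj <- sample_shutoff(p, "deterministic")
  full <- engine_run(build_engine(g, p, n_rho = 6, n_theta = 12, dt = 1e-2),
                     traj, place_rstar(g, "center"), t_end = 0.5)
  axi <- engine_run(build_engine(g, p, n_rho = 6, n_theta = 1, dt = 1e-2),
                    traj, place_rstar(g, "center"), t_end = 0.5)
  expect_equal(axi$j_tot, full$j_tot, tolerance = 1e-9)
})

test_that("space-resolved solver approaches the well-stirred limit at large diffusivities", {
  g <- build_geometry("mouse", incisures = list())
  p <- build_params("mouse", D_cG = 120 * 100, D_Ca = 60 * 100)
  traj <- sample_shutoff(p, "deterministic")
  eng <- build_engine(g, p, n_rho = 6, n_theta = 8, dt = 2.5e-4)
  tr <- engine_run(eng, traj, place_rstar(g, "rim"), t_end = 0.5)
  ws <- wellstirred_oracle(g, p, traj, 0.5, dt = 2.5e-4)
  expect_lt(max(abs(tr$j_tot - ws$j_tot)) / p$j_dark, 0.02)
})

test_that("transverse grid refinement changes the mouse response by under a percent", {
  g <- build_geometry("mouse")
  p <- build_params("mouse")
  traj <- sample_shutoff(p, "deterministic")
  pos <- place_rstar(g, "half")
  c1 <- engine_run(build_engine(g, p, n_rho = 8, n_theta = 12, dt = 5e-4),
                   traj, pos, t_end = 0.4)
  c2 <- engine_run(build_engine(g, p, n_rho = 16, n_theta = 24, dt = 5e-4),
                   traj, pos, t_end = 0.4)
  expect_lt(max(abs(c1$I - c2$I)) / max(c2$I), 0.05)
  expect_lt(abs(max(c1$I) - max(c2$I)) / max(c2$I), 0.01)
})
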