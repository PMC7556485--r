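test_that("a deterministic condition yields a zero-CV ensemble", {
  fx <- coarse_mouse()
  cond <- experiment_condition(fx$geometry, fx$params, set = "deterministic",
                               n_trials = 1, t_end = 0.05, mesh = fx$mesh)
  ens <- run_ensemble(cond)
  expect_equal(ncol(ens$J), 1L)
  expect_true(all(ens$sd_j == 0 | is.na(ens$sd_j)))
})

test_that("set-2 requires a fixed position and defaults to the centre", {
  fx <- coarse_mouse()
  cond <- experiment_condition(fx$geometry, fx$params, set = "set2",
                               n_trials = 2, t_end = 0.02, mesh = fx$mesh)
  expect_equal(cond$position$rho, 0)
  expect_error(experiment_condition(fx$geometry, fx$params, n_trials = 0),
               "n_trials")
})

test_that("ensembles are bit-identical under a repeated master seed", {
  fx <- coarse_mouse()
  cond <- experiment_condition(fx$geometry, fx$params, set = "set1",
                               n_trials = 20, seed = 7, t_end = 0.02,
                               mesh = fx$mesh)
  e1 <- run_ensemble(cond, surface_nodes = c(4, 3))
  e2 <- run_ensemble(cond, surface_nodes = c(4, 3))
  expect_identical(e1$J, e2$J)
  e3 <- run_ensemble(experiment_condition(fx$geometry, fx$params, set = "set1",
                                          n_trials = 20, seed = 8, t_end = 0.02,
                                          mesh = fx$mesh),
                     surface_nodes = c(4, 3))
  expect_false(identical(e1$J, e3$J))
})

test_that("set-3 randomizes both location and shutoff", {
  fx <- coarse_mouse()
  cond <- experiment_condition(fx$geometry, fx$params, set = "set3",
                               n_trials = 4, seed = 5, t_end = 0.02,
                               mesh = fx$mesh)
  ens <- run_ensemble(cond)
  expect_equal(ens$n_trials, 4L)
  late <- nrow(ens$J)
  expect_gt(sd(ens$J[late, ]), 0)
})

test_that("crossover detection interpolates linearly and honours the gate", {
  tt <- seq(0, 1, by = 0.01)
  cv_a <- rep(0.3, length(tt))
  cv_b <- 0.6 * tt
  expect_equal(crossover_time(cv_a, cv_b, tt, 0), 0.5, tolerance = 1e-9)
  # identical curves: the gate time itself (documented convention)
  expect_equal(crossover_time(cv_a, cv_a, tt, 0.2), 0.2)
  # no crossing inside the window
  expect_true(is.na(crossover_time(cv_a, rep(0.1, length(tt)), tt, 0)))
  # gate excludes an early spurious crossing
  cv_c <- c(rep(0.9, 5), rep(0.01, 96))[1:101] * 1
  expect_gt(crossover_time(cv_a, pmax(cv_c, 0.6 * tt), tt, 0.2), 0.2)
})

test_that("the default gate tracks one percent of the mean response peak", {
  tt <- seq(0, 1, by = 0.01)
  mean_I <- pmax(0, tt - 0.3)
  g <- default_gate(mean_I, tt, frac = 0.01)
  expect_gt(g, 0.3)
  expect_lt(g, 0.35)
})

test_that("mouse responses barely depend on R* location without the incisure", {
  g <- build_geometry("mouse", incisures = list())
  p <- build_params("mouse")
  mesh <- list(n_rho = 6, n_theta = 8, dt = 1e-3)
  peaks <- vapply(c("center", "half", "rim"), function(m) {
    cond <- experiment_condition(g, p, set = "deterministic",
                                 position = place_rstar(g, m),
                                 t_end = 0.5, mesh = mesh)
    peak_metrics(run_single(cond))$peak
  }, numeric(1))
  expect_lt(max(peaks) / min(peaks), 1.1)
})

test_that("radius sweep exposes the SD-versus-CV contrast", {
  rs <- radius_sweep(c(2, 5), n_trials = 30, seed = 5, t_end = 0.4,
                     mesh = list(n_rho = 6, n_theta = 12, dt = 1e-2))
  expect_length(rs, 2L)
  # SD of the total current grows with radius at matched times ...
  k2 <- which.min(abs(rs[[1]]$ensemble$time - 0.2))
  expect_gt(rs[[2]]$ensemble$sd_j[k2], rs[[1]]$ensemble$sd_j[k2])
  # ... while CV of the relative drop falls with radius at matched times
  k <- which.min(abs(rs[[1]]$ensemble$time - 0.3))
  expect_lt(rs[[1]]$ensemble$cv_I[k], rs[[2]]$ensemble$cv_I[k])
  # CV identity holds on every ensemble
  for (v in rs) {
    e <- v$ensemble
    ok <- is.finite(e$cv_I)
    expect_equal(e$cv_I[ok], (e$sd_j / (e$j_dark - e$mean_j))[ok],
                 tolerance = 1e-9)
  }
})

test_that("an idealized hybrid (mouse radius, salamander kinetics) runs", {
  v <- radius_sweep_presets(0.685)[[1]]
  cond <- experiment_condition(v$geometry, v$params, set = "deterministic",
                               position = place_rstar(v$geometry, "center"),
                               t_end = 0.3,
                               mesh = list(n_rho = 6, n_theta = 8, dt = 2e-3))
  tr <- run_single(cond)
  expect_gt(max(tr$I), 0)
})
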