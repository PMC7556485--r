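test_that("R* placement modes give the documented coordinates", {
  g <- build_geometry("salamander")
  expect_equal(place_rstar(g, "center")$rho, 0)
  expect_equal(place_rstar(g, "half")$rho, g$disk_radius_um / 2)
  expect_gt(place_rstar(g, "rim")$rho, 0.99 * g$disk_radius_um)
  adj <- place_rstar(g, "rim", tag = "adjacent")
  expect_lt(abs(adj$theta - g$incisures[[1]]$angle), 0.01)
  mid <- place_rstar(g, "half", tag = "midway")
  expect_equal(mid$theta, g$incisures[[1]]$angle + pi / 23, tolerance = 1e-9)
  expect_error(place_rstar(g, "explicit", rho = 7, theta = 0), "outside")
})

test_that("random placement is uniform by area", {
  g <- build_geometry("mouse")
  n <- 1e5
  u <- vapply(seq_len(n), function(k) {
    pos <- place_rstar(g, "random", rng_seed = k)
    (pos$rho / g$disk_radius_um)^2
  }, numeric(1))
  # rho^2/r^2 ~ Uniform(0,1): mean 1/2, SD 1/sqrt(12)
  expect_lt(abs(mean(u) - 0.5), 3 / sqrt(12 * n))
})

test_that("a centred source on a bare disk stays azimuthally symmetric", {
  g <- build_geometry("salamander", incisures = list())
  p <- build_params("salamander")
  tt <- seq(0, 0.5, by = 5e-3)
  f <- solve_estar(g, p, constant_source_traj(p, rate = 100), place_rstar(g, "center"),
                   tt, n_rho = 8, n_theta = 12)
  E <- matrix(f$E[, length(tt)], 8, 12)
  spread <- apply(E, 1, function(x) diff(range(x)))
  expect_lt(max(spread / (rowMeans(E) + 1e-12)), 1e-8)
})

test_that("total E* decays exponentially at k_E once the source stops", {
  g <- build_geometry("salamander", incisures = list())
  p <- build_params("salamander")
  traj <- impulse_traj(p, mass = 50)
  tt <- seq(0, 1, by = 5e-3)
  f <- solve_estar(g, p, traj, place_rstar(g, "half"), tt, n_rho = 8, n_theta = 12)
  tot <- estar_total(f)
  k0 <- 21; k1 <- 181
  observed <- log(tot[k0] / tot[k1]) / (tt[k1] - tt[k0])
  expect_equal(observed, p$k_E, tolerance = 1e-6)
  expect_true(all(f$E >= 0))
})

test_that("discrete mass ledger matches the analytic source integral", {
  g <- build_geometry("mouse")
  p <- build_params("mouse")
  traj <- sample_shutoff(p, "deterministic")
  tt <- seq(0, 0.3, by = 1e-3)
  f <- solve_estar(g, p, traj, place_rstar(g, "half"), tt, n_rho = 6, n_theta = 8)
  exact <- vapply(tt[-1], function(t1)
    rodspr:::source_integral(traj, 0, t1, p$k_E), numeric(1))
  expect_equal(estar_total(f)[-1], exact, tolerance = 1e-9)
})

test_that("symmetric incisures leave the centred field invariant under rotation", {
  g <- build_geometry("salamander")
  p <- build_params("salamander")
  tt <- seq(0, 0.6, by = 5e-3)
  f <- solve_estar(g, p, constant_source_traj(p, rate = 100), place_rstar(g, "center"),
                   tt, n_rho = 8, n_theta = 46)
  E <- matrix(f$E[, length(tt)], 8, 46)
  # rotation by 2*pi/23 shifts two azimuthal columns
  Erot <- E[, c(3:46, 1:2)]
  expect_lt(max(abs(E - Erot)) / max(E), 1e-8)
})

test_that("incisure slits are reflecting barriers for surface diffusion", {
  # single near-full-depth incisure: mass must not cross the slit line
  g <- build_geometry("custom", disk_radius_um = 2,
                      incisures = list(incisure(0, 1.999)))
  p <- build_params("salamander", D_E = 1)
  traj <- impulse_traj(p, mass = 10)
  tt <- seq(0, 0.4, by = 5e-3)
  n_th <- 16
  pos <- place_rstar(g, "explicit", rho = 1.5, theta = 2 * pi / n_th * 1.5)
  f <- solve_estar(g, p, traj, pos, tt, n_rho = 8, n_theta = n_th)
  E <- matrix(f$E[, length(tt)], 8, n_th)
  near <- sum(E[, 2])          # column just above the slit (source side)
  far <- sum(E[, n_th])        # column just below the slit
  expect_gt(near, 1e-3)
  expect_lt(far / near, 0.2)
  # removing the incisure lets mass cross and strictly raises the far side
  g0 <- build_geometry("custom", disk_radius_um = 2, incisures = list())
  f0 <- solve_estar(g0, p, traj, pos, tt, n_rho = 8, n_theta = n_th)
  E0 <- matrix(f0$E[, length(tt)], 8, n_th)
  expect_gt(sum(E0[, n_th]), 2 * far)
})

test_that("disk solver matches the Bessel eigenfunction oracle for a centred source", {
  g <- build_geometry("salamander", incisures = list())
  p <- build_params("salamander", k_E = 0)
  r <- g$disk_radius_um
  tt <- seq(0, r^2 / (4 * p$D_E), length.out = 401)
  f <- solve_estar(g, p, constant_source_traj(p), place_rstar(g, "center"), tt,
                   n_rho = 24, n_theta = 1, source_sigma = 0)
  mesh <- f$mesh
  orc <- bessel_heat_oracle(r, p$D_E, 0, c(0, 0), max(tt), mesh$rho,
                            rep(0, length(mesh$rho)), n_m = 0, n_r = 60)
  num <- f$E[, length(tt)]
  l2 <- sqrt(sum(mesh$area * (num - orc$u)^2) / sum(mesh$area * orc$u^2))
  expect_lt(l2, 0.01)
})

test_that("instantaneous second binding reduces the two-transducin model to single mode", {
  g <- build_geometry("mouse")
  p1 <- build_params("mouse")
  p2 <- build_params("mouse", two_transducin_mode = TRUE, second_binding_rate = 1e9)
  traj <- sample_shutoff(p1, "deterministic")
  tt <- seq(0, 0.2, by = 1e-3)
  pos <- place_rstar(g, "half")
  f1 <- solve_estar(g, p1, traj, pos, tt, n_rho = 6, n_theta = 8)
  f2 <- solve_estar(g, p2, traj, pos, tt, n_rho = 6, n_theta = 8)
  expect_equal(effective_activation(f2, p2), effective_activation(f1, p1),
               tolerance = 1e-6)
})

test_that("finite second binding delays and depresses the active density", {
  g <- build_geometry("mouse")
  p2 <- build_params("mouse", two_transducin_mode = TRUE, second_binding_rate = 20)
  p1 <- build_params("mouse")
  traj <- sample_shutoff(p1, "deterministic")
  tt <- seq(0, 0.1, by = 1e-3)
  pos <- place_rstar(g, "half")
  f1 <- solve_estar(g, p1, traj, pos, tt, n_rho = 6, n_theta = 8)
  f2 <- solve_estar(g, p2, traj, pos, tt, n_rho = 6, n_theta = 8)
  expect_lt(max(estar_total(f2)), max(estar_total(f1)))
  expect_true(all(f2$E >= 0))
})
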