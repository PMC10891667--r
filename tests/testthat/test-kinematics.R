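test_that("plate summation is element-wise and validated", {
  p1 <- gaitinit:::new_plate_forces(1L, 85, c(-3, 0), c(0, 0), c(400, 400))
  p2 <- gaitinit:::new_plate_forces(2L, 85, c(3, 0), c(0, 0), c(0, 100))
  g <- sum_plate_forces(list(p1, p2))
  expect_identical(g$fz, c(400, 500))
  expect_identical(g$fx, c(0, 0))
  expect_identical(g$plate_id, "global")
  # plate 2 all zeros leaves plate 1 unchanged
  p0 <- gaitinit:::new_plate_forces(2L, 85, c(0, 0), c(0, 0), c(0, 0))
  expect_identical(sum_plate_forces(list(p1, p0))$fz, p1$fz)
  pbad <- gaitinit:::new_plate_forces(2L, 85, 1, 1, 1)
  expect_error(sum_plate_forces(list(p1, pbad)), "length mismatch")
  pfs <- gaitinit:::new_plate_forces(2L, 100, c(0, 0), c(0, 0), c(0, 0))
  expect_error(sum_plate_forces(list(p1, pfs)), "sampling rates")
})

test_that("mass estimation divides mean quiet-standing force by g", {
  expect_equal(estimate_mass(rep(686.7, 85), 85, c(0, 0.5), g = 9.81), 70,
               tolerance = 1e-12)
  set.seed(SUITE_SEED)
  fz <- 686.7 + rnorm(85, 0, 2)
  expect_lt(abs(estimate_mass(fz, 85, c(0, 0.9)) - 70), 0.1)
  expect_error(estimate_mass(rep(-5, 85), 85, c(0, 0.5)), "non-positive")
  expect_error(estimate_mass(rep(700, 85), 85, c(0, 0.1)), "0.25 s")
})

test_that("Newton's second law conversion subtracts weight on the vertical axis", {
  g <- gaitinit:::new_plate_forces("global", 85, rep(70, 10), rep(0, 10),
                                   rep(70 * 9.81, 10))
  acc <- grf_to_acceleration(g, 70)
  expect_equal(acc$ax, rep(1, 10))
  expect_equal(acc$az, rep(0, 10))
})

test_that("rectangle integration follows the left-rule error bound", {
  # constant acceleration: 85 steps of 1 m/s^2 at 85 Hz accumulate to 1 m/s
  v <- integrate_rectangles(rep(1, 86), 85)
  expect_identical(v[1], 0)
  expect_equal(v[86], 1, tolerance = 1e-12)
  expect_true(all(integrate_rectangles(rep(0, 50), 85) == 0))
  # sinusoid vs closed form, classical left-Riemann bound max|a'| * dt / 2 * t
  tt <- seq(0, 1, by = 1 / 85)
  v2 <- integrate_rectangles(sin(2 * pi * tt), 85)
  exact <- (1 - cos(2 * pi * tt)) / (2 * pi)
  expect_lt(max(abs(v2 - exact)), 2 * pi / (2 * 85))
  expect_error(integrate_rectangles(numeric(0), 85), "length")
})

test_that("backward differences are exact for linear motion and half-sample lagged", {
  fs <- 85
  tt <- seq(0, 2, by = 1 / fs)
  traj <- gaitinit:::new_com_trajectory(fs, 0.5 * 3 * tt^2, tt * 0, 1 - 0.1 * tt)
  v <- finite_difference_velocity(traj)
  expect_equal(v$vz, rep(-0.1, length(tt)), tolerance = 1e-12)
  # quadratic position: backward difference equals a * (t - dt/2) exactly
  expect_equal(v$vx[-1], 3 * (tt[-1] - 1 / (2 * fs)), tolerance = 1e-10)
  expect_identical(v$vx[1], v$vx[2])
  const <- gaitinit:::new_com_trajectory(fs, tt * 0 + 2, tt * 0, tt * 0 + 1)
  expect_true(all(unlist(finite_difference_velocity(const)) == 0))
  short <- gaitinit:::new_com_trajectory(fs, 1, 0, 1)
  expect_error(finite_difference_velocity(short), "2 samples")
})

test_that("integration and differentiation are dual up to the boundary convention", {
  set.seed(SUITE_SEED)
  fs <- 85
  acc <- lowpass_zero_phase(rnorm(300), fs, filter_spec(cutoff = 8))
  v <- integrate_rectangles(acc, fs)
  pos <- c(0, cumsum(v[-length(v)]) / fs)
  traj <- gaitinit:::new_com_trajectory(fs, pos, pos * 0, pos)
  back <- finite_difference_velocity(traj)$vx
  expect_equal(back[-1], v[-length(v)], tolerance = 1e-10)
})

test_that("both chains return zero velocity in quiet standing", {
  trl <- quiet_trial()
  fps <- fps_com_velocity(trl)
  expect_identical(fps$vx[1], 0)
  expect_identical(fps$vz[1], 0)
  expect_lt(max(abs(fps$vz)), 1e-6)
  expect_lt(max(abs(fps$vx)), 1e-6)
  mls <- mls_com_velocity(trl)
  expect_lt(max(abs(mls$vz)), 1e-6)
  expect_identical(fps$system, "FPS")
  expect_identical(mls$system, "MLS")
})

test_that("chains agree with the analytic template and with each other (noiseless)", {
  trl <- noiseless_trial(bi = 0.7, mp = 1.8)
  fps <- fps_com_velocity(trl)
  mls <- mls_com_velocity(trl)
  # both estimators natively stamp v at t - dt/2 (see methods vignette)
  t_eff <- trl$time - 1 / (2 * trl$fs)
  expect_lt(max(abs(fps$vz - trl$templates$vz(t_eff))), 0.01)
  expect_lt(max(abs(mls$vz - trl$templates$vz(t_eff))), 0.01)
  expect_lt(max(abs(fps$vx - trl$templates$vx(t_eff))), 0.01)
  expect_lt(max(abs(fps$vz - mls$vz)), 0.02)
  expect_lt(max(abs(fps$vx - mls$vx)), 0.02)
  # determinism: running the chain twice gives identical output
  expect_identical(fps$vz, fps_com_velocity(trl)$vz)
})

test_that("filtering before vs after integration barely moves the braking index", {
  trl <- noiseless_trial(bi = 0.6, mp = 1.6)
  ind <- extract_indicators(trl, "FPS")
  # alternative order: integrate raw accelerations, then filter the velocity
  global <- sum_plate_forces(trl$plates)
  mass <- estimate_mass(global$fz, trl$fs, c(0, trl$events$t_onset - 0.1))
  acc <- grf_to_acceleration(global, mass)
  vz_alt <- lowpass_zero_phase(integrate_rectangles(acc$az, trl$fs), trl$fs)
  dv <- detect_vzmin(vz_alt, trl$fs, trl$events$t_onset, ind$t_fc)
  vz_fc_alt <- vz_alt[round(ind$t_fc * trl$fs) + 1]
  bi_alt <- braking_index(dv$vz_min, vz_fc_alt)
  expect_lt(abs(bi_alt - ind$braking_index), 0.01)
})
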