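test_that("foot contact is the first sustained threshold crossing", {
  fz <- c(rep(0, 100), rep(400, 100))
  expect_equal(detect_foot_contact(fz, 85, 70), 100 / 85, tolerance = 1e-12)
  expect_error(detect_foot_contact(rep(0, 200), 85, 70), "no foot contact")
  expect_error(detect_foot_contact(rep(400, 200), 85, 70), "loaded at record start")
  # brief spikes shorter than 3 samples are ignored
  fz2 <- c(rep(0, 50), 400, 400, rep(0, 48), rep(400, 100))
  expect_equal(detect_foot_contact(fz2, 85, 70), 100 / 85, tolerance = 1e-12)
})

test_that("detected foot contact matches simulator ground truth within 2 samples", {
  for (seed in SUITE_SEED + 0:2) {
    trl <- simulate_trial(sim_config(), meta_yh(), seed)
    t_fc <- detect_foot_contact(trl$plates[[2]]$fz, trl$fs, trl$meta$mass)
    expect_lt(abs(t_fc - trl$events$t_fc), 2 / trl$fs + 1e-12)
  }
})

test_that("Vzmin detection returns the deeper, later downward peak", {
  fs <- 85
  tt <- seq(0, 2, by = 1 / fs)
  vz <- -0.06 * exp(-((tt - 0.6) / 0.08)^2) - 0.20 * exp(-((tt - 1.3) / 0.10)^2)
  d <- detect_vzmin(vz, fs, 0.3, 1.7)
  expect_equal(d$vz_min, min(vz), tolerance = 1e-12)
  expect_lt(abs(d$t_vzmin - 1.3), 0.02)
  # ties broken toward foot contact
  vz2 <- rep(0, length(tt)); vz2[c(50, 100)] <- -0.2
  expect_equal(detect_vzmin(vz2, fs, 0, 2)$t_vzmin, 99 / fs)
  # monotone decrease to the window end: minimum sits at t_fc
  vz3 <- -0.2 * pmin(tt, 1.7) / 1.7
  expect_equal(detect_vzmin(vz3, fs, 0.3, 1.7)$t_vzmin,
               tt[max(which(tt <= 1.7))])
  expect_error(detect_vzmin(abs(vz), fs, 0.3, 1.7), "no downward phase")
  expect_error(detect_vzmin(vz, fs, 3, 4), "outside the record")
})

test_that("braking index arithmetic, guards and monotonicity", {
  expect_equal(braking_index(-0.20, -0.05), 0.75)
  expect_equal(braking_index(-0.20, -0.20), 0)
  expect_equal(braking_index(-0.20, 0), 1)
  expect_error(braking_index(-0.005, 0), "degenerate Vzmin")
  expect_error(braking_index(0.1, 0), "degenerate Vzmin")
  # holding Vzmin fixed, BI strictly decreases as VzFC becomes more negative
  vz_fc <- seq(0, -0.2, by = -0.01)
  bi <- vapply(vz_fc, function(v) braking_index(-0.2, v), numeric(1))
  expect_true(all(diff(bi) < 0))
  # window containment: vz_fc >= vz_min implies BI in [0, 1] when vz_fc <= 0
  set.seed(SUITE_SEED)
  for (i in 1:50) {
    vmin <- runif(1, -0.5, -0.05)
    vfc <- runif(1, vmin, 0)
    expect_true(braking_index(vmin, vfc) >= 0 && braking_index(vmin, vfc) <= 1)
  }
})

test_that("motor performance finds the peak and flags window-edge peaks", {
  fs <- 85
  tt <- seq(0, 3, by = 1 / fs)
  vx <- 1.5 * pmin(tt / 1.72, 1) * exp(-pmax(tt - 1.72, 0))
  mp <- motor_performance(vx, fs, 0.5, 1.7)
  expect_equal(mp$mp, max(vx), tolerance = 1e-9)
  expect_false(mp$edge_peak)
  # still-rising series peaks at the window edge
  mp2 <- suppressWarnings(motor_performance(tt, fs, 0.5, 1.7))
  expect_true(mp2$edge_peak)
  expect_warning(motor_performance(tt, fs, 0.5, 2.9), "truncated")
  expect_error(motor_performance(-tt - 1, fs, 0.5, 1.7), "no forward progression")
})

test_that("noiseless indicator recovery across the BI and MP grids", {
  for (bi in c(0.1, 0.5, 0.9)) {
    trl <- noiseless_trial(bi = bi, mp = 1.8)
    for (sys in c("FPS", "MLS")) {
      ind <- extract_indicators(trl, sys)
      expect_lt(abs(ind$braking_index - bi), 0.03)
      expect_lt(abs(ind$vz_min - trl$truth$vz_min), 0.005)
    }
  }
  for (mp in c(0.8, 1.2, 1.8, 2.4)) {
    trl <- noiseless_trial(bi = 0.75, mp = mp)
    for (sys in c("FPS", "MLS")) {
      expect_lt(abs(extract_indicators(trl, sys)$mp - mp), 0.02)
    }
  }
})

test_that("extract_indicators is deterministic and cross-system consistent", {
  trl <- noiseless_trial(bi = 0.8, mp = 2.0)
  a <- extract_indicators(trl, "FPS")
  b <- extract_indicators(trl, "FPS")
  expect_identical(a[setdiff(names(a), "flags")], b[setdiff(names(b), "flags")])
  m <- extract_indicators(trl, "MLS")
  expect_lt(abs(a$braking_index - m$braking_index), 0.02)
  expect_lt(abs(a$braking_index - 0.8), 0.03)
  expect_identical(a$t_fc, m$t_fc)  # both systems share the plate-2 event
})

test_that("extraction errors carry the trial identity", {
  trl <- noiseless_trial()
  trl$plates[[2]]$fz[] <- 0
  expect_error(extract_indicators(trl, "FPS"), "YH01/MVC/trial 1/FPS")
})

test_that("indicator_table emits one tidy row per trial and system", {
  cfg <- small_config(master_seed = SUITE_SEED)
  coh <- simulate_cohort(cfg)
  tab <- indicator_table(coh)
  expect_equal(nrow(tab), length(coh) * 2)
  expect_setequal(unique(tab$system), c("FPS", "MLS"))
  expect_true(all(c("participant", "group", "condition", "trial", "system",
                    "vz_min", "vz_fc", "bi", "mp", "t_fc", "flags",
                    "true_bi", "true_mp") %in% names(tab)))
  expect_true(all(tab$bi > 0 & tab$bi <= 1.05))
})
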