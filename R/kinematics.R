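#' Sum the two force-plates into the global ground reaction force
#'
#' Element-wise algebraic sum of the per-plate 3D ground-reaction forces,
#' yielding the force acting on the whole-body center of mass.
#'
#' @param plates List of two `gi_plate_forces` (as stored in a `gi_trial`).
#' @return A `gi_plate_forces` with `plate_id = "global"`.
#' @export
sum_plate_forces <- function(plates) {
  if (length(plates) != 2L) stopf("'plates' must contain exactly two plates")
  p1 <- plates[[1L]]; p2 <- plates[[2L]]
  if (!inherits(p1, "gi_plate_forces") || !inherits(p2, "gi_plate_forces")) {
    stopf("'plates' must contain gi_plate_forces objects")
  }
  if (length(p1$fz) != length(p2$fz)) {
    stopf("plate series length mismatch: %d vs %d", length(p1$fz), length(p2$fz))
  }
  if (p1$fs != p2$fs) stopf("plate sampling rates differ: %g vs %g", p1$fs, p2$fs)
  new_plate_forces("global", p1$fs,
                   p1$fx + p2$fx, p1$fy + p2$fy, p1$fz + p2$fz)
}

#' Estimate body mass from quiet standing
#'
#' Mean vertical force over a quiet-standing window divided by g. Used to
#' subtract the participant's weight before applying Newton's second law.
#'
#' @param global_fz Global vertical force series (N).
#' @param fs Sampling rate (Hz).
#' @param quiet_window Two-element interval (s) of quiet standing; must span
#'   at least 0.25 s.
#' @param g Gravitational acceleration (m/s^2).
#' @return Mass (kg).
#' @export
estimate_mass <- function(global_fz, fs, quiet_window = c(0, 0.5), g = 9.81) {
  assert_numeric_vec(global_fz, "global_fz", min_len = 2L)
  assert_number(fs, "fs", lower = 0, strict_lower = TRUE)
  if (length(quiet_window) != 2L || diff(quiet_window) < 0.25) {
    stopf("quiet_window must span at least 0.25 s")
  }
  idx <- which((seq_along(global_fz) - 1L) / fs >= quiet_window[1L] &
               (seq_along(global_fz) - 1L) / fs <= quiet_window[2L])
  if (length(idx) < 2L) stopf("quiet_window lies outside the record")
  mfz <- mean(global_fz[idx])
  if (mfz <= 0) stopf("mean vertical force %.3g N is non-positive: participant not on plates?", mfz)
  mfz / g
}

#' COM acceleration from the global ground reaction force
#'
#' Newton's second law per axis: `ax = fx / mass`,
#' `az = (fz - mass * g) / mass` (weight subtracted from the vertical
#' component).
#'
#' @param global A `gi_plate_forces` from [sum_plate_forces()].
#' @param mass Body mass (kg).
#' @param g Gravitational acceleration (m/s^2).
#' @return List with `ax` and `az` (m/s^2).
#' @export
grf_to_acceleration <- function(global, mass, g = 9.81) {
  if (!inherits(global, "gi_plate_forces")) stopf("'global' must be a gi_plate_forces")
  assert_number(mass, "mass", lower = 0, strict_lower = TRUE)
  assert_numeric_vec(global$fx, "fx"); assert_numeric_vec(global$fz, "fz")
  list(ax = global$fx / mass, az = (global$fz - mass * g) / mass)
}

#' Velocity by the rectangles method
#'
#' Single numerical integration of acceleration with the left-rectangle rule
#' and a null initial velocity: `v[1] = 0`,
#' `v[k] = v[k-1] + acc[k-1] / fs`.
#'
#' @param acc Acceleration series (m/s^2).
#' @param fs Sampling rate (Hz).
#' @return Velocity series (m/s), same length as `acc`.
#' @export
integrate_rectangles <- function(acc, fs) {
  assert_numeric_vec(acc, "acc", min_len = 1L)
  assert_number(fs, "fs", lower = 0, strict_lower = TRUE)
  c(0, cumsum(acc[-length(acc)]) / fs)
}

#' Velocity by backward finite differences
#'
#' `v(t_k) = (p(t_k) - p(t_{k-1})) * fs` for `k >= 2`; the first sample is
#' copied from the second (the backward difference leaves it undefined and a
#' zero there would inject a spurious spike into the filter).
#'
#' @param traj A `gi_com_trajectory`.
#' @return List with `vx` and `vz` (m/s).
#' @export
finite_difference_velocity <- function(traj) {
  if (!inherits(traj, "gi_com_trajectory")) stopf("'traj' must be a gi_com_trajectory")
  n <- length(traj$x)
  if (n < 2L) stopf("need at least 2 samples for a backward difference")
  bd <- function(p) {
    v <- c(NA_real_, diff(p)) * traj$fs
    v[1L] <- v[2L]
    v
  }
  list(vx = bd(traj$x), vz = bd(traj$z))
}

new_com_velocity <- function(fs, vx, vz, system) {
  structure(list(fs = fs, vx = vx, vz = vz, system = system),
            class = "gi_com_velocity")
}

#' Force-plate chain: COM velocity from ground reaction forces
#'
#' The gold-standard estimator: plate forces are summed, body mass is
#' estimated from the quiet-standing head of the record, accelerations follow
#' from Newton's second law, are zero-phase low-pass filtered, and a single
#' rectangles integration with null initial velocity yields the COM velocity.
#'
#' @param trial A `gi_trial`.
#' @param spec A [filter_spec()].
#' @param g Gravitational acceleration (m/s^2).
#' @return A `gi_com_velocity` with `system = "FPS"`.
#' @export
fps_com_velocity <- function(trial, spec = filter_spec(), g = 9.81) {
  if (!inherits(trial, "gi_trial")) stopf("'trial' must be a gi_trial")
  global <- sum_plate_forces(trial$plates)
  qw <- if (!is.null(trial$events)) {
    c(0, max(trial$events$t_onset - 0.1, 0.25))
  } else c(0, 0.5)
  mass <- estimate_mass(global$fz, trial$fs, qw, g)
  acc <- grf_to_acceleration(global, mass, g)
  ax <- lowpass_zero_phase(acc$ax, trial$fs, spec)
  az <- lowpass_zero_phase(acc$az, trial$fs, spec)
  new_com_velocity(trial$fs,
                   integrate_rectangles(ax, trial$fs),
                   integrate_rectangles(az, trial$fs),
                   "FPS")
}

#' Markerless chain: COM velocity from positional differentiation
#'
#' Backward finite differences of the COM trajectory scaled by the
#' acquisition frequency, then zero-phase low-pass filtered.
#'
#' @param trial A `gi_trial`.
#' @param spec A [filter_spec()].
#' @return A `gi_com_velocity` with `system = "MLS"`.
#' @export
mls_com_velocity <- function(trial, spec = filter_spec()) {
  if (!inherits(trial, "gi_trial")) stopf("'trial' must be a gi_trial")
  v <- finite_difference_velocity(trial$traj)
  new_com_velocity(trial$fs,
                   lowpass_zero_phase(v$vx, trial$fs, spec),
                   lowpass_zero_phase(v$vz, trial$fs, spec),
                   "MLS")
}

#' @export
print.gi_com_velocity <- function(x, ...) {
  cat(sprintf("<gi_com_velocity> system %s | %d samples @ %g Hz | vx range [%.3f, %.3f] m/s\n",
              x$system, length(x$vx), x$fs, min(x$vx), max(x$vx)))
  invisible(x)
}
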