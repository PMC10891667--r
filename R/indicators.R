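#' Detect swing-foot contact from front-plate loading
#'
#' Foot contact is the first time the front (initially unloaded) plate's
#' vertical force exceeds `threshold_frac * mass * g` and stays above it for
#' at least 3 samples.
#'
#' @param plate2_fz Front-plate vertical force series (N).
#' @param fs Sampling rate (Hz).
#' @param mass Body mass (kg).
#' @param threshold_frac Loading threshold as a fraction of body weight.
#' @param g Gravitational acceleration (m/s^2).
#' @return Foot-contact time (s).
#' @export
detect_foot_contact <- function(plate2_fz, fs, mass, threshold_frac = 0.05, g = 9.81) {
  assert_numeric_vec(plate2_fz, "plate2_fz", min_len = 4L)
  assert_number(fs, "fs", lower = 0, strict_lower = TRUE)
  assert_number(mass, "mass", lower = 0, strict_lower = TRUE)
  thr <- threshold_frac * mass * g
  head_idx <- seq_len(max(2L, floor(0.25 * fs)))
  if (mean(plate2_fz[head_idx]) >= thr) {
    stopf("front plate loaded at record start (mean %.1f N >= threshold %.1f N)",
          mean(plate2_fz[head_idx]), thr)
  }
  above <- plate2_fz > thr
  run <- 0L
  for (i in seq_along(above)) {
    run <- if (above[i]) run + 1L else 0L
    if (run >= 3L) return((i - run) / fs)   # first sample of the run, 0-based time
  }
  stopf("no foot contact: front-plate force never exceeds %.1f N for 3 samples", thr)
}

#' Peak downward vertical COM velocity
#'
#' Global minimum of the vertical COM velocity over `[t_onset, t_fc]` — the
#' larger of the two downward lobes. Ties are broken by the latest time
#' (closest to foot contact).
#'
#' @param vz Vertical COM velocity series (m/s).
#' @param fs Sampling rate (Hz).
#' @param t_onset,t_fc Search window bounds (s).
#' @return List with `vz_min` (m/s) and `t_vzmin` (s).
#' @export
detect_vzmin <- function(vz, fs, t_onset, t_fc) {
  assert_numeric_vec(vz, "vz", min_len = 2L)
  tt <- (seq_along(vz) - 1L) / fs
  idx <- which(tt >= t_onset & tt <= t_fc)
  if (length(idx) == 0L) stopf("window [%g, %g] s is empty or outside the record", t_onset, t_fc)
  w <- vz[idx]
  vmin <- min(w)
  if (vmin >= 0) stopf("no downward phase: min vertical velocity %.4f m/s >= 0", vmin)
  at <- idx[max(which(w == vmin))]
  list(vz_min = vmin, t_vzmin = tt[at])
}

#' Braking index
#'
#' `BI = (Vzmin - VzFC) / Vzmin`: the fraction of the peak downward vertical
#' COM velocity cancelled before swing-foot contact. 1 means the fall is
#' fully braked (`VzFC = 0`); 0 means a passive fall onto the foot
#' (`VzFC = Vzmin`). Values outside the unit interval (upward contact velocity, or a
#' contact velocity below the detected minimum) are returned unclamped so
#' callers can flag them.
#'
#' @param vz_min Peak downward vertical COM velocity (m/s), < 0.
#' @param vz_fc Vertical COM velocity at foot contact (m/s).
#' @return Dimensionless braking index.
#' @export
braking_index <- function(vz_min, vz_fc) {
  assert_number(vz_min, "vz_min")
  assert_number(vz_fc, "vz_fc")
  if (vz_min >= 0 || abs(vz_min) <= 0.01) {
    stopf("degenerate Vzmin = %.4f m/s: braking index undefined (need Vzmin < -0.01)", vz_min)
  }
  (vz_min - vz_fc) / vz_min
}

#' Motor performance
#'
#' Peak anteroposterior COM velocity over `[t_onset, t_fc + post_fc_window]`
#' and its time. If the window extends past the record it is truncated to the
#' record end with a warning (the peak may then sit on the window edge).
#'
#' @param vx Anteroposterior COM velocity series (m/s).
#' @param fs Sampling rate (Hz).
#' @param t_onset Movement onset (s).
#' @param t_fc Foot-contact time (s).
#' @param post_fc_window Search extension past foot contact (s).
#' @return List with `mp` (m/s), `t_mp` (s) and `edge_peak` (logical).
#' @export
motor_performance <- function(vx, fs, t_onset, t_fc, post_fc_window = 0.3) {
  assert_numeric_vec(vx, "vx", min_len = 2L)
  tt <- (seq_along(vx) - 1L) / fs
  t_hi <- t_fc + post_fc_window
  truncated <- FALSE
  if (t_hi > tt[length(tt)]) {
    truncated <- TRUE
    t_hi <- tt[length(tt)]
    warnf("motor-performance window truncated to record end (%.3f s)", t_hi)
  }
  idx <- which(tt >= t_onset & tt <= t_hi)
  if (length(idx) == 0L) stopf("window [%g, %g] s outside the record", t_onset, t_hi)
  w <- vx[idx]
  mp <- max(w)
  if (mp <= 0) stopf("no forward progression: peak anteroposterior velocity %.4f m/s <= 0", mp)
  at <- idx[which.max(w)]
  edge <- at == idx[length(idx)]
  if (edge && !truncated) warnf("anteroposterior peak sits on the search-window edge")
  list(mp = mp, t_mp = tt[at], edge_peak = edge)
}

# fallback onset detector: first time |vx| stays above 0.02 m/s for >= 5 samples
detect_onset <- function(vx, fs, threshold = 0.02, min_run = 5L) {
  above <- abs(vx) > threshold
  run <- 0L
  for (i in seq_along(above)) {
    run <- if (above[i]) run + 1L else 0L
    if (run >= min_run) return((i - run) / fs)
  }
  stopf("no movement onset detected (|vx| never exceeds %g m/s for %d samples)",
        threshold, min_run)
}

#' Extract the biomechanical indicators from one trial
#'
#' Runs the requested measurement chain (force-plate or markerless), detects
#' foot contact from front-plate loading (shared by both systems — the two
#' systems are hardware-synchronized), and computes the braking index and
#' motor performance.
#'
#' @param trial A `gi_trial`.
#' @param system `"FPS"` or `"MLS"`.
#' @param spec A [filter_spec()].
#' @param post_fc_window Motor-performance search extension (s).
#' @param threshold_frac Foot-contact loading threshold (fraction of body
#'   weight).
#' @param g Gravitational acceleration (m/s^2).
#' @return An object of class `gi_indicators`: `system`, `vz_min`, `t_vzmin`,
#'   `vz_fc`, `braking_index`, `mp`, `t_mp`, `t_fc`, `t_onset`, `flags`
#'   (character).
#' @export
extract_indicators <- function(trial, system = c("FPS", "MLS"),
                               spec = filter_spec(),
                               post_fc_window = 0.3,
                               threshold_frac = 0.05,
                               g = 9.81) {
  system <- match.arg(system)
  if (!inherits(trial, "gi_trial")) stopf("'trial' must be a gi_trial")
  id <- sprintf("%s/%s/trial %d/%s", trial$meta$participant_id,
                trial$meta$condition, trial$meta$trial_index, system)
  withCallingHandlers({
    mass <- trial$meta$mass %||%
      estimate_mass(sum_plate_forces(trial$plates)$fz, trial$fs, g = g)
    t_fc <- detect_foot_contact(trial$plates[[2L]]$fz, trial$fs, mass,
                                threshold_frac = threshold_frac, g = g)
    vel <- if (system == "FPS") fps_com_velocity(trial, spec, g) else
      mls_com_velocity(trial, spec)
    t_onset <- if (!is.null(trial$events)) trial$events$t_onset else
      detect_onset(vel$vx, trial$fs)
    dvz <- detect_vzmin(vel$vz, trial$fs, t_onset, t_fc)
    i_fc <- round(t_fc * trial$fs) + 1L
    vz_fc <- vel$vz[i_fc]
    bi <- braking_index(dvz$vz_min, vz_fc)
    mpres <- motor_performance(vel$vx, trial$fs, t_onset, t_fc, post_fc_window)
    flags <- character(0)
    if (bi > 1) flags <- c(flags, "bi_gt_1")
    if (bi < 0) flags <- c(flags, "bi_lt_0")
    if (mpres$edge_peak) flags <- c(flags, "mp_edge_peak")
    structure(list(system = system, vz_min = dvz$vz_min, t_vzmin = dvz$t_vzmin,
                   vz_fc = vz_fc, braking_index = bi,
                   mp = mpres$mp, t_mp = mpres$t_mp,
                   t_fc = t_fc, t_onset = t_onset, flags = flags),
              class = "gi_indicators")
  }, error = function(e) {
    stopf("indicator extraction failed for %s: %s", id, conditionMessage(e))
  })
}

#' Tidy indicator table for a set of trials
#'
#' Runs [extract_indicators()] for every trial and system and returns the
#' tidy per-trial table consumed by the agreement statistics.
#'
#' @param trials A `gi_cohort` or list of `gi_trial` objects.
#' @param systems Character vector of systems to run.
#' @param ... Passed to [extract_indicators()].
#' @return data.frame with columns participant, group, condition, trial,
#'   system, vz_min, vz_fc, bi, mp, t_fc, flags (";"-separated), and, when
#'   the trials carry simulator ground truth, true_bi and true_mp.
#' @export
indicator_table <- function(trials, systems = c("FPS", "MLS"), ...) {
  rows <- list()
  for (trl in trials) {
    for (sys in systems) {
      ind <- extract_indicators(trl, sys, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        participant = trl$meta$participant_id,
        group = trl$meta$group,
        condition = trl$meta$condition,
        trial = trl$meta$trial_index,
        system = sys,
        vz_min = ind$vz_min, vz_fc = ind$vz_fc,
        bi = ind$braking_index, mp = ind$mp,
        t_fc = ind$t_fc,
        flags = paste(ind$flags, collapse = ";"),
        true_bi = if (!is.null(trl$truth)) trl$truth$braking_index else NA_real_,
        true_mp = if (!is.null(trl$truth)) trl$truth$mp else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' @export
print.gi_indicators <- function(x, ...) {
  cat(sprintf("<gi_indicators> %s | BI %.3f (Vzmin %.3f, VzFC %.3f m/s) | MP %.3f m/s @ %.3f s%s\n",
              x$system, x$braking_index, x$vz_min, x$vz_fc, x$mp, x$t_mp,
              if (length(x$flags)) paste0(" | flags: ", paste(x$flags, collapse = ",")) else ""))
  invisible(x)
}
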