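new_plate_forces <- function(plate_id, fs, fx, fy, fz) {
  n <- length(fx)
  if (length(fy) != n || length(fz) != n) stopf("plate force series must share length")
  structure(list(plate_id = plate_id, fs = fs, fx = fx, fy = fy, fz = fz),
            class = "gi_plate_forces")
}

new_com_trajectory <- function(fs, x, y, z) {
  n <- length(x)
  if (length(y) != n || length(z) != n) stopf("trajectory series must share length")
  assert_numeric_vec(x, "x"); assert_numeric_vec(y, "y"); assert_numeric_vec(z, "z")
  structure(list(fs = fs, x = x, y = y, z = z), class = "gi_com_trajectory")
}

# band-limited Gaussian noise: white noise low-passed and rescaled to sd
drift_noise <- function(n, sd, cutoff_hz, fs) {
  w <- stats::rnorm(n)
  if (sd <= 0) return(numeric(n))
  d <- lowpass_zero_phase(w, fs, filter_spec(cutoff = cutoff_hz, order = 2))
  s <- stats::sd(d)
  if (s < .Machine$double.eps) return(numeric(n))
  d / s * sd
}

#' Simulate one gait-initiation trial
#'
#' Synthesizes a mutually consistent pair of measurement-system inputs from
#' the analytic velocity templates of [build_velocity_templates()]: the COM
#' trajectory is the exact closed-form integral of the templates, and the
#' total ground reaction force follows Newton's second law,
#' `Fz_total = m (g + az)` and `Fx_total = m ax`, so that running either
#' processing chain on a noiseless trial must recover the template (the
#' "physics oracle"). The total force rests entirely on plate 1 until foot
#' contact, after which a linear ramp transfers `transfer_frac` of the load
#' to plate 2 over `transfer_ramp_s`; the plate sum preserves the total to
#' machine precision. Gaussian sensor noise is added last (white on forces,
#' band-limited on positions, see [sim_config()]).
#'
#' @param config A [sim_config()].
#' @param meta A [trial_meta()].
#' @param seed Integer seed; the same seed reproduces the trial bitwise.
#' @param bi_true,mp_true True indicator values; drawn from the group preset
#'   when `NULL`.
#' @param events A [gait_events()]; jittered from the config means when `NULL`.
#' @return An object of class `gi_trial` with elements `meta`, `plates` (list
#'   of two plate force sets), `traj`, `events`, `truth`, `time`, `fs`.
#' @export
simulate_trial <- function(config, meta, seed, bi_true = NULL, mp_true = NULL,
                           events = NULL) {
  if (!inherits(config, "gi_sim_config")) stopf("'config' must be a gi_sim_config")
  if (!inherits(meta, "gi_trial_meta")) stopf("'meta' must be a gi_trial_meta")
  assert_number(seed, "seed")
  set.seed(as.integer(seed))

  fs <- config$fs
  n <- floor(config$trial_duration * fs) + 1L
  tt <- (seq_len(n) - 1L) / fs

  # 1) events (jittered, ordering preserved)
  if (is.null(events)) {
    j <- stats::rnorm(3L, 0, config$event_jitter_sd)
    on <- config$t_onset + j[1L]
    fo <- max(config$t_foot_off + j[2L], on + 0.25)
    fc <- max(config$t_fc + j[3L], fo + 0.2)
    fc <- min(fc, config$trial_duration - 0.5)
    events <- gait_events(on, fo, fc)
  } else if (!inherits(events, "gi_events")) {
    events <- do.call(gait_events, as.list(events)[c("t_onset", "t_foot_off", "t_fc")])
  }

  # 2) true indicators
  preset <- config$group_presets[[meta$group]]
  if (is.null(preset)) stopf("no preset for group '%s'", meta$group)
  if (is.null(bi_true)) {
    bi_true <- clamp(stats::rnorm(1L, preset$bi_mean, preset$bi_sd), 0.05, 0.98)
  }
  if (is.null(mp_true)) {
    mp_mean <- if (meta$condition == "MVC") preset$mp_mean_mvc else preset$mp_mean_svc
    mp_true <- max(stats::rnorm(1L, mp_mean, preset$mp_sd), 0.3)
  }

  tpl <- build_velocity_templates(bi_true, mp_true, events,
                                  trial_duration = config$trial_duration)

  m <- meta$mass
  fz_total <- m * (config$g + tpl$az(tt))
  fx_total <- m * tpl$ax(tt)

  # plate split: everything on plate 1 before foot contact, then a linear
  # ramp moves transfer_frac of the load to plate 2
  w2 <- config$transfer_frac *
    pmin(pmax((tt - events$t_fc) / config$transfer_ramp_s, 0), 1)
  fz2 <- w2 * fz_total
  fx2 <- w2 * fx_total
  fz1 <- fz_total - fz2
  fx1 <- fx_total - fx2

  x <- tpl$x(tt)
  z <- config$com_height_m + tpl$z(tt)

  # 3) noise, fixed draw order for reproducibility
  ns <- config$noise
  noisy <- function(v) v + stats::rnorm(n, ns$force_bias, ns$force_sd)
  p1 <- new_plate_forces(1L, fs, noisy(fx1), noisy(numeric(n)), noisy(fz1))
  p2 <- new_plate_forces(2L, fs, noisy(fx2), noisy(numeric(n)), noisy(fz2))
  pos_noise <- function() {
    drift_noise(n, ns$pos_sd, ns$pos_drift_hz, fs) + ns$pos_bias
  }
  traj <- new_com_trajectory(fs, x + pos_noise(), pos_noise(), z + pos_noise())

  truth <- tpl$truth
  truth$system <- "truth"

  structure(list(meta = meta, plates = list(p1, p2), traj = traj,
                 events = events, truth = truth, templates = tpl,
                 time = tt, fs = fs, seed = as.integer(seed)),
            class = "gi_trial")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Simulate a full gait-initiation cohort
#'
#' Emits `n_participants x groups x 2 conditions x n_trials` trials. True
#' braking index and motor performance are drawn once per participant and
#' condition from the group presets, then jittered per trial with half the
#' preset SD, giving within-participant variance. All randomness derives
#' deterministically from `config$master_seed` (participant-level draws from
#' the master seed, per-trial seeds from a counter), so cohort generation is
#' a pure function of the config.
#'
#' @param config A [sim_config()].
#' @return A list of `gi_trial` objects with a `manifest` attribute
#'   (data.frame: participant, group, condition, trial, mass, seed, true_bi,
#'   true_mp, t_onset, t_foot_off, t_fc).
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "gi_sim_config")) stopf("'config' must be a gi_sim_config")
  groups <- names(config$group_presets)
  conditions <- c("SVC", "MVC")
  set.seed(config$master_seed)

  plan <- list()
  for (gname in groups) {
    preset <- config$group_presets[[gname]]
    for (p in seq_len(config$n_participants)) {
      pid <- sprintf("%s%02d", gname, p)
      mass <- max(stats::rnorm(1L, config$mass_mean, config$mass_sd), 40)
      for (cond in conditions) {
        bi_pc <- clamp(stats::rnorm(1L, preset$bi_mean, preset$bi_sd), 0.05, 0.98)
        mp_mean <- if (cond == "MVC") preset$mp_mean_mvc else preset$mp_mean_svc
        mp_pc <- max(stats::rnorm(1L, mp_mean, preset$mp_sd), 0.3)
        for (tr in seq_len(config$n_trials)) {
          bi_t <- clamp(stats::rnorm(1L, bi_pc, preset$bi_sd / 2), 0.05, 0.98)
          mp_t <- max(stats::rnorm(1L, mp_pc, preset$mp_sd / 2), 0.3)
          plan[[length(plan) + 1L]] <- list(pid = pid, group = gname,
                                            cond = cond, tr = tr, mass = mass,
                                            bi = bi_t, mp = mp_t)
        }
      }
    }
  }

  trials <- vector("list", length(plan))
  man <- vector("list", length(plan))
  for (i in seq_along(plan)) {
    pl <- plan[[i]]
    seed_i <- derive_seed(config$master_seed, i)
    meta <- trial_meta(pl$pid, pl$group, pl$cond, pl$tr, pl$mass)
    trl <- simulate_trial(config, meta, seed_i, bi_true = pl$bi, mp_true = pl$mp)
    trials[[i]] <- trl
    man[[i]] <- data.frame(participant = pl$pid, group = pl$group,
                           condition = pl$cond, trial = pl$tr, mass = pl$mass,
                           seed = seed_i, true_bi = pl$bi, true_mp = pl$mp,
                           t_onset = trl$events$t_onset,
                           t_foot_off = trl$events$t_foot_off,
                           t_fc = trl$events$t_fc,
                           stringsAsFactors = FALSE)
  }
  attr(trials, "manifest") <- do.call(rbind, man)
  attr(trials, "config") <- config
  class(trials) <- "gi_cohort"
  trials
}

#' @export
print.gi_trial <- function(x, ...) {
  cat(sprintf("<gi_trial> %s %s %s trial %d | %d samples @ %g Hz | mass %.1f kg\n",
              x$meta$participant_id, x$meta$group, x$meta$condition,
              x$meta$trial_index, length(x$time), x$fs, x$meta$mass))
  cat(sprintf("  events: onset %.3f s, foot-off %.3f s, foot contact %.3f s\n",
              x$events$t_onset, x$events$t_foot_off, x$events$t_fc))
  if (!is.null(x$truth)) {
    cat(sprintf("  truth: BI %.3f, MP %.3f m/s, Vzmin %.3f m/s\n",
                x$truth$braking_index, x$truth$mp, x$truth$vz_min))
  }
  invisible(x)
}

#' @export
print.gi_cohort <- function(x, ...) {
  man <- attr(x, "manifest")
  cat(sprintf("<gi_cohort> %d trials | %d participants | groups: %s\n",
              length(x), length(unique(man$participant)),
              paste(unique(man$group), collapse = ", ")))
  invisible(x)
}
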