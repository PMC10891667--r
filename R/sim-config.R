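#' Default per-group indicator presets
#'
#' Group-level means and SDs of the true braking index (BI) and motor
#' performance (MP) used by the cohort simulator. The defaults are tunable
#' qualitative choices, ordered so that patients with Parkinson's disease
#' (PD) brake less than young (YH) and elderly (EH) healthy adults, and so
#' that MP is ordered PD < EH < YH with a clear maximal-velocity (MVC) gain
#' over the spontaneous condition (SVC).
#'
#' @return A named list, one entry per group (`YH`, `EH`, `PD`), each with
#'   `bi_mean`, `bi_sd` (dimensionless), `mp_mean_svc`, `mp_mean_mvc`,
#'   `mp_sd` (m/s).
#' @export
group_presets_default <- function() {
  list(
    YH = list(bi_mean = 0.75, bi_sd = 0.10, mp_mean_svc = 1.4, mp_mean_mvc = 2.2, mp_sd = 0.15),
    EH = list(bi_mean = 0.72, bi_sd = 0.10, mp_mean_svc = 1.2, mp_mean_mvc = 1.9, mp_sd = 0.15),
    PD = list(bi_mean = 0.40, bi_sd = 0.12, mp_mean_svc = 1.0, mp_mean_mvc = 1.4, mp_sd = 0.15)
  )
}

#' Simulation configuration
#'
#' Collects every knob of the synthetic gait-initiation cohort: study design
#' (3 groups x 2 velocity conditions x `n_trials` trials per participant),
#' sampling, event timing, group presets, sensor-noise model and body mass
#' distribution.
#'
#' The noise model adds white Gaussian noise to each force channel and
#' band-limited ("drift"-like) Gaussian noise to each COM position channel:
#' white noise low-passed at `pos_drift_hz` and rescaled to marginal SD
#' `pos_sd`. Markerless COM errors are dominated by slowly varying
#' segment-model and pose errors; per-frame white positional jitter would be
#' amplified by the differentiation step into velocity noise far in excess of
#' what the downstream 15 Hz filtering can remove, and would bias the
#' extreme-value indicators of the markerless chain relative to the
#' force-plate chain (see the methods vignette).
#'
#' @param master_seed Integer seed from which all trial seeds derive.
#' @param fs Sampling rate (Hz), shared by both systems.
#' @param trial_duration Trial length (s).
#' @param t_onset,t_foot_off,t_fc Mean event times (s); per-trial values are
#'   jittered with SD `event_jitter_sd` preserving ordering.
#' @param event_jitter_sd SD of the per-trial event-time jitter (s).
#' @param group_presets See [group_presets_default()].
#' @param n_participants Participants per group.
#' @param n_trials Trials per participant per velocity condition.
#' @param noise List with `force_sd` (N), `pos_sd` (m), `force_bias` (N),
#'   `pos_bias` (m), `pos_drift_hz` (Hz).
#' @param mass_mean,mass_sd Body-mass distribution (kg).
#' @param g Gravitational acceleration (m/s^2).
#' @param com_height_m Standing COM height used as the vertical position
#'   baseline (m).
#' @param transfer_frac Fraction of the total load transferred to the front
#'   plate by the end of the post-contact ramp.
#' @param transfer_ramp_s Duration of the load-transfer ramp after foot
#'   contact (s).
#' @return An object of class `gi_sim_config`.
#' @export
sim_config <- function(master_seed = 1L,
                       fs = 85,
                       trial_duration = 3.0,
                       t_onset = 0.8,
                       t_foot_off = 1.35,
                       t_fc = 1.70,
                       event_jitter_sd = 0.03,
                       group_presets = group_presets_default(),
                       n_participants = 10L,
                       n_trials = 5L,
                       noise = list(force_sd = 2, pos_sd = 0.002,
                                    force_bias = 0, pos_bias = 0,
                                    pos_drift_hz = 0.5),
                       mass_mean = 70,
                       mass_sd = 12,
                       g = 9.81,
                       com_height_m = 1.0,
                       transfer_frac = 0.7,
                       transfer_ramp_s = 0.15) {
  assert_number(master_seed, "master_seed", lower = 0, upper = 2^31 - 1)
  assert_number(fs, "fs", lower = 0, strict_lower = TRUE)
  assert_number(trial_duration, "trial_duration", lower = 0, strict_lower = TRUE)
  if (!(0 < t_onset && t_onset < t_foot_off && t_foot_off < t_fc &&
        t_fc < trial_duration)) {
    stopf("need 0 < t_onset < t_foot_off < t_fc < trial_duration (got %g, %g, %g, %g)",
          t_onset, t_foot_off, t_fc, trial_duration)
  }
  assert_number(event_jitter_sd, "event_jitter_sd", lower = 0)
  assert_number(n_participants, "n_participants", lower = 1)
  assert_number(n_trials, "n_trials", lower = 1)
  for (nm in c("force_sd", "pos_sd", "force_bias", "pos_bias", "pos_drift_hz")) {
    if (is.null(noise[[nm]])) stopf("noise$%s missing", nm)
  }
  assert_number(noise$force_sd, "noise$force_sd", lower = 0)
  assert_number(noise$pos_sd, "noise$pos_sd", lower = 0)
  assert_number(noise$pos_drift_hz, "noise$pos_drift_hz",
                lower = 0, upper = fs / 2, strict_lower = TRUE, strict_upper = TRUE)
  assert_number(mass_mean, "mass_mean", lower = 0, strict_lower = TRUE)
  assert_number(mass_sd, "mass_sd", lower = 0)
  assert_number(g, "g", lower = 0, strict_lower = TRUE)
  assert_number(transfer_frac, "transfer_frac", lower = 0, upper = 1)
  assert_number(transfer_ramp_s, "transfer_ramp_s", lower = 0, strict_lower = TRUE)
  if (!is.list(group_presets) || length(group_presets) == 0L) {
    stopf("group_presets must be a non-empty named list")
  }
  for (gname in names(group_presets)) {
    p <- group_presets[[gname]]
    assert_number(p$bi_mean, paste0(gname, "$bi_mean"),
                  lower = 0, upper = 1, strict_lower = TRUE)
    assert_number(p$bi_sd, paste0(gname, "$bi_sd"), lower = 0)
    assert_number(p$mp_mean_svc, paste0(gname, "$mp_mean_svc"), lower = 0, strict_lower = TRUE)
    assert_number(p$mp_mean_mvc, paste0(gname, "$mp_mean_mvc"), lower = 0, strict_lower = TRUE)
    assert_number(p$mp_sd, paste0(gname, "$mp_sd"), lower = 0)
  }
  structure(list(
    master_seed = as.integer(master_seed), fs = fs,
    trial_duration = trial_duration,
    t_onset = t_onset, t_foot_off = t_foot_off, t_fc = t_fc,
    event_jitter_sd = event_jitter_sd,
    group_presets = group_presets,
    n_participants = as.integer(n_participants),
    n_trials = as.integer(n_trials),
    noise = noise,
    mass_mean = mass_mean, mass_sd = mass_sd, g = g,
    com_height_m = com_height_m,
    transfer_frac = transfer_frac, transfer_ramp_s = transfer_ramp_s
  ), class = "gi_sim_config")
}

#' Trial metadata
#'
#' @param participant_id Participant identifier string.
#' @param group One of the configured groups (default levels `YH`, `EH`, `PD`).
#' @param condition Velocity condition, `"SVC"` or `"MVC"`.
#' @param trial_index Trial number within the condition.
#' @param mass Body mass (kg).
#' @return An object of class `gi_trial_meta`.
#' @export
trial_meta <- function(participant_id, group, condition, trial_index, mass) {
  stopifnot(is.character(participant_id), length(participant_id) == 1L)
  group <- match.arg(group, c("YH", "EH", "PD"))
  condition <- match.arg(condition, c("SVC", "MVC"))
  assert_number(trial_index, "trial_index", lower = 1)
  assert_number(mass, "mass", lower = 0, strict_lower = TRUE)
  structure(list(participant_id = participant_id, group = group,
                 condition = condition, trial_index = as.integer(trial_index),
                 mass = mass),
            class = "gi_trial_meta")
}
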