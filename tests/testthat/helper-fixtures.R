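# Shared fixtures. All fixed-seed tests use SUITE_SEED (pre-registered).
SUITE_SEED <- 20240217L

noiseless_config <- function(...) {
  sim_config(noise = list(force_sd = 0, pos_sd = 0, force_bias = 0,
                          pos_bias = 0, pos_drift_hz = 0.5),
             event_jitter_sd = 0, ...)
}

small_config <- function(...) {
  sim_config(n_participants = 2L, n_trials = 2L, ...)
}

meta_yh <- function(mass = 70) trial_meta("YH01", "YH", "MVC", 1L, mass)

noiseless_trial <- function(bi = 0.75, mp = 1.8, seed = SUITE_SEED, mass = 70) {
  simulate_trial(noiseless_config(), trial_meta("YH01", "YH", "MVC", 1L, mass),
                 seed, bi_true = bi, mp_true = mp)
}

# quiet-standing-only trial: constant forces m*g on plate 1, constant positions
quiet_trial <- function(mass = 70, fs = 85, duration = 3, g = 9.81) {
  n <- floor(duration * fs) + 1L
  zero <- numeric(n)
  structure(list(
    meta = trial_meta("QS01", "YH", "SVC", 1L, mass),
    plates = list(
      gaitinit:::new_plate_forces(1L, fs, zero, zero, rep(mass * g, n)),
      gaitinit:::new_plate_forces(2L, fs, zero, zero, zero)
    ),
    traj = gaitinit:::new_com_trajectory(fs, zero, zero, rep(1, n)),
    events = NULL, truth = NULL,
    time = (seq_len(n) - 1L) / fs, fs = fs, seed = NA_integer_
  ), class = "gi_trial")
}
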