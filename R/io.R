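fmt_num <- function(x) sprintf("%.17g", x)

#' Write a trial to CSV
#'
#' Plain UTF-8 CSV with a `#`-prefixed key-value header (metadata, events,
#' sampling rate, simulator truth when present) followed by the data columns
#' `time_s, fx1, fy1, fz1, fx2, fy2, fz2, com_x, com_y, com_z`. Numbers are
#' written with 17 significant digits so a write-read-write round trip is
#' byte-identical.
#'
#' @param trial A `gi_trial`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(trial, path) {
  if (!inherits(trial, "gi_trial")) stopf("'trial' must be a gi_trial")
  hdr <- c(
    sprintf("# participant_id,%s", trial$meta$participant_id),
    sprintf("# group,%s", trial$meta$group),
    sprintf("# condition,%s", trial$meta$condition),
    sprintf("# trial_index,%d", trial$meta$trial_index),
    sprintf("# mass,%s", fmt_num(trial$meta$mass)),
    sprintf("# fs,%s", fmt_num(trial$fs)),
    sprintf("# t_onset,%s", fmt_num(trial$events$t_onset)),
    sprintf("# t_foot_off,%s", fmt_num(trial$events$t_foot_off)),
    sprintf("# t_fc,%s", fmt_num(trial$events$t_fc))
  )
  if (!is.null(trial$truth)) {
    hdr <- c(hdr,
             sprintf("# true_bi,%s", fmt_num(trial$truth$braking_index)),
             sprintf("# true_mp,%s", fmt_num(trial$truth$mp)))
  }
  p1 <- trial$plates[[1L]]; p2 <- trial$plates[[2L]]
  cols <- list(trial$time, p1$fx, p1$fy, p1$fz, p2$fx, p2$fy, p2$fz,
               trial$traj$x, trial$traj$y, trial$traj$z)
  body <- do.call(paste, c(lapply(cols, fmt_num), sep = ","))
  writeLines(c(hdr,
               "time_s,fx1,fy1,fz1,fx2,fy2,fz2,com_x,com_y,com_z",
               body), path)
  invisible(path)
}

#' Read a trial from CSV
#'
#' Inverse of [write_trial_csv()]. Schema violations (missing columns,
#' malformed header, non-uniform time base) raise line-numbered errors.
#'
#' @param path Input file path.
#' @return A `gi_trial`.
#' @export
read_trial_csv <- function(path) {
  if (!file.exists(path)) stopf("no such trial file: %s", path)
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "# ")
  n_hdr <- sum(cumprod(is_hdr))              # leading header block only
  kv <- list()
  for (i in seq_len(n_hdr)) {
    parts <- strsplit(sub("^# ", "", lines[i]), ",", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) stopf("%s:%d: malformed header line", path, i)
    kv[[parts[1L]]] <- parts[2L]
  }
  for (key in c("participant_id", "group", "condition", "trial_index", "mass",
                "fs", "t_onset", "t_foot_off", "t_fc")) {
    if (is.null(kv[[key]])) stopf("%s: missing header key '%s'", path, key)
  }
  header_line <- n_hdr + 1L
  cols <- strsplit(lines[header_line], ",", fixed = TRUE)[[1L]]
  want <- c("time_s", "fx1", "fy1", "fz1", "fx2", "fy2", "fz2",
            "com_x", "com_y", "com_z")
  miss <- setdiff(want, cols)
  if (length(miss)) {
    stopf("%s:%d: missing column(s): %s", path, header_line,
          paste(miss, collapse = ", "))
  }
  dat <- utils::read.csv(text = paste(lines[(header_line):length(lines)],
                                      collapse = "\n"))
  fs <- as.numeric(kv$fs)
  dt <- diff(dat$time_s)
  bad <- which(dt <= 0 | dt > 1.5 / fs)
  if (length(bad)) {
    stopf("%s:%d: non-uniform time base (step %.6g s, expected %.6g s)",
          path, header_line + bad[1L] + 1L, dt[bad[1L]], 1 / fs)
  }
  meta <- trial_meta(kv$participant_id, kv$group, kv$condition,
                     as.integer(kv$trial_index), as.numeric(kv$mass))
  events <- gait_events(as.numeric(kv$t_onset), as.numeric(kv$t_foot_off),
                        as.numeric(kv$t_fc))
  truth <- NULL
  if (!is.null(kv$true_bi)) {
    truth <- list(braking_index = as.numeric(kv$true_bi),
                  mp = as.numeric(kv$true_mp))
  }
  structure(list(
    meta = meta,
    plates = list(new_plate_forces(1L, fs, dat$fx1, dat$fy1, dat$fz1),
                  new_plate_forces(2L, fs, dat$fx2, dat$fy2, dat$fz2)),
    traj = new_com_trajectory(fs, dat$com_x, dat$com_y, dat$com_z),
    events = events, truth = truth,
    time = dat$time_s, fs = fs, seed = NA_integer_
  ), class = "gi_trial")
}

#' Write a simulated cohort to a directory
#'
#' One CSV per trial plus `manifest.csv` (participant, group, condition,
#' trial, mass, seed, true indicators, event times, file) and `config.json`
#' (the full simulation config with its hash and the master seed).
#'
#' @param cohort A `gi_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The manifest data.frame, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  if (!inherits(cohort, "gi_cohort")) stopf("'cohort' must be a gi_cohort")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- attr(cohort, "manifest")
  files <- character(length(cohort))
  for (i in seq_along(cohort)) {
    trl <- cohort[[i]]
    files[i] <- sprintf("trial_%s_%s_%02d.csv", trl$meta$participant_id,
                        trl$meta$condition, trl$meta$trial_index)
    write_trial_csv(trl, file.path(dir, files[i]))
  }
  man$file <- files
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  cfg <- attr(cohort, "config")
  cfg_json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  writeLines(jsonlite::prettify(cfg_json), file.path(dir, "config.json"))
  writeLines(c(sprintf("config_hash,%s", fnv1a32(cfg_json)),
               sprintf("master_seed,%d", cfg$master_seed)),
             file.path(dir, "run_manifest.csv"))
  invisible(man)
}

#' Read a cohort directory written by [write_cohort_csv()]
#'
#' @param dir Directory containing `manifest.csv` and trial CSVs.
#' @return A `gi_cohort` (list of `gi_trial` with a `manifest` attribute).
#' @export
read_cohort_csv <- function(dir) {
  man_path <- file.path(dir, "manifest.csv")
  if (!file.exists(man_path)) stopf("no manifest.csv in %s", dir)
  man <- utils::read.csv(man_path, stringsAsFactors = FALSE)
  trials <- lapply(man$file, function(f) read_trial_csv(file.path(dir, f)))
  attr(trials, "manifest") <- man
  class(trials) <- "gi_cohort"
  trials
}
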