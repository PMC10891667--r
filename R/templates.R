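#' Gait-initiation event times
#'
#' Bundles the three landmark times of a gait-initiation trial: onset of the
#' anticipatory phase, swing-foot lift-off, and swing-foot contact.
#'
#' @param t_onset Movement onset time (s).
#' @param t_foot_off Swing-foot lift-off time (s).
#' @param t_fc Swing-foot contact time (s).
#' @return An object of class `gi_events`.
#' @export
gait_events <- function(t_onset, t_foot_off, t_fc) {
  assert_number(t_onset, "t_onset", lower = 0, strict_lower = TRUE)
  assert_number(t_foot_off, "t_foot_off")
  assert_number(t_fc, "t_fc")
  if (!(t_onset < t_foot_off && t_foot_off < t_fc)) {
    stopf("gait events must be strictly ordered: t_onset < t_foot_off < t_fc (got %g, %g, %g)",
          t_onset, t_foot_off, t_fc)
  }
  structure(list(t_onset = t_onset, t_foot_off = t_foot_off, t_fc = t_fc),
            class = "gi_events")
}

# ---- piecewise quintic "smoothstep" curve engine ------------------------
#
# Between consecutive knots (t_i, y_i) the curve follows
#   y(t) = y_i + (y_{i+1} - y_i) * S(u),  u = (t - t_i)/(t_{i+1} - t_i)
# with S(u) = 6u^5 - 15u^4 + 10u^3.  S' and S'' vanish at both ends, so the
# assembled curve is C^2 with zero slope and zero curvature at every knot,
# and value, first/second derivative and running integral all have closed
# forms. Constant extrapolation outside the knot range.

new_gi_curve <- function(t, y) {
  if (is.unsorted(t, strictly = TRUE)) stopf("curve knot times must be strictly increasing")
  w <- diff(t)
  dy <- diff(y)
  seg_int <- y[-length(y)] * w + 0.5 * dy * w   # integral of each segment
  structure(list(t = t, y = y, w = w, dy = dy, cum = c(0, cumsum(seg_int))),
            class = "gi_curve")
}

curve_eval <- function(crv, tt, what = c("value", "d1", "d2", "integral")) {
  what <- match.arg(what)
  n <- length(crv$t)
  i <- findInterval(tt, crv$t)
  out <- numeric(length(tt))
  pre <- i == 0L
  post <- i >= n
  mid <- !pre & !post
  if (what == "value") {
    out[pre] <- crv$y[1L]
    out[post] <- crv$y[n]
  } else if (what == "integral") {
    out[pre] <- (tt[pre] - crv$t[1L]) * crv$y[1L]
    out[post] <- crv$cum[n] + (tt[post] - crv$t[n]) * crv$y[n]
  }
  if (any(mid)) {
    j <- i[mid]
    u <- (tt[mid] - crv$t[j]) / crv$w[j]
    out[mid] <- switch(what,
      value = crv$y[j] + crv$dy[j] * (u * u * u * (10 + u * (-15 + 6 * u))),
      d1 = crv$dy[j] / crv$w[j] * (30 * u * u * (1 + u * (-2 + u))),
      d2 = crv$dy[j] / (crv$w[j]^2) * (60 * u * (1 + u * (-3 + 2 * u))),
      integral = crv$cum[j] + crv$y[j] * (tt[mid] - crv$t[j]) +
        crv$dy[j] * crv$w[j] * (u^4 * (2.5 + u * (-3 + u)))
    )
  }
  out
}

#' Analytic center-of-mass velocity templates for one simulated trial
#'
#' Builds closed-form vertical and anteroposterior COM velocity curves with a
#' known braking index and motor performance, reproducing the canonical
#' gait-initiation morphology: the vertical velocity shows a small downward
#' lobe just before swing-foot lift-off, a larger downward peak (`Vzmin`)
#' before swing-foot contact, and an active braking phase pinning the contact
#' velocity to `VzFC = (1 - bi_true) * Vzmin`; the anteroposterior velocity
#' rises monotonically to its peak (`mp_true`) shortly after foot contact.
#'
#' The curves are assembled from piecewise quintic smoothstep segments whose
#' first and second derivatives vanish at every knot, so velocity,
#' acceleration and position are all evaluable in closed form at any time —
#' this is what makes the simulator usable as a physics oracle for the two
#' measurement pipelines.
#'
#' @param bi_true True braking index, in (0, 1].
#' @param mp_true True motor performance (peak anteroposterior COM velocity,
#'   m/s), > 0.
#' @param events A [gait_events()] object.
#' @param trial_duration Trial length (s); must leave room for the post-contact
#'   decay (`t_fc + 0.45 <= trial_duration`).
#' @param vz_amp Amplitude of the main downward lobe `|Vzmin|` (m/s). Default
#'   `0.15 + 0.1 * mp_true`, scaling the vertical fall with forward vigor.
#' @param t_mp_offset Delay of the anteroposterior peak after foot contact (s).
#' @return A list with closures `vz`, `vx` (velocities, m/s), `az`, `ax`
#'   (accelerations, m/s^2), `x`, `z` (positions relative to the start, m),
#'   and a `truth` list holding the implied indicator values.
#' @export
build_velocity_templates <- function(bi_true, mp_true, events,
                                     trial_duration = 3,
                                     vz_amp = NULL,
                                     t_mp_offset = 0.03) {
  assert_number(bi_true, "bi_true", lower = 0, upper = 1, strict_lower = TRUE)
  assert_number(mp_true, "mp_true", lower = 0, strict_lower = TRUE)
  if (!inherits(events, "gi_events")) {
    events <- do.call(gait_events, as.list(events)[c("t_onset", "t_foot_off", "t_fc")])
  }
  assert_number(t_mp_offset, "t_mp_offset", lower = 0, strict_lower = TRUE)
  if (events$t_fc + t_mp_offset + 0.42 > trial_duration) {
    stopf("trial_duration = %g too short for t_fc = %g (need >= t_fc + %g)",
          trial_duration, events$t_fc, t_mp_offset + 0.42)
  }
  A <- vz_amp %||% (0.15 + 0.1 * mp_true)
  assert_number(A, "vz_amp", lower = 0.02, strict_lower = TRUE)

  swing <- events$t_fc - events$t_foot_off
  t_d1 <- events$t_foot_off - 0.04          # first (smaller) downward peak
  t_vzmin <- events$t_fc - max(0.4 * swing, 0.12)
  if (t_vzmin <= t_d1 + 0.08) t_vzmin <- t_d1 + 0.08
  t_reb <- (t_d1 + t_vzmin) / 2             # partial rebound between the lobes
  if (t_d1 <= events$t_onset) {
    stopf("events too tight: first downward lobe at %g precedes onset %g", t_d1, events$t_onset)
  }

  vz_crv <- new_gi_curve(
    t = c(0, events$t_onset, t_d1, t_reb, t_vzmin, events$t_fc, events$t_fc + 0.35),
    y = c(0, 0, -0.30 * A, -0.12 * A, -A, -(1 - bi_true) * A, 0)
  )

  t_mp <- events$t_fc + t_mp_offset
  if (events$t_fc - 0.12 <= events$t_onset) {
    stopf("events too tight: t_fc - t_onset must exceed 0.12 s (got %g)",
          events$t_fc - events$t_onset)
  }
  vx_crv <- new_gi_curve(
    t = c(0, events$t_onset, events$t_fc - 0.12, t_mp, t_mp + 0.25, trial_duration),
    y = c(0, 0, 0.90 * mp_true, mp_true, 0.82 * mp_true, 0.78 * mp_true)
  )

  list(
    vz = function(t) curve_eval(vz_crv, t, "value"),
    vx = function(t) curve_eval(vx_crv, t, "value"),
    az = function(t) curve_eval(vz_crv, t, "d1"),
    ax = function(t) curve_eval(vx_crv, t, "d1"),
    z = function(t) curve_eval(vz_crv, t, "integral"),
    x = function(t) curve_eval(vx_crv, t, "integral"),
    truth = list(
      braking_index = bi_true,
      mp = mp_true,
      vz_min = -A,
      vz_fc = -(1 - bi_true) * A,
      t_vzmin = t_vzmin,
      t_mp = t_mp,
      t_fc = events$t_fc
    ),
    events = events
  )
}
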