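#' Bland-Altman agreement analysis
#'
#' Trial-paired agreement between the markerless (MLS) and force-plate (FPS)
#' values of an indicator. Differences are `MLS - FPS` (the force-plate
#' system is the gold standard, so a positive difference reads as markerless
#' overestimation). Bias is the mean difference, the 95% limits of agreement
#' are `bias +/- 1.96 * SD` of the differences (sample SD, n-1 denominator),
#' and the relative (percentage) analogues use the per-pair mean of the two
#' systems as denominator. Normality of the differences is checked with the
#' Shapiro-Wilk test.
#'
#' @param fps_values,mls_values Paired indicator values, equal length n >= 3.
#' @param stratum Optional label (e.g. group x condition) carried in the
#'   result.
#' @return An object of class `gi_bland_altman` with fields `n`, `bias`,
#'   `sd_diff`, `loa_low`, `loa_high`, `rel_bias`, `rel_loa_low`,
#'   `rel_loa_high` (percent; `NA` and flagged when any pair mean is zero),
#'   `shapiro_W`, `shapiro_p`, `stratum`, plus per-pair `means` and `diffs`.
#' @export
bland_altman <- function(fps_values, mls_values, stratum = NULL) {
  assert_numeric_vec(fps_values, "fps_values", min_len = 3L)
  assert_numeric_vec(mls_values, "mls_values", min_len = 3L)
  n <- length(fps_values)
  if (length(mls_values) != n) stopf("paired series length mismatch: %d vs %d",
                                     n, length(mls_values))
  diffs <- mls_values - fps_values
  means <- (mls_values + fps_values) / 2
  bias <- mean(diffs)
  sd_diff <- stats::sd(diffs)
  loa_low <- bias - 1.96 * sd_diff
  loa_high <- bias + 1.96 * sd_diff

  rel_undefined <- any(means == 0)
  if (rel_undefined) {
    rel_bias <- rel_loa_low <- rel_loa_high <- NA_real_
  } else {
    rel <- 100 * diffs / means
    rel_bias <- mean(rel)
    rel_sd <- stats::sd(rel)
    rel_loa_low <- rel_bias - 1.96 * rel_sd
    rel_loa_high <- rel_bias + 1.96 * rel_sd
  }

  # Shapiro-Wilk is defined for 3..5000 non-constant values; outside that the
  # normality check is reported as NA rather than blocking the agreement stats
  sw <- if (sd_diff > 0 && n <= 5000L) shapiro_normality(diffs) else
    list(W = NA_real_, p = NA_real_)

  structure(list(n = n, bias = bias, sd_diff = sd_diff,
                 loa_low = loa_low, loa_high = loa_high,
                 rel_bias = rel_bias, rel_loa_low = rel_loa_low,
                 rel_loa_high = rel_loa_high,
                 rel_undefined = rel_undefined,
                 shapiro_W = sw$W, shapiro_p = sw$p,
                 stratum = stratum, means = means, diffs = diffs),
            class = "gi_bland_altman")
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper around [stats::shapiro.test()] (Royston approximation) with
#' the sample-size preconditions made explicit.
#'
#' @param x Numeric sample, 3 <= n <= 5000, non-constant.
#' @return List with `W` and `p`.
#' @export
shapiro_normality <- function(x) {
  assert_numeric_vec(x, "x", min_len = 3L)
  if (length(x) > 5000L) stopf("Shapiro-Wilk requires n <= 5000 (got %d)", length(x))
  if (stats::sd(x) == 0) stopf("Shapiro-Wilk undefined for constant input")
  sw <- stats::shapiro.test(x)
  list(W = unname(sw$statistic), p = sw$p.value)
}

#' Reliability verdict from relative limits of agreement
#'
#' Applies the conventional screening rule that both relative 95% limits of
#' agreement must be below 10% in absolute value for the alternative system
#' to be considered reliable. The comparison is strict: a limit exactly at
#' the threshold fails.
#'
#' @param ba A [bland_altman()] result.
#' @param threshold_pct Reliability threshold (percent).
#' @return List with `reliable` (logical) and `worst_rel_limit_pct`.
#' @export
reliability_verdict <- function(ba, threshold_pct = 10) {
  if (!inherits(ba, "gi_bland_altman")) stopf("'ba' must be a gi_bland_altman")
  if (isTRUE(ba$rel_undefined) || is.na(ba$rel_loa_low) || is.na(ba$rel_loa_high)) {
    stopf("relative limits of agreement are undefined for this stratum")
  }
  worst <- max(abs(ba$rel_loa_low), abs(ba$rel_loa_high))
  list(reliable = worst < threshold_pct, worst_rel_limit_pct = worst)
}

#' @export
print.gi_bland_altman <- function(x, ...) {
  cat(sprintf("<gi_bland_altman>%s n = %d\n",
              if (!is.null(x$stratum)) paste0(" [", paste(x$stratum, collapse = " "), "]") else "",
              x$n))
  cat(sprintf("  bias %.4f, SD %.4f, 95%% LoA [%.4f, %.4f]\n",
              x$bias, x$sd_diff, x$loa_low, x$loa_high))
  if (!isTRUE(x$rel_undefined)) {
    cat(sprintf("  relative: bias %.2f%%, LoA [%.2f%%, %.2f%%]\n",
                x$rel_bias, x$rel_loa_low, x$rel_loa_high))
  }
  cat(sprintf("  Shapiro-Wilk W = %.4f, p = %.4g\n", x$shapiro_W, x$shapiro_p))
  invisible(x)
}
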