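#' Full between-system agreement battery
#'
#' Runs, from a tidy indicator table, the statistical battery used to
#' compare the markerless and force-plate systems: per-stratum
#' (group x condition) Bland-Altman analyses with Shapiro-Wilk normality
#' checks and reliability verdicts for both indicators, paired JZS Bayes
#' factors 01 (trial-level pairs, with a prior-robustness curve), and the
#' mixed-design ANOVA with Tukey post hoc contrasts.
#'
#' @param indicator_table Tidy table from [indicator_table()] containing both
#'   systems.
#' @param r Cauchy prior scale for the Bayes factors.
#' @param unit ANOVA analysis unit, see [mixed_anova()].
#' @param threshold_pct Reliability threshold for [reliability_verdict()].
#' @return An object of class `gi_agreement`: `bland_altman` (data.frame, one
#'   row per stratum x dv), `bf` (list of `gi_bf` keyed by dv), `anova` (list
#'   of `gi_anova`), `posthoc_group` (list of data.frames), `ba_objects`.
#' @export
agreement_battery <- function(indicator_table, r = 0.707,
                              unit = "participant_mean", threshold_pct = 10) {
  tab <- indicator_table
  need <- c("participant", "group", "condition", "trial", "system", "bi", "mp")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stopf("indicator table lacks column(s): %s", paste(miss, collapse = ", "))

  key <- c("participant", "condition", "trial")
  fps <- tab[tab$system == "FPS", ]
  mls <- tab[tab$system == "MLS", ]
  if (!nrow(fps) || !nrow(mls)) stopf("indicator table must contain both systems")
  merged <- merge(fps, mls, by = c(key, "group"), suffixes = c("_fps", "_mls"))

  ba_rows <- list()
  ba_objects <- list()
  for (gname in unique(merged$group)) {
    for (cond in unique(merged$condition)) {
      sub <- merged[merged$group == gname & merged$condition == cond, ]
      if (nrow(sub) < 3L) next
      for (dv in c("bi", "mp")) {
        ba <- bland_altman(sub[[paste0(dv, "_fps")]], sub[[paste0(dv, "_mls")]],
                           stratum = c(gname, cond))
        verdict <- tryCatch(reliability_verdict(ba, threshold_pct),
                            error = function(e) list(reliable = NA,
                                                     worst_rel_limit_pct = NA_real_))
        ba_objects[[paste(gname, cond, dv, sep = "_")]] <- ba
        ba_rows[[length(ba_rows) + 1L]] <- data.frame(
          group = gname, condition = cond, dv = dv, n = ba$n,
          bias = ba$bias, sd_diff = ba$sd_diff,
          loa_low = ba$loa_low, loa_high = ba$loa_high,
          rel_bias = ba$rel_bias, rel_loa_low = ba$rel_loa_low,
          rel_loa_high = ba$rel_loa_high,
          shapiro_W = ba$shapiro_W, shapiro_p = ba$shapiro_p,
          reliable = verdict$reliable,
          worst_rel_limit_pct = verdict$worst_rel_limit_pct,
          stringsAsFactors = FALSE)
      }
    }
  }

  bf <- list(bi = jzs_bf01_paired(merged$bi_fps, merged$bi_mls, r = r),
             mp = jzs_bf01_paired(merged$mp_fps, merged$mp_mls, r = r))
  anova <- list(bi = mixed_anova(tab, "bi", unit),
                mp = mixed_anova(tab, "mp", unit))
  posthoc_group <- list(bi = tukey_posthoc(tab, "group", "bi"),
                        mp = tukey_posthoc(tab, "group", "mp"))

  structure(list(bland_altman = do.call(rbind, ba_rows),
                 bf = bf, anova = anova, posthoc_group = posthoc_group,
                 ba_objects = ba_objects, n_pairs = nrow(merged)),
            class = "gi_agreement")
}

#' Descriptive statistics in the group x condition x system layout
#'
#' Mean and SD of each indicator per group, velocity condition and
#' measurement system (participant means as the unit).
#'
#' @param indicator_table Tidy table from [indicator_table()].
#' @return data.frame with group, condition, system, dv, mean, sd, n.
#' @export
descriptives_table <- function(indicator_table) {
  rows <- list()
  for (dv in c("bi", "mp")) {
    pm <- stats::aggregate(indicator_table[[dv]],
                           by = indicator_table[c("participant", "group",
                                                  "condition", "system")],
                           FUN = mean)
    agg_m <- stats::aggregate(x ~ group + condition + system, data = pm, FUN = mean)
    agg_s <- stats::aggregate(x ~ group + condition + system, data = pm, FUN = stats::sd)
    agg_n <- stats::aggregate(x ~ group + condition + system, data = pm, FUN = length)
    out <- agg_m
    names(out)[names(out) == "x"] <- "mean"
    out$sd <- agg_s$x
    out$n <- agg_n$x
    out$dv <- dv
    rows[[dv]] <- out[, c("group", "condition", "system", "dv", "mean", "sd", "n")]
  }
  do.call(rbind, rows)
}

#' @export
print.gi_agreement <- function(x, ...) {
  cat(sprintf("<gi_agreement> %d trial pairs\n", x$n_pairs))
  cat("Bland-Altman per stratum:\n")
  print(x$bland_altman, digits = 4)
  cat(sprintf("BF01 (braking index): %.3f | BF01 (motor performance): %.3f\n",
              x$bf$bi$bf01, x$bf$mp$bf01))
  invisible(x)
}
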