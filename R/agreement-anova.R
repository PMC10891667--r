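prepare_anova_data <- function(indicator_table, dv, unit) {
  need <- c("participant", "group", "condition", "system", dv)
  miss <- setdiff(need, names(indicator_table))
  if (length(miss)) stopf("indicator table lacks column(s): %s", paste(miss, collapse = ", "))
  df <- indicator_table
  df$dv <- df[[dv]]
  if (unit == "participant_mean") {
    df <- stats::aggregate(dv ~ participant + group + condition + system,
                           data = df, FUN = mean)
  }
  df$participant <- factor(df$participant)
  df$group <- factor(df$group)
  df$velocity <- factor(df$condition)
  df$system <- factor(df$system)
  # balanced-enough check: every participant x velocity x system cell non-empty
  cells <- table(df$participant, df$velocity, df$system)
  if (any(cells == 0L)) {
    bad <- which(cells == 0L, arr.ind = TRUE)[1L, ]
    stopf("empty design cell: participant %s, velocity %s, system %s",
          dimnames(cells)[[1L]][bad[1L]], dimnames(cells)[[2L]][bad[2L]],
          dimnames(cells)[[3L]][bad[3L]])
  }
  df
}

#' Mixed-design repeated-measures ANOVA
#'
#' Univariate mixed ANOVA on an indicator with velocity condition and
#' measurement system as within-subject factors and group as the
#' between-subject factor, fitted with [stats::aov()] error strata
#' (`Error(participant/(velocity*system))`). The default analysis unit is
#' the participant-condition-system mean; `unit = "trial"` pools trials
#' (trial replicates then feed the residual stratum).
#'
#' @param indicator_table Tidy table from [indicator_table()].
#' @param dv Dependent variable: `"bi"` or `"mp"`.
#' @param unit `"participant_mean"` or `"trial"`.
#' @return An object of class `gi_anova`: `effects` (data.frame with effect,
#'   df1, df2, F, p), `dv`, `unit`, plus the underlying `aov` fit and data.
#' @export
mixed_anova <- function(indicator_table, dv = c("bi", "mp"),
                        unit = c("participant_mean", "trial")) {
  dv <- match.arg(dv)
  unit <- match.arg(unit)
  df <- prepare_anova_data(indicator_table, dv, unit)

  fit <- stats::aov(dv ~ group * velocity * system +
                      Error(participant / (velocity * system)), data = df)
  sm <- summary(fit)
  degenerate <- stats::var(df$dv) < 1e-20   # constant dv: report F = 0, p = 1

  rows <- list()
  for (stratum in sm) {
    tab <- stratum[[1L]]
    terms <- trimws(rownames(tab))
    res <- which(terms == "Residuals")
    if (!length(res)) next
    df2 <- tab[res, "Df"]
    ms_err <- tab[res, "Mean Sq"]
    for (i in seq_len(nrow(tab))) {
      if (i == res) next
      ss <- tab[i, "Sum Sq"]
      Fv <- tab[i, "F value"]
      pv <- tab[i, "Pr(>F)"]
      # constant-dv degenerate case (0/0 up to rounding noise)
      if (degenerate || !is.finite(Fv)) {
        if (degenerate || ss < 1e-12) { Fv <- 0; pv <- 1 } else {
          Fv <- NA_real_; pv <- NA_real_
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        effect = gsub("velocity", "velocity", terms[i]),
        df1 = tab[i, "Df"], df2 = df2, F = Fv, p = pv,
        stringsAsFactors = FALSE)
    }
  }
  effects <- do.call(rbind, rows)
  structure(list(effects = effects, dv = dv, unit = unit, fit = fit, data = df),
            class = "gi_anova")
}

anova_effect <- function(an, effect) {
  i <- match(effect, an$effects$effect)
  if (is.na(i)) stopf("effect '%s' not found; available: %s", effect,
                      paste(an$effects$effect, collapse = ", "))
  an$effects[i, ]
}

#' Tukey post hoc contrasts
#'
#' All pairwise Tukey-adjusted contrasts for a main effect of the mixed
#' design. For the between-subject factor (`group`) this is the classical
#' Tukey HSD on participant means (averaged over the within factors). For a
#' within-subject factor the data are aggregated to participant x level
#' means and the contrasts use the pooled cell-mean error; with two levels
#' this reduces to an unpaired comparison and is conservative relative to
#' the within-subject stratum F test.
#'
#' @param indicator_table Tidy table from [indicator_table()].
#' @param effect `"group"`, `"velocity"` or `"system"`.
#' @param dv Dependent variable: `"bi"` or `"mp"`.
#' @return data.frame with contrast, diff, p_adj.
#' @export
tukey_posthoc <- function(indicator_table, effect = c("group", "velocity", "system"),
                          dv = c("bi", "mp")) {
  effect <- match.arg(effect)
  dv <- match.arg(dv)
  df <- prepare_anova_data(indicator_table, dv, "participant_mean")
  fac <- df[[effect]]
  if (nlevels(factor(fac)) < 2L) stopf("effect '%s' has fewer than 2 levels", effect)

  agg <- stats::aggregate(dv ~ participant + level,
                          data = data.frame(dv = df$dv,
                                            participant = df$participant,
                                            level = fac),
                          FUN = mean)
  agg$level <- factor(agg$level)
  fit <- stats::aov(dv ~ level, data = agg)
  th <- stats::TukeyHSD(fit)$level
  data.frame(contrast = rownames(th), diff = th[, "diff"],
             p_adj = th[, "p adj"], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' @export
print.gi_anova <- function(x, ...) {
  cat(sprintf("<gi_anova> dv = %s, unit = %s\n", x$dv, x$unit))
  eff <- x$effects
  for (i in seq_len(nrow(eff))) {
    cat(sprintf("  %-25s F(%d, %d) = %8.3f, p = %.4g\n",
                eff$effect[i], eff$df1[i], eff$df2[i], eff$F[i], eff$p[i]))
  }
  invisible(x)
}
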