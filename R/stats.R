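# Statistical analyses: stage binning, the Condition x Band ANOVA with
# Tukey HSD post hoc tests, the Stage x Condition ANOVAs on Alpha and
# TBR, and stage-profile summaries.
#
# The ANOVAs are pooled two-way fixed-effects analyses treating every
# epoch x channel observation as independent; this matches the residual
# degrees of freedom of the design (e.g. 1440 task rows -> residual df
# 1434 for the 2x3 stage analysis). A participant-aggregated variant
# (mean per participant x cell) is available for data where pooling is
# not defensible.

#' Assign the experiment stage from a trial's presentation index
#'
#' Trials are binned by order of appearance into three equal stages:
#' with 12 trials, 1-4 -> first, 5-8 -> middle, 9-12 -> last.
#'
#' @param trial_index Integer vector of 1-based presentation indices.
#' @param n_trials Trials per condition (default 12); must be a multiple
#'   of 3.
#' @return Factor with levels `first`, `middle`, `last`.
#' @export
assign_stage <- function(trial_index, n_trials = 12) {
  if (n_trials %% 3 != 0 || n_trials < 3) {
    eeg_abort("eegdwt_bad_trial_index", "n_trials must be a positive multiple of 3")
  }
  ti <- as.integer(trial_index)
  if (any(is.na(ti)) || any(ti < 1 | ti > n_trials)) {
    eeg_abort("eegdwt_bad_trial_index",
              sprintf("trial_index outside 1..%d", n_trials))
  }
  bin <- ceiling(ti / (n_trials / 3))
  factor(c("first", "middle", "last")[bin],
         levels = c("first", "middle", "last"))
}

# Shared two-way fixed-effects ANOVA core: y ~ A * B fitted by stats::aov,
# returned as an eeg_anova object with the cell-mean table attached.
.two_way_anova <- function(df, a_name, b_name, measure_name) {
  df$A <- factor(df$A)
  df$B <- factor(df$B)
  cells <- tapply(df$y, list(df$A, df$B), mean)
  total_ss <- sum((df$y - mean(df$y))^2)
  if (total_ss <= .Machine$double.eps * length(df$y)) {
    terms <- data.frame(
      term = c(a_name, b_name, paste0(a_name, ":", b_name)),
      df = c(nlevels(df$A) - 1, nlevels(df$B) - 1,
             (nlevels(df$A) - 1) * (nlevels(df$B) - 1)),
      sum_sq = 0, mean_sq = 0, statistic = NA_real_, p_value = NA_real_)
    return(structure(list(terms = terms,
                          residual_df = nrow(df) - nlevels(df$A) * nlevels(df$B),
                          residual_ss = 0, cell_means = cells,
                          measure = measure_name, n = nrow(df),
                          degenerate = TRUE),
                     class = "eeg_anova"))
  }
  fit <- stats::aov(y ~ A * B, data = df)
  tab <- summary(fit)[[1]]
  rn <- trimws(rownames(tab))
  pick <- function(term) which(rn == term)
  terms <- data.frame(
    term = c(a_name, b_name, paste0(a_name, ":", b_name)),
    df = tab$Df[c(pick("A"), pick("B"), pick("A:B"))],
    sum_sq = tab$`Sum Sq`[c(pick("A"), pick("B"), pick("A:B"))],
    mean_sq = tab$`Mean Sq`[c(pick("A"), pick("B"), pick("A:B"))],
    statistic = tab$`F value`[c(pick("A"), pick("B"), pick("A:B"))],
    p_value = tab$`Pr(>F)`[c(pick("A"), pick("B"), pick("A:B"))])
  res <- pick("Residuals")
  structure(list(terms = terms, residual_df = tab$Df[res],
                 residual_ss = tab$`Sum Sq`[res], cell_means = cells,
                 measure = measure_name, n = nrow(df), degenerate = FALSE,
                 fit = fit),
            class = "eeg_anova")
}

#' @export
print.eeg_anova <- function(x, ...) {
  cat(sprintf("Two-way ANOVA on %s (N = %d%s)\n", x$measure, x$n,
              if (x$degenerate) "; DEGENERATE: zero variance" else ""))
  tab <- x$terms
  tab$F <- sprintf("%.3f", tab$statistic)
  tab$p <- format.pval(tab$p_value, digits = 3, eps = 1e-16)
  print(tab[, c("term", "df", "F", "p")], row.names = FALSE)
  cat(sprintf("Residual df: %d\n", x$residual_df))
  invisible(x)
}

# Exclude flagged rows; optionally aggregate to participant x cell means.
.analysis_rows <- function(features, cols, aggregate_by_participant) {
  keep <- !features$degenerate & stats::complete.cases(features[, cols, drop = FALSE])
  df <- features[keep, , drop = FALSE]
  df
}

#' Condition x Frequency-band ANOVA on relative energies
#'
#' The time-free analysis: a two-way ANOVA with Condition (rest, picking,
#' coordination) and Frequency band (Theta, Alpha, Beta) as factors and
#' the relative band energy as the dependent variable, one observation
#' per epoch x channel x band. Delta contributes to the relative-energy
#' denominator but is not a factor level here.
#'
#' @param features Feature table from [build_feature_table()].
#' @param bands Band factor levels (default Theta/Alpha/Beta).
#' @param aggregate_by_participant If `TRUE`, average observations within
#'   participant x condition x band before fitting (repeated-measures
#'   style summary for real data); default `FALSE` (pooled, df-consistent
#'   with the design).
#' @return An `eeg_anova` object; the interaction has
#'   `(3-1)(3-1) = 4` numerator df.
#' @export
anova_condition_band <- function(features, bands = c("theta", "alpha", "beta"),
                                 aggregate_by_participant = FALSE) {
  cols <- paste0("rel_", bands)
  missing_cols <- setdiff(cols, names(features))
  if (length(missing_cols)) {
    eeg_abort("eegdwt_missing_level",
              sprintf("feature table lacks %s", paste(missing_cols, collapse = ", ")))
  }
  df <- .analysis_rows(features, cols, aggregate_by_participant)
  if (length(unique(df$condition)) < 2) {
    eeg_abort("eegdwt_missing_level", "need at least 2 condition levels")
  }
  long <- data.frame(
    participant_id = rep(df$participant_id, times = length(bands)),
    y = unlist(df[, cols], use.names = FALSE),
    A = rep(df$condition, times = length(bands)),
    B = rep(bands, each = nrow(df))
  )
  if (aggregate_by_participant) {
    long <- stats::aggregate(y ~ participant_id + A + B, long, mean)
  }
  .two_way_anova(long, "condition", "band", "relative energy")
}

#' Tukey HSD post hoc contrasts between conditions within one band
#'
#' All pairwise condition contrasts on the relative energy of one
#' frequency band, with studentized-range adjusted p-values and a
#' significance flag at 0.05.
#'
#' @param features Feature table.
#' @param band One of `"theta"`, `"alpha"`, `"beta"`.
#' @param alpha Family-wise significance threshold (default 0.05).
#' @return Data frame (class `eeg_tukey`) with one row per condition
#'   pair: `band`, `contrast`, `diff`, `lwr`, `upr`, `p_adj`, `significant`.
#' @export
tukey_posthoc <- function(features, band, alpha = 0.05) {
  if (!band %in% c("theta", "alpha", "beta")) {
    eeg_abort("eegdwt_bad_tag", sprintf("unknown band '%s'", band))
  }
  col <- paste0("rel_", band)
  df <- .analysis_rows(features, col, FALSE)
  if (length(unique(df$condition)) < 2) {
    eeg_abort("eegdwt_missing_level", "need at least 2 condition levels")
  }
  dat <- data.frame(y = df[[col]], condition = factor(df$condition))
  hsd <- stats::TukeyHSD(stats::aov(y ~ condition, data = dat))$condition
  out <- data.frame(
    band = band,
    contrast = rownames(hsd),
    diff = hsd[, "diff"],
    lwr = hsd[, "lwr"],
    upr = hsd[, "upr"],
    p_adj = hsd[, "p adj"],
    row.names = NULL
  )
  out$significant <- out$p_adj < alpha
  class(out) <- c("eeg_tukey", "data.frame")
  out
}

#' Stage x Condition ANOVA on a temporal measure
#'
#' The time-on-task analysis: a two-way ANOVA with Stage (first, middle,
#' last) and task Condition (picking, coordination) as factors, on the
#' relative Alpha energy or the TBR, one observation per epoch x channel.
#' Rest epochs carry no trial index and are excluded. For the full design
#' (10 participants x 2 conditions x 12 trials x 6 electrodes = 1440
#' rows) the residual df is 1434.
#'
#' @param features Feature table.
#' @param measure `"rel_alpha"` or `"tbr"`.
#' @param aggregate_by_participant As in [anova_condition_band()].
#' @return An `eeg_anova` object.
#' @export
anova_stage_condition <- function(features, measure = c("rel_alpha", "tbr"),
                                  aggregate_by_participant = FALSE) {
  measure <- match.arg(measure)
  df <- .analysis_rows(features, measure, aggregate_by_participant)
  df <- df[df$condition %in% c("picking", "coordination") & !is.na(df$stage), ,
           drop = FALSE]
  if (length(unique(df$condition)) < 2 || length(unique(df$stage)) < 3) {
    eeg_abort("eegdwt_missing_level",
              "need both task conditions and all three stages")
  }
  long <- data.frame(participant_id = df$participant_id, y = df[[measure]],
                     A = factor(df$stage, levels = c("first", "middle", "last")),
                     B = df$condition)
  if (aggregate_by_participant) {
    long <- stats::aggregate(y ~ participant_id + A + B, long, mean)
  }
  .two_way_anova(long, "stage", "condition", measure)
}

#' Stage-profile cell means
#'
#' Mean and standard error of a measure per (task condition, stage) -
#' the 2 x 3 table behind the stage-trajectory plots and the
#' programmed-effect recovery check.
#'
#' @param features Feature table.
#' @param measure `"rel_alpha"` or `"tbr"`.
#' @return Data frame (class `eeg_stage_profile`) with `condition`,
#'   `stage`, `mean`, `se`, `n`.
#' @export
stage_profile <- function(features, measure = c("rel_alpha", "tbr")) {
  measure <- match.arg(measure)
  df <- .analysis_rows(features, measure, FALSE)
  df <- df[df$condition %in% c("picking", "coordination") & !is.na(df$stage), ,
           drop = FALSE]
  cells <- expand.grid(condition = c("picking", "coordination"),
                       stage = c("first", "middle", "last"),
                       stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    y <- df[[measure]][df$condition == cells$condition[i] &
                         df$stage == cells$stage[i]]
    if (length(y) == 0) {
      eeg_abort("eegdwt_empty_cell",
                sprintf("no observations for (%s, %s)", cells$condition[i],
                        cells$stage[i]))
    }
    data.frame(condition = cells$condition[i], stage = cells$stage[i],
               mean = mean(y), se = stats::sd(y) / sqrt(length(y)),
               n = length(y))
  })
  out <- do.call(rbind, rows)
  attr(out, "measure") <- measure
  class(out) <- c("eeg_stage_profile", "data.frame")
  out
}

#' Plot stage trajectories per condition
#'
#' Mean +/- 1 SE of the measure across the three experiment stages, one
#' line per task condition.
#'
#' @param profile An `eeg_stage_profile` from [stage_profile()].
#' @param main Plot title.
#' @return The profile, invisibly.
#' @export
plot_stage_profile <- function(profile, main = attr(profile, "measure")) {
  stages <- c("first", "middle", "last")
  conds <- unique(profile$condition)
  cols <- c(picking = "firebrick", coordination = "navy")
  ylim <- range(profile$mean - profile$se, profile$mean + profile$se)
  graphics::plot(NA, xlim = c(0.8, 3.2), ylim = ylim, xaxt = "n",
                 xlab = "experiment stage", ylab = attr(profile, "measure"),
                 main = main)
  graphics::axis(1, at = 1:3, labels = stages)
  for (cn in conds) {
    sub <- profile[profile$condition == cn, ]
    xs <- match(sub$stage, stages)
    o <- order(xs)
    graphics::lines(xs[o], sub$mean[o], col = cols[[cn]], lwd = 2, type = "b", pch = 16)
    graphics::arrows(xs, sub$mean - sub$se, xs, sub$mean + sub$se,
                     angle = 90, code = 3, length = 0.04, col = cols[[cn]])
  }
  graphics::legend("topleft", legend = conds, col = cols[conds], lwd = 2, bty = "n")
  invisible(profile)
}
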