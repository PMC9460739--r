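# Independent oracles and fixture factories used across the suite.

# Fraction of periodogram power in [lo, hi) Hz, over [0, fs/2]. Serves as
# the FFT band-power oracle against which DWT band fractions are checked.
fft_band_fraction <- function(x, fs, lo, hi) {
  n <- length(x)
  P <- Mod(stats::fft(x))^2
  half <- P[seq_len(floor(n / 2) + 1)]
  f <- (seq_along(half) - 1) * fs / n
  sum(half[f >= lo & f < hi]) / sum(half)
}

# FFT amplitude of the component at frequency f (assumes f is a Fourier
# frequency of the window).
fft_amplitude <- function(x, fs, f) {
  n <- length(x)
  2 * Mod(stats::fft(x))[round(f * n / fs) + 1] / n
}

# Brute-force two-way fixed-effects ANOVA from the weighted
# sum-of-squares partition (exact for balanced and proportional cell
# frequencies); independent of stats::aov.
ss_anova_oracle <- function(y, A, B) {
  A <- factor(A); B <- factor(B)
  a <- nlevels(A); b <- nlevels(B); N <- length(y)
  m <- mean(y)
  mi <- tapply(y, A, mean)
  mj <- tapply(y, B, mean)
  mij <- tapply(y, list(A, B), mean)
  nij <- table(A, B)
  ss_a <- sum(rowSums(nij) * (mi - m)^2)
  ss_b <- sum(colSums(nij) * (mj - m)^2)
  ss_cells <- sum(nij * (mij - m)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_e <- sum((y - mij[cbind(A, B)])^2)
  df <- c(a - 1, b - 1, (a - 1) * (b - 1))
  df_e <- N - a * b
  F <- (c(ss_a, ss_b, ss_ab) / df) / (ss_e / df_e)
  list(F = F, df = df, df_e = df_e,
       p = stats::pf(F, df, df_e, lower.tail = FALSE))
}

# Two-sample permutation test on the absolute mean difference.
perm_test <- function(x, y, n_perm = 2000) {
  obs <- abs(mean(x) - mean(y))
  pooled <- c(x, y)
  n <- length(x)
  hits <- 0
  for (i in seq_len(n_perm)) {
    idx <- sample(length(pooled), n)
    if (abs(mean(pooled[idx]) - mean(pooled[-idx])) >= obs) hits <- hits + 1
  }
  (hits + 1) / (n_perm + 1)
}

# Scaled-down cohort configuration for simulation studies: 128 Hz
# acquisition, short rest/trials. The full 16-channel montage is kept
# because average re-referencing couples channels through the montage
# mean; the analysis table dimensions (10 participants x 2 conditions x
# 12 trials x 6 frontal electrodes) are those of the full design.
fast_config <- function(seed = 1, map = amplitude_map_default(), ...) {
  sim_config(n_participants = 10, channels = default_montage(),
             fs_raw = 128, trial_duration = 1, rest_duration = 2,
             inter_trial_gap = 0.25, band_amplitude_map = map,
             seed = seed, ...)
}

# Minimal cohort for structural pipeline tests.
tiny_config <- function(seed = 1, n_participants = 2, ...) {
  sim_config(n_participants = n_participants, channels = frontal_electrodes(),
             fs_raw = 128, trial_duration = 1, rest_duration = 2,
             inter_trial_gap = 0.25, seed = seed, ...)
}

# Synthetic balanced feature table with programmable cell means for the
# stage/condition analysis (bypasses signal generation entirely).
synthetic_stage_table <- function(n_per_cell, mean_fun = function(cond, stage) 0,
                                  sd = 1) {
  cells <- expand.grid(condition = c("picking", "coordination"),
                       stage = c("first", "middle", "last"),
                       stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    stage_trials <- list(first = 1:4, middle = 5:8, last = 9:12)[[cells$stage[i]]]
    data.frame(participant_id = 1L,
               condition = cells$condition[i],
               trial_index = rep(stage_trials, length.out = n_per_cell),
               stage = cells$stage[i],
               rel_alpha = stats::rnorm(n_per_cell,
                                        mean_fun(cells$condition[i], cells$stage[i]), sd),
               tbr = stats::rnorm(n_per_cell, 1, sd),
               degenerate = FALSE)
  })
  do.call(rbind, rows)
}

raw_from_matrix <- function(samples, fs, labels = paste0("ch", seq_len(nrow(samples))),
                            events = NULL) {
  if (is.null(events)) {
    events <- data.frame(onset_sample = integer(), condition = character(),
                         trial_index = integer(), string_id = integer(),
                         duration_s = numeric())
  }
  eegdwt:::new_recording(samples, fs, labels, events)
}
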