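# Synthetic EEG cohort generator.
#
# Emulates a coordination-game experiment: 10 participants, 16 channels at
# 512 Hz, a 2-minute eyes-open rest block, then 12 picking trials and 12
# coordination trials with per-participant randomized string order. Each
# trial's signal is 1/f Gaussian background plus band-limited sinusoidal
# oscillators whose amplitudes depend on (condition, stage, band), so
# condition- and time-on-task effects can be programmed in (or switched
# off for null calibration).

.conditions <- c("rest", "picking", "coordination")
.stages <- c("first", "middle", "last")
.bands <- c("delta", "theta", "alpha", "beta")

# Representative in-band oscillator frequencies (Hz): one fixed tone per
# dyadic band, placed well inside the band so dyadic filter roll-off does
# not smear energy across edges.
.tone_freqs <- c(delta = 2, theta = 6, alpha = 10, beta = 20)

#' Standard 16-channel 10-20 montage labels
#' @return Character vector of 16 electrode labels.
#' @export
default_montage <- function() {
  c("Fp1", "Fp2", "F3", "F4", "F7", "F8", "C3", "C4",
    "T3", "T4", "P3", "P4", "T5", "T6", "O1", "O2")
}

#' Frontal/prefrontal electrode subset used for statistical analysis
#'
#' The symmetric prefrontal-frontal set over which band statistics are
#' pooled; prefrontal cortex involvement in effortful reasoning motivates
#' restricting analysis to these sites.
#' @return Character vector of 6 labels: Fp1, Fp2, F3, F4, F7, F8.
#' @export
frontal_electrodes <- function() c("Fp1", "Fp2", "F3", "F4", "F7", "F8")

#' Default condition/stage band-amplitude map
#'
#' Oscillator amplitudes (signal units, nominally uV) per (condition,
#' stage, band) encoding the motivating effect pattern: picking flat
#' across stages; coordination starts with suppressed Alpha and elevated
#' Beta (engagement) and ends with raised Alpha and Theta and lowered
#' Beta (fatigue) - a coordination-only late-stage Alpha rise of 100% and
#' a rising TBR; rest has high Alpha and low Beta throughout.
#'
#' @param alpha_rise Multiplicative late-stage Alpha increase for
#'   coordination relative to its first stage (default 2, i.e. +100%).
#' @return Data frame with columns `condition`, `stage`, `band`, `amplitude`.
#' @export
amplitude_map_default <- function(alpha_rise = 2) {
  stopifnot(alpha_rise >= 0)
  grid <- expand.grid(condition = .conditions, stage = .stages, band = .bands,
                      stringsAsFactors = FALSE)
  amp <- function(cond, stage, band) {
    if (cond == "rest") {
      return(c(delta = 1, theta = 1.5, alpha = 3, beta = 1)[band])
    }
    if (cond == "picking") {
      return(c(delta = 1, theta = 1.5, alpha = 2, beta = 2)[band])
    }
    # coordination: engagement -> fatigue trajectory
    base <- list(
      first = c(delta = 1, theta = 1.5, alpha = 1.5, beta = 2.4),
      middle = c(delta = 1, theta = 1.8, alpha = 2.0, beta = 2.2),
      last = c(delta = 1, theta = 2.4, alpha = 1.5 * alpha_rise, beta = 1.8)
    )
    base[[stage]][band]
  }
  grid$amplitude <- mapply(amp, grid$condition, grid$stage, grid$band)
  grid
}

#' Null (no-effect) band-amplitude map
#'
#' Identical amplitudes for every condition and stage; used for type-I
#' error calibration of the downstream tests.
#'
#' @param theta,alpha,beta,delta Common amplitudes per band.
#' @return Data frame as in [amplitude_map_default()].
#' @export
amplitude_map_null <- function(theta = 2, alpha = 2, beta = 2, delta = 1) {
  grid <- expand.grid(condition = .conditions, stage = .stages, band = .bands,
                      stringsAsFactors = FALSE)
  grid$amplitude <- c(delta = delta, theta = theta,
                      alpha = alpha, beta = beta)[grid$band]
  grid
}

#' Simulation configuration
#'
#' Full parameterization of a synthetic cohort. Validation errors name
#' the offending field.
#'
#' @param n_participants Number of participants (default 10).
#' @param n_trials_per_condition Trials per task condition (default 12);
#'   must be divisible by 3 for stage binning.
#' @param channels Ordered 10-20 channel labels (default 16-channel montage).
#' @param fs_raw Acquisition sampling rate in Hz; must be a positive
#'   power-of-two multiple of 64 (default 512).
#' @param trial_duration Trial length in seconds, at least 1 (default 2).
#' @param rest_duration Eyes-open rest block length in seconds (default 120).
#' @param inter_trial_gap Background-only gap between trials in seconds.
#' @param background_exponent 1/f spectral slope of the Gaussian background
#'   (default 1: pink noise).
#' @param band_amplitude_map Data frame (condition, stage, band, amplitude)
#'   of oscillator amplitudes; see [amplitude_map_default()].
#' @param noise_sd Standard deviation of the background (signal units).
#' @param seed Master integer seed; participant substreams are derived
#'   from it, so regenerating one participant is stable.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_participants = 10,
                       n_trials_per_condition = 12,
                       channels = default_montage(),
                       fs_raw = 512,
                       trial_duration = 2,
                       rest_duration = 120,
                       inter_trial_gap = 1,
                       background_exponent = 1,
                       band_amplitude_map = amplitude_map_default(),
                       noise_sd = 1,
                       seed = 1L) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    n_trials_per_condition = as.integer(n_trials_per_condition),
    channels = as.character(channels),
    fs_raw = as.integer(fs_raw),
    trial_duration = as.numeric(trial_duration),
    rest_duration = as.numeric(rest_duration),
    inter_trial_gap = as.numeric(inter_trial_gap),
    background_exponent = as.numeric(background_exponent),
    band_amplitude_map = band_amplitude_map,
    noise_sd = as.numeric(noise_sd),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks every invariant of the design; failures raise errors of class
#' `eegdwt_config_error` naming the field.
#'
#' @param config A `sim_config` (or plain list with the same fields).
#' @return The validated config, invisibly.
#' @export
validate_sim_config <- function(config) {
  bad <- function(field, why) {
    eeg_abort("eegdwt_config_error", sprintf("config field '%s': %s", field, why))
  }
  req <- c("n_participants", "n_trials_per_condition", "channels", "fs_raw",
           "trial_duration", "rest_duration", "background_exponent",
           "band_amplitude_map", "noise_sd", "seed")
  missing <- setdiff(req, names(config))
  if (length(missing)) bad(missing[1], "missing")
  if (config$n_participants < 1) bad("n_participants", "must be >= 1")
  if (config$n_trials_per_condition < 3 ||
      config$n_trials_per_condition %% 3 != 0) {
    bad("n_trials_per_condition", "must be a positive multiple of 3 (stage binning)")
  }
  if (length(config$channels) < 1 || anyDuplicated(config$channels)) {
    bad("channels", "must be a non-empty list of unique labels")
  }
  ratio <- config$fs_raw / 64
  if (config$fs_raw <= 0 || ratio < 1 || bitwAnd(as.integer(ratio), as.integer(ratio) - 1L) != 0 ||
      ratio != as.integer(ratio)) {
    bad("fs_raw", "must be a positive power-of-two multiple of 64 Hz")
  }
  if (config$trial_duration < 1) bad("trial_duration", "must be >= 1 s (epoch window)")
  if (config$rest_duration < 1) bad("rest_duration", "must be >= 1 s")
  if ((config$inter_trial_gap %||% 0) < 0) bad("inter_trial_gap", "must be >= 0")
  if (config$noise_sd < 0) bad("noise_sd", "must be >= 0")
  m <- config$band_amplitude_map
  if (!is.data.frame(m) ||
      !all(c("condition", "stage", "band", "amplitude") %in% names(m))) {
    bad("band_amplitude_map", "must be a data frame with condition/stage/band/amplitude")
  }
  if (any(m$amplitude < 0)) bad("band_amplitude_map", "amplitudes must be >= 0")
  need <- expand.grid(condition = .conditions, stage = .stages, band = .bands,
                      stringsAsFactors = FALSE)
  key <- function(d) paste(d$condition, d$stage, d$band)
  if (!all(key(need) %in% key(m))) {
    bad("band_amplitude_map", "missing (condition, stage, band) combinations")
  }
  invisible(config)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic EEG cohort configuration\n")
  cat(sprintf("  %d participants, %d channels at %d Hz\n",
              x$n_participants, length(x$channels), x$fs_raw))
  cat(sprintf("  %d trials/condition (%.3g s each), %.3g s rest block, seed %d\n",
              x$n_trials_per_condition, x$trial_duration, x$rest_duration, x$seed))
  invisible(x)
}

.amplitude_lookup <- function(map, condition, stage) {
  sel <- map$condition == condition & map$stage == stage
  amps <- map$amplitude[sel]
  names(amps) <- map$band[sel]
  amps[.bands]
}

# Gaussian background with a 1/f^exponent power spectrum, unit variance
# before scaling by sd. FFT-filtered white noise; DC removed.
.pink_noise <- function(n, exponent, sd) {
  if (sd == 0) return(numeric(n))
  w <- stats::rnorm(n)
  if (exponent == 0) return(sd * w)
  W <- stats::fft(w)
  k <- seq_len(n) - 1
  freq_idx <- pmin(k, n - k)          # symmetric frequency index
  scale <- c(0, freq_idx[-1]^(-exponent / 2))
  x <- Re(stats::fft(W * scale, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  sd * x / s
}

# Unseeded core: one segment of oscillators plus 1/f background. Phases
# are drawn independently per channel, band and segment, and each
# segment gets a fresh background realization, so band energies of
# different channels and different trials vary independently.
.segment_signal <- function(config, n_samples, amps = NULL) {
  nch <- length(config$channels)
  t <- (seq_len(n_samples) - 1) / config$fs_raw
  out <- matrix(0, nch, n_samples)
  for (ch in seq_len(nch)) {
    x <- .pink_noise(n_samples, config$background_exponent, config$noise_sd)
    if (!is.null(amps)) {
      for (b in .bands) {
        a <- amps[[b]]
        if (a > 0) {
          x <- x + a * sin(2 * pi * .tone_freqs[[b]] * t + stats::runif(1, 0, 2 * pi))
        }
      }
    }
    out[ch, ] <- x
  }
  out
}

.trial_signal <- function(config, condition, stage, n_samples) {
  .segment_signal(config, n_samples,
                  .amplitude_lookup(config$band_amplitude_map, condition, stage))
}

#' Generate one trial's multichannel signal
#'
#' 1/f-filtered Gaussian background plus sinusoidal oscillators at fixed
#' representative in-band frequencies (2, 6, 10, 20 Hz) with amplitudes
#' taken from the configuration's band-amplitude map and uniform random
#' phases drawn independently per channel and band. Deterministic given
#' `seed`.
#'
#' @param config A [sim_config()].
#' @param condition One of `"rest"`, `"picking"`, `"coordination"`.
#' @param stage One of `"first"`, `"middle"`, `"last"`.
#' @param seed Integer seed for this trial's random phases and background.
#' @return Channels x samples numeric matrix
#'   (`length(channels)` x `trial_duration * fs_raw`).
#' @export
generate_trial_signal <- function(config, condition, stage, seed = config$seed) {
  validate_sim_config(config)
  if (!condition %in% .conditions) {
    eeg_abort("eegdwt_bad_tag", sprintf("unknown condition '%s'", condition))
  }
  if (!stage %in% .stages) {
    eeg_abort("eegdwt_bad_tag", sprintf("unknown stage '%s'", stage))
  }
  n <- round(config$trial_duration * config$fs_raw)
  with_seed(seed, .trial_signal(config, condition, stage, n))
}

new_recording <- function(samples, fs, channel_labels, events,
                          participant_id = NA_integer_) {
  stopifnot(nrow(samples) == length(channel_labels))
  if (nrow(events) > 0) {
    stopifnot(!is.unsorted(events$onset_sample, strictly = TRUE),
              all(events$onset_sample >= 0),
              all(events$onset_sample + events$duration_s * fs <= ncol(samples)))
  }
  structure(list(samples = samples, fs = fs, channel_labels = channel_labels,
                 events = events, participant_id = participant_id),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording: %d channels x %d samples at %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs, ncol(x$samples) / x$fs))
  if (!is.na(x$participant_id)) cat(sprintf("  participant %d\n", x$participant_id))
  cat(sprintf("  %d events (%s)\n", nrow(x$events),
              paste(names(table(x$events$condition)), table(x$events$condition),
                    sep = ":", collapse = ", ")))
  invisible(x)
}

#' Generate one participant's continuous recording
#'
#' Assembles a continuous multichannel recording: the eyes-open rest
#' block first, then all picking trials, then all coordination trials,
#' separated by background-only gaps. The order of word strings within
#' each task condition is randomized per participant (a participant-keyed
#' substream of the master seed); event markers carry the condition, the
#' presentation index 1..n (which defines the experiment stage) and the
#' randomized string id. The 1/f background runs continuously across the
#' whole recording.
#'
#' @param config A [sim_config()].
#' @param participant_id Integer in `1..n_participants`.
#' @return An `eeg_recording` with an `events` data frame
#'   (`onset_sample` 0-based at `fs_raw`, `condition`, `trial_index`,
#'   `string_id`, `duration_s`).
#' @export
generate_participant_recording <- function(config, participant_id) {
  validate_sim_config(config)
  if (participant_id < 1 || participant_id > config$n_participants) {
    eeg_abort("eegdwt_bad_participant",
              sprintf("participant_id %d outside 1..%d", participant_id,
                      config$n_participants))
  }
  fs <- config$fs_raw
  ntr <- config$n_trials_per_condition
  gap <- round(config$inter_trial_gap * fs)
  n_trial <- round(config$trial_duration * fs)
  n_rest <- round(config$rest_duration * fs)

  with_seed(participant_seed(config$seed, participant_id), {
    ev <- list()
    segs <- list()
    pos <- 0  # 0-based sample cursor
    add_seg <- function(mat) {
      segs[[length(segs) + 1]] <<- mat
      pos <<- pos + ncol(mat)
    }

    # rest block
    ev[[1]] <- data.frame(onset_sample = pos, condition = "rest",
                          trial_index = NA_integer_, string_id = NA_integer_,
                          duration_s = config$rest_duration)
    add_seg(.trial_signal(config, "rest", "first", n_rest))

    for (cond in c("picking", "coordination")) {
      string_order <- sample.int(ntr)   # randomized order of appearance
      for (i in seq_len(ntr)) {
        if (gap > 0) add_seg(.segment_signal(config, gap))  # background-only gap
        ev[[length(ev) + 1]] <- data.frame(
          onset_sample = pos, condition = cond, trial_index = i,
          string_id = string_order[i], duration_s = config$trial_duration)
        add_seg(.trial_signal(config, cond, assign_stage(i, ntr), n_trial))
      }
    }
    samples <- do.call(cbind, segs)
    events <- do.call(rbind, ev)
    new_recording(samples, fs, config$channels, events, participant_id)
  })
}

#' Generate and write a full synthetic cohort
#'
#' Writes one EDF file plus a tab-separated events sidecar per
#' participant, a config YAML, and a JSON manifest listing the files, the
#' seed and the config hash. Generation is a pure function of
#' (config, seed): two runs produce identical signal content.
#'
#' @param config A [sim_config()].
#' @param output_dir Writable directory (created if absent).
#' @return The manifest, invisibly (list with `files`, `seed`,
#'   `config_hash`, ...). Also written as `manifest.json`.
#' @export
generate_cohort <- function(config, output_dir) {
  validate_sim_config(config)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(output_dir) || file.access(output_dir, 2) != 0) {
    eeg_abort("eegdwt_io_error", sprintf("cannot write to '%s'", output_dir))
  }
  cfg_path <- file.path(output_dir, "config.yaml")
  write_config(config, cfg_path)
  files <- list()
  for (p in seq_len(config$n_participants)) {
    rec <- generate_participant_recording(config, p)
    edf <- file.path(output_dir, sprintf("p%02d.edf", p))
    evf <- file.path(output_dir, sprintf("p%02d_events.tsv", p))
    write_edf(rec, edf)
    utils::write.table(rec$events, evf, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    files[[p]] <- list(participant_id = p, edf = basename(edf),
                       events = basename(evf))
  }
  manifest <- list(
    stage = "simulate",
    seed = config$seed,
    config_file = basename(cfg_path),
    config_hash = config_hash(config),
    n_participants = config$n_participants,
    files = files
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
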