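# Band-energy feature extraction: per-epoch, per-channel DWT energies,
# relative energies, TBR, frontal-subset selection and stage labelling.

#' Restrict band-energy records to an electrode subset
#'
#' @param features Feature table from [build_feature_table()] (one row
#'   per epoch x channel).
#' @param electrodes Non-empty character vector of channel labels; every
#'   label must occur in the table. Defaults to [frontal_electrodes()].
#' @return The filtered feature table.
#' @export
frontal_subset <- function(features, electrodes = frontal_electrodes()) {
  if (length(electrodes) == 0) {
    eeg_abort("eegdwt_bad_channel", "electrode list is empty")
  }
  present <- unique(features$channel)
  unknown <- setdiff(electrodes, present)
  if (length(unknown)) {
    eeg_abort("eegdwt_bad_channel",
              sprintf("electrode(s) not in records: %s",
                      paste(unknown, collapse = ", ")))
  }
  features[features$channel %in% electrodes, , drop = FALSE]
}

#' Build the per-epoch, per-channel band-energy feature table
#'
#' For every retained (epoch, channel) pair: absolute DWT band energies
#' for Delta/Theta/Alpha/Beta, relative energies (each band divided by
#' the four-band sum), the Theta/Beta ratio, and the experiment stage
#' derived from the trial's presentation index. Epochs with zero total
#' energy are flagged `degenerate` (relative energies and TBR set to NA)
#' and counted in a message; downstream analyses exclude them listwise.
#'
#' @param epochs A preprocessed `eeg_epochs` object (64 samples at 64 Hz).
#' @param wavelet Orthonormal wavelet for the decomposition (default `"db8"`).
#' @param electrodes Channels to retain; `NULL` keeps all. Default is the
#'   frontal/prefrontal analysis set.
#' @param n_trials Trials per task condition, for stage binning.
#' @return Data frame with one row per (epoch, channel):
#'   identifiers (`epoch_id`, `participant_id`, `condition`, `trial_index`,
#'   `stage`, `rest_epoch`, `channel`), energies `e_*`, fractions `rel_*`,
#'   `tbr`, and the `degenerate` flag. The wavelet name is attached as an
#'   attribute.
#' @export
build_feature_table <- function(epochs, wavelet = "db8",
                                electrodes = frontal_electrodes(),
                                n_trials = 12) {
  labels <- epochs$channel_labels
  if (is.null(electrodes)) electrodes <- labels
  unknown <- setdiff(electrodes, labels)
  if (length(electrodes) == 0 || length(unknown)) {
    eeg_abort("eegdwt_bad_channel",
              sprintf("electrode(s) not in montage: %s",
                      paste(unknown, collapse = ", ")))
  }
  idx <- match(electrodes, labels)
  ne <- dim(epochs$data)[1]
  nc <- length(idx)
  sub <- epochs$data[, idx, , drop = FALSE]
  # flatten (epoch, channel) onto rows; epoch index varies fastest
  traces <- matrix(sub, nrow = ne * nc, ncol = dim(sub)[3])
  E <- .dwt_band_energy_matrix(traces, wavelet = wavelet)
  tot <- rowSums(E)
  degenerate <- tot == 0
  rel <- E / ifelse(tot == 0, NA_real_, tot)
  tbr <- ifelse(E[, "beta"] > 0, E[, "theta"] / E[, "beta"], NA_real_)
  degenerate <- degenerate | E[, "beta"] == 0

  info <- epochs$info[rep(seq_len(ne), times = nc), , drop = FALSE]
  stage <- rep(NA_character_, nrow(info))
  task <- !is.na(info$trial_index)
  if (any(task)) stage[task] <- as.character(assign_stage(info$trial_index[task], n_trials))
  out <- data.frame(
    epoch_id = info$epoch_id,
    participant_id = info$participant_id,
    condition = info$condition,
    trial_index = info$trial_index,
    stage = stage,
    rest_epoch = info$rest_epoch,
    channel = rep(electrodes, each = ne),
    e_delta = E[, "delta"], e_theta = E[, "theta"],
    e_alpha = E[, "alpha"], e_beta = E[, "beta"],
    rel_delta = rel[, "delta"], rel_theta = rel[, "theta"],
    rel_alpha = rel[, "alpha"], rel_beta = rel[, "beta"],
    tbr = ifelse(degenerate, NA_real_, tbr),
    degenerate = degenerate,
    row.names = NULL
  )
  if (any(degenerate)) {
    message(sprintf("flagged %d degenerate epoch-channel record(s) (zero energy)",
                    sum(degenerate)))
  }
  attr(out, "wavelet") <- wavelet
  attr(out, "n_degenerate") <- sum(degenerate)
  out
}

#' Pipeline convenience: simulate a cohort and return its feature table
#'
#' Generates every participant's recording in memory, preprocesses each
#' one and concatenates the band-energy feature tables. Used for
#' simulation studies (type-I calibration, power) where writing EDF files
#' to disk adds nothing.
#'
#' @param config A [sim_config()].
#' @param wavelet,electrodes Passed to [build_feature_table()].
#' @return The combined feature table over all participants.
#' @export
cohort_features <- function(config, wavelet = "db8",
                            electrodes = frontal_electrodes()) {
  validate_sim_config(config)
  electrodes <- intersect(electrodes, config$channels)
  tabs <- vector("list", config$n_participants)
  for (p in seq_len(config$n_participants)) {
    rec <- generate_participant_recording(config, p)
    ep <- preprocess_recording(rec)
    tabs[[p]] <- build_feature_table(ep, wavelet = wavelet,
                                     electrodes = electrodes,
                                     n_trials = config$n_trials_per_condition)
  }
  out <- do.call(rbind, tabs)
  attr(out, "wavelet") <- wavelet
  out
}
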