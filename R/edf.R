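# Minimal EDF (European Data Format) writer/reader.
#
# Implements the 16-bit EDF container: fixed 256-byte header, 256 bytes
# of per-signal header fields, then 1-second data records of little-endian
# int16 samples. Physical calibration is symmetric per channel
# (phys_min = -phys_max), so the round-trip quantization error is bounded
# by phys_max / 32767. Events travel in a TSV sidecar (the generator
# writes one); EDF+ annotation channels are not used.

.edf_pad <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  substr(s, 1, width)
}

#' Write a recording to an EDF file
#'
#' 16-bit EDF with 1-second data records; the signal is zero-padded to a
#' whole number of seconds. Each channel gets a symmetric physical range
#' covering its observed amplitude.
#'
#' @param recording An `eeg_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  x <- recording$samples
  fs <- recording$fs
  nch <- nrow(x)
  n_rec <- ceiling(ncol(x) / fs)
  if (ncol(x) < n_rec * fs) {
    x <- cbind(x, matrix(0, nch, n_rec * fs - ncol(x)))
  }
  phys_max <- apply(abs(x), 1, max)
  phys_max[phys_max == 0] <- 1
  # store-then-parse so digitization uses exactly the calibration written
  # into the 8-char ASCII header; "x.ye+zz" keeps -phys_max within 8 chars
  phys_max <- as.numeric(sprintf("%.1e", phys_max * 1.06))

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_pad("0", 8),
    .edf_pad(sprintf("participant %s", recording$participant_id), 80),
    .edf_pad("synthetic EEG cohort", 80),
    .edf_pad("01.01.26", 8), .edf_pad("00.00.00", 8),
    .edf_pad(256 * (1 + nch), 8),
    .edf_pad("", 44),
    .edf_pad(n_rec, 8),
    .edf_pad(1, 8),
    .edf_pad(nch, 4),
    paste(.edf_pad(recording$channel_labels, 16), collapse = ""),
    paste(rep(.edf_pad("synthetic", 80), nch), collapse = ""),
    paste(rep(.edf_pad("uV", 8), nch), collapse = ""),
    paste(.edf_pad(-phys_max, 8), collapse = ""),
    paste(.edf_pad(phys_max, 8), collapse = ""),
    paste(rep(.edf_pad(-32767, 8), nch), collapse = ""),
    paste(rep(.edf_pad(32767, 8), nch), collapse = ""),
    paste(rep(.edf_pad("", 80), nch), collapse = ""),
    paste(rep(.edf_pad(fs, 8), nch), collapse = ""),
    paste(rep(.edf_pad("", 32), nch), collapse = "")
  )
  writeChar(hdr, con, eos = NULL)

  dig <- pmin(pmax(round(sweep(x, 1, phys_max, "/") * 32767), -32767), 32767)
  storage.mode(dig) <- "integer"
  # reorder to record-major: record slowest, then channel, sample fastest
  arr <- array(dig, dim = c(nch, fs, n_rec))
  writeBin(as.integer(aperm(arr, c(2, 1, 3))), con, size = 2, endian = "little")
  invisible(path)
}

#' Read an EDF file
#'
#' Reads a 16-bit EDF written by [write_edf()] (or any plain EDF with a
#' uniform sampling rate). Returns an `eeg_recording` with an empty event
#' table; use [read_recording()] to attach the TSV sidecar.
#'
#' @param path EDF file path.
#' @return An `eeg_recording`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8 + 80 + 80 + 8 + 8)
  header_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  labels <- trimws(vapply(seq_len(nch), function(i) rd(16), ""))
  rd(80 * nch); rd(8 * nch)
  phys_min <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  phys_max <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  dig_min <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  dig_max <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  rd(80 * nch)
  spr <- as.integer(vapply(seq_len(nch), function(i) rd(8), ""))
  rd(32 * nch)
  if (length(unique(spr)) != 1) {
    eeg_abort("eegdwt_io_error", "mixed per-signal sampling rates not supported")
  }
  fs <- spr[1] / rec_dur
  raw_int <- readBin(con, "integer", n = n_rec * sum(spr), size = 2,
                     endian = "little", signed = TRUE)
  arr <- array(raw_int, dim = c(spr[1], nch, n_rec))
  dig <- matrix(aperm(arr, c(2, 1, 3)), nrow = nch)
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  samples <- sweep(sweep(dig, 1, dig_min, "-"), 1, gain, "*") + phys_min
  new_recording(samples, fs, labels,
                data.frame(onset_sample = integer(), condition = character(),
                           trial_index = integer(), string_id = integer(),
                           duration_s = numeric()))
}

#' Read an events sidecar TSV
#'
#' @param path TSV with columns `onset_sample` (0-based), `condition`,
#'   `trial_index`, `string_id`, `duration_s`.
#' @return Data frame of events.
#' @export
read_events <- function(path) {
  ev <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("onset_sample", "condition", "trial_index", "duration_s")
  if (!all(need %in% names(ev))) {
    eeg_abort("eegdwt_io_error",
              sprintf("events file '%s' lacks columns: %s", path,
                      paste(setdiff(need, names(ev)), collapse = ", ")))
  }
  ev
}

#' Read an EDF recording together with its events sidecar
#'
#' @param edf_path EDF file.
#' @param events_path Events TSV; defaults to `<stem>_events.tsv` next to
#'   the EDF.
#' @param participant_id Optional participant id to attach.
#' @return An `eeg_recording` with events attached.
#' @export
read_recording <- function(edf_path,
                           events_path = sub("\\.edf$", "_events.tsv", edf_path),
                           participant_id = NA_integer_) {
  rec <- read_edf(edf_path)
  rec$events <- read_events(events_path)
  rec$participant_id <- as.integer(participant_id)
  rec
}
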