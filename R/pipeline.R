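# Orchestration: simulate -> preprocess -> features -> analyze as a
# logged, reproducible workflow over one output directory. Each stage
# records what it wrote in manifest.json; re-running a completed stage
# with an unchanged config hash is a no-op.

#' Write a simulation config as YAML
#' @param config A [sim_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  validate_sim_config(config)
  lst <- unclass(config)
  lst$band_amplitude_map <- lapply(seq_len(nrow(config$band_amplitude_map)),
                                   function(i) as.list(config$band_amplitude_map[i, ]))
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' Read a simulation config from YAML
#' @param path YAML file mirroring the [sim_config()] fields.
#' @return A validated `sim_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    eeg_abort("eegdwt_io_error", sprintf("config file '%s' not found", path))
  }
  lst <- yaml::read_yaml(path)
  if (!is.list(lst)) {
    eeg_abort("eegdwt_io_error",
              sprintf("config file '%s' is empty or not a YAML mapping", path))
  }
  if (!is.null(lst$band_amplitude_map)) {
    lst$band_amplitude_map <- do.call(rbind, lapply(lst$band_amplitude_map,
                                                    as.data.frame))
  }
  args <- lst[intersect(names(lst), names(formals(sim_config)))]
  do.call(sim_config, args)
}

#' Hash of a canonical config serialization
#'
#' MD5 of the YAML serialization; identical configs hash identically, so
#' manifests can detect stale outputs.
#' @param config A `sim_config`.
#' @return Hex string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_config(config, tmp)
  unname(tools::md5sum(tmp))
}

.log <- function(outdir, ...) {
  msg <- sprintf(...)
  line <- paste0(format(Sys.time(), "%H:%M:%S "), msg)
  cat(line, "\n", file = stderr(), sep = "")
  cat(line, "\n", file = file.path(outdir, "run.log"), append = TRUE, sep = "")
  invisible(msg)
}

.read_manifest <- function(outdir) {
  p <- file.path(outdir, "manifest.json")
  if (file.exists(p)) jsonlite::read_json(p) else NULL
}

.write_manifest <- function(outdir, manifest) {
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

.as_config <- function(config) {
  if (inherits(config, "sim_config")) config else read_config(config)
}

.stage_fail <- function(stage, e) {
  eeg_abort("eegdwt_stage_error",
            sprintf("[%s] stage failed: %s", stage, conditionMessage(e)))
}

#' Run the simulation stage
#'
#' Generates and writes the synthetic cohort (EDF + events sidecars +
#' manifest). Skipped if the directory already holds a cohort with the
#' same config hash.
#'
#' @param config A `sim_config` or path to a config YAML.
#' @param outdir Output directory.
#' @param seed Optional seed overriding the config's.
#' @return The manifest, invisibly.
#' @export
run_simulate <- function(config, outdir, seed = NULL) {
  config <- .as_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  old <- .read_manifest(outdir)
  h <- config_hash(config)
  if (!is.null(old) && identical(old$config_hash, h) &&
      all(file.exists(file.path(outdir, vapply(old$files, `[[`, "", "edf"))))) {
    .log(outdir, "[simulate] up to date (config hash %s); skipping", h)
    return(invisible(old))
  }
  manifest <- tryCatch(generate_cohort(config, outdir),
                       error = function(e) .stage_fail("simulate", e))
  .log(outdir, "[simulate] wrote %d participant recording(s)",
       config$n_participants)
  invisible(manifest)
}

#' Run the preprocessing stage
#'
#' Reads every EDF + events sidecar listed in the manifest, applies the
#' fixed preprocessing chain, and writes per-participant epoch containers
#' (`.rds`) plus a combined epoch-metadata TSV.
#'
#' @param outdir Directory holding a simulated cohort.
#' @param ... Passed to [preprocess_recording()].
#' @return Updated manifest, invisibly.
#' @export
run_preprocess <- function(outdir, ...) {
  manifest <- .read_manifest(outdir)
  if (is.null(manifest)) {
    eeg_abort("eegdwt_stage_error", "[preprocess] no manifest.json; run simulate first")
  }
  epoch_files <- character(0)
  meta <- list()
  for (f in manifest$files) {
    res <- tryCatch({
      rec <- read_recording(file.path(outdir, f$edf),
                            file.path(outdir, f$events),
                            participant_id = f$participant_id)
      ep <- preprocess_recording(rec, ...)
      out <- file.path(outdir, sprintf("p%02d_epochs.rds", f$participant_id))
      saveRDS(ep, out)
      list(ep = ep, out = out)
    }, error = function(e) .stage_fail("preprocess", e))
    epoch_files <- c(epoch_files, basename(res$out))
    meta[[length(meta) + 1]] <- res$ep$info
  }
  meta <- do.call(rbind, meta)
  utils::write.table(meta, file.path(outdir, "epochs_meta.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  manifest$stage <- "preprocess"
  manifest$epoch_files <- epoch_files
  manifest$n_epochs <- nrow(meta)
  .write_manifest(outdir, manifest)
  .log(outdir, "[preprocess] %d epochs across %d participant(s)", nrow(meta),
       length(epoch_files))
  invisible(manifest)
}

#' Run the feature-extraction stage
#'
#' Builds the band-energy feature table over the retained electrodes and
#' writes it as TSV plus a JSON metadata header (wavelet, band map,
#' electrode list, package version, degenerate count).
#'
#' @param outdir Directory holding preprocessed epochs.
#' @param wavelet Wavelet name (default `"db8"`).
#' @param electrodes Retained channels (default [frontal_electrodes()]).
#' @return Updated manifest, invisibly.
#' @export
run_features <- function(outdir, wavelet = "db8",
                         electrodes = frontal_electrodes()) {
  manifest <- .read_manifest(outdir)
  if (is.null(manifest) || is.null(manifest$epoch_files)) {
    eeg_abort("eegdwt_stage_error", "[features] no preprocessed epochs; run preprocess first")
  }
  config <- read_config(file.path(outdir, manifest$config_file))
  tabs <- lapply(manifest$epoch_files, function(f) {
    tryCatch({
      ep <- readRDS(file.path(outdir, f))
      build_feature_table(ep, wavelet = wavelet,
                          electrodes = intersect(electrodes, ep$channel_labels),
                          n_trials = config$n_trials_per_condition)
    }, error = function(e) .stage_fail("features", e))
  })
  features <- do.call(rbind, tabs)
  utils::write.table(features, file.path(outdir, "features.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  n_degen <- sum(features$degenerate)
  jsonlite::write_json(
    list(wavelet = wavelet, electrodes = electrodes,
         band_map = band_map(),
         n_rows = nrow(features), n_degenerate = n_degen,
         package_version = as.character(utils::packageVersion("eegdwt"))),
    file.path(outdir, "features_meta.json"),
    auto_unbox = TRUE, pretty = TRUE, dataframe = "rows")
  manifest$stage <- "features"
  manifest$feature_file <- "features.tsv"
  manifest$n_degenerate <- n_degen
  .write_manifest(outdir, manifest)
  .log(outdir, "[features] %d rows (%d degenerate) with wavelet %s",
       nrow(features), n_degen, wavelet)
  invisible(manifest)
}

.anova_to_tsv <- function(an, path) {
  tab <- an$terms
  tab <- rbind(tab, data.frame(term = "residuals", df = an$residual_df,
                               sum_sq = an$residual_ss,
                               mean_sq = an$residual_ss / max(an$residual_df, 1),
                               statistic = NA, p_value = NA))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Run the statistical-analysis stage
#'
#' Fits the Condition x Band ANOVA, the per-band Tukey HSD contrasts
#' (9 rows: 3 bands x 3 condition pairs), the Stage x Condition ANOVAs
#' on relative Alpha and TBR, and the stage-profile tables; writes all
#' as TSV plus trajectory/interaction plots as PNG.
#'
#' @param outdir Directory holding `features.tsv`.
#' @param plots Write PNG figures (default `TRUE`).
#' @return Updated manifest, invisibly (with an `analysis` list of file
#'   names).
#' @export
run_analyze <- function(outdir, plots = TRUE) {
  manifest <- .read_manifest(outdir)
  if (is.null(manifest) || is.null(manifest$feature_file)) {
    eeg_abort("eegdwt_stage_error", "[analyze] no feature table; run features first")
  }
  features <- utils::read.table(file.path(outdir, manifest$feature_file),
                                header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
  out <- list()
  res <- tryCatch({
    cb <- anova_condition_band(features)
    .anova_to_tsv(cb, file.path(outdir, "anova_condition_band.tsv"))
    out$anova_condition_band <- "anova_condition_band.tsv"

    tk <- do.call(rbind, lapply(c("theta", "alpha", "beta"),
                                function(b) tukey_posthoc(features, b)))
    utils::write.table(tk, file.path(outdir, "tukey_contrasts.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    out$tukey <- "tukey_contrasts.tsv"

    for (m in c("rel_alpha", "tbr")) {
      an <- anova_stage_condition(features, m)
      .anova_to_tsv(an, file.path(outdir, sprintf("anova_stage_%s.tsv", m)))
      prof <- stage_profile(features, m)
      utils::write.table(prof, file.path(outdir, sprintf("stage_profile_%s.tsv", m)),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      out[[paste0("anova_stage_", m)]] <- sprintf("anova_stage_%s.tsv", m)
      out[[paste0("stage_profile_", m)]] <- sprintf("stage_profile_%s.tsv", m)
      if (plots) {
        png_file <- file.path(outdir, sprintf("stage_profile_%s.png", m))
        grDevices::png(png_file, width = 800, height = 600)
        plot_stage_profile(prof)
        grDevices::dev.off()
        out[[paste0("plot_", m)]] <- basename(png_file)
      }
    }
    out
  }, error = function(e) {
    if (inherits(e, "eegdwt_stage_error")) stop(e)
    .stage_fail("analyze", e)
  })
  manifest$stage <- "analyze"
  manifest$analysis <- res
  .write_manifest(outdir, manifest)
  .log(outdir, "[analyze] wrote %d analysis output(s)", length(res))
  invisible(manifest)
}

#' Run the full pipeline end-to-end
#'
#' simulate -> preprocess -> features -> analyze with one config and one
#' output directory; with a fixed seed the whole chain is deterministic
#' (byte-identical feature tables across runs).
#'
#' @param config A `sim_config` or path to a config YAML.
#' @param outdir Output directory.
#' @param seed Optional seed overriding the config's.
#' @param wavelet,electrodes Passed to [run_features()].
#' @param plots Passed to [run_analyze()].
#' @return Final manifest, invisibly.
#' @export
run_all <- function(config, outdir, seed = NULL, wavelet = "db8",
                    electrodes = frontal_electrodes(), plots = TRUE) {
  run_simulate(config, outdir, seed = seed)
  run_preprocess(outdir)
  run_features(outdir, wavelet = wavelet, electrodes = electrodes)
  run_analyze(outdir, plots = plots)
}
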