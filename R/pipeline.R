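#' Run the full telemetry pipeline on a synthetic recording
#'
#' End-to-end chain: simulate a recording from a [gen_config()], mask
#' artifacts, high-pass and detect spikes against the baseline SD, compute
#' staging features and the hypnogram, band-power series, and 1-min
#' activity/spike series, and write the tidy CSV outputs. Fully
#' deterministic given `cfg$seed`: two runs with the same config produce
#' bit-identical files.
#'
#' @param cfg A [gen_config()].
#' @param out_dir Output directory (created if needed).
#' @param k Spike detection threshold in baseline SDs (default 10).
#' @return Invisibly, a named character vector of the written file paths.
#' @export
run_telemetry_pipeline <- function(cfg, out_dir, k = 10) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_recording(cfg)
  rec <- clip_artifacts(sim$recording)$recording
  eeg <- rec$channels$EEG
  filt <- highpass_eeg(eeg$data, eeg$rate)
  base <- estimate_baseline_sd(filt, eeg$rate, mask = eeg$mask)
  spikes <- detect_spikes(filt, eeg$rate, base, k = k, mask = eeg$mask)
  feats <- epoch_features(rec)
  hyp <- stage_epochs(feats, start = rec$start, lights_on = rec$lights_on)
  bp <- bandpower_series(rec)
  act_min <- aggregate_minutes(rec$channels$activity$data,
                               rec$channels$activity$rate,
                               rec$channels$activity$mask, fun = sum)
  spk_min <- spike_rate_series(spikes, recording_duration(rec))$minute

  paths <- c(hypnogram = file.path(out_dir, "hypnogram.csv"),
             spikes = file.path(out_dir, "spikes.csv"),
             bandpower = file.path(out_dir, "bandpower.csv"),
             activity = file.path(out_dir, "activity_minutes.csv"),
             spike_minutes = file.path(out_dir, "spike_minutes.csv"))
  utils::write.csv(hyp, paths["hypnogram"], row.names = FALSE)
  utils::write.csv(spikes, paths["spikes"], row.names = FALSE)
  utils::write.csv(bp, paths["bandpower"], row.names = FALSE)
  utils::write.csv(act_min, paths["activity"], row.names = FALSE)
  utils::write.csv(spk_min, paths["spike_minutes"], row.names = FALSE)
  invisible(paths)
}

#' Write a ground-truth sidecar for a simulated recording
#'
#' JSON sidecar next to an EDF export: hypnogram labels, spike list, seed
#' and the generator configuration echo.
#'
#' @param sim A [simulate_recording()] result.
#' @param cfg The [gen_config()] used.
#' @param path Output JSON path.
#' @export
write_truth_sidecar <- function(sim, cfg, path) {
  cfg_echo <- cfg
  cfg_echo$start <- format(cfg$start, "%Y-%m-%d %H:%M:%S")
  payload <- list(
    seed = cfg$seed,
    hypnogram = as.character(sim$truth$hypnogram$state),
    spikes = sim$truth$spikes,
    config = unclass(cfg_echo))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
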