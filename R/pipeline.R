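#' Default analysis configuration
#'
#' All analysis parameters of the pipeline with their protocol defaults:
#' 15-450 Hz EMG band, 5-100 Hz EEG band, 128 ms Hann windows at 75%
#' overlap, beta band 12-30 Hz, alpha 0.05, 15% tracking target, 30%
#' screening threshold over 10 trials, 3 s averaging window, 1 kHz common
#' analysis rate.
#'
#' @return named list of parameters.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    target_rate = 1000,
    emg_band = c(15, 450),
    eeg_band = c(5, 100),
    window_s = 0.128,
    overlap = 0.75,
    beta_band = c(12, 30),
    segment_rule = "effective",
    alpha = 0.05,
    target_level = 0.15,
    screening_threshold = 0.30,
    screening_trials = 10,
    analysis_window_s = 3,
    n_trials = 12,
    hold_s = 4,
    rest_s = 6,
    kurtosis_z = 5
  )
}

#' Validate and normalize an analysis configuration
#'
#' Fills in defaults from [default_run_config()], rejects out-of-range
#' values naming the offending key, and records derived quantities (the
#' window length and hop in samples at the target rate).
#'
#' @param config named list of overrides (possibly empty).
#' @return the normalized configuration, with `window_samples` and
#'   `hop_samples` added.
#' @export
validate_config <- function(config = list()) {
  cfg <- utils::modifyList(default_run_config(), config)
  bad <- function(key, why) {
    stop(sprintf("configuration error in '%s': %s", key, why))
  }
  band_ok <- function(key) {
    b <- cfg[[key]]
    if (length(b) != 2 || b[1] >= b[2]) bad(key, "band must be (low < high)")
    if (b[2] >= cfg$target_rate / 2 && key != "emg_band") {
      bad(key, "upper edge at or above Nyquist for target_rate")
    }
  }
  if (cfg$target_rate <= 0) bad("target_rate", "must be > 0")
  band_ok("eeg_band"); band_ok("beta_band")
  b <- cfg$emg_band
  if (length(b) != 2 || b[1] >= b[2]) bad("emg_band", "band must be (low < high)")
  if (cfg$overlap < 0 || cfg$overlap > 0.95) {
    bad("overlap", "must lie in [0, 0.95]")
  }
  if (cfg$window_s <= 0) bad("window_s", "must be > 0")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) bad("alpha", "must lie in (0, 1)")
  if (cfg$screening_threshold < 0 || cfg$screening_threshold > 1) {
    bad("screening_threshold", "must lie in [0, 1]")
  }
  if (cfg$analysis_window_s > cfg$hold_s) {
    bad("analysis_window_s", "longer than hold_s")
  }
  if (!cfg$segment_rule %in% c("effective", "disjoint", "raw")) {
    bad("segment_rule", "must be effective, disjoint or raw")
  }
  cfg$window_samples <- round(cfg$window_s * cfg$target_rate)
  cfg$hop_samples <- max(1L, round(cfg$window_samples * (1 - cfg$overlap)))
  cfg
}

#' Run the full synthetic-session pipeline
#'
#' Orchestrates simulate -> ER -> CMC -> group statistics on synthetic
#' data: generates an EMG tracking session and a coupled EEG/EMG session
#' (per task) plus a clinical table, runs [er_pipeline()],
#' [cmc_pipeline()] and [group_report()], writes all stage outputs under
#' `out_dir` and a manifest (configuration snapshot, seeds, package
#' version, per-file MD5 checksums).  Identical configuration and seed
#' give identical checksums.
#'
#' @param config list of configuration overrides (see
#'   [validate_config()]).
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  cfg <- validate_config(config)
  if (missing(out_dir)) stop("configuration error in 'out_dir': required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  emit <- function(obj, name, writer) {
    path <- file.path(out_dir, name)
    writer(obj, path)
    files <<- c(files, path)
    path
  }
  json_writer <- function(obj, path) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }

  # --- simulate ----------------------------------------------------------
  scfg <- synth_signal_config(seed = cfg$seed, n_trials = cfg$n_trials,
                              hold_s = cfg$hold_s, rest_s = cfg$rest_s,
                              extensor_level = cfg$target_level,
                              flexor_level = cfg$target_level)
  session <- generate_emg_session(scfg)
  coupled <- generate_coupled_eeg_emg(
    synth_signal_config(seed = cfg$seed + 1L, n_trials = cfg$n_trials,
                        hold_s = cfg$hold_s, rest_s = cfg$rest_s,
                        ipsilesional_gain = 1.5, contralesional_gain = 0.5))
  clinical <- generate_clinical_table(
    synth_clinical_config(seed = cfg$seed + 2L))
  map <- synth_channel_map(scfg)
  emit(session$recording, "emg_session.csv", write_recording)
  emit(session$schedule, "schedule.csv", write_schedule)
  emit(coupled$eeg, "eeg_session.csv", write_recording)
  emit(coupled$emg, "emg_coupled.csv", write_recording)
  emit(map, "channel_map.yaml", write_channel_map)
  emit(clinical, "clinical_table.csv", write_clinical_table)

  # --- er ----------------------------------------------------------------
  er <- er_pipeline(session$recording, session$schedule, map,
                    session$calibration,
                    analysis_window_s = cfg$analysis_window_s)
  emit(er$per_trial_means, "er_trials.csv",
       function(obj, p) utils::write.csv(obj, p, row.names = FALSE))
  emit(list(task = er$task, mean_er = er$mean_er,
            channels_used = as.list(er$channels_used),
            expected_er = session$true_params$expected_er),
       "er_result.json", json_writer)

  # --- cmc ---------------------------------------------------------------
  cmc <- cmc_pipeline(coupled$eeg, coupled$emg, map, coupled$schedule,
                      band = cfg$beta_band, window_s = cfg$window_s,
                      overlap = cfg$overlap,
                      segment_rule = cfg$segment_rule, alpha = cfg$alpha,
                      target_rate = cfg$target_rate)
  prof <- cmc$profiles[[1]]
  emit(data.frame(freq = prof$freqs, coherence = prof$coherence),
       "coherence_profile.csv",
       function(obj, p) utils::write.csv(obj, p, row.names = FALSE))
  emit(list(task = cmc$task,
            laterality = cmc$laterality$value,
            ipsilesional_z = cmc$ipsilesional$stouffer_z,
            contralesional_z = cmc$contralesional$stouffer_z,
            peak = cmc$peak, electrodes = as.list(cmc$electrodes),
            removed_labels = cmc$removed_labels,
            true_gains = coupled$true_params[c("ipsilesional_gain",
                                               "contralesional_gain")]),
       "cmc_result.json", json_writer)

  # --- stats -------------------------------------------------------------
  report <- group_report(clinical, alpha = cfg$alpha)
  emit(report$paired_tests, "paired_tests.csv",
       function(obj, p) utils::write.csv(obj, p, row.names = FALSE))
  emit(do.call(rbind, report$correlations), "correlations.csv",
       function(obj, p) utils::write.csv(obj, p, row.names = FALSE))

  manifest <- list(
    package = "emgcmc",
    version = as.character(utils::packageVersion("emgcmc")),
    config = cfg,
    files = as.list(tools::md5sum(files))
  )
  json_writer(manifest, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}
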