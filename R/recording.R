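#' Multichannel biosignal recording
#'
#' A `recording` holds a channels-by-time matrix of samples in microvolts
#' together with its sampling rate, ordered channel labels, per-channel
#' modality and a start time.  It is the container consumed by every
#' downstream analysis stage.
#'
#' @param samples numeric matrix, channels in rows and samples in columns.
#'   A plain numeric vector is treated as a single channel.
#' @param rate sampling frequency in Hz (> 0).
#' @param labels character vector of unique channel names; defaults to the
#'   row names of `samples`.
#' @param modality `"EMG"` or `"EEG"`, either one value for all channels or
#'   one per channel.
#' @param start_time recording start in seconds (offset 0 allowed).
#'
#' @return an object of class `recording` with elements `samples`, `rate`,
#'   `labels`, `modality` and `start_time`.
#' @examples
#' rec <- recording(matrix(rnorm(2000), nrow = 2), rate = 1000,
#'                  labels = c("C3", "C4"), modality = "EEG")
#' duration(rec)
#' @export
recording <- function(samples, rate, labels = rownames(samples),
                      modality = "EEG", start_time = 0) {
  if (is.vector(samples) && is.numeric(samples)) {
    samples <- matrix(samples, nrow = 1)
  }
  if (!is.matrix(samples) || !is.numeric(samples)) {
    stop("`samples` must be a numeric matrix (channels x time)")
  }
  if (ncol(samples) < 1L) stop("recording is empty: no samples")
  if (anyNA(samples) || any(!is.finite(samples))) {
    stop("ingestion error: recording contains NaN or non-finite samples")
  }
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("`rate` must be a single positive number (Hz)")
  }
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(samples)))
  labels <- as.character(labels)
  if (length(labels) != nrow(samples)) {
    stop("number of labels does not match number of channels")
  }
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  modality <- match_modality(modality, nrow(samples))
  rownames(samples) <- labels
  structure(
    list(samples = samples, rate = rate, labels = labels,
         modality = modality, start_time = start_time),
    class = "recording"
  )
}

match_modality <- function(modality, n_channels) {
  modality <- toupper(as.character(modality))
  if (!all(modality %in% c("EMG", "EEG"))) {
    stop("modality must be 'EMG' or 'EEG'")
  }
  if (length(modality) == 1L) modality <- rep(modality, n_channels)
  if (length(modality) != n_channels) {
    stop("modality must have length 1 or one entry per channel")
  }
  modality
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channel(s) x %d samples @ %g Hz (%.3f s)\n",
              n_channels(x), ncol(x$samples), x$rate, duration(x)))
  cat("  labels:", paste(x$labels, collapse = ", "), "\n")
  cat("  modality:", paste(unique(x$modality), collapse = "/"),
      " start:", x$start_time, "s\n")
  invisible(x)
}

#' Recording duration in seconds
#' @param rec a [recording()].
#' @return duration in seconds (`n_samples / rate`).
#' @export
duration <- function(rec) ncol(rec$samples) / rec$rate

#' Number of channels in a recording
#' @param rec a [recording()].
#' @export
n_channels <- function(rec) nrow(rec$samples)

#' Extract one channel as a numeric vector
#' @param rec a [recording()].
#' @param label channel name.
#' @export
get_channel <- function(rec, label) {
  if (!label %in% rec$labels) {
    stop(sprintf("mapping error: channel '%s' not present in recording", label))
  }
  rec$samples[label, ]
}

#' Channel map: muscles, EEG montage and lesion side
#'
#' Associates the four forearm muscles of the wrist tracking task with
#' recording channel labels, lists the sensorimotor EEG montage (a subset of
#' the 10-10 convention), and records which hemisphere is lesioned so that
#' lateral electrodes can be classified as ipsilesional or contralesional.
#'
#' @param muscle_channels named character vector mapping the muscle names
#'   `extensor_carpi_radialis_longus`, `extensor_carpi_ulnaris`,
#'   `flexor_carpi_radialis`, `flexor_carpi_ulnaris` to channel labels.
#' @param eeg_channels character vector of 10-10 electrode labels
#'   (e.g. `c("FC1","FC5","C3","CP1","CP5","FC2","FC6","C4","CP2","CP6")`).
#' @param lesion_side `"left"` or `"right"`.
#' @return an object of class `channel_map`.
#' @export
channel_map <- function(muscle_channels, eeg_channels,
                        lesion_side = c("left", "right")) {
  lesion_side <- match.arg(lesion_side)
  required <- c("extensor_carpi_radialis_longus", "extensor_carpi_ulnaris",
                "flexor_carpi_radialis", "flexor_carpi_ulnaris")
  muscle_channels <- unlist(muscle_channels)
  if (!all(required %in% names(muscle_channels))) {
    stop("muscle_channels must name all of: ",
         paste(required, collapse = ", "))
  }
  muscle_channels <- muscle_channels[required]
  eeg_channels <- as.character(eeg_channels)
  # every lateral EEG label must resolve to a hemisphere
  sides <- vapply(eeg_channels, electrode_side, character(1))
  if (any(is.na(sides))) {
    stop("EEG labels without a lateral 10-10 digit are not supported: ",
         paste(eeg_channels[is.na(sides)], collapse = ", "))
  }
  structure(
    list(muscle_channels = muscle_channels, eeg_channels = eeg_channels,
         lesion_side = lesion_side),
    class = "channel_map"
  )
}

#' @export
print.channel_map <- function(x, ...) {
  cat("<channel_map> lesion side:", x$lesion_side, "\n")
  cat("  muscles:\n")
  for (m in names(x$muscle_channels)) {
    cat(sprintf("    %-32s -> %s\n", m, x$muscle_channels[[m]]))
  }
  cat("  EEG:", paste(x$eeg_channels, collapse = ", "), "\n")
  invisible(x)
}

# 10-10 lateral labels end in a digit: odd = left hemisphere, even = right.
electrode_side <- function(label) {
  digits <- regmatches(label, regexpr("[0-9]+$", label))
  if (length(digits) == 0L) return(NA_character_)
  if (as.integer(digits) %% 2L == 1L) "left" else "right"
}

#' Hemisphere of an electrode relative to the lesion
#'
#' @param map a [channel_map()].
#' @param labels electrode labels.
#' @return `"ipsilesional"` or `"contralesional"` per label.
#' @export
hemisphere_of <- function(map, labels) {
  stopifnot(inherits(map, "channel_map"))
  sides <- vapply(labels, electrode_side, character(1))
  if (any(is.na(sides))) {
    stop("cannot assign a hemisphere to midline label(s): ",
         paste(labels[is.na(sides)], collapse = ", "))
  }
  ifelse(sides == map$lesion_side, "ipsilesional", "contralesional")
}

#' Muscle labels for one muscle group
#' @param map a [channel_map()].
#' @param group `"extensor"` or `"flexor"`.
#' @return channel labels in channel-map order.
#' @export
muscle_labels <- function(map, group = c("extensor", "flexor")) {
  group <- match.arg(group)
  idx <- if (group == "extensor") 1:2 else 3:4
  unname(map$muscle_channels[idx])
}

#' Trial schedule for the amplitude-tracking task
#'
#' Describes the timing of the quasi-isometric wrist tracking task: each
#' trial is a sustained hold at a target fraction of the maximal gross grasp
#' followed by rest.
#'
#' @param onsets trial hold onsets in seconds, strictly increasing.
#' @param hold_s hold duration(s) in seconds.
#' @param rest_s rest duration(s) in seconds.
#' @param task `"extension"` or `"flexion"`.
#' @param target_level hold target as a fraction of maximal gross grasp.
#' @return a data frame of class `trial_schedule` with columns `onset`,
#'   `hold_s`, `rest_s` and attributes `task` and `target_level`.
#' @seealso [periodic_schedule()] for the standard regular layout.
#' @export
trial_schedule <- function(onsets, hold_s, rest_s,
                           task = c("extension", "flexion"),
                           target_level = 0.15) {
  task <- match.arg(task)
  n <- length(onsets)
  if (n < 1L) stop("schedule error: no trials")
  hold_s <- rep_len(hold_s, n)
  rest_s <- rep_len(rest_s, n)
  if (any(hold_s <= 0) || any(rest_s < 0)) {
    stop("schedule error: hold_s must be > 0 and rest_s >= 0")
  }
  if (is.unsorted(onsets, strictly = TRUE)) {
    stop("schedule error: trial onsets must be strictly increasing")
  }
  ends <- onsets + hold_s + rest_s
  if (n > 1L && any(ends[-n] > onsets[-1L] + 1e-9)) {
    stop("schedule error: trials overlap")
  }
  out <- data.frame(onset = onsets, hold_s = hold_s, rest_s = rest_s)
  attr(out, "task") <- task
  attr(out, "target_level") <- target_level
  class(out) <- c("trial_schedule", "data.frame")
  out
}

#' Regular trial schedule
#'
#' The standard assessment layout: `n_trials` repetitions of a `hold_s`
#' second hold followed by `rest_s` seconds of rest (defaults: 12 trials of
#' 4 s hold + 6 s rest at a 15% target).
#'
#' @param n_trials number of trials.
#' @param hold_s,rest_s hold and rest durations in seconds.
#' @param start onset of the first hold in seconds.
#' @inheritParams trial_schedule
#' @return a [trial_schedule()].
#' @export
periodic_schedule <- function(n_trials = 12, hold_s = 4, rest_s = 6,
                              start = 0, task = c("extension", "flexion"),
                              target_level = 0.15) {
  onsets <- start + (seq_len(n_trials) - 1) * (hold_s + rest_s)
  trial_schedule(onsets, hold_s, rest_s, task = task,
                 target_level = target_level)
}

schedule_task <- function(schedule) attr(schedule, "task")
schedule_target <- function(schedule) attr(schedule, "target_level")
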