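#' Preprocess surface EMG into normalized amplitude envelopes
#'
#' Applies the standard surface-EMG chain: zero-phase 15-450 Hz Butterworth
#' bandpass, full-wave rectification, and division by the maximum-grasp
#' reference, yielding amplitude in fraction-of-maximum units.
#'
#' @param rec an EMG [recording()] with rate above 900 Hz (Nyquist for the
#'   450 Hz band edge).
#' @param reference maximum-grasp normalization reference: a single
#'   positive value, or a vector named by channel label (see
#'   [compute_max_grasp()]).
#' @param band bandpass edges in Hz.
#' @return an object of class `envelope_series`: list with `values`
#'   (channels x time matrix, nonnegative), `rate`, `labels`, `reference`.
#' @export
preprocess_emg <- function(rec, reference, band = c(15, 450)) {
  stopifnot(inherits(rec, "recording"))
  if (rec$rate <= 2 * band[2]) {
    stop(sprintf("Nyquist error: rate %g Hz too low for %g Hz band edge",
                 rec$rate, band[2]))
  }
  reference <- resolve_reference(reference, rec$labels)
  vals <- matrix(0, nrow = n_channels(rec), ncol = ncol(rec$samples))
  for (ch in seq_len(n_channels(rec))) {
    vals[ch, ] <- abs(bandpass_zerophase(rec$samples[ch, ], rec$rate,
                                         band[1], band[2])) / reference[ch]
  }
  rownames(vals) <- rec$labels
  structure(list(values = vals, rate = rec$rate, labels = rec$labels,
                 reference = reference),
            class = "envelope_series")
}

resolve_reference <- function(reference, labels) {
  if (length(reference) == 1L && is.null(names(reference))) {
    reference <- stats::setNames(rep(reference, length(labels)), labels)
  }
  if (!all(labels %in% names(reference))) {
    stop("normalization error: reference missing channel(s): ",
         paste(setdiff(labels, names(reference)), collapse = ", "))
  }
  reference <- reference[labels]
  if (any(!is.finite(reference)) || any(reference <= 0)) {
    stop("normalization error: reference must be positive")
  }
  reference
}

#' Maximum-grasp normalization reference
#'
#' Estimates the per-channel reference from one or more maximal gross grasp
#' calibration recordings as the 95th percentile of the 250 ms
#' moving-average rectified signal, robust to isolated spikes.  With
#' repeated calibrations the per-channel maximum across repeats is used.
#'
#' @param calibration a [recording()] or list of recordings (repeats), each
#'   at least 2 s long; channels are bandpassed 15-450 Hz and rectified
#'   before averaging.
#' @param window_s moving-average window in seconds.
#' @param prob percentile used as the reference.
#' @param band bandpass edges in Hz.
#' @return named numeric vector of references, one per channel.
#' @export
compute_max_grasp <- function(calibration, window_s = 0.25, prob = 0.95,
                              band = c(15, 450)) {
  recs <- if (inherits(calibration, "recording")) list(calibration) else calibration
  stopifnot(length(recs) >= 1,
            all(vapply(recs, inherits, logical(1), "recording")))
  refs <- lapply(recs, function(r) {
    if (duration(r) < 2) {
      stop("calibration segment must be at least 2 s long")
    }
    w <- max(1L, round(window_s * r$rate))
    vapply(seq_len(n_channels(r)), function(ch) {
      ma <- moving_average(abs(bandpass_zerophase(r$samples[ch, ], r$rate,
                                                  band[1], band[2])), w)
      stats::quantile(ma, prob, names = FALSE)
    }, numeric(1)) |> stats::setNames(r$labels)
  })
  Reduce(pmax, refs)
}

#' Select the feedback channel of a muscle group by signal-to-noise ratio
#'
#' Mirrors the online feedback rule: within a muscle group, the channel
#' with the largest hold-to-rest RMS ratio during voluntary activation is
#' used.  Ties break deterministically in channel-map order.
#'
#' @param env an [preprocess_emg()] `envelope_series`.
#' @param schedule a [trial_schedule()] with at least one hold and one rest
#'   epoch.
#' @param map a [channel_map()].
#' @param group `"extensor"` or `"flexor"`.
#' @return the selected channel label.
#' @export
select_feedback_channel <- function(env, schedule, map,
                                    group = c("extensor", "flexor")) {
  group <- match.arg(group)
  stopifnot(inherits(env, "envelope_series"))
  candidates <- muscle_labels(map, group)
  missing <- setdiff(candidates, env$labels)
  if (length(missing)) {
    stop("mapping error: channel(s) not in envelopes: ",
         paste(missing, collapse = ", "))
  }
  times <- (seq_len(ncol(env$values)) - 1) / env$rate
  hold <- hold_indicator(schedule, times)
  if (!any(hold) || all(hold)) {
    stop("schedule error: need at least one hold and one rest epoch")
  }
  rms <- function(x) sqrt(mean(x^2))
  snr <- vapply(candidates, function(lb) {
    rest_rms <- rms(env$values[lb, !hold])
    if (rest_rms == 0) return(NA_real_)
    rms(env$values[lb, hold]) / rest_rms
  }, numeric(1))
  if (all(is.na(snr))) {
    stop("degenerate-SNR error: zero rest RMS on all candidate channels")
  }
  candidates[which.max(snr)]  # which.max: first maximum = map order tie-break
}

#' Segment the analysis window of each trial
#'
#' Extracts the final `analysis_window_s` seconds of every sustained hold
#' (the portion averaged by the individuation statistic, default 3 s).
#'
#' @param x numeric vector (one channel's envelope).
#' @param schedule a [trial_schedule()].
#' @param rate sampling rate of `x` in Hz.
#' @param analysis_window_s analysis window length in seconds; every hold
#'   must be at least this long.
#' @return matrix with one row per trial and
#'   `round(analysis_window_s * rate)` columns.
#' @export
segment_trials <- function(x, schedule, rate, analysis_window_s = 3) {
  if (any(schedule$hold_s < analysis_window_s - 1e-9)) {
    stop("schedule error: hold shorter than the analysis window")
  }
  w <- round(analysis_window_s * rate)
  segs <- matrix(0, nrow = nrow(schedule), ncol = w)
  for (i in seq_len(nrow(schedule))) {
    end_idx <- floor((schedule$onset[i] + schedule$hold_s[i]) * rate)
    end_idx <- min(end_idx, length(x))
    idx <- (end_idx - w + 1):end_idx
    if (idx[1] < 1) stop("schedule error: trial window precedes recording")
    segs[i, ] <- x[idx]
  }
  segs
}

#' Extensor ratio (muscle individuation statistic)
#'
#' `ER = extensor / (extensor + flexor)` on mean rectified, normalized
#' activity.  1 indicates pure extensor recruitment, 0 pure flexor
#' recruitment, and 0.5 comparable recruitment from both muscle groups.
#'
#' @param extensor_mean,flexor_mean nonnegative mean activity of the
#'   extensor and flexor channels (sum must be positive).
#' @return ER in `[0, 1]`.
#' @export
compute_er <- function(extensor_mean, flexor_mean) {
  if (any(extensor_mean < 0) || any(flexor_mean < 0)) {
    stop("ER inputs must be nonnegative")
  }
  tot <- extensor_mean + flexor_mean
  if (any(tot <= 0)) {
    stop("undefined-ER error: extensor and flexor activity both zero")
  }
  extensor_mean / tot
}

#' Full extensor-ratio pipeline for one tracking session
#'
#' Preprocesses the EMG, selects the feedback channel per muscle group by
#' hold/rest SNR (or averages the two channels of each group when
#' `average_group = TRUE`), averages the last `analysis_window_s` seconds
#' of each hold, and computes per-trial and mean extensor ratios.
#'
#' @param rec EMG [recording()].
#' @param schedule [trial_schedule()].
#' @param map [channel_map()].
#' @param calibration maximum-grasp calibration passed to
#'   [compute_max_grasp()], or a precomputed named reference vector.
#' @param analysis_window_s averaging window (s).
#' @param average_group average both channels of each muscle group instead
#'   of using the SNR-selected channel.
#' @return an object of class `er_result`: list with `task`,
#'   `per_trial_er`, `mean_er`, `channels_used`, `per_trial_means`.
#' @export
er_pipeline <- function(rec, schedule, map, calibration,
                        analysis_window_s = 3, average_group = FALSE) {
  reference <- if (is.numeric(calibration)) {
    resolve_reference(calibration, rec$labels)
  } else {
    compute_max_grasp(calibration)
  }
  env <- preprocess_emg(rec, reference)
  group_mean <- function(group) {
    if (average_group) {
      labs <- muscle_labels(map, group)
      segs <- lapply(labs, function(lb) {
        segment_trials(env$values[lb, ], schedule, env$rate,
                       analysis_window_s)
      })
      list(label = paste(labs, collapse = "+"),
           means = rowMeans(Reduce(`+`, segs) / length(segs)))
    } else {
      lb <- select_feedback_channel(env, schedule, map, group)
      list(label = lb,
           means = rowMeans(segment_trials(env$values[lb, ], schedule,
                                           env$rate, analysis_window_s)))
    }
  }
  ext <- group_mean("extensor")
  flex <- group_mean("flexor")
  per_trial <- compute_er(ext$means, flex$means)
  structure(
    list(task = schedule_task(schedule),
         per_trial_er = per_trial,
         mean_er = mean(per_trial),
         channels_used = c(extensor = ext$label, flexor = flex$label),
         per_trial_means = data.frame(trial = seq_along(per_trial),
                                      extensor = ext$means,
                                      flexor = flex$means,
                                      er = per_trial)),
    class = "er_result"
  )
}

#' @export
print.er_result <- function(x, ...) {
  cat(sprintf("<er_result> task: %s, mean ER = %.3f over %d trials\n",
              x$task, x$mean_er, length(x$per_trial_er)))
  cat("  channels:", paste(names(x$channels_used), x$channels_used,
                           sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Screening test for minimum sustained extensor activity
#'
#' Eligibility rule of the training protocol: the participant must hold at
#' least 30% of the prerecorded maximum for 10 trials of 4 s.  A trial
#' passes when its hold-window mean normalized activity is at or above the
#' threshold (inclusive); the screen passes only if all trials pass.
#'
#' @param x normalized envelope of the monitored extensor channel.
#' @param schedule [trial_schedule()] with at least `n_trials` trials.
#' @param rate sampling rate of `x` in Hz.
#' @param threshold fraction of maximum to sustain.
#' @param n_trials number of screening trials evaluated.
#' @return list of class `screening_result`: `per_trial_pass`, `passed`,
#'   `threshold`, `n_trials`, `trial_means`.
#' @export
screening_test <- function(x, schedule, rate, threshold = 0.30,
                           n_trials = 10) {
  if (nrow(schedule) < n_trials) {
    stop("schedule error: fewer than ", n_trials, " trials in schedule")
  }
  sched <- schedule[seq_len(n_trials), , drop = FALSE]
  means <- vapply(seq_len(n_trials), function(i) {
    i0 <- floor(sched$onset[i] * rate) + 1
    i1 <- min(floor((sched$onset[i] + sched$hold_s[i]) * rate), length(x))
    mean(x[i0:i1])
  }, numeric(1))
  pass <- means >= threshold
  structure(list(per_trial_pass = pass, passed = all(pass),
                 threshold = threshold, n_trials = n_trials,
                 trial_means = means),
            class = "screening_result")
}

#' Instantaneous game control signal
#'
#' Regularized extensor ratio used to drive feedback:
#' `(ext + eps/2) / (ext + flex + eps)`.  Continuous in both inputs, equal
#' to 0.5 at rest (both zero), and approaching 1 (0) for pure extension
#' (flexion).
#'
#' @param ext,flex nonnegative instantaneous envelope samples (vectorized).
#' @param epsilon regularization constant (> 0) in the same
#'   fraction-of-maximum units.
#' @return values in `[0, 1]`.
#' @export
control_signal <- function(ext, flex, epsilon = 0.05) {
  if (epsilon <= 0) stop("parameter error: epsilon must be > 0")
  if (any(ext < 0) || any(flex < 0)) {
    stop("envelope samples must be nonnegative")
  }
  (ext + epsilon / 2) / (ext + flex + epsilon)
}
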