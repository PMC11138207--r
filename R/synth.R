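#' Configuration for the synthetic EMG/EEG session generator
#'
#' Defines the recording protocol emulated by [generate_emg_session()] and
#' [generate_coupled_eeg_emg()]: by default 12 trials of a 4 s hold followed
#' by 6 s of rest, surface EMG from four forearm muscles at 2148 Hz and
#' sensorimotor EEG at 500 Hz, with a 15%-of-maximum tracking target.
#'
#' Ground-truth knobs: `extensor_level` / `flexor_level` program the hold
#' amplitude of each muscle group as a fraction of the simulated maximum
#' grasp, so the extensor ratio recovered downstream should equal
#' `extensor_level / (extensor_level + flexor_level)`.
#' `ipsilesional_gain` / `contralesional_gain` set the amplitude with which
#' a shared narrowband beta source is injected into each hemisphere's EEG
#' channels; the same source amplitude-modulates the task muscles' EMG, so
#' beta-band corticomuscular coherence for a hemisphere grows monotonically
#' with its gain, approximately as `g^2 / (g^2 + noise_sd^2)` times an
#' EMG-side attenuation factor.
#'
#' @param seed integer master seed; all generators are pure functions of the
#'   configuration including this seed.
#' @param n_trials,hold_s,rest_s trial layout.
#' @param emg_rate,eeg_rate acquisition rates in Hz.
#' @param task `"extension"` or `"flexion"` (which muscle pair is tracked
#'   and beta-modulated).
#' @param extensor_level,flexor_level hold activation per muscle group, as
#'   fractions of the simulated maximum (in `[0, 1]`).
#' @param baseline_level resting muscle-tone level (scaled by the electrode
#'   gain like any muscle activity).
#' @param channel_gains length-4 per-channel electrode gain multipliers in
#'   muscle order (ECRL, ECU, FCR, FCU); the feedback-channel selector
#'   should pick the largest gain in each group.
#' @param sensor_noise_uV gain-independent additive sensor noise (uV RMS);
#'   dominates the rest floor so that hold/rest SNR grows with the
#'   electrode gain.
#' @param max_amplitude_uV amplitude of the simulated maximum contraction.
#' @param ipsilesional_gain,contralesional_gain EEG beta-source gains.
#' @param beta_source_freq center frequency of the shared source in Hz
#'   (must lie inside the 12-30 Hz analysis band).
#' @param beta_bandwidth source bandwidth in Hz (narrowband Gaussian
#'   process; a pure sine would make neighboring-bin coherence degenerate).
#' @param emg_beta_mod modulation depth of the beta source on the task
#'   muscles' EMG envelope.
#' @param neighbor_weight spatial decay of the source's scalp expression:
#'   weight 1 at the hemisphere's motor electrode (C3/C4), this weight at
#'   its same-hemisphere neighbors.  A focal (non-uniform) leadfield is
#'   required for hemispheric contrast to survive common-average
#'   re-referencing.
#' @param noise_sd EEG sensor-noise standard deviation.
#' @param line_noise_amp,line_freq mains interference amplitude and
#'   frequency.
#' @param lesion_side `"left"` or `"right"`; maps the ipsilesional gain onto
#'   odd- or even-numbered electrodes.
#' @param n_bad_channels number of EEG channels to corrupt via
#'   [inject_artifacts()].
#' @param eeg_labels montage; defaults to the ten lateral sensorimotor
#'   10-10 labels.
#' @return a list of class `synth_signal_config`.
#' @export
synth_signal_config <- function(seed = 1L, n_trials = 12, hold_s = 4,
                                rest_s = 6, emg_rate = 2148, eeg_rate = 500,
                                task = c("extension", "flexion"),
                                extensor_level = 0.15, flexor_level = 0.15,
                                baseline_level = 0.01,
                                channel_gains = c(1, 0.85, 1, 0.85),
                                sensor_noise_uV = 2,
                                max_amplitude_uV = 100,
                                ipsilesional_gain = 1,
                                contralesional_gain = 1,
                                beta_source_freq = 20, beta_bandwidth = 2,
                                emg_beta_mod = 0.5, neighbor_weight = 0.3,
                                noise_sd = 1,
                                line_noise_amp = 0.2, line_freq = 60,
                                lesion_side = c("left", "right"),
                                n_bad_channels = 0,
                                eeg_labels = c("FC1", "FC5", "C3", "CP1",
                                               "CP5", "FC2", "FC6", "C4",
                                               "CP2", "CP6")) {
  task <- match.arg(task)
  lesion_side <- match.arg(lesion_side)
  lv <- c(extensor_level, flexor_level, baseline_level)
  if (any(lv < 0) || any(lv > 1)) {
    stop("config error: activation levels must lie in [0, 1]")
  }
  if (ipsilesional_gain < 0 || contralesional_gain < 0) {
    stop("config error: coupling gains must be >= 0")
  }
  if (beta_source_freq <= 12 || beta_source_freq >= 30) {
    stop("config error: beta_source_freq must lie inside the 12-30 Hz band")
  }
  if (beta_bandwidth <= 0) stop("config error: beta_bandwidth must be > 0")
  if (hold_s < 3) {
    stop("config error: hold_s shorter than the 3 s analysis window")
  }
  if (length(channel_gains) != 4 || any(channel_gains <= 0)) {
    stop("config error: channel_gains must be 4 positive values")
  }
  structure(as.list(environment()), class = "synth_signal_config")
}

emg_channel_labels <- c("ECRL", "ECU", "FCR", "FCU")

#' Default channel map for synthetic sessions
#' @param config a [synth_signal_config()].
#' @return a [channel_map()] matching the generator's labels.
#' @export
synth_channel_map <- function(config) {
  channel_map(
    muscle_channels = c(extensor_carpi_radialis_longus = "ECRL",
                        extensor_carpi_ulnaris = "ECU",
                        flexor_carpi_radialis = "FCR",
                        flexor_carpi_ulnaris = "FCU"),
    eeg_channels = config$eeg_labels,
    lesion_side = config$lesion_side
  )
}

# per-channel hold level: extensors track extensor_level, flexors
# flexor_level, scaled by the electrode gain
channel_hold_levels <- function(config) {
  c(rep(config$extensor_level, 2), rep(config$flexor_level, 2))
}

# indicator of hold samples on a time grid
hold_indicator <- function(schedule, times) {
  ind <- logical(length(times))
  for (i in seq_len(nrow(schedule))) {
    ind <- ind | (times >= schedule$onset[i] &
                    times < schedule$onset[i] + schedule$hold_s[i])
  }
  ind
}

#' Generate a synthetic EMG tracking session
#'
#' Four broadband (20-450 Hz) Gaussian-carrier EMG channels whose amplitude
#' envelope is `baseline_level` at rest and the programmed group level
#' during holds.  Under the extensor-ratio definition the programmed ground
#' truth is `extensor_level / (extensor_level + flexor_level)`.
#'
#' @param config a [synth_signal_config()].
#' @return a list with elements `recording` (EMG at `emg_rate`), `schedule`
#'   (a [trial_schedule()]), `calibration` (a 4 s maximum-grasp recording
#'   used to derive the normalization reference) and `true_params`
#'   (programmed levels, per-channel gains and the expected ER).
#' @export
generate_emg_session <- function(config) {
  stopifnot(inherits(config, "synth_signal_config"))
  withr::with_seed(config$seed, {
    rate <- config$emg_rate
    sched <- periodic_schedule(config$n_trials, config$hold_s, config$rest_s,
                               task = config$task,
                               target_level = config$extensor_level)
    n <- round(config$n_trials * (config$hold_s + config$rest_s) * rate)
    times <- (seq_len(n) - 1) / rate
    hold <- hold_indicator(sched, times)
    levels <- channel_hold_levels(config)
    samples <- matrix(0, nrow = 4, ncol = n)
    for (ch in 1:4) {
      carrier <- bandlimited_noise(n, rate, 20, 450)
      env <- ifelse(hold, levels[ch], config$baseline_level)
      samples[ch, ] <- config$max_amplitude_uV * config$channel_gains[ch] *
        env * carrier + config$sensor_noise_uV * stats::rnorm(n)
    }
    calib <- generate_calibration(config, seconds = 4)
    expected_er <- config$extensor_level /
      (config$extensor_level + config$flexor_level)
    list(
      recording = recording(samples, rate = rate,
                            labels = emg_channel_labels, modality = "EMG"),
      schedule = sched,
      calibration = calib,
      true_params = list(extensor_level = config$extensor_level,
                         flexor_level = config$flexor_level,
                         channel_gains = config$channel_gains,
                         max_amplitude_uV = config$max_amplitude_uV,
                         expected_er = expected_er)
    )
  })
}

# maximum-grasp calibration: all four muscles at level 1
generate_calibration <- function(config, seconds = 4) {
  rate <- config$emg_rate
  n <- round(seconds * rate)
  samples <- matrix(0, nrow = 4, ncol = n)
  for (ch in 1:4) {
    samples[ch, ] <- config$max_amplitude_uV * config$channel_gains[ch] *
      bandlimited_noise(n, rate, 20, 450) +
      config$sensor_noise_uV * stats::rnorm(n)
  }
  recording(samples, rate = rate, labels = emg_channel_labels,
            modality = "EMG")
}

#' Generate a coupled EEG/EMG session with known coherence structure
#'
#' A narrowband Gaussian beta source (center `beta_source_freq`, bandwidth
#' `beta_bandwidth`) is added to every EEG channel with its hemisphere's
#' gain and amplitude-modulates the task muscle pair's EMG envelope during
#' holds.  Expected beta-band coherence for a hemisphere with gain `g` is
#' approximately `g^2 / (g^2 + noise_sd^2)` attenuated by the EMG envelope
#' extraction, so it increases monotonically with `g`; the laterality index
#' recovered downstream has the sign of `ipsilesional_gain -
#' contralesional_gain`.
#'
#' @param config a [synth_signal_config()].
#' @return list with `eeg` (recording at `eeg_rate`), `emg` (recording at
#'   `emg_rate`), `schedule`, `calibration`, `bad_labels` (channels
#'   corrupted when `n_bad_channels > 0`) and `true_params`.
#' @export
generate_coupled_eeg_emg <- function(config) {
  stopifnot(inherits(config, "synth_signal_config"))
  withr::with_seed(config$seed, {
    total_s <- config$n_trials * (config$hold_s + config$rest_s)
    sched <- periodic_schedule(config$n_trials, config$hold_s, config$rest_s,
                               task = config$task,
                               target_level = config$extensor_level)
    # shared source generated on the (finer) EMG grid
    n_emg <- round(total_s * config$emg_rate)
    t_emg <- (seq_len(n_emg) - 1) / config$emg_rate
    bw <- config$beta_bandwidth / 2
    src <- bandlimited_noise(n_emg, config$emg_rate,
                             config$beta_source_freq - bw,
                             config$beta_source_freq + bw)

    # EMG: task pair carries the beta modulation during holds
    hold <- hold_indicator(sched, t_emg)
    levels <- channel_hold_levels(config)
    task_idx <- if (config$task == "extension") 1:2 else 3:4
    emg <- matrix(0, nrow = 4, ncol = n_emg)
    for (ch in 1:4) {
      carrier <- bandlimited_noise(n_emg, config$emg_rate, 20, 450)
      env <- ifelse(hold, levels[ch], config$baseline_level)
      if (ch %in% task_idx) {
        env <- env * pmax(1 + config$emg_beta_mod * src, 0.05)
      }
      emg[ch, ] <- config$max_amplitude_uV * config$channel_gains[ch] *
        env * carrier + config$sensor_noise_uV * stats::rnorm(n_emg)
    }
    emg_rec <- recording(emg, rate = config$emg_rate,
                         labels = emg_channel_labels, modality = "EMG")

    # EEG: hemisphere gain times the source plus sensor and line noise
    n_eeg <- round(total_s * config$eeg_rate)
    t_eeg <- (seq_len(n_eeg) - 1) / config$eeg_rate
    src_eeg <- stats::approx(t_emg, src, xout = t_eeg, rule = 2)$y
    labels <- config$eeg_labels
    sides <- vapply(labels, electrode_side, character(1))
    ipsi_side <- config$lesion_side
    gains <- ifelse(sides == ipsi_side, config$ipsilesional_gain,
                    config$contralesional_gain)
    # focal leadfield: full gain at the motor electrode, decayed at its
    # same-hemisphere neighbors, so CAR keeps the hemispheric contrast
    motor <- labels %in% c("C3", "C4")
    gains <- gains * ifelse(motor, 1, config$neighbor_weight)
    eeg <- matrix(0, nrow = length(labels), ncol = n_eeg)
    for (ch in seq_along(labels)) {
      eeg[ch, ] <- gains[ch] * src_eeg +
        config$noise_sd * stats::rnorm(n_eeg) +
        config$line_noise_amp *
          sin(2 * pi * config$line_freq * t_eeg + stats::runif(1, 0, 2 * pi))
    }
    eeg_rec <- recording(eeg, rate = config$eeg_rate, labels = labels,
                         modality = "EEG")
    bad_labels <- character(0)
    if (config$n_bad_channels > 0) {
      art <- inject_artifacts(eeg_rec, config$n_bad_channels,
                              seed = config$seed + 1L)
      eeg_rec <- art$recording
      bad_labels <- art$bad_labels
    }
    calib <- generate_calibration(config, seconds = 4)
    list(
      eeg = eeg_rec, emg = emg_rec, schedule = sched, calibration = calib,
      bad_labels = bad_labels,
      true_params = list(
        ipsilesional_gain = config$ipsilesional_gain,
        contralesional_gain = config$contralesional_gain,
        lesion_side = config$lesion_side,
        beta_source_freq = config$beta_source_freq,
        expected_coh_ipsi = config$ipsilesional_gain^2 /
          (config$ipsilesional_gain^2 + config$noise_sd^2),
        expected_coh_contra = config$contralesional_gain^2 /
          (config$contralesional_gain^2 + config$noise_sd^2),
        expected_laterality_sign = sign(config$ipsilesional_gain -
                                          config$contralesional_gain)
      )
    )
  })
}

#' Corrupt channels with recording artifacts
#'
#' Replaces `n_bad_channels` randomly chosen channels with high-kurtosis
#' spike trains or flatlines (alternating), emulating broken electrodes for
#' the bad-channel detector.
#'
#' @param rec a [recording()].
#' @param n_bad_channels number of channels to corrupt
#'   (`< n_channels(rec)`).
#' @param seed integer seed.
#' @return list with `recording` (corrupted copy) and `bad_labels`.
#' @export
inject_artifacts <- function(rec, n_bad_channels, seed = 1L) {
  stopifnot(inherits(rec, "recording"))
  if (n_bad_channels == 0) return(list(recording = rec,
                                       bad_labels = character(0)))
  if (n_bad_channels >= n_channels(rec)) {
    stop("parameter error: n_bad_channels must be < number of channels")
  }
  withr::with_seed(seed, {
    idx <- sample(n_channels(rec), n_bad_channels)
    scale <- max(apply(rec$samples, 1, stats::sd))
    n <- ncol(rec$samples)
    for (k in seq_along(idx)) {
      ch <- idx[k]
      if (k %% 2L == 1L) {
        # spike train: quiet floor with sparse large deflections
        x <- stats::rnorm(n, 0, 0.05 * scale)
        at <- sample(n, max(5, round(0.003 * n)))
        x[at] <- x[at] + 40 * scale * sample(c(-1, 1), length(at),
                                             replace = TRUE)
        rec$samples[ch, ] <- x
      } else {
        rec$samples[ch, ] <- 0
      }
    }
    list(recording = rec, bad_labels = rec$labels[sort(idx)])
  })
}

#' Configuration for the synthetic clinical-score generator
#'
#' Paired pre/post scores for the study's outcome battery.  Defaults are
#' the group statistics of a nine-participant wrist biofeedback cohort:
#' pre mean/SD per measure, mean paired difference, and the SD of paired
#' differences implied by the group t statistic.  Change scores can be
#' correlated across measures.
#'
#' @param seed integer seed.
#' @param n_participants group size (default 9).
#' @param measures data frame with columns `measure`, `pre_mean`, `pre_sd`,
#'   `diff_mean`, `diff_sd`.
#' @param correlations list of `list(a =, b =, r =)` entries giving the
#'   correlation between the change scores of measures `a` and `b`; the
#'   implied correlation matrix must be positive definite.
#' @return a list of class `synth_clinical_config`.
#' @export
synth_clinical_config <- function(seed = 1L, n_participants = 9,
                                  measures = default_clinical_measures(),
                                  correlations = default_clinical_correlations()) {
  need <- c("measure", "pre_mean", "pre_sd", "diff_mean", "diff_sd")
  if (!all(need %in% names(measures))) {
    stop("config error: measures must have columns ",
         paste(need, collapse = ", "))
  }
  if (any(measures$pre_sd <= 0) || any(measures$diff_sd <= 0)) {
    stop("config error: SDs must be > 0")
  }
  for (co in correlations) {
    if (abs(co$r) > 1) stop("config error: correlations must lie in [-1, 1]")
    if (!all(c(co$a, co$b) %in% measures$measure)) {
      stop("config error: correlation names unknown measure")
    }
  }
  structure(list(seed = seed, n_participants = n_participants,
                 measures = measures, correlations = correlations),
            class = "synth_clinical_config")
}

#' @rdname synth_clinical_config
#' @export
default_clinical_measures <- function() {
  data.frame(
    measure = c("active_extension", "active_flexion", "er_extension",
                "er_flexion", "sis_total", "sis_adl", "sis_hand",
                "sis_participation", "sis_strength", "fma", "arat"),
    pre_mean = c(8.56, 19.56, 0.48, 0.39, 54.88, 37.11, 9.56, 27.44, 9.22,
                 26, 12.89),
    pre_sd = c(10, 14.16, 0.13, 0.12, 9.92, 6.72, 4.67, 5.27, 2.54, 9.89,
               8.78),
    diff_mean = c(11.55, 8.00, 0.03, -0.06, 2.68, 1.22, 0.55, 2.00, 0.22,
                  1.11, 3.22),
    # sd of paired differences implied by diff_mean, n = 9 and the group t
    diff_sd = c(10.828, 9.677, 0.180, 0.231, 4.188, 5.719, 2.171, 6.061,
                1.082, 2.622, 5.194),
    # instrument score ranges (NA = unbounded, e.g. ROM in degrees);
    # SIS subscale sums span items..5*items
    range_lo = c(NA, NA, 0, 0, 0, 10, 5, 8, 4, 0, 0),
    range_hi = c(NA, NA, 1, 1, 100, 50, 25, 40, 20, 66, 57)
  )
}

#' @rdname synth_clinical_config
#' @export
default_clinical_correlations <- function() {
  list(list(a = "er_extension", b = "sis_participation", r = 0.72),
       list(a = "er_extension", b = "sis_strength", r = 0.77),
       list(a = "sis_participation", b = "sis_strength", r = 0.60))
}

#' Generate a paired pre/post clinical score table
#'
#' Pre scores are drawn independently per measure from
#' `N(pre_mean, pre_sd^2)`; paired differences are drawn jointly from a
#' multivariate normal with the configured means, SDs and cross-measure
#' correlations; post = pre + difference.  Bounded instruments (ER, SIS
#' subscales, FMA, ARAT) are truncated to their score ranges, so extreme
#' draws shrink slightly toward the bounds.
#'
#' @param config a [synth_clinical_config()].
#' @return a [clinical_table()] with attribute `true_params` echoing the
#'   generating configuration.
#' @export
generate_clinical_table <- function(config) {
  stopifnot(inherits(config, "synth_clinical_config"))
  m <- config$measures
  p <- nrow(m)
  R <- diag(p)
  dimnames(R) <- list(m$measure, m$measure)
  for (co in config$correlations) {
    R[co$a, co$b] <- R[co$b, co$a] <- co$r
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    stop("config error: implied change-score correlation matrix is not ",
         "positive definite")
  }
  Sigma <- diag(m$diff_sd) %*% R %*% diag(m$diff_sd)
  withr::with_seed(config$seed, {
    n <- config$n_participants
    pre <- sapply(seq_len(p), function(j) {
      stats::rnorm(n, m$pre_mean[j], m$pre_sd[j])
    })
    d <- MASS::mvrnorm(n, mu = m$diff_mean, Sigma = Sigma)
    if (is.vector(d)) d <- matrix(d, nrow = 1)
    post <- pre + d
    # truncate bounded instruments to their score range
    if (!is.null(m$range_lo)) {
      for (j in seq_len(p)) {
        if (!is.na(m$range_lo[j])) {
          pre[, j] <- pmin(pmax(pre[, j], m$range_lo[j]), m$range_hi[j])
          post[, j] <- pmin(pmax(post[, j], m$range_lo[j]), m$range_hi[j])
        }
      }
    }
    tab <- data.frame(
      participant = rep(sprintf("P%02d", seq_len(n)), each = p),
      measure = rep(m$measure, times = n),
      pre = as.vector(t(pre)),
      post = as.vector(t(post))
    )
    out <- clinical_table(tab)
    attr(out, "true_params") <- list(measures = m,
                                     correlations = config$correlations)
    out
  })
}

#' Paired clinical score table
#'
#' Long-format table of participants x measures with `pre` and `post`
#' columns, as produced by the pre/post assessment battery.
#'
#' @param df data frame with columns `participant`, `measure`, `pre`,
#'   `post`.
#' @return the validated data frame with class `clinical_table`.
#' @export
clinical_table <- function(df) {
  need <- c("participant", "measure", "pre", "post")
  if (!all(need %in% names(df))) {
    stop("clinical table must have columns ", paste(need, collapse = ", "))
  }
  if (!is.numeric(df$pre) || !is.numeric(df$post)) {
    stop("clinical table scores must be numeric")
  }
  class(df) <- unique(c("clinical_table", class(df)))
  df
}

#' Read / write a clinical table as CSV
#' @param path file path.
#' @return a [clinical_table()].
#' @export
read_clinical_table <- function(path) clinical_table(utils::read.csv(path))

#' @rdname read_clinical_table
#' @param tab a [clinical_table()].
#' @export
write_clinical_table <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  invisible(path)
}
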