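#' Detect bad EEG channels
#'
#' Flags channels whose sample kurtosis is an outlier across the montage
#' (robust z-score of excess kurtosis, using the median and MAD across
#' channels, above `kurtosis_z`) and flatlined channels (near-zero
#' standard deviation).  Deterministic.  Intended for unfiltered signals:
#' filtering smears flatlines and spikes with edge transients and dilutes
#' both criteria.
#'
#' @param rec an EEG [recording()] with at least 4 channels.
#' @param kurtosis_z robust z-score threshold.
#' @return character vector of flagged labels (possibly empty).
#' @export
detect_bad_channels <- function(rec, kurtosis_z = 5) {
  stopifnot(inherits(rec, "recording"))
  if (n_channels(rec) < 4) stop("need at least 4 channels")
  sds <- apply(rec$samples, 1, stats::sd)
  flat <- sds < 1e-8 | sds < 1e-8 * max(sds)
  k <- apply(rec$samples, 1, e1071::kurtosis)
  k[flat] <- NA  # flatlines have undefined kurtosis
  kz <- rep(FALSE, length(k))
  if (sum(!is.na(k)) >= 4) {
    md <- stats::median(k, na.rm = TRUE)
    sc <- stats::mad(k, na.rm = TRUE)
    if (sc > 0) kz <- !is.na(k) & (k - md) / sc > kurtosis_z
  }
  rec$labels[flat | kz]
}

#' Preprocess EEG for coherence analysis
#'
#' Order of operations: zero-phase 5-100 Hz bandpass, bad-channel removal
#' ([detect_bad_channels()]), common-average re-reference over the retained
#' channels, and per-channel z-scoring.  Bad channels are detected on the
#' unfiltered signals (flatlines and spike trains are raw-signal
#' properties; the bandpass smears both with edge transients) but removed
#' after filtering.
#'
#' @param rec an EEG [recording()], at least 4 channels at >= 250 Hz.
#' @param band bandpass edges in Hz.
#' @param kurtosis_z bad-channel threshold.
#' @return list with `recording` (cleaned, z-scored) and `removed_labels`.
#' @export
preprocess_eeg <- function(rec, band = c(5, 100), kurtosis_z = 5) {
  stopifnot(inherits(rec, "recording"))
  if (n_channels(rec) < 4) stop("need at least 4 EEG channels")
  if (rec$rate < 250) stop("Nyquist error: EEG rate must be >= 250 Hz")
  removed <- detect_bad_channels(rec, kurtosis_z)
  filt <- rec
  for (ch in seq_len(n_channels(rec))) {
    filt$samples[ch, ] <- bandpass_zerophase(rec$samples[ch, ], rec$rate,
                                             band[1], band[2])
  }
  if (length(removed) > n_channels(rec) / 2) {
    stop("quality error: more than half of the EEG channels were removed (",
         paste(removed, collapse = ", "), ")")
  }
  keep <- setdiff(filt$labels, removed)
  samples <- filt$samples[keep, , drop = FALSE]
  samples <- sweep(samples, 2, colMeans(samples))  # common average reference
  for (ch in seq_len(nrow(samples))) {
    samples[ch, ] <- zscore(samples[ch, ], keep[ch])
  }
  out <- recording(samples, rate = rec$rate, labels = keep,
                   modality = rec$modality[match(keep, rec$labels)],
                   start_time = rec$start_time)
  list(recording = out, removed_labels = removed)
}

#' EMG envelopes for corticomuscular coherence
#'
#' Bandpasses each EMG channel 15-450 Hz, takes the magnitude of its
#' analytic (Hilbert-transformed) signal, and z-scores per channel.
#'
#' @param rec an EMG [recording()].
#' @param band bandpass edges in Hz.
#' @return a [recording()] of z-scored envelope channels.
#' @export
emg_for_cmc <- function(rec, band = c(15, 450)) {
  stopifnot(inherits(rec, "recording"))
  if (rec$rate <= 2 * band[2]) {
    stop(sprintf("Nyquist error: rate %g Hz too low for %g Hz band edge",
                 rec$rate, band[2]))
  }
  samples <- rec$samples
  for (ch in seq_len(n_channels(rec))) {
    env <- Mod(analytic_signal(bandpass_zerophase(rec$samples[ch, ],
                                                  rec$rate, band[1],
                                                  band[2])))
    samples[ch, ] <- zscore(env, rec$labels[ch])
  }
  recording(samples, rate = rec$rate, labels = rec$labels,
            modality = rec$modality, start_time = rec$start_time)
}

#' Analytic confidence level for magnitude-squared coherence
#'
#' `1 - alpha^(1/(L - 1))`, the `(1 - alpha)` confidence limit of the
#' coherence of independent signals estimated from `L` independent
#' segments.  Strictly decreasing in `L` and tending to 0 as `L` grows.
#'
#' @param L adjusted number of segments (>= 2).
#' @param alpha significance level.
#' @return the confidence level.
#' @export
confidence_level <- function(L, alpha = 0.05) {
  if (any(L < 2)) stop("parameter error: L must be >= 2")
  if (any(alpha < 0 | alpha > 1)) {
    stop("parameter error: alpha must lie in [0, 1]")
  }
  1 - alpha^(1 / (L - 1))
}

# effective number of independent segments for Welch averaging with
# overlapping windows (variance-equivalent count; c_m is the normalized
# window overlap correlation at lag m * hop)
effective_segments <- function(K, win, hop) {
  W <- length(win)
  mmax <- ceiling(W / hop) - 1L
  if (mmax < 1L || K < 2L) return(K)
  m <- seq_len(min(mmax, K - 1L))
  cm2 <- vapply(m * hop, function(lag) {
    i <- seq_len(W - lag)
    (sum(win[i] * win[i + lag]) / sum(win^2))^2
  }, numeric(1))
  K / (1 + 2 * sum((1 - m / K) * cm2))
}

#' Welch magnitude-squared coherence
#'
#' Estimates coherence between two equally sampled signals with Welch's
#' method: Hann-windowed segments of `window_s` seconds (128 ms, i.e. 128
#' samples at 1 kHz) with fractional `overlap` (75%), mean-detrended per
#' segment.  The adjusted segment count `L` used for the analytic
#' confidence level is, by default, the variance-equivalent number of
#' independent segments of the overlapped average (`"effective"`);
#' `"disjoint"` (`floor(N / W)`) and `"raw"` (the overlapped segment count)
#' are available alternatives.
#'
#' @param x,y numeric vectors of equal length (>= 2 windows).
#' @param rate sampling rate in Hz.
#' @param window_s segment length in seconds.
#' @param overlap fractional overlap in `[0, 0.95]`.
#' @param segment_rule how to count segments for the confidence level.
#' @param alpha significance level of the confidence level.
#' @param labels optional `c(x_label, y_label)`.
#' @return object of class `coherence_profile`: `freqs` (Hz), `coherence`
#'   in `[0, 1]`, `L`, `n_segments`, `confidence_level`, `window_s`,
#'   `overlap`, `labels`.
#' @export
compute_coherence <- function(x, y, rate = 1000, window_s = 0.128,
                              overlap = 0.75,
                              segment_rule = c("effective", "disjoint",
                                               "raw"),
                              alpha = 0.05, labels = c("x", "y")) {
  segment_rule <- match.arg(segment_rule)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (overlap < 0 || overlap > 0.95) {
    stop("parameter error: overlap must lie in [0, 0.95]")
  }
  W <- round(window_s * rate)
  if (W < 4) stop("parameter error: window too short")
  if (length(x) < 2 * W) {
    stop("segmentation error: need at least two windows of data")
  }
  hop <- max(1L, round(W * (1 - overlap)))
  win <- 0.5 * (1 - cos(2 * pi * (0:(W - 1)) / (W - 1)))  # Hann
  starts <- seq(1L, length(x) - W + 1L, by = hop)
  Sxx <- Syy <- numeric(W)
  Sxy <- complex(W)
  for (s in starts) {
    xs <- x[s:(s + W - 1L)]
    ys <- y[s:(s + W - 1L)]
    X <- stats::fft(win * (xs - mean(xs)))
    Y <- stats::fft(win * (ys - mean(ys)))
    Sxx <- Sxx + Mod(X)^2
    Syy <- Syy + Mod(Y)^2
    Sxy <- Sxy + X * Conj(Y)
  }
  k <- seq_len(W %/% 2 + 1L)
  denom <- Sxx[k] * Syy[k]
  coh <- ifelse(denom > 0, Mod(Sxy[k])^2 / denom, 0)
  coh <- pmin(pmax(coh, 0), 1)
  K <- length(starts)
  L <- switch(segment_rule,
              effective = effective_segments(K, win, hop),
              disjoint = floor(length(x) / W),
              raw = K)
  L <- max(L, 2)
  structure(
    list(freqs = (k - 1) * rate / W, coherence = coh, L = L,
         n_segments = K, confidence_level = confidence_level(L, alpha),
         window_s = window_s, overlap = overlap, rate = rate,
         labels = labels),
    class = "coherence_profile"
  )
}

#' @export
print.coherence_profile <- function(x, ...) {
  cat(sprintf(
    "<coherence_profile> %s ~ %s: %d bins to %g Hz, L = %.1f, conf = %.4f\n",
    x$labels[1], x$labels[2], length(x$freqs), max(x$freqs), x$L,
    x$confidence_level))
  invisible(x)
}

# Fisher variance-stabilizing transform of coherence -> approximate
# standard-normal score given L averaged segments
fisher_z_coherence <- function(coh, L) {
  atanh(sqrt(pmin(pmax(coh, 0), 1 - 1e-12))) * sqrt(2 * L)
}

#' Beta-band Fisher/Stouffer summary of a coherence profile
#'
#' Transforms each in-band coherence bin with the Fisher transform
#' `atanh(sqrt(coherence))`, scales by `sqrt(2 L)` to an approximate
#' standard-normal score, and combines the `K` in-band bins with Stouffer's
#' method (`sum(z) / sqrt(K)`).  Also reports the raw peak coherence and
#' its frequency (ties break to the lowest frequency).
#'
#' @param profile a [compute_coherence()] profile covering the band with at
#'   least 2 bins.
#' @param band frequency band in Hz (default beta, 12-30 Hz).
#' @return object of class `beta_summary`: `band`, `freqs`,
#'   `fisher_values`, `stouffer_z`, `peak_coherence`, `peak_freq`, `L`.
#' @export
beta_band_summary <- function(profile, band = c(12, 30)) {
  stopifnot(inherits(profile, "coherence_profile"))
  if (band[1] >= band[2]) stop("parameter error: empty band")
  sel <- profile$freqs >= band[1] & profile$freqs <= band[2]
  if (sum(sel) < 2) {
    stop("parameter error: band covered by fewer than 2 frequency bins")
  }
  coh <- profile$coherence[sel]
  freqs <- profile$freqs[sel]
  z <- fisher_z_coherence(coh, profile$L)
  peak_i <- which.max(coh)  # first maximum = lowest-frequency tie-break
  structure(
    list(band = band, freqs = freqs, fisher_values = z,
         stouffer_z = sum(z) / sqrt(length(z)),
         peak_coherence = coh[peak_i], peak_freq = freqs[peak_i],
         L = profile$L, labels = profile$labels),
    class = "beta_summary"
  )
}

# pool several beta summaries (e.g. the two muscles of a task) into one
# hemisphere-level Stouffer combination
combine_beta_summaries <- function(summaries) {
  z <- unlist(lapply(summaries, `[[`, "fisher_values"))
  freqs <- unlist(lapply(summaries, `[[`, "freqs"))
  coh <- tanh(unlist(lapply(summaries, function(s) {
    s$fisher_values / sqrt(2 * s$L)
  })))^2
  peak_i <- which.max(coh)
  structure(
    list(band = summaries[[1]]$band, freqs = freqs, fisher_values = z,
         stouffer_z = sum(z) / sqrt(length(z)),
         peak_coherence = coh[peak_i], peak_freq = freqs[peak_i],
         L = summaries[[1]]$L,
         labels = do.call(rbind, lapply(summaries, `[[`, "labels"))),
    class = "beta_summary"
  )
}

#' Laterality index of corticomuscular coherence
#'
#' `(ipsilesional - contralesional) / (ipsilesional + contralesional)` on
#' band-summarized coherence; positive values indicate ipsilesional
#' dominance.  Antisymmetric under swapping hemispheres and bounded in
#' `[-1, 1]` for nonnegative summaries.
#'
#' @param ipsi,contra [beta_band_summary()] objects (their `stouffer_z` is
#'   used) or nonnegative numbers; the sum must be positive.
#' @param task optional task annotation.
#' @return object of class `laterality_result`: `value`, `ipsilesional`,
#'   `contralesional`, `task`.
#' @export
laterality <- function(ipsi, contra, task = NULL) {
  val <- function(s) if (inherits(s, "beta_summary")) s$stouffer_z else s
  ci <- val(ipsi)
  cc <- val(contra)
  if (ci < 0 || cc < 0) {
    stop("laterality expects nonnegative band summaries")
  }
  if (ci + cc <= 0) {
    stop("undefined-laterality error: both summaries are zero")
  }
  structure(list(value = (ci - cc) / (ci + cc), ipsilesional = ci,
                 contralesional = cc, task = task),
            class = "laterality_result")
}

#' @export
print.laterality_result <- function(x, ...) {
  cat(sprintf("<laterality> %.3f (ipsi %.2f, contra %.2f)%s\n", x$value,
              x$ipsilesional, x$contralesional,
              if (is.null(x$task)) "" else paste0(" task: ", x$task)))
  invisible(x)
}

# neighbor priority when the primary motor electrode was removed
fallback_priority <- list(
  C3 = c("C3", "CP1", "FC1", "CP5", "FC5"),
  C4 = c("C4", "CP2", "FC2", "CP6", "FC6")
)

#' Sensorimotor electrode with fallback to same-hemisphere neighbors
#'
#' Returns the requested motor electrode (C3 or C4) if it survived channel
#' rejection; otherwise the first available neighbor over the same
#' sensorimotor hemisphere in a fixed priority order
#' (C3: CP1, FC1, CP5, FC5; C4: CP2, FC2, CP6, FC6).
#'
#' @param requested `"C3"` or `"C4"`.
#' @param removed_labels labels removed during preprocessing.
#' @param available labels present in the cleaned recording.
#' @return the electrode label to use.
#' @export
electrode_fallback <- function(requested, removed_labels, available) {
  requested <- match.arg(requested, c("C3", "C4"))
  usable <- setdiff(intersect(fallback_priority[[requested]], available),
                    removed_labels)
  if (length(usable) == 0) {
    stop("montage error: no same-hemisphere electrode available for ",
         requested)
  }
  # keep priority order
  fallback_priority[[requested]][fallback_priority[[requested]] %in%
                                   usable][1]
}

#' Corticomuscular coherence pipeline for one task
#'
#' End-to-end CMC analysis: resamples EEG and EMG to a common 1 kHz grid,
#' preprocesses the EEG (bandpass, bad-channel removal, common average,
#' z-score), extracts z-scored Hilbert envelopes of the task's two muscles,
#' concatenates the hold epochs, computes Welch coherence between each
#' hemisphere's motor electrode (C3/C4 with same-hemisphere fallback) and
#' each muscle, pools both muscles' in-band bins into one Stouffer
#' combination per hemisphere, and forms the laterality index.
#'
#' @param eeg,emg [recording()]s (any rates; resampled internally).
#' @param map a [channel_map()] (determines ipsi/contralesional sides).
#' @param schedule a [trial_schedule()].
#' @param task `"extension"` or `"flexion"`; defaults to the schedule's
#'   task.
#' @param band beta band in Hz.
#' @param window_s,overlap,segment_rule,alpha passed to
#'   [compute_coherence()].
#' @param target_rate common analysis rate in Hz.
#' @return object of class `cmc_result`: `ipsilesional` / `contralesional`
#'   (pooled [beta_band_summary()]s), `laterality`, `peak`
#'   (per-hemisphere peak coherence and frequency), `electrodes`,
#'   `removed_labels`, `profiles` (per hemisphere x muscle).
#' @export
cmc_pipeline <- function(eeg, emg, map, schedule, task = NULL,
                         band = c(12, 30), window_s = 0.128, overlap = 0.75,
                         segment_rule = "effective", alpha = 0.05,
                         target_rate = 1000) {
  if (is.null(task)) task <- schedule_task(schedule)
  task <- match.arg(task, c("extension", "flexion"))
  resampled <- resample_to_common(list(eeg, emg), target_rate)
  eeg_r <- resampled[[1]]
  emg_r <- resampled[[2]]
  prep <- preprocess_eeg(eeg_r)
  clean <- prep$recording
  group <- if (task == "extension") "extensor" else "flexor"
  muscles <- muscle_labels(map, group)
  env <- emg_for_cmc(recording(emg_r$samples[muscles, , drop = FALSE],
                               rate = emg_r$rate, labels = muscles,
                               modality = "EMG",
                               start_time = emg_r$start_time))
  times <- (seq_len(ncol(clean$samples)) - 1) / clean$rate +
    clean$start_time
  hold <- hold_indicator(schedule, times)
  if (!any(hold)) stop("schedule error: no hold samples in recording")
  left_e <- electrode_fallback("C3", prep$removed_labels, clean$labels)
  right_e <- electrode_fallback("C4", prep$removed_labels, clean$labels)
  hemis <- if (map$lesion_side == "left") {
    c(ipsilesional = left_e, contralesional = right_e)
  } else {
    c(ipsilesional = right_e, contralesional = left_e)
  }
  profiles <- list()
  summaries <- list()
  for (h in names(hemis)) {
    per_muscle <- list()
    for (m in muscles) {
      prof <- compute_coherence(get_channel(clean, hemis[[h]])[hold],
                                env$samples[m, hold], rate = target_rate,
                                window_s = window_s, overlap = overlap,
                                segment_rule = segment_rule, alpha = alpha,
                                labels = c(hemis[[h]], m))
      profiles[[paste(h, m, sep = ".")]] <- prof
      per_muscle[[m]] <- beta_band_summary(prof, band)
    }
    summaries[[h]] <- combine_beta_summaries(per_muscle)
  }
  lat <- laterality(summaries$ipsilesional, summaries$contralesional,
                    task = task)
  structure(
    list(task = task, ipsilesional = summaries$ipsilesional,
         contralesional = summaries$contralesional, laterality = lat,
         peak = list(
           ipsilesional = list(
             coherence = summaries$ipsilesional$peak_coherence,
             freq = summaries$ipsilesional$peak_freq),
           contralesional = list(
             coherence = summaries$contralesional$peak_coherence,
             freq = summaries$contralesional$peak_freq)),
         electrodes = hemis, removed_labels = prep$removed_labels,
         profiles = profiles),
    class = "cmc_result"
  )
}

#' @export
print.cmc_result <- function(x, ...) {
  cat(sprintf("<cmc_result> task: %s\n", x$task))
  cat(sprintf("  ipsilesional  (%s): stouffer z = %.2f, peak %.3f @ %g Hz\n",
              x$electrodes[["ipsilesional"]], x$ipsilesional$stouffer_z,
              x$peak$ipsilesional$coherence, x$peak$ipsilesional$freq))
  cat(sprintf("  contralesional(%s): stouffer z = %.2f, peak %.3f @ %g Hz\n",
              x$electrodes[["contralesional"]], x$contralesional$stouffer_z,
              x$peak$contralesional$coherence, x$peak$contralesional$freq))
  cat(sprintf("  laterality = %.3f\n", x$laterality$value))
  invisible(x)
}
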