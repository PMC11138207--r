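# Shared fixtures, built in code at test time.

# single- or multi-channel sine recording
sine_recording <- function(freq, rate = 1000, seconds = 2, amplitude = 1,
                           labels = "ch1", modality = "EMG") {
  t <- (seq_len(round(seconds * rate)) - 1) / rate
  samples <- do.call(rbind, lapply(seq_along(labels), function(i) {
    amplitude * sin(2 * pi * freq * t)
  }))
  recording(samples, rate = rate, labels = labels, modality = modality)
}

# small white-noise recording
noise_recording <- function(n_channels = 4, rate = 1000, seconds = 2,
                            sd = 1, labels = NULL, modality = "EEG",
                            seed = 42) {
  withr::with_seed(seed, {
    if (is.null(labels)) labels <- paste0("ch", seq_len(n_channels))
    recording(matrix(rnorm(n_channels * round(seconds * rate), sd = sd),
                     nrow = n_channels),
              rate = rate, labels = labels, modality = modality)
  })
}

# envelope_series built directly (bypasses filtering) for selector tests
fake_envelopes <- function(values, rate, labels) {
  rownames(values) <- labels
  structure(list(values = values, rate = rate, labels = labels,
                 reference = stats::setNames(rep(1, length(labels)),
                                             labels)),
            class = "envelope_series")
}

default_map <- function(lesion_side = "left") {
  channel_map(
    muscle_channels = c(extensor_carpi_radialis_longus = "ECRL",
                        extensor_carpi_ulnaris = "ECU",
                        flexor_carpi_radialis = "FCR",
                        flexor_carpi_ulnaris = "FCU"),
    eeg_channels = c("FC1", "FC5", "C3", "CP1", "CP5",
                     "FC2", "FC6", "C4", "CP2", "CP6"),
    lesion_side = lesion_side
  )
}

rms <- function(x) sqrt(mean(x^2))
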