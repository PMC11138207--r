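test_that("bad-channel detection flags spikes and flatlines, not noise", {
  rec <- noise_recording(11, rate = 500, seconds = 6, seed = 15,
                         labels = paste0("ch", 1:11))
  corrupted <- rec
  withr::with_seed(1, {
    x <- rnorm(ncol(rec$samples), 0, 0.1)
    at <- sample(ncol(rec$samples), 20)
    x[at] <- 30 * sample(c(-1, 1), 20, replace = TRUE)
    corrupted$samples[4, ] <- x
  })
  expect_identical(detect_bad_channels(corrupted), "ch4")

  flat <- rec
  flat$samples[7, ] <- 2.5
  expect_identical(detect_bad_channels(flat), "ch7")

  expect_error(detect_bad_channels(noise_recording(3)), "4 channels")
})

test_that("clean Gaussian montages are rarely flagged", {
  flags <- vapply(1:100, function(s) {
    rec <- noise_recording(10, rate = 250, seconds = 8, seed = 1000 + s)
    length(detect_bad_channels(rec)) > 0
  }, logical(1))
  expect_gte(mean(!flags), 0.95)
})

test_that("EEG preprocessing removes bad channels then re-references and z-scores", {
  rec <- noise_recording(10, rate = 500, seconds = 6, seed = 12,
                         labels = c("FC1", "FC5", "C3", "CP1", "CP5",
                                    "FC2", "FC6", "C4", "CP2", "CP6"))
  rec$samples["CP5", ] <- 0  # flatline
  out <- preprocess_eeg(rec)
  expect_identical(out$removed_labels, "CP5")
  expect_false("CP5" %in% out$recording$labels)
  clean <- out$recording$samples
  # z-score identity per channel
  expect_equal(unname(rowMeans(clean)), rep(0, nrow(clean)),
               tolerance = 1e-9)
  expect_equal(unname(apply(clean, 1, sd)), rep(1, nrow(clean)),
               tolerance = 1e-9)
  expect_error(preprocess_eeg(noise_recording(4, rate = 100)), "Nyquist")
})

test_that("preprocessing fails when most channels are bad", {
  rec <- noise_recording(5, rate = 500, seconds = 4, seed = 2)
  rec$samples[1, ] <- 0
  rec$samples[2, ] <- 1
  rec$samples[3, ] <- -3
  expect_error(preprocess_eeg(rec), "quality error")
})

test_that("common-average identity holds before z-scoring", {
  rec <- noise_recording(6, rate = 500, seconds = 4, seed = 19)
  filt <- rec
  for (ch in 1:6) {
    filt$samples[ch, ] <- bandpass_zerophase(rec$samples[ch, ], 500, 5, 100)
  }
  car <- sweep(filt$samples, 2, colMeans(filt$samples))
  expect_equal(max(abs(colMeans(car))), 0, tolerance = 1e-10)
})

test_that("Hilbert envelope extraction recovers an amplitude modulation", {
  rate <- 1000
  t <- (seq_len(20 * rate) - 1) / rate
  modulation <- 1 + 0.5 * sin(2 * pi * 2 * t)
  withr::with_seed(3, {
    carrier <- bandpass_zerophase(rnorm(length(t)), rate, 20, 450)
  })
  rec <- recording(matrix(carrier / sd(carrier) * modulation, nrow = 1),
                   rate, labels = "ECRL", modality = "EMG")
  env <- emg_for_cmc(rec)
  # z-score identity
  expect_equal(mean(env$samples[1, ]), 0, tolerance = 1e-9)
  expect_equal(sd(env$samples[1, ]), 1, tolerance = 1e-9)
  # smoothed envelope tracks the programmed modulation
  sm <- stats::filter(env$samples[1, ], rep(1 / 100, 100))
  ok <- !is.na(sm)
  expect_gt(cor(sm[ok], modulation[ok]), 0.9)

  zero <- recording(matrix(0, 1, 4000), rate, labels = "z",
                    modality = "EMG")
  expect_error(emg_for_cmc(zero), "z-score error")
})

test_that("self-coherence is one and coherence is bounded and scale invariant", {
  withr::with_seed(21, x <- rnorm(4000))
  self <- compute_coherence(x, x, rate = 1000)
  expect_equal(unname(self$coherence), rep(1, length(self$coherence)),
               tolerance = 1e-9)
  withr::with_seed(22, y <- rnorm(4000))
  a <- compute_coherence(x, y, rate = 1000)
  expect_true(all(a$coherence >= 0 & a$coherence <= 1))
  b <- compute_coherence(5 * x + 2, -0.3 * y, rate = 1000)
  expect_equal(a$coherence, b$coherence, tolerance = 1e-9)
  expect_error(compute_coherence(x[1:100], y[1:100], 1000),
               "segmentation error")
})

test_that("independent signals exceed the confidence level at the nominal rate", {
  fracs <- vapply(1:5, function(s) {
    withr::with_seed(300 + s, {
      x <- rnorm(60000)
      y <- rnorm(60000)
    })
    prof <- compute_coherence(x, y, rate = 1000)
    mean(prof$coherence > prof$confidence_level)
  }, numeric(1))
  expect_gte(mean(fracs), 0.01)
  expect_lte(mean(fracs), 0.10)
})

test_that("a shared narrowband source peaks at its frequency", {
  rate <- 1000
  withr::with_seed(41, {
    n <- 48000
    src <- bandpass_zerophase(rnorm(n), rate, 19, 21)
    src <- src / sd(src)
    x <- src + rnorm(n)
    y <- 0.8 * src + rnorm(n)
  })
  prof <- compute_coherence(x, y, rate = rate)
  bb <- beta_band_summary(prof)
  expect_lt(abs(bb$peak_freq - 20), 4)
  expect_gt(bb$peak_coherence, prof$confidence_level)
})

test_that("confidence level follows the analytic formula on a grid", {
  L <- 2:500
  cl <- confidence_level(L)
  oracle <- 1 - exp(log(0.05) / (L - 1))  # independent evaluation
  expect_equal(cl, oracle, tolerance = 1e-12)
  expect_equal(confidence_level(2), 0.95)
  expect_equal(confidence_level(21), 0.1391083, tolerance = 1e-6)
  expect_true(all(diff(cl) < 0))
  expect_lt(confidence_level(1e6), 1e-5)
  expect_equal(confidence_level(10, alpha = 1), 0)
  expect_error(confidence_level(1), "parameter error")
})

test_that("beta summary matches the closed-form Stouffer combination", {
  mk_profile <- function(coh_fun) {
    freqs <- (0:64) * 1000 / 128
    structure(list(freqs = freqs, coherence = coh_fun(freqs), L = 50,
                   n_segments = 50, confidence_level = confidence_level(50),
                   window_s = 0.128, overlap = 0.75, rate = 1000,
                   labels = c("x", "y")),
              class = "coherence_profile")
  }
  # zero coherence -> zero z
  expect_equal(beta_band_summary(mk_profile(function(f) 0 * f))$stouffer_z,
               0)
  # uniform coherence c: stouffer_z = atanh(sqrt(c)) * sqrt(2L) * sqrt(K)
  c0 <- 0.3
  bb <- beta_band_summary(mk_profile(function(f) rep(c0, length(f))))
  K <- length(bb$freqs)
  expect_equal(bb$stouffer_z, atanh(sqrt(c0)) * sqrt(2 * 50) * sqrt(K),
               tolerance = 1e-9)
  # single spike bin defines the peak
  spike <- mk_profile(function(f) ifelse(abs(f - 23.4375) < 0.1, 0.9, 0.05))
  bs <- beta_band_summary(spike)
  expect_equal(bs$peak_freq, 23.4375)
  expect_equal(bs$peak_coherence, 0.9)
  # tie: lowest frequency wins
  tie <- beta_band_summary(mk_profile(function(f) rep(0.4, length(f))))
  expect_equal(tie$peak_freq, min(tie$freqs))
  expect_error(beta_band_summary(mk_profile(function(f) 0 * f),
                                 band = c(30, 12)), "empty band")
})

test_that("laterality is antisymmetric, bounded and sign-correct", {
  expect_equal(laterality(3, 0)$value, 1)
  expect_equal(laterality(2, 2)$value, 0)
  expect_error(laterality(0, 0), "undefined-laterality")
  withr::with_seed(77, {
    for (i in 1:200) {
      a <- runif(1, 0, 10)
      b <- runif(1, 0, 10)
      if (a + b == 0) next
      v <- laterality(a, b)$value
      expect_equal(laterality(b, a)$value, -v, tolerance = 1e-12)
      expect_true(v >= -1 && v <= 1)
      expect_equal(sign(v), sign(a - b))
    }
  })
})

test_that("electrode fallback walks the same-hemisphere priority list", {
  avail <- c("FC1", "FC5", "C3", "CP1", "CP5", "FC2", "FC6", "C4", "CP2",
             "CP6")
  expect_identical(electrode_fallback("C3", character(0), avail), "C3")
  expect_identical(electrode_fallback("C3", "C3", avail), "CP1")
  expect_identical(electrode_fallback("C3", c("C3", "CP1"), avail), "FC1")
  expect_identical(electrode_fallback("C4", c("C4", "CP2", "FC2"), avail),
                   "CP6")
  expect_error(electrode_fallback("C3",
                                  c("C3", "CP1", "FC1", "CP5", "FC5"),
                                  avail),
               "montage error")
})

test_that("cmc pipeline recovers coupling laterality and survives bad channels", {
  cfg <- synth_signal_config(seed = 55, n_trials = 4,
                             ipsilesional_gain = 2, contralesional_gain = 0,
                             n_bad_channels = 1)
  co <- generate_coupled_eeg_emg(cfg)
  map <- synth_channel_map(cfg)
  res <- cmc_pipeline(co$eeg, co$emg, map, co$schedule)
  expect_gt(res$laterality$value, 0)
  expect_true(all(co$bad_labels %in% res$removed_labels))
  # hemisphere electrodes lie over the correct hemispheres
  expect_identical(unname(hemisphere_of(map, res$electrodes["ipsilesional"])),
                   "ipsilesional")
  expect_identical(
    unname(hemisphere_of(map, res$electrodes["contralesional"])),
    "contralesional")
})

test_that("band coherence grows with the coupling gain", {
  gains <- c(0, 0.5, 1, 2)
  mean_z <- vapply(gains, function(g) {
    zs <- vapply(1:8, function(s) {
      cfg <- synth_signal_config(seed = 700 + s, n_trials = 4,
                                 ipsilesional_gain = g,
                                 contralesional_gain = g)
      co <- generate_coupled_eeg_emg(cfg)
      res <- cmc_pipeline(co$eeg, co$emg, synth_channel_map(cfg),
                          co$schedule)
      (res$ipsilesional$stouffer_z + res$contralesional$stouffer_z) / 2
    }, numeric(1))
    mean(zs)
  }, numeric(1))
  expect_true(all(diff(mean_z) > 0))
})

test_that("equal coupling gains give near-zero mean laterality", {
  lats <- vapply(1:20, function(s) {
    cfg <- synth_signal_config(seed = 900 + s, n_trials = 6,
                               ipsilesional_gain = 1,
                               contralesional_gain = 1)
    co <- generate_coupled_eeg_emg(cfg)
    cmc_pipeline(co$eeg, co$emg, synth_channel_map(cfg),
                 co$schedule)$laterality$value
  }, numeric(1))
  expect_lt(abs(mean(lats)), 0.15)
})
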