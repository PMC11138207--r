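#' Read a biosignal recording from disk
#'
#' Supports two on-disk representations: delimited text (CSV, one column per
#' channel with a header row of labels, plus a YAML sidecar carrying the
#' sampling rate, start time and per-channel modality) and 16-bit EDF.
#' CSV round-trips samples losslessly; EDF quantizes samples to the 16-bit
#' grid of each channel's physical range.
#'
#' @param path file to read.
#' @param format `"csv"` or `"edf"`; guessed from the file extension when
#'   missing.
#' @param channel_map optional [channel_map()]; when supplied, every mapped
#'   label must exist in the file (otherwise a mapping error is raised) and
#'   channel modalities are resolved from the map.
#' @return a [recording()].
#' @export
read_recording <- function(path, format = NULL, channel_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- resolve_format(path, format)
  rec <- if (format == "csv") read_recording_csv(path) else read_edf(path)
  if (!is.null(channel_map)) {
    rec$modality <- apply_map_modality(rec, channel_map)
  }
  rec
}

#' Write a biosignal recording to disk
#'
#' @param rec a [recording()].
#' @param path output file.
#' @param format `"csv"` or `"edf"`; guessed from the file extension when
#'   missing.  CSV writes a `<path>.yaml` sidecar with rate, start time and
#'   modalities; EDF stores them in the EDF header.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = NULL) {
  stopifnot(inherits(rec, "recording"))
  format <- resolve_format(path, format)
  if (format == "csv") write_recording_csv(rec, path) else write_edf(rec, path)
  invisible(path)
}

resolve_format <- function(path, format) {
  if (is.null(format)) {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  match.arg(format, c("csv", "edf"))
}

# A recording may hold only one modality (an EMG-only or EEG-only file),
# so each mapped group must be fully present or fully absent.
apply_map_modality <- function(rec, map) {
  stopifnot(inherits(map, "channel_map"))
  check_group <- function(labels, what) {
    missing <- setdiff(labels, rec$labels)
    if (length(missing) > 0 && length(missing) < length(labels)) {
      stop("mapping error: ", what, " channel(s) not present in recording: ",
           paste(missing, collapse = ", "))
    }
    length(missing) == 0
  }
  has_emg <- check_group(unname(map$muscle_channels), "muscle")
  has_eeg <- check_group(map$eeg_channels, "EEG")
  if (!has_emg && !has_eeg) {
    stop("mapping error: no mapped channel present in recording")
  }
  modality <- rec$modality
  if (has_emg) modality[rec$labels %in% map$muscle_channels] <- "EMG"
  if (has_eeg) modality[rec$labels %in% map$eeg_channels] <- "EEG"
  modality
}

sidecar_path <- function(path) paste0(path, ".yaml")

read_recording_csv <- function(path) {
  dat <- utils::read.csv(path, check.names = FALSE)
  if (ncol(dat) < 1L || nrow(dat) < 1L) stop("ingestion error: empty csv")
  mat <- t(as.matrix(dat))
  if (!is.numeric(mat) || anyNA(mat)) {
    stop("ingestion error: non-numeric or NaN samples in ", path)
  }
  side <- sidecar_path(path)
  if (!file.exists(side)) {
    stop("sidecar config not found for csv recording: ", side)
  }
  meta <- yaml::read_yaml(side)
  if (is.null(meta$rate)) stop("sidecar config missing 'rate'")
  modality <- meta$modality
  if (is.null(modality)) modality <- "EEG"
  if (!is.null(names(modality))) modality <- unlist(modality)[colnames(dat)]
  recording(mat, rate = meta$rate, labels = colnames(dat),
            modality = unname(modality),
            start_time = if (is.null(meta$start_time)) 0 else meta$start_time)
}

write_recording_csv <- function(rec, path) {
  dat <- as.data.frame(t(rec$samples))
  names(dat) <- rec$labels
  utils::write.csv(dat, path, row.names = FALSE)
  meta <- list(rate = rec$rate, start_time = rec$start_time,
               modality = as.list(stats::setNames(rec$modality, rec$labels)))
  yaml::write_yaml(meta, sidecar_path(path))
}

# ---- minimal EDF (16-bit) ----------------------------------------------
# Single-data-record layout: the whole recording is one EDF data record, so
# no padding is needed and rate = samples_per_record / record_duration is
# recovered exactly for any rational rate.  Per-channel physical range is
# symmetric about zero at the observed absolute maximum; quantization error
# is at most half of one digital step, physmax / 32767 / 2.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop("EDF header field too wide: ", x)
  formatC(x, width = width, flag = "-")
}

write_edf <- function(rec, path) {
  nchan <- n_channels(rec)
  nsamp <- ncol(rec$samples)
  dur <- nsamp / rec$rate
  phys_max <- apply(abs(rec$samples), 1, max)
  phys_max[phys_max == 0] <- 1
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad("X X X X", 80),
    edf_pad(sprintf("Startdate X start_time %.9g", rec$start_time), 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 + 256 * nchan, 8),
    edf_pad("", 44),
    edf_pad(1, 8),
    edf_pad(formatC(dur, format = "fg", digits = 8, width = 1), 8),
    edf_pad(nchan, 4)
  )
  field <- function(values, width) {
    paste(vapply(values, edf_pad, character(1), width = width), collapse = "")
  }
  hdr <- paste0(
    hdr,
    field(rec$labels, 16),
    field(rec$modality, 80),
    field(rep("uV", nchan), 8),
    field(formatC(-phys_max, format = "g", digits = 6), 8),
    field(formatC(phys_max, format = "g", digits = 6), 8),
    field(rep(-32767L, nchan), 8),
    field(rep(32767L, nchan), 8),
    field(rep("", nchan), 80),
    field(rep(nsamp, nchan), 8),
    field(rep("", nchan), 32)
  )
  writeChar(hdr, con, eos = NULL)
  for (ch in seq_len(nchan)) {
    dig <- as.integer(round(rec$samples[ch, ] / phys_max[ch] * 32767))
    writeBin(dig, con, size = 2L, endian = "little")
  }
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  ver <- rd(8); rd(80)
  rec_id <- rd(80)
  rd(8); rd(8); rd(8); rd(44)
  n_records <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  nchan <- as.integer(rd(4))
  rdn <- function(width) {
    vapply(seq_len(nchan), function(i) rd(width), character(1))
  }
  labels <- rdn(16)
  transducer <- rdn(80)
  rdn(8)                                    # physical dimension
  phys_min <- as.numeric(rdn(8))
  phys_max <- as.numeric(rdn(8))
  dig_min <- as.numeric(rdn(8))
  dig_max <- as.numeric(rdn(8))
  rdn(80)                                   # prefilter
  spr <- as.integer(rdn(8))
  rdn(32)
  samples <- matrix(0, nrow = nchan, ncol = spr[1] * n_records)
  for (r in seq_len(n_records)) {
    for (ch in seq_len(nchan)) {
      dig <- readBin(con, integer(), n = spr[ch], size = 2L,
                     endian = "little")
      phys <- phys_min[ch] +
        (dig - dig_min[ch]) / (dig_max[ch] - dig_min[ch]) *
          (phys_max[ch] - phys_min[ch])
      samples[ch, ((r - 1) * spr[ch] + 1):(r * spr[ch])] <- phys
    }
  }
  rate <- spr[1] / rec_dur
  start_time <- 0
  st <- regmatches(rec_id, regexpr("start_time [-0-9.eE+]+", rec_id))
  if (length(st)) start_time <- as.numeric(sub("start_time ", "", st))
  modality <- ifelse(toupper(transducer) %in% c("EMG", "EEG"),
                     toupper(transducer), "EEG")
  recording(samples, rate = rate, labels = labels, modality = modality,
            start_time = start_time)
}

# ---- schedules, channel maps, clinical tables ---------------------------

#' Read / write a trial schedule as CSV
#'
#' Columns `onset`, `hold_s`, `rest_s`, `task`, `target_level` (the last two
#' constant across rows).
#' @param path file path.
#' @return a [trial_schedule()].
#' @export
read_schedule <- function(path) {
  dat <- utils::read.csv(path)
  trial_schedule(dat$onset, dat$hold_s, dat$rest_s,
                 task = as.character(dat$task[1]),
                 target_level = dat$target_level[1])
}

#' @rdname read_schedule
#' @param schedule a [trial_schedule()].
#' @export
write_schedule <- function(schedule, path) {
  dat <- as.data.frame(schedule)
  dat$task <- schedule_task(schedule)
  dat$target_level <- schedule_target(schedule)
  utils::write.csv(dat, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a channel map as YAML
#' @param path file path.
#' @return a [channel_map()].
#' @export
read_channel_map <- function(path) {
  y <- yaml::read_yaml(path)
  channel_map(y$muscle_channels, unlist(y$eeg_channels), y$lesion_side)
}

#' @rdname read_channel_map
#' @param map a [channel_map()].
#' @export
write_channel_map <- function(map, path) {
  yaml::write_yaml(list(muscle_channels = as.list(map$muscle_channels),
                        eeg_channels = map$eeg_channels,
                        lesion_side = map$lesion_side), path)
  invisible(path)
}

#' Resample recordings to a common rate on a common time grid
#'
#' All recordings are aligned by their `start_time`, truncated to the
#' overlapping interval and linearly interpolated onto a uniform grid at
#' `target_rate` (default 1000 Hz, the offline analysis rate).  A recording
#' already at the target rate whose samples fall on the common grid is
#' passed through unchanged.
#'
#' @param recordings a single [recording()] or a list of them.
#' @param target_rate target sampling rate in Hz.
#' @return the same shape as the input (single recording or list), all at
#'   `target_rate`.
#' @export
resample_to_common <- function(recordings, target_rate = 1000) {
  if (!is.numeric(target_rate) || length(target_rate) != 1 ||
      target_rate <= 0) {
    stop("parameter error: target_rate must be a positive number")
  }
  single <- inherits(recordings, "recording")
  recs <- if (single) list(recordings) else recordings
  stopifnot(all(vapply(recs, inherits, logical(1), "recording")))
  t0 <- max(vapply(recs, function(r) r$start_time, numeric(1)))
  t1 <- min(vapply(recs, function(r) r$start_time + duration(r) - 1 / r$rate,
                   numeric(1)))
  if (t1 <= t0) stop("recordings do not overlap in time")
  grid <- seq(t0, t1 + 1e-12, by = 1 / target_rate)
  out <- lapply(recs, function(r) {
    if (r$rate == target_rate && isTRUE(all.equal(r$start_time, t0)) &&
        duration(r) - 1 / r$rate <= t1 - t0 + 1e-12) {
      return(r)
    }
    tt <- r$start_time + (seq_len(ncol(r$samples)) - 1) / r$rate
    res <- t(apply(r$samples, 1, function(ch) {
      stats::approx(tt, ch, xout = grid, rule = 2)$y
    }))
    recording(res, rate = target_rate, labels = r$labels,
              modality = r$modality, start_time = t0)
  })
  if (single) out[[1]] else out
}
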