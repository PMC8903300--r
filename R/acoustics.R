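# Spectrograms and the averaged Acoustic Complexity Index (ACI) for soil
# recordings, plus the validity filter and 6-h aggregation used before
# time-series modelling.

#' Construct a recording object
#'
#' @param samples numeric amplitudes in \[-1, 1\].
#' @param rate sampling rate (samples/second).
#' @param start_time POSIXct timestamp of the first sample.
#' @param sensor_id sensor label.
#' @return object of class `soil_recording`.
#' @export
soil_recording <- function(samples, rate,
                           start_time = as.POSIXct("2019-01-01", tz = "UTC"),
                           sensor_id = "S1") {
  stopifnot(is.numeric(samples), rate > 0)
  structure(list(samples = as.numeric(samples), rate = rate,
                 start_time = as.POSIXct(start_time, tz = "UTC"),
                 sensor_id = as.character(sensor_id)),
            class = "soil_recording")
}

#' @export
print.soil_recording <- function(x, ...) {
  cat(sprintf("<soil_recording> sensor %s @ %s: %.2f s at %d Hz\n",
              x$sensor_id, format(x$start_time), length(x$samples) / x$rate,
              as.integer(x$rate)))
  invisible(x)
}

#' Magnitude spectrogram with non-overlapping rectangular windows
#'
#' The signal is cut into consecutive non-overlapping windows (any trailing
#' partial window is discarded), each window is Fourier transformed, and the
#' one-sided magnitude spectrum is kept with the DC bin dropped, so a window
#' of 512 samples yields 256 frequency bands. A ~20.69-s clip at 50 kHz thus
#' produces a 256-band x 2020-block intensity matrix.
#'
#' @param rec a `soil_recording` (or numeric vector, with `rate` supplied).
#' @param window window length in samples; must be a power of two.
#' @param rate sampling rate, only needed when `rec` is a bare vector.
#' @return object of class `soil_spectrogram`: list with `I` (band x frame
#'   magnitude matrix), `band_hz`, `frame_times`, `window`, `rate`.
#' @export
compute_spectrogram <- function(rec, window = 512, rate = NULL) {
  if (inherits(rec, "soil_recording")) {
    x <- rec$samples
    rate <- rec$rate
  } else {
    x <- as.numeric(rec)
    if (is.null(rate)) stop("`rate` must be supplied for a bare sample vector")
  }
  if (window < 2 || bitwAnd(as.integer(window), as.integer(window) - 1L) != 0L)
    stop("`window` must be a power of two >= 2")
  n_frames <- floor(length(x) / window)
  if (n_frames < 1) stop("recording shorter than one analysis window")
  frames <- matrix(x[seq_len(n_frames * window)], nrow = window)
  spec <- Mod(mvfft(frames))           # window x frames
  nb <- window / 2
  I <- spec[2:(nb + 1), , drop = FALSE]  # drop DC, keep through Nyquist
  structure(list(
    I = I,
    band_hz = (1:nb) * rate / window,
    frame_times = (seq_len(n_frames) - 0.5) * window / rate,
    window = window,
    rate = rate
  ), class = "soil_spectrogram")
}

#' @export
print.soil_spectrogram <- function(x, ...) {
  cat(sprintf("<soil_spectrogram> %d bands x %d frames (window %d, %d Hz)\n",
              nrow(x$I), ncol(x$I), x$window, as.integer(x$rate)))
  invisible(x)
}

#' Averaged Acoustic Complexity Index of a spectrogram
#'
#' Within each frequency band and each temporal clump (nominally 1 s of
#' frames), the absolute differences between adjacent intensity values are
#' summed (`D = sum |I_k - I_(k+1)|`) and divided by the total intensity of
#' the clump (`sum I_k`). The index is the plain average of these band-clump
#' ratios, which confines it to \[0, 2) — in practice near 0.59 for stationary
#' noise and approaching 2 for strongly intermittent sound. A clump whose
#' total intensity is zero contributes a ratio of 0 (silence carries no
#' complexity). A trailing clump shorter than the nominal length is
#' discarded.
#'
#' @param spec a `soil_spectrogram`, or a bare nonnegative band x frame
#'   intensity matrix (then `frames_per_clump` must be supplied or defaults
#'   to all frames as one clump).
#' @param clump_seconds temporal clump length in seconds (default 1).
#' @param frames_per_clump directly specify frames per clump, overriding
#'   `clump_seconds`.
#' @return object of class `aci_result`: list with `per_clump` (band x clump
#'   ratio matrix), `value` (their mean), `valid` (set by [filter_aci()]).
#' @export
compute_aci <- function(spec, clump_seconds = 1, frames_per_clump = NULL) {
  if (inherits(spec, "soil_spectrogram")) {
    I <- spec$I
    if (is.null(frames_per_clump))
      frames_per_clump <- floor(clump_seconds * spec$rate / spec$window)
  } else {
    I <- as.matrix(spec)
    if (is.null(frames_per_clump)) frames_per_clump <- ncol(I)
  }
  if (any(I < 0)) stop("spectrogram intensities must be nonnegative")
  fpc <- max(2L, as.integer(frames_per_clump))
  n_clumps <- floor(ncol(I) / fpc)
  if (n_clumps < 1) stop("fewer than one clump of frames; shorten the clump")
  per_clump <- matrix(0, nrow = nrow(I), ncol = n_clumps)
  for (c in seq_len(n_clumps)) {
    idx <- ((c - 1L) * fpc + 1L):(c * fpc)
    D <- rowSums(abs(I[, idx[-1], drop = FALSE] -
                     I[, idx[-length(idx)], drop = FALSE]))
    S <- rowSums(I[, idx, drop = FALSE])
    per_clump[, c] <- ifelse(S > 0, D / S, 0)
  }
  structure(list(per_clump = per_clump, value = mean(per_clump),
                 valid = NA, frames_per_clump = fpc),
            class = "aci_result")
}

#' @export
print.aci_result <- function(x, ...) {
  cat(sprintf("<aci_result> value %.4f (%d bands x %d clumps)\n",
              x$value, nrow(x$per_clump), ncol(x$per_clump)))
  invisible(x)
}

#' Build an ACI series table
#'
#' @param sensor_id character vector of sensor labels.
#' @param time POSIXct timestamps.
#' @param value ACI values.
#' @param valid logical validity flags (default NA until filtered).
#' @return data.frame of class `aci_series`, ordered by sensor then time.
#' @export
aci_series <- function(sensor_id, time, value, valid = NA) {
  df <- data.frame(sensor_id = as.character(sensor_id),
                   time = as.POSIXct(time, tz = "UTC"),
                   value = as.numeric(value),
                   valid = rep_len(as.logical(valid), length(value)))
  df <- df[order(df$sensor_id, df$time), , drop = FALSE]
  if (anyDuplicated(df[c("sensor_id", "time")]))
    stop("duplicate (sensor, time) records in ACI series")
  rownames(df) <- NULL
  class(df) <- c("aci_series", "data.frame")
  df
}

#' Flag ACI values inside the reliable range
#'
#' Values below `low` sit in the constant amplified background noise and are
#' unreliable; values above `high` are rain/irrigation noise. Both bounds are
#' inclusive. Invalid records are kept but flagged, so downstream stages can
#' drop or count them.
#'
#' @param series an `aci_series`.
#' @param low,high inclusive validity bounds (defaults 0.55 and 0.90).
#' @return the series with its `valid` column set.
#' @export
filter_aci <- function(series, low = 0.55, high = 0.90) {
  if (low >= high) stop("`low` must be < `high`")
  series$valid <- series$value >= low & series$value <= high
  series
}

#' Aggregate an ACI series into fixed daily intervals
#'
#' Arithmetic mean of the valid values per sensor within each interval
#' (default 6 h: 00-06, 06-12, 12-18, 18-24 local time). Intervals with no
#' valid value yield no record.
#'
#' @param series an `aci_series` that has passed [filter_aci()].
#' @param hours interval width in hours; must divide 24.
#' @return an `aci_series` timestamped at interval starts, all valid.
#' @export
aggregate_aci <- function(series, hours = 6) {
  stopifnot(hours > 0, 24 %% hours == 0)
  if (all(is.na(series$valid)))
    stop("series has no validity flags; run filter_aci() first")
  keep <- !is.na(series$valid) & series$valid
  s <- series[keep, , drop = FALSE]
  if (nrow(s) == 0) return(aci_series(character(), as.POSIXct(character()),
                                      numeric(), logical()))
  secs <- hours * 3600
  bin <- as.POSIXct(floor(as.numeric(s$time) / secs) * secs,
                    origin = "1970-01-01", tz = "UTC")
  agg <- aggregate(s$value, by = list(sensor_id = s$sensor_id, time = bin),
                   FUN = mean)
  aci_series(agg$sensor_id, agg$time, agg$x, valid = TRUE)
}

#' Compute ACI for a batch of recordings
#'
#' Convenience wrapper: spectrogram + ACI per recording, assembled into an
#' [aci_series()] and validity-filtered.
#'
#' @param recordings list of `soil_recording` objects.
#' @param window spectrogram window (samples).
#' @param clump_seconds ACI clump length (seconds).
#' @param low,high validity bounds passed to [filter_aci()].
#' @return an `aci_series` with validity flags set.
#' @export
aci_batch <- function(recordings, window = 512, clump_seconds = 1,
                      low = 0.55, high = 0.90) {
  stopifnot(length(recordings) > 0)
  vals <- vapply(recordings, function(r) {
    compute_aci(compute_spectrogram(r, window = window),
                clump_seconds = clump_seconds)$value
  }, numeric(1))
  ser <- aci_series(
    sensor_id = vapply(recordings, `[[`, character(1), "sensor_id"),
    time = as.POSIXct(vapply(recordings, function(r)
      as.numeric(r$start_time), numeric(1)), origin = "1970-01-01", tz = "UTC"),
    value = vals)
  filter_aci(ser, low = low, high = high)
}

#' Write / read an ACI series as CSV
#'
#' Columns: `sensor_id`, `iso_time` (UTC, ISO 8601), `aci`, `valid`.
#'
#' @param series an `aci_series`.
#' @param path CSV file path.
#' @return `path` invisibly (write); an `aci_series` (read).
#' @export
write_aci_csv <- function(series, path) {
  out <- data.frame(sensor_id = series$sensor_id,
                    iso_time = format(series$time, "%Y-%m-%dT%H:%M:%SZ",
                                      tz = "UTC"),
                    aci = series$value, valid = series$valid)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_aci_csv
#' @export
read_aci_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  aci_series(df$sensor_id,
             as.POSIXct(df$iso_time, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
             df$aci, df$valid)
}
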