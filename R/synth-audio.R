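# Synthetic soil soundscape audio: Gaussian noise floor plus Poisson trains
# of band-limited acoustic events, with rain rendered as loud clipped
# raindrop impacts.

#' Apply recording-chain gain
#'
#' Multiplies every sample by `10^(gain_db/20)`; +40 dB is a factor of 100.
#'
#' @param signal numeric amplitude series.
#' @param gain_db gain in decibels.
#' @return amplified series.
#' @export
apply_gain <- function(signal, gain_db) {
  stopifnot(is.numeric(signal), is.finite(gain_db))
  signal * 10^(gain_db / 20)
}

#' Linear-phase FIR high-pass filter
#'
#' Linear-phase finite impulse response high-pass built by spectral
#' inversion of a windowed-sinc low-pass ([signal::fir1()]) whose DC gain is
#' normalized to exactly 1, so the high-pass nulls DC exactly even at very
#' small normalized cutoffs (a 50 Hz cutoff at a 50 kHz rate). Applied by
#' FFT convolution with the group delay compensated.
#'
#' @param signal numeric amplitude series.
#' @param rate sampling rate in Hz.
#' @param cutoff_hz cutoff frequency (default 50 Hz).
#' @param taps filter length (default 512).
#' @return filtered series, same length (zero-padded tail discarded).
#' @export
highpass <- function(signal, rate, cutoff_hz = 50, taps = 512) {
  if (taps < 3) stop("`taps` must be >= 3")
  if (cutoff_hz <= 0 || cutoff_hz >= rate / 2)
    stop("`cutoff_hz` must lie in (0, rate/2)")
  n <- taps - 1L
  if (n %% 2L == 1L) n <- n + 1L  # even order so a high-pass is realizable
  blp <- signal::fir1(n, cutoff_hz / (rate / 2), type = "low")
  blp <- blp / sum(blp)            # exact unit DC gain
  b <- -blp
  b[n / 2 + 1] <- b[n / 2 + 1] + 1  # delta minus low-pass
  out <- signal::fftfilt(b, c(signal, numeric(n)))
  # compensate the linear-phase group delay of n/2 samples
  out[(n / 2 + 1):(n / 2 + length(signal))]
}

# one damped-sinusoid pulse at frequency f, length decided by decay
event_pulse <- function(f, decay_s, rate, amp) {
  n <- max(8L, ceiling(6 * decay_s * rate))
  t <- (seq_len(n) - 1) / rate
  amp * exp(-t / decay_s) * sin(2 * pi * f * t + runif(1, 0, 2 * pi))
}

# expand the archetype families into `n_variants` concrete event variants;
# variant v uses family ((v-1) mod 3)+1 with a deterministic frequency slot
# inside the family band, so richness r always activates the same first r
# variants
archetype_variants <- function(config) {
  fams <- config$archetype_set
  lapply(seq_len(config$n_variants), function(v) {
    fam <- fams[[(v - 1L) %% length(fams) + 1L]]
    slot <- (v - 1L) %/% length(fams)
    frac <- ((slot * 0.37) %% 1)
    f <- exp(log(fam$band[1]) + frac * (log(fam$band[2]) - log(fam$band[1])))
    c(fam, list(freq = f))
  })
}

#' Generate one synthetic soil recording
#'
#' The clip is a Gaussian noise floor plus, for each of the first
#' `min(richness, n_variants)` event variants, a Poisson train of
#' band-limited pulses. The Poisson rate is multiplied by an activity factor
#' `exp(activity_coef * dT30)` where `dT30` is the positive 30-min
#' surface-temperature change taken from `microclimate` at time `t` (no
#' microclimate: factor 1). If `t` falls inside the configured rain schedule
#' (or `rain = TRUE`), a dense train of near-full-scale broadband drop
#' impacts is added; these clip at full scale and push the averaged ACI
#' above the 0.90 validity bound.
#'
#' @param t POSIXct timestamp of the clip.
#' @param soundscape a [soundscape_config()].
#' @param microclimate optional `microclimate_series` for the same sensor.
#' @param richness number of active event variants (0 = noise floor only);
#'   values beyond `n_variants` are capped with a warning. Ignored for the
#'   event budget when `richness_coupling` is off.
#' @param sensor_id sensor label.
#' @param rain force rain on/off regardless of the schedule.
#' @return a [soil_recording()].
#' @export
generate_recording <- function(t, soundscape, microclimate = NULL,
                               richness = 3, sensor_id = "S1", rain = NULL) {
  stopifnot(inherits(soundscape, "soundscape_config"), richness >= 0)
  t <- as.POSIXct(t, tz = "UTC")
  cfg <- soundscape
  n <- floor(cfg$clip_seconds * cfg$rate)
  if (richness > cfg$n_variants) {
    warning("richness ", richness, " exceeds the ", cfg$n_variants,
            "-variant capacity; capped")
    richness <- cfg$n_variants
  }
  in_rain <- isTRUE(rain)
  if (is.null(rain) && !is.null(cfg$rain_schedule)) {
    rs <- cfg$rain_schedule
    in_rain <- any(t >= as.POSIXct(rs$start, tz = "UTC") &
                   t < as.POSIXct(rs$end, tz = "UTC"))
  }
  activity <- 1
  if (!is.null(microclimate)) {
    mc <- microclimate[microclimate$sensor_id == sensor_id |
                         length(unique(microclimate$sensor_id)) == 1, ,
                       drop = FALSE]
    i <- which.min(abs(as.numeric(mc$time) - as.numeric(t)))
    if (length(i) == 1 &&
        abs(as.numeric(mc$time[i]) - as.numeric(t)) <= 30 * 60) {
      dT <- surface_heating(mc)[i]
      activity <- exp(cfg$activity_coef * dT)
    }
  }
  clip_seed <- derive_seed(cfg$seed,
                           (as.numeric(t) / 60) %% 1e6 + richness * 31L)
  x <- with_seed(clip_seed, {
    x <- rnorm(n, sd = cfg$noise_sigma)
    n_active <- if (cfg$richness_coupling) as.integer(richness) else 3L
    if (n_active > 0) {
      vars <- archetype_variants(cfg)[seq_len(n_active)]
      for (v in vars) {
        n_ev <- rpois(1, cfg$event_rate * cfg$clip_seconds * activity)
        for (e in seq_len(n_ev)) {
          start <- sample.int(n, 1)
          for (p in seq_len(v$n_pulses)) {
            pulse <- event_pulse(v$freq, v$decay_s, cfg$rate, v$amp)
            at <- start + round((p - 1) * v$pulse_gap_s * cfg$rate)
            idx <- at:min(n, at + length(pulse) - 1L)
            if (idx[1] > n) break
            x[idx] <- x[idx] + pulse[seq_along(idx)]
          }
        }
      }
    }
    if (in_rain) {
      n_drops <- rpois(1, cfg$rain_drop_rate * cfg$clip_seconds)
      drop_len <- max(4L, round(0.002 * cfg$rate))
      for (d in seq_len(n_drops)) {
        at <- sample.int(n, 1)
        idx <- at:min(n, at + drop_len - 1L)
        x[idx] <- x[idx] + rnorm(length(idx), sd = 2.5)
      }
    }
    x
  })
  x <- apply_gain(x, cfg$gain_db)
  x <- pmax(-1, pmin(1, x))  # hard clipping at full scale
  soil_recording(x, cfg$rate, start_time = t, sensor_id = sensor_id)
}
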