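# Synthetic microclimate covariates at 10-min resolution.

#' Generate a synthetic microclimate series
#'
#' Surface temperature is a seasonal step (per meteorological season) plus a
#' diurnal sinusoid peaking mid-afternoon plus AR(1) noise. Soil temperature
#' at 10 cm is a lagged exponential low-pass of the surface series. Soil
#' moisture is a baseline plus exponentially decaying impulses at scheduled
#' rain/irrigation events, clipped to \[0, 1\]. Light follows the positive
#' part of the diurnal cycle.
#'
#' @param config a [microclimate_config()].
#' @param sensor_id label attached to the series.
#' @return data.frame of class `microclimate_series` with columns
#'   `sensor_id`, `time`, `surface_temp`, `soil_temp`, `soil_moisture`,
#'   `light`.
#' @export
generate_microclimate <- function(config, sensor_id = "S1") {
  stopifnot(inherits(config, "microclimate_config"))
  step_s <- config$step_minutes * 60
  n <- floor(config$days * 86400 / step_s)
  if (n < 2) stop("`days` too short for the configured step")
  time <- config$start + (seq_len(n) - 1) * step_s

  season <- season_of(time)
  season_step <- c(winter = -1, spring = 0, summer = 1, fall = 0)[season] *
    config$seasonal_amplitude
  hour <- as.numeric(time - as.POSIXct(format(time, "%Y-%m-%d", tz = "UTC"),
                                       tz = "UTC"), units = "hours")
  diurnal <- sin(2 * pi * (hour - 9) / 24)  # peaks at 15:00

  noise <- numeric(n)
  if (config$ar_noise_sigma > 0) {
    noise <- with_seed(derive_seed(config$seed, 1L), {
      e <- rnorm(n, sd = config$ar_noise_sigma)
      as.numeric(filter(e, config$ar_coef, method = "recursive"))
    })
  }
  surface <- config$mean_temp + season_step +
    config$diurnal_amplitude * diurnal + noise

  # soil temperature: exponential smoothing of the lagged surface series
  lagged <- c(rep(surface[1], config$soil_lag_steps),
              surface)[seq_len(n)]
  soil <- numeric(n)
  soil[1] <- lagged[1]
  a <- config$soil_damping
  for (t in 2:n) soil[t] <- soil[t - 1] + a * (lagged[t] - soil[t - 1])

  moisture <- rep(config$moisture_baseline, n)
  ev <- config$event_schedule
  if (!is.null(ev) && nrow(ev) > 0) {
    t_days <- (seq_len(n) - 1) * step_s / 86400
    for (i in seq_len(nrow(ev))) {
      dt <- t_days - ev$day[i]
      moisture <- moisture +
        ifelse(dt >= 0, ev$impulse[i] * exp(-dt / ev$tau_days[i]), 0)
    }
  }
  moisture <- pmax(0, pmin(1, moisture))

  light <- pmax(0, diurnal) * (1 + season_step / max(1, config$mean_temp))
  out <- data.frame(sensor_id = sensor_id, time = time,
                    surface_temp = surface, soil_temp = soil,
                    soil_moisture = moisture, light = light)
  class(out) <- c("microclimate_series", "data.frame")
  out
}

#' Positive 30-min surface-temperature change
#'
#' `dT30(t) = max(0, T_surf(t) - T_surf(t - 30 min))`, computed on the grid
#' of the series (rows without a measurement 30 min earlier get 0).
#'
#' @param mc a `microclimate_series` (single sensor).
#' @param minutes look-back window (default 30).
#' @return numeric vector aligned with `mc$time`.
#' @export
surface_heating <- function(mc, minutes = 30) {
  stopifnot(length(unique(mc$sensor_id)) <= 1)
  step <- as.numeric(median(diff(as.numeric(mc$time))))
  k <- round(minutes * 60 / step)
  if (k < 1) stop("series step longer than the look-back window")
  n <- nrow(mc)
  lagged <- c(rep(NA_real_, k), mc$surface_temp)[seq_len(n)]
  d <- mc$surface_temp - lagged
  ifelse(is.na(d) | d < 0, 0, d)
}
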