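# Configuration objects for the synthetic soundscape / microclimate /
# community generators. Each constructor validates its invariants so the
# generators can assume a sane config.

# run `expr` under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Default soil taxa list and relative abundances
#'
#' The 21 taxonomic groups used throughout, dominated by Acari (63% of
#' individuals), Diptera (28%) and Collembola (7%), with the remaining
#' groups sharing the residual 2% equally.
#'
#' @return named numeric vector of mean relative abundances summing to 1.
#' @export
default_taxa_proportions <- function() {
  rare <- c("Araneae", "Chilopoda", "Coleoptera", "Diplura", "Diplopoda",
            "Gastropoda", "Haplotaxida", "Hemiptera", "Hymenoptera",
            "Isopoda", "Lepidoptera", "Nematoda", "Opiliones", "Opisthopora",
            "Pauropoda", "Protura", "Psocoptera", "Thysanoptera")
  p <- c(Acari = 0.63, Diptera = 0.28, Collembola = 0.07,
         setNames(rep(0.02 / length(rare), length(rare)), rare))
  p / sum(p)
}

# default acoustic event archetypes; band limits follow the observed soil
# soundscape (background band 100-1000 Hz, louder events up to 10 kHz)
default_archetypes <- function() {
  list(
    list(name = "transient_train", band = c(1000, 10000),
         decay_s = 0.004, n_pulses = 1L, pulse_gap_s = 0, amp = 0.45),
    list(name = "rhythmic_pulses", band = c(300, 3000),
         decay_s = 0.010, n_pulses = 6L, pulse_gap_s = 0.05, amp = 0.35),
    list(name = "low_rumble", band = c(100, 1000),
         decay_s = 0.080, n_pulses = 1L, pulse_gap_s = 0, amp = 0.30)
  )
}

#' Soundscape generator configuration
#'
#' @param rate sampling rate in samples/second (field chain: 50 kHz).
#' @param clip_seconds clip duration; the default 20.6848 s yields exactly
#'   2020 non-overlapping 512-sample analysis frames at 50 kHz.
#' @param interval_minutes recording cadence.
#' @param noise_sigma amplitude SD of the Gaussian background noise floor.
#' @param archetype_set list of acoustic event archetypes (see
#'   `default_archetypes` in the sources); each has a frequency band in Hz,
#'   pulse shape parameters and a peak amplitude.
#' @param n_variants number of distinguishable event variants spread over the
#'   archetype families; caps the effective richness.
#' @param event_rate Poisson rate (events/second) contributed by each active
#'   variant.
#' @param richness_coupling logical: if `FALSE`, the event budget ignores
#'   richness (used for null checks of the richness-ACI link).
#' @param activity_coef multiplicative activity response `exp(coef * dT30)`
#'   to positive 30-min surface-temperature change, per degree C.
#' @param rain_schedule data.frame with POSIXct `start`/`end` columns; clips
#'   whose timestamp falls inside an interval are dominated by rain drops.
#' @param rain_drop_rate raindrop impacts per second during rain; the
#'   default `0.35 * rate / 512` keeps drops impulsive relative to a
#'   512-sample analysis frame at any sampling rate.
#' @param gain_db recording-chain gain applied to the synthetic signal.
#' @param seed integer seed; all generation is a pure function of
#'   (seed, timestamp, richness).
#' @return object of class `soundscape_config`.
#' @export
soundscape_config <- function(rate = 50000,
                              clip_seconds = 20.6848,
                              interval_minutes = 10,
                              noise_sigma = 0.05,
                              archetype_set = default_archetypes(),
                              n_variants = 12,
                              event_rate = 0.8,
                              richness_coupling = TRUE,
                              activity_coef = 0.12,
                              rain_schedule = NULL,
                              rain_drop_rate = NULL,
                              gain_db = 0,
                              seed = 1L) {
  if (is.null(rain_drop_rate)) rain_drop_rate <- 0.35 * rate / 512
  stopifnot(rate > 0, clip_seconds * rate >= 512, noise_sigma > 0,
            interval_minutes > 0, n_variants >= 1, event_rate >= 0,
            rain_drop_rate > 0)
  archetype_set <- lapply(archetype_set, function(a) {
    a$band[2] <- min(a$band[2], 0.9 * rate / 2)  # keep inside Nyquist
    if (a$band[1] <= 0 || a$band[1] >= a$band[2])
      stop("archetype band limits must satisfy 0 < low < high < rate/2")
    a
  })
  structure(list(rate = rate, clip_seconds = clip_seconds,
                 interval_minutes = interval_minutes,
                 noise_sigma = noise_sigma, archetype_set = archetype_set,
                 n_variants = as.integer(n_variants),
                 event_rate = event_rate,
                 richness_coupling = isTRUE(richness_coupling),
                 activity_coef = activity_coef,
                 rain_schedule = rain_schedule,
                 rain_drop_rate = rain_drop_rate,
                 gain_db = gain_db, seed = as.integer(seed)),
            class = "soundscape_config")
}

#' Soil community generator configuration
#'
#' @param taxa_names taxa labels.
#' @param mean_proportions expected relative abundances (sum to 1).
#' @param dispersion Dirichlet concentration; larger = samples closer to the
#'   mean proportions.
#' @param total_abundance_mean,total_abundance_size negative-binomial mean
#'   and size for per-sample totals.
#' @param season_shift named list season -> multiplicative perturbation of
#'   the mean proportions (renormalized); defaults shift the dominance of
#'   Acari/Diptera across seasons while leaving richness mostly unchanged.
#' @param seed integer seed.
#' @return object of class `community_config`.
#' @export
community_config <- function(taxa_names = names(default_taxa_proportions()),
                             mean_proportions = unname(default_taxa_proportions()),
                             dispersion = 40,
                             total_abundance_mean = 210,
                             total_abundance_size = 5,
                             season_shift = list(
                               winter = c(Acari = 1.15, Diptera = 0.55),
                               spring = c(Acari = 0.95, Diptera = 1.15),
                               summer = c(Acari = 0.90, Diptera = 1.35),
                               fall   = c(Acari = 1.05, Diptera = 0.80)),
                             seed = 1L) {
  mean_proportions <- as.numeric(mean_proportions)
  if (any(mean_proportions < 0)) stop("proportions must be nonnegative")
  if (abs(sum(mean_proportions) - 1) > 1e-6)
    stop("mean_proportions must sum to 1 (got ", sum(mean_proportions), ")")
  if (dispersion <= 0) stop("dispersion must be > 0")
  stopifnot(length(taxa_names) == length(mean_proportions),
            total_abundance_mean > 0, total_abundance_size > 0)
  structure(list(taxa_names = as.character(taxa_names),
                 mean_proportions = mean_proportions,
                 dispersion = dispersion,
                 total_abundance_mean = total_abundance_mean,
                 total_abundance_size = total_abundance_size,
                 season_shift = season_shift, seed = as.integer(seed)),
            class = "community_config")
}

#' Microclimate generator configuration
#'
#' Emulates 10-min-resolution field covariates: surface temperature (seasonal
#' step + diurnal sinusoid + AR(1) noise), soil temperature at 10 cm (lagged
#' low-pass of the surface series), volumetric soil moisture (baseline plus
#' exponentially decaying rain/irrigation impulses) and surface light.
#'
#' @param days simulation length in days.
#' @param start start timestamp (POSIXct, UTC).
#' @param step_minutes sampling step.
#' @param mean_temp annual mean surface temperature, deg C.
#' @param seasonal_amplitude seasonal step amplitude, deg C (winter
#'   `-amp`, summer `+amp`, spring/fall 0).
#' @param diurnal_amplitude diurnal sinusoid amplitude, deg C.
#' @param soil_damping low-pass coefficient (per step) for the soil series.
#' @param soil_lag_steps transport lag surface -> 10 cm, in steps.
#' @param moisture_baseline volumetric fraction in \[0, 1\].
#' @param event_schedule data.frame with `day` (fractional day of the event),
#'   `impulse` (added volumetric fraction) and `tau_days` (decay constant).
#' @param ar_noise_sigma innovation SD of the AR(1) temperature noise.
#' @param ar_coef AR(1) coefficient of the temperature noise.
#' @param seed integer seed.
#' @return object of class `microclimate_config`.
#' @export
microclimate_config <- function(days = 35,
                                start = as.POSIXct("2019-06-15", tz = "UTC"),
                                step_minutes = 10,
                                mean_temp = 14,
                                seasonal_amplitude = 8,
                                diurnal_amplitude = 6,
                                soil_damping = 0.02,
                                soil_lag_steps = 6,
                                moisture_baseline = 0.22,
                                event_schedule = data.frame(
                                  day = c(6, 16, 26),
                                  impulse = c(0.10, 0.08, 0.12),
                                  tau_days = c(3, 3, 3)),
                                ar_noise_sigma = 0.25,
                                ar_coef = 0.8,
                                seed = 1L) {
  if (days <= 0) stop("`days` must be positive")
  stopifnot(seasonal_amplitude >= 0, diurnal_amplitude >= 0,
            moisture_baseline >= 0, moisture_baseline <= 1,
            soil_damping > 0, soil_damping <= 1, soil_lag_steps >= 0,
            ar_noise_sigma >= 0, abs(ar_coef) < 1, step_minutes > 0)
  if (!is.null(event_schedule) && nrow(event_schedule) > 0)
    stopifnot(all(c("day", "impulse", "tau_days") %in% names(event_schedule)),
              all(event_schedule$tau_days > 0))
  structure(list(days = days, start = as.POSIXct(start, tz = "UTC"),
                 step_minutes = step_minutes, mean_temp = mean_temp,
                 seasonal_amplitude = seasonal_amplitude,
                 diurnal_amplitude = diurnal_amplitude,
                 soil_damping = soil_damping,
                 soil_lag_steps = as.integer(soil_lag_steps),
                 moisture_baseline = moisture_baseline,
                 event_schedule = event_schedule,
                 ar_noise_sigma = ar_noise_sigma, ar_coef = ar_coef,
                 seed = as.integer(seed)),
            class = "microclimate_config")
}

# meteorological seasons: Dec-Feb winter, Mar-May spring, Jun-Aug summer,
# Sep-Nov fall
season_of <- function(time) {
  m <- as.integer(format(as.POSIXct(time, tz = "UTC"), "%m", tz = "UTC"))
  c("winter", "winter", "spring", "spring", "spring", "summer",
    "summer", "summer", "fall", "fall", "fall", "winter")[m]
}

# 6-h daytime blocks: [00-06) night, [06-12) morning, [12-18) afternoon,
# [18-24) evening (local = UTC here)
daytime_of <- function(time) {
  h <- as.integer(format(as.POSIXct(time, tz = "UTC"), "%H", tz = "UTC"))
  c("night", "morning", "afternoon", "evening")[h %/% 6 + 1]
}
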