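# Synthetic microclimate, community and soundscape generators.

test_that("microclimate with no forcing is flat within a season", {
  cfg <- microclimate_config(days = 3, diurnal_amplitude = 0,
                             ar_noise_sigma = 0, event_schedule = NULL,
                             start = as.POSIXct("2019-06-15", tz = "UTC"))
  mc <- generate_microclimate(cfg)
  expect_equal(diff(range(mc$surface_temp)), 0)
  expect_equal(unique(mc$soil_moisture), cfg$moisture_baseline)
  expect_error(generate_microclimate(microclimate_config(days = -1)),
               "positive")
})

test_that("moisture impulses decay exponentially with the configured tau", {
  cfg <- microclimate_config(
    days = 8, ar_noise_sigma = 0, diurnal_amplitude = 0,
    moisture_baseline = 0.2,
    event_schedule = data.frame(day = 3, impulse = 0.1, tau_days = 2))
  mc <- generate_microclimate(cfg)
  t_days <- (seq_len(nrow(mc)) - 1) / 144
  at_day5 <- which.min(abs(t_days - 5))
  expect_equal(mc$soil_moisture[at_day5], 0.2 + 0.1 * exp(-1),
               tolerance = 1e-3)
  expect_lt(max(abs(mc$soil_moisture[t_days < 3] - 0.2)), 1e-12)
})

test_that("soil temperature is a damped, lagged transform of the surface", {
  mc <- generate_microclimate(microclimate_config(days = 10, seed = 4))
  expect_lt(sd(mc$soil_temp), sd(mc$surface_temp))
  # soil lags surface: ccf(x, y) peaks where surface (x) leads soil (y)
  cc <- ccf(mc$surface_temp, mc$soil_temp, lag.max = 80, plot = FALSE)
  expect_lt(cc$lag[which.max(cc$acf)], 0)
})

test_that("generators are deterministic given config and seed", {
  cfg <- microclimate_config(days = 2, seed = 11)
  expect_identical(generate_microclimate(cfg), generate_microclimate(cfg))

  cc <- community_config(seed = 12)
  expect_identical(generate_community(cc, 10)$counts,
                   generate_community(cc, 10)$counts)

  sc <- test_soundscape(seed = 13)
  t0 <- as.POSIXct("2019-06-01 10:00:00", tz = "UTC")
  r1 <- generate_recording(t0, sc, richness = 4)
  r2 <- generate_recording(t0, sc, richness = 4)
  expect_identical(r1$samples, r2$samples)
  # byte-identical WAV output
  p1 <- withr::local_tempfile(fileext = ".wav")
  p2 <- withr::local_tempfile(fileext = ".wav")
  write_wav(r1$samples, sc$rate, p1)
  write_wav(r2$samples, sc$rate, p2)
  expect_identical(readBin(p1, raw(), file.size(p1)),
                   readBin(p2, raw(), file.size(p2)))
})

test_that("community counts follow the configured dominance structure", {
  # degenerate case: a single taxon takes everything
  cc1 <- community_config(taxa_names = c("A", "B"),
                          mean_proportions = c(1, 0), seed = 3)
  tab1 <- generate_community(cc1, 20)
  expect_equal(sum(tab1$counts[, "B"]), 0)

  # high dispersion: empirical shares converge to the configured means
  cc2 <- community_config(dispersion = 1e6, seed = 4, season_shift = list())
  tab2 <- generate_community(cc2, 400)
  shares <- colSums(tab2$counts) / sum(tab2$counts)
  expect_equal(unname(shares["Acari"]), 0.63, tolerance = 0.02)
  expect_equal(unname(shares["Diptera"]), 0.28, tolerance = 0.02)
  expect_equal(unname(shares["Collembola"]), 0.07, tolerance = 0.015)

  expect_error(community_config(taxa_names = c("A", "B"),
                                mean_proportions = c(0.7, 0.7)),
               "sum to 1")
  expect_error(community_config(dispersion = 0), "dispersion")
})

test_that("recordings contain the configured noise floor and events", {
  sc <- test_soundscape(seed = 21, noise_sigma = 0.05)
  t0 <- as.POSIXct("2019-06-01 12:00:00", tz = "UTC")
  quiet <- generate_recording(t0, sc, richness = 0)
  # richness 0: pure Gaussian floor, so the peak stays near 4-5 sigma
  expect_lt(max(abs(quiet$samples)), 6 * sc$noise_sigma)
  expect_equal(sd(quiet$samples), sc$noise_sigma, tolerance = 0.01)

  busy <- generate_recording(t0, sc, richness = 8)
  expect_gt(max(abs(busy$samples)), 6 * sc$noise_sigma)

  rain <- generate_recording(t0, sc, richness = 0, rain = TRUE)
  expect_gte(max(abs(rain$samples)), 0.99)  # clipped drop impacts

  expect_warning(generate_recording(t0, sc, richness = 99), "capped")
})

test_that("rain schedule triggers high-ACI clips and the exclusion rule", {
  rs <- data.frame(start = as.POSIXct("2019-06-01 12:00:00", tz = "UTC"),
                   end = as.POSIXct("2019-06-01 13:00:00", tz = "UTC"))
  sc <- test_soundscape(seed = 22, rain_schedule = rs)
  wet <- generate_recording(as.POSIXct("2019-06-01 12:30:00", tz = "UTC"),
                            sc, richness = 2)
  dry <- generate_recording(as.POSIXct("2019-06-01 14:00:00", tz = "UTC"),
                            sc, richness = 2)
  aci_wet <- compute_aci(compute_spectrogram(wet))$value
  aci_dry <- compute_aci(compute_spectrogram(dry))$value
  expect_gt(aci_wet, 0.90)
  expect_lt(aci_dry, 0.90)
  ser <- filter_aci(aci_series(c("A", "A"), c(wet$start_time, dry$start_time),
                               c(aci_wet, aci_dry)))
  expect_equal(ser$valid, c(FALSE, TRUE))
})

test_that("averaged ACI increases with richness on average", {
  sc <- test_soundscape(seed = 23)
  t0 <- as.POSIXct("2019-06-10", tz = "UTC")
  grid <- expand.grid(rich = 1:10, rep = 1:10)
  vals <- mapply(function(rich, rep) {
    rec <- generate_recording(t0 + rep * 600 + rich * 7, sc, richness = rich)
    compute_aci(compute_spectrogram(rec))$value
  }, grid$rich, grid$rep)
  means <- tapply(vals, grid$rich, mean)
  expect_gt(cor(1:10, means, method = "spearman"), 0)
})

test_that("activity rises with positive 30-min surface heating", {
  cfg <- microclimate_config(days = 2, diurnal_amplitude = 8,
                             ar_noise_sigma = 0, seed = 6,
                             start = as.POSIXct("2019-06-15", tz = "UTC"))
  mc <- generate_microclimate(cfg)
  dT <- surface_heating(mc)
  heating <- mc$time[which.max(dT)]
  cooling <- mc$time[which(dT == 0)[80]]
  sc <- test_soundscape(seed = 24, event_rate = 2, activity_coef = 0.3)
  aci_at <- function(tt) mean(sapply(1:6, function(j)
    compute_aci(compute_spectrogram(
      generate_recording(tt + j, sc, microclimate = mc, richness = 5)))$value))
  expect_gt(aci_at(heating), aci_at(cooling))
})

test_that("gain arithmetic follows the decibel law", {
  expect_equal(apply_gain(1, 40), 100)
  expect_equal(apply_gain(c(-0.3, 0.2), 0), c(-0.3, 0.2))
  expect_equal(apply_gain(1, 18), 7.943, tolerance = 1e-3)
})

test_that("high-pass filter nulls DC, passes 1 kHz, rejects 10 Hz", {
  rate <- 50000
  tt <- (0:(rate - 1)) / rate
  gain_at <- function(f) {
    x <- sin(2 * pi * f * tt)
    y <- highpass(x, rate)
    i <- 10000:40000  # steady state
    sqrt(mean(y[i]^2) / mean(x[i]^2))
  }
  expect_lt(max(abs(highpass(rep(1, rate), rate)[10000:40000])), 1e-10)
  expect_gt(20 * log10(gain_at(1000)), -1)
  expect_lt(20 * log10(gain_at(10)), -20)
  expect_error(highpass(rnorm(100), 50000, taps = 2), "taps")
  expect_error(highpass(rnorm(100), 50000, cutoff_hz = 30000), "cutoff")
})
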