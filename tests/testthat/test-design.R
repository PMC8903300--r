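# Model-data preparation: designs, lag diagnostics, auxiliary mixed model.

make_series <- function(times, values, sensor = "A") {
  filter_aci(aci_series(rep(sensor, length(times)), times, values))
}

test_that("seasonal design maps calendar time and spans 16 cells", {
  t0 <- as.POSIXct("2019-01-01 00:00:00", tz = "UTC")
  times <- t0 + seq(0, 364 * 86400, by = 6 * 3600)
  set.seed(41)
  s <- aci_series(rep(c("A", "B"), length.out = length(times)), times,
                  runif(length(times), 0.56, 0.80), valid = TRUE)
  md <- build_seasonal_design(s)
  expect_s3_class(md, "soil_model_data")
  expect_equal(ncol(md$X), 15)  # saturated 4x4 factorial minus intercept
  expect_true(all(md$y > 0))
  # distinct fitted cell means: 16 unique rows of the design
  expect_equal(nrow(unique(as.data.frame(md$X))), 16)

  # calendar mapping: 2019-01-15 03:00 is winter night
  expect_equal(soundsoil:::season_of(as.POSIXct("2019-01-15 03:00:00",
                                                tz = "UTC")), "winter")
  expect_equal(soundsoil:::daytime_of(as.POSIXct("2019-01-15 03:00:00",
                                                 tz = "UTC")), "night")
  expect_equal(soundsoil:::season_of(as.POSIXct("2019-07-01", tz = "UTC")),
               "summer")

  # single-season input: season columns constant, flagged
  jan <- s[format(s$time, "%m") == "01", ]
  expect_warning(build_seasonal_design(jan), "constant design columns")
})

test_that("microclimate design derives, lags and scales covariates", {
  t0 <- as.POSIXct("2019-06-15", tz = "UTC")
  n <- 400
  times <- t0 + (0:(n - 1)) * 600
  mc <- data.frame(sensor_id = "A", time = times,
                   surface_temp = 15 + 5 * sin(2 * pi * (0:(n - 1)) / 144),
                   soil_temp = 15 + 2 * sin(2 * pi * (0:(n - 1)) / 144 - 0.5),
                   soil_moisture = 0.25 + 0.05 * cos(2 * pi * (0:(n - 1)) / 200),
                   light = 0)
  set.seed(42)
  s <- make_series(times, runif(n, 0.56, 0.8))
  md <- build_microclimate_design(s, mc, lag = -1)
  expect_setequal(colnames(md$X),
                  c("soil_moisture", "soil_moisture_sq", "soil_temp",
                    "surface_temp", "dT30"))
  # scaled columns have mean 0, sd 1
  expect_lt(max(abs(colMeans(md$X))), 1e-10)
  expect_equal(unname(apply(md$X, 2, sd)), rep(1, 5), tolerance = 1e-10)

  # quadratic column is the square of unscaled moisture, then scaled
  i <- match(paste("A", as.numeric(md$time)),
             paste(mc$sensor_id, as.numeric(mc$time)))
  raw_sq <- mc$soil_moisture[i + 1]^2  # lag -1: covariate one step later
  expect_equal(unname(md$X[, "soil_moisture_sq"]),
               unname(as.numeric(scale(raw_sq))), tolerance = 1e-10)

  # constant surface temperature gives an all-zero heating column
  expect_equal(unname(surface_heating(transform(mc, surface_temp = 14))),
               rep(0, n))
  # a 5 degree rise within 30 min shows up as 5 before scaling; once the
  # jump leaves the 30-min look-back the column returns to 0
  mc2 <- mc; mc2$surface_temp <- c(rep(10, 200), rep(15, 200))
  expect_equal(surface_heating(mc2)[c(201, 203, 204)], c(5, 5, 0))
})

test_that("planted lag-1 dependence is recovered after pre-whitening", {
  set.seed(43)
  x <- as.numeric(arima.sim(list(ar = 0.7), 500))
  y <- c(0, head(x, -1)) + rnorm(500, sd = 0.4)
  tab <- cross_correlation_lags(x, y, max_lag = 8)
  expect_equal(tab$lag[which.max(abs(tab$ccf))], 1)

  # aligned series peak at lag zero
  tab0 <- cross_correlation_lags(x, x + rnorm(500, sd = 0.2), max_lag = 5)
  expect_equal(tab0$lag[which.max(abs(tab0$ccf))], 0)

  # independent white series: ~95% of lags inside the Bartlett band
  set.seed(44)
  inside <- replicate(10, {
    a <- rnorm(400); b <- rnorm(400)
    tt <- cross_correlation_lags(a, b, max_lag = 10)
    mean(abs(tt$ccf) < 2 / sqrt(400))
  })
  expect_gt(mean(inside), 0.90)

  expect_error(cross_correlation_lags(rep(1, 100), rnorm(100), 5),
               "constant")
  expect_error(cross_correlation_lags(rnorm(20), rnorm(20), 10), "short")
})

test_that("maximum AR lag is chosen at a local ACF maximum", {
  # geometric (AR(1)-like) decay: boundary maximum at lag 1
  expect_equal(select_max_lag(0.6^(1:12), candidate_max = 10), 1L)
  # planted period-8 residual seasonality
  acf8 <- 0.02 + 0.3 * (cos(2 * pi * (1:12) / 8) > 0.999)
  expect_equal(select_max_lag(acf8, candidate_max = 10), 8L)
  # all-noise ACF below threshold: L = 1 with a warning
  expect_warning(L <- select_max_lag(rep(0.01, 12), candidate_max = 10),
                 "no local")
  expect_equal(L, 1L)
  expect_equal(select_max_lag(rep(0.01, 12), 10, override = 4), 4L)
})

test_that("auxiliary log-response mixed model behaves as a residualizer", {
  set.seed(45)
  n <- 120
  X <- matrix(rnorm(2 * n * 2), ncol = 2)
  beta <- c(0.5, -0.3)
  sensor <- rep(c("A", "B"), each = n)
  # sigma_alpha = 0: both sensors share the intercept
  y <- exp(1 + X %*% beta + rnorm(2 * n, sd = 0.2))
  md <- soil_model_data(y, X, sensor, time = rep(1:n, 2))
  aux <- fit_auxiliary_lmm(md)
  expect_length(aux$residuals, 2 * n)
  # residual mean per sensor is ~0 (least squares within the fit)
  expect_lt(max(abs(tapply(aux$residuals, sensor, mean))), 0.05)
  if (inherits(aux$model, "lme")) {
    re_sd <- as.numeric(nlme::VarCorr(aux$model)["(Intercept)", "StdDev"])
    expect_lt(re_sd, 0.1)
    # planted coefficients recovered within 2 SE
    tab <- summary(aux$model)$tTable
    expect_lt(abs(tab["x1", "Value"] - 0.5), 2 * tab["x1", "Std.Error"])
    expect_lt(abs(tab["x2", "Value"] + 0.3), 2 * tab["x2", "Std.Error"])
  }
})
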