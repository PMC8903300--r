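# Model data preparation for the hierarchical gamma autoregressive model:
# response offsetting, design matrices for the seasonal and microclimate
# analyses, and predictor scaling.

#' Construct model data for the gamma autoregressive model
#'
#' @param y positive response vector (ACI minus the 0.55 offset).
#' @param X design matrix (already scaled/dummy-coded).
#' @param sensor integer or factor sensor labels, one per row.
#' @param time ordered timestamps (POSIXct or numeric), one per row.
#' @param step nominal spacing between consecutive observations (seconds if
#'   `time` is POSIXct); used to detect gaps when building lags.
#' @param make_X optional closure mapping a data.frame of predictor values on
#'   their original scales to design-matrix rows (stored by the builders so
#'   scenario prediction can reuse the exact scaling).
#' @return object of class `soil_model_data`.
#' @export
soil_model_data <- function(y, X, sensor, time, step = NULL, make_X = NULL) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  if (any(y <= 0)) stop("all responses must be strictly positive")
  sensor <- as.factor(sensor)
  stopifnot(length(y) == nrow(X), length(sensor) == length(y),
            length(time) == length(y))
  if (is.null(step)) {
    tt <- as.numeric(time)
    d <- unlist(tapply(tt, sensor, function(v) diff(sort(v))))
    step <- if (length(d)) median(d) else 1
  }
  structure(list(y = y, X = X, sensor = sensor, time = time, step = step,
                 make_X = make_X),
            class = "soil_model_data")
}

#' @export
print.soil_model_data <- function(x, ...) {
  cat(sprintf("<soil_model_data> %d obs, %d predictors, %d sensors\n",
              length(x$y), ncol(x$X), nlevels(x$sensor)))
  invisible(x)
}

# drop zero-variance columns with a warning (degenerate designs, e.g. a
# single season present)
drop_constant_columns <- function(X) {
  v <- apply(X, 2, function(c) diff(range(c)))
  if (any(v == 0)) {
    warning("constant design columns dropped: ",
            paste(colnames(X)[v == 0], collapse = ", "))
    X <- X[, v > 0, drop = FALSE]
  }
  X
}

#' Seasonal/daytime design for the gamma AR model
#'
#' Builds dummy-coded daytime (night/morning/afternoon/evening, from 6-h
#' blocks), season (meteorological quarters) and all their interactions,
#' with night and winter as reference levels; subtracts `offset` (0.55)
#' from the ACI response. Rows at or below the offset are dropped.
#'
#' @param series a valid-filtered, 6-h aggregated [aci_series()].
#' @param offset value subtracted from ACI (default 0.55).
#' @return a [soil_model_data()] whose `make_X` accepts a data.frame with
#'   `daytime` and `season` columns.
#' @export
build_seasonal_design <- function(series, offset = 0.55) {
  s <- series[!is.na(series$valid) & series$valid, , drop = FALSE]
  keep <- s$value > offset
  if (any(!keep)) message(sum(!keep), " rows at/below the offset dropped")
  s <- s[keep, , drop = FALSE]
  if (nrow(s) == 0) stop("no usable rows after offsetting")
  day_levels <- c("night", "morning", "afternoon", "evening")
  sea_levels <- c("winter", "spring", "summer", "fall")
  fac <- function(df) {
    data.frame(daytime = factor(df$daytime, levels = day_levels),
               season = factor(df$season, levels = sea_levels))
  }
  make_X <- function(newdata) {
    nd <- fac(newdata)
    if (anyNA(nd)) stop("unmapped daytime/season level")
    model.matrix(~ daytime * season, nd)[, -1, drop = FALSE]
  }
  nd <- data.frame(daytime = daytime_of(s$time), season = season_of(s$time))
  X <- drop_constant_columns(make_X(nd))
  soil_model_data(s$value - offset, X, s$sensor_id, s$time,
                  step = 6 * 3600, make_X = make_X)
}

#' Microclimate design for the gamma AR model
#'
#' Joins a 10-min ACI series with microclimate covariates per sensor and
#' builds: soil moisture, its square (computed before scaling), soil
#' temperature, surface temperature and the positive 30-min surface
#' temperature change. All covariates are shifted by `lag` steps (default
#' -1: the covariate measured one step after the ACI record, compensating
#' the logging delay between the acoustic and microclimate chains) and then
#' scaled to mean 0, SD 1.
#'
#' @param series a valid-filtered [aci_series()] at the microclimate
#'   resolution.
#' @param mc a `microclimate_series` covering the same sensors/times.
#' @param lag covariate alignment in steps; -1 pairs `y_t` with `x_(t+1)`.
#' @param offset value subtracted from ACI (default 0.55).
#' @return a [soil_model_data()] whose `make_X` accepts a data.frame with
#'   columns `soil_moisture`, `soil_temp`, `surface_temp`, `dT30` on their
#'   original scales.
#' @export
build_microclimate_design <- function(series, mc, lag = -1, offset = 0.55) {
  s <- series[!is.na(series$valid) & series$valid & series$value > offset, ,
              drop = FALSE]
  if (nrow(s) == 0) stop("no usable ACI rows")
  cov_list <- lapply(split(mc, mc$sensor_id), function(m) {
    m <- m[order(m$time), , drop = FALSE]
    m$dT30 <- surface_heating(m)
    # shift covariates: value used at t is the one measured at t - lag steps
    if (lag != 0) {
      shift <- function(v) {
        n <- length(v)
        if (lag < 0) c(v[(1 - lag):n], rep(NA, -lag))
        else c(rep(NA, lag), v[seq_len(n - lag)])
      }
      for (cn in c("soil_moisture", "soil_temp", "surface_temp", "dT30"))
        m[[cn]] <- shift(m[[cn]])
    }
    m
  })
  mc2 <- do.call(rbind, cov_list)
  key_s <- paste(s$sensor_id, as.numeric(s$time))
  key_m <- paste(mc2$sensor_id, as.numeric(mc2$time))
  idx <- match(key_s, key_m)
  ok <- !is.na(idx)
  if (any(!ok)) message(sum(!ok), " ACI rows without matching microclimate dropped")
  s <- s[ok, , drop = FALSE]
  m <- mc2[idx[ok], , drop = FALSE]
  raw <- cbind(soil_moisture = m$soil_moisture,
               soil_moisture_sq = m$soil_moisture^2,
               soil_temp = m$soil_temp,
               surface_temp = m$surface_temp,
               dT30 = m$dT30)
  cc <- complete.cases(raw)
  if (any(!cc)) message(sum(!cc), " rows with missing covariates dropped")
  s <- s[cc, , drop = FALSE]
  raw <- raw[cc, , drop = FALSE]
  Xs <- scale_columns(raw)
  center <- attr(Xs, "center"); scl <- attr(Xs, "scale")
  make_X <- function(newdata) {
    r <- cbind(soil_moisture = newdata$soil_moisture,
               soil_moisture_sq = newdata$soil_moisture^2,
               soil_temp = newdata$soil_temp,
               surface_temp = newdata$surface_temp,
               dT30 = newdata$dT30)
    scale_columns(r, center = center, scale = scl)
  }
  soil_model_data(s$value - offset, Xs, s$sensor_id, s$time,
                  step = as.numeric(median(diff(as.numeric(mc$time[mc$sensor_id == mc$sensor_id[1]])))),
                  make_X = make_X)
}
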