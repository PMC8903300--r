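# Pipeline orchestration: a single config drives simulate -> aci ->
# fit-seasonal -> fit-microclimate -> diversity -> link, with per-stage
# manifests, explicit seeds and no-op reruns on identical config.

#' Default desk-scale run configuration
#'
#' A complete pipeline configuration sized so the whole default run finishes
#' in minutes on one CPU: three sensors, one hourly-recorded day per season
#' for the seasonal model, a two-day 10-min window for the microclimate
#' model, six seasonal sampling dates for the community stages, and reduced
#' MCMC settings. Audio uses an 8 kHz / ~2.1 s clip format (the index is
#' rate-agnostic; the field chain's 50 kHz / 20.7 s format is available via
#' [soundscape_config()] defaults).
#'
#' @param output_dir directory for stage artifacts.
#' @param seed master seed; stage seeds are derived from it.
#' @return nested list of class `run_config`.
#' @export
default_run_config <- function(output_dir = file.path(tempdir(), "soundsoil_run"),
                               seed = 1L) {
  structure(list(
    paths = list(output_dir = output_dir),
    seed = as.integer(seed),
    sensors = c("K1", "K2", "B1"),
    soundscape = list(rate = 16000, clip_seconds = 2.048, noise_sigma = 0.05,
                      event_rate = 0.8, n_variants = 12,
                      richness_coupling = TRUE, activity_coef = 0.12),
    season_days = list(winter = c("2019-01-15", "2019-01-16"),
                       spring = c("2019-04-15", "2019-04-16"),
                       summer = c("2019-07-15", "2019-07-16"),
                       fall = c("2019-10-15", "2019-10-16")),
    seasonal_cadence_minutes = 60,
    dense_window = list(start = "2019-07-10", days = 2,
                        cadence_minutes = 10),
    microclimate = list(days = 370, start = "2019-01-01", step_minutes = 10,
                        mean_temp = 12, seasonal_amplitude = 8,
                        diurnal_amplitude = 6),
    community = list(dispersion = 40, total_abundance_mean = 210,
                     total_abundance_size = 5),
    sampling_dates = c("2019-01-16", "2019-04-16", "2019-07-11",
                       "2019-07-16", "2019-10-16", "2019-12-16"),
    event_window_hours = 13,
    filter = list(low = 0.55, high = 0.90),
    model = list(chains = 2, iter = 2000, warmup = 800, max_lag = 6,
                 parameterization = "mean", ar_transform = "log"),
    window = 512, clump_seconds = 1
  ), class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Values present in the file override the defaults of
#' [default_run_config()]; everything else is inherited.
#'
#' @param path YAML file path.
#' @param seed optional master-seed override.
#' @return a `run_config`.
#' @export
load_run_config <- function(path, seed = NULL) {
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(unclass(default_run_config()), user)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  class(cfg) <- "run_config"
  cfg
}

#' Validate a run configuration
#'
#' Schema and cross-field checks; violations are collected, not thrown.
#'
#' @param config a `run_config`.
#' @return character vector of violations (empty when valid).
#' @export
validate_config <- function(config) {
  v <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  chk(is.numeric(config$seed) && length(config$seed) == 1,
      "seed must be a single integer (no wall-clock seeding)")
  chk(config$filter$low < config$filter$high,
      sprintf("filter bounds inverted: low = %s >= high = %s",
              config$filter$low, config$filter$high))
  sc <- config$soundscape
  chk(sc$rate > 0, "soundscape rate must be positive")
  chk(sc$clip_seconds * sc$rate >= config$window,
      sprintf("clip too short for the analysis window: %g * %g < %d",
              sc$clip_seconds, sc$rate, config$window))
  chk(length(config$sensors) >= 1, "at least one sensor required")
  chk(config$model$iter > config$model$warmup,
      "MCMC iter must exceed warmup")
  chk(config$microclimate$days > 0, "microclimate days must be positive")
  v
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".yml")
  on.exit(unlink(f))
  yaml::write_yaml(unclass(config), f)
  unname(tools::md5sum(f))
}

stage_dir <- function(config, stage) {
  d <- file.path(config$paths$output_dir, stage)
  if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  d
}

manifest_path <- function(config, stage)
  file.path(config$paths$output_dir, paste0(stage, ".manifest.json"))

write_manifest <- function(config, stage, artifacts, t0) {
  info <- list(stage = stage, config_hash = config_hash(config),
               seed = config$seed, artifacts = artifacts,
               elapsed_s = round(as.numeric(Sys.time()) - t0, 2),
               package_version = as.character(utils::packageVersion("soundsoil")))
  jsonlite::write_json(info, manifest_path(config, stage), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(info)
}

stage_current <- function(config, stage) {
  mp <- manifest_path(config, stage)
  if (!file.exists(mp)) return(FALSE)
  m <- jsonlite::read_json(mp)
  identical(m$config_hash, unname(config_hash(config))) &&
    all(file.exists(file.path(config$paths$output_dir,
                              unlist(m$artifacts))))
}

require_artifact <- function(config, rel, producer) {
  p <- file.path(config$paths$output_dir, rel)
  if (!file.exists(p))
    stop("missing artifact '", rel, "'; run stage '", producer, "' first")
  p
}

# season-dependent baseline richness used for clips away from sampling
# events: soil fauna active in spring/summer, quiescent in winter
season_richness <- function(season) {
  c(winter = 1, spring = 6, summer = 8, fall = 3)[season]
}

stage_simulate <- function(config) {
  t0 <- as.numeric(Sys.time())
  dir_audio <- stage_dir(config, "audio")
  dir_tab <- stage_dir(config, "tables")
  artifacts <- character(0)

  mc_all <- list()
  for (i in seq_along(config$sensors)) {
    sid <- config$sensors[i]
    mcc <- do.call(microclimate_config, c(
      config$microclimate[setdiff(names(config$microclimate), "start")],
      list(start = as.POSIXct(config$microclimate$start, tz = "UTC"),
           seed = derive_seed(config$seed, 100L + i))))
    mc_all[[sid]] <- generate_microclimate(mcc, sensor_id = sid)
  }
  mc <- do.call(rbind, mc_all)
  mc_out <- mc
  mc_out$time <- format(mc_out$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  mc_file <- file.path(dir_tab, "microclimate.csv")
  write.csv(mc_out, mc_file, row.names = FALSE)
  artifacts <- c(artifacts, file.path("tables", "microclimate.csv"))

  comm_cfg <- do.call(community_config, c(
    config$community, list(seed = derive_seed(config$seed, 200L))))
  dates <- as.Date(config$sampling_dates)
  grid <- expand.grid(sensor = config$sensors, date = dates,
                      stringsAsFactors = FALSE)
  grid$season <- season_of(as.POSIXct(paste(grid$date, "12:00:00"),
                                      tz = "UTC"))
  comm <- generate_community(comm_cfg, nrow(grid),
                             season_labels = grid$season,
                             sensor_labels = grid$sensor, dates = grid$date)
  comm_file <- file.path(dir_tab, "community.csv")
  write_community_csv(comm, comm_file)
  artifacts <- c(artifacts, file.path("tables", "community.csv"))
  events <- data.frame(sensor = grid$sensor,
                       time = as.POSIXct(paste(grid$date, "10:00:00"),
                                         tz = "UTC"))
  ev_file <- file.path(dir_tab, "sampling_events.csv")
  write.csv(data.frame(sensor = events$sensor,
                       iso_time = format(events$time, "%Y-%m-%dT%H:%M:%SZ")),
            ev_file, row.names = FALSE)
  artifacts <- c(artifacts, file.path("tables", "sampling_events.csv"))
  sample_richness <- apply(comm$counts, 1, function(x) sum(x > 0))

  # recording schedule: hourly days in each season (seasonal model), a
  # dense 10-min window (microclimate model), and an hourly window around
  # every sampling event plus +/- 30 min clips (link stage resolutions)
  schedule <- list()
  for (s in names(config$season_days)) {
    days <- as.POSIXct(config$season_days[[s]], tz = "UTC")
    schedule[[s]] <- as.POSIXct(
      unlist(lapply(days, function(d)
        d + seq(0, 86400 - 1, by = config$seasonal_cadence_minutes * 60))),
      origin = "1970-01-01", tz = "UTC")
  }
  dw <- config$dense_window
  schedule$dense <- as.POSIXct(dw$start, tz = "UTC") +
    seq(0, dw$days * 86400 - 1, by = dw$cadence_minutes * 60)
  ewh <- config$event_window_hours
  schedule$events <- as.POSIXct(
    unlist(lapply(unique(events$time), function(te)
      te + c(seq(-ewh * 3600, ewh * 3600, by = 3600), -1800, 1800))),
    origin = "1970-01-01", tz = "UTC")

  n_written <- 0L
  for (i in seq_along(config$sensors)) {
    sid <- config$sensors[i]
    sc <- do.call(soundscape_config, c(
      config$soundscape, list(seed = derive_seed(config$seed, 300L + i))))
    all_times <- sort(unique(do.call(c, unname(schedule))))
    rich <- season_richness(season_of(all_times)) +
      ((i + as.integer(format(all_times, "%d"))) %% 3L) - 1L
    # around each sampling event, activity tracks that sample's richness
    for (e in which(events$sensor == sid)) {
      near <- abs(as.numeric(all_times) - as.numeric(events$time[e])) <= 43200
      rich[near] <- round(sample_richness[e] * 0.6)
    }
    rich <- pmax(0L, pmin(sc$n_variants, as.integer(rich)))
    for (j in seq_along(all_times)) {
      rec <- generate_recording(all_times[j], sc, microclimate = mc_all[[sid]],
                                richness = rich[j], sensor_id = sid)
      fn <- sprintf("%s_%s.wav", sid,
                    format(all_times[j], "%Y%m%dT%H%M%SZ"))
      write_wav(rec$samples, rec$rate, file.path(dir_audio, fn))
      n_written <- n_written + 1L
    }
  }
  message("simulate: ", n_written, " clips, ", nrow(mc),
          " microclimate rows, ", nrow(comm$counts), " community samples")
  write_manifest(config, "simulate", artifacts, t0)
}

stage_aci <- function(config) {
  t0 <- as.numeric(Sys.time())
  audio_dir <- file.path(config$paths$output_dir, "audio")
  if (!dir.exists(audio_dir) || length(list.files(audio_dir)) == 0)
    stop("no audio found; run stage 'simulate' first")
  dir_tab <- stage_dir(config, "tables")
  files <- list.files(audio_dir, pattern = "\\.wav$", full.names = TRUE)
  parts <- regmatches(basename(files),
                      regexec("^(.+)_([0-9T]+Z)\\.wav$", basename(files)))
  recs <- lapply(seq_along(files), function(i) {
    w <- read_wav(files[i])
    soil_recording(w$samples, w$rate,
                   start_time = as.POSIXct(parts[[i]][3],
                                           format = "%Y%m%dT%H%M%SZ",
                                           tz = "UTC"),
                   sensor_id = parts[[i]][2])
  })
  series <- aci_batch(recs, window = config$window,
                      clump_seconds = config$clump_seconds,
                      low = config$filter$low, high = config$filter$high)
  write_aci_csv(series, file.path(dir_tab, "aci.csv"))
  message("aci: ", nrow(series), " records, ",
          sum(series$valid), " valid")
  write_manifest(config, "aci", file.path("tables", "aci.csv"), t0)
}

fit_and_export <- function(config, data, L, prefix, scenarios = NULL) {
  m <- config$model
  fit <- fit_gamma_ar(data, L = L,
                      parameterization = m$parameterization,
                      ar_transform = m$ar_transform,
                      chains = m$chains, iter = m$iter, warmup = m$warmup,
                      seed = derive_seed(config$seed, 400L + nchar(prefix)))
  dir_fit <- stage_dir(config, "fits")
  write.csv(summary(fit), file.path(dir_fit, paste0(prefix, "_posterior.csv")),
            row.names = FALSE)
  arts <- file.path("fits", paste0(prefix, "_posterior.csv"))
  if (!is.null(scenarios)) {
    pr <- predict_scenarios(fit, scenarios)
    pr <- cbind(scenarios, pr[-1])
    write.csv(pr, file.path(dir_fit, paste0(prefix, "_predictions.csv")),
              row.names = FALSE)
    arts <- c(arts, file.path("fits", paste0(prefix, "_predictions.csv")))
  }
  list(fit = fit, artifacts = arts)
}

stage_fit_seasonal <- function(config) {
  t0 <- as.numeric(Sys.time())
  aci_file <- require_artifact(config, file.path("tables", "aci.csv"), "aci")
  series <- read_aci_csv(aci_file)
  agg <- aggregate_aci(series, hours = 6)
  data <- build_seasonal_design(agg)
  aux <- fit_auxiliary_lmm(data)
  L <- select_max_lag(residual_acf(aux$residuals,
                                   lag_max = config$model$max_lag),
                      candidate_max = config$model$max_lag)
  scen <- expand.grid(daytime = c("night", "morning", "afternoon", "evening"),
                      season = c("winter", "spring", "summer", "fall"),
                      stringsAsFactors = FALSE)
  res <- fit_and_export(config, data, L, "seasonal", scen)
  message("fit-seasonal: L = ", L, ", ",
          if (res$fit$converged) "converged" else "NOT converged")
  write_manifest(config, "fit-seasonal", res$artifacts, t0)
}

stage_fit_microclimate <- function(config) {
  t0 <- as.numeric(Sys.time())
  aci_file <- require_artifact(config, file.path("tables", "aci.csv"), "aci")
  mc_file <- require_artifact(config, file.path("tables", "microclimate.csv"),
                              "simulate")
  series <- read_aci_csv(aci_file)
  mc <- read.csv(mc_file, stringsAsFactors = FALSE)
  mc$time <- as.POSIXct(mc$time, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  # restrict to the dense 10-min window
  dw <- config$dense_window
  t0w <- as.POSIXct(dw$start, tz = "UTC")
  sel <- series$time >= t0w & series$time < t0w + dw$days * 86400
  data <- build_microclimate_design(series[sel, ], mc)
  aux <- fit_auxiliary_lmm(data)
  L <- select_max_lag(residual_acf(aux$residuals,
                                   lag_max = config$model$max_lag),
                      candidate_max = config$model$max_lag)
  base <- data.frame(soil_moisture = mean(mc$soil_moisture),
                     soil_temp = mean(mc$soil_temp),
                     surface_temp = mean(mc$surface_temp), dT30 = 0)
  scen <- do.call(rbind, lapply(c("soil_moisture", "soil_temp",
                                  "surface_temp", "dT30"), function(v) {
    lo <- base; hi <- base
    if (v == "dT30") { lo[[v]] <- 0; hi[[v]] <- 5 } else {
      lo[[v]] <- mean(mc[[v]]) - sd(mc[[v]])
      hi[[v]] <- mean(mc[[v]]) + sd(mc[[v]])
    }
    cbind(variable = v, level = c("low", "high"), rbind(lo, hi))
  }))
  res <- fit_and_export(config, data, L, "microclimate",
                        scen[, -(1:2), drop = FALSE])
  message("fit-microclimate: L = ", L)
  write_manifest(config, "fit-microclimate", res$artifacts, t0)
}

stage_diversity <- function(config) {
  t0 <- as.numeric(Sys.time())
  comm_file <- require_artifact(config, file.path("tables", "community.csv"),
                                "simulate")
  comm <- read_community_csv(comm_file)
  dir_tab <- stage_dir(config, "tables")
  prof <- diversity_profile(comm)
  write.csv(prof, file.path(dir_tab, "diversity.csv"), row.names = FALSE)
  nm <- nmds_communities(comm, seed = derive_seed(config$seed, 500L))
  coords <- data.frame(comm$meta, nm$coordinates)
  write.csv(coords, file.path(dir_tab, "nmds.csv"), row.names = FALSE)
  pm <- permanova_strata(bray_curtis(comm), comm$meta$season,
                         strata = comm$meta$sensor, n_perm = 1000,
                         seed = derive_seed(config$seed, 501L))
  lmms <- lapply(c("abundance", "richness", "shannon", "simpson"),
                 function(a) {
                   f <- season_lmm(comm, a)
                   row <- f$anova[f$anova$term == "season", ]
                   data.frame(attribute = a, F = row$F, p = row$p,
                              r2_marginal = f$r2_marginal,
                              r2_conditional = f$r2_conditional)
                 })
  stats <- do.call(rbind, lmms)
  write.csv(stats, file.path(dir_tab, "season_tests.csv"), row.names = FALSE)
  jsonlite::write_json(list(nmds_stress = nm$stress, permanova_F = pm$F,
                            permanova_R2 = pm$R2, permanova_p = pm$p),
                       file.path(dir_tab, "composition_tests.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  message(sprintf("diversity: NMDS stress %.3f, PERMANOVA p = %.3f",
                  nm$stress, pm$p))
  write_manifest(config, "diversity",
                 file.path("tables", c("diversity.csv", "nmds.csv",
                                       "season_tests.csv",
                                       "composition_tests.json")), t0)
}

stage_link <- function(config) {
  t0 <- as.numeric(Sys.time())
  aci_file <- require_artifact(config, file.path("tables", "aci.csv"), "aci")
  comm_file <- require_artifact(config, file.path("tables", "community.csv"),
                                "simulate")
  ev_file <- require_artifact(config,
                              file.path("tables", "sampling_events.csv"),
                              "simulate")
  series <- read_aci_csv(aci_file)
  comm <- read_community_csv(comm_file)
  ev <- read.csv(ev_file, stringsAsFactors = FALSE)
  events <- data.frame(sensor = ev$sensor,
                       time = as.POSIXct(ev$iso_time,
                                         format = "%Y-%m-%dT%H:%M:%SZ",
                                         tz = "UTC"))
  linked <- link_community(align_aci(series, events), comm,
                           seed = derive_seed(config$seed, 600L))
  dir_tab <- stage_dir(config, "tables")
  write.csv(linked, file.path(dir_tab, "linked.csv"), row.names = FALSE)
  attrs <- c("abundance", "richness", "shannon", "simpson", "NMDS1", "NMDS2")
  resolutions <- c("aci_before", "aci_1h", "aci_24h")
  rows <- list()
  for (a in attrs) for (r in resolutions) {
    f <- tryCatch(fit_link_lmm(linked, a, r), error = function(e) NULL)
    if (!is.null(f))
      rows[[paste(a, r)]] <- data.frame(
        attribute = a, resolution = r, slope = f$slope, p = f$p,
        r2_marginal = f$r2_marginal, r2_conditional = f$r2_conditional,
        n = f$n)
  }
  if (length(rows) == 0) stop("no linkable attribute/resolution pair; ",
                              "too few linked samples?")
  res <- do.call(rbind, rows)
  write.csv(res, file.path(dir_tab, "link_results.csv"), row.names = FALSE)
  jsonlite::write_json(res, file.path(dir_tab, "link_results.json"),
                       dataframe = "rows", auto_unbox = TRUE, pretty = TRUE)
  message("link: ", nrow(res), " attribute x resolution fits")
  write_manifest(config, "link",
                 file.path("tables", c("linked.csv", "link_results.csv",
                                       "link_results.json")), t0)
}

#' Run one pipeline stage
#'
#' Stages: `simulate`, `aci`, `fit-seasonal`, `fit-microclimate`,
#' `diversity`, `link`, or `all`. Each stage writes its artifacts plus a
#' manifest (config hash, seed, elapsed time); rerunning with an identical
#' config is a no-op unless `force = TRUE`. A missing upstream artifact
#' raises an error naming the stage that produces it.
#'
#' @param stage stage name.
#' @param config a `run_config` (default: [default_run_config()]).
#' @param force rerun even when the manifest is current.
#' @return invisibly, the stage name(s) executed.
#' @export
run_stage <- function(stage, config = default_run_config(), force = FALSE) {
  stages <- c("simulate", "aci", "fit-seasonal", "fit-microclimate",
              "diversity", "link")
  if (identical(stage, "all")) {
    for (s in stages) run_stage(s, config, force = force)
    return(invisible(stages))
  }
  stage <- match.arg(stage, stages)
  issues <- validate_config(config)
  if (length(issues))
    stop("invalid config:\n  - ", paste(issues, collapse = "\n  - "))
  if (!force && stage_current(config, stage)) {
    message(stage, ": up to date, skipping (use force = TRUE to rerun)")
    return(invisible(stage))
  }
  switch(stage,
         "simulate" = stage_simulate(config),
         "aci" = stage_aci(config),
         "fit-seasonal" = stage_fit_seasonal(config),
         "fit-microclimate" = stage_fit_microclimate(config),
         "diversity" = stage_diversity(config),
         "link" = stage_link(config))
  invisible(stage)
}

#' @rdname run_stage
#' @export
run_pipeline <- function(config = default_run_config(), force = FALSE)
  run_stage("all", config, force = force)
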