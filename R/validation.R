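# Simulation-based validation harnesses: parameter-recovery / HDI-coverage
# study for the gamma AR model, and an end-to-end richness-ACI coupling
# study through the synthetic soundscape and the linking stage.

#' Parameter-recovery and HDI-coverage study for the gamma AR model
#'
#' Repeatedly simulates panels from the hierarchical gamma AR model at known
#' parameters ([simulate_from_model()]) and refits them with
#' [fit_gamma_ar()] under the same parameterization, recording for every
#' replicate whether each true parameter (sensor intercepts, predictor
#' coefficients, AR coefficients, gamma shape) falls inside its 95% highest
#' density interval, and the posterior probability that each predictor
#' coefficient carries its true sign.
#'
#' @param n_reps number of replicates.
#' @param n_sensors,n_times panel size per replicate.
#' @param true_params list as for [simulate_from_model()]; the default
#'   plants `beta = (0.3, -0.2)`, `phi = (0.2, 0.1)`, `k = 8`.
#' @param L autoregressive order (must match `length(true_params$phi)`).
#' @param parameterization gamma parameterization used for both simulator
#'   and fitter.
#' @param chains,iter,warmup MCMC settings per replicate.
#' @param seed master seed; replicate seeds are derived from it.
#' @param prob HDI mass checked for coverage.
#' @return data.frame with one row per replicate: `covered` / `checked`
#'   (HDI coverage counts over all true parameters), `sign_ok` (both
#'   coefficient signs recovered with posterior probability > 0.95),
#'   `min_sign_prob`, `max_rhat`.
#' @export
recovery_study <- function(n_reps = 40, n_sensors = 5, n_times = 120,
                           true_params = list(mu_alpha = -1, sigma_alpha = 0.3,
                                              beta = c(0.3, -0.2),
                                              phi = c(0.2, 0.1), k = 8),
                           L = length(true_params$phi),
                           parameterization = "mean",
                           chains = 2, iter = 800, warmup = 350,
                           seed = 1L, prob = 0.95) {
  P <- length(true_params$beta)
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    rs <- derive_seed(seed, 1000L + r)
    X <- with_seed(rs, matrix(rnorm(n_times * P), ncol = P))
    sim <- simulate_from_model(true_params, n_sensors, n_times, X = X,
                               L = L, seed = derive_seed(rs, 2L),
                               parameterization = parameterization)
    truth <- attr(sim, "truth")
    fit <- suppressWarnings(
      fit_gamma_ar(sim, L = L, parameterization = parameterization,
                   chains = chains, iter = iter, warmup = warmup,
                   seed = derive_seed(rs, 3L)))
    want <- c(setNames(truth$alpha, paste0("alpha[", seq_len(n_sensors), "]")),
              setNames(true_params$beta,
                       if (P == 1) "beta" else paste0("beta[", seq_len(P), "]")),
              if (L > 0) setNames(true_params$phi,
                                  if (L == 1) "phi" else paste0("phi[", seq_len(L), "]")),
              k = true_params$k)
    covered <- 0L; checked <- 0L
    for (pn in names(want)) {
      if (!pn %in% colnames(fit$draws)) next
      h <- hdi(fit$draws[, pn], prob)
      checked <- checked + 1L
      if (want[pn] >= h[1] && want[pn] <= h[2]) covered <- covered + 1L
    }
    bcols <- if (P == 1) "beta" else paste0("beta[", seq_len(P), "]")
    sign_prob <- vapply(seq_len(P), function(j)
      mean(sign(fit$draws[, bcols[j]]) == sign(true_params$beta[j])),
      numeric(1))
    rows[[r]] <- data.frame(rep = r, covered = covered, checked = checked,
                            sign_ok = all(sign_prob > 0.95),
                            min_sign_prob = min(sign_prob),
                            max_rhat = max(fit$rhat, na.rm = TRUE))
  }
  do.call(rbind, rows)
}

#' End-to-end richness-to-ACI coupling study
#'
#' For each replicate, plants a uniform 1-10 richness across sampling
#' events, synthesizes recordings around each event through the soundscape
#' generator (with the richness coupling on or off), computes and filters
#' the ACI, aligns it to the events ([align_aci()]) and fits the linking
#' mixed model of ACI on standardized richness ([fit_link_lmm()]).
#'
#' @param n_reps number of replicates.
#' @param coupled logical: richness drives the soundscape event budget
#'   (`TRUE`) or is ignored by it (`FALSE`, null case).
#' @param n_sensors,events_per_sensor sampling design per replicate.
#' @param resolution ACI resolution handed to the linking model.
#' @param rate,clip_seconds compact audio format used for the synthetic
#'   clips (the index is rate-agnostic).
#' @param seed master seed.
#' @return data.frame with one row per replicate: `slope`, `p`,
#'   `r2_marginal`.
#' @export
link_coupling_study <- function(n_reps = 8, coupled = TRUE, n_sensors = 4,
                                events_per_sensor = 6,
                                resolution = "aci_1h",
                                rate = 16000, clip_seconds = 2.048,
                                seed = 1L) {
  rows <- vector("list", n_reps)
  offsets <- seq(-30, 30, by = 10) * 60  # clips around each event
  for (r in seq_len(n_reps)) {
    rs <- derive_seed(seed, 500L + r)
    sensors <- paste0("S", seq_len(n_sensors))
    events <- expand.grid(sensor = sensors,
                          event = seq_len(events_per_sensor),
                          stringsAsFactors = FALSE)
    events$time <- as.POSIXct("2019-06-01 10:00:00", tz = "UTC") +
      (events$event - 1) * 7 * 86400
    richness <- with_seed(rs, sample(1:10, nrow(events), replace = TRUE))
    recs <- list()
    for (i in seq_len(nrow(events))) {
      sc <- soundscape_config(rate = rate, clip_seconds = clip_seconds,
                              richness_coupling = coupled,
                              seed = derive_seed(rs, i))
      for (o in offsets) {
        recs[[length(recs) + 1L]] <-
          generate_recording(events$time[i] + o, sc,
                             richness = richness[i],
                             sensor_id = events$sensor[i])
      }
    }
    series <- aci_batch(recs)
    linked <- align_aci(series, events)
    linked$richness <- as.numeric(scale(richness))
    f <- fit_link_lmm(linked, "richness", resolution)
    rows[[r]] <- data.frame(rep = r, slope = f$slope, p = f$p,
                            r2_marginal = f$r2_marginal)
  }
  do.call(rbind, rows)
}
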