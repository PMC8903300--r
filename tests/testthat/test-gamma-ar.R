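# Gamma AR simulator, MCMC fitter, and scenario predictions.

test_that("model simulator is deterministic and hits its marginal moments", {
  tp <- list(mu_alpha = -1, sigma_alpha = 0, beta = numeric(0),
             phi = numeric(0), k = 8)
  s1 <- simulate_from_model(tp, 2, 500, L = 0, seed = 5,
                            parameterization = "mean")
  s2 <- simulate_from_model(tp, 2, 500, L = 0, seed = 5,
                            parameterization = "mean")
  expect_identical(s1$y, s2$y)

  # intercept-only: sample mean approaches the marginal mean e^mu_alpha
  expect_equal(mean(s1$y), exp(-1), tolerance = 0.02)
  # same under the rate reading, where the mean is k e^-eta
  s3 <- simulate_from_model(tp, 2, 2000, L = 0, seed = 6,
                            parameterization = "rate")
  expect_equal(mean(s3$y), 8 * exp(1), tolerance = 0.05 * 8 * exp(1))

  # gamma CV = 1/sqrt(k): dispersion vanishes as k grows
  tp_big <- tp; tp_big$k <- 1e4
  s4 <- simulate_from_model(tp_big, 1, 2000, L = 0, seed = 7,
                            parameterization = "mean")
  expect_lt(var(s4$y) / mean(s4$y)^2, 2e-4)

  # explosive AR aborts with a diagnostic instead of returning garbage
  tp_bad <- list(mu_alpha = 2, sigma_alpha = 0, beta = numeric(0),
                 phi = 3, k = 5)
  expect_error(
    simulate_from_model(tp_bad, 1, 500, L = 1, seed = 8,
                        parameterization = "mean",
                        ar_transform = "identity"),
    "diverged")
  expect_error(simulate_from_model(tp, 1, 100, L = 2, seed = 1), "phi")
})

test_that("posterior recovers planted effects and matches a GLM oracle", {
  tp <- list(mu_alpha = -1, sigma_alpha = 0.2, beta = c(0.3, -0.2),
             phi = numeric(0), k = 20)
  set.seed(51)
  X <- matrix(rnorm(150 * 2), ncol = 2)
  sim <- simulate_from_model(tp, 2, 150, X = X, L = 0, seed = 51,
                             parameterization = "mean")
  fit <- suppressWarnings(
    fit_gamma_ar(sim, L = 0, parameterization = "mean", chains = 2,
                 iter = 700, warmup = 300, seed = 52))
  expect_s3_class(fit, "gamma_ar")
  expect_lt(max(fit$rhat, na.rm = TRUE), 1.1)

  # planted signs recovered with high posterior probability
  expect_gt(mean(fit$draws[, "beta[1]"] > 0), 0.95)
  expect_gt(mean(fit$draws[, "beta[2]"] < 0), 0.95)

  # with L = 0 and large k the posterior agrees with the log-link gamma
  # GLM (an independent likelihood maximizer) within 2 SE
  df <- data.frame(y = sim$y, x1 = sim$X[, 1], x2 = sim$X[, 2],
                   sensor = sim$sensor)
  or <- glm(y ~ sensor + x1 + x2, family = Gamma(link = "log"), data = df)
  se <- summary(or)$coefficients
  expect_lt(abs(mean(fit$draws[, "beta[1]"]) - se["x1", "Estimate"]),
            2 * se["x1", "Std. Error"])
  expect_lt(abs(mean(fit$draws[, "beta[2]"]) - se["x2", "Estimate"]),
            2 * se["x2", "Std. Error"])

  # posterior predictive draws live on the gamma's positive support
  yr <- simulate(fit, nsim = 3, seed = 1)
  expect_true(all(yr > 0))
  expect_equal(dim(yr), c(length(fit$y), 3))

  # summary/coef/print surface the parameters
  s <- summary(fit)
  expect_true(all(c("beta[1]", "k", "mu_alpha") %in% s$parameter))
  expect_true(all(s$hdi_lower <= s$map & s$map <= s$hdi_upper))
  expect_named(coef(fit)["k"], "k")
})

test_that("HDI and MAP summaries match brute-force oracles", {
  set.seed(53)
  draws <- rgamma(4000, shape = 3, rate = 2)  # skewed, unimodal
  h <- hdi(draws, 0.95)
  expect_equal(unname(h), brute_force_hdi(draws, 0.95), tolerance = 1e-10)
  expect_lt(h["upper"] - h["lower"],
            diff(quantile(draws, c(0.025, 0.975))))  # narrower than ETI
  m <- map_estimate(draws)
  expect_gt(m, h["lower"]); expect_lt(m, h["upper"])
  expect_equal(m, 1, tolerance = 0.15)  # gamma(3,2) mode = (3-1)/2
})

test_that("scenario predictions respect planted signs and stored scaling", {
  tp <- list(mu_alpha = -1, sigma_alpha = 0.1, beta = 0.4,
             phi = numeric(0), k = 15)
  set.seed(54)
  sim <- simulate_from_model(tp, 2, 150, X = matrix(rnorm(150), ncol = 1),
                             L = 0, seed = 54, parameterization = "mean")
  fit <- suppressWarnings(
    fit_gamma_ar(sim, L = 0, parameterization = "mean", chains = 2,
                 iter = 600, warmup = 250, seed = 55))
  pr <- predict_scenarios(fit, matrix(c(-1, 1), ncol = 1))
  expect_equal(nrow(pr), 2)
  expect_true(all(pr$hdi_lower <= pr$map & pr$map <= pr$hdi_upper))
  # positive beta: the high scenario exceeds the low one in >95% of draws
  d <- attr(pr, "draws")
  expect_gt(mean(d[, 2] > d[, 1]), 0.95)
  # predictions restore the 0.55 offset
  expect_gt(min(pr$map), 0.55)
  expect_error(predict_scenarios(fit, matrix(0, 1, 3)), "columns")
})

test_that("predictions are invariant to where the scaling happens", {
  # build a microclimate design so the stored scaler is exercised
  t0 <- as.POSIXct("2019-06-15", tz = "UTC")
  n <- 300
  times <- t0 + (0:(n - 1)) * 600
  set.seed(56)
  mc <- data.frame(sensor_id = "A", time = times,
                   surface_temp = 15 + cumsum(rnorm(n, sd = 0.3)),
                   soil_temp = 14 + cumsum(rnorm(n, sd = 0.1)),
                   soil_moisture = pmin(1, pmax(0, 0.25 + cumsum(rnorm(n, sd = 0.002)))),
                   light = 0)
  s <- filter_aci(aci_series(rep("A", n), times, runif(n, 0.56, 0.8)))
  md <- build_microclimate_design(s, mc)
  fit <- suppressWarnings(
    fit_gamma_ar(md, L = 0, parameterization = "mean", chains = 1,
                 iter = 500, warmup = 250, seed = 57))
  scen <- data.frame(soil_moisture = 0.25, soil_temp = 14,
                     surface_temp = 16, dT30 = 2)
  p1 <- predict_scenarios(fit, scen)
  p2 <- predict_scenarios(fit, md$make_X(scen))  # pre-built design row
  expect_equal(p1$map, p2$map, tolerance = 1e-12)
  expect_equal(p1$hdi_lower, p2$hdi_lower, tolerance = 1e-12)
})
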