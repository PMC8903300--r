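# Hierarchical Bayesian gamma regression with an autoregressive term,
# sampled by MCMC (JAGS). The linear predictor is
#   eta_it = alpha_i + X_it beta + sum_l phi_l g(y_(i,t-l))
# with g = log (default) or identity, sensor intercepts
# alpha_i ~ N(mu_alpha, sigma_alpha^2), coefficients beta_j ~ N(0,
# sigma_beta_j^2), and a gamma likelihood with shape k:
#   rate parameterization:  y ~ Gamma(shape = k, rate = e^eta)
#   mean parameterization:  y ~ Gamma(shape = k, rate = k e^-eta)

default_gamma_ar_priors <- function() {
  list(mu_alpha_sd = 5,    # normal(0, sd) on the global intercept
       sigma_sd = 1,       # half-normal(0, sd) on sigma_alpha and sigma_beta
       phi_sd = 0.5,       # normal(0, sd) on each AR coefficient
       k_rate = 1)         # exponential(rate) on the gamma shape
}

build_jags_model <- function(P, L, parameterization, priors) {
  lik <- if (parameterization == "rate")
    "y[t] ~ dgamma(k, exp(eta[t]))"
  else
    "y[t] ~ dgamma(k, k * exp(-eta[t]))"
  eta <- "alpha[sensor[t]]"
  if (P > 0) eta <- paste0(eta, " + inprod(X[t,], beta)")
  if (L > 0) eta <- paste0(eta, " + inprod(Z[t,], phi)")
  beta_block <- if (P > 0) sprintf("
  for (j in 1:%d) {
    beta[j] ~ dnorm(0, 1 / (sigma_beta[j] * sigma_beta[j]))
    sigma_beta[j] ~ dnorm(0, %g) T(0,)
  }", P, 1 / priors$sigma_sd^2) else ""
  phi_block <- if (L > 0) sprintf("
  for (l in 1:%d) { phi[l] ~ dnorm(0, %g) }",
                                  L, 1 / priors$phi_sd^2) else ""
  sprintf("
model {
  for (t in 1:N) {
    %s
    eta[t] <- %s
  }
  for (i in 1:S) { alpha[i] ~ dnorm(mu_alpha, 1 / (sigma_alpha * sigma_alpha)) }
  mu_alpha ~ dnorm(0, %g)
  sigma_alpha ~ dnorm(0, %g) T(0,)%s%s
  k ~ dexp(%g)
}", lik, eta, 1 / priors$mu_alpha_sd^2, 1 / priors$sigma_sd^2,
      beta_block, phi_block, priors$k_rate)
}

# lagged-response matrix Z (g-transformed), dropping rows without a complete
# within-sensor lag history of consecutive time steps
build_lag_matrix <- function(data, L, g) {
  n <- length(data$y)
  if (L == 0)
    return(list(Z = matrix(numeric(0), n, 0), keep = rep(TRUE, n)))
  Z <- matrix(NA_real_, n, L)
  tt <- as.numeric(data$time)
  for (s in levels(data$sensor)) {
    rows <- which(data$sensor == s)
    rows <- rows[order(tt[rows])]
    for (l in seq_len(L)) {
      ok <- seq_along(rows) > l
      src <- rows[which(ok) - l]
      gap_free <- abs(tt[rows[ok]] - tt[src] - l * data$step) < data$step / 2
      dest <- rows[ok][gap_free]
      Z[dest, l] <- g(data$y[src[gap_free]])
    }
  }
  keep <- complete.cases(Z)
  list(Z = Z, keep = keep)
}

#' Fit the hierarchical gamma autoregressive model
#'
#' Samples the joint posterior of the sensor intercepts, predictor
#' coefficients, AR coefficients and gamma shape by MCMC. Rows lacking a
#' complete within-sensor lag history (including rows after a time gap) are
#' dropped rather than imputed. Convergence is checked with the split-chain
#' potential scale reduction factor; a fit with any R-hat above 1.05 is
#' flagged (`converged = FALSE`) with a warning, never silently returned.
#'
#' @param data a [soil_model_data()] (from the design builders or
#'   [simulate_from_model()]).
#' @param L autoregressive order (see [select_max_lag()]).
#' @param parameterization `"rate"` for the literal shape-rate reading
#'   `Gamma(k, e^eta)` (default) or `"mean"` for mean `e^eta` with shape `k`.
#' @param ar_transform transform `g` of the lagged response: `"log"`
#'   (default; lags act on the same scale as the log-linked predictor) or
#'   `"identity"`.
#' @param priors list overriding any of `mu_alpha_sd`, `sigma_sd`, `phi_sd`,
#'   `k_rate` (see `default_gamma_ar_priors` in the sources).
#' @param chains,iter,warmup MCMC settings (default 4 chains x 2000
#'   iterations including 1000 warm-up).
#' @param seed integer seed driving all chains.
#' @param offset value that was subtracted from the ACI response; stored so
#'   predictions can restore it (default 0.55).
#' @param quiet suppress JAGS progress output.
#' @return object of class `gamma_ar`: posterior draws, diagnostics and the
#'   training data. Methods: `print`, `summary`, `coef`, `predict`
#'   (scenario predictions), `simulate` (posterior predictive).
#' @export
fit_gamma_ar <- function(data, L = 0,
                         parameterization = c("rate", "mean"),
                         ar_transform = c("log", "identity"),
                         priors = list(), chains = 4, iter = 2000,
                         warmup = 1000, seed = 1L, offset = 0.55,
                         quiet = TRUE) {
  stopifnot(inherits(data, "soil_model_data"), L >= 0, iter > warmup)
  parameterization <- match.arg(parameterization)
  ar_transform <- match.arg(ar_transform)
  priors <- utils::modifyList(default_gamma_ar_priors(), priors)
  g <- if (ar_transform == "log") log else identity

  lag <- build_lag_matrix(data, L, g)
  y <- data$y[lag$keep]
  X <- data$X[lag$keep, , drop = FALSE]
  Z <- lag$Z[lag$keep, , drop = FALSE]
  sensor <- as.integer(droplevels(data$sensor[lag$keep]))
  S <- max(sensor)
  P <- ncol(X)
  N <- length(y)
  if (N < 10) stop("too few rows (", N, ") after lag construction")

  # centre the lagged regressor: removes the strong intercept-phi
  # collinearity (g(y) has a nonzero mean) and is undone on the draws below,
  # so the reported parameters are on the uncentred scale of the model
  zc <- if (L > 0) colMeans(Z) else numeric(0)
  jdata <- list(y = y, sensor = sensor, N = N, S = S)
  if (P > 0) jdata$X <- X
  if (L > 0) jdata$Z <- sweep(Z, 2, zc, "-")

  # moment-based initial values keep early adaptation away from overflow
  k0 <- max(0.5, (mean(y) / sd(y))^2)
  alpha0 <- if (parameterization == "rate") log(k0 / mean(y)) else log(mean(y))
  inits <- lapply(seq_len(chains), function(ch) {
    ini <- list(mu_alpha = alpha0, alpha = rep(alpha0, S), sigma_alpha = 0.5,
                k = k0,
                .RNG.name = "base::Mersenne-Twister",
                .RNG.seed = derive_seed(seed, ch))
    if (P > 0) { ini$beta <- rep(0, P); ini$sigma_beta <- rep(0.5, P) }
    if (L > 0) ini$phi <- rep(0, L)
    ini
  })

  model_str <- build_jags_model(P, L, parameterization, priors)
  n_adapt <- min(500, warmup)
  run <- function() {
    jm <- rjags::jags.model(textConnection(model_str), data = jdata,
                            inits = inits, n.chains = chains,
                            n.adapt = n_adapt, quiet = quiet)
    if (warmup > n_adapt) update(jm, warmup - n_adapt,
                                 progress.bar = "none")
    monitors <- c("alpha", "mu_alpha", "sigma_alpha", "k",
                  if (P > 0) c("beta", "sigma_beta"), if (L > 0) "phi")
    rjags::coda.samples(jm, monitors, n.iter = iter - warmup,
                        progress.bar = "none")
  }
  mcmc <- if (quiet) suppressWarnings(run()) else run()

  uncentre <- function(m) {
    if (L == 0) return(m)
    shift <- as.numeric(par_col(m, "phi", L) %*% zc)
    for (cn in c(paste0("alpha[", seq_len(S), "]"),
                 if (S == 1) "alpha", "mu_alpha"))
      if (cn %in% colnames(m)) m[, cn] <- m[, cn] - shift
    m
  }
  mcmc <- coda::as.mcmc.list(lapply(mcmc, function(ch)
    coda::mcmc(uncentre(as.matrix(ch)), start = stats::start(ch),
               thin = coda::thin(ch))))
  draws <- do.call(rbind, lapply(mcmc, as.matrix))
  rhat <- vapply(colnames(draws), function(p)
    split_rhat(sapply(mcmc, function(ch) as.matrix(ch)[, p])), numeric(1))
  converged <- all(is.na(rhat) | rhat < 1.05)
  if (!converged)
    warning("chains not converged: max R-hat = ",
            round(max(rhat, na.rm = TRUE), 3))

  fit <- structure(list(
    draws = draws, mcmc = mcmc, rhat = rhat, converged = converged,
    y = y, X = X, Z = Z, sensor = sensor,
    sensor_levels = levels(droplevels(data$sensor[lag$keep])),
    make_X = data$make_X, L = L,
    parameterization = parameterization, ar_transform = ar_transform,
    ar_plugin = if (L > 0) colMeans(Z) else numeric(0),
    priors = priors, offset = offset,
    settings = list(chains = chains, iter = iter, warmup = warmup,
                    seed = seed)),
    class = "gamma_ar")
  fit
}

#' @export
print.gamma_ar <- function(x, ...) {
  cat(sprintf(paste0(
    "Hierarchical gamma AR model (%s parameterization, g = %s)\n",
    "  %d obs, %d sensors, %d predictors, L = %d\n",
    "  %d chains x %d draws; max R-hat %.3f (%s)\n"),
    x$parameterization, x$ar_transform, length(x$y),
    length(x$sensor_levels), ncol(x$X), x$L,
    x$settings$chains, x$settings$iter - x$settings$warmup,
    max(x$rhat, na.rm = TRUE),
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
summary.gamma_ar <- function(object, prob = 0.95, ...) {
  d <- object$draws
  out <- data.frame(
    parameter = colnames(d),
    mean = colMeans(d),
    sd = apply(d, 2, sd),
    map = apply(d, 2, map_estimate),
    hdi_lower = apply(d, 2, function(v) hdi(v, prob)[1]),
    hdi_upper = apply(d, 2, function(v) hdi(v, prob)[2]),
    rhat = object$rhat[colnames(d)],
    row.names = NULL)
  class(out) <- c("summary.gamma_ar", "data.frame")
  out
}

#' @export
print.summary.gamma_ar <- function(x, ...) {
  print.data.frame(x, digits = 3, row.names = FALSE)
  invisible(x)
}

#' @export
coef.gamma_ar <- function(object, ...) colMeans(object$draws)

#' Plot posterior summaries of a gamma AR fit
#'
#' Dot-and-interval plot of the posterior MAP and 95% HDI per parameter.
#'
#' @param x a `gamma_ar` fit.
#' @param pars optional character vector restricting the parameters shown.
#' @param ... passed to [graphics::plot()].
#' @export
plot.gamma_ar <- function(x, pars = NULL, ...) {
  s <- summary(x)
  if (!is.null(pars)) s <- s[s$parameter %in% pars, , drop = FALSE]
  n <- nrow(s)
  graphics::plot(s$map, seq_len(n), xlim = range(s$hdi_lower, s$hdi_upper),
                 yaxt = "n", ylab = "", xlab = "posterior value",
                 pch = 19, ...)
  graphics::segments(s$hdi_lower, seq_len(n), s$hdi_upper, seq_len(n))
  graphics::axis(2, at = seq_len(n), labels = s$parameter, las = 1,
                 cex.axis = 0.8)
  graphics::abline(v = 0, lty = 3)
  invisible(s)
}

# linear predictor draws for the training rows: draws x N matrix
eta_draws <- function(fit) {
  d <- fit$draws
  P <- ncol(fit$X); L <- fit$L
  eta <- d[, paste0("alpha[", fit$sensor, "]"), drop = FALSE]
  if (P == 1) eta <- eta + outer(d[, "beta"], as.numeric(fit$X))
  if (P > 1) eta <- eta + d[, paste0("beta[", seq_len(P), "]")] %*% t(fit$X)
  if (L == 1) eta <- eta + outer(d[, "phi"], as.numeric(fit$Z))
  if (L > 1) eta <- eta + d[, paste0("phi[", seq_len(L), "]")] %*% t(fit$Z)
  eta
}

par_col <- function(d, base, n) {
  if (n == 1 && base %in% colnames(d)) d[, base, drop = FALSE]
  else d[, paste0(base, "[", seq_len(n), "]"), drop = FALSE]
}

#' Posterior predictive simulation
#'
#' Draws replicate responses for the training rows from the fitted gamma
#' law, one replicate per posterior draw (thinned to `nsim`).
#'
#' @param object a `gamma_ar` fit.
#' @param nsim number of replicate datasets.
#' @param seed integer seed.
#' @param ... unused.
#' @return matrix with `length(object$y)` rows and `nsim` columns.
#' @export
simulate.gamma_ar <- function(object, nsim = 1, seed = NULL, ...) {
  eta <- eta_draws(object)
  idx <- round(seq(1, nrow(eta), length.out = nsim))
  k <- object$draws[, "k"]
  sim1 <- function(i) gamma_draw(ncol(eta), k[i], eta[i, ],
                                 object$parameterization)
  out <- if (is.null(seed)) vapply(idx, sim1, numeric(ncol(eta)))
         else with_seed(seed, vapply(idx, sim1, numeric(ncol(eta))))
  matrix(out, ncol = nsim)
}

#' @export
residuals.gamma_ar <- function(object, ...) {
  k <- mean(object$draws[, "k"])
  mu <- colMeans(gamma_mean(object$draws[, "k"], eta_draws(object),
                            object$parameterization))
  (object$y - mu) / (mu / sqrt(k))  # Pearson, gamma CV = 1/sqrt(k)
}

#' Scenario predictions with MAP and highest density interval
#'
#' For each scenario the linear predictor is assembled per posterior draw
#' using the global intercept `mu_alpha` (a typical sensor), the scenario's
#' design row, and the AR contribution fixed at its plug-in training mean.
#' The prediction is the expected response plus the stored offset (0.55),
#' summarized by its kernel-density MAP and narrowest 95% HDI.
#'
#' @param fit a `gamma_ar` fit.
#' @param scenarios data.frame of predictor values on their original scales
#'   (passed through the design's stored scaling), or a numeric matrix of
#'   ready-made design rows with one row per scenario.
#' @param prob HDI probability mass.
#' @return data.frame with one row per scenario: `map`, `hdi_lower`,
#'   `hdi_upper`, `mean`; prediction draws attached as attribute `"draws"`.
#' @export
predict_scenarios <- function(fit, scenarios, prob = 0.95) {
  stopifnot(inherits(fit, "gamma_ar"))
  Xs <- if (is.matrix(scenarios)) scenarios
        else if (!is.null(fit$make_X)) fit$make_X(scenarios)
        else stop("model has no stored design recipe; pass a design matrix")
  if (ncol(Xs) != ncol(fit$X))
    stop("scenario design has ", ncol(Xs), " columns; model expects ",
         ncol(fit$X))
  d <- fit$draws
  P <- ncol(fit$X); L <- fit$L
  ar_term <- if (L > 0)
    as.numeric(par_col(d, "phi", L) %*% fit$ar_plugin) else 0
  base <- d[, "mu_alpha"] + ar_term
  pred <- vapply(seq_len(nrow(Xs)), function(s) {
    eta <- base + if (P > 0)
      as.numeric(par_col(d, "beta", P) %*% as.numeric(Xs[s, ])) else 0
    gamma_mean(d[, "k"], eta, fit$parameterization) + fit$offset
  }, numeric(nrow(d)))
  pred <- matrix(pred, nrow = nrow(d))
  out <- data.frame(
    scenario = seq_len(nrow(Xs)),
    map = apply(pred, 2, map_estimate),
    hdi_lower = apply(pred, 2, function(v) hdi(v, prob)[1]),
    hdi_upper = apply(pred, 2, function(v) hdi(v, prob)[2]),
    mean = colMeans(pred))
  attr(out, "draws") <- pred
  out
}

#' @export
predict.gamma_ar <- function(object, newdata, prob = 0.95, ...) {
  predict_scenarios(object, newdata, prob = prob)
}
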