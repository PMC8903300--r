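# Generative counterpart of the hierarchical gamma autoregressive model,
# used for parameter-recovery and coverage validation of the fitter.

# expected response given the linear predictor, per parameterization
gamma_mean <- function(k, eta, parameterization) {
  switch(parameterization,
         rate = k * exp(-eta),   # Gamma(shape = k, rate = e^eta)
         mean = exp(eta))        # Gamma(shape = k, rate = k e^-eta)
}

gamma_draw <- function(n, k, eta, parameterization) {
  switch(parameterization,
         rate = rgamma(n, shape = k, rate = exp(eta)),
         mean = rgamma(n, shape = k, rate = k * exp(-eta)))
}

#' Simulate responses from the hierarchical gamma AR model
#'
#' Draws sensor intercepts `alpha_i ~ N(mu_alpha, sigma_alpha^2)` (unless
#' supplied), then generates each sensor's series sequentially: the first
#' `L` values are initialized at the marginal mean implied by the linear
#' predictor without the AR term; thereafter
#' `eta_t = alpha_i + X_t beta + sum_l phi_l g(y_(t-l))` with `g` the log
#' (default) or identity transform, and `y_t` is drawn from the gamma law
#' under the chosen parameterization.
#'
#' @param true_params list with `mu_alpha`, `sigma_alpha`, `beta` (length-p
#'   vector), `phi` (length-L vector, possibly empty), `k` (> 0), and
#'   optionally `alpha` (length `n_sensors`, drawn if absent).
#' @param n_sensors,n_times panel dimensions; `n_times` must exceed `L`.
#' @param X design matrix with `n_times` rows (recycled per sensor) or
#'   `n_sensors * n_times` rows.
#' @param L autoregressive order.
#' @param seed integer seed.
#' @param parameterization `"rate"` (literal shape-rate reading, default) or
#'   `"mean"` (mean `e^eta`, shape `k`).
#' @param ar_transform `"log"` (default) or `"identity"`.
#' @return a [soil_model_data()] with a `truth` attribute recording all
#'   parameters used.
#' @export
simulate_from_model <- function(true_params, n_sensors, n_times, X = NULL,
                                L = 0, seed = 1L,
                                parameterization = c("rate", "mean"),
                                ar_transform = c("log", "identity")) {
  parameterization <- match.arg(parameterization)
  ar_transform <- match.arg(ar_transform)
  stopifnot(n_times > L, true_params$k > 0)
  if (!is.null(true_params$sigma_alpha)) stopifnot(true_params$sigma_alpha >= 0)
  beta <- as.numeric(true_params$beta %||% numeric(0))
  phi <- as.numeric(true_params$phi %||% numeric(0))
  if (length(phi) != L) stop("length(phi) must equal L")
  if (is.null(X)) X <- matrix(numeric(0), nrow = n_times, ncol = 0)
  X <- as.matrix(X)
  if (nrow(X) == n_times) X <- X[rep(seq_len(n_times), n_sensors), , drop = FALSE]
  stopifnot(nrow(X) == n_sensors * n_times, ncol(X) == length(beta))
  g <- if (ar_transform == "log") log else identity
  k <- true_params$k

  res <- with_seed(seed, {
    alpha <- true_params$alpha %||%
      rnorm(n_sensors, true_params$mu_alpha, true_params$sigma_alpha)
    y <- numeric(n_sensors * n_times)
    for (i in seq_len(n_sensors)) {
      rows <- (i - 1L) * n_times + seq_len(n_times)
      eta0 <- alpha[i] + as.numeric(X[rows, , drop = FALSE] %*% beta)
      yi <- numeric(n_times)
      init <- gamma_mean(k, eta0[seq_len(max(L, 1L))], parameterization)
      if (L > 0) yi[seq_len(L)] <- init[seq_len(L)]
      start <- if (L > 0) L + 1L else 1L
      for (t in start:n_times) {
        ar <- if (L > 0) sum(phi * g(yi[t - seq_len(L)])) else 0
        eta <- eta0[t] + ar
        yi[t] <- gamma_draw(1, k, eta, parameterization)
        if (!is.finite(yi[t]) || yi[t] > 1e8 || yi[t] <= 0)
          stop("simulated series diverged (non-stationary phi?) at t = ", t)
      }
      y[rows] <- yi
    }
    list(alpha = alpha, y = y)
  })
  md <- soil_model_data(res$y, X,
                        sensor = rep(seq_len(n_sensors), each = n_times),
                        time = rep(seq_len(n_times), n_sensors), step = 1)
  attr(md, "truth") <- c(true_params[setdiff(names(true_params), "alpha")],
                         list(alpha = res$alpha, L = L,
                              parameterization = parameterization,
                              ar_transform = ar_transform))
  md
}

`%||%` <- function(a, b) if (is.null(a)) b else a
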