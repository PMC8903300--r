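# Lag diagnostics run before the hierarchical model: cross-correlation of
# pre-whitened differenced series, and choice of the autoregressive order
# from the residual autocorrelation of an auxiliary log-response mixed model.

#' Cross-correlation between a covariate and a response by lag
#'
#' Both series are first-differenced; an autoregressive filter fitted to the
#' differenced covariate (order chosen by AIC) is applied to both
#' (pre-whitening); the correlation is then reported for each lag in
#' `[-max_lag, max_lag]`. Sign convention: at lag `l >= 0` the response
#' `y_t` is correlated with the past covariate `x_(t-l)`; negative lags
#' correlate `y_t` with the future covariate `x_(t+|l|)` (a covariate
#' logged shortly after the response shows up at lag -1).
#'
#' @param x covariate series (numeric).
#' @param y response series, aligned with `x`.
#' @param max_lag maximum lag magnitude.
#' @param order_max maximum AR order tried for the pre-whitening filter.
#' @return data.frame with columns `lag` and `ccf`.
#' @export
cross_correlation_lags <- function(x, y, max_lag = 10, order_max = 10) {
  x <- as.numeric(x); y <- as.numeric(y)
  stopifnot(length(x) == length(y))
  if (length(x) <= 3 * max_lag)
    stop("series too short for max_lag = ", max_lag)
  if (sd(x) == 0 || sd(y) == 0)
    stop("constant series: cross-correlation undefined")
  dx <- diff(x); dy <- diff(y)
  fit <- ar(dx, order.max = order_max, aic = TRUE)
  whiten <- function(v) {
    if (fit$order == 0) return(v)
    w <- as.numeric(filter(v, c(1, -fit$ar), method = "convolution",
                           sides = 1))
    w[!is.na(w)]
  }
  wx <- whiten(dx); wy <- whiten(dy)
  n <- length(wx)
  lags <- (-max_lag):max_lag
  cc <- vapply(lags, function(l) {
    if (l >= 0) cor(wy[(1 + l):n], wx[1:(n - l)])
    else cor(wy[1:(n + l)], wx[(1 - l):n])
  }, numeric(1))
  data.frame(lag = lags, ccf = cc)
}

#' Auxiliary log-response linear mixed model
#'
#' Fits `log(y) ~ X` with a random sensor intercept by REML; its residuals
#' feed the autocorrelation plot from which the AR order of the hierarchical
#' model is chosen. A singular random-intercept fit falls back to a plain
#' linear model (with a message).
#'
#' @param data a [soil_model_data()].
#' @return list with `residuals` (within-sensor residuals in row order) and
#'   the underlying `model`.
#' @export
fit_auxiliary_lmm <- function(data) {
  stopifnot(inherits(data, "soil_model_data"))
  df <- data.frame(ly = log(data$y), sensor = data$sensor)
  Xd <- df[0]
  if (ncol(data$X) > 0) {
    Xd <- as.data.frame(data$X)
    names(Xd) <- paste0("x", seq_len(ncol(data$X)))
    df <- cbind(df, Xd)
  }
  rhs <- if (ncol(Xd)) paste(names(Xd), collapse = " + ") else "1"
  form <- stats::as.formula(paste("ly ~", rhs))
  model <- tryCatch(
    nlme::lme(form, random = ~ 1 | sensor, data = df, method = "REML"),
    error = function(e) {
      message("random-intercept fit failed (", conditionMessage(e),
              "); falling back to a fixed-effects fit")
      lm(form, data = df)
    })
  list(residuals = as.numeric(resid(model)), model = model)
}

#' Residual autocorrelation function
#'
#' @param residuals numeric residual series in time order.
#' @param lag_max largest lag computed.
#' @return data.frame with columns `lag` (1..lag_max) and `acf`.
#' @export
residual_acf <- function(residuals, lag_max = 20) {
  a <- acf(residuals, lag.max = lag_max, plot = FALSE)$acf[-1]
  data.frame(lag = seq_along(a), acf = as.numeric(a))
}

#' Choose the maximum autoregressive lag from a residual ACF
#'
#' Returns the largest lag `<= candidate_max` that is a local maximum of the
#' ACF and exceeds `threshold`. Lag 1 counts as a (boundary) local maximum
#' when the ACF decreases from it, so a plain AR(1)-like geometric decay
#' yields `L = 1`. The criterion mirrors a judgment call made on an ACF
#' plot, so a manual `override` is supported. With no qualifying lag, 1 is
#' returned with a warning.
#'
#' @param acf_table data.frame from [residual_acf()] (columns `lag`, `acf`)
#'   or a bare numeric vector of ACF values at lags 1, 2, ....
#' @param candidate_max largest admissible lag.
#' @param threshold minimum ACF value for a lag to qualify (default 0.05).
#' @param override manually chosen `L`, returned as-is when given.
#' @return integer lag order `L`.
#' @export
select_max_lag <- function(acf_table, candidate_max = 12, threshold = 0.05,
                           override = NULL) {
  if (!is.null(override)) return(as.integer(override))
  a <- if (is.data.frame(acf_table)) acf_table$acf else as.numeric(acf_table)
  K <- min(length(a), candidate_max)
  if (K < 1) stop("empty ACF")
  is_locmax <- vapply(seq_len(K), function(l) {
    left_ok <- l == 1 || a[l] >= a[l - 1]
    right_ok <- l == length(a) || a[l] >= a[l + 1]
    left_ok && right_ok
  }, logical(1))
  qual <- which(is_locmax & a[seq_len(K)] > threshold)
  if (length(qual) == 0) {
    warning("no local ACF maximum above ", threshold, "; using L = 1")
    return(1L)
  }
  as.integer(max(qual))
}
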