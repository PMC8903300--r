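# Linking acoustic complexity to soil community attributes: ACI extraction
# at three temporal resolutions around each sampling event, and linear
# mixed models of ACI on standardized community attributes.

#' Align an ACI series with soil-sampling events
#'
#' For every sampling event (sensor + timestamp) extracts: `aci_before`,
#' the most recent valid value strictly preceding the event; `aci_1h`, the
#' mean of valid values within +/- 30 min of the event; and `aci_24h`, the
#' mean within +/- 12 h. Windows with no valid value yield `NA`.
#'
#' @param series a valid-filtered [aci_series()].
#' @param events data.frame with columns `sensor` and `time` (POSIXct).
#' @return data.frame with `sample_id`, `sensor`, `time`, `aci_before`,
#'   `aci_1h`, `aci_24h`.
#' @export
align_aci <- function(series, events) {
  stopifnot(all(c("sensor", "time") %in% names(events)))
  s <- series[!is.na(series$valid) & series$valid, , drop = FALSE]
  t_ev <- as.POSIXct(events$time, tz = "UTC")
  out <- data.frame(sample_id = seq_len(nrow(events)),
                    sensor = as.character(events$sensor), time = t_ev,
                    aci_before = NA_real_, aci_1h = NA_real_,
                    aci_24h = NA_real_)
  for (i in seq_len(nrow(out))) {
    si <- s[s$sensor_id == out$sensor[i], , drop = FALSE]
    if (nrow(si) == 0) next
    dt <- as.numeric(si$time) - as.numeric(out$time[i])
    before <- which(dt < 0)
    if (length(before))
      out$aci_before[i] <- si$value[before[which.max(dt[before])]]
    in1h <- abs(dt) <= 1800
    if (any(in1h)) out$aci_1h[i] <- mean(si$value[in1h])
    in24h <- abs(dt) <= 43200
    if (any(in24h)) out$aci_24h[i] <- mean(si$value[in24h])
  }
  out
}

#' Attach standardized community attributes to aligned samples
#'
#' Standardizes each attribute (abundance, the three Hill numbers, the
#' first two NMDS axes) to zero mean and unit variance across the linked
#' set and binds them to the ACI columns.
#'
#' @param aligned output of [align_aci()], one row per community sample in
#'   the same order as `table`'s rows.
#' @param table the matching [community_table()].
#' @param nmds optional `soil_nmds` for the same samples (first two axes
#'   used); computed from `table` when `NULL`.
#' @param seed seed for the NMDS when it must be computed.
#' @return data.frame of linked samples with standardized attribute columns
#'   `abundance`, `richness`, `shannon`, `simpson`, `NMDS1`, `NMDS2`.
#' @export
link_community <- function(aligned, table, nmds = NULL, seed = 1L) {
  stopifnot(nrow(aligned) == nrow(table$counts))
  prof <- diversity_profile(table)
  if (is.null(nmds)) nmds <- nmds_communities(table, seed = seed)
  attrs <- cbind(prof[c("abundance", "richness", "shannon", "simpson")],
                 NMDS1 = nmds$coordinates[, 1],
                 NMDS2 = nmds$coordinates[, 2])
  z <- as.data.frame(scale_columns(as.matrix(attrs)))
  cbind(aligned, z)
}

#' Mixed model of ACI on one standardized community attribute
#'
#' Fits `ACI_resolution ~ attribute` with a random plot (sensor) intercept
#' by REML, returning the slope, its p-value, marginal and conditional R^2,
#' and a prediction curve with a pointwise 95% confidence band over the
#' attribute range.
#'
#' @param linked output of [link_community()].
#' @param attribute attribute column name (e.g. `"richness"`).
#' @param resolution one of `"aci_before"`, `"aci_1h"`, `"aci_24h"`.
#' @param curve_points grid size of the effect curve.
#' @return list of class `link_lmm`: `slope`, `se`, `p`, `r2_marginal`,
#'   `r2_conditional`, `curve` (attribute grid, fit, lower, upper), `model`.
#' @export
fit_link_lmm <- function(linked, attribute, resolution = "aci_before",
                         curve_points = 50) {
  stopifnot(attribute %in% names(linked), resolution %in% names(linked))
  df <- data.frame(aci = linked[[resolution]], attr = linked[[attribute]],
                   sensor = factor(linked$sensor))
  df <- df[complete.cases(df), , drop = FALSE]
  if (nrow(df) < 10) stop("fewer than 10 linked samples with data")
  if (nlevels(droplevels(df$sensor)) < 2) stop("need >= 2 plots")
  if (sd(df$attr) == 0) stop("attribute is constant")
  model <- nlme::lme(aci ~ attr, random = ~ 1 | sensor, data = df,
                     method = "REML")
  tab <- summary(model)$tTable
  r2 <- lme_r2(model, df)
  grid <- seq(min(df$attr), max(df$attr), length.out = curve_points)
  fe <- nlme::fixef(model)
  V <- vcov(model)
  Xg <- cbind(1, grid)
  fit_g <- as.numeric(Xg %*% fe)
  se_g <- sqrt(rowSums((Xg %*% V) * Xg))
  structure(list(
    attribute = attribute, resolution = resolution,
    slope = unname(tab["attr", "Value"]), se = unname(tab["attr", "Std.Error"]),
    p = unname(tab["attr", "p-value"]),
    r2_marginal = unname(r2["marginal"]),
    r2_conditional = unname(r2["conditional"]),
    n = nrow(df),
    curve = data.frame(attr = grid, fit = fit_g,
                       lower = fit_g - qnorm(0.975) * se_g,
                       upper = fit_g + qnorm(0.975) * se_g),
    model = model), class = "link_lmm")
}

#' @export
print.link_lmm <- function(x, ...) {
  cat(sprintf(
    "ACI (%s) ~ %s: slope %+.4f (p = %.3g), R2m = %.3f, R2c = %.3f, n = %d\n",
    x$resolution, x$attribute, x$slope, x$p, x$r2_marginal,
    x$r2_conditional, x$n))
  invisible(x)
}

#' Compare explanatory power across temporal resolutions
#'
#' Descriptive diagnostic: reports marginal R^2 per resolution for one
#' attribute and whether it decreases as the acoustic window moves away
#' from the sampling moment (before >= 1h >= 24h).
#'
#' @param fits list of `link_lmm` fits for the same attribute at different
#'   resolutions.
#' @return list: `table` (resolution, r2_marginal, r2_conditional),
#'   `ordered` (logical: non-increasing away from sampling over the
#'   resolutions present).
#' @export
resolution_contrast <- function(fits) {
  stopifnot(length(fits) >= 1)
  attrs <- unique(vapply(fits, `[[`, character(1), "attribute"))
  if (length(attrs) != 1) stop("fits must share one attribute")
  tab <- data.frame(
    resolution = vapply(fits, `[[`, character(1), "resolution"),
    r2_marginal = vapply(fits, `[[`, numeric(1), "r2_marginal"),
    r2_conditional = vapply(fits, `[[`, numeric(1), "r2_conditional"))
  ord <- c("aci_before", "aci_1h", "aci_24h")
  tab <- tab[order(match(tab$resolution, ord)), , drop = FALSE]
  list(attribute = attrs, table = tab,
       ordered = !is.unsorted(rev(tab$r2_marginal)))
}
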