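# Soil community analysis: Hill-number diversity, Bray-Curtis distances,
# NMDS ordination, stratified PERMANOVA, and seasonal mixed models.

#' Hill number (effective number of equally abundant taxa)
#'
#' With relative abundances `p_i`: `qD = (sum p_i^q)^(1/(1-q))` for
#' `q != 1`, the exponential of Shannon entropy at `q = 1` (entropy limit,
#' `0 log 0 := 0`), and the number of nonzero taxa at `q = 0`.
#'
#' @param counts nonnegative abundance vector with a positive total.
#' @param q diversity order (>= 0): 0 = richness, 1 = Shannon, 2 = Simpson.
#' @return effective taxa count (>= 1 for any non-empty sample).
#' @export
hill_number <- function(counts, q) {
  counts <- as.numeric(counts)
  if (any(counts < 0)) stop("negative counts")
  if (sum(counts) <= 0) stop("empty sample: Hill number undefined")
  if (q < 0) stop("q must be >= 0")
  p <- counts[counts > 0] / sum(counts)
  if (q == 0) return(length(p))
  if (abs(q - 1) < 1e-12) return(exp(-sum(p * log(p))))
  sum(p^q)^(1 / (1 - q))
}

#' Per-sample abundance and diversity profile
#'
#' @param table a [community_table()].
#' @return data.frame with the sample metadata plus `abundance`, `richness`
#'   (0D), `shannon` (1D), `simpson` (2D).
#' @export
diversity_profile <- function(table) {
  stopifnot(inherits(table, "community_table"))
  counts <- table$counts
  data.frame(table$meta,
             abundance = rowSums(counts),
             richness = apply(counts, 1, hill_number, q = 0),
             shannon = apply(counts, 1, hill_number, q = 1),
             simpson = apply(counts, 1, hill_number, q = 2))
}

#' Bray-Curtis distance matrix
#'
#' `d(x, y) = sum |x_i - y_i| / sum (x_i + y_i)`, via [vegan::vegdist()].
#'
#' @param table a [community_table()] or a samples x taxa matrix.
#' @return a `dist` object.
#' @export
bray_curtis <- function(table) {
  counts <- if (inherits(table, "community_table")) table$counts else
    as.matrix(table)
  if (nrow(counts) < 2) stop("need at least two samples")
  if (any(rowSums(counts) == 0))
    stop("all-zero samples: Bray-Curtis distance undefined")
  vegan::vegdist(counts, method = "bray")
}

#' NMDS ordination of community composition
#'
#' Non-metric multidimensional scaling on Bray-Curtis distances via
#' [vegan::metaMDS()] (iterative stress minimization over random restarts).
#'
#' @param table a [community_table()], matrix, or `dist`.
#' @param k embedding dimension (default 3).
#' @param restarts random restarts (default 20).
#' @param seed integer seed; identical seeds give identical stress.
#' @return list of class `soil_nmds`: `coordinates` (samples x k, centered),
#'   `stress` (Kruskal stress-1, 0-1 scale), `k`, `converged`.
#' @export
nmds_communities <- function(table, k = 3, restarts = 20, seed = 1L) {
  d <- if (inherits(table, "dist")) table else bray_curtis(table)
  n <- attr(d, "Size")
  if (k >= n - 1) stop("k must be < n - 1")
  m <- with_seed(seed,
    vegan::metaMDS(d, k = k, trymax = restarts, trace = 0,
                   autotransform = FALSE, wascores = FALSE))
  structure(list(coordinates = scale(m$points, scale = FALSE),
                 stress = m$stress, k = k, converged = m$converged > 0),
            class = "soil_nmds")
}

#' @export
print.soil_nmds <- function(x, ...) {
  cat(sprintf("<soil_nmds> k = %d, stress = %.3f%s\n", x$k, x$stress,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

# one permutation of group labels, shuffling only within strata
permute_within_strata <- function(groups, strata = NULL) {
  idx <- seq_along(groups)
  if (is.null(strata)) return(groups[sample(idx)])
  for (s in unique(strata)) {
    w <- which(strata == s)
    idx[w] <- w[sample(length(w))]
  }
  groups[idx]
}

# pseudo-F and R^2 for one labelling (d2 = squared distance matrix)
permanova_stat <- function(d2, groups) {
  N <- nrow(d2)
  groups <- as.factor(groups)
  a <- nlevels(droplevels(groups))
  ss_total <- sum(d2[upper.tri(d2)]) / N
  ss_within <- 0
  for (g in levels(droplevels(groups))) {
    w <- which(groups == g)
    if (length(w) > 1)
      ss_within <- ss_within +
        sum(d2[w, w][upper.tri(d2[w, w])]) / length(w)
  }
  ss_between <- ss_total - ss_within
  f <- (ss_between / (a - 1)) / (ss_within / (N - a))
  c(F = f, R2 = ss_between / ss_total)
}

#' PERMANOVA with restricted (within-strata) permutations
#'
#' One-way permutational multivariate ANOVA on a distance matrix:
#' `SS_total = (1/N) sum_(i<j) d^2_ij`, within-group sums analogously per
#' group, pseudo-F from the between/within partition. The p-value is the
#' proportion of permutations (group labels shuffled only within each
#' stratum) whose pseudo-F reaches the observed one, counting the observed
#' labelling itself, so the smallest attainable p is `1/(n_perm + 1)`.
#'
#' @param dist a `dist` or square distance matrix.
#' @param groups factor of group labels (>= 2 groups).
#' @param strata optional factor restricting permutations (e.g. sensor).
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @return list of class `soil_permanova`: `F`, `R2`, `p`, `n_perm`.
#' @export
permanova_strata <- function(dist, groups, strata = NULL, n_perm = 1000,
                             seed = 1L) {
  d2 <- as.matrix(dist)^2
  groups <- as.factor(groups)
  stopifnot(nrow(d2) == length(groups))
  if (nlevels(droplevels(groups)) < 2) stop("need at least two groups")
  if (!is.null(strata)) {
    stopifnot(length(strata) == length(groups))
    if (any(table(strata) < 2)) stop("every stratum needs >= 2 samples")
  }
  obs <- permanova_stat(d2, groups)
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      permanova_stat(d2, permute_within_strata(groups, strata))["F"] >=
        obs["F"]
    }, logical(1)))
  })
  structure(list(F = unname(obs["F"]), R2 = unname(obs["R2"]),
                 p = (exceed + 1) / (n_perm + 1), n_perm = n_perm),
            class = "soil_permanova")
}

#' @export
print.soil_permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.3f, R2 = %.3f, p = %.4f (%d permutations)\n",
              x$F, x$R2, x$p, x$n_perm))
  invisible(x)
}

# marginal / conditional R^2 by variance partition for an nlme::lme fit
# with a single random intercept
lme_r2 <- function(model, data) {
  fe <- as.numeric(fitted(model, level = 0))
  var_f <- var(fe)
  vc <- nlme::VarCorr(model)
  var_re <- suppressWarnings(as.numeric(vc["(Intercept)", "Variance"]))
  var_res <- suppressWarnings(as.numeric(vc["Residual", "Variance"]))
  tot <- var_f + var_re + var_res
  c(marginal = var_f / tot, conditional = (var_f + var_re) / tot)
}

#' Seasonal mixed model for one community attribute
#'
#' Fits `attribute ~ season` with a random sensor intercept (REML);
#' abundance and richness are sqrt-transformed first. Returns the
#' season ANOVA row plus marginal R^2 (fixed-effect variance over total)
#' and conditional R^2 (fixed + random over total).
#'
#' @param table a [community_table()].
#' @param attribute one of `"abundance"`, `"richness"`, `"shannon"`,
#'   `"simpson"`.
#' @return list of class `season_lmm`: `anova` (numDF, denDF, F, p),
#'   `r2_marginal`, `r2_conditional`, `model`.
#' @export
season_lmm <- function(table,
                       attribute = c("abundance", "richness", "shannon",
                                     "simpson")) {
  attribute <- match.arg(attribute)
  prof <- diversity_profile(table)
  if (length(unique(prof$season)) < 2) stop("need >= 2 seasons")
  if (length(unique(prof$sensor)) < 2) stop("need >= 2 sensors")
  y <- prof[[attribute]]
  if (sd(y) == 0) stop("attribute is constant")
  if (attribute %in% c("abundance", "richness")) y <- sqrt(y)
  df <- data.frame(y = y, season = factor(prof$season),
                   sensor = factor(prof$sensor))
  model <- nlme::lme(y ~ season, random = ~ 1 | sensor, data = df,
                     method = "REML")
  an <- anova(model)
  r2 <- lme_r2(model, df)
  structure(list(
    attribute = attribute,
    anova = data.frame(term = rownames(an), numDF = an$numDF,
                       denDF = an$denDF, F = an$`F-value`,
                       p = an$`p-value`),
    r2_marginal = unname(r2["marginal"]),
    r2_conditional = unname(r2["conditional"]),
    model = model), class = "season_lmm")
}

#' @export
print.season_lmm <- function(x, ...) {
  row <- x$anova[x$anova$term == "season", ]
  cat(sprintf(
    "Season effect on %s: F(%d, %d) = %.3f, p = %.3f; R2m = %.3f, R2c = %.3f\n",
    x$attribute, row$numDF, row$denDF, row$F, row$p,
    x$r2_marginal, x$r2_conditional))
  invisible(x)
}
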