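# Synthetic dominance-structured soil community counts.

#' Construct a community table
#'
#' @param counts samples x taxa nonnegative integer matrix (taxa as column
#'   names).
#' @param season,sensor,date per-sample metadata vectors.
#' @return object of class `community_table`: list with `counts` and `meta`.
#' @export
community_table <- function(counts, season, sensor, date = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  n <- nrow(counts)
  stopifnot(length(season) == n, length(sensor) == n)
  if (is.null(date)) date <- rep(as.Date(NA), n)
  structure(list(counts = counts,
                 meta = data.frame(season = as.character(season),
                                   sensor = as.character(sensor),
                                   date = as.Date(date))),
            class = "community_table")
}

#' @export
print.community_table <- function(x, ...) {
  cat(sprintf("<community_table> %d samples x %d taxa, %d individuals\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

# season-shifted mean proportions, renormalized
shifted_proportions <- function(config, season) {
  p <- setNames(config$mean_proportions, config$taxa_names)
  sh <- config$season_shift[[season]]
  if (!is.null(sh)) {
    common <- intersect(names(sh), names(p))
    p[common] <- p[common] * sh[common]
  }
  p / sum(p)
}

#' Generate synthetic soil community counts
#'
#' Per sample: relative abundances are drawn from a Dirichlet distribution
#' centred on the (season-shifted) mean proportions with concentration
#' `dispersion`; the sample total is negative-binomial; counts are
#' multinomial. As `dispersion` grows the empirical proportions converge to
#' the configured means (Acari 63%, Diptera 28%, Collembola 7% at defaults).
#'
#' @param config a [community_config()].
#' @param n_samples number of samples to draw.
#' @param season_labels per-sample season (recycled if length 1).
#' @param sensor_labels per-sample sensor label (recycled).
#' @param dates optional per-sample dates.
#' @return a [community_table()].
#' @export
generate_community <- function(config, n_samples,
                               season_labels = "summer",
                               sensor_labels = "S1",
                               dates = NULL) {
  stopifnot(inherits(config, "community_config"), n_samples >= 1)
  season_labels <- rep_len(as.character(season_labels), n_samples)
  sensor_labels <- rep_len(as.character(sensor_labels), n_samples)
  K <- length(config$taxa_names)
  counts <- with_seed(derive_seed(config$seed, 7L), {
    m <- matrix(0L, nrow = n_samples, ncol = K)
    for (s in seq_len(n_samples)) {
      p0 <- shifted_proportions(config, season_labels[s])
      g <- rgamma(K, shape = p0 * config$dispersion, rate = 1)
      p <- if (sum(g) > 0) g / sum(g) else p0
      total <- rnbinom(1, mu = config$total_abundance_mean,
                       size = config$total_abundance_size)
      if (total > 0) m[s, ] <- as.integer(rmultinom(1, total, p))
    }
    m
  })
  colnames(counts) <- config$taxa_names
  community_table(counts, season_labels, sensor_labels, dates)
}

#' Write / read a community table as CSV
#'
#' Metadata columns (`season`, `sensor`, `date`) followed by one column per
#' taxon.
#'
#' @param table a `community_table`.
#' @param path CSV file path.
#' @return `path` invisibly (write); a `community_table` (read).
#' @export
write_community_csv <- function(table, path) {
  out <- cbind(table$meta, as.data.frame(table$counts))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_community_csv
#' @export
read_community_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- c("season", "sensor", "date")
  counts <- as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE])
  community_table(counts, df$season, df$sensor, as.Date(df$date))
}
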