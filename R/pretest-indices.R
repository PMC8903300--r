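# Pre-test acoustic indices used to decide on ACI: acoustic evenness (AEI),
# acoustic richness (AR) and the median amplitude envelope (M).

gini <- function(x) {
  x <- sort(as.numeric(x))
  n <- length(x)
  if (n < 2 || sum(x) == 0) return(0)
  sum((2 * seq_len(n) - n - 1) * x) / (n * sum(x))
}

# Temporal entropy of the absolute amplitude envelope, normalized to [0, 1].
temporal_entropy <- function(samples) {
  env <- abs(samples)
  if (sum(env) == 0) return(0)
  p <- env / sum(env)
  p <- p[p > 0]
  -sum(p * log(p)) / log(length(samples))
}

#' Pre-test acoustic indices: AEI, AR and median amplitude envelope
#'
#' Computes, for each recording in a batch: `M`, the median of the absolute
#' amplitude envelope; `Ht`, the temporal entropy of the envelope; `AEI`, the
#' Gini coefficient of per-band occupancy (fraction of frames in which a band
#' exceeds a dB threshold relative to the loudest band); and `AR`, the
#' rank-based acoustic richness `rank(M) * rank(1 - Ht) / n^2` across the
#' batch. AR is rank-based and therefore needs at least two recordings.
#'
#' @param recordings list of `soil_recording` objects (a single recording may
#'   be passed, but then AR is undefined and an error is raised unless
#'   `ar = FALSE`).
#' @param window spectrogram window for AEI.
#' @param db_threshold occupancy threshold in dB below the global maximum
#'   band level (default -50).
#' @param ar compute AR? Set `FALSE` to allow a single recording.
#' @return data.frame with columns `M`, `Ht`, `AEI` and (if requested) `AR`.
#' @export
compute_pretest_indices <- function(recordings, window = 512,
                                    db_threshold = -50, ar = TRUE) {
  if (inherits(recordings, "soil_recording")) recordings <- list(recordings)
  n <- length(recordings)
  if (ar && n < 2)
    stop("AR is rank-based across a batch; supply >= 2 recordings or ar = FALSE")
  M <- numeric(n); Ht <- numeric(n); AEI <- numeric(n)
  for (i in seq_len(n)) {
    rec <- recordings[[i]]
    M[i] <- median(abs(rec$samples))
    Ht[i] <- temporal_entropy(rec$samples)
    spec <- compute_spectrogram(rec, window = window)
    ref <- max(spec$I)
    if (ref == 0) {
      AEI[i] <- 0
    } else {
      occ <- rowMeans(spec$I > ref * 10^(db_threshold / 20))
      AEI[i] <- gini(occ)
    }
  }
  out <- data.frame(M = M, Ht = Ht, AEI = AEI)
  if (ar) out$AR <- rank(M) * rank(1 - Ht) / n^2
  out
}
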