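# Independent oracles used across the suite. These deliberately re-derive
# quantities by brute force, never by calling the implementation under test.

# literal evaluation of the ACI formulas: d_k = |I_k - I_(k+1)| along frames
# within each clump, D their sum, ratio D / sum(I); index = mean of ratios
brute_force_aci <- function(I, frames_per_clump) {
  n_clumps <- floor(ncol(I) / frames_per_clump)
  ratios <- c()
  for (b in seq_len(nrow(I))) {
    for (cl in seq_len(n_clumps)) {
      idx <- ((cl - 1) * frames_per_clump + 1):(cl * frames_per_clump)
      D <- 0
      for (j in idx[-length(idx)]) D <- D + abs(I[b, j] - I[b, j + 1])
      S <- sum(I[b, idx])
      ratios <- c(ratios, if (S > 0) D / S else 0)
    }
  }
  mean(ratios)
}

# direct evaluation of the Hill-number formulas
brute_force_hill <- function(counts, q) {
  p <- counts[counts > 0] / sum(counts)
  if (q == 0) length(p)
  else if (q == 1) exp(-sum(p * log(p)))
  else sum(p^q)^(1 / (1 - q))
}

# narrowest-window HDI by exhaustive scan over sorted draws
brute_force_hdi <- function(x, prob = 0.95) {
  x <- sort(x)
  n <- length(x)
  m <- ceiling(prob * n)
  best <- c(x[1], x[n])
  for (i in 1:(n - m + 1)) {
    if (x[i + m - 1] - x[i] < best[2] - best[1])
      best <- c(x[i], x[i + m - 1])
  }
  best
}

# exact permutation p-value for a two-group PERMANOVA with paired strata
# (every stratum holds one sample of each group): enumerate all within-
# stratum label swaps
exact_strata_permanova_p <- function(d, groups, strata) {
  d2 <- as.matrix(d)^2
  groups <- as.character(groups)
  stat <- function(g) soundsoil:::permanova_stat(d2, g)["F"]
  obs <- stat(groups)
  strat_ids <- unique(strata)
  n_s <- length(strat_ids)
  count <- 0L; total <- 0L
  for (mask in 0:(2^n_s - 1)) {
    g <- groups
    for (j in seq_len(n_s)) {
      if (bitwAnd(mask, bitwShiftL(1L, j - 1L)) > 0) {
        w <- which(strata == strat_ids[j])
        g[w] <- rev(g[w])
      }
    }
    total <- total + 1L
    if (stat(g) >= obs - 1e-12) count <- count + 1L
  }
  count / total
}

# compact audio format used throughout the tests: the index chain is
# rate-agnostic, so tests run on short low-rate clips
test_soundscape <- function(...) {
  soundscape_config(rate = 16000, clip_seconds = 2.048, ...)
}
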