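# soundsoil

Passive acoustic monitoring of soil fauna. Soil mesofauna and macrofauna —
mites, springtails, fly larvae, earthworms and their predators — produce
movement, feeding and stridulation sounds in the litter and uppermost soil
layers. `soundsoil` turns belowground audio into a biodiversity signal and
provides the statistical machinery to relate that signal to time, weather
and the soil community itself. It is aimed at soil ecologists and
ecoacousticians who want a tested, reproducible version of this analysis
chain, exercisable end-to-end on built-in synthetic data.

The package implements:

* **Averaged Acoustic Complexity Index (ACI).** Non-overlapping 512-sample
  magnitude spectrograms (256 bands; a ~20.69-s clip at 50 kHz gives 2020
  time blocks); per band and per 1-s clump,
  `d_k = |I_k − I_(k+1)|`, `D = Σ d_k`, `ACI = D / Σ I_k`, averaged over
  bands and clumps so the index is bounded in [0, 2). Values in
  [0.55, 0.90] are flagged valid — below lies amplified background noise
  (Gaussian noise gives `2 − √2 ≈ 0.586`), above lies rain/irrigation
  clipping. Pre-test indices (AEI, AR, median amplitude envelope) are
  included.
* **Hierarchical Bayesian gamma time-series model.** For offset ACI
  `y = ACI − 0.55`:
  `η_it = α_i + X_it β + Σ_l φ_l ln y_(t−l)`, `y ~ Gamma(k, e^η)`,
  `α_i ~ N(μ_α, σ_α²)`, `β_j ~ N(0, σ_βj²)`, sampled by MCMC (JAGS),
  with lag-order selection from auxiliary mixed-model residual ACFs,
  pre-whitened cross-correlation screening of covariate lags, and
  scenario predictions summarized by MAP and 95% highest density
  intervals.
* **Community analysis.** Hill numbers ⁰D/¹D/²D, Bray–Curtis distances,
  NMDS (vegan), seasonal mixed models with marginal/conditional R², and a
  PERMANOVA with permutations restricted to within sensors.
* **Acoustic–biotic linking.** ACI at three temporal resolutions around
  each soil-sampling event (directly before, ±30 min, ±12 h) regressed on
  standardized community attributes with a random plot intercept.
* **Synthetic data generators.** Seeded soundscapes (noise floor +
  band-limited event trains + clipping rain), diurnal/seasonal
  microclimate, and dominance-structured community counts (Acari 63%,
  Diptera 28%, Collembola 7%), so the full pipeline runs without any
  field data.

## Worked example

```r
library(soundsoil)

## a synthetic field-format clip and its acoustic complexity
sc  <- soundscape_config(seed = 42)               # 50 kHz, ~20.69 s
rec <- generate_recording(as.POSIXct("2019-06-20 12:15:00", tz = "UTC"),
                          sc, richness = 5)
sp  <- compute_spectrogram(rec)                   # 256 bands x 2020 frames
compute_aci(sp)
#> <aci_result> value 0.5984 (256 bands x 20 clumps)

## simulate from the gamma AR model and recover the planted parameters
tp  <- list(mu_alpha = -2.2, sigma_alpha = 0.3, beta = c(0.25, -0.15),
            phi = 0.2, k = 12)
sim <- simulate_from_model(tp, n_sensors = 3, n_times = 200,
                           X = matrix(rnorm(400), ncol = 2), L = 1,
                           seed = 1, parameterization = "mean")
fit <- fit_gamma_ar(sim, L = 1, parameterization = "mean",
                    chains = 2, iter = 1200, warmup = 500, seed = 2)
fit
#> Hierarchical gamma AR model (mean parameterization, g = log)
#>   597 obs, 3 sensors, 2 predictors, L = 1
#>   2 chains x 700 draws; max R-hat 1.030 (converged)
head(summary(fit), 5)
#>  parameter   mean     sd    map hdi_lower hdi_upper  rhat
#>   alpha[1] -2.357 0.0843 -2.366    -2.509    -2.184 1.005
#>   alpha[2] -2.119 0.0782 -2.098    -2.281    -1.977 1.002
#>   alpha[3] -2.401 0.0870 -2.404    -2.570    -2.230 1.006
#>    beta[1]  0.244 0.0118  0.241     0.220     0.266 1.003
#>    beta[2] -0.147 0.0108 -0.144    -0.169    -0.126 0.999
```

The planted coefficients (0.25, −0.15), AR weight (0.2) and shape (12)
all sit inside their 95% HDIs. Scenario predictions restore the 0.55
offset and report the kernel-density MAP with the narrowest 95% interval;
raising the first (scaled) covariate from −1 to +1 lifts predicted ACI
from 0.598 to 0.629 here:

```r
predict_scenarios(fit, matrix(c(-1, -1, 1, -1), ncol = 2, byrow = TRUE))
#>   scenario   map hdi_lower hdi_upper  mean
#> 1        1 0.598     0.574     0.629 0.601
#> 2        2 0.629     0.587     0.676 0.633
```

Diversity of a dominance-structured sample (63/28/7/1/1):

```r
sapply(c(0, 1, 2), hill_number, counts = c(63, 28, 7, 1, 1))
#> [1] 5.000000 2.523797 2.081599
```

The full pipeline (simulate → aci → fit-seasonal → fit-microclimate →
diversity → link) runs from one config:

```r
cfg <- default_run_config(output_dir = "run1", seed = 4)
run_pipeline(cfg)          # ~2 min on one CPU at the desk-scale defaults
```

or from the shell via `Rscript inst/cli/soundsoil.R all --seed 4
--stage-dir run1`. Stage artifacts are plain CSV/WAV/JSON with manifests;
rerunning an up-to-date stage is a no-op unless `--force`.

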