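# tdaf — time-dispersion analysis of plant electrome and turgor signals

Plants answer local injury (a cut leaf, a heat shock) with fast
electrical and hydraulic signals that reach distant, unstimulated tissue.
The electrical record — the *electrome* — is a single channel of
microvolt variation sampled at 62.5 Hz for an hour per phase
(225,000 points), labeled by treatment (`W` wound, `HS` heat shock,
`W_HS` combined, `CONTROL`), tissue (`LOCAL`/`SYSTEMIC`) and phase
(`BEFORE`/`AFTER` the stimulus). Whole-series statistics hide effects
that live in the first minutes after a stimulus, so this package
implements a sliding-window scheme: cut each series into sub-minute
windows (48 s, 20 % overlap), compute per-window features, pool the
values of replicate recordings into time-indexed bins, and follow the
bins' dispersion (min, quartiles, median, max) through time.

Per-window features:

* **ApEn** — approximate entropy
  `ApEn = Phi_m(r) − Phi_{m+1}(r)` with `m = 2`, `tau = 1`,
  `r = 0.02·sigma` (Chebyshev distance, self-match included); low values
  mean regular, nearly deterministic dynamics.
* **DFA alpha** — detrended fluctuation analysis scaling exponent
  (profile integration, per-box linear detrending, log–log fit);
  `alpha ≈ 0.5` uncorrelated, `> 1` non-stationary fractional-Brownian.
* **ABP** — Welch PSD (512-sample Hann segments, 50 % overlap)
  integrated by composite Simpson over low (0–0.5 Hz), delta (0.5–4),
  theta (4–8), alpha (8–12) and beta (12–30 Hz) bands.

Because no raw recordings are public for this design, the package also
ships seeded generators of synthetic electrome series (colored-noise
baseline, >50 µV voltage spikes, calibrated post-stimulus slow-wave
regimes) and of leaf turgor (patch-pressure) series with controlled
coefficients of variation, plus the before/after comparison machinery.
`vignettes/tdaf-methods.Rmd` documents the model and every calibration.

The package is for electrophysiologists and biosignal methodologists who
want a tested, reproducible implementation of windowed
complexity/spectral dispersion analysis, and for anyone needing a
realistic synthetic testbed for such pipelines.

## Worked example

Ten replicate wounded plants, local leaf, one hour before and one hour
after the stimulus; recover the early entropy drop:

```r
library(tdaf)

cfg <- tdaf_config()                     # 48 s windows, 20 % overlap
before <- lapply(1:10, function(r)
  generate_electrome(electrome_gen_params(seed = r * 1000),
                     stimulus_scenario("W", "LOCAL"), "BEFORE"))
after  <- lapply(1:10, function(r)
  generate_electrome(electrome_gen_params(seed = 500 + r * 1000),
                     stimulus_scenario("W", "LOCAL"), "AFTER"))

reports <- run_tdaf(c(before, after), cfg)
compare_phases(reports[["tlb.apen"]], reports[["tla.apen"]])
#> <phase_comparison> apen: mean median-difference over first 10 min = -0.2828 (16 bins)

plot_tdaf(reports[["tla.apen"]], "tla_apen.png")   # median + quartile ribbons
```

The printed value is the average, over the 16 time bins that start
within 10 minutes of the stimulus, of the per-bin median ApEn difference
(after − before): the wounded plants' electrome loses about 0.3 of
approximate entropy — it becomes more regular — and reverts afterwards.
Control scenarios show differences near 0.

Turgor series work the same way at a 10 s sampling interval:

```r
ts <- generate_turgor(turgor_gen_params(seed = 21),
                      stimulus_scenario("W_HS", "SYSTEMIC"))
before_after_cv(ts)
#> cv_before_pct  cv_after_pct
#>      10.22760     25.51271
```

i.e. the combined stimulus raises the coefficient of variation of the
(percent-normalized) leaf pressure signal by a factor of about 2.5.

## Analysis workflow

The `analysis/` scripts run the whole study as a pipeline over the
package functions; each writes its tables under `results/` (bulky
simulated series and figures go under `scratch/`):

```sh
Rscript analysis/01_simulate.R        # synthetic experiment + manifest
Rscript analysis/02_tdaf.R            # windowing, features, dispersion bins
Rscript analysis/03_compare_phases.R  # before/after effect tables
Rscript analysis/04_turgor.R          # turgor CV before vs after
```

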