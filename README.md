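# flimscreen

Analysis of multiwell-plate protein–protein interaction screens read out
by FRET and automated time-gated FLIM.

## The problem

To test whether two proteins interact inside cells, one tags them with a
donor (EGFP) and an acceptor (mCherry) fluorophore. If they bind, Förster
resonance energy transfer quenches the donor and shortens its
fluorescence lifetime. A gated-intensifier FLIM plate reader samples the
donor decay with a few 1-ns gates per field of view, fast enough to walk
a 96-well plate unattended, producing hundreds of gated image stacks per
plate. `flimscreen` turns those stacks into interaction calls and binding
affinities:

* **Forward model** — expected counts per gate for multi-exponential
  decays, including IRF convolution, rectangular gate integration and the
  60 MHz incomplete-decay (wrap-around) correction
  `W = 1/(1 − exp(−P/τ))`; plus per-plate `t0` calibration from a
  reference dye and time-varying background from blank wells.
* **Fitting** — per-cell monoexponential fits
  `I(t) = I0·exp(−t/τ)` (the screening readout), and global
  double-exponential fits
  `I(t) = I0·[β·exp(−t/τ_DA) + (1−β)·exp(−t/τ_D)]` by variable
  projection: `τ_D` fixed from donor-only wells, one shared `τ_DA` per
  condition, per-cell non-negative amplitudes solved in closed form, so
  each cell gets an interacting donor fraction `β`.
* **Calling** — significance threshold = 2 × the maximum donor-only vs
  negative-control lifetime shift; test conditions whose mean lifetime
  drops by at least the threshold are called positive.
* **Affinity** — with intensity calibrations `D_tot = I_D/c_D`,
  `A_tot = I_A/c_A` (the donor intensity being the fitted t = 0
  amplitude), each cell yields
  `K_D = (1−β)(A_tot − β·D_tot)/β`, aggregated as median + IQR per
  condition with a validity-flag taxonomy.
* **Synthetic plates** — a ground-truthed generator (binding equilibrium
  with a chosen true K_D, log-uniform uncorrelated expression, gated
  Poisson detection, time-varying background) validates every stage
  end-to-end.

## Worked example

```r
library(flimscreen)

cfg <- plate_config()                        # 5 × 1 ns gates, 60 MHz, τ_D 2400 ps
lay <- plate_layout(c("RASSF1", "RASSF7"), beta = c(0.45, 0), n_fov = 2)
plate <- simulate_plate(lay, cfg, seed = 1)  # interactor + non-interactor
scr  <- analyze_plate(plate)                 # segment, aggregate, fit
sc   <- screen_calls(scr)
sc$calls
#>   condition baseline_tau test_tau delta_tau     call
#> 1    RASSF1       2399.3   1932.0  467.2308 positive
#> 2    RASSF7       2398.1   2399.9   -1.8164 negative
```

The interacting condition drops the mean donor lifetime by ~467 ps —
far beyond the control-derived threshold — while the non-interactor sits
within 2 ps of its donor-only baseline.

Estimating affinity for a plate simulated with a true K_D of 500 nM:

```r
kdlay <- plate_layout("RASSF1", kd = 500, n_fov = 5)
scr2  <- analyze_plate(simulate_plate(kdlay, cfg, seed = 2))
sd <- simulate_calibration_series(cfg, "donor",    seed = 3)
sa <- simulate_calibration_series(cfg, "acceptor", seed = 4)
cal_d <- fit_intensity_calibration(sd$concentration, sd$intensity, "EGFP")
cal_a <- fit_intensity_calibration(sa$concentration, sa$intensity, "mCherry")
kd <- estimate_kd_table(scr2, cal_d, cal_a)
aggregate_kd(kd, kd$condition)
#>   condition n_ok n_excluded ... kd_median kd_iqr kd_q1 kd_q3 kd_mean
#> 1    RASSF1  100          0 ...     499.1  26.94 485.6 512.5   499.1
```

100 of 100 cells give valid estimates and the per-condition median
(499 nM) recovers the generating constant within half a percent.

A thin command-line front end over the same functions lives at
`inst/scripts/flim-screen.R` (`simulate`, `fit`, `call`, `kd`, `report`
subcommands); the methods vignette
(`vignettes/flim-fret-screening.Rmd`) documents the model, parameters and
design decisions.

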