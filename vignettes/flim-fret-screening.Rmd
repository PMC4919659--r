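---
title: "Quantifying protein interactions by time-gated FLIM-FRET plate screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying protein interactions by time-gated FLIM-FRET plate screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flimscreen)
```

## The measurement

When a donor fluorophore (EGFP, unquenched lifetime $\tau_D \approx 2.4$ ns)
transfers energy to a nearby acceptor (mCherry) by Förster resonance energy
transfer, its fluorescence lifetime drops. In a cell co-expressing
donor-tagged and acceptor-tagged proteins, only the donors bound in a
complex are quenched, so the donor decay is a two-component mixture

$$ I(t) = I_0\left[\beta\, e^{-t/\tau_{DA}} + (1-\beta)\, e^{-t/\tau_D}\right], $$

where $\beta$ is the fraction of donor molecules in complex and
$\tau_{DA}$ the FRET-quenched lifetime. A wide-field gated optical
intensifier samples this decay with a handful of delayed exposure windows
("gates") per field of view, fast enough to walk a 96-well plate
automatically. This package implements the analysis chain for such
screens:

1. a forward model of gated detection of exponential decays,
2. per-cell monoexponential lifetime fits (the screening readout),
3. global double-exponential fits sharing $\tau_{DA}$ across all cells of
   a condition (the quantitative readout, giving per-cell $\beta$),
4. interaction calling from lifetime shifts against a control-derived
   significance threshold, and
5. per-cell dissociation constants $K_D$ from $\beta$ and calibrated
   donor/acceptor intensities,

plus a ground-truthed synthetic plate generator so that every stage can be
validated without instrument data.

## Forward model of gated detection

For a rectangular gate of width $w$ opening at delay $t$ after the decay
origin, a single exponential of amplitude $A$ (counts per ps) and lifetime
$\tau$ under pulsed excitation with repetition period $P$ contributes

$$ N(t) = A\,\tau\, e^{-t/\tau}\left(1 - e^{-w/\tau}\right) W, \qquad
   W = \frac{1}{1 - e^{-P/\tau}}. $$

$W$ is the incomplete-decay (wrap-around) correction: at 60 MHz
($P \approx 16.7$ ns) with $\tau = 2.5$ ns it is a $\sim 0.1\%$ effect,
but keeping it makes the model exact and free of rate-dependent bias.
Multi-component decays are fraction-weighted sums (`model_gate_signal()`).

A finite instrument response function (IRF) — measured on a scatterer or
parametrised as a Gaussian — enters by discrete convolution: each IRF
sample shifts the decay origin, and the gate integral of the shifted,
periodised decay is evaluated in closed form. Because the gate integration
itself is analytic, the only discretisation is the IRF sampling (default
step 25 ps, or FWHM/8 if finer; `oversample` controls it). The gate
integral is smooth in the delay except for a kink exactly at the decay
onset, where wrapped signal from the preceding pulse hands over to the
current one; convergence of a narrowing IRF to the ideal-IRF formula is
quadratic away from that point and only linear on it, which is physics
rather than a numerical artefact.

Two further per-plate calibrations mirror standard practice: the decay
time origin $t_0$ is fitted from a reference dye of known lifetime
(`estimate_t0_from_reference()`; rhodamine 6G is customary and its
lifetime is an *input* — the package defaults to 4080 ps but does not hard-code
chemistry), and the time-varying background is taken as the per-gate
median of a buffer-only well (`estimate_background()`).

## Fitting

**Monoexponential (screening) fit.** `fit_monoexponential()` fits
$(I_0, \tau)$ by weighted least squares against the gated model. The
amplitude is linear and profiled out, leaving a bounded 1-D search in
$\tau$ (Brent, then a parabolic Newton polish — see *Numerical choices*).
Weights are Poisson, $1/\max(\text{expected counts}, 1)$, initialised from
the data and re-derived from the fitted model. Even for a true mixture the
monoexponential $\tau$ is a well-behaved effective lifetime between
$\tau_{DA}$ and $\tau_D$, which is what makes it a robust screening
statistic.

**Global biexponential fit.** `fit_global_biexponential()` implements
separable (variable-projection) least squares: $\tau_D$ is fixed from
donor-only wells of the same plate, $\tau_{DA}$ is shared across all cells
of a condition, and for each candidate $\tau_{DA}$ the two non-negative
per-cell amplitudes are solved in closed form (a $2\times 2$ weighted
normal system with axis fallback, vectorised across cells). The pooled
residual is minimised over a coarse log grid followed by Brent refinement;
grid ties break toward larger $\tau_{DA}$ (weaker quenching). $\beta$ is
the amplitude fraction of the quenched component, which maps onto the
molecular bound fraction; an intensity-fraction reading would additionally
weight by component brightness and is deliberately not the default. Fits
where no cell shows an appreciable quenched amplitude flag $\tau_{DA}$ as
unidentifiable instead of reporting an arbitrary number, as do fits ending
on a search bound.

The pipeline fits summed per-cell decays rather than per-pixel ones: all
pixels of a cell share the same mixture, so summing maximises photons per
decay without changing the estimand. A per-pixel lifetime map
(`fit_flim_image()`) exists for visualisation and small regions.

## Calling interactions

Biological noise is measured where no interaction can occur: per
condition, the donor-only mean lifetime minus the negative-control mean
lifetime. The plate-level significance threshold is **twice the maximum
absolute control difference** (`significance_threshold()`); a test
condition is called positive when its mean lifetime is reduced by at least
that threshold (boundary inclusive, `call_interactions()`). With the
classic worked numbers — a maximum control shift of 16 ps — the threshold
is 32 ps, and genuine interactions shifting the donor lifetime by
100–300 ps clear it comfortably. One threshold serves the whole plate;
per-condition thresholds would let noisy controls loosen their own test.

## From fractions to dissociation constants

For the bimolecular reaction $D + A \rightleftharpoons DA$,

$$ K_D = \frac{[D][A]}{[DA]}, \qquad
   [DA] = \beta D_{tot} = \gamma A_{tot}, $$

with $\beta$, $\gamma$ the bound fractions of donor and acceptor. Totals
come from calibrated intensities, $D_{tot} = I_D/c_D$ and
$A_{tot} = I_A/c_A$, where the proportionality constants are fitted from
dilution series of purified fluorophore
(`fit_intensity_calibration()`). Substituting the free concentrations:

$$ K_D = \frac{(1-\beta)\left(A_{tot} - \beta D_{tot}\right)}{\beta}. $$

The donor intensity must be the fitted $t=0$ amplitude, not the total
detected intensity: FRETing donors are dimmer in proportion to their
shortened lifetime, so total intensity under-counts them while the $t=0$
amplitude is proportional to concentration regardless of quenching. The
acceptor uses the background-subtracted mean of its single directly
excited gate; no equivalent lifetime correction applies there.

Per-cell estimates are screened by a validity taxonomy rather than
truncated: $\beta$ exactly 0 or 1 (`beta_degenerate`),
$A_{tot} \le \beta D_{tot}$ (`negative_free_acceptor`), or
$\gamma > 1.05$ (`gamma_out_of_range`) exclude a cell from aggregates,
and exclusion counts are reported. Aggregation uses the median and IQR —
the per-cell $K_D$ distribution is heavy-tailed on the right because
cells with small $\beta$ divide by a small number — with the mean
reported alongside; conditions with fewer than 10 valid cells are
withheld. Both per-cell and per-FOV groupings can be computed by passing
the appropriate grouping vector to `aggregate_kd()`.

The inverse problem is exact by construction: for any cell of the
synthetic generator, plugging the true $\beta$ and exact intensities into
the estimator returns the generating $K_D$ to $10^{-10}$ relative, which
the test suite asserts.

## The synthetic plate generator

`simulate_plate()` emulates the acquisition a screen produces, with known
ground truth:

* **Expression.** $D_{tot}$ and $A_{tot}$ are drawn independently
  log-uniformly over 50 nM – 5 µM per cell. Co-transfection from separate
  plasmids gives uncorrelated stoichiometry, and the acceptor/donor ratio
  spanning more than a decade is exactly what the lifetime-vs-ratio plots
  are designed to cope with. Real screens do not report their expression
  distributions, so these are explicit, configurable stand-ins.
* **Binding.** Each cell's complex concentration solves the mass-action
  quadratic for the configured true $K_D$ (`solve_binding_equilibrium()`,
  evaluated in a cancellation-free form), or a fixed $\beta$ can be
  imposed (e.g. $\beta = 0$ negative conditions).
* **Cells.** Uniform disks (radius 6–10 px) with a minimum separation
  that keeps neighbours separable after segmentation smoothing. No
  sub-cellular structure: the analysis is per cell.
* **Detection.** Five 1-ns gates at 1-ns spacing, 60 MHz repetition,
  per-gate backgrounds ramping 1.2 → 0.8 counts (a time-varying
  background), donor gain $c_D = 0.01$ counts px⁻¹ ps⁻¹ nM⁻¹ and acceptor
  gain $c_A = 0.2$ counts px⁻¹ nM⁻¹ — chosen so the dimmest cells still
  collect $\gtrsim 10^4$ donor photons, consistent with using most of a
  CCD's dynamic range.
* **Noise.** Poisson counts; an optional negative-binomial
  excess-variance factor stands in for intensifier gain noise, whose true
  model the acquisition literature does not pin down. `noise = "none"`
  returns analytic expectations exactly, enabling the noiseless exactness
  tests.
* **Seeds.** One master seed derives per-FOV streams, so any FOV is
  independently reproducible and whole plates are bit-identical across
  runs.

What it does **not** emulate — optical point-spread blur, photobleaching,
autofluorescence, spectral bleed-through, cell morphology and motion,
spatial heterogeneity of $\beta$ within cells — bounds what green tests
prove: the pipeline's statistical machinery is correct under the stated
noise model, not that real-microscope systematics are absent.

## Segmentation and photometry

Cells are found by box-smoothing each channel, thresholding at
median + 5·MAD, intersecting channels where co-transfection is required,
and labelling connected components; components below 100 px or touching
the border are dropped (`segment_cells()`). Smoothing dilates bright
cells past their true edge, so the mask is eroded back by the smoothing
radius; for photometry the mask is eroded further (2 px default), because
means over edge pixels mix cell and background signal and would bias
concentrations — and hence $K_D$ — low. These interior means are what
`aggregate_per_cell()` feeds to the fitters.

## Numerical choices

* All 1-D minimisations (τ, $\tau_{DA}$, $t_0$) use a coarse bracketing
  grid plus Brent's method, followed by a two-step parabolic Newton
  polish. Brent alone stops near $\sqrt{\varepsilon}\,|x|$ ($\sim$2×10⁻⁵
  ps here), which is fine for data but visible in noiseless round-trip
  tests; the polish reaches $\sim$10⁻¹² relative.
* Residual sums of squares are computed from explicit residuals, never
  from the expanded quadratic form, which cancels catastrophically near
  zero-residual optima.
* Amplitudes are constrained non-negative; if the unconstrained $2\times2$
  solution violates this, the better of the two single-component fits is
  taken and the cell flagged `clipped`. $\beta$ therefore always lies in
  $[0, 1]$.
* $\tau_{DA}$ search bounds default to $[200\ \mathrm{ps}, \tau_D - 100\
  \mathrm{ps}]$; $\tau$ bounds for mono fits default to
  $[100, 10^4]$ ps. Fits at a bound are flagged, not silently returned.
* Degenerate inputs degrade explicitly: all-background decays are
  "not fittable", empty images give empty masks, empty record groups are
  withheld.
* Units are picoseconds and nanomolar throughout; conversions happen only
  at I/O boundaries. Counts written to TIFF are scaled into the float
  range with the factor recorded in the plate metadata.

## Validation scale

The test-suite simulations are sized for a desk run: plates of 10 FOV ×
20 cells (≈200 cells) at 192×192 px for the end-to-end $K_D$ recovery,
30-cell conditions for global-fit recovery, and 100-replicate bias checks
at 10⁴ photons per decay. At these sizes the whole suite completes in
well under a minute; the statistical conclusions (unbiasedness, recovery
within stated tolerances) are sample-size-aware, with tolerances set from
the corresponding sampling errors.

## Known limitations

* $\kappa^2$ orientation effects, dark acceptor states and competition
  by unlabelled endogenous partners all bias $\beta$ and hence $K_D$;
  none is modelled, so absolute $K_D$ values are estimates whose
  comparison across conditions is more trustworthy than their absolute
  scale.
* Spectral bleed-through correction is out of scope; the acceptor channel
  is assumed clean.
* The intensity calibration transfers only between acquisitions with
  matching optical settings; the `settings_tag` mechanism enforces the
  bookkeeping but cannot detect drift.
* A single plate-level $t_0$ is assumed (no colour- or field-dependent
  IRF shift).

## A compact worked example

```{r example, eval = FALSE}
cfg <- plate_config()                         # 5 × 1 ns gates, 60 MHz
lay <- plate_layout("PPI", kd = 500, n_fov = 2)
plate <- simulate_plate(lay, cfg, seed = 1)
scr <- analyze_plate(plate)
screen_calls(scr)$calls

cal <- list(
  d = fit_intensity_calibration(c(100, 1000, 5000),
                                c(100, 1000, 5000) * cfg$c_d, "EGFP"),
  a = fit_intensity_calibration(c(100, 1000, 5000),
                                c(100, 1000, 5000) * cfg$c_a, "mCherry"))
kd <- estimate_kd_table(scr, cal$d, cal$a)
aggregate_kd(kd, kd$condition)
```
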