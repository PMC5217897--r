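---
title: "Methods behind the gari quality-control pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind the gari quality-control pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gariqc)
```

`gariqc` reduces raw laboratory readings for gari — fermented, granulated,
roasted cassava pulp — to seven quality parameters and analyses how grain
size and moisture drive acidity. This vignette explains each model, its
assumptions, the tunable parameters, the numerical choices, and what the
synthetic-data generator does and does not emulate.

## Granulometry

A dry sieve stack partitions the sample into size classes: the pan, one
class per sieve, and an open-topped oversize class. With retained masses
$m_i$, the mass fractions are $\mu_{3,i} = m_i / \sum_j m_j$ and the
mass-weighted mean diameter is

$$\bar{x}_3 = \sum_{i=1}^{n} \frac{d_{i-1} + d_i}{2}\, \mu_{3,i},$$

the fraction-weighted average of class midpoints. Two bounds are not
physically observable and must be closed by convention:

* **Pan class**: bounded below at 0 µm, since diameters are non-negative.
  Its midpoint is therefore half the finest aperture.
* **Oversize class**: closed at 1.4 × the largest aperture (2800 µm for a
  2000 µm top sieve), continuing the roughly $\sqrt{2}$ progression of the
  default aperture series (125, 180, 250, 355, 500, 710, 1000, 1400,
  2000 µm). Both bounds are arguments of `sieve_spec()`.

The **median diameter** is where the cumulative undersize curve crosses
50%. We interpolate piecewise-linearly through the points (class upper
bound, cumulative fraction), anchored at (pan lower bound, 0) — the
algorithmic equivalent of the usual graphical read-off. Flat segments
(empty classes) are handled by taking the first crossing. Both statistics
are invariant under uniform rescaling of the retained masses, and for a
distribution symmetric about a class boundary both equal that boundary;
the tests exercise these properties together with brute-force oracles
(term-by-term summation; dense numerical inversion of the same curve).

Sieving time (10 vs 15 min in the protocol the pipeline mirrors) is
carried as metadata only — its effect on the result is indistinguishable
from replicate noise — and no correction is applied.

Replicates are summarised as the arithmetic mean and the sample ($n-1$)
standard deviation; for a single replicate the SD is reported as missing
rather than zero.

## Bulk density, swelling index, moisture

These are direct ratios of paired readings, with validation:

* BD = sample mass / tapped volume (cylinder tapped 40 times);
* SI = swollen volume / initial volume after 4 h of soaking — values
  below 1 are physically odd for gari and warn rather than error;
* moisture $h$ = (fresh − dry)/fresh after 48 h at 105 °C.

The moisture formula deserves a note. The dry-to-fresh *ratio*
$\mathrm{dwt/fwt}$ is sometimes tabulated as "moisture" in protocol
write-ups, but for a roasted granular product holding 4–10% water the
quantity of interest is the drying **loss**; `moisture_content()` returns
the loss and offers the literal ratio behind `as_printed = TRUE` for
traceability. An optional 24 h intermediate mass supports a
drying-adequacy check: if it differs from the final mass by more than 0.1%
(relative, configurable) the reading is flagged — not rejected, since a
flagged reading may still be the best available.

## Bomb calorimetry

A static-jacket calorimeter measures a temperature trace with three
phases: a quiet fore period, the combustion rise, and a drifting after
period. The corrected rise $\Delta T$ is obtained by fitting straight
lines to the fore and after periods and taking their gap at the mid-rise
time (where the trace crosses halfway between the two lines). Equal linear
drift before and after cancels exactly; the estimate is invariant under
shifting all times or temperatures.

Window detection is automatic: slopes of a lightly smoothed trace
(9-point running mean) are compared with the fore-period drift; the rise
region is the contiguous run around the peak slope whose excess exceeds a
threshold of $\max(5\,\mathrm{MAD}$ of the fore-period slope excess,
5% of the peak excess$)$, and the after window starts two rise-durations
past the rise end, where the exponential approach to equilibrium has
decayed to negligible amplitude. Explicit windows and thresholds override
the detection. A full Regnault–Pfaundler integral correction is
deliberately out of scope; the residual bias of the linear treatment on an
exponential-approach trace is of order $10^{-5}$ K for the default
geometry, far below the per-point noise.

The reduction chain is then algebraic:

$$K = \frac{H_{h,B} m_B + H_{h,I} m_I}{\Delta T} - m_W c_W, \qquad
H_{h,M} = \frac{(m_W c_W + K)\,\Delta T - H_{h,I} m_I}{m_M}, \qquad
H_{h,G} = \frac{H_{h,M} m_M - H_{h,F} m_F}{m_G},$$

benzoic-acid calibration, mixture value, and sample value net of the
spiking fuel (light fuel oil added to ensure complete combustion of a
low-energy sample). Certified values ($H_{h,B}$, wire and fuel calorific
values) are configuration, not constants. Internally all energy is in J;
reports use kJ/g. The chain composed with its inversions is exact to
machine precision, and on synthetic traces with 0.02 K point noise the
sample value is recovered within ±0.15 kJ/g in well over 95% of runs.

## Cyanide

Picrate-paper photometry converts the 510 nm absorbance of the eluted
strip to total cyanide: ppm = A × 396. The factor presumes the kit's
100 mg / 5.0 mL geometry; off-nominal inputs warn, and an optional
proportional rescaling (× 100/mass × volume/5) is the only dimensionally
consistent extension. The 10-shade colour chart spans 0–800 ppm; since
per-shade values are not standardised the defaults anchor the shades
evenly and are configurable. Chart classification snaps to the nearest
shade with ties to the lower shade, and is monotone in absorbance. The
chart is a rough screen; the photometric value is the reported quantity.

## Titratable acidity

Acidity is titrated with 0.05 M NaOH on a 20.0 mL aliquot of a
5.00 g / 100.0 mL extract and expressed as percent lactic acid on dry
matter:

$$\mathrm{TTA\%} = 0.450 \cdot V_{\mathrm{NaOH}}\,[\mathrm{mL}] / (1 - h).$$

The 0.450 coefficient is kept as the literal protocol constant for
bit-compatibility; an independent first-principles recomputation from the
stoichiometry (0.05 mmol/mL × 100/20 scale-up × 90.08 mg/mmol per 5000 mg,
as percent = 0.4504) agrees within 0.1% and lives in the test suite as an
oracle, not in the production path. The correction divides by $1-h$, so
corrected ≥ uncorrected always, with equality only for bone-dry samples.
Which moisture enters the correction is genuinely open — per-trial or
per-sample — and the pipeline uses the per-sample mean (the correction
refers acidity to the sample's dry matter, a sample-level property),
with a per-sample override argument. Only lactic-acid equivalents are
reported; acetic and other acids are not speciated.

## The 2 × 2 factorial analysis

The grain-size × moisture study is a balanced two-way factorial with two
levels per factor and $r \ge 2$ replicates per cell. The decomposition by
cell and marginal means writes every observation as

$$y_{ijk} = \mu + \alpha_i + \beta_j + (\alpha\beta)_{ij} + e_{ijk}$$

with sum-to-zero effects, row/column-zero interactions and cell-zero
residuals, so reconstruction is exact (to $10^{-12}$ in the tests). Sums
of squares are the squared components summed over observations; they
partition the total SS exactly, and F tests use df (1, 1, 1, $4(r-1)$).
The table carries both the p-value and a `probability` column,
$100(1-p)$%, the complement form in which factorial screening results are
often quoted. `stats::aov` serves as an independent oracle in the tests;
the package's own decomposition is the implementation. Unbalanced designs
are rejected rather than approximated — the sum-to-zero identities that
make the decomposition exact hold only under balance. Zero residual
variance yields infinite F and $p = 0$ rather than an error. The module is
response-agnostic; in the acidity study the responses are
moisture-corrected TTA values, displayed ×100 on the interaction graph.

## The synthetic-data generator

Every assay's raw readings are generated from declared truths by
inverting the reduction (titration volume = TTA(1−h)/0.450, absorbance =
ppm/396, dry weight = fwt(1−h), sieve masses from a discretised lognormal,
calorimeter ΔT from the energy balance) and adding Gaussian noise **on the
raw instrument scale**, truncated at physical bounds. Field studies report
only SDs of final quantities, so a raw-scale noise model is a modelling
choice; defaults are anchored to instrument accuracies typical of such a
lab (0.01 g technical balance, ~0.2 mL cylinder readings, 0.01 mL burette
with operator endpoint scatter of ~0.02 mL, 0.02 K trace noise, ~0.0025
absorbance units):

* grain size: mass-weighted lognormal (median, $\sigma_{\ln}$), 100 g
  charge, 0.5 g per-class noise, renormalised to the charge (sieving
  conserves mass);
* calorimetry: 30 min trace sampled every 2 s, ignition at 600 s, 45 s
  exponential approach, 1.0 g benzoic pellet, ~320 mg sample + ~80 mg
  fuel oil per firing, calorimeter constant 450 J/K;
* replicate counts mirror the emulated protocol where it states them
  (4 sieving runs, 4 firings, 5 moisture weighings) and use 3–4
  replicates otherwise.

The `togo_maritime_truths()` preset provides 14 samples named after gari
collection sites in Maritime Togo, with truths spread over the ranges
reported for market gari (weighted means within 557–960 µm, BD
0.541–0.699 g/cm³, SI 3.21–4.33, moisture 4.30–9.40%, GCV
15.45–15.81 kJ/g, cyanide 0–4.8 ppm, acidity 0.57–1.62 g/100 g). Each
preset truth is placed at least about three standard errors of its
replicate mean inside the range extremes, so that simulated studies
produce summary tables representative of those ranges rather than
straddling their edges; the preset demonstrates the pipeline and does not
reproduce any measured dataset. Given the same seed and truths the
generator is bit-reproducible.

What the generator does **not** emulate: sieve blinding and particle
agglomeration, incomplete combustion, drifting photometer baselines,
operator-correlated titration bias, and any between-assay correlation
within a sample (readings are conditionally independent given the
truths). Passing tests therefore show the reduction chain is correct and
robust to uncorrelated instrument noise at realistic levels — not that it
is robust to structured measurement pathology.

## Problem sizes and numerical choices

The test-bed sizes are chosen to make Monte-Carlo statements sharp while
keeping the suite quick to run: 1000 random distributions for the
weighted-mean oracle, 200 firings for calorimetric recovery, 2000 null
datasets for the ANOVA type-I rate (binomial SE ≈ 0.005 at α = 0.05),
500 trials for median recovery, and the full 14-sample study for the
end-to-end demonstration. Degenerate inputs error early with specific
messages (zero total sieve mass, non-positive volumes, dry weight above
fresh weight, non-positive ΔT, unbalanced factorial cells); physically
odd but possible readings (SI < 1, negative calorimeter constant,
off-nominal kit geometry, incomplete drying) warn and proceed. CSV
interchange is comma-delimited with period decimals and full
double-precision numerics, so write→read round trips are lossless and
repeated runs are byte-identical.

## Known limitations

* The ΔT extraction assumes the after-period drift is linear over the fit
  window; strongly curved backlash would need the integral correction.
* The 0.450 acidity coefficient and 396 cyanide factor are protocol
  constants valid only for their stated geometries.
* Only balanced 2 × 2 factorial designs are supported; more levels,
  unbalanced cells or mixed models are out of scope.
* Chart classification inherits the kit's coarse 10-shade resolution and
  the configurable (not standardised) shade values.
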