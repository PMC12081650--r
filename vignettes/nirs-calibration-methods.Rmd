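---
title: "Methods: multi-trait NIRS calibration with modified PLS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-trait NIRS calibration with modified PLS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirscal)
```

## The problem

Wet-chemistry assays of grain constituents (Kjeldahl protein, enzymatic
starch kits, colorimetric sugars, phenols and phytate) are accurate but slow,
destructive and expensive, which makes them a bottleneck for screening large
germplasm collections. Near-infrared reflectance spectroscopy measures, in
seconds and non-destructively, the apparent absorbance log(1/R) of milled
flour over 400–2500 nm, where overtones and combination bands of C–H, N–H,
O–H and C–O vibrations carry compositional information. A *calibration* links
those spectra to reference assay values so that future samples can be
predicted from the scan alone. `nirscal` implements the complete calibration
workflow used in practice for this kind of study and a synthetic data
generator that stands in for the instrument.

The package assumes spectra on a shared, strictly increasing wavelength grid
(the default conditions use 400–2500 nm at 2 nm, 1051 points) and per-sample
reference values in g/100 g. The central modelling assumption is the usual
one in NIR chemometrics: after scatter correction, absorbance is
approximately linear in constituent concentrations, with smooth baseline and
multiplicative/additive scatter as the dominant nuisance terms.

## Preprocessing

**SNV** standardizes each spectrum to mean 0, sd 1 (sample sd). It removes
exactly the per-spectrum affine nuisance `(1 + m)·A + o` produced by path
length and particle-size scatter. **Detrend** subtracts the least-squares
polynomial in wavelength, degree 2 by default (the standard detrend removes
offset, tilt and curvature); the fit uses an orthonormalized polynomial basis
on the wavelength grid rescaled to [−1, 1], so the result is a numerically
stable projection and idempotent to machine precision. **SNV-DT** applies SNV
first, then detrend — the conventional order; the configuration allows
swapping the scatter option if a sensitivity check is wanted.

**Gap–segment derivatives** follow the four-number code `"d,g,s1,s2"`:
boxcar smoothing with segment `s1`, then `d` applications of the centered gap
difference, then boxcar smoothing with `s2`. The gap difference is defined as

    D[i] = x[i + ceil(g/2)] − x[i − floor(g/2)]

so that a linear ramp with slope `a` per point maps to the constant `a·g` for
every gap, odd or even (for the even gaps used by the classic treatments the
window is exactly symmetric). A segment of 1 means no smoothing; even
segments are normalized up to the next odd value for a symmetric window, and
the normalization is announced as a message. Edges are handled by valid-region
trimming only — no values are fabricated at the spectrum ends — and the
trimmed wavelength grid travels with the result so that models and later
predictions stay aligned. Scatter correction is always applied before the
derivative.

## Outlier screening

Screening works in a principal-component score space fitted to the
(preprocessed) calibration spectra: the smallest number of components
explaining 99% of the spectral variance, capped at `min(20, n − 2)`. Scores
on each retained component are divided by that component's calibration score
sd, and

* **Global H** is the mean of the squared standardized scores,
  `GH = (1/k) Σ (t_i/s_i)²`. Its average over the fitting set is exactly
  `(n−1)/n`, so GH ≈ 1 for a typical sample and the conventional threshold
  GH &gt; 2.5 flags spectra far from the population (scanning errors, gross
  artefacts). This scaling — dividing by the component count — is the one on
  which the 2.5 threshold is meaningful.
* **Neighbourhood H** is the same standardized squared distance to the
  sample's *nearest neighbour*. Its conventional threshold is 0.6, but the
  literature is ambiguous about the direction: a large NH marks an isolated
  (artefact-like) spectrum, while a *small* NH marks a redundant
  near-duplicate. Both readings are implemented
  (`nh_mode = "isolate"`, the default, removes isolates;
  `"redundant"` greedily prunes near-duplicates); the default follows the
  outlier-removal reading.

Screening is performed once, on the preprocessed calibration spectra; an
optional second pass (`passes = 2`) re-fits the score model on the kept
samples and screens again, but is off by default. If every sample would be
flagged the screen refuses rather than return an empty calibration set, and
a calibration aborts if fewer than 10 samples survive.

One behaviour of this algebra is worth knowing: when a math treatment leaves
the spectra noise-dominated (in our simulations, gap-4 second/third
derivatives of smooth synthetic bands), the 99% variance rule climbs into
noise components, each standardized to unit variance, and nearest-neighbour
distances in that space exceed 0.6 for most samples. The screen then (rightly)
refuses to gut the set; `nirs_study()` logs the failure for that
trait/treatment combination and falls back to the surviving treatments.

## Splitting

`rank_ordered_split()` sorts samples in ascending order of the modelled trait
(ties broken by sample id, so the split is invariant to row order) and
assigns `n_validation` evenly spaced *interior* ranks to validation. The
minimum and maximum therefore always stay in calibration, calibration spans
the full trait range, and both sets sample the whole distribution — with 139
samples and 40 validation ranks this reproduces the conventional 99/40
(≈2:1) partition. Splits default to per-trait (each trait sorted on itself);
a shared split can be had by passing one trait's split to the lower-level
functions.

## Modified PLS

`fit_pls1()` implements single-response NIPALS PLS: center X and y; take the
factor weight proportional to `X_res' y_res`, scores as the projection on the
weight, x/y loadings by least squares, and deflate. With `modified = TRUE`
(the default, MPLS in the Shenk–Westerhaus sense) the spectral residuals at
each wavelength are divided by their standard deviation across samples after
every factor, so that later factors see all wavelengths' remaining
information on a common scale; y residuals are never scaled. The scaling
vectors are stored per factor and replayed exactly at prediction time.
With `modified = FALSE` the algorithm reduces to textbook PLS1, which the
test suite verifies coefficient-for-coefficient against an independent NIPALS
transcription.

Because deflation and rescaling are linear maps, the model also composes an
explicit coefficient vector per rank; predictions via coefficients and via
factor replay agree to 1e−8 by construction (tested). Extraction stops early
if the residual covariance vanishes (rank-deficient deflation), recording the
achieved rank. No variance scaling is applied to X or y before the first
factor — center-only, the common convention for this model family.

**Cross-validation.** Samples are shuffled into `n_groups = 5` groups by a
seeded draw (the count is a package default; the source studies rarely state
one) and every rank 0…max is scored by

    SECV(r) = sqrt( Σ (y_i − ŷ_i^(−g(i)))² / n )

from group-held-out predictions. Whether this denominator should be `n` or
`n − 1 − r` differs between software traditions, so both curves are stored
(`secv_n`, `secv_df`); `n` is the default and reports state which was used.
The chosen rank is the *smallest* whose SECV is within 2% of the minimum
(`parsimony_tol`, configurable) — a mild parsimony rule protecting against
the flat SECV minima typical of spectral data. `max_rank` defaults to
`min(16, floor(n/5))`, an overfitting guard at the ~100-sample scale.

## Validation statistics

For reference `y` and predictions `ŷ` on `n` held-out samples:
`bias = mean(ŷ − y)`; `SEP = sqrt(Σ(ŷ − y)²/n)`;
`SEP(C) = sqrt(Σ(ŷ − y − bias)²/(n−1))` (bias-corrected, the identity
`SEP² = SEP(C)²(n−1)/n + bias²` is a test invariant); `RPD = SD/SEP(C)` with
the conventional bands — below 1.5 unreliable, 1.5–2.0 screening-quality,
2.0–2.5 approximate quantitative, 2.5–3.0 good, at least 3.0 excellent. The
reported slope is the OLS slope of *reference on predicted* (values near 1
mean predictions track the assay one-to-one); RSQ is the squared Pearson
correlation, symmetric in its arguments, while the slope direction is not.
Sample standard deviations use the n−1 denominator throughout.

The paired t-test uses differences `d = y − ŷ`, `t = mean(d)/(sd(d)/√n)`,
`df = n − 1`, a two-tailed p-value and the symmetric 95% interval. Two-tailed
is a deliberate choice: the model is adequate when no systematic difference
is detectable. Degenerate cases are explicit: identical non-zero differences
are an error; exactly zero differences give t = 0 with a warning. Reliability
treats reference and prediction as strictly parallel measures: their common
correlation is the covariance over the pooled variance, stepped up by
Spearman–Brown at length two, `2r̄/(1 + r̄)`. Published "reliability
(unbiased)" values do not always follow this estimator exactly, so reports
state the formula used rather than treating those values as reproducible.

## The synthetic generator

`simulate_nirs()` emulates the study conditions the package's examples and
tests run under: 139 flour samples, five traits with the germplasm
distributions observed for horse gram (protein 23.7 ± 0.99, range 21.8–26.7;
starch 29.8 ± 1.36, 26.2–33.0; total soluble sugars 5.61 ± 2.50, 0.86–12.1;
phenols 0.701 ± 0.17, 0.340–1.13; phytic acid 1.02 ± 0.44, 0.110–2.12
g/100 g), drawn from truncated normals (rejection sampling, hard bounds).
Spectra are a linear Beer–Lambert mixture: each trait contributes Gaussian
absorption bands placed at the seven absorption maxima of legume flour
spectra (1196, 1468, 1736, 1934, 2100, 2310, 2482 nm), following the usual
functional-group assignments (protein near 2100–2310 nm, phenols at 1468 nm,
polysaccharides at 1934 nm, C–H overtones at 1196/1736 nm). Because no
quantitative absorptivities exist for this matrix, band strengths and widths
are stated generator defaults, not measured facts: widths of 20–32 nm
(FWHM ≈ 50–75 nm, the size of real NIR combination bands) and strengths that
put each trait's band-level signal well above noise. Under these defaults the
two traits with the largest spectral signal (band strength × concentration
sd) are total soluble sugars and starch. The nuisance model is a quadratic
baseline, per-sample multiplicative (sd 0.05) and additive (sd 0.02) scatter
— exactly the family SNV-DT removes — and additive Gaussian noise with
sd 1e−4 absorbance units, the order of the RMS noise a scanning
monochromator reaches after 32-scan averaging.

What the generator does *not* emulate: the dense forest of overlapping
minor-constituent bands of real flour (water, cellulose, lipids), wavelength-
dependent scatter, temperature/moisture drift, reference-assay error, and
trait-trait correlations (traits are drawn independently). Real calibrations
therefore achieve far lower RSQ/RPD than the synthetic ones — in the
simulation the model family matches the data-generating process, so recovery
is nearly perfect. Passing the end-to-end tests shows the pipeline is
implemented correctly and can recover known structure at realistic n, noise
and preprocessing; it does not certify field performance on real spectra.
Note also that with five paired t-tests per run, roughly one synthetic study
in four will show a single p &lt; 0.05 by chance alone under an unbiased
model; the documented end-to-end checks run at master seed 1.

## Numerical and design choices

* Treatment strings are parsed and rendered exactly as `"d,g,s1,s2"`.
* Treatment selection among a configured grid uses the smallest SECV by
  default; selecting on validation SEP(C) (`select_by = "validation"`), as
  some studies do, leaks the validation set into model choice and is
  available only as an explicit opt-in.
* All randomness in a study run (cross-validation grouping) flows from one
  seeded stream; identical seed and inputs give bit-identical tables, and
  reports carry a provenance JSON (seed, configuration, config hash,
  package version).
* Models serialize to JSON at full double precision; a saved model is a fixed
  point of write→read→write, and reloaded models reproduce predictions to
  better than 1e−12 relative.
* Degenerate inputs fail loudly and early: constant spectra (SNV), zero
  variance responses, grids too short for a treatment, all-samples-flagged
  screens, splits with out-of-range validation counts.
* Problem sizes: examples and tests use 139 samples × 1051 wavelengths for
  the end-to-end study (seconds on one core) and smaller seeded fixtures
  (15–60 samples, 25–120 wavelengths) for unit and property tests.

## Limitations

Only PLS1/MPLS is provided (no PLS2, PCR or MLR); MSC-family scatter
corrections are out of scope; spectra I/O is delimited text only (no
instrument binary formats); and the outlier thresholds, while conventional,
are scale-dependent — on data whose preprocessed variance is noise-dominated
the NH rule flags aggressively, which the pipeline surfaces as a logged
refusal rather than silently weakening the screen.
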