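---
title: "Quantifying ethanol in fermented beverages by MIR-PLS: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ethanol in fermented beverages by MIR-PLS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirpls)
```

## The calibration problem

Fermented beverages are, to first order, water, ethanol and sugars.
In the mid-infrared, ethanol absorbs through its C–O stretching bands
(roughly 1200–950 cm⁻¹) and an O–H bending band near 900–850 cm⁻¹, but
the C–O and C–C bands of glucose, fructose, sucrose and maltose crowd the
same window. No single wavenumber is selective for ethanol, so a
univariate Beer–Lambert calibration fails; a multivariate model that
exploits the *shape* difference between ethanol and sugar absorption is
required. `mirpls` works in the 1200–850 cm⁻¹ window at 1 cm⁻¹ spacing —
351 spectral variables — which captures both the sensitive C–O region and
the more ethanol-exclusive low-wavenumber band.

The calibration set is synthetic by design: 25 five-component standards
with ethanol spanning 2–10 % w/w and each sugar 0–5 % w/w, drawn
independently so that no sugar concentration is correlated with ethanol.
Building the model from synthetic standards rather than real beverages is
the point of the workflow — representative sampling of highly variable
traditional beverages is impractical, while a designed standard set spans
the composition space directly.

## PLS1 regression via NIPALS

With `X` the matrix of pre-treated spectra (n samples × 351 variables)
and `y` the ethanol concentrations, both column-centred, NIPALS extracts
latent variables one at a time:

1. weight vector `w = Xᵀy / ‖Xᵀy‖`;
2. scores `t = Xw`;
3. X-loadings `p = Xᵀt / tᵀt` and y-loading `q = yᵀt / tᵀt`;
4. deflation `X ← X − t pᵀ`.

Only `X` is deflated; for a single response deflating `y` as well changes
nothing. Successive score vectors are mutually orthogonal (asserted to
1 × 10⁻⁸ relative in the tests), the algorithm is deterministic, and the
model collapses to a single regression vector
`b = W (PᵀW)⁻¹ q`, so prediction is one affine map per spectrum. When as
many components as the data's rank are extracted, PLS1 predictions
coincide with the least-squares fit; the test suite checks this against
an SVD pseudo-inverse oracle at 10⁻⁶.

If deflation exhausts the data's effective rank before the requested
component count, `fitPLS()` and `looCV()` stop with a rank error (naming
the cross-validation fold at fault), while `selectNLV()` — whose job is to
scan component counts — reuses each fold's largest extractable model for
the higher counts so that the RMSECV curve flattens instead of erroring.

## Pre-treatment chains

Twelve named chains are registered (`pipelineNames()`): `"raw"` plus the
eleven combinations of

* **subtract minimum** — per spectrum, shifts the minimum to 0; removes
  constant offsets;
* **normalization** — per-spectrum min–max scaling to [0, 1] by default.
  The operation's definition is a genuine design choice: unit-vector and
  unit-area alternatives are available via `normMethod`, and the choice is
  recorded in the pipeline (and therefore in serialized models);
* **derivative** (1st or 2nd) — Savitzky–Golay, i.e. a least-squares
  polynomial fit in a sliding window, differentiated analytically.
  Defaults: window 9 points, polynomial degree 2 for the 1st derivative
  and 3 for the 2nd. Savitzky–Golay was chosen over plain finite
  differences because differencing amplifies high-frequency noise, which
  matters at 2nd order. Derivatives are taken with respect to wavenumber
  (AU per cm⁻¹ᵒʳᵈᵉʳ), so grids with different spacing give comparable
  values. Output keeps the full grid length — end points come from the
  filter's end-window polynomial fits — so every chain presents the same
  351 variables to the regression;
* **mean centering** — column means, *learned on the calibration set* and
  stored in the pipeline. Applying a fitted pipeline to new spectra always
  reuses the stored means; centring a prediction sample on itself would
  leak information and destroy the affine prediction map.

Operators apply in the order named, left to right. Region restriction to
1200–850 cm⁻¹ happens before any derivative, so filter edge effects sit at
the window boundaries rather than inside a wider grid that is cut later.

## Cross-validation and model size

`looCV()` implements full leave-one-out validation: for each of the n
standards, the pipeline *and* the PLS model are re-fitted from scratch on
the other n − 1 and the held-out spectrum is predicted, giving n
sub-models and n out-of-fold predictions. Re-fitting the pipeline state
inside each fold costs a little time but avoids leaking the held-out
sample's contribution to the column means.

Reported figures of merit:

| quantity | definition |
|---|---|
| RMSEE / RMSECV / RMSEP | √(Σe²/n) on calibration fit, LOO predictions, external set |
| SEC / SECV / SEP | √(Σe²/(n − nLV − 1)), the dof-corrected analogues |
| R²cal / R²cv / R²pred | 1 − SSres/SStot against the reference values |

Both the plain and dof-corrected errors are reported because conventions
differ between software packages; they agree as n grows (tested at
n = 10⁴ to 0.1 %).

`selectNLV()` picks the component count by parsimony: the smallest count
whose RMSECV lies within a margin of the curve minimum. The margin is the
larger of a 2 % relative tolerance and one standard error of the minimum
RMSECV (delta method over the held-out squared errors). The one-SE guard
matters: with only 20–25 LOO folds the RMSECV estimate itself fluctuates
by ~10 %, so a bare relative tolerance routinely "buys" an extra
component for a chance dip in the curve that carries no predictive
meaning. This is the standard one-standard-error rule of cross-validated
model selection. The relative tolerance remains a parameter.

`comparePretreatments()` ranks chains lexicographically: higher
validation R², then lower RMSEP, then fewer latent variables, then input
order. Preferring fewer components on ties reflects the usual robustness
argument — every extra latent variable is another direction along which
new samples can drift outside the calibrated space. A chain that fails on
a given data set (e.g. normalization of a flat spectrum) becomes a
flagged `NA` row rather than an error, so one degenerate transform cannot
sink a comparison.

`pcaScreen()` supports the pre-modelling habit of looking at the standard
spectra before trusting them: centred PCA via SVD, per-sample Hotelling
T² over the first k score dimensions, and the (1 − α) limit
`k(n−1)(n+1)/(n(n−k)) · F₁₋α(k, n−k)`. Flagged samples produce a warning
and a flag column; nothing is ever silently dropped, because an apparent
spectral outlier in a designed standard set is a preparation error to
investigate, not a point to delete automatically.

## The spectrum simulator

`simulateDataset()` exists so the entire workflow is exercisable, and
testable end to end, without an instrument. It emulates:

* the 25-standard composition design (independent uniform draws within
  the calibration ranges; a Latin-hypercube option is available);
* Beer–Lambert additivity: each noiseless spectrum is the
  concentration-weighted sum of pure-component spectra;
* pure components as sums of Gaussian bands. Band *locations* follow the
  known mid-IR assignments (ethanol C–O near 1087 and 1045 cm⁻¹, the
  weaker band near 880 cm⁻¹; sugar bands crowding 950–1150 cm⁻¹); widths
  and absorptivities are synthetic fixtures chosen to give realistic
  ATR-scale absorbances (the strongest ethanol band reaches ≈ 0.25 AU at
  10 % w/w). The deliberate sugar–ethanol overlap is what makes the
  multivariate model necessary, so the simulator reproduces the
  *structure* of the problem, not just its dimensions;
* instrument noise: i.i.d. Gaussian, σ = 5 × 10⁻⁴ AU by default, fresh
  per replicate (3 replicates per standard by default, averaged before
  modelling as instrument replicates would be);
* optionally, a random per-spectrum quadratic baseline drift of
  configurable amplitude, for studying which pre-treatments survive
  baseline variation (derivative chains do; normalization alone does
  not — a property the test suite checks by majority vote over 10 seeds).

Simulated absorbance is floored at zero: the additive-noise model can
otherwise dip below zero in near-transparent regions, and measured
absorbance of these mixtures cannot. The floor only bites where the
signal is already ≈ 0 and does not disturb calibration recovery.

All randomness flows from the single `seed` slot (the spectral noise
stream is offset from the design stream so the same design can carry
different noise realizations); equal seeds give bit-identical data sets.

What the simulator does **not** model: real-beverage matrix components
(proteins, polyphenols, organic acids), water displacement effects on the
baseline, ATR penetration-depth dispersion, detector nonlinearity, or
wavenumber calibration drift. Passing the recovery tests on simulated
data therefore demonstrates that the algorithms are correct and that the
figures of merit are attainable under the stated noise model — not that
any particular instrument will achieve them on real samples.

## GC-FID reference calibration

The reference method quantifies ethanol against n-propanol as internal
standard: an ordinary least-squares line of peak-area ratio versus
concentration, `fitCalibrationCurve()`. The residual standard deviation
uses n − 2 degrees of freedom, and the detection/quantification limits
follow the 3σ and 10σ convention, LOD = 3σ/|slope|, LOQ = 10σ/|slope| —
reading "σ of the residuals about the regression" in the standard ICH
sense, as the commonly quoted alternative (σ of repeated intercept
estimates) is not recoverable from a single calibration table. LOQ/LOD
= 10/3 identically, which the class validity enforces.

`wwToVv()` converts % w/w to % v/v with the empirical affine line used
alongside the GC method. Its intercept (0.137 % v/v at 0 % w/w) is
non-physical but is reproduced as the reference defines it; a clearly
separate density-ratio conversion (`method = "density"`, water/ethanol
densities at 20 °C, through the origin) is provided for users who prefer
a physical rule. The two disagree by design; the affine form is the
default because it is the one the reference results are expressed in.

## Numerical choices and degenerate inputs

* Grid: stored ascending; descending input (the native direction of many
  FT-IR exports) is reversed together with the spectra on ingestion.
  Uniform spacing is enforced at 10⁻⁶ relative tolerance because the
  derivative filters assume it.
* NIPALS rank tolerance: a component is refused when the residual
  covariance norm falls below 10⁻¹² of the initial spectral scale.
* Flat spectra cannot be min–max normalized (error, naming the sample);
  zero-variance responses cannot be regressed (error).
* `quantifyEthanol()` reports negative concentrations (ratios below the
  calibration intercept) with a warning rather than clipping: a censored
  zero would bias any downstream averaging.
* Presentation rounding (3 significant figures for recovery tables) is
  confined to a dedicated column; all stored values keep full precision.

## Problem sizes

The shipped tests and the acceptance script run the calibration study at
its native size — 25 standards × 3 replicates × 351 variables, full
leave-one-out — and the pre-treatment comparison on the same scale with
10-standard external validation sets; Monte-Carlo checks use 200
replications. The complete suite runs in about a minute on one core.

## Known limitations

* PLS1 only: one response per model. Quantifying the sugars would take
  one model each (or PLS2, out of scope).
* JCAMP-DX ingestion covers AFFN-encoded XYDATA/XYPOINTS records, not the
  SQZ/DIF/DUP compressed forms some instruments emit.
* No atmospheric compensation, ATR effective-pathlength correction, or
  interferogram-level processing: spectra are expected already processed
  to absorbance against the appropriate background.
* The validation statistics (recovery, paired comparison) assume the
  spiked and unspiked determinations come from the same calibrated
  instrument; between-instrument transfer is not addressed.
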