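---
title: "FT-IR chemometric model selection with ftirpls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FT-IR chemometric model selection with ftirpls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Mid-infrared fingerprints of plant material encode relative amounts of
polysaccharides, saponins, proteins, lipids and mineral salts. For *Panax
ginseng* root powder this opens a practical route to two quality-control
questions that are otherwise answered by slow chemical assays: how old was
the plant at harvest (5 versus 6 cultivation years), and which part of the
root system (tap root, rhizome, lateral root) went into a powder.

`ftirpls` implements the full chemometric workflow for these questions:

1. **Preprocessing.** Percent transmittance is converted to absorbance
   (A = -log10(T/100)); on the vector-normalization path the spectra are
   differentiated with a Savitzky-Golay filter (9 smoothing points,
   quadratic fit by default); the water-vapor region (4000-3500 cm^-1) and
   the two CO2 regions (2442-2208 and 914-600 cm^-1) are excised; and one
   of three normalizations is applied -- division by the trapezoidal
   integral (area), by the max-min range (min-max), or by the Euclidean
   norm (vector).
2. **Modelling.** NIPALS partial least squares on unit-variance (UV) or
   Pareto-scaled matrices, used as PLS-DA/PLSR with a dummy-coded class
   response. Fit is summarized by R2Y, predictive ability by Q2Y from
   7-fold venetian-blinds cross-validation (1 - PRESS/SS).
3. **Validation.** A permutation test (400 label permutations by default)
   plots R2Y and Q2Y against the absolute correlation between permuted and
   original responses; least-squares intercepts at zero correlation
   estimate the chance-fit level. A model is *valid* when the R2Y
   intercept is below 0.4 and the Q2Y intercept below 0.05.
4. **Selection.** Stage 1 screens every (normalization x scaling x
   1..3 components) cell by the validity gate and picks, per
   normalization, the valid cell with the highest Q2Y. Stage 2 holds out
   one analytical replicate per biological sample, computes VIP scores on
   a training-only fit, sweeps VIP cutoffs (0.5, 0.7, 1.0, 1.3, 1.5 by
   default), refits on the retained variables, and ranks valid candidates
   by RMSEP on the held-out replicate. For the two age classes, 12 months
   apart and dummy-coded 0/1, RMSEP in class units times 12 is the error
   in months.

```{r, eval = FALSE}
library(ftirpls)
s <- generate_spectra(default_design(), seed = 1)
report <- run_discrimination(s, "age_within_part", "tap_root",
                             grid_spec(n_permutations = 100, seed = 1))
report
report$winner
```

## Conventions and numerical choices

Several quantities in this workflow are convention-dependent; the package
fixes them as follows.

* **Dummy coding.** Two classes map to a single 0/1 column. This keeps
  RMSE in class units, so the months conversion is exact multiplication
  by the 12-month class gap; three classes map to one-hot columns with
  argmax class calls (threshold 0.5 for two classes).
* **Cross-validation.** Q2Y uses 7 contiguous-interleaved ("venetian
  blinds") folds over sample order by default; fold count and a
  randomized scheme are arguments. Scaling and response centering are
  refit inside every training fold.
* **RMSEE** divides by `n - 1 - A` (the estimation-error convention of
  commercial PLS software); `df_correct = FALSE` gives the plain
  root-mean-square residual.
* **NIPALS** deflates both blocks per component, tolerance 1e-10 on the
  score vector, at most 500 iterations; single-response models converge
  in one pass. The sign of each weight vector is fixed so its
  largest-magnitude element is positive, making fits reproducible to the
  bit under a fixed seed.
* **VIP** uses the explained-Y-variance-weighted formula whose mean
  square over variables is 1; selection is strict (`VIP > cutoff`).
* **Permutation intercepts** come from unconstrained least squares over
  the permuted points plus the unpermuted model at correlation 1. An
  alternative that anchors the line at the unpermuted point is available
  (`anchored = TRUE`). With a flat point cloud both reduce to the cloud
  mean.
* **Stage order.** Derivatives are taken on the full contiguous grid
  *before* region removal (a filter run across an excision boundary would
  manufacture edge artifacts), and normalization constants use only the
  retained points. Region boundaries are closed intervals: a grid point
  at exactly 3500 cm^-1 is removed.
* **Stage-1 screening fits on all replicates; stage-2 metrics are
  strictly split.** VIP scores are computed from a training-set-only fit:
  computing them on all data would leak the held-out replicate into
  variable selection. The held-out replicate demonstrably cannot affect
  any training-side number (a perturbation test asserts bit identity).
* **ATR correction** is deliberately not implemented: the instrument
  vendors' algorithms are proprietary. The preprocessing entry points
  accept absorbance matrices from any external correction.

## The synthetic data generator

No public FT-IR archive of aged ginseng root exists, so the package ships
a generator that emulates the *structure* of such a study rather than any
particular instrument: a 4000-652 cm^-1 grid at 4 cm^-1 spacing (838
points), eight Gaussian absorption bands at the characteristic
wavenumbers (3335, 2923, 1733, 1621, 1417, 1373, 1253, 1018 cm^-1),
atmospheric artifact bands inside the three excluded regions, 12 plants
per age class, three root parts, and six analytical replicates per
powdered sample (432 spectra in total).

The noise model has four layers with these defaults:

| parameter | default | meaning |
|---|---|---|
| `plant_amplitude_cv` | 0.06 | between-plant lognormal CV of every band amplitude |
| `scatter_sd` | 0.05 | per-replicate multiplicative (lognormal) scatter |
| `baseline` | (0.01, 1e-5) | per-replicate linear drift: offset sd (absorbance), slope sd (absorbance/cm^-1) |
| `replicate_noise_sd` | 0.002 | additive Gaussian noise per grid point |

Class effects are band-amplitude multipliers: the 6-year class raises the
ginsenoside-associated bands (3335, 2923) by 30% and the polysaccharide
band (1018) by 30%; parts differ through the calcium-oxalate band (1621:
rhizome 1.4, lateral root 0.7) and 1018 (tap root 1.2, lateral root 0.8).
`truth_table()` reports exactly these bands, with a one-FWHM window either
side, as the ground truth for variable-selection recovery.

Two design considerations behind the defaults are worth making explicit,
because they were genuinely open choices:

* **Band balance and closure.** All per-sample normalizations impose a
  closure constraint: raising some bands must lower the normalized value
  of the others. If the class-affected bands dominated the total spectral
  mass, normalization would transfer most of the class signal onto the
  *unaffected* bands and variable selection would "discover" the wrong
  wavenumbers -- a real phenomenon in normalized spectra, but fatal for a
  recovery benchmark. The default band library therefore puts the largest
  amplitudes on class-neutral bands (1621 strongest), keeping the truth
  bands identifiable after any of the three normalizations.
* **Noise floor and the validity gate.** The permutation R2Y intercept
  estimates the chance-fit level of the predictor matrix, which is almost
  independent of the true labels; the 0.4 gate therefore separates signal
  from chance only when the data's chance-fit R2Y sits near that value.
  The default noise floor is set so that the second-derivative/UV
  reference configuration has a chance-fit level above the gate (a
  structureless dataset is correctly declared invalid there) while the
  Pareto and underivatized paths remain below it (so screening can accept
  genuinely predictive cells). This is a known limitation of fixed
  intercept thresholds, not of the implementation: at other noise
  regimes, or other sample sizes, the same gate can pass structureless
  data or reject real structure wholesale.

What the generator does *not* emulate: ATR penetration-depth effects,
Lorentzian/Voigt line shapes, detector nonlinearity, wavenumber
calibration drift, or biologically realistic effect sizes (the true
5-versus-6-year differences are unknown; the defaults are tuned only so
that recovery is neither trivial nor impossible, and every number derived
from them is a property of this synthetic regime, not of ginseng).
Passing the recovery suite therefore shows the *machinery* is correct and
leak-free; it does not certify field performance on real spectra.

## Problem sizes used by the test and acceptance runs

Unit tests run on reduced layouts (2-6 plants per group, single part)
with 20-50 permutations; the end-to-end acceptance checks use the full
default design (432 spectra; 144 in the tap-root age task) with 100
permutations per screen cell across seeds 1-5, and 10-20 null-design
runs at 50 permutations. These sizes are the package's own choice of a
desk-scale experiment; all of them are arguments, and a study-scale run
(400 permutations, as in the validation literature) changes only
`n_permutations`.

## Known limitations

* JCAMP-DX support covers single-spectrum XYDATA/XYPOINTS files with
  AFFN/SQZ/DIF/DUP ordinates; compound and NTUPLES files are rejected
  rather than guessed at.
* Spectra on different grids are never interpolated; merging unequal
  grids is an error by design.
* The permutation validity gate inherits the fixed-threshold caveats
  described above; treat "valid" as "not obviously chance" rather than a
  calibrated error rate.
* Min-max normalization divides by the range without subtracting the
  minimum -- the convention of the workflow this package operationalizes
  -- so normalized spectra have unit range but not necessarily a zero
  minimum.
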