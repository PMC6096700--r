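---
title: "Water correction and chemometrics for live-cell infrared microspectroscopy"
author: "aquaspec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Water correction and chemometrics for live-cell infrared microspectroscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquaspec)
```

## The problem

Transmission FTIR microspectroscopy of *living* cells requires the cell to
sit in an aqueous chamber. Liquid water absorbs strongly near 1640
cm⁻¹ (O–H bending, overlapping amide I) and across 3000–3500 cm⁻¹ (O–H
stretching, overlapping the C–H region), so at usable pathlengths (6–12 µm)
the bulk-water signal dominates and, at the long end, drives the detector
toward saturation in the bending region. Before any biological
interpretation, the bulk-water contribution must be estimated and removed —
without also removing the cell's own structural water (roughly 70% of cell
mass) or the subtle band changes that carry the biology.

`aquaspec` implements a complete desk-scale version of this workflow:
reference-based water correction, spectral conditioning, supervised
classification, and a forward simulator of the measurement itself that
provides ground truth for validating every stage.

## The correction model

Each cell spectrum is acquired together with a paired bulk-PBS spectrum from
an adjacent cell-free area. Over the fit window 1500–1700 cm⁻¹ (amide
region), the sample is modelled by ordinary least squares as

$$ s(\tilde\nu) \;\approx\; \alpha\, m(\tilde\nu) \;+\; \beta\, w(\tilde\nu)
\;+\; b_0 + b_1 \tilde\nu , $$

where $m$ is a protein (Matrigel) reference, $w$ the cell's own paired PBS
spectrum, and $b_0, b_1$ a linear baseline. Only the scaled water term
$\beta\,w$ — the "water to be removed" — is subtracted, over the *full*
grid. The reference weight $\alpha$ and the baseline are diagnostics: they
exist so that protein signal and offset drift are not funnelled into
$\beta$, but they are never subtracted, which is what protects cellular
signal (including structural water) from removal.

Key choices, and why:

* **Joint two-component fit.** A fit of the sample to the reference alone
  does not identify a PBS coefficient; including the PBS spectrum as a
  second regressor is the minimal model in which $\beta$ is defined. The
  window is the default `waterFitConfig(fitLo = 1500, fitHi = 1700)`.
* **Non-negativity.** Negative bulk-water content is unphysical; if the
  unconstrained solution gives $\beta < 0$ it is clipped to zero, the other
  terms refit, and the result flagged (`nonneg_clipped`).
* **Collinearity guard.** If the reference and PBS spectra are nearly
  collinear over the window (design condition number > 1e8), the fit errors
  out rather than returning a silently meaningless $\beta$.

Two literature-style comparison methods are included: `fitByFlatness()`
chooses the water scale minimising the roughness (RMS deviation from a
straight line) of the corrected spectrum over the biochemically silent
1800–2500 cm⁻¹ region, with a default search bracket of [0, 3] covering
under- to strong over-correction at ≤ 20 µm paths; `iterativeReaddition()`
re-adds scaled water until the baseline means in 50 cm⁻¹ flanks on either
side of the 2900 cm⁻¹ C–H stretch (2750–2800 and 3000–3050) balance. The
flank widths are fixed so the operation is testable; the objective is
piecewise linear in the re-addition scale, so the closed-form root is used
with a dense-scan safety net.

## Preprocessing

Two preset chains are shipped (`preprocessConfig(preset = ...)`), matching
the two workflows the package targets:

* `spacer_eval`: quality control → 9-point Savitzky-Golay smoothing
  (order 2) → vector normalisation. The polynomial order for the 9-point
  smoother is not dictated by anything upstream; order 2 is the standard
  smoothing choice and is recorded as an assumption.
* `drug_study`: quality control → vector normalisation → second derivative
  (one Savitzky-Golay differentiation, 13 points, order 3) → cut to
  1100–1575 ∪ 2750–3000 cm⁻¹. The cut removes the saturated water-bending /
  amide I region, the noisy region below 1100 cm⁻¹ and the empty
  1800–2800 cm⁻¹ range. Differentiation and smoothing are a *single*
  operator — differencing first and smoothing afterwards is numerically
  inferior and is not what an SG derivative means.

Step order is configuration, not convention: normalising before or after
cutting changes the result (the norm is computed over the current grid), so
both orders remain expressible and the presets pin down the two reference
orders. Second-derivative spectra are not re-normalised unless the step
list says so.

Quality control computes three diagnostics per spectrum and excludes
(never mutates) failures: amide-region (1600–1700) peak height above a
local linear baseline ≥ 0.05 AU (empty-aperture guard), maximum absorbance
≤ 2.5 AU anywhere (saturation guard), and silent-region (1800–2500) noise
RMS after linear detrend ≤ 0.01 AU. The thresholds are package defaults
chosen to pass clean simulated spectra and fail the simulator's saturated
and noise-corrupted fixtures; no upstream criteria exist to inherit.

The Savitzky-Golay filter itself is `signal::sgolayfilt`: edge points come
from one-sided polynomial fits (no truncation), and derivative output is
scaled by the grid spacing to AU·(cm⁻¹)⁻ᵈ. It requires a uniform grid
(relative spacing tolerance 1e-6) and, after a region cut, is applied per
region so it never filters across the gap.

## Classification

Spectra are compressed by mean-centred PCA; the component count is the
smallest reaching a 95% cumulative variance target, with a hard cap of 21 —
this reproduces "21 PCs ≈ 95% of variance" behaviour on data of comparable
rank while staying defined on any input. Canonical variate analysis then
solves

$$ S_b\, v = \lambda\, (S_w + r I)\, v $$

for the between-class ($S_b$) and pooled within-class ($S_w$) scatter of
the PC scores, via Cholesky whitening and a symmetric eigendecomposition.
The ridge $r$ defaults to $10^{-8}\,\mathrm{tr}(S_w)/d$ — numerically
inert when $S_w$ is well-conditioned, decisive when it is singular. At most
(classes − 1) canonical vectors exist; they are unit-norm with a
deterministic sign convention.

Classification is nearest class centroid by Euclidean distance in canonical
space (no classifier is dictated upstream; nearest-centroid is the simplest
rule consistent with "grouping in the score plot", and a Mahalanobis-style
weighting can be emulated by the ridge). Exact ties go to the
lexicographically first class and are flagged.

Cross-validation is stratified k-fold (default k = 5) with a recorded seed.
Within each fold the PCA *and* the CVA are refit on the training rows only
and the held-out rows projected in — the held-out spectra never influence
the subspace, so the accuracy estimate is leakage-free. Stratification is
used because per-class counts around 120 make unstratified folds
needlessly noisy. A whole-data-PCA variant exists behind
`wholeDataPCA = TRUE` for comparison only.

## The measurement simulator

`generateStudy()` emulates the paired acquisition design: per class,
`nPerClass` cells (default 120) over `replicates` loadings (default 3),
each cell with its own adjacent-PBS measurement. The forward model is:

* **Cell**: a sum of Gaussian bands — amide I (1650/45 cm⁻¹ FWHM), amide II
  (1545/40), tyrosine ring (1515/16), C–H and COO⁻ bending (1455, 1398),
  DNA/RNA phosphate stretches (1244, 1217, both 25 FWHM), carbohydrate
  (1155), symmetric phosphate (1085), four lipid C–H stretches
  (2852–2958/20), and an O–H stretch band at 3390/180 for intracellular
  structural water scaled by the 0.70 mass fraction. The structural-water
  *bending* mode overlaps amide I completely and is absorbed into the
  amide I band height rather than double-counted. Band positions follow
  standard assignments; widths are package constants chosen so the analysis
  windows are meaningful.
* **Water**: bending band at 1640 (90 FWHM), a two-component stretching
  envelope (3280/260, 3490/200), and the weak combination band at 2130
  (8% of the bending peak). All heights scale linearly with the spacer
  pathlength (Beer–Lambert), at 0.25 AU/µm at the bending peak — placing a
  12 µm layer around 3 AU, at the edge of usability, as intended.
* **Measurement**: true absorbance `cell + c_w · water` with the per-cell
  water fraction `c_w ~ U(0.85, 1.15)` (local path variation around the
  cell) and an independent PBS draw near 1; detector saturation as a
  stray-light floor in transmittance space,
  $A_{app} = -\log_{10}(10^{-A} + 10^{-L})$ with ceiling $L$ = 3.5 AU
  (monotone, bounded, differentiable — it reproduces the flattening of
  strong bands with one parameter); additive Gaussian noise (default
  0.002 AU, bright-source quality) on sample and PBS independently.
* **Heterogeneity**: per-cell lognormal band-height jitter (sd 5%) and a
  per-replicate lognormal gain (sd 2%) emulating loading-to-loading
  variation.
* **Drug effects**: multiplicative band-height changes. The default
  three-class design is control; a DNA cross-linker raising the 1217/1244
  phosphate stretches by 30%; and a protein kinase inhibitor perturbing the
  amide II region (amide II ×1.15, tyrosine ring ×1.35). Effect sizes are
  calibration constants of the simulator, not measured values.

The Matrigel reference is synthesised water-free as the protein-only subset
of the cell profile (amide I, amide II, tyrosine, C–H/COO⁻ bending), and
PBS is modelled as pure water — its mid-IR salt features are negligible at
these pathlengths. The default grid is 1000–3600 cm⁻¹ at 2 cm⁻¹ spacing, a
typical mid-IR digitisation; nothing upstream fixes it.

### What the simulator does and does not capture

It captures the features the analysis chain actually exercises: paired
water scaling with pathlength, near-saturation of the bending mode at
12 µm, band-local drug effects, biological heterogeneity, replicate batch
gains and measurement noise. It does **not** simulate Mie or resonant-Mie
scattering (refractive-index matching in aqueous holders makes it
negligible, and it is out of scope), atmospheric water-vapour lines,
instrument line-shape effects, or real biochemical covariance between
bands. Passing tests therefore demonstrate the correctness and calibration
of the *algorithms* under a faithful forward model — not performance on any
particular real dataset.

### A real limitation found with the simulator

A *broad* class difference inside the 1500–1700 fit window (e.g. a pure
amide II height change, FWHM 40, overlapping the 1640 water bend) is
partially absorbed by the least-squares fit: part of the change is
attributed to water, biasing the per-cell coefficient by a few percent and
leaving a class-correlated water residual spread across the spectrum by
vector normalisation. Sharp features (the 25 FWHM phosphate bands, the 16
FWHM tyrosine band) are nearly orthogonal to the smooth regressors and
survive correction intact. This is a genuine property of reference-window
least-squares water correction — subtle broad protein changes inside the
fit window should be interpreted with caution, while sharp fingerprint
features are trustworthy. The default kinase signature includes the sharp
tyrosine component for exactly this reason.

## Numerical choices

* Axis order is ascending everywhere; descending files are silently
  reversed on read (one convention removes a class of derivative sign
  errors). Window intervals are closed on both ends, matching how
  "1100–1575" ranges are quoted.
* Core resampling is piecewise-linear only: monotone, exactly testable
  against a two-point oracle, and adequate at 2–4 cm⁻¹ spacing.
* Scalar flatness optimisation to 1e-6 on the scale; eigen-solutions
  validated against independent dense decompositions to 1e-8 in tests.
* Degenerate inputs have defined behaviour: an all-zero water spectrum in
  the flatness method returns the lower bracket end flagged `degenerate`;
  a single class refuses CVA; an unpaired cell is flagged and passed
  through rather than dropped; empty sets correct to empty sets.
* All randomness flows from one root seed (fold assignment and the
  simulator restore the caller's RNG state).

## Problem sizes used in validation

The shipped tests and the acceptance script run entirely on simulated
data: the three-class study at its design size (120 cells per class,
3 replicates, 10 and 12 µm), null calibrations at 100 cells per class over
20 seeds, 100-draw Monte-Carlo water-fit recovery, and 100 random
instances (≤ 30 dimensions) for the eigen-solver cross-checks. These sizes
keep every Monte-Carlo bound meaningful at desk scale.
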