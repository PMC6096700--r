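# aquaspec

Water correction and chemometrics for transmission FTIR microspectroscopy of
live single cells in aqueous media.

## The problem

Measuring living cells by infrared microspectroscopy means measuring them
*through* water: the O–H bending band (~1640 cm⁻¹) sits on top of amide I and
the stretching envelope (3000–3500 cm⁻¹) on top of the C–H region, and at
pathlengths of 10–12 µm the bending mode approaches detector saturation.
`aquaspec` is for spectroscopists who need to (1) remove the bulk-fluid
contribution from each cell spectrum without destroying cellular signal,
(2) condition the corrected spectra (quality control, Savitzky-Golay
smoothing / second derivative, vector normalisation, region cutting), and
(3) quantify whether treatment classes separate, with honest leakage-free
cross-validation. A forward simulator of the whole measurement (Beer–Lambert
band mixtures, pathlength-scaled water, detector saturation, paired PBS
acquisition, drug-effect band perturbations) provides ground truth for
validating every stage.

## The method

Each cell spectrum `s` comes with a paired bulk-PBS spectrum `w` measured in
an adjacent cell-free area. Over the 1500–1700 cm⁻¹ amide window, the
package fits by ordinary least squares

```
s(ν̃) ≈ α·m(ν̃) + β·w(ν̃) + b₀ + b₁ν̃
```

against a protein (Matrigel) reference `m`, and subtracts **only** the
scaled water term `β·w` over the full spectrum (α and the baseline are
diagnostics — they keep protein signal and drift out of β, and are never
removed). β is constrained non-negative; a collinear design is an error, not
a silent bad fit. Two literature comparison methods are included: scale
selection by silent-region (1800–2500 cm⁻¹) baseline flatness, and iterative
water re-addition balancing the flanks of the 2900 cm⁻¹ C–H stretch.

Classification is PCA (95% variance, capped at 21 components) followed by
canonical variate analysis — the generalized eigenproblem
`S_b v = λ (S_w + rI) v` on PC scores — with nearest-centroid assignment in
canonical space and stratified k-fold cross-validation in which PCA and CVA
are refit per training fold.

## Worked example

Simulate a paired measurement at a 10 µm pathlength, correct it, and run the
full three-class mode-of-action study (control / DNA cross-linker / kinase
inhibitor, 120 cells per class from 3 replicates):

```r
library(aquaspec)

grid     <- defaultGrid()                                   # 1000-3600 cm-1, 2 cm-1 step
matrigel <- matrigelReference(grid)
water    <- makeWaterSpectrum(grid, chamberConfig(spacer_um = 10))
cell     <- makeCellSpectrum(grid)

set.seed(1)
meas <- simulateMeasurement(cell, water, chamberConfig(spacer_um = 10), grid = grid)
fitWaterCoefficient(meas$sample, matrigel, meas$pbs, grid = grid)
#> WaterCorrection: coefficient 0.931372, reference weight 0.956219, RMS 0.00448 AU
meas$cw / meas$cwPbs     # the true water ratio this cell was simulated with
#> [1] 0.9344323

res <- runStudy(runConfig(input = list(type = "synthetic", nPerClass = 120),
                          seed = 1))
res$cv
#> 5-fold cross-validation (seed 1)
#> % correctly classified
#>  k control crosslinker kinase_inhibitor
#>  1      88          96               92
#>  2      92         100               92
#>  3      75          92               96
#>  4      92          92               92
#>  5      92          96               92
#> Range (%): control 75-92; crosslinker 92-100; kinase_inhibitor 92-96
#> Mean (%):  control 88; crosslinker 95; kinase_inhibitor 92
```

The fitted water coefficient (0.9314) recovers the simulated ground truth
(0.9344) to well within the noise; the per-class cross-validated accuracies
are the Table-style summary of how separable the three treatment classes
are. The band-difference report then localises *where* the classes differ:

```r
res$bands$summary[res$bands$summary$pair != "crosslinker vs kinase_inhibitor", ]
#>                          pair    window max_abs_effect wn_at_max
#> 1      control vs crosslinker phosphate      0.8662220      1220
#> 2      control vs crosslinker  amide_II      0.2837508      1518
#> 3 control vs kinase_inhibitor phosphate      0.2460884      1192
#> 4 control vs kinase_inhibitor  amide_II      1.3124443      1514
```

The cross-linker's largest standardized effect falls in the phosphate/DNA
window (1170–1250 cm⁻¹, peak at 1220) and the kinase inhibitor's in the
amide II window (1480–1560 cm⁻¹, peak at 1514) — each signature matching the
drug's mode of action, recovered from spectra that were dominated by water
before correction.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/aquaspec.R run-all --n-per-class 120 --spacer 10 --seed 1 --out run1
```

with subcommands `simulate`, `correct`, `preprocess`, `classify`, `run-all`
and `report`.

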