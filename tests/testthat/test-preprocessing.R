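test_that("Savitzky-Golay reproduces polynomials and their derivatives", {
  wn <- seq(1000, 1200, by = 2)
  cubic <- 2 + 0.5 * wn - 3e-4 * wn^2 + 1e-7 * wn^3
  x <- IRSpectra(wn, cbind(cubic))
  sm <- savitzkyGolay(x, 9, 3, 0)
  expect_lt(max(abs(absorbance(sm)[, 1] - cubic)), 1e-10)
  ## second derivative of a*x^2 is the constant 2a, everywhere incl. edges
  a <- 0.37
  quad <- IRSpectra(wn, cbind(a * wn^2))
  d2 <- savitzkyGolay(quad, 13, 3, 2)
  expect_lt(max(abs(absorbance(d2)[, 1] - 2 * a)), 1e-8)
  ## against the analytic second derivative of a Gaussian band sum: a
  ## 13-point window attenuates sharp second-derivative extrema by design
  ## (that is the smoothing), so the check allows ~10% systematic
  ## attenuation on 45-60 cm-1 FWHM bands; exact polynomial reproduction
  ## above carries the correctness burden
  wn2 <- seq(1000, 1400, by = 2)
  y <- gaussSum(wn2, c(1150, 1280), c(0.2, 0.1), c(45, 60))
  d2g <- absorbance(savitzkyGolay(IRSpectra(wn2, cbind(y)), 13, 3, 2))[, 1]
  truth <- gaussSumD2(wn2, c(1150, 1280), c(0.2, 0.1), c(45, 60))
  interior <- 7:(length(wn2) - 6)
  expect_lt(max(abs(d2g - truth)[interior]), 0.12 * max(abs(truth)))
})

test_that("Savitzky-Golay rejects invalid windows and non-uniform grids", {
  wn <- seq(1000, 1100, 2)
  x <- IRSpectra(wn, cbind(rnorm(51)))
  expect_error(savitzkyGolay(x, 8, 3, 0), "odd")
  expect_error(savitzkyGolay(x, 9, 2, 3), "deriv")
  wnb <- c(seq(1000, 1050, 2), seq(1055, 1099, 2))
  bad <- IRSpectra(wnb, cbind(rnorm(length(wnb))))
  expect_error(savitzkyGolay(bad, 9, 2, 0), "non-uniform")
})

test_that("vector normalisation is unit-norm, idempotent and scale-invariant", {
  set.seed(4)
  x <- IRSpectra(seq(1000, 1100, 2), matrix(rnorm(51 * 5), 51))
  n1 <- vectorNormalize(x)
  expect_lt(max(abs(sqrt(colSums(absorbance(n1)^2)) - 1)), 1e-12)
  expect_lt(max(abs(absorbance(vectorNormalize(n1)) - absorbance(n1))),
            1e-12)
  for (k in c(0.001, 7, 1e4)) {
    xs <- IRSpectra(wavenumbers(x), k * absorbance(x))
    expect_lt(max(abs(absorbance(vectorNormalize(xs)) - absorbance(n1))),
              1e-12)
  }
  expect_error(vectorNormalize(IRSpectra(c(1000, 1002), cbind(c(0, 0)))),
               "all-zero")
})

test_that("region cutting keeps exactly the closed-interval points, in order", {
  wn <- defaultGrid()
  x <- IRSpectra(wn, cbind(seq_along(wn)))
  cut <- cutRegions(x, list(c(1100, 1575), c(2750, 3000)))
  kept <- wavenumbers(cut)
  brute <- wn[(wn >= 1100 & wn <= 1575) | (wn >= 2750 & wn <= 3000)]
  expect_equal(kept, brute)
  expect_equal(length(kept),
               sum(wn >= 1100 & wn <= 1575) + sum(wn >= 2750 & wn <= 3000))
  ## intensities ride along untouched (no reordering, no interpolation)
  expect_equal(absorbance(cut)[, 1], match(kept, wn))
  ## single full-range window is the identity
  full <- cutRegions(x, list(range(wn)))
  expect_equal(absorbance(full), absorbance(x))
  expect_error(cutRegions(x, list(c(5000, 5100))), "no grid points")
})

test_that("SG after a cut never filters across the region gap", {
  wn <- defaultGrid()
  y <- gaussSum(wn, c(1300, 2850), c(0.3, 0.2), c(40, 25))
  x <- cutRegions(IRSpectra(wn, cbind(y)), list(c(1100, 1575), c(2750, 3000)))
  d2 <- absorbance(savitzkyGolay(x, 13, 3, 2))[, 1]
  ## manual per-region filtering is identical
  reg <- S4Vectors::metadata(x)$regions
  for (r in seq_len(nrow(reg))) {
    i <- reg$start[r]:reg$end[r]
    sub <- IRSpectra(wavenumbers(x)[i], cbind(absorbance(x)[i, 1]))
    expect_equal(d2[i], absorbance(savitzkyGolay(sub, 13, 3, 2))[, 1])
  }
})

test_that("quality control computes the three diagnostics and never mutates", {
  grid <- defaultGrid()
  cfg <- preprocessConfig()
  clean <- makeCellSpectrum(grid)
  q <- qualityCheck(clean, cfg)
  expect_true(q$report$pass)
  expect_gt(q$report$amide_height, cfg$minAmideHeight)
  expect_lt(q$report$noise_rms, cfg$maxNoiseRMS)
  ## flat zero spectrum fails on amide height
  zero <- IRSpectra(grid, cbind(numeric(length(grid))))
  expect_match(qualityCheck(zero, cfg)$report$failed, "min_amide_height")
  ## 12 um-equivalent raw water drives the bending mode past the 2.5 AU guard
  sat <- generateStudy(nPerClass = 2, replicates = 1,
                       classes = list(effectSpec("a")),
                       chamber = chamberConfig(spacer_um = 12), seed = 2)
  rawCells <- sat[, spectrumInfo(sat)$role == "cell"]
  qs <- qualityCheck(rawCells, cfg)
  expect_true(all(grepl("max_absorbance", qs$report$failed)))
  ## pass + fail partitions the input, input unchanged
  expect_equal(ncol(qs$pass) + sum(!qs$report$pass), ncol(rawCells))
  expect_equal(absorbance(rawCells),
               absorbance(sat[, spectrumInfo(sat)$role == "cell"]))
})

test_that("preprocessing presets apply the documented step orders", {
  x <- makePairedSet(c(0.8, 1.0, 1.2))
  corr <- correctWater(x, matrigelReference(defaultGrid()))$corrected
  pp <- preprocess(corr, preprocessConfig(preset = "drug_study"))
  kept <- wavenumbers(pp$spectra)
  expect_true(all((kept >= 1100 & kept <= 1575) |
                    (kept >= 2750 & kept <= 3000)))
  expect_equal(length(pp$log), 4)
  expect_false(is.null(pp$qc))
  ## spacer_eval: smoothing, no derivative, unit norm output
  sp <- preprocess(corr, preprocessConfig(preset = "spacer_eval"))
  expect_lt(max(abs(sqrt(colSums(absorbance(sp$spectra)^2)) - 1)), 1e-12)
  ## empty step list is the identity transform
  id <- preprocess(corr, preprocessConfig(steps = character()))
  expect_equal(absorbance(id$spectra), absorbance(corr))
})

test_that("normalize and cut do not commute (order is part of the method)", {
  x <- makePairedSet(1)
  corr <- correctWater(x, matrigelReference(defaultGrid()))$corrected
  winds <- list(c(1100, 1575), c(2750, 3000))
  a <- vectorNormalize(cutRegions(corr, winds))
  b <- cutRegions(vectorNormalize(corr), winds)
  ## norm computed over different grids: outputs differ by a per-spectrum scale
  expect_gt(max(abs(absorbance(a) - absorbance(b))), 1e-3)
  ## regression lock: the scale between the two orders is the norm retained
  ## by the cut
  big <- abs(absorbance(a)[, 1]) > 1e-6
  ratio <- absorbance(b)[big, 1] / absorbance(a)[big, 1]
  expect_lt(diff(range(ratio)), 1e-9)
})

test_that("invalid preprocessing configurations are refused", {
  expect_error(preprocessConfig(sgWindow = 8), "odd")
  expect_error(preprocessConfig(sgWindow = 3, sgPolyorder = 3),
               "sgPolyorder")
  expect_error(preprocessConfig(sgDeriv = 3, sgPolyorder = 2), "sgDeriv")
  expect_error(preprocessConfig(steps = c("derivative", "derivative")),
               "twice")
  expect_error(preprocessConfig(cutWindows = list(c(1100, 1600),
                                                  c(1500, 1700))),
               "disjoint")
  expect_error(preprocessConfig(steps = "explode"), "unknown")
})
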