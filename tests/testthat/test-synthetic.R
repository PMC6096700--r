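test_that("the water spectrum obeys Beer-Lambert scaling and band placement", {
  grid <- defaultGrid()
  w6 <- absorbance(makeWaterSpectrum(grid, chamberConfig(6)))[, 1]
  w12 <- absorbance(makeWaterSpectrum(grid, chamberConfig(12)))[, 1]
  expect_equal(w12, 2 * w6, tolerance = 1e-12)
  ## bending mode peaks near 1640, stretching envelope inside 3000-3500
  expect_equal(grid[which.max(w6[grid < 2500])], 1640)
  stretchPeak <- grid[grid > 2500][which.max(w6[grid > 2500])]
  expect_true(stretchPeak >= 3000 && stretchPeak <= 3500)
  ## combination band: present but weak
  a2130 <- w6[grid == 2130]
  expect_gt(a2130, 0)
  expect_lt(a2130, 0.1 * max(w6[grid < 2500]))
  ## the 1640 peak scales as spacer x absorptivity
  ch <- chamberConfig(10, waterAbsorptivityScale = 0.25)
  w10 <- absorbance(makeWaterSpectrum(grid, ch))[, 1]
  expect_equal(max(w10[abs(grid - 1640) < 2]), 2.5, tolerance = 1e-2)
})

test_that("cell spectra apply effects locally and deterministically", {
  grid <- defaultGrid()
  base <- absorbance(makeCellSpectrum(grid))[, 1]
  ## effect = NULL reproduces the default profile
  expect_identical(base, absorbance(makeCellSpectrum(grid, cellProfile()))[, 1])
  eff <- effectSpec("xl", c("1217" = 1.3, "1244" = 1.3))
  pert <- absorbance(makeCellSpectrum(grid, effect = eff))[, 1]
  ## phosphate bands grow by 30% at their centers
  prof <- cellProfile()$bands
  shape <- function(ctr) {
    i <- match(ctr, prof$center)
    prof$height[i] * gaussSum(grid, prof$center[i], 1, prof$fwhm[i])
  }
  expect_equal(pert - base, 0.3 * (shape(1217) + shape(1244)),
               tolerance = 1e-12)
  ## amide region untouched (band supports do not overlap the phosphates)
  amide <- grid >= 1500 & grid <= 1700
  expect_lt(max(abs(pert - base)[amide]), 1e-12)
  expect_error(makeCellSpectrum(grid, effect = effectSpec("z", c("1999" = 2))),
               "no band")
  expect_error(effectSpec("z", c("1217" = -1)), "> 0")
})

test_that("required band families are present in the default profile", {
  b <- cellProfile()$bands
  expect_true(any(abs(b$center - 1650) < 5))          # amide I
  expect_true(any(abs(b$center - 1545) < 5))          # amide II
  expect_gte(sum(b$center %in% c(1217, 1244)), 2)     # phosphates
  expect_gte(sum(b$center >= 2800 & b$center <= 3000), 3)  # lipid C-H
})

test_that("second-derivative minima sit at the analytic band minima", {
  grid <- defaultGrid()
  x <- makeCellSpectrum(grid)
  d2 <- absorbance(savitzkyGolay(x, 13, 3, 2))[, 1]
  prof <- cellProfile()$bands
  fine <- seq(1000, 3600, by = 0.01)
  truth <- gaussSumD2(fine, prof$center, prof$height, prof$fwhm)
  step <- 2
  for (ctr in prof$center) {
    i <- abs(fine - ctr) < 15
    analyticMin <- fine[i][which.min(truth[i])]
    j <- abs(grid - ctr) < 15
    sgMin <- grid[j][which.min(d2[j])]
    expect_lte(abs(sgMin - analyticMin), step)
  }
})

test_that("the saturation operator is monotone, bounded and closed-form", {
  sat <- aquaspec:::.saturate
  A <- seq(0, 6, by = 0.01)
  out <- sat(A, 2.5)
  expect_true(all(diff(out) > 0))
  expect_true(all(out <= 2.5))
  ## true absorbance 3.0 against a 2.5 ceiling: apparent peak below 2.6
  expect_equal(sat(3.0, 2.5), -log10(10^-3 + 10^-2.5), tolerance = 1e-12)
  expect_lte(sat(3.0, 2.5), 2.6)
  ## no ceiling: identity
  expect_identical(sat(A, Inf), A)
})

test_that("simulated measurements reduce to cell + water in the clean limit", {
  grid <- defaultGrid()
  cell <- absorbance(makeCellSpectrum(grid))[, 1]
  water <- absorbance(makeWaterSpectrum(grid, chamberConfig(10)))[, 1]
  clean <- chamberConfig(10, noiseSD = 0, saturationLimit = Inf)
  set.seed(8)
  m <- simulateMeasurement(cell, water, clean, grid = grid,
                           cwRange = c(1, 1), cwPbsRange = c(1, 1))
  expect_equal(m$sample, cell + water, tolerance = 1e-12)
  expect_equal(m$pbs, water, tolerance = 1e-12)
  ## noiseless round trip through the primary correction recovers the
  ## effective water ratio to 1e-6
  set.seed(9)
  for (r in 1:10) {
    m <- simulateMeasurement(cell, water, clean, grid = grid)
    fit <- fitWaterCoefficient(m$sample, matrigelReference(grid), m$pbs,
                               grid = grid)
    expect_lt(abs(fit@coefficient - m$cw / m$cwPbs), 1e-6)
  }
})

test_that("water-fraction recovery is unbiased across pathlength and noise", {
  grid <- defaultGrid()
  matg <- absorbance(matrigelReference(grid))[, 1]
  cell <- absorbance(makeCellSpectrum(grid))[, 1]
  amide <- max(cell)
  set.seed(10)
  for (cw in c(0.5, 1.0, 1.5)) {
    for (snr in c(50, 500)) {
      ch <- chamberConfig(10, noiseSD = amide / snr, saturationLimit = Inf)
      water <- absorbance(makeWaterSpectrum(grid, ch))[, 1]
      est <- replicate(100, {
        m <- simulateMeasurement(cell, water, ch, grid = grid,
                                 cwRange = c(cw, cw), cwPbsRange = c(1, 1))
        fitWaterCoefficient(m$sample, matg, m$pbs, grid = grid)@coefficient
      })
      mcErr <- 5 * sd(est) / sqrt(length(est))
      expect_lt(abs(mean(est) - cw), mcErr + 1e-4)
    }
  }
})

test_that("study generation matches the design and is seed-reproducible", {
  x <- generateStudy(nPerClass = 12, replicates = 3, seed = 5)
  info <- spectrumInfo(x)
  expect_equal(sum(info$role == "cell"), 36)
  expect_equal(sum(info$role == "pbs"), 36)
  expect_equal(as.integer(table(info$label[info$role == "cell"])),
               c(12L, 12L, 12L))
  ## every cell has a resolvable PBS partner
  expect_true(all(info$pbs_id[info$role == "cell"] %in% info$id))
  ## replicates split 4/4/4
  expect_equal(as.integer(table(info$replicate[info$role == "cell" &
                                               info$label == "control"])),
               c(4L, 4L, 4L))
  ## remainder spread deterministically: 13 over 3 -> 5,4,4
  y <- generateStudy(nPerClass = 13, replicates = 3, seed = 5,
                     classes = list(effectSpec("a")))
  expect_equal(as.integer(table(spectrumInfo(y)$replicate[
    spectrumInfo(y)$role == "cell"])), c(5L, 4L, 4L))
  ## same seed: bit-identical; different seed: different draws
  x2 <- generateStudy(nPerClass = 12, replicates = 3, seed = 5)
  expect_identical(absorbance(x), absorbance(x2))
  x3 <- generateStudy(nPerClass = 12, replicates = 3, seed = 6)
  expect_false(identical(absorbance(x), absorbance(x3)))
  ## the caller's RNG stream is left untouched
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(generateStudy(nPerClass = 2, seed = 1,
                                        classes = list(effectSpec("a"))))
  expect_identical(rnorm(1), before)
})

test_that("classification power grows with the phosphate effect size", {
  accFor <- function(mult) {
    x <- generateStudy(
      classes = list(effectSpec("control"),
                     effectSpec("xl", c("1217" = mult, "1244" = mult))),
      nPerClass = 40, seed = 77)
    corr <- correctWater(x, matrigelReference(wavenumbers(x)))
    pp <- preprocess(corr$corrected, preprocessConfig(preset = "drug_study"))
    mean(kfoldCrossValidate(pp$spectra, spectrumInfo(pp$spectra)$label,
                            seed = 77)@percentCorrect)
  }
  accs <- vapply(c(1.0, 1.1, 1.3), accFor, numeric(1))
  expect_true(all(diff(accs) >= 0))
  expect_gt(accs[3], 85)
})
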