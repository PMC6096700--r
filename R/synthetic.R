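#' Default wavenumber grid for simulated measurements
#'
#' 1000-3600 cm\eqn{^{-1}} at 2 cm\eqn{^{-1}} spacing, a typical mid-IR
#' digitisation covering the fingerprint, silent and C-H/O-H stretch regions.
#'
#' @return numeric vector of wavenumbers.
#' @export
defaultGrid <- function() seq(1000, 3600, by = 2)

.bandShape <- function(wn, center, fwhm, shape = "gaussian") {
  if (shape == "gaussian")
    exp(-4 * log(2) * (wn - center)^2 / fwhm^2)
  else
    (fwhm / 2)^2 / ((wn - center)^2 + (fwhm / 2)^2)
}

.bandMatrix <- function(wn, bands) {
  B <- vapply(seq_len(nrow(bands)), function(i)
    .bandShape(wn, bands$center[i], bands$fwhm[i], bands$shape[i]),
    numeric(length(wn)))
  matrix(B, nrow = length(wn),
         dimnames = list(NULL, bands$name))
}

#' Spectral profile of a generic cell
#'
#' Band list for the simulator's cell: amide I and II, protein C-H/COO-
#' bending bands, phosphate stretches of DNA/RNA at 1217 and 1244
#' cm\eqn{^{-1}}, a carbohydrate band, the symmetric phosphate band, four
#' lipid C-H stretches in 2800-3000 cm\eqn{^{-1}}, and an O-H stretch band
#' representing intracellular structural water (about 70% of cell mass),
#' scaled by `intracellularWaterFraction`. The structural-water bending mode
#' overlaps amide I completely and is absorbed into the amide I band height
#' rather than modelled separately.
#'
#' @param intracellularWaterFraction dimensionless mass fraction scaling the
#'   structural-water stretch band (default 0.70).
#' @param amideIHeight peak absorbance of amide I in AU (default 0.40 for a
#'   ~15 um cell); all other bands keep their default ratios to it.
#' @return list with elements `bands` (data.frame: `name`, `center`,
#'   `height`, `fwhm`, `shape`) and `intracellularWaterFraction`.
#' @export
cellProfile <- function(intracellularWaterFraction = 0.70,
                        amideIHeight = 0.40) {
  s <- amideIHeight / 0.40
  bands <- data.frame(
    name = c("amide_I", "amide_II", "tyr_ring", "ch_bend", "coo_sym",
             "phosphate_asym", "phosphate_rna", "carbohydrate",
             "phosphate_sym", "lipid_ch2_sym", "lipid_ch3_sym",
             "lipid_ch2_asym", "lipid_ch3_asym", "structural_water"),
    center = c(1650, 1545, 1515, 1455, 1398, 1244, 1217, 1155, 1085,
               2852, 2872, 2922, 2958, 3390),
    height = s * c(0.40, 0.22, 0.03, 0.05, 0.04, 0.07, 0.06, 0.035, 0.05,
                   0.05, 0.04, 0.09, 0.06,
                   intracellularWaterFraction * 0.35),
    fwhm = c(45, 40, 16, 30, 30, 25, 25, 30, 30, 20, 20, 20, 20, 180),
    shape = "gaussian")
  list(bands = bands,
       intracellularWaterFraction = intracellularWaterFraction)
}

#' Synthetic protein (Matrigel) reference spectrum
#'
#' Matrigel is protein-dominated, so the synthetic reference carries only the
#' protein bands of [cellProfile()] (amide I, amide II, C-H bending, COO-
#' symmetric stretch) at the same centers and widths — no phosphate, lipid or
#' water bands. Generated water-free.
#'
#' @param grid numeric wavenumber axis.
#' @param scale overall multiplicative scale (default 1, matching the default
#'   cell's protein content).
#' @return a one-column [IRSpectra-class] with `role = "matrigel"`.
#' @export
matrigelReference <- function(grid, scale = 1) {
  prof <- cellProfile()
  bands <- prof$bands[prof$bands$name %in%
                        c("amide_I", "amide_II", "tyr_ring", "ch_bend",
                          "coo_sym"), ]
  y <- .bandMatrix(grid, bands) %*% (scale * bands$height)
  IRSpectra(grid, y, info = data.frame(id = "matrigel", role = "matrigel"))
}

#' Measurement-chamber configuration
#'
#' @param spacer_um fluid pathlength in micrometres (typical values 6, 10,
#'   12).
#' @param waterAbsorptivityScale water bending-mode peak absorbance per
#'   micrometre of path at 1640 cm\eqn{^{-1}} (default 0.25 AU/um, which
#'   drives a 12 um layer to ~3 AU, at the saturation limit).
#' @param noiseSD additive Gaussian noise standard deviation in apparent
#'   absorbance, AU (default 0.002, synchrotron-source quality).
#' @param saturationLimit apparent-absorbance ceiling emulating detector
#'   nonlinearity/stray light, AU (default 3.5; `Inf` disables saturation).
#' @return list of class `"chamberConfig"`.
#' @export
chamberConfig <- function(spacer_um = 10, waterAbsorptivityScale = 0.25,
                          noiseSD = 0.002, saturationLimit = 3.5) {
  if (spacer_um <= 0) stop("spacer_um must be > 0")
  if (saturationLimit <= 0) stop("saturationLimit must be > 0")
  structure(list(spacer_um = spacer_um,
                 waterAbsorptivityScale = waterAbsorptivityScale,
                 noiseSD = noiseSD, saturationLimit = saturationLimit),
            class = "chamberConfig")
}

#' Bulk-water (PBS) spectrum scaled by pathlength
#'
#' Sum of the O-H bending band at 1640 cm\eqn{^{-1}}, a two-component O-H
#' stretching envelope over 3100-3500 cm\eqn{^{-1}} and the weak combination
#' band at 2130 cm\eqn{^{-1}}; all heights scale linearly with the spacer
#' pathlength (Beer-Lambert). PBS salt bands are neglected — negligible in
#' the mid-IR at these pathlengths.
#'
#' @param grid numeric wavenumber axis.
#' @param chamber a [chamberConfig()].
#' @return a one-column [IRSpectra-class] with `role = "pbs"`, true (i.e.
#'   unsaturated, noise-free) absorbance.
#' @export
makeWaterSpectrum <- function(grid, chamber = chamberConfig()) {
  bend <- chamber$spacer_um * chamber$waterAbsorptivityScale
  bands <- data.frame(
    name = c("oh_bend", "oh_stretch_lo", "oh_stretch_hi", "combination"),
    center = c(1640, 3280, 3490, 2130),
    height = bend * c(1, 2.0, 1.4, 0.08),
    fwhm = c(90, 260, 200, 160),
    shape = "gaussian")
  y <- .bandMatrix(grid, bands) %*% bands$height
  IRSpectra(grid, y, info = data.frame(id = "pbs", role = "pbs"))
}

#' Treatment-effect specification
#'
#' @param className class label.
#' @param multipliers named numeric vector of multiplicative band-height
#'   changes, names being band centers in cm\eqn{^{-1}} (e.g.
#'   `c("1217" = 1.3, "1244" = 1.3)` for a DNA cross-linker acting on the
#'   phosphate stretches); all values must be > 0.
#' @param timePointH sampling time in hours (metadata only).
#' @return list of class `"effectSpec"`.
#' @export
effectSpec <- function(className, multipliers = numeric(), timePointH = 20) {
  if (length(multipliers) && any(multipliers <= 0))
    stop("multipliers must be > 0")
  structure(list(className = className, multipliers = multipliers,
                 timePointH = timePointH), class = "effectSpec")
}

#' Default three-class study design
#'
#' Control, a DNA cross-linker raising the 1217/1244 cm\eqn{^{-1}} phosphate
#' stretches by 30%, and a protein kinase inhibitor perturbing the amide II
#' region (amide II at 1545 cm\eqn{^{-1}} up 15%, tyrosine ring mode at 1515
#' cm\eqn{^{-1}} up 35% — altered phosphotyrosine turnover leaves a sharp
#' signature inside 1480-1560 cm\eqn{^{-1}}).
#'
#' @return list of three [effectSpec()] objects.
#' @export
defaultEffects <- function() list(
  effectSpec("control"),
  effectSpec("crosslinker", c("1217" = 1.3, "1244" = 1.3)),
  effectSpec("kinase_inhibitor", c("1545" = 1.15, "1515" = 1.35)))

.applyEffect <- function(bands, effect) {
  if (is.null(effect) || !length(effect$multipliers)) return(bands)
  ctr <- as.numeric(names(effect$multipliers))
  for (i in seq_along(ctr)) {
    j <- which(abs(bands$center - ctr[i]) < 0.5)
    if (!length(j)) stop("no band at center ", ctr[i])
    bands$height[j] <- bands$height[j] * effect$multipliers[i]
  }
  bands
}

#' Noise-free cell absorbance spectrum
#'
#' Deterministic sum of the profile's band shapes, with any treatment-effect
#' multipliers applied to matching band heights.
#'
#' @param grid numeric wavenumber axis.
#' @param profile a [cellProfile()].
#' @param effect an [effectSpec()] or `NULL`.
#' @return a one-column [IRSpectra-class] with `role = "cell"`.
#' @export
makeCellSpectrum <- function(grid, profile = cellProfile(), effect = NULL) {
  bands <- .applyEffect(profile$bands, effect)
  y <- .bandMatrix(grid, bands) %*% bands$height
  IRSpectra(grid, y, info = data.frame(
    id = "cell", role = "cell",
    label = if (is.null(effect)) NA_character_ else effect$className))
}

.saturate <- function(A, limit) {
  if (is.infinite(limit)) A else -log10(10^(-A) + 10^(-limit))
}

#' Simulate one paired transmission measurement
#'
#' Forward model of the paired acquisition: the true sample absorbance is
#' `cell + cw * water` with a per-cell water fraction `cw` drawn uniformly
#' from `cwRange` (local pathlength variation around the cell); the paired
#' PBS spectrum, taken from an adjacent cell-free area, is `cwPbs * water`
#' with its own draw near 1. Both pass through the detector-saturation
#' operator \eqn{A_{app} = -log10(10^{-A} + 10^{-limit})} (a stray-light
#' floor in transmittance space: monotone, bounded by the limit) and receive
#' independent additive Gaussian noise. Uses the current RNG stream; seed
#' with `set.seed()` for reproducibility.
#'
#' @param cell single noise-free cell spectrum ([IRSpectra-class] or numeric
#'   vector).
#' @param water single bulk-water spectrum on the same grid.
#' @param chamber a [chamberConfig()].
#' @param grid optional axis when passing bare vectors.
#' @param cwRange range of the per-cell water fraction draw (default
#'   `c(0.85, 1.15)`).
#' @param cwPbsRange range of the PBS water fraction draw (default
#'   `c(0.98, 1.02)`).
#' @return list: `sample` and `pbs` (numeric apparent-absorbance vectors) and
#'   the true draws `cw` and `cwPbs`.
#' @export
simulateMeasurement <- function(cell, water, chamber = chamberConfig(),
                                grid = NULL, cwRange = c(0.85, 1.15),
                                cwPbsRange = c(0.98, 1.02)) {
  wn <- if (is(cell, "IRSpectra")) wavenumbers(cell) else grid
  y <- .col1(cell, "cell"); w <- .col1(water, "water")
  cw <- runif(1, cwRange[1], cwRange[2])
  cwp <- runif(1, cwPbsRange[1], cwPbsRange[2])
  s <- .saturate(y + cw * w, chamber$saturationLimit) +
    rnorm(length(y), 0, chamber$noiseSD)
  p <- .saturate(cwp * w, chamber$saturationLimit) +
    rnorm(length(w), 0, chamber$noiseSD)
  list(sample = s, pbs = p, cw = cw, cwPbs = cwp)
}

#' Generate a full labelled synthetic study
#'
#' Emulates the study design the analysis assumes: `nPerClass` cells per
#' treatment class, spread over `replicates` sample loadings, each cell
#' measured with a paired bulk-PBS spectrum. Per-replicate multiplicative
#' gain (lognormal, sd `replicateGainSD`) emulates loading-to-loading
#' variation; per-cell lognormal band-height jitter (sd `bandJitterSD`)
#' emulates biological heterogeneity. Fully reproducible from `seed`; the
#' caller's RNG stream is left untouched.
#'
#' @param grid numeric wavenumber axis (default [defaultGrid()]).
#' @param classes list of [effectSpec()] (default [defaultEffects()]).
#' @param nPerClass cells per class (default 120).
#' @param replicates number of loadings per class (default 3); remainders of
#'   `nPerClass / replicates` are spread deterministically.
#' @param chamber a [chamberConfig()].
#' @param seed integer root seed.
#' @param profile a [cellProfile()].
#' @param bandJitterSD per-cell lognormal band-height jitter sd (default
#'   0.05).
#' @param replicateGainSD per-replicate lognormal gain sd (default 0.02).
#' @return an [IRSpectra-class] containing all cell and paired PBS spectra;
#'   `colData` carries `id`, `role`, `pbs_id`, `label`, `replicate`,
#'   `time_h`, `spacer_um` and the true water fractions (`cw_true`).
#' @export
generateStudy <- function(grid = defaultGrid(), classes = defaultEffects(),
                          nPerClass = 120, replicates = 3,
                          chamber = chamberConfig(), seed = 1,
                          profile = cellProfile(), bandJitterSD = 0.05,
                          replicateGainSD = 0.02) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  water <- .col1(makeWaterSpectrum(grid, chamber), "water")
  perRep <- rep(nPerClass %/% replicates, replicates)
  extra <- nPerClass %% replicates
  if (extra > 0) perRep[seq_len(extra)] <- perRep[seq_len(extra)] + 1L
  cols <- list(); info <- list()
  for (cl in classes) {
    bands <- .applyEffect(profile$bands, cl)
    B <- .bandMatrix(grid, bands)
    cellIdx <- 0
    for (r in seq_len(replicates)) {
      gain <- exp(rnorm(1, 0, replicateGainSD))
      for (i in seq_len(perRep[r])) {
        cellIdx <- cellIdx + 1
        h <- bands$height * gain * exp(rnorm(nrow(bands), 0, bandJitterSD))
        y <- as.vector(B %*% h)
        meas <- simulateMeasurement(y, water, chamber, grid = grid)
        cid <- sprintf("cell_%s_%03d", cl$className, cellIdx)
        pid <- sprintf("pbs_%s_%03d", cl$className, cellIdx)
        cols[[cid]] <- meas$sample
        cols[[pid]] <- meas$pbs
        info[[cid]] <- data.frame(
          id = cid, role = "cell", pbs_id = pid, label = cl$className,
          replicate = r, time_h = cl$timePointH,
          spacer_um = chamber$spacer_um, cw_true = meas$cw)
        info[[pid]] <- data.frame(
          id = pid, role = "pbs", pbs_id = NA_character_,
          label = cl$className, replicate = r, time_h = cl$timePointH,
          spacer_um = chamber$spacer_um, cw_true = meas$cwPbs)
      }
    }
  }
  IRSpectra(grid, do.call(cbind, cols), info = do.call(rbind, info))
}
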