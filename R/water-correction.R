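#' Result of a single-spectrum water correction
#'
#' Returned by [fitWaterCoefficient()], [fitByFlatness()] and
#' [iterativeReaddition()]. `coefficient` is the net scale of the bulk-fluid
#' spectrum subtracted from the input (negative when water was re-added);
#' only `coefficient * water` is ever subtracted — the reference weight and
#' baseline parameters are fit diagnostics and never removed from the
#' spectrum, so cellular signal matched by the reference stays in place.
#'
#' @slot coefficient numeric, scale applied to the bulk-fluid (PBS/water)
#'   spectrum before subtraction (dimensionless).
#' @slot referenceWeight numeric, weight of the protein reference in the fit
#'   window (diagnostic; `NA` for methods without a reference).
#' @slot baseline numeric vector of baseline parameters (diagnostic).
#' @slot corrected numeric vector, corrected absorbance on the full grid.
#' @slot tbr numeric vector, the removed water ("to be removed") spectrum.
#' @slot fitResidualRMS numeric, RMS fit residual over the fit window (AU).
#' @slot flatness numeric, silent-region (1800-2500 cm-1) roughness of the
#'   corrected spectrum: RMS deviation from its best straight-line fit (AU).
#' @slot flags character, zero or more of `"nonneg_clipped"`,
#'   `"degenerate"`, `"multimodal"`.
#' @export
setClass("WaterCorrection",
  representation(coefficient = "numeric", referenceWeight = "numeric",
                 baseline = "numeric", corrected = "numeric",
                 tbr = "numeric", fitResidualRMS = "numeric",
                 flatness = "numeric", flags = "character"))

#' @describeIn WaterCorrection-class one-line summary.
#' @param object a `WaterCorrection`.
#' @export
setMethod("show", "WaterCorrection", function(object) {
  cat(sprintf(
    "WaterCorrection: coefficient %.6g, reference weight %.6g, RMS %.3g AU%s\n",
    object@coefficient, object@referenceWeight, object@fitResidualRMS,
    if (length(object@flags)) paste0(" [", paste(object@flags, collapse = ","),
                                     "]") else ""))
  invisible(NULL)
})

#' Water-fit configuration
#'
#' @param fitLo,fitHi fit window in cm\eqn{^{-1}} (default 1500-1700, the
#'   amide region where both the protein reference and the water bending mode
#'   have structure, so the water coefficient is identified).
#' @param baseline `"none"`, `"constant"` or `"linear"` baseline terms
#'   included in the fit design (diagnostic only, never subtracted).
#' @param nonneg constrain the water coefficient to be non-negative
#'   (negative bulk-water content is unphysical).
#' @return a list of class `"waterFitConfig"`.
#' @export
waterFitConfig <- function(fitLo = 1500, fitHi = 1700,
                           baseline = c("linear", "constant", "none"),
                           nonneg = TRUE) {
  baseline <- match.arg(baseline)
  if (fitLo >= fitHi) stop("fitLo must be < fitHi")
  structure(list(fitLo = fitLo, fitHi = fitHi, baseline = baseline,
                 nonneg = nonneg), class = "waterFitConfig")
}

## RMS deviation from the best straight-line fit over [lo, hi]
.flatness <- function(wn, y, lo = 1800, hi = 2500) {
  i <- .windowIdx(wn, lo, hi)
  if (length(i) < 3) return(NA_real_)
  r <- stats::lm.fit(cbind(1, wn[i]), y[i])$residuals
  sqrt(mean(r^2))
}

.col1 <- function(x, what) {
  if (is(x, "IRSpectra")) {
    if (ncol(x) != 1)
      stop(what, " must be a single spectrum (one-column IRSpectra)")
    absorbance(x)[, 1]
  } else as.numeric(x)
}

.baselineCols <- function(wn, baseline) {
  switch(baseline,
         none = NULL,
         constant = cbind(const = rep(1, length(wn))),
         linear = cbind(const = rep(1, length(wn)),
                        slope = wn - mean(wn)))
}

## Core least-squares engine on numeric vectors sharing one grid.
.fitWater <- function(wn, y, m, w, cfg) {
  i <- .windowIdx(wn, cfg$fitLo, cfg$fitHi)
  if (!length(i))
    stop(sprintf("fit window [%g, %g] contains no grid points",
                 cfg$fitLo, cfg$fitHi))
  B <- .baselineCols(wn[i], cfg$baseline)
  X <- cbind(matrigel = m[i], pbs = w[i], B)
  if (kappa(X, exact = TRUE) > 1e8)
    stop("degenerate design: reference and PBS spectra are collinear over ",
         "the fit window (condition number > 1e8)")
  fit <- stats::lm.fit(X, y[i])
  beta <- unname(fit$coefficients["pbs"])
  alpha <- unname(fit$coefficients["matrigel"])
  bl <- fit$coefficients[-(1:2)]
  flags <- character()
  if (cfg$nonneg && beta < 0) {
    beta <- 0
    X2 <- cbind(matrigel = m[i], B)
    fit <- stats::lm.fit(X2, y[i])
    alpha <- unname(fit$coefficients["matrigel"])
    bl <- fit$coefficients[-1]
    flags <- "nonneg_clipped"
  }
  corrected <- y - beta * w
  new("WaterCorrection",
      coefficient = beta, referenceWeight = alpha,
      baseline = if (length(bl)) unname(bl) else numeric(),
      corrected = corrected, tbr = beta * w,
      fitResidualRMS = sqrt(mean(fit$residuals^2)),
      flatness = .flatness(wn, corrected), flags = flags)
}

#' Fit and remove the bulk-water contribution of one cell spectrum
#'
#' The primary correction method: over the fit window (default 1500-1700
#' cm\eqn{^{-1}}) the sample spectrum is modelled by ordinary least squares as
#' \deqn{sample \approx \alpha \cdot matrigel + \beta \cdot pbs + baseline,}
#' i.e. a protein (Matrigel) reference plus the cell's own paired bulk-PBS
#' spectrum plus optional baseline terms. Only the scaled PBS term
#' \eqn{\beta \cdot pbs} — the "water to be removed" — is subtracted, over the
#' full grid; the reference weight and baseline absorb protein signal and
#' offset drift so that they do not leak into \eqn{\beta}.
#'
#' @param sample,matrigel,pbs single spectra (one-column
#'   [IRSpectra-class] objects or numeric vectors) on one shared grid.
#' @param config a [waterFitConfig()].
#' @param grid optional numeric wavenumber axis when spectra are passed as
#'   bare vectors.
#' @return a [WaterCorrection-class] object.
#' @examples
#' wn <- seq(1000, 3600, by = 2)
#' m <- matrigelReference(wn)
#' w <- makeWaterSpectrum(wn, chamberConfig(spacer_um = 10))
#' s <- IRSpectra(wn, absorbance(m) + 0.8 * absorbance(w))
#' fitWaterCoefficient(s, m, w)
#' @export
fitWaterCoefficient <- function(sample, matrigel, pbs,
                                config = waterFitConfig(), grid = NULL) {
  wn <- if (is(sample, "IRSpectra")) wavenumbers(sample) else grid
  if (is.null(wn)) stop("supply 'grid' when passing numeric vectors")
  for (ref in list(matrigel, pbs))
    if (is(ref, "IRSpectra") && !isTRUE(all.equal(wavenumbers(ref), wn)))
      stop("all spectra must share one grid; resampleToGrid() first")
  .fitWater(wn, .col1(sample, "sample"), .col1(matrigel, "matrigel"),
            .col1(pbs, "pbs"), config)
}

#' Water-correct every cell spectrum in a set against its paired PBS
#'
#' Applies [fitWaterCoefficient()] to each spectrum with `role == "cell"`,
#' using the PBS partner named in its `pbs_id` metadata. Cells whose partner
#' cannot be resolved are flagged in the report and passed through
#' uncorrected rather than dropped.
#'
#' @param x an [IRSpectra-class] set containing cell and PBS spectra, with
#'   `role` and `pbs_id` metadata columns.
#' @param matrigel the protein reference spectrum (single spectrum on the
#'   same grid).
#' @param config a [waterFitConfig()].
#' @return list with elements `corrected` (an `IRSpectra` of the cell
#'   spectra, corrected where possible) and `report` (data.frame with one
#'   row per cell: `cell_id`, `coefficient`, `reference_weight`,
#'   `fit_residual_rms`, `flatness_1800_2500`, `flags`).
#' @export
correctWater <- function(x, matrigel, config = waterFitConfig()) {
  info <- spectrumInfo(x)
  if (is.null(info$role)) stop("spectrumInfo(x) must contain a 'role' column")
  cells <- which(info$role == "cell")
  wn <- wavenumbers(x)
  m <- .col1(matrigel, "matrigel")
  a <- absorbance(x)
  out <- a[, cells, drop = FALSE]
  rep_rows <- vector("list", length(cells))
  for (k in seq_along(cells)) {
    j <- cells[k]
    id <- info$id[j]
    pid <- if (is.null(info$pbs_id)) NA_character_ else info$pbs_id[j]
    pj <- if (is.na(pid)) integer() else which(info$id == pid)
    if (!length(pj)) {
      rep_rows[[k]] <- data.frame(
        cell_id = id, coefficient = NA_real_, reference_weight = NA_real_,
        fit_residual_rms = NA_real_, flatness_1800_2500 = NA_real_,
        flags = "unpaired")
      next
    }
    fit <- .fitWater(wn, a[, j], m, a[, pj[1]], config)
    out[, k] <- fit@corrected
    rep_rows[[k]] <- data.frame(
      cell_id = id, coefficient = fit@coefficient,
      reference_weight = fit@referenceWeight,
      fit_residual_rms = fit@fitResidualRMS,
      flatness_1800_2500 = fit@flatness,
      flags = paste(fit@flags, collapse = ";"))
  }
  report <- do.call(rbind, rep_rows)
  if (is.null(report))
    report <- data.frame(cell_id = character(), coefficient = numeric(),
                         reference_weight = numeric(),
                         fit_residual_rms = numeric(),
                         flatness_1800_2500 = numeric(), flags = character())
  corrected <- IRSpectra(wn, out,
                         info = SummarizedExperiment::colData(x)[cells, ,
                                                                 drop = FALSE])
  list(corrected = corrected, report = report)
}

#' Water correction by silent-region baseline flatness
#'
#' Comparison method: chooses the water scale \eqn{\beta} minimising the
#' roughness (RMS deviation from a straight line) of `sample - beta * water`
#' over the biochemically silent 1800-2500 cm\eqn{^{-1}} region, which
#' contains the water combination band. Scalar minimisation to a tolerance of
#' `1e-6` on \eqn{\beta}.
#'
#' @param sample,water single spectra on one shared grid.
#' @param searchLo,searchHi search bracket for the scale (default `[0, 3]`,
#'   covering under- to strong over-correction at pathlengths up to ~20 um).
#' @param grid optional axis for bare numeric vectors.
#' @return a [WaterCorrection-class]; `flags` contains `"degenerate"` when
#'   the water spectrum is null over the silent region (any scale is then
#'   equivalent and `searchLo` is returned).
#' @export
fitByFlatness <- function(sample, water, searchLo = 0, searchHi = 3,
                          grid = NULL) {
  wn <- if (is(sample, "IRSpectra")) wavenumbers(sample) else grid
  if (is.null(wn)) stop("supply 'grid' when passing numeric vectors")
  y <- .col1(sample, "sample"); w <- .col1(water, "water")
  i <- .windowIdx(wn, 1800, 2500)
  if (length(i) < 3) stop("grid must cover the 1800-2500 cm-1 region")
  obj <- function(b) .flatness(wn, y - b * w)
  flags <- character()
  if (max(abs(w[i])) < 1e-12) {
    beta <- searchLo
    flags <- "degenerate"
  } else {
    o <- optimize(obj, c(searchLo, searchHi), tol = 1e-6)
    beta <- o$minimum
    if (!is.finite(o$objective)) stop("flatness metric non-finite in bracket")
    ## quadratic objective, but guard the bracket ends
    if (obj(searchLo) < o$objective) beta <- searchLo
    if (obj(searchHi) < o$objective) beta <- searchHi
  }
  corrected <- y - beta * w
  new("WaterCorrection", coefficient = beta, referenceWeight = NA_real_,
      baseline = numeric(), corrected = corrected, tbr = beta * w,
      fitResidualRMS = obj(beta), flatness = .flatness(wn, corrected),
      flags = flags)
}

#' Rebalance an over-corrected spectrum by water re-addition
#'
#' Comparison method: re-adds scaled water until the baselines flanking the
#' C-H alkyl stretch at 2900 cm\eqn{^{-1}} balance, i.e. finds \eqn{\gamma
#' \ge 0} minimising \eqn{|mean_{2750-2800}(s + \gamma w) -
#' mean_{3000-3050}(s + \gamma w)|}. The flank windows are 50 cm\eqn{^{-1}}
#' wide on either side of the stretch. The objective is piecewise linear in
#' \eqn{\gamma}; a dense scan is used as a safety net and multimodality is
#' flagged.
#'
#' @param corrected,water single spectra on one shared grid spanning at
#'   least 2750-3050 cm\eqn{^{-1}}.
#' @param gammaMax upper end of the scan (default 3).
#' @param grid optional axis for bare numeric vectors.
#' @return a [WaterCorrection-class] whose `corrected` slot holds
#'   `corrected + gamma * water`; `coefficient` is `-gamma` (net water
#'   subtracted relative to the input).
#' @export
iterativeReaddition <- function(corrected, water, gammaMax = 3, grid = NULL) {
  wn <- if (is(corrected, "IRSpectra")) wavenumbers(corrected) else grid
  if (is.null(wn)) stop("supply 'grid' when passing numeric vectors")
  y <- .col1(corrected, "corrected"); w <- .col1(water, "water")
  i1 <- .windowIdx(wn, 2750, 2800); i2 <- .windowIdx(wn, 3000, 3050)
  if (!length(i1) || !length(i2))
    stop("grid must span 2750-3050 cm-1 for the flank windows")
  a <- mean(y[i1]) - mean(y[i2])
  b <- mean(w[i1]) - mean(w[i2])
  flags <- character()
  if (abs(b) < 1e-15) {
    gamma <- 0
    flags <- "degenerate"
  } else {
    gamma <- max(0, -a / b)
    if (gamma > gammaMax) gamma <- gammaMax
  }
  ## dense-scan safety net over the bracket
  gs <- seq(0, gammaMax, length.out = 2001)
  fv <- abs(a + gs * b)
  gscan <- gs[which.min(fv)]
  if (abs(gscan - gamma) > (gammaMax / 2000) * 2) {
    gamma <- gscan
    flags <- c(flags, "multimodal")
  }
  adj <- y + gamma * w
  new("WaterCorrection", coefficient = -gamma, referenceWeight = NA_real_,
      baseline = numeric(), corrected = adj, tbr = -gamma * w,
      fitResidualRMS = abs(a + gamma * b), flatness = .flatness(wn, adj),
      flags = flags)
}
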