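#' End-to-end run configuration
#'
#' Describes a complete analysis: input (measured files or a synthetic
#' design), the water-correction method, the preprocessing preset, and the
#' classification settings. All randomness in a run flows from the single
#' root `seed` recorded here (study generation and fold assignment), so a
#' run is reproducible from its manifest alone.
#'
#' @param input either `list(type = "synthetic", nPerClass =, replicates =,
#'   spacer_um =, noiseSD =, ...)` or `list(type = "files", path =, format =)`.
#'   Referenced files are checked at configuration time (fail fast).
#' @param correction `"matrigel_fit"` (primary), `"flatness"`, or
#'   `"readdition_adjust"` (Matrigel fit followed by flank-balancing water
#'   re-addition).
#' @param preset preprocessing preset name for [preprocessConfig()].
#' @param varianceTarget,cap,k,ridge classification settings, see
#'   [kfoldCrossValidate()].
#' @param seed integer root seed.
#' @return list of class `"runConfig"`.
#' @export
runConfig <- function(input = list(type = "synthetic"),
                      correction = c("matrigel_fit", "flatness",
                                     "readdition_adjust"),
                      preset = "drug_study", varianceTarget = 0.95,
                      cap = 21, k = 5, ridge = NULL, seed = 1) {
  correction <- match.arg(correction)
  if (identical(input$type, "files")) {
    if (is.null(input$path) || !file.exists(input$path))
      stop("input file not found: ", input$path)
  } else if (!identical(input$type, "synthetic")) {
    stop("input$type must be 'synthetic' or 'files'")
  }
  structure(list(input = input, correction = correction, preset = preset,
                 varianceTarget = varianceTarget, cap = cap, k = k,
                 ridge = ridge, seed = seed), class = "runConfig")
}

.loadInput <- function(config) {
  inp <- config$input
  if (identical(inp$type, "files")) {
    readSpectra(inp$path,
                format = if (is.null(inp$format)) "wide" else inp$format)
  } else {
    chamber <- chamberConfig(
      spacer_um = if (is.null(inp$spacer_um)) 10 else inp$spacer_um,
      noiseSD = if (is.null(inp$noiseSD)) 0.002 else inp$noiseSD)
    generateStudy(
      grid = defaultGrid(),
      classes = if (is.null(inp$classes)) defaultEffects() else inp$classes,
      nPerClass = if (is.null(inp$nPerClass)) 120 else inp$nPerClass,
      replicates = if (is.null(inp$replicates)) 3 else inp$replicates,
      chamber = chamber, seed = config$seed)
  }
}

.correctStage <- function(x, config) {
  grid <- wavenumbers(x)
  matrigel <- matrigelReference(grid)
  res <- correctWater(x, matrigel)
  if (config$correction == "flatness") {
    info <- spectrumInfo(x)
    a <- absorbance(x)
    out <- absorbance(res$corrected)
    for (k in seq_len(ncol(res$corrected))) {
      id <- spectrumInfo(res$corrected)$id[k]
      j <- which(info$id == id)
      pj <- which(info$id == info$pbs_id[j])
      if (!length(pj)) next
      fit <- fitByFlatness(a[, j], a[, pj], grid = grid)
      out[, k] <- fit@corrected
      res$report$coefficient[res$report$cell_id == id] <- fit@coefficient
      res$report$flatness_1800_2500[res$report$cell_id == id] <- fit@flatness
    }
    res$corrected <- IRSpectra(
      grid, out, info = SummarizedExperiment::colData(res$corrected))
  } else if (config$correction == "readdition_adjust") {
    info <- spectrumInfo(x)
    a <- absorbance(x)
    out <- absorbance(res$corrected)
    for (k in seq_len(ncol(res$corrected))) {
      id <- spectrumInfo(res$corrected)$id[k]
      j <- which(info$id == id)
      pj <- which(info$id == info$pbs_id[j])
      if (!length(pj)) next
      adj <- iterativeReaddition(out[, k], a[, pj], grid = grid)
      out[, k] <- adj@corrected
    }
    res$corrected <- IRSpectra(
      grid, out, info = SummarizedExperiment::colData(res$corrected))
  }
  res
}

#' Per-class mean and standard-deviation spectra
#'
#' @param x an [IRSpectra-class].
#' @param labels class label per spectrum.
#' @return data.frame: `wavenumber`, then `mean_<class>` and `sd_<class>`
#'   columns.
#' @export
classMeans <- function(x, labels) {
  labels <- as.character(labels)
  a <- absorbance(x)
  out <- data.frame(wavenumber = wavenumbers(x))
  for (g in sort(unique(labels))) {
    sub <- a[, labels == g, drop = FALSE]
    out[[paste0("mean_", g)]] <- rowMeans(sub)
    out[[paste0("sd_", g)]] <- apply(sub, 1, sd)
  }
  out
}

#' Localise between-class differences in second-derivative spectra
#'
#' For each class pair and each wavenumber window, reports the pointwise mean
#' difference, pooled standard deviation and standardised mean difference
#' (Cohen's d), plus a per-window summary (largest absolute effect size and
#' its wavenumber). Intended for spectra already converted to the second
#' derivative, where band intensity changes appear as sharpened minima.
#'
#' @param x an [IRSpectra-class] (second-derivative spectra).
#' @param labels class label per spectrum.
#' @param windows named list of `c(lo, hi)` windows; defaults are the
#'   phosphate/DNA region (1170-1250 cm\eqn{^{-1}}) and the amide II region
#'   (1480-1560 cm\eqn{^{-1}}).
#' @return list with `pointwise` and `summary` data.frames.
#' @export
bandDifferenceReport <- function(x, labels,
                                 windows = list(phosphate = c(1170, 1250),
                                                amide_II = c(1480, 1560))) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need >= 2 classes")
  if (is.null(names(windows)))
    names(windows) <- vapply(windows, function(w)
      sprintf("%g-%g", w[1], w[2]), character(1))
  wn <- wavenumbers(x)
  a <- absorbance(x)
  pw <- list(); sm <- list()
  for (i in seq_len(length(classes) - 1)) for (j in (i + 1):length(classes)) {
    g1 <- classes[i]; g2 <- classes[j]
    a1 <- a[, labels == g1, drop = FALSE]
    a2 <- a[, labels == g2, drop = FALSE]
    n1 <- ncol(a1); n2 <- ncol(a2)
    for (wname in names(windows)) {
      w <- windows[[wname]]
      idx <- .windowIdx(wn, w[1], w[2])
      m1 <- rowMeans(a1[idx, , drop = FALSE])
      m2 <- rowMeans(a2[idx, , drop = FALSE])
      v1 <- apply(a1[idx, , drop = FALSE], 1, var)
      v2 <- apply(a2[idx, , drop = FALSE], 1, var)
      sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
      d <- ifelse(sp > 0, (m2 - m1) / sp, 0)
      pw[[length(pw) + 1]] <- data.frame(
        pair = paste(g1, "vs", g2), window = wname, wavenumber = wn[idx],
        mean_diff = m2 - m1, pooled_sd = sp, effect_size = d)
      sm[[length(sm) + 1]] <- data.frame(
        pair = paste(g1, "vs", g2), window = wname,
        max_abs_effect = max(abs(d)),
        wn_at_max = wn[idx][which.max(abs(d))],
        mean_abs_effect = mean(abs(d)))
    }
  }
  list(pointwise = do.call(rbind, pw), summary = do.call(rbind, sm))
}

#' Run the complete workflow
#'
#' Load or simulate -> water-correct -> preprocess -> cross-validated
#' classification -> reports. Artifacts written to `outDir`: the corrected
#' spectra (`corrected.csv` + metadata sidecar), per-cell correction report,
#' QC report, per-class mean +/- sd spectra of the preprocessed data
#' (`class_means.tsv`) and of the corrected data (`class_means_raw.tsv`),
#' CVA scores of the final model (`cva_scores.tsv`), cross-validation report
#' (`cv_report.tsv`), band-difference summary (`band_differences.tsv`) and a
#' JSON manifest capturing the configuration, seed and package version.
#'
#' @param config a [runConfig()].
#' @param outDir output directory, created if missing; `NULL` writes nothing.
#' @return list: `spectra` (preprocessed), `correction` report, `qc` report,
#'   `cv` ([CVReport-class]), `model` (final [CVAModel-class] on all data),
#'   `scores` (canonical coordinates), `means`, `bands` (band-difference
#'   report), `log`.
#' @export
runStudy <- function(config, outDir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  x <- stage("input", .loadInput(config))
  corr <- stage("water_correction", .correctStage(x, config))
  pp <- stage("preprocess",
              preprocess(corr$corrected,
                         preprocessConfig(preset = config$preset)))
  labels <- spectrumInfo(pp$spectra)$label
  if (length(unique(labels)) < 2)
    stop("stage 'classify': configuration error: a single class cannot be ",
         "classified", call. = FALSE)
  cv <- stage("classify",
              kfoldCrossValidate(pp$spectra, labels, k = config$k,
                                 seed = config$seed,
                                 varianceTarget = config$varianceTarget,
                                 cap = config$cap, ridge = config$ridge))
  model <- stage("classify",
                 fitCVAModel(pp$spectra, labels,
                             varianceTarget = config$varianceTarget,
                             cap = config$cap, ridge = config$ridge))
  scores <- cvaScores(model, pp$spectra)
  means <- classMeans(pp$spectra, labels)
  meansRaw <- classMeans(corr$corrected[, spectrumInfo(corr$corrected)$id %in%
                                          spectrumInfo(pp$spectra)$id],
                         labels)
  bands <- stage("report", bandDifferenceReport(pp$spectra, labels))
  log <- c(sprintf("input: %d spectra", ncol(x)),
           sprintf("correction: %s", config$correction), pp$log,
           sprintf("classify: %d-fold CV, seed %g", config$k, config$seed))
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeSpectra(corr$corrected, file.path(outDir, "corrected.csv"))
    wt <- function(d, f) write.table(d, file.path(outDir, f), sep = "\t",
                                     quote = FALSE, row.names = FALSE)
    wt(corr$report, "correction_report.tsv")
    if (!is.null(pp$qc)) wt(pp$qc, "qc_report.tsv")
    wt(means, "class_means.tsv")
    wt(meansRaw, "class_means_raw.tsv")
    wt(data.frame(id = rownames(scores), label = labels, scores),
       "cva_scores.tsv")
    pc <- cv@percentCorrect
    wt(cbind(data.frame(k = seq_len(nrow(pc))), as.data.frame(pc)),
       "cv_report.tsv")
    wt(bands$summary, "band_differences.tsv")
    manifest <- list(
      config = unclass(config),
      package = list(name = "aquaspec",
                     version = as.character(utils::packageVersion("aquaspec")),
                     r_version = R.version.string),
      log = log)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
  }
  list(spectra = pp$spectra, correction = corr$report, qc = pp$qc, cv = cv,
       model = model, scores = scores, means = means, bands = bands,
       log = log)
}
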