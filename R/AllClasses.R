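#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames rowData colData
#' @importFrom S4Vectors DataFrame metadata 'metadata<-'
#' @importFrom stats approx coef lm optimize quantile rnorm runif sd setNames var
#' @importFrom utils read.table write.table
NULL

#' Collection of infrared spectra on a shared wavenumber grid
#'
#' `IRSpectra` extends [SummarizedExperiment::SummarizedExperiment] to hold
#' one or more absorbance spectra measured on a single shared wavenumber
#' axis. Rows are wavenumbers (stored in `rowData(x)$wavenumber`, strictly
#' ascending, cm\eqn{^{-1}}), columns are individual spectra, and the single
#' assay `"absorbance"` holds absorbance in AU. Per-spectrum metadata lives
#' in `colData`: conventional columns are `id`, `role` (one of `"cell"`,
#' `"pbs"`, `"matrigel"`, `"background"`), `pbs_id` (the paired bulk-fluid
#' spectrum for a cell), `label` (class label), `replicate`, `time_h` and
#' `spacer_um`.
#'
#' The ascending axis is the package-wide canonical orientation; constructors
#' and readers silently reverse descending input (common in instrument
#' exports) together with the intensities.
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment]; no extra slots.
#' @seealso [IRSpectra()], [readSpectra()], [extractWindow()]
#' @export
setClass("IRSpectra", contains = "SummarizedExperiment")

.validIRSpectra <- function(object) {
  msg <- character()
  wn <- SummarizedExperiment::rowData(object)$wavenumber
  if (is.null(wn))
    return("rowData must contain a 'wavenumber' column")
  if (!is.numeric(wn) || anyNA(wn))
    msg <- c(msg, "wavenumbers must be numeric and non-missing")
  else {
    if (length(wn) < 2) msg <- c(msg, "grid must have length >= 2")
    if (any(wn <= 0)) msg <- c(msg, "wavenumbers must be positive")
    if (length(wn) >= 2 && any(diff(wn) <= 0))
      msg <- c(msg, "wavenumbers must be strictly ascending")
  }
  if (!"absorbance" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'absorbance' is required")
  else {
    a <- SummarizedExperiment::assay(object, "absorbance")
    if (!all(is.finite(a))) msg <- c(msg, "absorbance values must be finite")
  }
  if (length(msg)) msg else TRUE
}

setValidity("IRSpectra", .validIRSpectra)

#' Construct an IRSpectra object
#'
#' @param wavenumber numeric axis in cm\eqn{^{-1}}; may be descending, in
#'   which case axis and intensities are reversed to the canonical ascending
#'   order.
#' @param absorbance numeric matrix (wavenumber x spectrum) or a vector for a
#'   single spectrum, in AU.
#' @param info `data.frame` or `DataFrame` of per-spectrum metadata, one row
#'   per column of `absorbance`. An `id` column becomes the column names;
#'   otherwise names `s1, s2, ...` are generated.
#' @return an [IRSpectra-class] object.
#' @examples
#' wn <- seq(1000, 1100, by = 2)
#' x <- IRSpectra(wn, cbind(a = sin(wn / 50), b = cos(wn / 50)))
#' x
#' @export
IRSpectra <- function(wavenumber, absorbance, info = NULL) {
  if (is.null(dim(absorbance))) absorbance <- matrix(absorbance, ncol = 1)
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  rownames(absorbance) <- NULL
  wavenumber <- as.numeric(wavenumber)
  if (length(wavenumber) != nrow(absorbance))
    stop("length(wavenumber) must equal nrow(absorbance)")
  if (length(wavenumber) >= 2 && all(diff(wavenumber) < 0)) {
    wavenumber <- rev(wavenumber)
    absorbance <- absorbance[rev(seq_len(nrow(absorbance))), , drop = FALSE]
  }
  n <- ncol(absorbance)
  if (is.null(info)) {
    ids <- colnames(absorbance)
    if (is.null(ids)) ids <- paste0("s", seq_len(n))
    info <- S4Vectors::DataFrame(id = ids)
  } else {
    info <- as(info, "DataFrame")
    if (nrow(info) != n) stop("info must have one row per spectrum")
    if (is.null(info$id)) {
      ids <- colnames(absorbance)
      info$id <- if (is.null(ids)) paste0("s", seq_len(n)) else ids
    }
  }
  colnames(absorbance) <- info$id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(absorbance = absorbance),
    rowData = S4Vectors::DataFrame(wavenumber = wavenumber),
    colData = info)
  new("IRSpectra", se)
}

#' @describeIn IRSpectra-class number of spectra and axis summary.
#' @param object an `IRSpectra` object.
#' @export
setMethod("show", "IRSpectra", function(object) {
  wn <- wavenumbers(object)
  cat(sprintf("IRSpectra: %d spectra on %d-point grid [%g, %g] cm-1\n",
              ncol(object), length(wn), min(wn), max(wn)))
  roles <- SummarizedExperiment::colData(object)$role
  if (!is.null(roles)) {
    tab <- table(roles)
    cat("roles:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
  }
  labs <- SummarizedExperiment::colData(object)$label
  if (!is.null(labs) && !all(is.na(labs))) {
    tab <- table(labs)
    cat("labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
  }
  invisible(NULL)
})
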