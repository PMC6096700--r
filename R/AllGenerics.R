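#' Wavenumber axis of a spectra collection
#'
#' @param x an [IRSpectra-class] object.
#' @return numeric vector of wavenumbers in cm\eqn{^{-1}}, strictly ascending.
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))

#' Absorbance matrix of a spectra collection
#'
#' @param x an [IRSpectra-class] object.
#' @return numeric matrix, wavenumbers in rows, spectra in columns, AU.
#' @export
setGeneric("absorbance", function(x) standardGeneric("absorbance"))

#' Per-spectrum metadata as a data.frame
#'
#' @param x an [IRSpectra-class] object.
#' @return base `data.frame`, one row per spectrum.
#' @export
setGeneric("spectrumInfo", function(x) standardGeneric("spectrumInfo"))

#' @rdname wavenumbers
#' @export
setMethod("wavenumbers", "IRSpectra", function(x)
  SummarizedExperiment::rowData(x)$wavenumber)

#' @rdname absorbance
#' @export
setMethod("absorbance", "IRSpectra", function(x)
  SummarizedExperiment::assay(x, "absorbance"))

#' @rdname spectrumInfo
#' @export
setMethod("spectrumInfo", "IRSpectra", function(x)
  as.data.frame(SummarizedExperiment::colData(x)))
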