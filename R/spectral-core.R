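#' Test whether the wavenumber grid is uniformly spaced
#'
#' Savitzky-Golay filtering assumes uniform spacing; this predicate checks the
#' relative deviation of point spacings from their mean.
#'
#' @param x an [IRSpectra-class] object.
#' @param tol maximum allowed relative deviation of any spacing from the mean
#'   spacing (default `1e-6`).
#' @return logical scalar.
#' @export
isUniformGrid <- function(x, tol = 1e-6) {
  d <- diff(wavenumbers(x))
  max(abs(d - mean(d))) <= tol * mean(d)
}

#' Resample spectra onto a target wavenumber grid
#'
#' Piecewise-linear interpolation of every spectrum onto `target`. The target
#' range must lie inside the source range: extrapolation is refused because
#' band shapes outside the measured range are unknown.
#'
#' @param x an [IRSpectra-class] object.
#' @param target numeric vector of target wavenumbers (ascending) or an
#'   `IRSpectra` object whose grid is used.
#' @return an `IRSpectra` on the target grid, metadata preserved.
#' @export
resampleToGrid <- function(x, target) {
  if (is(target, "IRSpectra")) target <- wavenumbers(target)
  target <- as.numeric(target)
  if (is.unsorted(target, strictly = TRUE))
    stop("target grid must be strictly ascending")
  wn <- wavenumbers(x)
  if (min(target) < min(wn) || max(target) > max(wn))
    stop(sprintf(
      "target range [%g, %g] outside source range [%g, %g]: no extrapolation",
      min(target), max(target), min(wn), max(wn)))
  a <- absorbance(x)
  out <- apply(a, 2, function(y) approx(wn, y, xout = target)$y)
  out <- matrix(out, nrow = length(target))
  IRSpectra(target, out, info = SummarizedExperiment::colData(x))
}

#' Extract a closed wavenumber window
#'
#' Returns the sub-spectra whose grid points p satisfy `lo <= p <= hi` (both
#' ends included, matching how ranges such as 1100-1575 cm-1 are quoted).
#'
#' @param x an [IRSpectra-class] object.
#' @param lo,hi window bounds in cm\eqn{^{-1}}, `lo < hi`.
#' @return an `IRSpectra` restricted to the window.
#' @export
extractWindow <- function(x, lo, hi) {
  if (lo >= hi) stop("lo must be < hi")
  keep <- which(wavenumbers(x) >= lo & wavenumbers(x) <= hi)
  if (!length(keep))
    stop(sprintf("window [%g, %g] contains no grid points", lo, hi))
  x[keep, ]
}

.windowIdx <- function(wn, lo, hi) which(wn >= lo & wn <= hi)

.detectSep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

.metaPath <- function(path) paste0(path, ".meta.tsv")

#' Read spectra from delimited text
#'
#' Two layouts are supported. `"wide"`: first column is the wavenumber axis,
#' one column per spectrum, header row of spectrum ids. `"long"`: columns
#' `spectrum_id`, `wavenumber`, `absorbance`. The field separator (comma or
#' tab) is auto-detected. If a metadata sidecar `<path>.meta.tsv` exists its
#' rows are joined to the spectra by `id`. Files with a descending axis are
#' normalised to ascending order.
#'
#' @param path file to read.
#' @param format `"wide"` or `"long"`.
#' @return an [IRSpectra-class] object; column order follows file order.
#' @export
readSpectra <- function(path, format = c("wide", "long")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- .detectSep(path)
  raw <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    colClasses = "character", comment.char = "")
  if (format == "wide") {
    num <- suppressWarnings(
      vapply(raw, as.numeric, numeric(nrow(raw))))
    num <- matrix(num, nrow = nrow(raw), dimnames = dimnames(raw))
    bad <- which(is.na(num) & raw != "NA", arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("malformed numeric value at row %d, column '%s'",
                   bad[1, 1], colnames(raw)[bad[1, 2]]))
    wn <- num[, 1]
    a <- num[, -1, drop = FALSE]
    if (any(diff(wn) == 0)) stop("axis contains duplicate wavenumbers")
    if (all(diff(wn) < 0)) {
      wn <- rev(wn); a <- a[rev(seq_along(wn)), , drop = FALSE]
    }
    if (any(diff(wn) <= 0)) stop("axis is not monotonic")
    ids <- colnames(a)
  } else {
    need <- c("spectrum_id", "wavenumber", "absorbance")
    if (!all(need %in% colnames(raw)))
      stop("long format requires columns: ", paste(need, collapse = ", "))
    wnum <- suppressWarnings(as.numeric(raw$wavenumber))
    anum <- suppressWarnings(as.numeric(raw$absorbance))
    bad <- which(is.na(wnum) | is.na(anum))
    if (length(bad))
      stop(sprintf("malformed numeric value at row %d", bad[1]))
    ids <- unique(raw$spectrum_id)
    wn <- unique(wnum[raw$spectrum_id == ids[1]])
    if (all(diff(wn) < 0)) wn <- rev(wn)
    if (any(diff(wn) <= 0)) stop("axis is not monotonic")
    a <- vapply(ids, function(i) {
      sel <- raw$spectrum_id == i
      if (sum(sel) != length(wn)) stop("spectrum '", i,
                                       "' not on the shared axis")
      anum[sel][order(wnum[sel])]
    }, numeric(length(wn)))
    a <- matrix(a, nrow = length(wn), dimnames = list(NULL, ids))
  }
  info <- NULL
  mp <- .metaPath(path)
  if (file.exists(mp)) {
    meta <- read.table(mp, header = TRUE, sep = "\t", check.names = FALSE,
                       stringsAsFactors = FALSE)
    info <- meta[match(ids, meta$id), , drop = FALSE]
    rownames(info) <- NULL
    info$id <- ids
  }
  IRSpectra(wn, a, info = info)
}

#' Write spectra to delimited text
#'
#' Inverse of [readSpectra()]. Numeric fields are written with 15 significant
#' digits so a write/read round trip reproduces values to full double
#' precision for practical purposes. Metadata beyond the `id` column is
#' written to a tab-separated sidecar `<path>.meta.tsv`; when there is none,
#' no sidecar is produced.
#'
#' @param x an [IRSpectra-class] object, non-empty.
#' @param path output file.
#' @param format `"wide"` or `"long"`.
#' @param sep field separator for the main file (default comma).
#' @return `path`, invisibly.
#' @export
writeSpectra <- function(x, path, format = c("wide", "long"), sep = ",") {
  format <- match.arg(format)
  if (ncol(x) == 0) stop("refusing to write an empty spectra set")
  fmt <- function(v) sprintf("%.15g", v)
  wn <- wavenumbers(x)
  a <- absorbance(x)
  if (format == "wide") {
    out <- data.frame(wavenumber = fmt(wn), check.names = FALSE)
    for (j in seq_len(ncol(a))) out[[colnames(a)[j]]] <- fmt(a[, j])
  } else {
    out <- data.frame(
      spectrum_id = rep(colnames(a), each = length(wn)),
      wavenumber = rep(fmt(wn), ncol(a)),
      absorbance = fmt(as.vector(a)))
  }
  write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  info <- spectrumInfo(x)
  extra <- setdiff(colnames(info), "id")
  if (length(extra)) {
    write.table(info, .metaPath(path), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}
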