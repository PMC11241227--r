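#' Construct a spectra object
#'
#' A `milk_spectra` object holds a sample-by-wavenumber absorbance matrix
#' (log(1/Transmittance)) together with its wavenumber axis in cm^-1.
#' Wavenumbers are stored ascending internally; the original column order of a
#' file is remembered so [write_spectra()] can reproduce it.
#'
#' @param absorbance numeric matrix, one row per sample, one column per
#'   wavenumber.
#' @param wavenumbers numeric vector of wavenumbers (cm^-1), strictly monotone,
#'   one per column of `absorbance`.
#' @param sample_ids character vector of unique sample identifiers, one per
#'   row. Defaults to rownames of `absorbance` or `"S1"`, `"S2"`, ...
#' @param meta optional named list of provenance metadata (e.g. the
#'   preprocessing already applied).
#'
#' @return An object of class `milk_spectra`: a list with elements
#'   `absorbance` (matrix, rownames = sample ids), `wavenumbers` (ascending),
#'   and `meta`.
#' @export
milk_spectra <- function(absorbance, wavenumbers, sample_ids = NULL,
                         meta = list()) {
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  wavenumbers <- as.numeric(wavenumbers)
  if (length(wavenumbers) != ncol(absorbance)) {
    stop("length(wavenumbers) must equal ncol(absorbance)")
  }
  d <- diff(wavenumbers)
  if (length(d) && !(all(d > 0) || all(d < 0))) {
    stop("wavenumbers must be strictly monotone")
  }
  if (is.null(sample_ids)) {
    sample_ids <- rownames(absorbance)
    if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(absorbance)))
  }
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(absorbance)) {
    stop("length(sample_ids) must equal nrow(absorbance)")
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (!all(is.finite(absorbance))) stop("absorbance values must all be finite")
  # canonical ascending orientation
  if (length(d) && all(d < 0)) {
    ord <- rev(seq_along(wavenumbers))
    wavenumbers <- wavenumbers[ord]
    absorbance <- absorbance[, ord, drop = FALSE]
    meta$file_axis_descending <- TRUE
  }
  rownames(absorbance) <- sample_ids
  colnames(absorbance) <- format(wavenumbers, trim = TRUE, scientific = FALSE)
  structure(list(absorbance = absorbance, wavenumbers = wavenumbers,
                 meta = meta),
            class = "milk_spectra")
}

#' @export
print.milk_spectra <- function(x, ...) {
  cat(sprintf("milk_spectra: %d samples x %d wavenumbers (%.1f to %.1f cm^-1)\n",
              nrow(x$absorbance), length(x$wavenumbers),
              min(x$wavenumbers), max(x$wavenumbers)))
  if (!is.null(x$meta$preprocess)) {
    cat("  preprocessing:", format(x$meta$preprocess), "\n")
  }
  invisible(x)
}

#' @export
dim.milk_spectra <- function(x) dim(x$absorbance)

#' Subset spectra by sample id
#'
#' @param spectra a [milk_spectra()] object.
#' @param ids character vector of sample ids to keep (order respected).
#' @return A `milk_spectra` restricted to `ids`.
#' @export
subset_samples <- function(spectra, ids) {
  stopifnot(inherits(spectra, "milk_spectra"))
  missing_ids <- setdiff(ids, rownames(spectra$absorbance))
  if (length(missing_ids)) {
    stop("unknown sample ids: ", paste(missing_ids, collapse = ", "))
  }
  milk_spectra(spectra$absorbance[ids, , drop = FALSE], spectra$wavenumbers,
               sample_ids = ids, meta = spectra$meta)
}

#' Read a spectral table
#'
#' Reads a delimited text file whose first column is `sample_id` and whose
#' remaining column headers are numeric wavenumbers in cm^-1; cell values are
#' absorbances as log(1/Transmittance).
#'
#' @param path file path.
#' @param sep field separator (default comma).
#' @return A [milk_spectra()] object. Row order of the file is preserved;
#'   the axis is stored ascending.
#' @export
read_spectra <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = NA, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("spectral table needs a sample-id column plus data columns")
  ids <- as.character(df[[1L]])
  hdr <- names(df)[-1L]
  wn <- suppressWarnings(as.numeric(hdr))
  if (anyNA(wn)) {
    stop("non-wavenumber column headers: ",
         paste(hdr[is.na(wn)], collapse = ", "))
  }
  mat <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(!vapply(df[-1L], is.numeric, logical(1)))[1L]
    stop(sprintf("non-numeric cell(s) in column '%s'", hdr[bad]))
  }
  if (anyNA(mat)) {
    idx <- which(is.na(mat), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric or missing value at row %d, column '%s'",
                 idx[1L], hdr[idx[2L]]))
  }
  milk_spectra(mat, wn, sample_ids = ids)
}

#' Write a spectral table
#'
#' Inverse of [read_spectra()]: first column `sample_id`, remaining headers
#' the wavenumbers. Values are written at full double precision so that a
#' write/read round trip is lossless to numerical tolerance.
#'
#' @param spectra a [milk_spectra()] object.
#' @param path output file path.
#' @param sep field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path, sep = ",") {
  stopifnot(inherits(spectra, "milk_spectra"))
  mat <- spectra$absorbance
  wn <- spectra$wavenumbers
  if (isTRUE(spectra$meta$file_axis_descending)) {
    ord <- rev(seq_along(wn))
    mat <- mat[, ord, drop = FALSE]
    wn <- wn[ord]
  }
  df <- data.frame(sample_id = rownames(mat), mat,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("sample_id", format(wn, digits = 17, trim = TRUE,
                                     scientific = FALSE))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Default water-absorption regions
#'
#' Closed wavenumber intervals (cm^-1) dominated by water absorption in milk
#' MIR spectra, where the detector response is too noisy to carry chemical
#' information: 1566-1712 (O-H bending), 1817-2696, and 2975-3700 (O-H
#' stretch). All three are configurable in every masking call.
#'
#' @return A two-column matrix with columns `lo`, `hi`, one row per interval.
#' @export
water_regions <- function() {
  cbind(lo = c(1566, 1817, 2975), hi = c(1712, 2696, 3700))
}

validate_regions <- function(regions) {
  regions <- as.matrix(regions)
  if (ncol(regions) != 2L) stop("regions must have two columns (lo, hi)")
  storage.mode(regions) <- "double"
  colnames(regions) <- c("lo", "hi")
  if (nrow(regions) && any(regions[, "lo"] >= regions[, "hi"])) {
    stop("each region must satisfy lo < hi")
  }
  regions
}

#' Mask wavenumber regions
#'
#' Drops every spectral point whose wavenumber lies inside any of the given
#' closed intervals (inclusive at both ends). Used to remove the water-band
#' regions before modelling.
#'
#' @param spectra a [milk_spectra()] object.
#' @param regions two-column matrix of closed intervals `[lo, hi]` in cm^-1;
#'   defaults to [water_regions()]. A zero-row matrix masks nothing.
#' @return A `milk_spectra` restricted to the retained wavenumbers.
#' @export
mask_regions <- function(spectra, regions = water_regions()) {
  stopifnot(inherits(spectra, "milk_spectra"))
  regions <- validate_regions(regions)
  wn <- spectra$wavenumbers
  inside <- rep(FALSE, length(wn))
  for (i in seq_len(nrow(regions))) {
    inside <- inside | (wn >= regions[i, "lo"] & wn <= regions[i, "hi"])
  }
  if (all(inside)) stop("masking would remove every wavenumber")
  keep <- which(!inside)
  milk_spectra(spectra$absorbance[, keep, drop = FALSE], wn[keep],
               sample_ids = rownames(spectra$absorbance),
               meta = spectra$meta)
}

#' Build a uniform wavenumber axis
#'
#' The default instrument grid: `n` equally spaced points spanning
#' `lo` to `hi` cm^-1 (1060 points over 900-5000 by default).
#'
#' @param n number of points.
#' @param lo,hi axis endpoints in cm^-1 (inclusive).
#' @return Numeric vector of wavenumbers, ascending.
#' @export
default_axis <- function(n = 1060L, lo = 900, hi = 5000) {
  seq(lo, hi, length.out = n)
}
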