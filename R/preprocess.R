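#' Standard normal variate (SNV)
#'
#' Centres each spectrum to mean zero and scales it to standard deviation
#' exactly 1.0 (sample SD, n-1 denominator), reducing multiplicative
#' particle-size scatter. SNV is invariant to positive affine transforms of a
#' spectrum: `snv(a*x + b) == snv(x)` for `a > 0`.
#'
#' @param spectra a [milk_spectra()] object.
#' @return A `milk_spectra` with unit-SD rows.
#' @export
snv <- function(spectra) {
  stopifnot(inherits(spectra, "milk_spectra"))
  x <- spectra$absorbance
  mu <- rowMeans(x)
  sdv <- sqrt(rowSums((x - mu)^2) / (ncol(x) - 1L))
  if (any(sdv < 1e-12)) {
    stop("zero-variance spectrum; cannot apply SNV to sample(s): ",
         paste(rownames(x)[sdv < 1e-12], collapse = ", "))
  }
  milk_spectra((x - mu) / sdv, spectra$wavenumbers,
               sample_ids = rownames(x), meta = spectra$meta)
}

#' Detrend
#'
#' Removes the linear and quadratic curvature of each spectrum: every row is
#' replaced by its residual from an ordinary least-squares fit on
#' \{1, w, w^2\}, where w is the wavenumber axis (centred and scaled before
#' fitting for conditioning; the residuals are identical to the unscaled fit).
#' Detrending is idempotent.
#'
#' @param spectra a [milk_spectra()] object with at least 3 points per row.
#' @return A `milk_spectra` of degree-2 baseline residuals.
#' @export
detrend <- function(spectra) {
  stopifnot(inherits(spectra, "milk_spectra"))
  x <- spectra$absorbance
  if (ncol(x) < 3L) stop("detrend needs at least 3 spectral points")
  w <- spectra$wavenumbers
  ws <- (w - mean(w)) / stats::sd(w)
  basis <- cbind(1, ws, ws^2)
  qrb <- qr(basis)
  res <- t(qr.resid(qrb, t(x)))
  milk_spectra(res, w, sample_ids = rownames(x), meta = spectra$meta)
}

#' SNV followed by detrend (SNV+D)
#'
#' Evaluates SNV and detrending together: SNV is applied first, then the
#' degree-2 detrend.
#'
#' @inheritParams snv
#' @return A `milk_spectra`.
#' @export
snv_detrend <- function(spectra) {
  detrend(snv(spectra))
}

#' Mean reference spectrum for MSC
#'
#' @param spectra calibration-set spectra on the working (masked) axis.
#' @return Numeric vector: the mean spectrum, for use as the MSC reference.
#' @export
msc_reference <- function(spectra) {
  stopifnot(inherits(spectra, "milk_spectra"))
  colMeans(spectra$absorbance)
}

#' Multiplicative scatter correction (MSC)
#'
#' Corrects each spectrum for additive and multiplicative scatter against a
#' reference spectrum (conventionally the calibration-set mean): each row x is
#' regressed as x = a + b*ref by least squares and replaced by (x - a)/b.
#' A row equal to `c*ref + d` is corrected back to `ref` exactly.
#'
#' @param spectra a [milk_spectra()] object.
#' @param ref reference spectrum (numeric vector on the same axis), e.g. from
#'   [msc_reference()] computed on calibration rows only.
#' @return A `milk_spectra` of corrected spectra.
#' @export
msc <- function(spectra, ref) {
  stopifnot(inherits(spectra, "milk_spectra"))
  x <- spectra$absorbance
  ref <- as.numeric(ref)
  if (length(ref) != ncol(x)) stop("MSC reference length must match the axis")
  rc <- ref - mean(ref)
  vr <- sum(rc^2)
  if (vr < 1e-20) stop("MSC reference is constant")
  b <- as.numeric(x %*% rc) / vr         # per-row slope on ref
  a <- rowMeans(x) - b * mean(ref)
  if (any(abs(b) < 1e-8)) {
    stop("MSC slope ~ 0 for sample(s): ",
         paste(rownames(x)[abs(b) < 1e-8], collapse = ", "))
  }
  milk_spectra((x - a) / b, spectra$wavenumbers,
               sample_ids = rownames(x), meta = spectra$meta)
}

running_mean_kernel <- function(n, s) {
  # offsets of a centred window of s points; for even s the window extends one
  # point further to the right
  lo <- -((s - 1L) %/% 2L)
  hi <- s %/% 2L
  list(lo = lo, hi = hi)
}

smooth_rows <- function(x, s) {
  if (s == 1L) return(list(x = x, keep = seq_len(ncol(x))))
  k <- running_mean_kernel(ncol(x), s)
  n <- ncol(x)
  if (n - k$hi < 1L - k$lo) stop("smoothing window exceeds row length")
  idx <- seq.int(1L - k$lo, n - k$hi)        # centres where the window fits
  out <- matrix(0, nrow(x), length(idx))
  for (off in k$lo:k$hi) out <- out + x[, idx + off, drop = FALSE]
  list(x = out / s, keep = idx)
}

derivative_rows <- function(x, gap) {
  # centred gap difference: out_i = x[i + ceil(gap/2)] - x[i - floor(gap/2)]
  lo <- gap %/% 2L
  hi <- gap - lo
  n <- ncol(x)
  if (n - hi < 1L + lo) stop("derivative gap exceeds row length")
  idx <- seq.int(1L + lo, n - hi)
  list(x = x[, idx + hi, drop = FALSE] - x[, idx - lo, drop = FALSE], keep = idx)
}

#' Preprocessing specification
#'
#' Pairs a scatter correction with a WinISI-coded math treatment
#' "d,gap,s1,s2": derivative order `d` (0, 1 or 2), the gap over which the
#' derivative is calculated, and the window sizes of the first and second
#' running-mean smoothings. `"0,0,1,1"` is the identity treatment.
#'
#' @param scatter one of `"none"`, `"SNV"`, `"D"` (detrend), `"SNV+D"`,
#'   `"MSC"`.
#' @param math math-treatment code, either a string `"d,gap,s1,s2"` or an
#'   integer vector of length 4.
#' @return An object of class `preprocess_spec`.
#' @export
preprocess_spec <- function(scatter = "none", math = "0,0,1,1") {
  scatter <- match.arg(scatter, c("none", "SNV", "D", "SNV+D", "MSC"))
  if (is.character(math)) {
    math <- as.integer(strsplit(math, ",", fixed = TRUE)[[1L]])
  }
  math <- as.integer(math)
  if (length(math) != 4L) stop("math treatment must be d,gap,s1,s2")
  names(math) <- c("d", "gap", "s1", "s2")
  if (!math["d"] %in% 0:2) stop("derivative order d must be 0, 1 or 2")
  if (math["gap"] < 0L) stop("gap must be >= 0")
  if (math["d"] == 0L && math["gap"] != 0L) stop("d = 0 requires gap = 0")
  if (math["d"] > 0L && math["gap"] < 1L) stop("d > 0 requires gap >= 1")
  if (any(math[c("s1", "s2")] < 1L)) stop("smoothing sizes must be >= 1")
  structure(list(scatter = scatter, math = math), class = "preprocess_spec")
}

#' @export
format.preprocess_spec <- function(x, ...) {
  sprintf("%s / %s", x$scatter, paste(x$math, collapse = ","))
}

#' @export
print.preprocess_spec <- function(x, ...) {
  cat("preprocess_spec:", format(x), "\n")
  invisible(x)
}

#' Apply a WinISI math treatment
#'
#' Pipeline: running-mean smoothing over `s1` points, then the centred
#' gap-difference derivative applied `d` times (first derivative at point i =
#' difference of the smoothed signal across a gap of `gap` points), then a
#' second running-mean smoothing over `s2` points. The output keeps only the
#' points where every window fits (no padding or extrapolation) and the axis
#' is trimmed consistently. The treatment is linear in the spectra.
#'
#' @param spectra a [milk_spectra()] object.
#' @param math 4-tuple `(d, gap, s1, s2)` or code string, see
#'   [preprocess_spec()].
#' @return A `milk_spectra`, possibly with fewer points at the edges.
#' @export
math_treatment <- function(spectra, math) {
  stopifnot(inherits(spectra, "milk_spectra"))
  m <- preprocess_spec("none", math)$math
  x <- spectra$absorbance
  wn <- spectra$wavenumbers
  sm <- smooth_rows(x, m[["s1"]])
  x <- sm$x
  wn <- wn[sm$keep]
  if (m[["d"]] > 0L) {
    for (i in seq_len(m[["d"]])) {
      dv <- derivative_rows(x, m[["gap"]])
      x <- dv$x
      wn <- wn[dv$keep]
    }
  }
  sm2 <- smooth_rows(x, m[["s2"]])
  x <- sm2$x
  wn <- wn[sm2$keep]
  milk_spectra(x, wn, sample_ids = rownames(spectra$absorbance),
               meta = spectra$meta)
}

#' Apply a full preprocessing specification
#'
#' Applies the scatter correction first (WinISI convention), then the math
#' treatment, and records the specification in the output metadata.
#'
#' @param spectra a [milk_spectra()] object.
#' @param spec a [preprocess_spec()].
#' @param ref MSC reference spectrum (required iff `spec$scatter == "MSC"`),
#'   computed on calibration rows only.
#' @return A preprocessed `milk_spectra`.
#' @export
apply_preprocess <- function(spectra, spec, ref = NULL) {
  stopifnot(inherits(spectra, "milk_spectra"), inherits(spec, "preprocess_spec"))
  out <- switch(spec$scatter,
    "none"  = spectra,
    "SNV"   = snv(spectra),
    "D"     = detrend(spectra),
    "SNV+D" = snv_detrend(spectra),
    "MSC"   = {
      if (is.null(ref)) stop("MSC requires a reference spectrum")
      msc(spectra, ref)
    })
  out <- math_treatment(out, spec$math)
  out$meta$preprocess <- spec
  out
}
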