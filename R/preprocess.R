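#' Dark-spectrum subtraction
#'
#' Subtracts the instrument's dark counts (interpolated onto the spectrum
#' grid, or a \linkS4class{SpectraSet}/vector on the identical grid) from
#' every spectrum.  Negative results are clipped to zero: photon counts are
#' physical.
#'
#' @param x a \linkS4class{SpectraSet} of raw counts.
#' @param dark an \linkS4class{InstrumentModel}, or a numeric vector on
#'   exactly the grid of \code{x}.
#' @return the corrected \linkS4class{SpectraSet}, with the step logged.
#' @export
subtractDark <- function(x, dark) {
  wl <- wavelengths(x)
  if (is(dark, "InstrumentModel")) {
    d <- .instrumentAt(dark, wl, "dark")
  } else {
    d <- as.numeric(dark)
    if (length(d) != length(wl))
      stop("dark spectrum is not on the same wavelength grid")
  }
  m <- pmax(intensities(x) - d, 0)
  assay(x, "intensity") <- m
  .logStep(x, "dark")
}

.boxcar <- function(y, width) {
  n <- length(y)
  h <- (width - 1L) %/% 2L
  cs <- cumsum(c(0, y))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Boxcar (moving-average) smoothing
#'
#' Centered moving average of each spectrum.  Windows are truncated at the
#' spectrum edges, so the grid length is preserved.
#'
#' @param x a \linkS4class{SpectraSet}.
#' @param width odd window width in grid points (1 = identity).
#' @return the smoothed \linkS4class{SpectraSet}, with the step logged.
#' @export
boxcarSmooth <- function(x, width = 5) {
  if (width < 1 || width %% 2 == 0)
    stop("boxcar width must be a positive odd integer")
  if (width > nrow(x)) stop("boxcar width exceeds the number of grid points")
  m <- apply(intensities(x), 2, .boxcar, width = as.integer(width))
  assay(x, "intensity") <- m
  .logStep(x, sprintf("boxcar(%d)", as.integer(width)))
}

#' Spectral-sensitivity correction
#'
#' Divides each spectrum pointwise by the instrument's relative spectral
#' response (estimated from a calibration lamp as measured/reference),
#' removing the wavelength dependence of detector sensitivity.
#'
#' @param x a \linkS4class{SpectraSet}.
#' @param instrument an \linkS4class{InstrumentModel} (response > 0 on the
#'   grid), or a numeric response vector on exactly the grid of \code{x}.
#' @return the corrected \linkS4class{SpectraSet}, with the step logged.
#' @export
correctSensitivity <- function(x, instrument) {
  wl <- wavelengths(x)
  if (is(instrument, "InstrumentModel")) {
    r <- .instrumentAt(instrument, wl, "response")
  } else {
    r <- as.numeric(instrument)
    if (length(r) != length(wl))
      stop("response is not defined on the spectrum grid")
  }
  if (any(r <= 0)) stop("relative response must be > 0 on the whole grid")
  assay(x, "intensity") <- intensities(x) / r
  .logStep(x, "sensitivity")
}

#' Restrict spectra to the excitation-dependent wavelength window
#'
#' Keeps grid points with \eqn{\lambda_{min} \le \lambda \le \lambda_{max}}
#' (closed interval) for the window assigned to the set's excitation
#' wavelength.
#'
#' @param x a \linkS4class{SpectraSet}.
#' @param table data.frame with columns excitation_nm, lambda_min,
#'   lambda_max; default \code{\link{defaultRangeTable}()}.
#' @return the restricted \linkS4class{SpectraSet}, with the step logged.
#' @export
restrictRange <- function(x, table = defaultRangeTable()) {
  ex <- excitation(x)
  i <- match(ex, table$excitation_nm)
  if (is.na(i))
    stop(sprintf("no restriction range defined for excitation %g nm", ex))
  wl <- wavelengths(x)
  tol <- 1e-9
  keep <- wl >= table$lambda_min[i] - tol & wl <= table$lambda_max[i] + tol
  if (!any(keep)) stop("restriction window contains no grid points")
  out <- x[keep, ]
  .logStep(out, sprintf("restrict[%g,%g]", table$lambda_min[i],
                        table$lambda_max[i]))
}

#' Normalize spectra at a reference wavelength
#'
#' Divides every spectrum by its own intensity at the grid point nearest
#' \code{lambda_ref}, so that value becomes exactly 1.  Removes differences
#' caused by irradiation geometry and source power while preserving spectral
#' shape.  Idempotent.
#'
#' @param x a \linkS4class{SpectraSet}.
#' @param lambda_ref reference wavelength (nm), default 600.
#' @return the normalized \linkS4class{SpectraSet}, with the step logged.
#' @export
normalizeAt <- function(x, lambda_ref = 600) {
  wl <- wavelengths(x)
  if (lambda_ref < min(wl) || lambda_ref > max(wl))
    stop(sprintf("reference wavelength %g nm is outside the grid", lambda_ref))
  i <- which.min(abs(wl - lambda_ref))
  ref <- intensities(x)[i, ]
  if (any(ref <= 0))
    stop("non-positive intensity at the reference wavelength")
  assay(x, "intensity") <- sweep(intensities(x), 2, ref, "/")
  .logStep(x, sprintf("normalize(%g)", lambda_ref))
}

#' Full preprocessing pipeline
#'
#' Applies, in order: dark subtraction, spectral-sensitivity correction,
#' boxcar smoothing, excitation-dependent range restriction and
#' single-wavelength normalization.  The order is recorded in the
#' processing log of the result.
#'
#' @param x a \linkS4class{SpectraSet} of raw counts.
#' @param instrument an \linkS4class{InstrumentModel}.
#' @param boxcarWidth odd smoothing window, default 5.
#' @param rangeTable see \code{\link{restrictRange}}.
#' @param lambda_ref normalization wavelength (nm), default 600.
#' @return the preprocessed \linkS4class{SpectraSet}.
#' @export
preprocessSpectra <- function(x, instrument,
                              boxcarWidth = 5,
                              rangeTable = defaultRangeTable(),
                              lambda_ref = 600) {
  x <- subtractDark(x, instrument)
  x <- correctSensitivity(x, instrument)
  x <- boxcarSmooth(x, boxcarWidth)
  x <- restrictRange(x, rangeTable)
  normalizeAt(x, lambda_ref)
}
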