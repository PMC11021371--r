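## Preprocessing of absorbance spectra: resampling, axis conversion,
## LOESS smoothing, linear background subtraction, band maxima and
## difference spectra.

## Restrict a Spectrum to a wavelength window (inclusive).
cropSpectrum <- function(spec, window) {
  idx <- which(spec@wavelength >= window@loNm & spec@wavelength <= window@hiNm)
  if (!length(idx))
    bsError("bs_parameter_error", "window contains no points of the spectrum")
  new("Spectrum", wavelength = spec@wavelength[idx],
      absorbance = spec@absorbance[idx], label = spec@label,
      metadata = spec@metadata)
}

.checkWindowSupport <- function(spec, window) {
  if (window@loNm < min(spec@wavelength) - 1e-9 ||
      window@hiNm > max(spec@wavelength) + 1e-9)
    bsError("bs_parameter_error", sprintf(
      "window %g-%g nm exceeds the spectrum's support %g-%g nm",
      window@loNm, window@hiNm, min(spec@wavelength), max(spec@wavelength)))
  invisible(TRUE)
}

#' Resample a spectrum by linear interpolation
#'
#' Interpolates the spectrum linearly onto a new strictly increasing
#' wavelength grid. Extrapolation beyond the support is refused.
#'
#' @param spec a [Spectrum-class].
#' @param grid strictly increasing target wavelengths (nm) within the
#'   spectrum's support.
#' @return a [Spectrum-class] on `grid`.
#' @export
resampleSpectrum <- function(spec, grid) {
  stopifnot(methods::is(spec, "Spectrum"))
  grid <- as.numeric(grid)
  if (!length(grid)) bsError("bs_parameter_error", "empty target grid")
  if (length(grid) > 1 && any(diff(grid) <= 0))
    bsError("bs_parameter_error", "target grid must be strictly increasing")
  if (min(grid) < min(spec@wavelength) - 1e-9 ||
      max(grid) > max(spec@wavelength) + 1e-9)
    bsError("bs_extrapolation_error",
            "target grid extends beyond the spectrum's support; extrapolation is not performed")
  a <- stats::approx(spec@wavelength, spec@absorbance, xout = grid,
                     method = "linear", rule = 1)$y
  new("Spectrum", wavelength = grid, absorbance = a, label = spec@label,
      metadata = spec@metadata)
}

#' Convert a spectrum to the wavenumber axis
#'
#' Returns the curve on the wavenumber axis (cm^-1, ascending). Absorbance
#' values are carried over unchanged: the two-component mixture model is
#' linear and therefore invariant under any common axis transform, so no
#' Jacobian rescaling is applied.
#'
#' @param spec a [Spectrum-class].
#' @return a data.frame with columns `wavenumber_cm1` (ascending) and
#'   `absorbance`; the label and metadata travel as attributes.
#' @export
toWavenumber <- function(spec) {
  stopifnot(methods::is(spec, "Spectrum"))
  nu <- nmToWavenumber(spec@wavelength)
  o <- order(nu)
  out <- data.frame(wavenumber_cm1 = nu[o], absorbance = spec@absorbance[o])
  attr(out, "label") <- spec@label
  attr(out, "metadata") <- spec@metadata
  out
}

#' Convert a wavenumber-axis curve back to a Spectrum
#'
#' Inverse of [toWavenumber()].
#'
#' @param curve a data.frame with columns `wavenumber_cm1` and `absorbance`.
#' @return a [Spectrum-class].
#' @export
toWavelength <- function(curve) {
  if (!all(c("wavenumber_cm1", "absorbance") %in% names(curve)))
    bsError("bs_format_error",
            "curve must have columns wavenumber_cm1 and absorbance")
  label <- attr(curve, "label"); if (is.null(label)) label <- ""
  metadata <- attr(curve, "metadata"); if (is.null(metadata)) metadata <- list()
  Spectrum(wavenumberToNm(curve$wavenumber_cm1), curve$absorbance,
           label = label, metadata = metadata)
}

#' LOESS-smooth a spectrum
#'
#' Locally weighted quadratic regression with a proportional span
#' (default 0.1), evaluated on the spectrum's own grid with endpoints
#' retained. Exact local polynomial reproduction is guaranteed by using
#' direct (non-interpolated) LOESS evaluation.
#'
#' @param spec a [Spectrum-class] with at least 10 points.
#' @param span smoothing span as a fraction of the data, in (0, 1].
#' @return the smoothed [Spectrum-class] on the same grid.
#' @export
loessSmooth <- function(spec, span = 0.1) {
  stopifnot(methods::is(spec, "Spectrum"))
  if (!is.finite(span) || span <= 0 || span > 1)
    bsError("bs_parameter_error", "span must lie in (0, 1]")
  n <- length(spec@wavelength)
  if (n < 10L)
    bsError("bs_insufficient_data", "at least 10 points are required for smoothing")
  if (span * n < 4)
    bsError("bs_parameter_error", sprintf(
      "span %g covers fewer than 4 of the %d points", span, n))
  df <- data.frame(w = spec@wavelength, a = spec@absorbance)
  fit <- stats::loess(a ~ w, data = df, span = span, degree = 2,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  sm <- stats::predict(fit, newdata = df)
  new("Spectrum", wavelength = spec@wavelength, absorbance = as.numeric(sm),
      label = spec@label,
      metadata = c(spec@metadata[setdiff(names(spec@metadata), "smoothed")],
                   list(smoothed = TRUE)))
}

## Anchor-region linear background: the line through the mean (lambda, A)
## of the two edge regions. Returns list(slope, intercept).
.anchorLine <- function(w, a, window, anchorWidthNm) {
  loIdx <- which(w >= window@loNm & w <= window@loNm + anchorWidthNm)
  hiIdx <- which(w >= window@hiNm - anchorWidthNm & w <= window@hiNm)
  if (length(loIdx) < 3L || length(hiIdx) < 3L)
    bsError("bs_parameter_error",
            "each anchor region must contain at least 3 points")
  x1 <- mean(w[loIdx]); y1 <- mean(a[loIdx])
  x2 <- mean(w[hiIdx]); y2 <- mean(a[hiIdx])
  slope <- (y2 - y1) / (x2 - x1)
  list(slope = slope, intercept = y1 - slope * x1)
}

#' Subtract a linear scattering background over a window
#'
#' Fits a straight line through the mean (wavelength, absorbance) of two
#' anchor regions at the window edges (default width 10 nm) and subtracts
#' it; the result is restricted to the window. The operation is linear in
#' the spectrum, annihilates any affine baseline, and is idempotent.
#'
#' @param spec a [Spectrum-class] whose support covers `window`.
#' @param window the analysis [WavelengthWindow-class] (default Q band,
#'   550-850 nm).
#' @param anchorWidthNm width of the two anchor regions in nm (> 0).
#' @return the background-subtracted [Spectrum-class], restricted to
#'   `window`, with metadata flag `background_subtracted`.
#' @export
subtractLinearBackground <- function(spec, window = qBandWindow(),
                                     anchorWidthNm = 10) {
  stopifnot(methods::is(spec, "Spectrum"))
  if (!is.finite(anchorWidthNm) || anchorWidthNm <= 0)
    bsError("bs_parameter_error", "anchor width must be positive")
  .checkWindowSupport(spec, window)
  cropped <- cropSpectrum(spec, window)
  line <- .anchorLine(cropped@wavelength, cropped@absorbance, window,
                      anchorWidthNm)
  a <- cropped@absorbance - (line$intercept + line$slope * cropped@wavelength)
  md <- cropped@metadata
  md$background_subtracted <- TRUE
  md$background_window <- c(window@loNm, window@hiNm)
  new("Spectrum", wavelength = cropped@wavelength, absorbance = a,
      label = spec@label, metadata = md)
}

#' Locate the absorbance maximum within a window
#'
#' Smooths the windowed spectrum (LOESS, proportional span), takes the
#' discrete argmax (ties broken toward the longer wavelength) and refines
#' it by quadratic interpolation through the three points around the
#' maximum. A maximum at the window edge is returned unrefined.
#'
#' @param spec a [Spectrum-class].
#' @param window a [WavelengthWindow-class] with at least 5 points
#'   (default: the full support).
#' @param span LOESS span used for peak detection (default 0.1); smoothing
#'   is skipped for windows with fewer than 10 points.
#' @return the peak wavelength in nm.
#' @export
findLambdaMax <- function(spec, window = NULL, span = 0.1) {
  stopifnot(methods::is(spec, "Spectrum"))
  if (is.null(window))
    window <- WavelengthWindow(min(spec@wavelength), max(spec@wavelength))
  sub <- cropSpectrum(spec, window)
  n <- length(sub@wavelength)
  if (n < 5L)
    bsError("bs_insufficient_data", "window must contain at least 5 points")
  if (diff(range(sub@absorbance)) < 1e-9)
    bsError("bs_degenerate_input", "flat window: no discernible maximum")
  if (n >= 10L) {
    effSpan <- max(span, 4 / n)
    sub <- loessSmooth(sub, span = effSpan)
  }
  y <- sub@absorbance; x <- sub@wavelength
  i <- max(which(y >= max(y) - 0))        # ties -> longer wavelength
  if (i == 1L || i == n) return(x[i])
  # quadratic through the 3 points around the argmax (unequal spacing OK)
  xs <- x[(i - 1):(i + 1)]; ys <- y[(i - 1):(i + 1)]
  co <- tryCatch(solve(cbind(1, xs, xs^2), ys), error = function(e) NULL)
  if (is.null(co) || !is.finite(co[3]) || co[3] >= 0) return(x[i])
  vertex <- -co[2] / (2 * co[3])
  min(max(vertex, xs[1]), xs[3])
}

#' Difference of two spectra
#'
#' Pointwise `a - b` over the overlapping support; `b` is resampled onto
#' `a`'s grid. The result is flagged as a difference spectrum (negative
#' values allowed).
#'
#' @param a,b [Spectrum-class] objects with overlapping support.
#' @return the difference [Spectrum-class] on `a`'s grid restricted to the
#'   overlap.
#' @export
differenceSpectrum <- function(a, b) {
  stopifnot(methods::is(a, "Spectrum"), methods::is(b, "Spectrum"))
  lo <- max(min(a@wavelength), min(b@wavelength))
  hi <- min(max(a@wavelength), max(b@wavelength))
  if (lo >= hi)
    bsError("bs_parameter_error", "the two spectra have disjoint supports")
  aSub <- cropSpectrum(a, WavelengthWindow(lo, hi))
  bSub <- resampleSpectrum(b, aSub@wavelength)
  new("Spectrum", wavelength = aSub@wavelength,
      absorbance = aSub@absorbance - bSub@absorbance,
      label = sprintf("%s - %s", a@label, b@label),
      metadata = list(difference = TRUE))
}
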