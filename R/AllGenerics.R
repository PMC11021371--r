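## Generics and accessor/show methods.

#' Accessors for bathyspec objects
#'
#' `wavelengths` and `absorbances` return the grid and values of a
#' [Spectrum-class]; `specMetadata` its metadata list. `pfrFraction` and
#' `prFraction` return alpha and 1 - alpha of a [PhotostateFit-class];
#' `tHalf` the half-life of a [DarkReversionFit-class].
#'
#' @param x a bathyspec object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))
#' @rdname accessors
#' @export
setGeneric("absorbances", function(x) standardGeneric("absorbances"))
#' @rdname accessors
#' @export
setGeneric("specMetadata", function(x) standardGeneric("specMetadata"))
#' @rdname accessors
#' @export
setGeneric("pfrFraction", function(x) standardGeneric("pfrFraction"))
#' @rdname accessors
#' @export
setGeneric("prFraction", function(x) standardGeneric("prFraction"))
#' @rdname accessors
#' @export
setGeneric("tHalf", function(x) standardGeneric("tHalf"))

#' @rdname accessors
#' @export
setMethod("wavelengths", "Spectrum", function(x) x@wavelength)
#' @rdname accessors
#' @export
setMethod("absorbances", "Spectrum", function(x) x@absorbance)
#' @rdname accessors
#' @export
setMethod("specMetadata", "Spectrum", function(x) x@metadata)
#' @rdname accessors
#' @export
setMethod("pfrFraction", "PhotostateFit", function(x) x@alpha)
#' @rdname accessors
#' @export
setMethod("prFraction", "PhotostateFit", function(x) 1 - x@alpha)
#' @rdname accessors
#' @export
setMethod("tHalf", "DarkReversionFit", function(x) x@tHalf)

#' @param x a [Spectrum-class].
#' @describeIn Spectrum number of sampled points.
#' @export
setMethod("length", "Spectrum", function(x) length(x@wavelength))

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum '%s': %d points, %.1f-%.1f nm\n",
              object@label, length(object@wavelength),
              min(object@wavelength), max(object@wavelength)))
  flags <- names(Filter(isTRUE, object@metadata))
  if (length(flags)) cat("  flags:", paste(flags, collapse = ", "), "\n")
})

setMethod("show", "WavelengthWindow", function(object) {
  cat(sprintf("WavelengthWindow %g-%g nm\n", object@loNm, object@hiNm))
})

setMethod("show", "PureStateModel", function(object) {
  cat(sprintf("PureStateModel (%s): %d Gaussian band(s)\n",
              object@state, nrow(object@bands)))
  b <- object@bands
  for (i in seq_len(nrow(b)))
    cat(sprintf("  band %d: center %.0f cm^-1 (%.1f nm), sigma %.0f cm^-1, amplitude %.4f\n",
                i, b$center_cm1[i], 1e7 / b$center_cm1[i], b$sigma_cm1[i],
                b$amplitude[i]))
  if (nzchar(object@provenance)) cat("  provenance:", object@provenance, "\n")
})

setMethod("show", "PhotostateFit", function(object) {
  cat(sprintf("PhotostateFit [%s]: alpha (Pfr) = %.4f, Pr = %.4f, c = %.4f\n",
              object@condition, object@alpha, 1 - object@alpha, object@scale))
  cat(sprintf("  rss = %.3g AU^2 over %d points (%g-%g nm)%s\n",
              object@rss, object@nPoints, object@window@loNm,
              object@window@hiNm,
              if (object@boundary) " [boundary]" else ""))
  if (!is.na(object@alphaSe))
    cat(sprintf("  bootstrap se = %.4f, 95%% CI [%.4f, %.4f]\n",
                object@alphaSe, object@ci95[1], object@ci95[2]))
})

setMethod("show", "PhotocycleParams", function(object) {
  cat(sprintf("PhotocycleParams: kPr->Pfr = %g, kPfr->Pr = %g, kDR = %g s^-1\n",
              object@kPrToPfr, object@kPfrToPr, object@kDr))
})

setMethod("show", "DarkReversionSeries", function(object) {
  cat(sprintf("DarkReversionSeries '%s': %d points, t = %g-%g s, alpha = %.3f-%.3f\n",
              object@label, length(object@times), min(object@times),
              max(object@times), min(object@alphas), max(object@alphas)))
})

setMethod("show", "DarkReversionFit", function(object) {
  cat(sprintf("DarkReversionFit: order %d, alphaInf = %.3f, rss = %.3g\n",
              object@nExp, object@alphaInf, object@rss))
  for (i in seq_along(object@rates))
    cat(sprintf("  component %d: a = %.4f, k = %.4g s^-1\n", i,
                object@amplitudes[i], object@rates[i]))
  if (!is.na(object@tHalf)) {
    cat(sprintf("  t1/2 (50%% Pfr) = %.4g s", object@tHalf))
    if (!any(is.na(object@tHalfCi)))
      cat(sprintf(" [%.4g, %.4g]", object@tHalfCi[1], object@tHalfCi[2]))
    cat("\n")
  }
})

setMethod("show", "PhytochromePreset", function(object) {
  cat(sprintf("PhytochromePreset '%s': Pr %g/%g nm, Pfr %g/%g nm, eta %.2f%s, t1/2 %g s\n",
              object@name, object@soretPrNm, object@qPrNm, object@soretPfrNm,
              object@qPfrNm, object@eta,
              if (object@etaAssumed) " (assumed)" else "", object@tHalfDark))
})
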