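## S4 classes for the photostate-analysis pipeline.
##
## Central objects: Spectrum (sampled absorbance curve), WavelengthWindow,
## PureStateModel (Gaussian-band pure Pr/Pfr reference), PhotostateFit
## (unmixing result), PhotocycleParams / LightSource / IlluminationSchedule
## (two-state kinetic model), DarkReversionSeries / DarkReversionFit,
## PhytochromePreset and NoiseModel (synthetic-data generator).

#' Spectrum: a sampled absorbance curve
#'
#' An absorbance spectrum on a strictly increasing wavelength grid.
#' Wavelengths are in nanometres, absorbance in absorbance units (AU).
#' Negative absorbance is only meaningful for difference or
#' background-subtracted spectra; the validity method tolerates small
#' noise-level negatives on raw spectra but rejects grossly negative
#' unflagged data.
#'
#' @slot wavelength numeric, strictly increasing wavelength grid (nm, > 0).
#' @slot absorbance numeric, absorbance values (AU), same length.
#' @slot label single character label.
#' @slot metadata named list (illumination condition, time point, flags
#'   such as `difference`, `background_subtracted`, `noisy`, generator
#'   ground truth).
#' @export
setClass("Spectrum",
  representation(wavelength = "numeric", absorbance = "numeric",
                 label = "character", metadata = "list"))

setValidity("Spectrum", function(object) {
  w <- object@wavelength; a <- object@absorbance
  msg <- character()
  if (length(w) != length(a))
    msg <- c(msg, "wavelength and absorbance must have equal length")
  if (length(w) && (any(!is.finite(w)) || any(!is.finite(a))))
    msg <- c(msg, "all wavelengths and absorbances must be finite")
  if (length(w) && any(w <= 0))
    msg <- c(msg, "wavelengths must be positive")
  if (length(w) > 1 && any(diff(w) <= 0))
    msg <- c(msg, "wavelengths must be strictly increasing")
  if (length(object@label) != 1L)
    msg <- c(msg, "label must be a single string")
  flagged <- isTRUE(object@metadata$difference) ||
    isTRUE(object@metadata$background_subtracted) ||
    isTRUE(object@metadata$noisy)
  if (!flagged && length(a) && min(a) < -0.05)
    msg <- c(msg, "substantially negative absorbance requires a difference/background_subtracted/noisy metadata flag")
  if (length(msg)) msg else TRUE
})

#' Construct a Spectrum
#'
#' Points are sorted by wavelength; duplicate wavelengths are collapsed by
#' averaging their absorbance.
#'
#' @param wavelength wavelengths in nm.
#' @param absorbance absorbance values in AU, same length.
#' @param label free-text label.
#' @param metadata named list of metadata.
#' @return a [Spectrum-class] object.
#' @examples
#' s <- Spectrum(c(700, 600, 800), c(0.5, 0.1, 0.2))
#' wavelengths(s)
#' @export
Spectrum <- function(wavelength, absorbance, label = "", metadata = list()) {
  wavelength <- as.numeric(wavelength)
  absorbance <- as.numeric(absorbance)
  if (length(wavelength) != length(absorbance))
    bsError("bs_format_error", "wavelength and absorbance must have equal length")
  o <- order(wavelength)
  wavelength <- wavelength[o]; absorbance <- absorbance[o]
  if (anyDuplicated(wavelength)) {
    key <- match(wavelength, unique(wavelength))
    absorbance <- as.numeric(tapply(absorbance, key, mean))
    wavelength <- unique(wavelength)
  }
  new("Spectrum", wavelength = wavelength, absorbance = absorbance,
      label = as.character(label), metadata = metadata)
}

#' WavelengthWindow: an analysis region
#'
#' @slot loNm lower edge (nm).
#' @slot hiNm upper edge (nm), strictly larger.
#' @export
setClass("WavelengthWindow", representation(loNm = "numeric", hiNm = "numeric"))

setValidity("WavelengthWindow", function(object) {
  if (length(object@loNm) != 1L || length(object@hiNm) != 1L ||
      !is.finite(object@loNm) || !is.finite(object@hiNm))
    return("window edges must be single finite numbers")
  if (object@loNm >= object@hiNm) return("loNm must be < hiNm")
  TRUE
})

#' @param loNm,hiNm window edges in nm, `loNm < hiNm`.
#' @rdname WavelengthWindow-class
#' @export
WavelengthWindow <- function(loNm, hiNm)
  new("WavelengthWindow", loNm = as.numeric(loNm), hiNm = as.numeric(hiNm))

#' Default Q-band analysis window (550-850 nm)
#'
#' The long-wavelength band region used for Pr/Pfr unmixing.
#' @return a [WavelengthWindow-class].
#' @export
qBandWindow <- function() WavelengthWindow(550, 850)

#' PureStateModel: a Gaussian-band pure Pr or Pfr reference spectrum
#'
#' A pure-state reference spectrum at reference concentration, represented
#' as a superposition of 1-6 Gaussian bands parameterised in wavenumber.
#'
#' @slot state "Pr", "Pfr" or "unknown".
#' @slot bands data.frame with columns `center_cm1`, `sigma_cm1`,
#'   `amplitude`, sorted by center.
#' @slot window the reference [WavelengthWindow-class].
#' @slot provenance free text describing how the pure spectrum was obtained.
#' @export
setClass("PureStateModel",
  representation(state = "character", bands = "data.frame",
                 window = "WavelengthWindow", provenance = "character"))

setValidity("PureStateModel", function(object) {
  msg <- character()
  if (!object@state %in% c("Pr", "Pfr", "unknown"))
    msg <- c(msg, "state must be 'Pr', 'Pfr' or 'unknown'")
  b <- object@bands
  need <- c("center_cm1", "sigma_cm1", "amplitude")
  if (!all(need %in% names(b))) {
    msg <- c(msg, "bands must have columns center_cm1, sigma_cm1, amplitude")
  } else {
    if (nrow(b) < 1L || nrow(b) > 6L)
      msg <- c(msg, "between 1 and 6 bands are required")
    if (nrow(b) && any(b$sigma_cm1 <= 0))
      msg <- c(msg, "band widths must be positive")
    if (nrow(b) && any(b$amplitude < 0))
      msg <- c(msg, "band amplitudes must be nonnegative")
    if (nrow(b) > 1 && is.unsorted(b$center_cm1))
      msg <- c(msg, "bands must be sorted by center")
  }
  if (length(msg)) msg else TRUE
})

#' @param state "Pr", "Pfr" or "unknown".
#' @param bands data.frame with columns `center_cm1`, `sigma_cm1`,
#'   `amplitude` (one row per Gaussian band).
#' @param window reference [WavelengthWindow-class].
#' @param provenance free text.
#' @rdname PureStateModel-class
#' @export
PureStateModel <- function(state, bands, window = qBandWindow(),
                           provenance = "") {
  bands <- as.data.frame(bands)
  bands <- bands[order(bands$center_cm1), , drop = FALSE]
  rownames(bands) <- NULL
  new("PureStateModel", state = state, bands = bands, window = window,
      provenance = as.character(provenance))
}

#' PhotostateFit: result of two-component spectral unmixing
#'
#' @slot alpha Pfr fraction in `[0, 1]` (`[Pfr] / ([Pfr] + [Pr])`).
#' @slot scale overall concentration scale c (> 0).
#' @slot rss residual sum of squares (AU^2).
#' @slot nPoints number of fitted points.
#' @slot alphaSe bootstrap standard error of alpha (NA before bootstrap).
#' @slot ci95 percentile 95% interval for alpha (NA before bootstrap).
#' @slot window fitted [WavelengthWindow-class].
#' @slot condition illumination condition label.
#' @slot boundary TRUE if the optimum sits at alpha = 0 or 1.
#' @export
setClass("PhotostateFit",
  representation(alpha = "numeric", scale = "numeric", rss = "numeric",
                 nPoints = "integer", alphaSe = "numeric", ci95 = "numeric",
                 window = "WavelengthWindow", condition = "character",
                 boundary = "logical"))

setValidity("PhotostateFit", function(object) {
  msg <- character()
  if (object@alpha < 0 || object@alpha > 1)
    msg <- c(msg, "alpha must lie in [0, 1]")
  if (object@scale <= 0) msg <- c(msg, "scale must be positive")
  if (object@rss < 0) msg <- c(msg, "rss must be nonnegative")
  if (!is.na(object@alphaSe) && object@alphaSe < 0)
    msg <- c(msg, "alphaSe must be nonnegative")
  if (length(object@ci95) != 2L) msg <- c(msg, "ci95 must have length 2")
  if (length(msg)) msg else TRUE
})

#' PhotocycleParams: rates of the two-state photocycle model
#'
#' The binary kinetic model has two photochemical rates and one thermal
#' dark-reversion rate (Pr to Pfr in bathy phytochromes); all in s^-1.
#'
#' @slot kPrToPfr photochemical Pr -> Pfr rate (s^-1).
#' @slot kPfrToPr photochemical Pfr -> Pr rate (s^-1).
#' @slot kDr thermal dark-reversion rate Pr -> Pfr (s^-1).
#' @export
setClass("PhotocycleParams",
  representation(kPrToPfr = "numeric", kPfrToPr = "numeric", kDr = "numeric"))

setValidity("PhotocycleParams", function(object) {
  k <- c(object@kPrToPfr, object@kPfrToPr, object@kDr)
  if (length(k) != 3L || any(!is.finite(k)) || any(k < 0))
    return("all three rates must be finite and nonnegative")
  TRUE
})

#' @param kPrToPfr,kPfrToPr,kDr nonnegative rates in s^-1.
#' @rdname PhotocycleParams-class
#' @export
PhotocycleParams <- function(kPrToPfr = 0, kPfrToPr = 0, kDr = 0)
  new("PhotocycleParams", kPrToPfr = as.numeric(kPrToPfr),
      kPfrToPr = as.numeric(kPfrToPr), kDr = as.numeric(kDr))

#' LightSource: a (near-)monochromatic illumination source
#'
#' @slot wavelengthNm nominal wavelength (nm, 300-900).
#' @slot irradianceMwCm2 irradiance at the sample (mW/cm^2, >= 0).
#' @slot bandwidthNm informational spectral bandwidth (nm).
#' @export
setClass("LightSource",
  representation(wavelengthNm = "numeric", irradianceMwCm2 = "numeric",
                 bandwidthNm = "numeric"))

setValidity("LightSource", function(object) {
  msg <- character()
  if (object@wavelengthNm < 300 || object@wavelengthNm > 900)
    msg <- c(msg, "wavelength must lie in 300-900 nm")
  if (object@irradianceMwCm2 < 0) msg <- c(msg, "irradiance must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param wavelengthNm nominal wavelength in nm (300-900).
#' @param irradianceMwCm2 irradiance in mW/cm^2.
#' @param bandwidthNm informational bandwidth in nm.
#' @rdname LightSource-class
#' @export
LightSource <- function(wavelengthNm, irradianceMwCm2, bandwidthNm = 0)
  new("LightSource", wavelengthNm = as.numeric(wavelengthNm),
      irradianceMwCm2 = as.numeric(irradianceMwCm2),
      bandwidthNm = as.numeric(bandwidthNm))

#' IlluminationSchedule: contiguous segments of constant illumination
#'
#' Each segment is a list with `duration_s` (> 0) and `params`
#' (a [PhotocycleParams-class] holding the rates active in that segment;
#' darkness is encoded by zero photochemical rates).
#'
#' @slot segments list of segments.
#' @export
setClass("IlluminationSchedule", representation(segments = "list"))

setValidity("IlluminationSchedule", function(object) {
  if (!length(object@segments)) return("at least one segment is required")
  for (seg in object@segments) {
    if (!is.list(seg) || is.null(seg$duration_s) || is.null(seg$params))
      return("each segment needs duration_s and params")
    if (!is.finite(seg$duration_s) || seg$duration_s <= 0)
      return("segment durations must be positive")
    if (!methods::is(seg$params, "PhotocycleParams"))
      return("segment params must be PhotocycleParams")
  }
  TRUE
})

#' @param segments list of `list(duration_s =, params = PhotocycleParams)`.
#' @rdname IlluminationSchedule-class
#' @export
IlluminationSchedule <- function(segments) {
  new("IlluminationSchedule", segments = segments)
}

#' DarkReversionSeries: Pfr fraction versus time in darkness
#'
#' @slot times strictly increasing nonnegative times (s, t = 0 at transfer
#'   to darkness).
#' @slot alphas Pfr fractions in `[0, 1]`, same length (>= 5 points).
#' @slot label free text.
#' @slot metadata named list (generator ground truth, provenance).
#' @export
setClass("DarkReversionSeries",
  representation(times = "numeric", alphas = "numeric", label = "character",
                 metadata = "list"))

setValidity("DarkReversionSeries", function(object) {
  t <- object@times; a <- object@alphas
  msg <- character()
  if (length(t) != length(a)) msg <- c(msg, "times and alphas lengths differ")
  if (length(t) < 5L) msg <- c(msg, "at least 5 points are required")
  if (length(t) && (any(!is.finite(t)) || any(t < 0)))
    msg <- c(msg, "times must be finite and nonnegative")
  if (length(t) > 1 && any(diff(t) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (length(a) && (any(a < -1e-9) || any(a > 1 + 1e-9)))
    msg <- c(msg, "alphas must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @param times,alphas series data (see slots).
#' @param label free text.
#' @param metadata named list.
#' @rdname DarkReversionSeries-class
#' @export
DarkReversionSeries <- function(times, alphas, label = "", metadata = list()) {
  if (length(times) < 5L)
    bsError("bs_insufficient_data",
            "a dark-reversion series needs at least 5 time points")
  new("DarkReversionSeries", times = as.numeric(times),
      alphas = as.numeric(alphas), label = as.character(label),
      metadata = metadata)
}

#' DarkReversionFit: multiexponential model of alpha(t)
#'
#' Model: `alpha(t) = alphaInf - sum_i a_i * exp(-k_i * t)` with
#' amplitudes `a_i >= 0`, rates `k_i > 0` sorted descending, and terminal
#' Pfr fraction `alphaInf` in `[0.5, 1]`. The half-life `tHalf` is the
#' absolute 50%-Pfr crossing time, not a per-exponential half-life.
#'
#' @slot amplitudes amplitudes `a_i` (>= 0).
#' @slot rates rates `k_i` (s^-1, > 0, sorted descending).
#' @slot alphaInf terminal Pfr fraction.
#' @slot nExp model order (1-3).
#' @slot rss residual sum of squares.
#' @slot tHalf 50%-Pfr crossing time (s; NA if the series starts past 50%).
#' @slot tHalfCi bootstrap 95% interval for tHalf (NA if not computed).
#' @export
setClass("DarkReversionFit",
  representation(amplitudes = "numeric", rates = "numeric",
                 alphaInf = "numeric", nExp = "integer", rss = "numeric",
                 tHalf = "numeric", tHalfCi = "numeric"))

setValidity("DarkReversionFit", function(object) {
  msg <- character()
  if (any(object@amplitudes < 0)) msg <- c(msg, "amplitudes must be >= 0")
  if (any(object@rates <= 0)) msg <- c(msg, "rates must be positive")
  if (length(object@rates) > 1 && is.unsorted(rev(object@rates)))
    msg <- c(msg, "rates must be sorted descending")
  if (length(object@amplitudes) != length(object@rates))
    msg <- c(msg, "amplitudes and rates lengths differ")
  if (sum(object@amplitudes) > object@alphaInf + 1e-6)
    msg <- c(msg, "sum of amplitudes must not exceed alphaInf")
  if (object@nExp < 1L || object@nExp > 3L)
    msg <- c(msg, "model order must be 1-3")
  if (length(msg)) msg else TRUE
})

#' PhytochromePreset: generator parameters for one bathy phytochrome
#'
#' Band maxima, Q-band extinction ratio and dark-reversion half-life used
#' by the synthetic-spectrum generator.
#'
#' @slot name phytochrome name.
#' @slot soretPrNm,qPrNm Pr-state Soret and Q band maxima (nm).
#' @slot soretPfrNm,qPfrNm Pfr-state Soret and Q band maxima (nm).
#' @slot eta Q-band amplitude ratio Pfr/Pr at equal concentration.
#' @slot etaAssumed TRUE when eta was not determined and 1.0 is assumed.
#' @slot tHalfDark dark-reversion half-life (s).
#' @slot qSigmaCm1,soretSigmaCm1 Gaussian band widths (cm^-1).
#' @export
setClass("PhytochromePreset",
  representation(name = "character", soretPrNm = "numeric", qPrNm = "numeric",
                 soretPfrNm = "numeric", qPfrNm = "numeric", eta = "numeric",
                 etaAssumed = "logical", tHalfDark = "numeric",
                 qSigmaCm1 = "numeric", soretSigmaCm1 = "numeric"))

setValidity("PhytochromePreset", function(object) {
  msg <- character()
  if (object@qPfrNm <= object@qPrNm)
    msg <- c(msg, "Pfr Q maximum must be red-shifted relative to Pr (bathochromic)")
  if (object@eta <= 0) msg <- c(msg, "eta must be positive")
  if (object@tHalfDark <= 0) msg <- c(msg, "tHalfDark must be positive")
  if (object@qSigmaCm1 <= 0 || object@soretSigmaCm1 <= 0)
    msg <- c(msg, "band widths must be positive")
  if (length(msg)) msg else TRUE
})

#' @param name,soretPrNm,qPrNm,soretPfrNm,qPfrNm,eta,etaAssumed,tHalfDark,qSigmaCm1,soretSigmaCm1
#'   see slots.
#' @rdname PhytochromePreset-class
#' @export
PhytochromePreset <- function(name, soretPrNm, qPrNm, soretPfrNm, qPfrNm,
                              eta, tHalfDark, etaAssumed = FALSE,
                              qSigmaCm1 = 550, soretSigmaCm1 = 1300) {
  new("PhytochromePreset", name = name, soretPrNm = soretPrNm, qPrNm = qPrNm,
      soretPfrNm = soretPfrNm, qPfrNm = qPfrNm, eta = eta,
      etaAssumed = etaAssumed, tHalfDark = tHalfDark,
      qSigmaCm1 = qSigmaCm1, soretSigmaCm1 = soretSigmaCm1)
}

#' NoiseModel: measurement-noise and baseline model for the generator
#'
#' @slot additiveSd additive Gaussian noise sd (AU, or fraction of the
#'   Q-band peak when `sdIsFractionOfPeak`).
#' @slot sdIsFractionOfPeak interpret `additiveSd` relative to the peak.
#' @slot baselineSlopeRange uniform slope range (AU/nm).
#' @slot baselineOffsetRange uniform offset range (AU).
#' @slot seed mandatory RNG seed.
#' @export
setClass("NoiseModel",
  representation(additiveSd = "numeric", sdIsFractionOfPeak = "logical",
                 baselineSlopeRange = "numeric",
                 baselineOffsetRange = "numeric", seed = "numeric"))

setValidity("NoiseModel", function(object) {
  msg <- character()
  if (object@additiveSd < 0) msg <- c(msg, "noise sd must be >= 0")
  if (length(object@baselineSlopeRange) != 2L ||
      length(object@baselineOffsetRange) != 2L)
    msg <- c(msg, "baseline ranges must have length 2")
  if (length(object@seed) != 1L || !is.finite(object@seed))
    msg <- c(msg, "a finite seed is mandatory")
  if (length(msg)) msg else TRUE
})

#' @param additiveSd,sdIsFractionOfPeak,baselineSlopeRange,baselineOffsetRange,seed
#'   see slots; the defaults emulate instrument noise at 1% of the Q-band
#'   peak with mild scattering baselines.
#' @rdname NoiseModel-class
#' @export
NoiseModel <- function(seed, additiveSd = 0.01, sdIsFractionOfPeak = TRUE,
                       baselineSlopeRange = c(-1e-4, 1e-4),
                       baselineOffsetRange = c(0, 0.02)) {
  new("NoiseModel", additiveSd = additiveSd,
      sdIsFractionOfPeak = sdIsFractionOfPeak,
      baselineSlopeRange = as.numeric(baselineSlopeRange),
      baselineOffsetRange = as.numeric(baselineOffsetRange),
      seed = as.numeric(seed))
}
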