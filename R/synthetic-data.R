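## Synthetic-data generator: pure-state models, photostationary mixtures
## and dark-reversion series with the statistical structure the analysis
## assumes, plus presets for six bathy phytochromes parameterised from
## published band maxima, extinction ratios and dark-reversion half-lives.

## Preset parameter table. Band widths (Q sigma 550 cm^-1, Soret sigma
## 1300 cm^-1) are generator defaults chosen for a broad Soret and a
## sharper Q band; eta printed as "n.d." defaults to 1.0 (assumed flag).
.presetTable <- data.frame(
  name = c("PaBphP", "AtBphP2", "AvBphP2", "RtBphP2", "XccBphP",
           "XccBphPdPAS9"),
  soret_pr = c(398, 394, 388, 390, 392, 392),
  q_pr     = c(702, 702, 698, 684, 686, 686),
  soret_pfr = c(410, 407, 395, 405, 407, 414),
  q_pfr    = c(752, 753, 748, 757, 754, 754),
  eta      = c(0.65, 1.1, 1.0, 2.75, 0.76, 0.75),
  eta_assumed = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
  t_half_s = c(660, 4, 300, 66, 8280, 2940),
  stringsAsFactors = FALSE)

#' Catalogue of bathy phytochrome generator presets
#'
#' Six presets (PaBphP, AtBphP2, AvBphP2, RtBphP2, XccBphP, XccBphPdPAS9)
#' with Soret/Q band maxima for both pure states, the Q-band extinction
#' ratio eta (1.0 with an "assumed" flag where it was not determined) and
#' the dark-reversion half-life.
#'
#' @return a named list of [PhytochromePreset-class] objects.
#' @export
presetCatalogue <- function() {
  out <- lapply(seq_len(nrow(.presetTable)), function(i) {
    r <- .presetTable[i, ]
    PhytochromePreset(r$name, soretPrNm = r$soret_pr, qPrNm = r$q_pr,
                      soretPfrNm = r$soret_pfr, qPfrNm = r$q_pfr,
                      eta = r$eta, etaAssumed = r$eta_assumed,
                      tHalfDark = r$t_half_s)
  })
  stats::setNames(out, .presetTable$name)
}

#' Fetch a single preset by name
#'
#' @param name preset name (see [presetCatalogue()]).
#' @return a [PhytochromePreset-class].
#' @export
getPreset <- function(name) {
  cat <- presetCatalogue()
  if (!name %in% names(cat))
    bsError("bs_parameter_error", sprintf(
      "unknown preset '%s'; available: %s", name,
      paste(names(cat), collapse = ", ")))
  cat[[name]]
}

#' Build pure-state models from a preset
#'
#' Each state is a Soret Gaussian plus a Q Gaussian (optionally a 10%
#' amplitude blue shoulder on the Q band). The Pr Q-band peak is
#' normalised to 1 AU and the Pfr amplitudes are scaled so that the ratio
#' of the two Q-band peak values equals the preset's eta, emulating a pure
#' pair measured at the same concentration. The Soret amplitude is 0.55 of
#' the state's Q amplitude.
#'
#' @param preset a [PhytochromePreset-class].
#' @param shoulder include a 10%-amplitude vibronic shoulder 800 cm^-1
#'   blue of each Q band (default FALSE).
#' @return a list with elements `pr0` and `pfr0`.
#' @export
makePureStateModels <- function(preset, shoulder = FALSE) {
  stopifnot(methods::is(preset, "PhytochromePreset"))
  buildState <- function(state, soretNm, qNm, peakTarget) {
    qC <- nmToWavenumber(qNm)
    bands <- data.frame(
      center_cm1 = c(nmToWavenumber(soretNm), qC),
      sigma_cm1 = c(preset@soretSigmaCm1, preset@qSigmaCm1),
      amplitude = c(0.55, 1))
    if (shoulder)
      bands <- rbind(bands, data.frame(center_cm1 = qC + 800,
                                       sigma_cm1 = preset@qSigmaCm1,
                                       amplitude = 0.1))
    model <- PureStateModel(state, bands, window = qBandWindow(),
                            provenance = sprintf(
                              "synthetic preset %s (%s state)",
                              preset@name, state))
    peak <- evalModelNm(model, qNm)
    model@bands$amplitude <- model@bands$amplitude * (peakTarget / peak)
    model
  }
  pr0 <- buildState("Pr", preset@soretPrNm, preset@qPrNm, 1)
  pfr0 <- buildState("Pfr", preset@soretPfrNm, preset@qPfrNm, preset@eta)
  list(pr0 = pr0, pfr0 = pfr0)
}

#' Generate a photostationary mixture spectrum
#'
#' Evaluates `c * (alpha * Pfr0 + (1 - alpha) * Pr0)` on the grid and,
#' when a [NoiseModel-class] is supplied, adds a random linear baseline
#' (uniform slope/offset within the model's ranges) and additive Gaussian
#' noise, all deterministic given the noise model's seed. The true
#' parameters are recorded in the spectrum's metadata.
#'
#' @param pr0,pfr0 pure-state [PureStateModel-class] references.
#' @param alpha true Pfr fraction in `[0, 1]`.
#' @param scale overall concentration scale c (> 0).
#' @param grid wavelength grid in nm (default 500-900 nm in 1-nm steps,
#'   covering the Q-band analysis window with margin).
#' @param noise optional [NoiseModel-class]; NULL for a clean spectrum.
#' @return a [Spectrum-class] with ground truth in its metadata.
#' @export
generatePhotostateSpectrum <- function(pr0, pfr0, alpha, scale = 1,
                                       grid = seq(500, 900, by = 1),
                                       noise = NULL) {
  if (!is.finite(alpha) || alpha < 0 || alpha > 1)
    bsError("bs_domain_error", "alpha must lie in [0, 1]")
  if (!is.finite(scale) || scale <= 0)
    bsError("bs_domain_error", "scale must be positive")
  y <- scale * (alpha * evalModelNm(pfr0, grid) +
                (1 - alpha) * evalModelNm(pr0, grid))
  md <- list(true_alpha = alpha, true_c = scale)
  if (!is.null(noise)) {
    stopifnot(methods::is(noise, "NoiseModel"))
    qIdx <- grid >= 550 & grid <= 850
    peak <- if (any(qIdx)) max(y[qIdx]) else max(y)
    sdAu <- if (noise@sdIsFractionOfPeak) noise@additiveSd * peak
            else noise@additiveSd
    pieces <- withSeed(noise@seed, list(
      slope = stats::runif(1, noise@baselineSlopeRange[1],
                           noise@baselineSlopeRange[2]),
      offset = stats::runif(1, noise@baselineOffsetRange[1],
                            noise@baselineOffsetRange[2]),
      eps = stats::rnorm(length(grid), 0, sdAu)))
    y <- y + pieces$offset + pieces$slope * (grid - grid[1]) + pieces$eps
    md <- c(md, list(noisy = TRUE, noise_sd_au = sdAu,
                     baseline_slope = pieces$slope,
                     baseline_offset = pieces$offset, seed = noise@seed))
  }
  Spectrum(grid, y, label = sprintf("synthetic mixture alpha=%.3f", alpha),
           metadata = md)
}

#' Generate a dark-reversion series
#'
#' Either from a preset (mono-exponential with `k = ln(2) / tHalfDark`)
#' or from explicit amplitudes and rates. The noiseless model is
#' `alpha(t) = alphaInf - sum a_i exp(-k_i t)`; Gaussian noise is added
#' and the result clipped to `[0, 1]`. The true parameters are recorded
#' in the series metadata.
#'
#' @param tGrid strictly increasing times in s (>= 5 points).
#' @param preset optional [PhytochromePreset-class]; mono-exponential mode.
#' @param amplitudes,rates explicit kinetics (ignored when `preset` given).
#' @param alphaInf terminal Pfr fraction (default 1; e.g. 0.72 for a
#'   plateauing phytochrome).
#' @param alpha0 initial Pfr fraction in preset mode (default 0, i.e.
#'   far-red pre-irradiated).
#' @param noiseSd additive Gaussian noise sd on alpha (default 0).
#' @param seed RNG seed (required when `noiseSd > 0`).
#' @param label series label.
#' @return a [DarkReversionSeries-class].
#' @export
generateDarkReversionSeries <- function(tGrid, preset = NULL,
                                        amplitudes = NULL, rates = NULL,
                                        alphaInf = 1, alpha0 = 0,
                                        noiseSd = 0, seed = NULL,
                                        label = "") {
  if (!is.null(preset)) {
    stopifnot(methods::is(preset, "PhytochromePreset"))
    rates <- log(2) / preset@tHalfDark
    amplitudes <- alphaInf - alpha0
    if (!nzchar(label)) label <- preset@name
  }
  if (is.null(amplitudes) || is.null(rates) ||
      length(amplitudes) != length(rates))
    bsError("bs_parameter_error",
            "either a preset or matching amplitudes and rates are required")
  alphaTrue <- .drModel(amplitudes, rates, alphaInf, tGrid)
  alpha <- alphaTrue
  if (noiseSd > 0) {
    if (is.null(seed))
      bsError("bs_parameter_error", "a seed is required when noise is added")
    alpha <- withSeed(seed, alpha + stats::rnorm(length(tGrid), 0, noiseSd))
  }
  alpha <- pmin(pmax(alpha, 0), 1)
  DarkReversionSeries(tGrid, alpha, label = label,
                      metadata = list(true_amplitudes = amplitudes,
                                      true_rates = rates,
                                      true_alpha_inf = alphaInf,
                                      true_alpha = alphaTrue,
                                      noise_sd = noiseSd, seed = seed))
}
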