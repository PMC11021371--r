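## The two-state photocycle model:
##   d alpha / dt = (kPrToPfr + kDr) * (1 - alpha) - kPfrToPr * alpha
## with alpha the Pfr fraction. Photochemical rates derive from source
## irradiance, extinction coefficient and photoisomerisation quantum
## yield; integration uses the exact per-segment exponential solution.

# physical constants (SI)
.PLANCK <- 6.62607015e-34     # J s
.C_LIGHT <- 2.99792458e8      # m / s
.AVOGADRO <- 6.02214076e23    # 1 / mol

#' Photochemical rate from a light source
#'
#' Standard photochemistry: the absorption cross-section is
#' `sigma = ln(10) * 1000 * eps / N_A` (cm^2 per molecule, with `eps` in
#' M^-1 cm^-1) and the excitation rate is `k = sigma * phi * F`, where
#' `F = E * lambda / (h * c)` is the photon flux (photons cm^-2 s^-1) of a
#' source with irradiance `E` (W/cm^2) at its nominal wavelength
#' (monochromatic approximation).
#'
#' @param source a [LightSource-class].
#' @param epsilon molar extinction coefficient at the source wavelength
#'   (M^-1 cm^-1, >= 0).
#' @param phi photoisomerisation quantum yield in `[0, 1]`.
#' @return the photochemical rate in s^-1.
#' @export
photochemicalRate <- function(source, epsilon, phi) {
  stopifnot(methods::is(source, "LightSource"))
  if (!is.finite(epsilon) || epsilon < 0)
    bsError("bs_domain_error", "epsilon must be finite and >= 0")
  if (!is.finite(phi) || phi < 0 || phi > 1)
    bsError("bs_domain_error", "phi must lie in [0, 1]")
  irradianceW <- source@irradianceMwCm2 / 1000          # W / cm^2
  photonFlux <- irradianceW * (source@wavelengthNm * 1e-9) /
    (.PLANCK * .C_LIGHT)                                # photons / cm^2 / s
  log(10) * 1000 * (epsilon / .AVOGADRO) * phi * photonFlux
}

## Total relaxation rate of the model.
.kTot <- function(p) p@kPrToPfr + p@kPfrToPr + p@kDr

#' Photostationary Pfr fraction of the two-state model
#'
#' The fixed point of the model:
#' `alpha* = (kPrToPfr + kDr) / (kPrToPfr + kDr + kPfrToPr)`.
#' In darkness (photochemical rates zero, kDr > 0) this is exactly 1:
#' the population is driven fully into Pfr.
#'
#' @param params a [PhotocycleParams-class] with at least one positive
#'   rate.
#' @return the stationary Pfr fraction in `[0, 1]`.
#' @export
stationaryAlpha <- function(params) {
  stopifnot(methods::is(params, "PhotocycleParams"))
  kt <- .kTot(params)
  if (kt <= 0)
    bsError("bs_degenerate_input",
            "all rates are zero: the stationary state is undefined")
  (params@kPrToPfr + params@kDr) / kt
}

#' Integrate the photocycle over an illumination schedule
#'
#' Within each constant-rate segment the model has the exact solution
#' `alpha(t) = alpha* + (alpha_entry - alpha*) * exp(-k_tot * (t - t_entry))`
#' (constant when all rates vanish); trajectories are continuous at
#' segment boundaries and remain in `[0, 1]`.
#'
#' @param schedule an [IlluminationSchedule-class] whose segments carry
#'   the active [PhotocycleParams-class].
#' @param alpha0 initial Pfr fraction in `[0, 1]`.
#' @param tEval ordered evaluation times (s) within the schedule's total
#'   duration.
#' @return a data.frame with columns `time_s` and `alpha`.
#' @export
integratePhotocycle <- function(schedule, alpha0, tEval) {
  stopifnot(methods::is(schedule, "IlluminationSchedule"))
  if (!is.finite(alpha0) || alpha0 < 0 || alpha0 > 1)
    bsError("bs_domain_error", "alpha0 must lie in [0, 1]")
  tEval <- as.numeric(tEval)
  durations <- vapply(schedule@segments, function(s) s$duration_s, numeric(1))
  total <- sum(durations)
  if (any(tEval < 0) || any(tEval > total + 1e-9))
    bsError("bs_range_error", sprintf(
      "evaluation times must lie within the schedule's duration (0-%g s)", total))
  starts <- cumsum(c(0, durations[-length(durations)]))
  # alpha at segment entry, propagated through the closed form
  entryAlpha <- numeric(length(durations))
  a <- alpha0
  segAlpha <- function(params, aIn, dt) {
    kt <- .kTot(params)
    if (kt <= 0) return(aIn)
    aStar <- (params@kPrToPfr + params@kDr) / kt
    aStar + (aIn - aStar) * exp(-kt * dt)
  }
  for (i in seq_along(durations)) {
    entryAlpha[i] <- a
    a <- segAlpha(schedule@segments[[i]]$params, a, durations[i])
  }
  alpha <- vapply(tEval, function(t) {
    i <- findInterval(t, starts, rightmost.closed = FALSE)
    i <- min(max(i, 1L), length(durations))
    segAlpha(schedule@segments[[i]]$params, entryAlpha[i], t - starts[i])
  }, numeric(1))
  data.frame(time_s = tEval, alpha = pmin(pmax(alpha, 0), 1))
}

#' Convenience constructor for a darkness segment
#'
#' @param duration_s segment duration in s.
#' @param kDr thermal dark-reversion rate in s^-1.
#' @return a segment list usable in [IlluminationSchedule()].
#' @export
darkSegment <- function(duration_s, kDr)
  list(duration_s = duration_s, params = PhotocycleParams(0, 0, kDr))

#' Convenience constructor for an illuminated segment
#'
#' @param duration_s segment duration in s.
#' @param kPrToPfr,kPfrToPr photochemical rates in s^-1 (e.g. from
#'   [photochemicalRate()]).
#' @param kDr thermal dark-reversion rate in s^-1 (still active under
#'   illumination).
#' @return a segment list usable in [IlluminationSchedule()].
#' @export
lightSegment <- function(duration_s, kPrToPfr, kPfrToPr, kDr = 0)
  list(duration_s = duration_s,
       params = PhotocycleParams(kPrToPfr, kPfrToPr, kDr))
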