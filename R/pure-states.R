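## Pure-state (Pr0 / Pfr0) reference spectra as Gaussian-band
## superpositions in wavenumber, their fitting, and the extinction ratio
## eta = eps(lambda_max, Pfr) / eps(lambda_max, Pr).

## Evaluate a band table at wavenumbers nu (cm^-1).
.evalBandsNu <- function(bands, nu) {
  out <- numeric(length(nu))
  for (i in seq_len(nrow(bands)))
    out <- out + bands$amplitude[i] *
      exp(-(nu - bands$center_cm1[i])^2 / (2 * bands$sigma_cm1[i]^2))
  out
}

## Evaluate a PureStateModel at wavelengths (nm), returning numeric.
evalModelNm <- function(model, nm) .evalBandsNu(model@bands, nmToWavenumber(nm))

#' Evaluate a pure-state model on a wavelength grid
#'
#' Sums the model's Gaussian bands,
#' `amplitude * exp(-(nu - center)^2 / (2 sigma^2))` with
#' `nu = 1e7 / lambda`, at each grid wavelength.
#'
#' @param model a [PureStateModel-class].
#' @param grid wavelengths in nm (non-empty).
#' @return a [Spectrum-class] on `grid`.
#' @export
evaluateModel <- function(model, grid) {
  stopifnot(methods::is(model, "PureStateModel"))
  grid <- as.numeric(grid)
  if (!length(grid)) bsError("bs_parameter_error", "empty evaluation grid")
  Spectrum(grid, evalModelNm(model, grid),
           label = sprintf("%s0 model", model@state),
           metadata = list(state = model@state, model_evaluation = TRUE))
}

## Weighted quantiles of nu, weights = positive absorbance. Used to place
## starting centers for the band fit.
.weightedQuantiles <- function(nu, w, probs) {
  w <- pmax(w, 0)
  if (sum(w) <= 0) return(stats::quantile(nu, probs, names = FALSE))
  o <- order(nu)
  nu <- nu[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) nu[which(cw >= p)[1]], numeric(1))
}

## One bounded least-squares fit of m Gaussian bands from a given start.
## par layout: (center_1, sigma_1, amp_1, ..., center_m, sigma_m, amp_m).
.fitBandsOnce <- function(nu, y, start, lower, upper) {
  resFun <- function(par) {
    bands <- data.frame(center_cm1 = par[seq(1, length(par), 3)],
                        sigma_cm1 = par[seq(2, length(par), 3)],
                        amplitude = par[seq(3, length(par), 3)])
    y - .evalBandsNu(bands, nu)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = resFun, lower = lower, upper = upper,
                       control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  list(par = fit$par, rss = sum(fit$fvec^2))
}

#' Fit Gaussian bands to a spectrum
#'
#' Bounded nonlinear least squares of 1 to `maxBands` Gaussian bands (in
#' wavenumber) to a background-subtracted spectrum over a window. Each
#' model order is fitted from 5 deterministic multistarts (quantile-spaced
#' centers, seeded jitter); the order with the lowest BIC wins. Amplitudes
#' are constrained nonnegative and widths to 100-5000 cm^-1.
#'
#' @param spec a [Spectrum-class], background-subtracted over `window`.
#' @param window optional [WavelengthWindow-class]; default is the
#'   spectrum's full support.
#' @param maxBands maximum model order, 1-6 (default 4).
#' @param seed RNG seed for the multistart jitter.
#' @param state pure state this spectrum represents ("Pr", "Pfr" or
#'   "unknown").
#' @return a [PureStateModel-class]; the residual RMS is recorded in its
#'   provenance.
#' @export
fitGaussianBands <- function(spec, window = NULL, maxBands = 4, seed = 1,
                             state = "unknown") {
  stopifnot(methods::is(spec, "Spectrum"))
  if (maxBands < 1 || maxBands > 6)
    bsError("bs_parameter_error", "maxBands must lie in 1-6")
  if (is.null(window))
    window <- WavelengthWindow(min(spec@wavelength), max(spec@wavelength))
  sub <- cropSpectrum(spec, window)
  nu <- nmToWavenumber(sub@wavelength)
  y <- sub@absorbance
  if (max(y) < 1e-6)
    bsError("bs_degenerate_input",
            "insufficient signal: peak absorbance below 1e-6 AU")
  n <- length(y)
  if (n < 4L)
    bsError("bs_insufficient_data", "fewer points than parameters of a single band")
  nuRange <- range(nu)
  sigmaLo <- 100; sigmaHi <- 5000
  best <- NULL
  for (m in seq_len(maxBands)) {
    p <- 3L * m
    if (n <= p) next
    probs <- seq_len(m) / (m + 1)
    baseCenters <- .weightedQuantiles(nu, y, probs)
    starts <- withSeed(seed + m, {
      lapply(seq_len(5L), function(s) {
        centers <- baseCenters
        if (s > 1L)
          centers <- centers + stats::rnorm(m, 0, diff(nuRange) / 12)
        centers <- pmin(pmax(centers, nuRange[1]), nuRange[2])
        amp0 <- pmax(stats::approx(nu, y, xout = centers, rule = 2)$y,
                     max(y) / 20)
        as.numeric(rbind(centers, rep(600, m), amp0))
      })
    })
    lower <- rep(c(nuRange[1] - 2000, sigmaLo, 0), m)
    upper <- rep(c(nuRange[2] + 2000, sigmaHi, 2 * max(y) + 1), m)
    bestOrder <- NULL
    for (st in starts) {
      fit <- .fitBandsOnce(nu, y, st, lower, upper)
      if (!is.null(fit) && (is.null(bestOrder) || fit$rss < bestOrder$rss))
        bestOrder <- fit
    }
    if (is.null(bestOrder)) next
    bic <- n * log(max(bestOrder$rss, 1e-30) / n) + p * log(n)
    if (is.null(best) || bic < best$bic)
      best <- list(par = bestOrder$par, rss = bestOrder$rss, bic = bic, m = m)
  }
  if (is.null(best))
    bsError("bs_fit_error", "no model order converged")
  par <- best$par
  bands <- data.frame(center_cm1 = par[seq(1, length(par), 3)],
                      sigma_cm1 = par[seq(2, length(par), 3)],
                      amplitude = par[seq(3, length(par), 3)])
  PureStateModel(state, bands, window = window,
                 provenance = sprintf(
                   "fitGaussianBands: %d band(s), residual RMS %.3g AU over %d points (%g-%g nm), seed %d",
                   best$m, sqrt(best$rss / n), n, window@loNm, window@hiNm,
                   as.integer(seed)))
}

#' Extract pure Pr0 and Pfr0 reference models from a sample pair
#'
#' The fully dark-adapted spectrum (complete dark reversion) defines the
#' pure Pfr state; the far-red-clamped spectrum (continuous far-red
#' illumination suppressing dark reversion) defines the pure Pr state.
#' Both must come from the same sample at the same concentration: no
#' cross-normalisation is applied, which is what makes the extinction
#' ratio eta meaningful. Each spectrum is background-subtracted over the
#' window and fitted with Gaussian bands.
#'
#' @param darkSpec dark-adapted [Spectrum-class] (pure Pfr).
#' @param farredSpec far-red-clamped [Spectrum-class] (pure Pr).
#' @param window analysis [WavelengthWindow-class] (default Q band).
#' @param maxBands maximum Gaussian bands per state (default 4).
#' @param seed RNG seed for the fits.
#' @return a list with elements `pfr0` and `pr0`
#'   ([PureStateModel-class] objects).
#' @export
extractPureStates <- function(darkSpec, farredSpec, window = qBandWindow(),
                              maxBands = 4, seed = 1) {
  stopifnot(methods::is(darkSpec, "Spectrum"),
            methods::is(farredSpec, "Spectrum"))
  if (!isTRUE(all.equal(darkSpec@wavelength, farredSpec@wavelength))) {
    bsWarning("bs_grid_mismatch",
              "reference spectra are on different grids; resampling the far-red spectrum")
    lo <- max(min(darkSpec@wavelength), min(farredSpec@wavelength))
    hi <- min(max(darkSpec@wavelength), max(farredSpec@wavelength))
    grid <- darkSpec@wavelength[darkSpec@wavelength >= lo &
                                darkSpec@wavelength <= hi]
    farredSpec <- resampleSpectrum(farredSpec, grid)
  }
  prep <- function(s) {
    if (isTRUE(s@metadata$background_subtracted)) cropSpectrum(s, window)
    else subtractLinearBackground(s, window)
  }
  pfr0 <- fitGaussianBands(prep(darkSpec), window, maxBands, seed,
                           state = "Pfr")
  pr0 <- fitGaussianBands(prep(farredSpec), window, maxBands, seed + 1000,
                          state = "Pr")
  pfr0@provenance <- paste0("pure Pfr by complete dark reversion; ",
                            pfr0@provenance)
  pr0@provenance <- paste0("pure Pr by far-red clamp during measurement; ",
                           pr0@provenance)
  list(pfr0 = pfr0, pr0 = pr0)
}

## Peak wavelength and value of a model within its reference window.
.modelPeak <- function(model) {
  w <- model@window
  opt <- stats::optimize(function(l) evalModelNm(model, l),
                         interval = c(w@loNm, w@hiNm), maximum = TRUE,
                         tol = 1e-6)
  list(lambda = opt$maximum, value = opt$objective)
}

#' Extinction-coefficient ratio eta of a pure-state pair
#'
#' `eta = eps(lambda_max, Pfr) / eps(lambda_max, Pr)`: the Pfr0 model
#' evaluated at its own Q-band maximum divided by the Pr0 model evaluated
#' at its own Q-band maximum. Both models must refer to the same
#' concentration.
#'
#' @param pr0,pfr0 [PureStateModel-class] objects.
#' @return the dimensionless ratio.
#' @export
computeEta <- function(pr0, pfr0) {
  stopifnot(methods::is(pr0, "PureStateModel"),
            methods::is(pfr0, "PureStateModel"))
  prPeak <- .modelPeak(pr0)
  pfrPeak <- .modelPeak(pfr0)
  if (prPeak$value < 1e-9)
    bsError("bs_domain_error",
            "Pr0 peak below 1e-9 AU: eta would divide by zero")
  pfrPeak$value / prPeak$value
}

#' Serialise a pure-state model to JSON
#'
#' @param model a [PureStateModel-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writePureStateModel <- function(model, path) {
  stopifnot(methods::is(model, "PureStateModel"))
  doc <- list(
    state = model@state,
    bands = lapply(seq_len(nrow(model@bands)), function(i)
      list(center_cm1 = model@bands$center_cm1[i],
           sigma_cm1 = model@bands$sigma_cm1[i],
           amplitude = model@bands$amplitude[i])),
    window = list(lo_nm = model@window@loNm, hi_nm = model@window@hiNm),
    provenance = model@provenance)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a pure-state model from JSON
#'
#' @param path path to a file written by [writePureStateModel()].
#' @return a [PureStateModel-class].
#' @export
readPureStateModel <- function(path) {
  if (!file.exists(path))
    bsError("bs_io_error", sprintf("file not found: %s", path))
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  bands <- as.data.frame(doc$bands)
  PureStateModel(doc$state, bands,
                 window = WavelengthWindow(doc$window$lo_nm, doc$window$hi_nm),
                 provenance = if (is.null(doc$provenance)) "" else doc$provenance)
}
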