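## Multiexponential dark-reversion kinetics:
##   alpha(t) = alphaInf - sum_i a_i * exp(-k_i * t)
## fitted by bounded least squares with model order chosen by AICc, and
## the half-life defined as the absolute 50%-Pfr crossing time.

## Evaluate the kinetic model.
.drModel <- function(amplitudes, rates, alphaInf, t)
  alphaInf - as.numeric(exp(-outer(t, rates)) %*% amplitudes)

#' Evaluate a dark-reversion fit at given times
#'
#' @param fit a [DarkReversionFit-class].
#' @param t times in s.
#' @return the modelled Pfr fractions, clipped to `[0, 1]`.
#' @export
reversionCurve <- function(fit, t) {
  stopifnot(methods::is(fit, "DarkReversionFit"))
  pmin(pmax(.drModel(fit@amplitudes, fit@rates, fit@alphaInf, t), 0), 1)
}

## par layout for order m: (alphaInf, a_1, k_1, ..., a_m, k_m).
.drResiduals <- function(par, t, y, m) {
  alphaInf <- par[1]
  a <- par[seq(2, by = 2, length.out = m)]
  k <- par[seq(3, by = 2, length.out = m)]
  res <- y - .drModel(a, k, alphaInf, t)
  # soft constraint sum(a) <= alphaInf (alpha(0) >= 0)
  c(res, 30 * max(0, sum(a) - alphaInf))
}

.fitDrOrder <- function(t, y, m, seed) {
  n <- length(t)
  tPos <- t[t > 0]
  kLo <- 1e-6; kHi <- 10
  kMin <- max(kLo, 0.1 / max(tPos))
  kMax <- min(kHi, 5 / min(tPos))
  if (kMax <= kMin) kMax <- kMin * 10
  aInf0 <- min(max(max(tail(y, 3)), 0.5), 1)
  ampTot0 <- max(aInf0 - y[1], 0.05)
  baseRates <- exp(seq(log(kMin), log(kMax), length.out = max(m, 2)))[seq_len(m)]
  starts <- withSeed(seed + m, {
    lapply(seq_len(5L), function(s) {
      k0 <- baseRates
      if (s > 1L) k0 <- k0 * exp(stats::rnorm(m, 0, 0.8))
      k0 <- pmin(pmax(k0, kLo), kHi)
      c(aInf0, as.numeric(rbind(rep(ampTot0 / m, m), k0)))
    })
  })
  lower <- c(0.5, rep(c(0, kLo), m))
  upper <- c(1, rep(c(1, kHi), m))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = .drResiduals, t = t, y = y, m = m,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum((y - .drModel(fit$par[seq(2, by = 2, length.out = m)],
                             fit$par[seq(3, by = 2, length.out = m)],
                             fit$par[1], t))^2)
    if (is.null(best) || rss < best$rss) best <- list(par = fit$par, rss = rss)
  }
  best
}

.buildDrFit <- function(par, m, rss, tHalfCi = c(NA_real_, NA_real_)) {
  alphaInf <- par[1]
  a <- par[seq(2, by = 2, length.out = m)]
  k <- par[seq(3, by = 2, length.out = m)]
  # enforce the amplitude budget exactly (the fit uses a soft penalty)
  if (sum(a) > alphaInf) a <- a * (alphaInf / sum(a))
  o <- order(k, decreasing = TRUE)
  fit <- new("DarkReversionFit", amplitudes = a[o], rates = k[o],
             alphaInf = alphaInf, nExp = as.integer(m), rss = rss,
             tHalf = NA_real_, tHalfCi = tHalfCi)
  fit@tHalf <- tryCatch(halfLife(fit), bathyspec_error = function(e) NA_real_)
  fit
}

#' Fit multiexponential dark-reversion kinetics
#'
#' Fits `alpha(t) = alphaInf - sum a_i exp(-k_i t)` for each order 1 to
#' `maxExp` by bounded least squares (amplitudes >= 0, rates in
#' `[1e-6, 10]` s^-1, `alphaInf` in `[0.5, 1]`) with deterministic
#' multistarts from log-spaced rate grids. The order is selected by
#' small-sample-corrected AIC. The half-life (50%-Pfr crossing) and, if
#' requested, its residual-bootstrap interval are attached.
#'
#' `alphaInf` is fitted rather than pinned to 1 because some bathy
#' phytochromes plateau below full Pfr occupancy in darkness.
#'
#' @param series a [DarkReversionSeries-class].
#' @param maxExp maximum model order, 1-3.
#' @param seed RNG seed (multistart jitter and bootstrap).
#' @param nBoot bootstrap replicates for the half-life interval
#'   (default 200; 0 skips the bootstrap).
#' @return a [DarkReversionFit-class].
#' @export
fitMultiexponential <- function(series, maxExp = 3, seed = 1, nBoot = 200) {
  stopifnot(methods::is(series, "DarkReversionSeries"))
  if (maxExp < 1 || maxExp > 3)
    bsError("bs_parameter_error", "maxExp must lie in 1-3")
  t <- series@times; y <- series@alphas
  n <- length(t)
  if (diff(range(y)) < 1e-8)
    bsError("bs_degenerate_input", "constant series: no decay to fit")
  best <- NULL
  for (m in seq_len(maxExp)) {
    if (n < 2 * m + 1) next                       # fewer points than parameters
    p <- 2 * m + 1
    if (n - p - 1 <= 0) next                      # AICc undefined
    fit <- .fitDrOrder(t, y, m, seed)
    if (is.null(fit)) next
    aicc <- n * log(max(fit$rss, 1e-30) / n) + 2 * p +
      2 * p * (p + 1) / (n - p - 1)
    if (is.null(best) || aicc < best$aicc)
      best <- list(par = fit$par, rss = fit$rss, aicc = aicc, m = m)
  }
  if (is.null(best))
    bsError("bs_fit_error", "no model order could be fitted")
  central <- .buildDrFit(best$par, best$m, best$rss)
  if (nBoot > 0) {
    m <- best$m
    fitted <- .drModel(central@amplitudes, central@rates, central@alphaInf, t)
    resid <- y - fitted
    tHalves <- withSeed(seed + 7777, {
      vapply(seq_len(nBoot), function(b) {
        yStar <- pmin(pmax(fitted + sample(resid, replace = TRUE), 0), 1)
        refit <- tryCatch(
          minpack.lm::nls.lm(par = best$par, fn = .drResiduals, t = t,
                             y = yStar, m = m,
                             lower = c(0.5, rep(c(0, 1e-6), m)),
                             upper = c(1, rep(c(1, 10), m)),
                             control = minpack.lm::nls.lm.control(maxiter = 150)),
          error = function(e) NULL)
        if (is.null(refit)) return(NA_real_)
        bf <- .buildDrFit(refit$par, m, sum(refit$fvec^2))
        bf@tHalf
      }, numeric(1))
    })
    ok <- tHalves[is.finite(tHalves)]
    if (length(ok) >= 20)
      central@tHalfCi <- as.numeric(stats::quantile(ok, c(0.025, 0.975),
                                                    names = FALSE))
  }
  central
}

#' Half-life of dark reversion: the 50%-Pfr crossing time
#'
#' The smallest `t` with `alpha(t) = 0.5`, found by bisection. This is the
#' absolute Pfr-fraction crossing, not a per-exponential half-life; for a
#' mono-exponential rise from `alpha(0) = 0` to `alphaInf = 1` it equals
#' `ln(2) / k`.
#'
#' @param fit a [DarkReversionFit-class] with `alpha(0) < 0.5` and
#'   `alphaInf >= 0.5`.
#' @return the crossing time in s (relative accuracy 1e-6 or better).
#' @export
halfLife <- function(fit) {
  stopifnot(methods::is(fit, "DarkReversionFit"))
  alpha0 <- fit@alphaInf - sum(fit@amplitudes)
  if (alpha0 >= 0.5)
    bsError("bs_degenerate_input", sprintf(
      "alpha(0) = %.3f is already >= 0.5: the series starts past its half-life",
      alpha0))
  if (fit@alphaInf < 0.5)
    bsError("bs_degenerate_input", sprintf(
      "alphaInf = %.3f < 0.5: the trajectory never crosses 50%% Pfr",
      fit@alphaInf))
  f <- function(t) .drModel(fit@amplitudes, fit@rates, fit@alphaInf, t) - 0.5
  hi <- 10 / min(fit@rates)
  while (f(hi) < 0) {
    hi <- hi * 2
    if (hi > 1e15)
      bsError("bs_degenerate_input", "the trajectory does not reach 50% Pfr")
  }
  lo <- 0
  for (i in seq_len(200L)) {
    mid <- (lo + hi) / 2
    if (f(mid) >= 0) hi <- mid else lo <- mid
    if ((hi - lo) <= 1e-9 * max(hi, 1e-12)) break
  }
  (lo + hi) / 2
}

#' Assemble a dark-reversion series by unmixing timed spectra
#'
#' Applies [unmixPhotostate()] to each spectrum of a dark-reversion time
#' course and collects the recovered Pfr fractions.
#'
#' @param times times in s (>= 5 points, strictly increasing).
#' @param spectra list of [Spectrum-class] objects, same length.
#' @param pr0,pfr0 pure-state references.
#' @param window analysis window (default Q band).
#' @param label series label.
#' @return a [DarkReversionSeries-class].
#' @export
seriesFromSpectra <- function(times, spectra, pr0, pfr0,
                              window = qBandWindow(), label = "") {
  if (!length(spectra))
    bsError("bs_insufficient_data", "empty spectra list")
  if (length(times) != length(spectra))
    bsError("bs_parameter_error", "times and spectra lengths differ")
  if (length(times) < 5L)
    bsError("bs_insufficient_data", "at least 5 time points are required")
  alphas <- vapply(seq_along(spectra), function(i) {
    tryCatch(pfrFraction(unmixPhotostate(spectra[[i]], pr0, pfr0, window)),
             bathyspec_error = function(e)
               bsError("bs_fit_error", sprintf(
                 "unmixing failed at time point %d (t = %g s): %s",
                 i, times[i], conditionMessage(e))))
  }, numeric(1))
  DarkReversionSeries(times, alphas, label = label,
                      metadata = list(source = "unmixed spectra"))
}

#' Read a dark-reversion series from a two-column text file
#'
#' Columns `time_s` and `alpha` (comma or tab delimited, '#' comments).
#'
#' @param path path to the file.
#' @return a [DarkReversionSeries-class].
#' @export
readReversionSeries <- function(path) {
  if (!file.exists(path))
    bsError("bs_io_error", sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  dataLines <- lines[!grepl("^\\s*#", lines) & !grepl("^\\s*$", lines)]
  if (length(dataLines) < 2L)
    bsError("bs_insufficient_data", "no data rows found")
  sep <- if (grepl("\t", dataLines[1])) "\t" else ","
  tab <- utils::read.table(text = dataLines, sep = sep, header = TRUE,
                           check.names = FALSE)
  cols <- tolower(trimws(names(tab)))
  tIdx <- which(cols %in% c("time_s", "time", "t", "t_s"))[1]
  aIdx <- which(cols %in% c("alpha", "pfr_fraction", "a"))[1]
  if (is.na(tIdx) || is.na(aIdx))
    bsError("bs_format_error", "expected columns time_s and alpha")
  DarkReversionSeries(tab[[tIdx]], tab[[aIdx]], label = basename(path))
}

#' Write a dark-reversion series to a two-column text file
#'
#' @param series a [DarkReversionSeries-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeReversionSeries <- function(series, path) {
  stopifnot(methods::is(series, "DarkReversionSeries"))
  lines <- c(if (nzchar(series@label)) sprintf("# label: %s", series@label),
             "time_s,alpha",
             sprintf("%.15g,%.15g", series@times, series@alphas))
  writeLines(lines, path)
  invisible(path)
}
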