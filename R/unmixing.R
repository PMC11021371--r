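## Two-component spectral unmixing: fit
##   A(nu) = c * [alpha * Pfr0(nu) + (1 - alpha) * Pr0(nu)]
## to a photostationary Q-band spectrum. The scale c is profiled out in
## closed form (ratio of inner products, clipped positive) and alpha is
## found by golden-section search on [0, 1] of the profiled objective --
## globally convergent for this bilinear model, with no starting-point
## sensitivity.

## Profiled objective pieces: optimal c and rss for a fixed alpha.
.profiledC <- function(alpha, y, refPr, refPfr) {
  m <- alpha * refPfr + (1 - alpha) * refPr
  den <- sum(m * m)
  cOpt <- if (den > 0) sum(y * m) / den else 0
  cOpt <- max(cOpt, 1e-12)
  list(c = cOpt, rss = sum((y - cOpt * m)^2))
}

## Golden-section minimisation of the profiled rss over alpha in [0, 1].
## Returns list(alpha, c, rss, boundary).
profiledUnmix <- function(y, refPr, refPfr, tol = 1e-9) {
  f <- function(a) .profiledC(a, y, refPr, refPfr)$rss
  gr <- (sqrt(5) - 1) / 2
  lo <- 0; hi <- 1
  x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
  f1 <- f(x1); f2 <- f(x2)
  while (hi - lo > tol) {
    if (f1 <= f2) {
      hi <- x2; x2 <- x1; f2 <- f1
      x1 <- hi - gr * (hi - lo); f1 <- f(x1)
    } else {
      lo <- x1; x1 <- x2; f1 <- f2
      x2 <- lo + gr * (hi - lo); f2 <- f(x2)
    }
  }
  alpha <- (lo + hi) / 2
  # boundary check: the model admits no super-mixtures, so boundary optima
  # are reported as exactly 0 or 1
  cand <- c(0, alpha, 1)
  rssCand <- vapply(cand, f, numeric(1))
  alpha <- cand[which.min(rssCand)]
  boundary <- FALSE
  if (alpha < 1e-7) { alpha <- 0; boundary <- TRUE }
  if (alpha > 1 - 1e-7) { alpha <- 1; boundary <- TRUE }
  prof <- .profiledC(alpha, y, refPr, refPfr)
  list(alpha = alpha, c = prof$c, rss = prof$rss, boundary = boundary)
}

## Shared preparation: background-subtract the sample (unless already
## flagged), evaluate both references on the same grid and pass them
## through the identical linear background operator. Because the anchor
## operator is linear and annihilates affine baselines, the mixture
## relation is preserved exactly.
.prepareUnmix <- function(sample, pr0, pfr0, window, anchorWidthNm = 10) {
  stopifnot(methods::is(sample, "Spectrum"),
            methods::is(pr0, "PureStateModel"),
            methods::is(pfr0, "PureStateModel"))
  proc <- if (isTRUE(sample@metadata$background_subtracted))
    cropSpectrum(sample, window)
  else subtractLinearBackground(sample, window, anchorWidthNm)
  grid <- proc@wavelength
  refLine <- function(model) {
    raw <- evalModelNm(model, grid)
    ln <- .anchorLine(grid, raw, window, anchorWidthNm)
    raw - (ln$intercept + ln$slope * grid)
  }
  refPr <- refLine(pr0)
  refPfr <- refLine(pfr0)
  if (cosineSimilarity(refPr, refPfr) > 0.999)
    bsError("bs_degenerate_input",
            "indistinguishable references: Pr0 and Pfr0 are collinear over the window (cosine similarity > 0.999)")
  if (max(abs(proc@absorbance)) < 1e-6)
    bsError("bs_degenerate_input",
            "insufficient signal: sample peak below 1e-6 AU over the window")
  list(y = proc@absorbance, grid = grid, refPr = refPr, refPfr = refPfr)
}

#' Unmix a photostationary spectrum into Pr/Pfr fractions
#'
#' Fits the two-component mixture model
#' `A = c * (alpha * Pfr0 + (1 - alpha) * Pr0)` over the window by least
#' squares, with the scale `c > 0` profiled out in closed form and the Pfr
#' fraction `alpha` constrained to `[0, 1]` (golden-section search).
#' If the sample is not flagged as background-subtracted, a linear
#' background is first removed over the window; the evaluated references
#' pass through the same linear operator so that the mixture relation is
#' preserved exactly.
#'
#' @param sample the photostationary [Spectrum-class].
#' @param pr0,pfr0 pure-state [PureStateModel-class] references at the
#'   same concentration.
#' @param window analysis [WavelengthWindow-class] (default Q band,
#'   550-850 nm).
#' @param condition free-text illumination condition for reporting.
#' @param anchorWidthNm anchor width for background subtraction (nm).
#' @return a [PhotostateFit-class] (bootstrap slots unset; see
#'   [bootstrapAlphaError()]).
#' @export
unmixPhotostate <- function(sample, pr0, pfr0, window = qBandWindow(),
                            condition = "custom", anchorWidthNm = 10) {
  prep <- .prepareUnmix(sample, pr0, pfr0, window, anchorWidthNm)
  fit <- profiledUnmix(prep$y, prep$refPr, prep$refPfr)
  new("PhotostateFit", alpha = fit$alpha, scale = fit$c, rss = fit$rss,
      nPoints = length(prep$y), alphaSe = NA_real_,
      ci95 = c(NA_real_, NA_real_), window = window,
      condition = condition, boundary = fit$boundary)
}

#' Residual-bootstrap uncertainty of the Pfr fraction
#'
#' Refits the mixture model on `fitted + resampled residuals`, `nBoot`
#' times (deterministic given `seed`), and reports the standard deviation
#' and the 2.5/97.5 percentile interval of the bootstrapped alpha values.
#'
#' @param sample,pr0,pfr0,window,anchorWidthNm as in [unmixPhotostate()].
#' @param nBoot number of bootstrap replicates (>= 20; default 200).
#' @param seed mandatory RNG seed.
#' @return a list with `se`, `ci95` (length 2), `alphas` (the replicate
#'   values) and `fit` (the central [PhotostateFit-class] with the
#'   uncertainty slots filled in).
#' @export
bootstrapAlphaError <- function(sample, pr0, pfr0, window = qBandWindow(),
                                nBoot = 200, seed, anchorWidthNm = 10) {
  if (nBoot < 20)
    bsError("bs_parameter_error", "at least 20 bootstrap replicates are required")
  prep <- .prepareUnmix(sample, pr0, pfr0, window, anchorWidthNm)
  central <- profiledUnmix(prep$y, prep$refPr, prep$refPfr)
  m <- central$alpha * prep$refPfr + (1 - central$alpha) * prep$refPr
  fitted <- central$c * m
  resid <- prep$y - fitted
  alphas <- withSeed(seed, {
    vapply(seq_len(nBoot), function(b) {
      yStar <- fitted + base::sample(resid, replace = TRUE)
      profiledUnmix(yStar, prep$refPr, prep$refPfr, tol = 1e-7)$alpha
    }, numeric(1))
  })
  se <- stats::sd(alphas)
  ci <- as.numeric(stats::quantile(alphas, c(0.025, 0.975), names = FALSE))
  fit <- new("PhotostateFit", alpha = central$alpha, scale = central$c,
             rss = central$rss, nPoints = length(prep$y), alphaSe = se,
             ci95 = ci, window = window, condition = "custom",
             boundary = central$boundary)
  list(se = se, ci95 = ci, alphas = alphas, fit = fit)
}

#' Tabulate Pr/Pfr fractions from a batch of fits
#'
#' One row per phytochrome/condition with integer Pfr and Pr percentages.
#' Percentages are rounded half away from zero and `Pr% = 100 - Pfr%`, so
#' every row sums to 100.
#'
#' @param fits list of [PhotostateFit-class] objects.
#' @param labels optional character vector of row labels (default: the
#'   fits' condition strings).
#' @return a data.frame with columns `label`, `condition`, `pfr_pct`,
#'   `pr_pct`.
#' @export
fractionTable <- function(fits, labels = NULL) {
  if (methods::is(fits, "PhotostateFit")) fits <- list(fits)
  conditions <- vapply(fits, function(f) f@condition, character(1))
  if (is.null(labels)) labels <- conditions
  pfr <- vapply(fits, function(f) roundHalfUp(100 * f@alpha), numeric(1))
  data.frame(label = labels, condition = conditions,
             pfr_pct = as.integer(pfr), pr_pct = as.integer(100 - pfr),
             stringsAsFactors = FALSE)
}

#' Render a fraction table as aligned text
#'
#' @param tab a data.frame from [fractionTable()].
#' @return a character vector of aligned lines.
#' @export
formatFractionTable <- function(tab) {
  wl <- max(nchar(c("Phytochrome/condition", tab$label)))
  header <- sprintf("%-*s  %7s  %7s", wl, "Phytochrome/condition",
                    "Pfr (%)", "Pr (%)")
  rows <- sprintf("%-*s  %7d  %7d", wl, tab$label, tab$pfr_pct, tab$pr_pct)
  c(header, rows)
}
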