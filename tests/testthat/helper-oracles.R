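# Independent oracles and small fixture builders used across the suite.
# These deliberately avoid the package's internal code paths: background
# subtraction and the mixture fit are re-derived from scratch so that the
# implementation is checked against an independent route.

# Gaussian in wavenumber evaluated on an nm grid.
gaussNm <- function(nm, centerNm, sigmaCm1, amp = 1) {
  nu <- 1e7 / nm
  amp * exp(-(nu - 1e7 / centerNm)^2 / (2 * sigmaCm1^2))
}

# Independent linear background subtraction: line through the mean
# (lambda, A) of 10-nm anchor regions at the window edges.
oracleSubtractBackground <- function(w, a, lo = 550, hi = 850, aw = 10) {
  keep <- w >= lo & w <= hi
  w <- w[keep]; a <- a[keep]
  i1 <- w <= lo + aw; i2 <- w >= hi - aw
  x1 <- mean(w[i1]); y1 <- mean(a[i1])
  x2 <- mean(w[i2]); y2 <- mean(a[i2])
  slope <- (y2 - y1) / (x2 - x1)
  list(w = w, a = a - (y1 + slope * (w - x1)))
}

# Exhaustive grid-search unmixing with closed-form scale: the brute-force
# oracle for the golden-section fit. Operates on already-prepared vectors.
oracleGridUnmix <- function(y, refPr, refPfr, step = 0.001) {
  alphas <- seq(0, 1, by = step)
  best <- list(alpha = NA_real_, c = NA_real_, rss = Inf)
  for (al in alphas) {
    m <- al * refPfr + (1 - al) * refPr
    den <- sum(m * m)
    cc <- if (den > 0) max(sum(y * m) / den, 1e-12) else 1e-12
    rss <- sum((y - cc * m)^2)
    if (rss < best$rss) best <- list(alpha = al, c = cc, rss = rss)
  }
  best
}

# Full independent unmixing route for a raw generated spectrum: own
# background subtraction of sample and of the evaluated references, then
# grid search.
oracleUnmixSpectrum <- function(spec, pr0, pfr0, step = 0.001) {
  w <- wavelengths(spec)
  sub <- oracleSubtractBackground(w, absorbances(spec))
  prRaw <- bathyspec::evaluateModel(pr0, w)
  pfrRaw <- bathyspec::evaluateModel(pfr0, w)
  refPr <- oracleSubtractBackground(w, absorbances(prRaw))$a
  refPfr <- oracleSubtractBackground(w, absorbances(pfrRaw))$a
  oracleGridUnmix(sub$a, refPr, refPfr, step)
}

# Standard PaBphP fixture.
paModels <- function() makePureStateModels(getPreset("PaBphP"))

# Write a spectrum-format text file from raw lines (for reader tests).
writeLinesTmp <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}
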