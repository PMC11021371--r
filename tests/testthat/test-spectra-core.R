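test_that("reader parses delimited tables, sorts, averages duplicates and collects metadata", {
  p <- writeLinesTmp(c("# protein: PaBphP", "# time_min: 5",
                       "wavelength_nm,absorbance",
                       "600,0.1", "700,0.5", "800,0.2"))
  s <- readSpectrum(p, minRows = 3)
  expect_s4_class(s, "Spectrum")
  expect_equal(wavelengths(s), c(600, 700, 800))
  expect_equal(absorbances(s), c(0.1, 0.5, 0.2))
  expect_equal(specMetadata(s)$protein, "PaBphP")
  expect_equal(specMetadata(s)$time_min, 5)

  # sort invariance
  p2 <- writeLinesTmp(c("wavelength_nm,absorbance",
                        "800,0.2", "600,0.1", "700,0.5"))
  s2 <- readSpectrum(p2, minRows = 3)
  expect_equal(wavelengths(s2), wavelengths(s))
  expect_equal(absorbances(s2), absorbances(s))

  # duplicate wavelengths collapse to the mean
  p3 <- writeLinesTmp(c("wavelength_nm,absorbance", "700,0.4", "700,0.6"))
  s3 <- readSpectrum(p3, minRows = 1)
  expect_equal(wavelengths(s3), 700)
  expect_equal(absorbances(s3), 0.5)

  # tab-delimited with aliased headers
  p4 <- writeLinesTmp(c("lambda\tabs", paste(600:610, "0.1", sep = "\t")))
  expect_equal(length(readSpectrum(p4)), 11L)
})

test_that("reader rejects malformed tables with informative classed errors", {
  pMiss <- writeLinesTmp(c("foo,absorbance", "600,0.1", "601,0.1"))
  expect_error(readSpectrum(pMiss, minRows = 2), class = "bs_format_error")

  pBad <- writeLinesTmp(c("wavelength_nm,absorbance",
                          "600,0.1", "601,oops", "602,0.2"))
  err <- tryCatch(readSpectrum(pBad, minRows = 2), error = function(e) e)
  expect_s3_class(err, "bs_parse_error")
  expect_match(conditionMessage(err), "line 3")

  pShort <- writeLinesTmp(c("wavelength_nm,absorbance", "600,0.1", "601,0.2"))
  expect_error(readSpectrum(pShort), class = "bs_insufficient_data")
})

test_that("write/read round trip preserves grid, values and metadata", {
  s <- Spectrum(seq(550, 850, by = 2.5), runif(121, 0, 1), label = "rt",
                metadata = list(true_alpha = 0.375, condition = "667 nm"))
  path <- tempfile(fileext = ".csv")
  writeSpectrum(s, path)
  s2 <- readSpectrum(path)
  expect_equal(wavelengths(s2), wavelengths(s), tolerance = 1e-9)
  expect_equal(absorbances(s2), absorbances(s), tolerance = 1e-9)
  expect_equal(specMetadata(s2)$true_alpha, 0.375)
  expect_equal(specMetadata(s2)$condition, "667 nm")
})

test_that("resampling interpolates linearly and refuses extrapolation", {
  s <- Spectrum(c(600, 800), c(0, 2))
  expect_equal(absorbances(resampleSpectrum(s, 700)), 1.0)
  # identity on the spectrum's own grid
  g <- Spectrum(seq(550, 850, 1), 1 + sin(seq(550, 850, 1) / 40))
  expect_equal(absorbances(resampleSpectrum(g, wavelengths(g))),
               absorbances(g))
  # dense resampling of a smooth band stays close to the analytic curve
  grid1 <- seq(600, 800, by = 1)
  gau <- Spectrum(grid1, gaussNm(grid1, 700, 550))
  grid05 <- seq(600, 800, by = 0.5)
  res <- resampleSpectrum(gau, grid05)
  expect_lt(max(abs(absorbances(res) - gaussNm(grid05, 700, 550))), 1e-3)
  expect_error(resampleSpectrum(s, c(500, 700)),
               class = "bs_extrapolation_error")
})

test_that("wavenumber conversion is exact and involutive", {
  expect_equal(nmToWavenumber(700), 1e7 / 700)
  expect_equal(nmToWavenumber(791), 12642.2250316, tolerance = 1e-8)
  s <- Spectrum(seq(550, 850, 7), runif(43))
  nu <- toWavenumber(s)
  expect_false(is.unsorted(nu$wavenumber_cm1))
  back <- toWavelength(nu)
  expect_equal(wavelengths(back), wavelengths(s), tolerance = 1e-9)
  expect_equal(absorbances(back), absorbances(s), tolerance = 1e-9)
})

test_that("LOESS smoothing reproduces local polynomials and reduces noise", {
  g <- seq(550, 850, by = 2)
  expect_equal(absorbances(loessSmooth(Spectrum(g, rep(0.3, length(g))))),
               rep(0.3, length(g)), tolerance = 1e-12)
  line <- 0.05 + 0.002 * g
  expect_equal(absorbances(loessSmooth(Spectrum(g, line))), line,
               tolerance = 1e-9)
  clean <- gaussNm(g, 700, 550)
  set.seed(7)
  noisy <- clean + rnorm(length(g), 0, 0.01)
  sm <- loessSmooth(Spectrum(g, noisy), span = 0.1)
  rmsIn <- sqrt(mean((noisy - clean)^2))
  rmsOut <- sqrt(mean((absorbances(sm) - clean)^2))
  expect_lt(rmsOut, rmsIn)
  expect_error(loessSmooth(Spectrum(g, clean), span = 0.01),
               class = "bs_parameter_error")
  expect_error(loessSmooth(Spectrum(600:605, rep(1, 6))),
               class = "bs_insufficient_data")
})

test_that("linear background subtraction annihilates lines, keeps bands, and is idempotent", {
  g <- seq(550, 850, by = 1)
  line <- Spectrum(g, 0.2 - 3e-4 * g, metadata = list(noisy = TRUE))
  out <- subtractLinearBackground(line)
  expect_lt(max(abs(absorbances(out))), 1e-10)

  # narrow band (sigma 30 nm) + line: anchors see only the baseline
  band <- exp(-(g - 700)^2 / (2 * 30^2))
  spec <- Spectrum(g, band + 0.1 + 2e-4 * g)
  rec <- subtractLinearBackground(spec)
  expect_lt(max(abs(absorbances(rec) - band)), 1e-4)

  zero <- subtractLinearBackground(Spectrum(g, rep(0, length(g))))
  expect_equal(absorbances(zero), rep(0, length(g)))

  twice <- subtractLinearBackground(rec)
  expect_lt(max(abs(absorbances(twice) - absorbances(rec))), 1e-10)

  expect_error(subtractLinearBackground(spec, anchorWidthNm = -1),
               class = "bs_parameter_error")
  expect_error(subtractLinearBackground(Spectrum(600:700, rep(1, 101))),
               class = "bs_parameter_error")  # window beyond support
})

test_that("band maxima are located to sub-nm accuracy with edge and tie handling", {
  g <- seq(500, 900, by = 1)
  pfr <- Spectrum(g, gaussNm(g, 752, 550))
  expect_lt(abs(findLambdaMax(pfr, qBandWindow()) - 752), 1)
  pr <- Spectrum(g, gaussNm(g, 702, 550))
  expect_lt(abs(findLambdaMax(pr, qBandWindow()) - 702), 1)
  ramp <- Spectrum(g, g / 1000)
  expect_equal(findLambdaMax(ramp, WavelengthWindow(600, 800)), 800)
  flat <- Spectrum(g, rep(0.5, length(g)))
  expect_error(findLambdaMax(flat, qBandWindow()),
               class = "bs_degenerate_input")
})

test_that("difference spectra are antisymmetric and show the Pr/Pfr lobes", {
  m <- paModels()
  g <- seq(550, 850, 1)
  a <- evaluateModel(m$pr0, g)
  b <- evaluateModel(m$pfr0, g)
  zero <- differenceSpectrum(a, a)
  expect_equal(absorbances(zero), rep(0, length(g)))
  d1 <- differenceSpectrum(a, b)
  d2 <- differenceSpectrum(b, a)
  expect_equal(absorbances(d1), -absorbances(d2))
  expect_true(isTRUE(specMetadata(d1)$difference))
  # positive lobe near the Pr maximum, negative near the Pfr maximum;
  # overlap of unequal-amplitude bands shifts the extrema a few nm outward
  lobeMax <- wavelengths(d1)[which.max(absorbances(d1))]
  lobeMin <- wavelengths(d1)[which.min(absorbances(d1))]
  expect_lt(abs(lobeMax - 702), 15)
  expect_lt(abs(lobeMin - 752), 15)
  expect_lt(lobeMax, lobeMin)
  expect_gt(max(absorbances(d1)), 0)
  expect_lt(min(absorbances(d1)), 0)
  expect_error(differenceSpectrum(Spectrum(500:600, rep(1, 101)),
                                  Spectrum(700:800, rep(1, 101))),
               class = "bs_parameter_error")
})

test_that("Spectrum validity enforces the grid and negativity invariants", {
  expect_error(new("Spectrum", wavelength = c(700, 700),
                   absorbance = c(1, 1), label = "", metadata = list()))
  expect_error(new("Spectrum", wavelength = c(600, 700),
                   absorbance = c(1, NA), label = "", metadata = list()))
  # strongly negative values need a difference/processed flag
  expect_error(Spectrum(600:700, rep(-0.2, 101)))
  expect_s4_class(Spectrum(600:700, rep(-0.2, 101),
                           metadata = list(difference = TRUE)), "Spectrum")
})
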