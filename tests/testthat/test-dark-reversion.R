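test_that("mono-exponential kinetics are recovered exactly from clean data", {
  k <- 1.05e-3   # ~ ln 2 / 660 s
  ser <- generateDarkReversionSeries(c(0, 120, 300, 660, 1500, 3600, 7200),
                                     amplitudes = 1, rates = log(2) / 660)
  fit <- fitMultiexponential(ser, maxExp = 3, seed = 1, nBoot = 0)
  expect_equal(fit@nExp, 1L)
  expect_lt(abs(fit@rates - log(2) / 660) / (log(2) / 660), 1e-3)
  expect_lt(abs(tHalf(fit) - 660), 1)
  expect_equal(tHalf(fit), log(2) / fit@rates, tolerance = 1e-5)
})

test_that("biexponential data select order 2 and the half-life matches a grid-scan oracle", {
  a <- c(0.7, 0.3); k <- c(5e-3, 2e-4)
  tg <- exp(seq(log(1), log(86400), length.out = 40))
  ser <- generateDarkReversionSeries(c(0, tg), amplitudes = a, rates = k,
                                     noiseSd = 0.01, seed = 9)
  fit <- fitMultiexponential(ser, maxExp = 3, seed = 9, nBoot = 0)
  expect_equal(fit@nExp, 2L)
  # dense-grid scan of the noiseless generator curve for the crossing
  tScan <- seq(0, 2000, by = 0.01)
  curve <- 1 - a[1] * exp(-k[1] * tScan) - a[2] * exp(-k[2] * tScan)
  tOracle <- tScan[which(curve >= 0.5)[1]]
  expect_lt(abs(tHalf(fit) - tOracle) / tOracle, 0.05)
  # the fitted model's own crossing agrees with the scan of the fitted
  # curve to 0.05 s
  curveFit <- reversionCurve(fit, tScan)
  tFitScan <- tScan[which(curveFit >= 0.5)[1]]
  expect_lt(abs(tHalf(fit) - tFitScan), 0.05)
})

test_that("degenerate series and non-crossing fits raise classed errors", {
  flat <- DarkReversionSeries(c(0, 10, 20, 30, 40), rep(1, 5))
  expect_error(fitMultiexponential(flat), class = "bs_degenerate_input")
  # alpha(0) = 0.5: already past the half-life
  past <- new("DarkReversionFit", amplitudes = 0.5, rates = 1e-3,
              alphaInf = 1, nExp = 1L, rss = 0, tHalf = NA_real_,
              tHalfCi = c(NA_real_, NA_real_))
  expect_error(halfLife(past), class = "bs_degenerate_input")
  # alphaInf < 0.5: never crosses
  never <- new("DarkReversionFit", amplitudes = 0.2, rates = 1e-3,
               alphaInf = 0.4, nExp = 1L, rss = 0, tHalf = NA_real_,
               tHalfCi = c(NA_real_, NA_real_))
  expect_error(halfLife(never), class = "bs_degenerate_input")
})

test_that("the half-life equals ln(2)/k for mono-exponential fits across the rate range", {
  withr::with_seed(31, for (i in 1:10) {
    k <- exp(runif(1, log(log(2) / (4 * 3600)), log(log(2) / 5)))
    fit <- new("DarkReversionFit", amplitudes = 1, rates = k, alphaInf = 1,
               nExp = 1L, rss = 0, tHalf = NA_real_,
               tHalfCi = c(NA_real_, NA_real_))
    expect_lt(abs(halfLife(fit) - log(2) / k) / (log(2) / k), 1e-5)
  })
  # monotone: larger k, shorter half-life
  hl <- vapply(c(1e-4, 1e-3, 1e-2), function(k)
    halfLife(new("DarkReversionFit", amplitudes = 1, rates = k,
                 alphaInf = 1, nExp = 1L, rss = 0, tHalf = NA_real_,
                 tHalfCi = c(NA_real_, NA_real_))), numeric(1))
  expect_true(all(diff(hl) < 0))
})

test_that("series assembled from unmixed spectra reproduce the trajectory", {
  m <- paModels()
  g <- seq(500, 900, 2)
  k <- log(2) / 660
  times <- c(0, 2, 5, 20, 60, 120) * 60
  alphaTrue <- 1 - exp(-k * times)
  spectra <- lapply(alphaTrue, function(a)
    generatePhotostateSpectrum(m$pr0, m$pfr0, a, grid = g))
  ser <- seriesFromSpectra(times, spectra, m$pr0, m$pfr0)
  expect_lt(max(abs(ser@alphas - alphaTrue)), 1e-6)

  # with 0.5%-of-peak noise the 120-min point is recovered within 0.03
  spectraN <- lapply(seq_along(alphaTrue), function(i)
    generatePhotostateSpectrum(m$pr0, m$pfr0, alphaTrue[i], grid = g,
                               noise = NoiseModel(seed = 100 + i,
                                                  additiveSd = 0.005)))
  serN <- seriesFromSpectra(times, spectraN, m$pr0, m$pfr0)
  expect_lt(abs(serN@alphas[6] - alphaTrue[6]), 0.03)

  expect_error(seriesFromSpectra(numeric(0), list(), m$pr0, m$pfr0),
               class = "bs_insufficient_data")
})

test_that("reversion series survive a text round trip", {
  ser <- generateDarkReversionSeries(c(0, 60, 180, 600, 1800),
                                     preset = getPreset("PaBphP"))
  path <- tempfile(fileext = ".csv")
  writeReversionSeries(ser, path)
  back <- readReversionSeries(path)
  expect_equal(back@times, ser@times, tolerance = 1e-9)
  expect_equal(back@alphas, ser@alphas, tolerance = 1e-9)
})

test_that("the bootstrap half-life interval brackets the point estimate", {
  ser <- generateDarkReversionSeries(c(0, exp(seq(log(10), log(7200),
                                                  length.out = 20))),
                                     preset = getPreset("PaBphP"),
                                     noiseSd = 0.01, seed = 4)
  fit <- fitMultiexponential(ser, maxExp = 2, seed = 4, nBoot = 60)
  expect_false(any(is.na(fit@tHalfCi)))
  expect_lte(fit@tHalfCi[1], tHalf(fit))
  expect_gte(fit@tHalfCi[2], tHalf(fit))
  expect_lt(abs(tHalf(fit) - 660) / 660, 0.15)
})
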