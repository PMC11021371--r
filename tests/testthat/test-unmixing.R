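test_that("unmixing recovers the pure states exactly at the boundaries", {
  m <- paModels()
  g <- seq(500, 900, 1)
  fitPfr <- unmixPhotostate(generatePhotostateSpectrum(m$pr0, m$pfr0, 1,
                                                       grid = g),
                            m$pr0, m$pfr0)
  expect_equal(pfrFraction(fitPfr), 1, tolerance = 1e-3)
  expect_equal(fitPfr@scale, 1, tolerance = 1e-3)
  expect_true(fitPfr@boundary)
  fitPr <- unmixPhotostate(generatePhotostateSpectrum(m$pr0, m$pfr0, 0,
                                                      grid = g),
                           m$pr0, m$pfr0)
  expect_equal(pfrFraction(fitPr), 0, tolerance = 1e-3)
  expect_equal(prFraction(fitPr), 1, tolerance = 1e-3)
})

test_that("a noisy mixture is unmixed near its true composition and matches the grid oracle", {
  m <- paModels()
  g <- seq(500, 900, 1)
  clean <- 1.7 * (0.37 * absorbances(evaluateModel(m$pfr0, g)) +
                  0.63 * absorbances(evaluateModel(m$pr0, g)))
  noisy <- withr::with_seed(11, clean + rnorm(length(g), 0, 0.002))
  s <- Spectrum(g, noisy, metadata = list(noisy = TRUE))
  fit <- unmixPhotostate(s, m$pr0, m$pfr0)
  expect_gt(pfrFraction(fit), 0.34)
  expect_lt(pfrFraction(fit), 0.40)
  expect_gt(fit@scale, 1.65)
  expect_lt(fit@scale, 1.75)
  oracle <- oracleUnmixSpectrum(s, m$pr0, m$pfr0)
  expect_lt(abs(pfrFraction(fit) - oracle$alpha), 0.002)
})

test_that("unmixing is invariant to sample scale and additive linear baselines", {
  m <- paModels()
  g <- seq(500, 900, 1)
  base <- generatePhotostateSpectrum(m$pr0, m$pfr0, 0.4, grid = g)
  fit0 <- unmixPhotostate(base, m$pr0, m$pfr0)
  for (s in c(0.2, 3, 40)) {
    scaled <- Spectrum(g, s * absorbances(base),
                       metadata = list(noisy = TRUE))
    fitS <- unmixPhotostate(scaled, m$pr0, m$pfr0)
    expect_lt(abs(pfrFraction(fitS) - pfrFraction(fit0)), 1e-9)
    expect_equal(fitS@scale, s * fit0@scale, tolerance = 1e-6)
  }
  withr::with_seed(21, for (i in 1:5) {
    a <- runif(1, -0.05, 0.05); b <- runif(1, -1e-4, 1e-4)
    shifted <- Spectrum(g, absorbances(base) + a + b * g,
                        metadata = list(noisy = TRUE))
    fitB <- unmixPhotostate(shifted, m$pr0, m$pfr0)
    expect_lt(abs(pfrFraction(fitB) - pfrFraction(fit0)), 0.005)
  })
})

test_that("degenerate inputs are refused with classed errors", {
  m <- paModels()
  g <- seq(500, 900, 1)
  s <- generatePhotostateSpectrum(m$pr0, m$pfr0, 0.5, grid = g)
  expect_error(unmixPhotostate(s, m$pr0, m$pr0),
               class = "bs_degenerate_input")   # collinear references
  zero <- Spectrum(g, rep(0, length(g)))
  expect_error(unmixPhotostate(zero, m$pr0, m$pfr0),
               class = "bs_degenerate_input")   # no signal
})

test_that("the residual bootstrap quantifies alpha uncertainty sensibly", {
  m <- paModels()
  g <- seq(500, 900, 1)
  clean <- generatePhotostateSpectrum(m$pr0, m$pfr0, 0.5, grid = g)
  bootClean <- bootstrapAlphaError(clean, m$pr0, m$pfr0, nBoot = 50,
                                   seed = 1)
  expect_lt(bootClean$se, 1e-6)

  # Monte-Carlo cross-check: bootstrap sd within a factor 2 of the
  # empirical sd over independent noise realisations at alpha = 0.5
  alphaOf <- function(seed) {
    s <- generatePhotostateSpectrum(m$pr0, m$pfr0, 0.5, grid = g,
                                    noise = NoiseModel(seed = seed,
                                                       baselineSlopeRange = c(0, 0),
                                                       baselineOffsetRange = c(0, 0)))
    pfrFraction(unmixPhotostate(s, m$pr0, m$pfr0))
  }
  empirical <- sd(vapply(1:50, alphaOf, numeric(1)))
  one <- generatePhotostateSpectrum(m$pr0, m$pfr0, 0.5, grid = g,
                                    noise = NoiseModel(seed = 5,
                                                       baselineSlopeRange = c(0, 0),
                                                       baselineOffsetRange = c(0, 0)))
  boot <- bootstrapAlphaError(one, m$pr0, m$pfr0, nBoot = 200, seed = 5)
  expect_gt(boot$se, empirical / 2)
  expect_lt(boot$se, empirical * 2)

  # near the boundary the se is only required to be nonnegative
  hi <- generatePhotostateSpectrum(m$pr0, m$pfr0, 0.95, grid = g,
                                   noise = NoiseModel(seed = 6))
  bootHi <- bootstrapAlphaError(hi, m$pr0, m$pfr0, nBoot = 50, seed = 6)
  expect_gte(bootHi$se, 0)

  expect_error(bootstrapAlphaError(clean, m$pr0, m$pfr0, nBoot = 5,
                                   seed = 1),
               class = "bs_parameter_error")
})

test_that("fraction tables round half away from zero and always sum to 100", {
  mk <- function(alpha, cond) new("PhotostateFit", alpha = alpha, scale = 1,
                                  rss = 0, nPoints = 10L, alphaSe = NA_real_,
                                  ci95 = c(NA_real_, NA_real_),
                                  window = qBandWindow(), condition = cond,
                                  boundary = FALSE)
  tab <- fractionTable(list(mk(1, "dark"), mk(0.5, "red"), mk(0.334, "blue"),
                            mk(0.875, "x")))
  expect_equal(tab$pfr_pct, c(100L, 50L, 33L, 88L))
  expect_equal(tab$pr_pct, c(0L, 50L, 67L, 12L))
  expect_true(all(tab$pfr_pct + tab$pr_pct == 100L))
  txt <- formatFractionTable(tab)
  expect_length(txt, 5L)
  expect_match(txt[1], "Pfr")
  expect_match(txt[2], "100")
})
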