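test_that("sojourn density has the documented values, limits and domain", {
  expect_equal(sojournDensity(0.5, 0), 4)
  x <- c(0.05, 0.3, 0.9)
  expect_lt(max(abs(sojournDensity(x, 1e-8) / (2 / x) - 1)), 1e-6)
  expect_error(sojournDensity(0, 5))
  expect_error(sojournDensity(1, 5))
  expect_error(sojournDensity(0.5, -1))
  # stability at extreme G
  expect_true(is.finite(sojournDensity(0.999999, 1e5)))
  # mean sojourn frequency increases with G
  meanFreq <- vapply(c(0, 1, 5, 20, 100), function(G)
    integrate(function(x) x * sojournDensity(x, G), 1e-6, 1 - 1e-9,
              rel.tol = 1e-9)$value, numeric(1))
  expect_true(all(diff(meanFreq) > 0))
})

test_that("expected bin counts follow the closed-form neutral ratios", {
  e <- expectedBinCounts(0, c(0.1, 0.2, 0.4))
  expect_equal(e[1] / e[2], log(0.2 / 0.1) / log(0.4 / 0.2),
               tolerance = 1e-9)
  # per-bin distortion is exactly multiplicative
  e2 <- expectedBinCounts(5, c(0.1, 0.2, 0.4), r = c(1, 2))
  e1 <- expectedBinCounts(5, c(0.1, 0.2, 0.4))
  expect_equal(e2 / e1, c(1, 2), tolerance = 1e-12)
  expect_error(expectedBinCounts(0, c(0, 0.5, 1)), "positive")
  # fast likelihood quadrature agrees with the adaptive reference
  edges <- dafBinEdges(2184, 10)
  for (G in c(0, 1, 10, 100, 1e3, 1e5)) {
    fa <- hotspotErosion:::.binIntegralsFast(edges, G)
    ad <- hotspotErosion:::.binIntegrals(edges, G)
    expect_lt(max(abs(fa / ad - 1)), 1e-8)
  }
})

test_that("discrete class expectations reduce to 2*scale/i and match binning", {
  n <- 60L
  cls <- expectedClassCounts(0, n, scale = 3)
  expect_equal(cls, 2 * 3 / seq_len(n - 1L), tolerance = 1e-12)
  # the beta integral evaluates to 2/i also when computed numerically
  numint <- vapply(c(1L, 5L, 20L), function(i)
    integrate(function(x) exp(lchoose(n, i) + i * log(x) +
                                (n - i) * log1p(-x)) * 2 / x,
              0, 1, rel.tol = 1e-10)$value, numeric(1))
  expect_equal(numint, 2 / c(1, 5, 20), tolerance = 1e-6)
  # discrete and continuous binned expectations agree at n = 200, G = 10
  # (midpoint-paired ranges, interior classes)
  expect_lt(discreteVsContinuous(200, 10), 0.005)
  # the discrete binning path groups classes by their observed frequency
  edges <- dafBinEdges(200, 5)
  dd <- expectedBinCounts(0, edges, nChrom = 200, method = "discrete")
  expect_equal(sum(dd), sum(2 / (1:199)), tolerance = 1e-9)
})

test_that("model likelihood ordering holds on simulated spectra", {
  for (s in 1:6) {
    sp <- simulateDafSpectrum(simConfig(seed = s, gTrue = (s %% 3) * 5))
    f1 <- fitDbgc(sp, ci = FALSE)
    expect_gte(f1@lnLSaturated + 1e-6, f1@lnL)
    expect_gte(f1@lnL + 1e-6, f1@lnLM0)
    expect_gte(f1@lrt, 0)
    expect_gte(f1@gHat, 0)
  }
})

test_that("the reported interval sits two log-likelihood points down", {
  sp <- simulateDafSpectrum(simConfig(seed = 21, gTrue = 10))
  f <- fitDbgc(sp)
  expect_true(f@ciLo <= f@gHat && f@gHat <= f@ciHi)
  lnLat <- function(G) {
    I0 <- hotspotErosion:::.binIntegralsFast(sp@edges, 0)
    IG <- hotspotErosion:::.binIntegralsFast(sp@edges, G)
    hotspotErosion:::.fitScales(sp@countsNeutral, sp@countsTest, I0, IG)$lnL
  }
  expect_equal(lnLat(f@ciLo), f@lnL - 2, tolerance = 1e-3)
  if (is.finite(f@ciHi))
    expect_equal(lnLat(f@ciHi), f@lnL - 2, tolerance = 1e-3)
})

test_that("estimates are stable across the bin count m", {
  fits <- lapply(c(5L, 10L, 20L), function(m) {
    sp <- simulateDafSpectrum(simConfig(seed = 33, gTrue = 10), m = m)
    fitDbgc(sp)
  })
  lo <- max(vapply(fits, function(f) f@ciLo, numeric(1)))
  hi <- min(vapply(fits, function(f) f@ciHi, numeric(1)))
  expect_lt(lo, hi)     # intervals mutually overlap
  gs <- vapply(fits, function(f) f@gHat, numeric(1))
  expect_lt(max(gs) / min(gs), 3)
})

test_that("thinning the data does not narrow the interval", {
  # binomial 50% thinning of the same spectra: the profile interval on the
  # log scale is wider (or no narrower) in median across seeds
  widths <- vapply(1:8, function(s) {
    sp <- simulateDafSpectrum(simConfig(seed = 70L + s, gTrue = 10))
    f <- fitDbgc(sp)
    set.seed(s)
    spHalf <- dafSpectrum(rbinom(11, sp@countsNeutral, 0.5),
                          rbinom(11, sp@countsTest, 0.5),
                          sp@edges, sp@nChrom)
    fH <- fitDbgc(spHalf)
    w <- function(x) log(min(x@ciHi, 1e5)) - log(max(x@ciLo, 1e-3))
    w(fH) - w(f)
  }, numeric(1))
  expect_gte(median(widths), 0)
})

test_that("large conversion coefficients are barely distinguishable", {
  # below the near-fixation bin the expected shapes converge as G grows,
  # so upper limits of the interval blow up at strong conversion
  edges <- dafBinEdges(2184, 10)
  sh <- function(G) {
    e <- head(expectedBinCounts(G, edges), -1L)   # drop the f > 0.9 bin
    e / sum(e)
  }
  expect_lt(max(abs(sh(100) - sh(1000))), 0.02)
  expect_gt(max(abs(sh(1) - sh(30))), 0.05)
  f <- fitDbgc(simulateDafSpectrum(simConfig(seed = 81, gTrue = 100)))
  expect_gt(f@ciHi / max(f@gHat, 1), 5)
})

test_that("gamma rate fitting recovers parameters and handles edge cases", {
  set.seed(3)
  x <- rgamma(5000, shape = 0.28, scale = 5.02 / 0.28)
  ft <- fitGammaToRates(x)
  expect_lt(abs(ft$mean / 5.02 - 1), 0.1)
  expect_lt(abs(ft$shape / 0.28 - 1), 0.1)
  # independent oracle
  ref <- suppressWarnings(MASS::fitdistr(x, "gamma"))
  expect_lt(abs(ft$shape / ref$estimate[["shape"]] - 1), 0.02)
  # scale equivariance
  ft2 <- fitGammaToRates(2 * x)
  expect_equal(ft2$mean, 2 * ft$mean, tolerance = 1e-9)
  expect_equal(ft2$shape, ft$shape, tolerance = 1e-9)
  # zeros excluded and reported
  ft3 <- fitGammaToRates(c(x[1:100], rep(0, 25)))
  expect_equal(ft3$zeroFraction, 0.2)
  # degenerate constant input
  ft4 <- fitGammaToRates(rep(2.5, 50))
  expect_true(ft4$degenerate)
  expect_equal(ft4$mean, 2.5)
  expect_error(fitGammaToRates(rep(0, 50)))
})

test_that("the proportional model nests M0 and reports the implied mean", {
  rateFit <- list(mean = 5.02, shape = 0.28, zeroFraction = 0)
  sp0 <- simulateDafSpectrum(simConfig(seed = 2, gTrue = 0))
  fp <- fitProportional(sp0, rateFit)
  # data generated without conversion: c collapses to (near) zero and the
  # fit's likelihood cannot be materially above M0's
  expect_lt(fp$fit@lnL - fp$fit@lnLM0, 2.5)
  expect_equal(fp$gDist@mean, fp$cHat * 5.02, tolerance = 1e-9)
  if (fp$cHat > 0)
    expect_equal(fp$meanTail / fp$gDist@mean,
                 0.28 * (1 - pgamma(qgamma(0.92, 0.28), 1.28)) / 0.08 / 0.28,
                 tolerance = 1e-6)
})
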