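test_that("CpG masking matches a brute-force per-species rescan", {
  expect_equal(maskCpg(c(a = "ACGT", b = "AAAT")),
               c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(maskCpg(c(a = "ATATAT")), rep(FALSE, 6))  # no C before G
  expect_length(maskCpg(c(a = "")), 0L)

  set.seed(5)
  seqs <- replicate(4, paste(sample(c("A", "C", "G", "T"), 500,
                                    replace = TRUE), collapse = ""))
  oracle <- {
    mats <- lapply(seqs, function(s) strsplit(s, "")[[1]])
    m <- rep(FALSE, 500)
    for (ch in mats) for (i in seq_len(500)) {
      if (i > 1 && any(vapply(mats, function(x) x[i - 1] == "C",
                              logical(1))) && ch[i] == "G") m[i] <- TRUE
      if (i < 500 && any(vapply(mats, function(x) x[i + 1] == "G",
                                logical(1))) && ch[i] == "C") m[i] <- TRUE
    }
    m
  }
  expect_equal(maskCpg(seqs), oracle)
})

test_that("the flux-ratio estimator has the documented values and bounds", {
  expect_equal(gcStar(10, 5, 1000, 500), 0.5)
  expect_equal(gcStar(0, 7, 100, 100), 0)
  expect_equal(gcStar(7, 0, 100, 100), 1)
  expect_true(is.na(gcStar(0, 0, 100, 100)))
  expect_true(is.na(gcStar(3, 1, 0, 100)))
  set.seed(2)
  v <- gcStar(rpois(50, 5), rpois(50, 5), 200, 150)
  expect_true(all(is.na(v) | (v >= 0 & v <= 1)))
})

test_that("GC* recovers the planted substitution-direction balance", {
  # unbiased generator: target base uniform among the three alternatives,
  # so W->S and S->W per-base fluxes are equal and GC* = 1/2
  cfg <- simConfig(seed = 31, lHM = 50L, lCM = 50L, genomeLength = 150000L,
                   branchSubRates = c(chimpanzee = 0.01, hominini = 0.008,
                                      human = 0.006, denisovan = 0.006),
                   gbgcBias = 0, annotNoise = cleanNoise())
  qa <- simulateQuartetAlignment(cfg)
  sc <- countSubstitutions(qa, "chimpanzee", tier = NA, cpgMask = FALSE)
  est <- gcStar(sc)
  se <- 0.5 * sqrt(1 / sc@nWS + 1 / sc@nSW) / 2
  expect_lt(abs(est - 0.5), 4 * se)

  # masking can only reduce counts
  scM <- countSubstitutions(qa, "chimpanzee", tier = NA)
  expect_lte(scM@nWS, sc@nWS)
  expect_lte(scM@nSW, sc@nSW)
  expect_lte(scM@nAT, sc@nAT)
  expect_lte(scM@nGC, sc@nGC)
})

test_that("a planted W->S bias produces an anchored GC* peak in the biased branch only", {
  B <- 0.6
  cfg <- simConfig(seed = 37, lHM = 120L, lCM = 120L,
                   genomeLength = 360000L,
                   branchSubRates = c(chimpanzee = 0.01, hominini = 0.008,
                                      human = 0.008, denisovan = 0.006),
                   gbgcBias = B, gbgcBranches = "human",
                   hotspotFraction = 0.12, annotNoise = cleanNoise())
  qa <- simulateQuartetAlignment(cfg)
  pws <- 2 * (1 + B) / (2 * (1 + B) + (1 - B))
  psw <- 2 * (1 - B) / ((1 + B) + 2 * (1 - B))
  gcExp <- pws / (pws + psw)

  pr <- gcstarProfile(qa, branch = "human", tier = NA, cpg = FALSE)
  inner <- mean(pr$gcstarSmooth[abs(pr$offset) < 900], na.rm = TRUE)
  outer <- mean(pr$gcstarSmooth[abs(pr$offset) > 5000], na.rm = TRUE)
  expect_gt(inner, outer + 0.08)
  expect_lt(abs(inner - gcExp), 0.12)

  prc <- gcstarProfile(qa, branch = "chimpanzee", tier = NA, cpg = FALSE)
  innerC <- mean(prc$gcstarSmooth[abs(prc$offset) < 900], na.rm = TRUE)
  outerC <- mean(prc$gcstarSmooth[abs(prc$offset) > 5000], na.rm = TRUE)
  expect_lt(abs(innerC - outerC), 0.08)
})

test_that("profile pooling is associative and empty windows go missing", {
  cfg <- cleanConfig(seed = 41)
  qa <- simulateQuartetAlignment(cfg)
  pr10 <- gcstarProfile(qa, branch = "human", tier = NA, dotWindow = 10L,
                        smoothWindow = 500L)
  pr500 <- gcstarProfile(qa, branch = "human", tier = NA, dotWindow = 500L,
                         smoothWindow = 500L)
  # pooling 10-bp dots into 500-bp bins equals computing 500-bp dots
  expect_equal(pr10$gcstarSmooth[seq(1, nrow(pr10), by = 50)],
               pr500$gcstar, tolerance = 1e-12)

  # zero substitutions: profile defined nowhere
  cfg0 <- cleanConfig(seed = 42,
                      branchSubRates = c(chimpanzee = 0, hominini = 0,
                                         human = 0, denisovan = 0))
  cfg0@hmExtraLoss[] <- 0
  qa0 <- simulateQuartetAlignment(cfg0)
  pr0 <- gcstarProfile(qa0, branch = "human", tier = NA)
  expect_true(all(is.na(pr0$gcstar)))
})

test_that("windowed GC* regression detects coupling and rejects degenerate input", {
  # gBGC bias confined to hotspots, which carry high map rates: windows
  # covering hotspots have both higher rate and higher GC*
  B <- 0.7
  cfg <- simConfig(seed = 51, lHM = 150L, lCM = 150L,
                   genomeLength = 450000L,
                   branchSubRates = c(chimpanzee = 0.01, hominini = 0.01,
                                      human = 0.01, denisovan = 0.006),
                   gbgcBias = B, gbgcBranches = "human",
                   hotspotFraction = 0.25, annotNoise = cleanNoise())
  qa <- simulateQuartetAlignment(cfg)
  reg <- windowedGcstarVsRecomb(qa, branch = "human", window = 15000L,
                                tier = NA, cpg = FALSE)
  expect_gt(reg$slope, 0)
  expect_lt(reg$p, 0.05)
  # the unbiased chimpanzee branch shows no such coupling
  regC <- windowedGcstarVsRecomb(qa, branch = "chimpanzee",
                                 window = 15000L, tier = NA, cpg = FALSE)
  expect_lt(regC$r2, reg$r2)
  expect_error(windowedGcstarVsRecomb(qa, window = 400000L, tier = NA),
               "at least 10 windows")
})
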