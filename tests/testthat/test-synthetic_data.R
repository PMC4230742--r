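test_that("generators are byte-identical under a fixed seed", {
  c1 <- simConfig(seed = 11, gTrue = 5)
  expect_identical(simulateDafSpectrum(c1)@countsTest,
                   simulateDafSpectrum(c1)@countsTest)
  cfgQ <- cleanConfig(seed = 3)
  q1 <- simulateQuartetAlignment(cfgQ)
  q2 <- simulateQuartetAlignment(cfgQ)
  expect_identical(as.character(quartetSeqs(q1)), as.character(quartetSeqs(q2)))
  expect_identical(truthTable(q1), truthTable(q2))
  w1 <- simulateWrightFisher(50, 0.01, 0.2, 200, seed = 5)
  w2 <- simulateWrightFisher(50, 0.01, 0.2, 200, seed = 5)
  expect_identical(w1$generations, w2$generations)
  # distinct components draw from distinct streams
  expect_false(componentSeed(1, "sequence") == componentSeed(1, "mutations"))
})

test_that("spectrum simulator means converge to the model expectations", {
  cfg <- simConfig(seed = 1, gTrue = 8, scaledMutation = 40,
                   rDistortions = c(1, 1.4))
  edges <- dafBinEdges(cfg@nChrom, 6)
  nRep <- 400L
  draws <- vapply(seq_len(nRep), function(s) {
    sp <- simulateDafSpectrum(simConfig(seed = s, gTrue = 8,
                                        scaledMutation = 40,
                                        rDistortions = c(1, 1.4)), edges)
    c(sp@countsNeutral, sp@countsTest)
  }, numeric(2 * (length(edges) - 1L)))
  mu <- c(expectedBinCounts(0, edges, 40, r = c(1, 1.4)),
          expectedBinCounts(8, edges, 40, r = c(1, 1.4)))
  dev <- abs(rowMeans(draws) - mu) / sqrt(mu / nRep)
  expect_lt(max(dev), 4.5)            # 14 bins, 4.5 sigma family-wise
  # Poisson dispersion: variance ~ mean
  disp <- apply(draws, 1, var) / mu
  expect_true(all(disp > 0.6 & disp < 1.6))
})

test_that("bad bin edges and motif overcrowding are rejected", {
  cfg <- simConfig(seed = 1)
  expect_error(simulateDafSpectrum(cfg, edges = c(0.1, 0.05, 0.5)),
               "increasing")
  expect_error(simulateQuartetAlignment(
    simConfig(seed = 1, lHM = 500L, lCM = 500L, genomeLength = 20000L)),
    "density")
})

test_that("Wright-Fisher oracle reproduces neutral fixation behavior", {
  N <- 100L
  wf <- simulateWrightFisher(N, 0, x0 = 1 / (2 * N), nReps = 40000L,
                             seed = 9)
  p <- wf$summary$pFix
  expect_lt(abs(p - 1 / (2 * N)), 3 * sqrt((1 / (2 * N)) / 40000))
  tf <- wf$generations[wf$fixed]
  expect_gt(length(tf), 100)
  expect_lt(abs(mean(tf) - 4 * N) / (4 * N), 0.1)
  expect_error(simulateWrightFisher(1, 0, 0.5, 10), "at least 2")
})

test_that("Wright-Fisher matches the diffusion closed form under conversion", {
  N <- 200L; G <- 20
  wf <- simulateWrightFisher(N, G / (4 * N), x0 = 1 / (2 * N),
                             nReps = 30000L, seed = 13)
  u <- kimuraFixationProbability(G, N)
  expect_lt(abs(wf$summary$pFix - u), 3 * sqrt(u * (1 - u) / 30000))
})

test_that("quartet generator honors degenerate settings", {
  cfg0 <- cleanConfig(seed = 2,
                      branchSubRates = c(chimpanzee = 0, hominini = 0,
                                         human = 0, denisovan = 0))
  cfg0@hmExtraLoss[] <- 0
  qa <- simulateQuartetAlignment(cfg0)
  s <- as.character(quartetSeqs(qa))
  expect_identical(s[["human"]], s[["ancestor"]])
  expect_identical(s[["chimpanzee"]], s[["ancestor"]])
  expect_identical(s[["denisovan1"]], s[["denisovan2"]])
  expect_equal(nrow(truthTable(qa)), 0L)

  # hetRate = 0: every Denisovan genotype homozygous
  qa2 <- simulateQuartetAlignment(cleanConfig(seed = 4, hetRate = 0))
  s2 <- as.character(quartetSeqs(qa2))
  expect_identical(s2[["denisovan1"]], s2[["denisovan2"]])

  # hetRate = 1: every Denisovan-branch mutation heterozygous
  qa3 <- simulateQuartetAlignment(cleanConfig(seed = 4, hetRate = 1))
  tr3 <- truthTable(qa3)
  expect_true(all(tr3$het[tr3$branch == "denisovan"]))
})

test_that("planted motifs are recovered by scanning the ancestor", {
  qa <- simulateQuartetAlignment(cleanConfig(seed = 6))
  anc <- as.character(quartetSeqs(qa)[["ancestor"]])
  for (cls in c("HM", "CM")) {
    pat <- if (cls == "HM") hmMotif() else cmMotif()
    hits <- scanMotifs(c(chr1 = anc), pat)
    planted <- motifRanges(qa)
    planted <- planted[S4Vectors::mcols(planted)$motif_id == cls]
    expect_true(all(start(planted) %in% start(hits)))
  }
})

test_that("branch assignment recovers every planted mutation exactly", {
  qa <- simulateQuartetAlignment(cleanConfig(seed = 8))
  tr <- truthTable(qa)
  chars <- hotspotErosion:::quartetChars(qa)
  cl <- hotspotErosion:::classifyQuartetSites(chars, tr$pos)
  got <- as.character(cl$branch)
  got[got == "none" & cl$chimpMutated] <- "chimpanzee"
  expect_identical(got, tr$branch)
  # and no false positives: unmutated sites classify as none
  un <- setdiff(seq(1, 5000), tr$pos)
  cl0 <- hotspotErosion:::classifyQuartetSites(chars, un)
  expect_true(all(cl0$branch == "none" & !cl0$chimpMutated))
})
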