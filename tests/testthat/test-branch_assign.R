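test_that("quartet columns classify to the documented branches", {
  expect_equal(as.character(assignBranch("A", "G", "G", "G", "A")),
               "hominini")
  expect_equal(as.character(assignBranch("A", "G", "A", "A", "A")), "human")
  expect_equal(as.character(assignBranch("A", "A", "G", "G", "A")),
               "denisovan")
  expect_equal(as.character(assignBranch("A", "A", "A", "A", "T")),
               "chimpanzee")
  expect_equal(as.character(assignBranch("A", "C", "G", "G", "T")),
               "excluded")
  expect_equal(as.character(assignBranch("A", "A", "A", "A", "A")), "none")
})

test_that("heterozygote resolution splits evenly between the two readings", {
  # (anc A, hum G, den A/G, chimp A): den -> A gives human, den -> G
  # gives hominini; exhaustive over the two resolutions
  expect_equal(as.character(assignBranch("A", "G", "A", "G", "A",
                                         hetDraw = TRUE)), "human")
  expect_equal(as.character(assignBranch("A", "G", "A", "G", "A",
                                         hetDraw = FALSE)), "hominini")
  set.seed(1)
  draws <- replicate(4000, as.character(
    assignBranch("A", "G", "A", "G", "A")))
  p <- mean(draws == "human")
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / 4000))
})

test_that("filter tiers implement the documented predicates and nest", {
  ann <- S4Vectors::DataFrame(
    coverage = c(30L, 15L, 30L, 30L), denCalled = c(TRUE, TRUE, FALSE, TRUE),
    indel = FALSE, faMember = TRUE, concordance = c(4L, 4L, 4L, 2L),
    lowQual = FALSE, sysErr = FALSE, map20 = 1, humanSeqs = 1L,
    chimpSeqs = 1L)
  expect_equal(applyFilter(ann, "F1"), c(TRUE, TRUE, FALSE, TRUE))
  # coverage 15, all else clean: passes F1 and F2, fails F3
  expect_equal(applyFilter(ann, "F2")[2], TRUE)
  expect_equal(applyFilter(ann, "F3")[2], FALSE)
  # low concordance fails F2 but not F1
  expect_equal(applyFilter(ann, "F1")[4], TRUE)
  expect_equal(applyFilter(ann, "F2")[4], FALSE)
  expect_error(applyFilter(ann, "F9"))

  # all-clean annotations: identical motif sets across tiers
  qa <- simulateQuartetAlignment(cleanConfig(seed = 5))
  for (tier in c("F1", "F2", "F3"))
    expect_true(all(applyFilter(siteAnnotations(qa), tier)))
})

test_that("loss rates equal the truth table exactly without heterozygotes", {
  qa <- simulateQuartetAlignment(cleanConfig(seed = 12))
  lr <- computeLossRates(qa, tier = "F2", repeats = 2, seed = 1)
  for (cls in c("HM", "CM")) {
    oracle <- lossesFromTruth(qa, cls)
    sub <- lr[lr$motifClass == cls & lr$stratum == "all", ]
    expect_equal(sub$nLost[match(c("chimpanzee", "hominini", "human",
                                   "denisovan"), sub$branch)],
                 unname(oracle$losses))
    expect_equal(sub$nAncestral[sub$branch == "chimpanzee"], oracle$nMotifs)
    # terminal denominator: intact at the human-Denisovan ancestor
    expect_equal(sub$nAncestral[sub$branch == "human"],
                 oracle$nMotifs - oracle$nHominini)
    expect_true(all(sub$sdLossRate == 0))   # no het randomness
  }
})

test_that("a motif hit in hominini and a terminal branch counts once, as hominini", {
  # one HM motif at 11..23; informative site 11 mutated in hominini
  # (human+denisovan share G), informative site 15 mutated in human only
  anc <- paste0("AAAAAAAAAA", "CCTCCCTGACCAC", "AAAAAAAAAA")
  hum <- anc; den <- anc
  substr(hum, 11, 11) <- "G"; substr(den, 11, 11) <- "G"
  substr(hum, 15, 15) <- "T"
  qa <- manualQuartet(anc, hum, den, den, anc)
  lr <- computeLossRates(qa, tier = "F1", repeats = 1, strata = list(),
                         seed = 1)
  hm <- lr[lr$motifClass == "HM", ]
  expect_equal(hm$nLost[hm$branch == "hominini"], 1)
  expect_equal(hm$nLost[hm$branch == "human"], 0)
  # and the human denominator lost the motif
  expect_equal(hm$nAncestral[hm$branch == "human"], 0)
})

test_that("proportion test matches the textbook formula and the oracle", {
  # equal proportions: continuity correction pushes p to ~1
  expect_gt(proportionTest(50, 1000, 50, 1000)$p.value, 0.95)
  # reconstructed Table-1-style counts: highly significant
  p <- proportionTest(9, 134, 70, 4102)$p.value
  expect_gt(p, 5e-5)
  expect_lt(p, 1.3e-4)
  # independent oracle: prop.test's Yates chi-square is the squared Z
  set.seed(42)
  for (i in 1:25) {
    n1 <- sample(20:500, 1); n2 <- sample(20:500, 1)
    x1 <- rbinom(1, n1, 0.2); x2 <- rbinom(1, n2, 0.3)
    ours <- proportionTest(x1, n1, x2, n2)$p.value
    ref <- suppressWarnings(prop.test(c(x1, x2), c(n1, n2)))$p.value
    expect_lt(abs(ours - ref), 1e-12)
  }
  expect_error(proportionTest(1, 0, 1, 10))
})

test_that("DAF extraction follows the record/fixed/intact rules", {
  af <- data.frame(chrom = "chr1", pos = c(10L, 30L),
                   ref = c("A", "G"), alt = c("G", "A"),
                   af = c(0.12, 0.8))
  ref <- rep("A", 40); ref[15] <- "G"
  sites <- data.frame(pos = c(10L, 15L, 18L, 30L),
                      ancestralBase = c("A", "A", "A", "A"))
  out <- extractDaf(sites, af, ref)
  expect_equal(out$daf, c(0.12, 1, NA, 1 - 0.8))
  expect_equal(out$status, c("polymorphic", "fixed", "intact",
                             "polymorphic"))
  # allele mismatch: flagged and skipped with a warning
  afBad <- data.frame(chrom = "chr1", pos = 10L, ref = "C", alt = "G",
                      af = 0.5)
  expect_warning(res <- extractDaf(sites[1, , drop = FALSE], afBad, ref),
                 "mismatch")
  expect_equal(attr(res, "mismatches"), 1L)
})

test_that("recombination profiles behave on constructed maps", {
  # uniform map: flat profile at 1 with zero-width band
  m1 <- data.frame(Chromosome = "chr1", Position = c(0, 100000),
                   Rate = c(1, 0), Map = c(0, 0.1))
  rp <- recombProfile(c(30000, 60000), m1)
  expect_true(all(abs(rp$mean - 1) < 1e-9))
  expect_true(all(rp$hi - rp$lo < 1e-9))

  # single anchor in a planted 10 cM/Mb hotspot: peak at center equals the
  # by-hand window average of the step map
  m2 <- data.frame(Chromosome = "chr1",
                   Position = c(0, 49000, 51000, 100000),
                   Rate = c(1, 10, 1, 0),
                   Map = c(0, 0.049, 0.069, 0.118))
  rp2 <- recombProfile(50000, m2)
  expect_equal(rp2$mean[rp2$offset == 0], 10, tolerance = 1e-6)
  far <- rp2$mean[abs(rp2$offset) == 9000]
  expect_true(all(abs(far - 1) < 0.5))

  # doubling all rates doubles the profile
  m3 <- m2; m3$Rate <- 2 * m3$Rate; m3$Map <- 2 * m3$Map
  rp3 <- recombProfile(50000, m3)
  expect_equal(rp3$mean, 2 * rp2$mean, tolerance = 1e-9)
  expect_error(recombProfile(numeric(), m1), "empty")
})

test_that("local rates and terciles are deterministic", {
  m <- data.frame(Chromosome = "chr1", Position = c(0, 1000, 2000),
                  Rate = c(2, 0, 0), Map = c(0, 0.002, 0.002))
  expect_equal(meanMapRate(m, 501, 1500), 1.0, tolerance = 1e-9)
  r <- c(0.5, 0.5, 0.5, 1, 2, 3)
  expect_equal(rateTerciles(r), c(1L, 1L, 2L, 2L, 3L, 3L))
})
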