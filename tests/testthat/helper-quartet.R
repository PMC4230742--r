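# Shared fixtures built in code.

# Annotation defect rates all zero: every site passes every tier.
cleanNoise <- function() {
  list(noCall = 0, indel = 0, faDrop = 0, discord = 0, lowQual = 0,
       sysErr = 0, badMap = 0, paralog = 0, covBad = 0)
}

# A small, fully clean quartet configuration with a planted human-branch
# HM excess; every default overridable through ...
cleanConfig <- function(seed = 1L, ...) {
  defaults <- list(seed = seed, lHM = 80L, lCM = 80L,
                   genomeLength = 160000L,
                   hmExtraLoss = c(chimpanzee = 0, hominini = 0,
                                   human = 0.08, denisovan = 0),
                   annotNoise = cleanNoise())
  do.call(simConfig, utils::modifyList(defaults, list(...)))
}

# Build a QuartetAlignment by hand from five equal-length sequences, with
# all-clean annotations and a uniform 1 cM/Mb map.
manualQuartet <- function(anc, hum, den1, den2, chimp) {
  L <- nchar(anc)
  seqs <- Biostrings::DNAStringSet(c(ancestor = anc, human = hum,
                                     denisovan1 = den1, denisovan2 = den2,
                                     chimpanzee = chimp))
  ann <- S4Vectors::DataFrame(
    coverage = rep(30L, L), denCalled = rep(TRUE, L),
    indel = rep(FALSE, L), faMember = rep(TRUE, L),
    concordance = rep(4L, L), lowQual = rep(FALSE, L),
    sysErr = rep(FALSE, L), map20 = rep(1, L),
    humanSeqs = rep(1L, L), chimpSeqs = rep(1L, L))
  motifs <- scanMotifs(c(chr1 = anc), hmMotif(), strands = "plus")
  cms <- scanMotifs(c(chr1 = anc), cmMotif(), strands = "plus")
  motifs <- sort(c(motifs, cms), ignore.strand = TRUE)
  map <- data.frame(Chromosome = "chr1", Position = c(0, L),
                    Rate = c(1, 0), Map = c(0, L / 1e6))
  new("QuartetAlignment", seqs = seqs, annotations = ann,
      truth = data.frame(pos = integer(), branch = character(),
                         from = character(), to = character(),
                         het = logical(), motifId = character(),
                         informative = logical()),
      motifs = motifs, hotspots = GenomicRanges::GRanges(),
      the1 = GenomicRanges::GRanges(), map = map,
      afTable = data.frame(chrom = character(), pos = integer(),
                           ref = character(), alt = character(),
                           af = numeric()),
      config = simConfig(seed = 1L))
}

# Worst relative deviation between the exact binomial-sampled (discrete)
# binned expectations and the continuous approximation. Classes are paired
# with midpoint-extended integration ranges ((iMin-0.5)/n .. (iMax+0.5)/n).
# The collapse of the binomial onto the point frequency carries a local
# error ~ H''(x) * x(1-x)/(2n), which blows up at both boundaries (H ~ 1/x
# at 0, curvature ~ 1/(1-x)^2 at 1); bins are compared only where i >= 10
# and n(1-x)^2 >= 10. The rare-end residual outside this region is
# absorbed by the fitted scale through the r1 = 1 anchor (methods
# vignette).
discreteVsContinuous <- function(n, G, m = 10L) {
  edges <- dafBinEdges(n, m)
  cls <- expectedClassCounts(G, n)
  f <- seq_len(n - 1L) / n
  idx <- findInterval(f, edges)
  iHi <- n - ceiling(sqrt(10 * n))
  devs <- numeric()
  for (j in sort(unique(idx))) {
    is <- which(idx == j)
    if (min(is) < 10L || max(is) > iHi) next   # both rare ends
    lo <- (min(is) - 0.5) / n
    hi <- (max(is) + 0.5) / n
    ci <- integrate(sojournDensity, lo, hi, G = G, rel.tol = 1e-10,
                    subdivisions = 400L)$value
    devs <- c(devs, abs(sum(cls[is]) / ci - 1))
  }
  max(devs)
}

# Oracle: per-branch motif losses recomputed directly from a truth table
# (hominini precedence; only comparison-informative motif sites count).
lossesFromTruth <- function(qa, class = "HM") {
  tr <- truthTable(qa)
  tr <- tr[!is.na(tr$motifId) & tr$motifId == class & tr$informative, ]
  mot <- motifRanges(qa)
  mot <- mot[S4Vectors::mcols(mot)$motif_id == class]
  starts <- GenomicRanges::start(mot)
  motOf <- vapply(tr$pos, function(p) {
    which(starts <= p & starts + 12L >= p)[1]
  }, integer(1))
  perMotif <- split(tr$branch, motOf)
  branchLoss <- setNames(numeric(4), c("chimpanzee", "hominini", "human",
                                       "denisovan"))
  for (b in names(perMotif)) {
    brs <- perMotif[[b]]
    if ("chimpanzee" %in% brs) branchLoss["chimpanzee"] <-
      branchLoss["chimpanzee"] + 1
    hom <- "hominini" %in% brs
    if (hom) branchLoss["hominini"] <- branchLoss["hominini"] + 1
    if (!hom && "human" %in% brs) branchLoss["human"] <-
      branchLoss["human"] + 1
    if (!hom && "denisovan" %in% brs) branchLoss["denisovan"] <-
      branchLoss["denisovan"] + 1
  }
  list(losses = branchLoss, nMotifs = length(mot),
       nHominini = branchLoss[["hominini"]])
}
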