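# S4 classes for the motif-erosion pipeline.

#' Degenerate hotspot target motif
#'
#' A 13-bp PRDM9 target motif over the alphabet A/C/G/T/N. `N` positions
#' match any base. Two site sets matter downstream: the *disruptible* sites
#' (all non-N positions, length `k`, the mutation opportunity of the motif)
#' and the *comparison-informative* sites used when contrasting the hotspot
#' motif (HM) with its control (CM) -- the two N positions are always
#' ignored, and the second position, which discriminates HM from CM and so
#' differs in sequence context, is additionally excluded.
#'
#' @slot pattern character scalar over A/C/G/T/N.
#' @slot motifId label, e.g. `"HM"` or `"CM"`.
#' @slot comparisonInformative integer vector of 1-based offsets within the
#'   motif (N positions and the HM/CM-discriminating position excluded).
#' @slot k integer, number of non-N (disruptible) positions.
#' @export
setClass("MotifPattern", representation(
  pattern = "character", motifId = "character",
  comparisonInformative = "integer", k = "integer"))

setValidity("MotifPattern", function(object) {
  p <- object@pattern
  if (length(p) != 1L || nchar(p) < 1L) return("pattern must be one non-empty string")
  if (grepl("[^ACGTN]", p)) return("pattern letters must be A/C/G/T/N")
  nonN <- which(strsplit(p, "")[[1]] != "N")
  if (object@k != length(nonN)) return("k must equal the number of non-N positions")
  if (!all(object@comparisonInformative %in% nonN))
    return("comparisonInformative must be non-N positions of the pattern")
  TRUE
})

#' Construct a motif pattern
#'
#' @param pattern string over A/C/G/T/N.
#' @param motifId label for the motif.
#' @param comparisonInformative 1-based offsets of the comparison-informative
#'   sites; defaults to all non-N positions.
#' @return A [MotifPattern-class] object.
#' @examples
#' hmMotif()
#' motifPattern("CCNCC", "toy")
#' @export
motifPattern <- function(pattern, motifId,
                         comparisonInformative = NULL) {
  ch <- strsplit(pattern, "")[[1]]
  nonN <- which(ch != "N")
  if (is.null(comparisonInformative)) comparisonInformative <- nonN
  new("MotifPattern", pattern = pattern, motifId = motifId,
      comparisonInformative = as.integer(comparisonInformative),
      k = length(nonN))
}

#' @describeIn motifPattern The 13-bp PRDM9-A hotspot motif CCTCCCTNNCCAC
#'   (k = 11 disruptible sites; 10 comparison-informative sites, position 2
#'   excluded).
#' @export
hmMotif <- function() motifPattern("CCTCCCTNNCCAC", "HM",
                                   comparisonInformative = c(1L, 3:7, 10:13))

#' @describeIn motifPattern The non-recombinogenic control motif
#'   CTTCCCTNNCCAC, differing from HM only at position 2.
#' @export
cmMotif <- function() motifPattern("CTTCCCTNNCCAC", "CM",
                                   comparisonInformative = c(1L, 3:7, 10:13))

setMethod("show", "MotifPattern", function(object) {
  cat(sprintf("MotifPattern %s: %s (k = %d, %d comparison-informative sites)\n",
              object@motifId, object@pattern, object@k,
              length(object@comparisonInformative)))
})

#' Synthetic-data generator configuration
#'
#' Holds every parameter of the synthetic study conditions: sample size of
#' the frequency data, mutation scale, the true conversion coefficient, the
#' demographic distortions, motif counts, per-branch substitution rates,
#' gBGC fixation bias, Denisovan heterozygosity and the recombination-map
#' gamma law. Construct with [simConfig()].
#'
#' @slot seed root seed; all generator streams derive from it.
#' @slot nChrom number of sampled chromosomes n (frequency-spectrum depth).
#' @slot diploidSize diploid effective population size N.
#' @slot scaledMutation expected-mutation-count scale (theta*L analog) per
#'   motif class.
#' @slot gTrue population-scaled conversion coefficient G = 4Ne*g planted in
#'   the test-class spectrum.
#' @slot rDistortions per-bin demographic distortion multipliers, first
#'   element fixed at 1 (recycled across bins if length 1).
#' @slot lHM,lCM planted HM / CM motif counts.
#' @slot genomeLength simulated chromosome length (bp).
#' @slot gcContent background GC fraction of the ancestor sequence.
#' @slot branchSubRates named per-branch substitution probabilities per site
#'   (chimpanzee, hominini, human, denisovan).
#' @slot hmExtraLoss named per-branch probability that an HM motif receives
#'   one extra disrupting substitution at a comparison-informative site (the
#'   planted dBGC excess).
#' @slot gbgcBias W-to-S substitution-direction bias in [0,1) applied inside
#'   hotspot intervals for the branches in `gbgcBranches`.
#' @slot gbgcBranches branches carrying the planted gBGC bias.
#' @slot hetRate probability that a Denisovan-branch mutation is heterozygous.
#' @slot mapMean,mapShape gamma law (mean cM/Mb, shape) of background
#'   recombination-map segment rates.
#' @slot hotspotRate rate (cM/Mb) assigned to hotspot intervals in the map.
#' @slot hotspotFraction fraction of motifs seeding a 2-kb hotspot interval.
#' @slot the1Fraction fraction of motifs embedded in a THE1-like element.
#' @slot polymorphicFraction fraction of human-branch mutations still
#'   segregating (given an allele-frequency record) vs fixed.
#' @slot annotNoise named list of per-site annotation defect rates
#'   (noCall, indel, faDrop, discord, lowQual, sysErr, badMap, paralog,
#'   covBad -- the rate of Denisovan coverage outside the reliable 16-46
#'   range).
#' @export
setClass("SimConfig", representation(
  seed = "integer", nChrom = "integer", diploidSize = "integer",
  scaledMutation = "numeric", gTrue = "numeric", rDistortions = "numeric",
  lHM = "integer", lCM = "integer", genomeLength = "integer",
  gcContent = "numeric", branchSubRates = "numeric", hmExtraLoss = "numeric",
  gbgcBias = "numeric", gbgcBranches = "character", hetRate = "numeric",
  mapMean = "numeric", mapShape = "numeric", hotspotRate = "numeric",
  hotspotFraction = "numeric", the1Fraction = "numeric",
  polymorphicFraction = "numeric", annotNoise = "list"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@rDistortions[1] != 1) msg <- c(msg, "rDistortions[1] must be 1")
  if (any(object@rDistortions <= 0)) msg <- c(msg, "rDistortions must be positive")
  if (object@gTrue < 0) msg <- c(msg, "gTrue must be non-negative")
  if (object@nChrom < 4L) msg <- c(msg, "nChrom must be at least 4")
  if (object@gcContent <= 0 || object@gcContent >= 1)
    msg <- c(msg, "gcContent must be in (0,1)")
  if (!all(.BRANCHES %in% names(object@branchSubRates)))
    msg <- c(msg, "branchSubRates must name all four branches")
  if (any(object@branchSubRates < 0 | object@branchSubRates > 0.2))
    msg <- c(msg, "branchSubRates out of range [0, 0.2]")
  if (object@gbgcBias < 0 || object@gbgcBias >= 1)
    msg <- c(msg, "gbgcBias must be in [0,1)")
  if (object@hetRate < 0 || object@hetRate > 1) msg <- c(msg, "hetRate in [0,1]")
  if (object@mapMean <= 0 || object@mapShape <= 0) msg <- c(msg, "map gamma invalid")
  if (length(msg)) msg else TRUE
})

#' Build a generator configuration
#'
#' Defaults are the study conditions: n = 2184 sampled chromosomes, a
#' mutation scale giving about 500 segregating mutations per motif class, a
#' recombination-rate gamma law with mean 5.02 cM/Mb and shape 0.28, and
#' background GC content 0.4. Branch substitution rates default to a
#' human-chimpanzee-divergence-scale split across the four branches.
#'
#' @param seed integer root seed.
#' @param nChrom,diploidSize,scaledMutation,gTrue,rDistortions,lHM,lCM see
#'   [SimConfig-class].
#' @param genomeLength,gcContent,branchSubRates,hmExtraLoss see
#'   [SimConfig-class].
#' @param gbgcBias,gbgcBranches,hetRate,mapMean,mapShape,hotspotRate see
#'   [SimConfig-class].
#' @param hotspotFraction,the1Fraction,polymorphicFraction,annotNoise see
#'   [SimConfig-class].
#' @return A validated [SimConfig-class] object.
#' @examples
#' simConfig(seed = 1)
#' @export
simConfig <- function(seed = 1L, nChrom = 2184L, diploidSize = 10000L,
                      scaledMutation = 32.5, gTrue = 0,
                      rDistortions = 1,
                      lHM = 500L, lCM = 500L, genomeLength = 1000000L,
                      gcContent = 0.4,
                      branchSubRates = c(chimpanzee = 0.006, hominini = 0.0055,
                                         human = 0.0004, denisovan = 0.0004),
                      hmExtraLoss = c(chimpanzee = 0, hominini = 0,
                                      human = 0, denisovan = 0),
                      gbgcBias = 0, gbgcBranches = "human",
                      hetRate = 0, mapMean = 5.02, mapShape = 0.28,
                      hotspotRate = 10, hotspotFraction = 0.15,
                      the1Fraction = 0.03, polymorphicFraction = 0.5,
                      annotNoise = list(noCall = 0.01, indel = 0.005,
                                        faDrop = 0.05, discord = 0.02,
                                        lowQual = 0.02, sysErr = 0.01,
                                        badMap = 0.02, paralog = 0.01,
                                        covBad = 0.02)) {
  new("SimConfig", seed = as.integer(seed), nChrom = as.integer(nChrom),
      diploidSize = as.integer(diploidSize), scaledMutation = scaledMutation,
      gTrue = gTrue, rDistortions = rDistortions, lHM = as.integer(lHM),
      lCM = as.integer(lCM), genomeLength = as.integer(genomeLength),
      gcContent = gcContent,
      branchSubRates = branchSubRates[.BRANCHES],
      hmExtraLoss = hmExtraLoss[.BRANCHES],
      gbgcBias = gbgcBias, gbgcBranches = gbgcBranches, hetRate = hetRate,
      mapMean = mapMean, mapShape = mapShape, hotspotRate = hotspotRate,
      hotspotFraction = hotspotFraction, the1Fraction = the1Fraction,
      polymorphicFraction = polymorphicFraction, annotNoise = annotNoise)
}

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(paste0("SimConfig: seed=%d, n=%d chromosomes, G_true=%g, ",
                     "%d HM + %d CM motifs on %g bp\n"),
              object@seed, object@nChrom, object@gTrue, object@lHM,
              object@lCM, as.numeric(object@genomeLength)))
})

#' Paired derived-allele-frequency spectrum
#'
#' Binned DAF counts for a test class (HM-disrupting mutations) and a
#' neutral reference class (CM mutations). The first bin starts at 1/n (one
#' observable copy); fixed changes (DAF = 1) are excluded from the fitting
#' bins and carried separately.
#'
#' @slot nChrom sample size n.
#' @slot edges strictly increasing bin edges, `edges[1] = 1/nChrom`,
#'   last edge 1; bin j is `[edges[j], edges[j+1])`.
#' @slot countsNeutral,countsTest per-bin counts.
#' @slot fixedNeutral,fixedTest numbers of fixed (DAF = 1) changes.
#' @slot lNeutral,lTest motif counts behind each class.
#' @slot truth generator truth (list; empty for real data).
#' @export
setClass("DAFSpectrum", representation(
  nChrom = "integer", edges = "numeric",
  countsNeutral = "numeric", countsTest = "numeric",
  fixedNeutral = "numeric", fixedTest = "numeric",
  lNeutral = "integer", lTest = "integer", truth = "list"))

setValidity("DAFSpectrum", function(object) {
  nb <- length(object@edges) - 1L
  if (nb < 2L) return("need at least 2 bins")
  if (any(diff(object@edges) <= 0)) return("edges must be strictly increasing")
  if (object@edges[1] <= 0) return("first edge must be positive")
  if (length(object@countsNeutral) != nb || length(object@countsTest) != nb)
    return("counts length must match number of bins")
  if (any(object@countsNeutral < 0) || any(object@countsTest < 0))
    return("counts must be non-negative")
  TRUE
})

#' Construct a DAF spectrum from binned counts
#'
#' @param countsNeutral,countsTest per-bin counts for the neutral and test
#'   classes.
#' @param edges bin edges (see [dafBinEdges()]).
#' @param nChrom sample size n.
#' @param fixedNeutral,fixedTest counts of fixed (DAF = 1) changes, kept out
#'   of the likelihood.
#' @param lNeutral,lTest motif counts per class.
#' @param truth optional generator truth list.
#' @return A [DAFSpectrum-class].
#' @export
dafSpectrum <- function(countsNeutral, countsTest, edges, nChrom,
                        fixedNeutral = 0, fixedTest = 0,
                        lNeutral = NA_integer_, lTest = NA_integer_,
                        truth = list()) {
  new("DAFSpectrum", nChrom = as.integer(nChrom), edges = as.numeric(edges),
      countsNeutral = as.numeric(countsNeutral),
      countsTest = as.numeric(countsTest),
      fixedNeutral = fixedNeutral, fixedTest = fixedTest,
      lNeutral = as.integer(lNeutral), lTest = as.integer(lTest),
      truth = truth)
}

setMethod("show", "DAFSpectrum", function(object) {
  cat(sprintf(paste0("DAFSpectrum: n=%d, %d bins; %d neutral + %d test ",
                     "segregating mutations (%g / %g fixed)\n"),
              object@nChrom, length(object@edges) - 1L,
              sum(object@countsNeutral), sum(object@countsTest),
              object@fixedNeutral, object@fixedTest))
  if (length(object@truth))
    cat(sprintf("  truth: G=%g\n", object@truth$gTrue))
})

#' Fitted conversion-intensity model
#'
#' Result of the Poisson random-field fit of the conversion coefficient G
#' to a paired DAF spectrum. See [fitDbgc()].
#'
#' @slot model "M0" (no conversion), "M1" (constant G) or "gamma"
#'   (recombination-proportional G).
#' @slot gHat maximum-likelihood G (M1) or implied mean G (gamma model).
#' @slot ciLo,ciHi profile-likelihood interval (log-likelihood two points
#'   below the maximum).
#' @slot rHat per-bin demographic distortions (r1 = 1).
#' @slot scaleNeutral,scaleTest per-class mutation scales (2*Ne*u*L analogs).
#' @slot lnL,lnLM0,lnLSaturated log-likelihoods of the fitted, no-conversion
#'   and saturated models.
#' @slot lrt,pLrt likelihood-ratio statistic against M0 and its p-value
#'   (boundary-corrected 1/2 chi-square(1) mixture, since G >= 0).
#' @slot gof,gofDf deviance against the saturated model and its degrees of
#'   freedom.
#' @slot details list of optimizer diagnostics.
#' @export
setClass("DbgcFit", representation(
  model = "character", gHat = "numeric", ciLo = "numeric", ciHi = "numeric",
  rHat = "numeric", scaleNeutral = "numeric", scaleTest = "numeric",
  lnL = "numeric", lnLM0 = "numeric", lnLSaturated = "numeric",
  lrt = "numeric", pLrt = "numeric", gof = "numeric", gofDf = "numeric",
  details = "list"))

setMethod("show", "DbgcFit", function(object) {
  cat(sprintf("DbgcFit [%s]: G_hat = %.4g (CI %.4g - %.4g)\n",
              object@model, object@gHat, object@ciLo, object@ciHi))
  cat(sprintf("  lnL = %.4f (M0 %.4f, saturated %.4f); LRT = %.3f, p = %.3g\n",
              object@lnL, object@lnLM0, object@lnLSaturated, object@lrt,
              object@pLrt))
  cat(sprintf("  GoF deviance = %.3f on %g df\n", object@gof, object@gofDf))
})

#' Gamma law for the conversion coefficient induced by G = c*X
#'
#' When G is proportional to the local crossover rate X (gamma with mean
#' `rateMean` and shape `rateShape`), G follows a gamma law with the same
#' shape and mean `c * rateMean`. A zero-rate point mass maps to G = 0.
#'
#' @slot shape gamma shape of G.
#' @slot mean mean of G (= c * rateMean).
#' @slot c proportionality constant between G and the crossover rate.
#' @slot rateMean,rateShape fitted gamma law of the crossover rates.
#' @slot zeroFraction share of exactly-zero rates, carried as a G = 0 atom.
#' @export
setClass("GDistribution", representation(
  shape = "numeric", mean = "numeric", c = "numeric",
  rateMean = "numeric", rateShape = "numeric", zeroFraction = "numeric"))

setValidity("GDistribution", function(object) {
  if (object@shape <= 0) return("shape must be positive")
  if (object@c < 0) return("c must be non-negative")
  if (object@zeroFraction < 0 || object@zeroFraction >= 1)
    return("zeroFraction must be in [0,1)")
  TRUE
})

#' Construct a G distribution
#' @param shape,mean gamma shape and mean of G.
#' @param c proportionality constant (`mean = c * rateMean`).
#' @param rateMean,rateShape gamma law of the underlying crossover rates.
#' @param zeroFraction point mass at G = 0.
#' @return A [GDistribution-class].
#' @examples
#' gDistribution(shape = 0.28, mean = 28.2)
#' @export
gDistribution <- function(shape, mean, c = NA_real_, rateMean = NA_real_,
                          rateShape = shape, zeroFraction = 0) {
  if (is.na(c) && !is.na(rateMean)) c <- mean / rateMean
  if (is.na(c)) c <- 0
  new("GDistribution", shape = shape, mean = mean, c = c,
      rateMean = rateMean, rateShape = rateShape,
      zeroFraction = zeroFraction)
}

setMethod("show", "GDistribution", function(object) {
  cat(sprintf(paste0("GDistribution: gamma(shape %.3g, mean %.4g), c = %.4g",
                     ", zero mass %.3g\n"),
              object@shape, object@mean, object@c, object@zeroFraction))
})

#' Simulated quartet alignment with truth
#'
#' Container for one synthetic chromosome: the true human-chimpanzee
#' ancestor, the human reference, the two Denisovan haplotypes and the
#' chimpanzee sequence, together with per-site annotation tracks, planted
#' motif/hotspot/THE1 intervals, a recombination map, an allele-frequency
#' table for human-branch mutations, and the truth table of every planted
#' substitution. Produced by [simulateQuartetAlignment()].
#'
#' @slot seqs `DNAStringSet` named ancestor, human, denisovan1, denisovan2,
#'   chimpanzee (equal widths; columns are alignment columns).
#' @slot annotations per-site `DataFrame` of filter annotations.
#' @slot truth data.frame of planted mutations (pos, branch, from, to, het,
#'   motifId, informative).
#' @slot motifs,hotspots,the1 `GRanges` of planted features.
#' @slot map HapMap-style recombination map data.frame
#'   (Chromosome, Position, Rate, Map).
#' @slot afTable allele-frequency records (chrom, pos, ref, alt, af).
#' @slot config the generating [SimConfig-class].
#' @export
setClass("QuartetAlignment", representation(
  seqs = "DNAStringSet", annotations = "DataFrame", truth = "data.frame",
  motifs = "GRanges", hotspots = "GRanges", the1 = "GRanges",
  map = "data.frame", afTable = "data.frame", config = "SimConfig"))

setMethod("show", "QuartetAlignment", function(object) {
  cat(sprintf(paste0("QuartetAlignment: %d bp, %d motifs (%d hotspot, %d ",
                     "THE1 intervals), %d planted mutations\n"),
              width(object@seqs)[1], length(object@motifs),
              length(object@hotspots), length(object@the1),
              nrow(object@truth)))
})

#' @rdname QuartetAlignment-class
#' @param qa a [QuartetAlignment-class].
#' @export
quartetSeqs <- function(qa) qa@seqs

#' @rdname QuartetAlignment-class
#' @export
truthTable <- function(qa) qa@truth

#' @rdname QuartetAlignment-class
#' @export
motifRanges <- function(qa) qa@motifs

#' @rdname QuartetAlignment-class
#' @export
hotspotRanges <- function(qa) qa@hotspots

#' @rdname QuartetAlignment-class
#' @export
the1Ranges <- function(qa) qa@the1

#' @rdname QuartetAlignment-class
#' @export
recombMap <- function(qa) qa@map

#' @rdname QuartetAlignment-class
#' @export
siteAnnotations <- function(qa) qa@annotations

#' @rdname QuartetAlignment-class
#' @export
afTable <- function(qa) qa@afTable
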