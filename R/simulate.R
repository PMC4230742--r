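# Synthetic-data generators: every pipeline input with known ground truth.

#' Simulate a paired DAF spectrum under the Poisson-field model
#'
#' Draws per-bin Poisson counts for a neutral class (G = 0) and a test
#' class (G = `gTrue`), each with mean
#' `r_j * scaledMutation * integral of H(x, G) over bin j`,
#' i.e. exactly the model of [expectedBinCounts()]. The generating truth is
#' attached to the returned spectrum.
#'
#' @param config a [simConfig()].
#' @param edges bin edges; defaults to [dafBinEdges()] with `m` bins.
#' @param m number of bins above 0.01 when `edges` is not given.
#' @return A [DAFSpectrum-class] with a `truth` record.
#' @examples
#' simulateDafSpectrum(simConfig(seed = 1, gTrue = 10))
#' @export
simulateDafSpectrum <- function(config, edges = NULL, m = 10L) {
  if (is.null(edges)) edges <- dafBinEdges(config@nChrom, m)
  if (any(diff(edges) <= 0)) stop("bin edges must be strictly increasing")
  nb <- length(edges) - 1L
  r <- rep_len(config@rDistortions, nb)
  muN <- expectedBinCounts(0, edges, scale = config@scaledMutation, r = r)
  muT <- expectedBinCounts(config@gTrue, edges,
                           scale = config@scaledMutation, r = r)
  withStream(config@seed, "daf-spectrum", {
    kN <- rpois(nb, muN)
    kT <- rpois(nb, muT)
    dafSpectrum(kN, kT, edges, config@nChrom,
                lNeutral = config@lCM, lTest = config@lHM,
                truth = list(gTrue = config@gTrue, r = r,
                             scale = config@scaledMutation,
                             expectedNeutral = muN, expectedTest = muT))
  })
}

#' Simulate unbinned allele-count classes
#'
#' Draws Poisson counts of SNPs observed with i = 1..n-1 derived copies,
#' with means `scaledMutation * E_i` from the exact binomial-sampled class
#' expectations ([expectedClassCounts()]); at G = 0 the mean is the
#' analytic `2 * scaledMutation / i`. Intended for small n, where the
#' discrete spectrum is the natural object.
#'
#' @param config a [simConfig()] (class counts use `gTrue` and
#'   `scaledMutation`; `rDistortions` is recycled across classes).
#' @return Integer vector of class counts with attribute `expected`.
#' @export
simulateClassCounts <- function(config) {
  n <- config@nChrom
  mu <- expectedClassCounts(config@gTrue, n, scale = config@scaledMutation) *
    rep_len(config@rDistortions, n - 1L)
  withStream(config@seed, "class-counts", {
    k <- rpois(n - 1L, mu)
    attr(k, "expected") <- mu
    k
  })
}

#' Forward Wright-Fisher simulation of a converted allele
#'
#' Discrete-generation binomial-sampling simulator used as the independent
#' oracle for the diffusion formulas. Conversion acts in heterozygotes: the
#' favored allele is transmitted with probability (1+g)/2, so the expected
#' per-generation frequency change is `g x (1-x)` and the matching
#' diffusion scaling is G = 4N*g. All replicates are run in parallel as a
#' vectorised population of allele counts.
#'
#' @param N diploid population size (>= 2).
#' @param g conversion (transmission-advantage) coefficient, >= 0; the
#'   population-scaled coefficient is G = 4*N*g.
#' @param x0 initial allele frequency in (0, 1).
#' @param nReps number of independent replicates.
#' @param seed integer seed.
#' @param maxGen safety cap on generations (default 100*N).
#' @return A list with `fixed` (logical per replicate), `generations`
#'   (absorption time per replicate) and `summary` (fixation probability
#'   and conditional mean times with standard errors).
#' @examples
#' simulateWrightFisher(200, 0, x0 = 0.1, nReps = 500, seed = 1)$summary
#' @export
simulateWrightFisher <- function(N, g, x0, nReps, seed = 1L,
                                 maxGen = 100L * N) {
  if (N < 2) stop("N must be at least 2")
  stopifnot(x0 > 0, x0 < 1, g >= 0, nReps >= 1)
  withStream(seed, "wright-fisher", {
    two_n <- 2L * as.integer(N)
    j <- rep.int(as.integer(round(x0 * two_n)), nReps)
    if (j[1] == 0L || j[1] == two_n) stop("x0 too extreme for this N")
    fixed <- logical(nReps)
    gens <- integer(nReps)
    act <- seq_len(nReps)
    gen <- 0L
    while (length(act) && gen < maxGen) {
      gen <- gen + 1L
      p <- j[act] / two_n
      p2 <- p + g * p * (1 - p)
      j[act] <- rbinom(length(act), two_n, p2)
      done <- j[act] == 0L | j[act] == two_n
      if (any(done)) {
        d <- act[done]
        fixed[d] <- j[d] == two_n
        gens[d] <- gen
        act <- act[!done]
      }
    }
    if (length(act)) warning(length(act), " replicates unresolved at maxGen")
    tf <- gens[fixed]
    tl <- gens[!fixed & gens > 0L]
    summary <- data.frame(
      nReps = nReps, nFixed = sum(fixed),
      pFix = mean(fixed),
      pFixSE = sqrt(mean(fixed) * (1 - mean(fixed)) / nReps),
      meanFixTime = if (length(tf)) mean(tf) else NA_real_,
      meanFixTimeSE = if (length(tf) > 1) sd(tf) / sqrt(length(tf)) else NA_real_,
      meanLossTime = if (length(tl)) mean(tl) else NA_real_)
    list(fixed = fixed, generations = gens, summary = summary)
  })
}

# Choose substitution target base. `base` vector of current bases; `bias`
# in [0,1): weight (1+bias) on strong (G/C) targets, (1-bias) on weak.
.mutateBase <- function(base, bias = 0) {
  alphabet <- c("A", "C", "G", "T")
  strong <- c("C", "G")
  vapply(seq_along(base), function(i) {
    alt <- setdiff(alphabet, base[i])
    w <- ifelse(alt %in% strong, 1 + bias[i], 1 - bias[i])
    sample(alt, 1L, prob = w)
  }, character(1))
}

#' Simulate a quartet alignment with planted truth
#'
#' Generates one synthetic chromosome end-to-end: an i.i.d. ancestor
#' sequence at the configured GC content with HM and CM motifs planted at
#' spaced loci; hotspot and THE1-like intervals anchored on a subset of
#' motifs; a HapMap-style recombination map (gamma background rates,
#' elevated inside hotspots); branch-specific substitutions under an
#' infinite-sites assumption (at most one mutation per site across
#' branches), with optional extra disrupting mutations at HM
#' comparison-informative sites (the planted dBGC excess), an optional
#' W-to-S substitution bias inside hotspots for designated branches (the
#' planted gBGC), and Denisovan-branch mutations heterozygous with
#' probability `hetRate`; per-site annotation tracks with configurable
#' defect rates for the filter tiers; and an allele-frequency table for
#' human-branch mutations (polymorphic ones carry a record, fixed ones are
#' visible only through the reference sequence). Every planted mutation is
#' recorded in the truth table.
#'
#' @param config a [simConfig()].
#' @return A [QuartetAlignment-class].
#' @examples
#' qa <- simulateQuartetAlignment(simConfig(seed = 1, lHM = 30L, lCM = 30L,
#'                                          genomeLength = 60000L))
#' qa
#' @export
simulateQuartetAlignment <- function(config) {
  L <- config@genomeLength
  nm <- config@lHM + config@lCM
  motifLen <- 13L
  slot <- L %/% nm
  if (slot < motifLen + 40L)
    stop("motif density too high: need genomeLength >= ",
         nm * (motifLen + 40L), " for ", nm, " motifs")
  alphabet <- c("A", "C", "G", "T")
  gc <- config@gcContent
  baseProb <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)

  anc <- withStream(config@seed, "sequence",
                    sample(alphabet, L, replace = TRUE, prob = baseProb))

  # ---- plant motifs, one per slot at a random offset -------------------
  hm <- hmMotif(); cm <- cmMotif()
  plant <- withStream(config@seed, "motifs", {
    starts <- (seq_len(nm) - 1L) * slot +
      sample.int(slot - motifLen - 20L, nm, replace = TRUE) + 10L
    cls <- sample(rep(c("HM", "CM"), c(config@lHM, config@lCM)))
    seqs <- character(nm)
    for (i in seq_len(nm)) {
      pat <- strsplit(if (cls[i] == "HM") hm@pattern else cm@pattern, "")[[1]]
      pat[pat == "N"] <- sample(alphabet, sum(pat == "N"), replace = TRUE)
      seqs[i] <- paste(pat, collapse = "")
      anc[starts[i]:(starts[i] + motifLen - 1L)] <- pat
    }
    list(starts = starts, cls = cls, seqs = seqs)
  })
  motifs <- GRanges("chr1", IRanges(plant$starts, width = motifLen),
                    strand = "+")
  mcols(motifs)$motif_id <- plant$cls
  mcols(motifs)$matched_sequence <- plant$seqs

  # ---- hotspot and THE1-like intervals ---------------------------------
  feat <- withStream(config@seed, "features", {
    nHot <- max(1L, round(config@hotspotFraction * nm))
    nT1 <- max(1L, round(config@the1Fraction * nm))
    hotIdx <- sort(sample.int(nm, nHot))
    t1Idx <- sort(sample.int(nm, nT1))
    list(hotIdx = hotIdx, t1Idx = t1Idx)
  })
  mid <- (plant$starts + motifLen %/% 2L)
  hotspots <- GRanges("chr1", IRanges(pmax(1L, mid[feat$hotIdx] - 999L),
                                      width = 2000L))
  the1 <- GRanges("chr1", IRanges(pmax(1L, mid[feat$t1Idx] - 174L),
                                  width = 350L))

  # ---- recombination map (HapMap convention) ---------------------------
  segLen <- 2000L
  nSeg <- ceiling(L / segLen)
  map <- withStream(config@seed, "map", {
    rates <- rgamma(nSeg, shape = config@mapShape,
                    scale = config@mapMean / config@mapShape)
    segStart <- (seq_len(nSeg) - 1L) * segLen + 1L
    segGr <- GRanges("chr1", IRanges(segStart, width = segLen))
    inHot <- overlapsAny(segGr, hotspots)
    rates[inHot] <- pmax(rates[inHot], config@hotspotRate)
    pos <- c(segStart - 1L, L)              # 0-based HapMap positions
    cm <- c(0, cumsum(rates * segLen / 1e6))
    data.frame(Chromosome = "chr1", Position = pos,
               Rate = c(rates, 0), Map = cm)
  })

  # ---- branch substitutions (infinite sites) ---------------------------
  inHotspot <- logical(L)
  ov <- findOverlaps(GRanges("chr1", IRanges(seq_len(L), width = 1L)),
                     hotspots)
  inHotspot[S4Vectors::queryHits(ov)] <- TRUE

  hmMotifs <- which(plant$cls == "HM")
  infOffsets <- hm@comparisonInformative

  taken <- logical(L)
  truthRows <- list()
  branchSites <- list()
  withStream(config@seed, "mutations", {
    for (br in .BRANCHES) {
      rate <- config@branchSubRates[[br]]
      sites <- if (rate > 0) which(runif(L) < rate) else integer()
      sites <- sites[!taken[sites]]
      extra <- integer()
      xl <- config@hmExtraLoss[[br]]
      if (xl > 0 && length(hmMotifs)) {
        hit <- hmMotifs[runif(length(hmMotifs)) < xl]
        if (length(hit)) {
          off <- sample(infOffsets, length(hit), replace = TRUE)
          extra <- plant$starts[hit] + off - 1L
          extra <- extra[!taken[extra]]
          extra <- setdiff(extra, sites)
        }
      }
      sites <- sort(c(sites, extra))
      taken[sites] <- TRUE
      branchSites[[br]] <- sites
    }
  })

  hd <- anc
  chimp <- anc
  applySubs <- function(seqv, sites, startSeq, branch) {
    if (!length(sites)) return(list(seq = seqv, rows = NULL))
    bias <- ifelse(inHotspot[sites] & branch %in% config@gbgcBranches,
                   config@gbgcBias, 0)
    from <- startSeq[sites]
    to <- withStream(config@seed, paste0("targets-", branch),
                     .mutateBase(from, bias))
    seqv[sites] <- to
    ovm <- findOverlaps(GRanges("chr1", IRanges(sites, width = 1L)), motifs)
    mId <- rep(NA_character_, length(sites))
    inf <- rep(FALSE, length(sites))
    if (length(ovm)) {
      q <- S4Vectors::queryHits(ovm); s <- S4Vectors::subjectHits(ovm)
      mId[q] <- plant$cls[s]
      off <- sites[q] - plant$starts[s] + 1L
      # HM and CM share the same comparison-informative offsets
      inf[q] <- off %in% hm@comparisonInformative
    }
    rows <- data.frame(pos = sites, branch = branch, from = from, to = to,
                       het = FALSE, motifId = mId, informative = inf,
                       stringsAsFactors = FALSE)
    list(seq = seqv, rows = rows)
  }

  resC <- applySubs(chimp, branchSites$chimpanzee, anc, "chimpanzee")
  chimp <- resC$seq
  resH0 <- applySubs(hd, branchSites$hominini, anc, "hominini")
  hd <- resH0$seq
  human <- hd
  resHu <- applySubs(human, branchSites$human, hd, "human")
  human <- resHu$seq
  den <- hd
  resDe <- applySubs(den, branchSites$denisovan, hd, "denisovan")
  den1 <- resDe$seq
  den2 <- resDe$seq

  # Denisovan heterozygosity: planted mutations are het with prob hetRate
  # (second haplotype keeps the HD-ancestral base)
  if (!is.null(resDe$rows) && config@hetRate > 0) {
    het <- withStream(config@seed, "heterozygosity",
                      runif(nrow(resDe$rows)) < config@hetRate)
    resDe$rows$het <- het
    den2[resDe$rows$pos[het]] <- hd[resDe$rows$pos[het]]
  }
  truth <- do.call(rbind, Filter(Negate(is.null),
                                 list(resC$rows, resH0$rows, resHu$rows,
                                      resDe$rows)))
  if (is.null(truth))
    truth <- data.frame(pos = integer(), branch = character(),
                        from = character(), to = character(),
                        het = logical(), motifId = character(),
                        informative = logical())
  truth <- truth[order(truth$pos), , drop = FALSE]
  rownames(truth) <- NULL

  # ---- annotation tracks ----------------------------------------------
  an <- config@annotNoise
  if (is.null(an$covBad)) an$covBad <- 0
  annotations <- withStream(config@seed, "annotations", {
    covOk <- 16L + as.integer(floor(runif(L) * 31))   # uniform 16..46
    covBadPool <- c(0:15, 47:70)
    cov <- ifelse(runif(L) < an$covBad,
                  covBadPool[1L + as.integer(floor(runif(L) * length(covBadPool)))],
                  covOk)
    DataFrame(
      coverage = as.integer(cov),
      denCalled = runif(L) >= an$noCall,
      indel = runif(L) < an$indel,
      faMember = runif(L) >= an$faDrop,
      concordance = ifelse(runif(L) < an$discord,
                           sample(0:2, L, replace = TRUE),
                           ifelse(runif(L) < 0.05, 3L, 4L)),
      lowQual = runif(L) < an$lowQual,
      sysErr = runif(L) < an$sysErr,
      map20 = ifelse(runif(L) < an$badMap, 0.5, 1),
      humanSeqs = ifelse(runif(L) < an$paralog, 2L, 1L),
      chimpSeqs = ifelse(runif(L) < an$paralog, 2L, 1L))
  })

  # ---- allele-frequency table for human-branch mutations ---------------
  annotations$coverage <- as.integer(annotations$coverage)

  af <- data.frame(chrom = character(), pos = integer(), ref = character(),
                   alt = character(), af = numeric())
  if (!is.null(resHu$rows) && nrow(resHu$rows)) {
    af <- withStream(config@seed, "allele-frequencies", {
      hu <- resHu$rows
      poly <- runif(nrow(hu)) < config@polymorphicFraction
      freq <- round(stats::rbeta(nrow(hu), 0.4, 1) * 0.98 + 0.01, 4)
      data.frame(chrom = "chr1", pos = hu$pos[poly],
                 ref = hu$from[poly], alt = hu$to[poly],
                 af = freq[poly], stringsAsFactors = FALSE)
    })
  }

  seqs <- DNAStringSet(c(ancestor = paste(anc, collapse = ""),
                         human = paste(human, collapse = ""),
                         denisovan1 = paste(den1, collapse = ""),
                         denisovan2 = paste(den2, collapse = ""),
                         chimpanzee = paste(chimp, collapse = "")))
  new("QuartetAlignment", seqs = seqs, annotations = annotations,
      truth = truth, motifs = motifs, hotspots = hotspots, the1 = the1,
      map = map, afTable = af, config = config)
}
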