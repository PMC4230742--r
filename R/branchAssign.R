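# Filter tiers, branch assignment of quartet columns, motif loss rates,
# DAF extraction and recombination profiles.

#' Apply a quality-filter tier to per-site annotations
#'
#' Three increasingly stringent tiers. F1 keeps sites with a Denisovan
#' genotype call and no indel in any species; F2 additionally requires
#' membership in the filtered four-primate alignment and concordance of at
#' least 3 of the 4 primates; F3 additionally excludes low-quality and
#' systematic-error regions, Denisovan coverage below 16 or above 46,
#' mappability score different from 1, and paralogous segments (more than
#' one human or chimpanzee sequence in the alignment block). By
#' construction a site passing a stricter tier passes all looser ones.
#'
#' @param annotations per-site `DataFrame`/data.frame with columns
#'   `denCalled`, `indel`, `faMember`, `concordance`, `lowQual`, `sysErr`,
#'   `coverage`, `map20`, `humanSeqs`, `chimpSeqs`.
#' @param tier `"F1"`, `"F2"` or `"F3"`.
#' @return Logical site mask.
#' @examples
#' qa <- simulateQuartetAlignment(simConfig(seed = 1, lHM = 20L, lCM = 20L,
#'                                          genomeLength = 40000L))
#' mean(applyFilter(siteAnnotations(qa), "F3"))
#' @export
applyFilter <- function(annotations, tier = c("F2", "F1", "F3")) {
  tier <- match.arg(tier)
  a <- annotations
  m <- a$denCalled & !a$indel
  if (tier == "F1") return(m)
  m <- m & a$faMember & a$concordance >= 3L
  if (tier == "F2") return(m)
  m & !a$lowQual & !a$sysErr & a$coverage >= 16L & a$coverage <= 46L &
    a$map20 == 1 & a$humanSeqs == 1L & a$chimpSeqs == 1L
}

#' Motif-level filter mask
#'
#' A motif is retained under a tier iff every one of its
#' comparison-informative sites passes the tier's site mask.
#'
#' @param motifs `GRanges` of motif loci (plus strand, as planted/scanned).
#' @param siteMask logical per-site mask from [applyFilter()].
#' @param pattern [MotifPattern-class] supplying the informative offsets.
#' @return Logical vector, one element per motif.
#' @export
motifFilterMask <- function(motifs, siteMask, pattern = hmMotif()) {
  off <- pattern@comparisonInformative
  vapply(start(motifs), function(s) all(siteMask[s + off - 1L]), logical(1))
}

#' Assign a quartet column to a phylogeny branch
#'
#' Classifies one aligned position given the human-chimpanzee ancestral
#' base, the human base, the Denisovan diploid genotype and the chimpanzee
#' base. A mutation is inferred on the hominini branch when the ancestor
#' differs from human and Denisovan while those two agree; on the human
#' (resp. denisovan) branch when the ancestor differs from that terminal
#' lineage only; on the chimpanzee branch when only the chimpanzee differs;
#' a site where human and Denisovan both differ from the ancestor but
#' disagree with each other is `excluded`. Heterozygous Denisovan genotypes
#' are resolved by a random draw of one allele (`hetDraw`).
#'
#' @param anc,hum,den1,den2,chimp character vectors of bases (vectorised).
#' @param hetDraw logical vector: pick haplotype 1 at heterozygous sites
#'   (defaults to fresh random draws).
#' @return Factor with levels chimpanzee, hominini, human, denisovan,
#'   none, excluded.
#' @examples
#' assignBranch("A", "G", "G", "G", "A")   # hominini
#' assignBranch("A", "G", "A", "A", "A")   # human
#' @export
assignBranch <- function(anc, hum, den1, den2, chimp, hetDraw = NULL) {
  n <- length(anc)
  if (is.null(hetDraw)) hetDraw <- runif(n) < 0.5
  den <- ifelse(den1 == den2, den1, ifelse(hetDraw, den1, den2))
  dH <- hum != anc
  dD <- den != anc
  dC <- chimp != anc
  out <- rep("none", n)
  out[dC & !dH & !dD] <- "chimpanzee"
  out[dH & !dD] <- "human"
  out[!dH & dD] <- "denisovan"
  out[dH & dD & hum == den] <- "hominini"
  out[dH & dD & hum != den] <- "excluded"
  factor(out, levels = c(.BRANCHES, "none", "excluded"))
}

# Site-level classification of a quartet alignment at given positions.
# Returns a data.frame with the hominin-side branch label, an independent
# chimpanzee-mutation flag, and Denisovan homozygosity of the resolved
# genotype.
classifyQuartetSites <- function(chars, positions, hetDraw = NULL) {
  anc <- chars$ancestor[positions]
  hum <- chars$human[positions]
  d1 <- chars$denisovan1[positions]
  d2 <- chars$denisovan2[positions]
  ch <- chars$chimpanzee[positions]
  br <- assignBranch(anc, hum, d1, d2, ch, hetDraw)
  data.frame(pos = positions, branch = br,
             chimpMutated = ch != anc,
             denHom = d1 == d2)
}

# Split a QuartetAlignment's sequences into per-lineage character vectors.
quartetChars <- function(qa) {
  s <- qa@seqs
  setNames(lapply(seq_along(s),
                  function(i) strsplit(as.character(s[[i]]), "")[[1]]),
           names(s))
}

#' Motif loss rates per branch with stratification
#'
#' For each motif class, counts motifs lost along each branch of the
#' quartet phylogeny. A motif is lost on a branch as soon as one of its
#' comparison-informative sites carries a mutation assigned to that
#' branch; if a motif is mutated both on the hominini branch and on a
#' terminal branch, the loss is attributed to hominini. Terminal-branch
#' denominators are the motifs still intact at the human-Denisovan
#' ancestor (ancestral count minus hominini losses). Motifs with an
#' `excluded` site are dropped. Because Denisovan heterozygotes are
#' resolved at random, the whole count is repeated `repeats` times and
#' rates are averaged (their spread is reported as `sdLossRate`). Strata
#' are "all" plus within/outside each supplied interval track under the
#' any-overlap rule.
#'
#' @param qa a [QuartetAlignment-class] (or the list returned by
#'   `quartetChars`, for power users).
#' @param tier filter tier (see [applyFilter()]).
#' @param repeats number of heterozygote-resolution repeats (>= 1).
#' @param strata named list of `GRanges` tracks (defaults to the
#'   alignment's THE1 and hotspot tracks).
#' @param seed seed for the heterozygote draws.
#' @return A data.frame keyed by (motifClass, branch, stratum) with
#'   `nAncestral`, `nLost`, `lossRate`, `sdLossRate` and, for the
#'   denisovan branch, `homFraction` (share of denisovan-branch mutated
#'   sites with a derived/derived genotype).
#' @export
computeLossRates <- function(qa, tier = "F2", repeats = 100L,
                             strata = NULL, seed = 1L) {
  stopifnot(repeats >= 1L)
  if (is.null(strata))
    strata <- list(THE1 = qa@the1, hotspot = qa@hotspots)
  chars <- quartetChars(qa)
  siteMask <- applyFilter(qa@annotations, tier)
  motifs <- qa@motifs
  cls <- mcols(motifs)$motif_id
  pat <- hmMotif()                       # HM and CM share informative offsets
  keep <- motifFilterMask(motifs, siteMask, pat)
  motifs <- motifs[keep]
  cls <- cls[keep]
  nMot <- length(motifs)
  if (!nMot) stop("no motif passes the filter tier")
  off <- pat@comparisonInformative
  sitePos <- as.vector(vapply(start(motifs), function(s) s + off - 1L,
                              integer(length(off))))
  motIdx <- rep(seq_len(nMot), each = length(off))

  # stratum membership per motif (any overlap)
  stratCols <- list(all = rep(TRUE, nMot))
  for (nm in names(strata))
    stratCols[[nm]] <- overlapsAny(motifs, strata[[nm]])

  isHet <- chars$denisovan1[sitePos] != chars$denisovan2[sitePos]
  accum <- list()
  withStream(seed, "loss-rates", {
    for (r in seq_len(repeats)) {
      draw <- runif(length(sitePos)) < 0.5
      cl <- classifyQuartetSites(chars, sitePos, draw)
      br <- as.character(cl$branch)
      excl <- vapply(split(br == "excluded", motIdx), any, logical(1))
      lostIn <- function(b) vapply(split(br == b, motIdx), any, logical(1))
      lHom <- lostIn("hominini")
      lHum <- lostIn("human") & !lHom
      lDen <- lostIn("denisovan") & !lHom
      lChi <- vapply(split(cl$chimpMutated, motIdx), any, logical(1))
      denMutSites <- br == "denisovan"

      rows <- list()
      for (mc in unique(cls)) for (st in names(stratCols)) {
        for (io in if (st == "all") "" else c("within", "outside")) {
          sel <- cls == mc & !excl &
            (if (io == "") TRUE
             else if (io == "within") stratCols[[st]]
             else !stratCols[[st]])
          nAnc <- sum(sel)
          nHD <- nAnc - sum(lHom & sel)
          stName <- if (st == "all") "all" else paste(io, st)
          for (b in .BRANCHES) {
            nA <- if (b %in% c("human", "denisovan")) nHD else nAnc
            nL <- sum(switch(b, chimpanzee = lChi, hominini = lHom,
                             human = lHum, denisovan = lDen) & sel)
            homFrac <- NA_real_
            if (b == "denisovan") {
              siteSel <- denMutSites & sel[motIdx]
              if (any(siteSel)) homFrac <- mean(cl$denHom[siteSel])
            }
            rows[[length(rows) + 1L]] <- data.frame(
              motifClass = mc, branch = b, stratum = stName,
              nAncestral = nA, nLost = nL,
              lossRate = if (nA > 0) nL / nA else NA_real_,
              homFraction = homFrac)
          }
        }
      }
      accum[[r]] <- do.call(rbind, rows)
    }
  })
  key <- function(df) paste(df$motifClass, df$branch, df$stratum, sep = "|")
  base <- accum[[1]]
  rateMat <- vapply(accum, function(df) df$lossRate, numeric(nrow(base)))
  rateMat <- matrix(rateMat, nrow = nrow(base))
  lostMat <- matrix(vapply(accum, function(df) as.numeric(df$nLost),
                           numeric(nrow(base))), nrow = nrow(base))
  nAncMat <- matrix(vapply(accum, function(df) as.numeric(df$nAncestral),
                           numeric(nrow(base))), nrow = nrow(base))
  homMat <- matrix(vapply(accum, function(df) df$homFraction,
                          numeric(nrow(base))), nrow = nrow(base))
  out <- base
  out$nAncestral <- rowMeans(nAncMat)
  out$nLost <- rowMeans(lostMat)
  out$lossRate <- rowMeans(rateMat)
  out$sdLossRate <- if (repeats > 1) apply(rateMat, 1, sd) else 0
  out$homFraction <- rowMeans(homMat)
  rownames(out) <- key(out)
  out
}

#' Two-proportion Z-test with continuity correction
#'
#' Pooled-variance normal-approximation test of equality of two
#' proportions with the Yates continuity correction -- the "proportion
#' test" used throughout the loss-rate comparisons. The squared statistic
#' equals the Yates-corrected chi-square of `stats::prop.test`.
#'
#' @param x1,n1 successes and trials in group 1.
#' @param x2,n2 successes and trials in group 2.
#' @return A list of class `htest` with `statistic` (z) and `p.value`
#'   (two-sided, clipped to [0, 1]).
#' @examples
#' proportionTest(9, 134, 70, 4102)
#' @export
proportionTest <- function(x1, n1, x2, n2) {
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  num <- abs(p1 - p2) - (1 / n1 + 1 / n2) / 2
  num <- max(0, num)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (se > 0) num / se else 0
  p <- min(1, max(0, 2 * pnorm(-z)))
  structure(list(statistic = c(z = z), p.value = p,
                 estimate = c(p1 = p1, p2 = p2),
                 method = "two-proportion Z-test with continuity correction",
                 data.name = sprintf("%d/%d vs %d/%d", x1, n1, x2, n2)),
            class = "htest")
}

#' Derived-allele frequencies of motif-site mutations
#'
#' For each queried site: if an allele-frequency record exists, the DAF of
#' the derived (ancestral-differing) allele is returned; if no record
#' exists and the reference sequence differs from the ancestral base, the
#' change is considered fixed (DAF = 1); if no record exists and the
#' reference still carries the ancestral base, no value is emitted. Records
#' whose alleles do not involve the ancestral base are flagged and skipped
#' (counted in the `mismatches` attribute, with a warning).
#'
#' @param sites data.frame with columns `pos` and `ancestralBase`.
#' @param af allele-frequency table with columns `chrom`, `pos`, `ref`,
#'   `alt`, `af` (AF of the `alt` allele).
#' @param refSeq reference sequence (character vector of bases, character
#'   scalar or `DNAString`).
#' @param chrom chromosome of the queried sites.
#' @return data.frame with `pos`, `daf`, `status` in
#'   polymorphic/fixed/intact/mismatch; attribute `mismatches`.
#' @export
extractDaf <- function(sites, af, refSeq, chrom = "chr1") {
  if (is(refSeq, "DNAString")) refSeq <- as.character(refSeq)
  if (is.character(refSeq) && length(refSeq) == 1L)
    refSeq <- strsplit(refSeq, "")[[1]]
  af <- af[af$chrom == chrom, , drop = FALSE]
  idx <- match(sites$pos, af$pos)
  daf <- rep(NA_real_, nrow(sites))
  status <- rep("intact", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    ancB <- sites$ancestralBase[i]
    j <- idx[i]
    if (!is.na(j)) {
      if (af$ref[j] == ancB && af$alt[j] != ancB) {
        daf[i] <- af$af[j]; status[i] <- "polymorphic"
      } else if (af$alt[j] == ancB && af$ref[j] != ancB) {
        daf[i] <- 1 - af$af[j]; status[i] <- "polymorphic"
      } else {
        status[i] <- "mismatch"
      }
    } else if (refSeq[sites$pos[i]] != ancB) {
      daf[i] <- 1; status[i] <- "fixed"
    }
  }
  nm <- sum(status == "mismatch")
  if (nm) warning(nm, " allele-frequency records mismatched and skipped")
  out <- data.frame(pos = sites$pos, daf = daf, status = status)
  attr(out, "mismatches") <- nm
  out
}

# Piecewise-linear cumulative map (cM) at 0-based coordinate x; rate is
# valid from each stated position to the next (HapMap convention).
.cumMapAt <- function(map, x) {
  stats::approx(map$Position, map$Map, xout = x, rule = 2)$y
}

#' Mean recombination rate over intervals
#'
#' bp-weighted mean rate (cM/Mb) of a HapMap-convention map over 1-based
#' closed intervals; spans outside the map contribute zero rate.
#'
#' @param map data.frame with `Position` (0-based bp) and `Map` (cM); the
#'   rate is implied by the piecewise-linear cumulative map.
#' @param start,end 1-based closed interval bounds (vectorised).
#' @return Mean rates in cM/Mb.
#' @examples
#' m <- data.frame(Position = c(0, 1000, 2000), Rate = c(2, 0, 0),
#'                 Map = c(0, 0.002, 0.002))
#' meanMapRate(m, 501, 1500)   # 1.0
#' @export
meanMapRate <- function(map, start, end) {
  stopifnot(all(end >= start))
  (.cumMapAt(map, end) - .cumMapAt(map, start - 1)) * 1e6 / (end - start + 1)
}

#' Local recombination rate at motif positions
#'
#' bp-weighted mean rate over a window (default 2 kb) centered on each
#' motif midpoint -- the covariate X of the proportional conversion model.
#'
#' @param map HapMap-convention map (see [meanMapRate()]).
#' @param motifs `GRanges` of motif loci (or numeric midpoints).
#' @param window window width in bp.
#' @return Numeric vector of rates (cM/Mb).
#' @export
motifLocalRates <- function(map, motifs, window = 2000L) {
  mid <- if (is.numeric(motifs)) motifs
         else (start(motifs) + end(motifs)) %/% 2L
  meanMapRate(map, mid - window %/% 2L + 1L, mid + window %/% 2L)
}

#' Tercile stratification of per-motif rates
#'
#' Splits motifs into three equal-size groups by local rate; ties are
#' broken by input (position) order so the split is deterministic.
#'
#' @param rates per-motif rates.
#' @return Integer vector in 1..3 (1 = lowest tercile).
#' @export
rateTerciles <- function(rates) {
  rk <- rank(rates, ties.method = "first")
  as.integer(cut(rk, breaks = 3, labels = FALSE))
}

#' Mean recombination profile around anchors
#'
#' Averages the recombination rate in overlapping windows (default 2 kb
#' wide, 1 kb step) at fixed offsets around a set of anchor loci, with a
#' normal-approximation 95% confidence band across anchors.
#'
#' @param anchors `GRanges` (midpoints are used) or numeric positions.
#' @param map HapMap-convention map (see [meanMapRate()]).
#' @param halfSpan profile half-width in bp.
#' @param window,step window width and step in bp.
#' @return data.frame with `offset` (window center relative to anchor),
#'   `mean`, `lo`, `hi`, `n`.
#' @export
recombProfile <- function(anchors, map, halfSpan = 10000L, window = 2000L,
                          step = 1000L) {
  mid <- if (is.numeric(anchors)) anchors
         else (start(anchors) + end(anchors)) %/% 2L
  if (!length(mid)) stop("empty anchor set")
  centers <- seq(-halfSpan + window / 2, halfSpan - window / 2, by = step)
  vals <- vapply(centers, function(cc) {
    s <- mid + cc - window / 2 + 1
    e <- mid + cc + window / 2
    meanMapRate(map, pmax(s, 1), pmax(e, 1))
  }, numeric(length(mid)))
  vals <- matrix(vals, nrow = length(mid))
  mu <- colMeans(vals)
  se <- apply(vals, 2, sd) / sqrt(length(mid))
  data.frame(offset = centers, mean = mu,
             lo = mu - 1.96 * se, hi = mu + 1.96 * se, n = length(mid))
}
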