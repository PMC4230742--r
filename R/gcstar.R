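# Equilibrium GC content (GC*) from branch-assigned substitution counts.

#' Per-branch substitution counts after CpG masking
#'
#' @slot branch branch label.
#' @slot nWS,nSW numbers of W-to-S (A/T to G/C) and S-to-W substitutions.
#' @slot nAT,nGC numbers of W and S bases at the branch's ancestral node
#'   (the substitution opportunities).
#' @export
setClass("SubstitutionCounts", representation(
  branch = "character", nWS = "numeric", nSW = "numeric",
  nAT = "numeric", nGC = "numeric"))

setValidity("SubstitutionCounts", function(object) {
  if (any(c(object@nWS, object@nSW, object@nAT, object@nGC) < 0))
    return("counts must be non-negative")
  if (object@nWS > 2 * object@nAT) return("nWS exceeds opportunities")
  TRUE
})

setMethod("show", "SubstitutionCounts", function(object) {
  cat(sprintf("SubstitutionCounts [%s]: %g WS / %g AT, %g SW / %g GC; GC* = %.4f\n",
              object@branch, object@nWS, object@nAT, object@nSW,
              object@nGC, gcStar(object)))
})

#' CpG site mask for an alignment
#'
#' GC* estimates are biased by hypermutable CpG sites, so all potential
#' CpGs are discarded: a position is masked if it carries a G preceded by
#' a C, or a C followed by a G, in at least one of the aligned sequences.
#'
#' @param seqs a `DNAStringSet`, list of equal-length character vectors, or
#'   character vector of sequences (one per lineage).
#' @return Logical mask, TRUE at masked positions (length = alignment
#'   width; empty alignment gives an empty mask).
#' @examples
#' maskCpg(c(a = "ACGT", b = "AAAT"))
#' @export
maskCpg <- function(seqs) {
  if (is(seqs, "DNAStringSet"))
    seqs <- lapply(seq_along(seqs),
                   function(i) strsplit(as.character(seqs[[i]]), "")[[1]])
  if (is.character(seqs)) seqs <- lapply(seqs, function(s) strsplit(s, "")[[1]])
  L <- length(seqs[[1]])
  if (L == 0L) return(logical(0))
  anyC <- Reduce(`|`, lapply(seqs, function(s) s == "C"))
  anyG <- Reduce(`|`, lapply(seqs, function(s) s == "G"))
  prevC <- c(FALSE, anyC[-L])      # preceding site is C in >= 1 sequence
  nextG <- c(anyG[-1L], FALSE)     # following site is G in >= 1 sequence
  (anyG & prevC) | (anyC & nextG)
}

#' Count W/S substitutions along one branch
#'
#' Classifies every passing, CpG-unmasked site of a quartet alignment (see
#' [assignBranch()]) and tallies, for the requested branch, the W-to-S and
#' S-to-W substitutions together with the W and S base counts at the
#' branch's ancestral node (the human-chimpanzee ancestor for the
#' chimpanzee and hominini branches; the human-Denisovan ancestor --
#' i.e. the ancestor updated with hominini-derived changes -- for the
#' terminal branches). Denisovan heterozygotes are resolved by one random
#' draw under `seed`.
#'
#' @param qa a [QuartetAlignment-class].
#' @param branch one of chimpanzee, hominini, human, denisovan.
#' @param tier filter tier, or `NA` to keep all sites.
#' @param cpgMask logical mask from [maskCpg()] (computed if `NULL`); pass
#'   `FALSE` to disable masking.
#' @param seed heterozygote-resolution seed.
#' @return A [SubstitutionCounts-class].
#' @export
countSubstitutions <- function(qa, branch = "human", tier = "F2",
                               cpgMask = NULL, seed = 1L) {
  branch <- match.arg(branch, .BRANCHES)
  chars <- quartetChars(qa)
  L <- length(chars$ancestor)
  pass <- if (is.na(tier)) rep(TRUE, L) else applyFilter(qa@annotations, tier)
  if (is.null(cpgMask)) cpgMask <- maskCpg(chars)
  if (identical(cpgMask, FALSE)) cpgMask <- logical(L)
  keep <- which(pass & !cpgMask)
  cl <- withStream(seed, "gcstar-het",
                   classifyQuartetSites(chars, keep))
  br <- as.character(cl$branch)
  anc <- chars$ancestor[keep]
  hum <- chars$human[keep]
  # ancestral node of the terminal branches: HC ancestor updated with
  # hominini-derived changes
  ancNode <- if (branch %in% c("human", "denisovan"))
    ifelse(br == "hominini", hum, anc) else anc
  derived <- switch(branch,
                    chimpanzee = chars$chimpanzee[keep],
                    hominini = hum,
                    human = hum,
                    denisovan = ifelse(cl$denHom, chars$denisovan1[keep],
                                       chars$denisovan1[keep]))
  if (branch == "denisovan") {
    # resolved genotype: classifyQuartetSites already drew one allele; redo
    # the draw deterministically for the derived base
    derived <- withStream(seed, "gcstar-het", {
      d1 <- chars$denisovan1[keep]; d2 <- chars$denisovan2[keep]
      drw <- runif(length(keep)) < 0.5
      ifelse(d1 == d2, d1, ifelse(drw, d1, d2))
    })
  }
  isSub <- if (branch == "chimpanzee") cl$chimpMutated else br == branch
  strong <- c("C", "G")
  wAnc <- !(ancNode %in% strong)
  sAnc <- ancNode %in% strong
  ws <- sum(isSub & wAnc & derived %in% strong)
  sw <- sum(isSub & sAnc & !(derived %in% strong))
  new("SubstitutionCounts", branch = branch, nWS = ws, nSW = sw,
      nAT = sum(wAnc), nGC = sum(sAnc))
}

#' Equilibrium GC content from substitution fluxes
#'
#' `GC* = fWS / (fWS + fSW)` with per-base fluxes `fWS = nWS/nAT` and
#' `fSW = nSW/nGC`: the GC content at which the W-to-S and S-to-W
#' substitution flows balance. Undefined (NA) when either opportunity
#' count is zero or both fluxes vanish.
#'
#' @param x a [SubstitutionCounts-class], or `nWS` as a number.
#' @param nSW,nAT,nGC counts when `x` is numeric (vectorised).
#' @return GC* in [0, 1], or NA where undefined.
#' @examples
#' gcStar(10, 5, 1000, 500)   # equal per-base fluxes: 0.5
#' @export
gcStar <- function(x, nSW = NULL, nAT = NULL, nGC = NULL) {
  if (is(x, "SubstitutionCounts"))
    return(gcStar(x@nWS, x@nSW, x@nAT, x@nGC))
  nWS <- x
  fWS <- ifelse(nAT > 0, nWS / nAT, NA_real_)
  fSW <- ifelse(nGC > 0, nSW / nGC, NA_real_)
  out <- fWS / (fWS + fSW)
  out[!is.na(fWS) & !is.na(fSW) & (fWS + fSW) == 0] <- NA_real_
  out
}

# Per-site substitution/opportunity indicators for one branch; internal
# workhorse shared by the profile and the windowed regression.
.siteFlux <- function(qa, branch, tier, seed, cpg = TRUE) {
  chars <- quartetChars(qa)
  L <- length(chars$ancestor)
  pass <- if (is.na(tier)) rep(TRUE, L) else applyFilter(qa@annotations, tier)
  cpg <- if (cpg) maskCpg(chars) else logical(L)
  ok <- pass & !cpg
  cl <- withStream(seed, "gcstar-het", classifyQuartetSites(chars, seq_len(L)))
  br <- as.character(cl$branch)
  anc <- chars$ancestor
  hum <- chars$human
  ancNode <- if (branch %in% c("human", "denisovan"))
    ifelse(br == "hominini", hum, anc) else anc
  derived <- switch(branch,
                    chimpanzee = chars$chimpanzee,
                    hominini = hum,
                    human = hum,
                    # same stream as the classification above, so the same
                    # allele is drawn at each heterozygous site
                    denisovan = withStream(seed, "gcstar-het", {
                      drw <- runif(L) < 0.5
                      ifelse(chars$denisovan1 == chars$denisovan2,
                             chars$denisovan1,
                             ifelse(drw, chars$denisovan1, chars$denisovan2))
                    }))
  isSub <- if (branch == "chimpanzee") cl$chimpMutated else br == branch
  strong <- c("C", "G")
  wAnc <- ok & !(ancNode %in% strong)
  sAnc <- ok & (ancNode %in% strong)
  cbind(ws = as.numeric(isSub & wAnc & derived %in% strong),
        sw = as.numeric(isSub & sAnc & !(derived %in% strong)),
        at = as.numeric(wAnc), gc = as.numeric(sAnc))
}

#' GC* profile around anchor loci
#'
#' Pools substitutions and opportunities across anchors at each offset
#' window before applying the flux-ratio estimator (ratio of pooled
#' counts, not mean of per-anchor ratios -- tiny windows rarely contain a
#' substitution, so per-anchor ratios would be mostly undefined). Dots are
#' `dotWindow`-bp bins; a smoothed track pools `smoothWindow`-bp bins.
#'
#' @param qa a [QuartetAlignment-class].
#' @param anchors `GRanges` (midpoints used) or numeric positions; defaults
#'   to the alignment's hotspot intervals.
#' @param branch branch to profile.
#' @param span half-width of the profile in bp.
#' @param dotWindow,smoothWindow pooling window widths in bp.
#' @param tier filter tier (`NA` keeps all sites).
#' @param cpg apply the CpG mask (disable to measure the raw mutational
#'   flux ratio, e.g. against a CpG-blind simulation truth).
#' @param seed heterozygote-resolution seed.
#' @return data.frame with `offset` (bin center), pooled counts, `gcstar`
#'   and `gcstarSmooth` (NA where a pooled window is empty).
#' @export
gcstarProfile <- function(qa, anchors = NULL, branch = "human",
                          span = 10000L, dotWindow = 10L,
                          smoothWindow = 500L, tier = "F2", cpg = TRUE,
                          seed = 1L) {
  if (is.null(anchors)) anchors <- qa@hotspots
  mid <- if (is.numeric(anchors)) anchors
         else (start(anchors) + end(anchors)) %/% 2L
  if (!length(mid)) stop("empty anchor set")
  flux <- .siteFlux(qa, match.arg(branch, .BRANCHES), tier, seed, cpg)
  L <- nrow(flux)
  nBins <- 2L * span %/% dotWindow
  acc <- matrix(0, nBins, 4L, dimnames = list(NULL, colnames(flux)))
  for (m in mid) {
    lo <- m - span; hi <- m + span - 1L
    idx <- max(1L, lo):min(L, hi)
    bin <- (idx - lo) %/% dotWindow + 1L
    ok <- bin >= 1L & bin <= nBins
    acc2 <- rowsum(flux[idx[ok], , drop = FALSE], bin[ok])
    acc[as.integer(rownames(acc2)), ] <- acc[as.integer(rownames(acc2)), ] +
      acc2
  }
  offset <- (seq_len(nBins) - 1L) * dotWindow - span + dotWindow / 2
  gcs <- gcStar(acc[, "ws"], acc[, "sw"], acc[, "at"], acc[, "gc"])
  # smooth by pooling dot bins
  fold <- max(1L, smoothWindow %/% dotWindow)
  grp <- (seq_len(nBins) - 1L) %/% fold + 1L
  accS <- rowsum(acc, grp)
  gcsS <- gcStar(accS[, "ws"], accS[, "sw"], accS[, "at"], accS[, "gc"])
  data.frame(offset = offset, nWS = acc[, "ws"], nSW = acc[, "sw"],
             nAT = acc[, "at"], nGC = acc[, "gc"], gcstar = gcs,
             gcstarSmooth = gcsS[grp])
}

#' Windowed GC* versus recombination rate
#'
#' Computes GC* (pooled counts) and the mean recombination rate in
#' consecutive genomic windows and regresses GC* on rate by ordinary least
#' squares.
#'
#' @param qa a [QuartetAlignment-class].
#' @param branch branch for the GC* estimates.
#' @param window window width in bp (the genome-scale convention is 1 Mb;
#'   scale down for short simulated chromosomes).
#' @param tier filter tier.
#' @param cpg apply the CpG mask.
#' @param seed heterozygote-resolution seed.
#' @return A list with `windows` (per-window table), `r2`, `p`, `slope`,
#'   `intercept` and the `lm` fit.
#' @export
windowedGcstarVsRecomb <- function(qa, branch = "human", window = 1000000L,
                                   tier = "F2", cpg = TRUE, seed = 1L) {
  flux <- .siteFlux(qa, match.arg(branch, .BRANCHES), tier, seed, cpg)
  L <- nrow(flux)
  win <- (seq_len(L) - 1L) %/% window + 1L
  acc <- rowsum(flux, win)
  wStart <- (as.integer(rownames(acc)) - 1L) * window + 1L
  wEnd <- pmin(wStart + window - 1L, L)
  gcs <- gcStar(acc[, "ws"], acc[, "sw"], acc[, "at"], acc[, "gc"])
  rate <- meanMapRate(qa@map, wStart, wEnd)
  ok <- !is.na(gcs)
  if (sum(ok) < 10L) stop("need at least 10 windows with defined GC*")
  if (var(rate[ok]) == 0 || var(gcs[ok]) == 0)
    stop("degenerate variance in windowed GC* regression")
  fit <- lm(gcs[ok] ~ rate[ok])
  sf <- summary(fit)
  list(windows = data.frame(start = wStart, end = wEnd, gcstar = gcs,
                            rate = rate),
       r2 = sf$r.squared, p = sf$coefficients[2, 4],
       slope = coef(fit)[[2]], intercept = coef(fit)[[1]], fit = fit)
}
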