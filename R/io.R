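# File formats (FASTA, BED, HapMap map, allele frequencies) and the
# pipeline driver. Internal coordinates are 1-based closed (GRanges);
# BED's 0-based half-open convention is converted at this boundary only.

.readLinesNoComment <- function(path) {
  ln <- readLines(path)
  keep <- !grepl("^#", ln) & !grepl("^track", ln) & nzchar(ln)
  list(lines = ln[keep], lineNo = which(keep))
}

#' Read sequences from a FASTA file
#'
#' Thin validating wrapper around `Biostrings::readDNAStringSet`; rejects
#' records containing letters outside A/C/G/T/N.
#'
#' @param path FASTA file.
#' @return A `DNAStringSet`.
#' @export
readFastaSequences <- function(path) {
  s <- readDNAStringSet(path)
  bad <- grepl("[^ACGTN]", as.character(s))
  if (any(bad))
    stop("non-ACGTN letters in FASTA record(s): ",
         paste(names(s)[bad], collapse = ", "))
  s
}

#' Read a BED file of intervals
#'
#' Accepts BED3/BED6; comment (`#`) and `track` lines are skipped.
#' Malformed lines are reported with their line numbers. Coordinates are
#' converted from 0-based half-open to the package's 1-based closed
#' `GRanges`.
#'
#' @param path BED file.
#' @return A `GRanges` with a `name` metadata column when present.
#' @export
readBed <- function(path) {
  rd <- .readLinesNoComment(path)
  if (!length(rd$lines))
    return(GRanges())
  fields <- strsplit(rd$lines, "\t")
  nf <- lengths(fields)
  bad <- which(nf < 3L)
  if (length(bad))
    stop("malformed BED line(s) ", paste(rd$lineNo[bad], collapse = ", "),
         " in ", path, ": fewer than 3 fields")
  chrom <- vapply(fields, `[[`, character(1), 1L)
  s0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  e0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  bad <- which(is.na(s0) | is.na(e0) | e0 <= s0 | s0 < 0)
  if (length(bad))
    stop("malformed BED line(s) ", paste(rd$lineNo[bad], collapse = ", "),
         " in ", path, ": invalid coordinates")
  gr <- GRanges(chrom, IRanges(s0 + 1L, e0),
                strand = if (all(nf >= 6L))
                  vapply(fields, `[[`, character(1), 6L) else "*")
  if (all(nf >= 4L))
    mcols(gr)$name <- vapply(fields, `[[`, character(1), 4L)
  gr
}

#' Write intervals as BED6
#'
#' @param gr a `GRanges`; the `name` or `motif_id` metadata column fills
#'   the name field.
#' @param path output file.
#' @param seed recorded in the provenance header.
#' @return The path, invisibly.
#' @export
writeBed <- function(gr, path, seed = NA) {
  nm <- if (!is.null(mcols(gr)$name)) mcols(gr)$name
        else if (!is.null(mcols(gr)$motif_id)) mcols(gr)$motif_id
        else rep(".", length(gr))
  st <- as.character(strand(gr))
  st[st == "*"] <- "."
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr),
                   name = nm, score = 0L, strand = st)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenanceHeader(seed), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a HapMap-convention recombination map
#'
#' Expects tab-separated columns Chromosome, Position(bp), Rate(cM/Mb),
#' Map(cM); each rate is valid from its stated position to the next
#' (positions are 0-based; off-by-one segment semantics silently corrupt
#' profiles, hence the strictness here). Positions must be sorted within
#' each chromosome.
#'
#' @param path map file.
#' @return data.frame with columns Chromosome, Position, Rate, Map.
#' @export
readRecombMap <- function(path) {
  rd <- .readLinesNoComment(path)
  df <- read.table(text = rd$lines, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  names(df) <- c("Chromosome", "Position", "Rate", "Map")[seq_along(df)]
  for (ch in unique(df$Chromosome)) {
    p <- df$Position[df$Chromosome == ch]
    if (is.unsorted(p, strictly = TRUE)) {
      at <- which(diff(p) <= 0)[1]
      stop("unsorted map positions for ", ch, " near data row ", at + 1L,
           " of ", path)
    }
  }
  df
}

#' @rdname readRecombMap
#' @param map map data.frame.
#' @param seed recorded in the provenance header.
#' @export
writeRecombMap <- function(map, path, seed = NA) {
  writeTsvWithHeader(map, path, seed)
}

#' Read allele frequencies (TSV or minimal VCF)
#'
#' Accepts either a 5-column TSV (chrom, pos, ref, alt, af) or a minimal
#' VCF whose INFO field carries `AF=`. Positions are 1-based in both
#' dialects.
#'
#' @param path input file.
#' @return data.frame with columns chrom, pos, ref, alt, af.
#' @export
readAfTable <- function(path) {
  ln <- readLines(path, n = 50L)
  isVcf <- any(grepl("^##fileformat=VCF", ln)) || any(grepl("^#CHROM", ln))
  if (isVcf) {
    body <- readLines(path)
    body <- body[!grepl("^#", body) & nzchar(body)]
    if (!length(body))
      return(data.frame(chrom = character(), pos = integer(),
                        ref = character(), alt = character(), af = numeric()))
    f <- strsplit(body, "\t")
    info <- vapply(f, `[[`, character(1), 8L)
    afm <- regmatches(info, regexpr("AF=[0-9.eE+-]+", info))
    af <- suppressWarnings(as.numeric(sub("AF=", "", afm)))
    data.frame(chrom = vapply(f, `[[`, character(1), 1L),
               pos = as.integer(vapply(f, `[[`, character(1), 2L)),
               ref = vapply(f, `[[`, character(1), 4L),
               alt = vapply(f, `[[`, character(1), 5L),
               af = af, stringsAsFactors = FALSE)
  } else {
    rd <- .readLinesNoComment(path)
    df <- read.table(text = rd$lines, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    names(df) <- c("chrom", "pos", "ref", "alt", "af")[seq_along(df)]
    df
  }
}

#' Write a simulated quartet alignment to disk
#'
#' Emits the study's input formats: one FASTA with a record per lineage,
#' BED6 files for motifs, hotspots and THE1-like intervals, the HapMap
#' recombination map, the allele-frequency table, the per-site annotation
#' track and the truth table. Every text file carries a provenance header.
#'
#' @param qa a [QuartetAlignment-class].
#' @param dir output directory (created if needed).
#' @return Named vector of written paths, invisibly.
#' @export
writeQuartetAlignment <- function(qa, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  seed <- qa@config@seed
  paths <- c(fasta = file.path(dir, "quartet.fasta"),
             motifs = file.path(dir, "motifs.bed"),
             hotspots = file.path(dir, "hotspots.bed"),
             the1 = file.path(dir, "the1.bed"),
             map = file.path(dir, "map.tsv"),
             af = file.path(dir, "af.tsv"),
             annotations = file.path(dir, "annotations.tsv"),
             truth = file.path(dir, "truth.tsv"))
  s <- qa@seqs
  names(s) <- paste0(names(s), " hotspotErosion seed=", seed)
  writeXStringSet(s, paths["fasta"])
  writeBed(qa@motifs, paths["motifs"], seed)
  writeBed(qa@hotspots, paths["hotspots"], seed)
  writeBed(qa@the1, paths["the1"], seed)
  writeRecombMap(qa@map, paths["map"], seed)
  writeTsvWithHeader(qa@afTable, paths["af"], seed)
  writeTsvWithHeader(as.data.frame(qa@annotations), paths["annotations"],
                     seed)
  writeTsvWithHeader(qa@truth, paths["truth"], seed)
  invisible(paths)
}

#' Run the full synthetic pipeline
#'
#' Chains the stages on one simulated chromosome: simulate, scan motifs on
#' the ancestor, filter, compute loss rates, extract DAFs for human-branch
#' motif mutations, fit the conversion model to the resulting paired
#' spectrum, profile GC* around hotspots, and predict motif loss from the
#' proportional model. If the allele-frequency table is empty, the DAF and
#' fit stages are skipped and the rest completes. Artifacts can be written
#' with provenance headers via `outDir`.
#'
#' @param config a [simConfig()].
#' @param outDir optional output directory.
#' @param tier filter tier.
#' @param m spectrum bins above 0.01 (small by default: pipeline spectra
#'   hold only hundreds of mutations).
#' @param repeats heterozygote-resolution repeats for the loss rates.
#' @param verbose print stage timings and record counts.
#' @return A list with elements `qa`, `scanHM`, `scanCM`, `lossRates`,
#'   `dafHM`, `dafCM`, `spectrum`, `fit`, `gcstarProfile`, `lossPrediction`
#'   (NULL where skipped) and `timings`.
#' @export
runPipeline <- function(config, outDir = NULL, tier = "F2", m = 5L,
                        repeats = 20L, verbose = FALSE) {
  res <- list()
  tic <- function() proc.time()[["elapsed"]]
  timings <- c()
  stage <- function(name, expr) {
    t0 <- tic()
    out <- force(expr)
    timings[[name]] <<- round(tic() - t0, 3)
    if (verbose) message(sprintf("[%s] %.2fs", name, timings[[name]]))
    out
  }

  res$qa <- stage("simulate", simulateQuartetAlignment(config))
  qa <- res$qa
  anc <- as.character(qa@seqs[["ancestor"]])
  res$scanHM <- stage("scan", scanMotifs(c(chr1 = anc), hmMotif()))
  res$scanCM <- scanMotifs(c(chr1 = anc), cmMotif())
  res$lossRates <- stage("lossrates",
                         computeLossRates(qa, tier = tier, repeats = repeats,
                                          seed = config@seed))

  haveAf <- nrow(qa@afTable) > 0L
  if (haveAf) {
    chars <- quartetChars(qa)
    cl <- withStream(config@seed, "pipeline-class",
                     classifyQuartetSites(chars, seq_along(chars$ancestor)))
    humanSites <- which(as.character(cl$branch) == "human")
    dafFor <- function(class) {
      mot <- qa@motifs[mcols(qa@motifs)$motif_id == class]
      off <- hmMotif()@comparisonInformative
      inf <- as.vector(vapply(start(mot), function(s) s + off - 1L,
                              integer(length(off))))
      sites <- intersect(humanSites, inf)
      if (!length(sites)) return(data.frame(pos = integer(), daf = numeric(),
                                            status = character()))
      extractDaf(data.frame(pos = sites,
                            ancestralBase = chars$ancestor[sites]),
                 qa@afTable, chars$human)
    }
    res$dafHM <- stage("daf", dafFor("HM"))
    res$dafCM <- dafFor("CM")
    edges <- dafBinEdges(config@nChrom, m)
    kT <- binDafCounts(res$dafHM$daf, edges)
    kN <- binDafCounts(res$dafCM$daf, edges)
    res$spectrum <- dafSpectrum(kN, kT, edges, config@nChrom,
                                fixedNeutral = attr(kN, "fixed"),
                                fixedTest = attr(kT, "fixed"),
                                lNeutral = config@lCM, lTest = config@lHM)
    res$fit <- stage("fit-dbgc", fitDbgc(res$spectrum, ci = FALSE))
  } else {
    message("allele-frequency table empty: DAF and fit stages skipped")
    res$dafHM <- res$dafCM <- res$spectrum <- res$fit <- NULL
  }

  res$gcstarProfile <- stage("gcstar",
                             gcstarProfile(qa, branch = "human", tier = tier,
                                           seed = config@seed))

  rates <- motifLocalRates(qa@map,
                           qa@motifs[mcols(qa@motifs)$motif_id == "HM"])
  res$rateFit <- fitGammaToRates(rates)
  res$lossPrediction <- stage("lifespan", {
    gd <- gDistribution(shape = res$rateFit$shape,
                        mean = if (!is.null(res$fit) && res$fit@gHat > 0)
                          res$fit@gHat else res$rateFit$mean,
                        rateMean = res$rateFit$mean,
                        zeroFraction = res$rateFit$zeroFraction)
    data.frame(quantity = c("overall", "top8pct"),
               lossFraction = c(expectedLossFraction(gd),
                                expectedLossFraction(gd,
                                                     quantileRange = c(0.92, 1))))
  })
  res$timings <- timings

  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    writeQuartetAlignment(qa, file.path(outDir, "inputs"))
    writeTsvWithHeader(res$lossRates, file.path(outDir, "loss_rates.tsv"),
                       config@seed)
    if (haveAf) {
      writeTsvWithHeader(res$dafHM, file.path(outDir, "daf_hm.tsv"),
                         config@seed)
      writeTsvWithHeader(res$dafCM, file.path(outDir, "daf_cm.tsv"),
                         config@seed)
      fitDf <- data.frame(gHat = res$fit@gHat, lnL = res$fit@lnL,
                          lnLM0 = res$fit@lnLM0, lrt = res$fit@lrt,
                          pLrt = res$fit@pLrt)
      writeTsvWithHeader(fitDf, file.path(outDir, "fit.tsv"), config@seed)
    }
    writeTsvWithHeader(res$gcstarProfile,
                       file.path(outDir, "gcstar_profile.tsv"), config@seed)
    writeTsvWithHeader(res$lossPrediction,
                       file.path(outDir, "loss_prediction.tsv"),
                       config@seed)
  }
  res
}
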