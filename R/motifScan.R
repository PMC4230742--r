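# Degenerate motif scanning on DNA sequences.

#' Locate degenerate motifs in sequences
#'
#' Scans one or more DNA sequences for a degenerate motif (N in the pattern
#' matches any of A/C/G/T; N or gap characters in the subject never match).
#' Both strands are scanned by default -- the motif is non-palindromic and
#' its discovery considered both orientations. All overlapping occurrences
#' are reported; duplicate loci (same sequence, start and end) are
#' collapsed keeping the plus-strand hit.
#'
#' @param seqs a `DNAStringSet`, a single `DNAString`, or a named character
#'   vector of sequences.
#' @param pattern a [MotifPattern-class] (see [hmMotif()], [cmMotif()]) or a
#'   plain pattern string.
#' @param strands `"both"` (default) or `"plus"`.
#' @return A `GRanges`, 1-based closed coordinates, sorted by
#'   (seqnames, start), with metadata columns `motif_id` and
#'   `matched_sequence` (as read on the reported strand).
#' @examples
#' scanMotifs(c(chr1 = "CCTCCCTAACCACGGG"), hmMotif())
#' @export
scanMotifs <- function(seqs, pattern, strands = c("both", "plus")) {
  strands <- match.arg(strands)
  if (is(pattern, "MotifPattern")) {
    pat <- pattern@pattern
    motifId <- pattern@motifId
  } else {
    pat <- as.character(pattern)
    motifId <- pat
  }
  if (grepl("[^ACGTN]", pat)) stop("pattern letters must be A/C/G/T/N")
  if (is.character(seqs)) {
    if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
    seqs <- DNAStringSet(seqs)
  }
  if (is(seqs, "DNAString")) seqs <- DNAStringSet(setNames(list(seqs), "seq1"))
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))

  pfwd <- DNAString(pat)
  prev <- reverseComplement(pfwd)
  hits <- list()
  for (i in seq_along(seqs)) {
    subj <- seqs[[i]]
    nm <- names(seqs)[i]
    if (length(subj) == 0L) next
    # fixed="subject": ambiguity codes expanded in the pattern only, the
    # subject is read literally, so subject N never matches a concrete base.
    fw <- matchPattern(pfwd, subj, fixed = "subject")
    if (length(fw))
      hits[[length(hits) + 1L]] <- data.frame(
        chrom = nm, start = BiocGenerics::start(fw), end = BiocGenerics::end(fw),
        strand = "+", seq = as.character(fw))
    if (strands == "both") {
      rv <- matchPattern(prev, subj, fixed = "subject")
      if (length(rv))
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = nm, start = BiocGenerics::start(rv), end = BiocGenerics::end(rv),
          strand = "-",
          seq = as.character(reverseComplement(DNAStringSet(rv))))
    }
  }
  if (!length(hits)) {
    gr <- GRanges()
    mcols(gr)$motif_id <- character()
    mcols(gr)$matched_sequence <- character()
    return(gr)
  }
  df <- do.call(rbind, hits)
  # subject N (or any non-ACGT letter) never matches, defensively re-checked
  keep <- !grepl("[^ACGT]", df$seq)
  df <- df[keep, , drop = FALSE]
  # collapse duplicate loci, preferring the + strand
  df <- df[order(df$chrom, df$start, df$end, df$strand), , drop = FALSE]
  dup <- duplicated(df[, c("chrom", "start", "end")])
  df <- df[!dup, , drop = FALSE]
  gr <- GRanges(df$chrom, IRanges(df$start, df$end), strand = df$strand)
  mcols(gr)$motif_id <- rep(motifId, nrow(df))
  mcols(gr)$matched_sequence <- df$seq
  sort(gr, ignore.strand = TRUE)
}
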