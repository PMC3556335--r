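#' Paired-end insert geometry
#'
#' Converts a sequencing library's fragment (insert) size distribution into
#' the geometry of the unsequenced spacer between the two mates, the value a
#' spliced read aligner takes as its mate-inner-distance parameter.  With
#' 100-bp reads and the library's estimated 310-bp mean insert this gives
#' the 110-bp mean spacer (the standard deviation is unchanged by the
#' constant shift).
#'
#' @param fragment_mean Mean fragment (insert) size in bp.
#' @param fragment_sd Standard deviation of the fragment size in bp.
#' @param read_length Read length in bp (both mates equal).
#' @return A list with `spacer_mean` and `spacer_sd` (bp).
#' @examples
#' estimateInsertGeometry(310, 189, 100)  # spacer_mean 110, spacer_sd 189
#' @export
estimateInsertGeometry <- function(fragment_mean, fragment_sd, read_length) {
  stopifnot(is.numeric(fragment_mean), is.numeric(fragment_sd),
            is.numeric(read_length), fragment_sd >= 0, read_length > 0)
  if (fragment_mean < 2 * read_length)
    stop("fragment_mean (", fragment_mean, ") < 2 * read_length (",
         2 * read_length, "): overlapping mates are unsupported")
  list(spacer_mean = fragment_mean - 2 * read_length,
       spacer_sd = fragment_sd)
}

#' Per-base coverage from spliced alignments
#'
#' Depth at a base is the number of alignment blocks overlapping it.
#'
#' @param alignments A [SplicedAlignments-class] object.
#' @param genome A named [Biostrings::DNAStringSet] (chromosome lengths are
#'   taken from it); alternatively a named integer vector of lengths.
#' @return An [IRanges::RleList] of per-base depths, one run-length encoded
#'   track per chromosome (every chromosome of the genome is present).
#' @export
coverageFromAlignments <- function(alignments, genome) {
  lens <- if (is.numeric(genome)) {
    stats::setNames(as.integer(genome), names(genome))
  } else {
    stats::setNames(Biostrings::width(genome), names(genome))
  }
  blocks <- unlist(alnBlocks(alignments), use.names = FALSE)
  if (length(blocks)) {
    bad <- !as.character(seqnames(blocks)) %in% names(lens) |
      start(blocks) < 1L | end(blocks) > lens[as.character(seqnames(blocks))]
    if (any(bad))
      stop(sum(bad), " alignment block(s) outside chromosome bounds")
    blocks <- GRanges(factor(as.character(seqnames(blocks)), names(lens)),
                      ranges(blocks))
    seqlengths(blocks) <- lens
    coverage(blocks)
  } else {
    coverage(GRanges(seqlengths = lens))
  }
}

#' Classify genome bases covered above a depth threshold
#'
#' Every base covered by at least `min_depth` alignments is assigned exactly
#' one feature class: `annotated_exon` if it falls in any annotated exon,
#' else `intron` if it falls within a transcript span on the same
#' chromosome, else `intergenic`.  Exon precedence makes the accounting
#' mutually exclusive for bases exonic in one isoform and intronic in
#' another.
#'
#' @param track An [IRanges::RleList] per-base depth track (from
#'   [coverageFromAlignments()]).
#' @param annotation A [TranscriptModels-class] object on the same genome.
#' @param min_depth Depth threshold (default 3; results are typically robust
#'   to raising it to 6 or 10).
#' @return A list with `total_covered`, a named vector `counts` over the
#'   classes, `fractions` (counts / total, `NaN`-free only when total > 0),
#'   and `genome_fraction` (total covered / genome length).
#' @export
classifyCoveredBases <- function(track, annotation, min_depth = 3L) {
  covered <- IRanges::slice(track, lower = min_depth, rangesOnly = TRUE)
  coveredGr <- GRanges(rep(names(covered), lengths(covered)),
                       unlist(covered, use.names = FALSE))
  total <- sum(sum(width(covered)))

  exons <- reduce(unlist(exonRanges(annotation), use.names = FALSE),
                  ignore.strand = TRUE)
  spans <- reduce(txSpans(annotation), ignore.strand = TRUE)

  exonBases <- sum(width(GenomicRanges::intersect(coveredGr, exons,
                                                  ignore.strand = TRUE)))
  spanBases <- sum(width(GenomicRanges::intersect(coveredGr, spans,
                                                  ignore.strand = TRUE)))
  intronBases <- spanBases - exonBases
  intergenicBases <- total - spanBases

  counts <- c(annotated_exon = exonBases, intron = intronBases,
              intergenic = intergenicBases)
  genomeLen <- sum(vapply(track, length, numeric(1)))
  list(total_covered = total,
       counts = counts,
       fractions = if (total > 0) counts / total else counts * NA_real_,
       genome_fraction = total / genomeLen)
}
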