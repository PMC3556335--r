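#' Read spliced contig alignments from extended BED12
#'
#' The dialect is BED12 plus two extension columns: column 13 carries the
#' alignment identity (matches / aligned columns) and column 14 the fraction
#' of the contig covered by the record, both in `[0, 1]`.  The BED `name`
#' column holds the contig id; a contig aligned in several segments (a
#' chimera candidate) appears as several records with the same name, and
#' segments are numbered in file order.  BED half-open 0-based blocks are
#' converted to 1-based closed ranges on input.
#'
#' @param path Path to the BED12(+2) file.
#' @param contigs Optional [Biostrings::DNAStringSet] of contig sequences;
#'   when the extension columns are absent, identity defaults to `NA` and
#'   coverage is recomputed as aligned block length / contig length.
#' @return A [SplicedAlignments-class] object.
#' @export
readSplicedBed12 <- function(path, contigs = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  nCol <- length(strsplit(first, "\t", fixed = TRUE)[[1L]])
  extra <- if (nCol >= 14L)
    c(identity = "numeric", coverage = "numeric")
  else character()
  gr <- rtracklayer::import(path, format = "bed", extraCols = extra)
  if (is.null(gr$blocks))
    stop("not a BED12 file (blockCount/blockSizes/blockStarts missing): ", path)

  blocks <- GRangesList(lapply(seq_along(gr), function(i) {
    rel <- gr$blocks[[i]]           # 1-based relative to chromStart
    GRanges(seqnames(gr)[i],
            IRanges::shift(rel, start(gr)[i] - 1L),
            strand = strand(gr)[i])
  }))
  seg <- stats::ave(seq_along(gr), as.character(gr$name), FUN = seq_along)
  identity <- if (nCol >= 14L) gr$identity else rep(NA_real_, length(gr))
  coverage <- if (nCol >= 14L) {
    gr$coverage
  } else if (!is.null(contigs)) {
    alnLen <- vapply(blocks, function(b) sum(width(b)), numeric(1))
    ctgLen <- Biostrings::width(contigs)[match(as.character(gr$name), names(contigs))]
    pmin(1, alnLen / ctgLen)
  } else {
    rep(NA_real_, length(gr))
  }
  info <- DataFrame(
    contig_id = as.character(gr$name),
    segment = as.integer(seg),
    chrom = as.character(seqnames(gr)),
    strand = as.character(strand(gr)),
    identity = as.numeric(identity),
    coverage = as.numeric(coverage)
  )
  SplicedAlignments(blocks, info)
}

#' Write spliced alignments to extended BED12
#'
#' Inverse of [readSplicedBed12()]: blocks are emitted in the native BED
#' 0-based half-open convention, with identity and coverage as columns 13-14.
#' `readSplicedBed12(writeSplicedBed12(x))` reproduces `x` on canonical
#' records.
#'
#' @param x A [SplicedAlignments-class] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeSplicedBed12 <- function(x, path) {
  info <- alnInfo(x)
  blocks <- alnBlocks(x)
  lines <- vapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    chromStart <- min(start(b)) - 1L            # to 0-based
    chromEnd <- max(end(b))
    sizes <- width(b)
    starts <- start(b) - 1L - chromStart
    paste(info$chrom[i], chromStart, chromEnd, info$contig_id[i], 0L,
          info$strand[i], chromStart, chromEnd, "0,0,0", length(b),
          paste0(paste(sizes, collapse = ","), ","),
          paste0(paste(starts, collapse = ","), ","),
          format(info$identity[i], digits = 10),
          format(info$coverage[i], digits = 10),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
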