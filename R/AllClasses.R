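#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<- queryHits subjectHits
#' @importFrom IRanges IRanges ranges width start end "start<-" "end<-"
#' @importFrom GenomicRanges GRanges GRangesList seqnames strand "strand<-"
#'   granges findOverlaps countOverlaps reduce gaps pintersect coverage
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels seqnames
#' @importFrom BiocGenerics unlist relist sort range
#' @importFrom S4Vectors split
NULL

#' Transcript models of an annotated genome
#'
#' Container for the exon/CDS structure of every annotated transcript, the
#' transcript-to-gene map, and annotated repeat intervals.  All ranges are
#' 1-based closed [GenomicRanges::GRanges] on the reference genome; GFF3 input
#' is converted at the boundary by [readAnnotationGff3()].
#'
#' @slot exons [GenomicRanges::GRangesList], one element per transcript
#'   (named by transcript id), exons sorted by start and non-overlapping.
#' @slot cds [GenomicRanges::GRangesList] parallel to `exons`; zero-length
#'   elements for non-coding transcripts.  Each CDS piece lies within the
#'   transcript's exon union and the spliced CDS length is a multiple of 3
#'   (checked lazily at translation time, not by validity, so that annotation
#'   faults are reported where they matter).
#' @slot txInfo [S4Vectors::DataFrame] with columns `transcript_id`,
#'   `gene_id`, `chrom`, `strand`, parallel to `exons`.
#' @slot repeats [GenomicRanges::GRanges] of annotated repeat intervals.
#'
#' @seealso [readAnnotationGff3()], [exonRanges()], [cdsRanges()],
#'   [geneSpans()], [intronRanges()]
#' @export
setClass("TranscriptModels",
  representation(
    exons   = "CompressedGRangesList",
    cds     = "CompressedGRangesList",
    txInfo  = "DataFrame",
    repeats = "GRanges"
  )
)

setValidity("TranscriptModels", function(object) {
  msg <- character()
  n <- length(object@exons)
  if (length(object@cds) != n)
    msg <- c(msg, "exons and cds must have the same length")
  if (nrow(object@txInfo) != n)
    msg <- c(msg, "txInfo must have one row per transcript")
  need <- c("transcript_id", "gene_id", "chrom", "strand")
  if (!all(need %in% colnames(object@txInfo)))
    msg <- c(msg, paste("txInfo needs columns:", paste(need, collapse = ", ")))
  if (n > 0) {
    if (anyDuplicated(object@txInfo$transcript_id))
      msg <- c(msg, "duplicated transcript ids")
    nEx <- lengths(object@exons)
    if (any(nEx < 1L))
      msg <- c(msg, "every transcript needs at least one exon")
    # exons sorted and disjoint within each transcript
    ok <- vapply(seq_len(n), function(i) {
      ex <- object@exons[[i]]
      !is.unsorted(start(ex)) && IRanges::isDisjoint(ranges(ex))
    }, logical(1))
    if (!all(ok))
      msg <- c(msg, "exons must be sorted and non-overlapping within a transcript")
    # CDS within exon union
    okCds <- vapply(seq_len(n), function(i) {
      cd <- object@cds[[i]]
      if (length(cd) == 0L) return(TRUE)
      all(countOverlaps(cd, object@exons[[i]], type = "within") > 0L)
    }, logical(1))
    if (!all(okCds))
      msg <- c(msg, "CDS pieces must lie within the exon union of their transcript")
  }
  if (length(msg)) msg else TRUE
})

#' Spliced alignments of contigs on a genome
#'
#' One element per alignment *segment*: a contig aligned in several segments
#' (the chimera candidates) contributes several elements sharing a
#' `contig_id`.  Blocks within a segment are the aligned target intervals
#' (exons of the placement); gaps between blocks are the introns.
#'
#' @slot blocks [GenomicRanges::GRangesList]; element i holds the sorted,
#'   non-overlapping target blocks of segment i.
#' @slot info [S4Vectors::DataFrame] parallel to `blocks` with columns
#'   `contig_id`, `segment` (integer tag within contig), `chrom`, `strand`,
#'   `identity` and `coverage` (fraction of the contig covered by this
#'   segment), both in [0, 1].
#'
#' @seealso [readSplicedBed12()], [gateAlignments()], [classifyStructure()]
#' @export
setClass("SplicedAlignments",
  representation(
    blocks = "CompressedGRangesList",
    info   = "DataFrame"
  )
)

setValidity("SplicedAlignments", function(object) {
  msg <- character()
  if (nrow(object@info) != length(object@blocks))
    msg <- c(msg, "info must have one row per alignment segment")
  need <- c("contig_id", "segment", "chrom", "strand", "identity", "coverage")
  if (!all(need %in% colnames(object@info)))
    msg <- c(msg, paste("info needs columns:", paste(need, collapse = ", ")))
  else {
    idok <- is.numeric(object@info$identity) &&
      all(object@info$identity >= 0 & object@info$identity <= 1, na.rm = TRUE)
    cvok <- is.numeric(object@info$coverage) &&
      all(object@info$coverage >= 0 & object@info$coverage <= 1, na.rm = TRUE)
    if (!idok) msg <- c(msg, "identity must lie in [0, 1]")
    if (!cvok) msg <- c(msg, "coverage must lie in [0, 1]")
  }
  if (length(object@blocks) > 0) {
    ok <- vapply(seq_along(object@blocks), function(i) {
      b <- object@blocks[[i]]
      length(b) >= 1L && !is.unsorted(start(b)) &&
        IRanges::isDisjoint(ranges(b))
    }, logical(1))
    if (!all(ok))
      msg <- c(msg, "target blocks must be sorted and non-overlapping within a segment")
  }
  if (length(msg)) msg else TRUE
})

## ---- constructors ---------------------------------------------------------

#' @rdname TranscriptModels-class
#' @param exons,cds,txInfo,repeats see the corresponding slots.
#' @return A `TranscriptModels` object.
#' @export
TranscriptModels <- function(exons, cds = NULL, txInfo, repeats = GRanges()) {
  exons <- as(exons, "CompressedGRangesList")
  if (is.null(cds)) {
    cds <- as(GRangesList(lapply(seq_along(exons), function(i) GRanges())),
              "CompressedGRangesList")
  }
  cds <- as(cds, "CompressedGRangesList")
  txInfo <- as(txInfo, "DataFrame")
  names(exons) <- txInfo$transcript_id
  names(cds) <- txInfo$transcript_id
  new("TranscriptModels", exons = exons, cds = cds, txInfo = txInfo,
      repeats = repeats)
}

#' @rdname SplicedAlignments-class
#' @param blocks,info see the corresponding slots.
#' @return A `SplicedAlignments` object.
#' @export
SplicedAlignments <- function(blocks, info) {
  blocks <- as(blocks, "CompressedGRangesList")
  info <- as(info, "DataFrame")
  info$segment <- as.integer(info$segment)
  new("SplicedAlignments", blocks = blocks, info = info)
}

## ---- accessors ------------------------------------------------------------

#' Accessors for TranscriptModels
#'
#' @param x A [TranscriptModels-class] object.
#' @return `exonRanges`/`cdsRanges`/`intronRanges`: a
#'   [GenomicRanges::GRangesList] named by transcript id; `txInfo`: the
#'   transcript table; `repeatRanges`: annotated repeats; `txSpans`: one
#'   [GenomicRanges::GRanges] per transcript (hull of its exons) with
#'   `transcript_id`/`gene_id` metadata; `geneSpans`: one range per gene
#'   (hull of its transcripts).
#' @name TranscriptModels-accessors
NULL

#' @rdname TranscriptModels-accessors
#' @export
exonRanges <- function(x) x@exons

#' @rdname TranscriptModels-accessors
#' @export
cdsRanges <- function(x) x@cds

#' @rdname TranscriptModels-accessors
#' @export
txInfo <- function(x) x@txInfo

#' @rdname TranscriptModels-accessors
#' @export
repeatRanges <- function(x) x@repeats

#' @rdname TranscriptModels-accessors
#' @export
txSpans <- function(x) {
  if (length(x@exons) == 0L)
    return(GRanges())
  sp <- unlist(range(x@exons), use.names = FALSE)
  mcols(sp)$transcript_id <- x@txInfo$transcript_id
  mcols(sp)$gene_id <- x@txInfo$gene_id
  names(sp) <- x@txInfo$transcript_id
  sp
}

#' @rdname TranscriptModels-accessors
#' @export
geneSpans <- function(x) {
  sp <- txSpans(x)
  if (length(sp) == 0L)
    return(GRanges())
  byGene <- split(sp, mcols(sp)$gene_id)
  g <- unlist(range(byGene), use.names = TRUE)
  mcols(g)$gene_id <- names(g)
  g
}

#' @rdname TranscriptModels-accessors
#' @export
intronRanges <- function(x) {
  ex <- x@exons
  out <- GRangesList(lapply(seq_along(ex), function(i) {
    e <- ex[[i]]
    if (length(e) < 2L) return(GRanges())
    GRanges(seqnames(e)[1],
            IRanges(end(e)[-length(e)] + 1L, start(e)[-1L] - 1L),
            strand = strand(e)[1])
  }))
  names(out) <- names(ex)
  out
}

#' Accessors for SplicedAlignments
#'
#' @param x A [SplicedAlignments-class] object.
#' @return `alnBlocks`: the per-segment target blocks; `alnInfo`: the segment
#'   table; `contigIds`: unique contig ids present.
#' @name SplicedAlignments-accessors
NULL

#' @rdname SplicedAlignments-accessors
#' @export
alnBlocks <- function(x) x@blocks

#' @rdname SplicedAlignments-accessors
#' @export
alnInfo <- function(x) x@info

#' @rdname SplicedAlignments-accessors
#' @export
contigIds <- function(x) unique(as.character(x@info$contig_id))

## ---- show -----------------------------------------------------------------

setMethod("show", "TranscriptModels", function(object) {
  cat("TranscriptModels with", length(object@exons), "transcripts in",
      length(unique(object@txInfo$gene_id)), "genes;",
      length(object@repeats), "repeat intervals\n")
  if (length(object@exons)) {
    nEx <- lengths(object@exons)
    cat("  exons per transcript:", min(nEx), "-", max(nEx), "\n")
    cat("  chromosomes:",
        paste(unique(as.character(object@txInfo$chrom)), collapse = ", "), "\n")
  }
})

setMethod("show", "SplicedAlignments", function(object) {
  nSeg <- length(object@blocks)
  nCtg <- length(contigIds(object))
  cat("SplicedAlignments:", nSeg, "segments from", nCtg, "contigs\n")
  if (nSeg) {
    multi <- sum(table(object@info$contig_id) > 1L)
    cat("  multi-segment contigs (chimera candidates):", multi, "\n")
    cat("  identity range:",
        sprintf("%.3f-%.3f", min(object@info$identity), max(object@info$identity)),
        "\n")
  }
})
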