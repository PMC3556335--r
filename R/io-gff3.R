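#' Read a GFF3 gene annotation into TranscriptModels
#'
#' Expects the usual gene/mRNA/exon/CDS feature hierarchy with `ID`/`Parent`
#' attributes (any `*RNA`/`transcript` type is accepted as a transcript).
#' Repeat features (types containing "repeat", e.g. `dispersed_repeat`) are
#' collected into the `repeats` slot.  GFF3 1-based closed coordinates are
#' kept as 1-based closed [GenomicRanges::GRanges]; exons are sorted by
#' position within each transcript.
#'
#' @param path Path to a GFF3 file.
#' @param seqlengths Optional named integer vector of chromosome lengths used
#'   to reject out-of-range intervals.
#' @return A [TranscriptModels-class] object.
#' @details Errors are raised for exons or CDS without a resolvable parent
#'   transcript, for CDS pieces outside the exon union of their transcript,
#'   and for intervals outside `seqlengths` when those are supplied.
#' @export
readAnnotationGff3 <- function(path, seqlengths = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  gff <- rtracklayer::import(path, format = "gff3")
  type <- tolower(as.character(gff$type))
  isTx <- grepl("rna|transcript", type) & !grepl("repeat", type)
  isExon <- type == "exon"
  isCds <- type == "cds"
  isRepeat <- grepl("repeat", type)

  if (!is.null(seqlengths)) {
    bad <- start(gff) < 1L | end(gff) > seqlengths[as.character(seqnames(gff))]
    if (any(bad, na.rm = TRUE))
      stop("feature interval(s) outside chromosome bounds in ", path)
  }

  tx <- gff[isTx]
  txIds <- as.character(tx$ID)
  if (anyDuplicated(txIds)) stop("duplicated transcript IDs in ", path)
  txGene <- vapply(as.list(tx$Parent), function(p)
    if (length(p)) p[[1L]] else NA_character_, character(1))
  txGene[is.na(txGene) | txGene == ""] <- txIds[is.na(txGene) | txGene == ""]

  .parentOf <- function(feats, what) {
    par <- as.list(feats$Parent)
    if (any(lengths(par) == 0L))
      stop(what, " feature without a Parent transcript in ", path)
    par <- vapply(par, `[[`, character(1), 1L)
    unknown <- setdiff(unique(par), txIds)
    if (length(unknown))
      stop(what, " feature(s) with unknown parent transcript: ",
           paste(unknown, collapse = ", "))
    par
  }

  exon <- gff[isExon]
  exonParent <- .parentOf(exon, "exon")
  cds <- gff[isCds]
  cdsParent <- if (length(cds)) .parentOf(cds, "CDS") else character()

  strip <- function(gr) {
    mcols(gr) <- NULL
    gr
  }
  exonsBy <- split(strip(exon), factor(exonParent, levels = txIds))
  exonsBy <- GRangesList(lapply(exonsBy, sort, ignore.strand = TRUE))
  cdsBy <- split(strip(cds), factor(cdsParent, levels = txIds))
  cdsBy <- GRangesList(lapply(cdsBy, sort, ignore.strand = TRUE))

  info <- DataFrame(
    transcript_id = txIds,
    gene_id = txGene,
    chrom = as.character(seqnames(tx)),
    strand = as.character(strand(tx))
  )
  reps <- strip(gff[isRepeat])
  TranscriptModels(exonsBy, cdsBy, info, repeats = reps)
}

#' Write TranscriptModels to GFF3
#'
#' Emits the gene/mRNA/exon/CDS hierarchy in the native 1-based closed GFF3
#' convention; [readAnnotationGff3()] on the result reconstructs the object.
#'
#' @param x A [TranscriptModels-class] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeAnnotationGff3 <- function(x, path) {
  info <- txInfo(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  fmt <- function(chrom, type, s, e, strand, attr)
    sprintf("%s\ttriage\t%s\t%d\t%d\t.\t%s\t.\t%s", chrom, type, s, e, strand, attr)
  lines <- character()
  genes <- geneSpans(x)
  for (g in seq_along(genes)) {
    gid <- mcols(genes)$gene_id[g]
    lines <- c(lines, fmt(as.character(seqnames(genes)[g]), "gene",
                          start(genes)[g], end(genes)[g],
                          as.character(strand(genes)[g]),
                          paste0("ID=", gid)))
    for (i in which(info$gene_id == gid)) {
      tid <- info$transcript_id[i]
      ex <- exonRanges(x)[[i]]
      cd <- cdsRanges(x)[[i]]
      lines <- c(lines, fmt(info$chrom[i], "mRNA", min(start(ex)), max(end(ex)),
                            info$strand[i], paste0("ID=", tid, ";Parent=", gid)))
      for (j in seq_along(ex))
        lines <- c(lines, fmt(info$chrom[i], "exon", start(ex)[j], end(ex)[j],
                              info$strand[i], paste0("Parent=", tid)))
      for (j in seq_along(cd))
        lines <- c(lines, fmt(info$chrom[i], "CDS", start(cd)[j], end(cd)[j],
                              info$strand[i], paste0("Parent=", tid)))
    }
  }
  reps <- repeatRanges(x)
  for (j in seq_along(reps))
    lines <- c(lines, fmt(as.character(seqnames(reps)[j]), "dispersed_repeat",
                          start(reps)[j], end(reps)[j], ".",
                          paste0("ID=repeat_", j)))
  writeLines(lines, con)
  invisible(path)
}
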