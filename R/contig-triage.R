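## ---- greedy clustering ----------------------------------------------------

.kmerSet <- function(seq, k = 31L) {
  n <- nchar(seq)
  if (n < k) return(seq)
  unique(substring(seq, 1:(n - k + 1L), k:n))
}

## local alignment similarity of the shorter sequence within the longer one
.pairSimilarity <- function(shorter, longer) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3)
  aln <- Biostrings::pairwiseAlignment(shorter, longer, type = "local",
                                       substitutionMatrix = sm,
                                       gapOpening = 5, gapExtension = 2)
  cols <- nchar(aln)
  if (cols == 0L) return(c(identity = 0, short_coverage = 0))
  pat <- Biostrings::pattern(aln)
  c(identity = as.numeric(Biostrings::nmatch(aln) / cols),
    short_coverage = as.numeric((end(pat) - start(pat) + 1L) /
                                  nchar(unname(shorter))))
}

#' Greedy length-sorted clustering of assembled contigs
#'
#' Reproduces redundancy removal of an assembly: contigs are sorted by
#' length descending (ties by id ascending) and each joins the first
#' existing cluster whose representative aligns with identity strictly
#' above `min_identity` over at least `min_short_coverage` of the shorter
#' sequence; otherwise it founds a new cluster.  The representative is the
#' longest (first) member, so only the longest fragment of each redundancy
#' group is retained.  Candidate pairs are pre-screened for a shared
#' `k`-mer, which makes unrelated pairs cheap without changing the result
#' at these thresholds (a local alignment with identity > 0.9 over a
#' full-length >= 31 bp sequence necessarily shares a 31-mer only when the
#' shorter sequence is long; for shorter queries the screen falls back to
#' alignment).
#'
#' @param contigs A named [Biostrings::DNAStringSet].
#' @param min_identity Identity threshold, strict `>` (default 0.90).
#' @param min_short_coverage Required aligned fraction of the shorter
#'   sequence (default 1.0, i.e. full containment).
#' @param k Pre-screen k-mer size (default 31).
#' @return A `data.frame` with columns `contig_id` and `representative`;
#'   clusters partition the input and each representative is at least as
#'   long as every member.
#' @export
clusterContigs <- function(contigs, min_identity = 0.90,
                           min_short_coverage = 1.0, k = 31L) {
  stopifnot(length(contigs) > 0)
  lens <- Biostrings::width(contigs)
  ord <- order(-lens, names(contigs))
  seqs <- as.character(contigs)[ord]
  ids <- names(contigs)[ord]
  kmers <- lapply(seqs, .kmerSet, k = k)

  repIdx <- integer(0)                       # indices (into ord) of representatives
  assign <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    found <- 0L
    for (r in repIdx) {
      if (nchar(seqs[i]) >= k && !any(kmers[[i]] %in% kmers[[r]])) next
      sim <- .pairSimilarity(seqs[i], seqs[r])
      if (sim["identity"] > min_identity &&
          sim["short_coverage"] >= min_short_coverage) {
        found <- r
        break
      }
    }
    if (found == 0L) {
      repIdx <- c(repIdx, i)
      assign[i] <- i
    } else {
      assign[i] <- found
    }
  }
  data.frame(contig_id = ids, representative = ids[assign],
             stringsAsFactors = FALSE)
}

## ---- assembly statistics --------------------------------------------------

#' Length statistics of a sequence set
#'
#' `N50` is the largest length L such that the summed length of all
#' sequences of length >= L reaches half the total (computed from the
#' descending cumulative sum); `N90` is the analogue at 90%.
#'
#' @param lengths Positive sequence lengths in bp.
#' @return A list: `n`, `max`, `min`, `mean`, `median`, `N50`, `N90`,
#'   `total`.
#' @examples
#' assemblyStats(c(200, 300, 400, 500, 600))$N50  # 500
#' @export
assemblyStats <- function(lengths) {
  if (length(lengths) == 0L) stop("empty length list")
  stopifnot(all(lengths > 0))
  sorted <- sort(lengths, decreasing = TRUE)
  cum <- cumsum(as.numeric(sorted))
  total <- cum[length(cum)]
  nAt <- function(frac) sorted[which(cum >= frac * total)[1L]]
  list(n = length(lengths), max = max(lengths), min = min(lengths),
       mean = mean(lengths), median = stats::median(lengths),
       N50 = nAt(0.5), N90 = nAt(0.9), total = total)
}

## ---- alignment gating -----------------------------------------------------

#' Gate spliced alignments on identity and coverage; flag chimeras
#'
#' A contig is a chimera iff its alignment comprises two or more segments,
#' each covering at least `min_segment_coverage` of the query, that lie on
#' different chromosomes, on different strands, or more than `max_gap`
#' apart.  Otherwise the contig is mapped iff its best single segment
#' (highest coverage, ties by identity) passes both inclusive thresholds;
#' else it is unmapped.
#'
#' @param alignments A [SplicedAlignments-class] object.
#' @param min_identity,min_coverage Inclusive gates (default 0.90 both).
#' @param min_segment_coverage Minimum query fraction for a segment to count
#'   towards the chimera rule (default 0.2).
#' @param max_gap Maximum genomic distance between same-chromosome segments
#'   before they count as discordant (default 1e6).
#' @return A list: `mapped` (a [SplicedAlignments-class] holding the best
#'   segment per mapped contig), `unmapped` (contig ids failing the gates),
#'   `chimeras` (contig ids).
#' @export
gateAlignments <- function(alignments, min_identity = 0.90,
                           min_coverage = 0.90, min_segment_coverage = 0.2,
                           max_gap = 1e6) {
  info <- alnInfo(alignments)
  blocks <- alnBlocks(alignments)
  spanStart <- vapply(blocks, function(b) min(start(b)), numeric(1))
  spanEnd <- vapply(blocks, function(b) max(end(b)), numeric(1))
  byContig <- split(seq_len(nrow(info)), info$contig_id)

  mappedIdx <- integer(0)
  unmapped <- character(0)
  chimeras <- character(0)
  for (ctg in names(byContig)) {
    rows <- byContig[[ctg]]
    big <- rows[info$coverage[rows] >= min_segment_coverage]
    isChimera <- FALSE
    if (length(big) >= 2L) {
      for (a in seq_len(length(big) - 1L)) for (b in (a + 1L):length(big)) {
        i <- big[a]; j <- big[b]
        discordant <- info$chrom[i] != info$chrom[j] ||
          info$strand[i] != info$strand[j] ||
          max(spanStart[i], spanStart[j]) - min(spanEnd[i], spanEnd[j]) > max_gap
        if (discordant) { isChimera <- TRUE; break }
      }
    }
    if (isChimera) {
      chimeras <- c(chimeras, ctg)
      next
    }
    best <- rows[order(-info$coverage[rows], -info$identity[rows])][1L]
    if (info$identity[best] >= min_identity && info$coverage[best] >= min_coverage)
      mappedIdx <- c(mappedIdx, best)
    else
      unmapped <- c(unmapped, ctg)
  }
  list(mapped = SplicedAlignments(blocks[mappedIdx], info[mappedIdx, , drop = FALSE]),
       unmapped = unmapped, chimeras = chimeras)
}

## ---- structural classification --------------------------------------------

#' Classify the block structure of mapped alignments
#'
#' Multi-block alignments are `multi_exon` (retained).  Single-block
#' alignments are `single_exon` if they match one annotated exon within
#' `end_tol` bp per end, `exon_fragment` if they lie inside an annotated
#' exon without matching it, `partial_intron` if more than `intron_frac` of
#' the block overlaps an annotated intron; single blocks in non-annotated
#' regions are `novel_single_exon` (retained) when at least
#' `min_novel_length` bp, else `exon_fragment`.  Remaining annotated-region
#' single blocks (e.g. straddling an exon boundary with minor intron
#' overlap) fall back to `exon_fragment`.  Classes `single_exon`,
#' `exon_fragment` and `partial_intron` correspond to the removal of
#' single-exon matches, exon fragments and partial introns from the contig
#' set.
#'
#' @param alignments A [SplicedAlignments-class] object (gated, one segment
#'   per contig).
#' @param annotation A [TranscriptModels-class] object.
#' @param end_tol Per-end tolerance for the exon-match test (default 10 bp,
#'   absorbing assembly end errors).
#' @param intron_frac Overlap fraction defining `partial_intron`
#'   (default 0.5, strict `>`).
#' @param min_novel_length Minimum length for a retained novel single-exon
#'   block (default 200 bp, the assembler's minimum contig length).
#' @return A character vector of structure classes, one per alignment
#'   segment, named by contig id.
#' @export
classifyStructure <- function(alignments, annotation, end_tol = 10L,
                              intron_frac = 0.5, min_novel_length = 200L) {
  info <- alnInfo(alignments)
  blocks <- alnBlocks(alignments)
  exons <- unlist(exonRanges(annotation), use.names = FALSE)
  introns <- unlist(intronRanges(annotation), use.names = FALSE)
  spans <- txSpans(annotation)

  out <- vapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    if (length(b) >= 2L) return("multi_exon")
    blk <- b[1L]
    exHits <- exons[as.character(seqnames(exons)) == as.character(seqnames(blk))]
    match <- any(abs(start(exHits) - start(blk)) <= end_tol &
                 abs(end(exHits) - end(blk)) <= end_tol)
    if (match) return("single_exon")
    inside <- any(start(blk) >= start(exHits) & end(blk) <= end(exHits))
    if (inside) return("exon_fragment")
    inHits <- introns[as.character(seqnames(introns)) == as.character(seqnames(blk))]
    if (length(inHits)) {
      ov <- pmin(end(blk), end(inHits)) - pmax(start(blk), start(inHits)) + 1L
      if (max(c(ov, 0L)) > intron_frac * width(blk)) return("partial_intron")
    }
    annotated <- any(countOverlaps(blk, spans, ignore.strand = TRUE) > 0L)
    if (!annotated) {
      if (width(blk) >= min_novel_length) return("novel_single_exon")
      return("exon_fragment")
    }
    "exon_fragment"
  }, character(1))
  stats::setNames(out, info$contig_id)
}

## ---- locus assignment -----------------------------------------------------

#' Assign mapped contigs to annotated, merged, repeat or novel loci
#'
#' Each contig is assigned to the annotated gene with maximal exonic
#' overlap on the same strand (any strand when the alignment is
#' unstranded).  A contig overlapping exons of two or more genes is
#' assigned to a synthetic merged locus listing the member genes.  Contigs
#' overlapping no annotated gene go to `repeat_region` if they overlap an
#' annotated repeat, otherwise they are grouped into novel loci by
#' single-linkage overlap of their target spans (either strand).
#'
#' @param alignments A [SplicedAlignments-class] object (gated and
#'   structure-filtered, one segment per contig).
#' @param annotation A [TranscriptModels-class] object.
#' @return A list: `assignments`, a `data.frame` with columns `contig_id`,
#'   `locus_id`, `locus_type` (`known`/`merged`/`repeat`/`novel`),
#'   `member_genes` (comma-separated, merged loci only); `merged_loci`, a
#'   `data.frame` of merged locus ids and their member genes;
#'   `novel_loci`, a [GenomicRanges::GRanges] of novel locus footprints.
#' @export
assignLoci <- function(alignments, annotation) {
  info <- alnInfo(alignments)
  blocks <- alnBlocks(alignments)
  exons <- unlist(exonRanges(annotation), use.names = FALSE)
  exGene <- rep(txInfo(annotation)$gene_id, lengths(exonRanges(annotation)))
  exStrand <- as.character(strand(exons))

  n <- length(blocks)
  locus <- character(n); type <- character(n); members <- character(n)
  novelIdx <- integer(0)
  for (i in seq_len(n)) {
    b <- blocks[[i]]
    st <- info$strand[i]
    hits <- findOverlaps(b, exons, ignore.strand = TRUE)
    if (length(hits) && st %in% c("+", "-")) {
      keep <- exStrand[subjectHits(hits)] == st
      hits <- hits[keep]
    }
    if (length(hits)) {
      ov <- width(pintersect(b[queryHits(hits)], exons[subjectHits(hits)],
                             ignore.strand = TRUE))
      perGene <- tapply(ov, exGene[subjectHits(hits)], sum)
      genes <- sort(names(perGene))
      if (length(genes) >= 2L) {
        locus[i] <- paste0("merged:", paste(genes, collapse = "+"))
        type[i] <- "merged"
        members[i] <- paste(genes, collapse = ",")
      } else {
        locus[i] <- names(which.max(perGene))
        type[i] <- "known"
        members[i] <- ""
      }
    } else if (length(repeatRanges(annotation)) &&
               any(countOverlaps(b, repeatRanges(annotation),
                                 ignore.strand = TRUE) > 0L)) {
      locus[i] <- "repeat"
      type[i] <- "repeat"
      members[i] <- ""
    } else {
      novelIdx <- c(novelIdx, i)
    }
  }
  novelLoci <- GRanges()
  if (length(novelIdx)) {
    spans <- unlist(range(blocks[novelIdx]), use.names = FALSE)
    merged <- reduce(spans, ignore.strand = TRUE)     # single linkage on overlap
    names(merged) <- sprintf("novel_%s_%d", as.character(seqnames(merged)),
                             start(merged))
    hit <- findOverlaps(spans, merged, ignore.strand = TRUE)
    locus[novelIdx[queryHits(hit)]] <- names(merged)[subjectHits(hit)]
    type[novelIdx] <- "novel"
    members[novelIdx] <- ""
    novelLoci <- merged
  }
  assignments <- data.frame(contig_id = as.character(info$contig_id),
                            locus_id = locus, locus_type = type,
                            member_genes = members, stringsAsFactors = FALSE)
  mergedTab <- unique(assignments[assignments$locus_type == "merged",
                                  c("locus_id", "member_genes")])
  rownames(mergedTab) <- NULL
  list(assignments = assignments, merged_loci = mergedTab,
       novel_loci = novelLoci)
}

## ---- fraction-of-major-isoform filter -------------------------------------

#' Fraction-of-major-isoform (FMI) expression filter
#'
#' Within one locus, the major isoform is the contig with the highest
#' expression; any other member is discarded as a potential pre-mRNA iff
#' its expression falls strictly below `threshold` times the major
#' isoform's.  The major isoform is always kept.  The default 5% is the
#' study threshold (10% and 15% were tested and degraded coding-gene
#' recovery, hence configurable).
#'
#' @param expression Named numeric vector of per-contig expression (FPKM)
#'   for the members of one locus.
#' @param threshold Fraction of the major isoform (default 0.05), strict `<`.
#' @return A list: `kept` and `discarded` (contig ids), `major` (id of the
#'   major isoform).
#' @export
fmiFilter <- function(expression, threshold = 0.05) {
  stopifnot(length(expression) >= 1L, !is.null(names(expression)),
            !anyNA(expression))
  if (all(expression == 0)) {
    warning("all-zero expression at locus; all members kept")
    return(list(kept = names(expression), discarded = character(0),
                major = names(expression)[1L]))
  }
  major <- names(expression)[which.max(expression)]
  discard <- expression < threshold * max(expression)
  discard[major] <- FALSE
  list(kept = names(expression)[!discard],
       discarded = names(expression)[discard],
       major = major)
}

## ---- intron-chain comparison ----------------------------------------------

.intronChain <- function(gr) {
  if (length(gr) < 2L) return(integer(0))
  s <- sort(gr, ignore.strand = TRUE)
  as.integer(rbind(end(s)[-length(s)] + 1L, start(s)[-1L] - 1L))
}

#' Compare a contig's intron chain with reference transcripts
#'
#' The intron chain is the ordered list of intron intervals (target gaps
#' between alignment blocks).  The contig is `identical` iff its chain
#' exactly equals the chain of some reference transcript at the locus;
#' otherwise it is a `novel_isoform`.  A single-block contig at a locus
#' whose transcripts are all multi-exon is a `novel_isoform`; at a
#' single-exon locus the chains are both empty and it is `identical`.
#'
#' @param blocks [GenomicRanges::GRanges] of the contig's target blocks.
#' @param reference_exons [GenomicRanges::GRangesList] of exons of the
#'   reference transcripts at the locus.
#' @return `"identical"` or `"novel_isoform"`.
#' @export
compareIntronChain <- function(blocks, reference_exons) {
  chain <- .intronChain(blocks)
  for (ex in as.list(reference_exons)) {
    if (identical(chain, .intronChain(ex))) return("identical")
  }
  "novel_isoform"
}

## ---- evidence overlap ------------------------------------------------------

#' Count contigs supported by external evidence intervals
#'
#' A contig overlaps an evidence source iff at least one of its exonic
#' blocks intersects (>= 1 bp) an interval of that source; each contig is
#' counted at most once per source regardless of how many intervals it
#' touches.
#'
#' @param calls A `data.frame` with columns `contig_id` and `class` (e.g.
#'   the triage table of [triageContigs()]).
#' @param alignments A [SplicedAlignments-class] object giving each
#'   contig's blocks.
#' @param evidence A [GenomicRanges::GRanges] with a metadata column
#'   `source` (e.g. `est`, `cdna`, `alt_annotation`).
#' @return A class-by-source matrix of contig counts.
#' @export
evidenceOverlap <- function(calls, alignments, evidence) {
  info <- alnInfo(alignments)
  blocks <- alnBlocks(alignments)
  sources <- sort(unique(as.character(mcols(evidence)$source)))
  classes <- sort(unique(calls$class))
  out <- matrix(0L, length(classes), length(sources),
                dimnames = list(classes, sources))
  for (src in sources) {
    ev <- evidence[mcols(evidence)$source == src]
    hitCtg <- unique(info$contig_id[
      vapply(seq_along(blocks), function(i)
        any(countOverlaps(blocks[[i]], ev, ignore.strand = TRUE) > 0L),
        logical(1))])
    tab <- table(calls$class[calls$contig_id %in% hitCtg])
    out[names(tab), src] <- as.integer(tab)
  }
  out
}

## ---- full triage ----------------------------------------------------------

#' Triage de novo contigs against genome alignments and annotation
#'
#' Runs the mapped-contig decision chain: identity/coverage gating with
#' chimera exclusion, structural filtering of single-exon matches, exon
#' fragments and partial introns, locus assignment (annotated, merged,
#' repeat, novel), the FMI pre-mRNA filter at annotated and merged loci,
#' and intron-chain comparison of the survivors.  Contigs without any
#' alignment record are classed `unmapped` (triage of those against
#' homology evidence is [triageUnmapped()]'s job).
#'
#' @param contig_ids Character vector of all contig ids under triage.
#' @param alignments A [SplicedAlignments-class] object (may cover only a
#'   subset of `contig_ids`).
#' @param annotation A [TranscriptModels-class] object.
#' @param expression Named numeric vector of per-contig expression (FPKM);
#'   required for every contig that reaches the FMI filter.
#' @param fmi_threshold See [fmiFilter()].
#' @param min_identity,min_coverage See [gateAlignments()].
#' @param structure_args Optional list of overrides for
#'   [classifyStructure()] (`end_tol`, `intron_frac`, `min_novel_length`).
#' @return A list with `calls`: a `data.frame` (one row per contig) with
#'   columns `contig_id`, `class` (one of `identical_isoform`,
#'   `novel_isoform`, `pre_mrna_filtered`, `fragment_removed`,
#'   `chimera_excluded`, `repeat_region`, `novel_locus`, `unmapped`),
#'   `locus_id`, `merged` (flag); `merged_loci` and `novel_loci` from
#'   [assignLoci()]; and `class_counts`.  Classes partition the input:
#'   `sum(class_counts) == length(contig_ids)`.
#' @export
triageContigs <- function(contig_ids, alignments, annotation, expression,
                          fmi_threshold = 0.05, min_identity = 0.90,
                          min_coverage = 0.90, structure_args = list()) {
  calls <- data.frame(contig_id = contig_ids, class = "unmapped",
                      locus_id = NA_character_, merged = FALSE,
                      stringsAsFactors = FALSE)
  rownames(calls) <- contig_ids
  aln <- alignments
  have <- intersect(contigIds(aln), contig_ids)
  keepSeg <- alnInfo(aln)$contig_id %in% have
  aln <- SplicedAlignments(alnBlocks(aln)[keepSeg],
                           alnInfo(aln)[keepSeg, , drop = FALSE])

  gated <- gateAlignments(aln, min_identity = min_identity,
                          min_coverage = min_coverage)
  calls[gated$chimeras, "class"] <- "chimera_excluded"
  # gate-failing contigs stay "unmapped"

  mapped <- gated$mapped
  if (length(alnBlocks(mapped)) > 0L) {
    structure <- do.call(classifyStructure,
                         c(list(mapped, annotation), structure_args))
    removed <- names(structure)[structure %in%
      c("single_exon", "exon_fragment", "partial_intron")]
    calls[removed, "class"] <- "fragment_removed"

    keep <- !alnInfo(mapped)$contig_id %in% removed
    retained <- SplicedAlignments(alnBlocks(mapped)[keep],
                                  alnInfo(mapped)[keep, , drop = FALSE])
    la <- assignLoci(retained, annotation)
    asg <- la$assignments
    calls[asg$contig_id, "locus_id"] <- asg$locus_id
    calls[asg$contig_id[asg$locus_type == "repeat"], "class"] <- "repeat_region"
    calls[asg$contig_id[asg$locus_type == "novel"], "class"] <- "novel_locus"
    calls[asg$contig_id[asg$locus_type == "merged"], "merged"] <- TRUE

    genic <- asg[asg$locus_type %in% c("known", "merged"), , drop = FALSE]
    exonsByTx <- exonRanges(annotation)
    txGene <- txInfo(annotation)$gene_id
    retBlocks <- alnBlocks(retained)
    retIds <- alnInfo(retained)$contig_id
    for (loc in unique(genic$locus_id)) {
      members <- genic$contig_id[genic$locus_id == loc]
      expr <- expression[members]
      if (anyNA(expr))
        stop("missing expression value for contig(s): ",
             paste(members[is.na(expr)], collapse = ", "))
      names(expr) <- members
      fmi <- fmiFilter(expr, threshold = fmi_threshold)
      calls[fmi$discarded, "class"] <- "pre_mrna_filtered"
      locGenes <- if (startsWith(loc, "merged:")) {
        strsplit(genic$member_genes[genic$locus_id == loc][1L], ",")[[1L]]
      } else loc
      refEx <- exonsByTx[txGene %in% locGenes]
      for (ctg in fmi$kept) {
        b <- retBlocks[[match(ctg, retIds)]]
        calls[ctg, "class"] <- compareIntronChain(b, refEx)
      }
    }
    calls$class[calls$class == "identical"] <- "identical_isoform"
  } else {
    la <- list(merged_loci = data.frame(locus_id = character(0),
                                        member_genes = character(0)),
               novel_loci = GRanges())
  }
  classLevels <- c("identical_isoform", "novel_isoform", "pre_mrna_filtered",
                   "fragment_removed", "chimera_excluded", "repeat_region",
                   "novel_locus", "unmapped")
  counts <- table(factor(calls$class, classLevels))
  rownames(calls) <- NULL
  list(calls = calls, merged_loci = la$merged_loci,
       novel_loci = la$novel_loci,
       class_counts = stats::setNames(as.integer(counts), classLevels))
}
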