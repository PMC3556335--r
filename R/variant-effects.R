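.regionSeverity <- c(splice_site = 1L, CDS = 2L, five_prime_UTR = 3L,
                     three_prime_UTR = 3L, intron = 4L, intergenic = 5L)

.consequenceSeverity <- c(splice_site = 1L, stop_gain = 2L, stop_loss = 2L,
                          frameshift = 2L, missense = 3L, in_frame_indel = 4L,
                          synonymous = 5L, none = 6L)

#' Filter called variants on depth, quality and allele frequency
#'
#' A record is kept iff read depth >= `min_depth` AND call quality >=
#' `min_qual` AND alternative-allele frequency >= `min_alt_freq`; all three
#' thresholds are inclusive.  The defaults are the study-design values
#' (depth 5, quality 80, frequency 0.75).
#'
#' @param variants A [GenomicRanges::GRanges] from [readVariantsVcf()].
#' @param min_depth,min_qual,min_alt_freq Inclusive thresholds.
#' @return A list with `kept` (GRanges) and `rejected` (GRanges with an
#'   additional `reason` column naming the first failing criterion, in the
#'   order depth, quality, frequency).  `kept` and `rejected` partition the
#'   input.
#' @export
filterVariants <- function(variants, min_depth = 5, min_qual = 80,
                           min_alt_freq = 0.75) {
  depthOk <- mcols(variants)$depth >= min_depth
  qualOk <- mcols(variants)$qual >= min_qual
  freqOk <- mcols(variants)$alt_freq >= min_alt_freq
  keep <- depthOk & qualOk & freqOk
  rejected <- variants[!keep]
  reason <- ifelse(!depthOk[!keep], "depth",
                   ifelse(!qualOk[!keep], "quality", "frequency"))
  mcols(rejected)$reason <- reason
  list(kept = variants[keep], rejected = rejected)
}

## region of a single position within one transcript
.regionInTranscript <- function(pos, exons, cds, strand, splice_window) {
  spanStart <- min(start(exons)); spanEnd <- max(end(exons))
  if (pos < spanStart || pos > spanEnd) return("intergenic")
  inExon <- any(pos >= start(exons) & pos <= end(exons))
  if (!inExon) {
    # intronic: splice site iff within splice_window of an intron boundary
    if (length(exons) >= 2L) {
      intronStarts <- end(exons)[-length(exons)] + 1L
      intronEnds <- start(exons)[-1L] - 1L
      nearBoundary <- any((pos - intronStarts >= 0 & pos - intronStarts < splice_window) |
                          (intronEnds - pos >= 0 & intronEnds - pos < splice_window))
      if (nearBoundary) return("splice_site")
    }
    return("intron")
  }
  if (length(cds) == 0L) return("intron")      # non-coding transcript: span-level
  if (any(pos >= start(cds) & pos <= end(cds))) return("CDS")
  cdsStart <- min(start(cds)); cdsEnd <- max(end(cds))
  upstream <- if (strand == "-") pos > cdsEnd else pos < cdsStart
  if (upstream) "five_prime_UTR" else "three_prime_UTR"
}

#' Classify variant positions by annotated genomic region
#'
#' For every variant and every transcript it falls in, the position is
#' classified as `splice_site` (within `splice_window` bases of an intron
#' boundary, inside the intron), `CDS`, `five_prime_UTR`,
#' `three_prime_UTR` or `intron`; variants outside all transcript spans are
#' `intergenic`.  When a variant hits several transcripts of a gene, the
#' most severe region (splice_site > CDS > UTR > intron) is reported for
#' that gene.
#'
#' @param variants A [GenomicRanges::GRanges] of variants.
#' @param annotation A [TranscriptModels-class] object.
#' @param splice_window Bases into the intron counted as splice site
#'   (default 2, the canonical donor/acceptor dinucleotides).
#' @return A `data.frame` with one row per (variant, gene) pair — plus one
#'   `intergenic` row (gene `NA`) per variant hitting no transcript — and
#'   columns `variant` (index into `variants`), `gene_id`, `transcript_id`
#'   (the transcript providing the most severe region), `region`.
#' @export
classifyVariantRegion <- function(variants, annotation, splice_window = 2L) {
  info <- txInfo(annotation)
  exons <- exonRanges(annotation)
  cds <- cdsRanges(annotation)
  spans <- txSpans(annotation)
  knownChroms <- unique(info$chrom)
  unknown <- setdiff(unique(as.character(seqnames(variants))), knownChroms)
  if (length(unknown) && length(variants))
    warning("chromosome(s) absent from annotation, variants set intergenic: ",
            paste(unknown, collapse = ", "))

  # seqlevel mismatches are reported via the explicit warning above, not
  # through findOverlaps' own combine warning
  hits <- suppressWarnings(findOverlaps(variants, spans, ignore.strand = TRUE))
  rows <- list()
  if (length(hits)) {
    vIdx <- queryHits(hits); tIdx <- subjectHits(hits)
    region <- vapply(seq_along(vIdx), function(k) {
      i <- tIdx[k]
      .regionInTranscript(start(variants)[vIdx[k]], exons[[i]], cds[[i]],
                          info$strand[i], splice_window)
    }, character(1))
    det <- data.frame(variant = vIdx,
                      gene_id = info$gene_id[tIdx],
                      transcript_id = info$transcript_id[tIdx],
                      region = region, stringsAsFactors = FALSE)
    # most severe region per (variant, gene)
    sev <- .regionSeverity[det$region]
    ord <- order(det$variant, det$gene_id, sev)
    det <- det[ord, , drop = FALSE]
    det <- det[!duplicated(det[, c("variant", "gene_id")]), , drop = FALSE]
    rows[["genic"]] <- det
  }
  inSpan <- unique(queryHits(hits))
  outIdx <- setdiff(seq_along(variants), inSpan)
  if (length(outIdx)) {
    rows[["intergenic"]] <- data.frame(variant = outIdx, gene_id = NA_character_,
                                       transcript_id = NA_character_,
                                       region = "intergenic",
                                       stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$variant), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## spliced CDS sequence of a transcript (5'->3'), from genomic pieces
.cdsSequence <- function(tx_index, annotation, genome) {
  info <- txInfo(annotation)
  cd <- cdsRanges(annotation)[[tx_index]]
  if (length(cd) == 0L)
    stop("transcript ", info$transcript_id[tx_index], " has no CDS")
  chromSeq <- genome[[info$chrom[tx_index]]]
  pieces <- lapply(seq_along(cd), function(j)
    subseq(chromSeq, start(cd)[j], end(cd)[j]))
  s <- do.call(Biostrings::xscat, pieces)
  if (info$strand[tx_index] == "-") s <- reverseComplement(s)
  s
}

## genomic position -> 1-based coordinate within the spliced CDS (NA if outside)
.cdsCoordinate <- function(pos, cd, strand) {
  w <- width(cd)
  before <- c(0L, cumsum(w))[-(length(w) + 1L)]
  j <- which(pos >= start(cd) & pos <= end(cd))
  if (length(j) == 0L) return(NA_integer_)
  fromLeft <- before[j] + (pos - start(cd)[j]) + 1L
  if (strand == "-") sum(w) - fromLeft + 1L else fromLeft
}

.complementBase <- function(b) {
  chartr("ACGTN", "TGCAN", b)
}

## fast CDS translation by codon-table lookup (codons with N -> X)
.translateCds <- function(seqChar) {
  n <- nchar(seqChar)
  starts <- seq(1L, n - 2L, by = 3L)
  codons <- substring(seqChar, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Project one variant onto one coding transcript
#'
#' Determines the coding consequence of a variant whose region in the
#' transcript is `CDS` or `splice_site`.  Length-changing alleles are
#' classified by indel length: `frameshift` when the length difference is
#' not a multiple of 3, else `in_frame_indel`.  Substitutions are projected
#' by translating the reference and mutated CDS: a new in-frame stop before
#' the terminal codon is `stop_gain`, loss of the terminal stop is
#' `stop_loss`, any other amino-acid change `missense`, none `synonymous`.
#' Multi-nucleotide substitutions are decomposed into per-base
#' substitutions and the most severe consequence is reported.  Splice-site
#' variants are reported as consequence `splice_site` without translation.
#'
#' @param variant A length-1 [GenomicRanges::GRanges] with `ref`/`alt`
#'   metadata columns (VCF-anchored alleles, 1-based position).
#' @param transcript_id Transcript to project onto (must have a CDS).
#' @param annotation A [TranscriptModels-class] object.
#' @param genome A named [Biostrings::DNAStringSet].
#' @param region Optional pre-computed region class for this (variant,
#'   transcript) pair; computed when missing.
#' @param splice_window See [classifyVariantRegion()].
#' @param cache Optional environment used to memoize per-transcript CDS
#'   sequences and reference translations across calls (as
#'   [variantEffects()] does).
#' @return A one-row `data.frame`: `transcript_id`, `gene_id`, `region`,
#'   `consequence`.
#' @export
annotateCodingEffect <- function(variant, transcript_id, annotation, genome,
                                 region = NULL, splice_window = 2L,
                                 cache = NULL) {
  info <- txInfo(annotation)
  i <- match(transcript_id, info$transcript_id)
  if (is.na(i)) stop("unknown transcript: ", transcript_id)
  exons <- exonRanges(annotation)[[i]]
  cd <- cdsRanges(annotation)[[i]]
  strand <- info$strand[i]
  pos <- start(variant)
  ref <- as.character(mcols(variant)$ref)
  alt <- as.character(mcols(variant)$alt)

  if (is.null(region))
    region <- .regionInTranscript(pos, exons, cd, strand, splice_window)
  if (!region %in% c("CDS", "splice_site"))
    stop("annotateCodingEffect needs region CDS or splice_site, got ", region)

  if (region == "splice_site") {
    consequence <- "splice_site"
  } else if (nchar(ref) != nchar(alt)) {
    consequence <- if (abs(nchar(alt) - nchar(ref)) %% 3L != 0L)
      "frameshift" else "in_frame_indel"
  } else {
    ctx <- if (!is.null(cache) && !is.null(cache[[transcript_id]])) {
      cache[[transcript_id]]
    } else {
      cdsSeq <- .cdsSequence(i, annotation, genome)
      if (length(cdsSeq) %% 3L != 0L)
        stop("reference CDS length of ", transcript_id,
             " is not a multiple of 3 (annotation fault)")
      x <- list(seq = as.character(cdsSeq),
                aa = .translateCds(as.character(cdsSeq)))
      if (!is.null(cache)) cache[[transcript_id]] <- x
      x
    }
    refAA <- ctx$aa
    mut <- ctx$seq
    changed <- FALSE
    for (k in seq_len(nchar(ref))) {          # MNV decomposed per base
      cc <- .cdsCoordinate(pos + k - 1L, cd, strand)
      if (is.na(cc)) next
      base <- substr(alt, k, k)
      if (strand == "-") base <- .complementBase(base)
      substr(mut, cc, cc) <- base
      changed <- TRUE
    }
    if (!changed) {
      consequence <- "none"
    } else {
      altAA <- .translateCds(mut)
      nAA <- nchar(refAA)
      refStop <- substr(refAA, nAA, nAA) == "*"
      internalStop <- function(p) {
        body <- substr(p, 1L, nAA - 1L)
        grepl("*", body, fixed = TRUE)
      }
      consequence <- if (!internalStop(refAA) && internalStop(altAA)) {
        "stop_gain"
      } else if (refStop && substr(altAA, nAA, nAA) != "*") {
        "stop_loss"
      } else if (altAA != refAA) {
        "missense"
      } else {
        "synonymous"
      }
    }
  }
  data.frame(transcript_id = transcript_id, gene_id = info$gene_id[i],
             region = region, consequence = consequence,
             stringsAsFactors = FALSE)
}

#' Project all filtered variants onto all overlapping transcripts
#'
#' Convenience wrapper: classifies every variant's region per transcript
#' with [classifyVariantRegion()] and computes coding consequences with
#' [annotateCodingEffect()] where the region is `CDS` or `splice_site`
#' (consequence `none` elsewhere).
#'
#' @inheritParams classifyVariantRegion
#' @param genome A named [Biostrings::DNAStringSet].
#' @return A `data.frame` with columns `variant`, `chrom`, `pos`, `ref`,
#'   `alt`, `gene_id`, `transcript_id`, `region`, `consequence`.
#' @export
variantEffects <- function(variants, annotation, genome, splice_window = 2L) {
  regions <- classifyVariantRegion(variants, annotation, splice_window)
  consequence <- rep("none", nrow(regions))
  idx <- which(regions$region %in% c("CDS", "splice_site"))
  cache <- new.env(parent = emptyenv())
  for (k in idx) {
    eff <- annotateCodingEffect(variants[regions$variant[k]],
                                regions$transcript_id[k], annotation, genome,
                                region = regions$region[k],
                                splice_window = splice_window, cache = cache)
    consequence[k] <- eff$consequence
  }
  data.frame(variant = regions$variant,
             chrom = as.character(seqnames(variants))[regions$variant],
             pos = start(variants)[regions$variant],
             ref = mcols(variants)$ref[regions$variant],
             alt = mcols(variants)$alt[regions$variant],
             gene_id = regions$gene_id,
             transcript_id = regions$transcript_id,
             region = regions$region,
             consequence = consequence,
             stringsAsFactors = FALSE)
}

#' Roll variant effects up to gene-level impact
#'
#' A gene is `potentially_destroyed` iff any of its transcripts carries a
#' frameshift, stop_gain, stop_loss or splice_site effect; otherwise
#' `changed` iff any missense or in_frame_indel; otherwise `unaffected`.
#'
#' @param effects A `data.frame` from [variantEffects()].
#' @param annotation A [TranscriptModels-class] object (supplies the full
#'   gene universe, so untouched genes are counted as `unaffected`).
#' @return A list with `genes` (`data.frame` of `gene_id`, `impact`) and
#'   `counts` (named vector over the three impact categories).
#' @export
summarizeGeneImpact <- function(effects, annotation) {
  allGenes <- unique(txInfo(annotation)$gene_id)
  destroyed <- unique(effects$gene_id[
    effects$consequence %in% c("frameshift", "stop_gain", "stop_loss", "splice_site")])
  changed <- setdiff(unique(effects$gene_id[
    effects$consequence %in% c("missense", "in_frame_indel")]), destroyed)
  impact <- rep("unaffected", length(allGenes))
  impact[allGenes %in% changed] <- "changed"
  impact[allGenes %in% destroyed] <- "potentially_destroyed"
  genes <- data.frame(gene_id = allGenes, impact = impact,
                      stringsAsFactors = FALSE)
  counts <- c(unaffected = sum(impact == "unaffected"),
              changed = sum(impact == "changed"),
              potentially_destroyed = sum(impact == "potentially_destroyed"))
  list(genes = genes, counts = counts)
}
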