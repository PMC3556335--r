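.BASES <- c("A", "C", "G", "T")
## codon prefixes whose third position is fully degenerate
.FOURFOLD_PREFIXES <- c("CT", "GT", "TC", "CC", "AC", "GC", "CG", "GG")

.aaOf <- function(codon) Biostrings::GENETIC_CODE[[codon]]

## genomic intron intervals of a gene meta record (ascending)
.geneIntronsG <- function(g) {
  e <- g$exon_g
  if (length(e) < 2L) return(NULL)
  cbind(end(e)[-length(e)] + 1L, start(e)[-1L] - 1L)
}

#' Plant variants of every effect class into the toy genome
#'
#' Emits `variants_per_class` variants of each of the eight classes —
#' synonymous, missense, stop_gain, stop_loss, frameshift (1-2 bp
#' insertions in the CDS), splice_site (within 2 bp of an intron
#' boundary), intron, intergenic — engineered at the codon level so the
#' planted class is true by construction (genetic-code facts, independent
#' of any projection code), plus `n_subthreshold_variants` records that
#' fail exactly one of the depth/quality/frequency filters (depth 4,
#' quality 79 or frequency 0.74; truth class `filtered`).  The first
#' variant of each effect class carries the exact inclusive boundary
#' values (depth 5, quality 80, frequency 0.75).
#'
#' @param config A [simulationConfig()].
#' @param sim Output of [generateGenomeAndAnnotation()].
#' @return A list: `variants` (a [GenomicRanges::GRanges] ready for
#'   [writeVariantsVcf()]) and `truth` (a `data.frame` with `chrom`,
#'   `pos`, `ref`, `alt`, `class`, `gene_id`).
#' @export
plantVariants <- function(config, sim) {
  set.seed(config$seed + 1L)
  genes <- sim$meta$genes
  chromSeq <- as.character(sim$genome)
  used <- new.env(parent = emptyenv())
  baseAt <- function(chrom, pos) substr(chromSeq[[chrom]], pos, pos)
  claim <- function(chrom, pos) {
    key <- paste0(chrom, ":", pos)
    if (!is.null(used[[key]])) return(FALSE)
    used[[key]] <- TRUE
    TRUE
  }
  txSnv <- function(g, p, refT, altT) {
    gpos <- .txToGenome(g, p)
    ref <- if (g$strand == "+") refT else .complementBase(refT)
    alt <- if (g$strand == "+") altT else .complementBase(altT)
    stopifnot(baseAt(g$chrom, gpos) == ref)   # generator self-check
    list(chrom = g$chrom, pos = gpos, ref = ref, alt = alt)
  }

  rows <- list()
  add <- function(chrom, pos, ref, alt, class, gene) {
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom = chrom, pos = pos, ref = ref, alt = alt, class = class,
      gene_id = gene, stringsAsFactors = FALSE)
  }

  nPer <- config$variants_per_class
  geneCycle <- function(k) genes[[(k - 1L) %% length(genes) + 1L]]

  ## --- CDS substitution classes -------------------------------------------
  plantCodonClass <- function(class, finder) {
    planted <- 0L; k <- 0L
    while (planted < nPer) {
      k <- k + 1L
      if (k > 50L * nPer) stop("could not place ", class, " variants")
      g <- geneCycle(k)
      site <- finder(g)
      if (is.null(site)) next
      v <- txSnv(g, site$p, site$refT, site$altT)
      if (!claim(v$chrom, v$pos)) next
      add(v$chrom, v$pos, v$ref, v$alt, class, g$gene_id)
      planted <- planted + 1L
    }
  }
  codonPos <- function(g, idx, within) g$utr5 + 3L * (idx - 1L) + within

  plantCodonClass("synonymous", function(g) {
    cand <- which(substr(g$codons, 1L, 2L) %in% .FOURFOLD_PREFIXES)
    cand <- setdiff(cand, c(1L, g$ncod))
    if (!length(cand)) return(NULL)
    idx <- sample(cand, 1L)
    refT <- substr(g$codons[idx], 3L, 3L)
    altT <- sample(setdiff(.BASES, refT), 1L)
    list(p = codonPos(g, idx, 3L), refT = refT, altT = altT)
  })
  plantCodonClass("missense", function(g) {
    for (idx in sample(setdiff(2:(g$ncod - 1L), 0L))) {
      cod <- g$codons[idx]
      for (w in sample(1:3)) for (b in sample(setdiff(.BASES, substr(cod, w, w)))) {
        new <- cod; substr(new, w, w) <- b
        if (.aaOf(new) != "*" && .aaOf(new) != .aaOf(cod))
          return(list(p = codonPos(g, idx, w), refT = substr(cod, w, w), altT = b))
      }
    }
    NULL
  })
  plantCodonClass("stop_gain", function(g) {
    for (idx in sample(setdiff(2:(g$ncod - 1L), 0L))) {
      cod <- g$codons[idx]
      if (cod %in% .STOP_CODONS) next
      for (stp in sample(.STOP_CODONS)) {
        diff <- which(strsplit(cod, "")[[1L]] != strsplit(stp, "")[[1L]])
        if (length(diff) == 1L)
          return(list(p = codonPos(g, idx, diff), refT = substr(cod, diff, diff),
                      altT = substr(stp, diff, diff)))
      }
    }
    NULL
  })
  plantCodonClass("stop_loss", function(g) {
    cod <- g$codons[g$ncod]
    for (w in sample(1:3)) for (b in sample(setdiff(.BASES, substr(cod, w, w)))) {
      new <- cod; substr(new, w, w) <- b
      if (!new %in% .STOP_CODONS)
        return(list(p = codonPos(g, g$ncod, w), refT = substr(cod, w, w), altT = b))
    }
    NULL
  })

  ## --- frameshift insertions ----------------------------------------------
  planted <- 0L; k <- 0L
  while (planted < nPer) {
    k <- k + 1L
    g <- geneCycle(k)
    p <- sample((g$cds_tx[1L] + 3L):(g$cds_tx[2L] - 3L), 1L)
    gpos <- .txToGenome(g, p)
    if (!claim(g$chrom, gpos)) next
    ref <- baseAt(g$chrom, gpos)
    ins <- paste(sample(.BASES, if (k %% 2L == 0L) 2L else 1L, replace = TRUE),
                 collapse = "")
    add(g$chrom, gpos, ref, paste0(ref, ins), "frameshift", g$gene_id)
    planted <- planted + 1L
  }

  ## --- splice sites and introns -------------------------------------------
  plantIntronic <- function(class, picker) {
    planted <- 0L; k <- 0L
    while (planted < nPer) {
      k <- k + 1L
      if (k > 50L * nPer) stop("could not place ", class, " variants")
      g <- geneCycle(k)
      introns <- .geneIntronsG(g)
      if (is.null(introns)) next
      j <- sample(nrow(introns), 1L)
      pos <- picker(introns[j, 1L], introns[j, 2L])
      if (is.null(pos) || !claim(g$chrom, pos)) next
      ref <- baseAt(g$chrom, pos)
      add(g$chrom, pos, ref, sample(setdiff(.BASES, ref), 1L), class, g$gene_id)
      planted <- planted + 1L
    }
  }
  plantIntronic("splice_site", function(s, e) sample(c(s, s + 1L, e - 1L, e), 1L))
  plantIntronic("intron", function(s, e) {
    if (e - s + 1L < 12L) return(NULL)
    sample((s + 4L):(e - 4L), 1L)
  })

  ## --- intergenic (and sub-threshold) --------------------------------------
  occupied <- reduce(c(
    GRanges(vapply(genes, `[[`, character(1), "chrom"),
            IRanges(vapply(genes, function(g) g$offset, numeric(1)),
                    vapply(genes, function(g) g$offset + g$L - 1L, numeric(1)))),
    repeatRanges(sim$annotation),
    GRanges(unlist(lapply(unlist(sim$meta$hidden, recursive = FALSE),
                          `[[`, "chrom")),
            IRanges(vapply(unlist(sim$meta$hidden, recursive = FALSE),
                           `[[`, numeric(1), "start"),
                    vapply(unlist(sim$meta$hidden, recursive = FALSE),
                           `[[`, numeric(1), "end")))),
    ignore.strand = TRUE)
  sampleIntergenic <- function() {
    repeat {
      chrom <- sample(sim$meta$chrom_ids, 1L)
      pos <- sample(200:(config$chrom_length - 200L), 1L)
      gr <- GRanges(chrom, IRanges(pos, pos))
      if (!any(countOverlaps(gr, occupied) > 0L) && claim(chrom, pos))
        return(list(chrom = chrom, pos = pos))
    }
  }
  for (k in seq_len(nPer)) {
    s <- sampleIntergenic()
    ref <- baseAt(s$chrom, s$pos)
    add(s$chrom, s$pos, ref, sample(setdiff(.BASES, ref), 1L), "intergenic", NA)
  }
  for (k in seq_len(config$n_subthreshold_variants)) {
    s <- sampleIntergenic()
    ref <- baseAt(s$chrom, s$pos)
    add(s$chrom, s$pos, ref, sample(setdiff(.BASES, ref), 1L), "filtered", NA)
  }

  truth <- do.call(rbind, rows)
  n <- nrow(truth)
  depth <- sample(8:60, n, replace = TRUE)
  qual <- sample(100:900, n, replace = TRUE)
  freq <- round(stats::runif(n, 0.80, 1.00), 3)
  # exact inclusive boundary on the first variant of each effect class
  firstOf <- !duplicated(truth$class) & truth$class != "filtered"
  depth[firstOf] <- 5L; qual[firstOf] <- 80; freq[firstOf] <- 0.75
  # sub-threshold records fail exactly one filter each, cycling
  sub <- which(truth$class == "filtered")
  fail <- rep(c("depth", "quality", "frequency"), length.out = length(sub))
  depth[sub[fail == "depth"]] <- 4L
  qual[sub[fail == "quality"]] <- 79
  freq[sub[fail == "frequency"]] <- 0.74

  variants <- GRanges(truth$chrom, IRanges(truth$pos, truth$pos))
  mcols(variants)$ref <- truth$ref
  mcols(variants)$alt <- truth$alt
  mcols(variants)$depth <- depth
  mcols(variants)$qual <- as.numeric(qual)
  mcols(variants)$alt_freq <- freq
  mcols(variants)$class <- truth$class
  ord <- order(as.character(seqnames(variants)), start(variants))
  list(variants = variants[ord], truth = truth[ord, , drop = FALSE])
}
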