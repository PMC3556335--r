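## Seeded generator of a toy cultivar-transcriptome study with planted truth.

.SENSE_CODONS <- setdiff(names(Biostrings::GENETIC_CODE), .STOP_CODONS)
## skewed codon-usage weights: planted coding sequences carry the codon bias
## real coding regions have, which the coding-potential heuristic measures
.CODON_WEIGHTS <- stats::setNames(exp(-0.08 * (seq_along(.SENSE_CODONS) - 1)),
                                  .SENSE_CODONS)

.randSeq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.biasedCodons <- function(n) {
  sample(.SENSE_CODONS, n, replace = TRUE, prob = .CODON_WEIGHTS)
}

## random sequence with a clearly negative coding-potential call (random
## sequences carry chance partial ORFs, so "no ORF at all" is the wrong
## requirement; what the planted non-coding classes need is a low score)
.noncodingSeq <- function(n, max_score = 0.4) {
  for (tries in 1:100) {
    s <- .randSeq(n)
    if (codingPotential(s)$score <= max_score) return(s)
  }
  stop("could not generate a low-coding-potential sequence of length ", n)
}

## flanked full-ORF construct; the ORF spans most of the sequence
.codingSeq <- function(n_codons, flank = 30L) {
  paste0(.randSeq(flank),
         "ATG", paste(.biasedCodons(n_codons - 2L), collapse = ""),
         sample(.STOP_CODONS, 1L),
         .randSeq(flank))
}

#' Configuration of the synthetic study
#'
#' Bundles every knob of the generator with defaults that emulate the study
#' design at desk scale: a 2-chromosome 1-Mb toy genome with 60 annotated
#' genes; planted contigs of every triage class; 8 variant-effect classes
#' at 25 variants each (200 planted effects) plus sub-threshold records
#' straddling the depth/quality/frequency filters; negative-binomial counts
#' for 3 berry stages (PFS, PR, PHWII) x 3 replicates with planted
#' profile patterns realized as x8 / x(1/8) stage-mean multipliers.
#'
#' @param seed Integer seed; a fixed seed makes every generated file
#'   byte-identical between runs.
#' @param n_chroms,chrom_length,n_genes,exons_per_gene Genome layout.
#' @param n_identical,n_novel_isoform,n_pre_mrna,n_chimera,n_merged_pairs,n_fragment,n_repeat_contig
#'   Planted mapped-contig class counts (`n_pre_mrna` genes each emit a
#'   major isoform plus an intron-retaining low-expression contig).
#' @param n_novel_coding,n_novel_noncoding,n_novel_transposon,n_novel_rfam,n_novel_homology
#'   Planted novel-locus class counts.
#' @param n_private,n_private_clusters,n_gap_coding,n_gap_noncoding,n_contaminant,n_no_evidence
#'   Planted unmapped-contig class counts.
#' @param variants_per_class,n_subthreshold_variants Variant planting.
#' @param nb_mean,nb_dispersion,pattern_props Count simulation; pattern
#'   proportions over `flat` and profile clusters 1-4.
#' @param substitution_rate Per-base contig substitution error rate
#'   (default 0.01); set 0 for noise-free contigs.
#' @param edge_jitter Optional +/- bp perturbation of alignment block edges
#'   (default 0) to exercise structural tolerances.
#' @return A classed list (`simulation_config`).
#' @export
simulationConfig <- function(seed = 1L,
                             n_chroms = 2L, chrom_length = 500000L,
                             n_genes = 60L, exons_per_gene = c(3L, 5L),
                             n_identical = 15L, n_novel_isoform = 10L,
                             n_pre_mrna = 8L, n_chimera = 5L,
                             n_merged_pairs = 3L, n_fragment = 5L,
                             n_repeat_contig = 3L,
                             n_novel_coding = 6L, n_novel_noncoding = 4L,
                             n_novel_transposon = 2L, n_novel_rfam = 2L,
                             n_novel_homology = 2L,
                             n_private = 8L, n_private_clusters = 5L,
                             n_gap_coding = 3L, n_gap_noncoding = 2L,
                             n_contaminant = 6L, n_no_evidence = 3L,
                             variants_per_class = 25L,
                             n_subthreshold_variants = 18L,
                             nb_mean = 200, nb_dispersion = 0.05,
                             pattern_props = c(flat = 0.6, `1` = 0.1, `2` = 0.1,
                                               `3` = 0.1, `4` = 0.1),
                             substitution_rate = 0.01, edge_jitter = 0L) {
  cfg <- as.list(environment())
  counts <- unlist(cfg[grep("^n_", names(cfg))])
  if (any(counts < 0)) stop("all planted counts must be >= 0")
  needGenes <- n_identical + n_novel_isoform + n_pre_mrna + 2L * n_chimera +
    2L * n_merged_pairs + n_fragment
  if (needGenes > n_genes)
    stop("n_genes too small: planted mapped classes need ", needGenes, " genes")
  if (abs(sum(pattern_props) - 1) > 1e-9)
    stop("pattern_props must sum to 1")
  if (n_private < n_private_clusters)
    stop("n_private must be >= n_private_clusters")
  structure(cfg, class = "simulation_config")
}

## transcript coordinate -> genomic position for one gene's meta record
.txToGenome <- function(g, p) {
  i <- which(p >= g$exon_tx[, 1L] & p <= g$exon_tx[, 2L])
  if (length(i) != 1L) stop("transcript position ", p, " not exonic")
  cass <- g$exon_cass[i, 1L] + (p - g$exon_tx[i, 1L])
  if (g$strand == "+") g$offset + cass - 1L else g$offset + g$L - cass
}

## build one gene cassette; returns sequence + meta
.buildGene <- function(gene_id, tx_id, chrom, strand, offset, exon_range) {
  nExons <- sample(exon_range[1L]:exon_range[2L], 1L)
  ncod <- sample(60:180, 1L)
  utr5 <- sample(30:80, 1L)
  mrna <- paste0(.randSeq(utr5),
                 "ATG", paste(.biasedCodons(ncod - 2L), collapse = ""),
                 sample(.STOP_CODONS, 1L),
                 .randSeq(sample(30:80, 1L)))
  M <- nchar(mrna)
  nExons <- max(2L, min(nExons, M %/% 60L))
  repeat {
    cuts <- sort(sample(51:(M - 51L), nExons - 1L))
    if (all(diff(c(0L, cuts, M)) >= 50L)) break
  }
  exTx <- cbind(c(1L, cuts + 1L), c(cuts, M))
  intronLens <- sample(80:300, nExons - 1L, replace = TRUE)
  introns <- vapply(intronLens, function(l)
    paste0("GT", .randSeq(l - 4L), "AG"), character(1))

  pieces <- character(0)
  exCass <- matrix(0L, nExons, 2L)
  cursor <- 0L
  for (i in seq_len(nExons)) {
    w <- exTx[i, 2L] - exTx[i, 1L] + 1L
    exCass[i, ] <- c(cursor + 1L, cursor + w)
    pieces <- c(pieces, substr(mrna, exTx[i, 1L], exTx[i, 2L]))
    cursor <- cursor + w
    if (i < nExons) {
      pieces <- c(pieces, introns[i])
      cursor <- cursor + nchar(introns[i])
    }
  }
  cassette <- paste(pieces, collapse = "")
  L <- nchar(cassette)
  toG <- function(a, b) {
    if (strand == "+") c(offset + a - 1L, offset + b - 1L)
    else c(offset + L - b, offset + L - a)
  }
  exG <- t(apply(exCass, 1L, function(r) toG(r[1L], r[2L])))
  exonGr <- sort(GRanges(chrom, IRanges(exG[, 1L], exG[, 2L]), strand = strand),
                 ignore.strand = TRUE)
  cdsTx <- c(utr5 + 1L, utr5 + 3L * ncod)
  cdsPieces <- list()
  for (i in seq_len(nExons)) {
    a <- max(exTx[i, 1L], cdsTx[1L]); b <- min(exTx[i, 2L], cdsTx[2L])
    if (a <= b) {
      ca <- exCass[i, 1L] + (a - exTx[i, 1L])
      cb <- exCass[i, 1L] + (b - exTx[i, 1L])
      cdsPieces[[length(cdsPieces) + 1L]] <- toG(ca, cb)
    }
  }
  cdsMat <- do.call(rbind, cdsPieces)
  cdsGr <- sort(GRanges(chrom, IRanges(cdsMat[, 1L], cdsMat[, 2L]),
                        strand = strand), ignore.strand = TRUE)
  insert <- if (strand == "+") cassette else
    as.character(reverseComplement(DNAString(cassette)))
  list(gene_id = gene_id, tx_id = tx_id, chrom = chrom, strand = strand,
       offset = offset, L = L, mrna = mrna, ncod = ncod, utr5 = utr5,
       exon_tx = exTx, exon_cass = exCass, exon_g = exonGr, cds_tx = cdsTx,
       cds_g = cdsGr, insert = insert,
       codons = substring(mrna, utr5 + 1L + 3L * (0:(ncod - 1L)),
                          utr5 + 3L * (1:ncod)))
}

#' Generate the toy genome and its annotation
#'
#' Lays `n_genes` gene cassettes (valid ATG...stop CDS, length a multiple
#' of 3, GT..AG introns, both strands) along random chromosome
#' backgrounds, with the first `2 * n_merged_pairs` genes placed as
#' close adjacent same-strand pairs (the merged-locus substrate).  Hidden
#' novel-locus cassettes (coding and non-coding) and annotated repeat
#' intervals are written into the genome but kept out of the gene
#' annotation.
#'
#' @param config A [simulationConfig()].
#' @return A list: `genome` ([Biostrings::DNAStringSet]), `annotation`
#'   ([TranscriptModels-class]), and `meta` (internal layout records used
#'   by the other generators, including the hidden novel loci).
#' @export
generateGenomeAndAnnotation <- function(config) {
  set.seed(config$seed)
  chromIds <- sprintf("chr%d", seq_len(config$n_chroms))
  chromSeq <- lapply(chromIds, function(x) .randSeq(config$chrom_length))
  names(chromSeq) <- chromIds

  nG <- config$n_genes
  genes <- vector("list", nG)
  cursor <- stats::setNames(rep(5000L, config$n_chroms), chromIds)
  chromOf <- chromIds[(seq_len(nG) - 1L) %% config$n_chroms + 1L]
  # merged pairs: both genes of a pair on the same chromosome and strand
  pairGenes <- seq_len(2L * config$n_merged_pairs)
  if (length(pairGenes))
    chromOf[pairGenes] <- chromIds[(ceiling(pairGenes / 2) - 1L) %%
                                     config$n_chroms + 1L]
  strandOf <- sample(c("+", "-"), nG, replace = TRUE)
  if (length(pairGenes))
    strandOf[pairGenes] <- rep(strandOf[pairGenes[c(TRUE, FALSE)]], each = 2L)

  if (nG > 0) for (i in seq_len(nG)) {
    chrom <- chromOf[i]
    gap <- if (i %in% pairGenes && i %% 2L == 0L)
      sample(200:400, 1L) else sample(2000:5000, 1L)
    offset <- cursor[chrom] + gap
    g <- .buildGene(sprintf("g%03d", i), sprintf("g%03d.t1", i), chrom,
                    strandOf[i], offset, config$exons_per_gene)
    if (offset + g$L > config$chrom_length - 5000L)
      stop("genome too small for ", nG, " genes; need about ",
           ceiling((offset + g$L + 10000) / 1000), " kb per chromosome")
    substr(chromSeq[[chrom]], offset, offset + g$L - 1L) <- g$insert
    cursor[chrom] <- offset + g$L
    genes[[i]] <- g
  }

  placeHidden <- function(n, maker, prefix) {
    out <- vector("list", n)
    if (n > 0) for (i in seq_len(n)) {
      s <- maker()
      chrom <- chromIds[(i - 1L) %% config$n_chroms + 1L]
      offset <- cursor[chrom] + sample(2000:4000, 1L)
      if (offset + nchar(s) > config$chrom_length - 2000L)
        stop("genome too small for hidden loci")
      tmp <- chromSeq[[chrom]]
      substr(tmp, offset, offset + nchar(s) - 1L) <- s
      chromSeq[[chrom]] <<- tmp
      cursor[chrom] <<- offset + nchar(s)
      out[[i]] <- list(id = sprintf("%s%02d", prefix, i), chrom = chrom,
                       start = offset, end = offset + nchar(s) - 1L, seq = s)
    }
    out
  }
  hidden <- list(
    coding = placeHidden(config$n_novel_coding,
                         function() .codingSeq(sample(100:150, 1L)), "hidc"),
    noncoding = placeHidden(config$n_novel_noncoding,
                            function() .noncodingSeq(sample(300:500, 1L)), "hidn"),
    transposon = placeHidden(config$n_novel_transposon,
                             function() .codingSeq(sample(100:150, 1L)), "hidt"),
    rfam = placeHidden(config$n_novel_rfam,
                       function() .noncodingSeq(sample(300:500, 1L)), "hidr"),
    homology = placeHidden(config$n_novel_homology,
                           function() .noncodingSeq(sample(300:500, 1L)), "hidh"))
  repeats <- placeHidden(config$n_repeat_contig,
                         function() .randSeq(500L), "rep")

  genome <- DNAStringSet(vapply(chromSeq, identity, character(1)))
  names(genome) <- chromIds

  if (nG > 0) {
    exons <- GRangesList(lapply(genes, `[[`, "exon_g"))
    cds <- GRangesList(lapply(genes, `[[`, "cds_g"))
    info <- DataFrame(transcript_id = vapply(genes, `[[`, character(1), "tx_id"),
                      gene_id = vapply(genes, `[[`, character(1), "gene_id"),
                      chrom = vapply(genes, `[[`, character(1), "chrom"),
                      strand = vapply(genes, `[[`, character(1), "strand"))
  } else {
    exons <- GRangesList(); cds <- GRangesList()
    info <- DataFrame(transcript_id = character(0), gene_id = character(0),
                      chrom = character(0), strand = character(0))
  }
  repGr <- if (length(repeats))
    GRanges(vapply(repeats, `[[`, character(1), "chrom"),
            IRanges(vapply(repeats, `[[`, numeric(1), "start"),
                    vapply(repeats, `[[`, numeric(1), "end")))
  else GRanges()
  annotation <- TranscriptModels(exons, cds, info, repeats = repGr)
  list(genome = genome, annotation = annotation,
       meta = list(genes = genes, hidden = hidden, repeats = repeats,
                   chrom_ids = chromIds))
}
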