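## splice the genomic sequence of a block chain (tx orientation)
.spliceBlocks <- function(genome, blocks, strand) {
  chrom <- as.character(seqnames(blocks))[1L]
  s <- paste(vapply(seq_along(blocks), function(j)
    as.character(subseq(genome[[chrom]], start(blocks)[j], end(blocks)[j])),
    character(1)), collapse = "")
  if (strand == "-") s <- as.character(reverseComplement(DNAString(s)))
  s
}

## uniform substitution errors; returns sequence and realized error count
.addErrors <- function(seq, rate) {
  n <- nchar(seq)
  nSub <- stats::rbinom(1L, n, rate)
  if (nSub > 0L) {
    pos <- sample.int(n, nSub)
    for (p in pos) {
      old <- substr(seq, p, p)
      substr(seq, p, p) <- sample(setdiff(.BASES, old), 1L)
    }
  }
  list(seq = seq, n_sub = nSub)
}

#' Simulate assembled contigs, their alignments, homology hits and truth
#'
#' Emits one contig per planted class instance: exact isoform copies,
#' exon-skipping novel isoforms, intron-retaining pre-mRNA contigs at low
#' planted expression (each alongside an exact major isoform of the same
#' gene), two-segment cross-chromosome chimeras, read-through contigs
#' spanning two adjacent genes, exon fragments / exact single exons /
#' exon-intron blocks (all removed as fragments by triage), repeat-region
#' copies, novel-locus contigs over the hidden cassettes (coding,
#' non-coding, transposon-like, RNA-family-like, homology-supported), and
#' the unmapped set: private-gene candidates sharing plant-database
#' subjects in planted clusters, assembly-gap genes matched by a raw-read
#' pool, contaminants with non-plant best hits, and no-evidence contigs.
#' Alignments are emitted from generative truth; substitution errors at
#' `substitution_rate` perturb the sequences and are reflected in the
#' identity column.
#'
#' @param config A [simulationConfig()].
#' @param sim Output of [generateGenomeAndAnnotation()].
#' @return A list: `contigs` ([Biostrings::DNAStringSet]), `alignments`
#'   ([SplicedAlignments-class]), `hits` (homology `data.frame`),
#'   `expression` (named FPKM vector), `raw_reads`
#'   ([Biostrings::DNAStringSet] read pool for the gap genes), and `truth`
#'   (`data.frame`: `contig_id`, `class`, `merged`, `gene_id`,
#'   `novel_class`, `unmapped_class`, `private_cluster`).
#' @export
simulateContigs <- function(config, sim) {
  set.seed(config$seed + 2L)
  genes <- sim$meta$genes
  genome <- sim$genome
  rate <- config$substitution_rate

  seqs <- character(0)
  segBlocks <- list()        # one element per alignment segment
  segInfo <- list()
  truthRows <- list()
  expr <- numeric(0)
  hitRows <- list()
  ctgN <- 0L

  newId <- function() {
    ctgN <<- ctgN + 1L
    sprintf("contig_%04d", ctgN)
  }
  addTruth <- function(id, class, merged = FALSE, gene = NA, novel = NA,
                       unmapped = NA, privCluster = NA) {
    truthRows[[length(truthRows) + 1L]] <<- data.frame(
      contig_id = id, class = class, merged = merged, gene_id = gene,
      novel_class = novel, unmapped_class = unmapped,
      private_cluster = privCluster, stringsAsFactors = FALSE)
  }
  addSegment <- function(id, blocks, strand, identity, coverage) {
    segBlocks[[length(segBlocks) + 1L]] <<- blocks
    segInfo[[length(segInfo) + 1L]] <<- data.frame(
      contig_id = id, segment = NA_integer_,
      chrom = as.character(seqnames(blocks))[1L], strand = strand,
      identity = identity, coverage = coverage, stringsAsFactors = FALSE)
  }
  addHit <- function(query, subject, database, taxon, e_value = 1e-30,
                     bitscore = 300, identity = 0.95, coverage = 0.8) {
    hitRows[[length(hitRows) + 1L]] <<- data.frame(
      query_id = query, subject_id = subject, identity = identity,
      e_value = e_value, bitscore = bitscore, database = database,
      taxon = taxon, query_coverage = coverage, stringsAsFactors = FALSE)
  }
  jitter <- function(blocks) {
    if (config$edge_jitter == 0L) return(blocks)
    d <- sample(-config$edge_jitter:config$edge_jitter, 2L, replace = TRUE)
    start(blocks)[1L] <- max(1L, start(blocks)[1L] + d[1L])
    end(blocks)[length(blocks)] <- end(blocks)[length(blocks)] + d[2L]
    blocks
  }
  mappedContig <- function(blocks, strand, class, gene, fpkm, merged = FALSE,
                           novel = NA) {
    id <- newId()
    s <- .spliceBlocks(genome, blocks, strand)
    e <- .addErrors(s, rate)
    seqs[id] <<- e$seq
    addSegment(id, jitter(blocks), strand, 1 - e$n_sub / nchar(e$seq), 1.0)
    addTruth(id, class, merged = merged, gene = gene, novel = novel)
    expr[id] <<- fpkm
    id
  }

  ## ---- allocate genes to mapped classes -----------------------------------
  nPairs <- config$n_merged_pairs
  pairIdx <- seq_len(2L * nPairs)
  pool <- setdiff(seq_along(genes), pairIdx)
  nExonsOf <- vapply(genes, function(g) length(g$exon_g), integer(1))
  widestExon <- vapply(genes, function(g) max(width(g$exon_g)), integer(1))
  take <- function(n, criterion = rep(TRUE, length(genes))) {
    avail <- pool[criterion[pool]]
    if (length(avail) < n) stop("not enough genes for the requested classes")
    picked <- avail[seq_len(n)]
    pool <<- setdiff(pool, picked)
    picked
  }
  gNovel <- take(config$n_novel_isoform, nExonsOf >= 3L)
  gPre <- take(config$n_pre_mrna, nExonsOf >= 3L)
  gFrag <- take(config$n_fragment, widestExon >= 90L)
  gIdent <- take(config$n_identical)
  gChim <- take(2L * config$n_chimera)

  ## ---- mapped classes -----------------------------------------------------
  for (i in gIdent) {
    g <- genes[[i]]
    mappedContig(g$exon_g, g$strand, "identical_isoform", g$gene_id,
                 round(stats::runif(1, 20, 80), 2))
  }
  for (i in gNovel) {
    g <- genes[[i]]
    skip <- sample(2:(length(g$exon_g) - 1L), 1L)     # drop an internal exon
    mappedContig(g$exon_g[-skip], g$strand, "novel_isoform", g$gene_id,
                 round(stats::runif(1, 20, 80), 2))
  }
  for (i in gPre) {
    g <- genes[[i]]
    major <- round(stats::runif(1, 40, 80), 2)
    mappedContig(g$exon_g, g$strand, "identical_isoform", g$gene_id, major)
    j <- sample(length(g$exon_g) - 1L, 1L)            # retained intron j
    b <- g$exon_g
    retained <- c(
      if (j > 1L) b[seq_len(j - 1L)] else GRanges(),
      GRanges(seqnames(b)[1L], IRanges(start(b)[j], end(b)[j + 1L]),
              strand = g$strand),
      if (j + 1L < length(b)) b[seq(j + 2L, length(b))] else GRanges())
    mappedContig(retained, g$strand, "pre_mrna_filtered", g$gene_id,
                 round(0.02 * major, 3))
  }
  if (nPairs > 0) for (p in seq_len(nPairs)) {
    a <- genes[[2L * p - 1L]]; b <- genes[[2L * p]]
    blocks <- sort(c(a$exon_g, b$exon_g), ignore.strand = TRUE)
    mappedContig(blocks, a$strand, "merged_readthrough",
                 paste(sort(c(a$gene_id, b$gene_id)), collapse = "+"),
                 round(stats::runif(1, 20, 60), 2), merged = TRUE)
  }
  # pair chimera donor genes so the two segments are discordant
  # (different chromosomes when available, else different strands)
  if (config$n_chimera > 0) {
    chromOfPick <- vapply(genes[gChim], `[[`, character(1), "chrom")
    ord <- order(chromOfPick)
    half <- length(gChim) %/% 2L
    gChim <- as.vector(rbind(gChim[ord][seq_len(half)],
                             gChim[ord][seq(length(gChim), half + 1L)]))
  }
  if (config$n_chimera > 0) for (c_ in seq_len(config$n_chimera)) {
    a <- genes[[gChim[2L * c_ - 1L]]]; b <- genes[[gChim[2L * c_]]]
    if (a$chrom == b$chrom && a$strand == b$strand)
      stop("cannot plant a discordant chimera from genes ", a$gene_id,
           " and ", b$gene_id)
    id <- newId()
    sA <- .spliceBlocks(genome, a$exon_g, a$strand)
    sB <- .spliceBlocks(genome, b$exon_g, b$strand)
    e <- .addErrors(paste0(sA, sB), rate)
    seqs[id] <- e$seq
    lenA <- nchar(sA); lenB <- nchar(sB)
    idy <- 1 - e$n_sub / (lenA + lenB)
    addSegment(id, a$exon_g, a$strand, idy, lenA / (lenA + lenB))
    addSegment(id, b$exon_g, b$strand, idy, lenB / (lenA + lenB))
    addTruth(id, "chimera_excluded", gene = paste(a$gene_id, b$gene_id, sep = "+"))
    expr[id] <- 5
  }
  fragKind <- rep(c("exon_fragment", "single_exon", "partial_intron"),
                  length.out = length(gFrag))
  for (k in seq_along(gFrag)) {
    g <- genes[[gFrag[k]]]
    j <- which.max(width(g$exon_g))
    ex <- g$exon_g[j]
    blocks <- switch(fragKind[k],
      exon_fragment = GRanges(seqnames(ex), IRanges(start(ex) + 15L,
                                                    end(ex) - 15L),
                              strand = g$strand),
      single_exon = granges(ex),
      partial_intron = {
        introns <- .geneIntronsG(g)
        j2 <- sample(nrow(introns), 1L)
        dI <- min(introns[j2, 2L] - introns[j2, 1L] - 1L, 120L)
        GRanges(g$chrom, IRanges(introns[j2, 1L] - 40L,
                                 introns[j2, 1L] + dI - 1L),
                strand = g$strand)
      })
    strand(blocks) <- g$strand
    mappedContig(blocks, g$strand, "fragment_removed", g$gene_id, 5)
  }
  for (r in sim$meta$repeats) {
    blocks <- GRanges(r$chrom, IRanges(r$start, r$end), strand = "+")
    mappedContig(blocks, "+", "repeat_region", NA, 5)
  }

  ## ---- novel loci ---------------------------------------------------------
  novelClassOf <- c(coding = NA, noncoding = "putative_ncRNA",
                    transposon = "transposon_like", rfam = "rna_family_like",
                    homology = "homology_supported")
  for (kind in names(sim$meta$hidden)) {
    for (h in sim$meta$hidden[[kind]]) {
      blocks <- GRanges(h$chrom, IRanges(h$start, h$end), strand = "+")
      novel <- if (kind == "coding") "coding_full_orf" else novelClassOf[[kind]]
      id <- mappedContig(blocks, "+", "novel_locus", NA, 10, novel = novel)
      if (kind == "transposon")
        addHit(id, sprintf("TPASE_%s", h$id), "transposon_protein", "Viridiplantae")
      if (kind == "rfam")
        addHit(id, sprintf("RF%s", h$id), "rfam", "Viridiplantae")
      if (kind == "homology")
        addHit(id, sprintf("NRP_%s", h$id), "nr_protein", "Viridiplantae")
    }
  }

  ## ---- unmapped classes ---------------------------------------------------
  clusterOf <- sort(rep(seq_len(config$n_private_clusters),
                        length.out = config$n_private))
  for (k in seq_len(config$n_private)) {
    id <- newId()
    cl <- clusterOf[k]
    coding <- cl %% 2L == 1L
    seqs[id] <- if (coding) .codingSeq(sample(100:150, 1L))
                else .noncodingSeq(sample(300:500, 1L))
    addHit(id, sprintf("VVGI_%03d", cl), "vvgi_est", "Viridiplantae",
           bitscore = 200 + cl)
    addTruth(id, "unmapped", unmapped = "private_candidate",
             privCluster = sprintf("pc%02d", cl))
    expr[id] <- 2
  }
  gapKinds <- rep(c(TRUE, FALSE), c(config$n_gap_coding, config$n_gap_noncoding))
  rawReads <- character(0)
  for (k in seq_along(gapKinds)) {
    id <- newId()
    s <- if (gapKinds[k]) .codingSeq(sample(120:160, 1L))
         else .noncodingSeq(sample(300:500, 1L))
    seqs[id] <- s
    addHit(id, sprintf("rawpool_%02d", k), "genome_raw_reads", "Viridiplantae")
    addTruth(id, "unmapped",
             unmapped = if (gapKinds[k]) "missing_from_assembly_coding"
                        else "missing_from_assembly")
    expr[id] <- 2
    starts <- seq(1L, max(1L, nchar(s) - 99L), by = 50L)
    frags <- substring(s, starts, pmin(starts + 99L, nchar(s)))
    names(frags) <- sprintf("%s_read_%02d", id, seq_along(frags))
    rawReads <- c(rawReads, frags)
  }
  contamTaxa <- c(rep("Fungi", ceiling(0.82 * config$n_contaminant)),
                  rep(c("Bacteria", "Metazoa"),
                      length.out = max(0L, config$n_contaminant -
                                         ceiling(0.82 * config$n_contaminant))))
  for (k in seq_len(config$n_contaminant)) {
    id <- newId()
    seqs[id] <- .randSeq(sample(300:600, 1L))
    addHit(id, sprintf("XPROT_%03d", k), "nr_protein", contamTaxa[k],
           bitscore = 400)
    addTruth(id, "unmapped", unmapped = "contaminant")
    expr[id] <- 2
  }
  for (k in seq_len(config$n_no_evidence)) {
    id <- newId()
    seqs[id] <- .randSeq(sample(300:600, 1L))
    # a hit too weak to survive the E-value pre-filter
    addHit(id, sprintf("WEAK_%02d", k), "nr_protein", "Viridiplantae",
           e_value = 1e-3, bitscore = 30)
    addTruth(id, "unmapped", unmapped = "no_evidence")
    expr[id] <- 2
  }

  info <- do.call(rbind, segInfo)
  info$segment <- stats::ave(seq_len(nrow(info)), info$contig_id,
                             FUN = seq_along)
  contigs <- DNAStringSet(seqs)
  list(contigs = contigs,
       alignments = SplicedAlignments(GRangesList(segBlocks),
                                      DataFrame(info)),
       hits = do.call(rbind, hitRows),
       expression = expr,
       raw_reads = DNAStringSet(rawReads),
       truth = do.call(rbind, truthRows))
}
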