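# Shared synthetic studies, generated once per test run and cached.
.studyCache <- new.env(parent = emptyenv())

syntheticStudy <- function(noise = c("default", "none"), seed = 101L) {
  noise <- match.arg(noise)
  key <- paste0(noise, "_", seed)
  if (is.null(.studyCache[[key]])) {
    cfg <- simulationConfig(
      seed = seed,
      substitution_rate = if (noise == "none") 0 else 0.01)
    dir <- file.path(tempdir(), paste0("study_", key))
    .studyCache[[key]] <- simulateStudy(cfg, dir)
  }
  .studyCache[[key]]
}

# triage calls vs planted truth: read-through contigs are judged by the
# merged flag, every other class by exact label equality
triageMatchesTruth <- function(calls, truth) {
  m <- merge(calls, truth, by = "contig_id", suffixes = c("", ".truth"))
  ifelse(m$class.truth == "merged_readthrough", m$merged,
         m$class == m$class.truth)
}

# hand-built toy genome + annotation with known gene structures:
#   gA: plus strand, single exon [101,140], CDS [111,119] = ATG AAA TGA
#   gB: plus strand, exons [201,230]+[261,290], intron [231,260],
#       CDS pieces [211,230]+[261,270] = ATG (AAA x8) TGA split 20/10
#   gC: minus strand mirror of gA, exon [301,340], CDS [311,319]
tinyModels <- function() {
  base <- paste(rep("ACGT", 100), collapse = "")   # 400 bp background
  g <- base
  substr(g, 111, 119) <- "ATGAAATGA"
  cdsB <- paste0("ATG", strrep("AAA", 8), "TGA")
  substr(g, 211, 230) <- substr(cdsB, 1, 20)
  substr(g, 231, 232) <- "GT"                      # donor
  substr(g, 259, 260) <- "AG"                      # acceptor
  substr(g, 261, 270) <- substr(cdsB, 21, 30)
  rcA <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("ATGAAATGA")))
  substr(g, 311, 319) <- rcA
  genome <- Biostrings::DNAStringSet(c(chr1 = g))

  exons <- GenomicRanges::GRangesList(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 140), strand = "+"),
    GenomicRanges::GRanges("chr1", IRanges::IRanges(c(201, 261), c(230, 290)),
                           strand = "+"),
    GenomicRanges::GRanges("chr1", IRanges::IRanges(301, 340), strand = "-"))
  cds <- GenomicRanges::GRangesList(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(111, 119), strand = "+"),
    GenomicRanges::GRanges("chr1", IRanges::IRanges(c(211, 261), c(230, 270)),
                           strand = "+"),
    GenomicRanges::GRanges("chr1", IRanges::IRanges(311, 319), strand = "-"))
  info <- S4Vectors::DataFrame(
    transcript_id = c("gA.t1", "gB.t1", "gC.t1"),
    gene_id = c("gA", "gB", "gC"),
    chrom = "chr1",
    strand = c("+", "+", "-"))
  list(genome = genome, annotation = TranscriptModels(exons, cds, info))
}

snv <- function(chrom, pos, ref, alt, depth = 50L, qual = 500, freq = 0.9) {
  v <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  S4Vectors::mcols(v)$ref <- ref
  S4Vectors::mcols(v)$alt <- alt
  S4Vectors::mcols(v)$depth <- depth
  S4Vectors::mcols(v)$qual <- qual
  S4Vectors::mcols(v)$alt_freq <- freq
  v
}
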