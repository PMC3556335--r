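mkAln <- function(blockList, ids = NULL, identity = 1, coverage = 1,
                  strand = "+") {
  blocks <- GenomicRanges::GRangesList(lapply(blockList, function(b)
    GenomicRanges::GRanges(b$chrom, IRanges::IRanges(b$start, b$end),
                           strand = if (!is.null(b$strand)) b$strand else strand)))
  n <- length(blockList)
  info <- S4Vectors::DataFrame(
    contig_id = if (is.null(ids)) sprintf("c%d", seq_len(n)) else ids,
    segment = 1L,
    chrom = vapply(blockList, `[[`, character(1), "chrom"),
    strand = vapply(blockList, function(b)
      if (!is.null(b$strand)) b$strand else strand, character(1)),
    identity = rep_len(identity, n), coverage = rep_len(coverage, n))
  info$segment <- stats::ave(seq_len(n), info$contig_id, FUN = seq_along)
  SplicedAlignments(blocks, info)
}

test_that("greedy clustering keeps the longest member and absorbs contained sequences", {
  s <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = "")
  contigs <- Biostrings::DNAStringSet(c(long = s, copy = s))
  cl <- clusterContigs(contigs)
  expect_equal(unique(cl$representative), "copy")   # tie broken by id order

  sub <- substr(s, 11, 11 + ceiling(0.95 * 400) - 1)  # 95%-length substring
  contigs <- Biostrings::DNAStringSet(c(whole = s, part = sub))
  cl <- clusterContigs(contigs)
  expect_equal(unique(cl$representative), "whole")
  expect_equal(nrow(cl), 2L)
})

test_that("clustering agrees with the all-pairs brute force and is order invariant", {
  set.seed(91)
  base <- vapply(1:12, function(i)
    paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE), collapse = ""),
    character(1))
  # add contained fragments of some sequences
  seqs <- c(base, substr(base[1], 20, 140), substr(base[2], 1, 120))
  names(seqs) <- sprintf("s%02d", seq_along(seqs))
  contigs <- Biostrings::DNAStringSet(seqs)
  got <- clusterContigs(contigs)
  want <- bruteClusterContigs(contigs)
  expect_equal(got[order(got$contig_id), ], want[order(want$contig_id), ],
               ignore_attr = TRUE)
  # 50 unrelated random sequences stay singletons
  rnd <- Biostrings::DNAStringSet(vapply(1:50, function(i)
    paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = ""),
    character(1)))
  names(rnd) <- sprintf("r%02d", 1:50)
  expect_equal(length(unique(clusterContigs(rnd)$representative)), 50L)
  # input order does not matter
  perm <- sample(seq_along(contigs))
  got2 <- clusterContigs(contigs[perm])
  expect_equal(got2[order(got2$contig_id), ], got[order(got$contig_id), ],
               ignore_attr = TRUE)
})

test_that("assembly statistics follow the cumulative-sum definition", {
  st <- assemblyStats(c(200, 300, 400, 500, 600))
  expect_equal(st$N50, 500)                         # 600+500 = 1100 >= 1000
  expect_equal(assemblyStats(10)$N50, 10)
  expect_equal(assemblyStats(10)$N90, 10)
  st1 <- assemblyStats(rep(1, 100))
  expect_equal(st1$N50, 1)
  expect_equal(st1$median, 1)
  expect_error(assemblyStats(numeric(0)), "empty")
  set.seed(13)
  for (i in 1:50) {
    lens <- sample(1:5000, sample(1:60, 1), replace = TRUE)
    st <- assemblyStats(lens)
    expect_equal(st$N50, bruteNStat(lens, 0.5))
    expect_equal(st$N90, bruteNStat(lens, 0.9))
    expect_true(st$N90 <= st$N50 && st$N50 <= st$max)
    expect_true(st$min <= st$median && st$median <= st$max)
  }
})

test_that("alignment gating separates mapped, unmapped and chimeric contigs", {
  aln <- mkAln(list(
    list(chrom = "chr1", start = 100L, end = 600L)), ids = "ok",
    identity = 0.95, coverage = 0.92)
  g <- gateAlignments(aln)
  expect_equal(contigIds(g$mapped), "ok")

  # 60/40 split across two chromosomes is a chimera
  aln <- mkAln(list(
    list(chrom = "chr1", start = 100L, end = 600L),
    list(chrom = "chr5", start = 100L, end = 400L)),
    ids = c("chi", "chi"), identity = 0.95, coverage = c(0.6, 0.4))
  g <- gateAlignments(aln)
  expect_equal(g$chimeras, "chi")

  # coverage below the gate: unmapped
  aln <- mkAln(list(list(chrom = "chr1", start = 100L, end = 600L)),
               ids = "low", identity = 0.95, coverage = 0.80)
  g <- gateAlignments(aln)
  expect_equal(g$unmapped, "low")

  # inclusive boundary: exactly 0.90/0.90 maps
  aln <- mkAln(list(list(chrom = "chr1", start = 100L, end = 600L)),
               ids = "edge", identity = 0.90, coverage = 0.90)
  expect_equal(contigIds(gateAlignments(aln)$mapped), "edge")

  # two same-chromosome segments > 1 Mb apart
  aln <- mkAln(list(
    list(chrom = "chr1", start = 100L, end = 600L),
    list(chrom = "chr1", start = 2000000L, end = 2000500L)),
    ids = c("far", "far"), identity = 0.95, coverage = c(0.5, 0.5))
  expect_equal(gateAlignments(aln)$chimeras, "far")
})

test_that("structural classification implements the removal rules", {
  tm <- tinyModels()
  # two blocks: retained multi-exon
  aln <- mkAln(list(list(chrom = "chr1", start = 201L, end = 230L)))
  two <- SplicedAlignments(
    GenomicRanges::GRangesList(GenomicRanges::GRanges(
      "chr1", IRanges::IRanges(c(201, 261), c(230, 290)), strand = "+")),
    alnInfo(aln))
  expect_equal(unname(classifyStructure(two, tm$annotation)), "multi_exon")

  cls <- function(s, e) unname(classifyStructure(
    mkAln(list(list(chrom = "chr1", start = s, end = e))), tm$annotation))
  expect_equal(cls(315L, 330L), "exon_fragment")    # strictly inside an exon
  expect_equal(cls(301L, 340L), "single_exon")      # matches the exon exactly
  expect_equal(cls(305L, 338L), "single_exon")      # within the 10 bp tolerance
  expect_equal(cls(225L, 255L), "partial_intron")   # 25 of 31 bases intronic
  # a single block in a non-annotated region is a novel candidate iff long
  tm2 <- tinyModels()
  big <- Biostrings::DNAStringSet(c(chr1 = strrep("ACGT", 500)))
  ann2 <- tm2$annotation
  expect_equal(unname(classifyStructure(
    mkAln(list(list(chrom = "chr1", start = 800L, end = 1100L))), ann2)),
    "novel_single_exon")
  expect_equal(unname(classifyStructure(
    mkAln(list(list(chrom = "chr1", start = 800L, end = 900L))), ann2)),
    "exon_fragment")
})

test_that("locus assignment resolves known, merged, repeat and novel loci", {
  tm <- tinyModels()
  # within gB only
  la <- assignLoci(mkAln(list(list(chrom = "chr1", start = 205L, end = 228L))),
                   tm$annotation)
  expect_equal(la$assignments$locus_id, "gB")
  expect_equal(la$assignments$locus_type, "known")

  # spanning exons of gA and gB (same strand): merged locus
  span <- SplicedAlignments(
    GenomicRanges::GRangesList(GenomicRanges::GRanges(
      "chr1", IRanges::IRanges(c(120, 210), c(140, 230)), strand = "+")),
    S4Vectors::DataFrame(contig_id = "m1", segment = 1L, chrom = "chr1",
                         strand = "+", identity = 1, coverage = 1))
  la <- assignLoci(span, tm$annotation)
  expect_equal(la$assignments$locus_id, "merged:gA+gB")
  expect_equal(la$merged_loci$member_genes, "gA,gB")

  # strand-mismatched overlap does not attach to the gene
  laMinus <- assignLoci(
    mkAln(list(list(chrom = "chr1", start = 205L, end = 228L, strand = "-"))),
    tm$annotation)
  expect_equal(laMinus$assignments$locus_type, "novel")

  # two overlapping contigs in empty space form one novel locus
  la2 <- assignLoci(mkAln(list(
    list(chrom = "chr1", start = 800L, end = 1000L),
    list(chrom = "chr1", start = 950L, end = 1150L))), tm$annotation)
  expect_equal(length(unique(la2$assignments$locus_id)), 1L)
  expect_equal(la2$assignments$locus_type, c("novel", "novel"))

  # repeats win over novel grouping
  ann3 <- tm$annotation
  ann3@repeats <- GenomicRanges::GRanges("chr1", IRanges::IRanges(900, 1000))
  la3 <- assignLoci(mkAln(list(list(chrom = "chr1", start = 920L, end = 980L))),
                    ann3)
  expect_equal(la3$assignments$locus_type, "repeat")
})

test_that("the FMI filter discards members strictly below the threshold", {
  f <- fmiFilter(c(A = 100, B = 4.9))
  expect_equal(f$discarded, "B")                    # 4.9 < 5% of 100
  f <- fmiFilter(c(A = 100, B = 5.0))
  expect_equal(f$discarded, character(0))           # exactly 5% is kept
  expect_equal(f$major, "A")
  expect_warning(f0 <- fmiFilter(c(A = 0, B = 0)), "all-zero")
  expect_equal(sort(f0$kept), c("A", "B"))

  set.seed(8)
  for (i in 1:50) {
    x <- round(runif(sample(2:8, 1), 0, 50), 2)
    names(x) <- paste0("m", seq_along(x))
    if (all(x == 0)) next
    f <- fmiFilter(x, threshold = 0.1)
    major <- names(x)[which.max(x)]
    want <- names(x)[x < 0.1 * max(x) & names(x) != major]
    expect_equal(sort(f$discarded), sort(want))
    expect_equal(sort(c(f$kept, f$discarded)), sort(names(x)))
  }
})

test_that("intron-chain comparison equals exhaustive chain equality", {
  ref <- GenomicRanges::GRangesList(
    t1 = GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 201), c(100, 300))),
    t2 = GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 201, 401),
                                                         c(100, 300, 500))))
  sameAsT1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(10, 201),
                                                              c(100, 290)))
  expect_equal(compareIntronChain(sameAsT1, ref), "identical")
  skipped <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(10, 401),
                                                             c(100, 500)))
  expect_equal(compareIntronChain(skipped, ref), "novel_isoform")
  single <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10, 500))
  expect_equal(compareIntronChain(single, ref), "novel_isoform")

  # fuzz: random exon chains against random reference sets
  set.seed(55)
  randChain <- function() {
    n <- sample(1:4, 1)
    starts <- cumsum(sample(50:150, n)) + sample(0:50, 1)
    GenomicRanges::GRanges("chr1", IRanges::IRanges(starts, starts +
                                                      sample(20:40, n, TRUE)))
  }
  chainOf <- function(gr) {
    if (length(gr) < 2) return(integer(0))
    c(rbind(end(gr)[-length(gr)] + 1L, start(gr)[-1L] - 1L))
  }
  for (i in 1:30) {
    refs <- GenomicRanges::GRangesList(lapply(1:3, function(j) randChain()))
    cand <- if (runif(1) < 0.5) refs[[sample(3, 1)]] else randChain()
    want <- if (any(vapply(refs, function(r)
      identical(chainOf(cand), chainOf(r)), logical(1))))
      "identical" else "novel_isoform"
    expect_equal(compareIntronChain(cand, refs), want)
  }
})

test_that("evidence overlap counts each contig once per source", {
  tm <- tinyModels()
  aln <- mkAln(list(list(chrom = "chr1", start = 101L, end = 140L),
                    list(chrom = "chr1", start = 800L, end = 900L)),
               ids = c("cA", "cB"))
  calls <- data.frame(contig_id = c("cA", "cB"),
                      class = c("identical_isoform", "novel_locus"))
  ev <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(c(101, 120, 130, 850),
                                                c(110, 125, 145, 860)))
  S4Vectors::mcols(ev)$source <- c("est", "est", "est", "cdna")
  out <- evidenceOverlap(calls, aln, ev)
  expect_equal(out["identical_isoform", "est"], 1L)   # 3 ESTs, counted once
  expect_equal(out["novel_locus", "cdna"], 1L)
  expect_equal(out["identical_isoform", "cdna"], 0L)
})

test_that("end-to-end triage recovers every planted class and partitions the input", {
  study <- syntheticStudy("none")
  contigs <- study$contigs$contigs
  truth <- study$contigs$truth
  tr <- triageContigs(names(contigs), study$contigs$alignments,
                      study$annotation, study$contigs$expression)
  expect_equal(sum(tr$class_counts), length(contigs))  # classes partition
  expect_equal(mean(triageMatchesTruth(tr$calls, truth)), 1)
  # merged read-throughs are flagged and listed with their member genes
  expect_equal(nrow(tr$merged_loci), sum(truth$class == "merged_readthrough"))
})
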