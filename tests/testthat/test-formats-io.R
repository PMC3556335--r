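test_that("FASTA parsing preserves ids and sequences, folds case, rejects bad input", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c1", "ACGT"), fa)
  x <- readContigFasta(fa)
  expect_equal(names(x), "c1")
  expect_equal(Biostrings::width(x), 4L)

  writeLines(c(">a", "ac", "gt", ">b", "NNN"), fa)
  x <- readContigFasta(fa)
  expect_equal(unname(Biostrings::width(x)), c(4L, 3L))
  expect_equal(as.character(x[["a"]]), "ACGT")

  writeLines(c(">x"), fa)
  expect_error(readContigFasta(fa), "empty")
  writeLines(c(">d", "AAA", ">d", "CCC"), fa)
  expect_error(readContigFasta(fa), "duplicate")
})

test_that("GFF3 reading builds validated transcript models with 1-based closed intervals", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t11\t60\t.\t+\t.\tID=G1",
    "chr1\tsrc\tmRNA\t11\t60\t.\t+\t.\tID=T1;Parent=G1",
    "chr1\tsrc\texon\t11\t20\t.\t+\t.\tParent=T1",
    "chr1\tsrc\texon\t31\t40\t.\t+\t.\tParent=T1"), gff)
  ann <- readAnnotationGff3(gff)
  ex <- exonRanges(ann)[["T1"]]
  expect_equal(width(ex), c(10L, 10L))              # exon 11-20 spans 10 bases
  intr <- intronRanges(ann)[["T1"]]
  expect_equal(c(start(intr), end(intr)), c(21L, 30L))  # inter-exon gap

  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tmRNA\t11\t60\t.\t+\t.\tID=T1",
    "chr1\tsrc\texon\t11\t20\t.\t+\t.\tParent=T9"), gff)
  expect_error(readAnnotationGff3(gff), "unknown parent")

  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tmRNA\t11\t60\t.\t+\t.\tID=T1",
    "chr1\tsrc\texon\t11\t20\t.\t+\t.\tParent=T1",
    "chr1\tsrc\tCDS\t25\t27\t.\t+\t.\tParent=T1"), gff)
  expect_error(readAnnotationGff3(gff), "within the exon union")
})

test_that("GFF3 write/read round-trips the synthetic annotation", {
  study <- syntheticStudy("none")
  ann <- readAnnotationGff3(study$files["annotation"])
  expect_true(validObject(ann))
  expect_equal(sort(txInfo(ann)$transcript_id),
               sort(txInfo(study$annotation)$transcript_id))
  i <- match("g001.t1", txInfo(ann)$transcript_id)
  j <- match("g001.t1", txInfo(study$annotation)$transcript_id)
  expect_equal(as.data.frame(exonRanges(ann)[[i]])[, 1:5],
               as.data.frame(exonRanges(study$annotation)[[j]])[, 1:5])
})

test_that("BED12 block arithmetic and the identity/coverage extension columns", {
  bed <- withr::local_tempfile(fileext = ".bed")
  # 2 blocks of 100 and 50 bp at relative starts 0 and 200 from chromStart 1000
  writeLines(paste(c("chr1", 1000, 1250, "ctg1", 0, "+", 1000, 1250, "0,0,0",
                     2, "100,50,", "0,200,", 0.95, 0.87), collapse = "\t"), bed)
  aln <- readSplicedBed12(bed)
  b <- alnBlocks(aln)[[1]]
  expect_equal(start(b), c(1001L, 1201L))
  expect_equal(end(b), c(1100L, 1250L))
  # the gap between the blocks is the intron [1101, 1200]
  expect_equal(c(end(b)[1] + 1L, start(b)[2] - 1L), c(1101L, 1200L))
  expect_equal(alnInfo(aln)$identity, 0.95)
  expect_equal(alnInfo(aln)$coverage, 0.87)

  # length mismatch between blockSizes and blockCount
  writeLines(paste(c("chr1", 0, 100, "bad", 0, "+", 0, 100, "0,0,0",
                     2, "100,", "0,", 0.9, 0.9), collapse = "\t"), bed)
  expect_error(suppressWarnings(readSplicedBed12(bed)))
})

test_that("BED12 write-then-read is the identity on random valid records", {
  set.seed(71)
  mk <- function(i) {
    n <- sample(1:4, 1)
    starts <- sort(sample(seq(1, 5000, by = 120), n))
    w <- sample(50:100, n, replace = TRUE)
    GenomicRanges::GRanges("chr2", IRanges::IRanges(starts, starts + w),
                           strand = sample(c("+", "-"), 1))
  }
  blocks <- GenomicRanges::GRangesList(lapply(1:10, mk))
  info <- S4Vectors::DataFrame(
    contig_id = sprintf("c%02d", 1:10), segment = 1L, chrom = "chr2",
    strand = vapply(blocks, function(b) as.character(strand(b))[1],
                    character(1)),
    identity = round(runif(10, 0.9, 1), 4),
    coverage = round(runif(10, 0.5, 1), 4))
  aln <- SplicedAlignments(blocks, info)
  bed <- withr::local_tempfile(fileext = ".bed")
  writeSplicedBed12(aln, bed)
  back <- readSplicedBed12(bed)
  expect_equal(as.data.frame(alnInfo(back)), as.data.frame(alnInfo(aln)))
  for (i in 1:10)
    expect_equal(ranges(alnBlocks(back)[[i]]), ranges(alnBlocks(aln)[[i]]))
})

test_that("VCF reading converts conventions, splits multi-allelics, computes AO/RO frequency", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"f\">",
    "##INFO=<ID=AO,Number=A,Type=Integer,Description=\"a\">",
    "##INFO=<ID=RO,Number=1,Type=Integer,Description=\"r\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t100\t.\tA\tT\t99\t.\tDP=10;AF=0.8",
    "chr1\t200\t.\tG\tT,C\t50\t.\tDP=20;AF=0.5,0.3",
    "chr1\t300\t.\tC\tG\t60\t.\tDP=8;AO=6;RO=2",
    "chr1\t400\t.\tT\tA\t60\t.\tDP=5"), vcf)
  v <- suppressWarnings(readVariantsVcf(vcf))
  expect_equal(length(v), 4L)                      # record without AF/AO dropped
  expect_equal(start(v)[1], 100L)                  # POS preserved 1-based
  expect_equal(mcols(v)$alt_freq[1], 0.8)
  expect_equal(mcols(v)$alt[2:3], c("T", "C"))     # multi-allelic split
  expect_equal(mcols(v)$alt_freq[2:3], c(0.5, 0.3))
  # AO/RO fallback: 6 / (6 + 2)
  v300 <- v[start(v) == 300]
  expect_equal(mcols(v300)$alt_freq, 0.75)
  expect_equal(S4Vectors::metadata(v)$io_counts[["rejected"]], 1)
  expect_warning(readVariantsVcf(vcf), "excluded")
})

test_that("VCF write/read round-trips variant records", {
  v <- suppressWarnings(
    c(snv("chr1", 150, "A", "T", depth = 12L, qual = 88, freq = 0.91),
      snv("chr2", 99, "G", "GAT", depth = 30L, qual = 120, freq = 0.8)))
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeVariantsVcf(v, vcf)
  back <- readVariantsVcf(vcf)
  expect_equal(start(back), start(v))
  expect_equal(mcols(back)$ref, mcols(v)$ref)
  expect_equal(mcols(back)$alt, mcols(v)$alt)
  expect_equal(mcols(back)$depth, mcols(v)$depth)
  expect_equal(mcols(back)$alt_freq, mcols(v)$alt_freq)
})

test_that("homology table parsing validates labels and converts percent identity", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  row <- paste(c("q1", "s1", "98.0", 100, 2, 0, 1, 100, 1, 100, "1e-30", 250,
                 "nr_protein", "Fungi", 0.8), collapse = "\t")
  writeLines(row, tsv)
  h <- readHomologyTab(tsv)
  expect_equal(h$identity, 0.98)
  expect_equal(h$e_value, 1e-30)
  expect_equal(h$taxon, "Fungi")

  writeLines(sub("nr_protein", "mystery_db", row), tsv)
  expect_error(readHomologyTab(tsv), "mystery_db.*allowed", perl = TRUE)
})

test_that("count tables load as SummarizedExperiment with stage labels", {
  cts <- withr::local_tempfile(fileext = ".tsv")
  stg <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\ts1\ts2", "g1\t5\t7", "g2\t0\t3"), cts)
  writeLines(c("sample_id\tstage\treplicate", "s1\tPFS\t1", "s2\tPR\t1"), stg)
  se <- readCountsTable(cts, stg)
  expect_equal(unname(SummarizedExperiment::assay(se)["g1", ]), c(5L, 7L))
  expect_equal(SummarizedExperiment::colData(se)$stage, c("PFS", "PR"))

  writeLines(c("sample_id\tstage", "s1\tPFS"), stg)
  expect_error(readCountsTable(cts, stg), "without a stage")
})
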