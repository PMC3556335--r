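codingConstruct <- function(n_codons = 34, flank = 0) {
  paste0(strrep("C", flank), "ATG", strrep("GCT", n_codons - 2), "TAA",
         strrep("C", flank))
}

test_that("ORF finding reports maximal ORFs with correct completeness", {
  s <- codingConstruct(34)                     # ATG + 32 codons + TAA
  orfs <- findOrfs(s)
  full <- orfs[orfs$completeness == "full", ]
  expect_equal(nrow(full), 1L)
  expect_equal(full$codons, 34L)
  expect_equal(full$start, 1L)
  expect_equal(full$end, 102L)

  # reading through the end without a stop: 3'-partial
  s2 <- paste0("ATG", strrep("GCT", 40))
  orfs2 <- findOrfs(s2)
  expect_true(any(orfs2$completeness == "partial_3prime" & orfs2$codons == 41))

  # open at the 5' end, no ATG, terminated by a stop: 5'-partial
  s3 <- paste0(strrep("GCT", 40), "TAA", strrep("CCC", 10))
  orfs3 <- findOrfs(s3)
  expect_true(any(orfs3$completeness == "partial_5prime" & orfs3$codons == 41))
})

test_that("ORF finding equals the brute-force six-frame scan on random sequence", {
  set.seed(23)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
               collapse = "")
    got <- findOrfs(s)
    want <- bruteOrfs(s)
    key <- function(d) if (is.null(d) || nrow(d) == 0) character(0) else
      sort(paste(d$strand, d$frame, d$start, d$end, d$codons, d$completeness))
    expect_equal(key(got), key(want))
  }
})

test_that("coding potential separates constructs from random sequence", {
  # a full ORF over 90% of the sequence with biased codon usage
  set.seed(97)
  coding <- DeNovoTriage:::.codingSeq(120, flank = 20)
  cp <- codingPotential(coding)
  expect_true(cp$is_coding)
  expect_gte(cp$score, 0.5)

  # sequences shorter than the minimum ORF cannot be coding
  expect_false(codingPotential(strrep("ACGT", 20))$is_coding)

  # specificity on uniform random sequence (planted non-coding truth)
  calls <- vapply(1:100, function(i) {
    s <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
               collapse = "")
    codingPotential(s)$is_coding
  }, logical(1))
  expect_gte(mean(!calls), 0.95)
})

test_that("novel-locus classification follows the decision-tree precedence", {
  seqs <- Biostrings::DNAStringSet(c(x = DeNovoTriage:::.codingSeq(100)))
  hit <- function(db, taxon = "Viridiplantae")
    data.frame(query_id = "x", subject_id = "s", identity = 0.9,
               e_value = 1e-20, bitscore = 100, database = db, taxon = taxon,
               query_coverage = 0.8, stringsAsFactors = FALSE)
  none <- hit("nr_protein")[0, ]
  # transposon evidence outranks a perfectly good ORF
  expect_equal(classifyNovelLocus(seqs, hit("transposon_protein")),
               "transposon_like")
  expect_equal(classifyNovelLocus(seqs, none), "coding_full_orf")
  rnd <- Biostrings::DNAStringSet(c(x = DeNovoTriage:::.noncodingSeq(400)))
  expect_equal(classifyNovelLocus(rnd, none), "putative_ncRNA")
  expect_equal(classifyNovelLocus(rnd, hit("nr_protein")), "homology_supported")
  expect_equal(classifyNovelLocus(rnd, hit("rfam")), "rna_family_like")
  # deterministic in hit order
  h2 <- rbind(hit("rfam"), hit("transposon_protein"), hit("nr_protein"))
  expect_equal(classifyNovelLocus(seqs, h2),
               classifyNovelLocus(seqs, h2[3:1, ]))
})

test_that("unmapped triage follows the contaminant/raw-read/plant decision order", {
  ctg <- Biostrings::DNAStringSet(c(u1 = DeNovoTriage:::.codingSeq(100)))
  hit <- function(id, db, taxon, bits = 100, e = 1e-20)
    data.frame(query_id = id, subject_id = paste0(db, "_s"), identity = 0.9,
               e_value = e, bitscore = bits, database = db, taxon = taxon,
               query_coverage = 0.8, stringsAsFactors = FALSE)
  expect_equal(triageUnmapped(ctg, hit("u1", "nr_protein", "Fungi"))$class,
               "contaminant")
  expect_equal(triageUnmapped(ctg, hit("u1", "vvgi_est", "Viridiplantae"))$class,
               "private_candidate")
  expect_equal(triageUnmapped(
    ctg, hit("u1", "genome_raw_reads", "Viridiplantae"))$class,
    "missing_from_assembly_coding")
  rnd <- Biostrings::DNAStringSet(c(u1 = DeNovoTriage:::.noncodingSeq(400)))
  expect_equal(triageUnmapped(
    rnd, hit("u1", "genome_raw_reads", "Viridiplantae"))$class,
    "missing_from_assembly")
  expect_equal(triageUnmapped(ctg, hit("u1", "nr_protein", "Fungi")[0, ])$class,
               "no_evidence")
  # raw-read evidence outranks plant-database similarity
  expect_equal(triageUnmapped(ctg, rbind(
    hit("u1", "vvgi_est", "Viridiplantae"),
    hit("u1", "genome_raw_reads", "Viridiplantae")))$class,
    "missing_from_assembly_coding")
  # a plant best nr hit is not a contaminant
  expect_equal(triageUnmapped(ctg, rbind(
    hit("u1", "nr_protein", "Viridiplantae", bits = 200),
    hit("u1", "nr_protein", "Fungi", bits = 100),
    hit("u1", "vvgi_est", "Viridiplantae")))$class,
    "private_candidate")
  # equal-best hits with conflicting taxa resolve conservatively
  expect_equal(triageUnmapped(ctg, rbind(
    hit("u1", "nr_protein", "Viridiplantae", bits = 200),
    hit("u1", "nr_protein", "Fungi", bits = 200)))$class,
    "contaminant")
  # hits failing the E-value pre-filter do not count
  expect_equal(triageUnmapped(ctg, hit("u1", "nr_protein", "Fungi",
                                       e = 1e-3))$class, "no_evidence")
})

test_that("private-gene clustering equals connected components of the evidence graph", {
  set.seed(61)
  mkSeq <- function() paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                            collapse = "")
  n <- 12
  ctg <- Biostrings::DNAStringSet(vapply(1:n, function(i) mkSeq(),
                                         character(1)))
  names(ctg) <- sprintf("p%02d", 1:n)
  # shared best subjects define the edges
  subjects <- sample(sprintf("VV_%d", 1:6), n, replace = TRUE)
  hits <- data.frame(query_id = names(ctg), subject_id = subjects,
                     identity = 0.95, e_value = 1e-25, bitscore = 100,
                     database = "vvgi_est", taxon = "Viridiplantae",
                     query_coverage = 0.8, stringsAsFactors = FALSE)
  out <- clusterPrivate(ctg, hits)
  edges <- which(outer(subjects, subjects, "==") & upper.tri(diag(n)),
                 arr.ind = TRUE)
  comp <- bruteComponents(n, edges)
  # same partition: cluster labels must be a relabelling of the components
  got <- out$cluster_id[match(names(ctg), out$contig_id)]
  expect_equal(length(unique(got)), length(unique(comp)))
  expect_true(all(tapply(comp, got, function(x) length(unique(x))) == 1))
  # representative is the longest member of its cluster
  for (cl in unique(out$cluster_id)) {
    member <- out$contig_id[out$cluster_id == cl]
    rep <- unique(out$representative[out$cluster_id == cl])
    expect_equal(max(Biostrings::width(ctg[member])),
                 Biostrings::width(ctg[rep]))
  }
  # three candidates with no shared evidence stay singletons
  h3 <- hits[1:3, ]; h3$subject_id <- c("a", "b", "c")
  out3 <- clusterPrivate(ctg[1:3], h3)
  expect_equal(length(unique(out3$cluster_id)), 3L)
})

test_that("planted unmapped contigs are recovered class-exactly", {
  study <- syntheticStudy("none")
  truth <- study$contigs$truth
  hits <- study$contigs$hits
  unmapped <- truth$contig_id[truth$class == "unmapped"]
  um <- triageUnmapped(study$contigs$contigs[unmapped], hits)
  cmp <- merge(um, truth[, c("contig_id", "unmapped_class", "private_cluster")],
               by = "contig_id")
  expect_equal(mean(cmp$class == cmp$unmapped_class), 1)
  # private clustering reproduces the planted clusters
  priv <- clusterPrivate(
    study$contigs$contigs[cmp$contig_id[cmp$class == "private_candidate"]],
    hits)
  planted <- cmp$private_cluster[match(priv$contig_id, cmp$contig_id)]
  expect_equal(length(unique(priv$cluster_id)), length(unique(planted)))
  expect_true(all(tapply(planted, priv$cluster_id,
                         function(x) length(unique(x))) == 1))
})
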