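.STAGES <- c("PFS", "PR", "PHWII")

## stage-mean multipliers realizing the four development profiles
.PATTERN_MULT <- list(
  flat = c(1, 1, 1),
  `1` = c(1, 1 / 8, 1 / 8),      # repressed
  `2` = c(1, 1 / 8, 1),          # transiently repressed
  `3` = c(1, 8, 1),              # transiently induced
  `4` = c(1, 8, 8))              # induced

#' Simulate NB fragment counts with planted development profiles
#'
#' Negative-binomial counts for 3 stages x 3 replicates.  Each feature is
#' assigned a pattern (`flat` or profile cluster 1-4) by the configured
#' proportions; patterns are realized as x8 / x(1/8) multipliers of the
#' base stage mean, the effect size at which profile recovery is expected
#' to be essentially complete at the default dispersion.
#'
#' @param config A [simulationConfig()].
#' @param features Character vector of feature ids (e.g. the annotated
#'   gene ids).
#' @return A list: `counts` (a
#'   [SummarizedExperiment::SummarizedExperiment] with `counts` assay and
#'   `colData` stage/replicate) and `truth` (`data.frame`: `feature_id`,
#'   `pattern`).
#' @export
simulateCounts <- function(config, features) {
  set.seed(config$seed + 3L)
  n <- length(features)
  props <- config$pattern_props
  nPer <- floor(n * props)
  nPer["flat"] <- n - sum(nPer[names(nPer) != "flat"])
  pattern <- sample(rep(names(props), nPer))
  mu <- t(vapply(pattern, function(p)
    rep(config$nb_mean * .PATTERN_MULT[[p]], each = 3L), numeric(9L)))
  m <- matrix(stats::rnbinom(length(mu), mu = mu,
                             size = 1 / config$nb_dispersion),
              nrow = n)
  rownames(m) <- features
  colnames(m) <- paste0(rep(.STAGES, each = 3L), "_", rep(1:3, 3L))
  storage.mode(m) <- "integer"
  cd <- DataFrame(stage = rep(.STAGES, each = 3L),
                  replicate = rep(1:3, 3L), row.names = colnames(m))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = m), colData = cd)
  list(counts = se,
       truth = data.frame(feature_id = features, pattern = pattern,
                          stringsAsFactors = FALSE))
}

#' Simulate a gene-to-term map with one planted enriched term
#'
#' Every feature gets 1-2 terms drawn from a background vocabulary; in
#' addition, 80% of the features with planted pattern 4 (induced, the
#' withering-response profile) share the term `TERM_INDUCED`, giving the
#' enrichment test a true positive to find.
#'
#' @param config A [simulationConfig()].
#' @param profile_truth Truth `data.frame` from [simulateCounts()].
#' @return A `data.frame` with columns `gene_id`, `term_id`.
#' @export
simulateTermMap <- function(config, profile_truth) {
  set.seed(config$seed + 4L)
  vocab <- sprintf("TERM_%02d", 1:10)
  rows <- lapply(profile_truth$feature_id, function(f)
    data.frame(gene_id = f, term_id = sample(vocab, sample(1:2, 1L)),
               stringsAsFactors = FALSE))
  induced <- profile_truth$feature_id[profile_truth$pattern == "4"]
  induced <- induced[stats::runif(length(induced)) < 0.8]
  if (length(induced))
    rows[[length(rows) + 1L]] <- data.frame(gene_id = induced,
                                            term_id = "TERM_INDUCED",
                                            stringsAsFactors = FALSE)
  unique(do.call(rbind, rows))
}

#' Generate and write the full synthetic study
#'
#' Runs every generator with the configured seed and writes the study to
#' `outdir`: `genome.fa`, `annotation.gff3`, `contigs.fa`,
#' `alignments.bed`, `variants.vcf`, `hits.tsv`, `expression.tsv`
#' (per-contig FPKM), `counts.tsv` + `stages.tsv` + `lengths.tsv`,
#' `terms.tsv`, `raw_reads.fa`, and the planted truth
#' (`truth_contigs.tsv`, `truth_variants.tsv`, `truth_profiles.tsv`).
#' Identical config and seed produce byte-identical files.
#'
#' @param config A [simulationConfig()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with all in-memory objects and `files`, the
#'   named vector of written paths.
#' @export
simulateStudy <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)

  sim <- generateGenomeAndAnnotation(config)
  vars <- plantVariants(config, sim)
  ctg <- simulateContigs(config, sim)
  geneIds <- unique(txInfo(sim$annotation)$gene_id)
  cnt <- simulateCounts(config, geneIds)
  terms <- simulateTermMap(config, cnt$truth)

  writeFasta(sim$genome, p("genome.fa"))
  writeAnnotationGff3(sim$annotation, p("annotation.gff3"))
  writeFasta(ctg$contigs, p("contigs.fa"))
  writeSplicedBed12(ctg$alignments, p("alignments.bed"))
  writeVariantsVcf(vars$variants, p("variants.vcf"))
  writeHomologyTab(ctg$hits, p("hits.tsv"))
  utils::write.table(
    data.frame(contig_id = names(ctg$expression), fpkm = ctg$expression),
    p("expression.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  m <- SummarizedExperiment::assay(cnt$counts, "counts")
  utils::write.table(data.frame(feature_id = rownames(m), m,
                                check.names = FALSE),
                     p("counts.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cd <- SummarizedExperiment::colData(cnt$counts)
  utils::write.table(data.frame(sample_id = rownames(cd),
                                stage = cd$stage, replicate = cd$replicate),
                     p("stages.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  exLen <- vapply(exonRanges(sim$annotation), function(e) sum(width(e)),
                  numeric(1))
  names(exLen) <- txInfo(sim$annotation)$gene_id
  utils::write.table(data.frame(feature_id = names(exLen), length = exLen),
                     p("lengths.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(terms, p("terms.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeFasta(ctg$raw_reads, p("raw_reads.fa"))
  utils::write.table(ctg$truth, p("truth_contigs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(vars$truth, p("truth_variants.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cnt$truth, p("truth_profiles.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  files <- stats::setNames(
    file.path(outdir, c("genome.fa", "annotation.gff3", "contigs.fa",
                        "alignments.bed", "variants.vcf", "hits.tsv",
                        "expression.tsv", "counts.tsv", "stages.tsv",
                        "lengths.tsv", "terms.tsv", "raw_reads.fa",
                        "truth_contigs.tsv", "truth_variants.tsv",
                        "truth_profiles.tsv")),
    c("genome", "annotation", "contigs", "alignments", "variants", "hits",
      "expression", "counts", "stages", "lengths", "terms", "raw_reads",
      "truth_contigs", "truth_variants", "truth_profiles"))
  invisible(list(genome = sim$genome, annotation = sim$annotation,
                 meta = sim$meta, variants = vars, contigs = ctg,
                 counts = cnt, terms = terms, files = files))
}
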