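#' Pipeline configuration with study-default thresholds
#'
#' Bundles input paths and every tunable threshold, defaulting each to the
#' study value, so a bare run reproduces the published decision rules:
#' variant filters depth 5 / quality 80 / frequency 0.75; alignment gates
#' 90% identity and coverage; FMI 5%; coverage depth 3; homology filters
#' E <= 1e-5 and 20% query coverage; expression thresholds FDR 0.05 and
#' |log2 fold change| 1.
#'
#' @param genome,annotation,contigs,alignments,variants,hits,expression,counts,stages,lengths,terms
#'   Input file paths (any may be `NA` to skip the stages needing it).
#' @param outdir Output directory for stage tables.
#' @param min_depth,min_qual,min_alt_freq,splice_window Variant stage.
#' @param min_identity,min_coverage,fmi_threshold Contig stage.
#' @param coverage_depth Coverage stage.
#' @param max_evalue,min_hit_coverage Homology evidence.
#' @param fdr,lfc Expression stage.
#' @return A classed list (`pipeline_config`).
#' @export
pipelineConfig <- function(genome = NA, annotation = NA, contigs = NA,
                           alignments = NA, variants = NA, hits = NA,
                           expression = NA, counts = NA, stages = NA,
                           lengths = NA, terms = NA, outdir = ".",
                           min_depth = 5, min_qual = 80, min_alt_freq = 0.75,
                           splice_window = 2L, min_identity = 0.90,
                           min_coverage = 0.90, fmi_threshold = 0.05,
                           coverage_depth = 3L, max_evalue = 1e-5,
                           min_hit_coverage = 0.2, fdr = 0.05, lfc = 1) {
  stopifnot(min_identity >= 0, min_identity <= 1, min_coverage >= 0,
            min_coverage <= 1, fmi_threshold >= 0, fmi_threshold <= 1,
            min_alt_freq >= 0, min_alt_freq <= 1, fdr > 0, fdr <= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

.writeStage <- function(x, outdir, name) {
  path <- file.path(outdir, paste0(name, ".tsv"))
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full post-assembly pipeline
#'
#' Executes, in order: variant filtering and effect projection; genome
#' coverage classification; contig clustering and triage; unmapped-contig
#' triage and private-gene clustering; expression profiling (two
#' adjacent-stage contrasts, profile clusters, term enrichment).  Stages
#' whose inputs are absent from the config are skipped.  Each stage writes
#' its tables under `outdir` and contributes class-count tables to the run
#' report; the pipeline fails fast with the failing stage named.
#'
#' @param config A [pipelineConfig()].
#' @return A run report: list with per-stage `counts` tables, `config`
#'   echo, and written `files`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  report <- list(config = config, stages = list(), files = character(0))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  hasInput <- function(...) all(!is.na(unlist(config[c(...)])))

  genome <- if (hasInput("genome")) readGenomeFasta(config$genome) else NULL
  annotation <- if (hasInput("annotation"))
    readAnnotationGff3(config$annotation) else NULL

  if (hasInput("variants") && !is.null(annotation) && !is.null(genome)) {
    stage("variants", {
      raw <- readVariantsVcf(config$variants)
      flt <- filterVariants(raw, config$min_depth, config$min_qual,
                            config$min_alt_freq)
      eff <- variantEffects(flt$kept, annotation, genome,
                            config$splice_window)
      impact <- summarizeGeneImpact(eff, annotation)
      report$files["effects"] <- .writeStage(eff, config$outdir, "variant_effects")
      report$files["gene_impact"] <- .writeStage(impact$genes, config$outdir,
                                                  "gene_impact")
      report$stages$variants <- list(
        n_input = length(raw), n_kept = length(flt$kept),
        n_rejected = length(flt$rejected),
        region_counts = table(eff$region),
        consequence_counts = table(eff$consequence),
        impact_counts = impact$counts)
    })
  }

  aln <- if (hasInput("alignments")) readSplicedBed12(config$alignments) else NULL
  if (!is.null(aln) && !is.null(annotation) && !is.null(genome)) {
    stage("coverage", {
      track <- coverageFromAlignments(aln, genome)
      cls <- classifyCoveredBases(track, annotation, config$coverage_depth)
      report$stages$coverage <- cls
    })
  }

  triage <- NULL
  contigs <- if (hasInput("contigs")) readContigFasta(config$contigs) else NULL
  if (!is.null(contigs) && !is.null(aln) && !is.null(annotation) &&
      hasInput("expression")) {
    stage("contigs", {
      expTab <- utils::read.table(config$expression, header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE)
      fpkm <- stats::setNames(expTab$fpkm, expTab$contig_id)
      clusters <- clusterContigs(contigs)
      reps <- unique(clusters$representative)
      triage <- triageContigs(reps, aln, annotation, fpkm,
                               fmi_threshold = config$fmi_threshold,
                               min_identity = config$min_identity,
                               min_coverage = config$min_coverage)
      stats <- assemblyStats(Biostrings::width(contigs))
      report$files["triage"] <- .writeStage(triage$calls, config$outdir,
                                             "triage_calls")
      report$files["merged"] <- .writeStage(triage$merged_loci, config$outdir,
                                             "merged_loci")
      report$stages$contigs <- list(
        n_contigs = length(contigs), n_representatives = length(reps),
        class_counts = triage$class_counts, assembly_stats = stats)
    })
  }

  if (!is.null(triage) && !is.null(contigs) && hasInput("hits")) {
    stage("unmapped", {
      hits <- readHomologyTab(config$hits)
      hits <- filterHomologyHits(hits, config$max_evalue,
                                 config$min_hit_coverage)
      unmappedIds <- triage$calls$contig_id[triage$calls$class == "unmapped"]
      um <- triageUnmapped(contigs[unmappedIds], hits)
      priv <- clusterPrivate(
        contigs[um$contig_id[um$class == "private_candidate"]], hits)
      report$files["unmapped"] <- .writeStage(um, config$outdir,
                                               "unmapped_calls")
      report$files["private"] <- .writeStage(priv, config$outdir,
                                              "private_clusters")
      report$stages$unmapped <- list(
        class_counts = table(um$class),
        n_private_clusters = length(unique(priv$cluster_id)))
    })
  }

  if (hasInput("counts", "stages", "lengths")) {
    stage("express", {
      se <- readCountsTable(config$counts, config$stages)
      lens <- utils::read.table(config$lengths, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
      lengths <- stats::setNames(lens$length, lens$feature_id)
      fpkm <- computeFpkm(se, lengths)
      fpkm$expressed <- isExpressed(fpkm$fpkm, fpkm$ci_low)
      de1 <- nbExactTest(se, "PFS", "PR")
      de2 <- nbExactTest(se, "PR", "PHWII")
      prof <- assignProfileClusters(de1, de2, config$fdr, config$lfc)
      report$files["fpkm"] <- .writeStage(fpkm, config$outdir, "expression_records")
      report$files["de_pfs_pr"] <- .writeStage(de1, config$outdir, "de_PFS_PR")
      report$files["de_pr_phwii"] <- .writeStage(de2, config$outdir, "de_PR_PHWII")
      report$files["profiles"] <- .writeStage(prof, config$outdir,
                                               "profile_clusters")
      enr <- NULL
      if (hasInput("terms")) {
        map <- readTermMap(config$terms)
        groups <- split(prof$feature_id, prof$cluster)
        groups <- groups[names(groups) != "none"]
        enr <- enrichTerms(groups, map, rownames(se), config$fdr)
        report$files["enrichment"] <- .writeStage(enr, config$outdir,
                                                   "enrichment")
      }
      report$stages$express <- list(
        n_features = nrow(se),
        n_expressed_any = length(unique(fpkm$feature_id[fpkm$expressed])),
        n_de = sum(prof$cluster != "none"),
        cluster_counts = table(prof$cluster),
        n_enriched = if (is.null(enr)) NA_integer_ else sum(enr$enriched))
    })
  }
  report
}
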