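#' Filter homology hits on significance and query coverage
#'
#' Standard pre-filter for all downstream evidence use: E-value at most
#' `max_evalue` (default 1e-5) and query coverage at least `min_coverage`
#' (default 0.2).  Hits with missing coverage are retained (coverage
#' unknown is not evidence of a short alignment).
#'
#' @param hits A `data.frame` from [readHomologyTab()].
#' @param max_evalue,min_coverage Thresholds.
#' @return The filtered `data.frame`.
#' @export
filterHomologyHits <- function(hits, max_evalue = 1e-5, min_coverage = 0.2) {
  keep <- hits$e_value <= max_evalue &
    (is.na(hits$query_coverage) | hits$query_coverage >= min_coverage)
  hits[keep, , drop = FALSE]
}

#' Classify a novel locus by transposon, coding and homology evidence
#'
#' Decision tree for contigs mapping to non-annotated genomic regions, in
#' precedence order: a transposon-protein hit makes the locus
#' `transposon_like` (even when it also has an ORF); otherwise a positive
#' coding call ([codingPotential()]) gives `coding_full_orf` or
#' `coding_partial_orf` by the completeness of the longest ORF; otherwise a
#' protein-database hit (`nr_protein` or `plant_protein`) gives
#' `homology_supported`; otherwise an `rfam` hit gives `rna_family_like`;
#' the default leaf is `putative_ncRNA`.  The call is a deterministic
#' function of the hits and sequences; hit order never matters.
#'
#' @param sequences [Biostrings::DNAStringSet] of the locus's contigs.
#' @param hits Homology hits of those contigs, pre-filtered with
#'   [filterHomologyHits()] (re-applied defensively here).
#' @param min_codons See [findOrfs()].
#' @return The class label (length-1 character).
#' @export
classifyNovelLocus <- function(sequences, hits, min_codons = 33L) {
  hits <- filterHomologyHits(hits)
  hits <- hits[hits$query_id %in% names(sequences), , drop = FALSE]
  if (any(hits$database == "transposon_protein")) return("transposon_like")
  cp <- lapply(as.character(sequences), codingPotential, min_codons = min_codons)
  coding <- vapply(cp, `[[`, logical(1), "is_coding")
  if (any(coding)) {
    # full beats partial: a qualifying full ORF in any coding member makes
    # the locus full-ORF coding, even if a chance stop-free partial frame
    # happens to be longer
    anyFull <- any(vapply(which(coding), function(i) {
      orfs <- findOrfs(as.character(sequences[[i]]), min_codons)
      any(orfs$completeness == "full")
    }, logical(1)))
    return(if (anyFull) "coding_full_orf" else "coding_partial_orf")
  }
  if (any(hits$database %in% c("nr_protein", "plant_protein")))
    return("homology_supported")
  if (any(hits$database == "rfam")) return("rna_family_like")
  "putative_ncRNA"
}

#' Triage contigs that fail to map onto the reference genome
#'
#' Decision order per contig: (1) if the best `nr_protein` hit (highest
#' bitscore, ties broken by lowest E-value) has a taxon outside
#' Viridiplantae, the contig is a `contaminant`; equal-best hits with
#' conflicting taxa resolve to `contaminant` (conservative).  (2) A hit
#' against the reference's raw sequencing reads (`genome_raw_reads`) makes
#' it `missing_from_assembly` — a gap in the reference assembly, not a
#' private gene — refined to `missing_from_assembly_coding` when the contig
#' is coding.  (3) A hit against the expressed-sequence index (`vvgi_est`)
#' or other plant proteins (`plant_protein`) makes it a
#' `private_candidate`.  (4) Otherwise `no_evidence`.
#'
#' @param contigs [Biostrings::DNAStringSet] of unmapped contigs.
#' @param hits Homology hits (pre-filtered or not; [filterHomologyHits()]
#'   is applied).
#' @param plant_taxon Taxon label counting as in-clade (default
#'   `"Viridiplantae"`).
#' @return A `data.frame` with columns `contig_id`, `class`, `support`
#'   (subject id of the deciding hit, or `NA`).
#' @export
triageUnmapped <- function(contigs, hits, plant_taxon = "Viridiplantae") {
  hits <- filterHomologyHits(hits)
  out <- data.frame(contig_id = names(contigs), class = "no_evidence",
                    support = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_along(contigs)) {
    h <- hits[hits$query_id == names(contigs)[i], , drop = FALSE]
    nr <- h[h$database == "nr_protein", , drop = FALSE]
    if (nrow(nr)) {
      nr <- nr[order(-nr$bitscore, nr$e_value), , drop = FALSE]
      top <- nr[nr$bitscore == nr$bitscore[1L] & nr$e_value == nr$e_value[1L],
                , drop = FALSE]
      taxa <- unique(top$taxon)
      if (length(taxa) > 1L || taxa[1L] != plant_taxon) {
        out$class[i] <- "contaminant"
        out$support[i] <- top$subject_id[1L]
        next
      }
    }
    raw <- h[h$database == "genome_raw_reads", , drop = FALSE]
    if (nrow(raw)) {
      coding <- codingPotential(as.character(contigs[[i]]))$is_coding
      out$class[i] <- if (coding) "missing_from_assembly_coding"
                      else "missing_from_assembly"
      out$support[i] <- raw$subject_id[which.max(raw$bitscore)]
      next
    }
    pl <- h[h$database %in% c("vvgi_est", "plant_protein"), , drop = FALSE]
    if (nrow(pl)) {
      out$class[i] <- "private_candidate"
      out$support[i] <- pl$subject_id[which.max(pl$bitscore)]
    }
  }
  out
}

#' Cluster private-gene candidates into putative private genes
#'
#' Builds a similarity graph over candidates — an edge when two candidates
#' share a best-subject hit in the expressed-sequence or plant-protein
#' databases, or when they align to each other with identity above 0.9
#' over at least 0.8 of the shorter sequence — and takes connected
#' components (single linkage).  The representative of each cluster is its
#' longest member; the cluster's coding flag is the representative's
#' [codingPotential()] call.
#'
#' @param candidates [Biostrings::DNAStringSet] of `private_candidate`
#'   contigs.
#' @param hits Homology hits of the candidates.
#' @param min_identity,min_short_coverage Direct-similarity edge thresholds.
#' @return A `data.frame` with columns `contig_id`, `cluster_id`,
#'   `representative`, `coding`.
#' @export
clusterPrivate <- function(candidates, hits, min_identity = 0.9,
                           min_short_coverage = 0.8) {
  n <- length(candidates)
  ids <- names(candidates)
  if (n == 0L)
    return(data.frame(contig_id = character(0), cluster_id = character(0),
                      representative = character(0), coding = logical(0)))
  hits <- filterHomologyHits(hits)
  hits <- hits[hits$database %in% c("vvgi_est", "plant_protein") &
               hits$query_id %in% ids, , drop = FALSE]
  bestSubject <- vapply(ids, function(id) {
    h <- hits[hits$query_id == id, , drop = FALSE]
    if (!nrow(h)) return(NA_character_)
    h$subject_id[order(-h$bitscore, h$e_value)][1L]
  }, character(1))

  edges <- matrix(integer(0), ncol = 2)
  if (n >= 2L) {
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      shared <- !is.na(bestSubject[i]) && !is.na(bestSubject[j]) &&
        bestSubject[i] == bestSubject[j]
      if (!shared) {
        si <- as.character(candidates[[i]]); sj <- as.character(candidates[[j]])
        shorter <- if (nchar(si) <= nchar(sj)) si else sj
        longer <- if (nchar(si) <= nchar(sj)) sj else si
        if (nchar(shorter) >= 31L &&
            !any(.kmerSet(shorter) %in% .kmerSet(longer))) {
          sim <- c(identity = 0, short_coverage = 0)
        } else {
          sim <- .pairSimilarity(shorter, longer)
        }
        shared <- sim["identity"] > min_identity &&
          sim["short_coverage"] >= min_short_coverage
      }
      if (shared) edges <- rbind(edges, c(i, j))
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership

  lens <- Biostrings::width(candidates)
  out <- data.frame(contig_id = ids, cluster_id = NA_character_,
                    representative = NA_character_, coding = NA,
                    stringsAsFactors = FALSE)
  for (cl in sort(unique(comp))) {
    member <- which(comp == cl)
    rep <- member[order(-lens[member], ids[member])][1L]
    out$cluster_id[member] <- sprintf("private_%03d", cl)
    out$representative[member] <- ids[rep]
    out$coding[member] <- codingPotential(as.character(candidates[[rep]]))$is_coding
  }
  out
}
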