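.homologyDatabases <- c("nr_protein", "vvgi_est", "plant_protein",
                        "genome_raw_reads", "transposon_protein", "rfam",
                        "est", "cdna")

#' Read tabular homology hits
#'
#' Consumes the 12-column tabular hit format (query, subject, percent
#' identity, alignment length, mismatches, gap opens, qstart, qend, sstart,
#' send, e-value, bitscore) extended with column 13 (database label) and
#' column 14 (taxon label), with an optional column 15 carrying the query
#' coverage fraction.  Percent identity is divided by 100; when column 15 is
#' absent, query coverage is `NA` unless `query_lengths` is supplied, in
#' which case it is computed as `(qend - qstart + 1) / query length`.
#'
#' @param path Path to the tab-separated hits file (no header).
#' @param query_lengths Optional named vector of query sequence lengths.
#' @return A `data.frame` with columns `query_id`, `subject_id`, `identity`,
#'   `e_value`, `bitscore`, `database`, `taxon`, `query_coverage`.
#' @export
readHomologyTab <- function(path, query_lengths = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  if (ncol(raw) < 14L)
    stop("homology table needs >= 14 columns (12-column hits + database + taxon)")
  db <- as.character(raw[[13L]])
  bad <- setdiff(unique(db), .homologyDatabases)
  if (length(bad))
    stop("unknown database label(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(.homologyDatabases, collapse = ", "))
  qcov <- if (ncol(raw) >= 15L) {
    as.numeric(raw[[15L]])
  } else if (!is.null(query_lengths)) {
    (raw[[8L]] - raw[[7L]] + 1) / as.numeric(query_lengths[as.character(raw[[1L]])])
  } else {
    rep(NA_real_, nrow(raw))
  }
  data.frame(
    query_id = as.character(raw[[1L]]),
    subject_id = as.character(raw[[2L]]),
    identity = as.numeric(raw[[3L]]) / 100,
    e_value = as.numeric(raw[[11L]]),
    bitscore = as.numeric(raw[[12L]]),
    database = db,
    taxon = as.character(raw[[14L]]),
    query_coverage = qcov,
    stringsAsFactors = FALSE
  )
}

#' Write homology hits in the tabular dialect read by readHomologyTab
#'
#' @param hits A `data.frame` as returned by [readHomologyTab()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeHomologyTab <- function(hits, path) {
  n <- nrow(hits)
  raw <- data.frame(hits$query_id, hits$subject_id,
                    round(hits$identity * 100, 2),
                    0L, 0L, 0L, 1L, 1L, 1L, 1L,
                    hits$e_value, hits$bitscore, hits$database, hits$taxon,
                    hits$query_coverage)
  utils::write.table(raw, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a fragment-count table with its stage map
#'
#' The count file is a TSV with a header of sample ids and feature ids in
#' the first column; the sidecar stage map is a TSV with columns
#' `sample_id`, `stage`, `replicate`.  Stage labels follow the berry
#' sampling design: `PFS` (post fruit-set), `PR` (pre-ripening), `PHWII`
#' (post-harvest withering, second month).
#'
#' @param path Path to the count TSV.
#' @param stage_path Path to the stage map TSV.
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `counts` (integer matrix) and `colData` columns `stage` and `replicate`.
#' @export
readCountsTable <- function(path, stage_path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (!file.exists(stage_path)) stop("no such file: ", stage_path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1L,
                           check.names = FALSE)
  m <- as.matrix(tab)
  if (any(m < 0) || any(m != round(m)))
    stop("counts must be non-negative integers")
  storage.mode(m) <- "integer"
  stages <- utils::read.table(stage_path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
  need <- c("sample_id", "stage")
  if (!all(need %in% colnames(stages)))
    stop("stage map needs columns sample_id and stage")
  missing <- setdiff(colnames(m), stages$sample_id)
  if (length(missing))
    stop("samples without a stage label: ", paste(missing, collapse = ", "))
  idx <- match(colnames(m), stages$sample_id)
  cd <- DataFrame(stage = stages$stage[idx],
                  replicate = if ("replicate" %in% colnames(stages))
                    stages$replicate[idx] else NA_integer_,
                  row.names = colnames(m))
  SummarizedExperiment::SummarizedExperiment(assays = list(counts = m),
                                             colData = cd)
}

#' Read a gene-to-term mapping
#'
#' @param path TSV with columns `gene_id` and `term_id` (one pair per row,
#'   header required).
#' @return A `data.frame` with columns `gene_id` and `term_id`.
#' @export
readTermMap <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  map <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  if (!all(c("gene_id", "term_id") %in% colnames(map)))
    stop("term map needs columns gene_id and term_id")
  map[, c("gene_id", "term_id")]
}
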