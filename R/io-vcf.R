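#' Read called variants from VCF
#'
#' Wraps [VariantAnnotation::readVcf()].  Multi-allelic rows are expanded to
#' one record per alternative allele.  Read depth is taken from `INFO/DP`;
#' the alternative-allele frequency from `INFO/AF` when present, otherwise
#' computed as `AO / (AO + RO)`; the caller-reported `AF` takes precedence.
#' Records with neither `AF` nor `AO`/`RO` (or without `DP`) are excluded
#' with a warning.
#'
#' @param path Path to a VCF 4.x file.
#' @return A [GenomicRanges::GRanges] (1-based positions, as in the VCF) with
#'   metadata columns `ref`, `alt`, `depth`, `qual`, `alt_freq`.  The number
#'   of parsed, kept, and excluded records is attached as
#'   `metadata(x)$io_counts`.
#' @export
readVariantsVcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  vcf <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  n <- length(rr)

  getNum <- function(field) {
    if (!field %in% colnames(info)) return(rep(NA_real_, n))
    v <- info[[field]]
    if (is(v, "List") || is.list(v))
      v <- vapply(as.list(v), function(e) if (length(e)) as.numeric(e[[1L]]) else NA_real_,
                  numeric(1))
    as.numeric(v)
  }
  depth <- getNum("DP")
  af <- getNum("AF")
  ao <- getNum("AO")
  ro <- getNum("RO")
  freq <- ifelse(!is.na(af), af, ao / (ao + ro))

  out <- granges(rr)
  mcols(out) <- NULL
  mcols(out)$ref <- as.character(rr$REF)
  mcols(out)$alt <- as.character(rr$ALT)
  mcols(out)$depth <- as.integer(round(depth))
  mcols(out)$qual <- as.numeric(rr$QUAL)
  mcols(out)$alt_freq <- as.numeric(freq)
  names(out) <- NULL

  bad <- is.na(mcols(out)$depth) | is.na(mcols(out)$alt_freq)
  if (any(bad)) {
    warning(sum(bad), " VCF record(s) without DP and AF/AO+RO excluded")
    out <- out[!bad]
  }
  metadata(out)$io_counts <- c(read = n, kept = length(out), rejected = sum(bad))
  out
}

#' Write variant records to VCF
#'
#' Writes the minimal VCF 4.2 dialect read back by [readVariantsVcf()]:
#' `DP` and `AF` in INFO, call quality in QUAL.  Extra metadata columns of
#' `x` (e.g. a planted truth class) are not written.
#'
#' @param x A [GenomicRanges::GRanges] with metadata columns `ref`, `alt`,
#'   `depth`, `qual`, `alt_freq` (1-based positions).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeVariantsVcf <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Alternative allele frequency\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (length(x)) {
    rows <- sprintf("%s\t%d\t.\t%s\t%s\t%s\t.\tDP=%d;AF=%s",
                    as.character(seqnames(x)), start(x),
                    mcols(x)$ref, mcols(x)$alt,
                    format(mcols(x)$qual, trim = TRUE, digits = 10),
                    mcols(x)$depth,
                    format(mcols(x)$alt_freq, trim = TRUE, digits = 10))
    writeLines(rows, con)
  }
  invisible(path)
}
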