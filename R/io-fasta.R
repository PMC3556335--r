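#' @importFrom Biostrings readDNAStringSet writeXStringSet DNAStringSet
#'   DNAString subseq reverseComplement translate nchar nmatch pattern
#'   pairwiseAlignment nucleotideSubstitutionMatrix
NULL

.checkFastaSet <- function(x, path) {
  if (anyDuplicated(names(x)))
    stop("duplicate FASTA ids in ", path, ": ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  if (any(Biostrings::width(x) == 0L))
    stop("empty FASTA record(s) in ", path, ": ",
         paste(names(x)[Biostrings::width(x) == 0L], collapse = ", "))
  bad <- grepl("[^ACGTN]", as.character(x))
  if (any(bad))
    stop("non-ACGTN characters in FASTA record(s): ",
         paste(names(x)[bad], collapse = ", "))
  x
}

#' Read a genome or contig FASTA file
#'
#' Sequences are folded to upper case and validated (unique ids, non-empty
#' records, A/C/G/T/N alphabet).  FASTA ids are truncated at the first
#' whitespace, the common convention for sequence identifiers.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet].  For a genome the names are
#'   chromosome ids; for an assembly they are contig ids.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "acgt"), fa)
#' readContigFasta(fa)
#' @export
readGenomeFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x <- DNAStringSet(toupper(as.character(x)))
  .checkFastaSet(x, path)
}

#' @rdname readGenomeFasta
#' @export
readContigFasta <- readGenomeFasta

#' Write sequences to FASTA
#'
#' @param x A named [Biostrings::DNAStringSet] (or named character vector).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(x, path) {
  if (is.character(x)) x <- DNAStringSet(x)
  writeXStringSet(x, path, width = 70L)
  invisible(path)
}
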