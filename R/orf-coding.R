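.STOP_CODONS <- c("TAA", "TAG", "TGA")

## ORFs of one frame of one strand; coordinates on the scanned strand
.frameOrfs <- function(codons, offset, min_codons) {
  n <- length(codons)
  if (n == 0L) return(NULL)
  isStop <- codons %in% .STOP_CODONS
  stops <- which(isStop)
  segStart <- c(1L, stops + 1L)
  segStop <- c(stops, NA_integer_)[seq_along(segStart)]   # terminating stop index
  out <- list()
  for (s in seq_along(segStart)) {
    i0 <- segStart[s]
    stopIdx <- segStop[s]
    i1 <- if (is.na(stopIdx)) n else stopIdx - 1L
    if (i0 > i1 && is.na(stopIdx)) next
    atg <- if (i0 <= i1) which(codons[i0:i1] == "ATG") else integer(0)
    if (length(atg)) {
      m <- i0 + atg[1L] - 1L
      if (!is.na(stopIdx)) {
        orf <- list(start_codon = m, end_codon = stopIdx, completeness = "full")
      } else {
        orf <- list(start_codon = m, end_codon = n, completeness = "partial_3prime")
      }
    } else if (i0 == 1L) {                    # possibly truncated at 5'
      if (!is.na(stopIdx)) {
        if (stopIdx == 1L) next               # stop in first codon: nothing open
        orf <- list(start_codon = 1L, end_codon = stopIdx,
                    completeness = "partial_5prime")
      } else {
        orf <- list(start_codon = 1L, end_codon = n, completeness = "partial_both")
      }
    } else {
      next
    }
    codonsLen <- orf$end_codon - orf$start_codon + 1L
    if (codonsLen >= min_codons) {
      out[[length(out) + 1L]] <- data.frame(
        start = offset + 3L * (orf$start_codon - 1L) + 1L,
        end = offset + 3L * orf$end_codon,
        codons = codonsLen,
        completeness = orf$completeness,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

.codonsOf <- function(s, offset) {
  n <- nchar(s)
  k <- (n - offset) %/% 3L
  if (k <= 0L) return(character(0))
  starts <- offset + 3L * (0:(k - 1L)) + 1L
  substring(s, starts, starts + 2L)
}

#' Find open reading frames in all six frames
#'
#' Reports all maximal ORFs of at least `min_codons` codons over both
#' strands and all three frames.  An ORF is `full` when it begins with ATG
#' and ends with an in-frame stop codon inside the sequence,
#' `partial_3prime` when it reads through the sequence end without a stop,
#' `partial_5prime` when a frame opens at the sequence start without an
#' upstream ATG but terminates in a stop, `partial_both` when neither
#' feature is present.  Codon counts include the terminating stop codon.
#'
#' @param sequence A [Biostrings::DNAString], or a single character string.
#' @param min_codons Minimum ORF length in codons (default 33, i.e. about
#'   100 nt, a common convention).
#' @return A `data.frame` with columns `strand` (`+`/`-`), `frame` (1-3),
#'   `start`, `end` (1-based nt coordinates on the reported strand; for `-`
#'   they refer to the reverse complement), `codons`, `completeness`;
#'   zero rows when no ORF qualifies.
#' @export
findOrfs <- function(sequence, min_codons = 33L) {
  s <- toupper(as.character(sequence))
  stopifnot(nchar(s) >= 3L)
  rc <- as.character(reverseComplement(DNAString(s)))
  rows <- list()
  for (str in c("+", "-")) {
    ss <- if (str == "+") s else rc
    for (off in 0:2) {
      fr <- .frameOrfs(.codonsOf(ss, off), off, min_codons)
      if (!is.null(fr)) {
        fr$strand <- str
        fr$frame <- off + 1L
        rows[[length(rows) + 1L]] <- fr
      }
    }
  }
  if (!length(rows))
    return(data.frame(strand = character(0), frame = integer(0),
                      start = integer(0), end = integer(0),
                      codons = integer(0), completeness = character(0)))
  out <- do.call(rbind, rows)
  out[order(-out$codons, out$strand, out$frame, out$start),
      c("strand", "frame", "start", "end", "codons", "completeness")]
}

#' @rdname findOrfs
#' @return `longestOrf`: the single longest qualifying ORF (one-row
#'   `data.frame`), or `NULL` when none.
#' @export
longestOrf <- function(sequence, min_codons = 33L) {
  orfs <- findOrfs(sequence, min_codons)
  if (nrow(orfs) == 0L) return(NULL)
  orfs[1L, , drop = FALSE]
}

#' Heuristic coding-potential score
#'
#' A transparent stand-in for an SVM coding-potential classifier, combining
#' two signals: the fraction of the sequence occupied by the longest ORF,
#' and the codon-usage bias of that ORF measured as the Kullback-Leibler
#' divergence of its sense-codon frequencies from the uniform distribution,
#' corrected for the expected small-sample bias `(k - 1) / (2 N ln 2)` so
#' that unbiased random sequences score near zero.  The score is
#' `0.6 * min(1, orf_fraction / 0.8) + 0.4 * min(1, kl_adj / 0.5)` and the
#' sequence is called coding iff it has a full or partial ORF of at least
#' `min_codons` codons and the score reaches 0.5.  Deterministic.
#'
#' @inheritParams findOrfs
#' @return A list: `score` in `[0, 1]`, `is_coding` flag, `orf` (the
#'   longest ORF row or `NULL`).
#' @export
codingPotential <- function(sequence, min_codons = 33L) {
  s <- toupper(as.character(sequence))
  if (nchar(s) < 3L * min_codons)
    return(list(score = 0, is_coding = FALSE, orf = NULL))
  orf <- longestOrf(s, min_codons)
  if (is.null(orf))
    return(list(score = 0, is_coding = FALSE, orf = NULL))
  orfFrac <- (orf$codons * 3L) / nchar(s)

  strandSeq <- if (orf$strand == "+") s else
    as.character(reverseComplement(DNAString(s)))
  body <- substr(strandSeq, orf$start, orf$end)
  codons <- substring(body, seq(1L, nchar(body) - 2L, 3L),
                      seq(3L, nchar(body), 3L))
  codons <- codons[!codons %in% .STOP_CODONS & !grepl("N", codons)]
  klAdj <- 0
  if (length(codons) >= 10L) {
    f <- table(codons) / length(codons)
    kl <- sum(f * log2(f * 61))
    klAdj <- max(0, kl - 60 / (2 * length(codons) * log(2)))
  }
  score <- 0.6 * min(1, orfFrac / 0.8) + 0.4 * min(1, klAdj / 0.5)
  list(score = score, is_coding = score >= 0.5, orf = orf)
}
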