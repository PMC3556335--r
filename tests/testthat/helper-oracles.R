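# Independent brute-force oracles used to check the implementation.

# N50/N90 by direct definition: largest L with sum(lengths >= L) >= frac*total
bruteNStat <- function(lengths, frac) {
  total <- sum(as.numeric(lengths))
  cand <- sort(unique(lengths), decreasing = TRUE)
  for (L in cand) {
    if (sum(as.numeric(lengths[lengths >= L])) >= frac * total) return(L)
  }
  min(lengths)
}

# per-base coverage counting by explicit loops (small instances only)
bruteCoverage <- function(blockList, chromLens) {
  out <- lapply(chromLens, function(n) integer(n))
  for (b in blockList) {
    for (i in seq_along(b$start)) {
      idx <- b$start[i]:b$end[i]
      out[[b$chrom]][idx] <- out[[b$chrom]][idx] + 1L
    }
  }
  out
}

# per-base feature classification: exon > intron > intergenic
bruteClassifyBases <- function(depth, exonIv, spanIv, minDepth) {
  counts <- c(annotated_exon = 0L, intron = 0L, intergenic = 0L)
  inAny <- function(p, iv) any(p >= iv$start & p <= iv$end)
  for (p in seq_along(depth)) {
    if (depth[p] < minDepth) next
    cls <- if (inAny(p, exonIv)) "annotated_exon"
           else if (inAny(p, spanIv)) "intron" else "intergenic"
    counts[cls] <- counts[cls] + 1L
  }
  counts
}

# greedy clustering without the k-mer pre-screen, alignment done directly
bruteClusterContigs <- function(contigs, min_identity = 0.9,
                                min_short_coverage = 1.0) {
  lens <- Biostrings::width(contigs)
  ord <- order(-lens, names(contigs))
  seqs <- as.character(contigs)[ord]
  ids <- names(contigs)[ord]
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3)
  reps <- integer(0)
  assign <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    found <- 0L
    for (r in reps) {
      aln <- Biostrings::pairwiseAlignment(seqs[i], seqs[r], type = "local",
                                           substitutionMatrix = sm,
                                           gapOpening = 5, gapExtension = 2)
      cols <- Biostrings::nchar(aln)
      if (cols == 0) next
      idy <- Biostrings::nmatch(aln) / cols
      pat <- Biostrings::pattern(aln)
      cov <- (BiocGenerics::end(pat) - BiocGenerics::start(pat) + 1) /
        nchar(seqs[i])
      if (idy > min_identity && cov >= min_short_coverage) { found <- r; break }
    }
    if (found == 0L) { reps <- c(reps, i); assign[i] <- i } else assign[i] <- found
  }
  data.frame(contig_id = ids, representative = ids[assign],
             stringsAsFactors = FALSE)
}

# exhaustive 6-frame ORF scan, coded independently: walks codon by codon
bruteOrfs <- function(s, min_codons = 33L) {
  s <- toupper(s)
  stops <- c("TAA", "TAG", "TGA")
  res <- list()
  for (strand in c("+", "-")) {
    ss <- if (strand == "+") s else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    for (off in 0:2) {
      nCod <- (nchar(ss) - off) %/% 3
      if (nCod < 1) next
      cods <- vapply(seq_len(nCod), function(i)
        substr(ss, off + 3 * (i - 1) + 1, off + 3 * i), character(1))
      i <- 1L
      while (i <= nCod) {
        # find next stop from i
        j <- i
        while (j <= nCod && !cods[j] %in% stops) j <- j + 1L
        hasStop <- j <= nCod
        seg <- i:(if (hasStop) j else nCod)
        atg <- seg[cods[seg] == "ATG"][1]
        orf <- NULL
        if (!is.na(atg)) {
          orf <- list(from = atg, to = if (hasStop) j else nCod,
                      comp = if (hasStop) "full" else "partial_3prime")
        } else if (i == 1L) {
          if (hasStop && j > 1L) orf <- list(from = 1L, to = j, comp = "partial_5prime")
          if (!hasStop) orf <- list(from = 1L, to = nCod, comp = "partial_both")
        }
        if (!is.null(orf) && orf$to - orf$from + 1L >= min_codons)
          res[[length(res) + 1L]] <- data.frame(
            strand = strand, frame = off + 1L,
            start = off + 3L * (orf$from - 1L) + 1L,
            end = off + 3L * orf$to,
            codons = orf$to - orf$from + 1L,
            completeness = orf$comp, stringsAsFactors = FALSE)
        i <- j + 1L
      }
    }
  }
  if (!length(res)) return(NULL)
  do.call(rbind, res)
}

# Benjamini-Hochberg by the step-up definition
bruteBH <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (k in n:1) {
    val <- min(prev, p[o[k]] * n / k)
    adj[o[k]] <- val
    prev <- val
  }
  adj
}

# connected components by breadth-first search over an edge list
bruteComponents <- function(n, edges) {
  comp <- rep(NA_integer_, n)
  cur <- 0L
  adj <- lapply(seq_len(n), function(i) integer(0))
  if (nrow(edges)) for (e in seq_len(nrow(edges))) {
    adj[[edges[e, 1]]] <- c(adj[[edges[e, 1]]], edges[e, 2])
    adj[[edges[e, 2]]] <- c(adj[[edges[e, 2]]], edges[e, 1])
  }
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, adj[[v]][is.na(comp[adj[[v]]])])
    }
  }
  comp
}
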