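#' FPKM with a count-level confidence interval
#'
#' FPKM = count / (exon-model length in kb x mapped fragments in millions).
#' The 95% CI comes from a normal approximation on the count scale,
#' `count +/- 1.96 sqrt(count)` floored at zero and rescaled to FPKM units;
#' a zero count gets the upper bound `1.96^2 = 3.84` fragments (the usual
#' continuity guard, so that "never observed" still has an upper bound).
#'
#' @param counts A [SummarizedExperiment::SummarizedExperiment] from
#'   [readCountsTable()], or a plain integer matrix (features x samples).
#' @param lengths Named numeric vector of exon-model lengths in bp.
#' @return A `data.frame` with columns `feature_id`, `sample_id`, `count`,
#'   `fpkm`, `ci_low`, `ci_high`.
#' @export
computeFpkm <- function(counts, lengths) {
  m <- if (is(counts, "SummarizedExperiment"))
    SummarizedExperiment::assay(counts, "counts") else counts
  stopifnot(all(rownames(m) %in% names(lengths)))
  len <- lengths[rownames(m)]
  if (any(len <= 0)) stop("exon-model lengths must be positive")
  totals <- colSums(m)
  if (any(totals == 0)) stop("sample(s) with zero total count: ",
                             paste(colnames(m)[totals == 0], collapse = ", "))
  scale <- outer(len / 1e3, totals / 1e6)     # fpkm = count / scale
  lowC <- pmax(0, m - 1.96 * sqrt(m))
  highC <- m + 1.96 * sqrt(m)
  highC[m == 0] <- 1.96^2
  data.frame(
    feature_id = rep(rownames(m), ncol(m)),
    sample_id = rep(colnames(m), each = nrow(m)),
    count = as.vector(m),
    fpkm = as.vector(m / scale),
    ci_low = as.vector(lowC / scale),
    ci_high = as.vector(highC / scale),
    stringsAsFactors = FALSE)
}

#' Expressed-feature rule
#'
#' A feature is expressed in a sample iff the lower bound of its FPKM 95%
#' confidence interval is strictly greater than zero and its FPKM is
#' strictly greater than 0.001.
#'
#' @param fpkm,ci_low Numeric vectors (recycled), e.g. columns of
#'   [computeFpkm()]'s output.
#' @return Logical vector.
#' @export
isExpressed <- function(fpkm, ci_low) {
  ci_low > 0 & fpkm > 0.001
}

#' Median-of-ratios size factors
#'
#' The size factor of a sample is the median, over features with nonzero
#' counts in every sample, of the ratio of the sample's count to the
#' feature's geometric mean across samples.
#'
#' @param counts Integer matrix (features x samples) or a
#'   SummarizedExperiment with a `counts` assay.
#' @return Named numeric vector of size factors (> 0).
#' @export
sizeFactorsMedianRatio <- function(counts) {
  m <- if (is(counts, "SummarizedExperiment"))
    SummarizedExperiment::assay(counts, "counts") else counts
  ok <- rowSums(m == 0) == 0L
  if (!any(ok))
    stop("no feature with nonzero counts in all samples; ",
         "median-of-ratios undefined (consider a pseudo-reference)")
  geo <- exp(rowMeans(log(m[ok, , drop = FALSE])))
  apply(m[ok, , drop = FALSE] / geo, 2, stats::median)
}

.normalizedCounts <- function(m, sf) {
  sweep(m, 2, sf, "/")
}

## pooled method-of-moments dispersion per feature (floored)
.pooledDispersion <- function(normA, normB, floor = 1e-8) {
  nA <- ncol(normA); nB <- ncol(normB)
  mA <- rowMeans(normA); mB <- rowMeans(normB)
  vA <- apply(normA, 1, stats::var); vB <- apply(normB, 1, stats::var)
  pooledVar <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
  baseMean <- (nA * mA + nB * mB) / (nA + nB)
  disp <- (pooledVar - baseMean) / baseMean^2
  disp[!is.finite(disp)] <- floor
  pmax(disp, floor)
}

## two-sided exact-style NB test of one feature, conditional on the total
.nbExactP <- function(kA, kB, muA, muB, sizeA, sizeB) {
  k <- kA + kB
  a <- 0:k
  pa <- stats::dnbinom(a, mu = muA, size = sizeA)
  pb <- stats::dnbinom(k - a, mu = muB, size = sizeB)
  joint <- pa * pb
  tot <- sum(joint)
  if (tot == 0) return(1)
  pObs <- joint[kA + 1L]
  min(1, sum(joint[joint <= pObs]) / tot)
}

#' Exact-style negative-binomial test between two stages
#'
#' Per feature: counts are normalized by median-of-ratios size factors, a
#' pooled method-of-moments dispersion is estimated (floored at 1e-8), and
#' the two groups' count sums are compared with a two-sided exact-style NB
#' test — the probabilities of all ways of splitting the observed total
#' between the groups are summed over outcomes at most as probable as the
#' observed split, with each group's sum modelled as NB with
#' moment-matched mean and size under the null of equal normalized means.
#' P-values are BH-adjusted across features; all-zero features get p = 1
#' and are excluded from the BH denominator.  The log2 fold change is
#' computed from normalized group means with pseudocount 1.
#'
#' @param counts Integer matrix or SummarizedExperiment with `counts`.
#' @param stages Character vector of stage labels per sample (taken from
#'   `colData(counts)$stage` when missing).
#' @param stage_a,stage_b The two stages to contrast (fold change is B over
#'   A).
#' @param size_factors Optional pre-computed size factors.
#' @return A `data.frame`: `feature_id`, `base_mean_a`, `base_mean_b`,
#'   `log2fc`, `dispersion`, `pvalue`, `padj`.
#' @export
nbExactTest <- function(counts, stage_a, stage_b, stages = NULL,
                        size_factors = NULL) {
  m <- if (is(counts, "SummarizedExperiment")) {
    if (is.null(stages))
      stages <- as.character(SummarizedExperiment::colData(counts)$stage)
    SummarizedExperiment::assay(counts, "counts")
  } else counts
  stopifnot(!is.null(stages), length(stages) == ncol(m))
  selA <- which(stages == stage_a); selB <- which(stages == stage_b)
  if (length(selA) < 2L || length(selB) < 2L)
    stop("need >= 2 replicates per stage")
  if (is.null(size_factors)) size_factors <- sizeFactorsMedianRatio(m)
  sfA <- size_factors[selA]; sfB <- size_factors[selB]
  normA <- .normalizedCounts(m[, selA, drop = FALSE], sfA)
  normB <- .normalizedCounts(m[, selB, drop = FALSE], sfB)
  disp <- .pooledDispersion(normA, normB)
  # dispersion sharing across features: with 2-3 replicates the per-feature
  # moment estimate is extremely noisy and its low tail makes the exact test
  # anti-conservative, so each feature's dispersion is floored at the
  # across-feature median (the "maximum" sharing rule used at low
  # replication); within-group estimation keeps power for true changes
  expressed <- rowSums(m[, c(selA, selB), drop = FALSE]) > 0
  if (sum(expressed) >= 20L)
    disp <- pmax(disp, stats::median(disp[expressed]))
  meanA <- rowMeans(normA); meanB <- rowMeans(normB)

  kA <- rowSums(m[, selA, drop = FALSE])
  kB <- rowSums(m[, selB, drop = FALSE])
  qNull <- (kA + kB) / (sum(sfA) + sum(sfB))   # common normalized mean
  pvalue <- rep(1, nrow(m))
  nz <- which(kA + kB > 0)
  for (i in nz) {
    muA <- qNull[i] * sum(sfA)
    muB <- qNull[i] * sum(sfB)
    varA <- sum(qNull[i] * sfA + disp[i] * (qNull[i] * sfA)^2)
    varB <- sum(qNull[i] * sfB + disp[i] * (qNull[i] * sfB)^2)
    sizeA <- if (varA > muA) muA^2 / (varA - muA) else 1e8
    sizeB <- if (varB > muB) muB^2 / (varB - muB) else 1e8
    pvalue[i] <- .nbExactP(kA[i], kB[i], muA, muB, sizeA, sizeB)
  }
  padj <- rep(1, nrow(m))
  padj[nz] <- stats::p.adjust(pvalue[nz], method = "BH")
  data.frame(feature_id = rownames(m) %||% as.character(seq_len(nrow(m))),
             base_mean_a = meanA, base_mean_b = meanB,
             log2fc = log2((meanB + 1) / (meanA + 1)),
             dispersion = disp, pvalue = pvalue, padj = padj,
             row.names = NULL, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Moderated (shrunken) log2 fold change
#'
#' A shifted-log moderated estimate playing the role of a
#' variance-stabilizing transformation for profile clustering: the
#' difference of group means of `log2(normalized count + c)`.  The
#' pseudocount `c` (default 8) damps fold changes at low counts —
#' `|moderated| <= |raw|` there — while converging to the raw log-ratio as
#' counts grow.
#'
#' @inheritParams nbExactTest
#' @param pseudocount The stabilizing constant `c`.
#' @return Named numeric vector of moderated log2 fold changes (B over A).
#' @export
moderatedLog2FC <- function(counts, stage_a, stage_b, stages = NULL,
                            size_factors = NULL, pseudocount = 8) {
  m <- if (is(counts, "SummarizedExperiment")) {
    if (is.null(stages))
      stages <- as.character(SummarizedExperiment::colData(counts)$stage)
    SummarizedExperiment::assay(counts, "counts")
  } else counts
  if (is.null(size_factors)) size_factors <- sizeFactorsMedianRatio(m)
  norm <- .normalizedCounts(m, size_factors)
  a <- rowMeans(log2(norm[, stages == stage_a, drop = FALSE] + pseudocount))
  b <- rowMeans(log2(norm[, stages == stage_b, drop = FALSE] + pseudocount))
  stats::setNames(b - a, rownames(m))
}

#' Assign four-pattern development profiles
#'
#' From the two adjacent-stage contrasts (early to mid, mid to late), each
#' feature gets a signed significance `+1`/`-1`/`0` per contrast
#' (significant iff `padj <= fdr` and `|log2fc| >= lfc`).  Profiles:
#' down/down, down/flat and flat/down are cluster 1 (repressed); down/up is
#' cluster 2 (transiently repressed); up/down is cluster 3 (transiently
#' induced); up/up, up/flat and flat/up are cluster 4 (induced); flat/flat
#' is unclustered (`none`).
#'
#' @param de_ab,de_bc `data.frame`s from [nbExactTest()] for the first and
#'   second adjacent-stage contrast (same feature order).
#' @param fdr,lfc Significance thresholds (defaults 0.05 and 1).
#' @return A `data.frame`: `feature_id`, `d1`, `d2` (signed significance),
#'   `cluster` (`"1"`-`"4"` or `"none"`).
#' @export
assignProfileClusters <- function(de_ab, de_bc, fdr = 0.05, lfc = 1) {
  stopifnot(identical(de_ab$feature_id, de_bc$feature_id))
  sig <- function(de) {
    s <- integer(nrow(de))
    hit <- de$padj <= fdr & abs(de$log2fc) >= lfc
    s[hit] <- sign(de$log2fc[hit])
    s
  }
  d1 <- sig(de_ab); d2 <- sig(de_bc)
  cluster <- rep("none", length(d1))
  cluster[(d1 == -1 & d2 <= 0) | (d1 == 0 & d2 == -1)] <- "1"
  cluster[d1 == -1 & d2 == 1] <- "2"
  cluster[d1 == 1 & d2 == -1] <- "3"
  cluster[(d1 == 1 & d2 >= 0) | (d1 == 0 & d2 == 1)] <- "4"
  data.frame(feature_id = de_ab$feature_id, d1 = d1, d2 = d2,
             cluster = cluster, stringsAsFactors = FALSE)
}

#' Hypergeometric term enrichment
#'
#' One-sided upper-tail hypergeometric test of each term's overlap with
#' each feature group, BH-adjusted across terms within a group; a term is
#' enriched iff its adjusted p is below `fdr`.  Terms with no member in
#' the universe are skipped.
#'
#' @param groups Named list of feature-id vectors (each a subset of
#'   `universe`).
#' @param term_map `data.frame` with columns `gene_id`, `term_id`.
#' @param universe Character vector of all features under consideration.
#' @param fdr Enrichment threshold on the adjusted p (default 0.05,
#'   strict `<`).
#' @return A `data.frame`: `group`, `term_id`, `overlap`, `group_size`,
#'   `term_size`, `universe_size`, `pvalue`, `padj`, `enriched`.
#' @export
enrichTerms <- function(groups, term_map, universe, fdr = 0.05) {
  term_map <- term_map[term_map$gene_id %in% universe, , drop = FALSE]
  terms <- split(term_map$gene_id, term_map$term_id)
  terms <- terms[lengths(terms) > 0L]
  N <- length(universe)
  rows <- list()
  for (g in names(groups)) {
    members <- intersect(groups[[g]], universe)
    n <- length(members)
    res <- data.frame(
      group = g,
      term_id = names(terms),
      overlap = vapply(terms, function(t) length(intersect(t, members)),
                       integer(1)),
      group_size = n,
      term_size = lengths(terms),
      universe_size = N,
      stringsAsFactors = FALSE)
    res$pvalue <- stats::phyper(res$overlap - 1L, res$term_size,
                                N - res$term_size, n, lower.tail = FALSE)
    res$padj <- stats::p.adjust(res$pvalue, method = "BH")
    rows[[g]] <- res
  }
  out <- do.call(rbind, rows)
  out$enriched <- out$padj < fdr
  rownames(out) <- NULL
  out
}
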