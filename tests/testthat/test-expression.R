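mkCounts <- function(m, stages = rep(c("A", "B"), each = 3)) {
  rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
  colnames(m) <- sprintf("s%d", seq_len(ncol(m)))
  attr(m, "stages") <- stages
  m
}

test_that("FPKM follows the count / (kb x million) formula with a count-scale CI", {
  m <- matrix(c(10L, 0L), nrow = 2,
              dimnames = list(c("f1", "f2"), "s1"))
  m["f2", 1] <- 0L
  m <- rbind(m, other = 999990L)               # bring the total to 1e6
  lens <- c(f1 = 1000, f2 = 500, other = 1000)
  out <- computeFpkm(m, lens)
  expect_equal(out$fpkm[out$feature_id == "f1"], 10)
  z <- out[out$feature_id == "f2", ]
  expect_equal(z$fpkm, 0)
  expect_equal(z$ci_low, 0)
  expect_equal(z$ci_high, 1.96^2 / (0.5 * 1))  # 3.84 rescaled to FPKM units

  # fuzzed tables against direct recomputation
  set.seed(3)
  m <- matrix(rpois(60, 50), nrow = 10)
  rownames(m) <- paste0("g", 1:10); colnames(m) <- paste0("s", 1:6)
  lens <- setNames(sample(500:3000, 10), rownames(m))
  out <- computeFpkm(m, lens)
  for (k in sample(nrow(out), 10)) {
    f <- out$feature_id[k]; s <- out$sample_id[k]
    expect_equal(out$fpkm[k],
                 m[f, s] / (lens[[f]] / 1e3 * sum(m[, s]) / 1e6))
  }
  expect_error(computeFpkm(m * 0L, lens), "zero total")
})

test_that("the expressed rule uses strict inequalities on CI and FPKM", {
  expect_true(isExpressed(3.0, 0.5))
  expect_false(isExpressed(0.0005, 0.0001))    # FPKM not above 0.001
  expect_false(isExpressed(3.0, 0))            # CI lower bound exactly zero
})

test_that("median-of-ratios size factors behave like the normalization they define", {
  set.seed(11)
  base <- rpois(200, 100) + 1L
  m <- cbind(s1 = base, s2 = 2L * base)
  rownames(m) <- paste0("g", 1:200)
  sf <- sizeFactorsMedianRatio(m)
  expect_equal(unname(sf[2] / sf[1]), 2)
  expect_equal(unname(prod(sf)), 1, tolerance = 1e-12)  # geometric mean 1
  expect_equal(unname(sizeFactorsMedianRatio(cbind(s1 = base, s2 = base))),
               c(1, 1))

  # fuzz vs direct recomputation
  for (i in 1:10) {
    m <- matrix(rpois(120, 60) + 1L, ncol = 4)
    rownames(m) <- paste0("g", 1:30); colnames(m) <- paste0("s", 1:4)
    sf <- sizeFactorsMedianRatio(m)
    geo <- exp(rowMeans(log(m)))
    want <- apply(m / geo, 2, median)
    expect_equal(unname(sf), unname(want))
  }
  # scaling invariance: multiplying a sample by k multiplies its factor by k
  # relative to the others (factors are identified only up to the overall
  # geometric-mean normalization)
  m <- matrix(rpois(90, 80) + 1L, ncol = 3)
  rownames(m) <- paste0("g", 1:30); colnames(m) <- paste0("s", 1:3)
  m2 <- m; m2[, 2] <- m2[, 2] * 5L
  sf <- sizeFactorsMedianRatio(m); sf2 <- sizeFactorsMedianRatio(m2)
  expect_equal(unname((sf2[2] / sf2[1]) / (sf[2] / sf[1])), 5,
               tolerance = 1e-9)

  expect_error(sizeFactorsMedianRatio(matrix(c(0L, 1L, 1L, 0L), 2)),
               "no feature")
})

test_that("the NB exact-style test is null-calibrated and finds planted changes", {
  # identical replicate counts in both groups: no evidence
  m <- mkCounts(matrix(rep(c(40L, 50L, 60L), 2), nrow = 1))
  de <- nbExactTest(m, "A", "B", stages = attr(m, "stages"))
  expect_gte(de$pvalue, 0.99)
  expect_equal(de$log2fc, 0)

  # an all-zero feature gets p = 1 and does not dilute the BH correction
  set.seed(29)
  m <- matrix(rnbinom(300, mu = 100, size = 10), ncol = 6)
  m[1, ] <- 0L
  m <- mkCounts(m)
  de <- nbExactTest(m, "A", "B", stages = attr(m, "stages"))
  expect_equal(de$pvalue[1], 1)
  expect_equal(de$padj[1], 1)

  # a planted 8-fold change at mean 200 is detected
  set.seed(41)
  m <- matrix(rnbinom(600, mu = 200, size = 20), ncol = 6)
  m[1:5, 4:6] <- rnbinom(15, mu = 1600, size = 20)
  m <- mkCounts(m)
  de <- nbExactTest(m, "A", "B", stages = attr(m, "stages"))
  expect_true(all(de$padj[1:5] < 0.05))
  expect_true(all(abs(de$log2fc[1:5]) >= 1))
})

test_that("moderated fold changes shrink at low counts and converge at high counts", {
  stages <- rep(c("A", "B"), each = 3)
  mk <- function(a, b) {
    m <- matrix(c(rep(a, 3), rep(b, 3)), nrow = 1)
    m <- rbind(m, matrix(rep(50L, 6), nrow = 1))   # anchor for size factors
    rownames(m) <- c("g1", "anchor"); colnames(m) <- paste0("s", 1:6)
    m
  }
  sf <- rep(1, 6)
  expect_equal(unname(moderatedLog2FC(mk(0L, 0L), "A", "B", stages,
                                      size_factors = sf)["g1"]), 0)
  lowShrink <- 3 - unname(moderatedLog2FC(mk(1L, 8L), "A", "B", stages,
                                          size_factors = sf)["g1"])
  highShrink <- 3 - unname(moderatedLog2FC(mk(1000L, 8000L), "A", "B", stages,
                                           size_factors = sf)["g1"])
  expect_gt(lowShrink, highShrink)               # more shrinkage at low counts
  huge <- unname(moderatedLog2FC(mk(10000L, 80000L), "A", "B", stages,
                                 size_factors = sf)["g1"])
  expect_lt(abs(huge - 3), 0.01)                 # asymptotically the raw lfc
})

test_that("profile clusters implement the signed-significance mapping", {
  de <- function(d) data.frame(feature_id = "f", log2fc = d * 2,
                               padj = ifelse(d == 0, 0.9, 0.001))
  cl <- function(d1, d2)
    assignProfileClusters(de(d1), de(d2))$cluster
  expect_equal(cl(-1, -1), "1")
  expect_equal(cl(-1, 0), "1")
  expect_equal(cl(0, -1), "1")
  expect_equal(cl(-1, 1), "2")                   # transiently repressed
  expect_equal(cl(1, -1), "3")                   # transiently induced
  expect_equal(cl(1, 1), "4")
  expect_equal(cl(1, 0), "4")
  expect_equal(cl(0, 1), "4")
  expect_equal(cl(0, 0), "none")
})

test_that("hypergeometric enrichment matches exact enumeration; BH matches step-up", {
  # N = 10, term 5, group 4, overlap 4: C(5,4) C(5,0) / C(10,4) = 5/210
  universe <- paste0("g", 1:10)
  map <- data.frame(gene_id = universe[1:5], term_id = "T1")
  out <- enrichTerms(list(grp = universe[1:4]), map, universe)
  expect_equal(out$pvalue, 5 / 210)
  # zero overlap with a tiny term: upper tail from 0 is ~1
  map2 <- data.frame(gene_id = universe[10], term_id = "T2")
  out2 <- enrichTerms(list(grp = universe[1:4]), map2, universe)
  expect_equal(out2$pvalue, 1, tolerance = 1e-9)

  expect_equal(p.adjust(c(0.01, 0.02, 0.04), "BH"), c(0.03, 0.03, 0.04))
  set.seed(77)
  for (i in 1:25) {
    p <- round(runif(sample(1:20, 1)), 3)
    adj <- p.adjust(p, "BH")
    expect_equal(adj, bruteBH(p))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))   # monotone in rank order
  }
})

test_that("planted profile patterns are recovered from simulated counts", {
  cfg <- simulationConfig(seed = 19)
  cnt <- simulateCounts(cfg, sprintf("f%03d", 1:150))
  d1 <- nbExactTest(cnt$counts, "PFS", "PR")
  d2 <- nbExactTest(cnt$counts, "PR", "PHWII")
  pc <- assignProfileClusters(d1, d2)
  cmp <- merge(pc, cnt$truth, by = "feature_id")
  patterned <- cmp$pattern != "flat"
  expect_gte(mean(cmp$cluster[patterned] == cmp$pattern[patterned]), 0.95)
  expect_lte(mean(cmp$cluster[!patterned] != "none"), 0.05)
})
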