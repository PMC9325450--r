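# windows GRanges with hand-set statistics for the caller tests
statWindows <- function(piW, piC, fst, width = 100) {
  n <- length(fst)
  gr <- GRanges("chr1", IRanges::IRanges((seq_len(n) - 1) * width + 1,
                                         width = width))
  mcols(gr) <- DataFrame(nSites = rep(1L, n), pi_W = piW, pi_C = piC,
                         fst_W_C = fst)
  gr
}

test_that("log2 pi-ratio handles finite, sentinel and undefined cases", {
  expect_equal(log2PiRatio(0.004, 0.001), 2)
  expect_equal(log2PiRatio(0.003, 0.003), 0)
  expect_identical(log2PiRatio(0.004, 0), Inf)
  expect_true(is.na(log2PiRatio(0, 0)))
  expect_error(log2PiRatio(-1e-3, 0.001), "negative")
  # the +Inf sentinel ranks above every finite value
  v <- c(1, 5, Inf, 3)
  pct <- empiricalPercentile(v)
  expect_equal(pct[3], 100)
  expect_true(all(pct[3] >= pct[-3]))
})

test_that("empirical percentiles use mid-rank ties", {
  pct <- empiricalPercentile(1:100)
  expect_equal(pct[100], 99.5)
  expect_identical(which(pct >= 95), 96:100)     # top-5% set
  expect_warning(pctT <- empiricalPercentile(rep(2, 10)), "identical")
  expect_equal(pctT, rep(50, 10))
  set.seed(3)
  v <- rnorm(50)
  perm <- sample(50)
  expect_equal(empiricalPercentile(v)[perm], empiricalPercentile(v[perm]))
  expect_true(is.na(empiricalPercentile(c(1, NA, 2))[2]))
})

test_that("sweep windows need both statistics in the top tail", {
  set.seed(41)
  n <- 200
  fst <- runif(n); ratio <- runif(n)
  fst[1] <- 2            # top-1% FST ...
  ratio[1] <- 0.5        # ... but middling pi-ratio
  win <- statWindows(piW = 0.001 * 2^ratio, piC = rep(0.001, n), fst = fst)
  called <- callSweepWindows(win, "W", "C", q = 0.05)
  expect_false(called$selected[1])
  expect_error(callSweepWindows(win, "W", "C", q = 0.7), "q must")
})

test_that("planted extreme windows are all selected, bounded by q", {
  set.seed(43)
  n <- 500
  fst <- runif(n, 0, 0.5); piC <- runif(n, 5e-4, 2e-3)
  piW <- runif(n, 5e-4, 2e-3)
  planted <- sample(n, 10)
  fst[planted] <- runif(10, 0.9, 1)
  piC[planted] <- runif(10, 1e-6, 1e-5)   # ratio maximal
  win <- statWindows(piW, piC, fst)
  called <- callSweepWindows(win, "W", "C", q = 0.05)
  expect_true(all(called$selected[planted]))
  expect_lte(sum(called$selected), 25)
  # brute-force joint-threshold oracle
  thrF <- sort(fst, decreasing = TRUE)[floor(0.05 * n)]
  ratio <- log2(piW / piC)
  thrR <- sort(ratio, decreasing = TRUE)[floor(0.05 * n)]
  want <- fst >= thrF & ratio >= thrR
  expect_identical(unname(called$selected), unname(want))
})

test_that("independent null statistics select ~ q^2 of windows", {
  set.seed(47)
  frac <- replicate(3, {
    n <- 10000
    win <- statWindows(piW = 0.001 * 2^runif(n), piC = rep(0.001, n),
                       fst = runif(n))
    mean(callSweepWindows(win, "W", "C", q = 0.05)$selected)
  })
  expect_gt(mean(frac), 0.0025 - 0.0015)
  expect_lt(mean(frac), 0.0025 + 0.0015)
})

test_that("scaling all pi values leaves sweep calls unchanged", {
  set.seed(53)
  n <- 300
  piW <- runif(n, 1e-4, 3e-3); piC <- runif(n, 1e-4, 3e-3)
  fst <- runif(n)
  a <- callSweepWindows(statWindows(piW, piC, fst), "W", "C")
  b <- callSweepWindows(statWindows(7.3 * piW, 7.3 * piC, fst), "W", "C")
  expect_identical(a$selected, b$selected)
  expect_equal(a$pctRatio, b$pctRatio)
})

test_that("window merging follows closed-interval overlap and gap rules", {
  w <- GRanges(c("chr1", "chr1"), IRanges::IRanges(c(1, 51), c(100, 150)))
  mcols(w) <- DataFrame(log2PiRatio = c(1, 2), fst_W_C = c(0.5, 0.9))
  m <- mergeSweepWindows(w)
  expect_equal(GenomicRanges::start(m), 1)
  expect_equal(GenomicRanges::end(m), 150)
  expect_equal(m$maxFst, 0.9)
  expect_equal(m$maxLog2PiRatio, 2)
  w2 <- GRanges(c("chr1", "chr2"), IRanges::IRanges(c(1, 1), c(100, 100)))
  expect_length(mergeSweepWindows(w2), 2)
})

test_that("random merges equal the quadratic interval-union oracle", {
  set.seed(59)
  for (trial in 1:30) {
    n <- sample(2:25, 1)
    gap <- sample(c(0, 10), 1)
    chrom <- sample(c("chr1", "chr2"), n, TRUE)
    start <- sample.int(2000, n)
    end <- start + sample.int(300, n, TRUE)
    w <- GRanges(factor(chrom, levels = c("chr1", "chr2")),
                 IRanges::IRanges(start, end))
    got <- mergeSweepWindows(w, gapBp = gap)
    want <- oracleMerge(chrom, start, end, gapBp = gap)
    expect_equal(length(got), nrow(want))
    expect_equal(GenomicRanges::start(got), want$start)
    expect_equal(GenomicRanges::end(got), want$end)
  }
})

test_that("gene overlap uses >= 1 bp on closed intervals", {
  genes <- list(genes = GRanges("chr1", IRanges::IRanges(100, 200),
                                gene_id = "g1"))
  r1 <- genesInSweeps(GRanges("chr1", IRanges::IRanges(150, 300)), genes)
  expect_identical(unlist(r1$gene_ids), "g1")
  r2 <- genesInSweeps(GRanges("chr1", IRanges::IRanges(201, 300)), genes)
  expect_length(unlist(r2$gene_ids), 0)     # adjacency is not overlap
})

test_that("random gene overlaps equal the quadratic scan oracle", {
  set.seed(61)
  for (trial in 1:20) {
    genes <- randomGenes(50, chromLength = 3e4)
    start <- sample.int(3e4, 5)
    regions <- GRanges("chr1", IRanges::IRanges(start, start +
                                                  sample.int(2000, 5)))
    got <- genesInSweeps(regions, genes)
    want <- oracleOverlapPairs(
      rep("chr1", 5), GenomicRanges::start(regions),
      GenomicRanges::end(regions),
      as.character(seqnames(genes$genes)),
      GenomicRanges::start(genes$genes), GenomicRanges::end(genes$genes))
    wantIds <- if (is.null(want)) character() else
      sort(unique(genes$genes$gene_id[want[, 2]]))
    expect_identical(sort(S4Vectors::metadata(got)$sweepGenes), wantIds)
    perRegion <- vapply(seq_along(regions), function(i)
      length(got$gene_ids[[i]]), integer(1))
    wantPer <- vapply(seq_along(regions), function(i)
      if (is.null(want)) 0L else sum(want[, 1] == i), integer(1))
    expect_identical(perRegion, wantPer)
  }
})

test_that("sweep-set overlap reports region pairs and shared genes", {
  genes <- list(genes = GRanges("chr1", IRanges::IRanges(c(10, 500), c(60, 700)),
                                gene_id = c("g1", "g2")))
  a <- GRanges("chr1", IRanges::IRanges(c(1, 400), c(100, 800)))
  b <- GRanges("chr1", IRanges::IRanges(2000, 2100))
  ovDisjoint <- sweepOverlap(a, b, genes)
  expect_equal(ovDisjoint$nOverlaps, 0)
  expect_length(ovDisjoint$sharedGenes, 0)
  ovSelf <- sweepOverlap(a, a, genes)
  expect_gte(ovSelf$nOverlaps, length(a))
  expect_setequal(ovSelf$sharedGenes, c("g1", "g2"))
  set.seed(67)
  sa <- sample.int(5000, 8); sb <- sample.int(5000, 6)
  ra <- GRanges("chr1", IRanges::IRanges(sa, sa + 300))
  rb <- GRanges("chr1", IRanges::IRanges(sb, sb + 300))
  got <- sweepOverlap(ra, rb)
  want <- oracleOverlapPairs(rep("chr1", 8), sa, sa + 300,
                             rep("chr1", 6), sb, sb + 300)
  expect_equal(got$nOverlaps, if (is.null(want)) 0L else nrow(want))
})
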