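test_that("F = 0 populations copy the ancestral frequencies exactly", {
  cfg <- simConfig(seed = 11, nSites = 500,
                   populations = data.frame(label = c("A", "B"),
                                            n = c(5L, 5L), F = c(0, 0)))
  tr <- simulateFrequencies(cfg)
  expect_identical(popFrequencies(tr)[, "A"], tr@ancestralFreq)
  expect_identical(popFrequencies(tr)[, "B"], tr@ancestralFreq)
})

test_that("invalid drift parameters are rejected at configuration", {
  expect_error(simConfig(populations = data.frame(
    label = "A", n = 5L, F = 1)), "F must lie")
  expect_error(simConfig(populations = data.frame(
    label = "A", n = 5L, F = -0.1)), "F must lie")
  expect_error(simConfig(sweeps = data.frame(
    chrom = "chr1", start = 0, end = 10, population = "WL", s = 0.5)),
    "within")
})

test_that("same config and seed reproduce identical truth and outputs", {
  cfg <- simConfig(seed = 42, nSites = 300, nGenes = 10)
  d1 <- simulateDataset(cfg)
  d2 <- simulateDataset(cfg)
  expect_identical(popFrequencies(d1$truth), popFrequencies(d2$truth))
  expect_identical(dosage(d1$geno), dosage(d2$geno))
  t1 <- file.path(tempfile("fixA"), "f")
  t2 <- file.path(tempfile("fixB"), "f")
  p1 <- writeFixture(d1$geno, d1$truth, d1$genes, t1)
  p2 <- writeFixture(d2$geno, d2$truth, d2$genes, t2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
})

test_that("Balding-Nichols frequency variance matches F p (1 - p)", {
  cfg <- simConfig(seed = 5, nSites = 50000, ancestralSfs = "uniform",
                   populations = data.frame(label = "P", n = 2L, F = 0.2))
  tr <- simulateFrequencies(cfg)
  mid <- abs(tr@ancestralFreq - 0.5) < 0.05
  v <- mean((popFrequencies(tr)[mid, "P"] - tr@ancestralFreq[mid])^2)
  expected <- 0.2 * mean(tr@ancestralFreq[mid] * (1 - tr@ancestralFreq[mid]))
  expect_lt(abs(v - expected) / expected, 0.10)
})

test_that("planted sweeps follow p' = p(1-s) + round(p)s with round(0.5) = 1", {
  pf <- matrix(c(0.5, 0.3, 0.8, 0.2), ncol = 2,
               dimnames = list(NULL, c("W", "C")))
  truth <- makeTruth(pf, pos = c(100, 200), chromLength = 1000)
  base <- simConfig(populations = data.frame(label = c("W", "C"),
                                             n = c(2L, 2L), F = c(0.1, 0.1)),
                    chromLengths = c(chr1 = 1000), nSites = 2L)

  noop <- base; noop@sweeps <- data.frame(chrom = "chr1", start = 1,
                                          end = 1000, population = "C",
                                          s = 0)
  expect_identical(popFrequencies(plantSweeps(truth, noop)), pf)

  fix <- base; fix@sweeps <- data.frame(chrom = "chr1", start = 1,
                                        end = 1000, population = "C", s = 1)
  pfF <- popFrequencies(plantSweeps(truth, fix))
  expect_true(all(pfF[, "C"] %in% c(0, 1)))
  expect_identical(pfF[, "W"], pf[, "W"])

  part <- base; part@sweeps <- data.frame(chrom = "chr1", start = 1,
                                          end = 150, population = "W",
                                          s = 0.9)
  pfP <- popFrequencies(plantSweeps(truth, part))
  expect_equal(unname(pfP[1, "W"]), 0.5 * 0.1 + 1 * 0.9)  # tie: 0.95
  expect_equal(unname(pfP[2, "W"]), unname(pf[2, "W"]))   # outside
})

test_that("sweep intervals outside chromosome bounds error", {
  pf <- matrix(0.5, 2, 1, dimnames = list(NULL, "W"))
  truth <- makeTruth(pf, pos = c(10, 20), chromLength = 100)
  cfg <- simConfig(populations = data.frame(label = "W", n = 2L, F = 0.1),
                   chromLengths = c(chr1 = 100), nSites = 2L)
  cfg@sweeps <- data.frame(chrom = "chr1", start = 50, end = 200,
                           population = "W", s = 0.5)
  expect_error(plantSweeps(truth, cfg), "bounds|within")
})

test_that("genotype sampling honours degenerate and HWE frequencies", {
  pf <- cbind(P = c(0, 1, rep(0.5, 100)))
  truth <- makeTruth(pf, pos = seq_len(102) * 5, chromLength = 1000)
  cfg <- simConfig(seed = 8, chromLengths = c(chr1 = 1000), nSites = 102L,
                   populations = data.frame(label = "P", n = 500L, F = 0),
                   missingRate = 0)
  g <- sampleGenotypes(truth, cfg)
  d <- dosage(g)
  expect_true(all(d[1, ] == 0))            # p = 0: no alt allele anywhere
  expect_true(all(d[2, ] == 2))            # p = 1: fixed alt
  expect_identical(unname(siteRecords(g)$callFraction), rep(1, 102))
  hetFrac <- mean(d[-(1:2), ] == 1)        # HWE 2pq at p = 0.5
  expect_lt(abs(hetFrac - 0.5) / 0.5, 0.05)
})

test_that("sample allele frequencies regress on truth with slope ~ 1", {
  cfg <- simConfig(seed = 13, nSites = 20000, ancestralSfs = "uniform")
  d <- simulateDataset(cfg)
  truthP <- popFrequencies(d$truth)
  grp <- sampleGroups(d$geno)
  for (g in levels(grp)) {
    dg <- dosage(d$geno)[, grp == g]
    pObs <- rowSums(dg, na.rm = TRUE) / (2 * rowSums(!is.na(dg)))
    slope <- stats::coef(stats::lm(pObs ~ truthP[, g]))[2]
    expect_lt(abs(slope - 1), 0.05)
  }
})

test_that("planted sweeps depress target-population diversity below the genome median", {
  ok <- 0L
  for (seed in 1:10) {
    cfg <- simConfig(seed = seed, chromLengths = c(chr1 = 5e5),
                     nSites = 5000L, ancestralSfs = "uniform",
                     populations = data.frame(label = c("W", "C"),
                                              n = c(15L, 15L),
                                              F = c(0.1, 0.1)),
                     sweeps = data.frame(chrom = "chr1", start = 2e5,
                                         end = 2.5e5, population = "C",
                                         s = 0.95),
                     nGenes = 0L)
    d <- simulateDataset(cfg)
    ws <- windowStats(d$geno, size = 1e4, step = 1e4, groups = "C")
    inside <- GenomicRanges::start(ws) >= 2e5 & GenomicRanges::end(ws) <= 2.5e5
    if (mean(ws$pi_C[inside]) < stats::median(ws$pi_C)) ok <- ok + 1L
  }
  expect_gte(ok, 10 * 0.95)
})

test_that("empty annotation and population-count bookkeeping hold in fixtures", {
  cfg <- simConfig(seed = 3, nSites = 60, nGenes = 0L,
                   populations = data.frame(label = c("A", "B"),
                                            n = c(10L, 10L),
                                            F = c(0.05, 0.05)))
  d <- simulateDataset(cfg)
  out <- tempfile("fix0")
  p <- writeFixture(d$geno, d$truth, d$genes, out)
  gff <- readLines(p["gff"])
  expect_identical(gff, "##gff-version 3")   # header-only GFF3
  vcfHeaderCols <- strsplit(grep("^#CHROM", readLines(p["vcf"]),
                                 value = TRUE), "\t")[[1]]
  expect_length(vcfHeaderCols, 9 + 20)       # 2 populations x 10 samples
})
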