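# distance matrix of a random unrooted tree via path lengths
additiveMatrix <- function(tree) ape::cophenetic.phylo(tree)

test_that("allele-sharing p-distance matches its definition", {
  d <- cbind(a = c(0L, 1L, 2L, 2L), b = c(2L, 1L, 0L, 2L))
  D <- pDistance(makeGeno(d, c("x", "x")))
  expect_equal(D["a", "b"], 0.5)            # (1 + 0 + 1 + 0) / 4
  expect_equal(diag(D), c(a = 0, b = 0))
  same <- cbind(a = c(0L, 1L, 2L), b = c(0L, 1L, 2L))
  expect_equal(pDistance(makeGeno(same, c("x", "x")))["a", "b"], 0)
  opp <- cbind(a = c(0L, 0L), b = c(2L, 2L))
  expect_equal(pDistance(makeGeno(opp, c("x", "x")))["a", "b"], 1)
  # pairwise deletion: only co-called sites count
  md <- cbind(a = c(0L, NA, 2L), b = c(2L, 1L, NA))
  Dm <- pDistance(makeGeno(md, c("x", "x")))
  expect_equal(Dm["a", "b"], 1)
  expect_equal(attr(Dm, "nShared")["a", "b"], 1L)
  # genotype-mismatch mode
  gm <- pDistance(makeGeno(d, c("x", "x")), mode = "genotype")
  expect_equal(gm["a", "b"], 0.5)           # 2 of 4 genotypes differ
})

test_that("a pair with no co-called sites errors with the pair named", {
  d <- cbind(a = c(0L, NA), b = c(NA, 1L))
  expect_error(pDistance(makeGeno(d, c("x", "x"))), "a and b")
})

test_that("p-distance is symmetric with entries in [0, 1]", {
  set.seed(71)
  d <- matrix(sample(c(0L, 1L, 2L, NA), 200 * 8, TRUE), nrow = 200)
  D <- pDistance(makeGeno(d, rep("x", 8)))
  expect_equal(unname(D), unname(t(D)))
  expect_true(all(D >= 0 & D <= 1))
})

test_that("three-taxon NJ matches the closed-form branch lengths", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- njTree(D)
  bl <- setNames(tr$edge.length,
                 tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[c("A", "B", "C")], c(A = 1, B = 2, C = 3))
})

test_that("the four-point additive case recovers the generating tree", {
  # tree ((A:1,B:2):1,(C:2,D:3)) gives AB=3 AC=4 AD=5 BC=5 BD=6 CD=5
  D <- matrix(c(0, 3, 4, 5, 3, 0, 5, 6, 4, 5, 0, 5, 5, 6, 5, 0), 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- njTree(D)
  expect_equal(additiveMatrix(tr)[LETTERS[1:4], LETTERS[1:4]], D)
  gen <- ape::read.tree(text = "((A:1,B:2):1,C:2,D:3);")
  expect_equal(as.numeric(ape::dist.topo(tr, gen)), 0)
})

test_that("input taxon order does not change the unrooted NJ tree", {
  set.seed(73)
  tr0 <- ape::rtree(7, rooted = FALSE)
  tr0$edge.length <- runif(11, 0.2, 2)
  D <- additiveMatrix(tr0)
  t1 <- njTree(D)
  perm <- sample(7)
  t2 <- njTree(D[perm, perm])
  expect_equal(as.numeric(ape::dist.topo(t1, t2)), 0)
  expect_equal(additiveMatrix(t2)[rownames(D), rownames(D)],
               additiveMatrix(t1)[rownames(D), rownames(D)],
               tolerance = 1e-12)
})

test_that("NJ recovers random additive trees exactly (Atteson)", {
  set.seed(79)
  for (trial in 1:25) {
    n <- sample(4:8, 1)
    tr0 <- ape::unroot(ape::rtree(n, rooted = FALSE))
    tr0$edge.length <- runif(length(tr0$edge.length), 0.1, 2)
    D <- additiveMatrix(tr0)
    tr <- njTree(D)
    expect_equal(as.numeric(ape::dist.topo(tr, tr0)), 0)
    expect_lt(max(abs(additiveMatrix(tr)[rownames(D), rownames(D)] - D)),
              1e-9)
  }
})

test_that("NJ agrees with an independent implementation off additivity", {
  set.seed(83)
  for (trial in 1:10) {
    n <- sample(5:12, 1)
    X <- matrix(runif(n * 20), n)
    D <- as.matrix(stats::dist(X)) / 10
    rownames(D) <- colnames(D) <- paste0("t", seq_len(n))
    mine <- njTree(D)
    ref <- ape::nj(D)
    ref$edge.length[ref$edge.length < 0] <- 0
    expect_equal(as.numeric(ape::dist.topo(mine, ref)), 0)
  }
})

test_that("NJ input validation rejects malformed matrices", {
  bad <- matrix(c(0, 1, 2, 0), 2)
  expect_error(njTree(bad), ">= 3")
  asym <- matrix(c(0, 1, 5, 2, 0, 1, 5, 3, 0), 3)
  expect_error(njTree(asym), "symmetric")
  neg <- matrix(c(0, -1, 1, -1, 0, 1, 1, 1, 0), 3)
  expect_error(njTree(neg), "non-negative")
})

test_that("PCA has spectral properties and a deterministic sign", {
  set.seed(89)
  d <- matrix(sample(c(0L, 1L, 2L), 300 * 12, TRUE), nrow = 300)
  d <- cbind(d, d[, 1])                      # duplicated sample
  p <- genotypePca(makeGeno(d, rep("x", 13)), k = 5)
  expect_equal(p$coordinates[1, ], p$coordinates[13, ])
  expect_true(all(diff(p$explained) <= 1e-12))
  expect_lte(sum(p$explained), 1 + 1e-9)
  # reordering samples permutes coordinates identically (fixed signs)
  perm <- sample(13)
  p2 <- genotypePca(makeGeno(d[, perm], rep("x", 13)), k = 5)
  expect_equal(unname(p2$coordinates), unname(p$coordinates[perm, ]),
               tolerance = 1e-6)
  expect_warning(genotypePca(makeGeno(d[, 1:3], rep("x", 3)), k = 10),
                 "rank")
})

test_that("PC1 separates two drifted populations with no overlap", {
  cfg <- simConfig(seed = 97, nSites = 2000, ancestralSfs = "uniform",
                   populations = data.frame(label = c("A", "B"),
                                            n = c(20L, 20L),
                                            F = c(0.3, 0.3)))
  d <- simulateDataset(cfg)
  p <- genotypePca(d$geno, k = 2)
  pc1 <- split(p$coordinates[, 1], sampleGroups(d$geno))
  expect_true(max(pc1$A) < min(pc1$B) || max(pc1$B) < min(pc1$A))
})
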