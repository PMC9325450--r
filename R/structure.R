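#' @include AllClasses.R
NULL

#' Allele-sharing p-distance matrix between samples
#'
#' For diploid dosages the default allele-sharing distance between two
#' samples is the mean of `|dosage_i - dosage_j| / 2` over sites called
#' in both (pairwise deletion): opposite homozygotes score 1,
#' homozygote vs heterozygote 0.5, identical genotypes 0. With
#' `mode = "genotype"` the distance is instead the fraction of co-called
#' sites with unequal genotypes. A pair with zero co-called sites is
#' undefined and raises an error naming the pair.
#'
#' @param geno A [GenotypeData-class] (>= 2 samples).
#' @param mode `"allele"` (default, allele-sharing) or `"genotype"`
#'   (genotype mismatch fraction).
#' @param checkTriangle If `TRUE`, count and report triangle-inequality
#'   violations (possible under heavy missingness with pairwise
#'   deletion); they are reported, never repaired.
#' @return Symmetric numeric matrix with zero diagonal and entries in
#'   \[0, 1\], sample ids as dimnames; the per-pair co-called site count
#'   is attached as attribute `"nShared"`.
#' @examples
#' gr <- GenomicRanges::GRanges("1", IRanges::IRanges(1:4, width = 1))
#' d <- matrix(c(0L, 1L, 2L, 2L, 2L, 1L, 0L, 2L), ncol = 2,
#'             dimnames = list(NULL, c("a", "b")))
#' pDistance(GenotypeData(d, gr, groups = c("x", "x")))["a", "b"]  # 0.5
#' @export
pDistance <- function(geno, mode = c("allele", "genotype"),
                      checkTriangle = FALSE) {
  mode <- match.arg(mode)
  d <- dosage(geno)
  n <- ncol(d)
  if (n < 2) stop("p-distance needs >= 2 samples")
  ids <- colnames(d)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  nShared <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    di <- d[, i]
    for (j in (i + 1):n) {
      dj <- d[, j]
      both <- !is.na(di) & !is.na(dj)
      m <- sum(both)
      if (m == 0L)
        stop("no co-called sites between samples ", ids[i], " and ",
             ids[j], "; p-distance undefined")
      val <- if (mode == "allele") mean(abs(di[both] - dj[both]) / 2)
      else mean(di[both] != dj[both])
      D[i, j] <- D[j, i] <- val
      nShared[i, j] <- nShared[j, i] <- m
    }
  }
  if (checkTriangle && n >= 3) {
    viol <- 0L
    for (i in seq_len(n)) for (j in seq_len(n)) if (j != i)
      viol <- viol + sum(D[i, j] > D[i, ] + D[, j] + 1e-12)
    if (viol > 0)
      message("pDistance: ", viol,
              " triangle-inequality violation(s) (reported, not repaired)")
  }
  attr(D, "nShared") <- nShared
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou-Nei agglomeration: repeatedly join the pair (i, j)
#' minimizing Q(i, j) = (m - 2) d(i, j) - r_i - r_j, with the standard
#' branch-length formulas, down to a final unrooted trifurcation. Ties
#' in Q break deterministically to the lowest (i, j) index pair in the
#' current cluster order, so the result is invariant across runs and
#' (up to the unrooted topology) to input taxon order. For an additive
#' distance matrix the generating topology and branch lengths are
#' recovered exactly. Negative branch lengths are clamped to zero after
#' construction (display convention; the agglomeration math is
#' untouched), with a message.
#'
#' @param D Symmetric numeric matrix (or `dist`) with zero diagonal and
#'   taxon labels; >= 3 taxa.
#' @return An unrooted `ape::phylo` tree with the taxa as tips.
#' @examples
#' D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' tr <- njTree(D)
#' tr$edge.length  # 1, 2, 3
#' @export
njTree <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  n <- nrow(D)
  if (n < 3) stop("neighbor-joining needs >= 3 taxa")
  if (!isSymmetric(unname(D), tol = 1e-8))
    stop("distance matrix must be symmetric")
  if (any(D < 0)) stop("distance matrix must be non-negative")
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  newick <- labels  # newick substring per active cluster
  Dm <- unname(D)
  m <- n
  fmt <- function(x) sprintf("%.17g", x)
  while (m > 3) {
    r <- rowSums(Dm)
    Q <- (m - 2) * Dm - outer(r, r, "+")
    diag(Q) <- Inf
    cand <- which(Q == min(Q), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    li <- Dm[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- Dm[i, j] - li
    merged <- sprintf("(%s:%s,%s:%s)", newick[i], fmt(li),
                      newick[j], fmt(lj))
    dNew <- (Dm[i, ] + Dm[j, ] - Dm[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    Dm <- rbind(cbind(Dm[keep, keep, drop = FALSE], dNew[keep]),
                c(dNew[keep], 0))
    newick <- c(newick[keep], merged)
    m <- m - 1L
  }
  l1 <- (Dm[1, 2] + Dm[1, 3] - Dm[2, 3]) / 2
  l2 <- (Dm[1, 2] + Dm[2, 3] - Dm[1, 3]) / 2
  l3 <- (Dm[1, 3] + Dm[2, 3] - Dm[1, 2]) / 2
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", newick[1], fmt(l1),
                 newick[2], fmt(l2), newick[3], fmt(l3))
  tree <- ape::read.tree(text = txt)
  neg <- tree$edge.length < 0
  if (any(neg)) {
    message("njTree: clamped ", sum(neg),
            " negative branch length(s) to 0")
    tree$edge.length[neg] <- 0
  }
  tree
}

#' Genotype principal component analysis
#'
#' Missing dosages are mean-imputed per site, sites are centered by
#' twice the sample allele frequency and scaled by
#' `sqrt(2 p (1 - p))` (Patterson normalization; sites monomorphic
#' across the samples are dropped), and the sample coordinates come from
#' the singular value decomposition of the normalized matrix (the
#' eigendecomposition of the sample covariance). Components are ordered
#' by decreasing eigenvalue with a deterministic sign convention (first
#' nonzero site loading of each component positive).
#'
#' @param geno A [GenotypeData-class] (>= 2 samples).
#' @param k Number of components to return; truncated to the matrix
#'   rank with a warning when larger.
#' @return List of class `"genotypePca"` with `coordinates` (samples x
#'   k, rownames = sample ids), `explained` (per-component fraction of
#'   total variance, non-increasing), `loadings` (retained sites x k)
#'   and `groups`.
#' @examples
#' d <- simulateDataset(simConfig(seed = 4, nSites = 500,
#'   populations = data.frame(label = c("A", "B"), n = c(10L, 10L),
#'                            F = c(0.3, 0.3))))
#' p <- genotypePca(d$geno, k = 2)
#' head(p$coordinates)
#' @export
genotypePca <- function(geno, k = 10) {
  X <- t(dosage(geno))  # samples x sites
  if (nrow(X) < 2) stop("PCA needs >= 2 samples")
  pHat <- colMeans(X, na.rm = TRUE) / 2
  keep <- !is.na(pHat) & pHat > 0 & pHat < 1
  X <- X[, keep, drop = FALSE]
  pHat <- pHat[keep]
  mu <- rep(2 * pHat, each = nrow(X))
  X[is.na(X)] <- mu[is.na(X)]
  Z <- sweep(sweep(X, 2, 2 * pHat), 2, sqrt(2 * pHat * (1 - pHat)), "/")
  s <- svd(Z)
  tol <- max(dim(Z)) * max(s$d) * .Machine$double.eps
  r <- sum(s$d > tol)
  if (k > r) {
    warning("requested ", k, " components but rank is ", r,
            "; truncating")
    k <- r
  }
  U <- s$u[, seq_len(k), drop = FALSE]
  V <- s$v[, seq_len(k), drop = FALSE]
  dv <- s$d[seq_len(k)]
  for (c in seq_len(k)) {
    nz <- which(abs(V[, c]) > tol)
    if (length(nz) && V[nz[1], c] < 0) {
      V[, c] <- -V[, c]
      U[, c] <- -U[, c]
    }
  }
  coords <- U %*% diag(dv, nrow = k)
  dimnames(coords) <- list(colnames(dosage(geno)),
                           paste0("PC", seq_len(k)))
  colnames(V) <- paste0("PC", seq_len(k))
  structure(list(coordinates = coords,
                 explained = s$d[seq_len(k)]^2 / sum(s$d^2),
                 loadings = V,
                 groups = sampleGroups(geno)),
            class = "genotypePca")
}

#' @export
print.genotypePca <- function(x, ...) {
  cat("genotypePca:", nrow(x$coordinates), "samples,",
      ncol(x$coordinates), "components\n")
  cat("  explained variance:",
      paste(sprintf("%.1f%%", 100 * x$explained), collapse = ", "), "\n")
  invisible(x)
}
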