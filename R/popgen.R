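#' @include AllClasses.R
NULL

#' Per-site nucleotide diversity from allele counts
#'
#' The unbiased mean pairwise difference among called allele copies at a
#' biallelic site: pi = 2 * refCount * altCount / (n * (n - 1)) with
#' n = refCount + altCount. Sites with n < 2 are not estimable and
#' return `NA` (they contribute no site, not zero diversity).
#'
#' @param refCount,altCount Numeric vectors of called reference / alt
#'   allele copies (recycled).
#' @return Numeric vector of per-site pi values in
#'   \[0, n / (2 (n - 1))\].
#' @examples
#' sitePi(2, 2)  # 2/3: 4 of the 6 allele pairs differ
#' sitePi(1, 3)  # 1/2
#' @export
sitePi <- function(refCount, altCount) {
  n <- refCount + altCount
  ifelse(n >= 2, 2 * refCount * altCount / (n * (n - 1)), NA_real_)
}

#' Hudson's per-site FST components
#'
#' Returns the numerator and denominator of Hudson's estimator from
#' sample allele frequencies and called allele counts:
#' N = (p1 - p2)^2 - p1 (1 - p1) / (n1 - 1) - p2 (1 - p2) / (n2 - 1),
#' D = p1 (1 - p2) + p2 (1 - p1).
#' Window-level FST is the ratio of the sums of these components
#' ("ratio of averages"), which is robust to rare variants. Sites where
#' either group has fewer than 2 called alleles are not estimable and
#' return `NA` components (excluded from a window's sums).
#'
#' @param p1,p2 Alt-allele sample frequencies in the two groups.
#' @param n1,n2 Called allele counts (2 x called diploids).
#' @return List with numeric vectors `N` and `D`.
#' @examples
#' hudsonFstComponents(0.5, 10, 0.5, 10)  # N = -0.0556, D = 0.5
#' hudsonFstComponents(1, 100, 0, 100)    # fixed difference: N ~ D ~ 1
#' @export
hudsonFstComponents <- function(p1, n1, p2, n2) {
  ok <- n1 >= 2 & n2 >= 2
  N <- ifelse(ok,
              (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) -
                p2 * (1 - p2) / (n2 - 1),
              NA_real_)
  D <- ifelse(ok, p1 * (1 - p2) + p2 * (1 - p1), NA_real_)
  list(N = N, D = D)
}

## per-site called allele counts and alt frequency for one subgroup
.groupAlleleCounts <- function(geno, group) {
  grp <- sampleGroups(geno)
  sel <- grp == group
  if (!any(sel)) stop("empty or unknown subgroup: ", group)
  dg <- dosage(geno)[, sel, drop = FALSE]
  n <- 2L * rowSums(!is.na(dg))
  alt <- rowSums(dg, na.rm = TRUE)
  list(n = n, alt = alt, p = ifelse(n > 0, alt / n, NA_real_))
}

#' Tile sliding windows over the genome of a GenotypeData object
#'
#' Windows are 1-based closed intervals `[start, start + size - 1]`
#' placed every `step` bp from position 1, per chromosome; only windows
#' fully inside the chromosome are kept (a chromosome shorter than
#' `size` yields one window covering it). Chromosome lengths come from
#' `seqlengths` when set, otherwise from the last SNP position.
#'
#' @param geno A [GenotypeData-class] (or `GRanges` with seqlengths).
#' @param size,step Window size and step in bp; `0 < step <= size`.
#' @return `GRanges` of windows.
#' @export
tileWindows <- function(geno, size, step = size / 10) {
  stopifnot(size > 0, step > 0, step <= size)
  gr <- if (is(geno, "GenotypeData")) siteRecords(geno) else geno
  lens <- GenomeInfoDb::seqlengths(gr)
  if (any(is.na(lens))) {
    obs <- tapply(GenomicRanges::end(gr),
                  as.character(GenomicRanges::seqnames(gr)), max)
    lens[is.na(lens)] <- obs[names(lens)[is.na(lens)]]
  }
  win <- lapply(names(lens), function(ch) {
    L <- lens[[ch]]
    if (L < size)
      return(GenomicRanges::GRanges(ch, IRanges::IRanges(1, L)))
    starts <- seq(1, L - size + 1, by = step)
    GenomicRanges::GRanges(ch, IRanges::IRanges(starts, width = size))
  })
  out <- do.call(c, win)
  GenomeInfoDb::seqlengths(out) <- lens
  out
}

#' Windowed nucleotide diversity, Hudson FST and SNP counts
#'
#' For each window: `nSites` (SNPs falling in the window), per-subgroup
#' pi per bp (`pi_<group>`; the sum of per-site pi over SNPs in the
#' window divided by the full window length, so monomorphic and
#' non-SNP positions contribute zero to the numerator and full length
#' to the denominator), and per-pair Hudson FST (`fst_<a>_<b>`, ratio
#' of summed numerator and denominator components over sites where both
#' groups have >= 2 called alleles). Windows with no usable site or a
#' zero denominator get `NA` FST (undefined; excluded from downstream
#' percentile ranking, never silently zeroed).
#'
#' @param geno A (filtered) [GenotypeData-class].
#' @param size,step Window geometry in bp (see [tileWindows()]).
#' @param groups Subgroups for which to compute pi; default all groups
#'   appearing in any `pairs` entry, or all subgroups if `pairs` is
#'   empty.
#' @param pairs List of length-2 character vectors naming subgroup pairs
#'   for FST (e.g. `list(c("WL", "SL"))`).
#' @return `GRanges` of windows with the statistic metadata columns;
#'   window geometry recorded in `metadata()`.
#' @examples
#' d <- simulateDataset(simConfig(seed = 5, nSites = 2000))
#' ws <- windowStats(d$geno, size = 1e5, step = 1e4,
#'                   pairs = list(c("WL", "SL")))
#' head(as.data.frame(ws))
#' @export
windowStats <- function(geno, size = 1e5, step = size / 10,
                        groups = NULL, pairs = list()) {
  stopifnot(is(geno, "GenotypeData"))
  if (is.null(groups)) {
    groups <- if (length(pairs)) unique(unlist(pairs))
    else levels(sampleGroups(geno))
  }
  win <- tileWindows(geno, size, step)
  sites <- siteRecords(geno)
  hits <- GenomicRanges::findOverlaps(sites, win)
  si <- S4Vectors::queryHits(hits)
  wi <- S4Vectors::subjectHits(hits)
  sumByWin <- function(v) {
    ## NA site values are excluded from the window sum
    keep <- !is.na(v[si])
    out <- numeric(length(win))
    if (any(keep)) {
      agg <- rowsum(v[si][keep], wi[keep])
      out[as.integer(rownames(agg))] <- agg[, 1]
    }
    out
  }
  mc <- S4Vectors::DataFrame(nSites = tabulate(wi, nbins = length(win)))
  counts <- lapply(stats::setNames(groups, groups),
                   function(g) .groupAlleleCounts(geno, g))
  for (g in groups) {
    pi <- sitePi(counts[[g]]$n - counts[[g]]$alt, counts[[g]]$alt)
    mc[[paste0("pi_", g)]] <- sumByWin(pi) / GenomicRanges::width(win)
  }
  for (pr in pairs) {
    a <- counts[[pr[1]]]; b <- counts[[pr[2]]]
    cmp <- hudsonFstComponents(a$p, a$n, b$p, b$n)
    sn <- sumByWin(cmp$N)
    sd <- sumByWin(cmp$D)
    nUse <- sumByWin(as.numeric(!is.na(cmp$N)))
    fst <- ifelse(nUse > 0 & sd != 0, sn / sd, NA_real_)
    mc[[paste0("fst_", pr[1], "_", pr[2])]] <- fst
  }
  S4Vectors::mcols(win) <- mc
  S4Vectors::metadata(win) <- list(windowSize = size, windowStep = step,
                                   groups = groups, pairs = pairs)
  win
}

#' Per-sample and per-subgroup heterozygosity
#'
#' The heterozygosity ratio of a sample is the fraction of its called
#' genotypes that are heterozygous (dosage 1). Samples with zero called
#' genotypes get `NA` and a warning.
#'
#' @param geno A [GenotypeData-class].
#' @return List with `perSample` (`data.frame(sample, group, nCalled,
#'   het)`) and `perGroup` (named mean over member samples).
#' @export
heterozygosity <- function(geno) {
  d <- dosage(geno)
  grp <- sampleGroups(geno)
  nCalled <- colSums(!is.na(d))
  het <- ifelse(nCalled > 0, colSums(d == 1L, na.rm = TRUE) / nCalled,
                NA_real_)
  if (any(nCalled == 0))
    warning("sample(s) with zero called genotypes: ",
            paste(colnames(d)[nCalled == 0], collapse = ", "))
  perSample <- data.frame(sample = colnames(d), group = as.character(grp),
                          nCalled = nCalled, het = het, row.names = NULL)
  perGroup <- tapply(het, grp, mean, na.rm = TRUE)
  list(perSample = perSample, perGroup = c(perGroup))
}
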