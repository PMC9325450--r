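#' @include AllClasses.R
NULL

#' log2 diversity ratio between a wild and a cultivated group
#'
#' `log2(piWild / piCult)` per window; elevated where domestication
#' purged diversity in the cultivated group. When the cultivated window
#' has lost all diversity (`piCult = 0`, `piWild > 0`) the value is the
#' `+Inf` sentinel, which ranks above every finite value; when both are
#' zero the window is undefined (`NA`) and excluded from ranking.
#'
#' @param piWild,piCult Non-negative window diversities (per bp).
#' @return Numeric vector (may contain `Inf` and `NA`).
#' @examples
#' log2PiRatio(c(0.004, 0.001, 0.002, 0), c(0.001, 0.001, 0, 0))
#' @export
log2PiRatio <- function(piWild, piCult) {
  if (any(stats::na.omit(c(piWild, piCult)) < 0))
    stop("negative window diversity: upstream invariant violated")
  out <- suppressWarnings(log2(piWild / piCult))
  out[piWild == 0 & piCult == 0] <- NA_real_
  out[is.na(piWild) | is.na(piCult)] <- NA_real_
  out
}

#' Empirical percentile ranks with mid-rank ties
#'
#' The percentile of a value v among n rankable values is
#' `100 * (#less + 0.5 * #equal) / n` (mid-rank tie handling: stable and
#' invariant to permutation of the input). `+Inf` sentinel values rank
#' above all finite values and are assigned percentile 100; `NA` values
#' are not rankable and stay `NA` (they do not enter n).
#'
#' @param values Numeric vector of window statistics.
#' @return Numeric vector of percentiles in \[0, 100\], `NA` preserved.
#' @examples
#' empiricalPercentile(1:100)[100]  # 99.5
#' @export
empiricalPercentile <- function(values) {
  out <- rep(NA_real_, length(values))
  rankable <- !is.na(values)
  n <- sum(rankable)
  if (n == 0L) return(out)
  r <- rank(values[rankable], ties.method = "average")
  out[rankable] <- 100 * (r - 0.5) / n
  out[rankable][is.infinite(values[rankable]) & values[rankable] > 0] <- 100
  if (n >= 2 && all(values[rankable] == values[rankable][1]))
    warning("all window statistics identical; every percentile is 50 ",
            "and no window can reach the top-", 5, "% set")
  out
}

#' Call sweep windows jointly in the top tail of FST and log2 pi-ratio
#'
#' Adds the log2 pi-ratio and the empirical percentiles of window FST
#' and ratio to a [windowStats()] result, then selects windows whose
#' percentiles are both at or above `100 * (1 - q)` — the joint "top
#' 5%" rule at the default `q = 0.05`. Only windows where both
#' statistics are defined are rankable; under mid-rank ties the selected
#' fraction cannot exceed roughly `q` of the rankable windows (heavy
#' ties at the threshold may push it slightly above `q * n`; `+Inf`
#' ratio sentinels are always in the selected tail).
#'
#' @param windows `GRanges` from [windowStats()] containing
#'   `pi_<wild>`, `pi_<cult>` and `fst_<wild>_<cult>` columns.
#' @param wild,cult Subgroup labels of the wild and cultivated group.
#' @param q Upper-tail fraction in (0, 0.5\]; default 0.05.
#' @return The input `GRanges` with added columns `log2PiRatio`,
#'   `pctFst`, `pctRatio` and logical `selected`.
#' @seealso [mergeSweepWindows()], [sweepScan()]
#' @export
callSweepWindows <- function(windows, wild, cult, q = 0.05) {
  if (q <= 0 || q > 0.5) stop("q must lie in (0, 0.5]")
  mc <- S4Vectors::mcols(windows)
  fstCol <- paste0("fst_", wild, "_", cult)
  for (col in c(paste0("pi_", wild), paste0("pi_", cult), fstCol))
    if (!col %in% colnames(mc))
      stop("window statistics lack column ", col)
  ratio <- log2PiRatio(mc[[paste0("pi_", wild)]],
                       mc[[paste0("pi_", cult)]])
  fst <- mc[[fstCol]]
  ## a window is rankable only if both statistics are defined
  rankable <- !is.na(ratio) & !is.na(fst)
  if (sum(rankable) < 20)
    warning("fewer than 20 rankable windows; the top-", 100 * q,
            "% set is degenerate")
  pctF <- pctR <- rep(NA_real_, length(windows))
  pctF[rankable] <- empiricalPercentile(fst[rankable])
  pctR[rankable] <- empiricalPercentile(ratio[rankable])
  thr <- 100 * (1 - q)
  mc$log2PiRatio <- ratio
  mc$pctFst <- pctF
  mc$pctRatio <- pctR
  mc$selected <- !is.na(pctF) & !is.na(pctR) & pctF >= thr & pctR >= thr
  S4Vectors::mcols(windows) <- mc
  S4Vectors::metadata(windows)$q <- q
  S4Vectors::metadata(windows)$pair <- c(wild = wild, cult = cult)
  windows
}

#' Merge selected windows into sweep regions
#'
#' Overlapping or book-ended windows (gap <= `gapBp`, default 0 =
#' touching) merge into maximal regions; windows on different
#' chromosomes never merge. Region statistics are the maxima over member
#' windows.
#'
#' @param windows Output of [callSweepWindows()] (only rows with
#'   `selected == TRUE` are used), or any `GRanges` of selected windows.
#' @param gapBp Maximum gap between windows to merge across.
#' @return `GRanges` of sweep regions with metadata columns `nWindows`,
#'   `maxFst`, `maxLog2PiRatio`.
#' @export
mergeSweepWindows <- function(windows, gapBp = 0) {
  mc <- S4Vectors::mcols(windows)
  sel <- if ("selected" %in% colnames(mc))
    windows[!is.na(mc$selected) & mc$selected] else windows
  if (length(sel) == 0L)
    return(GenomicRanges::GRanges(
      nWindows = integer(), maxFst = numeric(),
      maxLog2PiRatio = numeric()))
  regions <- GenomicRanges::reduce(sel, min.gapwidth = gapBp + 1L,
                                   ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(sel, regions)
  ri <- S4Vectors::subjectHits(hits)
  mcs <- S4Vectors::mcols(sel)
  maxBy <- function(v) {
    if (is.null(v)) return(rep(NA_real_, length(regions)))
    out <- rep(-Inf, length(regions))
    agg <- tapply(v[S4Vectors::queryHits(hits)], ri, max, na.rm = TRUE)
    out[as.integer(names(agg))] <- agg
    out
  }
  fstCol <- grep("^fst_", colnames(mcs), value = TRUE)
  S4Vectors::mcols(regions) <- S4Vectors::DataFrame(
    nWindows = as.integer(tabulate(ri, nbins = length(regions))),
    maxFst = maxBy(if (length(fstCol)) mcs[[fstCol[1]]] else NULL),
    maxLog2PiRatio = maxBy(mcs$log2PiRatio))
  regions
}

#' Genes overlapping sweep regions
#'
#' A gene is counted for a region iff its 1-based closed span overlaps
#' the region by at least 1 bp (adjacency is not overlap). The distinct
#' total deduplicates genes spanning several regions.
#'
#' @param regions `GRanges` of sweep regions.
#' @param genes Gene-model list (element `genes` with `gene_id`).
#' @return The regions with an added `CharacterList` column `gene_ids`,
#'   plus attributes; the vector of distinct overlapped gene ids is in
#'   `metadata(regions)$sweepGenes`.
#' @export
genesInSweeps <- function(regions, genes) {
  g <- genes$genes
  hits <- GenomicRanges::findOverlaps(regions, g, ignore.strand = TRUE)
  idList <- IRanges::CharacterList(
    split(g$gene_id[S4Vectors::subjectHits(hits)],
          factor(S4Vectors::queryHits(hits), levels = seq_along(regions))))
  names(idList) <- NULL
  S4Vectors::mcols(regions)$gene_ids <- idList
  S4Vectors::metadata(regions)$sweepGenes <-
    unique(g$gene_id[S4Vectors::subjectHits(hits)])
  regions
}

#' Overlap between two sweep-region sets
#'
#' Reports region pairs overlapping by >= 1 bp between two scans (e.g.
#' the wild-vs-seed and wild-vs-rhizome comparisons) and the genes
#' shared by the two scans' gene sets.
#'
#' @param regionsA,regionsB `GRanges` from [genesInSweeps()] (or plain
#'   region `GRanges`; gene sharing then requires `genes`).
#' @param genes Optional gene-model list to (re)compute each side's gene
#'   set.
#' @return List with `pairs` (`data.frame` of overlapping region index
#'   pairs and their span coordinates), `nOverlaps`, and `sharedGenes`.
#' @export
sweepOverlap <- function(regionsA, regionsB, genes = NULL) {
  if (!is.null(genes)) {
    regionsA <- genesInSweeps(regionsA, genes)
    regionsB <- genesInSweeps(regionsB, genes)
  }
  hits <- GenomicRanges::findOverlaps(regionsA, regionsB,
                                      ignore.strand = TRUE)
  qa <- S4Vectors::queryHits(hits)
  qb <- S4Vectors::subjectHits(hits)
  pairs <- data.frame(
    regionA = qa, regionB = qb,
    chrom = as.character(GenomicRanges::seqnames(regionsA))[qa],
    startA = GenomicRanges::start(regionsA)[qa],
    endA = GenomicRanges::end(regionsA)[qa],
    startB = GenomicRanges::start(regionsB)[qb],
    endB = GenomicRanges::end(regionsB)[qb])
  genesA <- S4Vectors::metadata(regionsA)$sweepGenes
  genesB <- S4Vectors::metadata(regionsB)$sweepGenes
  shared <- if (!is.null(genesA) && !is.null(genesB))
    intersect(genesA, genesB) else character()
  list(pairs = pairs, nOverlaps = nrow(pairs), sharedGenes = shared)
}

#' One-call sweep scan for a wild/cultivated pair
#'
#' Runs [callSweepWindows()], [mergeSweepWindows()] and (when a gene
#' annotation is given) [genesInSweeps()].
#'
#' @inheritParams callSweepWindows
#' @inheritParams mergeSweepWindows
#' @param genes Optional gene-model list.
#' @return List with `windows` (annotated window `GRanges`) and
#'   `regions` (merged sweep regions, genes attached when available).
#' @examples
#' d <- simulateDataset(standardFixtureConfig(seed = 1))
#' ws <- windowStats(d$geno[filterSites(d$geno)$pass, ],
#'                   size = 2000, step = 200, pairs = list(c("WL", "SL")))
#' scan <- sweepScan(ws, "WL", "SL", genes = d$genes)
#' length(scan$regions)
#' @export
sweepScan <- function(windows, wild, cult, q = 0.05, gapBp = 0,
                      genes = NULL) {
  win <- callSweepWindows(windows, wild, cult, q = q)
  regions <- mergeSweepWindows(win, gapBp = gapBp)
  if (!is.null(genes)) regions <- genesInSweeps(regions, genes)
  list(windows = win, regions = regions)
}
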