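#' @include AllGenerics.R
#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom GenomicRanges GRanges
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowRanges colData
NULL

MISSING_DOSAGE_DOMAIN <- c(0L, 1L, 2L)

#' GenotypeData: diploid SNP dosage matrix with site and sample annotation
#'
#' Container for a biallelic SNP genotype matrix, the substrate of all
#' statistics in the package. Extends
#' [SummarizedExperiment::RangedSummarizedExperiment]: the single assay
#' `"dosage"` holds alt-allele counts per (site, sample) in \{0, 1, 2\}
#' with `NA` for uncalled genotypes; `rowRanges` carries one width-1 range
#' per site with metadata columns `ref`, `alt` (single-nucleotide
#' alleles), `depth` (mean site coverage), `rmsMQ` (root-mean-square
#' mapping quality), `callFraction` (fraction of non-missing genotypes)
#' and `maf` (minor-allele frequency over called alleles); `colData`
#' carries the population map as the factor column `group`.
#'
#' Sites are strictly sorted by (chromosome, position).
#'
#' @seealso [GenotypeData()] for construction, [readGenotypeVcf()] to
#'   build one from a VCF, [simulateDataset()] to simulate one.
#' @aliases GenotypeData-class
#' @exportClass GenotypeData
setClass("GenotypeData", contains = "RangedSummarizedExperiment")

setValidity("GenotypeData", function(object) {
  msg <- character()
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- SummarizedExperiment::assay(object, "dosage")
    bad <- !(d %in% MISSING_DOSAGE_DOMAIN | is.na(d))
    if (any(bad))
      msg <- c(msg, "dosage values must be in {0, 1, 2} or NA")
  }
  if (!"group" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain a 'group' column")
  rr <- SummarizedExperiment::rowRanges(object)
  need <- c("ref", "alt", "depth", "rmsMQ", "callFraction", "maf")
  miss <- setdiff(need, colnames(S4Vectors::mcols(rr)))
  if (length(miss))
    msg <- c(msg, paste0("rowRanges lacks metadata column(s): ",
                         paste(miss, collapse = ", ")))
  if (length(rr) > 1L && S4Vectors::isSorted(rr) == FALSE)
    msg <- c(msg, "sites must be sorted by (chrom, pos)")
  cf <- S4Vectors::mcols(rr)$callFraction
  if (!is.null(cf) && any(!is.na(cf) & (cf < 0 | cf > 1)))
    msg <- c(msg, "callFraction must lie in [0, 1]")
  mafv <- S4Vectors::mcols(rr)$maf
  if (!is.null(mafv) && any(!is.na(mafv) & (mafv < 0 | mafv > 0.5 + 1e-12)))
    msg <- c(msg, "maf must lie in [0, 0.5]")
  if (length(msg)) msg else TRUE
})

#' SimConfig: configuration of the multi-population genotype simulator
#'
#' Describes a synthetic diploid genotype dataset: one or more
#' chromosomes, a set of populations diverged from a common ancestral
#' allele-frequency pool under the Balding-Nichols model with
#' per-population drift parameter `F`, site-level QC covariates (depth,
#' RMS mapping quality), independent per-genotype missingness, and
#' optional planted selective sweeps driving a target population toward
#' fixation inside stated intervals.
#'
#' @slot seed Integer RNG seed; a fixed seed makes all outputs
#'   byte-identical across runs.
#' @slot chromLengths Named numeric, chromosome lengths in bp.
#' @slot nSites Integer, total SNP count across chromosomes.
#' @slot populations `data.frame` with columns `label`, `n` (diploid
#'   sample count) and `F` (drift parameter in \[0, 1)).
#' @slot ancestralSfs `"uniform"` (p ~ U(0.05, 0.95)) or `"neutral"`
#'   (density proportional to 1/p truncated to \[0.01, 0.99\]).
#' @slot missingRate Per-genotype missingness probability in \[0, 1).
#' @slot depthMean,depthDispersion Negative-binomial mean and size for
#'   per-site mean coverage.
#' @slot mqMean,mqSd Normal mean/sd for per-site RMS mapping quality.
#' @slot sweeps `data.frame` with columns `chrom`, `start`, `end`,
#'   `population`, `s` (sweep intensity in \[0, 1\]).
#' @slot nGenes Integer, number of non-overlapping toy genes to draw for
#'   the annotation fixture.
#' @seealso [simConfig()], [standardFixtureConfig()]
#' @aliases SimConfig-class
#' @exportClass SimConfig
setClass("SimConfig", slots = c(
  seed = "integer",
  chromLengths = "numeric",
  nSites = "integer",
  populations = "data.frame",
  ancestralSfs = "character",
  missingRate = "numeric",
  depthMean = "numeric",
  depthDispersion = "numeric",
  mqMean = "numeric",
  mqSd = "numeric",
  sweeps = "data.frame",
  nGenes = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  p <- object@populations
  if (!all(c("label", "n", "F") %in% names(p)))
    msg <- c(msg, "populations needs columns label, n, F")
  else {
    if (anyDuplicated(p$label)) msg <- c(msg, "population labels must be unique")
    if (any(p$F < 0 | p$F >= 1))
      msg <- c(msg, "all drift parameters F must lie in [0, 1)")
    if (any(p$n < 1)) msg <- c(msg, "each population needs >= 1 sample")
  }
  if (is.null(names(object@chromLengths)) || any(object@chromLengths < 1))
    msg <- c(msg, "chromLengths must be named and positive")
  if (object@nSites < 1L) msg <- c(msg, "nSites must be positive")
  if (!object@ancestralSfs %in% c("uniform", "neutral"))
    msg <- c(msg, "ancestralSfs must be 'uniform' or 'neutral'")
  if (object@missingRate < 0 || object@missingRate >= 1)
    msg <- c(msg, "missingRate must lie in [0, 1)")
  sw <- object@sweeps
  if (nrow(sw)) {
    if (!all(c("chrom", "start", "end", "population", "s") %in% names(sw)))
      msg <- c(msg, "sweeps needs columns chrom, start, end, population, s")
    else {
      if (!all(sw$population %in% p$label))
        msg <- c(msg, "sweep target populations must exist")
      if (!all(sw$chrom %in% names(object@chromLengths)))
        msg <- c(msg, "sweep chromosomes must exist")
      else {
        len <- object@chromLengths[as.character(sw$chrom)]
        if (any(sw$start < 1 | sw$end > len | sw$start > sw$end))
          msg <- c(msg, "sweep intervals must lie within [1, chrom length]")
      }
      if (any(sw$s < 0 | sw$s > 1))
        msg <- c(msg, "sweep intensity s must lie in [0, 1]")
    }
  }
  if (length(msg)) msg else TRUE
})

#' SimTruth: ground truth of a simulated dataset
#'
#' Holds everything the simulator knows that an analysis must recover:
#' per-site ancestral allele frequencies, per-population post-drift (and
#' post-sweep) frequencies, the planted sweep intervals, and the
#' per-population drift parameters.
#'
#' @slot sites `GRanges`, one width-1 range per site, sorted.
#' @slot ancestralFreq Numeric, ancestral alt-allele frequency per site.
#' @slot popFreq Numeric matrix (sites x populations), column names are
#'   population labels.
#' @slot F Named numeric, drift parameter per population.
#' @slot sweeps `GRanges` of planted sweep intervals with metadata
#'   columns `population` and `s`.
#' @seealso [simulateFrequencies()], [plantSweeps()]
#' @aliases SimTruth-class
#' @exportClass SimTruth
setClass("SimTruth", slots = c(
  sites = "GRanges",
  ancestralFreq = "numeric",
  popFreq = "matrix",
  F = "numeric",
  sweeps = "GRanges"
))

setValidity("SimTruth", function(object) {
  msg <- character()
  if (length(object@sites) != length(object@ancestralFreq) ||
      length(object@sites) != nrow(object@popFreq))
    msg <- c(msg, "sites, ancestralFreq and popFreq rows must agree")
  if (any(object@ancestralFreq < 0 | object@ancestralFreq > 1) ||
      any(object@popFreq < 0 | object@popFreq > 1))
    msg <- c(msg, "frequencies must lie in [0, 1]")
  if (is.null(colnames(object@popFreq)))
    msg <- c(msg, "popFreq must have population labels as column names")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GenotypeData", function(object) {
  d <- SummarizedExperiment::assay(object, "dosage")
  grp <- table(SummarizedExperiment::colData(object)$group)
  cat("GenotypeData:", nrow(object), "SNP sites x", ncol(object), "samples\n")
  cat("  chromosomes:",
      paste(GenomeInfoDb::seqlevels(SummarizedExperiment::rowRanges(object)),
            collapse = ", "), "\n")
  cat("  subgroups:",
      paste(sprintf("%s (%d)", names(grp), as.integer(grp)), collapse = ", "),
      "\n")
  cat(sprintf("  missing genotypes: %.2f%%\n", 100 * mean(is.na(d))))
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nSites, "sites on",
      length(object@chromLengths), "chromosome(s); seed", object@seed, "\n")
  cat("  populations:",
      paste(sprintf("%s (n=%d, F=%g)", object@populations$label,
                    object@populations$n, object@populations$F),
            collapse = ", "), "\n")
  cat("  planted sweeps:", nrow(object@sweeps), "\n")
})

setMethod("show", "SimTruth", function(object) {
  cat("SimTruth:", length(object@sites), "sites,",
      ncol(object@popFreq), "populations,",
      length(object@sweeps), "planted sweep(s)\n")
})

#' @rdname dosage
#' @export
setMethod("dosage", "GenotypeData", function(x)
  SummarizedExperiment::assay(x, "dosage"))

#' @rdname sampleGroups
#' @export
setMethod("sampleGroups", "GenotypeData", function(x) {
  g <- SummarizedExperiment::colData(x)$group
  stats::setNames(as.factor(g), colnames(x))
})

#' @rdname siteRecords
#' @export
setMethod("siteRecords", "GenotypeData", function(x)
  SummarizedExperiment::rowRanges(x))

#' @rdname popFrequencies
#' @export
setMethod("popFrequencies", "SimTruth", function(x) x@popFreq)

#' @rdname plantedSweeps
#' @export
setMethod("plantedSweeps", "SimTruth", function(x) x@sweeps)

#' Construct a GenotypeData object
#'
#' @param dosage Integer matrix (sites x samples) of alt-allele dosages
#'   in \{0, 1, 2\}, `NA` for missing.
#' @param sites `GRanges` of width-1 site positions (same length as
#'   `nrow(dosage)`); metadata columns `ref`, `alt`, `depth`, `rmsMQ` are
#'   kept if present, `callFraction` and `maf` are (re)computed from the
#'   genotypes unless supplied.
#' @param groups Character or factor of subgroup labels, one per sample.
#' @param sampleIds Sample identifiers; defaults to `colnames(dosage)`.
#' @return A validated [GenotypeData-class] object with sites sorted by
#'   (chrom, pos).
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(10, 20), width = 1))
#' d <- matrix(c(0L, 1L, 2L, NA), nrow = 2,
#'             dimnames = list(NULL, c("s1", "s2")))
#' gd <- GenotypeData(d, gr, groups = c("A", "B"))
#' dosage(gd)
#' @export
GenotypeData <- function(dosage, sites, groups,
                         sampleIds = colnames(dosage)) {
  stopifnot(is.matrix(dosage), length(sites) == nrow(dosage),
            length(groups) == ncol(dosage))
  if (is.null(sampleIds))
    sampleIds <- paste0("sample", seq_len(ncol(dosage)))
  storage.mode(dosage) <- "integer"
  colnames(dosage) <- sampleIds
  mc <- S4Vectors::mcols(sites)
  for (col in c("ref", "alt"))
    if (!col %in% colnames(mc)) mc[[col]] <- NA_character_
  for (col in c("depth", "rmsMQ"))
    if (!col %in% colnames(mc)) mc[[col]] <- NA_real_
  called <- !is.na(dosage)
  if (!"callFraction" %in% colnames(mc))
    mc$callFraction <- rowMeans(called)
  if (!"maf" %in% colnames(mc)) {
    nAllele <- 2 * rowSums(called)
    pAlt <- ifelse(nAllele > 0, rowSums(dosage, na.rm = TRUE) / nAllele, NA_real_)
    mc$maf <- pmin(pAlt, 1 - pAlt)
  }
  S4Vectors::mcols(sites) <- mc
  o <- GenomicRanges::order(sites)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = dosage[o, , drop = FALSE]),
    rowRanges = sites[o],
    colData = S4Vectors::DataFrame(group = as.factor(groups),
                                   row.names = sampleIds))
  methods::new("GenotypeData", se)
}
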