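#' @include AllClasses.R
NULL

#' Site-level SNP quality filter
#'
#' Applies the standard resequencing call-set filter: a site passes iff
#' depth >= `minDepth` AND RMS mapping quality >= `minMQ` AND minor
#' allele frequency >= `minMaf` AND missingness (1 - call fraction)
#' <= `maxMiss`. All comparisons are inclusive, so boundary sites
#' (depth 4, MQ 20, MAF 0.05, miss 0.10 at the defaults) are retained.
#' A site may fail several criteria; the summary counts each criterion
#' independently.
#'
#' A covariate column that is entirely `NA` (e.g. a VCF without INFO/DP)
#' skips its criterion with a warning; isolated `NA` values fail it.
#'
#' @param x A [GenotypeData-class] object (or a `GRanges` of site
#'   records with the QC metadata columns).
#' @param minDepth,minMQ,minMaf,maxMiss Inclusive thresholds; defaults
#'   depth >= 4, MQ >= 20, MAF >= 0.05, missingness <= 0.1.
#' @return List of class `"siteFilter"` with elements `pass` (logical
#'   per site), `summary` (`data.frame` of per-criterion failure counts),
#'   `nTotal`, `nPass` and the thresholds used. Subset the object with
#'   `geno[filter$pass, ]`.
#' @examples
#' d <- simulateDataset(simConfig(seed = 2, nSites = 300))
#' f <- filterSites(d$geno)
#' f$summary
#' filtered <- d$geno[f$pass, ]
#' @export
filterSites <- function(x, minDepth = 4, minMQ = 20,
                        minMaf = 0.05, maxMiss = 0.1) {
  if (is(x, "GenotypeData")) x <- siteRecords(x)
  if (minDepth < 0 || minMQ < 0 || minMaf < 0 || minMaf > 0.5 ||
      maxMiss < 0 || maxMiss > 1)
    stop("filter thresholds outside valid ranges")
  mc <- S4Vectors::mcols(x)
  crit <- list(
    depth = list(v = mc$depth, ok = function(v) v >= minDepth),
    mq = list(v = mc$rmsMQ, ok = function(v) v >= minMQ),
    maf = list(v = mc$maf, ok = function(v) v >= minMaf),
    miss = list(v = mc$callFraction,
                ok = function(v) (1 - v) <= maxMiss + 1e-12))
  n <- length(x)
  evalCrit <- function(nm) {
    v <- crit[[nm]]$v
    if (is.null(v) || all(is.na(v))) {
      warning("covariate for criterion '", nm,
              "' unavailable; criterion skipped")
      rep(TRUE, n)
    } else {
      ok <- crit[[nm]]$ok(v)
      ok[is.na(ok)] <- FALSE
      ok
    }
  }
  passMat <- matrix(unlist(lapply(names(crit), evalCrit)), nrow = n,
                    dimnames = list(NULL, names(crit)))
  pass <- rowSums(passMat) == ncol(passMat)
  structure(list(
    pass = pass,
    summary = data.frame(criterion = colnames(passMat),
                         failed = colSums(!passMat), row.names = NULL),
    nTotal = n, nPass = sum(pass),
    thresholds = c(minDepth = minDepth, minMQ = minMQ,
                   minMaf = minMaf, maxMiss = maxMiss)),
    class = "siteFilter")
}

#' @export
print.siteFilter <- function(x, ...) {
  cat(sprintf("siteFilter: %d of %d sites pass (%.2f%%)\n",
              x$nPass, x$nTotal, 100 * x$nPass / max(1, x$nTotal)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Classify SNPs by genomic region
#'
#' Assigns each site one of `exonic`, `intronic`, `upstream`,
#' `downstream` or `intergenic`, with precedence
#' exonic > intronic > upstream/downstream > intergenic. A site inside a
#' gene span but in no exon is intronic. Upstream/downstream means
#' within `flankBp` of the gene span, strand-aware; with the default
#' `flankBp = 0` those categories are empty. Sites on chromosomes absent
#' from the annotation are intergenic (warned once).
#'
#' @param x A [GenotypeData-class] or a `GRanges` of sites.
#' @param genes Gene-model list from [readGeneModels()] or
#'   [simulateGeneModels()] (elements `genes` and `exons`).
#' @param flankBp Flank width in bp for upstream/downstream (default 0).
#' @return Factor per site with the five levels above; the proportion
#'   table is attached as attribute `"proportions"`.
#' @export
classifySnpRegions <- function(x, genes, flankBp = 0) {
  sites <- if (is(x, "GenotypeData")) siteRecords(x) else x
  g <- genes$genes
  e <- genes$exons
  lvl <- c("exonic", "intronic", "upstream", "downstream", "intergenic")
  out <- factor(rep("intergenic", length(sites)), levels = lvl)
  chromMissing <- setdiff(as.character(GenomeInfoDb::seqnames(sites)),
                          as.character(GenomeInfoDb::seqnames(g)))
  if (length(chromMissing) && length(g))
    warning("chromosome(s) absent from annotation, classified intergenic: ",
            paste(unique(chromMissing), collapse = ", "))
  if (length(g) == 0L) {
    attr(out, "proportions") <- prop.table(table(out))
    return(out)
  }
  if (flankBp > 0) {
    up <- suppressWarnings(GenomicRanges::flank(g, flankBp, start = TRUE))
    down <- suppressWarnings(GenomicRanges::flank(g, flankBp, start = FALSE))
    out[IRanges::overlapsAny(sites, down, ignore.strand = TRUE)] <- "downstream"
    out[IRanges::overlapsAny(sites, up, ignore.strand = TRUE)] <- "upstream"
  }
  out[IRanges::overlapsAny(sites, g, ignore.strand = TRUE)] <- "intronic"
  out[IRanges::overlapsAny(sites, e, ignore.strand = TRUE)] <- "exonic"
  attr(out, "proportions") <- prop.table(table(out))
  out
}

#' Subgroup SNP sharing (common and unique counts)
#'
#' A SNP is "present" in a subgroup iff at least one called genotype in
#' that subgroup carries at least one alt allele. Reports per-subgroup
#' presence totals, the number of SNPs present in every subgroup
#' (common), and per-subgroup exclusive (unique) counts. With
#' `mode = "polymorphic"`, presence instead requires the site to be
#' polymorphic within the subgroup (both alleles observed).
#'
#' @param geno A [GenotypeData-class]; subgroups from `sampleGroups()`.
#' @param mode `"presence"` (default) or `"polymorphic"`.
#' @return List with `perGroup` (named totals), `common`, `unique`
#'   (named exclusive counts), `nSites`, and the logical presence
#'   matrix in `presence`.
#' @export
snpSharing <- function(geno, mode = c("presence", "polymorphic")) {
  mode <- match.arg(mode)
  grp <- sampleGroups(geno)
  d <- dosage(geno)
  labs <- levels(grp)
  if (any(table(grp)[labs] == 0) || length(labs) == 0)
    stop("empty subgroup in population map")
  pres <- vapply(labs, function(g) {
    dg <- d[, grp == g, drop = FALSE]
    if (ncol(dg) == 0L) stop("empty subgroup: ", g)
    hasAlt <- rowSums(dg > 0, na.rm = TRUE) > 0
    if (mode == "presence") hasAlt
    else hasAlt & rowSums(dg < 2, na.rm = TRUE) > 0
  }, logical(nrow(d)))
  nPresent <- rowSums(pres)
  uniq <- colSums(pres & nPresent == 1L)
  list(perGroup = colSums(pres),
       common = sum(nPresent == length(labs)),
       unique = uniq,
       nSites = nrow(d),
       presence = pres)
}
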