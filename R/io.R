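#' @include AllClasses.R
NULL

#' Read a population map (sample-to-subgroup TSV)
#'
#' Expects a two-column tab-separated file with a header line; the first
#' column is the sample id, the second the subgroup label.
#'
#' @param path Path to the TSV.
#' @return `data.frame` with columns `sample` and `group`.
#' @export
readPopulationMap <- function(path) {
  pm <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(pm) < 2L)
    stop("population map must have two columns: sample<TAB>group")
  names(pm)[1:2] <- c("sample", "group")
  if (anyDuplicated(pm$sample))
    stop("duplicated sample ids in population map: ",
         paste(unique(pm$sample[duplicated(pm$sample)]), collapse = ", "))
  pm[, 1:2]
}

#' Read a multi-sample VCF into a GenotypeData object
#'
#' Loads biallelic SNP records only; multiallelic and indel records are
#' skipped with a logged count. Dosage is the alt-allele count of the
#' diploid GT field (`./.` becomes missing). Site depth and RMS mapping
#' quality are taken from INFO `DP` and `MQ` when present (`NA`
#' otherwise); call fraction and minor-allele frequency are always
#' computed from the genotypes.
#'
#' @param vcfPath Path to a VCF (v4.x, plain or bgzipped).
#' @param popmap Either a path to a population-map TSV or a `data.frame`
#'   as returned by [readPopulationMap()]. Every VCF sample must be
#'   mapped; offenders are listed in the error.
#' @return A [GenotypeData-class] object.
#' @examples
#' d <- simulateDataset(simConfig(seed = 3, nSites = 50, nGenes = 2))
#' out <- file.path(tempdir(), "fixture-example")
#' paths <- writeFixture(d$geno, d$truth, d$genes, out)
#' g <- readGenotypeVcf(paths["vcf"], paths["popmap"])
#' identical(dosage(g), dosage(d$geno))
#' @export
readGenotypeVcf <- function(vcfPath, popmap) {
  if (!file.exists(vcfPath)) stop("VCF not found: ", vcfPath)
  if (is.character(popmap)) popmap <- readPopulationMap(popmap)
  vcf <- VariantAnnotation::readVcf(vcfPath)
  keep <- VariantAnnotation::isSNV(vcf, singleAltOnly = TRUE)
  nSkip <- sum(!keep)
  if (nSkip > 0)
    message("readGenotypeVcf: skipped ", nSkip,
            " non-biallelic-SNP record(s)")
  vcf <- vcf[keep, ]
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT genotype field")
  missing <- setdiff(colnames(gt), popmap$sample)
  if (length(missing))
    stop("VCF sample(s) absent from population map: ",
         paste(missing, collapse = ", "))
  code <- c("0/0" = 0L, "0|0" = 0L,
            "0/1" = 1L, "1/0" = 1L, "0|1" = 1L, "1|0" = 1L,
            "1/1" = 2L, "1|1" = 2L)
  d <- matrix(unname(code[gt]), nrow = nrow(gt),
              dimnames = list(NULL, colnames(gt)))
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  sites <- GenomicRanges::granges(rr)
  names(sites) <- NULL
  S4Vectors::mcols(sites) <- S4Vectors::DataFrame(
    ref = as.character(rr$REF),
    alt = as.character(unlist(rr$ALT)),
    depth = if ("DP" %in% colnames(info)) as.numeric(info$DP) else NA_real_,
    rmsMQ = if ("MQ" %in% colnames(info)) as.numeric(info$MQ) else NA_real_)
  groups <- popmap$group[match(colnames(d), popmap$sample)]
  GenotypeData(d, sites, groups = groups, sampleIds = colnames(d))
}

#' Read gene models from a GFF3 annotation
#'
#' Keeps `gene` and `exon` features; exon gene ids are resolved through
#' `Parent` (falling back to `gene_id` when present). Coordinates are
#' 1-based closed, as in GFF3.
#'
#' @param gffPath Path to a GFF3 file.
#' @return List with `genes` and `exons` `GRanges`, both carrying a
#'   `gene_id` metadata column and sorted by position.
#' @export
readGeneModels <- function(gffPath) {
  if (!file.exists(gffPath)) stop("GFF3 not found: ", gffPath)
  gff <- rtracklayer::import(gffPath, format = "gff3")
  genes <- gff[gff$type == "gene"]
  exons <- gff[gff$type == "exon"]
  geneId <- if (!is.null(genes$gene_id)) genes$gene_id else genes$ID
  S4Vectors::mcols(genes) <- S4Vectors::DataFrame(gene_id = geneId)
  exId <- if (!is.null(exons$gene_id) && !all(is.na(exons$gene_id)))
    exons$gene_id
  else as.character(S4Vectors::unstrsplit(exons$Parent, sep = ","))
  S4Vectors::mcols(exons) <- S4Vectors::DataFrame(gene_id = exId)
  list(genes = sort(genes, ignore.strand = TRUE),
       exons = sort(exons, ignore.strand = TRUE))
}

#' Read the full input triple for an analysis run
#'
#' @param vcfPath,gffPath,popmapPath Paths to the VCF, GFF3 and
#'   population-map files.
#' @return List with `geno` ([GenotypeData-class]), `genes` (gene-model
#'   list) and `popmap` (`data.frame`).
#' @export
readInputs <- function(vcfPath, gffPath, popmapPath) {
  popmap <- readPopulationMap(popmapPath)
  list(geno = readGenotypeVcf(vcfPath, popmap),
       genes = readGeneModels(gffPath),
       popmap = popmap)
}
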