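NULL

#' Access the dosage matrix of a GenotypeData object
#'
#' @param x A [GenotypeData-class] object.
#' @return Integer matrix (sites x samples) of alt-allele dosages in
#'   \{0, 1, 2\} with `NA` for missing genotypes.
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))

#' Access the subgroup assignment of each sample
#'
#' @param x A [GenotypeData-class] object.
#' @return Factor of subgroup labels, one per sample, named by sample id.
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' Access per-site records (coordinates, alleles, QC covariates)
#'
#' @param x A [GenotypeData-class] object.
#' @return `GRanges` with metadata columns `ref`, `alt`, `depth`,
#'   `rmsMQ`, `callFraction`, `maf`.
#' @export
setGeneric("siteRecords", function(x) standardGeneric("siteRecords"))

#' Ground-truth population allele frequencies of a simulation
#'
#' @param x A [SimTruth-class] object.
#' @return Numeric matrix (sites x populations).
#' @export
setGeneric("popFrequencies", function(x) standardGeneric("popFrequencies"))

#' Ground-truth planted sweep intervals of a simulation
#'
#' @param x A [SimTruth-class] object.
#' @return `GRanges` with metadata columns `population` and `s`
#'   (zero-length if no sweeps were planted).
#' @export
setGeneric("plantedSweeps", function(x) standardGeneric("plantedSweeps"))
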