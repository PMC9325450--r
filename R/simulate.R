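#' @include AllClasses.R
NULL

## derived seed streams for the individual simulator stages; kept inside
## 32-bit integer range so any small user seed is safe
.deriveSeed <- function(seed, offset) {
  as.integer((as.double(seed) + offset) %% (.Machine$integer.max - 10L))
}

#' Configure the multi-population genotype simulator
#'
#' Builds a validated [SimConfig-class]. Populations diverge from a
#' shared ancestral allele-frequency pool under the Balding-Nichols
#' model: at a site with ancestral frequency p, a population with drift
#' parameter F draws its frequency from
#' Beta(p(1-F)/F, (1-p)(1-F)/F), whose mean is p and whose variance is
#' F p (1-p); F = 0 copies p exactly. Planted sweeps push the target
#' population's frequencies toward fixation inside stated intervals.
#'
#' Default covariate models reflect a medium-coverage resequencing
#' panel: mean site depth ~ NegBin(mean 10, size 5), RMS mapping quality
#' ~ Normal(45, 8) truncated at 0, and 2% independent per-genotype
#' missingness, so a small realistic fraction of sites fails each of the
#' standard QC thresholds (depth >= 4, MQ >= 20, miss <= 0.1).
#'
#' @param seed Integer seed; fixes every downstream draw.
#' @param chromLengths Named numeric of chromosome lengths (bp).
#' @param nSites Total number of SNP sites.
#' @param populations `data.frame(label, n, F)`.
#' @param ancestralSfs `"uniform"` or `"neutral"` (see [SimConfig-class]).
#' @param missingRate Per-genotype missing probability.
#' @param depthMean,depthDispersion Negative-binomial mean/size of site depth.
#' @param mqMean,mqSd Normal mean/sd of site RMS mapping quality.
#' @param sweeps `data.frame(chrom, start, end, population, s)` of planted
#'   sweeps (possibly empty).
#' @param nGenes Number of toy genes for the annotation fixture.
#' @return A [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(seed = 1, nSites = 500)
#' cfg
#' @export
simConfig <- function(seed = 1L,
                      chromLengths = c(chr1 = 2e6),
                      nSites = 20000L,
                      populations = data.frame(
                        label = c("WL", "SL"), n = c(20L, 20L),
                        F = c(0.05, 0.05)),
                      ancestralSfs = c("uniform", "neutral"),
                      missingRate = 0.02,
                      depthMean = 10, depthDispersion = 5,
                      mqMean = 45, mqSd = 8,
                      sweeps = data.frame(chrom = character(),
                                          start = numeric(), end = numeric(),
                                          population = character(),
                                          s = numeric()),
                      nGenes = 100L) {
  ancestralSfs <- match.arg(ancestralSfs)
  cfg <- methods::new("SimConfig",
    seed = as.integer(seed), chromLengths = chromLengths,
    nSites = as.integer(nSites), populations = populations,
    ancestralSfs = ancestralSfs, missingRate = missingRate,
    depthMean = depthMean, depthDispersion = depthDispersion,
    mqMean = mqMean, mqSd = mqSd, sweeps = sweeps,
    nGenes = as.integer(nGenes))
  cfg
}

#' The standard two-population sweep benchmark configuration
#'
#' A 2 Mb chromosome with 20 000 SNPs, a wild (WL, n = 20, F = 0.05) and
#' a cultivated (SL, n = 20, F = 0.05) population, and ten planted
#' 7.5 kb sweeps of intensity s = 0.95 in SL, evenly spaced. The
#' benchmark is built for a scan with 2 kb windows sliding by 200 bp
#' (each sweep then fully contains 28 windows): the joint top-5% rule
#' can select at most a fraction q of all windows, so a meaningful
#' recovery benchmark must keep the swept windows rarer than that
#' capacity — here sweeps plus their window halo cover ~4.5% of all
#' windows, matching the method's assumption that sweeps are rare.
#'
#' @param seed Integer seed.
#' @return A [SimConfig-class] object.
#' @export
standardFixtureConfig <- function(seed = 1L) {
  starts <- 100000 + (0:9) * 190000
  simConfig(
    seed = seed,
    chromLengths = c(chr1 = 2e6),
    nSites = 20000L,
    populations = data.frame(label = c("WL", "SL"), n = c(20L, 20L),
                             F = c(0.05, 0.05)),
    ancestralSfs = "uniform",
    sweeps = data.frame(chrom = "chr1", start = starts,
                        end = starts + 7500 - 1,
                        population = "SL", s = 0.95),
    nGenes = 200L)
}

#' Window geometry matched to [standardFixtureConfig()]
#'
#' @return Named list with `size` (2000 bp) and `step` (200 bp).
#' @export
standardFixtureWindows <- function() list(size = 2000, step = 200)

.drawAncestralFreq <- function(n, sfs) {
  switch(sfs,
    uniform = stats::runif(n, 0.05, 0.95),
    ## density proportional to 1/x on [0.01, 0.99]: inverse-CDF transform
    neutral = 0.01 * (0.99 / 0.01)^stats::runif(n))
}

#' Draw ancestral and per-population allele frequencies
#'
#' Site positions are drawn uniformly (without replacement, sorted) along
#' each chromosome, with sites allocated to chromosomes proportionally to
#' length. The ancestral alt-allele frequency p comes from the configured
#' spectrum; each population's frequency is Balding-Nichols
#' Beta(p(1-F)/F, (1-p)(1-F)/F), or exactly p when F = 0.
#'
#' @param config A [SimConfig-class].
#' @return A [SimTruth-class] (sweeps not yet planted).
#' @seealso [plantSweeps()], [sampleGenotypes()]
#' @export
simulateFrequencies <- function(config) {
  stopifnot(is(config, "SimConfig"))
  methods::validObject(config)
  set.seed(config@seed)
  lens <- config@chromLengths
  nPer <- round(config@nSites * lens / sum(lens))
  ## rounding can drop/add a site; fix up on the first chromosome
  nPer[1] <- nPer[1] + config@nSites - sum(nPer)
  pos <- lapply(seq_along(lens), function(i)
    sort(sample.int(lens[i], nPer[i])))
  sites <- GenomicRanges::GRanges(
    rep(names(lens), nPer),
    IRanges::IRanges(unlist(pos), width = 1),
    seqlengths = lens)
  p <- .drawAncestralFreq(length(sites), config@ancestralSfs)
  pops <- config@populations
  popFreq <- vapply(seq_len(nrow(pops)), function(i) {
    Fi <- pops$F[i]
    if (Fi == 0) p
    else stats::rbeta(length(p), p * (1 - Fi) / Fi, (1 - p) * (1 - Fi) / Fi)
  }, numeric(length(sites)))
  colnames(popFreq) <- pops$label
  methods::new("SimTruth",
    sites = sites, ancestralFreq = p, popFreq = popFreq,
    F = stats::setNames(pops$F, pops$label),
    sweeps = GenomicRanges::GRanges(seqlengths = lens))
}

#' Plant selective sweeps into simulated frequencies
#'
#' Inside each configured sweep interval the target population's
#' frequency moves toward fixation: p' = p (1 - s) + round(p) s, with
#' round(0.5) defined as 1 (deterministic tie toward the alt allele).
#' s = 1 forces fixation (expected heterozygosity 0); s = 0 is a no-op.
#' Other populations and sites outside the intervals are untouched.
#'
#' @param truth A [SimTruth-class] from [simulateFrequencies()].
#' @param config The same [SimConfig-class] (supplies the sweep table).
#' @return The updated [SimTruth-class] with `plantedSweeps()` filled in.
#' @export
plantSweeps <- function(truth, config) {
  stopifnot(is(truth, "SimTruth"), is(config, "SimConfig"))
  methods::validObject(config)
  sw <- config@sweeps
  if (!nrow(sw)) return(truth)
  lens <- config@chromLengths
  if (any(sw$start < 1 | sw$end > lens[as.character(sw$chrom)]))
    stop("sweep interval outside chromosome bounds")
  gr <- GenomicRanges::GRanges(sw$chrom, IRanges::IRanges(sw$start, sw$end),
                               seqlengths = lens)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(population = sw$population,
                                               s = sw$s)
  pf <- truth@popFreq
  for (k in seq_along(gr)) {
    hit <- IRanges::overlapsAny(truth@sites, gr[k])
    lab <- sw$population[k]
    s <- sw$s[k]
    p <- pf[hit, lab]
    pf[hit, lab] <- p * (1 - s) + ifelse(p >= 0.5, 1, 0) * s
  }
  methods::initialize(truth, popFreq = pf, sweeps = gr)
}

#' Sample diploid genotypes and site QC covariates
#'
#' Each genotype is a Binomial(2, p_pop) alt-allele dosage; genotypes are
#' masked missing independently with the configured rate. Per-site depth
#' and RMS mapping quality are drawn from the configured site-level
#' models; the recorded call fraction is the realized non-missing
#' fraction and MAF is computed from the sampled genotypes.
#'
#' @param truth A [SimTruth-class] (after [plantSweeps()] if sweeps are
#'   configured).
#' @param config The matching [SimConfig-class].
#' @return A [GenotypeData-class] with samples named `<label>_<i>`.
#' @export
sampleGenotypes <- function(truth, config) {
  stopifnot(is(truth, "SimTruth"), is(config, "SimConfig"))
  set.seed(.deriveSeed(config@seed, 1))
  nSites <- length(truth@sites)
  pops <- config@populations
  mats <- lapply(seq_len(nrow(pops)), function(i) {
    p <- truth@popFreq[, pops$label[i]]
    matrix(stats::rbinom(nSites * pops$n[i], 2L, p), nrow = nSites)
  })
  d <- do.call(cbind, mats)
  if (config@missingRate > 0)
    d[stats::runif(length(d)) < config@missingRate] <- NA_integer_
  ids <- unlist(lapply(seq_len(nrow(pops)), function(i)
    sprintf("%s_%02d", pops$label[i], seq_len(pops$n[i]))))
  groups <- rep(pops$label, pops$n)
  sites <- truth@sites
  nucs <- c("A", "C", "G", "T")
  refIdx <- sample.int(4L, nSites, replace = TRUE)
  altShift <- sample.int(3L, nSites, replace = TRUE)
  S4Vectors::mcols(sites)$ref <- nucs[refIdx]
  S4Vectors::mcols(sites)$alt <- nucs[(refIdx - 1L + altShift) %% 4L + 1L]
  S4Vectors::mcols(sites)$depth <- stats::rnbinom(
    nSites, mu = config@depthMean, size = config@depthDispersion)
  S4Vectors::mcols(sites)$rmsMQ <- round(
    pmax(0, stats::rnorm(nSites, config@mqMean, config@mqSd)), 2)
  GenotypeData(d, sites, groups = groups, sampleIds = ids)
}

#' Simulate a toy gene annotation
#'
#' Draws non-overlapping genes (lengths 2-8 kb) spread over the
#' chromosomes, each with 1-3 non-overlapping exons inside its span and a
#' random strand. Genes are allocated to evenly spaced slots so
#' non-overlap holds by construction.
#'
#' @param config A [SimConfig-class].
#' @return List with elements `genes` (`GRanges`, metadata column
#'   `gene_id`, strand set) and `exons` (`GRanges`, metadata column
#'   `gene_id`).
#' @export
simulateGeneModels <- function(config) {
  stopifnot(is(config, "SimConfig"))
  set.seed(.deriveSeed(config@seed, 2))
  lens <- config@chromLengths
  nGenes <- config@nGenes
  if (nGenes == 0L)
    return(list(genes = GenomicRanges::GRanges(seqlengths = lens),
                exons = GenomicRanges::GRanges(seqlengths = lens)))
  nPer <- round(nGenes * lens / sum(lens))
  nPer[1] <- nPer[1] + nGenes - sum(nPer)
  geneList <- list(); exonList <- list(); counter <- 0L
  for (ci in seq_along(lens)) {
    if (nPer[ci] == 0L) next
    slot <- floor(lens[ci] / nPer[ci])
    glen <- pmin(stats::runif(nPer[ci], 2000, 8000), slot - 2)
    offs <- floor(stats::runif(nPer[ci]) * (slot - glen - 1)) + 1
    starts <- (seq_len(nPer[ci]) - 1) * slot + offs
    ends <- starts + floor(glen) - 1
    ids <- sprintf("gene%04d", counter + seq_len(nPer[ci]))
    counter <- counter + nPer[ci]
    strand <- sample(c("+", "-"), nPer[ci], replace = TRUE)
    geneList[[ci]] <- GenomicRanges::GRanges(
      names(lens)[ci], IRanges::IRanges(starts, ends), strand = strand,
      gene_id = ids, seqlengths = lens)
    exonList[[ci]] <- do.call(c, lapply(seq_len(nPer[ci]), function(g) {
      nEx <- sample.int(3L, 1L)
      span <- ends[g] - starts[g] + 1
      ## split the span into nEx exon / intron alternations
      cuts <- sort(sample.int(span - 1, 2 * nEx - 2)) ## interior boundaries
      bounds <- c(0, cuts, span)
      exStart <- starts[g] + bounds[seq(1, 2 * nEx - 1, by = 2)]
      exEnd <- starts[g] + bounds[seq(2, 2 * nEx, by = 2)] - 1
      keep <- exEnd >= exStart
      GenomicRanges::GRanges(names(lens)[ci],
                             IRanges::IRanges(exStart[keep], exEnd[keep]),
                             strand = strand[g], gene_id = ids[g],
                             seqlengths = lens)
    }))
  }
  list(genes = sort(do.call(c, geneList), ignore.strand = TRUE),
       exons = sort(do.call(c, exonList), ignore.strand = TRUE))
}

#' Simulate a full dataset (frequencies, sweeps, genotypes, genes)
#'
#' Convenience wrapper running [simulateFrequencies()], [plantSweeps()],
#' [sampleGenotypes()] and [simulateGeneModels()] in order. Fully
#' deterministic given `config@seed`.
#'
#' @param config A [SimConfig-class].
#' @return List with elements `geno` ([GenotypeData-class]), `truth`
#'   ([SimTruth-class]) and `genes` (list of `genes`/`exons` `GRanges`).
#' @examples
#' d <- simulateDataset(simConfig(seed = 7, nSites = 200, nGenes = 5))
#' d$geno
#' @export
simulateDataset <- function(config) {
  truth <- simulateFrequencies(config)
  truth <- plantSweeps(truth, config)
  geno <- sampleGenotypes(truth, config)
  genes <- simulateGeneModels(config)
  list(geno = geno, truth = truth, genes = genes)
}

#' Write a simulated dataset to standard-format files
#'
#' Emits `sim.vcf` (VCF v4.2; GT per sample, site-level INFO DP and MQ),
#' `genes.gff3` (1-based closed intervals, gene + exon features),
#' `popmap.tsv` (`sample<TAB>group`) and `sweeps_truth.tsv`
#' (`chrom start end population s`). Reading the VCF back with
#' [readGenotypeVcf()] reproduces the dosage matrix exactly.
#'
#' @param geno A [GenotypeData-class].
#' @param truth A [SimTruth-class] (for the sweep truth table).
#' @param genes Gene model list from [simulateGeneModels()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
writeFixture <- function(geno, truth, genes, dir) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", dir)
  paths <- c(vcf = file.path(dir, "sim.vcf"),
             gff = file.path(dir, "genes.gff3"),
             popmap = file.path(dir, "popmap.tsv"),
             truth = file.path(dir, "sweeps_truth.tsv"))
  .writeVcf(geno, paths["vcf"])
  .writeGff3(genes, paths["gff"])
  grp <- sampleGroups(geno)
  utils::write.table(
    data.frame(sample = names(grp), group = as.character(grp)),
    paths["popmap"], sep = "\t", quote = FALSE, row.names = FALSE)
  sw <- plantedSweeps(truth)
  utils::write.table(
    data.frame(chrom = as.character(GenomicRanges::seqnames(sw)),
               start = GenomicRanges::start(sw),
               end = GenomicRanges::end(sw),
               population = if (length(sw)) sw$population else character(),
               s = if (length(sw)) sw$s else numeric()),
    paths["truth"], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

## minimal deterministic VCF v4.2 emitter for fixtures; read back (and
## validated) with VariantAnnotation::readVcf
.writeVcf <- function(geno, path) {
  rr <- siteRecords(geno)
  d <- dosage(geno)
  lens <- GenomeInfoDb::seqlengths(rr)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(lens), lens),
           "##INFO=<ID=DP,Number=1,Type=Float,Description=\"Mean site coverage depth\">",
           "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(d)), collapse = "\t"))
  gtCode <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = nrow(d), ncol = ncol(d))
  ok <- !is.na(d)
  gt[ok] <- gtCode[d[ok] + 1L]
  body <- paste(
    as.character(GenomicRanges::seqnames(rr)),
    GenomicRanges::start(rr), ".",
    S4Vectors::mcols(rr)$ref, S4Vectors::mcols(rr)$alt, ".", "PASS",
    sprintf("DP=%s;MQ=%s", S4Vectors::mcols(rr)$depth,
            S4Vectors::mcols(rr)$rmsMQ),
    "GT", apply(gt, 1, paste, collapse = "\t"),
    sep = "\t")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
}

.writeGff3 <- function(genes, path) {
  g <- genes$genes
  e <- genes$exons
  if (length(g)) {
    gid <- g$gene_id
    eid <- e$gene_id
    S4Vectors::mcols(g) <- S4Vectors::DataFrame(
      source = "SweepScan", type = "gene", ID = gid, gene_id = gid,
      Parent = IRanges::CharacterList(rep(list(character(0)), length(g))))
    S4Vectors::mcols(e) <- S4Vectors::DataFrame(
      source = "SweepScan", type = "exon",
      ID = paste0(eid, ".exon", seq_along(e)), gene_id = eid,
      Parent = IRanges::CharacterList(as.list(eid)))
    all <- sort(c(g, e), ignore.strand = TRUE)
    rtracklayer::export(all, path, format = "gff3")
  } else {
    writeLines("##gff-version 3", path)
  }
}
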