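# Small in-code fixture builders shared across the test files.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(S4Vectors)
})

# GenotypeData from a bare dosage matrix (sites x samples)
makeGeno <- function(d, groups, pos = seq_len(nrow(d)), chrom = "chr1",
                     chromLength = max(pos) + 10, ...) {
  storage.mode(d) <- "integer"
  if (is.null(colnames(d)))
    colnames(d) <- sprintf("s%02d", seq_len(ncol(d)))
  gr <- GRanges(chrom, IRanges::IRanges(pos, width = 1),
                seqlengths = setNames(chromLength, chrom))
  extra <- list(...)
  for (nm in names(extra)) mcols(gr)[[nm]] <- extra[[nm]]
  GenotypeData(d, gr, groups = groups)
}

# site-record GRanges with explicit QC covariates (for filter tests)
makeSites <- function(depth, mq, maf, callFraction, chrom = "chr1") {
  n <- length(depth)
  GRanges(chrom, IRanges::IRanges(seq_len(n) * 10, width = 1),
          ref = rep("A", n), alt = rep("G", n),
          depth = depth, rmsMQ = mq, callFraction = callFraction,
          maf = maf)
}

# a SimTruth with frequencies fixed by hand (for limit-case tests)
makeTruth <- function(popFreq, pos = seq_len(nrow(popFreq)) * 10,
                      chrom = "chr1", chromLength = max(pos) + 10,
                      F = setNames(rep(0.1, ncol(popFreq)),
                                   colnames(popFreq))) {
  sites <- GRanges(chrom, IRanges::IRanges(pos, width = 1),
                   seqlengths = setNames(chromLength, chrom))
  methods::new("SimTruth", sites = sites,
               ancestralFreq = rowMeans(popFreq), popFreq = popFreq,
               F = F, sweeps = GRanges())
}

# random gene-model list on one chromosome (possibly overlapping genes
# are fine for the overlap oracles)
randomGenes <- function(n, chromLength = 1e5, chrom = "chr1") {
  start <- sample.int(chromLength - 2000, n)
  end <- start + sample.int(1500, n, replace = TRUE)
  g <- GRanges(chrom, IRanges::IRanges(start, end),
               strand = sample(c("+", "-"), n, replace = TRUE))
  mcols(g)$gene_id <- sprintf("g%03d", seq_len(n))
  ex <- lapply(seq_len(n), function(i) {
    w <- GenomicRanges::width(g)[i]
    exEnd <- GenomicRanges::start(g)[i] + sample.int(w, 1) - 1
    GRanges(chrom, IRanges::IRanges(GenomicRanges::start(g)[i], exEnd),
            strand = GenomicRanges::strand(g)[i], gene_id = g$gene_id[i])
  })
  list(genes = sort(g, ignore.strand = TRUE),
       exons = sort(do.call(c, ex), ignore.strand = TRUE))
}
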