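#' @include AllClasses.R
NULL

.stageLog <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

.writeTsv <- function(df, path, comments = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Configure an end-to-end analysis run
#'
#' Exactly one of \{`vcf` + `gff` + `popmap` paths\} or a `sim` block
#' ([SimConfig-class]) must be given; in simulate mode the fixture files
#' are written under `<outDir>/fixture` and then analyzed through the
#' same code path as real inputs. All defaults (window geometry, FST
#' estimator, merge gap, thresholds) are echoed into the run manifest so
#' they are always on record.
#'
#' @param vcf,gff,popmap Input file paths (VCF v4.x, GFF3,
#'   sample<TAB>group TSV), or `NULL` in simulate mode.
#' @param sim A [SimConfig-class], or `NULL` in file mode.
#' @param filters Named list of site-filter thresholds (see
#'   [filterSites()]).
#' @param windowSize,windowStep Window geometry in bp.
#' @param pairs List of `c(wild, cultivated)` subgroup pairs for the
#'   FST / pi-ratio scan.
#' @param q Upper-tail fraction for the joint sweep rule.
#' @param gapBp Merge gap for selected windows.
#' @param flankBp Flank for upstream/downstream SNP classification.
#' @param outDir Output directory.
#' @param seed Integer seed (simulate mode randomness only; the
#'   analysis itself is deterministic).
#' @return List of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(vcf = NULL, gff = NULL, popmap = NULL,
                           sim = NULL,
                           filters = list(minDepth = 4, minMQ = 20,
                                          minMaf = 0.05, maxMiss = 0.1),
                           windowSize = 1e5, windowStep = windowSize / 10,
                           pairs = list(), q = 0.05, gapBp = 0,
                           flankBp = 0, outDir, seed = 1L) {
  fileMode <- !is.null(vcf) || !is.null(gff) || !is.null(popmap)
  simMode <- !is.null(sim)
  if (fileMode == simMode)
    stop("config error: exactly one of {vcf/gff/popmap paths, sim block} ",
         "must be given")
  if (fileMode && (is.null(vcf) || is.null(popmap)))
    stop("config error: file mode needs at least vcf and popmap paths")
  if (simMode && !is(sim, "SimConfig"))
    stop("config error: sim must be a SimConfig")
  if (q <= 0 || q > 0.5) stop("config error: q must lie in (0, 0.5]")
  if (missing(outDir)) stop("config error: outDir is required")
  if (simMode) {
    sim@seed <- as.integer(seed)
    bad <- setdiff(unlist(pairs), sim@populations$label)
    if (length(bad))
      stop("config error: group(s) in pairs absent from simulated ",
           "populations: ", paste(bad, collapse = ", "))
  }
  structure(list(vcf = vcf, gff = gff, popmap = popmap, sim = sim,
                 filters = filters, windowSize = windowSize,
                 windowStep = windowStep, pairs = pairs, q = q,
                 gapBp = gapBp, flankBp = flankBp, outDir = outDir,
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Run the full analysis pipeline
#'
#' Stages, each written to `outDir` before the next starts:
#' simulate/read, site filtering, SNP region classification, subgroup
#' SNP sharing, heterozygosity, windowed pi/FST, per-pair sweep scans
#' (TSV + BED + gene lists), cross-pair sweep overlap, p-distance + NJ
#' tree (Newick) and genotype PCA, and a JSON run manifest with an MD5
#' checksum for every output file. Identical config and seed give
#' byte-identical outputs (the manifest's timestamps aside). Any stage
#' error aborts with the stage name in the message.
#'
#' All interval TSVs use 1-based closed coordinates; BED exports are
#' 0-based half-open.
#'
#' @param config A [pipelineConfig()] object.
#' @return The manifest, invisibly (also written to
#'   `<outDir>/manifest.json`).
#' @examples
#' cfg <- pipelineConfig(sim = simConfig(seed = 1, nSites = 1000),
#'                       windowSize = 1e5, windowStep = 1e4,
#'                       pairs = list(c("WL", "SL")),
#'                       outDir = file.path(tempdir(), "mini-run"))
#' mf <- runPipeline(cfg)
#' names(mf$files)
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  t0 <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  out <- config$outDir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- "input"
  tryCatch({
    if (!is.null(config$sim)) {
      .stageLog(stage, "simulating dataset (seed ", config$seed, ")")
      d <- simulateDataset(config$sim)
      fixDir <- file.path(out, "fixture")
      writeFixture(d$geno, d$truth, d$genes, fixDir)
      geno <- d$geno
      genes <- d$genes
    } else {
      ## validate the group pairs against the population map before any
      ## heavier input is read or any output written
      popmap <- readPopulationMap(config$popmap)
      bad <- setdiff(unlist(config$pairs), popmap$group)
      if (length(bad))
        stop("config error: group(s) in pairs absent from population ",
             "map: ", paste(bad, collapse = ", "))
      .stageLog(stage, "reading ", config$vcf)
      geno <- readGenotypeVcf(config$vcf, popmap)
      genes <- if (!is.null(config$gff)) readGeneModels(config$gff)
      else list(genes = GenomicRanges::GRanges(),
                exons = GenomicRanges::GRanges())
    }
    labs <- levels(sampleGroups(geno))

    stage <- "filter"
    flt <- do.call(filterSites, c(list(geno), config$filters))
    .stageLog(stage, flt$nPass, " of ", flt$nTotal, " sites pass QC")
    .writeTsv(flt$summary, file.path(out, "filter_summary.tsv"),
              c("per-criterion failure counts (a site may fail several)",
                paste0("thresholds: ",
                       paste(names(flt$thresholds), flt$thresholds,
                             sep = "=", collapse = " ")),
                paste0("sites total=", flt$nTotal, " pass=", flt$nPass)))
    genoF <- geno[flt$pass, ]

    stage <- "classify"
    cls <- classifySnpRegions(genoF, genes, flankBp = config$flankBp)
    rr <- siteRecords(genoF)
    .writeTsv(data.frame(chrom = as.character(GenomicRanges::seqnames(rr)),
                         pos = GenomicRanges::start(rr),
                         category = as.character(cls)),
              file.path(out, "snp_regions.tsv"),
              "SNP region classification; pos is 1-based")
    prop <- attr(cls, "proportions")
    .writeTsv(data.frame(category = names(prop),
                         proportion = as.numeric(prop)),
              file.path(out, "snp_region_proportions.tsv"),
              "fraction of filtered SNPs per region category")

    stage <- "sharing"
    if (length(labs) >= 2) {
      sh <- snpSharing(genoF)
      .writeTsv(data.frame(group = c(names(sh$perGroup), "COMMON"),
                           present = c(sh$perGroup, sh$common),
                           unique = c(sh$unique, NA)),
                file.path(out, "snp_sharing.tsv"),
                c("present = sites with >= 1 alt carrier in the subgroup",
                  "unique = present in that subgroup only; COMMON = all subgroups"))
    }

    stage <- "heterozygosity"
    het <- heterozygosity(genoF)
    .writeTsv(het$perSample, file.path(out, "heterozygosity.tsv"),
              "het = heterozygous fraction of called genotypes per sample")

    stage <- "stats"
    ws <- windowStats(genoF, size = config$windowSize,
                      step = config$windowStep, pairs = config$pairs)
    wsDf <- data.frame(chrom = as.character(GenomicRanges::seqnames(ws)),
                       start = GenomicRanges::start(ws),
                       end = GenomicRanges::end(ws),
                       as.data.frame(S4Vectors::mcols(ws)))
    .writeTsv(wsDf, file.path(out, "window_stats.tsv"),
              c("1-based closed windows; pi per bp; Hudson FST (ratio of averages)",
                paste0("window size=", config$windowSize, " step=",
                       config$windowStep)))

    stage <- "sweep"
    scans <- list()
    for (pr in config$pairs) {
      tag <- paste0(pr[1], "_", pr[2])
      scan <- sweepScan(ws, pr[1], pr[2], q = config$q,
                        gapBp = config$gapBp, genes = genes)
      scans[[tag]] <- scan
      reg <- scan$regions
      regDf <- data.frame(
        chrom = if (length(reg)) as.character(GenomicRanges::seqnames(reg)) else character(),
        start = GenomicRanges::start(reg), end = GenomicRanges::end(reg),
        nWindows = if (length(reg)) reg$nWindows else integer(),
        maxFst = if (length(reg)) reg$maxFst else numeric(),
        maxLog2PiRatio = if (length(reg)) reg$maxLog2PiRatio else numeric(),
        genes = if (length(reg))
          vapply(reg$gene_ids, paste, "", collapse = ",") else character())
      .writeTsv(regDf, file.path(out, paste0("sweeps_", tag, ".tsv")),
                c(paste0("sweep regions ", pr[1], " vs ", pr[2],
                         "; joint top-", 100 * config$q,
                         "% FST and log2 pi-ratio windows, merged"),
                  "1-based closed; region stats are maxima over member windows"))
      .writeBed(reg, file.path(out, paste0("sweeps_", tag, ".bed")), tag)
      writeLines(S4Vectors::metadata(reg)$sweepGenes %||% character(),
                 file.path(out, paste0("sweep_genes_", tag, ".txt")))
    }
    if (length(scans) >= 2) {
      tags <- names(scans)
      for (i in seq_len(length(tags) - 1)) for (j in (i + 1):length(tags)) {
        ov <- sweepOverlap(scans[[tags[i]]]$regions,
                           scans[[tags[j]]]$regions)
        .writeTsv(data.frame(nOverlaps = ov$nOverlaps,
                             sharedGenes = paste(ov$sharedGenes,
                                                 collapse = ",")),
                  file.path(out, paste0("sweep_overlap_", tags[i], "_vs_",
                                        tags[j], ".tsv")),
                  "overlapping sweep regions and shared genes between two scans")
      }
    }

    stage <- "structure"
    D <- pDistance(genoF)
    .writeTsv(data.frame(sample = rownames(D), as.data.frame(D),
                         check.names = FALSE),
              file.path(out, "p_distance.tsv"),
              "allele-sharing p-distance, pairwise deletion")
    if (ncol(genoF) >= 3)
      ape::write.tree(njTree(D), file.path(out, "nj_tree.nwk"))
    pca <- genotypePca(genoF, k = min(10, ncol(genoF) - 1))
    .writeTsv(data.frame(sample = rownames(pca$coordinates),
                         as.data.frame(pca$coordinates),
                         group = as.character(pca$groups)),
              file.path(out, "pca_coordinates.tsv"),
              "genotype PCA, Patterson normalization, mean-imputed missing")
    .writeTsv(data.frame(component = seq_along(pca$explained),
                         explained = pca$explained),
              file.path(out, "pca_explained.tsv"),
              "fraction of total variance per component")

    stage <- "manifest"
    files <- setdiff(list.files(out, recursive = TRUE), "manifest.json")
    paths <- file.path(out, files)
    manifest <- list(
      package = "SweepScan",
      version = as.character(utils::packageVersion("SweepScan")),
      seed = config$seed,
      started = t0,
      finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      config = list(
        mode = if (is.null(config$sim)) "files" else "simulate",
        filters = config$filters, windowSize = config$windowSize,
        windowStep = config$windowStep, pairs = config$pairs,
        q = config$q, gapBp = config$gapBp, flankBp = config$flankBp,
        fstEstimator = "hudson (ratio of averages)",
        piDenominator = "full window length (bp)"),
      counts = list(
        samples = ncol(geno), sitesTotal = flt$nTotal,
        sitesPass = flt$nPass, windows = length(ws),
        sweepRegions = lapply(scans, function(s) length(s$regions)),
        sweepGenes = lapply(scans, function(s)
          length(S4Vectors::metadata(s$regions)$sweepGenes))),
      files = as.list(stats::setNames(unname(tools::md5sum(paths)), files)))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(manifest)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.writeBed <- function(regions, path, name) {
  ## BED is 0-based half-open
  if (length(regions) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  score <- regions$maxFst
  score[!is.finite(score)] <- 1
  df <- data.frame(as.character(GenomicRanges::seqnames(regions)),
                   GenomicRanges::start(regions) - 1L,
                   GenomicRanges::end(regions),
                   paste0(name, "_sweep", seq_along(regions)),
                   round(pmin(1000, pmax(0, score * 1000))))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Summarize a completed pipeline run
#'
#' Re-reads the manifest and the written TSVs and prints a
#' human-readable summary: SNP counts by filter, region-category
#' proportions, per-subgroup heterozygosity, genome-wide per-subgroup
#' pi, pairwise window FST means, and sweep region/gene counts. All
#' numbers are recomputed from the files on disk.
#'
#' @param outDir A pipeline output directory containing
#'   `manifest.json`.
#' @return Character vector of summary lines, invisibly (also printed).
#' @export
reportPipeline <- function(outDir) {
  mfPath <- file.path(outDir, "manifest.json")
  if (!file.exists(mfPath)) stop("no manifest.json under ", outDir)
  mf <- jsonlite::read_json(mfPath, simplifyVector = TRUE)
  rd <- function(f) utils::read.delim(file.path(outDir, f),
                                      comment.char = "#")
  lines <- c(sprintf("SweepScan %s run (seed %s, %s mode)",
                     mf$version, mf$seed, mf$config$mode))
  fs <- rd("filter_summary.tsv")
  lines <- c(lines, sprintf("sites: %s total, %s pass QC",
                            mf$counts$sitesTotal, mf$counts$sitesPass),
             sprintf("  failed %s: %s", fs$criterion, fs$failed))
  pr <- rd("snp_region_proportions.tsv")
  lines <- c(lines, "SNP region proportions:",
             sprintf("  %s: %.2f%%", pr$category, 100 * pr$proportion))
  het <- rd("heterozygosity.tsv")
  hg <- tapply(het$het, het$group, mean, na.rm = TRUE)
  lines <- c(lines, "mean heterozygosity per subgroup:",
             sprintf("  %s: %.4f", names(hg), hg))
  ws <- rd("window_stats.tsv")
  piCols <- grep("^pi_", names(ws), value = TRUE)
  lines <- c(lines, "genome-wide mean window pi (per bp):",
             sprintf("  %s: %.3e", sub("pi_", "", piCols),
                     colMeans(ws[piCols], na.rm = TRUE)))
  fstCols <- grep("^fst_", names(ws), value = TRUE)
  if (length(fstCols))
    lines <- c(lines, "mean window FST:",
               sprintf("  %s: %.3f", sub("fst_", "", fstCols),
                       colMeans(ws[fstCols], na.rm = TRUE)))
  for (tag in names(mf$counts$sweepRegions))
    lines <- c(lines, sprintf("sweep scan %s: %d region(s), %d gene(s)",
                              tag, mf$counts$sweepRegions[[tag]],
                              mf$counts$sweepGenes[[tag]]))
  writeLines(lines)
  invisible(lines)
}

#' Manhattan-style plot of the windowed sweep statistics
#'
#' Plots window FST and log2 pi-ratio along the genome with the
#' empirical top-tail thresholds drawn; selected windows highlighted.
#' Requires ggplot2.
#'
#' @param windows Output of [callSweepWindows()].
#' @return A ggplot object.
#' @export
plotSweepScan <- function(windows) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotSweepScan needs ggplot2")
  mc <- S4Vectors::mcols(windows)
  q <- S4Vectors::metadata(windows)$q %||% 0.05
  fstCol <- grep("^fst_", colnames(mc), value = TRUE)[1]
  mid <- (GenomicRanges::start(windows) + GenomicRanges::end(windows)) / 2
  df <- rbind(
    data.frame(chrom = as.character(GenomicRanges::seqnames(windows)),
               pos = mid, value = mc[[fstCol]], stat = "FST",
               selected = mc$selected),
    data.frame(chrom = as.character(GenomicRanges::seqnames(windows)),
               pos = mid,
               value = ifelse(is.finite(mc$log2PiRatio), mc$log2PiRatio, NA),
               stat = "log2 pi-ratio", selected = mc$selected))
  thr <- do.call(rbind, lapply(split(df, df$stat), function(s)
    data.frame(stat = s$stat[1],
               thr = stats::quantile(s$value, 1 - q, na.rm = TRUE))))
  ggplot2::ggplot(df, ggplot2::aes(x = pos / 1e6, y = value,
                                   color = selected)) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::geom_hline(data = thr,
                        ggplot2::aes(yintercept = thr), linetype = 2) +
    ggplot2::facet_grid(stat ~ chrom, scales = "free") +
    ggplot2::scale_color_manual(values = c("grey40", "firebrick")) +
    ggplot2::labs(x = "position (Mb)", y = NULL) +
    ggplot2::theme_minimal()
}
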