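# Brute-force oracles, written independently of the implementation:
# plain loops and set algebra only, no GenomicRanges machinery.

# per-site pi by enumerating allele pairs
oracleSitePi <- function(refCount, altCount) {
  n <- refCount + altCount
  if (n < 2) return(NA_real_)
  alleles <- c(rep(0, refCount), rep(1, altCount))
  diff <- 0; tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + 1
    if (alleles[i] != alleles[j]) diff <- diff + 1
  }
  diff / tot
}

# windowed pi / FST by looping over sites within each window
oracleWindowStats <- function(d, groups, winStart, winEnd, pos,
                              wild, cult) {
  nWin <- length(winStart)
  out <- data.frame(nSites = integer(nWin), piWild = numeric(nWin),
                    piCult = numeric(nWin), fst = numeric(nWin))
  for (w in seq_len(nWin)) {
    inWin <- which(pos >= winStart[w] & pos <= winEnd[w])
    sumPiW <- 0; sumPiC <- 0; sumN <- 0; sumD <- 0; anyFst <- FALSE
    for (s in inWin) {
      for (side in c("wild", "cult")) {
        g <- if (side == "wild") wild else cult
        dg <- d[s, groups == g]
        called <- dg[!is.na(dg)]
        n <- 2 * length(called)
        alt <- sum(called)
        if (n >= 2) {
          pi <- 2 * (n - alt) * alt / (n * (n - 1))
          if (side == "wild") sumPiW <- sumPiW + pi
          else sumPiC <- sumPiC + pi
        }
      }
      d1 <- d[s, groups == wild]; d2 <- d[s, groups == cult]
      c1 <- d1[!is.na(d1)]; c2 <- d2[!is.na(d2)]
      n1 <- 2 * length(c1); n2 <- 2 * length(c2)
      if (n1 >= 2 && n2 >= 2) {
        p1 <- sum(c1) / n1; p2 <- sum(c2) / n2
        sumN <- sumN + (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) -
          p2 * (1 - p2) / (n2 - 1)
        sumD <- sumD + p1 * (1 - p2) + p2 * (1 - p1)
        anyFst <- TRUE
      }
    }
    L <- winEnd[w] - winStart[w] + 1
    out$nSites[w] <- length(inWin)
    out$piWild[w] <- sumPiW / L
    out$piCult[w] <- sumPiC / L
    out$fst[w] <- if (anyFst && sumD != 0) sumN / sumD else NA_real_
  }
  out
}

# quadratic interval-union merge of closed intervals (gap <= gapBp joins)
oracleMerge <- function(chrom, start, end, gapBp = 0) {
  o <- order(chrom, start)
  chrom <- chrom[o]; start <- start[o]; end <- end[o]
  res <- list()
  for (i in seq_along(start)) {
    merged <- FALSE
    for (k in seq_along(res)) {
      r <- res[[k]]
      if (r$chrom == chrom[i] && start[i] <= r$end + 1 + gapBp &&
          end[i] >= r$start - 1 - gapBp) {
        res[[k]]$start <- min(r$start, start[i])
        res[[k]]$end <- max(r$end, end[i])
        merged <- TRUE
        break
      }
    }
    if (!merged)
      res[[length(res) + 1]] <- list(chrom = chrom[i], start = start[i],
                                     end = end[i])
  }
  df <- do.call(rbind, lapply(res, as.data.frame))
  df[order(df$chrom, df$start), , drop = FALSE]
}

# quadratic closed-interval overlap scan (>= 1 bp)
oracleOverlapPairs <- function(aChrom, aStart, aEnd, bChrom, bStart, bEnd) {
  pairs <- NULL
  for (i in seq_along(aStart)) for (j in seq_along(bStart))
    if (aChrom[i] == bChrom[j] && aStart[i] <= bEnd[j] &&
        bStart[j] <= aEnd[i])
      pairs <- rbind(pairs, c(i, j))
  pairs
}

# region classification by scanning every gene/exon per SNP
oracleClassify <- function(pos, chrom, genes, flankBp = 0) {
  gdf <- data.frame(chrom = as.character(GenomicRanges::seqnames(genes$genes)),
                    start = GenomicRanges::start(genes$genes),
                    end = GenomicRanges::end(genes$genes),
                    strand = as.character(GenomicRanges::strand(genes$genes)))
  edf <- data.frame(chrom = as.character(GenomicRanges::seqnames(genes$exons)),
                    start = GenomicRanges::start(genes$exons),
                    end = GenomicRanges::end(genes$exons))
  vapply(seq_along(pos), function(s) {
    p <- pos[s]; ch <- chrom[s]
    inEx <- any(edf$chrom == ch & edf$start <= p & p <= edf$end)
    if (inEx) return("exonic")
    inGene <- any(gdf$chrom == ch & gdf$start <= p & p <= gdf$end)
    if (inGene) return("intronic")
    if (flankBp > 0) {
      up <- FALSE; down <- FALSE
      for (k in seq_len(nrow(gdf))) {
        if (gdf$chrom[k] != ch) next
        if (gdf$strand[k] == "-") {
          upHit <- p > gdf$end[k] && p <= gdf$end[k] + flankBp
          downHit <- p < gdf$start[k] && p >= gdf$start[k] - flankBp
        } else {
          upHit <- p < gdf$start[k] && p >= gdf$start[k] - flankBp
          downHit <- p > gdf$end[k] && p <= gdf$end[k] + flankBp
        }
        up <- up || upHit; down <- down || downHit
      }
      if (up) return("upstream")
      if (down) return("downstream")
    }
    "intergenic"
  }, character(1))
}

# subgroup presence/common/unique by explicit set algebra
oracleSharing <- function(d, groups) {
  labs <- sort(unique(as.character(groups)))
  carriers <- lapply(labs, function(g) {
    which(vapply(seq_len(nrow(d)), function(s) {
      dg <- d[s, groups == g]
      any(!is.na(dg) & dg > 0)
    }, logical(1)))
  })
  names(carriers) <- labs
  common <- Reduce(intersect, carriers)
  uniq <- vapply(labs, function(g) {
    others <- unlist(carriers[setdiff(labs, g)])
    length(setdiff(carriers[[g]], others))
  }, integer(1))
  list(perGroup = vapply(carriers, length, integer(1)),
       common = length(common), unique = uniq)
}
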