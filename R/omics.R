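## Dosage integration: band-level expression summaries, gene-wise
## CN-expression correlation, a rank-based two-group differential test, and
## methylation-copy-number correlations by CpG category and by band.

#' Counts-per-million normalization
#'
#' @param counts gene-by-sample raw count matrix.
#' @param log return log2(CPM + 1) (default) instead of raw CPM.
#' @return matrix of the same shape.
#' @export
cpmNormalize <- function(counts, log = TRUE) {
  libs <- colSums(counts)
  if (any(libs == 0)) stop("sample with zero library size")
  cpm <- sweep(counts, 2, libs, "/") * 1e6
  if (log) log2(cpm + 1) else cpm
}

# per-gene z-scores across samples; zero-variance genes -> 0
.geneZ <- function(norm) {
  mu <- rowMeans(norm)
  sd <- apply(norm, 1, stats::sd)
  z <- (norm - mu) / ifelse(sd > 0, sd, 1)
  z[sd == 0, ] <- 0
  z
}

# gene midpoint -> band index map (NA when a gene's midpoint escapes bands)
.geneBandIndex <- function(model, geneIds) {
  g <- model@genes[match(geneIds, model@genes$gene_id)]
  mid <- floor((start(g) + end(g)) / 2)
  findOverlaps(GRanges(seqnames(g), IRanges(mid, mid)), model@bands,
               select = "first")
}

#' Band-level expression summary matrix
#'
#' Band value = mean per-gene z-score (of log2 CPM) over the genes whose
#' midpoint falls in the band; bands with no genes are NA.
#'
#' @param counts gene-by-sample count matrix (rownames = gene ids matching
#'   the model's genes).
#' @param model a [GenomeModel-class] with genes loaded.
#' @return band-by-sample numeric matrix (band names as rownames).
#' @export
bandExpressionMatrix <- function(counts, model) {
  z <- .geneZ(cpmNormalize(counts))
  idx <- .geneBandIndex(model, rownames(counts))
  b <- model@bands
  out <- matrix(NA_real_, length(b), ncol(counts),
                dimnames = list(b$name, colnames(counts)))
  keep <- !is.na(idx)
  for (bi in unique(idx[keep])) {
    rows <- which(idx == bi)
    out[bi, ] <- if (length(rows) == 1) z[rows, ] else colMeans(z[rows, , drop = FALSE])
  }
  out
}

#' Per-gene copy-number estimates averaged across callers
#'
#' For each source (caller/platform) the gene copy number is the
#' length-weighted mean total copy number of the segments overlapping the
#' gene span; the final estimate is the unweighted mean across sources.
#'
#' @param ktsBySource list of [VirtualKaryotype-class], one per source, all
#'   for the same sample.
#' @param model a [GenomeModel-class] with genes loaded.
#' @return numeric vector of gene copy numbers (gene ids as names).
#' @export
geneCopyNumber <- function(ktsBySource, model) {
  g <- model@genes
  perSource <- vapply(ktsBySource, function(kt) {
    s <- kt@segments
    hits <- findOverlaps(g, s)
    ow <- width(pintersect(g[queryHits(hits)], s[subjectHits(hits)]))
    num <- tapply(ow * s$totalCN[subjectHits(hits)], queryHits(hits), sum)
    den <- tapply(ow, queryHits(hits), sum)
    cn <- rep(NA_real_, length(g))
    cn[as.integer(names(num))] <- as.numeric(num) / as.numeric(den)
    cn
  }, numeric(length(g)))
  if (length(g) == 1) perSource <- matrix(perSource, nrow = 1)
  stats::setNames(rowMeans(perSource, na.rm = TRUE), g$gene_id)
}

#' Gene copy-number matrix for a cohort
#'
#' @param cohortKts list (per sample) of lists (per source) of
#'   [VirtualKaryotype-class].
#' @param model a [GenomeModel-class].
#' @return gene-by-sample numeric matrix.
#' @export
geneCopyNumberMatrix <- function(cohortKts, model) {
  cols <- lapply(cohortKts, geneCopyNumber, model = model)
  ids <- vapply(cohortKts, function(l) l[[1]]@sampleId, "")
  m <- do.call(cbind, cols)
  colnames(m) <- ids
  m
}

#' Gene-wise correlation between copy number and expression
#'
#' Spearman correlation per gene between its copy-number estimate and its
#' normalized expression across samples. Genes with zero copy-number
#' variance (or fewer than `minSamples` samples) are excluded. Genes
#' crossing `|rho| > cutoff` are tallied by sign.
#'
#' @param counts gene-by-sample count matrix.
#' @param cnMat gene-by-sample copy-number matrix (same gene order/ids).
#' @param minSamples minimum cohort size.
#' @param cutoff the moderate/high-correlation flag threshold.
#' @return data.frame per retained gene (gene, rho, p, flagged, sign) with
#'   tallies in `attr(, "tallies")`.
#' @export
cnExpressionCorrelation <- function(counts, cnMat, minSamples = 5,
                                    cutoff = 0.5) {
  common <- intersect(rownames(counts), rownames(cnMat))
  norm <- cpmNormalize(counts[common, , drop = FALSE])
  cn <- cnMat[common, colnames(counts), drop = FALSE]
  n <- ncol(norm)
  keep <- apply(cn, 1, function(x) sum(!is.na(x)) >= minSamples && stats::sd(x, na.rm = TRUE) > 0)
  res <- lapply(which(keep), function(i) {
    ct <- suppressWarnings(stats::cor.test(cn[i, ], norm[i, ],
                                           method = "spearman", exact = FALSE))
    data.frame(gene = common[i], rho = unname(ct$estimate), p = ct$p.value)
  })
  df <- if (length(res)) do.call(rbind, c(res, list(make.row.names = FALSE))) else
    data.frame(gene = character(), rho = numeric(), p = numeric())
  df$flagged <- !is.na(df$rho) & abs(df$rho) > cutoff
  df$sign <- ifelse(df$rho > 0, "positive", "negative")
  attr(df, "tallies") <- c(positive = sum(df$flagged & df$sign == "positive"),
                           negative = sum(df$flagged & df$sign == "negative"))
  df
}

#' Rank-based two-group differential expression
#'
#' Per-gene Mann-Whitney test on log2 CPM, Benjamini-Hochberg correction,
#' and log2 fold change of group CPM means (second factor level over the
#' first). Genes with `|FC| > fcCutoff` and `q < qCutoff` are flagged as
#' differentially expressed.
#'
#' @param counts gene-by-sample count matrix.
#' @param groups factor (or coercible) of length ncol(counts) with exactly
#'   two levels, each with at least 2 samples.
#' @param fcCutoff fold-change cutoff (default 2).
#' @param qCutoff BH q-value cutoff (default 0.05).
#' @return data.frame per gene: gene, log2FC, p, q, deg.
#' @export
twoGroupDifferential <- function(counts, groups, fcCutoff = 2, qCutoff = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups required")
  if (any(table(groups) < 2)) stop("each group needs at least 2 samples")
  norm <- cpmNormalize(counts)
  cpm <- cpmNormalize(counts, log = FALSE)
  g1 <- groups == levels(groups)[1]; g2 <- groups == levels(groups)[2]
  p <- apply(norm, 1, function(x)
    suppressWarnings(stats::wilcox.test(x[g2], x[g1], exact = FALSE)$p.value))
  p[is.na(p)] <- 1
  lfc <- log2((rowMeans(cpm[, g2, drop = FALSE]) + 0.5) /
                (rowMeans(cpm[, g1, drop = FALSE]) + 0.5))
  q <- stats::p.adjust(p, method = "BH")
  data.frame(gene = rownames(counts), log2FC = lfc, p = p, q = q,
             deg = abs(lfc) > log2(fcCutoff) & q < qCutoff,
             row.names = NULL)
}

#' Chromosomal distribution of differentially expressed genes
#'
#' Counts up- and down-regulated DEGs per chromosome and tests each
#' chromosome and direction for enrichment against the genome-wide DEG rate
#' with a one-sided binomial test, BH-corrected within direction.
#'
#' @param diffRes result of [twoGroupDifferential()].
#' @param model a [GenomeModel-class] with genes loaded.
#' @return data.frame per chromosome: chrom, nGenes, up, down, pUp, pDown,
#'   qUp, qDown.
#' @export
chromosomeDistributionOfDegs <- function(diffRes, model) {
  g <- model@genes
  chrom <- as.character(seqnames(g))[match(diffRes$gene, g$gene_id)]
  ch <- model@chromosomes$chrom
  up <- diffRes$deg & diffRes$log2FC > 0
  dn <- diffRes$deg & diffRes$log2FC < 0
  nGenes <- as.integer(table(factor(chrom, levels = ch)))
  nUp <- as.integer(table(factor(chrom[up], levels = ch)))
  nDn <- as.integer(table(factor(chrom[dn], levels = ch)))
  rateUp <- sum(nUp) / sum(nGenes); rateDn <- sum(nDn) / sum(nGenes)
  btest <- function(x, n, r) {
    if (n == 0 || r == 0) return(1)
    stats::binom.test(x, n, p = r, alternative = "greater")$p.value
  }
  pUp <- mapply(btest, nUp, nGenes, rateUp)
  pDn <- mapply(btest, nDn, nGenes, rateDn)
  data.frame(chrom = ch, nGenes = nGenes, up = nUp, down = nDn,
             pUp = pUp, pDown = pDn,
             qUp = stats::p.adjust(pUp, "BH"), qDown = stats::p.adjust(pDn, "BH"))
}

#' Correlate CpG-category methylation with genomic instability
#'
#' For each sample and CpG category (island/shore/shelf/open_sea and the
#' seven gene regions), the median beta value is computed; each category's
#' median profile is Spearman-correlated with the per-sample CNA count.
#'
#' @param meth probe-by-sample beta matrix (rownames = probe ids).
#' @param model a [GenomeModel-class] with probes loaded.
#' @param metrics data.frame from [cohortInstability()] (columns sample,
#'   cnaCount), rows matching the columns of `meth`.
#' @return data.frame per category: category, type, rho, p (NA when
#'   undefined, e.g. single-sample cohorts).
#' @export
methylationCategoryCorrelation <- function(meth, model, metrics) {
  p <- model@probes[match(rownames(meth), model@probes$probe_id)]
  x <- metrics$cnaCount[match(colnames(meth), metrics$sample)]
  cats <- list(island_category = c("island", "shore", "shelf", "open_sea"),
               gene_region = c("tss1500", "tss200", "utr5", "exon1", "body",
                               "utr3", "intergenic"))
  rows <- list()
  for (type in names(cats)) {
    for (cat in cats[[type]]) {
      sel <- mcols(p)[[type]] == cat
      rho <- pv <- NA_real_
      if (sum(sel) >= 3 && length(x) >= 3 && stats::sd(x) > 0) {
        med <- apply(meth[sel, , drop = FALSE], 2, stats::median)
        if (stats::sd(med) > 0) {
          ct <- suppressWarnings(stats::cor.test(x, med, method = "spearman",
                                                 exact = FALSE))
          rho <- unname(ct$estimate); pv <- ct$p.value
        }
      }
      rows[[paste(type, cat)]] <- data.frame(category = cat, type = type,
                                             rho = rho, p = pv)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Band-level correlation between methylation and copy number
#'
#' For each band, the band's integer copy number across samples is Pearson-
#' correlated with the per-sample median beta value of the band's filtered
#' probes (CpG-island probes or gene-5' probes). Bands with fewer than
#' `minProbes` probes or zero copy-number variance are NA.
#'
#' @param meth probe-by-sample beta matrix.
#' @param bm a [BandCnaMatrix-class] (columns matching `meth`).
#' @param model a [GenomeModel-class] with probes loaded.
#' @param probeFilter "island" (island_category == island) or "five_prime"
#'   (tss200/tss1500/utr5/exon1).
#' @param minProbes minimum probes per band.
#' @return data.frame per band: band, chrom, nProbes, r, p.
#' @export
bandMethylationCnCorrelation <- function(meth, bm, model,
                                         probeFilter = c("island", "five_prime"),
                                         minProbes = 3) {
  probeFilter <- match.arg(probeFilter)
  p <- model@probes[match(rownames(meth), model@probes$probe_id)]
  sel <- if (probeFilter == "island") p$island_category == "island" else
    p$gene_region %in% c("tss200", "tss1500", "utr5", "exon1")
  bandIdx <- findOverlaps(p, bm@bands, select = "first")
  cn <- bm@cn[, colnames(meth), drop = FALSE]
  out <- lapply(seq_along(bm@bands), function(bi) {
    rows <- which(sel & !is.na(bandIdx) & bandIdx == bi)
    r <- pv <- NA_real_
    if (length(rows) >= minProbes && stats::sd(cn[bi, ]) > 0) {
      med <- apply(meth[rows, , drop = FALSE], 2, stats::median)
      if (stats::sd(med) > 0) {
        ct <- suppressWarnings(stats::cor.test(cn[bi, ], med, method = "pearson"))
        r <- unname(ct$estimate); pv <- ct$p.value
      }
    }
    data.frame(band = bm@bands$name[bi],
               chrom = as.character(seqnames(bm@bands))[bi],
               nProbes = length(rows), r = r, p = pv)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
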