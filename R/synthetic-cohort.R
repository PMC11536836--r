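## Synthetic cohort generator: ground-truth karyotypes for four archetypes
## and emission of all five data layers (binned read depth, SNP LRR/BAF,
## expression counts, methylation beta values) with the statistical
## structure the downstream analysis assumes.

#' Configuration for a synthetic cohort
#'
#' Defaults encode the study conditions the package targets: a 40-sample
#' cohort split into 15 WGD-like high-aneuploidy samples, 6 samples with
#' chromosome-11 monosomy, 3 multi-deletion samples and 16 near-stable
#' samples; purity 0.5-0.9; read-depth bins of 10 kb. Gains are placed
#' preferentially on gene-poor chromosomes and losses on gene-dense ones,
#' expression is dosage-coupled, and deletions couple to CpG-island /
#' 5'-region hypermethylation.
#'
#' @param nWgd,nChr11Loss,nMultidel,nStable archetype group sizes (>= 0).
#' @param purityRange sampling range for per-sample tumor purity, in (0, 1].
#' @param depthPerCopy expected read count per haploid copy per bin.
#' @param binSize read-depth bin size in bp.
#' @param rdSize negative-binomial size (inverse dispersion) of bin counts.
#' @param lrrSd,bafSd Gaussian noise sd of the SNP-array LRR and BAF signals.
#' @param snpDensity SNPs per kb.
#' @param exprSlope dosage slope: expression mean scales as (CN/2)^slope.
#' @param exprDispersion negative-binomial dispersion of expression counts.
#' @param dosageInsensitiveFrac fraction of genes whose expression ignores
#'   copy number.
#' @param compensation if TRUE, the dosage slope is attenuated by 2/ploidy in
#'   high-ploidy samples (transcriptome-wide compensation mode).
#' @param methDeltaBeta beta-value shift added to CpG-island and gene-5'
#'   probes lying on segments with total copy number < 2 (scaled by purity).
#' @param betaPrecision precision of the beta distributions for probe
#'   baselines.
#' @param focalLenRange length range (bp) for focal events, on the scaled
#'   genome frame.
#' @param genomeScale the division factor of the genome model the cohort is
#'   simulated on; carried so segment lengths can be mapped back to
#'   real-genome size classes (see [encodeSegments()]).
#' @param seed mandatory integer random seed.
#' @return a list of class `CohortConfig`.
#' @export
cohortConfig <- function(nWgd = 15, nChr11Loss = 6, nMultidel = 3, nStable = 16,
                         purityRange = c(0.5, 0.9), depthPerCopy = 50,
                         binSize = 1e4, rdSize = 30, lrrSd = 0.13, bafSd = 0.03,
                         snpDensity = 0.2, exprSlope = 1, exprDispersion = 0.1,
                         dosageInsensitiveFrac = 0.2, compensation = FALSE,
                         methDeltaBeta = 0.25, betaPrecision = 30,
                         focalLenRange = c(4e5, 2e6), genomeScale = 35,
                         seed) {
  if (missing(seed) || is.null(seed)) stop("a random seed is mandatory")
  sizes <- c(nWgd, nChr11Loss, nMultidel, nStable)
  if (any(sizes < 0)) stop("group sizes must be >= 0")
  if (any(purityRange <= 0) || any(purityRange > 1) ||
      purityRange[1] > purityRange[2])
    stop("purityRange must be within (0, 1] and ordered")
  if (depthPerCopy <= 0) stop("depthPerCopy must be positive")
  cfg <- list(nWgd = nWgd, nChr11Loss = nChr11Loss, nMultidel = nMultidel,
              nStable = nStable, purityRange = purityRange,
              depthPerCopy = depthPerCopy, binSize = binSize, rdSize = rdSize,
              lrrSd = lrrSd, bafSd = bafSd, snpDensity = snpDensity,
              exprSlope = exprSlope, exprDispersion = exprDispersion,
              dosageInsensitiveFrac = dosageInsensitiveFrac,
              compensation = compensation, methDeltaBeta = methDeltaBeta,
              betaPrecision = betaPrecision, focalLenRange = focalLenRange,
              genomeScale = genomeScale, seed = as.integer(seed))
  class(cfg) <- "CohortConfig"
  cfg
}

# diploid 1+1 tiling of every autosome
.diploidTile <- function(model) {
  ch <- model@chromosomes
  gr <- GRanges(ch$chrom, IRanges(1, ch$length), cnA = 1L, cnB = 1L)
  seqlevels(gr) <- ch$chrom
  seqlengths(gr) <- stats::setNames(ch$length, ch$chrom)
  gr
}

# overlay events (GRanges with cnA, cnB; later events win) on a base tiling
.overlayEvents <- function(base, events) {
  if (!length(events)) return(base)
  all <- c(base, events)
  pieces <- GenomicRanges::disjoin(all)
  hits <- findOverlaps(pieces, all)
  lastCover <- tapply(subjectHits(hits), queryHits(hits), max)
  idx <- as.integer(lastCover[as.character(seq_along(pieces))])
  pieces$cnA <- all$cnA[idx]
  pieces$cnB <- all$cnB[idx]
  pieces <- GenomicRanges::sort(pieces)
  # merge adjacent pieces with identical allele copy numbers
  key <- paste(seqnames(pieces), pieces$cnA, pieces$cnB)
  newRun <- c(TRUE, key[-1] != key[-length(key)] |
                start(pieces)[-1] != end(pieces)[-length(pieces)] + 1)
  grp <- cumsum(newRun)
  df <- data.frame(chrom = as.character(seqnames(pieces)), start = start(pieces),
                   end = end(pieces), cnA = pieces$cnA, cnB = pieces$cnB, grp = grp)
  agg <- do.call(rbind, lapply(split(df, df$grp), function(d)
    data.frame(chrom = d$chrom[1], start = min(d$start), end = max(d$end),
               cnA = d$cnA[1], cnB = d$cnB[1])))
  out <- GRanges(agg$chrom, IRanges(agg$start, agg$end),
                 cnA = as.integer(agg$cnA), cnB = as.integer(agg$cnB))
  seqlevels(out) <- seqlevels(base)
  seqlengths(out) <- seqlengths(base)
  GenomicRanges::sort(out)
}

# per-chromosome gene density (genes per Mb) used to bias event placement
.chromGeneDensity <- function(model) {
  ch <- model@chromosomes
  if (!length(model@genes)) return(stats::setNames(rep(1, nrow(ch)), ch$chrom))
  cnt <- table(factor(as.character(seqnames(model@genes)), levels = ch$chrom))
  stats::setNames(as.numeric(cnt) / (ch$length / 1e6), ch$chrom)
}

.fullLevels <- function(gr, model) {
  seqlevels(gr) <- model@chromosomes$chrom
  gr
}

# recurrent focal-gain hotspot loci: the gene-poorest bands, at most one
# per chromosome, derived deterministically from the model (focal
# duplications in these tumors concentrate at recurrent gene-poor loci)
.gainHotspots <- function(model, k = 10) {
  b <- model@bands
  dens <- if (length(model@genes)) geneDensityPerBand(model) else
    rep(0, length(b))
  o <- order(dens, width(b) * -1)
  sel <- integer()
  seen <- character()
  for (i in o) {
    cn <- as.character(seqnames(b))[i]
    if (cn %in% seen) next
    sel <- c(sel, i); seen <- c(seen, cn)
    if (length(sel) >= k) break
  }
  b[sel]
}

# one focal event, centered on a cytogenetic band. Gains are recurrent:
# with high probability they center on one of the fixed gene-poor hotspot
# loci; losses center on a band drawn with probability proportional to its
# gene density (gene-dense territory is where deletions matter and where
# they are seen).
.focalEvent <- function(model, type, lenRange, occupied = NULL) {
  ch <- model@chromosomes
  hot <- .gainHotspots(model)
  bandDens <- if (length(model@genes)) geneDensityPerBand(model) else
    rep(1, length(model@bands))
  for (try in 1:25) {
    h <- if (type == "gain" && stats::runif(1) < 0.8 && length(hot)) {
      hot[sample(length(hot), 1)]
    } else if (type == "loss") {
      model@bands[sample(length(model@bands), 1, prob = bandDens + 0.05)]
    } else {
      model@bands[sample(length(model@bands), 1,
                         prob = 1 / (bandDens + 0.2))]
    }
    cn <- as.character(seqnames(h))
    L <- ch$length[match(cn, ch$chrom)]
    len <- round(stats::runif(1, lenRange[1], min(lenRange[2], L - 2)))
    ctr <- floor((start(h) + end(h)) / 2 + stats::runif(1, -2e5, 2e5))
    s <- max(1, min(ctr - len %/% 2, L - len))
    ev <- GRanges(cn, IRanges(s, s + len - 1))
    if (is.null(occupied) || !any(overlapsAny(ev, occupied))) break
  }
  if (type == "loss") { ev$cnA <- 1L; ev$cnB <- 0L } else { ev$cnA <- 2L; ev$cnB <- 1L }
  .fullLevels(ev, model)
}

#' Simulate one ground-truth karyotype
#'
#' Draws a [TrueKaryotype-class] for one of four archetypes:
#' \describe{
#'   \item{wgd_high_aneuploidy}{whole-chromosome / whole-arm gains placed
#'     preferentially on gene-poor chromosomes until a per-sample target
#'     fraction of the genome (uniform in 0.5-0.8, reflecting the spread of
#'     CNA coverage seen in high-aneuploidy tumors) is gained; gained units
#'     are total copy 3 (2+1) or 4 (split 60\% 2+2, 20\% 3+1, 20\% 4+0 —
#'     the balanced, pre-WGD-trisomy and doubled-LOH states of a
#'     genome-doubled tumor); no losses.}
#'   \item{chr11_loss}{monosomy of all of chromosome 11 (1+0) plus at most
#'     two focal events.}
#'   \item{multidel}{monosomies / arm losses drawn from 1p, 15q, 16 and 22.}
#'   \item{stable}{0-3 focal events, otherwise diploid.}
#' }
#' Uses the current RNG stream (seed it, or call via [simulateCohort()]).
#'
#' @param model a [GenomeModel-class].
#' @param archetype one of the four archetype names.
#' @param purity tumor purity recorded in the karyotype.
#' @return a [TrueKaryotype-class].
#' @export
simulateKaryotype <- function(model,
                              archetype = c("wgd_high_aneuploidy", "chr11_loss",
                                            "multidel", "stable"),
                              purity = 1) {
  archetype <- match.arg(archetype)
  ch <- model@chromosomes
  genomeLen <- sum(ch$length)
  dens <- .chromGeneDensity(model)
  events <- .fullLevels(GRanges(), model)
  cfgLen <- c(4e5, 2e6)

  if (archetype == "wgd_high_aneuploidy") {
    pool <- ch$chrom
    gained <- 0
    target <- stats::runif(1, 0.5, 0.8)
    while (gained / genomeLen < target && length(pool)) {
      pick <- if (length(pool) == 1) pool else
        sample(pool, 1, prob = 1 / pmax(dens[pool], 1e-6))
      pool <- setdiff(pool, pick)
      whole <- stats::runif(1) < 0.7
      reg <- if (whole) {
        GRanges(pick, IRanges(1, ch$length[match(pick, ch$chrom)]))
      } else {
        a <- model@arms[as.character(seqnames(model@arms)) == pick]
        a[sample(length(a), 1)]
      }
      tot <- sample(c(3L, 4L), 1)
      if (tot == 3L) { cnA <- 2L; cnB <- 1L } else {
        cnB <- sample(c(2L, 1L, 0L), 1, prob = c(0.6, 0.2, 0.2))
        cnA <- 4L - cnB
      }
      reg <- .fullLevels(granges(reg), model); reg$cnA <- cnA; reg$cnB <- cnB
      events <- c(events, reg)
      gained <- gained + sum(width(reg))
    }
  } else if (archetype == "chr11_loss") {
    if (!"chr11" %in% ch$chrom) stop("model has no chromosome 11")
    reg <- .fullLevels(GRanges("chr11", IRanges(1, ch$length[match("chr11", ch$chrom)]),
                               cnA = 1L, cnB = 0L), model)
    events <- c(events, reg)
    nF <- sample(0:2, 1)
    for (k in seq_len(nF)) {
      ev <- .focalEvent(model, sample(c("gain", "loss"), 1), cfgLen, events)
      events <- c(events, ev)
    }
  } else if (archetype == "multidel") {
    units <- list(c("chr1", "p"), c("chr15", "q"), c("chr16", "whole"),
                  c("chr22", "whole"))
    units <- Filter(function(u) u[1] %in% ch$chrom, units)
    if (!length(units)) stop("model lacks the multidel target chromosomes")
    k <- min(length(units), sample(2:4, 1))
    for (u in units[sample(length(units), k)]) {
      reg <- if (u[2] == "whole") {
        GRanges(u[1], IRanges(1, ch$length[match(u[1], ch$chrom)]))
      } else {
        a <- model@arms
        granges(a[as.character(seqnames(a)) == u[1] & a$arm == u[2]])
      }
      reg <- .fullLevels(granges(reg), model); reg$cnA <- 1L; reg$cnB <- 0L
      events <- c(events, reg)
    }
  } else { # stable
    # nearly every tumor carries at least one CNA; fully flat genomes are rare
    nF <- sample(0:3, 1, prob = c(0.1, 0.3, 0.3, 0.3))
    for (k in seq_len(nF)) {
      ev <- .focalEvent(model, sample(c("gain", "loss"), 1, prob = c(0.6, 0.4)),
                        cfgLen, events)
      events <- c(events, ev)
    }
  }

  seqs <- .overlayEvents(.diploidTile(model), events)
  new("TrueKaryotype", sampleId = "sample", purity = purity, segments = seqs)
}

# total and B-allele copy number of a karyotype at given positions
.cnAt <- function(kt, chrom, pos) {
  q <- GRanges(chrom, IRanges(pos, pos))
  hits <- findOverlaps(q, kt@segments, select = "first")
  s <- kt@segments
  list(total = s$cnA[hits] + s$cnB[hits], b = s$cnB[hits])
}

#' Emit binned read-depth counts for one sample
#'
#' Per-bin counts are negative binomial with mean
#' `depthPerCopy * (purity * CN + 2 * (1 - purity))`, i.e. a pure diploid
#' bin has mean `2 * depthPerCopy`.
#'
#' @param kt a [TrueKaryotype-class].
#' @param model a [GenomeModel-class].
#' @param config a [cohortConfig()] list.
#' @return data.frame with chrom, start, end (0-based half-open), count.
#' @export
emitReadDepth <- function(kt, model, config) {
  if (config$depthPerCopy <= 0) stop("depthPerCopy must be positive")
  ch <- model@chromosomes
  out <- lapply(seq_len(nrow(ch)), function(i) {
    L <- ch$length[i]; bs <- config$binSize
    s0 <- seq(0, L - bs, by = bs)
    mids <- s0 + bs %/% 2
    cn <- .cnAt(kt, ch$chrom[i], mids + 1)$total
    mu <- config$depthPerCopy * (kt@purity * cn + 2 * (1 - kt@purity))
    data.frame(chrom = ch$chrom[i], start = s0, end = s0 + bs,
               count = stats::rnbinom(length(mu), mu = mu, size = config$rdSize))
  })
  do.call(rbind, out)
}

#' Emit SNP-array signals (LRR and BAF) for one sample
#'
#' LRR is `log2((purity * CN + 2(1-purity)) / 2)` plus Gaussian noise; half
#' the SNPs are heterozygous with BAF centered at
#' `(purity * CN_B + (1-purity)) / (purity * CN + 2(1-purity))` (the B allele
#' is the minor or major parental allele with equal probability, so allelic
#' imbalance produces mirrored BAF clusters); homozygous SNPs sit at 0/1.
#' BAF is truncated to [0, 1]. Regions with no DNA at all (homozygous
#' deletion at purity 1) emit a floored LRR and uniform BAF.
#'
#' @inheritParams emitReadDepth
#' @return data.frame with chrom, pos (0-based), lrr, baf, het (truth flag).
#' @export
emitSnpSignals <- function(kt, model, config) {
  stopifnot(config$snpDensity > 0)
  ch <- model@chromosomes
  out <- lapply(seq_len(nrow(ch)), function(i) {
    L <- ch$length[i]
    n <- max(2L, round(L / 1000 * config$snpDensity))
    pos <- sort(sample.int(L - 1L, n))
    cn <- .cnAt(kt, ch$chrom[i], pos + 1)
    denom <- kt@purity * cn$total + 2 * (1 - kt@purity)
    lrr <- ifelse(denom > 0, log2(pmax(denom, 1e-6) / 2), -5) +
      stats::rnorm(n, 0, config$lrrSd)
    het <- stats::runif(n) < 0.5
    bAllele <- ifelse(stats::runif(n) < 0.5, cn$b, cn$total - cn$b)
    bafMean <- ifelse(het,
                      ifelse(denom > 0,
                             (kt@purity * bAllele + (1 - kt@purity)) / denom,
                             NA_real_),
                      ifelse(stats::runif(n) < 0.5, 0, 1))
    baf <- bafMean + stats::rnorm(n, 0, config$bafSd)
    noDna <- is.na(bafMean)
    baf[noDna] <- stats::runif(sum(noDna))
    data.frame(chrom = ch$chrom[i], pos = pos, lrr = lrr,
               baf = pmin(1, pmax(0, baf)), het = het)
  })
  do.call(rbind, out)
}

# bulk (tumor + admixed normal) copy number experienced by each gene
.geneBulkCN <- function(kt, model) {
  g <- model@genes
  mids <- floor((start(g) + end(g)) / 2)
  cn <- .cnAt(kt, as.character(seqnames(g)), mids)$total
  kt@purity * cn + 2 * (1 - kt@purity)
}

#' Emit an expression count matrix for a cohort
#'
#' Gene-level counts are negative binomial with mean
#' `baseline_g * (bulkCN_g / 2)^slope` for dosage-sensitive genes; a
#' configurable fraction of genes ignores copy number. Baselines are
#' log-normal. With `compensation = TRUE` the slope is attenuated by
#' `2 / ploidy` per sample.
#'
#' @param kts list of [TrueKaryotype-class] (one per sample).
#' @param model a [GenomeModel-class] with genes.
#' @param config a [cohortConfig()] list.
#' @return list with `counts` (gene x sample matrix) and `dosageSensitive`
#'   (logical ground-truth vector per gene).
#' @export
emitExpression <- function(kts, model, config) {
  g <- model@genes
  nG <- length(g); nS <- length(kts)
  baseline <- exp(stats::rnorm(nG, log(200), 1))
  insens <- rep(FALSE, nG)
  nIns <- floor(config$dosageInsensitiveFrac * nG)
  if (nIns > 0) insens[sample.int(nG, nIns)] <- TRUE
  counts <- matrix(0L, nG, nS,
                   dimnames = list(g$gene_id,
                                   vapply(kts, function(k) k@sampleId, "")))
  for (j in seq_len(nS)) {
    cn <- .geneBulkCN(kts[[j]], model)
    slope <- config$exprSlope
    if (isTRUE(config$compensation))
      slope <- slope * 2 / max(impliedPloidy(kts[[j]]), 2)
    mu <- baseline * ifelse(insens, 1, (cn / 2)^slope)
    counts[, j] <- stats::rnbinom(nG, mu = mu, size = 1 / config$exprDispersion)
  }
  list(counts = counts, dosageSensitive = !insens)
}

# probes counted as CpG-island / gene-5' regulatory context
.fivePrimeProbes <- function(model) {
  p <- model@probes
  p$island_category == "island" |
    p$gene_region %in% c("tss200", "tss1500", "utr5", "exon1")
}

#' Emit a methylation beta-value matrix for a cohort
#'
#' Probe baselines are beta-distributed: low (mean 0.12) for CpG-island and
#' gene-5' probes, high (mean 0.75) elsewhere. Probes lying on segments with
#' tumor total copy number below 2 gain `methDeltaBeta * purity` on island
#' and 5'-region probes only (deletion-coupled hypermethylation); all values
#' stay in [0, 1].
#'
#' @inheritParams emitExpression
#' @return probe x sample matrix of beta values.
#' @export
emitMethylation <- function(kts, model, config) {
  p <- model@probes
  nP <- length(p); nS <- length(kts)
  low <- .fivePrimeProbes(model)
  baseMu <- ifelse(low, 0.12, 0.75)
  beta <- matrix(0, nP, nS,
                 dimnames = list(p$probe_id,
                                 vapply(kts, function(k) k@sampleId, "")))
  nu <- config$betaPrecision
  for (j in seq_len(nS)) {
    cn <- .cnAt(kts[[j]], as.character(seqnames(p)), start(p))$total
    mu <- baseMu
    shift <- low & cn < 2
    mu[shift] <- pmin(0.95, mu[shift] + config$methDeltaBeta * kts[[j]]@purity)
    beta[, j] <- stats::rbeta(nP, mu * nu, (1 - mu) * nu)
  }
  beta
}

#' Simulate a full synthetic cohort
#'
#' Seeds the RNG from `config$seed`, draws per-sample purities and
#' archetypes (WGD-like, chromosome-11 monosomy, multi-deletion, stable in
#' that order) and emits all five layers. The same config always yields a
#' byte-identical cohort.
#'
#' @param config a [cohortConfig()] list.
#' @param model a [GenomeModel-class]; defaults to [syntheticGenomeModel()].
#' @param layers which data layers to emit; restrict to speed up tests.
#' @return a [SyntheticCohort-class].
#' @export
simulateCohort <- function(config, model = syntheticGenomeModel(),
                           layers = c("readDepth", "snp", "expression",
                                      "methylation")) {
  stopifnot(inherits(config, "CohortConfig"))
  layers <- match.arg(layers, several.ok = TRUE)
  set.seed(config$seed)
  arche <- rep(c("wgd_high_aneuploidy", "chr11_loss", "multidel", "stable"),
               c(config$nWgd, config$nChr11Loss, config$nMultidel, config$nStable))
  n <- length(arche)
  kts <- list(); rd <- list(); snp <- list()
  if (n) {
    pur <- stats::runif(n, config$purityRange[1], config$purityRange[2])
    for (i in seq_len(n)) {
      kt <- simulateKaryotype(model, arche[i], purity = pur[i])
      kt@sampleId <- sprintf("S%02d", i)
      kts[[kt@sampleId]] <- kt
      if ("readDepth" %in% layers) rd[[kt@sampleId]] <- emitReadDepth(kt, model, config)
      if ("snp" %in% layers) snp[[kt@sampleId]] <- emitSnpSignals(kt, model, config)
    }
  }
  expr <- matrix(0L, 0, 0); meth <- matrix(0, 0, 0); sens <- logical()
  if (n && "expression" %in% layers) {
    e <- emitExpression(kts, model, config)
    expr <- e$counts; sens <- e$dosageSensitive
  }
  if (n && "methylation" %in% layers) meth <- emitMethylation(kts, model, config)
  cfg <- unclass(config)
  cfg$dosageSensitive <- sens
  out <- new("SyntheticCohort", model = model, config = cfg, karyotypes = kts,
             archetypes = stats::setNames(arche, names(kts)), readDepth = rd,
             snp = snp, expression = expr, methylation = meth)
  out
}

#' Convert a ground-truth karyotype into a perfect virtual karyotype
#'
#' Re-expresses a [TrueKaryotype-class] as a [VirtualKaryotype-class] with
#' exact integer calls — the ideal caller. Used to exercise downstream
#' stages (band matrices, recurrence, signatures, dosage integration)
#' independently of the signal-reconstruction stages.
#'
#' @param kt a [TrueKaryotype-class].
#' @param baseline copy number against which the `class` encoding is
#'   computed (default 2; `class2` is always diploid-relative).
#' @return a [VirtualKaryotype-class] with `source = "truth"`.
#' @export
asVirtualKaryotype <- function(kt, baseline = 2) {
  s <- kt@segments
  tot <- s$cnA + s$cnB
  s$totalCN <- as.integer(tot)
  s$minorCN <- as.integer(pmin(s$cnA, s$cnB))
  s$class <- ifelse(tot > baseline, "gain",
                    ifelse(tot < baseline, "loss", "neutral"))
  s$class2 <- ifelse(tot > 2, "gain", ifelse(tot < 2, "loss", "neutral"))
  s$nMarkers <- NA_integer_
  s$lrr <- NA_real_
  s$bafDev <- NA_real_
  s$flagged <- FALSE
  new("VirtualKaryotype", sampleId = kt@sampleId, purity = kt@purity,
      ploidy = impliedPloidy(kt), segments = s, source = "truth",
      bafInformed = TRUE)
}

#' Genome fraction altered in a ground-truth karyotype
#'
#' Fraction of the autosomal genome whose total copy number differs from 2.
#' @param kt a [TrueKaryotype-class].
#' @return a fraction in [0, 1].
#' @export
trueFractionAltered <- function(kt) {
  s <- kt@segments
  sum(width(s)[s$cnA + s$cnB != 2L]) / sum(width(s))
}

#' Write a synthetic cohort to disk
#'
#' Emits per-sample read-depth and SNP TSVs, expression and methylation
#' matrices, a ground-truth SEG file (1-based inclusive coordinates) and a
#' JSON manifest echoing the configuration and seed.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(x, file.path(dir, f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  for (id in names(cohort@karyotypes)) {
    if (length(cohort@readDepth)) wt(cohort@readDepth[[id]], paste0(id, "_readdepth.tsv"))
    if (length(cohort@snp)) wt(cohort@snp[[id]], paste0(id, "_snp.tsv"))
  }
  if (nrow(cohort@expression))
    utils::write.table(cohort@expression, file.path(dir, "expression_counts.tsv"),
                       sep = "\t", quote = FALSE)
  if (nrow(cohort@methylation))
    utils::write.table(round(cohort@methylation, 4),
                       file.path(dir, "methylation_beta.tsv"),
                       sep = "\t", quote = FALSE)
  seg <- do.call(rbind, lapply(cohort@karyotypes, function(kt) {
    s <- kt@segments
    data.frame(sample = kt@sampleId, chrom = as.character(seqnames(s)),
               start = start(s), end = end(s), cnA = s$cnA, cnB = s$cnB,
               total = s$cnA + s$cnB)
  }))
  wt(seg, "ground_truth.seg")
  cfg <- cohort@config
  cfg$dosageSensitive <- NULL
  jsonlite::write_json(list(config = cfg,
                            archetypes = as.list(cohort@archetypes)),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
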