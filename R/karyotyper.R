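## Purity/ploidy lattice fitting, integer copy-number assignment, platform
## integration and exclusion filtering.
##
## The signal model: LRR and read-depth log ratios are *relative* signals
## (arrays are intensity-normalized, sequencing depth is arbitrary), so the
## observed log ratio of a segment with total copy number n in a tumor of
## purity p and baseline ploidy psi is
##     LRR*(n) = log2((p n + 2(1-p))/2) - log2((p psi + 2(1-p))/2)
## after length-weighted centering, and the expected mirrored heterozygous
## BAF deviation of an (n, b) state is |1/2 - (p b + (1-p)) / (p n + 2(1-p))|.

.LRR_FLOOR <- -5  # model log-ratio floor for zero-DNA states (array saturation)

# allele-specific lattice up to maxTotal: all (total n, minor b) states
.lattice <- function(maxTotal) {
  n <- unlist(lapply(0:maxTotal, function(t) rep(t, t %/% 2 + 1)))
  b <- unlist(lapply(0:maxTotal, function(t) 0:(t %/% 2)))
  list(n = n, b = b)
}

.modelLogR <- function(n, p) {
  v <- log2((p * n + 2 * (1 - p)) / 2)
  v[!is.finite(v) | v < .LRR_FLOOR] <- .LRR_FLOOR
  v
}

.modelBafDev <- function(n, b, p) {
  denom <- p * n + 2 * (1 - p)
  dev <- abs(0.5 - (p * b + (1 - p)) / denom)
  dev[denom <= 0] <- 0  # no DNA: BAF uninformative
  dev
}

# expected observed mean of |BAF - 1/2| when the true deviation is mu and
# per-SNP noise sd is sigma: the folded-normal mean. Without this the noise
# floor (sigma * sqrt(2/pi) even for balanced segments) biases the grid
# search toward dense low-purity lattices.
.foldedDev <- function(mu, sigma) {
  if (is.na(sigma) || sigma <= 0) return(mu)
  sigma * sqrt(2 / pi) * exp(-mu^2 / (2 * sigma^2)) +
    mu * (1 - 2 * stats::pnorm(-mu / sigma))
}

#' Fit tumor purity and baseline ploidy by lattice grid search
#'
#' Searches the (purity, ploidy) grid; for each candidate every segment is
#' mapped to its nearest integer (total, minor) lattice point under the
#' relative-LRR and BAF closed forms, and the objective is the
#' length-weighted squared distance (the BAF term enters only with
#' `useBaf = TRUE` and only for segments that have heterozygous-BAF
#' summaries). Candidates whose implied ploidy (length-weighted mean fitted
#' total copy number) strays more than 0.5 from the grid baseline are
#' rejected — the baseline must be self-consistent. Ties are broken toward
#' lower ploidy: candidates whose objective lies within the tie band
#' (`3 * minimum + tieTol`, i.e. the same noise floor up to grid snapping)
#' are considered equivalent, the branch around the lowest such ploidy is
#' selected, and that branch's own optimum is returned. The band is
#' relative because genome-doubling degeneracies (every allele count
#' doubled, purity p mapped to p/(2-p)) produce *exactly* equivalent fits
#' that differ only by noise and grid snapping; BAF evidence overrides the
#' preference when it is decisive, which is exactly how whole-genome
#' doubled samples get re-baselined.
#'
#' @param segs GRanges of segment calls with mcols `lrr`, `bafDev`,
#'   `nMarkers` (from [segmentSnp()] or [segmentReadDepth()]).
#' @param useBaf include the BAF channel in the objective.
#' @param purityGrid,ploidyGrid candidate grids.
#' @param maxTotal largest total copy number on the lattice.
#' @param tieTol absolute floor of the lower-ploidy tie band.
#' @param bafNoise per-SNP BAF noise sd used to unfold the mirrored-BAF
#'   deviation (default: the estimate stored by [segmentSnp()]).
#' @param maxHomdelFraction admissibility cap on the genome fraction a
#'   candidate may assign to total copy number 0: large homozygous
#'   deletions are lethal, and unconstrained zero-copy assignments admit
#'   degenerate low-purity interpretations in which the diploid bulk is
#'   "deleted" and every alteration becomes LOH.
#' @return a [PurityPloidyFit-class].
#' @export
fitPurityPloidy <- function(segs, useBaf = TRUE,
                            purityGrid = seq(0.2, 1.0, by = 0.01),
                            ploidyGrid = seq(1.5, 5.5, by = 0.05),
                            maxTotal = 8, tieTol = 1e-4, bafNoise = NULL,
                            maxHomdelFraction = 0.05) {
  if (is.null(segs) || !length(segs)) stop("no usable segments")
  if (is.null(bafNoise))
    bafNoise <- S4Vectors::metadata(segs)$bafNoise
  if (is.null(bafNoise) || is.na(bafNoise)) bafNoise <- 0
  w <- width(segs) / sum(width(segs))
  lrrOffset <- sum(w * segs$lrr)
  lrrC <- segs$lrr - lrrOffset
  obsDev <- segs$bafDev
  hasDev <- useBaf & !is.na(obsDev)
  lat <- .lattice(maxTotal)
  totals <- 0:maxTotal
  S <- length(segs)

  nCand <- length(purityGrid) * length(ploidyGrid)
  objV <- rep(Inf, nCand); pV <- psiV <- impV <- rep(NA_real_, nCand)
  ci <- 0L
  for (p in purityGrid) {
    A <- .modelLogR(totals, p)
    bafErr <- matrix(0, S, length(totals))
    if (any(hasDev)) {
      devTab <- .foldedDev(.modelBafDev(lat$n, lat$b, p), bafNoise)
      E <- (matrix(obsDev[hasDev], sum(hasDev), length(lat$n)) -
              matrix(devTab, sum(hasDev), length(lat$n), byrow = TRUE))^2
      for (t in totals) {
        cols <- which(lat$n == t)
        bafErr[hasDev, t + 1] <- if (length(cols) == 1) E[, cols] else
          do.call(pmin, as.data.frame(E[, cols, drop = FALSE]))
      }
    }
    for (psi in ploidyGrid) {
      Apsi <- log2((p * psi + 2 * (1 - p)) / 2)
      # residuals are scored in units of the local lattice spacing (the
      # LRR step between adjacent totals and the BAF step between adjacent
      # minor states at the baseline), so that dense low-purity lattices
      # gain no artificial advantage from small absolute residuals
      sL <- log2((p * (psi + 1) + 2 * (1 - p)) / (p * psi + 2 * (1 - p)))
      sB <- p / (p * psi + 2 * (1 - p))
      Lerr <- (matrix(lrrC, S, length(totals)) -
                 matrix(A - Apsi, S, length(totals), byrow = TRUE))^2
      tot <- Lerr / sL^2 + bafErr / sB^2
      bestN <- max.col(-tot, ties.method = "first") - 1L
      implied <- sum(w * bestN)
      if (abs(implied - psi) > 0.5) next
      if (sum(w[bestN == 0L]) > maxHomdelFraction) next
      ci <- ci + 1L
      objV[ci] <- sum(w * tot[cbind(seq_len(S), bestN + 1L)])
      pV[ci] <- p; psiV[ci] <- psi; impV[ci] <- implied
    }
  }
  if (ci == 0L) stop("no admissible (purity, ploidy) candidate")
  objV <- objV[seq_len(ci)]; pV <- pV[seq_len(ci)]
  psiV <- psiV[seq_len(ci)]; impV <- impV[seq_len(ci)]
  minObj <- min(objV)
  targetPsi <- min(psiV[objV <= 3 * minObj + tieTol])
  # the branch spans the grid neighborhood of the lowest equivalent ploidy;
  # competing degenerate interpretations (half/double purity families) sit
  # at implied ploidies at least ~0.2 away and must stay outside it
  branch <- which(abs(psiV - targetPsi) <= 0.1 + 1e-9)
  k <- branch[which.min(objV[branch])]
  new("PurityPloidyFit", purity = pV[k], ploidy = impV[k],
      psi = psiV[k], fit = objV[k],
      bafInformed = isTRUE(useBaf) && any(hasDev), lrrOffset = lrrOffset)
}

# nearest lattice state per segment under a fixed (purity, psi)
.assignLattice <- function(lrrC, obsDev, p, psi, maxTotal = 8, bafNoise = 0) {
  lat <- .lattice(maxTotal)
  Apsi <- log2((p * psi + 2 * (1 - p)) / 2)
  modelL <- .modelLogR(lat$n, p) - Apsi
  modelD <- .foldedDev(.modelBafDev(lat$n, lat$b, p), bafNoise)
  S <- length(lrrC)
  Lerr <- (matrix(lrrC, S, length(lat$n)) -
             matrix(modelL, S, length(lat$n), byrow = TRUE))^2
  Derr <- (matrix(ifelse(is.na(obsDev), 0, obsDev), S, length(lat$n)) -
             matrix(modelD, S, length(lat$n), byrow = TRUE))^2
  Derr[is.na(obsDev), ] <- 0
  sL <- log2((p * (psi + 1) + 2 * (1 - p)) / (p * psi + 2 * (1 - p)))
  sB <- p / (p * psi + 2 * (1 - p))
  k <- max.col(-(Lerr / sL^2 + Derr / sB^2), ties.method = "first")
  list(total = lat$n[k], minor = ifelse(is.na(obsDev), NA_integer_, lat$b[k]))
}

#' Assign integer allele-specific copy numbers to segments
#'
#' Maps each segment to the nearest (total, minor) lattice point under a
#' fitted purity/ploidy and attaches both CNA class encodings: `class`
#' relative to the rounded fitted ploidy and `class2` relative to the
#' diploid state. Segments without BAF summaries get `minorCN = NA`.
#'
#' @param segs GRanges of segment calls (`lrr`, `bafDev`, `nMarkers`).
#' @param fit a [PurityPloidyFit-class].
#' @param sampleId sample identifier for the returned karyotype.
#' @param source platform label carried into the karyotype.
#' @param offset "fit" reuses the centering offset stored in the fit (same
#'   platform); "recenter" recomputes the length-weighted mean from `segs`
#'   (use when assigning a different platform's segments under the same
#'   fit); or a numeric offset.
#' @param maxTotal largest total copy number on the lattice.
#' @return a [VirtualKaryotype-class].
#' @export
assignIntegerCopyNumber <- function(segs, fit, sampleId = "sample",
                                    source = unique(segs$source),
                                    offset = c("fit", "recenter"),
                                    maxTotal = 8) {
  if (!length(segs)) stop("no segments to assign")
  off <- if (is.numeric(offset)) offset else {
    offset <- match.arg(offset)
    if (offset == "fit") fit@lrrOffset else
      sum(width(segs) * segs$lrr) / sum(width(segs))
  }
  lrrC <- segs$lrr - off
  bafNoise <- S4Vectors::metadata(segs)$bafNoise
  if (is.null(bafNoise) || is.na(bafNoise)) bafNoise <- 0
  asg <- .assignLattice(lrrC, segs$bafDev, fit@purity, fit@psi, maxTotal,
                        bafNoise = bafNoise)
  base <- round(fit@ploidy)
  segs$totalCN <- as.integer(asg$total)
  segs$minorCN <- as.integer(asg$minor)
  segs$class <- ifelse(asg$total > base, "gain",
                       ifelse(asg$total < base, "loss", "neutral"))
  segs$class2 <- ifelse(asg$total > 2, "gain",
                        ifelse(asg$total < 2, "loss", "neutral"))
  if (is.null(segs$flagged)) segs$flagged <- FALSE
  new("VirtualKaryotype", sampleId = sampleId, purity = fit@purity,
      ploidy = fit@ploidy, segments = segs,
      source = if (length(source)) source[1] else "snp",
      bafInformed = fit@bafInformed)
}

# per-chromosome covered span of a set of karyotypes
.coveredSpan <- function(...) {
  segs <- do.call(c, lapply(list(...), function(k) granges(k@segments)))
  unlist(range(GenomicRanges::split(segs, seqnames(segs))))
}

# fill gaps with neutral baseline segments
.retileNeutral <- function(cna, span, baseTotal) {
  gaps <- intervalSubtract(span, cna)
  if (length(gaps)) {
    gaps$totalCN <- as.integer(baseTotal)
    gaps$minorCN <- as.integer(baseTotal %/% 2)
    gaps$class <- "neutral"
    gaps$class2 <- ifelse(baseTotal > 2, "gain",
                          ifelse(baseTotal < 2, "loss", "neutral"))
    gaps$nMarkers <- NA_integer_
    gaps$lrr <- NA_real_; gaps$bafDev <- NA_real_
    gaps$nHet <- NA_integer_; gaps$source <- "consensus"
    gaps$flagged <- FALSE
  }
  gaps
}

# short baseline filler pieces created by platform boundary jitter adopt
# the copy number of their wider neighbor, so they do not masquerade as
# independent CNA segments
.fillSmallGaps <- function(segs, fillerIdx, base, maxGap = 1e5) {
  if (!length(segs)) return(segs)
  segs <- GenomicRanges::sort(segs)
  chrom <- as.character(seqnames(segs))
  for (i in which(seq_along(segs) %in% fillerIdx & width(segs) < maxGap)) {
    nb <- integer()
    if (i > 1 && chrom[i - 1] == chrom[i] &&
        end(segs)[i - 1] + 1 == start(segs)[i]) nb <- c(nb, i - 1)
    if (i < length(segs) && chrom[i + 1] == chrom[i] &&
        end(segs)[i] + 1 == start(segs)[i + 1]) nb <- c(nb, i + 1)
    if (!length(nb)) next
    j <- nb[which.max(width(segs)[nb])]
    segs$totalCN[i] <- segs$totalCN[j]
    segs$minorCN[i] <- segs$minorCN[j]
    segs$class[i] <- ifelse(segs$totalCN[i] > base, "gain",
                            ifelse(segs$totalCN[i] < base, "loss", "neutral"))
    segs$class2[i] <- ifelse(segs$totalCN[i] > 2, "gain",
                             ifelse(segs$totalCN[i] < 2, "loss", "neutral"))
  }
  segs
}

# merge adjacent segments carrying identical copy-number state
.consolidateSegments <- function(segs) {
  if (length(segs) < 2) return(segs)
  segs <- GenomicRanges::sort(segs)
  key <- paste(as.character(seqnames(segs)), segs$totalCN,
               ifelse(is.na(segs$minorCN), "na", segs$minorCN),
               segs$class, segs$class2)
  adj <- c(FALSE, key[-1] == key[-length(key)] &
             start(segs)[-1] == end(segs)[-length(segs)] + 1)
  grp <- cumsum(!adj)
  if (max(grp) == length(segs)) return(segs)
  keep <- which(!adj)
  out <- segs[keep]
  ord <- as.character(seq_len(max(grp)))
  GenomicRanges::end(out) <- as.numeric(tapply(end(segs), grp, max)[ord])
  mk <- tapply(segs$nMarkers, grp, function(x)
    if (all(is.na(x))) NA_integer_ else as.integer(sum(x, na.rm = TRUE)))
  out$nMarkers <- as.integer(mk[ord])
  out
}

.cnaSegs <- function(kt) kt@segments[kt@segments$class != "neutral"]

# carry copy-number values onto consensus pieces from a donor karyotype
.donateCN <- function(pieces, donor) {
  hits <- findOverlaps(pieces, donor@segments)
  ow <- width(pintersect(pieces[queryHits(hits)], donor@segments[subjectHits(hits)]))
  bestHit <- tapply(seq_along(ow), queryHits(hits),
                    function(i) i[which.max(ow[i])])
  idx <- rep(NA_integer_, length(pieces))
  idx[as.integer(names(bestHit))] <- subjectHits(hits)[unlist(bestHit)]
  list(total = donor@segments$totalCN[idx], minor = donor@segments$minorCN[idx],
       markers = donor@segments$nMarkers[idx])
}

#' Integrate CNA calls from two platforms
#'
#' `intersect` keeps only genomic extents where both platforms agree on the
#' CNA class (relative to the fitted baseline), with coordinates equal to
#' the overlap — the high-confidence consensus. `union` merges the extents;
#' where the platforms call opposite classes the class of the platform with
#' more markers in the region wins and the piece is flagged, and regions
#' supported by a single platform are kept flagged. Copy-number values on
#' consensus pieces are taken from the second karyotype (the SNP platform
#' carrying allele-specific calls) where it covers them, else from the
#' first. Everything outside consensus CNA is re-tiled as neutral baseline.
#'
#' @param wgsKt,snpKt [VirtualKaryotype-class] objects fitted under the same
#'   purity/ploidy baseline.
#' @param mode "intersect" or "union".
#' @param gapFill baseline filler pieces shorter than this (bp), created by
#'   platform boundary jitter, adopt the copy number of their wider
#'   neighbor instead of standing as independent segments.
#' @return a consensus [VirtualKaryotype-class].
#' @export
mergePlatformCalls <- function(wgsKt, snpKt, mode = c("intersect", "union"),
                               gapFill = 1e5) {
  mode <- match.arg(mode)
  span <- .coveredSpan(wgsKt, snpKt)
  base <- round(snpKt@ploidy)
  pieces <- GRanges()
  for (cls in c("gain", "loss")) {
    a <- reduce(granges(.cnaSegs(wgsKt)[.cnaSegs(wgsKt)$class == cls]))
    b <- reduce(granges(.cnaSegs(snpKt)[.cnaSegs(snpKt)$class == cls]))
    pc <- if (mode == "intersect") intervalIntersect(a, b) else intervalUnion(a, b)
    if (length(pc)) {
      pc$class <- cls
      pc$flagged <- if (mode == "union")
        !(overlapsAny(pc, a) & overlapsAny(pc, b)) else FALSE
      pieces <- c(pieces, pc)
    }
  }
  if (mode == "union" && length(pieces)) {
    # opposite-class conflicts: winner is the platform with more markers
    conf <- intervalIntersect(granges(pieces[pieces$class == "gain"]),
                              granges(pieces[pieces$class == "loss"]))
    if (length(conf)) {
      resolved <- GRanges()
      for (i in seq_along(conf)) {
        mA <- .donateCN(conf[i], wgsKt)$markers
        mB <- .donateCN(conf[i], snpKt)$markers
        winner <- if (!is.na(mA) && (is.na(mB) || mA > mB)) wgsKt else snpKt
        piece <- granges(conf[i])
        hit <- findOverlaps(piece, winner@segments, select = "first")
        piece$class <- winner@segments$class[hit]
        piece$flagged <- TRUE
        resolved <- c(resolved, piece)
      }
      unconf <- GRanges()
      for (cls in c("gain", "loss")) {
        pp <- pieces[pieces$class == cls]
        cut <- intervalSubtract(granges(pp), conf)
        if (length(cut)) {
          cut$class <- cls
          hitIdx <- findOverlaps(cut, pp, select = "first")
          cut$flagged <- pp$flagged[hitIdx]
          unconf <- c(unconf, cut)
        }
      }
      pieces <- c(unconf, resolved)
    }
  }
  if (length(pieces)) {
    don <- .donateCN(pieces, snpKt)
    fallback <- .donateCN(pieces, wgsKt)
    pieces$totalCN <- as.integer(ifelse(is.na(don$total), fallback$total, don$total))
    pieces$minorCN <- as.integer(ifelse(is.na(don$total), fallback$minor, don$minor))
    # drop pieces whose donated value contradicts the class (rare edge)
    pieces$totalCN[is.na(pieces$totalCN)] <- base
    pieces$class2 <- ifelse(pieces$totalCN > 2, "gain",
                            ifelse(pieces$totalCN < 2, "loss", "neutral"))
    pieces$nMarkers <- NA_integer_; pieces$lrr <- NA_real_
    pieces$bafDev <- NA_real_; pieces$nHet <- NA_integer_
    pieces$source <- "consensus"
  }
  gaps <- .retileNeutral(pieces, span, base)
  segs <- GenomicRanges::sort(c(pieces, gaps))
  if (length(gaps)) {
    fillerIdx <- which(overlapsAny(segs, gaps, type = "equal"))
    segs <- .fillSmallGaps(segs, fillerIdx, base, maxGap = gapFill)
  }
  segs <- .consolidateSegments(segs)
  new("VirtualKaryotype", sampleId = snpKt@sampleId, purity = snpKt@purity,
      ploidy = snpKt@ploidy, segments = segs, source = "consensus",
      bafInformed = snpKt@bafInformed)
}

#' Remove CNA calls falling in excluded regions
#'
#' Subtracts exclusion intervals (blacklist-style regions) from every CNA
#' segment, drops resulting fragments shorter than `minLen`, and re-tiles
#' the freed genome as neutral baseline.
#'
#' @param kt a [VirtualKaryotype-class].
#' @param exclusion GRanges of regions to exclude.
#' @param minLen minimum surviving fragment length in bp.
#' @return the filtered [VirtualKaryotype-class].
#' @export
filterExcludedRegions <- function(kt, exclusion, minLen = 5e4) {
  if (!length(exclusion)) return(kt)
  span <- .coveredSpan(kt)
  cna <- kt@segments[kt@segments$class != "neutral"]
  neutral <- kt@segments[kt@segments$class == "neutral"]
  kept <- GRanges()
  for (i in seq_along(cna)) {
    frags <- intervalSubtract(granges(cna[i]), exclusion)
    frags <- frags[width(frags) >= minLen]
    if (length(frags)) {
      mcols(frags) <- mcols(cna[i])[rep(1, length(frags)), , drop = FALSE]
      kept <- c(kept, frags)
    }
  }
  base <- round(kt@ploidy)
  gaps <- .retileNeutral(intervalUnion(granges(kept), granges(neutral)), span, base)
  cols <- names(mcols(kt@segments))
  if (length(gaps)) {
    extra <- setdiff(cols, names(mcols(gaps)))
    for (nm in extra) mcols(gaps)[[nm]] <- NA
  }
  parts <- Filter(length, list(kept, neutral, gaps))
  parts <- lapply(parts, function(g) g[, cols])
  segs <- GenomicRanges::sort(do.call(c, parts))
  kt@segments <- .consolidateSegments(segs)
  kt
}

#' Reconstruct a consensus virtual karyotype from raw signal layers
#'
#' The full per-sample workflow: segment binned read depth and SNP signals,
#' fit purity and baseline ploidy from the SNP segments (BAF-informed by
#' default), assign integer allele-specific copy numbers to both platforms
#' under the shared fit, intersect the platform calls into a consensus, and
#' optionally filter excluded regions.
#'
#' @param readDepth binned count data.frame (chrom, start, end, count).
#' @param snp SNP table (chrom, pos, lrr, baf).
#' @param sampleId sample identifier.
#' @param exclusion optional GRanges of excluded regions (removed from the
#'   inputs before segmentation and from the calls after).
#' @param minBins,minMarkers,alpha,nPerm segmentation controls.
#' @param useBaf use the BAF channel for purity/ploidy fitting.
#' @param minSegLen minimum CNA fragment length kept after exclusion.
#' @param mode platform integration mode.
#' @param seed RNG seed for the permutation streams.
#' @return list with `consensus`, `wgs`, `snp` ([VirtualKaryotype-class])
#'   and `fit` ([PurityPloidyFit-class]).
#' @export
buildKaryotype <- function(readDepth, snp, sampleId = "sample",
                           exclusion = NULL, minBins = 5, minMarkers = 10,
                           alpha = 0.01, nPerm = 1000, useBaf = TRUE,
                           minSegLen = 5e4, mode = "intersect", seed = 1) {
  if (!is.null(exclusion) && length(exclusion)) {
    binGr <- GRanges(readDepth$chrom, IRanges(readDepth$start + 1, readDepth$end))
    readDepth <- readDepth[!overlapsAny(binGr, exclusion), , drop = FALSE]
    snpGr <- GRanges(snp$chrom, IRanges(snp$pos + 1, snp$pos + 1))
    snp <- snp[!overlapsAny(snpGr, exclusion), , drop = FALSE]
  }
  segR <- segmentReadDepth(readDepth, minBins = minBins, alpha = alpha,
                           nPerm = nPerm, seed = seed)
  segS <- segmentSnp(snp, minMarkers = minMarkers, alpha = alpha,
                     nPerm = nPerm, seed = seed + 1L)
  fit <- fitPurityPloidy(segS, useBaf = useBaf)
  ktS <- assignIntegerCopyNumber(segS, fit, sampleId, source = "snp",
                                 offset = "fit")
  ktW <- assignIntegerCopyNumber(segR, fit, sampleId, source = "wgs",
                                 offset = "recenter")
  cons <- mergePlatformCalls(ktW, ktS, mode = mode)
  if (!is.null(exclusion) && length(exclusion))
    cons <- filterExcludedRegions(cons, exclusion, minLen = minSegLen)
  list(consensus = cons, wgs = ktW, snp = ktS, fit = fit)
}

#' Write a karyotype as a SEG file
#'
#' Standard SEG columns (sample, chrom, start, end, num markers, seg mean)
#' in 1-based inclusive coordinates, plus total/minor copy number and both
#' class encodings; purity and ploidy ride in header comment lines.
#'
#' @param kt a [VirtualKaryotype-class].
#' @param file output path.
#' @return the path, invisibly.
#' @export
writeSeg <- function(kt, file) {
  s <- kt@segments
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# coordinates: 1-based inclusive",
               sprintf("# sample=%s purity=%.3f ploidy=%.3f source=%s",
                       kt@sampleId, kt@purity, kt@ploidy, kt@source)), con)
  df <- data.frame(sample = kt@sampleId, chrom = as.character(seqnames(s)),
                   start = start(s), end = end(s), num_markers = s$nMarkers,
                   seg_mean = round(ifelse(is.na(s$lrr), 0, s$lrr), 4),
                   total_cn = s$totalCN, minor_cn = s$minorCN,
                   class = s$class, class_vs_diploid = s$class2)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
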