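## Recursive binary segmentation with permutation significance testing.
## One engine serves both channels: a single series (log2 read-depth
## ratios) or a joint two-channel series (LRR + mirrored heterozygous BAF
## deviation), scored by the sum of per-channel squared t statistics.

# all-splits two-sample t^2 for one series, via cumulative sums;
# returns vector over split points 1..(n-1) (split after index i),
# NA where a side is smaller than minSize
.tsqAllSplits <- function(x, minSize) {
  n <- length(x)
  if (n < 2 * minSize) return(rep(NA_real_, max(n - 1, 0)))
  cs <- cumsum(x); css <- cumsum(x^2)
  i <- seq_len(n - 1)
  n1 <- i; n2 <- n - i
  m1 <- cs[i] / n1; m2 <- (cs[n] - cs[i]) / n2
  ss1 <- css[i] - cs[i]^2 / n1
  ss2 <- (css[n] - css[i]) - (cs[n] - cs[i])^2 / n2
  s2 <- (ss1 + ss2) / pmax(n - 2, 1)
  t2 <- (m1 - m2)^2 / (s2 * (1 / n1 + 1 / n2))
  t2[s2 <= 0] <- ifelse(abs(m1 - m2)[s2 <= 0] > 0, Inf, 0)
  t2[i < minSize | n2 < minSize] <- NA_real_
  t2
}

# joint statistic over two channels; channel 2 (d) only defined on rows
# where use2 is TRUE and needs >= 3 points per side to contribute
.jointStat <- function(l, d, use2, minSize) {
  t2 <- .tsqAllSplits(l, minSize)
  if (any(use2)) {
    n <- length(l)
    d0 <- ifelse(use2, d, 0)
    cs <- cumsum(d0); css <- cumsum(d0^2); cn <- cumsum(use2)
    i <- seq_len(n - 1)
    n1 <- cn[i]; n2 <- cn[n] - cn[i]
    ok <- n1 >= 3 & n2 >= 3
    m1 <- cs[i] / pmax(n1, 1); m2 <- (cs[n] - cs[i]) / pmax(n2, 1)
    ss1 <- css[i] - cs[i]^2 / pmax(n1, 1)
    ss2 <- (css[n] - css[i]) - (cs[n] - cs[i])^2 / pmax(n2, 1)
    s2 <- (ss1 + ss2) / pmax(n1 + n2 - 2, 1)
    tb <- (m1 - m2)^2 / (s2 * (1 / pmax(n1, 1) + 1 / pmax(n2, 1)))
    tb[s2 <= 0] <- ifelse(abs(m1 - m2)[s2 <= 0] > 0, Inf, 0)
    tb[!ok] <- 0
    t2 <- t2 + tb
  }
  t2
}

# permutation p-value for the best split of a (possibly two-channel)
# series; permutes rows jointly; early-stops once the split is clearly
# non-significant (sequential batches)
.permPValue <- function(l, d, use2, minSize, obs, nPerm) {
  exceed <- 0L; done <- 0L; batch <- 100L
  n <- length(l)
  while (done < nPerm) {
    b <- min(batch, nPerm - done)
    for (k in seq_len(b)) {
      idx <- sample.int(n)
      t2 <- .jointStat(l[idx], if (is.null(d)) NULL else d[idx],
                       if (is.null(use2)) rep(FALSE, n) else use2[idx], minSize)
      mx <- suppressWarnings(max(t2, na.rm = TRUE))
      if (!is.finite(mx)) mx <- if (is.na(mx)) 0 else mx
      if (mx >= obs) exceed <- exceed + 1L
    }
    done <- done + b
    if (exceed >= 20L) break  # p clearly above any usual alpha
  }
  (exceed + 1) / (done + 1)
}

# recursive driver on index range; returns split boundaries (indices after
# which a change point occurs)
.recursiveSplits <- function(l, d, use2, minSize, alpha, nPerm) {
  n <- length(l)
  if (n < 2 * minSize) return(integer())
  t2 <- .jointStat(l, d, if (is.null(use2)) rep(FALSE, n) else use2, minSize)
  if (all(is.na(t2))) return(integer())
  obs <- suppressWarnings(max(t2, na.rm = TRUE))
  if (!is.finite(obs) && is.na(obs)) return(integer())
  cut <- which.max(ifelse(is.na(t2), -Inf, t2))
  p <- .permPValue(l, d, use2, minSize, obs, nPerm)
  if (p >= alpha) return(integer())
  left <- .recursiveSplits(l[seq_len(cut)],
                           if (is.null(d)) NULL else d[seq_len(cut)],
                           if (is.null(use2)) NULL else use2[seq_len(cut)],
                           minSize, alpha, nPerm)
  rightIdx <- (cut + 1):n
  right <- .recursiveSplits(l[rightIdx],
                            if (is.null(d)) NULL else d[rightIdx],
                            if (is.null(use2)) NULL else use2[rightIdx],
                            minSize, alpha, nPerm)
  c(left, cut, cut + right)
}

#' Segment binned read-depth into constant-copy-number calls
#'
#' Bin counts are converted to log2 ratios against the sample median
#' (read depth carries no absolute scale) and each chromosome is segmented
#' by recursive binary splitting: the boundary maximizing the two-sample t
#' statistic is accepted when its permutation p-value falls below `alpha`
#' and both sides keep at least `minBins` bins. Segmentation is invariant
#' to a constant multiplicative factor on all counts.
#'
#' @param bins data.frame with chrom, start, end (0-based half-open), count.
#' @param minBins minimum bins per segment.
#' @param alpha split acceptance level for the permutation p-value.
#' @param nPerm number of permutations per tested split.
#' @param seed RNG seed for the permutation stream.
#' @return GRanges of segments with mcols `lrr` (mean log2 ratio),
#'   `nMarkers`, `source = "wgs"`.
#' @export
segmentReadDepth <- function(bins, minBins = 5, alpha = 0.01, nPerm = 1000,
                             seed = 1) {
  if (is.null(bins) || !nrow(bins)) stop("empty read-depth input")
  set.seed(seed)
  med <- stats::median(bins$count)
  if (med <= 0) stop("median bin count is not positive")
  bins$ratio <- log2((bins$count + 0.5) / (med + 0.5))
  out <- lapply(split(bins, factor(bins$chrom, levels = unique(bins$chrom))),
                function(d) {
    d <- d[order(d$start), ]
    cuts <- .recursiveSplits(d$ratio, NULL, NULL, minBins, alpha, nPerm)
    bnd <- c(0, sort(cuts), nrow(d))
    data.frame(chrom = d$chrom[1],
               start = d$start[bnd[-length(bnd)] + 1] + 1,
               end = d$end[bnd[-1]],
               lrr = vapply(seq_len(length(bnd) - 1), function(i)
                 mean(d$ratio[(bnd[i] + 1):bnd[i + 1]]), 0),
               nMarkers = diff(bnd))
  })
  df <- do.call(rbind, out)
  GRanges(df$chrom, IRanges(df$start, df$end), lrr = df$lrr,
          bafDev = NA_real_, nMarkers = df$nMarkers, nHet = 0L,
          source = "wgs", flagged = FALSE)
}

#' Jointly segment SNP-array LRR and BAF into allele-aware calls
#'
#' Recursive binary segmentation on the two-channel statistic (sum of
#' per-channel squared t statistics over LRR and mirrored heterozygous BAF
#' deviation `|BAF - 0.5|`). Heterozygous SNPs are taken as those with BAF
#' in (0.15, 0.85); a region without usable heterozygous SNPs falls back to
#' LRR-only evidence and its segments are flagged.
#'
#' @param snp data.frame with chrom, pos, lrr, baf and optionally `het`
#'   (logical germline genotype call, as array genotyping provides; without
#'   it heterozygosity falls back to BAF in (0.15, 0.85), which cannot see
#'   fully collapsed LOH at high purity).
#' @param minMarkers minimum heterozygous SNPs per segment (the SNP-count
#'   minimum per side is `2 * minMarkers` so both channels stay estimable).
#' @param alpha,nPerm,seed as in [segmentReadDepth()].
#' @return GRanges of segments with mcols `lrr`, `bafDev` (mean mirrored
#'   het-BAF deviation; NA when no hets), `nMarkers`, `nHet`,
#'   `source = "snp"`, `flagged`.
#' @export
segmentSnp <- function(snp, minMarkers = 10, alpha = 0.01, nPerm = 1000,
                       seed = 1) {
  if (is.null(snp) || !nrow(snp)) stop("empty SNP input")
  set.seed(seed)
  out <- lapply(split(snp, factor(snp$chrom, levels = unique(snp$chrom))),
                function(d) {
    d <- d[order(d$pos), ]
    het <- if (!is.null(d$het)) d$het else d$baf > 0.15 & d$baf < 0.85
    dev <- abs(d$baf - 0.5)
    cuts <- .recursiveSplits(d$lrr, dev, het, 2 * minMarkers, alpha, nPerm)
    bnd <- c(0, sort(cuts), nrow(d))
    seg <- lapply(seq_len(length(bnd) - 1), function(i) {
      idx <- (bnd[i] + 1):bnd[i + 1]
      nh <- sum(het[idx])
      data.frame(chrom = d$chrom[1], start = d$pos[idx[1]] + 1,
                 end = d$pos[idx[length(idx)]] + 1,
                 lrr = mean(d$lrr[idx]),
                 bafDev = if (nh >= 3) mean(dev[idx][het[idx]]) else NA_real_,
                 nMarkers = length(idx), nHet = nh)
    })
    do.call(rbind, seg)
  })
  df <- do.call(rbind, out)
  gr <- GRanges(df$chrom, IRanges(df$start, df$end), lrr = df$lrr,
                bafDev = df$bafDev, nMarkers = df$nMarkers, nHet = df$nHet,
                source = "snp", flagged = is.na(df$bafDev))
  # BAF noise sd estimated from the homozygous clusters at 0/1 (half-normal
  # mean after clamping); consumed by the lattice fit to unfold the
  # mirrored-BAF deviation bias
  hom <- if (!is.null(snp$het)) !snp$het else snp$baf <= 0.15 | snp$baf >= 0.85
  resid <- abs(snp$baf[hom] - round(snp$baf[hom]))
  resid <- resid[resid > 0]  # clamping at 0/1 piles mass at exactly zero
  if (length(resid) >= 50)
    S4Vectors::metadata(gr)$bafNoise <-
      stats::median(resid) / stats::qnorm(0.75)
  gr
}
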