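## Band-level CNA representation (the 60% rule), representation-quality
## scores, per-sample genomic-instability metrics (including the arm-level
## aneuploidy score) and cohort-level correlation summaries.

# covered fraction of each band by a set of ranges
.bandCoverage <- function(bandsGr, ranges) {
  cov <- rep(0, length(bandsGr))
  if (!length(ranges)) return(cov)
  rr <- reduce(granges(ranges))
  hits <- findOverlaps(bandsGr, rr)
  if (length(hits)) {
    ow <- width(pintersect(bandsGr[queryHits(hits)], rr[subjectHits(hits)]))
    agg <- tapply(ow, queryHits(hits), sum)
    cov[as.integer(names(agg))] <- as.numeric(agg)
  }
  cov / width(bandsGr)
}

#' Map a karyotype onto cytogenetic-band states
#'
#' A band is labeled gain (loss) when segments of that class cover at least
#' `threshold` (default 60\%) of the band. If both classes reach the
#' threshold after fragmentation, the class with the larger covered
#' fraction wins; an exact tie goes to neutral with a warning. The band
#' copy number is the length-weighted mean total copy number over the band,
#' rounded to the nearest integer. Classes are read from the diploid-relative
#' encoding (`class2`) by default, which is what cohort-level band matrices
#' consume; set `relativeTo = "ploidy"` for baseline-relative states.
#'
#' @param kt a [VirtualKaryotype-class].
#' @param model a [GenomeModel-class].
#' @param threshold minimum covered fraction for a band label.
#' @param relativeTo "diploid" (class2) or "ploidy" (class).
#' @return list with `state` (integer -1/0/1 per band) and `cn` (integer
#'   per band).
#' @export
mapToBands <- function(kt, model, threshold = 0.6,
                       relativeTo = c("diploid", "ploidy")) {
  relativeTo <- match.arg(relativeTo)
  cls <- if (relativeTo == "diploid") kt@segments$class2 else kt@segments$class
  b <- model@bands
  covGain <- .bandCoverage(b, kt@segments[cls == "gain"])
  covLoss <- .bandCoverage(b, kt@segments[cls == "loss"])
  eps <- 1e-9
  state <- integer(length(b))
  gainOk <- covGain >= threshold - eps
  lossOk <- covLoss >= threshold - eps
  state[gainOk & !lossOk] <- 1L
  state[lossOk & !gainOk] <- -1L
  both <- gainOk & lossOk
  if (any(both)) {
    tie <- both & abs(covGain - covLoss) < eps
    state[both & covGain > covLoss] <- 1L
    state[both & covLoss > covGain] <- -1L
    if (any(tie)) {
      state[tie] <- 0L
      warning(sum(tie), " band(s) with an exact gain/loss coverage tie set neutral")
    }
  }
  # length-weighted mean total CN over each band
  s <- kt@segments
  hits <- findOverlaps(b, s)
  cn <- rep(2, length(b))
  if (length(hits)) {
    ow <- width(pintersect(b[queryHits(hits)], s[subjectHits(hits)]))
    num <- tapply(ow * s$totalCN[subjectHits(hits)], queryHits(hits), sum)
    den <- tapply(ow, queryHits(hits), sum)
    cn[as.integer(names(num))] <- as.numeric(num) / as.numeric(den)
  }
  list(state = state, cn = as.integer(floor(cn + 0.5)))
}

#' Build a band-by-sample CNA matrix
#'
#' @param kts list of [VirtualKaryotype-class] (typically consensus calls).
#' @param model a [GenomeModel-class].
#' @param threshold the band-coverage rule (default 0.6).
#' @return a [BandCnaMatrix-class]; rows follow genome order.
#' @export
bandCnaMatrix <- function(kts, model, threshold = 0.6) {
  ord <- .genomeOrder(model)
  b <- model@bands[ord]
  ids <- vapply(kts, function(k) k@sampleId, "")
  st <- matrix(0L, length(b), length(kts), dimnames = list(b$name, ids))
  cn <- matrix(2L, length(b), length(kts), dimnames = list(b$name, ids))
  for (j in seq_along(kts)) {
    m <- mapToBands(kts[[j]], model, threshold)
    st[, j] <- m$state[ord]
    cn[, j] <- m$cn[ord]
  }
  new("BandCnaMatrix", bands = b, states = st, cn = cn)
}

#' Score how well band labels represent the underlying segments
#'
#' Treats base-pair-resolution band labels as the prediction and segment
#' labels as the truth. `F10` is the F-beta score with beta = 10 (recall
#' weighted), computed separately for gains and losses and combined by
#' alteration-length weighting. `RBS` (region boundary score) is the mean,
#' over the CNA segment boundaries, of the distance to the nearest band
#' boundary divided by the chromosome length — 0 means every segment
#' boundary coincides with a band boundary. A sample with no CNA returns NA
#' for both (undefined, not perfect).
#'
#' @param kt a [VirtualKaryotype-class].
#' @param bandState integer -1/0/1 vector as produced by [mapToBands()]
#'   (same band order as `model@bands`).
#' @param model a [GenomeModel-class].
#' @param beta recall weight of the F score.
#' @return list with `F10` and `RBS`.
#' @export
representationQuality <- function(kt, bandState, model, beta = 10) {
  b <- model@bands
  cls <- kt@segments$class2
  fScore <- function(truth, pred) {
    tp <- sum(width(intervalIntersect(truth, pred)))
    lenP <- sum(width(reduce(pred))); lenT <- sum(width(reduce(truth)))
    if (lenT == 0) return(NA_real_)
    if (lenP == 0) return(0)
    prec <- tp / lenP; rec <- tp / lenT
    if (prec + rec == 0) return(0)
    (1 + beta^2) * prec * rec / (beta^2 * prec + rec)
  }
  res <- c(gain = NA_real_, loss = NA_real_)
  wts <- c(gain = 0, loss = 0)
  for (cl in c("gain", "loss")) {
    truth <- granges(kt@segments[cls == cl])
    pred <- granges(b[bandState == if (cl == "gain") 1L else -1L])
    wts[cl] <- sum(width(reduce(truth)))
    if (wts[cl] > 0) res[cl] <- fScore(truth, pred)
  }
  if (sum(wts) == 0) return(list(F10 = NA_real_, RBS = NA_real_))
  f10 <- sum(res * wts, na.rm = TRUE) / sum(wts)

  cna <- kt@segments[cls != "neutral"]
  bounds <- c(start(cna) - 1, end(cna))  # 0-based boundary coordinates
  chroms <- rep(as.character(seqnames(cna)), 2)
  dists <- vapply(seq_along(bounds), function(i) {
    bb <- b[as.character(seqnames(b)) == chroms[i]]
    bandBounds <- unique(c(start(bb) - 1, end(bb)))
    L <- model@chromosomes$length[match(chroms[i], model@chromosomes$chrom)]
    min(abs(bandBounds - bounds[i])) / L
  }, 0)
  list(F10 = f10, RBS = mean(dists))
}

#' Per-sample genomic-instability metrics
#'
#' Three measures per sample: the number of CNA segments (diploid-relative),
#' the fraction of the autosomal genome covered by CNA, and the aneuploidy
#' score — the number of chromosome arms whose union of CNA segments (any
#' class) covers at least `armCoverage` (default 80\%) of the arm.
#'
#' @param kt a [VirtualKaryotype-class].
#' @param model a [GenomeModel-class].
#' @param armCoverage arm-coverage threshold for the aneuploidy score.
#' @param armSubset optional character vector of arms to score, as
#'   "chrN_p"/"chrN_q" (default: all autosomal arms; acrocentric p arms can
#'   be excluded by dropping them here).
#' @return list with `cnaCount`, `fractionAltered`, `aneuploidyScore`.
#' @export
instabilityMetrics <- function(kt, model, armCoverage = 0.8, armSubset = NULL) {
  cna <- kt@segments[kt@segments$class2 != "neutral"]
  cnaU <- reduce(granges(cna))
  fraction <- sum(width(cnaU)) / .autosomeLength(model)
  a <- model@arms
  armIds <- paste0(as.character(seqnames(a)), "_", a$arm)
  if (!is.null(armSubset)) a <- a[armIds %in% armSubset]
  eps <- 1e-9
  cov <- .bandCoverage(a, cnaU)
  list(cnaCount = length(cna), fractionAltered = fraction,
       aneuploidyScore = sum(cov >= armCoverage - eps))
}

#' Cohort-level instability metrics table
#'
#' @param kts list of [VirtualKaryotype-class].
#' @param model a [GenomeModel-class].
#' @param ... passed to [instabilityMetrics()].
#' @return data.frame with one row per sample.
#' @export
cohortInstability <- function(kts, model, ...) {
  rows <- lapply(kts, function(k) {
    m <- instabilityMetrics(k, model, ...)
    data.frame(sample = k@sampleId, cnaCount = m$cnaCount,
               fractionAltered = m$fractionAltered,
               aneuploidyScore = m$aneuploidyScore)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Pairwise Pearson correlations among the instability metrics
#'
#' @param metrics data.frame from [cohortInstability()] (columns cnaCount,
#'   fractionAltered, aneuploidyScore).
#' @return 3x3 symmetric Pearson correlation matrix; all-NA with a warning
#'   when any metric has zero variance across samples.
#' @export
metricCorrelations <- function(metrics) {
  m <- as.matrix(metrics[, c("cnaCount", "fractionAltered", "aneuploidyScore")])
  if (any(apply(m, 2, stats::sd) == 0) || nrow(m) < 3) {
    warning("metric correlations undefined (zero variance or too few samples)")
    out <- matrix(NA_real_, 3, 3, dimnames = list(colnames(m), colnames(m)))
    return(out)
  }
  stats::cor(m)
}

#' Correlate per-band CNA frequency with gene density
#'
#' For each band, the loss (gain) frequency is the fraction of samples in
#' the loss (gain) state; each frequency vector is Spearman-correlated with
#' the band gene density, with a large-sample two-sided p-value.
#'
#' @param bm a [BandCnaMatrix-class].
#' @param model a [GenomeModel-class] with genes loaded.
#' @return list with `loss` and `gain`, each holding `rho` and `p` (NA when
#'   gene density is constant).
#' @export
cnaFrequencyVsGeneDensity <- function(bm, model) {
  dens <- geneDensityPerBand(model)
  dens <- dens[match(bm@bands$name, names(dens))]
  if (stats::sd(dens) == 0)
    return(list(loss = list(rho = NA_real_, p = NA_real_),
                gain = list(rho = NA_real_, p = NA_real_)))
  one <- function(freq) {
    if (stats::sd(freq) == 0) return(list(rho = NA_real_, p = NA_real_))
    ct <- suppressWarnings(stats::cor.test(freq, dens, method = "spearman",
                                           exact = FALSE))
    list(rho = unname(ct$estimate), p = ct$p.value)
  }
  list(loss = one(rowMeans(bm@states == -1L)),
       gain = one(rowMeans(bm@states == 1L)))
}

#' Write a band CNA matrix as TSV
#'
#' Two files: `<stem>_states.tsv` with -1/0/+1 states and
#' `<stem>_cn.tsv` with integer copy numbers; band coordinates (0-based
#' half-open) lead the columns.
#'
#' @param bm a [BandCnaMatrix-class].
#' @param stem output path stem.
#' @return the two paths, invisibly.
#' @export
writeBandMatrix <- function(bm, stem) {
  b <- bm@bands
  meta <- data.frame(chrom = as.character(seqnames(b)), start = start(b) - 1L,
                     end = end(b), band = b$name)
  f1 <- paste0(stem, "_states.tsv"); f2 <- paste0(stem, "_cn.tsv")
  for (fp in list(list(f1, bm@states), list(f2, bm@cn))) {
    con <- file(fp[[1]], "w")
    writeLines("# coordinates: 0-based half-open", con)
    utils::write.table(cbind(meta, fp[[2]]), con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
  }
  invisible(c(f1, f2))
}
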