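# Shared fixtures, built in code and cached for the session.

.fixtureEnv <- new.env(parent = emptyenv())

.cached <- function(key, expr) {
  if (!exists(key, envir = .fixtureEnv))
    assign(key, expr, envir = .fixtureEnv)
  get(key, envir = .fixtureEnv)
}

# full-size scaled genome (the default study frame)
fullModel <- function() .cached("full", syntheticGenomeModel())

# reduced genome for fast unit tests; includes the chromosomes the
# archetypes need (chr1/16/22 for multidel, chr11, a trisomy target chr8)
smallModel <- function() .cached(
  "small", syntheticGenomeModel(chroms = c(1, 8, 11, 16, 19, 22)))

# write a cytoBand-format file from rows (chrom, start, end, name, stain)
writeToyCytobands <- function(rows) {
  tf <- tempfile(fileext = ".txt")
  write.table(rows, tf, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  tf
}

# 10 kb toy genome with two chromosomes, for per-base-pair oracles
toyModel <- function() .cached("toy", {
  rows <- data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2", "chr2", "chr2"),
    start = c(0, 1000, 2500, 6000, 0, 2000, 5000),
    end   = c(1000, 2500, 6000, 10000, 2000, 5000, 8000),
    name  = c("p2.1", "p1.1", "q1.1", "q2.1", "p1.1", "q1.1", "q2.1"),
    stain = c("gneg", "gpos50", "gneg", "gpos50", "gneg", "gneg", "gpos50"))
  loadCytobands(writeToyCytobands(rows))
})

# a TrueKaryotype built directly from (chrom, start, end, cnA, cnB) rows;
# unspecified genome stays 1+1
makeTrueKt <- function(model, events = NULL, purity = 1, id = "T") {
  base <- karyoscope:::.diploidTile(model)
  ev <- if (is.null(events) || !nrow(events)) GenomicRanges::GRanges() else {
    g <- GenomicRanges::GRanges(events$chrom,
                                IRanges::IRanges(events$start, events$end),
                                cnA = as.integer(events$cnA),
                                cnB = as.integer(events$cnB))
    GenomeInfoDb::seqlevels(g) <- model@chromosomes$chrom
    g
  }
  segs <- karyoscope:::.overlayEvents(base, ev)
  methods::new("TrueKaryotype", sampleId = id, purity = purity, segments = segs)
}

# turn ground truth into a VirtualKaryotype (perfect caller), for tests of
# downstream stages that do not exercise the karyotyper itself
asVirtualKt <- function(kt, baseline = 2) asVirtualKaryotype(kt, baseline)

# balanced-tetraploid truth: total copy number 4 on every chromosome,
# mostly 2+2 with doubled-LOH (4+0) and 3+1 chromosomes — LRR-flat, so
# depth-only baselining sees a diploid
makeTetraploidKt <- function(model, purity, id = "TET") {
  ch <- model@chromosomes
  segs <- GenomicRanges::GRanges(ch$chrom, IRanges::IRanges(1, ch$length),
                                 cnA = 2L, cnB = 2L)
  n <- nrow(ch)
  loh <- unique(pmax(1, round(c(0.2, 0.4, 0.6) * n)))
  thr <- setdiff(unique(pmax(1, round(c(0.75, 0.9) * n))), loh)
  segs$cnA[loh] <- 4L; segs$cnB[loh] <- 0L
  segs$cnA[thr] <- 3L; segs$cnB[thr] <- 1L
  GenomeInfoDb::seqlevels(segs) <- ch$chrom
  GenomeInfoDb::seqlengths(segs) <- setNames(ch$length, ch$chrom)
  methods::new("TrueKaryotype", sampleId = id, purity = purity, segments = segs)
}

# a low-burden background sample with uniformly placed focal events (no
# density bias, no recurrent loci): the exchangeable background that
# permutation-validity experiments assume
mkUniformBackground <- function(model, id) {
  ch <- chromosomes(model)
  n <- sample(0:3, 1, prob = c(0.1, 0.3, 0.3, 0.3))
  ev <- NULL
  if (n > 0) {
    ci <- sample(nrow(ch), n, replace = TRUE)
    maxLen <- pmin(2e6, ch$length[ci] * 0.8)
    len <- round(runif(n, pmin(4e5, maxLen / 2), maxLen))
    st <- pmax(1, floor(runif(n, 1, ch$length[ci] - len)))
    ev <- data.frame(chrom = ch$chrom[ci], start = st, end = st + len - 1,
                     cnA = ifelse(runif(n) < 0.6, 2, 1), cnB = 1)
    ev$cnB[ev$cnA == 1] <- 0
    ev <- ev[!duplicated(ev$chrom), , drop = FALSE]
  }
  makeTrueKt(model, ev, purity = 0.8, id = id)
}

# small emission config for unit tests
testConfig <- function(seed = 1, ...) cohortConfig(seed = seed, ...)

quietCohort <- function(...) suppressWarnings(simulateCohort(...))
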