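# helper: bins data.frame for a single synthetic chromosome
.mkBins <- function(counts, chrom = "chr1", bin = 1e4) {
  n <- length(counts)
  data.frame(chrom = chrom, start = (0:(n - 1)) * bin, end = (1:n) * bin,
             count = counts)
}

test_that("read-depth segmentation finds no, one and two change points", {
  set.seed(21)
  flat <- .mkBins(rnbinom(400, mu = 100, size = 50))
  seg <- segmentReadDepth(flat, seed = 1)
  expect_equal(length(seg), 1)

  step <- .mkBins(c(rnbinom(200, mu = 100, size = 50),
                    rnbinom(200, mu = 150, size = 50)))
  seg1 <- segmentReadDepth(step, seed = 1)
  expect_equal(length(seg1), 2)
  # boundary recovered within +/- 2 bins of bin 200
  expect_lt(abs(GenomicRanges::end(seg1)[1] / 1e4 - 200), 2.5)

  two <- .mkBins(c(rnbinom(150, mu = 100, size = 50),
                   rnbinom(100, mu = 50, size = 50),
                   rnbinom(150, mu = 100, size = 50)))
  seg2 <- segmentReadDepth(two, seed = 1)
  expect_equal(length(seg2), 3)
  expect_error(segmentReadDepth(flat[0, ]), "empty")
})

test_that("segmentation is invariant to a constant multiplicative factor", {
  set.seed(22)
  counts <- c(rnbinom(150, mu = 80, size = 60), rnbinom(150, mu = 130, size = 60))
  s1 <- segmentReadDepth(.mkBins(counts), seed = 3)
  s2 <- segmentReadDepth(.mkBins(counts * 4), seed = 3)
  expect_equal(GenomicRanges::start(s1), GenomicRanges::start(s2))
  expect_equal(GenomicRanges::end(s1), GenomicRanges::end(s2))
})

# helper: SNP table for one chromosome from per-SNP truth
.mkSnp <- function(n, lrrMean, devMean, chrom = "chr1", lrrSd = 0.12, bafSd = 0.03) {
  pos <- sort(sample.int(n * 2000, n))
  het <- runif(n) < 0.5
  baf <- ifelse(het,
                0.5 + sample(c(-1, 1), n, TRUE) * devMean + rnorm(n, 0, bafSd),
                round(runif(n)) + rnorm(n, 0, bafSd))
  data.frame(chrom = chrom, pos = pos, lrr = lrrMean + rnorm(n, 0, lrrSd),
             baf = pmin(1, pmax(0, baf)), het = het)
}

test_that("SNP segmentation sees copy-neutral LOH and degrades gracefully", {
  set.seed(23)
  # 1+1 | 2+0 (LRR flat, BAF collapses) | 1+1
  s <- rbind(.mkSnp(300, 0, 0), .mkSnp(200, 0, 0.5), .mkSnp(300, 0, 0))
  s$pos <- sort(sample.int(2e6, nrow(s)))
  seg <- segmentSnp(s, seed = 1)
  expect_equal(length(seg), 3)
  expect_gt(seg$bafDev[2], 0.4)
  expect_lt(max(seg$bafDev[c(1, 3)]), 0.1)

  flatAll <- .mkSnp(400, 0, 0)
  expect_equal(length(segmentSnp(flatAll, seed = 1)), 1)

  # no heterozygous SNPs at all: LRR-only fallback, flagged
  noHet <- .mkSnp(300, 0, 0)
  noHet$het <- FALSE
  segNH <- segmentSnp(noHet, seed = 1)
  expect_true(all(is.na(segNH$bafDev)))
  expect_true(all(segNH$flagged))
})

test_that("purity/ploidy fit recovers a trisomy sample and honors BAF", {
  m <- smallModel()
  cfg <- testConfig(seed = 31)
  ch <- chromosomes(m)
  ev <- data.frame(chrom = "chr8", start = 1,
                   end = ch$length[match("chr8", ch$chrom)], cnA = 2, cnB = 1)
  set.seed(31)
  kt <- makeTrueKt(m, ev, purity = 0.7)
  snp <- emitSnpSignals(kt, m, cfg)
  fit <- fitPurityPloidy(segmentSnp(snp, seed = 2))
  expect_lt(abs(fit@purity - 0.7), 0.05)
  expect_lt(abs(fit@ploidy - impliedPloidy(kt)), 0.1)
  expect_true(fit@bafInformed)
  expect_error(fitPurityPloidy(GenomicRanges::GRanges()), "no usable segments")
})

test_that("balanced tetraploid is re-baselined with BAF and missed without", {
  m <- smallModel()
  cfg <- testConfig(seed = 32)
  set.seed(32)
  kt <- makeTetraploidKt(m, purity = 0.75)
  snp <- emitSnpSignals(kt, m, cfg)
  segs <- segmentSnp(snp, seed = 3)
  fitB <- fitPurityPloidy(segs, useBaf = TRUE)
  fitN <- fitPurityPloidy(segs, useBaf = FALSE)
  expect_gte(fitB@ploidy, 3.5)
  expect_lt(abs(fitB@purity - 0.75), 0.05)
  expect_lte(fitN@ploidy, 2.5)
  expect_false(fitN@bafInformed)
})

test_that("integer assignment reproduces the closed-form lattice points", {
  segs <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(c(1, 11e6, 21e6),
                                                  c(10e6, 20e6, 30e6)),
                                 lrr = c(0.585, 1.0, -1.0),
                                 bafDev = c(1 / 6, 0, 0.5),
                                 nMarkers = 100L, nHet = 50L,
                                 source = "snp", flagged = FALSE)
  fit <- methods::new("PurityPloidyFit", purity = 1, ploidy = 2, psi = 2,
                      fit = 0, bafInformed = TRUE, lrrOffset = 0)
  kt <- assignIntegerCopyNumber(segs, fit, "S", offset = 0)
  expect_equal(segments(kt)$totalCN, c(3L, 4L, 1L))
  expect_equal(segments(kt)$minorCN, c(1L, 2L, 0L))
  expect_equal(segments(kt)$class, c("gain", "gain", "loss"))
  expect_equal(segments(kt)$class2, c("gain", "gain", "loss"))
})

# tiny two-karyotype fixtures for merge tests
.mkVk <- function(rows, id = "S", ploidy = 2, source = "snp") {
  g <- GenomicRanges::GRanges(rows$chrom, IRanges::IRanges(rows$start, rows$end),
                              totalCN = as.integer(rows$total),
                              minorCN = as.integer(rows$minor),
                              class = rows$class, class2 = rows$class,
                              nMarkers = as.integer(rows$markers),
                              lrr = 0, bafDev = 0, nHet = 10L,
                              source = source, flagged = FALSE)
  methods::new("VirtualKaryotype", sampleId = id, purity = 1, ploidy = ploidy,
               segments = g, source = source, bafInformed = TRUE)
}

test_that("platform merging intersects, unions and resolves conflicts", {
  a <- .mkVk(data.frame(chrom = "chr1", start = 1e6, end = 10e6, total = 3,
                        minor = 1, class = "gain", markers = 100))
  b <- .mkVk(data.frame(chrom = "chr1", start = 5e6, end = 15e6, total = 3,
                        minor = 1, class = "gain", markers = 200))
  mi <- mergePlatformCalls(a, b, "intersect")
  cna <- segments(mi)[segments(mi)$class != "neutral"]
  expect_equal(GenomicRanges::start(cna), 5e6)
  expect_equal(GenomicRanges::end(cna), 10e6)

  # identical call sets: identical CNA extents under both modes
  mi2 <- mergePlatformCalls(a, a, "intersect")
  mu2 <- mergePlatformCalls(a, a, "union")
  for (mm in list(mi2, mu2)) {
    cna <- segments(mm)[segments(mm)$class != "neutral"]
    expect_equal(GenomicRanges::start(cna), 1e6)
    expect_equal(GenomicRanges::end(cna), 10e6)
    expect_false(any(cna$flagged))
  }

  # disjoint calls: intersect empty, union keeps both flagged
  c2 <- .mkVk(data.frame(chrom = "chr1", start = 20e6, end = 25e6, total = 1,
                         minor = 0, class = "loss", markers = 50))
  mi3 <- mergePlatformCalls(a, c2, "intersect")
  expect_equal(length(segments(mi3)[segments(mi3)$class != "neutral"]), 0)
  mu3 <- mergePlatformCalls(a, c2, "union")
  cna <- segments(mu3)[segments(mu3)$class != "neutral"]
  expect_equal(length(cna), 2)
  expect_true(all(cna$flagged))

  # conflicting classes: platform with more markers wins, flagged
  d <- .mkVk(data.frame(chrom = "chr1", start = 1e6, end = 10e6, total = 1,
                        minor = 0, class = "loss", markers = 500))
  mu4 <- mergePlatformCalls(a, d, "union")
  cna <- segments(mu4)[segments(mu4)$class != "neutral"]
  expect_equal(unique(cna$class), "loss")
  expect_true(all(cna$flagged))
})

test_that("intersect consensus is always contained in union consensus", {
  set.seed(33)
  for (rep in 1:10) {
    mkRand <- function() {
      n <- sample(1:4, 1)
      s <- sort(sample.int(40e6, n))
      tot <- sample(c(1, 3), n, TRUE)
      .mkVk(data.frame(chrom = "chr1", start = s, end = s + sample(2e6:8e6, n),
                       total = tot, minor = ifelse(tot == 1, 0, 1),
                       class = sample(c("gain", "loss"), n, TRUE),
                       markers = sample(50:200, n)))
    }
    a <- mkRand(); b <- mkRand()
    ii <- segments(mergePlatformCalls(a, b, "intersect"))
    uu <- segments(mergePlatformCalls(a, b, "union"))
    iCna <- GenomicRanges::reduce(GenomicRanges::granges(ii[ii$class != "neutral"]))
    uCna <- GenomicRanges::reduce(GenomicRanges::granges(uu[uu$class != "neutral"]))
    leftover <- intervalSubtract(iCna, uCna)
    expect_equal(length(leftover), 0)
  }
})

test_that("exclusion filtering removes, splits and leaves segments", {
  kt <- .mkVk(data.frame(chrom = "chr1", start = c(1e6, 20e6),
                         end = c(2e6, 21e6), total = c(3, 1), minor = c(1, 0),
                         class = c("gain", "loss"), markers = 100))
  # fully contained exclusion removes the first call
  ex1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5e5, 3e6))
  f1 <- filterExcludedRegions(kt, ex1)
  cna <- segments(f1)[segments(f1)$class != "neutral"]
  expect_equal(length(cna), 1)
  expect_equal(cna$class, "loss")

  # 100 kb exclusion in the middle of a 1 Mb call splits it in two
  ex2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1.4e6, 1.5e6))
  f2 <- filterExcludedRegions(kt, ex2, minLen = 1e5)
  cna <- segments(f2)[segments(f2)$class == "gain"]
  expect_equal(length(cna), 2)

  # empty exclusion: identity on the CNA set
  f3 <- filterExcludedRegions(kt, GenomicRanges::GRanges())
  expect_equal(length(segments(f3)[segments(f3)$class != "neutral"]), 2)
})

test_that("end-to-end karyotyping recovers a contaminated trisomy", {
  m <- smallModel()
  cfg <- testConfig(seed = 35)
  ch <- chromosomes(m)
  ev <- data.frame(chrom = "chr8", start = 1,
                   end = ch$length[match("chr8", ch$chrom)], cnA = 2, cnB = 1)
  set.seed(35)
  kt <- makeTrueKt(m, ev, purity = 0.7)
  rd <- emitReadDepth(kt, m, cfg)
  snp <- emitSnpSignals(kt, m, cfg)
  res <- buildKaryotype(rd, snp, "T8", seed = 4)
  bs <- mapToBands(res$consensus, m)
  b <- bands(m)
  on8 <- as.character(GenomicRanges::seqnames(b)) == "chr8"
  expect_true(all(bs$cn[on8] == 3))
  expect_true(all(bs$cn[!on8] == 2))
})
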