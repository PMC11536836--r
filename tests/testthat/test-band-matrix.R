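test_that("whole-chromosome monosomy labels every band of that chromosome", {
  m <- smallModel()
  kt <- asVirtualKt(makeTrueKt(m, data.frame(
    chrom = "chr11", start = 1,
    end = chromosomes(m)$length[match("chr11", chromosomes(m)$chrom)],
    cnA = 1, cnB = 0)))
  bs <- mapToBands(kt, m)
  on11 <- as.character(GenomicRanges::seqnames(bands(m))) == "chr11"
  expect_true(all(bs$state[on11] == -1L))
  expect_true(all(bs$state[!on11] == 0L))
  expect_true(all(bs$cn[on11] == 1L))
})

test_that("the 60% band rule is exact at its boundary", {
  m <- toyModel()
  b1 <- bands(m)[1]  # chr1 [1, 1000]
  mk <- function(covBp) asVirtualKt(makeTrueKt(m, data.frame(
    chrom = "chr1", start = 1, end = covBp, cnA = 2, cnB = 1)))
  expect_equal(mapToBands(mk(599), m)$state[1], 0L)   # 59.9% -> neutral
  expect_equal(mapToBands(mk(600), m)$state[1], 1L)   # 60.0% -> gain
})

test_that("representation quality is exact against a per-base oracle", {
  m <- toyModel()
  beta <- 10
  L <- sum(chromosomes(m)$length)
  oracle <- function(kt, state) {
    # base-pair truth/prediction labels over the concatenated genome
    lab <- function(gr) {
      v <- character(0)
      for (cn in chromosomes(m)$chrom) {
        Lc <- chromosomes(m)$length[match(cn, chromosomes(m)$chrom)]
        x <- rep("neutral", Lc)
        gg <- gr[as.character(GenomicRanges::seqnames(gr)) == cn]
        for (i in seq_along(gg))
          x[GenomicRanges::start(gg)[i]:GenomicRanges::end(gg)[i]] <- gg$cls[i]
        v <- c(v, x)
      }
      v
    }
    s <- segments(kt); s$cls <- s$class2
    truth <- lab(s[s$class2 != "neutral"])
    bb <- bands(m); bb$cls <- c("loss", "neutral", "gain")[state + 2]
    pred <- lab(bb[bb$cls != "neutral"])
    perClass <- sapply(c("gain", "loss"), function(cl) {
      tl <- sum(truth == cl)
      if (tl == 0) return(c(f = NA, w = 0))
      tp <- sum(truth == cl & pred == cl)
      pl <- sum(pred == cl)
      if (pl == 0) return(c(f = 0, w = tl))
      prec <- tp / pl; rec <- tp / tl
      c(f = (1 + beta^2) * prec * rec / (beta^2 * prec + rec), w = tl)
    })
    if (sum(perClass["w", ]) == 0) return(NA_real_)
    sum(perClass["f", ] * perClass["w", ], na.rm = TRUE) / sum(perClass["w", ])
  }
  set.seed(51)
  for (rep in 1:20) {
    n <- sample(1:3, 1)
    ch <- sample(chromosomes(m)$chrom, 1)
    Lc <- chromosomes(m)$length[match(ch, chromosomes(m)$chrom)]
    s <- sort(sample.int(Lc - 100, n))
    e <- pmin(Lc, s + sample(200:4000, n, replace = TRUE))
    keep <- c(TRUE, s[-1] > e[-n] + 1)
    ev <- data.frame(chrom = ch, start = s, end = e,
                     cnA = sample(c(0, 2), n, TRUE), cnB = sample(0:1, n, TRUE))
    ev <- ev[keep & ev$cnA + ev$cnB != 2, , drop = FALSE]
    if (!nrow(ev)) next
    kt <- asVirtualKt(makeTrueKt(m, ev))
    st <- mapToBands(kt, m)$state
    rq <- representationQuality(kt, st, m)
    expect_equal(rq$F10, oracle(kt, st), tolerance = 1e-12)
  }
})

test_that("representation quality handles exact boundaries and no-CNA samples", {
  m <- toyModel()
  # CNA exactly covering bands -> F10 = 1, RBS = 0
  b <- bands(m)[3]  # chr1 q1.1 [2501, 6000]
  kt <- asVirtualKt(makeTrueKt(m, data.frame(
    chrom = "chr1", start = GenomicRanges::start(b), end = GenomicRanges::end(b),
    cnA = 2, cnB = 1)))
  st <- mapToBands(kt, m)$state
  rq <- representationQuality(kt, st, m)
  expect_equal(rq$F10, 1)
  expect_equal(rq$RBS, 0)
  # no CNA -> undefined sentinels, not 1
  kt0 <- asVirtualKt(makeTrueKt(m))
  rq0 <- representationQuality(kt0, mapToBands(kt0, m)$state, m)
  expect_true(is.na(rq0$F10) && is.na(rq0$RBS))
})

test_that("aneuploidy score counts arms at the 80% rule exactly", {
  m <- smallModel()
  ch <- chromosomes(m)
  # whole-chromosome trisomy of one chromosome: both arms -> AS = 2
  kt <- asVirtualKt(makeTrueKt(m, data.frame(
    chrom = "chr8", start = 1, end = ch$length[match("chr8", ch$chrom)],
    cnA = 2, cnB = 1)))
  met <- instabilityMetrics(kt, m)
  expect_equal(met$aneuploidyScore, 2)
  expect_equal(met$cnaCount, 1)

  # arm covered 79% vs 80%
  arm <- arms(m)[1]  # chr1 p
  aw <- GenomicRanges::width(arm)
  mkCov <- function(frac) asVirtualKt(makeTrueKt(m, data.frame(
    chrom = "chr1", start = GenomicRanges::start(arm),
    end = GenomicRanges::start(arm) + round(frac * aw) - 1, cnA = 2, cnB = 1)))
  expect_equal(instabilityMetrics(mkCov(0.79), m)$aneuploidyScore, 0)
  expect_equal(instabilityMetrics(mkCov(0.80), m)$aneuploidyScore, 1)

  # every chromosome duplicated -> every scored arm counts
  evAll <- data.frame(chrom = ch$chrom, start = 1, end = ch$length,
                      cnA = 2, cnB = 1)
  ktAll <- asVirtualKt(makeTrueKt(m, evAll))
  expect_equal(instabilityMetrics(ktAll, m)$aneuploidyScore, length(arms(m)))
})

test_that("aneuploidy score is monotone under added CNA segments", {
  m <- smallModel()
  set.seed(52)
  ch <- chromosomes(m)
  for (rep in 1:10) {
    n <- sample(1:3, 1)
    ci <- sample(nrow(ch), n, replace = TRUE)
    ev <- data.frame(chrom = ch$chrom[ci], start = 1,
                     end = round(ch$length[ci] * runif(n, 0.3, 1)),
                     cnA = 2, cnB = 1)
    ev <- ev[!duplicated(ev$chrom), , drop = FALSE]
    as1 <- instabilityMetrics(asVirtualKt(makeTrueKt(m, ev)), m)$aneuploidyScore
    extraChrom <- setdiff(ch$chrom, ev$chrom)
    if (!length(extraChrom)) next
    ev2 <- rbind(ev, data.frame(chrom = extraChrom[1], start = 1,
                                end = ch$length[match(extraChrom[1], ch$chrom)],
                                cnA = 1, cnB = 0))
    as2 <- instabilityMetrics(asVirtualKt(makeTrueKt(m, ev2)), m)$aneuploidyScore
    expect_gte(as2, as1)
  }
})

test_that("metric correlations handle degenerate and proportional inputs", {
  same <- data.frame(cnaCount = rep(3, 5), fractionAltered = rep(0.1, 5),
                     aneuploidyScore = rep(2, 5))
  expect_warning(cm <- metricCorrelations(same), "undefined")
  expect_true(all(is.na(cm)))

  prop <- data.frame(cnaCount = 1:5, fractionAltered = (1:5) / 10,
                     aneuploidyScore = (1:5) * 2)
  cm2 <- metricCorrelations(prop)
  expect_equal(min(cm2), 1)
})

test_that("losses track gene-dense and gains gene-poor territory in a cohort", {
  m <- fullModel()
  cfg <- cohortConfig(seed = 1001)
  co <- quietCohort(cfg, m, layers = "readDepth")
  bm <- bandCnaMatrix(lapply(karyotypes(co), asVirtualKt), m)
  gd <- cnaFrequencyVsGeneDensity(bm, m)
  expect_gt(gd$loss$rho, 0)
  expect_lt(gd$loss$p, 0.05)
  expect_lt(gd$gain$rho, 0)
  expect_lt(gd$gain$p, 0.05)
})

test_that("CNA frequency vs gene density has the right sentinel behavior", {
  m <- smallModel()
  kts <- lapply(1:3, function(i) {
    k <- asVirtualKt(makeTrueKt(m, data.frame(
      chrom = "chr11", start = 1,
      end = chromosomes(m)$length[match("chr11", chromosomes(m)$chrom)],
      cnA = 1, cnB = 0)))
    k@sampleId <- paste0("S", i)
    k
  })
  bm <- bandCnaMatrix(kts, m)
  r <- cnaFrequencyVsGeneDensity(bm, m)
  expect_false(is.na(r$loss$rho))
  expect_true(is.na(r$gain$rho))  # no gains anywhere -> zero variance sentinel
})
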