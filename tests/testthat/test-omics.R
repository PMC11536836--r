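test_that("CPM normalization round-trips and rejects empty libraries", {
  set.seed(81)
  counts <- matrix(rnbinom(200, mu = 100, size = 5), 20, 10,
                   dimnames = list(paste0("g", 1:20), paste0("S", 1:10)))
  cpm <- cpmNormalize(counts, log = FALSE)
  expect_equal(unname(colSums(cpm)), rep(1e6, 10))
  counts[, 1] <- 0
  expect_error(cpmNormalize(counts), "zero library")
})

test_that("band expression summarizes gene z-scores with NA for empty bands", {
  m <- toyModel()
  genes <- data.frame(chrom = c("chr1", "chr1"), start = c(100, 300),
                      end = c(200, 400), gene_id = c("gA", "gB"))
  m <- addGenes(m, genes)
  set.seed(82)
  counts <- matrix(rnbinom(8, mu = 200, size = 20), 2, 4,
                   dimnames = list(c("gA", "gB"), paste0("S", 1:4)))
  be <- bandExpressionMatrix(counts, m)
  # both genes sit in band 1; its value is the mean of their z-scores
  z <- karyoscope:::.geneZ(cpmNormalize(counts))
  expect_equal(be[1, ], colMeans(z))
  expect_true(all(is.na(be[2, ])))  # band with no genes
})

test_that("gene copy number is length-weighted within and averaged across sources", {
  m <- toyModel()
  g <- data.frame(chrom = "chr1", start = 1000, end = 3000, gene_id = "gX")
  m <- addGenes(m, g)
  mkSrc <- function(rows) asVirtualKt(makeTrueKt(m, rows))
  # CN 1 everywhere in all sources
  s1 <- mkSrc(data.frame(chrom = "chr1", start = 1, end = 10000, cnA = 1, cnB = 0))
  expect_equal(unname(geneCopyNumber(list(s1, s1), m)), 1)
  # gene spans equal halves at CN 2 and CN 3 in one source -> 2.5
  s2 <- mkSrc(data.frame(chrom = "chr1", start = 2002, end = 10000, cnA = 2, cnB = 1))
  expect_equal(unname(geneCopyNumber(list(s2), m)), 2.5, tolerance = 1e-3)
  # sources calling 2 and 3 over the whole gene -> 2.5
  s3 <- mkSrc(data.frame(chrom = "chr1", start = 1, end = 10000, cnA = 2, cnB = 1))
  s4 <- asVirtualKt(makeTrueKt(m))
  expect_equal(unname(geneCopyNumber(list(s3, s4), m)), 2.5)
})

test_that("CN-expression correlation flags dosage genes and excludes flat ones", {
  set.seed(83)
  n <- 30
  cn <- matrix(2, 40, n, dimnames = list(paste0("g", 1:40), paste0("S", 1:n)))
  cn[1:15, ] <- matrix(sample(1:4, 15 * n, TRUE), 15, n)   # variable CN
  base <- exp(rnorm(40, log(300), 0.4))
  mu <- base * (cn / 2)
  mu[16:25, ] <- base[16:25]                                # insensitive but CN varies
  cn[16:25, ] <- matrix(sample(1:4, 10 * n, TRUE), 10, n)
  counts <- matrix(rnbinom(40 * n, mu = mu, size = 20), 40, n,
                   dimnames = dimnames(cn))
  res <- cnExpressionCorrelation(counts, cn)
  expect_false(any(res$gene %in% paste0("g", 26:40)))       # constant CN excluded
  dos <- res[res$gene %in% paste0("g", 1:15), ]
  ins <- res[res$gene %in% paste0("g", 16:25), ]
  expect_gte(mean(dos$flagged & dos$sign == "positive"), 0.8)
  expect_lte(mean(ins$flagged), 0.2)
  tal <- attr(res, "tallies")
  expect_equal(unname(tal["positive"]), sum(res$flagged & res$rho > 0))
})

test_that("the rank-based differential test controls type I error and finds planted DEGs", {
  set.seed(84)
  # null: label permutations of one homogeneous cohort
  rates <- replicate(20, {
    counts <- matrix(rnbinom(50 * 12, mu = 200, size = 10), 50, 12,
                     dimnames = list(paste0("g", 1:50), paste0("S", 1:12)))
    res <- twoGroupDifferential(counts, rep(c("a", "b"), each = 6))
    mean(res$p < 0.05)
  })
  expect_lte(mean(rates), 0.07)

  # planted 4-fold knockdown in a 6-vs-9 comparison
  set.seed(85)
  counts <- matrix(rnbinom(60 * 15, mu = 400, size = 25), 60, 15,
                   dimnames = list(paste0("g", 1:60), paste0("S", 1:15)))
  groups <- rep(c("loss", "stable"), c(6, 9))
  counts[1:20, groups == "loss"] <-
    rnbinom(20 * 6, mu = 100, size = 25)
  res <- twoGroupDifferential(counts, factor(groups, levels = c("stable", "loss")))
  planted <- res[res$gene %in% paste0("g", 1:20), ]
  expect_gte(mean(planted$deg & planted$log2FC < 0), 0.8)
  expect_error(twoGroupDifferential(counts, rep(c("a", "b"), c(1, 14))),
               "at least 2")
})

test_that("DEG chromosome distribution localizes a planted chr11 signal", {
  m <- smallModel()
  gid <- genes(m)$gene_id
  on11 <- as.character(GenomicRanges::seqnames(genes(m))) == "chr11"
  set.seed(86)
  n <- 15
  counts <- matrix(rnbinom(length(gid) * n, mu = 300, size = 25), length(gid), n,
                   dimnames = list(gid, paste0("S", 1:n)))
  groups <- factor(rep(c("stable", "loss"), c(9, 6)), levels = c("stable", "loss"))
  counts[on11, groups == "loss"] <-
    rnbinom(sum(on11) * 6, mu = 70, size = 25)
  res <- twoGroupDifferential(counts, groups)
  dist <- chromosomeDistributionOfDegs(res, m)
  expect_lt(dist$qDown[dist$chrom == "chr11"], 0.05)
  expect_true(all(dist$qDown[dist$chrom != "chr11"] > 0.05))
  expect_true(all(dist$qUp > 0.05))

  # no DEGs at all -> counts 0 and p = 1
  none <- res; none$deg <- FALSE
  d0 <- chromosomeDistributionOfDegs(none, m)
  expect_true(all(d0$up == 0 & d0$down == 0))
  expect_true(all(d0$pUp == 1 & d0$pDown == 1))
})

test_that("methylation-instability correlation separates categories and handles sentinels", {
  m <- smallModel()
  cfg <- testConfig(seed = 87)
  set.seed(87)
  # cohort where CNA burden varies: deletions of increasing extent
  ch <- chromosomes(m)
  kts <- lapply(1:8, function(i) {
    nDel <- (i - 1) %/% 2
    ev <- if (nDel == 0) NULL else
      data.frame(chrom = ch$chrom[seq_len(nDel)], start = 1,
                 end = ch$length[seq_len(nDel)], cnA = 1, cnB = 0)
    kt <- makeTrueKt(m, ev, purity = 0.9, id = sprintf("S%02d", i))
    kt
  })
  beta <- emitMethylation(kts, m, cfg)
  mets <- cohortInstability(lapply(kts, asVirtualKt), m)
  cc <- methylationCategoryCorrelation(beta, m, mets)
  isl <- cc$rho[cc$category == "island"]
  openSea <- cc$rho[cc$category == "open_sea"]
  expect_gt(isl, 0.5)      # more deletions -> higher island methylation
  expect_lt(abs(openSea), abs(isl))

  one <- methylationCategoryCorrelation(beta[, 1, drop = FALSE], m, mets[1, ])
  expect_true(all(is.na(one$rho)))
})

test_that("band-level methylation-CN correlation is negative on deleted bands only", {
  m <- smallModel()
  cfg <- testConfig(seed = 88)
  set.seed(88)
  kts <- lapply(1:10, function(i) {
    ev <- if (i <= 4) data.frame(
      chrom = "chr11", start = 1,
      end = chromosomes(m)$length[match("chr11", chromosomes(m)$chrom)],
      cnA = 1, cnB = 0) else NULL
    makeTrueKt(m, ev, purity = 0.9, id = sprintf("S%02d", i))
  })
  beta <- emitMethylation(kts, m, cfg)
  vks <- lapply(kts, asVirtualKt)
  bm <- bandCnaMatrix(vks, m)
  res <- bandMethylationCnCorrelation(beta, bm, m, "island")
  on11 <- res$chrom == "chr11" & !is.na(res$r)
  expect_gte(mean(res$r[on11] < -0.5), 0.7)
  expect_true(all(is.na(res$r[res$chrom != "chr11"])))  # never altered -> NA
})
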