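test_that("archetype karyotypes match their defining structure", {
  m <- smallModel()
  set.seed(11)
  kt <- simulateKaryotype(m, "chr11_loss", purity = 0.8)
  s11 <- segments(kt)[as.character(GenomicRanges::seqnames(segments(kt))) == "chr11"]
  expect_true(all(s11$cnA + s11$cnB == 1L))

  fr <- replicate(5, trueFractionAltered(simulateKaryotype(m, "wgd_high_aneuploidy")))
  expect_true(all(fr > 0.5))

  # stable: never more than 3 events; a zero-event draw exists and is all 1+1
  allDiploid <- FALSE
  for (seed in 1:60) {
    set.seed(seed)
    kt <- simulateKaryotype(m, "stable")
    cna <- segments(kt)[segments(kt)$cnA + segments(kt)$cnB != 2L]
    expect_lte(length(cna), 3)
    if (length(cna) == 0) allDiploid <- TRUE
  }
  expect_true(allDiploid)

  set.seed(3)
  kt <- simulateKaryotype(m, "multidel")
  cna <- segments(kt)[segments(kt)$cnA + segments(kt)$cnB < 2L]
  expect_true(all(as.character(GenomicRanges::seqnames(cna)) %in%
                    c("chr1", "chr16", "chr22")))
  expect_error(simulateKaryotype(m, "nonsense"))
})

test_that("read-depth emission follows the purity-weighted closed form", {
  m <- smallModel()
  cfg <- testConfig(seed = 5)
  # pure diploid: mean 2 * depthPerCopy
  set.seed(5)
  kt <- makeTrueKt(m, purity = 1)
  rd <- emitReadDepth(kt, m, cfg)
  se <- sd(rd$count) / sqrt(nrow(rd))
  expect_lt(abs(mean(rd$count) - 2 * cfg$depthPerCopy), 3 * se)

  # CN 4 segment doubles the diploid mean
  ch <- chromosomes(m)
  ev <- data.frame(chrom = "chr1", start = 1, end = ch$length[1], cnA = 2, cnB = 2)
  kt4 <- makeTrueKt(m, ev, purity = 1)
  rd4 <- emitReadDepth(kt4, m, cfg)
  on1 <- rd4$chrom == "chr1"
  expect_lt(abs(mean(rd4$count[on1]) / mean(rd4$count[!on1]) - 2), 0.1)

  # homozygous deletion at purity 0.5: mean = half the diploid mean
  ev0 <- data.frame(chrom = "chr1", start = 1, end = ch$length[1], cnA = 0, cnB = 0)
  kt0 <- makeTrueKt(m, ev0, purity = 0.5)
  rd0 <- emitReadDepth(kt0, m, cfg)
  on1 <- rd0$chrom == "chr1"
  expect_lt(abs(mean(rd0$count[on1]) / mean(rd0$count[!on1]) - 0.5), 0.05)
  expect_error(emitReadDepth(kt, m, modifyList(cfg, list(depthPerCopy = -1))),
               "positive")
})

test_that("SNP emission follows the LRR/BAF closed forms", {
  m <- smallModel()
  cfg <- testConfig(seed = 6)
  ch <- chromosomes(m)
  set.seed(6)
  kt <- makeTrueKt(m, purity = 1)
  snp <- emitSnpSignals(kt, m, cfg)
  expect_lt(abs(mean(snp$lrr)), 3 * sd(snp$lrr) / sqrt(nrow(snp)))
  expect_lt(abs(mean(snp$baf[snp$het]) - 0.5), 0.01)

  # trisomy: het BAF clusters at 1/3 and 2/3, i.e. mirrored deviation 1/6
  ev <- data.frame(chrom = "chr1", start = 1, end = ch$length[1], cnA = 2, cnB = 1)
  kt3 <- makeTrueKt(m, ev, purity = 1)
  snp3 <- emitSnpSignals(kt3, m, cfg)
  on1 <- snp3$chrom == "chr1" & snp3$het
  dev <- abs(snp3$baf[on1] - 0.5)
  expect_lt(abs(mean(dev) - 1 / 6), 0.01)
  expect_gt(mean(snp3$baf[on1] > 0.5), 0.4)  # both mirror images populated

  # balanced tetrasomy: LRR ~ 1, het BAF ~ 0.5 (the WGD ambiguity)
  ev4 <- data.frame(chrom = "chr1", start = 1, end = ch$length[1], cnA = 2, cnB = 2)
  kt4 <- makeTrueKt(m, ev4, purity = 1)
  snp4 <- emitSnpSignals(kt4, m, cfg)
  on1 <- snp4$chrom == "chr1"
  expect_lt(abs(mean(snp4$lrr[on1]) - 1), 0.02)
  expect_lt(abs(mean(snp4$baf[on1 & snp4$het]) - 0.5), 0.01)
  expect_true(all(snp4$baf >= 0 & snp4$baf <= 1))
})

test_that("expression emission is dosage-coupled with the stated slope", {
  m <- smallModel()
  ch <- chromosomes(m)
  ev <- data.frame(chrom = "chr1", start = 1, end = ch$length[1], cnA = 2, cnB = 2)
  set.seed(8)
  ktA <- makeTrueKt(m, purity = 1, id = "A")          # diploid
  ktB <- makeTrueKt(m, ev, purity = 1, id = "B")      # chr1 at CN 4
  cfg0 <- testConfig(seed = 8, exprSlope = 0, dosageInsensitiveFrac = 0)
  e0 <- emitExpression(list(A = ktA, B = ktB), m, cfg0)
  on1 <- as.character(GenomicRanges::seqnames(genes(m))) == "chr1"
  r0 <- mean(e0$counts[on1, "B"]) / mean(e0$counts[on1, "A"])
  expect_lt(abs(r0 - 1), 0.15)  # slope 0: CN and expression independent

  set.seed(8)
  cfg1 <- testConfig(seed = 8, exprSlope = 1, dosageInsensitiveFrac = 0)
  e1 <- emitExpression(list(A = ktA, B = ktB), m, cfg1)
  r1 <- mean(e1$counts[on1, "B"]) / mean(e1$counts[on1, "A"])
  expect_lt(abs(r1 - 2), 0.3)   # slope 1: CN 4 doubles the mean
})

test_that("methylation emission couples deletions to island/5' hypermethylation", {
  m <- smallModel()
  cfg <- testConfig(seed = 9)
  set.seed(9)
  kt11 <- simulateKaryotype(m, "chr11_loss", purity = 0.8)
  kt11@sampleId <- "L"
  beta <- emitMethylation(list(L = kt11), m, cfg)
  expect_true(all(beta >= 0 & beta <= 1))
  p <- probes(m)
  isl <- p$island_category == "island"
  on11 <- as.character(GenomicRanges::seqnames(p)) == "chr11"
  delta <- median(beta[isl & on11, 1]) - median(beta[isl & !on11, 1])
  expect_lt(abs(delta - cfg$methDeltaBeta * 0.8), 0.05)

  # zero effect size: no association
  cfg0 <- testConfig(seed = 9, methDeltaBeta = 0)
  set.seed(10)
  beta0 <- emitMethylation(list(L = kt11), m, cfg0)
  d0 <- median(beta0[isl & on11, 1]) - median(beta0[isl & !on11, 1])
  expect_lt(abs(d0), 0.03)
})

test_that("cohorts are reproducible, sized as configured, and empty-safe", {
  m <- smallModel()
  cfg <- cohortConfig(nWgd = 2, nChr11Loss = 1, nMultidel = 1, nStable = 2,
                      seed = 77)
  c1 <- quietCohort(cfg, m, layers = c("readDepth", "snp"))
  c2 <- quietCohort(cfg, m, layers = c("readDepth", "snp"))
  expect_identical(c1@readDepth, c2@readDepth)
  expect_identical(c1@snp, c2@snp)
  expect_identical(c1@archetypes, c2@archetypes)
  expect_equal(unname(table(c1@archetypes)[c("wgd_high_aneuploidy", "chr11_loss",
                                             "multidel", "stable")]),
               c(2, 1, 1, 2), ignore_attr = TRUE)

  e <- quietCohort(cohortConfig(nWgd = 0, nChr11Loss = 0, nMultidel = 0,
                                nStable = 0, seed = 1), m)
  expect_equal(length(karyotypes(e)), 0)
  expect_error(cohortConfig(nWgd = 2, nChr11Loss = 0, nMultidel = 0,
                            nStable = 0), "seed")
})

test_that("written cohorts round-trip through the manifest", {
  m <- smallModel()
  cfg <- cohortConfig(nWgd = 0, nChr11Loss = 1, nMultidel = 0, nStable = 1,
                      seed = 3)
  co <- quietCohort(cfg, m)
  d <- tempfile("cohort_")
  writeCohort(co, d)
  expect_true(file.exists(file.path(d, "ground_truth.seg")))
  man <- jsonlite::read_json(file.path(d, "manifest.json"))
  expect_equal(man$config$seed, 3)
  expect_equal(length(man$archetypes), 2)
})
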