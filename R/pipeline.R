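## End-to-end orchestration: one config drives simulate -> karyotype ->
## bands -> metrics -> cluster -> recur -> signatures -> omics, with a run
## manifest recording seed, thresholds and per-stage output checksums.

#' Pipeline configuration
#'
#' Bundles the synthetic-cohort configuration with every analysis threshold
#' (band rule, arm rule, segmentation alpha, permutation count, recurrence
#' q cutoff, correlation and fold-change cutoffs), the master seed and the
#' output directory. All thresholds default to the values the analysis is
#' designed around (60\% band rule, 80\% arm rule, q < 0.25, |rho| > 0.5,
#' |FC| > 2).
#'
#' @param cohort a [cohortConfig()] (synthetic mode; the pipeline input).
#' @param outdir output directory.
#' @param seed master seed; per-stage seeds are derived from it.
#' @param bandThreshold band-coverage rule.
#' @param armThreshold aneuploidy-score arm-coverage rule.
#' @param alpha segmentation split-acceptance level.
#' @param nPerm permutation count (segmentation and recurrence); must be > 0.
#' @param qCutoff recurrence q-value threshold.
#' @param rhoCutoff dosage-correlation flag threshold.
#' @param fcCutoff differential-expression fold-change cutoff.
#' @param clusterK number of clusters to cut.
#' @param distance clustering distance ("binary" or "cosine").
#' @return a validated list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(cohort, outdir = tempfile("karyoscope_run_"),
                           seed = 1, bandThreshold = 0.6, armThreshold = 0.8,
                           alpha = 0.01, nPerm = 1000, qCutoff = 0.25,
                           rhoCutoff = 0.5, fcCutoff = 2, clusterK = 3,
                           distance = "binary") {
  stopifnot(inherits(cohort, "CohortConfig"))
  if (nPerm <= 0) stop("nPerm must be positive")
  if (bandThreshold <= 0 || bandThreshold > 1) stop("bandThreshold must be in (0, 1]")
  if (armThreshold <= 0 || armThreshold > 1) stop("armThreshold must be in (0, 1]")
  if (!distance %in% c("binary", "cosine")) stop("unknown distance")
  cfg <- list(cohort = cohort, outdir = outdir, seed = as.integer(seed),
              bandThreshold = bandThreshold, armThreshold = armThreshold,
              alpha = alpha, nPerm = nPerm, qCutoff = qCutoff,
              rhoCutoff = rhoCutoff, fcCutoff = fcCutoff,
              clusterK = clusterK, distance = distance)
  class(cfg) <- "PipelineConfig"
  cfg
}

.logStage <- function(stage, msg = "start") {
  message(format(Sys.time(), "%H:%M:%S"), " [", stage, "] ", msg)
}

#' Run the full analysis pipeline
#'
#' Executes all eight stages on a synthetic cohort and writes standard-
#' format outputs (SEG karyotypes, band-matrix TSVs, metrics/recurrence/
#' signature/omics tables, Newick dendrogram) plus `manifest.json` with the
#' configuration echo, seed and md5 checksum of every output file. Re-running
#' with the same config yields identical checksums. Any stage failure aborts
#' with the stage name in the error.
#'
#' @param config a [pipelineConfig()].
#' @param model a [GenomeModel-class] (default [syntheticGenomeModel()]).
#' @return invisibly, a list with the manifest and in-memory stage results.
#' @export
runPipeline <- function(config, model = syntheticGenomeModel()) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- character(); results <- list()
  stage <- function(name, fun) {
    .logStage(name)
    out <- tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    stages <<- c(stages, name)
    out
  }

  cohort <- stage("simulate", function()
    simulateCohort(config$cohort, model = model))
  results$cohort <- cohort
  writeCohort(cohort, file.path(config$outdir, "cohort"))

  kts <- stage("karyotype", function() {
    ids <- names(cohort@karyotypes)
    out <- lapply(seq_along(ids), function(i)
      buildKaryotype(cohort@readDepth[[i]], cohort@snp[[i]], sampleId = ids[i],
                     alpha = config$alpha, nPerm = config$nPerm,
                     seed = config$seed + 101L * i))
    names(out) <- ids
    out
  })
  results$karyotypes <- kts
  segDir <- file.path(config$outdir, "karyotypes")
  dir.create(segDir, showWarnings = FALSE)
  for (id in names(kts)) writeSeg(kts[[id]]$consensus, file.path(segDir, paste0(id, ".seg")))

  bm <- stage("bands", function()
    bandCnaMatrix(lapply(kts, `[[`, "consensus"), model,
                  threshold = config$bandThreshold))
  results$bandMatrix <- bm
  writeBandMatrix(bm, file.path(config$outdir, "band_matrix"))

  metrics <- stage("metrics", function() {
    m <- cohortInstability(lapply(kts, `[[`, "consensus"), model,
                           armCoverage = config$armThreshold)
    m
  })
  results$metrics <- metrics
  utils::write.table(metrics, file.path(config$outdir, "instability_metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  tree <- stage("cluster", function() clusterSamples(bm, config$distance))
  results$tree <- tree
  results$clusters <- cutClusters(tree, config$clusterK)
  writeNewick(tree, file.path(config$outdir, "dendrogram.nwk"))
  utils::write.table(data.frame(sample = names(results$clusters),
                                cluster = results$clusters),
                     file.path(config$outdir, "clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  recur <- stage("recur", function()
    gisticLikeScores(bm, nPerm = config$nPerm, seed = config$seed + 7L))
  results$recurrence <- recur
  utils::write.table(recur, file.path(config$outdir, "recurrence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  sigs <- stage("signatures", function() {
    refs <- referenceSignatures()
    lapply(split(names(results$clusters), results$clusters), function(ids) {
      prof <- cohortProfile(lapply(kts[ids], `[[`, "snp"),
                            lengthScale = config$cohort$genomeScale)
      hit <- bestMatch(prof, refs)
      list(samples = ids, profile = prof@values, best = hit$name,
           similarity = hit$similarity)
    })
  })
  results$signatures <- sigs
  jsonlite::write_json(sigs, file.path(config$outdir, "signatures.json"),
                       auto_unbox = TRUE, digits = 6, pretty = TRUE)

  omics <- stage("omics", function() {
    cnMat <- geneCopyNumberMatrix(
      lapply(kts, function(k) list(k$consensus, k$wgs, k$snp)), model)
    corr <- cnExpressionCorrelation(cohort@expression, cnMat,
                                    cutoff = config$rhoCutoff)
    bandExpr <- bandExpressionMatrix(cohort@expression, model)
    methCat <- methylationCategoryCorrelation(cohort@methylation, model, metrics)
    bandMeth <- bandMethylationCnCorrelation(cohort@methylation, bm, model,
                                             probeFilter = "island")
    list(cnExpression = corr, bandExpression = bandExpr,
         methCategory = methCat, bandMethylation = bandMeth)
  })
  results$omics <- omics
  utils::write.table(omics$cnExpression,
                     file.path(config$outdir, "cn_expression_correlation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(omics$methCategory,
                     file.path(config$outdir, "methylation_category_correlation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(omics$bandMethylation,
                     file.path(config$outdir, "band_methylation_correlation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  files <- list.files(config$outdir, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  sums <- tools::md5sum(files)
  manifest <- list(
    package = "karyoscope",
    version = as.character(utils::packageVersion("karyoscope")),
    seed = config$seed,
    stages = stages,
    config = c(unclass(config)[setdiff(names(config), c("cohort"))],
               list(cohort = unclass(config$cohort))),
    checksums = as.list(stats::setNames(unname(sums),
                                        substring(files, nchar(config$outdir) + 2)))
  )
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  .logStage("done", paste(length(stages), "stages complete"))
  invisible(list(manifest = manifest, results = results))
}
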